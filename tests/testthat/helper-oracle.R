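# Independent oracles used against the main implementation.

# Event-driven (continuous-time) simulation of the shared-pool rules for a
# single nucleus with constant background demand.  Deliberately written as
# a plain next-event queue, independent of the fixed-timestep core.
oracleNucleus <- function(kOn, kOff, kLoad, transit, capacity,
                          bgRate = 0, bgDwell = 1, replenish = 0,
                          duration = 20) {
    nA <- length(kOn)
    t <- 0
    promOn <- rep(FALSE, nA)
    free <- capacity
    returns <- numeric(0)           # scheduled return times
    succ <- integer(nA)
    att <- integer(nA)
    repeat {
        switchRate <- ifelse(promOn, kOff, kOn)
        attemptRate <- ifelse(promOn, kLoad, 0)
        rates <- c(switchRate, attemptRate, bgRate, replenish)
        total <- sum(rates)
        tNext <- if (total > 0) t + rexp(1, total) else Inf
        tRet <- if (length(returns)) min(returns) else Inf
        if (min(tNext, tRet) > duration) break
        if (tRet <= tNext) {
            t <- tRet
            returns <- returns[-which.min(returns)]
            if (free < capacity) free <- free + 1
            next
        }
        t <- tNext
        ev <- sample.int(length(rates), 1L, prob = rates)
        if (ev <= nA) {                       # promoter toggle
            promOn[ev] <- !promOn[ev]
        } else if (ev <= 2 * nA) {            # initiation attempt
            a <- ev - nA
            att[a] <- att[a] + 1L
            if (free >= 1) {
                free <- free - 1
                succ[a] <- succ[a] + 1L
                returns <- c(returns, t + transit[a])
            }
        } else if (ev == 2 * nA + 1) {        # background draw
            if (free >= 1) {
                free <- free - 1
                returns <- c(returns, t + bgDwell)
            }
        } else {                              # replenishment
            if (free < capacity) free <- free + 1
        }
    }
    list(successes = succ, attempts = att)
}

# mean per-allele success count over replicate oracle runs
oracleMeanSuccess <- function(reps, ...) {
    rowMeans(vapply(seq_len(reps),
                    function(i) oracleNucleus(...)$successes,
                    numeric(length(list(...)$kOn))))
}

# fixed-step per-allele success count through the package simulator, with
# a constant background rate matching the oracle's
fixedStepSuccess <- function(reps, kOn, kOff, kLoad, transit, capacity,
                             bgRate = 0, bgDwell = 1, replenish = 0,
                             duration = 20, frameInterval = 20) {
    hub <- HubParams(capacity = capacity, replenishRate = replenish,
                     bgDemandNC13 = bgRate, bgDemandNC14Start = bgRate,
                     bgDemandNC14End = bgRate, bgDwell = bgDwell)
    nA <- length(kOn)
    alleles <- lapply(seq_len(nA), function(i)
        AlleleSpec(channel = c("MS2", "PP7")[i],
                   geneLength = transit[i] * 1.8, loopStart = 0,
                   loopLength = transit[i] * 1.8,
                   telegraph = TelegraphParams(kOnMax = kOn[i],
                                               kOff = kOff[i],
                                               kLoad = kLoad[i],
                                               vEl = 1.8,
                                               steepness = 30),
                   parentOfOrigin = c("paternal", "maternal")[i]))
    rowMeans(vapply(seq_len(reps), function(i)
        simulateNucleus(alleles, hub, x = 0, nc = "NC13",
                        duration = duration,
                        frameInterval = frameInterval,
                        keepTruth = FALSE)$successes,
        numeric(nA)))
}

# Riemann-sum integration oracle: linear interpolation on a 10x oversampled
# grid, midpoint rule
riemannAUC <- function(time, signal, oversample = 10L) {
    n <- (length(time) - 1L) * oversample
    grid <- seq(time[1], time[length(time)], length.out = n + 1L)
    mid <- (grid[-1] + grid[-length(grid)]) / 2
    y <- approx(time, pmax(signal, 0), xout = mid)$y
    sum(y * diff(grid))
}
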