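#' Dorsoventral modulation of the promoter ON rate
#'
#' The Dorsal activator gradient is modelled as a logistic profile of the
#' telegraph ON-switching rate along the dorsoventral axis:
#' \code{kOnMax / (1 + exp(steepness * (x - xBoundary)))}.  Ventral nuclei
#' (x near 0) switch on at close to the maximal rate; nuclei beyond the
#' boundary are essentially silent.
#'
#' @param x dorsoventral coordinate(s) in [0, 1]; 0 = ventral midline.
#' @param telegraph a \linkS4class{TelegraphParams}.
#' @return ON-switching rate(s), 1/min; monotone nonincreasing in \code{x}.
#' @examples
#' dorsalKon(c(0, 0.5, 1), TelegraphParams(xBoundary = 0.5))
#' @export
dorsalKon <- function(x, telegraph) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
        stop("dorsoventral coordinate 'x' must lie in [0, 1]")
    telegraph@kOnMax /
        (1 + exp(telegraph@steepness * (x - telegraph@xBoundary)))
}

#' Fluorescence of a set of elongating Pol II
#'
#' Each Pol II contributes no signal before its 3' end reaches the
#' stem-loop cassette, a linearly growing contribution while transcribing
#' through it (loops accumulate on the nascent RNA), and one full
#' \code{unitIntensity} from cassette completion until termination.
#'
#' @param positions Pol II positions along the gene (kb from the TSS).
#' @param spec an \linkS4class{AlleleSpec} giving the gene geometry.
#' @param unitIntensity fluorescence of one completed cassette (a.u.).
#' @return Total fluorescence (a.u.).
#' @examples
#' a <- AlleleSpec(geneLength = 6.5, loopStart = 0.1, loopLength = 1.3)
#' pol2Signal(c(0.75, 3), a)  # half a cassette + one full cassette
#' @export
pol2Signal <- function(positions, spec, unitIntensity = 1) {
    if (length(positions) == 0L) return(0)
    if (any(positions < 0 | positions > spec@geneLength))
        stop("Pol II positions must lie within [0, geneLength]")
    frac <- pmin(pmax(positions - spec@loopStart, 0) / spec@loopLength, 1)
    sum(frac * unitIntensity)
}

.bgRateVector <- function(hub, nc, nSteps, dt) {
    if (nc == "NC13") {
        rep(hub@bgDemandNC13, nSteps)
    } else {
        tm <- (seq_len(nSteps) - 0.5) * dt   # step midpoints
        hub@bgDemandNC14Start +
            (hub@bgDemandNC14End - hub@bgDemandNC14Start) * tm / (nSteps * dt)
    }
}

#' Simulate one nucleus for one nuclear cycle
#'
#' Runs the fixed-timestep shared-pool telegraph simulation for the alleles
#' of a single nucleus at dorsoventral position \code{x}.  The step equals
#' the imaging frame interval; per-step event probabilities are
#' \code{1 - exp(-rate * dt)} and initiation attempts are Poisson draws
#' thinned by pool availability.  Signals are noise-free; measurement noise
#' is added at the embryo level.
#'
#' @param alleles list of \linkS4class{AlleleSpec} (length 1 or 2).
#' @param hub a \linkS4class{HubParams}.
#' @param x dorsoventral coordinate in [0, 1].
#' @param nc \code{"NC13"} or \code{"NC14"} (selects the background-demand
#'   schedule).
#' @param duration cycle duration (minutes).
#' @param frameInterval imaging interval (seconds).
#' @param unitIntensity fluorescence of one completed cassette (a.u.).
#' @param keepTruth keep pool-level ground truth (free pool, held units,
#'   cumulative replenishment/discards) per frame.
#' @return A list with \code{time} (minutes, frame 0 at cycle onset),
#'   \code{signal}, \code{polCount}, \code{promoterState} (frames x
#'   alleles), \code{firstSuccess} (true onset per allele, min, NA if
#'   never), per-allele \code{successes} and \code{attempts}, background
#'   counters, and — when \code{keepTruth} — \code{freePool}, \code{held},
#'   \code{cumReplenish}, \code{cumDiscard}.
#' @examples
#' set.seed(1)
#' r <- simulateNucleus(list(AlleleSpec()), HubParams(), x = 0.1,
#'                      nc = "NC14", duration = 10, frameInterval = 20)
#' @export
simulateNucleus <- function(alleles, hub, x, nc = c("NC14", "NC13"),
                            duration, frameInterval, unitIntensity = 1,
                            keepTruth = TRUE) {
    nc <- match.arg(nc)
    stopifnot(length(alleles) >= 1L, length(alleles) <= 2L,
              duration > 0, frameInterval > 0)
    dt <- frameInterval / 60
    nSteps <- max(1L, as.integer(round(duration / dt)))
    nA <- length(alleles)
    kOn <- kOff <- kLoad <- gl <- ls <- ll <- vel <- sq <- numeric(nA)
    isRep <- holdSteps <- integer(nA)
    for (i in seq_len(nA)) {
        a <- alleles[[i]]
        isRep[i] <- as.integer(a@construct == "full")
        tg <- a@telegraph
        kOn[i] <- dorsalKon(x, tg); kOff[i] <- tg@kOff; kLoad[i] <- tg@kLoad
        gl[i] <- a@geneLength; ls[i] <- a@loopStart; ll[i] <- a@loopLength
        vel[i] <- tg@vEl
        sq[i] <- a@sequesterRate
        holdSteps[i] <- if (isRep[i]) max(1L, as.integer(round(gl[i] / vel[i] / dt)))
                        else max(1L, as.integer(round(a@sequesterDwell / dt)))
    }
    bg <- .bgRateVector(hub, nc, nSteps, dt)
    res <- .sim_nucleus_cpp(nSteps, dt, kOn, kOff, kLoad, isRep,
                            gl, ls, ll, vel, sq, holdSteps, unitIntensity,
                            hub@capacity, hub@replenishRate, bg,
                            max(1L, as.integer(round(hub@bgDwell / dt))),
                            keepTruth)
    res$time <- seq(0, by = dt, length.out = nSteps + 1L)
    res$nc <- nc
    res
}

.newTraceSet <- function(signal, nc, time, info, config = NULL,
                         polCount = NULL, promoterState = NULL) {
    assays <- S4Vectors::SimpleList(signal = signal)
    if (!is.null(polCount)) assays$polCount <- polCount
    if (!is.null(promoterState)) assays$promoterState <- promoterState
    se <- SummarizedExperiment(
        assays = assays,
        rowData = S4Vectors::DataFrame(nc = nc, time = time),
        colData = info)
    md <- metadata(se)
    md$config <- config
    metadata(se) <- md
    new("TraceSet", se)
}

#' Simulate one embryo
#'
#' Lays nuclei on a fixed \code{rows x cols} lattice whose columns span the
#' dorsoventral axis on [0, 1] (embryos are simulated pre-aligned), then
#' simulates NC13 followed by NC14 for every nucleus with an independent
#' hub pool per nucleus per cycle, and finally adds i.i.d. zero-mean
#' Gaussian measurement noise to the signals.  Deterministic given
#' \code{(config@seed, embryoIndex)}.
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @param embryoIndex replicate index (1-based); the embryo RNG stream is
#'   seeded with \code{config@seed + embryoIndex}.
#' @param keepTruth keep per-frame Pol II counts and promoter states as
#'   extra assays (and true onsets in colData).
#' @return A \linkS4class{TraceSet} with one column per reporter allele per
#'   nucleus, rows covering NC13 then NC14.
#' @examples
#' cfg <- scenarioPreset("control_chr3_hemi")
#' cfg@nucleiGrid <- c(2L, 6L); cfg@nc14Duration <- 5
#' ts <- simulateEmbryo(cfg, 1)
#' @export
simulateEmbryo <- function(config, embryoIndex = 1L, keepTruth = TRUE) {
    stopifnot(is(config, "ScenarioConfig"))
    set.seed(config@seed + as.integer(embryoIndex))
    rows <- config@nucleiGrid[1]; cols <- config@nucleiGrid[2]
    dv <- (rep(seq_len(cols), each = rows) - 0.5) / cols
    nNuc <- rows * cols
    reporters <- which(vapply(config@alleles, function(a)
        a@channel != "none", logical(1)))
    nRep <- length(reporters)
    dt <- config@frameInterval / 60
    n13 <- as.integer(round(config@nc13Duration / dt))
    n14 <- as.integer(round(config@nc14Duration / dt))
    nF <- (n13 + 1L) + (n14 + 1L)
    nCol <- nNuc * nRep

    signal <- matrix(0, nF, nCol)
    if (keepTruth) {
        polCount <- matrix(0L, nF, nCol)
        promoterState <- matrix(0L, nF, nCol)
        onset13 <- onset14 <- rep(NA_real_, nCol)
    }
    i13 <- seq_len(n13 + 1L)
    i14 <- (n13 + 1L) + seq_len(n14 + 1L)

    for (n in seq_len(nNuc)) {
        colIdx <- (n - 1L) * nRep + seq_len(nRep)
        for (nc in c("NC13", "NC14")) {
            r <- simulateNucleus(config@alleles, config@hub, dv[n], nc = nc,
                duration = if (nc == "NC13") config@nc13Duration
                           else config@nc14Duration,
                frameInterval = config@frameInterval,
                unitIntensity = config@unitIntensity, keepTruth = FALSE)
            rws <- if (nc == "NC13") i13 else i14
            signal[rws, colIdx] <- r$signal[, reporters, drop = FALSE]
            if (keepTruth) {
                polCount[rws, colIdx] <- r$polCount[, reporters, drop = FALSE]
                promoterState[rws, colIdx] <-
                    r$promoterState[, reporters, drop = FALSE]
                if (nc == "NC13") onset13[colIdx] <- r$firstSuccess[reporters]
                else onset14[colIdx] <- r$firstSuccess[reporters]
            }
        }
    }
    if (config@noiseSd > 0)
        signal <- signal + matrix(rnorm(nF * nCol, 0, config@noiseSd),
                                  nF, nCol)

    chans <- vapply(config@alleles[reporters], function(a) a@channel,
                    character(1))
    poo <- vapply(config@alleles[reporters], function(a) a@parentOfOrigin,
                  character(1))
    info <- S4Vectors::DataFrame(
        embryo_id = sprintf("e%02d", as.integer(embryoIndex)),
        nucleus_id = rep(sprintf("n%04d", seq_len(nNuc)), each = nRep),
        dv_position = rep(dv, each = nRep),
        channel = rep(chans, nNuc),
        parent_of_origin = rep(poo, nNuc))
    if (keepTruth) {
        info$true_onset_nc13 <- onset13
        info$true_onset_nc14 <- onset14
    }
    rownames(info) <- paste(info$embryo_id, info$nucleus_id, info$channel,
                            sep = ".")
    ncLab <- rep(c("NC13", "NC14"), c(n13 + 1L, n14 + 1L))
    tim <- c(seq(0, by = dt, length.out = n13 + 1L),
             seq(0, by = dt, length.out = n14 + 1L))
    .newTraceSet(signal, ncLab, tim, info, config = config,
                 polCount = if (keepTruth) polCount,
                 promoterState = if (keepTruth) promoterState)
}

#' Simulate a full scenario
#'
#' Simulates all replicate embryos of a scenario and concatenates their
#' traces.  Per-embryo RNG streams are derived from the scenario's root
#' seed by a fixed offset, so the result is reproducible as a whole and
#' per embryo.
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @param nEmbryos optional override of \code{config@nEmbryos}.
#' @param seed optional override of \code{config@seed}.
#' @param keepTruth keep ground-truth assays.
#' @return A \linkS4class{TraceSet}.
#' @examples
#' cfg <- scenarioPreset("control_chr3_hemi", nEmbryos = 1)
#' cfg@nucleiGrid <- c(2L, 6L); cfg@nc14Duration <- 5
#' ts <- simulateScenario(cfg)
#' @export
simulateScenario <- function(config, nEmbryos = NULL, seed = NULL,
                             keepTruth = TRUE) {
    if (!is.null(seed)) config@seed <- as.integer(seed)
    if (!is.null(nEmbryos)) config@nEmbryos <- as.integer(nEmbryos)
    parts <- lapply(seq_len(config@nEmbryos), function(e)
        simulateEmbryo(config, e, keepTruth = keepTruth))
    ts <- do.call(cbind, parts)
    md <- metadata(ts)
    md$config <- config
    metadata(ts) <- md
    ts <- new("TraceSet", ts)
    validObject(ts)
    ts
}
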