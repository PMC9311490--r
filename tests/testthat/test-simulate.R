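test_that("per-Pol II fluorescence follows the cassette ramp", {
    a <- AlleleSpec(geneLength = 6.5, loopStart = 0.1, loopLength = 1.3)
    expect_equal(pol2Signal(numeric(0), a), 0)
    expect_equal(pol2Signal(0.1 + 0.65, a, unitIntensity = 2), 1)  # mid-ramp
    expect_equal(pol2Signal(c(3, 4, 5), a), 3)                     # plateau
    expect_equal(pol2Signal(0.05, a), 0)                           # pre-loop
    expect_error(pol2Signal(7, a), "positions")
})

test_that("telegraph promoter reaches its stationary ON fraction", {
    # capacity effectively infinite: no pool interference
    set.seed(42)
    hub <- HubParams(capacity = 1e6, replenishRate = 0, bgDemandNC13 = 0,
                     bgDemandNC14Start = 0, bgDemandNC14End = 0)
    tg <- TelegraphParams(kOnMax = 0.6, kOff = 0.3, kLoad = 5,
                          steepness = 30)
    al <- list(AlleleSpec(telegraph = tg))
    occ <- vapply(1:40, function(i) {
        r <- simulateNucleus(al, hub, x = 0, nc = "NC14", duration = 120,
                             frameInterval = 20, keepTruth = FALSE)
        mean(r$promoterState[-seq_len(30), 1])  # discard burn-in
    }, numeric(1))
    expect_equal(mean(occ), 0.6 / 0.9, tolerance = 0.04)
})

test_that("a silent promoter loads no polymerase", {
    set.seed(1)
    tg <- TelegraphParams(kOnMax = 0)
    r <- simulateNucleus(list(AlleleSpec(telegraph = tg)), HubParams(),
                         x = 0, nc = "NC14", duration = 10,
                         frameInterval = 20)
    expect_equal(sum(r$signal), 0)
    expect_equal(r$successes, 0L)
    expect_true(is.na(r$firstSuccess))
})

test_that("embryo simulation is deterministic and honours the genotype", {
    cfg <- tinyConfig("control_chr3_hemi")
    a <- simulateEmbryo(cfg, 1)
    b <- simulateEmbryo(cfg, 1)
    expect_identical(traceSignal(a), traceSignal(b))
    expect_identical(as.data.frame(traceInfo(a)), as.data.frame(traceInfo(b)))
    expect_setequal(unique(traceInfo(a)$channel), "MS2")
    hom <- simulateEmbryo(tinyConfig("control_chr3_hom"), 1)
    expect_setequal(unique(traceInfo(hom)$channel), c("MS2", "PP7"))
    # different embryo index gives a different realisation
    c2 <- simulateEmbryo(cfg, 2)
    expect_false(identical(traceSignal(a), traceSignal(c2)))
})

test_that("nuclei beyond the expression boundary stay silent", {
    cfg <- tinyConfig("control_chr3_hemi", rows = 4L, cols = 8L, nc14 = 20)
    ts <- simulateEmbryo(cfg, 1)
    cd <- traceInfo(ts)
    dorsal <- which(cd$dv_position > 0.8)
    expect_gt(length(dorsal), 0)
    expect_true(all(is.na(cd$true_onset_nc14[dorsal])))
})

test_that("hub resources are conserved at every step", {
    set.seed(7)
    hub <- HubParams(capacity = 50, replenishRate = 2, bgDemandNC13 = 5,
                     bgDemandNC14Start = 5, bgDemandNC14End = 20,
                     bgDwell = 2)
    cfg <- scenarioPreset("control_chr3_hom")
    r <- simulateNucleus(cfg@alleles, hub, x = 0.05, nc = "NC14",
                         duration = 30, frameInterval = 20,
                         keepTruth = TRUE)
    expect_true(all(r$freePool >= 0))
    expect_true(all(r$freePool <= hub@capacity))
    expect_equal(r$freePool + r$held,
                 hub@capacity + r$cumReplenish - r$cumDiscard)
})

test_that("competition vanishes when the pool is effectively infinite", {
    set.seed(11)
    hub <- HubParams(capacity = 1e6, replenishRate = 1e4,
                     bgDemandNC13 = 0.6, bgDemandNC14Start = 8,
                     bgDemandNC14End = 12.75)
    hom <- scenarioPreset("control_chr3_hom")@alleles
    hemi <- scenarioPreset("control_chr3_hemi")@alleles
    n <- 1200L
    sHom <- vapply(seq_len(n), function(i)
        simulateNucleus(hom, hub, x = 0, nc = "NC14", duration = 15,
                        frameInterval = 20, keepTruth = FALSE)$successes[1],
        numeric(1))
    sHemi <- vapply(seq_len(n), function(i)
        simulateNucleus(hemi, hub, x = 0, nc = "NC14", duration = 15,
                        frameInterval = 20, keepTruth = FALSE)$successes[1],
        numeric(1))
    expect_lt(abs(1 - mean(sHom) / mean(sHemi)), 0.02)
})

test_that("fixed-step simulator matches the event-driven queue oracle", {
    # two full alleles against a finite pool, moderate contention
    set.seed(99)
    kOn <- c(2, 2); kOff <- c(0.5, 0.5); kLoad <- c(12, 12)
    transit <- c(5, 5) / 3; capacity <- 12; bgRate <- 6; bgDwell <- 1
    reps <- 400L
    orc <- oracleMeanSuccess(reps, kOn = kOn, kOff = kOff, kLoad = kLoad,
                             transit = transit, capacity = capacity,
                             bgRate = bgRate, bgDwell = bgDwell,
                             duration = 20)
    fs20 <- fixedStepSuccess(reps, kOn, kOff, kLoad, transit, capacity,
                             bgRate, bgDwell, duration = 20,
                             frameInterval = 20)
    fs5 <- fixedStepSuccess(reps, kOn, kOff, kLoad, transit, capacity,
                            bgRate, bgDwell, duration = 20,
                            frameInterval = 5)
    # competition is substantial in this regime: both report fewer
    # successes than the demand kLoad would give unconstrained
    expect_lt(mean(orc), 12 * (2 / 2.5) * 20 * 0.95)
    # the default frame interval already sits within a few percent
    expect_lt(abs(mean(fs20) - mean(orc)) / mean(orc), 0.06)
    # and the discretisation error shrinks as the step is refined
    expect_lt(abs(mean(fs5) - mean(orc)) / mean(orc), 0.035)
})

test_that("channel symmetry holds within homozygous nuclei", {
    cfg <- scenarioPreset("control_chr3_hom", nEmbryos = 4, seed = 303L)
    m <- traceMetrics(simulateScenario(cfg, keepTruth = FALSE), nc = "NC14")
    m <- m[m$dv_position < 0.5, ]
    ms2 <- mean(m$total_production[m$channel == "MS2"])
    pp7 <- mean(m$total_production[m$channel == "PP7"])
    expect_lt(abs(1 - pp7 / ms2), 0.05)
})
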