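test_that("activity calling behaves on constructed traces", {
    expect_false(any(callActive(rep(0, 60))))
    # clean step: active exactly on the step
    step <- c(rep(0, 20), rep(50, 20), rep(0, 20))
    mask <- callActive(step, ActivityCallParams(thresholdK = 3, minRun = 3))
    expect_equal(which(mask), 21:40)
    # runs shorter than minRun are suppressed
    blip <- c(rep(0, 20), 50, 50, rep(0, 20))
    expect_false(any(callActive(blip,
                                ActivityCallParams(minRun = 3))))
    expect_error(callActive(rep(0, 5)), "too short")
})

test_that("frame-level activity calls match simulation ground truth", {
    cfg <- tinyConfig("control_chr3_hemi", rows = 4L, cols = 4L, nc14 = 30,
                      seed = 404L)
    cfg@nucleiGrid <- c(4L, 4L)
    ts <- simulateEmbryo(cfg, 1)
    sig <- traceSignal(ts, "NC14")
    pol <- assays(ncWindow(ts, "NC14"))$polCount
    cd <- traceInfo(ts)
    ventral <- which(cd$dv_position < 0.5)
    acc <- vapply(ventral, function(j) {
        mask <- callActive(sig[, j])
        mean(mask == (pol[, j] > 0))
    }, numeric(1))
    expect_gt(mean(acc), 0.90)
})

test_that("onset, duration and amplitude summarise masks correctly", {
    tm <- seq(0, 10, by = 0.5)
    mask <- tm >= 3
    expect_equal(onsetTime(tm, mask), 3)
    expect_true(is.na(onsetTime(tm, rep(FALSE, length(tm)))))
    expect_equal(onsetTime(tm, rep(TRUE, length(tm))), 0)
    expect_equal(activeFraction(rep(TRUE, 10)), 1)
    expect_equal(activeFraction(rep(FALSE, 10)), 0)
    expect_equal(activeFraction(rep(c(TRUE, FALSE), 10)), 0.5)
    expect_equal(meanAmplitude(rep(7, 10), rep(TRUE, 10)), 7)
    expect_equal(meanAmplitude(seq(0, 10), rep(TRUE, 11)), 5)
    expect_true(is.na(meanAmplitude(1:5, rep(FALSE, 5))))
})

test_that("detected onset tracks true onset at default noise", {
    cfg <- tinyConfig("control_chr3_hemi", rows = 4L, cols = 4L, nc14 = 30,
                      seed = 505L)
    ts <- simulateEmbryo(cfg, 1)
    sig <- traceSignal(ts, "NC14")
    tm <- traceTime(ts, "NC14")
    cd <- traceInfo(ts)
    sel <- which(cd$dv_position < 0.5 & !is.na(cd$true_onset_nc14) &
                 cd$true_onset_nc14 < 20)
    d <- vapply(sel, function(j)
        onsetTime(tm, callActive(sig[, j])) - cd$true_onset_nc14[j],
        numeric(1))
    expect_true(all(d >= -1/3))         # never earlier than truth - 1 frame
    expect_lt(median(d, na.rm = TRUE), 2.5)  # frame + signal-rise delay
})

test_that("total production integrates the trace", {
    tm <- seq(0, 10)
    expect_equal(totalProduction(rep(3, 11), tm), 30)
    tri <- c(seq(0, 5), seq(4, 0))          # triangle 0 -> 5 -> 0
    expect_equal(totalProduction(tri, tm), 25)
    # negative excursions are clipped before integration
    expect_equal(totalProduction(c(-5, rep(3, 10)), tm), 28.5)
    # random trace matches a 10x oversampled Riemann oracle
    set.seed(8)
    y <- pmax(rnorm(151, 20, 10), 0)
    tm2 <- seq(0, 50, by = 1/3)
    expect_equal(totalProduction(y, tm2), riemannAUC(tm2, y),
                 tolerance = 1e-3)
})

test_that("quartile production partitions the total exactly", {
    tm <- seq(0, 10)
    expect_equal(quartileProduction(rep(2, 11), tm), rep(5, 4))
    lateOnly <- ifelse(tm >= 7.5, 4, 0)
    q <- quartileProduction(lateOnly, tm, ncDuration = 10)
    expect_equal(q[1:2], c(0, 0))
    set.seed(9)
    y <- rnorm(151, 30, 15)
    tm2 <- seq(0, 50, by = 1/3)
    expect_equal(sum(quartileProduction(y, tm2)),
                 totalProduction(y, tm2), tolerance = 1e-9)
})

test_that("amplitude x duration x cycle length approximates production", {
    cfg <- tinyConfig("control_chr3_hemi", rows = 3L, cols = 4L, nc14 = 40,
                      seed = 606L)
    ts <- simulateEmbryo(cfg, 1)
    m <- traceMetrics(ts, nc = "NC14")
    m <- m[m$dv_position < 0.4 & m$is_active & m$active_fraction > 0.3, ]
    approxProd <- m$mean_amplitude * m$active_fraction * 40
    expect_lt(abs(1 - mean(approxProd) / mean(m$total_production)), 0.05)
})

test_that("metrics scale correctly under a change of signal units", {
    cfg <- tinyConfig("control_chr3_hemi", rows = 2L, cols = 4L, nc14 = 20,
                      seed = 707L)
    ts <- simulateEmbryo(cfg, 1)
    m1 <- traceMetrics(ts, nc = "NC14")
    ts2 <- ts
    assay(ts2, "signal") <- assay(ts, "signal") * 3.5
    m2 <- traceMetrics(ts2, nc = "NC14")
    expect_equal(m2$onset, m1$onset)
    expect_equal(m2$active_fraction, m1$active_fraction)
    expect_equal(m2$mean_amplitude, m1$mean_amplitude * 3.5)
    expect_equal(m2$total_production, m1$total_production * 3.5)
})

test_that("cumulative activation curve is monotone and well normalised", {
    m <- S4Vectors::DataFrame(dv_position = c(0.1, 0.2, 0.3, 0.45, 0.9),
                              onset = c(0, 0, 5, NA, 2),
                              channel = "MS2")
    cv <- cumulativeActiveFraction(m, time = 0:10)
    expect_equal(cv$fraction[1], 0.5)       # two of four domain nuclei at 0
    expect_true(all(diff(cv$fraction) >= 0))
    expect_equal(max(cv$fraction), 0.75)    # one domain nucleus never active
    none <- S4Vectors::DataFrame(dv_position = 0.1, onset = NA_real_,
                                 channel = "MS2")
    expect_true(all(cumulativeActiveFraction(none, 0:5)$fraction == 0))
})
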