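test_that("dorsoventral profile averages per embryo then across embryos", {
    m <- S4Vectors::DataFrame(
        embryo_id = rep(c("e01", "e02"), each = 40),
        channel = "MS2",
        dv_position = rep((seq_len(40) - 0.5) / 40, 2),
        total_production = c(rep(10, 40), rep(14, 40)))
    p <- dvProfile(m, nBins = 10)
    expect_equal(nrow(p), 10)
    expect_true(all(abs(p$mean_production - 12) < 1e-9))
    expect_true(all(p$sem > 0))
    expect_equal(sum(p$n), 80)
    # step profile is reproduced at bin resolution
    m$total_production <- ifelse(m$dv_position < 0.5, 10, 0)
    p2 <- dvProfile(m, nBins = 10)
    expect_equal(p2$mean_production, c(rep(10, 5), rep(0, 5)))
    # empty bins are NA, not zero
    m3 <- m[m$dv_position < 0.3, ]
    p3 <- dvProfile(m3, nBins = 10)
    expect_true(all(is.na(p3$mean_production[p3$n == 0])))
})

test_that("profile conserves the global mean under n-weighting", {
    cfg <- tinyConfig("control_chr3_hemi", rows = 3L, cols = 10L, nc14 = 15,
                      seed = 808L)
    m <- traceMetrics(simulateScenario(cfg, nEmbryos = 3), nc = "NC14")
    m <- m[m$channel == "MS2", ]
    p <- dvProfile(m, nBins = 10)
    weighted <- sum(p$mean_production * p$n, na.rm = TRUE) /
        sum(p$n[!is.na(p$mean_production)])
    expect_equal(weighted, mean(m$total_production), tolerance = 1e-9)
})

test_that("boundary position finds the half-plateau crossing", {
    xs <- seq(0.025, 0.975, by = 0.05)
    p <- data.frame(bin_center = xs,
                    mean_production = 10 / (1 + exp(30 * (xs - 0.47))),
                    sem = 0, n = 10)
    expect_equal(boundaryPosition(p), 0.47, tolerance = 0.025)  # half a bin
    flat <- data.frame(bin_center = xs, mean_production = 5, sem = 0, n = 10)
    expect_error(boundaryPosition(flat), "never falls")
})

test_that("hemizygous and homozygous boundaries agree within one bin", {
    mh <- traceMetrics(simulateScenario(
        scenarioPreset("control_chr3_hemi", nEmbryos = 2, seed = 909L)),
        nc = "NC14")
    mo <- traceMetrics(simulateScenario(
        scenarioPreset("control_chr3_hom", nEmbryos = 2, seed = 910L)),
        nc = "NC14")
    bh <- boundaryPosition(dvProfile(mh, nBins = 20, channel = "MS2"))
    bo <- boundaryPosition(dvProfile(mo, nBins = 20, channel = "MS2"))
    expect_lt(abs(bh - bo), 0.05)          # one bin of 20
    # and the homozygous profile is lower throughout the domain
    ph <- dvProfile(mh, nBins = 20, channel = "MS2")
    po <- dvProfile(mo, nBins = 20, channel = "MS2")
    ventral <- ph$bin_center < 0.4
    expect_true(all(po$mean_production[ventral] <
                    ph$mean_production[ventral]))
})

test_that("production heatmap maps nuclei onto the lattice", {
    cfg <- tinyConfig("control_chr3_hemi", rows = 2L, cols = 4L, nc14 = 6,
                      seed = 111L)
    m <- traceMetrics(simulateEmbryo(cfg, 1), nc = "NC14")
    field <- productionHeatmap(m, grid = c(2L, 4L))
    expect_equal(dim(field), c(2L, 4L))
    expect_equal(as.vector(field), m$total_production)
    # all-zero metrics give a uniform background
    m0 <- m; m0$total_production <- 0
    expect_true(all(productionHeatmap(m0, grid = c(2L, 4L)) == 0))
    # identical inputs render identical images under the shared scale
    f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
    productionHeatmap(m, grid = c(2L, 4L), file = f1, zlim = c(0, 5000))
    productionHeatmap(m, grid = c(2L, 4L), file = f2, zlim = c(0, 5000))
    expect_identical(png::readPNG(f1), png::readPNG(f2))
    unlink(c(f1, f2))
    expect_error(productionHeatmap(m, grid = c(3L, 4L)), "do not match")
})
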