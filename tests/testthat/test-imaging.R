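test_that("nucleus segmentation handles blank, separated and fused disks", {
    expect_equal(nrow(segmentNuclei(matrix(0, 40, 40))$centroids), 0)
    # six well-separated disks on a grid
    img <- matrix(0, 72, 96)
    centers <- expand.grid(y = c(18, 54), x = c(16, 48, 80))
    for (i in seq_len(nrow(centers))) {
        yy <- outer((seq_len(72) - 1 - centers$y[i])^2,
                    (seq_len(96) - 1 - centers$x[i])^2, "+")
        img[yy <= 81] <- 1
    }
    seg <- segmentNuclei(img)
    expect_equal(nrow(seg$centroids), 6)
    d <- vapply(seq_len(6), function(i)
        min(sqrt((seg$centroids$x - centers$x[i])^2 +
                 (seg$centroids$y - centers$y[i])^2)), numeric(1))
    expect_true(all(d <= 1))
    # two disks fused by a 1-px overlap are split by the watershed
    img2 <- matrix(0, 48, 64)
    for (cx in c(23, 40)) {
        yy <- outer((seq_len(48) - 1 - 24)^2, (seq_len(64) - 1 - cx)^2, "+")
        img2[yy <= 81] <- 1
    }
    expect_equal(nrow(segmentNuclei(img2)$centroids), 2)
})

test_that("spot detection rejects noise and flat frames", {
    set.seed(12)
    fp <- vapply(1:50, function(i)
        nrow(detectSpots(matrix(rnorm(96 * 96, 100, 4), 96, 96))),
        numeric(1))
    expect_lt(mean(fp), 1)                   # < 1 false positive per frame
    expect_equal(nrow(detectSpots(matrix(500, 64, 64))), 0)  # saturated
})

test_that("a rendered spot is localised and integrated accurately", {
    set.seed(13)
    img <- matrix(rnorm(96 * 96, 100, 4), 96, 96)
    img <- alleleHub:::.gaussianSpot(img, cx = 40.3, cy = 55.7,
                                     sigma = 1.5, total = 800)
    sp <- detectSpots(img)
    expect_equal(nrow(sp), 1)
    expect_lt(abs(sp$x - 40.3), 0.7)
    expect_lt(abs(sp$y - 55.7), 0.7)
    expect_lt(abs(sp$intensity - 800) / 800, 0.10)
})

test_that("detection is equivariant under whole-pixel translations", {
    set.seed(14)
    base <- matrix(rnorm(96 * 96, 100, 4), 96, 96)
    base <- alleleHub:::.gaussianSpot(base, 30, 30, 1.5, 900)
    base <- alleleHub:::.gaussianSpot(base, 60, 70, 1.5, 700)
    shifted <- matrix(100, 96, 96)
    shifted[4:96, 6:96] <- base[1:93, 1:91]   # shift by (+3 rows, +5 cols)
    s0 <- detectSpots(base)
    s1 <- detectSpots(shifted)
    expect_equal(nrow(s1), nrow(s0))
    o0 <- order(s0$x); o1 <- order(s1$x)
    expect_equal(s1$x[o1], s0$x[o0] + 5, tolerance = 0.15)
    expect_equal(s1$y[o1], s0$y[o0] + 3, tolerance = 0.15)
})

test_that("trace assembly keeps the brightest spot and fills silence", {
    img <- matrix(0, 48, 48)
    img[12:36, 12:36][outer((12:36 - 24)^2, (12:36 - 24)^2, "+") <= 144] <- 1
    lm <- segmentNuclei(img)
    expect_equal(nrow(lm$centroids), 1)
    spots <- data.frame(frame = c(1, 1, 3), channel = "MS2",
                        x = c(23, 25, 24), y = c(23, 25, 24),
                        intensity = c(5, 9, 4))
    ts <- extractTraces(spots, lm, time = c(0, 1, 2, 3) / 3)
    sig <- traceSignal(ts)
    expect_equal(as.vector(sig), c(9, 0, 4, 0))  # brightest kept; gaps zero
    # a spot far outside every nucleus is dropped with a message
    far <- rbind(spots, data.frame(frame = 2, channel = "MS2", x = 2, y = 2,
                                   intensity = 50))
    expect_message(ts2 <- extractTraces(far, lm, time = c(0, 1, 2, 3) / 3),
                   "dropped")
    expect_equal(unname(traceSignal(ts2)[2, 1]), 0)
})

test_that("simulate -> render -> extract preserves traces and production", {
    cfg <- tinyConfig("control_chr3_hemi", rows = 3L, cols = 6L, nc14 = 40,
                      seed = 1515L)
    set.seed(15)
    ts <- simulateEmbryo(cfg, 1)
    mv <- renderMovie(ts, nc = "NC14")
    ex <- extractFromStack(mv$stack, time = mv$time)
    expect_equal(ncol(ex), 18)
    cent <- segmentNuclei(mv$stack[1, , , 1])$centroids
    simSig <- traceSignal(ts, "NC14")
    gain <- mv$optics$gain
    # perfect detections from the ground-truth sidecar: assembled traces
    # must track the simulated signals almost exactly
    truth <- mv$sidecar[mv$sidecar$intensity_counts > 0, ]
    spots <- data.frame(frame = truth$frame, channel = truth$channel,
                        x = truth$x, y = truth$y,
                        intensity = truth$intensity_counts)
    exT <- extractTraces(spots, segmentNuclei(mv$stack[1, , , 1]),
                         time = mv$time)
    infoT <- traceInfo(exT)
    rs <- vapply(seq_len(ncol(exT)), function(j) {
        lab <- match(sub("^n0*", "", infoT$nucleus_id[j]), cent$label)
        d2 <- (mv$centers$x - cent$x[lab])^2 +
              (mv$centers$y - cent$y[lab])^2
        sim <- simSig[, which.min(d2)]
        if (max(sim) < 100) return(NA_real_)  # clearly active only
        cor(traceSignal(exT)[, j], sim)
    }, numeric(1))
    expect_true(all(rs > 0.95, na.rm = TRUE))
    # production means agree within 10% in the expression domain
    md <- traceMetrics(ts, nc = "NC14")
    me <- traceMetrics(ex, nc = "NC14")
    d <- md[md$dv_position < 0.5, ]; e <- me[me$dv_position < 0.5, ]
    expect_lt(abs(1 - mean(e$total_production) / gain /
                      mean(d$total_production)), 0.10)
})

test_that("rendering validates density and writes a readable stack", {
    cfg <- tinyConfig("control_chr3_hemi", rows = 2L, cols = 2L, nc14 = 2,
                      seed = 116L)
    ts <- simulateEmbryo(cfg, 1)
    expect_error(renderMovie(ts, optics = RenderOptics(nucleusRadius = 13,
                                                       spacing = 24)),
                 "overlap")
    f <- tempfile(fileext = ".tiff")
    mv <- renderMovie(ts, nc = "NC14", file = f)
    expect_true(file.exists(f))
    back <- readStack(f)
    expect_equal(dim(back), dim(mv$stack))
    expect_lt(max(abs(back - pmin(pmax(mv$stack, 0), 65535))), 1.01)
    expect_true(file.exists(sub("\\.tiff$", "_sidecar.csv", f)))
    unlink(c(f, sub("\\.tiff$", "_sidecar.csv", f)))
})
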