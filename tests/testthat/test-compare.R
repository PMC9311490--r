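test_that("percent reduction arithmetic and bootstrap behave", {
    x <- rep(c(4, 5, 6), 4)
    emb <- rep(c("a", "b", "c", "d"), each = 3)
    eq <- percentReduction(x, x, emb, emb)
    expect_equal(eq@percentReduction, 0)
    expect_true(eq@ciLow <= 0 && eq@ciHigh >= 0)
    sc <- percentReduction(x, 0.75 * x, emb, emb)
    expect_equal(sc@percentReduction, 25)
    expect_true(sc@ciLow <= sc@percentReduction &&
                sc@ciHigh >= sc@percentReduction)
    expect_warning(percentReduction(x, x, emb, rep("a", 12)),
                   "single embryo")
    expect_error(percentReduction(numeric(0), x, character(0), emb),
                 "finite values")
    # bootstrap is reproducible under a fixed seed
    set.seed(99); y <- 0.8 * x + rnorm(12)
    a <- percentReduction(x, y, emb, emb, seed = 5)
    b <- percentReduction(x, y, emb, emb, seed = 5)
    expect_equal(c(a@ciLow, a@ciHigh), c(b@ciLow, b@ciHigh))
    expect_s4_class(a, "GenotypeComparison")
})

test_that("projected homozygous total doubles the per-allele mean", {
    expect_equal(projectedTotal(c(8, 10, 12)), 20)
    expect_error(projectedTotal(numeric(0)), "no finite")
})

test_that("parent-of-origin check recovers symmetry and injected bias", {
    # identical values with swapped labels: exactly zero
    v <- rnorm(40, 100, 5)
    emb <- rep(1:4, each = 10)
    same <- parentOfOriginCheck(v, v, emb, emb)
    expect_equal(same@percentReduction, 0)
    # deliberately weakened second orientation is detected
    set.seed(21)
    cfgA <- tinyConfig("control_chr3_hom", rows = 4L, cols = 6L, nc14 = 25,
                       seed = 212L)
    cfgB <- cfgA
    cfgB@alleles <- lapply(cfgB@alleles, function(a) {
        if (a@channel == "MS2") a@telegraph@kLoad <- a@telegraph@kLoad * 0.8
        a
    })
    mA <- traceMetrics(simulateScenario(cfgA, nEmbryos = 6), nc = "NC14")
    mB <- traceMetrics(simulateScenario(cfgB, nEmbryos = 6, seed = 999L),
                       nc = "NC14")
    mA <- mA[mA$channel == "MS2" & mA$dv_position < 0.5, ]
    mB <- mB[mB$channel == "MS2" & mB$dv_position < 0.5, ]
    biased <- parentOfOriginCheck(mA$total_production, mB$total_production,
                                  mA$embryo_id, mB$embryo_id)
    expect_gt(biased@ciLow, 0)   # reduction detected with confidence
})

test_that("nuclear-cycle contrast pairs the two comparisons", {
    x <- rep(1:10, 2); emb <- rep(1:4, 5)
    a <- percentReduction(x, x, emb, emb)
    b <- percentReduction(x, 0.8 * x, emb, emb)
    ct <- ncContrast(a, b)
    expect_equal(ct$difference, 20, tolerance = 1e-9)
    expect_equal(ncContrast(a, a)$difference, 0)
})

test_that("boxplot summary follows the study's quantile conventions", {
    bs <- boxplotSummary(1:100)
    expect_equal(unname(bs$quartiles[2]), 50.5)
    expect_equal(unname(bs$whiskers), c(10.9, 90.1))
    expect_true(bs$quartiles[1] <= bs$quartiles[2] &&
                bs$quartiles[2] <= bs$quartiles[3])
    expect_true(bs$whiskers[1] <= bs$quartiles[1] &&
                bs$whiskers[2] >= bs$quartiles[3])
    expect_length(bs$scatter, 100)           # fewer than 200: keep all
    set.seed(4); v <- rnorm(1000)
    big <- boxplotSummary(v, seed = 3)
    expect_length(big$scatter, 200)
    expect_identical(big$scatter, boxplotSummary(v, seed = 3)$scatter)
    const <- boxplotSummary(rep(2, 50))
    expect_true(all(const$quartiles == 2))
})
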