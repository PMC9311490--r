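#' Percent reduction of a metric between two arms
#'
#' The headline comparison of the study: how much lower a per-nucleus
#' metric (typically NC14 total production) is in a test arm (one
#' homozygous allele) than in a reference arm (the hemizygous allele).
#' The point estimate is computed from pooled per-nucleus values,
#' \code{100 * (1 - mean(test) / mean(ref))}; uncertainty comes from
#' resampling embryos — the biological replicates — with replacement in
#' each arm.
#'
#' @param ref,test numeric per-nucleus values of the two arms.
#' @param refEmbryo,testEmbryo embryo identifier per value (used for the
#'   bootstrap).
#' @param metric label of the compared metric.
#' @param labels character(2): arm labels.
#' @param nBoot bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return A \linkS4class{GenotypeComparison}.
#' @examples
#' pr <- percentReduction(c(4, 5, 6), c(3, 4, 5) * 0.75,
#'                        refEmbryo = c(1, 1, 2), testEmbryo = c(1, 2, 2))
#' @export
percentReduction <- function(ref, test, refEmbryo, testEmbryo,
                             metric = "total_production",
                             labels = c("reference", "test"),
                             nBoot = 2000L, seed = 1L) {
    ok1 <- is.finite(ref); ok2 <- is.finite(test)
    ref <- ref[ok1]; refEmbryo <- as.character(refEmbryo)[ok1]
    test <- test[ok2]; testEmbryo <- as.character(testEmbryo)[ok2]
    if (length(ref) == 0L || length(test) == 0L)
        stop("both arms must contain finite values")
    est <- 100 * (1 - mean(test) / mean(ref))
    eR <- split(ref, refEmbryo); eT <- split(test, testEmbryo)
    ciLow <- ciHigh <- NA_real_
    if (length(eR) < 2L || length(eT) < 2L) {
        warning("an arm has a single embryo; bootstrap CI not reported")
    } else {
        old <- .Random.seed_save()
        on.exit(.Random.seed_restore(old), add = TRUE)
        set.seed(seed)
        bs <- vapply(seq_len(nBoot), function(i) {
            r <- unlist(eR[sample.int(length(eR), replace = TRUE)],
                        use.names = FALSE)
            t <- unlist(eT[sample.int(length(eT), replace = TRUE)],
                        use.names = FALSE)
            100 * (1 - mean(t) / mean(r))
        }, numeric(1))
        q <- unname(quantile(bs, c(0.025, 0.975)))
        ciLow <- min(q[1], est); ciHigh <- max(q[2], est)
    }
    new("GenotypeComparison", metric = metric,
        refLabel = labels[1], testLabel = labels[2],
        meanRef = mean(ref), meanTest = mean(test),
        percentReduction = est, ciLow = ciLow, ciHigh = ciHigh,
        nNuclei = c(length(ref), length(test)),
        nEmbryos = c(length(eR), length(eT)))
}

.Random.seed_save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Projected total production of a homozygote
#'
#' Doubles the mean per-allele production of homozygous nuclei, the
#' projection of what the two alleles produce together.  Its validity rests
#' on parent-of-origin symmetry (see
#' \code{\link{parentOfOriginCheck}}).
#'
#' @param perAllele per-nucleus production values of one homozygous allele
#'   (a.u. * min).
#' @return 2 * mean(perAllele).
#' @examples
#' projectedTotal(c(8, 10, 12))
#' @export
projectedTotal <- function(perAllele) {
    perAllele <- perAllele[is.finite(perAllele)]
    if (length(perAllele) == 0L) stop("no finite per-allele values")
    2 * mean(perAllele)
}

#' Parent-of-origin symmetry check
#'
#' Compares mean production between two homozygous orientations (MS2
#' marking the paternal vs the maternal allele).  Reports the percent
#' difference with an embryo-level bootstrap CI; symmetry holds when the
#' CI contains zero.
#'
#' @param valuesA,valuesB per-nucleus values of the two orientations.
#' @param embryoA,embryoB embryo identifiers per value.
#' @param nBoot,seed bootstrap controls.
#' @return A \linkS4class{GenotypeComparison} with metric
#'   \code{"parent_of_origin"}; \code{percentReduction} is the percent
#'   difference of orientation B relative to A.
#' @examples
#' parentOfOriginCheck(rnorm(20, 10), rnorm(20, 10),
#'                     rep(1:2, 10), rep(1:2, 10))
#' @export
parentOfOriginCheck <- function(valuesA, valuesB, embryoA, embryoB,
                                nBoot = 2000L, seed = 1L) {
    percentReduction(valuesA, valuesB, embryoA, embryoB,
                     metric = "parent_of_origin",
                     labels = c("MS2_paternal", "MS2_maternal"),
                     nBoot = nBoot, seed = seed)
}

#' Nuclear-cycle contrast of allelic competition
#'
#' Pairs the NC13 and NC14 comparisons of the same scenario pair: the
#' signature of the limiting-hub mechanism is essentially no reduction in
#' NC13 (few zygotic genes active, pool not limiting) and a substantial
#' reduction in NC14.
#'
#' @param nc13,nc14 \linkS4class{GenotypeComparison} objects for the two
#'   cycles.
#' @return A list with elements \code{nc13}, \code{nc14} and
#'   \code{difference} (NC14 minus NC13 reduction, percentage points).
#' @examples
#' a <- percentReduction(1:10, 1:10, rep(1:2, 5), rep(1:2, 5))
#' b <- percentReduction(1:10, 0.8 * (1:10), rep(1:2, 5), rep(1:2, 5))
#' ncContrast(a, b)$difference
#' @export
ncContrast <- function(nc13, nc14) {
    stopifnot(is(nc13, "GenotypeComparison"), is(nc14, "GenotypeComparison"))
    list(nc13 = nc13, nc14 = nc14,
         difference = nc14@percentReduction - nc13@percentReduction)
}

#' Boxplot summary in the study's convention
#'
#' Quantiles use linear interpolation between order statistics; the box is
#' the 25/50/75\% quantiles, the whiskers extend to the 10th and 90th
#' percentiles, and a seeded subsample of up to 200 values is kept for the
#' scatter overlay.
#'
#' @param values numeric vector.
#' @param seed RNG seed for the scatter subsample.
#' @param nScatter subsample size (without replacement; all values if
#'   fewer).
#' @return A list with \code{quartiles} (named, 25/50/75\%),
#'   \code{whiskers} (10/90\%), \code{n} and \code{scatter}.
#' @examples
#' boxplotSummary(1:100)$quartiles
#' @export
boxplotSummary <- function(values, seed = 1L, nScatter = 200L) {
    values <- values[is.finite(values)]
    if (length(values) == 0L) stop("no finite values")
    q <- quantile(values, c(0.25, 0.5, 0.75), type = 7)
    w <- quantile(values, c(0.10, 0.90), type = 7)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    sc <- if (length(values) > nScatter)
        sample(values, nScatter) else values
    list(quartiles = q, whiskers = w, n = length(values), scatter = sc)
}

#' Convert a comparison to a one-row data.frame
#'
#' @param x a \linkS4class{GenotypeComparison}.
#' @param ... ignored.
#' @return A one-row data.frame (used by the report writers).
#' @export
as.data.frame.GenotypeComparison <- function(x, ...) {
    data.frame(metric = x@metric, ref = x@refLabel, test = x@testLabel,
               mean_ref = x@meanRef, mean_test = x@meanTest,
               percent_reduction = x@percentReduction,
               ci_low = x@ciLow, ci_high = x@ciHigh,
               n_nuclei_ref = x@nNuclei[1], n_nuclei_test = x@nNuclei[2],
               n_embryos_ref = x@nEmbryos[1], n_embryos_test = x@nEmbryos[2])
}
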