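#' Activity-calling parameters
#'
#' A frame is called transcriptionally active when its signal exceeds
#' \code{baseline + thresholdK * noiseSd} and belongs to a run of at least
#' \code{minRun} consecutive supra-threshold frames.  Baseline and noise
#' are estimated per trace (arbitrary units differ across embryos) from
#' the first \code{baselineWindow} frames of the cycle — the post-mitotic
#' quiet period before most nuclei initiate: the baseline is the median of
#' the lowest-quartile frames of that window (robust to nuclei that
#' initiate early), and the noise sd is a MAD estimate from the window's
#' first differences.  Estimating from the quiet window rather than the
#' whole trace keeps the threshold comparable between bright and dim
#' traces instead of tracking the signal's own fluctuations.
#'
#' @param thresholdK threshold in multiples of the noise sd (> 0).
#' @param minRun consecutive supra-threshold frames required (>= 1).
#' @param baselineWindow number of frames at the cycle start used to
#'   estimate baseline and noise.
#' @return An \code{ActivityCallParams} object.
#' @examples
#' ActivityCallParams(thresholdK = 4)
#' @export
ActivityCallParams <- function(thresholdK = 7, minRun = 3L,
                               baselineWindow = 12L) {
    stopifnot(thresholdK > 0, minRun >= 1, baselineWindow >= 4)
    structure(list(thresholdK = thresholdK, minRun = as.integer(minRun),
                   baselineWindow = as.integer(baselineWindow)),
              class = "ActivityCallParams")
}

#' Call transcriptionally active frames
#'
#' @param signal numeric fluorescence trace (one allele, one nuclear
#'   cycle).
#' @param params an \code{\link{ActivityCallParams}}.
#' @return Logical frame mask.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(20), rnorm(20, 10), rnorm(20))
#' mean(callActive(x, ActivityCallParams())[21:40])
#' @export
callActive <- function(signal, params = ActivityCallParams()) {
    n <- length(signal)
    W <- params$baselineWindow
    if (n < W)
        stop("trace too short for activity calling (", n, " frames, ",
             "baseline window ", W, ")")
    win <- signal[seq_len(W)]
    nBase <- max(3L, ceiling(W / 4))
    baseline <- median(sort(win)[seq_len(nBase)])
    noiseSd <- mad(diff(win)) / sqrt(2)
    above <- signal > baseline + params$thresholdK * noiseSd
    if (params$minRun > 1L) {
        r <- rle(above)
        r$values <- r$values & r$lengths >= params$minRun
        above <- inverse.rle(r)
    }
    above
}

#' Transcription onset time
#'
#' @param time frame times (minutes since the nuclear-cycle onset).
#' @param mask logical mask from \code{\link{callActive}}.
#' @return Time of the first active frame (min), or \code{NA} if the trace
#'   is never active.
#' @examples
#' onsetTime(0:9, c(rep(FALSE, 4), rep(TRUE, 6)))
#' @export
onsetTime <- function(time, mask) {
    i <- which(mask)
    if (length(i) == 0L) NA_real_ else time[i[1]]
}

#' Fraction of the nuclear cycle spent actively transcribing
#'
#' The total cycle duration is scaled to one, so the value is the fraction
#' of frames called active.
#'
#' @param mask logical mask from \code{\link{callActive}}.
#' @return Dimensionless fraction in [0, 1].
#' @examples
#' activeFraction(c(TRUE, TRUE, FALSE, FALSE))
#' @export
activeFraction <- function(mask) {
    mean(mask)
}

#' Mean transcription amplitude over active frames
#'
#' @param signal fluorescence trace.
#' @param mask logical mask from \code{\link{callActive}}.
#' @return Mean signal over active frames (a.u.), or \code{NA} when no
#'   frame is active (such traces are excluded from amplitude statistics).
#' @examples
#' meanAmplitude(c(0, 5, 7, 0), c(FALSE, TRUE, TRUE, FALSE))
#' @export
meanAmplitude <- function(signal, mask) {
    if (!any(mask)) return(NA_real_)
    mean(signal[mask])
}

#' Total RNA production (area under the trace)
#'
#' Trapezoidal integral of the fluorescence trace over the nuclear cycle,
#' the proxy for the number of RNAs produced.  Negative (noise) excursions
#' are clipped to zero before integration so that noise cannot create
#' negative production.
#'
#' @param signal fluorescence trace.
#' @param time frame times (min).
#' @return Production in a.u. * min.
#' @examples
#' totalProduction(rep(2, 11), 0:10)  # 2 a.u. for 10 min -> 20
#' @export
totalProduction <- function(signal, time) {
    stopifnot(length(signal) == length(time), length(signal) >= 2L)
    pracma::trapz(time, pmax(signal, 0))
}

# integral of the linear interpolant of (time, y) over [a, b]
.trapzWindow <- function(time, y, a, b) {
    a <- max(a, time[1]); b <- min(b, time[length(time)])
    if (b <= a) return(0)
    inner <- time > a & time < b
    tt <- c(a, time[inner], b)
    yy <- approx(time, y, xout = tt)$y
    pracma::trapz(tt, yy)
}

#' RNA production within each temporal quarter of the cycle
#'
#' Splits the nuclear cycle into four equal temporal classes and integrates
#' the (negative-clipped) trace within each, splitting boundary frames by
#' linear interpolation.  The four entries sum to
#' \code{\link{totalProduction}} exactly.
#'
#' @param signal fluorescence trace.
#' @param time frame times (min).
#' @param ncDuration cycle duration (min); defaults to the last frame time.
#' @return Numeric vector of length 4 (a.u. * min).
#' @examples
#' quartileProduction(rep(2, 11), 0:10)
#' @export
quartileProduction <- function(signal, time, ncDuration = max(time)) {
    y <- pmax(signal, 0)
    br <- seq(0, ncDuration, length.out = 5L)
    vapply(seq_len(4L), function(q)
        .trapzWindow(time, y, br[q], br[q + 1]), numeric(1))
}

#' Per-trace metrics table
#'
#' Applies activity calling and all per-nucleus quantifications to every
#' trace of one nuclear cycle: activity flag, onset time, active-duration
#' fraction, mean amplitude, total production (AUC) and the four temporal
#' quartile productions.
#'
#' @param x a \linkS4class{TraceSet}.
#' @param nc which nuclear cycle to quantify.
#' @param params an \code{\link{ActivityCallParams}}.
#' @return A \link[S4Vectors]{DataFrame} with one row per trace carrying
#'   the trace metadata plus columns \code{is_active}, \code{onset},
#'   \code{active_fraction}, \code{mean_amplitude}, \code{total_production}
#'   and \code{q1_production} .. \code{q4_production}.
#' @examples
#' cfg <- scenarioPreset("control_chr3_hemi")
#' cfg@nucleiGrid <- c(2L, 4L); cfg@nc14Duration <- 8
#' m <- traceMetrics(simulateEmbryo(cfg, 1), nc = "NC14")
#' @export
traceMetrics <- function(x, nc = "NC14", params = ActivityCallParams()) {
    xx <- ncWindow(x, nc)
    sig <- assay(xx, "signal")
    tim <- rowData(xx)$time
    ncDur <- max(tim)
    n <- ncol(sig)
    isActive <- logical(n)
    onset <- amp <- tot <- numeric(n)
    qm <- matrix(0, n, 4)
    frac <- numeric(n)
    for (j in seq_len(n)) {
        s <- sig[, j]
        mask <- callActive(s, params)
        isActive[j] <- any(mask)
        onset[j] <- onsetTime(tim, mask)
        frac[j] <- activeFraction(mask)
        amp[j] <- meanAmplitude(s, mask)
        tot[j] <- totalProduction(s, tim)
        qm[j, ] <- quartileProduction(s, tim, ncDur)
    }
    out <- as(traceInfo(x), "DataFrame")
    keep <- intersect(c("embryo_id", "nucleus_id", "dv_position", "channel",
                        "parent_of_origin"), colnames(out))
    out <- out[, keep, drop = FALSE]
    out$nc <- nc
    out$is_active <- isActive
    out$onset <- onset
    out$active_fraction <- frac
    out$mean_amplitude <- amp
    out$total_production <- tot
    out$q1_production <- qm[, 1]; out$q2_production <- qm[, 2]
    out$q3_production <- qm[, 3]; out$q4_production <- qm[, 4]
    out
}

#' Cumulative fraction of active nuclei over the nuclear cycle
#'
#' At each frame time, the fraction of expression-domain nuclei whose
#' detected onset is at or before that time.  The curve is monotone
#' nondecreasing and ends at the fraction of domain nuclei that were ever
#' active.
#'
#' @param metrics a metrics table from \code{\link{traceMetrics}}.
#' @param time frame times at which to evaluate the curve (min).
#' @param xBoundary dorsoventral boundary; nuclei with
#'   \code{dv_position < xBoundary} form the expression domain.
#' @param channel optionally restrict to one channel.
#' @return A data.frame with columns \code{time} and \code{fraction}.
#' @examples
#' m <- S4Vectors::DataFrame(dv_position = c(0.1, 0.2, 0.9),
#'                           onset = c(1, 4, NA),
#'                           channel = "MS2")
#' cumulativeActiveFraction(m, time = 0:5)
#' @export
cumulativeActiveFraction <- function(metrics, time, xBoundary = 0.5,
                                     channel = NULL) {
    m <- metrics[metrics$dv_position < xBoundary, , drop = FALSE]
    if (!is.null(channel)) m <- m[m$channel == channel, , drop = FALSE]
    if (nrow(m) == 0L) stop("no nuclei inside the expression domain")
    on <- m$onset
    frac <- vapply(time, function(t) mean(!is.na(on) & on <= t), numeric(1))
    data.frame(time = time, fraction = frac)
}
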