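#' Dorsoventral production profile
#'
#' Bins nuclei along the dorsoventral axis, averages per-nucleus total
#' production within each bin per embryo, then averages the per-embryo bin
#' means across embryos (so each biological replicate contributes equally)
#' and reports the cross-embryo SEM.
#'
#' @param metrics a metrics table from \code{\link{traceMetrics}} (needs
#'   \code{dv_position}, \code{total_production}, \code{embryo_id}).
#' @param nBins number of equal-width bins partitioning [0, 1].
#' @param channel optionally restrict to one channel.
#' @return A data.frame with columns \code{bin_center}, \code{mean_production},
#'   \code{sem}, \code{n} (nuclei pooled over embryos).  Bins containing no
#'   nuclei are reported with \code{NA} means, not zero.
#' @examples
#' m <- S4Vectors::DataFrame(embryo_id = "e01", channel = "MS2",
#'                           dv_position = runif(50),
#'                           total_production = runif(50))
#' dvProfile(m, nBins = 5)
#' @export
dvProfile <- function(metrics, nBins = 20L, channel = NULL) {
    m <- as.data.frame(metrics)
    if (!is.null(channel)) m <- m[m$channel == channel, , drop = FALSE]
    br <- seq(0, 1, length.out = nBins + 1L)
    bin <- cut(m$dv_position, br, include.lowest = TRUE, labels = FALSE)
    centers <- (br[-1] + br[-length(br)]) / 2
    perEmb <- tapply(m$total_production,
                     list(factor(bin, levels = seq_len(nBins)), m$embryo_id),
                     mean)
    mu <- rowMeans(perEmb, na.rm = TRUE)
    nEmb <- rowSums(!is.na(perEmb))
    sdv <- apply(perEmb, 1, sd, na.rm = TRUE)
    sem <- ifelse(nEmb > 1, sdv / sqrt(nEmb), 0)
    nNuc <- tabulate(bin, nbins = nBins)
    data.frame(bin_center = centers,
               mean_production = ifelse(nNuc > 0, mu, NA_real_),
               sem = ifelse(nNuc > 0, sem, NA_real_),
               n = nNuc)
}

#' Position of the expression-domain boundary
#'
#' The ventral plateau is the mean of the three most ventral non-empty
#' bins; the boundary is the linearly interpolated dorsoventral position at
#' which the profile first falls below 50\% of that plateau.
#'
#' @param profile a data.frame from \code{\link{dvProfile}}.
#' @return Boundary position in DV units.
#' @examples
#' p <- data.frame(bin_center = seq(0.025, 0.975, by = 0.05),
#'                 mean_production = 10 / (1 + exp(30 * (seq(0.025, 0.975,
#'                 by = 0.05) - 0.5))), sem = 0, n = 10)
#' boundaryPosition(p)
#' @export
boundaryPosition <- function(profile) {
    p <- profile[!is.na(profile$mean_production), , drop = FALSE]
    if (nrow(p) < 4L) stop("profile has too few populated bins")
    plateau <- mean(p$mean_production[seq_len(3L)])
    half <- plateau / 2
    below <- which(p$mean_production < half)
    below <- below[below > 1L]
    if (length(below) == 0L)
        stop("profile never falls below half of the ventral plateau")
    i <- below[1]
    x0 <- p$bin_center[i - 1]; x1 <- p$bin_center[i]
    y0 <- p$mean_production[i - 1]; y1 <- p$mean_production[i]
    x0 + (half - y0) * (x1 - x0) / (y1 - y0)
}

#' Per-nucleus production heatmap
#'
#' Arranges per-nucleus total production on the embryo's nuclear lattice
#' and optionally renders it to PNG with a fixed colour scale, so that
#' genotypes rendered with the same \code{zlim} are directly comparable.
#'
#' @param metrics a metrics table from \code{\link{traceMetrics}} for one
#'   embryo and channel.
#' @param grid integer \code{c(rows, cols)} of the nuclear lattice.
#' @param file optional PNG path.
#' @param zlim fixed colour-scale range; defaults to \code{c(0, max)}.
#' @return The rows x cols production matrix, invisibly when \code{file}
#'   is given.
#' @examples
#' cfg <- scenarioPreset("control_chr3_hemi")
#' cfg@nucleiGrid <- c(2L, 4L); cfg@nc14Duration <- 4
#' m <- traceMetrics(simulateEmbryo(cfg, 1))
#' productionHeatmap(m, grid = c(2L, 4L))
#' @export
productionHeatmap <- function(metrics, grid, file = NULL, zlim = NULL) {
    m <- as.data.frame(metrics)
    rows <- grid[1]; cols <- grid[2]
    if (nrow(m) != rows * cols)
        stop("metrics rows (", nrow(m), ") do not match grid ",
             rows, " x ", cols)
    idx <- as.integer(sub("^n", "", m$nucleus_id))
    field <- matrix(NA_real_, rows, cols)
    field[idx] <- m$total_production   # lattice is filled column-major
    if (is.null(zlim)) zlim <- c(0, max(field, 1e-12, na.rm = TRUE))
    if (!is.null(file)) {
        grDevices::png(file, width = 480, height = 360)
        on.exit(grDevices::dev.off(), add = TRUE)
        graphics::image(t(field), zlim = zlim, axes = FALSE,
                        col = grDevices::hcl.colors(64, "viridis"),
                        xlab = "dorsoventral axis", ylab = "")
        graphics::box()
        return(invisible(field))
    }
    field
}
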