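#' Segment nuclei in a histone-channel frame
#'
#' Classical pipeline: global Otsu threshold, hole filling,
#' distance-transform watershed to split touching nuclei, and removal of
#' components below a minimum area.  A blank frame yields an empty label
#' map rather than an error.
#'
#' @param frame 2-D numeric matrix (single channel).
#' @param minArea minimum component area (px^2).
#' @param tolerance watershed tolerance (see
#'   \code{\link[EBImage]{watershed}}).
#' @return A list of class \code{NucleusLabelMap}: \code{labels} (integer
#'   matrix, background 0), \code{centroids} (data.frame label, x, y in
#'   0-based pixel-centre coordinates) and \code{areas} (px^2).
#' @examples
#' img <- matrix(0, 32, 32); img[8:16, 8:16] <- 1
#' segmentNuclei(img)$centroids
#' @export
segmentNuclei <- function(frame, minArea = 30, tolerance = 1) {
    rng <- range(frame)
    empty <- list(labels = matrix(0L, nrow(frame), ncol(frame)),
                  centroids = data.frame(label = integer(), x = numeric(),
                                         y = numeric()),
                  areas = numeric())
    class(empty) <- c("NucleusLabelMap", "list")
    if (diff(rng) <= 0) return(empty)
    norm <- (frame - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(norm))
    bw <- norm > thr
    if (!any(bw)) return(empty)
    bw <- EBImage::fillHull(bw)
    dm <- EBImage::distmap(bw)
    labels <- EBImage::imageData(EBImage::watershed(dm,
                                                    tolerance = tolerance))
    areas <- tabulate(labels[labels > 0])
    keep <- which(areas >= minArea)
    relab <- integer(length(areas))
    relab[keep] <- seq_along(keep)
    labels[labels > 0] <- relab[labels[labels > 0]]
    labels <- matrix(as.integer(labels), nrow(frame), ncol(frame))
    if (!length(keep)) return(empty)
    idx <- which(labels > 0, arr.ind = TRUE)
    lab <- labels[labels > 0]
    cx <- tapply(idx[, 2] - 1, lab, mean)   # columns -> x
    cy <- tapply(idx[, 1] - 1, lab, mean)   # rows    -> y
    out <- list(labels = labels,
                centroids = data.frame(label = as.integer(names(cx)),
                                       x = as.numeric(cx),
                                       y = as.numeric(cy)),
                areas = areas[keep])
    class(out) <- c("NucleusLabelMap", "list")
    out
}

#' @export
print.NucleusLabelMap <- function(x, ...) {
    cat("NucleusLabelMap:", nrow(x$centroids), "nuclei in a",
        nrow(x$labels), "x", ncol(x$labels), "frame\n")
    invisible(x)
}

#' Detect fluorescence spots in one frame
#'
#' Difference-of-Gaussians band-pass, local maxima above a robust
#' threshold (median + k * MAD of the filtered frame), subpixel
#' localisation by intensity-weighted centroid in a fixed window, and
#' background-subtracted integrated intensity (window sum minus the local
#' annulus median times the window area).
#'
#' @param frame 2-D numeric matrix.
#' @param channel label stored in the output (\code{"MS2"}/\code{"PP7"}).
#' @param sigmaSmall,sigmaLarge band-pass Gaussian sigmas (px).
#' @param k detection threshold in MADs above the median of the filtered
#'   frame.
#' @param window half-width of the localisation/integration window (px).
#' @param annulusWidth width of the background annulus around the window
#'   (px).
#' @return A data.frame of spot records: \code{channel}, \code{x},
#'   \code{y} (0-based pixel-centre), \code{intensity} (background
#'   subtracted, >= 0); zero rows when nothing is found.
#' @examples
#' img <- matrix(rnorm(64 * 64), 64, 64)
#' nrow(detectSpots(img))  # noise only: almost always 0
#' @export
detectSpots <- function(frame, channel = "MS2", sigmaSmall = 1.2,
                        sigmaLarge = 3, k = 8, window = 4L,
                        annulusWidth = 2L) {
    empty <- data.frame(channel = character(), x = numeric(), y = numeric(),
                        intensity = numeric())
    if (diff(range(frame)) <= 0) return(empty)
    f1 <- EBImage::imageData(EBImage::gblur(EBImage::Image(frame),
                                            sigma = sigmaSmall))
    f2 <- EBImage::imageData(EBImage::gblur(EBImage::Image(frame),
                                            sigma = sigmaLarge))
    dog <- f1 - f2
    thr <- median(dog) + k * mad(dog)
    H <- nrow(frame); W <- ncol(frame)
    cand <- which(dog > thr, arr.ind = TRUE)
    if (nrow(cand) == 0L) return(empty)
    # strict local maxima over the 8-neighbourhood
    isMax <- vapply(seq_len(nrow(cand)), function(i) {
        r <- cand[i, 1]; c <- cand[i, 2]
        rs <- max(1, r - 1):min(H, r + 1)
        cs <- max(1, c - 1):min(W, c + 1)
        dog[r, c] >= max(dog[rs, cs])
    }, logical(1))
    cand <- cand[isMax, , drop = FALSE]
    if (nrow(cand) == 0L) return(empty)
    w <- as.integer(window); aw <- as.integer(annulusWidth)
    out <- lapply(seq_len(nrow(cand)), function(i) {
        r <- cand[i, 1]; c <- cand[i, 2]
        rs <- max(1, r - w):min(H, r + w)
        cs <- max(1, c - w):min(W, c + w)
        ra <- max(1, r - w - aw):min(H, r + w + aw)
        ca <- max(1, c - w - aw):min(W, c + w + aw)
        ann <- frame[ra, ca]
        inWin <- matrix(FALSE, length(ra), length(ca))
        inWin[ra %in% rs, ca %in% cs] <- TRUE
        bg <- median(ann[!inWin])
        win <- frame[rs, cs] - bg
        tot <- sum(win)
        wpos <- pmax(win, 0)
        if (sum(wpos) <= 0) return(NULL)
        cy <- sum((rs - 1) * rowSums(wpos)) / sum(wpos)
        cx <- sum((cs - 1) * colSums(wpos)) / sum(wpos)
        data.frame(channel = channel, x = cx, y = cy,
                   intensity = max(tot, 0))
    })
    out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(out)) empty else out
}

#' Assemble traces from detected spots and a nucleus label map
#'
#' Assigns each spot to the nucleus whose label contains its centroid
#' (falling back to the nearest nucleus centroid within
#' \code{maxDistance}), keeps the single brightest spot per nucleus,
#' channel and frame (one locus per channel per nucleus), fills frames with
#' no detection with zero signal, and returns one trace per
#' nucleus/channel — including all-zero traces for nuclei never seen
#' spotting.  Spots beyond \code{maxDistance} of any nucleus are dropped
#' and counted in a message.
#'
#' @param spots data.frame of detections across frames: columns
#'   \code{frame}, \code{channel}, \code{x}, \code{y}, \code{intensity}.
#' @param labelMap a \code{NucleusLabelMap} (nuclei are static in the
#'   rendered movies, so a single map serves all frames).
#' @param time frame times (min).
#' @param nc nuclear-cycle label for the output rows.
#' @param channels channels to emit (every nucleus gets one trace per
#'   channel).
#' @param maxDistance fallback assignment radius (px).
#' @param embryoId embryo label for the output.
#' @return A \linkS4class{TraceSet}; \code{dv_position} is the nucleus
#'   centre's x coordinate scaled to [0, 1] (columns of the rendered frame
#'   span the dorsoventral axis).
#' @examples
#' lm <- segmentNuclei({m <- matrix(0, 24, 24); m[6:18, 6:18] <- 1; m})
#' sp <- data.frame(frame = 1:2, channel = "MS2", x = 11, y = 11,
#'                  intensity = c(5, 7))
#' extractTraces(sp, lm, time = c(0, 1/3))
#' @export
extractTraces <- function(spots, labelMap, time, nc = "NC14",
                          channels = c("MS2"), maxDistance = 6,
                          embryoId = "e01") {
    cent <- labelMap$centroids
    if (nrow(cent) == 0L) stop("label map contains no nuclei")
    nF <- length(time)
    nNuc <- nrow(cent)
    H <- nrow(labelMap$labels); W <- ncol(labelMap$labels)
    sig <- array(0, dim = c(nF, nNuc, length(channels)),
                 dimnames = list(NULL, NULL, channels))
    dropped <- 0L
    if (nrow(spots)) {
        ri <- pmin(pmax(round(spots$y) + 1L, 1L), H)
        ci <- pmin(pmax(round(spots$x) + 1L, 1L), W)
        lab <- labelMap$labels[cbind(ri, ci)]
        for (i in seq_len(nrow(spots))) {
            l <- lab[i]
            if (l == 0L) {
                d2 <- (cent$x - spots$x[i])^2 + (cent$y - spots$y[i])^2
                j <- which.min(d2)
                if (sqrt(d2[j]) <= maxDistance) l <- cent$label[j]
            }
            if (l == 0L) { dropped <- dropped + 1L; next }
            ch <- as.character(spots$channel[i])
            if (!ch %in% channels) next
            f <- spots$frame[i]
            nIdx <- match(l, cent$label)
            if (spots$intensity[i] > sig[f, nIdx, ch])
                sig[f, nIdx, ch] <- spots$intensity[i]
        }
    }
    if (dropped > 0L)
        message(dropped, " spot(s) dropped: outside all nuclei beyond ",
                maxDistance, " px")
    mat <- matrix(0, nF, nNuc * length(channels))
    for (c_ in seq_along(channels))
        mat[, (c_ - 1L) * nNuc + seq_len(nNuc)] <- sig[, , c_]
    info <- S4Vectors::DataFrame(
        embryo_id = embryoId,
        nucleus_id = rep(sprintf("n%04d", cent$label), length(channels)),
        dv_position = rep(pmin(pmax(cent$x / max(W - 1, 1), 0), 1),
                          length(channels)),
        channel = rep(channels, each = nNuc))
    rownames(info) <- paste(info$embryo_id, info$nucleus_id, info$channel,
                            sep = ".")
    .newTraceSet(mat, rep(nc, nF), time, info)
}

#' Recover traces from a rendered stack
#'
#' Convenience wrapper for the full imaging pipeline on one movie:
#' segments nuclei on the first histone frame (nuclei are static), runs
#' spot detection per frame on the MS2/PP7 channels and assembles a
#' \linkS4class{TraceSet} with \code{\link{extractTraces}}.
#'
#' @param stack array frames x rows x cols x 3 (see
#'   \code{\link{renderMovie}}) or a TIFF path.
#' @param time frame times (min); required when \code{stack} is a file.
#' @param nc nuclear-cycle label.
#' @param channels channels to extract (\code{"MS2"} is channel 2,
#'   \code{"PP7"} channel 3).
#' @param detectParams list of arguments passed to
#'   \code{\link{detectSpots}}.
#' @param ... passed to \code{\link{extractTraces}}.
#' @return A \linkS4class{TraceSet}.
#' @examples
#' cfg <- scenarioPreset("control_chr3_hemi")
#' cfg@nucleiGrid <- c(2L, 3L); cfg@nc14Duration <- 3
#' mv <- renderMovie(simulateEmbryo(cfg, 1), nc = "NC14")
#' ts <- extractFromStack(mv$stack, time = mv$time)
#' @export
extractFromStack <- function(stack, time, nc = "NC14",
                             channels = c("MS2"),
                             detectParams = list(), ...) {
    if (is.character(stack)) stack <- readStack(stack)
    labelMap <- segmentNuclei(stack[1, , , 1])
    chanOf <- c(MS2 = 2L, PP7 = 3L)
    allSpots <- list()
    for (ch in channels) {
        for (f in seq_len(dim(stack)[1])) {
            sp <- do.call(detectSpots,
                          c(list(frame = stack[f, , , chanOf[[ch]]],
                                 channel = ch), detectParams))
            if (nrow(sp)) { sp$frame <- f; allSpots[[length(allSpots) + 1L]] <- sp }
        }
    }
    spots <- if (length(allSpots)) do.call(rbind, allSpots)
             else data.frame(frame = integer(), channel = character(),
                             x = numeric(), y = numeric(),
                             intensity = numeric())
    extractTraces(spots, labelMap, time, nc = nc, channels = channels, ...)
}
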