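#' Rendering optics
#'
#' Parameters of the synthetic microscope used by \code{\link{renderMovie}}.
#'
#' @param nucleusRadius nucleus radius (px).
#' @param spacing centre-to-centre nucleus spacing (px); must exceed
#'   \code{2 * nucleusRadius} or rendering refuses (overlapping nuclei).
#' @param spotSigma Gaussian sigma of a transcription spot (px).
#' @param background camera background level (counts).
#' @param cameraNoiseSd Gaussian camera noise sd (counts).
#' @param gain integrated spot counts per arbitrary fluorescence unit.
#' @param nucleusLevel peak nucleus brightness above background (counts).
#' @return A named list of optics parameters.
#' @examples
#' RenderOptics(spotSigma = 2)
#' @export
RenderOptics <- function(nucleusRadius = 9, spacing = 24, spotSigma = 1.5,
                         background = 100, cameraNoiseSd = 4, gain = 4,
                         nucleusLevel = 300) {
    list(nucleusRadius = nucleusRadius, spacing = spacing,
         spotSigma = spotSigma, background = background,
         cameraNoiseSd = cameraNoiseSd, gain = gain,
         nucleusLevel = nucleusLevel)
}

.gaussianSpot <- function(img, cx, cy, sigma, total) {
    # add a 2-D Gaussian with integrated intensity `total` at (cx, cy)
    # (0-based pixel-centre coordinates)
    r <- ceiling(4 * sigma)
    xs <- floor(cx - r):ceiling(cx + r)
    ys <- floor(cy - r):ceiling(cy + r)
    xs <- xs[xs >= 0 & xs < ncol(img)]
    ys <- ys[ys >= 0 & ys < nrow(img)]
    if (!length(xs) || !length(ys)) return(img)
    gx <- exp(-((xs - cx)^2) / (2 * sigma^2))
    gy <- exp(-((ys - cy)^2) / (2 * sigma^2))
    patch <- outer(gy, gx) * (total / (2 * pi * sigma^2))
    img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + patch
    img
}

#' Render a trace set as a synthetic three-channel movie
#'
#' Produces a 2-D time-lapse emulating the live-imaging data the
#' quantification pipeline consumes: channel 1 shows nuclei as filled disks
#' (histone marker), channels 2 and 3 one Gaussian spot per active MS2 /
#' PP7 locus, with integrated spot intensity proportional to the trace
#' signal at that frame, plus camera background and Gaussian noise.  Each
#' locus keeps a fixed position inside its nucleus across frames.  A
#' ground-truth sidecar lists every reporter locus per frame with its true
#' centre and intensity.
#'
#' @param x a \linkS4class{TraceSet}.
#' @param nc nuclear cycle to render.
#' @param embryo embryo id to render (default: first).
#' @param optics a \code{\link{RenderOptics}} list.
#' @param file optional TIFF path; the stack is written frame by frame as
#'   16-bit RGB pages (time-channel-y-x order).
#' @param seed seed for locus placement and camera noise.
#' @return A list with \code{stack} (array frames x rows x cols x 3,
#'   counts), \code{sidecar} (data.frame: frame, channel, embryo_id,
#'   nucleus_id, x, y, signal_au, intensity_counts), \code{centers}
#'   (nucleus centres, 0-based px), \code{optics}, and the frame
#'   \code{time} vector.
#' @examples
#' cfg <- scenarioPreset("control_chr3_hemi")
#' cfg@nucleiGrid <- c(2L, 3L); cfg@nc14Duration <- 3
#' mv <- renderMovie(simulateEmbryo(cfg, 1), nc = "NC14")
#' dim(mv$stack)
#' @export
renderMovie <- function(x, nc = "NC14", embryo = NULL,
                        optics = RenderOptics(), file = NULL, seed = 1L) {
    stopifnot(is(x, "TraceSet"))
    cd <- traceInfo(x)
    if (is.null(embryo)) embryo <- cd$embryo_id[1]
    x <- x[, cd$embryo_id == embryo]
    cd <- traceInfo(x)
    cfg <- metadata(x)$config
    if (is.null(cfg)) stop("TraceSet carries no ScenarioConfig metadata")
    if (optics$spacing <= 2 * optics$nucleusRadius)
        stop("nuclei would overlap at the requested density ",
             "(spacing <= 2 * nucleusRadius)")
    sig <- traceSignal(x, nc = nc)
    tim <- traceTime(x, nc = nc)
    nF <- length(tim)

    rows <- cfg@nucleiGrid[1]; cols <- cfg@nucleiGrid[2]
    sp <- optics$spacing; rad <- optics$nucleusRadius
    H <- rows * sp; W <- cols * sp
    nucIdx <- as.integer(sub("^n", "", cd$nucleus_id))
    # lattice is column-major: nucleus k sits at (row, col)
    nRow <- (nucIdx - 1L) %% rows
    nCol <- (nucIdx - 1L) %/% rows
    cxAll <- (nCol + 0.5) * sp - 0.5
    cyAll <- (nRow + 0.5) * sp - 0.5

    set.seed(seed)
    # fixed locus offset inside each nucleus, one per trace
    ang <- runif(ncol(x), 0, 2 * pi)
    rr <- runif(ncol(x), 0, 0.5 * rad)
    lx <- cxAll + rr * cos(ang)
    ly <- cyAll + rr * sin(ang)

    nucFrame <- matrix(0, H, W)
    for (k in unique(nucIdx)) {
        i <- which(nucIdx == k)[1]
        yy <- pmax(0, floor(cyAll[i] - rad)):pmin(H - 1, ceiling(cyAll[i] + rad))
        xx <- pmax(0, floor(cxAll[i] - rad)):pmin(W - 1, ceiling(cxAll[i] + rad))
        d2 <- outer((yy - cyAll[i])^2, (xx - cxAll[i])^2, "+")
        patch <- nucFrame[yy + 1L, xx + 1L]
        patch[d2 <= rad^2] <- optics$nucleusLevel
        nucFrame[yy + 1L, xx + 1L] <- patch
    }

    chanOf <- c(MS2 = 2L, PP7 = 3L)
    stack <- array(0, dim = c(nF, H, W, 3))
    sidecar <- vector("list", nF)
    for (f in seq_len(nF)) {
        frames <- list(nucFrame, matrix(0, H, W), matrix(0, H, W))
        rows_f <- data.frame(frame = integer(), channel = character(),
                             embryo_id = character(), nucleus_id = character(),
                             x = numeric(), y = numeric(),
                             signal_au = numeric(),
                             intensity_counts = numeric())
        for (j in seq_len(ncol(x))) {
            s <- max(sig[f, j], 0)
            ch <- chanOf[[cd$channel[j]]]
            if (s > 0)
                frames[[ch]] <- .gaussianSpot(frames[[ch]], lx[j], ly[j],
                                              optics$spotSigma,
                                              s * optics$gain)
            rows_f <- rbind(rows_f, data.frame(
                frame = f, channel = cd$channel[j],
                embryo_id = cd$embryo_id[j], nucleus_id = cd$nucleus_id[j],
                x = lx[j], y = ly[j], signal_au = sig[f, j],
                intensity_counts = s * optics$gain))
        }
        for (ch in 1:3)
            stack[f, , , ch] <- frames[[ch]] + optics$background +
                matrix(rnorm(H * W, 0, optics$cameraNoiseSd), H, W)
        sidecar[[f]] <- rows_f
    }
    sidecar <- do.call(rbind, sidecar)
    out <- list(stack = stack, sidecar = sidecar,
                centers = data.frame(nucleus_id = cd$nucleus_id,
                                     x = cxAll, y = cyAll),
                optics = optics, time = tim, nc = nc)
    if (!is.null(file)) {
        writeStack(stack, file)
        utils::write.csv(sidecar, paste0(tools::file_path_sans_ext(file),
                                         "_sidecar.csv"), row.names = FALSE)
    }
    out
}

#' Write / read a rendered stack as 16-bit multi-page TIFF
#'
#' Each frame is stored as one RGB page (rows x cols x 3), so the file is
#' in time-channel-y-x order when read plane-wise.  Counts are clipped to
#' [0, 65535].
#'
#' @param stack array frames x rows x cols x 3 (counts).
#' @param file TIFF path.
#' @return \code{writeStack}: \code{file}, invisibly. \code{readStack}: the
#'   stack array in counts.
#' @examples
#' f <- tempfile(fileext = ".tiff")
#' writeStack(array(1000, c(2, 8, 8, 3)), f)
#' dim(readStack(f))
#' @export
writeStack <- function(stack, file) {
    pages <- lapply(seq_len(dim(stack)[1]), function(f)
        pmin(pmax(stack[f, , , , drop = TRUE] / 65535, 0), 1))
    tiff::writeTIFF(pages, file, bits.per.sample = 16L,
                    compression = "none")
    invisible(file)
}

#' @rdname writeStack
#' @export
readStack <- function(file) {
    pages <- tiff::readTIFF(file, all = TRUE)
    stack <- array(0, dim = c(length(pages), dim(pages[[1]])))
    for (f in seq_along(pages)) stack[f, , , ] <- pages[[f]]
    stack * 65535
}
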