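#' @describeIn TraceSet-class compact display.
#' @param object a \linkS4class{TraceSet}.
#' @export
setMethod("show", "TraceSet", function(object) {
    cd <- colData(object)
    cfg <- metadata(object)$config
    cat("TraceSet:", ncol(object), "traces x", nrow(object), "frames\n")
    if (!is.null(cfg))
        cat("  scenario:", cfg@scenarioName, paste0("(", cfg@genotype, ")"),
            "\n")
    cat("  embryos:", length(unique(cd$embryo_id)),
        "| nuclei:", length(unique(paste(cd$embryo_id, cd$nucleus_id))),
        "| channels:", paste(unique(cd$channel), collapse = ", "), "\n")
    cat("  cycles:", paste(unique(rowData(object)$nc), collapse = ", "),
        "| assays:", paste(assayNames(object), collapse = ", "), "\n")
})

#' Trace accessors
#'
#' \code{traceSignal} returns the frames x traces fluorescence matrix,
#' \code{traceTime} the frame times (minutes since the cycle onset),
#' \code{traceNC} the nuclear-cycle label per frame, and \code{traceInfo}
#' the per-trace metadata (colData).
#'
#' @param x a \linkS4class{TraceSet}.
#' @param nc optionally restrict to one nuclear cycle
#'   (\code{"NC13"}/\code{"NC14"}).
#' @return See description.
#' @examples
#' cfg <- scenarioPreset("control_chr3_hemi")
#' cfg@nucleiGrid <- c(2L, 4L); cfg@nc14Duration <- 4
#' ts <- simulateEmbryo(cfg, 1)
#' dim(traceSignal(ts, nc = "NC14"))
#' @export
traceSignal <- function(x, nc = NULL) {
    assay(ncWindow(x, nc), "signal")
}

#' @rdname traceSignal
#' @export
traceTime <- function(x, nc = NULL) {
    rowData(ncWindow(x, nc))$time
}

#' @rdname traceSignal
#' @export
traceNC <- function(x) rowData(x)$nc

#' @rdname traceSignal
#' @export
traceInfo <- function(x) colData(x)

#' @rdname traceSignal
#' @export
ncWindow <- function(x, nc = NULL) {
    if (is.null(nc)) return(x)
    nc <- match.arg(nc, c("NC13", "NC14"))
    x[rowData(x)$nc == nc, ]
}
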