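.traceCols <- c("embryo_id", "nucleus_id", "dv_position", "channel",
                "nc_label", "time_min", "signal_au")

.fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a trace table
#'
#' Traces travel as long-format delimited text: one row per frame with
#' columns \code{embryo_id, nucleus_id, dv_position, channel, nc_label,
#' time_min, signal_au} plus, when ground truth is present,
#' \code{pol_count, promoter_state, true_onset_min}.  Numeric columns are
#' written with 17 significant digits so the round trip is lossless at
#' double precision.  \code{readTraces} accepts arbitrary row order
#' (a canonical sort by embryo, nucleus, channel, cycle and time is applied)
#' and reports schema violations with the offending row.
#'
#' @param x a \linkS4class{TraceSet}.
#' @param path CSV file path.
#' @return \code{writeTraces} returns \code{path} invisibly;
#'   \code{readTraces} returns a \linkS4class{TraceSet}.
#' @examples
#' cfg <- scenarioPreset("control_chr3_hemi")
#' cfg@nucleiGrid <- c(1L, 4L); cfg@nc14Duration <- 4
#' ts <- simulateEmbryo(cfg, 1)
#' f <- tempfile(fileext = ".csv")
#' writeTraces(ts, f)
#' ts2 <- readTraces(f)
#' @export
writeTraces <- function(x, path) {
    stopifnot(is(x, "TraceSet"))
    cd <- traceInfo(x)
    nF <- nrow(x); nT <- ncol(x)
    truth <- all(c("polCount", "promoterState") %in% assayNames(x))
    ncl <- traceNC(x); tim <- rowData(x)$time
    df <- data.frame(
        embryo_id = rep(cd$embryo_id, each = nF),
        nucleus_id = rep(cd$nucleus_id, each = nF),
        dv_position = .fmt17(rep(cd$dv_position, each = nF)),
        channel = rep(cd$channel, each = nF),
        nc_label = rep(ncl, nT),
        time_min = .fmt17(rep(tim, nT)),
        signal_au = .fmt17(as.vector(assay(x, "signal"))),
        stringsAsFactors = FALSE)
    if (truth) {
        df$pol_count <- as.vector(assay(x, "polCount"))
        df$promoter_state <- as.vector(assay(x, "promoterState"))
        on13 <- cd$true_onset_nc13; on14 <- cd$true_onset_nc14
        onset <- ifelse(rep(ncl, nT) == "NC13",
                        rep(on13, each = nF), rep(on14, each = nF))
        df$true_onset_min <- .fmt17(onset)
    }
    if (requireNamespace("data.table", quietly = TRUE))
        data.table::fwrite(df, path, quote = FALSE)
    else
        utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeTraces
#' @export
readTraces <- function(path) {
    df <- if (requireNamespace("data.table", quietly = TRUE))
        as.data.frame(data.table::fread(path, colClasses = list(
            character = c("embryo_id", "nucleus_id", "channel", "nc_label"))))
    else utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(embryo_id = "character",
                                        nucleus_id = "character",
                                        channel = "character",
                                        nc_label = "character"))
    missing <- setdiff(.traceCols, colnames(df))
    if (length(missing))
        stop("trace file is missing required column(s): ",
             paste(missing, collapse = ", "))
    key <- paste(df$embryo_id, df$nucleus_id, df$channel, sep = ".")
    o <- order(key, df$nc_label, df$time_min)
    df <- df[o, , drop = FALSE]
    key <- key[o]
    ids <- unique(key)
    nper <- table(key)
    if (length(unique(nper)) != 1L)
        stop("trace file is truncated or ragged: trace '",
             names(nper)[which.min(nper)], "' has ", min(nper),
             " rows where others have ", max(nper))
    nF <- as.integer(nper[1])
    first <- df[key == ids[1], , drop = FALSE]
    grid <- paste(first$nc_label, .fmt17(first$time_min))
    if (!all(paste(df$nc_label, .fmt17(df$time_min)) ==
             rep(grid, length(ids))))
        stop("traces do not share a common (nc_label, time_min) frame grid")
    for (id in ids[c(1L, length(ids))]) {
        sub <- df[key == id, , drop = FALSE]
        for (nc in unique(sub$nc_label)) {
            tt <- sub$time_min[sub$nc_label == nc]
            bad <- which(diff(tt) <= 0)
            if (length(bad))
                stop("non-monotone time in trace '", id, "' (", nc,
                     ") at row ", bad[1] + 1L, " of that trace")
        }
    }
    sig <- matrix(df$signal_au, nrow = nF)
    firstRows <- df[!duplicated(key), , drop = FALSE]
    info <- S4Vectors::DataFrame(
        embryo_id = firstRows$embryo_id,
        nucleus_id = firstRows$nucleus_id,
        dv_position = firstRows$dv_position,
        channel = firstRows$channel)
    if ("parent_of_origin" %in% colnames(df))
        info$parent_of_origin <- firstRows$parent_of_origin
    truth <- all(c("pol_count", "promoter_state") %in% colnames(df))
    pol <- prom <- NULL
    if (truth) {
        pol <- matrix(as.integer(df$pol_count), nrow = nF)
        prom <- matrix(as.integer(df$promoter_state), nrow = nF)
        if ("true_onset_min" %in% colnames(df)) {
            for (nc in unique(df$nc_label)) {
                dd <- df[df$nc_label == nc, , drop = FALSE]
                kk <- paste(dd$embryo_id, dd$nucleus_id, dd$channel,
                            sep = ".")
                firstNc <- dd[!duplicated(kk), , drop = FALSE]
                info[[paste0("true_onset_",
                             tolower(nc))]] <- firstNc$true_onset_min
            }
        }
    }
    rownames(info) <- ids
    ts <- .newTraceSet(sig, first$nc_label, first$time_min, info,
                       polCount = pol, promoterState = prom)
    validObject(ts)
    ts
}

#' Run the simulation-to-comparison pipeline
#'
#' Executes the requested stages for a set of named scenario presets under
#' a single root seed, writing all artifacts beneath \code{outDir}:
#' trace CSVs (\code{simulate}), per-nucleus metrics and cumulative
#' activation curves (\code{quantify}), dorsoventral profiles
#' (\code{spatial}), and hemizygous-vs-homozygous comparison reports
#' (\code{compare}, CSV + JSON).  Per-scenario seeds are derived from the
#' root seed by a fixed offset, so re-running with the same arguments
#' reproduces identical trace CSVs byte for byte.
#'
#' @param scenarios character vector of preset names
#'   (see \code{\link{scenarioPreset}}).
#' @param stages subset of \code{c("simulate", "quantify", "spatial",
#'   "compare")}, executed in that order.
#' @param outDir output directory (created if absent).
#' @param seed root seed.
#' @param nEmbryos optional replicate-count override applied to every
#'   scenario.
#' @return A run-manifest list (scenario names, config hashes, seeds,
#'   artifact paths, package version, timestamp), also written to
#'   \code{manifest.json}, invisibly.
#' @examples
#' td <- tempfile(); dir.create(td)
#' runPipeline("control_chr3_hemi", stages = c("simulate", "quantify"),
#'             outDir = td, seed = 1, nEmbryos = 1)
#' @export
runPipeline <- function(scenarios,
                        stages = c("simulate", "quantify", "compare"),
                        outDir, seed = 20220711L, nEmbryos = NULL) {
    known <- c("simulate", "quantify", "spatial", "compare")
    bad <- setdiff(stages, known)
    if (length(bad))
        stop("unknown stage(s): ", paste(bad, collapse = ", "))
    stages <- known[known %in% stages]
    bad <- setdiff(scenarios, .presetNames)
    if (length(bad))
        stop("unknown scenario(s): ", paste(bad, collapse = ", "))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    artifacts <- list()
    hashes <- list()
    metricsAll <- list()
    gridAll <- list()

    for (i in seq_along(scenarios)) {
        sc <- scenarios[i]
        scSeed <- as.integer(seed) + 10000L *
            (match(sc, .presetNames) - 1L)
        cfg <- scenarioPreset(sc, nEmbryos = nEmbryos, seed = scSeed)
        cfgPath <- file.path(outDir, paste0(sc, "_config.yaml"))
        writeScenario(cfg, cfgPath)
        hashes[[sc]] <- unname(tools::md5sum(cfgPath))
        tracePath <- file.path(outDir, paste0(sc, "_traces.csv"))
        if ("simulate" %in% stages) {
            ts <- simulateScenario(cfg)
            writeTraces(ts, tracePath)
            message(sprintf("[simulate] %s: %d nuclei x %d embryos -> %s",
                            sc, prod(cfg@nucleiGrid), cfg@nEmbryos,
                            basename(tracePath)))
            artifacts[[paste0(sc, "_traces")]] <- tracePath
        }
        if (any(c("quantify", "spatial", "compare") %in% stages)) {
            if (!file.exists(tracePath))
                stop("stage 'quantify' requires traces for '", sc,
                     "'; run the 'simulate' stage first")
            ts <- readTraces(tracePath)
            m <- traceMetrics(ts, nc = "NC14")
            metricsAll[[sc]] <- m
            gridAll[[sc]] <- cfg@nucleiGrid
            if ("quantify" %in% stages) {
                mPath <- file.path(outDir, paste0(sc, "_metrics_nc14.csv"))
                utils::write.csv(as.data.frame(m), mPath, row.names = FALSE)
                cum <- cumulativeActiveFraction(m, traceTime(ts, "NC14"))
                cPath <- file.path(outDir, paste0(sc, "_cumulative.csv"))
                utils::write.csv(cum, cPath, row.names = FALSE)
                message(sprintf("[quantify] %s: %d traces quantified (%d active)",
                                sc, nrow(m), sum(m$is_active)))
                artifacts[[paste0(sc, "_metrics")]] <- mPath
                artifacts[[paste0(sc, "_cumulative")]] <- cPath
            }
            if ("spatial" %in% stages) {
                pr <- dvProfile(m, channel = "MS2")
                pPath <- file.path(outDir, paste0(sc, "_dv_profile.csv"))
                utils::write.csv(pr, pPath, row.names = FALSE)
                hPath <- file.path(outDir, paste0(sc, "_heatmap.png"))
                e1 <- m[m$embryo_id == m$embryo_id[1] & m$channel == "MS2", ]
                productionHeatmap(e1, grid = cfg@nucleiGrid, file = hPath)
                message(sprintf("[spatial] %s: profile + heatmap written", sc))
                artifacts[[paste0(sc, "_profile")]] <- pPath
            }
        }
    }

    if ("compare" %in% stages) {
        pairs <- list(c("control_chr3_hemi", "control_chr3_hom"),
                      c("weak_chr2_hemi", "weak_chr2_hom"),
                      c("distal_enhancer_hemi", "distal_enhancer_hom"),
                      c("endogenous_sna_hemi", "endogenous_sna_hom"))
        rows <- list()
        for (p in pairs) {
            if (!all(p %in% names(metricsAll))) next
            ref <- metricsAll[[p[1]]]
            tst <- metricsAll[[p[2]]]
            ref <- ref[ref$channel == "MS2" &
                       ref$dv_position < 0.5, , drop = FALSE]
            tst <- tst[tst$channel == "MS2" &
                       tst$dv_position < 0.5, , drop = FALSE]
            cmp <- percentReduction(ref$total_production,
                                    tst$total_production,
                                    ref$embryo_id, tst$embryo_id,
                                    labels = p, seed = as.integer(seed))
            message(sprintf("[compare] %s vs %s: %.1f%% reduction",
                            p[2], p[1], cmp@percentReduction))
            rows[[paste(p, collapse = "_vs_")]] <- as.data.frame(cmp)
        }
        if (length(rows)) {
            rep <- do.call(rbind, rows)
            cPath <- file.path(outDir, "comparisons.csv")
            utils::write.csv(rep, cPath, row.names = FALSE)
            jsonlite::write_json(rep, file.path(outDir, "comparisons.json"),
                                 dataframe = "rows", auto_unbox = TRUE,
                                 digits = NA)
            artifacts$comparisons <- cPath
        }
    }

    manifest <- list(scenarios = scenarios, stages = stages,
                     root_seed = as.integer(seed),
                     config_hash = hashes, artifacts = artifacts,
                     package_version =
                         as.character(utils::packageVersion("alleleHub")),
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
}
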