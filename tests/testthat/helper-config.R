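suppressMessages(library(SummarizedExperiment))

# Small configurations for fast unit tests.

tinyConfig <- function(name = "control_chr3_hemi", rows = 2L, cols = 6L,
                       nc13 = 4, nc14 = 8, seed = 101L, ...) {
    cfg <- scenarioPreset(name, seed = seed, ...)
    cfg@nucleiGrid <- c(as.integer(rows), as.integer(cols))
    cfg@nc13Duration <- nc13
    cfg@nc14Duration <- nc14
    cfg
}

domainMS2 <- function(m) m[m$dv_position < 0.5 & m$channel == "MS2", ,
                           drop = FALSE]
activeOnly <- function(m) m[m$is_active, , drop = FALSE]
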