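#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @import SummarizedExperiment
NULL

#' Telegraph promoter parameters
#'
#' Two-state (ON/OFF) promoter kinetics together with the dorsoventral
#' modulation of the switching-on rate.  The ON-switching rate at
#' dorsoventral coordinate \code{x} is
#' \code{kOnMax / (1 + exp(steepness * (x - xBoundary)))}, a logistic
#' profile mimicking the ventral-to-dorsal Dorsal activator gradient that
#' sets the \emph{snail} expression domain.
#'
#' @slot kOnMax maximal OFF-to-ON switching rate at the ventral midline
#'   (1/min).
#' @slot kOff ON-to-OFF switching rate (1/min).
#' @slot kLoad Pol II initiation-attempt rate while the promoter is ON
#'   (1/min).  Attempts succeed only when the shared hub pool has a free
#'   unit.
#' @slot vEl elongation speed (kb/min).
#' @slot xBoundary dorsoventral coordinate of the expression-domain
#'   boundary; dimensionless, 0 = ventral midline, 1 = dorsal midline.
#' @slot steepness dimensionless logistic slope of the boundary.
#' @export
setClass("TelegraphParams",
    representation(
        kOnMax    = "numeric",
        kOff      = "numeric",
        kLoad     = "numeric",
        vEl       = "numeric",
        xBoundary = "numeric",
        steepness = "numeric"
    )
)

setValidity("TelegraphParams", function(object) {
    msg <- character()
    num1 <- function(x) length(x) == 1L && is.finite(x)
    for (s in c("kOnMax", "kOff", "kLoad", "vEl", "steepness"))
        if (!num1(slot(object, s)) || slot(object, s) < 0)
            msg <- c(msg, sprintf("'%s' must be a single nonnegative number", s))
    if (!num1(object@xBoundary) || object@xBoundary <= 0 || object@xBoundary >= 1)
        msg <- c(msg, "'xBoundary' must lie strictly inside (0, 1)")
    if (length(msg)) msg else TRUE
})

#' Shared hub pool parameters
#'
#' A nucleus holds one local transcription hub: a finite pool of initiating
#' Pol II / PIC units shared by both homologous alleles and by a background
#' demand standing in for all the other zygotic genes activated in that
#' nuclear cycle.  Each successful draw occupies one unit for the duration
#' of its engagement (gene transit for a reporter allele, a fixed dwell for
#' background and sequestering partners) and then returns it to the pool.
#' The background-demand rate is constant in NC13 and ramps linearly across
#' NC14 between the two configured endpoints, reflecting the far larger
#' cohort of genes activated as NC14 progresses.
#'
#' @slot capacity number of Pol II units in the hub pool (>= 1).
#' @slot replenishRate rate at which fresh units arrive from the
#'   nucleoplasm (units/min); arrivals beyond \code{capacity} are discarded.
#' @slot bgDemandNC13 background initiation-attempt rate during NC13
#'   (units/min).
#' @slot bgDemandNC14Start background attempt rate at NC14 onset
#'   (units/min).
#' @slot bgDemandNC14End background attempt rate at the end of NC14
#'   (units/min); the rate ramps linearly between the two.
#' @slot bgDwell time a background draw occupies a unit (min).
#' @export
setClass("HubParams",
    representation(
        capacity         = "numeric",
        replenishRate    = "numeric",
        bgDemandNC13     = "numeric",
        bgDemandNC14Start = "numeric",
        bgDemandNC14End  = "numeric",
        bgDwell          = "numeric"
    )
)

setValidity("HubParams", function(object) {
    msg <- character()
    num1 <- function(x) length(x) == 1L && is.finite(x)
    if (!num1(object@capacity) || object@capacity < 1)
        msg <- c(msg, "'capacity' must be >= 1")
    for (s in c("replenishRate", "bgDemandNC13", "bgDemandNC14Start",
                "bgDemandNC14End", "bgDwell"))
        if (!num1(slot(object, s)) || slot(object, s) < 0)
            msg <- c(msg, sprintf("'%s' must be a single nonnegative number", s))
    if (num1(object@bgDemandNC14End) && num1(object@bgDemandNC14Start) &&
        object@bgDemandNC14End < object@bgDemandNC14Start)
        msg <- c(msg, "'bgDemandNC14End' must be >= 'bgDemandNC14Start'")
    if (length(msg)) msg else TRUE
})

#' One allele of a nucleus
#'
#' Describes one transgene (or endogenous locus) on one homolog: the
#' fluorescence channel reporting it, whether it is a full transcription
#' unit or a partial one (enhancer only / promoter only), the reporter-gene
#' geometry seen by elongating Pol II, and its promoter kinetics.  Partial
#' constructs carry no stem-loop cassette and produce no signal; they engage
#' hub units at \code{sequesterRate}, holding each for
#' \code{sequesterDwell} minutes, modelling Pol II/PIC recruitment to a
#' transcribed enhancer (eRNA production) or to an enhancerless promoter.
#'
#' @slot channel one of \code{"MS2"}, \code{"PP7"}, \code{"none"}.
#' @slot construct one of \code{"full"}, \code{"enhancer_only"},
#'   \code{"promoter_only"}.
#' @slot geneLength reporter transcription-unit length (kb).
#' @slot loopStart position of the stem-loop cassette start, kb from the
#'   TSS.
#' @slot loopLength cassette length (kb); fluorescence per Pol II ramps
#'   linearly from 0 to one unit across the cassette.
#' @slot telegraph a \linkS4class{TelegraphParams}.
#' @slot sequesterRate hub-draw attempt rate of a partial construct
#'   (attempts/min).
#' @slot sequesterDwell time a partial construct holds a drawn unit (min).
#' @slot parentOfOrigin \code{"maternal"} or \code{"paternal"}.
#' @export
setClass("AlleleSpec",
    representation(
        channel        = "character",
        construct      = "character",
        geneLength     = "numeric",
        loopStart      = "numeric",
        loopLength     = "numeric",
        telegraph      = "TelegraphParams",
        sequesterRate  = "numeric",
        sequesterDwell = "numeric",
        parentOfOrigin = "character"
    )
)

setValidity("AlleleSpec", function(object) {
    msg <- character()
    if (!object@channel %in% c("MS2", "PP7", "none"))
        msg <- c(msg, "'channel' must be \"MS2\", \"PP7\" or \"none\"")
    if (!object@construct %in% c("full", "enhancer_only", "promoter_only"))
        msg <- c(msg, "'construct' must be \"full\", \"enhancer_only\" or \"promoter_only\"")
    if (object@construct != "full" && object@channel != "none")
        msg <- c(msg, "partial constructs carry no stem-loop cassette: 'channel' must be \"none\"")
    if (!(object@loopStart >= 0 &&
          object@loopStart + object@loopLength <= object@geneLength &&
          object@loopLength > 0))
        msg <- c(msg, "need 0 <= loopStart < loopStart + loopLength <= geneLength")
    if (object@sequesterRate < 0 || object@sequesterDwell < 0)
        msg <- c(msg, "'sequesterRate' and 'sequesterDwell' must be >= 0")
    if (!object@parentOfOrigin %in% c("maternal", "paternal"))
        msg <- c(msg, "'parentOfOrigin' must be \"maternal\" or \"paternal\"")
    if (length(msg)) msg else TRUE
})

#' A virtual-embryo experiment
#'
#' Everything needed to simulate one genotype end to end: the alleles
#' present at the homologous locus, the hub pool, the nuclear grid, nuclear
#' cycle durations, imaging cadence, measurement noise and the root seed.
#'
#' @slot scenarioName label used in file names and reports.
#' @slot genotype one of \code{"hemizygous"}, \code{"homozygous"},
#'   \code{"enhancer_only_partner"}, \code{"promoter_only_partner"}.
#' @slot constructClass one of \code{"control_chr3"}, \code{"weak_chr2"},
#'   \code{"distal_enhancer"}, \code{"endogenous_sna"}.
#' @slot alleles list of \linkS4class{AlleleSpec} (length 1 or 2).
#' @slot nEmbryos number of biological-replicate embryos.
#' @slot nucleiGrid integer \code{c(rows, cols)}; columns span the
#'   dorsoventral axis.
#' @slot frameInterval imaging interval (seconds).
#' @slot nc13Duration,nc14Duration interphase durations (minutes).
#' @slot hub a \linkS4class{HubParams}.
#' @slot noiseSd additive Gaussian measurement noise (arbitrary
#'   fluorescence units).
#' @slot unitIntensity fluorescence of one Pol II past the full cassette
#'   (arbitrary units).
#' @slot seed root random seed for the scenario; per-embryo streams are
#'   derived from it by a fixed offset.
#' @export
setClass("ScenarioConfig",
    representation(
        scenarioName  = "character",
        genotype      = "character",
        constructClass = "character",
        alleles       = "list",
        nEmbryos      = "integer",
        nucleiGrid    = "integer",
        frameInterval = "numeric",
        nc13Duration  = "numeric",
        nc14Duration  = "numeric",
        hub           = "HubParams",
        noiseSd       = "numeric",
        unitIntensity = "numeric",
        seed          = "integer"
    )
)

setValidity("ScenarioConfig", function(object) {
    msg <- character()
    al <- object@alleles
    if (!all(vapply(al, is, logical(1), "AlleleSpec")))
        return("'alleles' must be a list of AlleleSpec objects")
    chans <- vapply(al, function(a) a@channel, character(1))
    cons  <- vapply(al, function(a) a@construct, character(1))
    gt <- object@genotype
    if (!gt %in% c("hemizygous", "homozygous",
                   "enhancer_only_partner", "promoter_only_partner"))
        msg <- c(msg, "unknown 'genotype'")
    else if (gt == "hemizygous") {
        if (!(length(al) == 1L && cons == "full" && chans %in% c("MS2", "PP7")))
            msg <- c(msg, "hemizygous: exactly one full reporter allele with an MS2 or PP7 channel")
    } else if (gt == "homozygous") {
        if (!(length(al) == 2L && all(cons == "full") &&
              setequal(chans, c("MS2", "PP7"))))
            msg <- c(msg, "homozygous: two full reporter alleles with distinct channels (MS2 + PP7)")
    } else {
        partner <- sub("_partner$", "", gt)
        ok <- length(al) == 2L && sum(cons == "full") == 1L &&
            any(cons == partner) &&
            chans[cons == "full"] %in% c("MS2", "PP7")
        if (!ok)
            msg <- c(msg, sprintf("%s: one full reporter allele plus one %s partner", gt, partner))
    }
    if (!object@constructClass %in% c("control_chr3", "weak_chr2",
                                      "distal_enhancer", "endogenous_sna"))
        msg <- c(msg, "unknown 'constructClass'")
    if (length(object@nucleiGrid) != 2L || any(object@nucleiGrid < 1L))
        msg <- c(msg, "'nucleiGrid' must be two positive integers (rows, cols)")
    for (s in c("frameInterval", "nc13Duration", "nc14Duration"))
        if (slot(object, s) <= 0)
            msg <- c(msg, sprintf("'%s' must be > 0", s))
    if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
    if (object@unitIntensity <= 0) msg <- c(msg, "'unitIntensity' must be > 0")
    if (object@nEmbryos < 1L) msg <- c(msg, "'nEmbryos' must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Set of allele-specific fluorescence traces
#'
#' A \linkS4class{SummarizedExperiment} whose rows are imaging frames
#' (rowData: \code{nc}, the nuclear-cycle label, and \code{time}, minutes
#' since that cycle's onset) and whose columns are traces — one reporter
#' allele in one nucleus of one embryo.  Assays: \code{signal} (arbitrary
#' fluorescence units, always present) and, when ground truth is kept,
#' \code{polCount} (Pol II on the gene) and \code{promoterState} (0/1).
#' colData columns: \code{embryo_id}, \code{nucleus_id}, \code{dv_position},
#' \code{channel}, \code{parent_of_origin}, \code{true_onset_nc13},
#' \code{true_onset_nc14}.  The generating \linkS4class{ScenarioConfig}
#' travels in \code{metadata(x)$config}.
#'
#' @export
setClass("TraceSet", contains = "SummarizedExperiment")

setValidity("TraceSet", function(object) {
    msg <- character()
    rd <- rowData(object)
    cd <- colData(object)
    need_rd <- c("nc", "time")
    need_cd <- c("embryo_id", "nucleus_id", "dv_position", "channel")
    if (!all(need_rd %in% colnames(rd)))
        return("rowData must contain 'nc' and 'time'")
    if (!all(need_cd %in% colnames(cd)))
        return("colData must contain embryo_id, nucleus_id, dv_position, channel")
    if (!"signal" %in% assayNames(object))
        return("assay 'signal' is required")
    for (nc in unique(rd$nc)) {
        tt <- rd$time[rd$nc == nc]
        if (any(diff(tt) <= 0))
            msg <- c(msg, sprintf("time must be strictly increasing within %s", nc))
    }
    if (!all(is.finite(assay(object, "signal"))))
        msg <- c(msg, "signal values must all be finite")
    key <- paste(cd$embryo_id, cd$nucleus_id, cd$channel, sep = "\r")
    if (anyDuplicated(key))
        msg <- c(msg, "duplicate (embryo_id, nucleus_id, channel) trace keys")
    if (any(cd$dv_position < 0 | cd$dv_position > 1))
        msg <- c(msg, "dv_position must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Genotype comparison
#'
#' Effect-size summary of one metric between a reference arm (typically
#' hemizygous) and a test arm (typically one homozygous allele):
#' \code{percentReduction = 100 * (1 - meanTest / meanRef)} from pooled
#' per-nucleus values, with a 95\% confidence interval from resampling
#' embryos (the biological replicates) with replacement.
#'
#' @slot metric name of the compared metric.
#' @slot refLabel,testLabel arm labels.
#' @slot meanRef,meanTest pooled per-nucleus means.
#' @slot percentReduction point estimate (percent).
#' @slot ciLow,ciHigh 95\% bootstrap interval (NA when an arm has a single
#'   embryo).
#' @slot nNuclei,nEmbryos integer \code{c(ref, test)} counts.
#' @export
setClass("GenotypeComparison",
    representation(
        metric           = "character",
        refLabel         = "character",
        testLabel        = "character",
        meanRef          = "numeric",
        meanTest         = "numeric",
        percentReduction = "numeric",
        ciLow            = "numeric",
        ciHigh           = "numeric",
        nNuclei          = "integer",
        nEmbryos         = "integer"
    )
)

setValidity("GenotypeComparison", function(object) {
    msg <- character()
    if (any(object@nNuclei <= 0L)) msg <- c(msg, "empty arm")
    if (is.finite(object@ciLow) && is.finite(object@ciHigh) &&
        (object@percentReduction < object@ciLow ||
         object@percentReduction > object@ciHigh))
        msg <- c(msg, "confidence interval must contain the point estimate")
    if (length(msg)) msg else TRUE
})
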