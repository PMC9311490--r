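#' Construct telegraph promoter parameters
#'
#' Defaults describe the strong \emph{snail} shadow enhancer + core promoter
#' configuration used by the control reporter: near-saturating activation in
#' the ventral domain, long ON bursts, and a high Pol II initiation-attempt
#' rate while ON.
#'
#' @param kOnMax maximal OFF-to-ON rate at the ventral midline (1/min).
#' @param kOff ON-to-OFF rate (1/min).
#' @param kLoad initiation-attempt rate while ON (1/min).
#' @param vEl elongation speed (kb/min).
#' @param xBoundary dorsoventral boundary coordinate in (0, 1).
#' @param steepness logistic slope of the boundary.
#' @return A \linkS4class{TelegraphParams} object.
#' @examples
#' TelegraphParams(kOnMax = 0.3)
#' @export
TelegraphParams <- function(kOnMax = 0.15, kOff = 0.015, kLoad = 56,
                            vEl = 1.8, xBoundary = 0.5, steepness = 30) {
    new("TelegraphParams", kOnMax = kOnMax, kOff = kOff, kLoad = kLoad,
        vEl = vEl, xBoundary = xBoundary, steepness = steepness)
}

#' Construct shared hub pool parameters
#'
#' Defaults give a hub of 400 Pol II units whose background demand is low in
#' NC13 (around 950 zygotic genes active) and ramps up steeply across NC14
#' (around 3,500 genes active), the regime in which the pool becomes
#' limiting for a strong reporter pair.
#'
#' @param capacity Pol II units in the hub.
#' @param replenishRate fresh-unit arrival rate (units/min).
#' @param bgDemandNC13 background attempt rate in NC13 (units/min).
#' @param bgDemandNC14Start,bgDemandNC14End endpoints of the linear NC14
#'   background-demand ramp (units/min).
#' @param bgDwell time a background draw holds a unit (min).
#' @return A \linkS4class{HubParams} object.
#' @examples
#' HubParams(capacity = 50)
#' @export
HubParams <- function(capacity = 400, replenishRate = 0,
                      bgDemandNC13 = 0.6, bgDemandNC14Start = 8,
                      bgDemandNC14End = 12.6, bgDwell = 17) {
    new("HubParams", capacity = capacity, replenishRate = replenishRate,
        bgDemandNC13 = bgDemandNC13, bgDemandNC14Start = bgDemandNC14Start,
        bgDemandNC14End = bgDemandNC14End, bgDwell = bgDwell)
}

#' Construct an allele specification
#'
#' Defaults describe the full MS2-tagged \emph{yellow} reporter: a 6.5 kb
#' transcription unit with a 1.3 kb 24x stem-loop cassette near the 5' end,
#' so fluorescence per Pol II rises quickly after initiation and stays flat
#' until termination.
#'
#' @param channel \code{"MS2"}, \code{"PP7"} or \code{"none"}.
#' @param construct \code{"full"}, \code{"enhancer_only"} or
#'   \code{"promoter_only"}.
#' @param geneLength transcription-unit length (kb).
#' @param loopStart cassette start (kb from TSS).
#' @param loopLength cassette length (kb).
#' @param telegraph a \linkS4class{TelegraphParams}.
#' @param sequesterRate,sequesterDwell hub-draw rate (attempts/min) and
#'   holding time (min) for partial constructs; ignored for \code{"full"}.
#' @param parentOfOrigin \code{"maternal"} or \code{"paternal"}.
#' @return An \linkS4class{AlleleSpec} object.
#' @examples
#' AlleleSpec(channel = "PP7", parentOfOrigin = "maternal")
#' @export
AlleleSpec <- function(channel = "MS2", construct = "full",
                       geneLength = 6.5, loopStart = 0.1, loopLength = 1.3,
                       telegraph = TelegraphParams(),
                       sequesterRate = 0, sequesterDwell = 0,
                       parentOfOrigin = "paternal") {
    new("AlleleSpec", channel = channel, construct = construct,
        geneLength = geneLength, loopStart = loopStart,
        loopLength = loopLength, telegraph = telegraph,
        sequesterRate = sequesterRate, sequesterDwell = sequesterDwell,
        parentOfOrigin = parentOfOrigin)
}

#' Construct a scenario configuration
#'
#' @param scenarioName label.
#' @param genotype \code{"hemizygous"}, \code{"homozygous"},
#'   \code{"enhancer_only_partner"} or \code{"promoter_only_partner"}.
#' @param constructClass \code{"control_chr3"}, \code{"weak_chr2"},
#'   \code{"distal_enhancer"} or \code{"endogenous_sna"}.
#' @param alleles list of \linkS4class{AlleleSpec} (length 1 or 2).
#' @param nEmbryos replicate embryos to simulate.
#' @param nucleiGrid integer \code{c(rows, cols)}; columns span the DV axis.
#' @param frameInterval imaging interval (seconds).
#' @param nc13Duration,nc14Duration interphase durations (minutes).
#' @param hub a \linkS4class{HubParams}.
#' @param noiseSd additive measurement noise sd (a.u.).
#' @param unitIntensity fluorescence of one Pol II past the cassette (a.u.).
#' @param seed root seed of the scenario.
#' @return A \linkS4class{ScenarioConfig} object.
#' @examples
#' cfg <- ScenarioConfig(genotype = "hemizygous",
#'                       alleles = list(AlleleSpec()))
#' @export
ScenarioConfig <- function(scenarioName = "custom",
                           genotype = "homozygous",
                           constructClass = "control_chr3",
                           alleles = list(
                               AlleleSpec(channel = "PP7",
                                          parentOfOrigin = "maternal"),
                               AlleleSpec(channel = "MS2",
                                          parentOfOrigin = "paternal")),
                           nEmbryos = 1L, nucleiGrid = c(24L, 26L),
                           frameInterval = 20, nc13Duration = 15,
                           nc14Duration = 50, hub = HubParams(),
                           noiseSd = 10, unitIntensity = 1, seed = 20220711L) {
    new("ScenarioConfig", scenarioName = scenarioName, genotype = genotype,
        constructClass = constructClass, alleles = alleles,
        nEmbryos = as.integer(nEmbryos),
        nucleiGrid = as.integer(nucleiGrid),
        frameInterval = frameInterval, nc13Duration = nc13Duration,
        nc14Duration = nc14Duration, hub = hub, noiseSd = noiseSd,
        unitIntensity = unitIntensity, seed = as.integer(seed))
}

setMethod("show", "TelegraphParams", function(object) {
    cat("TelegraphParams: kOnMax", object@kOnMax, "kOff", object@kOff,
        "kLoad", object@kLoad, "/min; vEl", object@vEl,
        "kb/min; boundary", object@xBoundary,
        "(steepness", paste0(object@steepness, ")\n"))
})

setMethod("show", "HubParams", function(object) {
    cat("HubParams: capacity", object@capacity, "units; replenish",
        object@replenishRate, "/min; background demand NC13",
        object@bgDemandNC13, "/min, NC14 ramp",
        object@bgDemandNC14Start, "->", object@bgDemandNC14End,
        "/min (dwell", object@bgDwell, "min)\n")
})

setMethod("show", "AlleleSpec", function(object) {
    cat("AlleleSpec:", object@construct, "construct, channel",
        object@channel, paste0("(", object@parentOfOrigin, ")"),
        "| gene", object@geneLength, "kb, cassette",
        object@loopStart, "-", object@loopStart + object@loopLength, "kb\n")
})

setMethod("show", "ScenarioConfig", function(object) {
    cat("ScenarioConfig '", object@scenarioName, "': ", object@genotype,
        " ", object@constructClass, "\n", sep = "")
    cat(" ", length(object@alleles), "allele(s);", object@nEmbryos,
        "embryo(s); grid", object@nucleiGrid[1], "x", object@nucleiGrid[2],
        "\n")
    cat("  NC13", object@nc13Duration, "min, NC14", object@nc14Duration,
        "min @", object@frameInterval, "s/frame; noise sd",
        object@noiseSd, "a.u.; seed", object@seed, "\n")
})

setMethod("show", "GenotypeComparison", function(object) {
    cat("GenotypeComparison [", object@metric, "]: ", object@testLabel,
        " vs ", object@refLabel, "\n", sep = "")
    cat(sprintf("  mean ref %.4g, mean test %.4g -> %.1f%% reduction",
                object@meanRef, object@meanTest, object@percentReduction))
    if (is.finite(object@ciLow))
        cat(sprintf(" (95%% CI %.1f to %.1f)", object@ciLow, object@ciHigh))
    cat(sprintf("\n  n = %d/%d nuclei, %d/%d embryos\n",
                object@nNuclei[1], object@nNuclei[2],
                object@nEmbryos[1], object@nEmbryos[2]))
})

#' Read or write a scenario configuration as YAML
#'
#' The on-disk format carries a \code{schema_version} key and mirrors the
#' slot structure of \linkS4class{ScenarioConfig}.
#'
#' @param path file path.
#' @return \code{readScenario} returns a \linkS4class{ScenarioConfig};
#'   \code{writeScenario} returns \code{path} invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeScenario(scenarioPreset("control_chr3_hemi"), f)
#' cfg <- readScenario(f)
#' @export
readScenario <- function(path) {
    y <- yaml::read_yaml(path)
    if (is.null(y$schema_version))
        stop("not a scenario file (missing 'schema_version'): ", path)
    tg <- function(t) TelegraphParams(kOnMax = t$k_on_max, kOff = t$k_off,
        kLoad = t$k_load, vEl = t$v_el, xBoundary = t$x_boundary,
        steepness = t$steepness)
    al <- lapply(y$alleles, function(a)
        AlleleSpec(channel = a$channel, construct = a$construct,
                   geneLength = a$gene_length, loopStart = a$loop_start,
                   loopLength = a$loop_length, telegraph = tg(a$telegraph),
                   sequesterRate = a$sequester_rate,
                   sequesterDwell = a$sequester_dwell,
                   parentOfOrigin = a$parent_of_origin))
    h <- y$hub
    ScenarioConfig(scenarioName = y$scenario_name, genotype = y$genotype,
        constructClass = y$construct_class, alleles = al,
        nEmbryos = y$n_embryos, nucleiGrid = unlist(y$nuclei_grid),
        frameInterval = y$frame_interval, nc13Duration = y$nc13_duration,
        nc14Duration = y$nc14_duration,
        hub = HubParams(capacity = h$capacity,
                        replenishRate = h$replenish_rate,
                        bgDemandNC13 = h$background_demand_nc13,
                        bgDemandNC14Start = h$background_demand_nc14_start,
                        bgDemandNC14End = h$background_demand_nc14_end,
                        bgDwell = h$background_dwell),
        noiseSd = y$noise_sd, unitIntensity = y$unit_intensity,
        seed = y$seed)
}

#' @rdname readScenario
#' @param config a \linkS4class{ScenarioConfig}.
#' @export
writeScenario <- function(config, path) {
    tg <- function(t) list(k_on_max = t@kOnMax, k_off = t@kOff,
        k_load = t@kLoad, v_el = t@vEl, x_boundary = t@xBoundary,
        steepness = t@steepness)
    y <- list(
        schema_version = 1L,
        scenario_name = config@scenarioName,
        genotype = config@genotype,
        construct_class = config@constructClass,
        alleles = lapply(config@alleles, function(a) list(
            channel = a@channel, construct = a@construct,
            gene_length = a@geneLength, loop_start = a@loopStart,
            loop_length = a@loopLength, telegraph = tg(a@telegraph),
            sequester_rate = a@sequesterRate,
            sequester_dwell = a@sequesterDwell,
            parent_of_origin = a@parentOfOrigin)),
        n_embryos = config@nEmbryos,
        nuclei_grid = as.list(config@nucleiGrid),
        frame_interval = config@frameInterval,
        nc13_duration = config@nc13Duration,
        nc14_duration = config@nc14Duration,
        hub = list(capacity = config@hub@capacity,
                   replenish_rate = config@hub@replenishRate,
                   background_demand_nc13 = config@hub@bgDemandNC13,
                   background_demand_nc14_start = config@hub@bgDemandNC14Start,
                   background_demand_nc14_end = config@hub@bgDemandNC14End,
                   background_dwell = config@hub@bgDwell),
        noise_sd = config@noiseSd,
        unit_intensity = config@unitIntensity,
        seed = config@seed)
    yaml::write_yaml(y, path)
    invisible(path)
}
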