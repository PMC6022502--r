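#' Build a demographic model
#'
#' @param populations data.frame(`name`, `size`): diploid sizes at time 0.
#' @param events data.frame(`time`, `type`, `pop`, `dest`, `value`); see
#'   [DemographicModel-class]. May be empty.
#' @param mutationRate per-site per-generation mutation rate.
#' @param generationTime generation time in years.
#' @param recombRate uniform recombination rate, Morgans per bp
#'   (1e-8 = 1 cM/Mb).
#' @param geneticMap optional data.frame(`chrom`, `pos`, `morgans`).
#' @return A [DemographicModel-class].
#' @export
DemographicModel <- function(populations, events = NULL,
                             mutationRate = 4e-9, generationTime = 3,
                             recombRate = 1e-8, geneticMap = NULL) {
    if (is.null(events))
        events <- data.frame(time = numeric(), type = character(),
                             pop = character(), dest = character(),
                             value = numeric(), stringsAsFactors = FALSE)
    if (nrow(events)) {
        if (is.null(events$dest)) events$dest <- NA_character_
        events <- events[order(events$time), , drop = FALSE]
        rownames(events) <- NULL
    }
    methods::new("DemographicModel", populations = as.data.frame(populations),
                 events = as.data.frame(events), mutationRate = mutationRate,
                 generationTime = generationTime, recombRate = recombRate,
                 geneticMap = geneticMap)
}

#' Default two-population dog/wolf split model
#'
#' A simplified neutral demography for dog and wolf lineages: a single
#' ancestral population splitting into "dog" and "wolf" a configurable
#' number of generations ago. Default sizes and split time are fixed,
#' literature-informed choices for village-dog and gray-wolf cohorts (see
#' the methods vignette); the mutation rate defaults to 4e-9 per site per
#' generation with a 3-year generation time.
#'
#' @param dogSize,wolfSize diploid sizes of the two present-day lineages.
#' @param ancestralSize diploid size of the ancestral population.
#' @param splitGen split time in generations before present.
#' @param dogBottleneckSize diploid dog size during the post-split
#'   domestication bottleneck (applies from the present back to
#'   `bottleneckEndGen`; set NULL to disable).
#' @param bottleneckEndGen generations ago at which, looking into the past,
#'   the dog lineage switches from `dogSize` to `dogBottleneckSize`.
#' @param ... passed on to [DemographicModel()].
#' @return A [DemographicModel-class] with lineages "dog" and "wolf".
#' @export
twoPopModel <- function(dogSize = 13000, wolfSize = 17000,
                        ancestralSize = 32000, splitGen = 5000,
                        dogBottleneckSize = 2500, bottleneckEndGen = 4500,
                        ...) {
    ev <- data.frame(time = splitGen, type = "merge", pop = "dog",
                     dest = "wolf", value = NA_real_,
                     stringsAsFactors = FALSE)
    if (!is.null(dogBottleneckSize)) {
        ev <- rbind(data.frame(time = bottleneckEndGen, type = "size",
                               pop = "dog", dest = NA_character_,
                               value = dogBottleneckSize,
                               stringsAsFactors = FALSE), ev)
    }
    ev <- rbind(ev, data.frame(time = splitGen, type = "size", pop = "wolf",
                               dest = NA_character_, value = ancestralSize,
                               stringsAsFactors = FALSE))
    DemographicModel(
        populations = data.frame(name = c("dog", "wolf"),
                                 size = c(dogSize, wolfSize)),
        events = ev, ...)
}

#' Read a demographic model from a YAML config
#'
#' The config mirrors the [DemographicModel-class] slots:
#' ```yaml
#' mutation_rate: 4.0e-9
#' generation_time: 3
#' recombination_rate: 1.0e-8
#' populations:
#'   - {name: dog, size: 13000}
#'   - {name: wolf, size: 17000}
#' events:
#'   - {time: 4500, type: size, pop: dog, value: 2500}
#'   - {time: 5000, type: merge, pop: dog, dest: wolf}
#' ```
#' Any number of lineages is supported, so multi-lineage histories (e.g. a
#' 10-lineage dog/wolf configuration) can be expressed without code changes.
#'
#' @param path YAML file path.
#' @return A [DemographicModel-class].
#' @export
readDemographyConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    pops <- do.call(rbind, lapply(cfg$populations, function(p)
        data.frame(name = p$name, size = as.numeric(p$size),
                   stringsAsFactors = FALSE)))
    ev <- if (length(cfg$events)) do.call(rbind, lapply(cfg$events, function(e)
        data.frame(time = as.numeric(e$time), type = e$type, pop = e$pop,
                   dest = if (is.null(e$dest)) NA_character_ else e$dest,
                   value = if (is.null(e$value)) NA_real_ else as.numeric(e$value),
                   stringsAsFactors = FALSE))) else NULL
    DemographicModel(pops, ev,
        mutationRate = as.numeric(cfg$mutation_rate %||% 4e-9),
        generationTime = as.numeric(cfg$generation_time %||% 3),
        recombRate = as.numeric(cfg$recombination_rate %||% 1e-8))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# lower demography to the flat vectors the C++ simulator consumes
demogToCpp <- function(model) {
    pops <- model@populations
    idx <- function(nm) match(nm, pops$name) - 1L
    ev <- model@events
    list(popSize0 = as.numeric(pops$size),
         popNames = pops$name,
         evTime = as.numeric(ev$time),
         evType = as.integer(c(size = 0L, merge = 1L, pulse = 2L)[ev$type]),
         evPop = idx(ev$pop),
         evDest = { d <- idx(ev$dest); d[is.na(d)] <- -1L; as.integer(d) },
         evValue = { v <- as.numeric(ev$value); v[is.na(v)] <- 0; v })
}
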