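# Strain definitions and fixture/population generators: every pipeline input
# is synthesized here, so all stages are testable with no external data.

#' Register a strain
#'
#' A strain is a genotype template (in [make_genotype()] field layout) plus
#' population composition parameters.
#'
#' @param registry A `wb_registry`.
#' @param name Strain name.
#' @param homozygous,heterozygous,balancers,balancer_homozygous,arrays
#'   Genotype template fields, as in [make_genotype()].
#' @param male_fraction Fraction of males in a stock population.
#' @param carrier_fraction Fraction of animals carrying the strain's
#'   arrays (mixed-carrier stocks); 1 means every animal carries them.
#' @param default_n Default population size.
#' @return The updated registry.
#' @export
add_strain <- function(registry, name, homozygous = character(),
                       heterozygous = character(), balancers = character(),
                       balancer_homozygous = character(), arrays = character(),
                       male_fraction = 0, carrier_fraction = 1,
                       default_n = 30L) {
  stopifnot(inherits(registry, "wb_registry"))
  if (name %in% names(registry$strains)) {
    stop("strain already registered: ", name, call. = FALSE)
  }
  # validate the template against the registry now
  make_genotype(registry, homozygous = unlist(homozygous) %||% character(),
                heterozygous = unlist(heterozygous) %||% character(),
                balancers = unlist(balancers) %||% character(),
                balancer_homozygous = unlist(balancer_homozygous) %||% character(),
                arrays = unlist(arrays) %||% character())
  registry$strains[[name]] <- list(
    name = name,
    homozygous = as.character(unlist(homozygous) %||% character()),
    heterozygous = as.character(unlist(heterozygous) %||% character()),
    balancers = as.character(unlist(balancers) %||% character()),
    balancer_homozygous = as.character(unlist(balancer_homozygous) %||% character()),
    arrays = as.character(unlist(arrays) %||% character()),
    male_fraction = male_fraction, carrier_fraction = carrier_fraction,
    default_n = as.integer(default_n))
  registry
}

# Stock strain table: lab staples plus the strains of the three procedures.
# Balancer strains are balanced heterozygotes so Green males can be picked.
.add_default_strains <- function(r) {
  r <- add_strain(r, "N2", male_fraction = 0.3)  # male-enriched mating stock
  r <- add_strain(r, "CB61", homozygous = "e61")
  r <- add_strain(r, "LX831", homozygous = "vsIs28")
  r <- add_strain(r, "LX811", homozygous = "vsIs33")
  r <- add_strain(r, "hT2_strain", balancers = "hT2", male_fraction = 0.3)
  r <- add_strain(r, "eT1_strain", balancers = "eT1", male_fraction = 0.3)
  r <- add_strain(r, "nT1_strain", balancers = "nT1", male_fraction = 0.3)
  r <- add_strain(r, "mIn1_strain", balancers = "mIn1", male_fraction = 0.3)
  r <- add_strain(r, "NQ1155", arrays = "qnEx615", male_fraction = 0.3)
  r <- add_strain(r, "YX293", arrays = "qhEx265")
  r <- add_strain(r, "YX256", arrays = "qhEx265", carrier_fraction = 0.5)
  r
}

#' Strain genotype from its template
#'
#' @param registry A `wb_registry`.
#' @param name Registered strain name.
#' @param sex Sex of the built genotype.
#' @param carrier Include the strain's arrays? Default `TRUE`.
#' @return A `wb_genotype`.
#' @export
strain_genotype <- function(registry, name, sex = "hermaphrodite", carrier = TRUE) {
  s <- registry$strains[[name]]
  if (is.null(s)) stop("unknown strain: ", name, call. = FALSE)
  make_genotype(registry, homozygous = s$homozygous,
                heterozygous = s$heterozygous, balancers = s$balancers,
                balancer_homozygous = s$balancer_homozygous,
                arrays = if (carrier) s$arrays else character(), sex = sex)
}

#' Generate a strain population
#'
#' Builds `n` individuals from the strain template: males at the strain's
#' male fraction, and (for mixed-carrier array stocks) carriers at the
#' carrier fraction.
#'
#' @param registry A `wb_registry`.
#' @param name Strain name.
#' @param n Population size (default the strain's `default_n`).
#' @param stage Stage label given to the animals.
#' @return List of `wb_individual`.
#' @export
make_strain_population <- function(registry, name, n = NULL, stage = "L4") {
  s <- registry$strains[[name]]
  if (is.null(s)) stop("unknown strain: ", name, call. = FALSE)
  n <- as.integer(n %||% s$default_n)
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sex <- if (stats::runif(1) < s$male_fraction) "male" else "hermaphrodite"
    carrier <- length(s$arrays) > 0 && stats::runif(1) < s$carrier_fraction
    g <- strain_genotype(registry, name, sex = sex, carrier = carrier)
    w <- new_individual(g, registry, stage = stage)
    out[[i]] <- w
  }
  out
}

#' Build a mapping scenario with a known true placement
#'
#' Constructs the parameter-recovery harness for the mapping pipeline: a
#' registry in which the Red transgene of interest (`vsIs33` analog) is
#' integrated on `true_chromosome`, together with the strain of interest, the
#' four balancer strains, and the Green-array helper male strain. With
#' `true_chromosome = NA` the transgene is left unintegrated — it is carried
#' on an extrachromosomal array, segregating independently of every
#' chromosome, so every test should read unlinked and inference should
#' return the empty set.
#'
#' @param true_chromosome One of [chromosomes()], or `NA` for the
#'   unintegrated control.
#' @param transmission_prob Transmission probability of the control array
#'   (only used when `true_chromosome` is `NA`).
#' @return A list: `registry` (with the scenario transgene placed),
#'   `transgene` (its symbol), `true_chromosome`, `strain` (strain-of-
#'   interest name).
#' @export
make_mapping_scenario <- function(true_chromosome, transmission_prob = 0.65) {
  r <- default_registry()
  if (is.na(true_chromosome)) {
    r <- add_array(r, "scnEx1", tags = "Red", transmission_prob = transmission_prob)
    r <- add_strain(r, "SOI", arrays = "scnEx1")
    return(list(registry = r, transgene = "scnEx1", true_chromosome = NA_character_,
                strain = "SOI", integrated = FALSE))
  }
  .check_chromosome(true_chromosome)
  r <- add_locus(r, "scnIs1", true_chromosome)
  r <- add_allele(r, "scnIs1", "scnIs1", "dominant", tags = "Red")
  r <- add_strain(r, "SOI", homozygous = "scnIs1")
  list(registry = r, transgene = "scnIs1", true_chromosome = true_chromosome,
       strain = "SOI", integrated = TRUE)
}

#' Run the full mapping panel on a scenario
#'
#' Convenience wrapper: builds the strain of interest from the scenario and
#' runs [run_linkage_mapping()]. For the unintegrated (array) control the
#' "transgene of interest" is the control array, and the strain-of-interest
#' hermaphrodites are array carriers rather than homozygotes.
#'
#' @param scenario Result of [make_mapping_scenario()].
#' @param n_scored Animals scored per test.
#' @param control A `wb_control`.
#' @param threshold Linked-call threshold.
#' @return A `wb_linkage_map`.
#' @export
map_scenario <- function(scenario, n_scored = 200, control = wb_control(),
                         threshold = 0.5) {
  run_linkage_mapping(scenario$transgene, n_scored = n_scored,
                      registry = scenario$registry, control = control,
                      threshold = threshold)
}

#' Make a mixed sorting plate
#'
#' A plate of `n` mixed animals of which a Bernoulli(`carrier_fraction`)
#' subset carries a Green array — the input of a fluorescence sorting task.
#'
#' @param bench A `wb_bench`.
#' @param n Number of worms.
#' @param carrier_fraction Probability each worm is a Green carrier.
#' @param array Array name used for the carriers.
#' @param label Plate label.
#' @return The new plate's barcode.
#' @export
make_sorting_plate <- function(bench, n, carrier_fraction, array = "qhEx265",
                               label = "sorting") {
  stopifnot(n >= 0, carrier_fraction >= 0, carrier_fraction <= 1)
  worms <- vector("list", n)
  for (i in seq_len(n)) {
    carrier <- stats::runif(1) < carrier_fraction
    g <- make_genotype(bench$registry, arrays = if (carrier) array else character())
    worms[[i]] <- new_individual(g, bench$registry)
  }
  plate_db_register(bench, label = label, worms = worms)
}
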