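#' @keywords internal
"_PACKAGE"

# The six C. elegans chromosomes; X is the sole sex chromosome.
WB_CHROMOSOMES <- c("I", "II", "III", "IV", "V", "X")
WB_AUTOSOMES <- c("I", "II", "III", "IV", "V")

#' Chromosome identifiers
#'
#' @return Character vector of the six chromosome names, `"I"` to `"V"` plus
#'   `"X"`.
#' @export
chromosomes <- function() WB_CHROMOSOMES

.check_chromosome <- function(chrom) {
  if (!all(chrom %in% WB_CHROMOSOMES)) {
    stop("unknown chromosome: ", paste(setdiff(chrom, WB_CHROMOSOMES), collapse = ", "),
         call. = FALSE)
  }
  chrom
}

#' Create an empty genetic registry
#'
#' The registry is the genetic universe a simulation runs in: loci with their
#' chromosome assignments, alleles with dominance and phenotype tags, balancer
#' elements (reciprocal translocations and inversions) with their fluorescent
#' markers and homozygote fates, extrachromosomal arrays with their
#' transmission probabilities, and named strains.
#'
#' @return An object of class `wb_registry`.
#' @seealso [default_registry()] for the stock laboratory universe.
#' @export
new_registry <- function() {
  structure(
    list(
      loci = list(),      # id -> list(id, name, chromosome)
      alleles = list(),   # symbol -> list(symbol, locus, chromosome, dominance, tags)
      balancers = list(), # name -> list(name, kind, chromosomes, marker, homozygote_fate)
      arrays = list(),    # name -> list(name, tags, transmission_prob)
      strains = list()    # name -> strain template (see add_strain())
    ),
    class = "wb_registry"
  )
}

#' Register a locus
#'
#' @param registry A `wb_registry`.
#' @param id Unique locus identifier (conventionally the gene name).
#' @param chromosome One of `chromosomes()`.
#' @param name Display name; defaults to `id`.
#' @return The updated registry.
#' @export
add_locus <- function(registry, id, chromosome, name = id) {
  stopifnot(inherits(registry, "wb_registry"))
  .check_chromosome(chromosome)
  if (id %in% names(registry$loci)) {
    stop("locus already registered: ", id, call. = FALSE)
  }
  registry$loci[[id]] <- list(id = id, name = name, chromosome = chromosome)
  registry
}

#' Register an allele
#'
#' @param registry A `wb_registry`.
#' @param symbol Allele symbol, e.g. `"e61"` or `"vsIs28"`.
#' @param locus Identifier of a registered locus.
#' @param dominance `"dominant"` or `"recessive"`.
#' @param tags Character vector of phenotype tags conferred when expressed
#'   (e.g. `"Green"`, `"Dpy"`); may be empty.
#' @return The updated registry.
#' @export
add_allele <- function(registry, symbol, locus, dominance = c("dominant", "recessive"),
                       tags = character()) {
  stopifnot(inherits(registry, "wb_registry"))
  dominance <- match.arg(dominance)
  if (!locus %in% names(registry$loci)) {
    stop("unknown locus: ", locus, call. = FALSE)
  }
  if (symbol %in% names(registry$alleles)) {
    stop("allele already registered: ", symbol, call. = FALSE)
  }
  registry$alleles[[symbol]] <- list(
    symbol = symbol, locus = locus,
    chromosome = registry$loci[[locus]]$chromosome,
    dominance = dominance, tags = as.character(tags)
  )
  registry
}

#' Register a balancer element
#'
#' Reciprocal translocations balance exactly two chromosomes and segregate as
#' a unit (alternate segregation); inversions balance one chromosome and
#' segregate like an ordinary homolog. The marker allele (typically a
#' pharyngeal GFP insertion) rides on the balancer element and is expressed
#' dominantly.
#'
#' @param registry A `wb_registry`.
#' @param name Balancer name, e.g. `"nT1"`.
#' @param kind `"reciprocal_translocation"` or `"inversion"`.
#' @param chromosomes Chromosomes balanced: two for a translocation, one for
#'   an inversion.
#' @param marker Symbol of a registered dominant marker allele carried on the
#'   element; its tags must include `"Green"`.
#' @param homozygote_fate `"lethal"`, `"viable"` or `"viable_with_phenotype"`.
#' @param homozygote_tags Extra tags expressed by viable homozygotes (only
#'   used when `homozygote_fate == "viable_with_phenotype"`).
#' @return The updated registry.
#' @export
add_balancer <- function(registry, name,
                         kind = c("reciprocal_translocation", "inversion"),
                         chromosomes, marker,
                         homozygote_fate = c("lethal", "viable", "viable_with_phenotype"),
                         homozygote_tags = character()) {
  stopifnot(inherits(registry, "wb_registry"))
  kind <- match.arg(kind)
  homozygote_fate <- match.arg(homozygote_fate)
  .check_chromosome(chromosomes)
  n_expected <- if (kind == "reciprocal_translocation") 2L else 1L
  if (length(chromosomes) != n_expected) {
    stop(kind, " must balance exactly ", n_expected, " chromosome(s)", call. = FALSE)
  }
  if (!marker %in% names(registry$alleles)) {
    stop("marker allele not registered: ", marker, call. = FALSE)
  }
  if (!"Green" %in% registry$alleles[[marker]]$tags) {
    stop("balancer marker must carry the Green tag: ", marker, call. = FALSE)
  }
  if (name %in% names(registry$balancers)) {
    stop("balancer already registered: ", name, call. = FALSE)
  }
  registry$balancers[[name]] <- list(
    name = name, kind = kind, chromosomes = chromosomes, marker = marker,
    homozygote_fate = homozygote_fate, homozygote_tags = as.character(homozygote_tags)
  )
  registry
}

#' Register an extrachromosomal array
#'
#' Arrays are repetitive transgenic elements unattached to any chromosome;
#' they pass to each offspring of a carrier with probability
#' `transmission_prob`, independent of chromosomal segregation. Array tags are
#' always expressed dominantly.
#'
#' @param registry A `wb_registry`.
#' @param name Array name, e.g. `"qhEx265"`.
#' @param tags Phenotype tags conferred on carriers.
#' @param transmission_prob Per-offspring transmission probability in `[0, 1]`.
#' @return The updated registry.
#' @export
add_array <- function(registry, name, tags = character(), transmission_prob = 0.65) {
  stopifnot(inherits(registry, "wb_registry"))
  if (transmission_prob < 0 || transmission_prob > 1) {
    stop("transmission_prob must lie in [0, 1]", call. = FALSE)
  }
  if (name %in% names(registry$arrays)) {
    stop("array already registered: ", name, call. = FALSE)
  }
  registry$arrays[[name]] <- list(
    name = name, tags = as.character(tags), transmission_prob = transmission_prob
  )
  registry
}

.get_allele <- function(registry, symbol) {
  a <- registry$alleles[[symbol]]
  if (is.null(a)) stop("unknown allele: ", symbol, call. = FALSE)
  a
}

.get_balancer <- function(registry, name) {
  b <- registry$balancers[[name]]
  if (is.null(b)) stop("unknown balancer: ", name, call. = FALSE)
  b
}

.get_array <- function(registry, name) {
  a <- registry$arrays[[name]]
  if (is.null(a)) stop("unknown array: ", name, call. = FALSE)
  a
}

#' The stock laboratory registry
#'
#' Builds the default genetic universe used throughout: the dpy-5(e61)
#' recessive Dumpy mutation on chromosome I; the dominant GFP transgene
#' vsIs28 (chromosome IV) and RFP transgene vsIs33 (chromosome V); the four
#' GFP-marked balancers hT2[qIs48] (I;III), eT1[umnIs12] (III;V), nT1[qIs51]
#' (IV;V) and mIn1[mIs14] (II); the extrachromosomal arrays qnEx615 and
#' qhEx265 (65% transmission); and the standard strains (N2, CB61, LX831,
#' LX811, the balancer strains, NQ1155, YX293, YX256).
#'
#' Chromosome placements not fixed by the strain genotype nomenclature
#' (vsIs28, vsIs33) and balancer homozygote fates are configuration facts,
#' overridable via [registry_from_config()].
#'
#' @return A populated `wb_registry`.
#' @export
default_registry <- function() {
  r <- new_registry()
  r <- add_locus(r, "dpy-5", "I")
  r <- add_allele(r, "e61", "dpy-5", "recessive", tags = "Dpy")

  r <- add_locus(r, "vsIs28", "IV")
  r <- add_allele(r, "vsIs28", "vsIs28", "dominant", tags = "Green")
  r <- add_locus(r, "vsIs33", "V")
  r <- add_allele(r, "vsIs33", "vsIs33", "dominant", tags = "Red")

  # Balancer GFP markers live on their element; locus records anchor them to
  # the first balanced chromosome for bookkeeping.
  r <- add_locus(r, "qIs48", "I")
  r <- add_allele(r, "qIs48", "qIs48", "dominant", tags = "Green")
  r <- add_locus(r, "umnIs12", "III")
  r <- add_allele(r, "umnIs12", "umnIs12", "dominant", tags = "Green")
  r <- add_locus(r, "qIs51", "IV")
  r <- add_allele(r, "qIs51", "qIs51", "dominant", tags = "Green")
  r <- add_locus(r, "mIs14", "II")
  r <- add_allele(r, "mIs14", "mIs14", "dominant", tags = "Green")

  r <- add_balancer(r, "hT2", "reciprocal_translocation", c("I", "III"),
                    marker = "qIs48", homozygote_fate = "lethal")
  r <- add_balancer(r, "eT1", "reciprocal_translocation", c("III", "V"),
                    marker = "umnIs12", homozygote_fate = "viable_with_phenotype",
                    homozygote_tags = "Unc")
  r <- add_balancer(r, "nT1", "reciprocal_translocation", c("IV", "V"),
                    marker = "qIs51", homozygote_fate = "lethal")
  r <- add_balancer(r, "mIn1", "inversion", "II",
                    marker = "mIs14", homozygote_fate = "viable")

  r <- add_array(r, "qnEx615", tags = "Green", transmission_prob = 0.65)
  r <- add_array(r, "qhEx265", tags = "Green", transmission_prob = 0.65)

  r <- .add_default_strains(r)
  r
}

#' Build a registry from a configuration list
#'
#' Accepts the `registry:` section of a run configuration (see
#' [read_run_config()]): lists of loci, alleles, balancers and arrays in the
#' same field layout as the registration functions. Starts from an empty
#' registry unless `base` is supplied.
#'
#' @param config A named list with optional elements `loci`, `alleles`,
#'   `balancers`, `arrays`, `strains`.
#' @param base Registry to extend; default a fresh empty one.
#' @return A `wb_registry`.
#' @export
registry_from_config <- function(config, base = new_registry()) {
  r <- base
  for (x in config$loci %||% list()) {
    r <- add_locus(r, x$id, x$chromosome, name = x$name %||% x$id)
  }
  for (x in config$alleles %||% list()) {
    r <- add_allele(r, x$symbol, x$locus, x$dominance %||% "dominant",
                    tags = unlist(x$tags) %||% character())
  }
  for (x in config$balancers %||% list()) {
    r <- add_balancer(r, x$name, x$kind, unlist(x$chromosomes), x$marker,
                      homozygote_fate = x$homozygote_fate %||% "lethal",
                      homozygote_tags = unlist(x$homozygote_tags) %||% character())
  }
  for (x in config$arrays %||% list()) {
    r <- add_array(r, x$name, tags = unlist(x$tags) %||% character(),
                   transmission_prob = x$transmission_prob %||% 0.65)
  }
  for (x in config$strains %||% list()) {
    r <- do.call(add_strain, c(list(registry = r), x))
  }
  r
}

#' Export a registry as plain data frames
#'
#' @param registry A `wb_registry`.
#' @return Named list of data frames (`loci`, `alleles`, `balancers`,
#'   `arrays`), suitable for CSV reporting; see [write_registry_csv()].
#' @export
registry_tables <- function(registry) {
  stopifnot(inherits(registry, "wb_registry"))
  loci <- do.call(rbind, lapply(registry$loci, function(x) {
    data.frame(id = x$id, name = x$name, chromosome = x$chromosome,
               stringsAsFactors = FALSE)
  }))
  alleles <- do.call(rbind, lapply(registry$alleles, function(x) {
    data.frame(symbol = x$symbol, locus = x$locus, chromosome = x$chromosome,
               dominance = x$dominance, tags = paste(x$tags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  balancers <- do.call(rbind, lapply(registry$balancers, function(x) {
    data.frame(name = x$name, kind = x$kind,
               chromosomes = paste(x$chromosomes, collapse = ";"),
               marker = x$marker, homozygote_fate = x$homozygote_fate,
               stringsAsFactors = FALSE)
  }))
  arrays <- do.call(rbind, lapply(registry$arrays, function(x) {
    data.frame(name = x$name, tags = paste(x$tags, collapse = ";"),
               transmission_prob = x$transmission_prob, stringsAsFactors = FALSE)
  }))
  list(loci = loci %||% data.frame(), alleles = alleles %||% data.frame(),
       balancers = balancers %||% data.frame(), arrays = arrays %||% data.frame())
}

#' Write / read registry CSV reports
#'
#' `write_registry_csv()` writes one CSV per registry table into `dir`;
#' `read_registry_csv()` reconstructs a registry from them (strains are not
#' round-tripped; they are configuration, not observations).
#'
#' @param registry A `wb_registry`.
#' @param dir Output directory, created if needed.
#' @return `write_registry_csv()` returns the file paths invisibly;
#'   `read_registry_csv()` returns a `wb_registry`.
#' @export
write_registry_csv <- function(registry, dir) {
  tabs <- registry_tables(registry)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(tabs), function(nm) {
    p <- file.path(dir, paste0("registry_", nm, ".csv"))
    utils::write.csv(tabs[[nm]], p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_registry_csv
#' @export
read_registry_csv <- function(dir) {
  rd <- function(nm) {
    p <- file.path(dir, paste0("registry_", nm, ".csv"))
    utils::read.csv(p, stringsAsFactors = FALSE, colClasses = NA)
  }
  r <- new_registry()
  loci <- rd("loci")
  for (i in seq_len(nrow(loci))) {
    r <- add_locus(r, loci$id[i], loci$chromosome[i], name = loci$name[i])
  }
  al <- rd("alleles")
  for (i in seq_len(nrow(al))) {
    tags <- if (nzchar(al$tags[i])) strsplit(al$tags[i], ";")[[1]] else character()
    r <- add_allele(r, al$symbol[i], al$locus[i], al$dominance[i], tags = tags)
  }
  ba <- rd("balancers")
  for (i in seq_len(nrow(ba))) {
    r <- add_balancer(r, ba$name[i], ba$kind[i], strsplit(ba$chromosomes[i], ";")[[1]],
                      ba$marker[i], homozygote_fate = ba$homozygote_fate[i])
  }
  ar <- rd("arrays")
  for (i in seq_len(nrow(ar))) {
    tags <- if (nzchar(ar$tags[i])) strsplit(ar$tags[i], ";")[[1]] else character()
    r <- add_array(r, ar$name[i], tags = tags,
                   transmission_prob = ar$transmission_prob[i])
  }
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wb_registry <- function(x, ...) {
  cat("<wb_registry>\n")
  cat("  loci:     ", paste(names(x$loci), collapse = ", "), "\n")
  cat("  alleles:  ", paste(names(x$alleles), collapse = ", "), "\n")
  cat("  balancers:", paste(names(x$balancers), collapse = ", "), "\n")
  cat("  arrays:   ", paste(names(x$arrays), collapse = ", "), "\n")
  cat("  strains:  ", paste(names(x$strains), collapse = ", "), "\n")
  invisible(x)
}
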