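# Haplotypes, genotypes, and the genotype -> phenotype / viability / sex maps.

#' Construct a haplotype
#'
#' A haplotype is the content of one chromosome slot of one gamete: either a
#' normal homolog carrying zero or more alleles, or a balancer element (an
#' inversion chromosome, or one half of a reciprocal translocation).
#'
#' @param chromosome One of [chromosomes()].
#' @param alleles Character vector of allele symbols carried.
#' @param balancer Balancer name if this haplotype is a balancer element,
#'   else `NA`.
#' @return An object of class `wb_haplotype`.
#' @export
haplotype <- function(chromosome, alleles = character(), balancer = NA_character_) {
  .check_chromosome(chromosome)
  structure(
    list(chromosome = chromosome, alleles = as.character(alleles),
         balancer = balancer),
    class = "wb_haplotype"
  )
}

.hap_key <- function(h) {
  paste0(h$chromosome, ":",
         if (is.na(h$balancer)) "+" else h$balancer, ":",
         paste(sort(h$alleles), collapse = ","))
}

#' Balancer haplotypes for one element
#'
#' Returns the haplotype(s) a balancer contributes: two (one per balanced
#' chromosome) for a reciprocal translocation, one for an inversion. The GFP
#' marker allele rides on the haplotype of the first balanced chromosome.
#'
#' @param registry A `wb_registry`.
#' @param name Registered balancer name.
#' @return Named list of `wb_haplotype` keyed by chromosome.
#' @export
balancer_haplotypes <- function(registry, name) {
  b <- .get_balancer(registry, name)
  haps <- lapply(seq_along(b$chromosomes), function(i) {
    haplotype(b$chromosomes[i],
              alleles = if (i == 1L) b$marker else character(),
              balancer = b$name)
  })
  names(haps) <- b$chromosomes
  haps
}

#' Construct a genotype
#'
#' Builds a diploid genotype from allele and balancer content. Hermaphrodites
#' carry two X haplotypes, males one. Heterozygous alleles are placed on the
#' first haplotype of their chromosome (in a male, a "heterozygous" X-linked
#' allele is hemizygous on his single X). Balancer elements replace the
#' *second* haplotype of each chromosome they balance, so a heterozygous
#' allele on a balanced chromosome sits in cis to the normal homolog — the
#' configuration a balancer is used to maintain.
#'
#' @param registry A `wb_registry`.
#' @param homozygous Allele symbols present on both homologs.
#' @param heterozygous Allele symbols present on one homolog.
#' @param balancers Balancer names carried heterozygously (element/normal).
#' @param balancer_homozygous Balancer names carried homozygously.
#' @param arrays Extrachromosomal array names carried.
#' @param sex `"hermaphrodite"` or `"male"`.
#' @return An object of class `wb_genotype`.
#' @examples
#' r <- default_registry()
#' g <- make_genotype(r, homozygous = "e61", heterozygous = "vsIs28")
#' phenotype_of(g, r)
#' @export
make_genotype <- function(registry, homozygous = character(),
                          heterozygous = character(), balancers = character(),
                          balancer_homozygous = character(), arrays = character(),
                          sex = c("hermaphrodite", "male")) {
  sex <- match.arg(sex)
  slots <- lapply(WB_CHROMOSOMES, function(ch) list(haplotype(ch), haplotype(ch)))
  names(slots) <- WB_CHROMOSOMES
  for (sym in homozygous) {
    a <- .get_allele(registry, sym)
    for (k in 1:2) {
      slots[[a$chromosome]][[k]]$alleles <- c(slots[[a$chromosome]][[k]]$alleles, sym)
    }
  }
  for (sym in heterozygous) {
    a <- .get_allele(registry, sym)
    slots[[a$chromosome]][[1]]$alleles <- c(slots[[a$chromosome]][[1]]$alleles, sym)
  }
  for (nm in c(balancers, balancer_homozygous)) {
    hom <- nm %in% balancer_homozygous
    bh <- balancer_haplotypes(registry, nm)
    for (ch in names(bh)) {
      slots[[ch]][[2]] <- bh[[ch]]
      if (hom) slots[[ch]][[1]] <- bh[[ch]]
    }
  }
  for (nm in arrays) .get_array(registry, nm)
  if (sex == "male") slots[["X"]] <- slots[["X"]][1]
  structure(
    list(slots = slots, arrays = sort(unique(as.character(arrays)))),
    class = "wb_genotype"
  )
}

.genotype_from_slots <- function(slots, arrays = character()) {
  structure(list(slots = slots, arrays = sort(unique(as.character(arrays)))),
            class = "wb_genotype")
}

.genotype_key <- function(g) {
  slot_keys <- vapply(g$slots, function(hh) {
    paste(sort(vapply(hh, .hap_key, character(1))), collapse = "|")
  }, character(1))
  paste(paste(slot_keys, collapse = " / "),
        paste(g$arrays, collapse = ","), sep = " @ ")
}

# Copy number of each allele symbol across the genotype.
.allele_counts <- function(g) {
  syms <- unlist(lapply(g$slots, function(hh) lapply(hh, function(h) h$alleles)),
                 use.names = FALSE)
  if (is.null(syms) || length(syms) == 0L) return(integer())
  table(syms)
}

#' Phenotype of a genotype
#'
#' Dominant-allele tags are expressed from one copy; recessive-allele tags
#' require every haplotype of the locus' chromosome slot to carry the allele
#' (two copies in a diploid slot, one in the hemizygous male X). Balancer
#' marker alleles are dominant, array tags are always expressed by carriers,
#' and viable balancer homozygotes add their homozygote tags (e.g. Unc).
#'
#' @param genotype A `wb_genotype`.
#' @param registry A `wb_registry`.
#' @return Sorted character vector of phenotype tags.
#' @export
phenotype_of <- function(genotype, registry) {
  stopifnot(inherits(genotype, "wb_genotype"))
  tags <- character()
  counts <- .allele_counts(genotype)
  for (sym in names(counts)) {
    a <- .get_allele(registry, sym)
    ploidy <- length(genotype$slots[[a$chromosome]])
    expressed <- if (a$dominance == "dominant") counts[[sym]] >= 1L
                 else counts[[sym]] >= ploidy
    if (expressed) tags <- c(tags, a$tags)
  }
  for (nm in genotype$arrays) {
    tags <- c(tags, .get_array(registry, nm)$tags)
  }
  for (b in registry$balancers) {
    if (b$homozygote_fate == "viable_with_phenotype" &&
        .balancer_dose(genotype, b) == 2L) {
      tags <- c(tags, b$homozygote_tags)
    }
  }
  sort(unique(tags))
}

# Number of copies of balancer b, judged on its first balanced chromosome.
.balancer_dose <- function(genotype, b) {
  ch <- b$chromosomes[1]
  sum(vapply(genotype$slots[[ch]],
             function(h) identical(h$balancer, b$name), logical(1)))
}

#' Karyotypic viability of a genotype
#'
#' A conception is inviable if any reciprocal-translocation product is
#' unbalanced (a translocation half present without its partner half — an
#' aneuploid duplication/deficiency), or if it is homozygous for a balancer
#' whose homozygote fate is lethal.
#'
#' @inheritParams phenotype_of
#' @return `"viable"` or `"inviable"`.
#' @export
viability_of <- function(genotype, registry) {
  stopifnot(inherits(genotype, "wb_genotype"))
  for (b in registry$balancers) {
    doses <- vapply(b$chromosomes, function(ch) {
      sum(vapply(genotype$slots[[ch]],
                 function(h) identical(h$balancer, b$name), logical(1)))
    }, integer(1))
    if (b$kind == "reciprocal_translocation" && length(unique(doses)) > 1L) {
      return("inviable")  # unbalanced translocation product
    }
    if (all(doses == 2L) && b$homozygote_fate == "lethal") {
      return("inviable")
    }
  }
  "viable"
}

#' Sex of a genotype
#'
#' Sex in C. elegans is set by X dosage: two X haplotypes make a
#' hermaphrodite, one makes a male.
#'
#' @inheritParams phenotype_of
#' @return `"hermaphrodite"` or `"male"`.
#' @export
sex_of <- function(genotype, registry) {
  stopifnot(inherits(genotype, "wb_genotype"))
  nx <- length(genotype$slots[["X"]])
  if (nx == 2L) "hermaphrodite"
  else if (nx == 1L) "male"
  else stop("invalid karyotype: ", nx, " X haplotypes", call. = FALSE)
}

#' Format a genotype as a nomenclature-style string
#'
#' @inheritParams phenotype_of
#' @return A single string, e.g. `"e61/e61 I; vsIs28/+ IV"`.
#' @export
format_genotype <- function(genotype, registry = NULL) {
  fmt_hap <- function(h) {
    base <- if (is.na(h$balancer)) NULL else h$balancer
    al <- sort(h$alleles)
    if (!is.null(base)) {
      if (length(al)) paste0(base, "[", paste(al, collapse = " "), "]") else base
    } else {
      if (length(al)) paste(al, collapse = " ") else "+"
    }
  }
  parts <- character()
  for (ch in WB_CHROMOSOMES) {
    hh <- genotype$slots[[ch]]
    strs <- sort(vapply(hh, fmt_hap, character(1)), decreasing = TRUE)
    if (all(strs == "+") && length(strs) == (if (ch == "X") length(strs) else 2L)) {
      if (ch != "X" || length(hh) == 2L) next
    }
    parts <- c(parts, paste0(paste(strs, collapse = "/"),
                             if (ch == "X" && length(hh) == 1L) "/0" else "",
                             " ", ch))
  }
  if (length(genotype$arrays)) {
    parts <- c(parts, paste0("Ex[", paste(genotype$arrays, collapse = " "), "]"))
  }
  if (!length(parts)) "+/+ (wild type)" else paste(parts, collapse = "; ")
}

#' @export
print.wb_genotype <- function(x, ...) {
  cat("<wb_genotype> ", format_genotype(x), "\n", sep = "")
  invisible(x)
}

#' Construct an individual worm
#'
#' @param genotype A `wb_genotype`.
#' @param registry A `wb_registry`.
#' @param id Identifier string; autogenerated if `NULL`.
#' @param stage Developmental stage label (`"L1"`..`"L4"`, `"adult"`); purely
#'   a label advanced by the bench, not continuous time.
#' @param parents Character vector of parent ids.
#' @return An object of class `wb_individual` with cached sex and phenotype.
#' @export
new_individual <- function(genotype, registry, id = NULL, stage = "L4",
                           parents = character()) {
  structure(
    list(id = id %||% paste0("w", .next_id()),
         sex = sex_of(genotype, registry),
         stage = stage,
         phenotype = phenotype_of(genotype, registry),
         genotype = genotype,
         parents = as.character(parents)),
    class = "wb_individual"
  )
}

.wb_state <- new.env(parent = emptyenv())
.wb_state$counter <- 0L

.next_id <- function() {
  .wb_state$counter <- .wb_state$counter + 1L
  .wb_state$counter
}

#' Reset the individual-id counter (used for reproducible fixtures)
#' @return Invisibly, the counter value before reset.
#' @export
reset_id_counter <- function() {
  old <- .wb_state$counter
  .wb_state$counter <- 0L
  invisible(old)
}

#' @export
print.wb_individual <- function(x, ...) {
  cat("<wb_individual> ", x$id, " ", x$sex, " [",
      paste(x$phenotype, collapse = ","), "] ", format_genotype(x$genotype),
      "\n", sep = "")
  invisible(x)
}

#' Tabulate a brood as a data frame
#'
#' @param individuals List of `wb_individual`.
#' @return Data frame with one row per worm: id, parents, sex, stage,
#'   phenotype tags (semicolon-joined) and genotype string.
#' @export
brood_table <- function(individuals) {
  if (!length(individuals)) {
    return(data.frame(id = character(), parents = character(), sex = character(),
                      stage = character(), phenotype = character(),
                      genotype = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    id = vapply(individuals, `[[`, character(1), "id"),
    parents = vapply(individuals, function(w) paste(w$parents, collapse = ";"),
                     character(1)),
    sex = vapply(individuals, `[[`, character(1), "sex"),
    stage = vapply(individuals, `[[`, character(1), "stage"),
    phenotype = vapply(individuals, function(w) paste(w$phenotype, collapse = ";"),
                       character(1)),
    genotype = vapply(individuals, function(w) format_genotype(w$genotype),
                      character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a brood to CSV
#'
#' @inheritParams brood_table
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_brood_csv <- function(individuals, path) {
  utils::write.csv(brood_table(individuals), path, row.names = FALSE)
  invisible(path)
}

#' Does a worm's phenotype match a predicate?
#'
#' @param phenotype Character vector of tags.
#' @param sex Sex string, or `NULL` to skip the sex clause.
#' @param predicate List with optional elements `tags_all` (all must be
#'   present), `tags_none` (none may be present), `sex`, `stage`.
#' @param stage Stage string or `NULL`.
#' @return Logical scalar.
#' @export
matches_predicate <- function(phenotype, sex = NULL, predicate = list(), stage = NULL) {
  if (!is.null(predicate$tags_all) && !all(predicate$tags_all %in% phenotype)) {
    return(FALSE)
  }
  if (!is.null(predicate$tags_none) && any(predicate$tags_none %in% phenotype)) {
    return(FALSE)
  }
  if (!is.null(predicate$sex) && !is.null(sex) && !identical(sex, predicate$sex)) {
    return(FALSE)
  }
  if (!is.null(predicate$stage) && !is.null(stage) && !identical(stage, predicate$stage)) {
    return(FALSE)
  }
  TRUE
}
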