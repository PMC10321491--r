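# The two end-to-end procedures built on the virtual bench: the
# multi-generation genetic cross and the genomic-integration screen.

#' Run the automated genetic cross
#'
#' Executes the full hybridization scheme combining a dominant Green
#' transgene (vsIs28 analog) with the recessive Dumpy mutation dpy-5(e61):
#'
#' 1. generation cross: wild-type males are mated to transgene-homozygous
#'    hermaphrodites to produce Green heterozygous males;
#' 2. P0: Green males are mated to Dpy-homozygous hermaphrodites;
#' 3. F1: Green nonDpy hermaphrodites (double heterozygotes) are singled;
#' 4. F2: Dpy-Green animals are singled;
#' 5. F3: each line is screened (expected 100% Dpy, 75% or 100% Green) and
#'    Dpy-Green animals are singled onward through F4;
#' 6. F5: each line is screened; a line is called homozygous iff 100% of the
#'    screened progeny are Green.
#'
#' @param bench A `wb_bench` (its rates, control and brood mode govern the
#'   run). Use `exact_broods = TRUE` with [perfect_rates()] for the
#'   deterministic, expectation-exact protocol.
#' @param n_males_gen,n_herms_gen Picks for the generation cross (17 + 4).
#' @param n_males_p0,n_herms_p0 Picks for the P0 mating (6 + 2).
#' @param f1_singles,f2_singles,f3_singles,f4_singles Numbers singled per
#'   stage (2, 3, 3, 11).
#' @param screen_n Progeny screened per line at the F3 and F5 checks.
#' @param transgene,mutation Allele symbols of the dominant transgene and
#'   recessive mutation combined.
#' @param transgene_strain,mutant_strain,wild_strain Strain names.
#' @return A list of class `wb_cross_report`: per-stage records, screened
#'   fractions, the homozygous line barcodes, and `success`; or a
#'   `wb_failure` when a stage exhausts its retries.
#' @export
run_genetic_cross <- function(bench,
                              n_males_gen = 17L, n_herms_gen = 4L,
                              n_males_p0 = 6L, n_herms_p0 = 2L,
                              f1_singles = 2L, f2_singles = 3L,
                              f3_singles = 3L, f4_singles = 11L,
                              screen_n = 40L,
                              transgene = "vsIs28", mutation = "e61",
                              transgene_strain = "LX831",
                              mutant_strain = "CB61", wild_strain = "N2") {
  stopifnot(inherits(bench, "wb_bench"))
  r <- bench$registry
  tg_tags <- .get_allele(r, transgene)$tags      # Green
  mut_tags <- .get_allele(r, mutation)$tags      # Dpy
  report <- list(stages = list())
  fail <- function(stage, why) protocol_failure(stage, why)

  # source stocks
  wild <- plate_db_register(bench, "wild_stock", strain = wild_strain,
                            worms = make_strain_population(r, wild_strain, 80))
  tgp <- plate_db_register(bench, "transgene_stock", strain = transgene_strain,
                           worms = make_strain_population(r, transgene_strain, 30))
  mut <- plate_db_register(bench, "mutant_stock", strain = mutant_strain,
                           worms = make_strain_population(r, mutant_strain, 30))

  # generation cross: wild males x transgene hermaphrodites -> Green het males
  gen <- plate_db_register(bench, "generation_cross", generation = 0L,
                           parent_barcodes = c(wild, tgp))
  execute(script_cross_worms(wild, n_males_gen, tgp, n_herms_gen, gen), bench)
  if (!length(Filter(function(w) w$sex == "male", plate_worms(bench, gen))) ||
      !length(Filter(function(w) w$sex == "hermaphrodite", plate_worms(bench, gen)))) {
    return(fail("generation cross", "mating plate lacks one sex"))
  }
  grow_plate(bench, gen)
  green_males <- screen_plate(bench, gen, list(tags_all = tg_tags, sex = "male"))
  report$stages$generation_cross <- list(barcode = gen,
                                         green_males = length(green_males))
  if (!length(green_males)) return(fail("generation cross", "no Green males"))

  # P0: Green het males x mutant hermaphrodites
  p0 <- plate_db_register(bench, "P0_mating", generation = 0L,
                          parent_barcodes = c(gen, mut))
  execute(script_cross_worms(gen, n_males_p0, mut, n_herms_p0, p0,
                             male_predicate = list(tags_all = tg_tags)), bench)
  ok_males <- Filter(function(w) w$sex == "male", plate_worms(bench, p0))
  ok_herms <- Filter(function(w) w$sex == "hermaphrodite", plate_worms(bench, p0))
  if (!length(ok_males) || !length(ok_herms)) {
    return(fail("P0 mating", "mating plate lacks one sex"))
  }
  grow_plate(bench, p0)
  report$stages$P0 <- list(barcode = p0, brood = length(plate_worms(bench, p0)))

  # F1: single Green nonDpy hermaphrodites (double heterozygotes)
  f1_pred <- list(tags_all = tg_tags, tags_none = mut_tags, sex = "hermaphrodite")
  f1 <- single_worms(bench, p0, f1_singles, f1_pred, "F1", generation = 1L)
  if (!length(f1)) return(fail("F1 singling", "no Green nonDpy hermaphrodite found"))
  for (bc in f1) grow_plate(bench, bc)
  report$stages$F1 <- list(barcodes = f1)

  # F2: single Dpy-Green animals across the F1 plates
  dg_pred <- list(tags_all = c(tg_tags, mut_tags), sex = "hermaphrodite")
  f2 <- .single_across(bench, f1, f2_singles, dg_pred, "F2", 2L)
  if (!length(f2)) return(fail("F2 singling", "no Dpy-Green animal found"))
  for (bc in f2) grow_plate(bench, bc)
  report$stages$F2 <- list(barcodes = f2)

  # F3 screen: fractions of Dpy and of Green per line
  f3_screen <- lapply(f2, function(bc) {
    worms <- plate_worms(bench, bc)
    n <- min(screen_n, length(worms))
    sub <- worms[seq_len(n)]
    list(barcode = bc, n = n,
         frac_dpy = mean(vapply(sub, function(w) all(mut_tags %in% w$phenotype),
                                logical(1))),
         frac_green = mean(vapply(sub, function(w) all(tg_tags %in% w$phenotype),
                                  logical(1))))
  })
  report$stages$F3_screen <- f3_screen

  # F3 -> F4: single Dpy-Green onward
  f3 <- .single_across(bench, f2, f3_singles, dg_pred, "F3", 3L)
  if (!length(f3)) return(fail("F3 singling", "no Dpy-Green animal found"))
  for (bc in f3) grow_plate(bench, bc)
  f4 <- .single_across(bench, f3, f4_singles, dg_pred, "F4", 4L)
  if (!length(f4)) return(fail("F4 singling", "no Dpy-Green animal found"))
  for (bc in f4) grow_plate(bench, bc)
  report$stages$F4 <- list(barcodes = f4)

  # F5 homozygosity screen: a line is homozygous iff 100% of screened progeny
  # are Green
  f5_screen <- lapply(f4, function(bc) {
    worms <- plate_worms(bench, bc)
    n <- min(screen_n, length(worms))
    sub <- worms[seq_len(n)]
    fg <- mean(vapply(sub, function(w) all(tg_tags %in% w$phenotype), logical(1)))
    list(barcode = bc, n = n, frac_green = fg, homozygous = n > 0 && fg == 1)
  })
  report$stages$F5_screen <- f5_screen
  hom <- vapply(f5_screen, `[[`, logical(1), "homozygous")
  report$homozygous_lines <- vapply(f5_screen[hom], `[[`, character(1), "barcode")
  report$success <- TRUE

  # final-line verification: phenotype and breeding true
  if (length(report$homozygous_lines)) {
    bc <- report$homozygous_lines[[1]]
    w <- plate_worms(bench, bc)[[1]]
    report$final_line <- list(
      barcode = bc, phenotype = w$phenotype,
      breeds_true = all(vapply(
        if (bench$exact_broods) brood_exact(w$genotype, NULL, 20, r, bench$control)
        else self_cross(w$genotype, 20, r, bench$control),
        function(k) all(c(tg_tags, mut_tags) %in% k$phenotype), logical(1))))
  }
  class(report) <- "wb_cross_report"
  report
}

# Single `total` worms spread round-robin across source plates.
.single_across <- function(bench, sources, total, predicate, prefix, generation) {
  out <- character()
  i <- 0L
  while (length(out) < total && i < total * 2L) {
    src <- sources[[1L + i %% length(sources)]]
    got <- single_worms(bench, src, 1L, predicate,
                        paste0(prefix, "_", length(out) + 1L), generation)
    out <- c(out, got)
    i <- i + 1L
  }
  out
}

#' @export
print.wb_cross_report <- function(x, ...) {
  cat("<wb_cross_report> success:", isTRUE(x$success), "\n")
  if (!is.null(x$stages$F3_screen)) {
    for (s in x$stages$F3_screen) {
      cat(sprintf("  F3 %s: Dpy %.2f Green %.2f (n=%d)\n",
                  s$barcode, s$frac_dpy, s$frac_green, s$n))
    }
  }
  if (!is.null(x$stages$F5_screen)) {
    for (s in x$stages$F5_screen) {
      cat(sprintf("  F5 %s: Green %.2f (n=%d)%s\n", s$barcode, s$frac_green,
                  s$n, if (s$homozygous) "  << homozygous" else ""))
    }
  }
  if (length(x$homozygous_lines)) {
    cat("  homozygous lines:", paste(x$homozygous_lines, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the genomic-integration screen
#'
#' Models the UV-integration experiment at the line level: each of `n_f1`
#' F1 lines (all array carriers) independently carries a heterozygous
#' integration of the array into a random autosome with probability
#' `p_integration` (the irradiation dose enters only through this
#' probability). `n_f2` F2 animals are singled round-robin across the F1
#' lines, each drawn from its parent's self-progeny conditioned on carrying
#' the marker. Every F2 line is then screened across `generations`
#' generations (F3, F4, ...) plus `confirm_generations` confirmation
#' generations: at each generation a carrier founder is propagated and
#' `screen_n` of its progeny are inspected; the line is called an integrant
#' iff every screened animal in every generation carries the marker.
#'
#' @param registry A `wb_registry`.
#' @param p_integration Per-F1 heterozygous-integration probability.
#' @param n_p0 Number of irradiated P0 animals (bookkeeping only).
#' @param n_f1 Number of F1 lines isolated.
#' @param n_f2 Total F2 animals singled.
#' @param screen_n Progeny screened per line per generation.
#' @param generations Screened generations before confirmation (2 = F3, F4).
#' @param confirm_generations Extra generations screened for called lines.
#' @param array Array name (defines marker tags and transmission).
#' @param control A `wb_control`.
#' @return A list of class `wb_integration_report`: per-F2-line records
#'   (`integrated`, zygosity of the founder, `called`), and summary counts.
#' @export
run_integration_screen <- function(registry = default_registry(),
                                   p_integration = 0.01,
                                   n_p0 = 68L, n_f1 = 216L, n_f2 = 612L,
                                   screen_n = 30L, generations = 2L,
                                   confirm_generations = 3L,
                                   array = "qhEx265",
                                   control = wb_control()) {
  arr <- .get_array(registry, array)
  tags <- arr$tags
  lines <- list()
  f1_integrated <- stats::runif(n_f1) < p_integration
  f1_chrom <- sample(WB_AUTOSOMES, n_f1, replace = TRUE)

  # registry clones with the integrated allele, one per chromosome used
  int_reg <- list()
  for (ch in unique(f1_chrom[f1_integrated])) {
    r2 <- add_locus(registry, paste0("intIs_", ch), ch)
    r2 <- add_allele(r2, paste0("intIs_", ch), paste0("intIs_", ch), "dominant",
                     tags = tags)
    int_reg[[ch]] <- r2
  }

  carrier_founder <- function(brood, reg) {
    hits <- Filter(function(w) w$sex == "hermaphrodite" && all(tags %in% w$phenotype),
                   brood)
    if (!length(hits)) NULL else hits[[sample.int(length(hits), 1L)]]
  }

  for (j in seq_len(n_f2)) {
    f1_idx <- 1L + (j - 1L) %% n_f1
    integrated <- f1_integrated[f1_idx]
    if (integrated) {
      reg <- int_reg[[f1_chrom[f1_idx]]]
      sym <- paste0("intIs_", f1_chrom[f1_idx])
      f1_geno <- make_genotype(reg, heterozygous = sym)
    } else {
      reg <- registry
      f1_geno <- make_genotype(reg, arrays = array)
    }
    # the F2 single: a marker-carrying self-progeny of the F1
    f2w <- NULL
    for (try in 1:20) {
      brood <- self_cross(f1_geno, 8L, reg, control)
      f2w <- carrier_founder(brood, reg)
      if (!is.null(f2w)) break
    }
    if (is.null(f2w)) next

    founder <- f2w
    called <- TRUE
    total_gens <- generations + confirm_generations
    gens_screened <- 0L
    for (g in seq_len(total_gens)) {
      brood <- self_cross(founder$genotype, screen_n, reg, control)
      all_carry <- all(vapply(brood, function(w) all(tags %in% w$phenotype),
                              logical(1)))
      gens_screened <- g
      if (!all_carry) { called <- FALSE; break }
      nf <- carrier_founder(brood, reg)
      if (is.null(nf)) { called <- FALSE; break }
      founder <- nf
    }
    lines[[length(lines) + 1L]] <- list(
      f2_line = j, f1_line = f1_idx, integrated = integrated,
      founder_zygosity = if (!integrated) "carrier" else {
        sym <- paste0("intIs_", f1_chrom[f1_idx])
        n <- sum(unlist(lapply(f2w$genotype$slots[[f1_chrom[f1_idx]]],
                               function(h) sym %in% h$alleles)))
        if (n == 2L) "homozygous" else "heterozygous"
      },
      generations_screened = gens_screened, called = called)
  }

  calls <- Filter(function(l) l$called, lines)
  structure(
    list(lines = lines,
         n_p0 = n_p0, n_f1 = n_f1, n_f2_lines = length(lines),
         n_called = length(calls),
         called_lines = vapply(calls, `[[`, integer(1), "f2_line"),
         false_positives = sum(vapply(calls, function(l) !l$integrated, logical(1))),
         p_integration = p_integration,
         transmission_prob = arr$transmission_prob,
         screen_n = screen_n, generations = generations),
    class = "wb_integration_report"
  )
}

#' @export
print.wb_integration_report <- function(x, ...) {
  cat(sprintf("<wb_integration_report> %d F2 lines from %d F1 (p_integration = %g)\n",
              x$n_f2_lines, x$n_f1, x$p_integration))
  cat(sprintf("  called integrant: %d (false positives: %d)\n",
              x$n_called, x$false_positives))
  invisible(x)
}

#' Closed-form integration-screen error rates
#'
#' The per-line false-positive probability for a non-integrated carrier line
#' (every screened animal must carry an array transmitting at `p`) is
#' `p^(screen_n * generations)`; the probability that a heterozygous
#' integrant survives one generation's screen is `0.75^screen_n`.
#'
#' @param transmission_prob Array transmission probability.
#' @param screen_n Animals screened per generation.
#' @param generations Number of screened generations.
#' @return Named list with `false_positive` and `het_pass_one_gen`.
#' @export
integration_screen_theory <- function(transmission_prob = 0.65, screen_n = 30L,
                                      generations = 2L) {
  list(false_positive = transmission_prob^(screen_n * generations),
       het_pass_one_gen = 0.75^screen_n)
}
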