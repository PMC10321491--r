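# Balancer-based linkage mapping: expected segregation fractions, the
# Linkage Index, the two test schemes, and chromosome inference.

#' Expected scored fraction under linkage or non-linkage
#'
#' The autosomal balancer scheme scores the fraction of Red animals among
#' nonGreen F2 self-progeny of a Red-Green F1 (transgene/+; balancer/+): 100%
#' when the transgene is on a balanced chromosome, 75% when it is not. The
#' X-linkage scheme scores the fraction of Red animals among F2 males sired
#' by a Red-Green F1 male: 0% if the transgene is X-linked, 50% if autosomal.
#'
#' @param test_kind `"autosomal_balancer"` or `"x_linked"`.
#' @param linked Logical: is the transgene linked to the tested region?
#' @return The expected fraction.
#' @export
expected_fraction <- function(test_kind = c("autosomal_balancer", "x_linked"),
                              linked) {
  test_kind <- match.arg(test_kind)
  stopifnot(is.logical(linked), length(linked) == 1L, !is.na(linked))
  if (test_kind == "autosomal_balancer") {
    if (linked) 1.00 else 0.75
  } else {
    if (linked) 0.00 else 0.50
  }
}

#' Linkage Index
#'
#' Normalizes an observed scored fraction against the two analytic
#' expectations: `LI = (p_obs - p_unlinked) / (p_linked - p_unlinked)`,
#' clipped to `[-1, 1]`. By construction LI is 1 at the fully linked
#' expectation (strongest possible linkage) and 0 at the unlinked expectation
#' (weakest); it increases with the observed fraction for autosomal tests and
#' decreases for X tests.
#'
#' @param p_obs Observed fraction in `[0, 1]`.
#' @param test_kind `"autosomal_balancer"` or `"x_linked"`.
#' @return The Linkage Index, a number in `[-1, 1]`.
#' @export
linkage_index <- function(p_obs, test_kind = c("autosomal_balancer", "x_linked")) {
  test_kind <- match.arg(test_kind)
  if (any(p_obs < 0 | p_obs > 1)) {
    stop("p_obs must lie in [0, 1]", call. = FALSE)
  }
  p1 <- expected_fraction(test_kind, TRUE)
  p0 <- expected_fraction(test_kind, FALSE)
  li <- (p_obs - p0) / (p1 - p0)
  pmin(1, pmax(-1, li))
}

#' Balancer coverage map for chromosome inference
#'
#' @param registry A `wb_registry`; balancer tests cover their balanced
#'   chromosomes, and the X test covers the X.
#' @return Named list mapping test name to covered chromosomes.
#' @export
balancer_coverage <- function(registry = default_registry()) {
  cov <- lapply(registry$balancers, `[[`, "chromosomes")
  cov[["X"]] <- "X"
  cov
}

.linkage_result <- function(test_kind, test_name, scored_total, scored_positive,
                            n_requested) {
  p_obs <- if (scored_total > 0) scored_positive / scored_total else NA_real_
  p1 <- expected_fraction(test_kind, TRUE)
  p0 <- expected_fraction(test_kind, FALSE)
  # exact binomial test of H0: p = p_unlinked, reported alongside the LI
  btest <- if (scored_total > 0) {
    stats::binom.test(scored_positive, scored_total, p = p0)$p.value
  } else NA_real_
  structure(
    list(test_kind = test_kind, test = test_name,
         n_scored = n_requested, scored_total = scored_total,
         scored_positive = scored_positive, p_obs = p_obs,
         p_linked_expected = p1, p_unlinked_expected = p0,
         linkage_index = if (is.na(p_obs)) NA_real_ else linkage_index(p_obs, test_kind),
         p_value_vs_unlinked = btest),
    class = "wb_linkage_result"
  )
}

#' @export
print.wb_linkage_result <- function(x, ...) {
  cat(sprintf("<wb_linkage_result> %s (%s): %d/%d positive, p_obs = %.4f, LI = %.3f\n",
              x$test, x$test_kind, x$scored_positive, x$scored_total,
              x$p_obs, x$linkage_index))
  invisible(x)
}

#' Protocol failure record
#'
#' Returned (not thrown) when a procedure cannot find the animals it needs
#' within its configured attempts; downstream code branches on it.
#'
#' @param stage Name of the failing stage.
#' @param reason Human-readable explanation.
#' @return An object of classes `wb_failure`.
#' @export
protocol_failure <- function(stage, reason) {
  structure(list(stage = stage, reason = reason), class = "wb_failure")
}

#' @rdname protocol_failure
#' @param x Object to test.
#' @export
is_failure <- function(x) inherits(x, "wb_failure")

#' @export
print.wb_failure <- function(x, ...) {
  cat("<wb_failure> at stage '", x$stage, "': ", x$reason, "\n", sep = "")
  invisible(x)
}

# Resolve the "transgene of interest": an integrated allele or, for
# unintegrated controls, an extrachromosomal array.
.resolve_transgene <- function(registry, symbol) {
  if (symbol %in% names(registry$alleles)) {
    list(kind = "allele", tags = registry$alleles[[symbol]]$tags)
  } else if (symbol %in% names(registry$arrays)) {
    list(kind = "array", tags = registry$arrays[[symbol]]$tags)
  } else {
    stop("unknown transgene: ", symbol, call. = FALSE)
  }
}

.transgene_herm <- function(registry, symbol, kind) {
  if (kind == "allele") make_genotype(registry, homozygous = symbol)
  else make_genotype(registry, arrays = symbol)
}

# Find a worm in a brood matching a predicate; NULL if none.
.first_match <- function(brood, predicate) {
  for (w in brood) {
    if (matches_predicate(w$phenotype, w$sex, predicate)) return(w)
  }
  NULL
}

#' Run one autosomal balancer linkage test
#'
#' Simulates the full scheme: Green balancer-strain males are mated to
#' hermaphrodites homozygous for the transgene of interest; an F1 carrying
#' both the transgene tag and the balancer's Green marker is selected and
#' selfed; nonGreen F2 hermaphrodites are scored for the transgene tag until
#' `n_scored` animals have been scored.
#'
#' @param transgene Allele symbol of the (dominant) transgene of interest.
#' @param balancer Name of the balancer tested.
#' @param n_scored Number of nonGreen F2 animals to score (must be > 0).
#' @param registry A `wb_registry`.
#' @param control A `wb_control`.
#' @param score_males Include males in the scored nonGreen population?
#'   Default `FALSE`.
#' @param f1_brood P0 brood size searched for the required F1.
#' @param f1_attempts Maximum P0 broods tried before declaring failure.
#' @return A `wb_linkage_result`, or a `wb_failure` if no suitable F1 arises.
#' @export
run_autosomal_linkage_test <- function(transgene, balancer, n_scored,
                                       registry = default_registry(),
                                       control = wb_control(),
                                       score_males = FALSE,
                                       f1_brood = 40, f1_attempts = 25) {
  if (n_scored <= 0) stop("n_scored must be positive", call. = FALSE)
  tg <- .resolve_transgene(registry, transgene)
  b <- .get_balancer(registry, balancer)
  herm <- .transgene_herm(registry, transgene, tg$kind)
  male <- make_genotype(registry, balancers = balancer, sex = "male")
  marker_tags <- .get_allele(registry, b$marker)$tags
  want <- list(tags_all = unique(c(tg$tags, marker_tags)), sex = "hermaphrodite")

  f1 <- NULL
  for (i in seq_len(f1_attempts)) {
    brood <- mate(herm, male, f1_brood, registry, control)
    f1 <- .first_match(brood, want)
    if (!is.null(f1)) break
  }
  if (is.null(f1)) {
    return(protocol_failure("F1 selection",
                            paste("no", paste(want$tags_all, collapse = "-"),
                                  "hermaphrodite F1 found")))
  }

  scored <- 0L; positive <- 0L
  batches <- 0L
  nonGreen <- list(tags_none = "Green")
  if (!score_males) nonGreen$sex <- "hermaphrodite"
  while (scored < n_scored) {
    batches <- batches + 1L
    if (batches > 200L) break
    need <- n_scored - scored
    f2 <- self_cross(f1$genotype, max(20L, ceiling(need * 4)), registry, control)
    for (w in f2) {
      if (!matches_predicate(w$phenotype, w$sex, nonGreen)) next
      scored <- scored + 1L
      if (all(tg$tags %in% w$phenotype)) positive <- positive + 1L
      if (scored >= n_scored) break
    }
  }
  .linkage_result("autosomal_balancer", balancer, scored, positive, n_scored)
}

#' Run the X-linkage test
#'
#' Simulates the X scheme: hermaphrodites homozygous for the transgene are
#' crossed to wild-type males carrying a dominant Green helper array; an F1
#' male showing both the transgene tag and Green (i.e. a cross-progeny male)
#' is mated to wild-type hermaphrodites, and F2 males are scored for the
#' transgene tag. F2 males inherit their X from their wild-type mother, so an
#' X-linked transgene never appears in them, while an autosomal heterozygous
#' one appears in half.
#'
#' @inheritParams run_autosomal_linkage_test
#' @param helper_array Name of the dominant Green array carried by the P0
#'   males.
#' @param n_scored Number of F2 males to score.
#' @return A `wb_linkage_result`, or a `wb_failure`.
#' @export
run_x_linkage_test <- function(transgene, helper_array = "qnEx615", n_scored,
                               registry = default_registry(),
                               control = wb_control(),
                               f1_brood = 40, f1_attempts = 25) {
  if (n_scored <= 0) stop("n_scored must be positive", call. = FALSE)
  tg <- .resolve_transgene(registry, transgene)
  arr <- .get_array(registry, helper_array)
  herm <- .transgene_herm(registry, transgene, tg$kind)
  p0_male <- make_genotype(registry, arrays = helper_array, sex = "male")
  want <- list(tags_all = unique(c(tg$tags, arr$tags)), sex = "male")

  f1 <- NULL
  for (i in seq_len(f1_attempts)) {
    brood <- mate(herm, p0_male, f1_brood, registry, control)
    f1 <- .first_match(brood, want)
    if (!is.null(f1)) break
  }
  if (is.null(f1)) {
    return(protocol_failure("F1 male selection",
                            paste("no", paste(want$tags_all, collapse = "-"),
                                  "male F1 found")))
  }

  n2 <- make_genotype(registry)
  scored <- 0L; positive <- 0L
  batches <- 0L
  while (scored < n_scored) {
    batches <- batches + 1L
    if (batches > 200L) break
    need <- n_scored - scored
    f2 <- mate(n2, f1$genotype, max(20L, ceiling(need * 2.5)), registry, control)
    for (w in f2) {
      if (w$sex != "male") next
      scored <- scored + 1L
      if (all(tg$tags %in% w$phenotype)) positive <- positive + 1L
      if (scored >= n_scored) break
    }
  }
  .linkage_result("x_linked", "X", scored, positive, n_scored)
}

#' Infer the transgene-bearing chromosome set from linkage tests
#'
#' A test is called linked when its Linkage Index reaches `threshold`. A
#' chromosome is implicated iff it lies in the coverage of every linked test
#' and in no unlinked test's coverage; with no linked test, or an
#' inconsistent pattern, the result is empty (unmapped).
#'
#' @param results List of `wb_linkage_result` (failures are dropped).
#' @param coverage Named list mapping test name to covered chromosomes; see
#'   [balancer_coverage()].
#' @param threshold Linked-call threshold on the LI (default 0.5).
#' @return Character vector of implicated chromosomes (possibly empty).
#' @export
infer_chromosome <- function(results, coverage = balancer_coverage(),
                             threshold = 0.5) {
  results <- Filter(function(x) inherits(x, "wb_linkage_result"), results)
  if (!length(results)) stop("at least one linkage result is required", call. = FALSE)
  linked <- character(); unlinked <- character()
  for (res in results) {
    nm <- res$test
    if (!nm %in% names(coverage)) stop("no coverage entry for test: ", nm, call. = FALSE)
    if (!is.na(res$linkage_index) && res$linkage_index >= threshold) {
      linked <- c(linked, nm)
    } else {
      unlinked <- c(unlinked, nm)
    }
  }
  if (!length(linked)) return(character())
  cand <- Reduce(intersect, coverage[linked])
  cand <- setdiff(cand, unlist(coverage[unlinked], use.names = FALSE))
  sort(unique(cand))
}

#' Run the full mapping panel
#'
#' Runs the four autosomal balancer tests plus the X test against one strain
#' of interest and infers the chromosome set.
#'
#' @inheritParams run_autosomal_linkage_test
#' @param balancers Balancer names to test (default all registered).
#' @param include_x Run the X-linkage test too?
#' @param threshold Linked-call threshold passed to [infer_chromosome()].
#' @param helper_array Helper array for the X test.
#' @return An object of class `wb_linkage_map`: `results` (named list),
#'   `indices` (named numeric LI per test), `coverage`, and `inferred`.
#' @export
run_linkage_mapping <- function(transgene, n_scored = 200,
                                registry = default_registry(),
                                control = wb_control(),
                                balancers = names(registry$balancers),
                                include_x = TRUE, threshold = 0.5,
                                helper_array = "qnEx615") {
  results <- list()
  for (b in balancers) {
    results[[b]] <- run_autosomal_linkage_test(transgene, b, n_scored,
                                               registry, control)
  }
  if (include_x) {
    results[["X"]] <- run_x_linkage_test(transgene, helper_array, n_scored,
                                         registry, control)
  }
  ok <- Filter(function(x) inherits(x, "wb_linkage_result"), results)
  indices <- vapply(ok, `[[`, numeric(1), "linkage_index")
  cov <- balancer_coverage(registry)[names(ok)]
  structure(
    list(results = results, indices = indices, coverage = cov,
         inferred = infer_chromosome(ok, cov, threshold), threshold = threshold),
    class = "wb_linkage_map"
  )
}

#' @export
print.wb_linkage_map <- function(x, ...) {
  cat("<wb_linkage_map>\n")
  for (nm in names(x$indices)) {
    cat(sprintf("  %-5s (covers %-8s) LI = %6.3f\n", nm,
                paste(x$coverage[[nm]], collapse = ","), x$indices[[nm]]))
  }
  cat("  inferred chromosome set: {",
      paste(x$inferred, collapse = ", "), "}\n")
  invisible(x)
}

#' Linkage-Index matrix in heat-map layout
#'
#' Lays out the tests as rows and the six chromosomes as columns, replicating
#' each test's LI across the chromosomes it covers (NA elsewhere).
#'
#' @param map A `wb_linkage_map`.
#' @return A numeric matrix, tests by chromosomes.
#' @export
linkage_matrix <- function(map) {
  stopifnot(inherits(map, "wb_linkage_map"))
  m <- matrix(NA_real_, nrow = length(map$indices), ncol = length(WB_CHROMOSOMES),
              dimnames = list(names(map$indices), WB_CHROMOSOMES))
  for (nm in names(map$indices)) {
    m[nm, map$coverage[[nm]]] <- map$indices[[nm]]
  }
  m
}

#' Write a mapping report (TSV matrix plus JSON summary)
#'
#' @param map A `wb_linkage_map`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_linkage_report <- function(map, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- linkage_matrix(map)
  tsv <- file.path(dir, "linkage_index_matrix.tsv")
  utils::write.table(data.frame(test = rownames(m), m, check.names = FALSE),
                     tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  js <- file.path(dir, "linkage_summary.json")
  summary <- list(
    indices = as.list(map$indices),
    coverage = map$coverage,
    threshold = map$threshold,
    inferred = as.list(map$inferred),
    tests = lapply(map$results, function(res) {
      if (is_failure(res)) {
        list(failure = TRUE, stage = res$stage, reason = res$reason)
      } else {
        res_fields <- c("test", "test_kind", "scored_total", "scored_positive",
                        "p_obs", "p_linked_expected", "p_unlinked_expected",
                        "linkage_index", "p_value_vs_unlinked")
        res[res_fields]
      }
    })
  )
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(tsv = tsv, json = js))
}
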