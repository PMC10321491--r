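# The virtual picking bench: barcoded plates, a CSV-backed plate database,
# stochastic pick/screen actions, and the protocol-script executor.

#' Stochastic action success rates
#'
#' Defaults follow the measured robot performance: ~90% success for both
#' picking up and putting down an animal, ~97% post-transfer survival, and an
#' aseptic workflow (contamination 0; the manual-bench preset is 0.034).
#'
#' @param pick_up_success Probability a pick-up attempt lifts the worm.
#' @param put_down_success Probability a lifted worm is deposited.
#' @param post_pick_survival Probability a transferred worm survives.
#' @param escape_prob Probability a failed put-down loses the worm.
#' @param phenotype_error Per-worm misclassification probability in screens.
#' @param contamination_prob_per_plate Per-plate contamination probability.
#' @return An object of class `wb_rates`.
#' @export
action_rates <- function(pick_up_success = 0.90, put_down_success = 0.90,
                         post_pick_survival = 0.97, escape_prob = 0.01,
                         phenotype_error = 0.0,
                         contamination_prob_per_plate = 0.0) {
  vals <- c(pick_up_success, put_down_success, post_pick_survival,
            escape_prob, phenotype_error, contamination_prob_per_plate)
  if (any(vals < 0 | vals > 1)) stop("all rates must lie in [0, 1]", call. = FALSE)
  structure(
    list(pick_up_success = pick_up_success, put_down_success = put_down_success,
         post_pick_survival = post_pick_survival, escape_prob = escape_prob,
         phenotype_error = phenotype_error,
         contamination_prob_per_plate = contamination_prob_per_plate),
    class = "wb_rates"
  )
}

#' Manual-bench action rates
#'
#' Same picking performance as the robot defaults but with the measured
#' manual contamination incidence (3.4% of plates).
#' @return A `wb_rates`.
#' @export
manual_bench_rates <- function() {
  action_rates(contamination_prob_per_plate = 0.034)
}

#' Perfect (deterministic) action rates
#' @return A `wb_rates` with every success probability 1 and every error 0.
#' @export
perfect_rates <- function() {
  action_rates(pick_up_success = 1, put_down_success = 1,
               post_pick_survival = 1, escape_prob = 0, phenotype_error = 0,
               contamination_prob_per_plate = 0)
}

#' Create a virtual bench
#'
#' The bench is a mutable environment holding the plate set, the plate
#' database, the run log, and the engine configuration. All stochastic
#' actions draw from R's global RNG; seed it once (`set.seed`) at protocol
#' start for a fully reproducible run.
#'
#' @param registry A `wb_registry`.
#' @param rates A `wb_rates`.
#' @param control A `wb_control`.
#' @param retries Retries per target worm in multi-pick steps.
#' @param exact_broods Use enumeration-backed (expectation-exact,
#'   class-stratified) plate growth instead of stochastic broods.
#' @return An object of class `wb_bench` (an environment).
#' @export
virtual_bench <- function(registry = default_registry(), rates = action_rates(),
                          control = wb_control(), retries = 3L,
                          exact_broods = FALSE) {
  b <- new.env(parent = emptyenv())
  b$registry <- registry
  b$rates <- rates
  b$control <- control
  b$retries <- as.integer(retries)
  b$exact_broods <- exact_broods
  b$plates <- list()
  b$db <- data.frame(barcode = character(), label = character(),
                     strain = character(), generation = integer(),
                     parent_barcodes = character(), created_step = character(),
                     stringsAsFactors = FALSE)
  b$log <- list()
  b$step <- 0L
  b$barcode_counter <- 0L
  class(b) <- c("wb_bench", "environment")
  b
}

#' @export
print.wb_bench <- function(x, ...) {
  cat("<wb_bench> ", length(x$plates), " plates, ", length(x$log),
      " log entries\n", sep = "")
  invisible(x)
}

.log_action <- function(bench, action, ...) {
  bench$step <- bench$step + 1L
  entry <- c(list(step = bench$step, action = action), list(...))
  bench$log[[length(bench$log) + 1L]] <- entry
  invisible(entry)
}

.next_barcode <- function(bench) {
  bench$barcode_counter <- bench$barcode_counter + 1L
  sprintf("BC%05d", bench$barcode_counter)
}

#' Register a plate in the database
#'
#' @param bench A `wb_bench`.
#' @param label Free-text plate label.
#' @param strain Strain name recorded for provenance.
#' @param worms List of `wb_individual` seeded onto the plate.
#' @param barcode Explicit barcode; autogenerated when `NULL`. Duplicate
#'   barcodes are an error.
#' @param generation Generation number recorded in the database.
#' @param parent_barcodes Provenance barcodes.
#' @return The barcode, invisibly for `plate_db_register`; the plate record
#'   for `plate_db_lookup`.
#' @export
plate_db_register <- function(bench, label, strain = "", worms = list(),
                              barcode = NULL, generation = 0L,
                              parent_barcodes = character()) {
  stopifnot(inherits(bench, "wb_bench"))
  barcode <- barcode %||% .next_barcode(bench)
  if (barcode %in% bench$db$barcode) {
    stop("duplicate barcode: ", barcode, call. = FALSE)
  }
  contaminated <- stats::runif(1) < bench$rates$contamination_prob_per_plate
  bench$plates[[barcode]] <- list(barcode = barcode, label = label,
                                  worms = worms, seeded_lawn = TRUE,
                                  contaminated = contaminated,
                                  generation = as.integer(generation))
  bench$db <- rbind(bench$db, data.frame(
    barcode = barcode, label = label, strain = strain,
    generation = as.integer(generation),
    parent_barcodes = paste(parent_barcodes, collapse = ";"),
    created_step = as.character(bench$step), stringsAsFactors = FALSE))
  .log_action(bench, "register_plate", barcode = barcode, label = label)
  invisible(barcode)
}

#' @rdname plate_db_register
#' @export
plate_db_lookup <- function(bench, barcode) {
  stopifnot(inherits(bench, "wb_bench"))
  i <- match(barcode, bench$db$barcode)
  if (is.na(i)) stop("unknown barcode: ", barcode, call. = FALSE)
  as.list(bench$db[i, , drop = FALSE])
}

#' Save / load the plate database as CSV
#'
#' The database round-trips losslessly: `plate_db_load()` of a saved file
#' reproduces the data frame exactly.
#'
#' @param bench A `wb_bench`.
#' @param path CSV path.
#' @return The path (save) or the database data frame (load).
#' @export
plate_db_save <- function(bench, path) {
  utils::write.csv(bench$db, path, row.names = FALSE)
  invisible(path)
}

#' @rdname plate_db_save
#' @export
plate_db_load <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(barcode = "character", label = "character",
                                 strain = "character", generation = "integer",
                                 parent_barcodes = "character",
                                 created_step = "character"))
}

.get_plate <- function(bench, barcode) {
  p <- bench$plates[[barcode]]
  if (is.null(p)) stop("unknown barcode: ", barcode, call. = FALSE)
  p
}

#' Worms currently on a plate
#' @param bench A `wb_bench`.
#' @param barcode Plate barcode.
#' @return List of `wb_individual`.
#' @export
plate_worms <- function(bench, barcode) .get_plate(bench, barcode)$worms

# Observed phenotype/sex match, with per-worm misclassification.
.observed_match <- function(worm, predicate, phenotype_error) {
  truth <- matches_predicate(worm$phenotype, worm$sex, predicate, worm$stage)
  if (phenotype_error > 0 && stats::runif(1) < phenotype_error) !truth else truth
}

#' Screen a plate for worms matching a predicate
#'
#' Returns the worms whose *observed* classification matches: each worm is
#' independently misclassified with probability `phenotype_error`. Screens on
#' a contaminated plate return nothing (the plate is voided).
#'
#' @param bench A `wb_bench`.
#' @param barcode Plate barcode.
#' @param predicate Predicate list (see [matches_predicate()]).
#' @return List of `wb_individual`.
#' @export
screen_plate <- function(bench, barcode, predicate = list()) {
  plate <- .get_plate(bench, barcode)
  if (plate$contaminated) {
    .log_action(bench, "screen_plate", barcode = barcode, outcome = "contaminated")
    return(list())
  }
  hits <- Filter(function(w) .observed_match(w, predicate, bench$rates$phenotype_error),
                 plate$worms)
  .log_action(bench, "screen_plate", barcode = barcode, n_matched = length(hits))
  hits
}

#' Pick one worm from a source plate to a destination plate
#'
#' Attempts to transfer a worm whose observed phenotype matches the
#' predicate. The transfer succeeds with probability
#' `pick_up_success * put_down_success`; on a failed pick-up the worm stays
#' on the source, on a failed put-down it is either lost (`escape_prob`) or
#' returned to the source, and a transferred worm dies on the destination
#' with probability `1 - post_pick_survival`.
#'
#' @param bench A `wb_bench`.
#' @param src,dst Source and destination barcodes.
#' @param predicate Predicate list; see [matches_predicate()].
#' @return An outcome record: `outcome` is one of `"moved"`, `"not_found"`,
#'   `"pickup_failed"`, `"stayed"`, `"escaped"`; `alive` says whether a moved
#'   worm survived; `worm_id` identifies the worm targeted.
#' @export
pick_worm <- function(bench, src, dst, predicate = list()) {
  splate <- .get_plate(bench, src)
  .get_plate(bench, dst)
  rates <- bench$rates
  idx <- which(vapply(splate$worms, function(w) {
    .observed_match(w, predicate, rates$phenotype_error)
  }, logical(1)))
  if (!length(idx)) {
    rec <- list(outcome = "not_found", worm_id = NA_character_, src = src, dst = dst)
    .log_action(bench, "pick_worm", src = src, dst = dst, outcome = "not_found")
    return(rec)
  }
  # stochastic mode picks a random matching worm; enumeration-backed mode
  # takes the first (broods are class-stratified, so picks span classes)
  i <- if (bench$exact_broods) idx[1] else idx[sample.int(length(idx), 1L)]
  worm <- splate$worms[[i]]
  outcome <- "moved"; alive <- TRUE
  if (stats::runif(1) >= rates$pick_up_success) {
    outcome <- "pickup_failed"
  } else if (stats::runif(1) >= rates$put_down_success) {
    if (stats::runif(1) < rates$escape_prob) {
      outcome <- "escaped"
      splate$worms[[i]] <- NULL
    } else {
      outcome <- "stayed"
    }
  } else {
    splate$worms[[i]] <- NULL
    if (stats::runif(1) >= rates$post_pick_survival) alive <- FALSE
    dplate <- bench$plates[[dst]]
    if (alive) dplate$worms[[length(dplate$worms) + 1L]] <- worm
    bench$plates[[dst]] <- dplate
  }
  bench$plates[[src]] <- splate
  .log_action(bench, "pick_worm", src = src, dst = dst, worm_id = worm$id,
              outcome = outcome, alive = alive)
  list(outcome = outcome, worm_id = worm$id, alive = alive, src = src, dst = dst)
}

#' Pick several worms matching a predicate
#'
#' Retries each target up to `bench$retries` times; stops early when the
#' source runs out of matches.
#'
#' @inheritParams pick_worm
#' @param n Number of worms to transfer.
#' @return Number of live worms transferred.
#' @export
pick_n_worms <- function(bench, src, dst, n, predicate = list()) {
  moved <- 0L
  for (target in seq_len(n)) {
    for (attempt in seq_len(max(1L, bench$retries))) {
      rec <- pick_worm(bench, src, dst, predicate)
      if (rec$outcome == "moved" && rec$alive) {
        moved <- moved + 1L
        break
      }
      if (rec$outcome == "not_found") return(moved)
    }
  }
  moved
}

#' Single worms onto fresh plates
#'
#' "Singling" transfers one matching animal to its own fresh barcoded plate
#' to found a clonal line.
#'
#' @inheritParams pick_n_worms
#' @param label_prefix Label stem for the new plates.
#' @param generation Generation recorded for the new plates.
#' @return Character vector of new barcodes (one per successfully singled
#'   worm; may be shorter than `n`).
#' @export
single_worms <- function(bench, src, n, predicate = list(),
                         label_prefix = "single", generation = 0L) {
  out <- character()
  for (k in seq_len(n)) {
    dst <- plate_db_register(bench, label = paste0(label_prefix, "_", k),
                             generation = generation, parent_barcodes = src)
    got <- pick_n_worms(bench, src, dst, 1L, predicate)
    if (got == 1L) out <- c(out, dst)
  }
  out
}

#' Grow a plate by one generation
#'
#' Replaces the worms on a plate with their brood: if both hermaphrodites
#' and males are present the hermaphrodites are outcrossed (male sperm
#' precedence), otherwise they self. In enumeration-backed mode the brood
#' follows the exact viable offspring distribution ([brood_exact()]);
#' otherwise it is sampled.
#'
#' @param bench A `wb_bench`.
#' @param barcode Plate barcode.
#' @param n Brood size; defaults to `bench$control$brood_size`.
#' @return The barcode, invisibly.
#' @export
grow_plate <- function(bench, barcode, n = NULL) {
  plate <- .get_plate(bench, barcode)
  n <- n %||% bench$control$brood_size
  herms <- Filter(function(w) w$sex == "hermaphrodite", plate$worms)
  males <- Filter(function(w) w$sex == "male", plate$worms)
  if (!length(herms)) stop("no hermaphrodite on plate ", barcode, call. = FALSE)
  per <- diff(round(seq(0, n, length.out = length(herms) + 1L)))
  brood <- list()
  for (i in seq_along(herms)) {
    mom <- herms[[i]]
    if (length(males)) {
      dad <- males[[1L + (i - 1L) %% length(males)]]
      kids <- if (bench$exact_broods) {
        brood_exact(mom$genotype, dad$genotype, per[i], bench$registry,
                    bench$control, parent_ids = c(mom$id, dad$id))
      } else {
        mate(mom$genotype, dad$genotype, per[i], bench$registry, bench$control,
             parent_ids = c(mom$id, dad$id))
      }
    } else {
      kids <- if (bench$exact_broods) {
        brood_exact(mom$genotype, NULL, per[i], bench$registry, bench$control,
                    parent_ids = mom$id)
      } else {
        self_cross(mom$genotype, per[i], bench$registry, bench$control,
                   parent_ids = mom$id)
      }
    }
    brood <- c(brood, kids)
  }
  plate$worms <- brood
  plate$generation <- plate$generation + 1L
  bench$plates[[barcode]] <- plate
  .log_action(bench, "grow_plate", barcode = barcode, n = length(brood))
  invisible(barcode)
}

#' Export the run log
#'
#' @param bench A `wb_bench`.
#' @param path Optional path; when given, the log is written as JSON lines.
#' @return The log as a list (invisibly when writing).
#' @export
run_log <- function(bench, path = NULL) {
  stopifnot(inherits(bench, "wb_bench"))
  if (!is.null(path)) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (entry in bench$log) {
      writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), con)
    }
    return(invisible(bench$log))
  }
  bench$log
}
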