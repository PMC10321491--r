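# The low/mid/high-level protocol script hierarchy and its executor.

#' Construct a protocol script node
#'
#' Scripts form a strict three-tier hierarchy: high-level scripts contain
#' only mid-level children, mid-level scripts only low-level children, and
#' low-level scripts are atomic bench actions.
#'
#' @param level `"low"`, `"mid"` or `"high"`.
#' @param name Script name (e.g. `"PickNWorms"`, `"CrossWorms"`).
#' @param args Named list of arguments.
#' @param children Ordered list of sub-scripts.
#' @return An object of class `wb_script`.
#' @export
protocol_script <- function(level = c("low", "mid", "high"), name,
                            args = list(), children = list()) {
  level <- match.arg(level)
  child_levels <- vapply(children, `[[`, character(1), "level")
  ok <- switch(level,
               low = length(children) == 0L,
               mid = all(child_levels == "low"),
               high = all(child_levels == "mid"))
  if (!ok) {
    stop(level, "-level scripts may only contain ",
         switch(level, low = "no", mid = "low-level", high = "mid-level"),
         " children", call. = FALSE)
  }
  structure(list(level = level, name = name, args = args, children = children),
            class = "wb_script")
}

#' @export
print.wb_script <- function(x, indent = 0, ...) {
  cat(strrep("  ", indent), "[", x$level, "] ", x$name, sep = "")
  if (length(x$args)) {
    shown <- vapply(x$args, function(a) paste(format(a), collapse = ","), character(1))
    cat("(", paste(names(x$args), shown, sep = "=", collapse = ", "), ")", sep = "")
  }
  cat("\n")
  for (ch in x$children) print(ch, indent = indent + 1)
  invisible(x)
}

# ---- low-level atoms --------------------------------------------------------

#' Low-level atomic scripts
#'
#' The atomic vocabulary of the bench: sterilizing the pick, picking one
#' worm, screening a plate, creating a fresh plate, and growing a plate by
#' one generation. `dst = "$last_created"` in a pick refers to the most
#' recently created plate, which is how singling chains an atom pair.
#'
#' @param src,dst,barcode Plate barcodes.
#' @param predicate Predicate list; see [matches_predicate()].
#' @param label Label for a created plate.
#' @param generation Generation recorded on a created plate.
#' @param n Brood size for growth.
#' @return A low-level `wb_script`.
#' @name low_level_scripts
NULL

#' @rdname low_level_scripts
#' @export
script_sterilize <- function() protocol_script("low", "SterilizePick")

#' @rdname low_level_scripts
#' @export
script_pick_worm <- function(src, dst, predicate = list()) {
  protocol_script("low", "PickWorm",
                  args = list(src = src, dst = dst, predicate = predicate))
}

#' @rdname low_level_scripts
#' @export
script_screen <- function(barcode, predicate = list()) {
  protocol_script("low", "Screen",
                  args = list(barcode = barcode, predicate = predicate))
}

#' @rdname low_level_scripts
#' @export
script_create_plate <- function(label, generation = 0L) {
  protocol_script("low", "CreatePlate",
                  args = list(label = label, generation = generation))
}

#' @rdname low_level_scripts
#' @export
script_grow_plate <- function(barcode, n = NULL) {
  protocol_script("low", "GrowPlate", args = list(barcode = barcode, n = n))
}

# ---- mid-level scripts ------------------------------------------------------

#' Mid-level script: pick N worms matching a predicate
#'
#' Expands to a sterilize/pick atom pair per target worm.
#'
#' @param src,dst Plate barcodes.
#' @param n Number of worms.
#' @param predicate Predicate list.
#' @return A mid-level `wb_script`.
#' @export
script_pick_n_worms <- function(src, dst, n, predicate = list()) {
  kids <- list()
  for (k in seq_len(n)) {
    kids <- c(kids, list(script_sterilize(), script_pick_worm(src, dst, predicate)))
  }
  protocol_script("mid", "PickNWorms",
                  args = list(src = src, dst = dst, n = n, predicate = predicate),
                  children = kids)
}

#' Mid-level script: single one worm onto a fresh plate
#'
#' @param src Source barcode.
#' @param predicate Predicate list.
#' @param label Label for the fresh plate.
#' @param generation Generation recorded on the fresh plate.
#' @return A mid-level `wb_script`.
#' @export
script_single_worm <- function(src, predicate = list(), label = "single",
                               generation = 0L) {
  protocol_script("mid", "SingleWorm",
                  args = list(src = src, predicate = predicate, label = label),
                  children = list(
                    script_create_plate(label, generation),
                    script_sterilize(),
                    script_pick_worm(src, "$last_created", predicate)))
}

#' Mid-level script: screen one plate
#'
#' @param barcode Plate barcode.
#' @param predicate Predicate list.
#' @return A mid-level `wb_script`.
#' @export
script_screen_plate <- function(barcode, predicate = list()) {
  protocol_script("mid", "ScreenPlate",
                  args = list(barcode = barcode, predicate = predicate),
                  children = list(script_screen(barcode, predicate)))
}

# ---- high-level scripts -----------------------------------------------------

#' High-level script: set up a mating
#'
#' Expands to two `PickNWorms` calls — one for the males, one for the
#' hermaphrodites — onto the same mating plate.
#'
#' @param males_src,herms_src Source barcodes.
#' @param n_males,n_herms Numbers to pick.
#' @param dst Mating-plate barcode.
#' @param male_predicate,herm_predicate Extra predicate fields merged with
#'   the sex clause.
#' @return A high-level `wb_script`.
#' @export
script_cross_worms <- function(males_src, n_males, herms_src, n_herms, dst,
                               male_predicate = list(), herm_predicate = list()) {
  male_predicate$sex <- "male"
  herm_predicate$sex <- "hermaphrodite"
  protocol_script("high", "CrossWorms",
                  args = list(males_src = males_src, n_males = n_males,
                              herms_src = herms_src, n_herms = n_herms, dst = dst),
                  children = list(
                    script_pick_n_worms(males_src, dst, n_males, male_predicate),
                    script_pick_n_worms(herms_src, dst, n_herms, herm_predicate)))
}

#' High-level script: single several worms onto fresh plates
#'
#' @param src Source barcode.
#' @param n Number of singles.
#' @param predicate Predicate list.
#' @param label_prefix Label stem.
#' @param generation Generation recorded on the new plates.
#' @return A high-level `wb_script`.
#' @export
script_single_worms <- function(src, n, predicate = list(),
                                label_prefix = "single", generation = 0L) {
  kids <- lapply(seq_len(n), function(k) {
    script_single_worm(src, predicate, paste0(label_prefix, "_", k), generation)
  })
  protocol_script("high", "SingleWorms",
                  args = list(src = src, n = n, predicate = predicate),
                  children = kids)
}

#' High-level script: screen a set of plates
#'
#' @param barcodes Plate barcodes.
#' @param predicate Predicate list.
#' @return A high-level `wb_script`.
#' @export
script_screen_plates <- function(barcodes, predicate = list()) {
  protocol_script("high", "ScreenPlates",
                  args = list(barcodes = barcodes, predicate = predicate),
                  children = lapply(barcodes, script_screen_plate, predicate = predicate))
}

# ---- executor ---------------------------------------------------------------

#' Execute a protocol script on the bench
#'
#' Depth-first execution with per-action logging; identical seed and
#' configuration give an identical log. Atomic picks are retried up to
#' `bench$retries` times; an atom that still cannot be satisfied appends a
#' protocol-failure record to the log (execution continues, and the returned
#' summary flags the failure).
#'
#' @param script A `wb_script`.
#' @param bench A `wb_bench`; all barcodes referenced must already exist,
#'   except plates the script itself creates.
#' @return A list: `log` (the bench log entries appended by this run),
#'   `failures` (list of `wb_failure`), `screens` (results of screen atoms,
#'   named by barcode), `created` (barcodes created).
#' @export
execute <- function(script, bench) {
  stopifnot(inherits(script, "wb_script"), inherits(bench, "wb_bench"))
  state <- new.env(parent = emptyenv())
  state$failures <- list()
  state$screens <- list()
  state$created <- character()
  state$last_created <- NA_character_
  log_start <- length(bench$log)
  .exec_node(script, bench, state)
  list(log = bench$log[seq(log_start + 1L, length.out = length(bench$log) - log_start)],
       failures = state$failures, screens = state$screens,
       created = state$created)
}

.exec_node <- function(node, bench, state) {
  if (node$level != "low") {
    for (ch in node$children) .exec_node(ch, bench, state)
    return(invisible())
  }
  a <- node$args
  resolve <- function(bc) {
    if (identical(bc, "$last_created")) {
      if (is.na(state$last_created)) stop("no plate created yet", call. = FALSE)
      state$last_created
    } else bc
  }
  switch(node$name,
    SterilizePick = {
      .log_action(bench, "sterilize_pick")
    },
    CreatePlate = {
      bc <- plate_db_register(bench, label = a$label,
                              generation = a$generation %||% 0L)
      state$last_created <- bc
      state$created <- c(state$created, bc)
    },
    PickWorm = {
      src <- resolve(a$src); dst <- resolve(a$dst)
      done <- FALSE
      for (attempt in seq_len(max(1L, bench$retries))) {
        rec <- pick_worm(bench, src, dst, a$predicate %||% list())
        if (rec$outcome == "moved" && rec$alive) { done <- TRUE; break }
        if (rec$outcome == "not_found") break
      }
      if (!done) {
        f <- protocol_failure("PickWorm",
                              paste0("could not move a matching worm from ", src))
        state$failures[[length(state$failures) + 1L]] <- f
        .log_action(bench, "protocol_failure", stage = "PickWorm", src = src)
      }
    },
    Screen = {
      bc <- resolve(a$barcode)
      state$screens[[bc]] <- screen_plate(bench, bc, a$predicate %||% list())
    },
    GrowPlate = {
      grow_plate(bench, resolve(a$barcode), a$n)
    },
    stop("unknown low-level action: ", node$name, call. = FALSE)
  )
  invisible()
}
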