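# Gametogenesis, crossing/selfing, brood generation, and the exhaustive
# enumeration oracle for offspring genotype distributions.

#' Engine control parameters
#'
#' Tunables of the transmission model. Translocation heterozygotes emit only
#' alternate-segregation (balanced) gametes unless `emit_unbalanced` is set,
#' in which case unbalanced products are emitted with total probability
#' `unbalanced_prob` and die as aneuploids. `recombination` is a per-meiosis
#' breakthrough-recombination probability between a balancer element and the
#' alleles on the homolog it balances (0 = complete balancing; linkage is
#' binary at chromosome scale). Inviable conceptions are redrawn by default
#' so that brood sizes count scorable animals; set `keep_inviable` to retain
#' them as dead records.
#'
#' @param spontaneous_male_rate Rate of X-nondisjunction males among
#'   self-progeny.
#' @param emit_unbalanced Emit unbalanced translocation gametes?
#' @param unbalanced_prob Total probability of unbalanced products when on.
#' @param recombination Breakthrough recombination probability per meiosis.
#' @param keep_inviable Return inviable conceptions as dead records?
#' @param brood_size Default brood size for plate growth.
#' @param max_attempts Redraw budget multiplier when conditioning on viable.
#' @return An object of class `wb_control`.
#' @export
wb_control <- function(spontaneous_male_rate = 0.002, emit_unbalanced = FALSE,
                       unbalanced_prob = 0.5, recombination = 0,
                       keep_inviable = FALSE, brood_size = 100,
                       max_attempts = 1000) {
  stopifnot(spontaneous_male_rate >= 0, spontaneous_male_rate <= 1,
            unbalanced_prob >= 0, unbalanced_prob <= 1,
            recombination >= 0, recombination <= 1)
  structure(
    list(spontaneous_male_rate = spontaneous_male_rate,
         emit_unbalanced = emit_unbalanced, unbalanced_prob = unbalanced_prob,
         recombination = recombination, keep_inviable = keep_inviable,
         brood_size = brood_size, max_attempts = max_attempts),
    class = "wb_control"
  )
}

# ---- segregation plan -------------------------------------------------------

# Decompose a parent's meiosis into independent segregation groups. Each group
# covers one or more chromosome slots and offers haplotype bundles with
# probabilities. Heterozygous reciprocal translocations make their two slots
# segregate jointly (both halves or both normal homologs); everything else
# assorts independently at 1/2. The X group of a male offers his X or nullo-X.
.segregation_plan <- function(genotype, registry, control = wb_control()) {
  slots <- genotype$slots
  groups <- list()
  covered <- character()

  for (b in registry$balancers) {
    if (b$kind != "reciprocal_translocation") next
    doses <- vapply(b$chromosomes, function(ch) {
      sum(vapply(slots[[ch]], function(h) identical(h$balancer, b$name), logical(1)))
    }, integer(1))
    if (all(doses == 0L)) next
    if (all(doses == 2L)) next  # homozygous: every bundle balanced, slots independent
    if (!all(doses == 1L)) {
      stop("unbalanced translocation carrier cannot undergo meiosis: ", b$name,
           call. = FALSE)
    }
    if (any(b$chromosomes %in% covered)) {
      stop("overlapping heterozygous translocations are not supported", call. = FALSE)
    }
    covered <- c(covered, b$chromosomes)
    normals <- lapply(b$chromosomes, function(ch) {
      hh <- slots[[ch]]
      hh[[which(!vapply(hh, function(h) identical(h$balancer, b$name), logical(1)))[1]]]
    })
    halves <- lapply(b$chromosomes, function(ch) {
      hh <- slots[[ch]]
      hh[[which(vapply(hh, function(h) identical(h$balancer, b$name), logical(1)))[1]]]
    })
    names(normals) <- names(halves) <- b$chromosomes
    if (control$emit_unbalanced) {
      u <- control$unbalanced_prob
      opts <- list(normals, halves,
                   stats::setNames(list(normals[[1]], halves[[2]]), b$chromosomes),
                   stats::setNames(list(halves[[1]], normals[[2]]), b$chromosomes))
      probs <- c((1 - u) / 2, (1 - u) / 2, u / 2, u / 2)
    } else {
      opts <- list(normals, halves)
      probs <- c(0.5, 0.5)
    }
    groups[[length(groups) + 1L]] <- list(slots = b$chromosomes, options = opts,
                                          probs = probs)
  }

  for (ch in WB_AUTOSOMES) {
    if (ch %in% covered) next
    hh <- slots[[ch]]
    if (.hap_key(hh[[1]]) == .hap_key(hh[[2]])) {
      groups[[length(groups) + 1L]] <- list(
        slots = ch, options = list(stats::setNames(hh[1], ch)), probs = 1)
    } else {
      groups[[length(groups) + 1L]] <- list(
        slots = ch,
        options = list(stats::setNames(hh[1], ch), stats::setNames(hh[2], ch)),
        probs = c(0.5, 0.5))
    }
  }

  xx <- slots[["X"]]
  if (length(xx) == 2L) {
    if (.hap_key(xx[[1]]) == .hap_key(xx[[2]])) {
      xopts <- list(stats::setNames(xx[1], "X"))
      xprobs <- 1
    } else {
      xopts <- list(stats::setNames(xx[1], "X"), stats::setNames(xx[2], "X"))
      xprobs <- c(0.5, 0.5)
    }
  } else {
    # male: X-bearing or nullo-X sperm, 1/2 each
    xopts <- list(stats::setNames(xx[1], "X"), list())
    xprobs <- c(0.5, 0.5)
  }
  groups[[length(groups) + 1L]] <- list(slots = "X", options = xopts, probs = xprobs)

  structure(list(groups = groups), class = "wb_segplan")
}

# Apply breakthrough recombination to one drawn gamete: with probability eps
# per balanced slot, the emitted haplotype's non-marker alleles are exchanged
# with those of the homolog that was not emitted.
.apply_recombination <- function(haps, genotype, registry, eps) {
  if (eps <= 0) return(haps)
  for (b in registry$balancers) {
    for (ch in b$chromosomes) {
      if (is.null(haps[[ch]])) next
      hh <- genotype$slots[[ch]]
      onbal <- vapply(hh, function(h) identical(h$balancer, b$name), logical(1))
      if (sum(onbal) != 1L) next  # only heterozygous balancer slots recombine here
      if (stats::runif(1) < eps) {
        emitted <- haps[[ch]]
        keys <- vapply(hh, .hap_key, character(1))
        idx <- match(.hap_key(emitted), keys)
        if (is.na(idx)) next
        other <- hh[[3L - idx]]
        marker <- .get_balancer(registry, b$name)$marker
        keep <- intersect(emitted$alleles, marker)
        swap_in <- setdiff(other$alleles, marker)
        emitted$alleles <- c(keep, swap_in)
        haps[[ch]] <- emitted
      }
    }
  }
  haps
}

#' Draw one gamete from a parent
#'
#' Each independent segregation group contributes one haplotype bundle;
#' heterozygous translocation halves co-segregate (alternate segregation), a
#' male's gamete carries his X with probability 1/2 (nullo-X otherwise), and
#' each extrachromosomal array carried by the parent is flagged independently
#' with its transmission probability.
#'
#' @param parent A viable `wb_genotype`.
#' @param registry A `wb_registry`.
#' @param control A `wb_control`.
#' @return An object of class `wb_gamete`: `haps` (named list of haplotypes,
#'   possibly lacking `"X"`) and `arrays` (character).
#' @export
make_gamete <- function(parent, registry, control = wb_control()) {
  stopifnot(inherits(parent, "wb_genotype"))
  if (viability_of(parent, registry) != "viable") {
    stop("cannot draw gametes from an inviable parent", call. = FALSE)
  }
  plan <- .segregation_plan(parent, registry, control)
  haps <- list()
  for (g in plan$groups) {
    k <- if (length(g$probs) == 1L) 1L else sample.int(length(g$probs), 1L, prob = g$probs)
    haps <- c(haps, g$options[[k]])
  }
  haps <- .apply_recombination(haps, parent, registry, control$recombination)
  arr <- character()
  for (nm in parent$arrays) {
    if (stats::runif(1) < .get_array(registry, nm)$transmission_prob) arr <- c(arr, nm)
  }
  structure(list(haps = haps, arrays = arr), class = "wb_gamete")
}

#' Fuse two gametes into a zygote genotype
#'
#' @param egg,sperm `wb_gamete` objects; the egg must carry an X.
#' @param registry A `wb_registry`.
#' @return A `wb_genotype`; sex follows the X count, arrays are the union of
#'   gamete flags. Viability is not enforced here — evaluate with
#'   [viability_of()].
#' @export
fertilize <- function(egg, sperm, registry) {
  stopifnot(inherits(egg, "wb_gamete"), inherits(sperm, "wb_gamete"))
  if (is.null(egg$haps[["X"]])) stop("egg gamete must carry an X", call. = FALSE)
  slots <- lapply(WB_AUTOSOMES, function(ch) list(egg$haps[[ch]], sperm$haps[[ch]]))
  names(slots) <- WB_AUTOSOMES
  xx <- c(egg$haps["X"], sperm$haps["X"])
  xx <- xx[!vapply(xx, is.null, logical(1))]
  names(xx) <- NULL
  slots[["X"]] <- xx
  .genotype_from_slots(slots, arrays = union(egg$arrays, sperm$arrays))
}

# ---- class-level brood sampling --------------------------------------------

# Per-offspring array carriage: an array passes from each carrier parent with
# its transmission probability, once per parent per conception (the
# per-progeny "transmission rate" as measured on broods).
.array_carry_probs <- function(parents, registry) {
  arrs <- unique(unlist(lapply(parents, function(p) p$arrays)))
  if (!length(arrs)) return(stats::setNames(numeric(), character()))
  vapply(arrs, function(nm) {
    p <- .get_array(registry, nm)$transmission_prob
    k <- sum(vapply(parents, function(g) nm %in% g$arrays, logical(1)))
    1 - (1 - p)^k
  }, numeric(1))
}

# Draw n conceptions as class keys, materializing one genotype per distinct
# class. `mother` supplies eggs; `father` NULL means selfing (sperm drawn from
# the mother's own plan). Returns list(individuals, dead) of wb_individual.
.sample_brood <- function(mother, father, n, registry, control, parent_ids = character()) {
  if (n == 0L) return(list(individuals = list(), dead = list()))
  selfing <- is.null(father)
  sire <- if (selfing) mother else father
  if (control$recombination > 0) {
    return(.sample_brood_slow(mother, father, n, registry, control, parent_ids))
  }
  eplan <- .segregation_plan(mother, registry, control)
  splan <- .segregation_plan(sire, registry, control)
  aprobs <- .array_carry_probs(if (selfing) list(mother) else list(mother, father),
                               registry)
  mrate <- if (selfing) control$spontaneous_male_rate else 0

  draw_keys <- function(m) {
    cols <- list()
    for (i in seq_along(eplan$groups)) {
      g <- eplan$groups[[i]]
      cols[[paste0("e", i)]] <- if (length(g$probs) == 1L) rep(1L, m)
        else sample.int(length(g$probs), m, replace = TRUE, prob = g$probs)
    }
    for (i in seq_along(splan$groups)) {
      g <- splan$groups[[i]]
      cols[[paste0("s", i)]] <- if (length(g$probs) == 1L) rep(1L, m)
        else sample.int(length(g$probs), m, replace = TRUE, prob = g$probs)
    }
    for (nm in names(aprobs)) {
      cols[[paste0("a_", nm)]] <- as.integer(stats::runif(m) < aprobs[[nm]])
    }
    cols[["male"]] <- if (mrate > 0) as.integer(stats::runif(m) < mrate) else rep(0L, m)
    cols
  }

  # Materialize the genotype for one class key (a row of choice indices).
  class_cache <- new.env(parent = emptyenv())
  materialize <- function(choice) {
    ehaps <- list()
    for (i in seq_along(eplan$groups)) {
      ehaps <- c(ehaps, eplan$groups[[i]]$options[[choice[[paste0("e", i)]]]])
    }
    shaps <- list()
    for (i in seq_along(splan$groups)) {
      shaps <- c(shaps, splan$groups[[i]]$options[[choice[[paste0("s", i)]]]])
    }
    if (choice[["male"]] == 1L) shaps[["X"]] <- NULL  # X nondisjunction self-male
    arrs <- names(aprobs)[vapply(names(aprobs),
                                 function(nm) choice[[paste0("a_", nm)]] == 1L,
                                 logical(1))]
    egg <- structure(list(haps = ehaps, arrays = character()), class = "wb_gamete")
    spm <- structure(list(haps = shaps, arrays = character()), class = "wb_gamete")
    g <- fertilize(egg, spm, registry)
    g$arrays <- sort(as.character(arrs))
    viable <- viability_of(g, registry) == "viable"
    # sex and phenotype are deterministic per class: compute once, reuse
    list(genotype = g, viable = viable,
         sex = sex_of(g, registry), phenotype = phenotype_of(g, registry))
  }

  out <- list(); dead <- list()
  need <- n
  attempts <- 0L
  while (need > 0L) {
    attempts <- attempts + 1L
    if (attempts > 60L) stop("brood sampling failed to produce viable offspring",
                             call. = FALSE)
    m <- max(need + 10L, ceiling(need * 1.6))
    cols <- draw_keys(m)
    keys <- do.call(paste, c(cols, sep = "."))
    for (j in seq_len(m)) {
      key <- keys[[j]]
      cls <- class_cache[[key]]
      if (is.null(cls)) {
        cls <- materialize(lapply(cols, `[[`, j))
        class_cache[[key]] <- cls
      }
      if (cls$viable) {
        out[[length(out) + 1L]] <- structure(
          list(id = paste0("w", .next_id()), sex = cls$sex, stage = "L4",
               phenotype = cls$phenotype, genotype = cls$genotype,
               parents = parent_ids),
          class = "wb_individual")
        need <- need - 1L
      } else if (control$keep_inviable) {
        # with keep_inviable, n counts conceptions: dead records use up slots
        dead[[length(dead) + 1L]] <- structure(
          list(id = paste0("w", .next_id()), sex = cls$sex, stage = "dead",
               phenotype = cls$phenotype, genotype = cls$genotype,
               parents = parent_ids),
          class = "wb_individual")
        need <- need - 1L
      }
      if (need <= 0L) break
    }
  }
  list(individuals = out, dead = dead)
}

.sample_brood_slow <- function(mother, father, n, registry, control, parent_ids) {
  selfing <- is.null(father)
  sire <- if (selfing) mother else father
  aprobs <- .array_carry_probs(if (selfing) list(mother) else list(mother, father),
                               registry)
  mrate <- if (selfing) control$spontaneous_male_rate else 0
  out <- list(); dead <- list()
  attempts <- 0L
  while (length(out) < n) {
    attempts <- attempts + 1L
    if (attempts > control$max_attempts * max(n, 1L)) {
      stop("brood sampling failed to produce viable offspring", call. = FALSE)
    }
    egg <- make_gamete(mother, registry, control)
    spm <- make_gamete(sire, registry, control)
    if (selfing && mrate > 0 && stats::runif(1) < mrate) spm$haps[["X"]] <- NULL
    g <- fertilize(egg, spm, registry)
    g$arrays <- sort(names(aprobs)[stats::runif(length(aprobs)) < aprobs])
    if (viability_of(g, registry) == "viable") {
      out[[length(out) + 1L]] <- new_individual(g, registry, parents = parent_ids)
    } else if (control$keep_inviable) {
      w <- new_individual(g, registry, parents = parent_ids)
      w$stage <- "dead"
      dead[[length(dead) + 1L]] <- w
    }
  }
  list(individuals = out, dead = dead)
}

#' Self-fertilize a hermaphrodite
#'
#' Samples `n` viable self-progeny (inviable conceptions are redrawn unless
#' `control$keep_inviable` is set, in which case they are returned as dead
#' records alongside). Self-progeny are hermaphrodite apart from spontaneous
#' X-nondisjunction males at `control$spontaneous_male_rate`.
#'
#' @param herm A hermaphrodite `wb_genotype`.
#' @param n Brood size (number of scorable animals).
#' @param registry A `wb_registry`.
#' @param control A `wb_control`.
#' @param parent_ids Parent id strings recorded on each offspring.
#' @return List of `wb_individual`. When `keep_inviable` is on, dead records
#'   are attached as attribute `"dead"`.
#' @export
self_cross <- function(herm, n, registry, control = wb_control(),
                       parent_ids = character()) {
  stopifnot(inherits(herm, "wb_genotype"), n >= 0)
  if (sex_of(herm, registry) != "hermaphrodite") {
    stop("self_cross requires a hermaphrodite", call. = FALSE)
  }
  res <- .sample_brood(herm, NULL, as.integer(n), registry, control, parent_ids)
  structure(res$individuals, dead = res$dead)
}

#' Mate a hermaphrodite with a male
#'
#' Samples `n` viable cross-progeny. Sex follows the male's X-bearing versus
#' nullo-X sperm, giving an expected 1:1 sex ratio.
#'
#' @param herm A hermaphrodite `wb_genotype`.
#' @param male A male `wb_genotype`.
#' @inheritParams self_cross
#' @return List of `wb_individual` (dead records as attribute `"dead"` when
#'   kept).
#' @export
mate <- function(herm, male, n, registry, control = wb_control(),
                 parent_ids = character()) {
  stopifnot(inherits(herm, "wb_genotype"), inherits(male, "wb_genotype"), n >= 0)
  if (sex_of(herm, registry) != "hermaphrodite") {
    stop("first parent must be a hermaphrodite", call. = FALSE)
  }
  if (sex_of(male, registry) != "male") {
    stop("second parent must be a male (two hermaphrodites cannot mate)",
         call. = FALSE)
  }
  res <- .sample_brood(herm, male, as.integer(n), registry, control, parent_ids)
  structure(res$individuals, dead = res$dead)
}

# ---- exhaustive enumeration oracle -----------------------------------------

.gamete_classes <- function(plan) {
  idx <- lapply(plan$groups, function(g) seq_along(g$probs))
  grid <- expand.grid(idx, KEEP.OUT.ATTRS = FALSE)
  classes <- list()
  for (row in seq_len(nrow(grid))) {
    haps <- list(); p <- 1
    for (gi in seq_along(plan$groups)) {
      g <- plan$groups[[gi]]
      k <- grid[row, gi]
      haps <- c(haps, g$options[[k]])
      p <- p * g$probs[k]
    }
    key <- paste(vapply(names(haps), function(nm) .hap_key(haps[[nm]]), character(1)),
                 collapse = "|")
    if (!is.null(classes[[key]])) {
      classes[[key]]$prob <- classes[[key]]$prob + p
    } else {
      classes[[key]] <- list(haps = haps, prob = p)
    }
  }
  unname(classes)
}

#' Exact offspring distribution by exhaustive enumeration
#'
#' Enumerates every gamete class of each parent with its exact probability,
#' forms all zygote combinations, expands extrachromosomal arrays as
#' carry/no-carry branches and (for selfing) the spontaneous-male branch, and
#' aggregates by canonical genotype. This is the analytic oracle the
#' stochastic brood samplers are checked against.
#'
#' Breakthrough recombination is not enumerated; call with
#' `control$recombination == 0`.
#'
#' @param parentA A hermaphrodite `wb_genotype`.
#' @param parentB A male `wb_genotype`, or `NULL` for selfing of `parentA`.
#' @param registry A `wb_registry`.
#' @param control A `wb_control`; `spontaneous_male_rate` and
#'   `emit_unbalanced` shape the enumeration.
#' @return An object of class `wb_offspring_dist`: a list with `classes`
#'   (each holding `genotype`, `prob`, `prob_viable`, `viable`, `sex`,
#'   `phenotype`) and `table`, a data frame summary. Unconditional
#'   probabilities sum to 1 over viable and inviable classes; `prob_viable`
#'   is conditioned on viability and sums to 1 over viable classes.
#' @examples
#' r <- default_registry()
#' f1 <- make_genotype(r, heterozygous = c("vsIs28", "e61"))
#' d <- enumerate_offspring(f1, registry = r)
#' phenotype_fraction(d, tags_all = c("Green", "Dpy"))  # 3/16
#' @export
enumerate_offspring <- function(parentA, parentB = NULL, registry,
                                control = wb_control(spontaneous_male_rate = 0)) {
  stopifnot(inherits(parentA, "wb_genotype"))
  if (control$recombination > 0) {
    stop("enumeration requires control$recombination == 0", call. = FALSE)
  }
  selfing <- is.null(parentB)
  if (sex_of(parentA, registry) != "hermaphrodite") {
    stop("parentA must be a hermaphrodite", call. = FALSE)
  }
  if (!selfing && sex_of(parentB, registry) != "male") {
    stop("parentB must be a male or NULL (selfing)", call. = FALSE)
  }
  sire <- if (selfing) parentA else parentB
  eggs <- .gamete_classes(.segregation_plan(parentA, registry, control))
  sperm <- .gamete_classes(.segregation_plan(sire, registry, control))
  aprobs <- .array_carry_probs(if (selfing) list(parentA) else list(parentA, parentB),
                               registry)
  mrate <- if (selfing) control$spontaneous_male_rate else 0

  arr_branches <- list(list(arrays = character(), prob = 1))
  for (nm in names(aprobs)) {
    p <- aprobs[[nm]]
    arr_branches <- unlist(lapply(arr_branches, function(br) {
      list(list(arrays = c(br$arrays, nm), prob = br$prob * p),
           list(arrays = br$arrays, prob = br$prob * (1 - p)))
    }), recursive = FALSE)
  }

  acc <- new.env(parent = emptyenv())
  add_class <- function(g, p) {
    if (p <= 0) return(invisible())
    key <- .genotype_key(g)
    cur <- acc[[key]]
    if (is.null(cur)) acc[[key]] <- list(genotype = g, prob = p)
    else {
      cur$prob <- cur$prob + p
      acc[[key]] <- cur
    }
  }

  for (e in eggs) {
    for (s in sperm) {
      base <- e$prob * s$prob
      egg <- structure(list(haps = e$haps, arrays = character()), class = "wb_gamete")
      for (br in arr_branches) {
        spm <- structure(list(haps = s$haps, arrays = character()), class = "wb_gamete")
        g <- fertilize(egg, spm, registry)
        g$arrays <- sort(br$arrays)
        if (selfing && mrate > 0 && !is.null(s$haps[["X"]])) {
          gm <- g
          gm$slots[["X"]] <- gm$slots[["X"]][1]  # drop the sperm X
          add_class(gm, base * br$prob * mrate)
          add_class(g, base * br$prob * (1 - mrate))
        } else {
          add_class(g, base * br$prob)
        }
      }
    }
  }

  classes <- lapply(ls(acc), function(k) acc[[k]])
  viable <- vapply(classes, function(cl) {
    viability_of(cl$genotype, registry) == "viable"
  }, logical(1))
  pv <- sum(vapply(classes[viable], `[[`, numeric(1), "prob"))
  classes <- lapply(seq_along(classes), function(i) {
    cl <- classes[[i]]
    cl$viable <- viable[i]
    cl$prob_viable <- if (viable[i]) cl$prob / pv else 0
    if (viable[i]) {
      cl$sex <- sex_of(cl$genotype, registry)
      cl$phenotype <- phenotype_of(cl$genotype, registry)
    } else {
      cl$sex <- NA_character_
      cl$phenotype <- character()
    }
    cl
  })
  ord <- order(vapply(classes, function(cl) -cl$prob, numeric(1)),
               vapply(classes, function(cl) .genotype_key(cl$genotype), character(1)))
  classes <- classes[ord]
  tab <- data.frame(
    genotype = vapply(classes, function(cl) format_genotype(cl$genotype), character(1)),
    sex = vapply(classes, `[[`, character(1), "sex"),
    phenotype = vapply(classes, function(cl) paste(cl$phenotype, collapse = ";"),
                       character(1)),
    viable = vapply(classes, `[[`, logical(1), "viable"),
    prob = vapply(classes, `[[`, numeric(1), "prob"),
    prob_viable = vapply(classes, `[[`, numeric(1), "prob_viable"),
    stringsAsFactors = FALSE
  )
  structure(list(classes = classes, table = tab, p_viable = pv),
            class = "wb_offspring_dist")
}

#' @export
print.wb_offspring_dist <- function(x, ...) {
  cat("<wb_offspring_dist> ", nrow(x$table), " genotype classes, P(viable) = ",
      format(x$p_viable, digits = 6), "\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Probability of a phenotype among enumerated offspring
#'
#' Computes the probability, conditioned on viability (and optionally on a
#' sub-population), that an offspring matches a phenotype/sex predicate.
#'
#' @param dist A `wb_offspring_dist`.
#' @param tags_all Tags that must all be present.
#' @param tags_none Tags that must all be absent.
#' @param sex Restrict to one sex, or `NULL`.
#' @param among Optional predicate list (fields as in [matches_predicate()])
#'   defining the conditioning sub-population (e.g. nonGreen animals).
#' @return A probability.
#' @export
phenotype_fraction <- function(dist, tags_all = character(),
                               tags_none = character(), sex = NULL,
                               among = NULL) {
  stopifnot(inherits(dist, "wb_offspring_dist"))
  num <- 0; den <- 0
  pred <- list(tags_all = if (length(tags_all)) tags_all else NULL,
               tags_none = if (length(tags_none)) tags_none else NULL,
               sex = sex)
  for (cl in dist$classes) {
    if (!cl$viable) next
    if (!is.null(among) && !matches_predicate(cl$phenotype, cl$sex, among)) next
    den <- den + cl$prob_viable
    if (matches_predicate(cl$phenotype, cl$sex, pred)) num <- num + cl$prob_viable
  }
  if (den == 0) stop("conditioning population has probability zero", call. = FALSE)
  num / den
}

#' Distinct viable phenotype classes of an offspring distribution
#'
#' @param dist A `wb_offspring_dist`.
#' @return Data frame of phenotype strings (semicolon-joined tags) with their
#'   viability-conditioned probabilities, in decreasing order.
#' @export
phenotype_classes <- function(dist) {
  stopifnot(inherits(dist, "wb_offspring_dist"))
  keys <- vapply(dist$classes, function(cl) {
    if (cl$viable) paste(cl$phenotype, collapse = ";") else NA_character_
  }, character(1))
  probs <- vapply(dist$classes, `[[`, numeric(1), "prob_viable")
  keep <- !is.na(keys)
  agg <- tapply(probs[keep], keys[keep], sum)
  out <- data.frame(phenotype = names(agg), prob = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out[order(-out$prob, out$phenotype), , drop = FALSE]
}

#' Allocate an exact expected brood (enumeration-backed growth)
#'
#' Deterministically converts the viable offspring distribution into `n`
#' individuals whose class counts follow the exact probabilities by
#' largest-remainder rounding. Used by the virtual bench's
#' enumeration-backed mode, where plate growth reproduces Mendelian
#' expectations without sampling noise.
#'
#' @inheritParams enumerate_offspring
#' @param n Brood size.
#' @param parent_ids Parent ids recorded on offspring.
#' @return List of `wb_individual`, class-stratified (round-robin over
#'   classes) so any prefix is approximately proportional.
#' @export
brood_exact <- function(parentA, parentB = NULL, n, registry,
                        control = wb_control(spontaneous_male_rate = 0),
                        parent_ids = character()) {
  dist <- enumerate_offspring(parentA, parentB, registry, control)
  viable <- Filter(function(cl) cl$viable, dist$classes)
  probs <- vapply(viable, `[[`, numeric(1), "prob_viable")
  counts <- floor(probs * n)
  rem <- probs * n - counts
  short <- n - sum(counts)
  if (short > 0) {
    take <- order(-rem)[seq_len(short)]
    counts[take] <- counts[take] + 1
  }
  # spread each class evenly through the brood so any prefix of the plate is
  # close to proportional (deterministic low-discrepancy interleave)
  cls_idx <- rep(seq_along(viable), counts)
  pos <- unlist(lapply(seq_along(viable), function(i) {
    if (counts[i] == 0) numeric() else (seq_len(counts[i]) - 0.5) / counts[i]
  }))
  ord <- order(pos, cls_idx)
  lapply(cls_idx[ord], function(i) {
    cl <- viable[[i]]
    structure(
      list(id = paste0("w", .next_id()), sex = cl$sex, stage = "L4",
           phenotype = cl$phenotype, genotype = cl$genotype,
           parents = parent_ids),
      class = "wb_individual")
  })
}
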