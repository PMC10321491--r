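# Shared fixtures: the stock registry and a few frequently used genotypes.

REG <- default_registry()

# deterministic engine (no spontaneous males) for oracle comparisons
quiet_control <- function(...) wb_control(spontaneous_male_rate = 0, ...)

# class key for comparing simulated broods against enumerated classes
class_key <- function(genotype, sex) paste(sex, format_genotype(genotype), sep = " | ")

dist_class_keys <- function(dist) {
  viable <- Filter(function(cl) cl$viable, dist$classes)
  keys <- vapply(viable, function(cl) class_key(cl$genotype, cl$sex), character(1))
  probs <- vapply(viable, `[[`, numeric(1), "prob_viable")
  stats::setNames(probs, keys)
}

# assert that brood class counts lie within 3 binomial SD of enumeration
expect_brood_matches_oracle <- function(brood, dist, n) {
  probs <- dist_class_keys(dist)
  keys <- vapply(brood, function(w) class_key(w$genotype, w$sex), character(1))
  obs <- table(keys)
  expect_true(all(names(obs) %in% names(probs)),
              info = paste("unexpected classes:",
                           paste(setdiff(names(obs), names(probs)), collapse = "; ")))
  for (k in names(probs)) {
    p <- probs[[k]]
    x <- if (k %in% names(obs)) as.integer(obs[[k]]) else 0L
    tol <- 3 * sqrt(n * p * (1 - p)) + 1
    expect_lt(abs(x - n * p), tol,
              label = paste0("count for class ", k, " (", x, " vs ", n * p, ")"))
  }
}
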