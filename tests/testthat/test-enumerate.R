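# The exhaustive enumeration oracle.

test_that("offspring probabilities sum to one, conditioned and not", {
  parents <- list(
    self = list(make_genotype(REG, heterozygous = c("vsIs28", "e61")), NULL),
    balancer_self = list(make_genotype(REG, balancers = "nT1"), NULL),
    balancer_unbalanced = list(make_genotype(REG, balancers = "hT2"), NULL),
    cross = list(make_genotype(REG, homozygous = "vsIs33"),
                 make_genotype(REG, balancers = "eT1", sex = "male")),
    array_self = list(make_genotype(REG, arrays = "qhEx265"), NULL)
  )
  for (nm in names(parents)) {
    ctl <- if (nm == "balancer_unbalanced") {
      wb_control(spontaneous_male_rate = 0.002, emit_unbalanced = TRUE)
    } else {
      wb_control(spontaneous_male_rate = 0.002)
    }
    d <- enumerate_offspring(parents[[nm]][[1]], parents[[nm]][[2]], REG, ctl)
    expect_equal(sum(d$table$prob), 1, tolerance = 1e-12)
    expect_equal(sum(d$table$prob_viable), 1, tolerance = 1e-12)
  }
})

test_that("the dihybrid self shows four phenotype classes at 9:3:3:1", {
  f1 <- make_genotype(REG, heterozygous = c("vsIs28", "e61"))
  d <- enumerate_offspring(f1, registry = REG)
  expect_equal(phenotype_fraction(d, tags_all = c("Green", "Dpy")), 3 / 16)
  cls <- phenotype_classes(d)
  expect_equal(nrow(cls), 4L)
  expect_equal(sort(cls$prob), sort(c(9, 3, 3, 1) / 16))
})

test_that("the cross's F3 stage segregates 100% Dpy and 75% Green", {
  g <- make_genotype(REG, homozygous = "e61", heterozygous = "vsIs28")
  d <- enumerate_offspring(g, registry = REG)
  expect_equal(phenotype_fraction(d, tags_all = "Green"), 0.75)
  expect_equal(phenotype_fraction(d, tags_all = "Dpy"), 1.0)
})

test_that("selfing a homozygote yields a single class with probability one", {
  hom <- make_genotype(REG, homozygous = c("vsIs28", "e61"))
  d <- enumerate_offspring(hom, registry = REG)
  expect_equal(nrow(d$table), 1L)
  expect_equal(d$table$prob, 1)
})

test_that("enumeration reproduces all four linkage-test expectations", {
  # autosomal, linked: transgene in cis to the normal homolog of a balanced
  # chromosome
  linked <- make_genotype(REG, heterozygous = "vsIs33", balancers = "nT1")
  d <- enumerate_offspring(linked, registry = REG)
  expect_equal(phenotype_fraction(d, tags_all = "Red",
                                  among = list(tags_none = "Green")),
               expected_fraction("autosomal_balancer", linked = TRUE))

  # autosomal, unlinked: transgene on an uncovered chromosome
  unlinked <- make_genotype(REG, heterozygous = "vsIs33", balancers = "mIn1")
  d <- enumerate_offspring(unlinked, registry = REG)
  expect_equal(phenotype_fraction(d, tags_all = "Red",
                                  among = list(tags_none = "Green")),
               expected_fraction("autosomal_balancer", linked = FALSE))

  # X test, autosomal transgene: half the F2 males are Red
  n2 <- make_genotype(REG)
  f1m <- make_genotype(REG, heterozygous = "vsIs33", sex = "male")
  d <- enumerate_offspring(n2, f1m, REG)
  expect_equal(phenotype_fraction(d, tags_all = "Red", among = list(sex = "male")),
               expected_fraction("x_linked", linked = FALSE))

  # X test, X-linked transgene: no Red F2 males
  rx <- add_locus(REG, "xIs", "X")
  rx <- add_allele(rx, "xIs1", "xIs", "dominant", tags = "Red")
  f1mx <- make_genotype(rx, heterozygous = "xIs1", sex = "male")
  d <- enumerate_offspring(make_genotype(rx), f1mx, rx)
  expect_equal(phenotype_fraction(d, tags_all = "Red", among = list(sex = "male")),
               expected_fraction("x_linked", linked = TRUE))
})

test_that("balancer self distributions match the balanced-segregation model", {
  het <- make_genotype(REG, balancers = "nT1")
  d <- enumerate_offspring(het, registry = REG)
  # lethal homozygote class is enumerated but conditioned away
  expect_equal(d$p_viable, 0.75)
  expect_equal(phenotype_fraction(d, tags_all = "Green"), 2 / 3)
})

test_that("simulated broods track enumerated class frequencies", {
  set.seed(20)
  configs <- list(
    list(make_genotype(REG, heterozygous = c("vsIs28", "e61")), NULL),
    list(make_genotype(REG, balancers = "nT1"), NULL),
    list(make_genotype(REG, arrays = "qhEx265"), NULL)
  )
  n <- 4000
  for (cfg in configs) {
    d <- enumerate_offspring(cfg[[1]], cfg[[2]], REG, quiet_control())
    brood <- if (is.null(cfg[[2]])) {
      self_cross(cfg[[1]], n, REG, quiet_control())
    } else {
      mate(cfg[[1]], cfg[[2]], n, REG, quiet_control())
    }
    expect_brood_matches_oracle(brood, d, n)
  }
})

test_that("enumeration-backed broods allocate exact expected counts", {
  g <- make_genotype(REG, homozygous = "e61", heterozygous = "vsIs28")
  brood <- brood_exact(g, NULL, 100, REG)
  expect_length(brood, 100L)
  green <- sum(vapply(brood, function(w) "Green" %in% w$phenotype, logical(1)))
  expect_equal(green, 75L)
  # any prefix of the plate is close to proportional
  first <- brood[1:20]
  green20 <- sum(vapply(first, function(w) "Green" %in% w$phenotype, logical(1)))
  expect_equal(green20, 15L)
})

test_that("enumeration rejects unsupported inputs", {
  male <- make_genotype(REG, sex = "male")
  expect_error(enumerate_offspring(male, registry = REG), "hermaphrodite")
  herm <- make_genotype(REG)
  expect_error(enumerate_offspring(herm, registry = REG,
                                   control = wb_control(recombination = 0.1)),
               "recombination")
})
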