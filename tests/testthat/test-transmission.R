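# Gametogenesis, selfing, mating, and their stochastic properties.

test_that("homozygous wild-type parents emit identical gametes", {
  n2 <- make_genotype(REG)
  set.seed(1)
  keys <- replicate(20, {
    g <- make_gamete(n2, REG)
    paste(vapply(g$haps, function(h) paste(h$chromosome, h$alleles, collapse = ","),
                 character(1)), collapse = "|")
  })
  expect_length(unique(keys), 1L)
})

test_that("translocation heterozygotes emit only balanced gametes at 1:1", {
  het <- make_genotype(REG, balancers = "nT1")
  set.seed(42)
  n <- 10000
  on4 <- logical(n); on5 <- logical(n)
  for (i in seq_len(n)) {
    g <- make_gamete(het, REG)
    on4[i] <- identical(g$haps[["IV"]]$balancer, "nT1")
    on5[i] <- identical(g$haps[["V"]]$balancer, "nT1")
  }
  expect_identical(on4, on5)  # halves co-segregate: both or neither
  p <- mean(on4)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / n))
})

test_that("arrays with transmission 1 are flagged on every gamete", {
  r <- add_array(REG, "exFull", tags = "Green", transmission_prob = 1)
  parent <- make_genotype(r, arrays = "exFull")
  set.seed(1)
  expect_true(all(replicate(50, "exFull" %in% make_gamete(parent, r)$arrays)))
})

test_that("fertilization sets sex by X count and keeps balanced products viable", {
  n2 <- make_genotype(REG)
  set.seed(2)
  egg <- make_gamete(n2, REG)
  nullo <- make_gamete(make_genotype(REG, sex = "male"), REG)
  while (!is.null(nullo$haps[["X"]])) {
    nullo <- make_gamete(make_genotype(REG, sex = "male"), REG)
  }
  boy <- fertilize(egg, nullo, REG)
  expect_equal(sex_of(boy, REG), "male")

  xegg <- make_gamete(n2, REG)
  xsperm <- make_gamete(n2, REG)
  girl <- fertilize(xegg, xsperm, REG)
  expect_equal(sex_of(girl, REG), "hermaphrodite")
  expect_equal(viability_of(girl, REG), "viable")

  # normal egg + translocation-carrying sperm = balanced heterozygote
  het <- make_genotype(REG, balancers = "nT1")
  sperm <- make_gamete(het, REG)
  while (!identical(sperm$haps[["IV"]]$balancer, "nT1")) {
    sperm <- make_gamete(het, REG)
  }
  z <- fertilize(egg, sperm, REG)
  expect_equal(viability_of(z, REG), "viable")
})

test_that("selfing reproduces the printed segregation fractions", {
  # true-breeding double homozygote
  hom <- make_genotype(REG, homozygous = c("vsIs28", "e61"))
  set.seed(3)
  brood <- self_cross(hom, 50, REG, quiet_control())
  expect_true(all(vapply(brood, function(w) {
    setequal(w$phenotype, c("Dpy", "Green"))
  }, logical(1))))

  # dpy-5 homozygote, vsIs28 heterozygote: 100% Dpy, 75% Green
  f3 <- make_genotype(REG, homozygous = "e61", heterozygous = "vsIs28")
  n <- 10000
  brood <- self_cross(f3, n, REG, quiet_control())
  expect_true(all(vapply(brood, function(w) "Dpy" %in% w$phenotype, logical(1))))
  green <- mean(vapply(brood, function(w) "Green" %in% w$phenotype, logical(1)))
  expect_lt(abs(green - 0.75), 3 * sqrt(0.75 * 0.25 / n))

  expect_length(self_cross(f3, 0, REG), 0L)
  expect_error(self_cross(make_genotype(REG, sex = "male"), 5, REG),
               "hermaphrodite")
})

test_that("cross-progeny sex ratio is 1:1 and hermaphrodite pairs cannot mate", {
  herm <- make_genotype(REG, homozygous = "vsIs28")
  male <- make_genotype(REG, sex = "male")
  set.seed(4)
  n <- 10000
  brood <- mate(herm, male, n, REG, quiet_control())
  # all cross-progeny inherit the dominant transgene from their homozygous mother
  expect_true(all(vapply(brood, function(w) "Green" %in% w$phenotype, logical(1))))
  pmale <- mean(vapply(brood, function(w) w$sex == "male", logical(1)))
  expect_lt(abs(pmale - 0.5), 3 * sqrt(0.25 / n))
  expect_error(mate(herm, make_genotype(REG), 5, REG), "male")
})

test_that("spontaneous males arise in self-broods at the configured rate", {
  herm <- make_genotype(REG)
  set.seed(5)
  n <- 4000
  brood <- self_cross(herm, n, REG, wb_control(spontaneous_male_rate = 0.05))
  pmale <- mean(vapply(brood, function(w) w$sex == "male", logical(1)))
  expect_lt(abs(pmale - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("inviable conceptions can be returned as dead records", {
  het <- make_genotype(REG, balancers = "nT1")
  set.seed(6)
  n <- 400
  brood <- self_cross(het, n, REG, quiet_control(keep_inviable = TRUE))
  dead <- attr(brood, "dead")
  # conceptions split into viable + dead, one quarter lethal homozygotes
  expect_equal(length(brood) + length(dead), n)
  expect_gt(length(dead), 0)
  expect_true(all(vapply(dead, function(w) {
    viability_of(w$genotype, REG) == "inviable"
  }, logical(1))))
  frac_dead <- length(dead) / n
  expect_lt(abs(frac_dead - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("translocation halves never appear singly in viable offspring", {
  het <- make_genotype(REG, balancers = "nT1")
  set.seed(7)
  brood <- self_cross(het, 500, REG,
                      quiet_control(emit_unbalanced = TRUE))
  for (w in brood) {
    d4 <- sum(vapply(w$genotype$slots[["IV"]],
                     function(h) identical(h$balancer, "nT1"), logical(1)))
    d5 <- sum(vapply(w$genotype$slots[["V"]],
                     function(h) identical(h$balancer, "nT1"), logical(1)))
    expect_identical(d4, d5)
  }
})

test_that("unbalanced emission produces inviable aneuploid conceptions", {
  het <- make_genotype(REG, balancers = "nT1")
  set.seed(8)
  brood <- self_cross(het, 300, REG,
                      quiet_control(emit_unbalanced = TRUE, keep_inviable = TRUE))
  dead <- attr(brood, "dead")
  aneuploid <- vapply(dead, function(w) {
    d4 <- sum(vapply(w$genotype$slots[["IV"]],
                     function(h) identical(h$balancer, "nT1"), logical(1)))
    d5 <- sum(vapply(w$genotype$slots[["V"]],
                     function(h) identical(h$balancer, "nT1"), logical(1)))
    d4 != d5
  }, logical(1))
  expect_gt(sum(aneuploid), 0)
})

test_that("array transmission is memoryless across genetic backgrounds", {
  set.seed(9)
  n <- 4000
  for (parent in list(make_genotype(REG, arrays = "qhEx265"),
                      make_genotype(REG, homozygous = "e61",
                                    heterozygous = "vsIs28",
                                    arrays = "qhEx265"))) {
    brood <- self_cross(parent, n, REG, quiet_control())
    carriers <- mean(vapply(brood, function(w) {
      "qhEx265" %in% w$genotype$arrays
    }, logical(1)))
    expect_lt(abs(carriers - 0.65), 3 * sqrt(0.65 * 0.35 / n))
  }
})

test_that("breakthrough recombination moves alleles onto the balancer element", {
  f1 <- make_genotype(REG, heterozygous = "vsIs33", balancers = "nT1")
  set.seed(10)
  ctl <- quiet_control(recombination = 1)
  found <- FALSE
  for (i in 1:40) {
    g <- make_gamete(f1, REG, ctl)
    if (identical(g$haps[["V"]]$balancer, "nT1") &&
        "vsIs33" %in% g$haps[["V"]]$alleles) {
      found <- TRUE
      break
    }
  }
  expect_true(found)
})
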