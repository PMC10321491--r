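# Genotype -> phenotype / viability / sex maps and the registry.

test_that("dominance rules drive phenotype expression", {
  het_green <- make_genotype(REG, heterozygous = "vsIs28")
  expect_equal(phenotype_of(het_green, REG), "Green")
  hom_green <- make_genotype(REG, homozygous = "vsIs28")
  expect_equal(phenotype_of(hom_green, REG), "Green")

  het_dpy <- make_genotype(REG, heterozygous = "e61")
  expect_equal(phenotype_of(het_dpy, REG), character(0))
  hom_dpy <- make_genotype(REG, homozygous = "e61")
  expect_equal(phenotype_of(hom_dpy, REG), "Dpy")

  both <- make_genotype(REG, homozygous = c("vsIs28", "e61"))
  expect_setequal(phenotype_of(both, REG), c("Green", "Dpy"))

  n2 <- make_genotype(REG)
  expect_equal(phenotype_of(n2, REG), character(0))
})

test_that("balancer markers and arrays are expressed dominantly", {
  bal_het <- make_genotype(REG, balancers = "nT1")
  expect_equal(phenotype_of(bal_het, REG), "Green")
  carrier <- make_genotype(REG, arrays = "qhEx265")
  expect_equal(phenotype_of(carrier, REG), "Green")
  # viable balancer homozygote expresses its homozygote tags
  eT1_hom <- make_genotype(REG, balancer_homozygous = "eT1")
  expect_setequal(phenotype_of(eT1_hom, REG), c("Green", "Unc"))
})

test_that("recessive X-linked alleles express hemizygously in males", {
  r <- add_locus(REG, "xrec", "X")
  r <- add_allele(r, "xm1", "xrec", "recessive", tags = "Unc")
  male <- make_genotype(r, heterozygous = "xm1", sex = "male")
  expect_equal(phenotype_of(male, r), "Unc")
  herm <- make_genotype(r, heterozygous = "xm1")
  expect_equal(phenotype_of(herm, r), character(0))
})

test_that("viability: lethal balancer homozygotes and aneuploids die", {
  # homozygote fate comes from the registry record
  expect_identical(REG$balancers[["nT1"]]$homozygote_fate, "lethal")
  nT1_hom <- make_genotype(REG, balancer_homozygous = "nT1")
  expect_equal(viability_of(nT1_hom, REG), "inviable")

  # eT1 homozygotes are viable (Unc) under the default configuration
  expect_equal(viability_of(make_genotype(REG, balancer_homozygous = "eT1"), REG),
               "viable")

  # one translocation half without its partner is an aneuploid
  g <- make_genotype(REG)
  bh <- balancer_haplotypes(REG, "nT1")
  g$slots[["IV"]][[2]] <- bh[["IV"]]   # half on IV, no half on V
  expect_equal(viability_of(g, REG), "inviable")

  expect_equal(viability_of(make_genotype(REG), REG), "viable")
})

test_that("all-normal genotypes are always viable", {
  combos <- list(character(), "e61", "vsIs28", c("e61", "vsIs28"), "vsIs33")
  for (hom in combos) {
    for (het in combos) {
      g <- make_genotype(REG, homozygous = hom, heterozygous = het)
      expect_equal(viability_of(g, REG), "viable")
    }
  }
})

test_that("sex follows X dosage and round-trips through construction", {
  expect_equal(sex_of(make_genotype(REG), REG), "hermaphrodite")
  expect_equal(sex_of(make_genotype(REG, sex = "male"), REG), "male")
  g <- make_genotype(REG)
  g$slots[["X"]] <- list()
  expect_error(sex_of(g, REG), "invalid karyotype")
})

test_that("registry enforces its invariants", {
  r <- new_registry()
  expect_error(add_allele(r, "a1", "nope"), "unknown locus")
  r <- add_locus(r, "l1", "I")
  r <- add_allele(r, "a1", "l1", "dominant", tags = "Green")
  expect_error(add_allele(r, "a1", "l1"), "already registered")
  expect_error(add_locus(r, "l2", "VII"), "unknown chromosome")
  # translocations balance exactly two chromosomes, inversions one
  expect_error(add_balancer(r, "tx", "reciprocal_translocation", "I", marker = "a1"),
               "exactly 2")
  expect_error(add_balancer(r, "inv", "inversion", c("I", "II"), marker = "a1"),
               "exactly 1")
  # marker must be Green
  r2 <- add_allele(r, "red1", "l1", "dominant", tags = "Red")
  expect_error(add_balancer(r2, "tx", "reciprocal_translocation", c("I", "III"),
                            marker = "red1"), "Green")
  expect_error(add_array(r, "ex1", transmission_prob = 1.2), "\\[0, 1\\]")
})

test_that("phenotype errors on unknown allele references", {
  g <- make_genotype(REG, heterozygous = "vsIs28")
  g$slots[["I"]][[1]]$alleles <- "ghost"
  expect_error(phenotype_of(g, REG), "unknown allele")
})

test_that("registry round-trips through CSV reports", {
  dir <- withr::local_tempdir()
  write_registry_csv(REG, dir)
  r2 <- read_registry_csv(dir)
  expect_equal(registry_tables(r2)[c("loci", "alleles", "balancers", "arrays")],
               registry_tables(REG)[c("loci", "alleles", "balancers", "arrays")])
})

test_that("heterozygous alleles on balanced chromosomes sit in cis to the normal homolog", {
  f1 <- make_genotype(REG, heterozygous = "vsIs33", balancers = "nT1")
  vslot <- f1$slots[["V"]]
  normal <- Filter(function(h) is.na(h$balancer), vslot)
  expect_length(normal, 1L)
  expect_true("vsIs33" %in% normal[[1]]$alleles)
})
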