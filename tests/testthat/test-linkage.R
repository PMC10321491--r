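# Linkage Index, the two test schemes, and chromosome inference.

fake_result <- function(test, li) {
  structure(list(test = test, linkage_index = li), class = "wb_linkage_result")
}

test_that("the Linkage Index anchors at the two expectations and clips", {
  expect_equal(linkage_index(1.00, "autosomal_balancer"), 1)
  expect_equal(linkage_index(0.75, "autosomal_balancer"), 0)
  expect_equal(linkage_index(0.50, "x_linked"), 0)
  expect_equal(linkage_index(0.00, "x_linked"), 1)
  # raw value (0 - 0.75) / 0.25 = -3 clips to -1
  expect_equal(linkage_index(0.00, "autosomal_balancer"), -1)
  expect_error(linkage_index(1.5, "autosomal_balancer"), "\\[0, 1\\]")
})

test_that("the Linkage Index is monotone and bounded on a grid", {
  p <- seq(0, 1, by = 0.01)
  la <- linkage_index(p, "autosomal_balancer")
  lx <- linkage_index(p, "x_linked")
  expect_true(all(diff(la) >= 0))
  expect_true(all(diff(lx) <= 0))
  expect_true(all(la >= -1 & la <= 1))
  expect_true(all(lx >= -1 & lx <= 1))
})

test_that("autosomal balancer tests read 100% linked and 75% unlinked", {
  set.seed(30)
  linked <- run_autosomal_linkage_test("vsIs33", "nT1", 600, REG, quiet_control())
  expect_s3_class(linked, "wb_linkage_result")
  expect_equal(linked$p_obs, 1.0)          # zero breakthrough recombination
  expect_equal(linked$linkage_index, 1.0)
  expect_equal(linked$scored_total, 600L)

  unlinked <- run_autosomal_linkage_test("vsIs33", "mIn1", 600, REG, quiet_control())
  expect_lt(abs(unlinked$p_obs - 0.75), 3 * sqrt(0.75 * 0.25 / 600))
  expect_lt(abs(unlinked$linkage_index), 0.25)

  expect_error(run_autosomal_linkage_test("vsIs33", "nT1", 0, REG), "positive")
})

test_that("the X test reads 0% X-linked and 50% autosomal", {
  set.seed(31)
  auto <- run_x_linkage_test("vsIs33", n_scored = 600, registry = REG,
                             control = quiet_control())
  expect_lt(abs(auto$p_obs - 0.5), 3 * sqrt(0.25 / 600))

  sc <- make_mapping_scenario("X")
  xres <- run_x_linkage_test(sc$transgene, n_scored = 600,
                             registry = sc$registry, control = quiet_control())
  expect_equal(xres$p_obs, 0)
  expect_equal(xres$linkage_index, 1)

  # degenerate helper: array that never transmits means no Green F1 males
  r0 <- add_array(REG, "exNull", tags = "Green", transmission_prob = 0)
  fail <- run_x_linkage_test("vsIs33", helper_array = "exNull", n_scored = 100,
                             registry = r0, control = quiet_control(),
                             f1_attempts = 3)
  expect_true(is_failure(fail))
})

test_that("chromosome inference applies coverage set algebra", {
  cov <- balancer_coverage(REG)
  res <- list(fake_result("eT1", 0.98), fake_result("nT1", 0.95),
              fake_result("hT2", 0.02), fake_result("mIn1", -0.04),
              fake_result("X", 0.01))
  expect_equal(infer_chromosome(res, cov), "V")

  flat <- list(fake_result("eT1", 0.03), fake_result("nT1", -0.01),
               fake_result("hT2", 0.02), fake_result("mIn1", 0.04),
               fake_result("X", 0.01))
  expect_equal(infer_chromosome(flat, cov), character(0))

  # hT2 linked alone implicates I: III is excluded by the unlinked eT1
  partial <- list(fake_result("hT2", 0.97), fake_result("eT1", 0.05),
                  fake_result("nT1", 0.01), fake_result("mIn1", 0.02),
                  fake_result("X", 0.00))
  expect_equal(infer_chromosome(partial, cov), "I")

  expect_error(infer_chromosome(list(), cov), "at least one")
})

test_that("a placement uncovered by the tests run yields the empty set", {
  set.seed(32)
  sc <- make_mapping_scenario("V")
  m <- run_linkage_mapping(sc$transgene, n_scored = 150,
                           registry = sc$registry, control = quiet_control(),
                           balancers = c("hT2", "mIn1"), include_x = TRUE)
  expect_equal(m$inferred, character(0))
})

test_that("the full panel recovers the true placement end to end", {
  set.seed(33)
  for (ch in c("II", "V")) {
    sc <- make_mapping_scenario(ch)
    m <- map_scenario(sc, n_scored = 200, control = quiet_control())
    expect_equal(m$inferred, ch)
  }
  sc <- make_mapping_scenario(NA)
  m <- map_scenario(sc, n_scored = 200, control = quiet_control())
  expect_equal(m$inferred, character(0))
})

test_that("mapping reports lay the LI matrix out over covered chromosomes", {
  set.seed(34)
  sc <- make_mapping_scenario("V")
  m <- map_scenario(sc, n_scored = 100, control = quiet_control())
  mat <- linkage_matrix(m)
  expect_equal(dim(mat), c(5L, 6L))
  expect_equal(mat["eT1", "III"], mat["eT1", "V"])  # replicated across coverage
  expect_true(is.na(mat["mIn1", "I"]))

  dir <- withr::local_tempdir()
  paths <- write_linkage_report(m, dir)
  expect_true(all(file.exists(paths)))
  tsv <- utils::read.delim(paths[["tsv"]], check.names = FALSE)
  expect_equal(tsv$test, rownames(mat))
  js <- jsonlite::read_json(paths[["json"]])
  expect_equal(unlist(js$inferred), "V")
})
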