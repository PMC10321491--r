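# Virtual bench: plates, database, stochastic actions, script execution.

fresh_bench <- function(rates = perfect_rates(), ...) {
  virtual_bench(registry = REG, rates = rates, control = quiet_control(), ...)
}

test_that("plate database enforces barcode uniqueness and round-trips CSV", {
  b <- fresh_bench()
  bc <- plate_db_register(b, "stock", strain = "N2")
  rec <- plate_db_lookup(b, bc)
  expect_equal(rec$barcode, bc)
  expect_equal(rec$label, "stock")
  expect_error(plate_db_register(b, "again", barcode = bc), "duplicate")
  expect_error(plate_db_lookup(b, "BC99999"), "unknown barcode")

  plate_db_register(b, "other", strain = "CB61", generation = 2L,
                    parent_barcodes = bc)
  path <- withr::local_tempfile(fileext = ".csv")
  plate_db_save(b, path)
  expect_identical(plate_db_load(path), b$db)
})

test_that("picking at perfect rates moves a worm deterministically", {
  b <- fresh_bench()
  src <- plate_db_register(b, "src", worms = make_strain_population(REG, "LX831", 5))
  dst <- plate_db_register(b, "dst")
  rec <- pick_worm(b, src, dst, list(tags_all = "Green"))
  expect_equal(rec$outcome, "moved")
  expect_true(rec$alive)
  expect_length(plate_worms(b, src), 4L)
  expect_length(plate_worms(b, dst), 1L)

  # no Green worms on an N2 plate
  n2p <- plate_db_register(b, "n2", worms = make_strain_population(REG, "N2", 5))
  rec <- pick_worm(b, n2p, dst, list(tags_all = "Green"))
  expect_equal(rec$outcome, "not_found")
})

test_that("pick success frequency is the pick-up x put-down product", {
  set.seed(40)
  b <- fresh_bench(rates = action_rates())  # defaults 0.9 x 0.9
  a <- plate_db_register(b, "a", worms = make_strain_population(REG, "N2", 150))
  bpl <- plate_db_register(b, "b", worms = make_strain_population(REG, "N2", 150))
  n <- 2000
  moved <- 0L
  for (i in seq_len(n)) {
    from <- if (i %% 2 == 0) a else bpl
    to <- if (i %% 2 == 0) bpl else a
    if (!length(plate_worms(b, from))) next
    rec <- pick_worm(b, from, to)
    if (rec$outcome == "moved") moved <- moved + 1L
  }
  p <- moved / n
  expect_lt(abs(p - 0.81), 3 * sqrt(0.81 * 0.19 / n))
})

test_that("screening misclassifies each worm independently", {
  b <- fresh_bench(rates = action_rates(phenotype_error = 0.1))
  bc <- plate_db_register(b, "green",
                          worms = make_strain_population(REG, "LX831", 100))
  set.seed(41)
  reps <- 50
  total <- 0L
  for (i in seq_len(reps)) {
    total <- total + length(screen_plate(b, bc, list(tags_all = "Green")))
  }
  n <- 100 * reps
  expect_lt(abs(total / n - 0.9), 3 * sqrt(0.9 * 0.1 / n))

  b0 <- fresh_bench()
  bc0 <- plate_db_register(b0, "exact",
                           worms = make_strain_population(REG, "LX831", 20))
  expect_length(screen_plate(b0, bc0, list(tags_all = "Green")), 20L)
  empty <- plate_db_register(b0, "empty")
  expect_length(screen_plate(b0, empty, list()), 0L)
})

test_that("script hierarchy is enforced and CrossWorms expands to two PickNWorms", {
  s <- script_cross_worms("A", 6, "B", 2, "C")
  expect_equal(s$level, "high")
  expect_length(s$children, 2L)
  expect_true(all(vapply(s$children, `[[`, character(1), "name") == "PickNWorms"))
  expect_equal(s$children[[1]]$args$n, 6)
  expect_equal(s$children[[2]]$args$n, 2)
  # mid-level children of a mid-level script are rejected
  expect_error(protocol_script("mid", "bad", children = list(s$children[[1]])),
               "low-level")
  expect_error(protocol_script("high", "bad", children = list(script_sterilize())),
               "mid-level")
})

test_that("executing scripts acts on the bench and logs every action", {
  b <- fresh_bench()
  src <- plate_db_register(b, "males",
                           worms = make_strain_population(REG, "N2", 120))
  dst <- plate_db_register(b, "mating")
  res <- execute(script_pick_n_worms(src, dst, 17, list(sex = "male")), b)
  expect_length(Filter(function(w) w$sex == "male", plate_worms(b, dst)), 17L)
  expect_length(res$failures, 0L)
  expect_gt(length(res$log), 0L)

  # empty high-level script executes to an empty log
  empty <- protocol_script("high", "Nothing")
  res0 <- execute(empty, b)
  expect_length(res0$log, 0L)

  # unknown barcode surfaces as an error
  bad <- script_pick_n_worms("BC99999", dst, 1)
  expect_error(execute(bad, b), "unknown barcode")
})

test_that("singling scripts create fresh plates and move one worm each", {
  b <- fresh_bench()
  src <- plate_db_register(b, "src",
                           worms = make_strain_population(REG, "LX831", 10))
  res <- execute(script_single_worms(src, 3, list(tags_all = "Green")), b)
  expect_length(res$created, 3L)
  for (bc in res$created) expect_length(plate_worms(b, bc), 1L)
  expect_length(plate_worms(b, src), 7L)
})

test_that("runs are deterministic: same seed, same log and artifacts", {
  run_once <- function() {
    set.seed(99)
    reset_id_counter()
    b <- fresh_bench(rates = action_rates())
    src <- plate_db_register(b, "src",
                             worms = make_strain_population(REG, "N2", 30))
    dst <- plate_db_register(b, "dst")
    execute(script_pick_n_worms(src, dst, 10, list()), b)
    grow_plate(b, dst, 30)
    path <- tempfile(fileext = ".jsonl")
    run_log(b, path)
    list(log = b$log, bytes = readBin(path, "raw", file.size(path)),
         db = b$db)
  }
  r1 <- run_once()
  r2 <- run_once()
  expect_identical(r1$log, r2$log)
  expect_identical(r1$bytes, r2$bytes)
  expect_identical(r1$db, r2$db)
})

test_that("worms are conserved across lossy picking", {
  set.seed(43)
  b <- fresh_bench(rates = action_rates(pick_up_success = 0.7,
                                        put_down_success = 0.7,
                                        post_pick_survival = 0.8,
                                        escape_prob = 0.3))
  src <- plate_db_register(b, "src",
                           worms = make_strain_population(REG, "N2", 60))
  dst <- plate_db_register(b, "dst")
  for (i in 1:80) pick_worm(b, src, dst)
  onplates <- length(plate_worms(b, src)) + length(plate_worms(b, dst))
  picks <- Filter(function(e) identical(e$action, "pick_worm"), b$log)
  died <- sum(vapply(picks, function(e) {
    identical(e$outcome, "moved") && identical(e$alive, FALSE)
  }, logical(1)))
  escaped <- sum(vapply(picks, function(e) identical(e$outcome, "escaped"),
                        logical(1)))
  expect_equal(onplates + died + escaped, 60L)
})

test_that("enumeration-backed growth reproduces exact expectations on plates", {
  b <- fresh_bench(exact_broods = TRUE)
  g <- make_genotype(REG, homozygous = "e61", heterozygous = "vsIs28")
  bc <- plate_db_register(b, "line",
                          worms = list(new_individual(g, REG)))
  grow_plate(b, bc, 100)
  worms <- plate_worms(b, bc)
  green <- sum(vapply(worms, function(w) "Green" %in% w$phenotype, logical(1)))
  expect_equal(green, 75L)
  expect_true(all(vapply(worms, function(w) "Dpy" %in% w$phenotype, logical(1))))
})

test_that("contaminated plates are voided in screens", {
  set.seed(44)
  b <- fresh_bench(rates = action_rates(contamination_prob_per_plate = 1))
  bc <- plate_db_register(b, "doomed",
                          worms = make_strain_population(REG, "LX831", 10))
  expect_length(screen_plate(b, bc, list(tags_all = "Green")), 0L)
  expect_equal(manual_bench_rates()$contamination_prob_per_plate, 0.034)
})
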