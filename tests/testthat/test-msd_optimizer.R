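test_that("the initial pool is the seed plus distinct single-point mutants", {
  sh <- make_shell(4)
  lc <- make_landscape(sh, m = 2, seed = 60)
  wt <- wild_type_sequence(sh)
  set.seed(61)
  pool <- initialize_pool(wt, 10L, lc, sh)
  expect_length(pool$sequences, 10L)
  expect_true(wt %in% pool$sequences)
  others <- setdiff(pool$sequences, wt)
  expect_length(others, 9L)
  d <- vapply(others, function(m) sum(utf8ToInt(m) != utf8ToInt(wt)),
              integer(1L), USE.NAMES = FALSE)
  expect_true(all(d == 1L))
  set.seed(61)
  expect_identical(initialize_pool(wt, 10L, lc, sh)$sequences,
                   pool$sequences)
  # ranked by exact score, best first
  expect_equal(pool$rs_3dm, sort(pool$rs_3dm))
  expect_equal(mean_pool_score(pool), mean(pool$rs_3dm))
  expect_error(initialize_pool("A", 25L, make_landscape(make_shell(1), 1),
                               make_shell(1)), "distinct single-point")
})

test_that("an NN iteration scores floor(s/2) novel candidates and keeps the elite", {
  sh <- make_shell(5)
  lc <- make_landscape(sh, m = 2, seed = 62)
  set.seed(63)
  pool <- initialize_pool(wild_type_sequence(sh), 12L, lc, sh)
  archive <- msdnn:::new_archive(pool)
  sur <- build_surrogate(sh, m = 2)
  cfg <- fast_config("nn")
  step <- nn_iteration(pool, archive, sur, lc, cfg, fast_training())
  expect_length(step$pool$sequences, 12L)
  expect_equal(step$diagnostics$oracle_calls, 6L)
  expect_length(step$diagnostics$cand$sequences, 6L)
  # all new candidates are novel relative to the pre-iteration archive
  expect_false(any(step$diagnostics$cand$sequences %in% archive$sequences))
  # elitism: the previous best survives, so the best score cannot worsen
  expect_true(pool$sequences[1] %in% step$pool$sequences)
  expect_lte(step$pool$rs_3dm[1], pool$rs_3dm[1])
  # archive extended by exactly the new candidates
  expect_equal(length(step$archive$sequences),
               length(archive$sequences) + 6L)
})

test_that("GA offspring are single-point mutants of pool members", {
  sh <- make_shell(5)
  lc <- make_landscape(sh, m = 2, seed = 64)
  set.seed(65)
  pool <- initialize_pool(wild_type_sequence(sh), 12L, lc, sh)
  step <- ga_iteration(pool, lc, fast_config("ga"), sh)
  expect_length(step$pool$sequences, 12L)
  d <- vapply(step$diagnostics$cand$sequences,
              function(sq) min_mutations_to_pool(sq, pool$sequences),
              integer(1L), USE.NAMES = FALSE)
  expect_true(all(d <= 1L))  # distance 0 only if a pool member is re-created
  expect_true(all(vapply(step$diagnostics$cand$sequences, function(sq)
    min(vapply(pool$sequences, function(p) sum(utf8ToInt(p) != utf8ToInt(sq)),
               integer(1L))) <= 1L, logical(1L))))
})

test_that("mmGA offspring carry 1..n mutations and reduce to the GA at k = 1", {
  sh <- make_shell(5)
  lc <- make_landscape(sh, m = 2, seed = 66)
  set.seed(67)
  pool <- initialize_pool(wild_type_sequence(sh), 12L, lc, sh)
  set.seed(68)
  step <- mmga_iteration(pool, lc, fast_config("mmga"), sh)
  d <- vapply(step$diagnostics$cand$sequences,
              function(sq) min_mutations_to_pool(sq, pool$sequences),
              integer(1L), USE.NAMES = FALSE)
  expect_true(all(d >= 0L & d <= 5L))
  # forcing k = 1 reproduces the GA draw-for-draw
  set.seed(69)
  ga <- ga_iteration(pool, lc, fast_config("ga"), sh)
  set.seed(69)
  mm <- mmga_iteration(pool, lc, fast_config("mmga", mmga_max_mutations = 1L),
                       sh)
  expect_identical(mm$pool$sequences, ga$pool$sequences)
  expect_identical(mm$pool$rs_3dm, ga$pool$rs_3dm)
})

test_that("protocol runs obey pool-size, elitism, accounting and budget invariants", {
  sh <- make_shell(5)
  lc <- make_landscape(sh, m = 2, seed = 70)
  for (proto in c("nn", "ga", "mmga")) {
    cfg <- fast_config(proto, s = 12L, Z = 400L, max_iterations = 5L)
    tr <- run_protocol(sh, lc, cfg, training = fast_training(), seed = 71)
    expect_length(tr$records, 5L)
    sizes <- vapply(tr$records, function(r) length(r$pool$sequences),
                    integer(1L))
    expect_true(all(sizes == 12L))
    best <- vapply(tr$records, function(r) r$best, numeric(1L))
    expect_true(all(diff(best) <= 1e-12))
    # oracle budget: s + (r - 1) * floor(s/2), with equality for the NN
    calls <- vapply(tr$records, function(r) as.integer(r$oracle_calls),
                    integer(1L))
    expect_equal(calls[1], 12L)
    if (proto == "nn") expect_true(all(calls[-1] == 6L))
    else expect_true(all(calls[-1] <= 6L))
    expect_lte(tr$oracle_calls_total, 12L + 4L * 6L)
  }
})

test_that("identical seeds reproduce a run; different seeds diverge", {
  sh <- make_shell(4)
  lc <- make_landscape(sh, m = 2, seed = 72)
  cfg <- fast_config("nn", s = 10L, Z = 300L, max_iterations = 3L)
  t1 <- run_protocol(sh, lc, cfg, training = fast_training(), seed = 5)
  t2 <- run_protocol(sh, lc, cfg, training = fast_training(), seed = 5)
  expect_identical(t1$rs_opt, t2$rs_opt)
  expect_identical(t1$records[[3]]$pool$sequences,
                   t2$records[[3]]$pool$sequences)
  t3 <- run_protocol(sh, lc, cfg, training = fast_training(), seed = 6)
  expect_false(identical(t1$records[[3]]$pool$sequences,
                         t3$records[[3]]$pool$sequences))
})

test_that("the archive never shrinks and no sequence is scored twice", {
  sh <- make_shell(4)
  lc <- make_landscape(sh, m = 2, seed = 73)
  set.seed(74)
  pool <- initialize_pool(wild_type_sequence(sh), 10L, lc, sh)
  archive <- msdnn:::new_archive(pool)
  cfg <- fast_config("ga", s = 10L)
  sizes <- integer(0)
  calls <- 0L
  for (i in 1:6) {
    step <- ga_iteration(pool, lc, cfg, sh, archive)
    pool <- step$pool
    archive <- step$archive
    sizes <- c(sizes, length(archive$sequences))
    calls <- calls + step$diagnostics$oracle_calls
  }
  expect_true(all(diff(sizes) >= 0))
  expect_false(anyDuplicated(archive$sequences) > 0)
  # every oracle call added a novel sequence to the archive
  expect_equal(length(archive$sequences), 10L + calls)
})

test_that("config inconsistencies fail before any oracle call", {
  sh <- make_shell(2)
  lc <- make_landscape(sh, m = 1, seed = 75)
  expect_error(protocol_config("nn", s = 1L), "s must be")
  expect_error(protocol_config("nn", s = 100L, Z = 10L), "Z must be")
  expect_error(run_protocol(sh, lc, fast_config("nn", s = 50L, Z = 400L)),
               "within one mutation")
  expect_error(run_protocol(sh, lc,
                            fast_config("mmga", mmga_max_mutations = 7L)),
               "1..n")
})

test_that("plateau stopping ends a stalled run early", {
  sh <- make_shell(4)
  lc <- make_landscape(sh, m = 1, seed = 76)
  cfg <- protocol_config("ga", s = 10L, Z = 100L, max_iterations = 40L,
                         stop_on_plateau = TRUE, plateau_window = 5L,
                         plateau_eps = 10)  # impossible improvement bar
  tr <- run_protocol(sh, lc, cfg, seed = 77)
  expect_lt(length(tr$records), 40L)
})
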