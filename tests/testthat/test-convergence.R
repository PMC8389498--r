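test_that("NAA matches hand-computed trapezoids and edge cases", {
  expect_equal(naa(c(0, 0, 0), global_min = -1), 0)      # flat curve
  expect_equal(naa(c(0, -1, -1), global_min = -1), 0.75) # (0.5 + 1) / 2
  expect_equal(naa(c(0, -0.5, -1), global_min = -1), 0.5)
  # instant drop approaches 1 as the curve stays at the minimum
  expect_gt(naa(c(0, rep(-1, 50)), global_min = -1), 0.98)
  expect_error(naa(c(0, -1), global_min = 0.5), "global_min")
  expect_error(naa(c(0, 0, 0), global_min = 0), "degenerate")
  expect_error(naa(0, -1), "at least 2")
  # range property on random admissible curves
  set.seed(80)
  for (i in 1:20) {
    curve <- cumsum(c(0, -runif(10)))
    v <- naa(curve, global_min = min(curve) - runif(1, 0.01, 1))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("first iteration reaching a threshold uses <= on minimized scores", {
  expect_equal(first_iteration_reaching(c(0, -1, -2), -1), 2L)
  expect_equal(first_iteration_reaching(c(0, -1, -2), 0), 1L)
  expect_true(is.na(first_iteration_reaching(c(0, -1, -2), -5)))
  expect_error(first_iteration_reaching(numeric(0), 0), "empty")
})

test_that("reference generation search is earliest-closest", {
  expect_equal(find_reference_generation(c(-1, -2, -3), -2), 2L)
  expect_equal(find_reference_generation(c(0, -1, 0, -1), -1), 2L)  # tie -> earliest
  expect_equal(find_reference_generation(c(-1, -2, -3), -10), 3L)   # endpoint
  expect_error(find_reference_generation(numeric(0), 0), "empty")
})

test_that("frequency tables are normalized per-position compositions", {
  sh <- make_shell(2, c("A", "A"))
  ft <- frequency_tables(c("AA", "CA"), sh)
  expect_equal(dim(ft), c(2L, 20L))
  expect_equal(rowSums(ft), c(p1 = 1, p2 = 1))
  expect_equal(unname(ft[1, c("A", "C")]), c(0.5, 0.5))
  expect_equal(unname(ft[2, "A"]), 1)
  # identical sequences give point masses
  ftp <- frequency_tables(rep("WY", 5), make_shell(2, c("W", "Y")))
  expect_equal(unname(ftp[1, "W"]), 1)
  expect_equal(unname(ftp[2, "Y"]), 1)
})

test_that("table distances span [0, sqrt(2)] with the printed maximum", {
  a <- c(1, rep(0, 19)); b <- c(0, 1, rep(0, 18))
  expect_equal(table_distance(a, a), 0)
  expect_equal(table_distance(a, b), sqrt(2))
  expect_equal(round(table_distance(a, b), 1), 1.4)
  half <- c(0.5, 0.5, rep(0, 18)); other <- c(0, 0, 0.5, 0.5, rep(0, 16))
  expect_equal(table_distance(half, other), 1.0)
  expect_error(table_distance(a, rep(0.1, 20) * 2), "not normalized")
  expect_error(table_distance(a, rep(0.05, 10)), "20 entries")
  # no valid pair exceeds the point-mass supremum
  set.seed(81)
  for (i in 1:200) {
    f1 <- -log(runif(20)); f1 <- f1 / sum(f1)
    f2 <- -log(runif(20)); f2 <- f2 / sum(f2)
    expect_lte(table_distance(f1, f2), sqrt(2))
  }
})

test_that("mean shell distance averages per-position distances", {
  a <- rbind(c(1, rep(0, 19)), c(1, rep(0, 19)))
  b <- rbind(c(1, rep(0, 19)), c(0, 1, rep(0, 18)))
  expect_equal(mean_shell_distance(a, a), 0)
  expect_equal(mean_shell_distance(a, b), sqrt(2) / 2, tolerance = 1e-9)
  expect_equal(mean_shell_distance(a[1, , drop = FALSE],
                                   b[2, , drop = FALSE]),
               table_distance(a[1, ], b[2, ]))
  expect_error(mean_shell_distance(a, b[1, , drop = FALSE]), "differ in n")
  # agreement with an independent implementation on random tables
  set.seed(82)
  fa <- t(replicate(4, { x <- runif(20); x / sum(x) }))
  fb <- t(replicate(4, { x <- runif(20); x / sum(x) }))
  expect_equal(mean_shell_distance(fa, fb), brute_mean_dist(fa, fb))
})

test_that("the shuffled null permutes within positions, preserving multisets", {
  set.seed(83)
  fts <- t(replicate(3, { x <- runif(20); x / sum(x) }))
  sh <- shuffled_null(fts)
  expect_equal(rowSums(sh), rowSums(fts))
  for (p in 1:3) expect_equal(sort(sh[p, ]), sort(fts[p, ]))
  unif <- matrix(1 / 20, 2, 20)
  expect_equal(shuffled_null(unif), unif)
  set.seed(84); s1 <- shuffled_null(fts)
  set.seed(84); s2 <- shuffled_null(fts)
  expect_identical(s1, s2)
})

test_that("GA mutation histograms place all mass at one mutation", {
  sh <- make_shell(4)
  lc <- make_landscape(sh, m = 2, seed = 85)
  tr <- run_protocol(sh, lc, fast_config("ga", s = 10L, max_iterations = 6L),
                     seed = 86)
  hist <- mutation_histogram(tr)
  expect_named(hist, c("1", "2", "3", "4"))
  expect_equal(sum(hist[-1]), 0L)
  # total mass = number of candidates over iterations 2..R (distance-0
  # re-creations of pool members are not mutations and fall outside 1..n)
  n_cand <- sum(vapply(tr$records[-1], function(r)
    length(r$cand$sequences), integer(1L)))
  expect_lte(sum(hist), n_cand)
  expect_gt(sum(hist), 0L)
  # mmGA spreads mass over 1..n
  tr2 <- run_protocol(sh, lc, fast_config("mmga", s = 10L,
                                          max_iterations = 8L), seed = 87)
  expect_gt(sum(mutation_histogram(tr2)[-1]), 0L)
})

test_that("generation PCC is the Pearson coefficient with input checks", {
  x <- c(1, 2, 3, 4)
  expect_equal(generation_pcc(x, 2 * x + 1), 1.0)
  expect_equal(generation_pcc(x, -x), -1.0)
  expect_equal(generation_pcc(c(1, 2, 3), c(2, 1, 3)), 0.5)
  expect_error(generation_pcc(x, rep(1, 4)), "constant")
  expect_error(generation_pcc(x, x[1:3]), "length")
  expect_error(generation_pcc(c(1, 2), c(2, 1)), "at least 3")
})

test_that("composition distances fall with convergence and sit below the null", {
  sh <- make_shell(4)
  lc <- make_landscape(sh, m = 2, seed = 88)
  nn <- run_protocol(sh, lc, fast_config("nn", s = 12L, Z = 500L,
                                         max_iterations = 10L),
                     training = fast_training(), seed = 89)
  ga <- run_protocol(sh, lc, fast_config("ga", s = 12L, max_iterations = 10L),
                     seed = 89)
  ref_gen <- find_reference_generation(score_curve(ga),
                                       score_curve(nn)[10])
  ref_ft <- frequency_tables(ga$records[[ref_gen]]$pool, sh)
  set.seed(90)
  summ <- composition_distance_summary(nn, ref_ft)
  expect_equal(nrow(summ), 10L)
  expect_true(all(summ$dist >= 0 & summ$dist <= sqrt(2) + 1e-12))
  # shuffled-null distances exceed the observed ones on average once both
  # protocols have converged onto structured compositions
  expect_gt(mean(summ$null_dist), mean(summ$dist))
})
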