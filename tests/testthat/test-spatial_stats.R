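line_map <- function() {
  # 5 collinear cells, labels Q Q O O O
  tumor_map(x = 0:4, y = rep(0, 5),
            qcc = c(TRUE, TRUE, FALSE, FALSE, FALSE),
            cell_id = paste0("C", 1:5))
}

test_that("neighbor_fraction matches hand geometry and the discard rule", {
  cfg <- cluster_index_config(k = 2, window = 500, B = 1)
  map <- line_map()
  # focal C1 at x=0: 2 nearest are x=1 (Q) and x=2 (O) -> 1/2
  nf <- neighbor_fraction(map, "C1", cfg)
  expect_equal(nf$fraction, 0.5)
  expect_false(nf$discarded)
  # window too small to find k neighbours -> discarded
  tight <- cluster_index_config(k = 2, window = 0.5, B = 1)
  expect_true(neighbor_fraction(map, "C1", tight)$discarded)
  # saturation: everything QCC -> fraction 1
  all_q <- line_map(); all_q$qcc <- TRUE
  expect_equal(neighbor_fraction(all_q, "C3", cfg)$fraction, 1)
  # focal must be a QCC tumor cell
  expect_error(neighbor_fraction(map, "C4", cfg), "QCC")
})

test_that("qcc_ci averages retained focal fractions", {
  cfg <- cluster_index_config(k = 2, window = 500, B = 1)
  map <- line_map()
  # C1 sees {C2:Q, C3:O} -> 0.5; C2 sees {C1:Q, C3:O} -> 0.5
  res <- qcc_ci(map, cfg)
  expect_equal(res$qcc_ci, 0.5)
  expect_equal(res$n_focal_retained, 2)
  # all-QCC dense field saturates at 1
  all_q <- line_map(); all_q$qcc <- TRUE
  expect_equal(qcc_ci(all_q, cfg)$qcc_ci, 1)
  # zero QCCs is an error distinct from all-discarded undefined
  none <- line_map(); none$qcc <- FALSE
  expect_error(qcc_ci(none, cfg), "no QCC")
  tight <- cluster_index_config(k = 2, window = 0.5, B = 1)
  und <- qcc_ci(map, tight)
  expect_true(und$undefined)
  expect_true(is.na(und$qcc_ci))
})

test_that("exact_null enumerates labelings; square example multiset", {
  cfg <- cluster_index_config(k = 1, window = 500, B = 1)
  map <- square_map()
  ex <- exact_null(map, 2, cfg)
  expect_equal(ex$n_labelings, choose(4, 2))
  expect_equal(sort(ex$scores), c(0, 0, 0, 0, 1, 1))
  expect_equal(exact_null(map, 4, cfg)$n_labelings, 1)
  big <- random_map(60)
  expect_error(exact_null(big, 20, cfg), "Monte-Carlo")
})

test_that("permutation_null is seeded, bounded and degenerate-safe", {
  map <- square_map()
  cfg <- cluster_index_config(k = 1, window = 500, B = 50, seed = 99)
  s1 <- permutation_null(map, 2, cfg)
  s2 <- permutation_null(map, 2, cfg)
  expect_identical(as.numeric(s1), as.numeric(s2))
  expect_true(all(s1 %in% c(0, 0.5, 1)))
  # n_qcc = N: every replicate labels everything -> score 1
  sN <- permutation_null(map, 4, cfg)
  expect_true(all(sN == 1))
  expect_error(permutation_null(map, 5, cfg), "exceeds")
  # seeded draws do not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(permutation_null(map, 2, cfg)); b <- runif(1)
  expect_identical(a, b)
})

test_that("empirical_p uses the add-one one-sided rule", {
  scores <- c(rep(0.1, 1000))
  expect_equal(empirical_p(0.5, scores)$p_value, 1 / 1001)
  expect_equal(empirical_p(0.1, scores)$p_value, 1)  # observed == minimum
  ep <- empirical_p(0.5, c(0.6, NA, 0.4))
  expect_equal(ep$n_defined, 2)
  expect_equal(ep$p_value, 2 / 3)
  und <- empirical_p(0.5, c(NA_real_, NA_real_))
  expect_true(und$undefined)
  expect_true(is.na(und$p_value))
})

test_that("cluster_index on the square example recovers the exact p", {
  map <- square_map()
  cfg <- cluster_index_config(k = 1, window = 500, B = 6000, seed = 4)
  res <- cluster_index(map, cfg)
  expect_equal(res$qcc_ci, 1)
  expect_equal(res$n_qcc, 2)
  # exact one-sided p is 2/6; the add-one MC estimate converges to it
  expect_lt(abs(res$p_value - 2 / 6), 3 * sqrt((1 / 3) * (2 / 3) / 6000) + 1e-3)
})

test_that("QCC-CI is invariant under rigid motion and window-matched scaling", {
  set.seed(42)
  map <- random_map(300, q_frac = 0.1, extent = 1000)
  cfg <- cluster_index_config(k = 10, window = 200, B = 1)
  base <- qcc_ci(map, cfg)
  th <- 0.7
  rot <- tumor_map(x = cos(th) * map$x - sin(th) * map$y + 5000,
                   y = sin(th) * map$x + cos(th) * map$y - 120,
                   qcc = map$qcc, cell_id = map$cell_id)
  # rotation changes which cells fall in the axis-aligned window box, so use
  # a window large enough to be non-binding in both frames
  loose <- cluster_index_config(k = 10, window = 5000, B = 1)
  expect_equal(qcc_ci(rot, loose)$fractions, qcc_ci(map, loose)$fractions)
  scaled <- tumor_map(x = 3 * map$x, y = 3 * map$y, qcc = map$qcc,
                      cell_id = map$cell_id)
  cfg3 <- cluster_index_config(k = 10, window = 600, B = 1)
  expect_equal(qcc_ci(scaled, cfg3)$fractions, base$fractions)
})

test_that("hypergeometric mean under exchangeable labels (dense field)", {
  set.seed(7)
  n <- 300; q <- 30; k <- 15
  map <- tumor_map(x = runif(n, 0, 100), y = runif(n, 0, 100),
                   qcc = FALSE, cell_id = sprintf("C%03d", 1:n))
  cfg <- cluster_index_config(k = k, window = 500, B = 400, seed = 31)
  scores <- permutation_null(map, q, cfg)
  expect_equal(attr(scores, "n_undefined"), 0)
  expected <- (q - 1) / (n - 1)
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores) - expected), 3 * se + 1e-8)
})

test_that("k-NN path agrees with the full-distance-matrix oracle", {
  set.seed(13)
  for (rep in 1:6) {
    n <- sample(50:400, 1)
    map <- random_map(n, q_frac = 0.1, extent = 800)
    k <- sample(c(3, 5, 10), 1)
    window <- sample(c(60, 150, 400), 1)
    cfg <- cluster_index_config(k = k, window = window, B = 1)
    got <- qcc_ci(map, cfg)
    want <- oracle_qcc_ci(map, k, window)
    expect_equal(got$fractions, unname(want$fractions))
    expect_equal(got$qcc_ci, want$qcc_ci)
  }
})
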