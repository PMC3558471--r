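test_that("d-statistics match the mean/(se + s0) definition", {
  z <- matrix(rep(2, 6), 1, 6, dimnames = list("flat", paste0("D", 1:6)))
  expect_equal(unname(sam_scores(z, s0 = 1)), 2)  # se = 0, d = 2/(0+1)
  expect_error(sam_scores(z, s0 = 0), "zero-variance")

  zt <- toy_z(m = 5, n = 6, seed = 2)
  expect_equal(sam_scores(zt, 0.3), oracle_scores(zt$values, 0.3))
  # antisymmetry
  expect_equal(sam_scores(paired_diff(-zt$values), 0.3),
               -sam_scores(zt, 0.3))
})

test_that("fudge-factor selection follows the percentile-CV rule", {
  expect_identical(choose_s0(1:3, c(0.1, 0.2, 0.3), method = "zero"), 0)
  expect_error(choose_s0(1:3, c(0.1, 0.2, 0.3), method = "fixed"),
               "s0_fixed")
  expect_identical(choose_s0(1:3, c(0.1, 0.2, 0.3), method = "fixed",
                             s0_fixed = 0.7), 0.7)
  # degenerate: equal standard errors -> the common value
  expect_equal(choose_s0(rnorm(30), rep(0.4, 30)), 0.4)
  # dual-implementation agreement on a fixed dataset
  set.seed(1)
  means <- rnorm(300); ses <- abs(rnorm(300, 0.3, 0.1))
  expect_equal(choose_s0(means, ses), oracle_s0(means, ses))
})

test_that("single-donor null is exactly {+d, -d}", {
  z <- matrix(c(1.5, -0.7), 2, 1, dimnames = list(c("a", "b"), "D1"))
  null <- permutation_null(z, sam_config(), s0 = 0.5)
  d <- sam_scores(z, 0.5)
  expect_true(null$exhaustive)
  expect_identical(ncol(null$permuted_scores), 2L)
  expect_setequal(as.vector(null$permuted_scores), c(d, -d))
})

test_that("all-zero input gives a degenerate null with pi0 = 1", {
  z <- matrix(0, 4, 3, dimnames = list(letters[1:4], paste0("D", 1:3)))
  null <- permutation_null(z, sam_config(), s0 = 0.5)
  expect_true(all(null$permuted_scores == 0))
  expect_identical(null$pi0, 1)
})

test_that("exhaustive enumeration matches the brute-force null", {
  zt <- toy_z(m = 7, n = 4, seed = 8)
  s0 <- 0.4
  null <- permutation_null(zt, sam_config(n_permutations = 16), s0)
  expect_true(null$exhaustive)
  expect_identical(null$n_permutations, 16L)
  onull <- oracle_null(zt$values, s0)
  expect_equal(null$expected_order_stats, unname(onull$expected))
  # same multiset of permutation score vectors
  key <- function(m) sort(apply(m, 2, paste, collapse = ","))
  expect_identical(key(round(null$permuted_scores, 10)),
                   key(round(onull$sorted, 10)))
  expect_equal(null$pi0, onull$pi0)
  expect_identical(sum(null$degenerate), 2L)
})

test_that("sampled permutation mode is seed-reproducible", {
  zt <- toy_z(m = 6, n = 10, seed = 4)
  cfg <- sam_config(n_permutations = 50, seed = 99)
  n1 <- permutation_null(zt, cfg, 0.3)
  n2 <- permutation_null(zt, cfg, 0.3)
  expect_false(n1$exhaustive)
  expect_identical(n1$permuted_scores, n2$permuted_scores)
  n3 <- permutation_null(zt, sam_config(n_permutations = 50, seed = 100), 0.3)
  expect_false(identical(n1$permuted_scores, n3$permuted_scores))
})

test_that("calling at extreme deltas behaves as specified", {
  zt <- toy_z(m = 9, n = 4, seed = 21)
  s0 <- 0.3
  d <- sam_scores(zt, s0)
  null <- permutation_null(zt, sam_config(), s0)
  # huge delta: nothing called, FDR 0
  far <- call_at_delta(d, null, 1e6)
  expect_identical(far$called, character())
  expect_identical(far$fdr_percent, 0)
  # delta = 0: everything called
  all0 <- call_at_delta(d, null, 0)
  expect_setequal(all0$called, names(d))
})

test_that("call sets and FDR agree with the brute-force SAM at every delta", {
  zt <- toy_z(m = 5, n = 4, seed = 13)
  s0 <- 0.25
  d <- sam_scores(zt, s0)
  null <- permutation_null(zt, sam_config(), s0)
  onull <- oracle_null(zt$values, s0)
  grid <- seq(0, 4, by = 0.1)
  for (delta in grid) {
    mine <- call_at_delta(d, null, delta)
    theirs <- oracle_call(d, onull, delta)
    expect_setequal(mine$called, theirs$called)
    expect_equal(mine$cutup, theirs$cutup)
    expect_equal(mine$cutlow, theirs$cutlow)
    expect_equal(mine$fdr_percent, theirs$fdr)
  }
})

test_that("delta selection takes the smallest grid point meeting the target", {
  zt <- toy_z(m = 20, n = 4, seed = 31)
  s0 <- 0.3
  d <- sam_scores(zt, s0)
  null <- permutation_null(zt, sam_config(), s0)
  cfg <- sam_config(target_fdr_percent = 100)
  delta <- select_delta(d, null, cfg)
  grid <- attr(delta, "delta_table")$delta
  expect_equal(as.numeric(delta), grid[1])
})

test_that("delta selection is stable under grid refinement", {
  set.seed(77)
  z <- matrix(rnorm(50 * 6, 0, 0.4), 50, 6)
  z[1:10, ] <- z[1:10, ] + 2
  dimnames(z) <- list(sprintf("m%02d", 1:50), paste0("D", 1:6))
  s0 <- 0.2
  d <- sam_scores(z, s0)
  null <- permutation_null(z, sam_config(), s0)
  coarse_grid <- seq(0, 5, by = 0.1)
  fine_grid <- seq(0, 5, by = 0.01)
  dc <- select_delta(d, null, sam_config(delta_grid = coarse_grid))
  df <- select_delta(d, null, sam_config(delta_grid = fine_grid))
  expect_lte(abs(as.numeric(dc) - as.numeric(df)), 0.1 + 1e-12)
})

test_that("q-values equal the brute-force minimum over calling deltas", {
  zt <- toy_z(m = 6, n = 4, seed = 17)
  s0 <- 0.35
  d <- sam_scores(zt, s0)
  null <- permutation_null(zt, sam_config(), s0)
  grid <- seq(0, 3, by = 0.05)
  q <- q_values(d, null, delta_grid = grid)
  onull <- oracle_null(zt$values, s0)
  fdr_raw <- vapply(grid, function(dl) oracle_call(d, onull, dl)$fdr,
                    numeric(1))
  fdr_adj <- cummin(fdr_raw)
  for (i in seq_along(d)) {
    calling <- vapply(grid, function(dl) {
      oc <- oracle_call(d, onull, dl)
      names(d)[i] %in% oc$called
    }, logical(1))
    expected <- if (any(calling)) min(fdr_adj[calling]) else 100
    expect_equal(unname(q[i]), min(max(expected, 0), 100))
  }
})

test_that("q-values are maximal for null input and ordered by score", {
  z <- matrix(0, 5, 4, dimnames = list(letters[1:5], paste0("D", 1:4)))
  null <- permutation_null(z, sam_config(), 0.5)
  d <- sam_scores(z, 0.5)
  q0 <- q_values(d, null)
  # degenerate all-zero input: every q sits at the common maximal value
  expect_identical(length(unique(q0)), 1L)
  expect_gte(q0[1], 90)

  zt <- toy_z(m = 30, n = 5, seed = 23)
  s0 <- 0.3
  d2 <- sam_scores(zt, s0)
  null2 <- permutation_null(zt, sam_config(), s0)
  q2 <- q_values(d2, null2)
  pos <- which(d2 > 0)
  # the largest positive score has the smallest q among positive scores
  expect_equal(unname(q2[which.max(d2)]), min(q2[pos]))
})

test_that("run_sam is deterministic and antisymmetric", {
  set.seed(55)
  z <- matrix(rnorm(40 * 6, 0, 0.4), 40, 6)
  z[1:8, ] <- z[1:8, ] + 2.5
  z[9:12, ] <- z[9:12, ] - 2.5
  dimnames(z) <- list(sprintf("m%02d", 1:40), paste0("D", 1:6))
  zp <- paired_diff(z)
  fc <- fold_change(zp)
  cfg <- sam_config(target_fdr_percent = 5)
  s1 <- run_sam(zp, fc, cfg)
  s2 <- run_sam(zp, fc, cfg)
  expect_identical(s1, s2)
  expect_identical(attr(s1, "exhaustive"), TRUE)

  zn <- paired_diff(-z)
  s3 <- run_sam(zn, fold_change(zn), cfg)
  expect_identical(nrow(s1), nrow(s3))
  expect_setequal(s1$miRNA[s1$direction == "beta"],
                  s3$miRNA[s3$direction == "alpha"])
  d1 <- attr(s1, "diagnostics"); d3 <- attr(s3, "diagnostics")
  expect_equal(d3$d_score, -d1$d_score)
  # every reported q is within the achieved FDR of the selected delta
  if (nrow(s1) > 0)
    expect_true(all(s1$q_percent <= attr(s1, "fdr_percent") + 1e-12))
})

test_that("zero-variance rows from censoring are tolerated via s0", {
  z <- rbind(flat = rep(0, 6),
             signal = c(2.1, 1.9, 2.2, 2.0, 1.8, 2.05))
  colnames(z) <- paste0("D", 1:6)
  zp <- paired_diff(z)
  s <- run_sam(zp, fold_change(zp), sam_config(target_fdr_percent = 5))
  expect_gt(attr(s, "s0"), 0)
  expect_true("signal" %in% s$miRNA || nrow(s) == 0)
})
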