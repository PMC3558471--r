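#' One-class SAM configuration
#'
#' Settings for the one-class Significance Analysis of Microarrays on
#' paired per-donor differences. With `n_permutations` at least
#' `2^n_donors` the sign-flip null is enumerated exhaustively (the
#' default 1000 covers the 64 sign vectors of a 6-donor design, making
#' the null — and hence the whole analysis — deterministic).
#'
#' @param n_permutations number of sign-flip permutations; exhaustive
#'   enumeration is used automatically when `2^n_donors <=
#'   n_permutations`.
#' @param seed RNG seed for sampled (non-exhaustive) permutation mode.
#' @param target_fdr_percent target false discovery rate in percent
#'   (default 0.5, i.e. FDR = 0.5%).
#' @param s0_method how the fudge factor s0 is chosen:
#'   `"percentile_cv_min"` (the percentile of the per-miRNA standard
#'   errors minimizing the coefficient of variation of the d-statistic
#'   spread across standard-error windows), `"fixed"` (use `s0_fixed`)
#'   or `"zero"` (plain paired t-like statistic; fails on zero-variance
#'   rows, which detection-limit censoring does create).
#' @param s0_fixed fixed s0 value when `s0_method = "fixed"`.
#' @param fdr_count how the per-permutation counts of null scores
#'   beyond the cuts are aggregated into the expected number of false
#'   calls: `"mean"` (default; add-one-corrected average over the
#'   non-degenerate permutations, so the estimate can never be exactly
#'   zero) or `"median"` (the classical SAM median count over all
#'   permutations).
#' @param delta_grid ordered non-negative thresholds scanned for the
#'   FDR; `NULL` for the default grid of `n_delta` points from 0 to the
#'   largest observed deviation from the expected order statistics.
#' @param n_delta size of the default delta grid (default 200).
#' @return A list of class `sam_config`.
#' @export
sam_config <- function(n_permutations = 1000, seed = 1L,
                       target_fdr_percent = 0.5,
                       s0_method = c("percentile_cv_min", "fixed", "zero"),
                       s0_fixed = NULL,
                       fdr_count = c("mean", "median"),
                       delta_grid = NULL, n_delta = 200) {
  s0_method <- match.arg(s0_method)
  fdr_count <- match.arg(fdr_count)
  stopifnot(n_permutations >= 1,
            target_fdr_percent > 0, target_fdr_percent <= 100,
            n_delta >= 2)
  if (!is.null(delta_grid)) {
    stopifnot(all(delta_grid >= 0), !is.unsorted(delta_grid),
              length(delta_grid) >= 1)
  }
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 target_fdr_percent = target_fdr_percent,
                 s0_method = s0_method, s0_fixed = s0_fixed,
                 fdr_count = fdr_count,
                 delta_grid = delta_grid, n_delta = as.integer(n_delta)),
            class = "sam_config")
}

# row means and standard errors of a paired-difference matrix;
# se = sd/sqrt(n), with se = 0 for the degenerate single-donor case
row_stats <- function(v) {
  n <- ncol(v)
  m <- rowMeans(v)
  if (n > 1) {
    ss <- rowSums(v * v) - n * m * m
    se <- sqrt(pmax(ss, 0) / (n - 1)) / sqrt(n)
  } else se <- rep(0, nrow(v))
  list(mean = m, se = se, n = n)
}

#' SAM d-statistics
#'
#' `d_i = mean(z_i) / (se_i + s0)` per miRNA, where `se_i` is the
#' standard error of the per-donor paired differences and s0 is the
#' fudge factor stabilizing low-variance rows. The sign of d equals the
#' sign of the mean difference (positive = beta-enriched under the
#' `z = alpha dCt - beta dCt` convention).
#'
#' @param z a [paired_diff()] or numeric matrix (assays x donors).
#' @param s0 fudge factor, `>= 0`; with `s0 = 0` any zero-variance row
#'   is a hard error (division by zero).
#' @return Named numeric vector of d scores.
#' @export
sam_scores <- function(z, s0) {
  v <- if (inherits(z, "paired_diff")) z$values else z
  stopifnot(is.matrix(v), is.numeric(s0), length(s0) == 1, s0 >= 0)
  st <- row_stats(v)
  if (s0 == 0 && any(st$se == 0))
    stop("zero-variance row(s) with s0 = 0 would divide by zero; ",
         "use s0 > 0 (e.g. s0_method = 'percentile_cv_min')")
  stats::setNames(st$mean / (st$se + s0), rownames(v))
}

#' Choose the SAM fudge factor s0
#'
#' `"percentile_cv_min"` evaluates candidate s0 values at the 0, 5, ...,
#' 100 percentiles of the per-miRNA standard errors and keeps the one
#' minimizing the coefficient of variation of the median absolute
#' deviation of d across standard-error quantile windows — the standard
#' SAM recipe for making the spread of d roughly independent of the
#' standard error.
#'
#' @param means per-miRNA mean paired differences.
#' @param ses per-miRNA standard errors (non-negative).
#' @param method `"percentile_cv_min"`, `"fixed"` or `"zero"`.
#' @param s0_fixed value used when `method = "fixed"`.
#' @param n_windows number of standard-error quantile windows used to
#'   measure the spread of d (default 100, reduced automatically for
#'   small panels).
#' @return A single s0 value.
#' @export
choose_s0 <- function(means, ses,
                      method = c("percentile_cv_min", "fixed", "zero"),
                      s0_fixed = NULL, n_windows = 100) {
  method <- match.arg(method)
  stopifnot(length(means) == length(ses), all(ses >= 0))
  if (method == "zero") return(0)
  if (method == "fixed") {
    if (is.null(s0_fixed)) stop("s0_method = 'fixed' requires `s0_fixed`")
    return(s0_fixed)
  }
  cand <- stats::quantile(ses, probs = seq(0, 1, by = 0.05),
                          names = FALSE, type = 7)
  n_windows <- max(2, min(n_windows, floor(length(ses) / 3)))
  brk <- unique(stats::quantile(ses, probs = seq(0, 1, length.out =
                                                   n_windows + 1),
                                names = FALSE, type = 7))
  grp <- if (length(brk) > 2)
    cut(ses, breaks = brk, include.lowest = TRUE) else
    factor(rep(1, length(ses)))
  cv <- vapply(cand, function(s0) {
    d <- means / (ses + s0)
    mads <- tapply(d, grp, stats::mad)
    mads <- mads[!is.na(mads)]
    mu <- mean(mads)
    if (length(mads) < 2 || mu == 0) return(NA_real_)
    stats::sd(mads) / mu
  }, numeric(1))
  s0 <- if (all(is.na(cv))) cand[1] else cand[which.min(cv)]
  # zero-variance rows (a product of detection-limit censoring) need a
  # strictly positive denominator
  if (s0 == 0 && any(ses == 0)) {
    pos <- cand[cand > 0]
    s0 <- if (length(pos)) min(pos) else 1
  }
  s0
}

#' Sign-flip permutation null for one-class SAM
#'
#' Each permutation multiplies each donor's paired-difference column by
#' an independent +/-1 and recomputes all d-statistics (the appropriate
#' null for a one-class test of mean zero on paired differences). When
#' `2^n_donors <= n_permutations`, all sign vectors are enumerated
#' exhaustively — an exact, deterministic null (64 vectors for 6
#' donors). Otherwise sign vectors are sampled with the configured
#' seed.
#'
#' The null object carries each permutation's scores sorted within its
#' column, the expected order statistics (row-wise means of the sorted
#' columns), and the pi0 estimate
#' `min(1, #\{d in [q25, q75] of the pooled null\} / (0.5 m))`. Sign
#' vectors that reproduce the observed configuration exactly (all +1)
#' or its mirror (all -1) are flagged `degenerate`: they enter the
#' expected order statistics but are excluded from false-call counting,
#' where they would count every true discovery as a false one.
#'
#' @param z a [paired_diff()] or numeric matrix (assays x donors).
#' @param cfg a [sam_config()].
#' @param s0 fudge factor used for all permuted scores.
#' @return A list of class `sam_null` with elements `permuted_scores`
#'   (m x B, columns sorted), `expected_order_stats`, `pi0`,
#'   `exhaustive` and `n_permutations`.
#' @export
permutation_null <- function(z, cfg, s0) {
  v <- if (inherits(z, "paired_diff")) z$values else z
  stopifnot(is.matrix(v))
  n <- ncol(v); m <- nrow(v)
  exhaustive <- 2^n <= cfg$n_permutations
  signs <- if (exhaustive) {
    as.matrix(t(expand.grid(rep(list(c(-1, 1)), n))))
  } else {
    withr_seed <- cfg$seed
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(withr_seed)
    s <- matrix(sample(c(-1, 1), n * cfg$n_permutations, replace = TRUE),
                nrow = n)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    s
  }
  B <- ncol(signs)
  # d for all permutations at once: the row sum of squares is invariant
  # under sign flips, so only the permuted means need a matrix product
  means <- (v %*% signs) / n
  if (n > 1) {
    ss <- rowSums(v * v)
    se <- sqrt(pmax(ss - n * means * means, 0) / (n - 1)) / sqrt(n)
  } else se <- matrix(0, m, B)
  if (s0 == 0 && any(se == 0))
    stop("zero-variance permuted row(s) with s0 = 0; use s0 > 0")
  dperm <- means / (se + s0)
  sorted <- apply(dperm, 2, sort)
  if (m == 1) sorted <- matrix(sorted, nrow = 1)
  expected <- rowMeans(sorted)
  d_obs <- sam_scores(v, s0)
  qq <- stats::quantile(dperm, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, sum(d_obs >= qq[1] & d_obs <= qq[2]) / (0.5 * m))
  degenerate <- colSums(signs == 1) == n | colSums(signs == -1) == n
  structure(list(permuted_scores = sorted, expected_order_stats = expected,
                 pi0 = pi0, exhaustive = exhaustive, n_permutations = B,
                 degenerate = degenerate),
            class = "sam_null")
}

# rank alignment of observed d to the expected order statistics, with a
# stable (d, assay id) tie-break
sam_order <- function(d) {
  ids <- if (is.null(names(d))) as.character(seq_along(d)) else names(d)
  order(d, ids)
}

# cut thresholds at a given delta: scanning outward from the origin
# (first non-negative sorted d), the first rank whose absolute deviation
# from the expected order statistic reaches delta sets the cut on that
# side; everything beyond the cut is called
sam_cuts <- function(dsort, dbar, delta) {
  mm <- length(dsort)
  i0 <- which(dsort >= 0)[1]
  dev <- abs(dsort - dbar)
  cutup <- Inf
  if (!is.na(i0)) {
    up <- which(dev[i0:mm] >= delta)
    if (length(up)) cutup <- unname(dsort[i0 + up[1] - 1])
  }
  cutlow <- -Inf
  lo_end <- if (is.na(i0)) mm else i0 - 1
  if (lo_end >= 1) {
    lo <- which(dev[lo_end:1] >= delta)
    if (length(lo)) cutlow <- unname(dsort[lo_end - lo[1] + 1])
  }
  c(cutlow = cutlow, cutup = cutup)
}

#' Call significant miRNAs at a given delta
#'
#' Ranks the observed d-statistics against the expected order statistics
#' of the permutation null and calls every miRNA beyond the first rank
#' (scanning outward from the origin on each side) whose deviation
#' `|d_(i) - dbar_(i)|` reaches `delta`. The FDR estimate is
#' `100 * pi0 * E[false calls] / max(1, #called)`, where the expected
#' false-call count is, by default, the add-one-corrected average of the
#' per-permutation exceedance counts over the non-degenerate
#' permutations (see [permutation_null()]); `count = "median"` gives
#' the classical SAM median count over all permutations instead.
#'
#' @param d named vector of observed d scores.
#' @param null a `sam_null` from [permutation_null()].
#' @param delta non-negative threshold.
#' @param count `"mean"` or `"median"` aggregation of the
#'   per-permutation false-call counts.
#' @return A list with `called` (character vector of miRNA ids),
#'   `cutlow`, `cutup`, `n_false` (the aggregated count) and
#'   `fdr_percent`.
#' @export
call_at_delta <- function(d, null, delta, count = c("mean", "median")) {
  stopifnot(inherits(null, "sam_null"), delta >= 0)
  count <- match.arg(count)
  ord <- sam_order(d)
  dsort <- d[ord]
  cuts <- sam_cuts(dsort, null$expected_order_stats, delta)
  called <- d >= cuts["cutup"] | d <= cuts["cutlow"]
  agg <- expected_false_calls(null, cuts["cutlow"], cuts["cutup"], count)
  # an empty call set makes no discoveries, false or otherwise
  fdr <- if (!any(called)) 0 else 100 * null$pi0 * agg / sum(called)
  list(called = names(d)[called], cutlow = unname(cuts["cutlow"]),
       cutup = unname(cuts["cutup"]), n_false = agg,
       fdr_percent = fdr)
}

# per-permutation counts of null scores beyond the cuts; columns are
# sorted, so binary search is exact
null_exceedances <- function(sorted, cutlow, cutup) {
  mm <- nrow(sorted)
  vapply(seq_len(ncol(sorted)), function(b) {
    col <- sorted[, b]
    n_up <- if (is.finite(cutup)) mm - findInterval(cutup, col,
                                                    left.open = TRUE) else 0L
    n_lo <- if (is.finite(cutlow)) findInterval(cutlow, col) else 0L
    as.integer(n_up + n_lo)
  }, integer(1))
}

# expected number of falsely called features. "mean": the average count
# over the non-degenerate permutations with an add-one correction (a
# permutation estimate of an expectation should never be exactly zero);
# "median": the classical SAM median count over all permutations.
expected_false_calls <- function(null, cutlow, cutup, count = "mean") {
  nf <- null_exceedances(null$permuted_scores, cutlow, cutup)
  if (count == "median") return(stats::median(nf))
  keep <- !null$degenerate
  if (!any(keep)) keep <- rep(TRUE, length(nf))  # 1-donor degenerate case
  (1 + sum(nf[keep])) / (sum(keep) + 1)
}

# FDR profile over the whole delta grid; fdr_adj is the running minimum
# along increasing delta, making the profile non-increasing (a feature
# called at some delta is called at every smaller delta, so the best FDR
# available at or below a delta is the honest achievable figure there)
sam_delta_table <- function(d, null, delta_grid, count = "mean") {
  ord <- sam_order(d)
  dsort <- d[ord]
  dbar <- null$expected_order_stats
  rows <- lapply(delta_grid, function(delta) {
    cuts <- sam_cuts(dsort, dbar, delta)
    n_called <- sum(d >= cuts["cutup"] | d <= cuts["cutlow"])
    agg <- expected_false_calls(null, cuts["cutlow"], cuts["cutup"], count)
    c(cuts, n_called = n_called, n_false = agg,
      fdr_raw = if (n_called == 0) 0 else
        100 * null$pi0 * agg / n_called)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab$delta <- delta_grid
  tab$fdr_adj <- cummin(tab$fdr_raw)
  tab[, c("delta", "cutlow", "cutup", "n_called", "n_false",
          "fdr_raw", "fdr_adj")]
}

default_delta_grid <- function(d, null, n_delta) {
  ord <- sam_order(d)
  dev <- abs(d[ord] - null$expected_order_stats)
  top <- max(dev, 0)
  seq(0, top * (1 + 1e-9), length.out = n_delta)
}

#' Select the delta achieving a target FDR
#'
#' Scans the delta grid in increasing order and returns the smallest
#' delta whose (monotonized, non-increasing) FDR estimate is at or below
#' the target. If no grid point achieves the target the largest delta is
#' returned with attribute `warning = TRUE`.
#'
#' @param d named vector of observed d scores.
#' @param null a `sam_null`.
#' @param cfg a [sam_config()] (supplies the target and the grid).
#' @return The selected delta (numeric scalar) with attributes
#'   `fdr_percent`, `n_called` and `warning`.
#' @export
select_delta <- function(d, null, cfg) {
  grid <- cfg$delta_grid
  if (is.null(grid)) grid <- default_delta_grid(d, null, cfg$n_delta)
  if (!length(grid)) stop("empty delta grid")
  count <- if (is.null(cfg$fdr_count)) "mean" else cfg$fdr_count
  tab <- sam_delta_table(d, null, grid, count = count)
  ok <- which(tab$fdr_adj <= cfg$target_fdr_percent)
  if (length(ok)) {
    i <- ok[1]; warn <- FALSE
  } else {
    i <- nrow(tab); warn <- TRUE
    warning("no delta on the grid achieves the target FDR of ",
            cfg$target_fdr_percent, "%; returning the largest delta")
  }
  structure(tab$delta[i], fdr_percent = tab$fdr_adj[i],
            n_called = tab$n_called[i], warning = warn,
            delta_table = tab)
}

#' Per-miRNA q-values
#'
#' A miRNA's q-value is the minimum estimated FDR (in percent) over all
#' deltas at which it is called; miRNAs never called on the grid get
#' 100. Because call sets are nested in delta and the FDR profile is
#' monotonized, q is non-increasing in d on the positive side and
#' non-decreasing on the negative side.
#'
#' @param d named vector of observed d scores.
#' @param null a `sam_null`.
#' @param delta_grid optional grid; defaults to the same construction as
#'   [select_delta()].
#' @param n_delta grid size when `delta_grid` is `NULL`.
#' @param count `"mean"` or `"median"` false-call count aggregation.
#' @return Named numeric vector of q-values in `[0, 100]`.
#' @export
q_values <- function(d, null, delta_grid = NULL, n_delta = 200,
                     count = "mean") {
  if (is.null(delta_grid)) delta_grid <- default_delta_grid(d, null, n_delta)
  tab <- sam_delta_table(d, null, delta_grid, count = count)
  q <- rep(100, length(d))
  names(q) <- names(d)
  # largest delta index at which each miRNA is still called; fdr_adj is
  # non-increasing so that index gives the minimum over calling deltas
  for (i in seq_along(d)) {
    idx <- which(d[i] >= tab$cutup | d[i] <= tab$cutlow)
    if (length(idx)) q[i] <- tab$fdr_adj[max(idx)]
  }
  pmin(pmax(q, 0), 100)
}

#' Run the one-class SAM
#'
#' Full procedure on a paired-difference matrix: fudge-factor selection,
#' sign-flip permutation null, delta selection at the target FDR,
#' q-values, and assembly of the significant-miRNA table. Each
#' significant row carries the d score, q-value (percent), the fold
#' change restated in its direction of enrichment, and the direction
#' (`beta` for d > 0, `alpha` for d < 0). The table is ordered beta
#' before alpha, descending fold change within direction.
#'
#' @param z a [paired_diff()].
#' @param fc fold-change data.frame from [fold_change()], aligned with
#'   the assays of `z`.
#' @param cfg a [sam_config()].
#' @return A data.frame of class `sam_table` with columns `miRNA`,
#'   `score_d`, `q_percent`, `fold_change`, `direction`, and attributes
#'   `s0`, `pi0`, `delta`, `fdr_percent`, `exhaustive`, `diagnostics`
#'   (per-miRNA mean z, se, d, q, FC for the whole input) and
#'   `delta_table` (the scanned FDR profile).
#' @export
run_sam <- function(z, fc, cfg = sam_config()) {
  stopifnot(inherits(z, "paired_diff"))
  v <- z$values
  if (ncol(v) < 2) stop("one-class SAM requires at least 2 donors")
  if (!setequal(rownames(v), fc$mirna))
    stop("assays of `z` and `fc` are not aligned")
  fc <- fc[match(rownames(v), fc$mirna), ]
  st <- row_stats(v)
  s0 <- choose_s0(st$mean, st$se, method = cfg$s0_method,
                  s0_fixed = cfg$s0_fixed)
  d <- sam_scores(v, s0)
  null <- permutation_null(v, cfg, s0)
  delta <- select_delta(d, null, cfg)
  tab <- attr(delta, "delta_table")
  call <- call_at_delta(d, null, as.numeric(delta), count = cfg$fdr_count)
  q <- q_values(d, null, delta_grid = tab$delta, count = cfg$fdr_count)
  sig <- names(d) %in% call$called
  direction <- ifelse(d > 0, "beta", "alpha")
  fc_dir <- ifelse(d > 0, fc$fc_beta_vs_alpha, 1 / fc$fc_beta_vs_alpha)
  out <- data.frame(miRNA = names(d)[sig],
                    score_d = unname(d[sig]),
                    q_percent = unname(q[sig]),
                    fold_change = fc_dir[sig],
                    direction = direction[sig],
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(match(out$direction, c("beta", "alpha")),
                   -out$fold_change), ]
  rownames(out) <- NULL
  diagnostics <- data.frame(mirna = names(d), mean_z = st$mean,
                            se = st$se, d_score = unname(d),
                            q_percent = unname(q),
                            fc_beta_vs_alpha = fc$fc_beta_vs_alpha,
                            row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("sam_table", "data.frame"),
            s0 = s0, pi0 = null$pi0, delta = as.numeric(delta),
            fdr_percent = attr(delta, "fdr_percent"),
            fdr_warning = attr(delta, "warning"),
            exhaustive = null$exhaustive,
            diagnostics = diagnostics, delta_table = tab)
}

#' @export
print.sam_table <- function(x, ...) {
  cat(sprintf(
    "one-class SAM: %d significant miRNAs (%d beta, %d alpha) at delta = %.4g (est. FDR %.3g%%, s0 = %.4g, pi0 = %.3g)\n",
    nrow(x), sum(x$direction == "beta"), sum(x$direction == "alpha"),
    attr(x, "delta"), attr(x, "fdr_percent"), attr(x, "s0"),
    attr(x, "pi0")))
  NextMethod()
}
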