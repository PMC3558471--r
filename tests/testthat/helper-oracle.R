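# Independent brute-force implementation of the one-class SAM,
# written with plain loops over explicit sign enumerations. Used as the
# oracle against the vectorized implementation.

oracle_scores <- function(z, s0) {
  out <- numeric(nrow(z))
  for (i in seq_len(nrow(z))) {
    x <- z[i, ]
    n <- length(x)
    m <- sum(x) / n
    se <- if (n > 1) sqrt(sum((x - m)^2) / (n - 1)) / sqrt(n) else 0
    out[i] <- m / (se + s0)
  }
  names(out) <- rownames(z)
  out
}

# enumerate all 2^n sign vectors via binary counting
oracle_sign_vectors <- function(n) {
  lapply(0:(2^n - 1), function(b) {
    bits <- as.integer(intToBits(b))[seq_len(n)]
    ifelse(bits == 1, 1, -1)
  })
}

oracle_null <- function(z, s0) {
  svs <- oracle_sign_vectors(ncol(z))
  cols <- sapply(svs, function(s) {
    zz <- z
    for (j in seq_len(ncol(z))) zz[, j] <- z[, j] * s[j]
    oracle_scores(zz, s0)
  })
  if (nrow(z) == 1) cols <- matrix(cols, nrow = 1)
  sorted <- apply(cols, 2, sort)
  if (nrow(z) == 1) sorted <- matrix(sorted, nrow = 1)
  degen <- vapply(svs, function(s) all(s == 1) || all(s == -1), logical(1))
  pooled <- as.vector(cols)
  qq <- stats::quantile(pooled, c(0.25, 0.75), names = FALSE)
  d <- oracle_scores(z, s0)
  pi0 <- min(1, sum(d >= qq[1] & d <= qq[2]) / (0.5 * nrow(z)))
  list(cols = cols, sorted = sorted, expected = rowMeans(sorted),
       degen = degen, pi0 = pi0)
}

# cut thresholds, call set and FDR at one delta, worked out step by step
oracle_call <- function(d, onull, delta, count = "mean") {
  ids <- names(d)
  ord <- order(d, ids)
  dsort <- d[ord]
  dbar <- onull$expected
  mm <- length(d)
  i0 <- NA
  for (i in seq_len(mm)) if (dsort[i] >= 0) { i0 <- i; break }
  cutup <- Inf
  if (!is.na(i0))
    for (i in i0:mm)
      if (abs(dsort[i] - dbar[i]) >= delta) { cutup <- unname(dsort[i]); break }
  cutlow <- -Inf
  lo_start <- if (is.na(i0)) mm else i0 - 1
  if (lo_start >= 1)
    for (i in lo_start:1)
      if (abs(dsort[i] - dbar[i]) >= delta) { cutlow <- unname(dsort[i]); break }
  called <- ids[d >= cutup | d <= cutlow]
  counts <- integer(ncol(onull$cols))
  for (b in seq_len(ncol(onull$cols)))
    counts[b] <- sum(onull$cols[, b] >= cutup) +
      sum(onull$cols[, b] <= cutlow)
  nf <- if (count == "median") stats::median(counts) else {
    keep <- !onull$degen
    if (!any(keep)) keep <- rep(TRUE, length(counts))
    (1 + sum(counts[keep])) / (sum(keep) + 1)
  }
  fdr <- if (length(called) == 0) 0 else
    100 * onull$pi0 * nf / length(called)
  list(called = called, cutup = cutup, cutlow = cutlow, fdr = fdr)
}

# independently coded percentile-CV rule for the fudge factor
oracle_s0 <- function(means, ses, n_windows = 100) {
  cand <- stats::quantile(ses, probs = seq(0, 1, by = 0.05),
                          names = FALSE, type = 7)
  nw <- max(2, min(n_windows, floor(length(ses) / 3)))
  brk <- unique(stats::quantile(ses, probs = seq(0, 1, length.out = nw + 1),
                                names = FALSE, type = 7))
  grp <- if (length(brk) > 2)
    cut(ses, breaks = brk, include.lowest = TRUE) else
    factor(rep(1, length(ses)))
  best <- NA; best_cv <- Inf
  for (s0 in cand) {
    d <- means / (ses + s0)
    mads <- c()
    for (g in levels(grp)) {
      dd <- d[grp == g]
      if (length(dd)) mads <- c(mads, stats::mad(dd))
    }
    mads <- mads[!is.na(mads)]
    if (length(mads) < 2 || mean(mads) == 0) next
    cv <- stats::sd(mads) / mean(mads)
    if (cv < best_cv) { best_cv <- cv; best <- s0 }
  }
  res <- if (is.na(best)) cand[1] else best
  if (res == 0 && any(ses == 0)) {
    pos <- cand[cand > 0]
    res <- if (length(pos)) min(pos) else 1
  }
  res
}
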