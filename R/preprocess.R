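#' Censor Ct values at the detection limit
#'
#' Replaces every Ct above the cutoff, and every undetected well, by the
#' cutoff value (instrument detection limit, 32 cycles for the TLDA
#' panel), leaving values at or below the cutoff unchanged. The
#' pre-censoring detection mask (Ct strictly below the cutoff) is
#' retained in the returned object so that detection filtering stays
#' available after censoring. Idempotent: censoring a censored matrix
#' changes nothing.
#'
#' @param m a [ct_matrix()].
#' @param cutoff detection limit in cycles (default 32).
#' @return A [ct_matrix()] with no undetected entries, all values
#'   `<= cutoff`, and a filled-in `detected` mask.
#' @export
censor_cts <- function(m, cutoff = 32) {
  stopifnot(inherits(m, "ct_matrix"))
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0)
    stop("`cutoff` must be a single positive number")
  v <- m$values
  detected <- if (!is.null(m$detected)) m$detected else
    !is.na(v) & v < cutoff
  v[is.na(v) | v > cutoff] <- cutoff
  m$values <- v
  m$detected <- detected
  m
}

#' Detection filter across donors
#'
#' Returns the assays considered reliably measured: detected (Ct
#' strictly below the cutoff, before censoring) in at least
#' `min_detected` of the donors. Because a miRNA can be genuinely absent
#' from one cell type yet solidly expressed in the other, the default
#' scope requires the detection quorum in *at least one* cell
#' population; `"both"` requires it in each population and `"pooled"`
#' counts a donor as detected if either of its samples is. Control
#' assays are never returned.
#'
#' @param m a [ct_matrix()] (censored or not; the pre-censoring mask is
#'   used either way).
#' @param cutoff detection limit in cycles (default 32).
#' @param min_detected minimum number of donors with detection
#'   (default 4, i.e. 4 of the 6 donors of the paired design).
#' @param scope `"either"`, `"both"` or `"pooled"`; see Details.
#' @return Character vector of retained assay ids, in matrix order.
#' @export
detection_filter <- function(m, cutoff = 32, min_detected = 4,
                             scope = c("either", "both", "pooled")) {
  stopifnot(inherits(m, "ct_matrix"))
  scope <- match.arg(scope)
  check_pairing(m$samples)
  donors <- unique(m$samples$donor_id)
  if (min_detected > length(donors))
    stop("min_detected (", min_detected, ") exceeds the number of donors (",
         length(donors), ")")
  det <- if (!is.null(m$detected)) m$detected else
    !is.na(m$values) & m$values < cutoff
  # donor-level detection per population: any detected sample of that
  # donor/cell type counts (handles technical replicates)
  donor_det <- function(cell) {
    cols <- m$samples$cell_type == cell
    sub <- det[, cols, drop = FALSE]
    grp <- m$samples$donor_id[cols]
    hits <- vapply(donors, function(d)
      rowSums(sub[, grp == d, drop = FALSE]) > 0, logical(nrow(det)))
    matrix(hits, nrow = nrow(det))
  }
  da <- donor_det("alpha"); db <- donor_det("beta")
  na_ <- rowSums(da); nb <- rowSums(db)
  keep <- switch(scope,
    either = na_ >= min_detected | nb >= min_detected,
    both   = na_ >= min_detected & nb >= min_detected,
    pooled = rowSums(da | db) >= min_detected)
  setdiff(rownames(m$values)[keep], m$control_assays)
}

#' Normalize to an endogenous control
#'
#' Computes `deltaCt = Ct(assay) - Ct(control)` within each sample,
#' removing per-sample loading/abundance differences (including the
#' double-sided control drift seen across fixed-cell preparations).
#' Control rows are dropped from the output. The control must be
#' detected in every sample; an undetected control makes normalization
#' meaningless and is a hard error rather than an imputation.
#'
#' @param m a censored [ct_matrix()] (see [censor_cts()]).
#' @param control id of the control assay (default `"RNU48"`, the small
#'   nucleolar RNA control of the TLDA panel).
#' @return A [delta_ct_matrix()].
#' @export
delta_ct <- function(m, control = "RNU48") {
  stopifnot(inherits(m, "ct_matrix"))
  if (!control %in% m$control_assays)
    stop("control assay not flagged in matrix: ", control)
  ctl <- m$values[control, ]
  und <- is.na(ctl)
  if (!is.null(m$detected)) und <- und | !m$detected[control, ]
  if (any(und))
    stop("control ", control, " undetected in sample(s): ",
         paste(m$samples$sample_id[und], collapse = ", "))
  vals <- sweep(m$values, 2, ctl, "-")
  keep <- setdiff(rownames(vals), m$control_assays)
  delta_ct_matrix(vals[keep, , drop = FALSE], m$samples,
                  control_used = control)
}

#' Collapse within-donor technical replicates on the Ct scale
#'
#' If an export carries more than one sample per (donor, cell type),
#' their Cts are averaged (undetected wells excluded; a well undetected
#' in all replicates stays undetected) before normalization.
#'
#' @param m a [ct_matrix()].
#' @return A [ct_matrix()] with one sample per (donor, cell type).
#' @export
collapse_replicates <- function(m) {
  stopifnot(inherits(m, "ct_matrix"))
  key <- paste(m$samples$donor_id, m$samples$cell_type, sep = "\r")
  if (!anyDuplicated(key)) return(m)
  keys <- unique(key)
  vals <- vapply(keys, function(k)
    rowMeans(m$values[, key == k, drop = FALSE], na.rm = TRUE),
    numeric(nrow(m$values)))
  vals[is.nan(vals)] <- NA_real_
  first <- match(keys, key)
  meta <- m$samples[first, , drop = FALSE]
  colnames(vals) <- meta$sample_id
  ct_matrix(vals, meta, control_assays = m$control_assays)
}

#' Paired per-donor differences
#'
#' For each donor, `z = deltaCt(alpha) - deltaCt(beta)`; positive z
#' means beta-enriched. This is the one-class SAM input: under the null
#' of equal expression the per-donor differences are symmetric around
#' zero, which is what the sign-flip permutation null exploits.
#'
#' @param d a [delta_ct_matrix()]; each donor must have exactly one
#'   alpha and one beta sample (collapse replicates first, see
#'   [collapse_replicates()]).
#' @return A [paired_diff()] with one column per donor.
#' @export
paired_differences <- function(d) {
  stopifnot(inherits(d, "delta_ct_matrix"))
  s <- d$samples
  donors <- unique(s$donor_id)
  cols <- lapply(donors, function(dn) {
    ia <- which(s$donor_id == dn & s$cell_type == "alpha")
    ib <- which(s$donor_id == dn & s$cell_type == "beta")
    if (length(ia) != 1 || length(ib) != 1)
      stop("donor ", dn, " does not have exactly one alpha and one beta ",
           "sample (", length(ia), " alpha, ", length(ib), " beta)")
    d$values[, ia] - d$values[, ib]
  })
  z <- do.call(cbind, cols)
  dimnames(z) <- list(rownames(d$values), donors)
  paired_diff(z)
}

#' Fold changes from paired differences
#'
#' Relative quantity on the beta-vs-alpha axis per miRNA. With
#' `aggregate = "geometric"` (default, the instrument-software
#' convention) the per-donor differences are averaged on the Ct scale
#' and `FC = 2^mean(z)`, i.e. `2^-mean(ddCt)`; `"arithmetic"` averages
#' the per-donor relative quantities `2^z` instead. MiRNAs with FC
#' inside the equal band (default `[2/3, 3/2]`, band endpoints
#' inclusive) are categorized `equal`; strictly above / below the band,
#' `beta_enriched` / `alpha_enriched`. `fc_reported` restates the fold
#' change in the direction of enrichment (`1/FC` for alpha-enriched).
#'
#' @param z a [paired_diff()] with finite values.
#' @param equal_band numeric length-2 interval of fold changes treated
#'   as equal expression.
#' @param aggregate `"geometric"` or `"arithmetic"`, see Details.
#' @return data.frame with columns `mirna`, `fc_beta_vs_alpha`,
#'   `category`, `fc_reported`.
#' @export
fold_change <- function(z, equal_band = c(2 / 3, 3 / 2),
                        aggregate = c("geometric", "arithmetic")) {
  stopifnot(inherits(z, "paired_diff"))
  aggregate <- match.arg(aggregate)
  v <- z$values
  if (any(!is.finite(v))) stop("paired differences must be finite")
  stopifnot(length(equal_band) == 2, equal_band[1] < equal_band[2])
  fc <- switch(aggregate,
    geometric  = 2 ^ rowMeans(v),
    arithmetic = rowMeans(2 ^ v))
  category <- ifelse(fc > equal_band[2], "beta_enriched",
              ifelse(fc < equal_band[1], "alpha_enriched", "equal"))
  data.frame(mirna = rownames(v),
             fc_beta_vs_alpha = fc,
             category = category,
             fc_reported = ifelse(category == "alpha_enriched", 1 / fc, fc),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Single-assay relative quantification
#'
#' The follow-up qRT-PCR convention: `RQ = 2^-(Ct_gene - Ct_control)`,
#' with Ct at or above the undetermined cutoff (35 cycles) reported as
#' undetermined (`NA`). Vectorized over its first two arguments.
#'
#' @param ct_gene Ct of the gene/miRNA of interest (cycles).
#' @param ct_control Ct of the endogenous control in the same sample.
#' @param undetermined_cutoff Ct at or above which the assay is
#'   considered undetermined (default 35).
#' @return numeric vector of RQ values; `NA` marks undetermined.
#' @export
single_assay_rq <- function(ct_gene, ct_control, undetermined_cutoff = 35) {
  rq <- 2 ^ -(ct_gene - ct_control)
  rq[ct_gene >= undetermined_cutoff] <- NA_real_
  rq
}
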