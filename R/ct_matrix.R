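#' Ct matrix container
#'
#' Bundles a threshold-cycle (Ct) matrix (assays in rows, samples in
#' columns) with per-sample metadata and the set of endogenous-control
#' assays. Undetected wells ("Undetermined" in instrument exports) are
#' carried as `NA`, a marker distinct from any numeric Ct, so that the
#' censoring policy is applied explicitly downstream (see
#' [censor_cts()]) rather than silently at parse time.
#'
#' @param values numeric matrix of Ct values (cycles); rownames are assay
#'   ids, `NA` marks undetected wells. All finite values must be > 0.
#' @param samples data.frame with columns `sample_id`, `donor_id`,
#'   `cell_type` (`"alpha"`/`"beta"`) and `card` (`"A"`, `"B"` or
#'   `"merged"`), one row per column of `values`, in column order.
#' @param control_assays character vector of assay ids flagged as
#'   endogenous controls (e.g. `"RNU48"`); must be a subset of the
#'   rownames of `values`.
#' @param detected optional logical matrix of the same shape recording
#'   which wells were detected below the censoring cutoff. Filled in by
#'   [censor_cts()]; before censoring it may be `NULL`.
#'
#' @return An object of class `ct_matrix`: a list with elements
#'   `values`, `samples`, `control_assays` and `detected`.
#' @seealso [read_ct_table()], [censor_cts()], [delta_ct()]
#' @export
ct_matrix <- function(values, samples, control_assays = character(),
                      detected = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    stop("`values` must have assay ids as rownames")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "donor_id", "cell_type", "card")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  samples <- samples[, req]
  if (nrow(samples) != ncol(values))
    stop("metadata rows (", nrow(samples), ") do not match sample columns (",
         ncol(values), ")")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  bad <- setdiff(samples$cell_type, c("alpha", "beta"))
  if (length(bad))
    stop("cell_type must be 'alpha' or 'beta'; found: ",
         paste(bad, collapse = ", "))
  bad <- setdiff(samples$card, c("A", "B", "merged"))
  if (length(bad))
    stop("card must be 'A', 'B' or 'merged'; found: ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(rownames(values)))
    stop("duplicate assay_id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (!all(control_assays %in% rownames(values)))
    stop("control assay(s) not present in matrix: ",
         paste(setdiff(control_assays, rownames(values)), collapse = ", "))
  fin <- values[is.finite(values)]
  if (any(fin <= 0))
    stop("all finite Ct values must be > 0")
  if (!is.null(detected)) {
    stopifnot(is.logical(detected), all(dim(detected) == dim(values)))
    dimnames(detected) <- dimnames(values)
  }
  colnames(values) <- samples$sample_id
  structure(list(values = values, samples = samples,
                 control_assays = as.character(control_assays),
                 detected = detected),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d assays x %d samples (%d donors; %d controls; %d undetected wells)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$donor_id)),
              length(x$control_assays), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$values)

# every donor present must have >= 1 alpha and >= 1 beta sample
check_pairing <- function(samples) {
  tab <- table(samples$donor_id, samples$cell_type)
  need <- c("alpha", "beta")
  have <- colnames(tab)
  bad <- rownames(tab)[!apply(tab[, intersect(need, have), drop = FALSE] > 0,
                              1, all) | length(setdiff(need, have)) > 0]
  if (length(setdiff(need, have)) > 0) bad <- rownames(tab)
  if (length(bad))
    stop("donor(s) lacking an alpha/beta pair: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Delta-Ct matrix container
#'
#' Control-normalized Ct values: `delta Ct = Ct(assay) - Ct(control)`
#' within each sample. Produced by [delta_ct()].
#'
#' @param values numeric matrix of delta-Ct values (assays x samples).
#' @param samples sample metadata data.frame (as in [ct_matrix()]).
#' @param control_used id of the endogenous-control assay used.
#' @return An object of class `delta_ct_matrix`.
#' @export
delta_ct_matrix <- function(values, samples, control_used) {
  stopifnot(is.matrix(values), nrow(samples) == ncol(values))
  structure(list(values = values, samples = samples,
                 control_used = control_used),
            class = "delta_ct_matrix")
}

#' @export
print.delta_ct_matrix <- function(x, ...) {
  cat(sprintf("delta_ct_matrix: %d assays x %d samples (control %s)\n",
              nrow(x$values), ncol(x$values), x$control_used))
  invisible(x)
}

#' Paired-difference matrix container
#'
#' Per-donor paired differences `z = deltaCt(alpha) - deltaCt(beta)`,
#' one column per donor. Positive z means the miRNA is relatively less
#' abundant in alpha cells, i.e. beta-enriched (one Ct cycle is about a
#' 2-fold abundance difference). This is the input to the one-class SAM.
#'
#' @param values numeric matrix, assays x donors; colnames are donor ids.
#' @return An object of class `paired_diff`.
#' @export
paired_diff <- function(values) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  structure(list(values = values), class = "paired_diff")
}

#' @export
print.paired_diff <- function(x, ...) {
  cat(sprintf("paired_diff: %d assays x %d donors\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
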