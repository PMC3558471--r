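#' Read a Ct matrix with sample metadata
#'
#' Reads threshold-cycle data exported from a TLDA-style qPCR run into a
#' [ct_matrix()]. Two text dialects are supported:
#'
#' * `"simple_tsv"` — wide, tab-delimited: first column assay ids, one
#'   column per sample, header row of sample ids. The canonical format
#'   written by [write_ct_table()].
#' * `"tlda_export"` — long, tab-delimited with a header naming columns
#'   `sample_id`, `assay_id`, `ct` (extra columns ignored), one well per
#'   line, as produced by flattening an instrument results export.
#'
#' In both dialects the cells "Undetermined", "undetermined" and empty
#' strings map to the undetected marker (`NA`). Sample metadata comes
#' from a sidecar tab-delimited file (or data.frame) with columns
#' `sample_id`, `donor_id`, `cell_type` (alpha/beta) and `card`
#' (A/B/merged). Assay and sample order is preserved from the file.
#'
#' @param path path to the Ct table.
#' @param metadata path to the metadata TSV, or an equivalent data.frame.
#' @param dialect input dialect, see above.
#' @param control_assays character vector of control assay ids, or
#'   `NULL` to auto-flag assays matching `control_pattern`.
#' @param control_pattern regular expression used to flag endogenous
#'   controls when `control_assays` is `NULL`. The default matches the
#'   small-RNA controls of the human TLDA panel (RNU44/RNU48/U6).
#' @return A [ct_matrix()].
#' @export
read_ct_table <- function(path, metadata,
                          dialect = c("simple_tsv", "tlda_export"),
                          control_assays = NULL,
                          control_pattern = "^(RNU|MammU6|U6)") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read_sample_metadata(metadata)
  if (dialect == "simple_tsv") {
    tab <- utils::read.delim(path, check.names = FALSE,
                             colClasses = "character")
    assay_ids <- tab[[1]]
    vals <- as.matrix(tab[, -1, drop = FALSE])
    rownames(vals) <- assay_ids
  } else {
    long <- utils::read.delim(path, colClasses = "character")
    need <- c("sample_id", "assay_id", "ct")
    miss <- setdiff(need, names(long))
    if (length(miss))
      stop("tlda_export file lacks column(s): ", paste(miss, collapse = ", "))
    assay_ids <- unique(long$assay_id)
    sample_ids <- unique(long$sample_id)
    vals <- matrix(NA_character_, length(assay_ids), length(sample_ids),
                   dimnames = list(assay_ids, sample_ids))
    dup <- duplicated(long[, c("sample_id", "assay_id")])
    if (any(dup))
      stop("duplicate (sample, assay) wells in export: ",
           paste(utils::head(paste(long$sample_id[dup], long$assay_id[dup],
                                   sep = "/")), collapse = ", "))
    vals[cbind(long$assay_id, long$sample_id)] <- long$ct
  }
  values <- parse_ct_cells(vals)
  missing_meta <- setdiff(colnames(values), meta$sample_id)
  if (length(missing_meta))
    stop("no metadata for sample(s): ", paste(missing_meta, collapse = ", "))
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  if (is.null(control_assays))
    control_assays <- grep(control_pattern, rownames(values), value = TRUE)
  ct_matrix(values, meta, control_assays = control_assays)
}

# "Undetermined"/empty -> NA; anything else must parse as a number
parse_ct_cells <- function(chr_mat) {
  x <- trimws(chr_mat)
  und <- x %in% c("Undetermined", "undetermined", "UNDETERMINED", "", "NA")
  num <- suppressWarnings(as.numeric(x))
  bad <- !und & is.na(num)
  if (any(bad))
    stop("unparseable Ct value(s): ",
         paste(utils::head(unique(x[bad])), collapse = ", "))
  num[und] <- NA_real_
  out <- matrix(num, nrow(chr_mat), ncol(chr_mat),
                dimnames = dimnames(chr_mat))
  out
}

#' Read sample metadata
#'
#' @param metadata path to a tab-delimited file with columns
#'   `sample_id`, `donor_id`, `cell_type`, `card`, or a data.frame with
#'   those columns.
#' @return data.frame with the four metadata columns, character-typed.
#' @export
read_sample_metadata <- function(metadata) {
  meta <- if (is.character(metadata)) {
    if (!file.exists(metadata)) stop("metadata file not found: ", metadata)
    utils::read.delim(metadata, colClasses = "character")
  } else as.data.frame(metadata, stringsAsFactors = FALSE)
  req <- c("sample_id", "donor_id", "cell_type", "card")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  incomplete <- !stats::complete.cases(meta[, req]) |
    apply(meta[, req] == "", 1, any)
  if (any(incomplete))
    stop("incomplete metadata for sample(s): ",
         paste(meta$sample_id[incomplete], collapse = ", "))
  meta[, req]
}

#' Write a Ct matrix in the simple_tsv dialect
#'
#' Writes the wide Ct table (undetected wells as "Undetermined") and,
#' optionally, the sidecar metadata TSV, such that
#' `read_ct_table(path, metadata_path)` round-trips the object.
#'
#' @param m a [ct_matrix()].
#' @param path output path for the Ct table.
#' @param metadata_path optional output path for the metadata TSV.
#' @return invisibly, `path`.
#' @export
write_ct_table <- function(m, path, metadata_path = NULL) {
  stopifnot(inherits(m, "ct_matrix"))
  chr <- format_num(m$values)
  chr[is.na(m$values)] <- "Undetermined"
  tab <- data.frame(assay_id = rownames(m$values), chr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(tab, path)
  if (!is.null(metadata_path)) write_tsv(m$samples, metadata_path)
  invisible(path)
}

#' Read a GEO series-matrix text file as a Ct matrix
#'
#' Thin adapter for an already-downloaded series-matrix file of a qPCR
#' array series (such as accession GSE38360): parses the
#' `!series_matrix_table_begin` block, maps "Undetermined"/null cells to
#' the undetected marker and attaches user-supplied sample metadata
#' (GEO sample titles rarely encode donor/cell-type unambiguously, so
#' the sidecar metadata remains the caller's responsibility). No network
#' access is performed.
#'
#' @inheritParams read_ct_table
#' @return A [ct_matrix()].
#' @export
read_geo_series_matrix <- function(path, metadata, control_assays = NULL,
                                   control_pattern = "^(RNU|MammU6|U6)") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1 || length(end) != 1 || end <= beg + 1)
    stop("no series-matrix table block found in ", path)
  block <- lines[(beg + 1):(end - 1)]
  con <- textConnection(block)
  on.exit(close(con))
  tab <- utils::read.delim(con, check.names = FALSE, colClasses = "character")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- gsub('^"|"$', "", tab[[1]])
  colnames(vals) <- gsub('^"|"$', "", colnames(vals))
  vals[] <- gsub('^"|"$', "", vals)
  vals[vals %in% c("null", "NULL")] <- ""
  values <- parse_ct_cells(vals)
  meta <- read_sample_metadata(metadata)
  missing_meta <- setdiff(colnames(values), meta$sample_id)
  if (length(missing_meta))
    stop("no metadata for sample(s): ", paste(missing_meta, collapse = ", "))
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  if (is.null(control_assays))
    control_assays <- grep(control_pattern, rownames(values), value = TRUE)
  ct_matrix(values, meta, control_assays = control_assays)
}

#' Merge the A and B cards of a TLDA run
#'
#' The 667-assay human panel is split over two microfluidic cards run
#' from the same preparation; this stacks them into one matrix. Samples
#' are matched across cards by (donor, cell type); assay sets must be
#' disjoint except for shared endogenous controls, which are kept with
#' card-suffixed names (e.g. `RNU48_A`, `RNU48_B`) rather than averaged,
#' so that the control choice stays an explicit preprocessing decision.
#'
#' @param a,b [ct_matrix()] objects for the two cards.
#' @return A merged [ct_matrix()] whose samples carry `card = "merged"`
#'   and the sample ids of `a`.
#' @export
merge_cards <- function(a, b) {
  stopifnot(inherits(a, "ct_matrix"), inherits(b, "ct_matrix"))
  key <- function(s) paste(s$donor_id, s$cell_type, sep = "\r")
  ka <- key(a$samples); kb <- key(b$samples)
  if (anyDuplicated(ka) || anyDuplicated(kb))
    stop("multiple samples per (donor, cell type) on one card; ",
         "collapse replicates before merging")
  only_a <- setdiff(ka, kb); only_b <- setdiff(kb, ka)
  if (length(only_a) || length(only_b)) {
    miss <- c(a$samples$sample_id[ka %in% only_a],
              b$samples$sample_id[kb %in% only_b])
    stop("sample(s) present on only one card: ",
         paste(miss, collapse = ", "))
  }
  shared <- intersect(rownames(a$values), rownames(b$values))
  not_ctrl <- setdiff(shared, intersect(a$control_assays, b$control_assays))
  if (length(not_ctrl))
    stop("non-control assay(s) shared between cards: ",
         paste(not_ctrl, collapse = ", "))
  suffix <- function(m, which) {
    lab <- unique(m$samples$card)
    lab <- if (length(lab) == 1 && lab %in% c("A", "B")) lab else which
    rn <- rownames(m$values)
    rn[rn %in% shared] <- paste(rn[rn %in% shared], lab, sep = "_")
    ctl <- m$control_assays
    ctl[ctl %in% shared] <- paste(ctl[ctl %in% shared], lab, sep = "_")
    rownames(m$values) <- rn
    m$control_assays <- ctl
    m
  }
  a2 <- suffix(a, "A"); b2 <- suffix(b, "B")
  ord <- match(ka, kb)
  vals <- rbind(a2$values, b2$values[, ord, drop = FALSE])
  colnames(vals) <- a$samples$sample_id
  meta <- a$samples
  meta$card <- "merged"
  ct_matrix(vals, meta,
            control_assays = c(a2$control_assays, b2$control_assays))
}

# ---- result-table writers (tab-delimited, '.' decimal, UTF-8) ----------

format_num <- function(x) {
  # %.17g guarantees read.delim round-trips doubles bit-exactly
  chr <- sprintf("%.17g", x)
  chr[is.na(x)] <- NA_character_
  dim(chr) <- dim(x)
  dimnames(chr) <- dimnames(x)
  chr
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) {
    out <- sprintf("%.17g", col); out[is.na(col)] <- "NA"; out
  })
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Write / read a SAM significant-miRNA table
#'
#' Tab-delimited with columns `miRNA`, `score_d`, `q_percent`,
#' `fold_change`, `direction`, ordered beta-enriched before
#' alpha-enriched and by descending fold change within each direction
#' (the layout of the published SAM tables for this design).
#'
#' @param t a `sam_table` (or equivalently shaped data.frame); must be
#'   non-empty.
#' @param path output path.
#' @return `write_sam_table` invisibly returns `path`;
#'   `read_sam_table` returns the table as a data.frame.
#' @export
write_sam_table <- function(t, path) {
  t <- as.data.frame(t)
  req <- c("miRNA", "score_d", "q_percent", "fold_change", "direction")
  miss <- setdiff(req, names(t))
  if (length(miss))
    stop("SAM table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(t) == 0) stop("refusing to write an empty SAM table")
  t <- t[order(match(t$direction, c("beta", "alpha")), -t$fold_change), req]
  write_tsv(t, path)
}

#' @rdname write_sam_table
#' @export
read_sam_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read the global per-miRNA fold-change table
#'
#' One row per detected miRNA with its beta-vs-alpha fold change and
#' expression category (`beta_enriched` / `equal` / `alpha_enriched`),
#' ordered by descending fold change.
#'
#' @param fc data.frame as returned by [fold_change()]; must be
#'   non-empty.
#' @param path output path.
#' @return `write_global_table` invisibly returns `path`;
#'   `read_global_table` returns the table as a data.frame.
#' @export
write_global_table <- function(fc, path) {
  fc <- as.data.frame(fc)
  req <- c("mirna", "fc_beta_vs_alpha", "category", "fc_reported")
  miss <- setdiff(req, names(fc))
  if (length(miss))
    stop("fold-change table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(fc) == 0) stop("refusing to write an empty fold-change table")
  fc <- fc[order(-fc$fc_beta_vs_alpha), req]
  write_tsv(fc, path)
}

#' @rdname write_global_table
#' @export
read_global_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a target-intersection report
#'
#' Tab-delimited with columns `mirna`, `group`, `source`, `gene`,
#' `consensus` sorted by (mirna, group, source, gene).
#'
#' @param report a `target_report` (see [intersect_targets()]); must be
#'   non-empty.
#' @param path output path.
#' @return `write_target_report` invisibly returns `path`;
#'   `read_target_report` returns the report rows as a data.frame.
#' @export
write_target_report <- function(report, path) {
  report <- as.data.frame(report)
  req <- c("mirna", "group", "source", "gene", "consensus")
  miss <- setdiff(req, names(report))
  if (length(miss))
    stop("target report lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(report) == 0) stop("refusing to write an empty target report")
  report <- report[order(report$mirna, report$group, report$source,
                         report$gene), req]
  write_tsv(report, path)
}

#' @rdname write_target_report
#' @export
read_target_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
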