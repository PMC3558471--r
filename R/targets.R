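#' Canonicalize miRNA identifiers
#'
#' Array assay names and the three prediction databases use mutually
#' inconsistent miRNA nomenclature; joining them needs one canonical
#' form. The rule: trim whitespace, strip the species prefix (default
#' `"hsa"`), lower-case (normalizing `miR`/`let` capitalization), then
#' apply an optional alias table. Star (`*`) and `-3p`/`-5p` suffixes
#' are preserved verbatim — they name distinct mature strands. The
#' transformation is idempotent. Identifiers that do not look like
#' miRNA names after normalization are passed through unchanged with a
#' warning, never dropped silently.
#'
#' @param raw character vector of identifiers (non-empty strings).
#' @param species_prefix species prefix to strip (default `"hsa"`).
#' @param aliases optional named character vector mapping canonical ids
#'   to replacement canonical ids (applied last), or a two-column
#'   data.frame `(from, to)`.
#' @return Character vector of canonical ids, e.g. `"hsa-miR-200c"` ->
#'   `"mir-200c"`, `"miR-7-1*"` -> `"mir-7-1*"`.
#' @export
normalize_mirna_id <- function(raw, species_prefix = "hsa", aliases = NULL) {
  if (any(is.na(raw) | !nzchar(trimws(raw))))
    stop("miRNA ids must be non-empty")
  x <- trimws(raw)
  x <- sub(paste0("^", species_prefix, "-"), "", x, ignore.case = TRUE)
  x <- tolower(x)
  if (!is.null(aliases)) {
    if (is.data.frame(aliases))
      aliases <- stats::setNames(as.character(aliases[[2]]),
                                 as.character(aliases[[1]]))
    hit <- x %in% names(aliases)
    x[hit] <- unname(aliases[x[hit]])
  }
  odd <- !grepl("^(mir|let)-", x)
  if (any(odd))
    warning("identifier(s) not in recognizable miRNA form, passed through: ",
            paste(utils::head(unique(raw[odd])), collapse = ", "))
  x
}

#' Read a miRNA alias table
#'
#' Two-column tab-delimited file (`from`, `to`), `#` comments allowed;
#' both columns are taken as already-canonical ids.
#'
#' @param path path to the TSV.
#' @return Named character vector usable as the `aliases` argument of
#'   [normalize_mirna_id()].
#' @export
read_mirna_aliases <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, comment.char = "#",
                           colClasses = "character")
  if (ncol(tab) < 2) stop("alias table needs two columns (from, to)")
  stats::setNames(tab[[2]], tab[[1]])
}

#' miRNA target-prediction database
#'
#' A canonical container for miRNA-to-gene predictions: one row per
#' (miRNA, gene) pair with an optional score, with miRNA ids
#' canonicalized via [normalize_mirna_id()] and gene symbols upper-cased
#' and trimmed.
#'
#' @param pairs data.frame with columns `mirna`, `gene` and optionally
#'   `score`.
#' @param source label of the originating database.
#' @return An object of class `prediction_db`.
#' @export
prediction_db <- function(pairs, source = "generic") {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("mirna", "gene") %in% names(pairs)))
    stop("`pairs` needs columns mirna, gene")
  if (is.null(pairs$score)) pairs$score <- NA_real_
  pairs$gene <- toupper(trimws(pairs$gene))
  if (nrow(pairs)) {
    # collapse duplicate pairs keeping the best (largest) score
    key <- paste(pairs$mirna, pairs$gene, sep = "\r")
    ord <- order(key, -xtfrm(ifelse(is.na(pairs$score), -Inf, pairs$score)))
    pairs <- pairs[ord, ]
    pairs <- pairs[!duplicated(paste(pairs$mirna, pairs$gene, sep = "\r")), ]
    rownames(pairs) <- NULL
  }
  structure(list(source = source,
                 pairs = pairs[, c("mirna", "gene", "score")]),
            class = "prediction_db")
}

#' @export
print.prediction_db <- function(x, ...) {
  cat(sprintf("prediction_db [%s]: %d pairs, %d miRNAs\n", x$source,
              nrow(x$pairs), length(unique(x$pairs$mirna))))
  invisible(x)
}

#' Genes predicted as targets of a miRNA
#'
#' @param db a [prediction_db()].
#' @param mirna canonical miRNA id.
#' @return Character vector of gene symbols (possibly empty).
#' @export
targets_of <- function(db, mirna) {
  stopifnot(inherits(db, "prediction_db"))
  unique(db$pairs$gene[db$pairs$mirna == mirna])
}

#' Read a target-prediction table
#'
#' Parses one of four delimited-text dialects into a [prediction_db()]:
#'
#' * `"generic"` — headerless 3-column TSV: miRNA, gene symbol, score
#'   (score may be empty).
#' * `"pictar4way"` — the 4-species-conserved PicTar rendering:
#'   headerless TSV with miRNA in column 1, gene symbol in column 2 and
#'   the PicTar score in column 3.
#' * `"targetscan_conserved"` — headered TSV; the miRNA/family column is
#'   the first of `miRNA`, `miR Family` or `miR.Family` present, the
#'   gene column `Gene Symbol`/`Gene.Symbol`, score `PCT` if present.
#' * `"microcosm_v5"` — the 13-column miRanda/microcosm v5 download
#'   (GFF-like): miRNA id in field 2, score in field 10, gene symbol in
#'   field 13. `#` comment lines skipped.
#'
#' Malformed lines (wrong field count, unparseable score) are skipped
#' and counted; more than 10% malformed is a hard error. An empty file
#' yields an empty database with a warning.
#'
#' @param path path to the file.
#' @param dialect one of the four dialects above.
#' @param species_prefix,aliases passed to [normalize_mirna_id()].
#' @return A [prediction_db()] with attribute `n_malformed`.
#' @export
read_predictions <- function(path,
                             dialect = c("generic", "pictar4way",
                                         "targetscan_conserved",
                                         "microcosm_v5"),
                             species_prefix = "hsa", aliases = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  header <- dialect == "targetscan_conserved"
  if (header && length(lines)) {
    hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    lines <- lines[-1]
  }
  if (!length(lines)) {
    warning("no prediction rows in ", path)
    db <- prediction_db(data.frame(mirna = character(), gene = character(),
                                   score = numeric()), source = dialect)
    attr(db, "n_malformed") <- 0L
    return(db)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  pick <- switch(dialect,
    generic = ,
    pictar4way = function(f)
      if (length(f) >= 2) c(f[1], f[2], if (length(f) >= 3) f[3] else "")
      else NULL,
    targetscan_conserved = local({
      mir_col <- match(c("miRNA", "miR Family", "miR.Family"), hdr)
      mir_col <- mir_col[!is.na(mir_col)][1]
      gene_col <- match(c("Gene Symbol", "Gene.Symbol"), hdr)
      gene_col <- gene_col[!is.na(gene_col)][1]
      score_col <- match("PCT", hdr)
      if (is.na(mir_col) || is.na(gene_col))
        stop("targetscan_conserved file lacks a miRNA or Gene Symbol column")
      function(f)
        if (length(f) >= max(mir_col, gene_col))
          c(f[mir_col], f[gene_col],
            if (!is.na(score_col) && length(f) >= score_col) f[score_col]
            else "")
        else NULL
    }),
    microcosm_v5 = function(f)
      if (length(f) >= 13) c(f[2], f[13], f[10]) else NULL)
  parsed <- lapply(fields, pick)
  bad <- vapply(parsed, is.null, logical(1))
  rows <- do.call(rbind, parsed[!bad])
  score <- suppressWarnings(as.numeric(rows[, 3]))
  score_bad <- !is.na(rows[, 3]) & nzchar(trimws(rows[, 3])) & is.na(score)
  gene_bad <- !nzchar(trimws(rows[, 2])) | !nzchar(trimws(rows[, 1]))
  drop <- score_bad | gene_bad
  n_malformed <- sum(bad) + sum(drop)
  if (n_malformed > 0.10 * length(lines))
    stop(n_malformed, " of ", length(lines), " lines malformed in ", path,
         " (> 10%)")
  if (n_malformed)
    message(n_malformed, " malformed line(s) skipped in ", path, "; ",
            length(lines) - n_malformed, " kept")
  keep <- !drop
  db <- prediction_db(
    data.frame(mirna = suppressWarnings(
                 normalize_mirna_id(rows[keep, 1],
                                    species_prefix = species_prefix,
                                    aliases = aliases)),
               gene = rows[keep, 2], score = score[keep],
               stringsAsFactors = FALSE),
    source = dialect)
  attr(db, "n_malformed") <- as.integer(n_malformed)
  db
}

#' Islet gene groups
#'
#' The five gene groups used to screen predicted targets: genes enriched
#' in alpha cells (`aG`) or beta cells (`bG`), and transcription factors
#' expressed in both (`abTF`), only alpha (`aTF`) or only beta (`bTF`)
#' cells. Symbols are upper-cased and trimmed; groups may overlap only
#' if the source lists do.
#'
#' @param aG,bG,abTF,aTF,bTF character vectors of gene symbols.
#' @return An object of class `gene_group_set`: a named list of the
#'   five symbol sets.
#' @export
gene_group_set <- function(aG = character(), bG = character(),
                           abTF = character(), aTF = character(),
                           bTF = character()) {
  groups <- list(aG = aG, bG = bG, abTF = abTF, aTF = aTF, bTF = bTF)
  groups <- lapply(groups, function(g) unique(toupper(trimws(g))))
  structure(groups, class = "gene_group_set")
}

#' Read the five islet gene-group files
#'
#' Each group is a plain-text file, one gene symbol per line, `#`
#' comments and blank lines ignored. Either pass a directory containing
#' `aG.txt`, `bG.txt`, `abTF.txt`, `aTF.txt`, `bTF.txt`, or a named list
#' of five paths.
#'
#' @param dir directory holding the five files (ignored when `paths`
#'   given).
#' @param paths optional named list/vector of paths with names exactly
#'   `aG`, `bG`, `abTF`, `aTF`, `bTF`.
#' @return A [gene_group_set()].
#' @export
read_gene_groups <- function(dir = NULL, paths = NULL) {
  nm <- c("aG", "bG", "abTF", "aTF", "bTF")
  if (is.null(paths)) {
    if (is.null(dir)) stop("supply `dir` or `paths`")
    paths <- stats::setNames(file.path(dir, paste0(nm, ".txt")), nm)
  }
  miss <- setdiff(nm, names(paths))
  if (length(miss))
    stop("gene-group path(s) missing: ", paste(miss, collapse = ", "))
  read_one <- function(p) {
    if (!file.exists(p)) stop("gene-group file not found: ", p)
    lines <- readLines(p, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines[nzchar(lines)]
  }
  do.call(gene_group_set, lapply(paths[nm], read_one))
}

#' Select beta-enriched miRNAs above a fold-change threshold
#'
#' The miRNAs carried into target analysis: significant in the beta
#' direction with a beta-vs-alpha fold change strictly greater than
#' `min_fc` (default 3; `min_fc = 0` returns every beta-direction row).
#'
#' @param t a `sam_table` (see [run_sam()]) or equivalently shaped
#'   data.frame with `miRNA`, `fold_change`, `direction` columns.
#' @param min_fc strict lower fold-change bound.
#' @return Character vector of miRNA ids.
#' @export
filter_beta_mirnas <- function(t, min_fc = 3) {
  t <- as.data.frame(t)
  if (is.null(t$direction)) stop("table lacks a `direction` column")
  t$miRNA[t$direction == "beta" & t$fold_change > min_fc]
}

#' Intersect miRNA target predictions with islet gene groups
#'
#' For every (miRNA, database) pair, intersects the predicted target
#' genes with each of the five gene groups, yielding one report row per
#' (mirna, group, source, gene). The `consensus` column counts how many
#' of the supplied databases predict that (mirna, gene) pair in any
#' group; it is reported but never used as a filter (each database is
#' screened independently). MiRNAs absent from every database are not an
#' error — they are listed in the `unmatched` attribute with zero rows.
#'
#' @param mirnas character vector of miRNA ids (canonicalized
#'   internally).
#' @param dbs list of [prediction_db()] objects; names label the
#'   `source` column (defaults to each db's own source).
#' @param groups a [gene_group_set()].
#' @param min_sources keep only pairs predicted by at least this many
#'   databases (default 1, i.e. no consensus filtering).
#' @return data.frame of class `target_report` with columns `mirna`,
#'   `group`, `source`, `gene`, `consensus`, sorted by
#'   (mirna, group, source, gene); attributes `unmatched` (miRNAs with
#'   no prediction in any db) and `summary` (per miRNA x group x source
#'   gene counts).
#' @export
intersect_targets <- function(mirnas, dbs, groups, min_sources = 1) {
  stopifnot(inherits(groups, "gene_group_set"))
  if (inherits(dbs, "prediction_db")) dbs <- list(dbs)
  if (is.null(names(dbs)) || any(!nzchar(names(dbs))))
    names(dbs) <- vapply(dbs, function(d) d$source, character(1))
  mirnas <- unique(suppressWarnings(normalize_mirna_id(mirnas)))
  grp_names <- names(groups)
  rows <- list()
  pair_seen <- character()  # "mirna\rgene" per db, for consensus
  for (src in names(dbs)) {
    db <- dbs[[src]]
    stopifnot(inherits(db, "prediction_db"))
    sub <- db$pairs[db$pairs$mirna %in% mirnas, , drop = FALSE]
    pair_seen <- c(pair_seen,
                   unique(paste(sub$mirna, sub$gene, sep = "\r")))
    for (g in grp_names) {
      hit <- sub[sub$gene %in% groups[[g]], , drop = FALSE]
      if (nrow(hit))
        rows[[length(rows) + 1L]] <-
          data.frame(mirna = hit$mirna, group = g, source = src,
                     gene = hit$gene, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(), group = character(),
               source = character(), gene = character(),
               stringsAsFactors = FALSE)
  consensus_tab <- table(pair_seen)
  out$consensus <- if (nrow(out))
    as.integer(consensus_tab[paste(out$mirna, out$gene, sep = "\r")]) else
    integer()
  out <- out[is.na(out$consensus) | out$consensus >= min_sources, ,
             drop = FALSE]
  out <- out[order(out$mirna, out$group, out$source, out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  matched <- unique(unlist(lapply(dbs, function(db)
    intersect(db$pairs$mirna, mirnas))))
  summ <- if (nrow(out))
    stats::aggregate(gene ~ mirna + group + source, data = out, FUN = length)
  else NULL
  structure(out, class = c("target_report", "data.frame"),
            unmatched = setdiff(mirnas, matched), summary = summ)
}

#' @export
print.target_report <- function(x, ...) {
  cat(sprintf("target_report: %d rows, %d miRNAs matched, %d unmatched\n",
              nrow(x), length(unique(x$mirna)),
              length(attr(x, "unmatched"))))
  NextMethod()
}
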