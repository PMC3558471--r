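#' Pipeline configuration
#'
#' Collects every path and parameter of the end-to-end run. File-based
#' configs (YAML, flat keys matching these argument names) can be read
#' with [read_pipeline_config()]; explicit arguments override file
#' values which override defaults.
#'
#' @param ct_path path to the Ct matrix (or card A when `ct_path_b`
#'   given).
#' @param ct_path_b optional path to card B; the two cards are merged.
#' @param metadata_path path to the sample-metadata TSV.
#' @param dialect Ct input dialect, see [read_ct_table()].
#' @param control endogenous-control assay id (default `"RNU48"`).
#' @param cutoff_ct detection limit in cycles (default 32).
#' @param detection_min minimum donors with detection (default 4).
#' @param detection_scope `"either"`, `"both"` or `"pooled"`.
#' @param fc_aggregation `"geometric"` or `"arithmetic"`.
#' @param target_fdr_percent SAM target FDR in percent (default 0.5).
#' @param n_permutations sign-flip permutations (default 1000;
#'   exhaustive enumeration engages automatically for small designs).
#' @param min_fc strict fold-change bound for target analysis
#'   (default 3).
#' @param db_paths named list of prediction-database paths; names are
#'   source labels.
#' @param db_dialects named character vector of dialects per database
#'   (default `"generic"` for each).
#' @param groups_dir directory with the five gene-group files.
#' @param out_dir output directory.
#' @param seed RNG seed (used only when permutations are sampled).
#' @param run_targets whether to run the target-analysis stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(ct_path, metadata_path, out_dir,
                            ct_path_b = NULL,
                            dialect = "simple_tsv",
                            control = "RNU48", cutoff_ct = 32,
                            detection_min = 4,
                            detection_scope = "either",
                            fc_aggregation = "geometric",
                            target_fdr_percent = 0.5,
                            n_permutations = 1000,
                            min_fc = 3,
                            db_paths = NULL, db_dialects = NULL,
                            groups_dir = NULL,
                            seed = 1L, run_targets = TRUE) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @param ... overrides applied on top of the file values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  do.call(pipeline_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full differential-expression pipeline
#'
#' Ingest -> censor -> detection filter -> normalize -> paired
#' differences -> fold changes -> one-class SAM -> (optionally) target
#' intersection, writing four artifacts into `out_dir`:
#' `global_fc.tsv` (per-detected-miRNA fold-change table),
#' `sam_significant.tsv` (the significant-miRNA table),
#' `target_report.tsv` (when the target stage runs) and
#' `run_manifest.json` (config echo, seed, versions, per-stage row
#' counts). Any stage error aborts the run naming the stage.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with the artifact paths, the stage counts
#'   and the in-memory `sam_table`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- stage("ingest", {
    a <- read_ct_table(cfg$ct_path, cfg$metadata_path, dialect = cfg$dialect)
    if (!is.null(cfg$ct_path_b)) {
      b <- read_ct_table(cfg$ct_path_b, cfg$metadata_path,
                         dialect = cfg$dialect)
      merge_cards(a, b)
    } else a
  })
  n_panel <- nrow(m$values) - length(m$control_assays)
  cens <- stage("censor", censor_cts(m, cutoff = cfg$cutoff_ct))
  detected <- stage("detection_filter",
    detection_filter(cens, cutoff = cfg$cutoff_ct,
                     min_detected = cfg$detection_min,
                     scope = cfg$detection_scope))
  dct <- stage("normalize", {
    d <- delta_ct(collapse_replicates(cens), control = cfg$control)
    d$values <- d$values[intersect(rownames(d$values), detected), ,
                         drop = FALSE]
    d
  })
  z <- stage("paired_differences", paired_differences(dct))
  fc <- stage("fold_change",
              fold_change(z, aggregate = cfg$fc_aggregation))
  sam <- stage("sam", run_sam(z, fc, sam_config(
    n_permutations = cfg$n_permutations, seed = cfg$seed,
    target_fdr_percent = cfg$target_fdr_percent)))
  paths <- list(global_fc = file.path(cfg$out_dir, "global_fc.tsv"),
                sam = file.path(cfg$out_dir, "sam_significant.tsv"),
                manifest = file.path(cfg$out_dir, "run_manifest.json"))
  stage("write_global", write_global_table(fc, paths$global_fc))
  if (nrow(sam) > 0) stage("write_sam", write_sam_table(sam, paths$sam))
  target_rows <- NA_integer_
  beta_ids <- character()
  if (isTRUE(cfg$run_targets) && !is.null(cfg$db_paths)) {
    trep <- stage("targets", {
      dialects <- cfg$db_dialects
      if (is.null(dialects))
        dialects <- stats::setNames(rep("generic", length(cfg$db_paths)),
                                    names(cfg$db_paths))
      dbs <- lapply(names(cfg$db_paths), function(s)
        read_predictions(cfg$db_paths[[s]], dialect = dialects[[s]]))
      names(dbs) <- names(cfg$db_paths)
      groups <- read_gene_groups(cfg$groups_dir)
      beta_ids <<- filter_beta_mirnas(sam, min_fc = cfg$min_fc)
      intersect_targets(beta_ids, dbs, groups)
    })
    paths$targets <- file.path(cfg$out_dir, "target_report.tsv")
    if (nrow(trep) > 0)
      stage("write_targets", write_target_report(trep, paths$targets))
    target_rows <- nrow(trep)
  }
  counts <- list(n_panel = n_panel,
                 n_detected = length(detected),
                 n_significant = nrow(sam),
                 n_beta = sum(sam$direction == "beta"),
                 n_alpha = sum(sam$direction == "alpha"),
                 n_equal_band = sum(fc$category == "equal"),
                 n_alpha_band = sum(fc$category == "alpha_enriched"),
                 n_beta_filtered = length(beta_ids),
                 n_target_rows = target_rows)
  manifest <- list(
    config = cfg[!vapply(cfg, is.null, logical(1))],
    seed = cfg$seed,
    versions = list(package = as.character(utils::packageVersion("isletmir")),
                    r = paste(R.version$major, R.version$minor, sep = ".")),
    sam = list(s0 = attr(sam, "s0"), pi0 = attr(sam, "pi0"),
               delta = attr(sam, "delta"),
               fdr_percent = attr(sam, "fdr_percent"),
               exhaustive = attr(sam, "exhaustive")),
    counts = counts)
  stage("manifest",
        jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE))
  message(sprintf(
    "pipeline: %d panel -> %d detected -> %d significant (%d beta, %d alpha)",
    counts$n_panel, counts$n_detected, counts$n_significant,
    counts$n_beta, counts$n_alpha))
  invisible(list(paths = paths, counts = counts, sam = sam, fc = fc))
}

#' Analyze a Ct matrix in memory
#'
#' The core analysis chain without file IO: censor at the detection
#' limit, apply the donor detection filter, normalize to the endogenous
#' control, form paired per-donor differences, compute fold changes and
#' run the one-class SAM.
#'
#' @param m a [ct_matrix()].
#' @param control endogenous-control assay id.
#' @param cutoff detection limit in cycles.
#' @param min_detected,scope detection-filter settings, see
#'   [detection_filter()].
#' @param fc_aggregation fold-change aggregation, see [fold_change()].
#' @param sam a [sam_config()].
#' @return A list with `detected` (retained assay ids), `z` (the
#'   [paired_diff()]), `fc` (fold-change table over detected assays)
#'   and `sam` (the `sam_table`).
#' @export
analyze_ct_matrix <- function(m, control = "RNU48", cutoff = 32,
                              min_detected = 4, scope = "either",
                              fc_aggregation = "geometric",
                              sam = sam_config()) {
  cens <- censor_cts(m, cutoff = cutoff)
  detected <- detection_filter(cens, cutoff = cutoff,
                               min_detected = min_detected, scope = scope)
  d <- delta_ct(collapse_replicates(cens), control = control)
  d$values <- d$values[intersect(rownames(d$values), detected), ,
                       drop = FALSE]
  z <- paired_differences(d)
  fc <- fold_change(z, aggregate = fc_aggregation)
  list(detected = detected, z = z, fc = fc,
       sam = run_sam(z, fc, sam))
}

#' Summarize stage counts from pipeline artifacts
#'
#' Recomputes the headline counts from the written artifact files, not
#' from any in-memory state, as a self-audit of a finished run.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return A list with `n_panel`, `n_detected`, `n_significant`,
#'   `n_beta`, `n_alpha`, `n_equal_band`, `n_alpha_band`.
#' @export
summarize_counts <- function(out_dir) {
  man_path <- file.path(out_dir, "run_manifest.json")
  fc_path <- file.path(out_dir, "global_fc.tsv")
  if (!file.exists(man_path)) stop("missing artifact: ", man_path)
  if (!file.exists(fc_path)) stop("missing artifact: ", fc_path)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  fc <- read_global_table(fc_path)
  sam_path <- file.path(out_dir, "sam_significant.tsv")
  sam <- if (file.exists(sam_path)) read_sam_table(sam_path) else
    data.frame(direction = character())
  list(n_panel = man$counts$n_panel,
       n_detected = nrow(fc),
       n_significant = nrow(sam),
       n_beta = sum(sam$direction == "beta"),
       n_alpha = sum(sam$direction == "alpha"),
       n_equal_band = sum(fc$category == "equal"),
       n_alpha_band = sum(fc$category == "alpha_enriched"))
}
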