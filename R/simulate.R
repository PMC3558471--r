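#' Simulation configuration
#'
#' Parameters of the synthetic Ct-data generator, sized to the study
#' design it emulates: a 667-assay human miRNA panel measured in 6
#' donors' paired alpha/beta preparations, censored at the 32-cycle
#' detection limit. Category fractions default to the observed
#' composition (about 20% beta-enriched, 1.3% alpha-enriched, 5% inside
#' the equal band, the remainder null); planted beta effects default to
#' 1-7 cycles of ddCt shift (2- to 128-fold), alpha effects to the
#' moderate 0.8-1.6 cycles seen for alpha-enriched miRNAs.
#'
#' @param n_mirnas number of miRNA assays on the panel (default 667).
#' @param n_donors number of donors, each with one alpha and one beta
#'   sample (default 6).
#' @param frac_beta_enriched,frac_alpha_enriched,frac_equal fractions of
#'   the panel planted as beta-enriched, alpha-enriched, or with a small
#'   effect inside the equal band; the remainder is exactly null.
#' @param effect_log2 planted beta-enrichment effect in cycles: a single
#'   value, or a length-2 range drawn uniformly per miRNA.
#' @param effect_log2_alpha planted alpha-enrichment effect (same
#'   convention).
#' @param donor_sd SD (cycles) of per-donor biological noise shared
#'   across a donor's alpha/beta pair — the preparation effect the
#'   paired design cancels.
#' @param assay_sd SD (cycles) of independent per-well technical noise.
#' @param baseline_ct_range range of per-miRNA baseline Ct, drawn
#'   uniformly (default `[20, 31]`).
#' @param control_ct baseline Ct of the endogenous control (default 22:
#'   an abundant small RNA, far from the detection limit).
#' @param control_drift_sd SD (cycles) of the per-sample additive shift
#'   applied to every assay of a sample including the control — the
#'   double-sided drift in endogenous-RNA content across fixed-cell
#'   preparations that delta-Ct normalization removes.
#' @param censor_ct detection limit (default 32); wells above it are
#'   emitted as undetected.
#' @param undetected_fraction extra fraction of non-control wells
#'   dropped at random (failed wells), default 0.02.
#' @param seed RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_mirnas = 667, n_donors = 6,
                       frac_beta_enriched = 0.20,
                       frac_alpha_enriched = 0.013,
                       frac_equal = 0.05,
                       effect_log2 = c(1, 7),
                       effect_log2_alpha = c(0.8, 1.6),
                       donor_sd = 0.5, assay_sd = 0.25,
                       baseline_ct_range = c(20, 31),
                       control_ct = 22,
                       control_drift_sd = 1.5,
                       censor_ct = 32,
                       undetected_fraction = 0.02,
                       seed = 1L) {
  stopifnot(n_mirnas >= 1, n_donors >= 1,
            donor_sd >= 0, assay_sd >= 0, control_drift_sd >= 0,
            undetected_fraction >= 0, undetected_fraction <= 1,
            frac_beta_enriched >= 0, frac_alpha_enriched >= 0,
            frac_equal >= 0,
            frac_beta_enriched + frac_alpha_enriched + frac_equal <= 1,
            length(baseline_ct_range) == 2, censor_ct > 0)
  structure(as.list(environment()), class = "sim_config")
}

draw_effect <- function(range_or_value, n) {
  if (length(range_or_value) == 1) rep(range_or_value, n)
  else stats::runif(n, range_or_value[1], range_or_value[2])
}

#' Simulate a Ct matrix with planted enrichment effects
#'
#' Generative model per miRNA i, donor j, cell type c:
#' `Ct = baseline_i + donor_noise_ij + drift_(j,c) + well_noise -
#' effect_i * [c is the enriched type]`, with `baseline_i ~
#' U(baseline_ct_range)`, donor noise shared across the donor's
#' alpha/beta pair, drift a per-sample shift applied to every assay
#' including the control (so delta-Ct normalization removes it), and
#' independent well noise. Wells whose Ct exceeds the detection limit
#' are emitted as undetected; additional stochastic detection failure
#' strikes with probability `undetected_fraction` at the limit, halving
#' per cycle of abundance below it. Strongly beta-enriched miRNAs
#' therefore drop out of alpha samples at high effect sizes, as real
#' cell-type-specific miRNAs do. Reproducible: the same config
#' (including seed) yields bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `ct` (a [ct_matrix()] including the
#'   control assay `RNU48`) and `truth` (data.frame `mirna`,
#'   `true_category`, `true_effect_cycles`).
#' @export
simulate_ct_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- cfg$n_mirnas; nd <- cfg$n_donors
  ids <- sprintf("sim-mir-%04d", seq_len(m))
  n_beta <- round(cfg$frac_beta_enriched * m)
  n_alpha <- round(cfg$frac_alpha_enriched * m)
  n_equal <- round(cfg$frac_equal * m)
  category <- rep("null", m)
  planted <- sample.int(m, n_beta + n_alpha + n_equal)
  category[planted] <- rep(c("beta_enriched", "alpha_enriched", "equal"),
                           c(n_beta, n_alpha, n_equal))
  effect <- numeric(m)
  effect[category == "beta_enriched"] <- draw_effect(cfg$effect_log2, n_beta)
  effect[category == "alpha_enriched"] <-
    draw_effect(cfg$effect_log2_alpha, n_alpha)
  # equal band: |log2 FC| below log2(1.5)
  effect[category == "equal"] <-
    stats::runif(n_equal, -log2(1.5), log2(1.5))
  baseline <- stats::runif(m, cfg$baseline_ct_range[1],
                           cfg$baseline_ct_range[2])
  donors <- sprintf("D%d", seq_len(nd))
  meta <- data.frame(
    sample_id = c(paste0(donors, "_alpha"), paste0(donors, "_beta")),
    donor_id = rep(donors, 2),
    cell_type = rep(c("alpha", "beta"), each = nd),
    card = "merged", stringsAsFactors = FALSE)
  drift <- stats::rnorm(2 * nd, 0, cfg$control_drift_sd)
  donor_noise <- matrix(stats::rnorm(m * nd, 0, cfg$donor_sd), m, nd)
  # signed effect on the log2 beta-vs-alpha axis, split symmetrically
  # around the baseline: the enriched cell type moves down in Ct, the
  # depleted one up — so strong beta enrichment pushes alpha wells
  # toward (and past) the detection limit, as real cell-type-specific
  # miRNAs behave
  signed <- ifelse(category == "beta_enriched", effect,
            ifelse(category == "alpha_enriched", -effect,
            ifelse(category == "equal", effect, 0)))
  shift_alpha <- -signed / 2
  shift_beta <- signed / 2
  ct_cell <- function(cell_shift, col_offset) {
    well <- matrix(stats::rnorm(m * nd, 0, cfg$assay_sd), m, nd)
    base <- baseline + donor_noise - cell_shift + well
    sweep(base, 2, drift[col_offset + seq_len(nd)], "+")
  }
  # alpha samples occupy columns 1..nd, beta nd+1..2nd of the drift draw
  va <- ct_cell(shift_alpha, 0)
  vb <- ct_cell(shift_beta, nd)
  vals <- cbind(va, vb)
  # the control is an abundant, precisely measured reference: it carries
  # the per-sample drift (which delta-Ct must remove) but no well noise,
  # keeping the paired differences independent across miRNAs
  ctl <- cfg$control_ct + drift
  vals <- rbind(vals, ctl)
  rownames(vals) <- c(ids, "RNU48")
  colnames(vals) <- meta$sample_id
  if (cfg$undetected_fraction > 0) {
    # stochastic detection failure concentrates near the limit: a well
    # at the cutoff fails with probability undetected_fraction, halving
    # per cycle of abundance below it
    p_fail <- cfg$undetected_fraction *
      2 ^ -pmax(cfg$censor_ct - vals[seq_len(m), , drop = FALSE], 0)
    fail <- matrix(stats::runif(m * 2 * nd) < p_fail, m, 2 * nd)
    vals[seq_len(m), ][fail] <- NA_real_
  }
  vals[!is.na(vals) & vals > cfg$censor_ct] <- NA_real_
  truth <- data.frame(mirna = ids, true_category = category,
                      true_effect_cycles = effect,
                      stringsAsFactors = FALSE)
  list(ct = ct_matrix(vals, meta, control_assays = "RNU48"),
       truth = truth)
}

#' Simulate target-prediction databases and gene groups
#'
#' Plants (miRNA, gene, group) triples for the beta-enriched miRNAs of a
#' truth table into a configurable number of the three prediction
#' databases, then adds random decoy pairs and decoy genes, so that the
#' target-intersection stage can be tested end-to-end with known
#' consensus counts.
#'
#' @param truth truth data.frame from [simulate_ct_matrix()] (non-empty).
#' @param n_planted_per_mirna planted target genes per beta-enriched
#'   miRNA (default 2).
#' @param dbs_per_plant how many of the 3 databases carry each planted
#'   pair (default 3, i.e. full consensus).
#' @param n_decoy_pairs random non-planted (miRNA, gene) pairs added per
#'   database.
#' @param n_decoy_genes_per_group extra genes per group that no planted
#'   pair touches.
#' @param seed RNG seed.
#' @return A list with `dbs` (named list of three [prediction_db()]s:
#'   pictar, targetscan, microcosm), `groups` (a [gene_group_set()]) and
#'   `planted` (data.frame `mirna`, `gene`, `group`, `n_dbs`).
#' @export
simulate_prediction_dbs <- function(truth, n_planted_per_mirna = 2,
                                    dbs_per_plant = 3, n_decoy_pairs = 100,
                                    n_decoy_genes_per_group = 20,
                                    seed = 1L) {
  stopifnot(nrow(truth) > 0, dbs_per_plant >= 0, dbs_per_plant <= 3)
  set.seed(seed)
  src <- c("pictar", "targetscan", "microcosm")
  grp_names <- c("aG", "bG", "abTF", "aTF", "bTF")
  beta <- truth$mirna[truth$true_category == "beta_enriched"]
  n_plant <- length(beta) * n_planted_per_mirna
  planted <- if (n_plant > 0) {
    genes <- sprintf("PLANT%04d", seq_len(n_plant))
    data.frame(mirna = rep(beta, each = n_planted_per_mirna),
               gene = genes,
               group = sample(grp_names, n_plant, replace = TRUE),
               n_dbs = dbs_per_plant, stringsAsFactors = FALSE)
  } else data.frame(mirna = character(), gene = character(),
                    group = character(), n_dbs = integer(),
                    stringsAsFactors = FALSE)
  pair_db <- lapply(src, function(s)
    data.frame(mirna = character(), gene = character(), score = numeric(),
               stringsAsFactors = FALSE))
  names(pair_db) <- src
  if (nrow(planted) && dbs_per_plant > 0) {
    for (i in seq_len(nrow(planted))) {
      into <- sample(src, dbs_per_plant)
      for (s in into)
        pair_db[[s]] <- rbind(pair_db[[s]],
          data.frame(mirna = planted$mirna[i], gene = planted$gene[i],
                     score = stats::runif(1), stringsAsFactors = FALSE))
    }
  }
  decoy_genes <- sprintf("DECOY%04d", seq_len(max(n_decoy_pairs, 1)))
  if (n_decoy_pairs > 0) {
    for (s in src) {
      dec <- data.frame(mirna = sample(truth$mirna, n_decoy_pairs,
                                       replace = TRUE),
                        gene = sample(decoy_genes, n_decoy_pairs,
                                      replace = TRUE),
                        score = stats::runif(n_decoy_pairs),
                        stringsAsFactors = FALSE)
      if (nrow(planted))
        dec <- dec[!paste(dec$mirna, dec$gene) %in%
                     paste(planted$mirna, planted$gene), ]
      pair_db[[s]] <- rbind(pair_db[[s]], dec)
    }
  }
  groups <- lapply(grp_names, function(g) {
    own <- planted$gene[planted$group == g]
    extra <- if (n_decoy_genes_per_group > 0)
      sprintf("%s_FILLER%03d", toupper(g), seq_len(n_decoy_genes_per_group))
    else character()
    c(own, extra)
  })
  names(groups) <- grp_names
  dbs <- lapply(src, function(s) prediction_db(pair_db[[s]], source = s))
  names(dbs) <- src
  list(dbs = dbs, groups = do.call(gene_group_set, groups),
       planted = planted)
}

#' Recovery metrics against a simulation truth table
#'
#' Compares a SAM significant-miRNA table with the generator's truth:
#' sensitivity (recovered truly-enriched / all truly-enriched), false
#' discovery proportion (calls that are not truly enriched / calls;
#' 0 when nothing is called), and direction accuracy among true
#' positives.
#'
#' @param sam_table a `sam_table` (or data.frame with `miRNA` and
#'   `direction` columns).
#' @param truth truth data.frame from [simulate_ct_matrix()].
#' @return A list with `sensitivity`, `false_discovery_proportion`,
#'   `direction_accuracy`, and the underlying counts `n_true`,
#'   `n_called`, `n_true_positive`, `n_false_positive`.
#' @export
recovery_metrics <- function(sam_table, truth) {
  t <- as.data.frame(sam_table)
  enriched <- truth$true_category %in% c("beta_enriched", "alpha_enriched")
  true_ids <- truth$mirna[enriched]
  called <- t$miRNA
  tp <- intersect(called, true_ids)
  fp <- setdiff(called, true_ids)
  dir_truth <- stats::setNames(
    ifelse(truth$true_category == "beta_enriched", "beta", "alpha"),
    truth$mirna)
  dir_ok <- if (length(tp))
    mean(t$direction[match(tp, t$miRNA)] == dir_truth[tp]) else NA_real_
  list(sensitivity = if (length(true_ids))
         length(tp) / length(true_ids) else NA_real_,
       false_discovery_proportion = length(fp) / max(1, length(called)),
       direction_accuracy = dir_ok,
       n_true = length(true_ids), n_called = length(called),
       n_true_positive = length(tp), n_false_positive = length(fp))
}

#' Write a simulated study to disk
#'
#' Emits the same plain-text artifact set the pipeline reads: the
#' simple_tsv Ct matrix with metadata sidecar, three generic-dialect
#' prediction TSVs, the five gene-group files and a truth TSV.
#'
#' @param sim result of [simulate_ct_matrix()].
#' @param dbs optional result of [simulate_prediction_dbs()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dbs = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(ct = file.path(dir, "ct_matrix.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_ct_table(sim$ct, paths["ct"], metadata_path = paths["metadata"])
  write_tsv(sim$truth, paths["truth"])
  if (!is.null(dbs)) {
    for (s in names(dbs$dbs)) {
      p <- file.path(dir, paste0("predictions_", s, ".tsv"))
      pairs <- dbs$dbs[[s]]$pairs
      pairs$score <- sprintf("%.17g", pairs$score)
      utils::write.table(pairs, p, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      paths[paste0("db_", s)] <- p
    }
    for (g in names(dbs$groups)) {
      p <- file.path(dir, paste0(g, ".txt"))
      writeLines(dbs$groups[[g]], p)
      paths[paste0("group_", g)] <- p
    }
  }
  invisible(paths)
}
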