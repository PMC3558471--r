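# Small in-code fixtures shared across test files.

toy_samples <- function(n_donors = 2, card = "A") {
  donors <- paste0("D", seq_len(n_donors))
  data.frame(
    sample_id = c(paste0(donors, "_a"), paste0(donors, "_b")),
    donor_id = rep(donors, 2),
    cell_type = rep(c("alpha", "beta"), each = n_donors),
    card = card, stringsAsFactors = FALSE)
}

toy_ct <- function(values, n_donors = 2, controls = "RNU48", card = "A") {
  ct_matrix(values, toy_samples(n_donors, card), control_assays = controls)
}

# deterministic paired-difference matrix for SAM toys
toy_z <- function(m = 5, n = 4, seed = 42) {
  set.seed(seed)
  z <- matrix(round(rnorm(m * n), 2), m, n,
              dimnames = list(sprintf("mir-%02d", seq_len(m)),
                              paste0("D", seq_len(n))))
  paired_diff(z)
}

flat_fc <- function(z) {
  fold_change(z)
}

# rows lifted from the published significant-miRNA table, used as a
# fixture for the fold-change boundary of the target stage
table1_rows <- function() {
  data.frame(
    miRNA = c("miR-204", "miR-125b", "miR-200c", "miR-182", "miR-375",
              "miR-149"),
    score_d = c(6.41, 5.45, 2.07, 3.27, 2.15, 2.66),
    q_percent = c(0, 0, 0.18, 0, 0, 0),
    fold_change = c(108.42, 27.70, 3.38, 9.80, 2.01, 1.99),
    direction = "beta", stringsAsFactors = FALSE)
}
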