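test_that("miRNA id normalization strips prefixes and preserves strands", {
  expect_identical(normalize_mirna_id("hsa-miR-200c"), "mir-200c")
  expect_identical(normalize_mirna_id("miR-7-1*"), "mir-7-1*")
  expect_identical(normalize_mirna_id("hsa-let-7c"), "let-7c")
  expect_identical(normalize_mirna_id(" hsa-miR-409-3p "), "mir-409-3p")
  expect_error(normalize_mirna_id(""), "non-empty")
  expect_warning(out <- normalize_mirna_id("RNU48"), "passed through")
  expect_identical(out, "rnu48")
})

test_that("normalization is idempotent over a fuzzed corpus", {
  set.seed(19)
  stems <- c("miR-", "let-", "mir-")
  pre <- c("hsa-", "", "HSA-")
  suf <- c("", "*", "-3p", "-5p", "a", "b-2*")
  corpus <- paste0(sample(pre, 60, TRUE), sample(stems, 60, TRUE),
                   sample(1:999, 60, TRUE), sample(suf, 60, TRUE))
  once <- normalize_mirna_id(corpus)
  expect_identical(normalize_mirna_id(once), once)
})

test_that("alias table is applied after canonicalization", {
  al <- c("mir-213" = "mir-181a-1*")
  expect_identical(normalize_mirna_id("hsa-miR-213", aliases = al),
                   "mir-181a-1*")
})

test_that("generic prediction files are parsed with pair deduplication", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "g.tsv")
  writeLines(c("hsa-miR-200c\tMAF\t0.5",
               "hsa-miR-200c\tmaf\t0.9",
               "hsa-miR-125b\tGCG\t0.3"), p)
  db <- suppressWarnings(read_predictions(p, "generic"))
  expect_identical(nrow(db$pairs), 2L)
  # best score kept for the duplicate pair
  expect_equal(db$pairs$score[db$pairs$mirna == "mir-200c"], 0.9)
  expect_setequal(targets_of(db, "mir-200c"), "MAF")
})

test_that("dialects yield the same mapping as a generic rendering", {
  dir <- withr::local_tempdir()
  g <- file.path(dir, "g.tsv")
  writeLines(c("hsa-miR-200c\tMAF\t0.72",
               "hsa-miR-125b\tZFPM2\t0.31"), g)
  ts <- file.path(dir, "ts.tsv")
  writeLines(c("miR Family\tGene ID\tGene Symbol\tPCT",
               "hsa-miR-200c\t4094\tMAF\t0.72",
               "hsa-miR-125b\t23414\tZFPM2\t0.31"), ts)
  mc <- file.path(dir, "mc.tsv")
  writeLines(c("## microcosm-style comment",
               paste("m1", "hsa-miR-200c", "miranda", "utr", "chr16", "1",
                     "2", "+", ".", "0.72", "1e-3", "ENST1", "MAF",
                     sep = "\t"),
               paste("m2", "hsa-miR-125b", "miranda", "utr", "chr8", "1",
                     "2", "+", ".", "0.31", "1e-2", "ENST2", "ZFPM2",
                     sep = "\t")), mc)
  dg <- read_predictions(g, "generic")
  dt <- read_predictions(ts, "targetscan_conserved")
  dm <- read_predictions(mc, "microcosm_v5")
  expect_identical(dg$pairs[, c("mirna", "gene", "score")],
                   dt$pairs[, c("mirna", "gene", "score")])
  expect_identical(dg$pairs[, c("mirna", "gene", "score")],
                   dm$pairs[, c("mirna", "gene", "score")])
})

test_that("malformed prediction lines are skipped, or fatal above 10%", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.tsv")
  writeLines(c(sprintf("hsa-miR-%d\tG%d\t0.5", 1:20, 1:20),
               "brokenline"), p)
  expect_message(db <- suppressWarnings(read_predictions(p, "generic")),
                 "malformed")
  expect_identical(nrow(db$pairs), 20L)
  expect_identical(attr(db, "n_malformed"), 1L)
  writeLines(c("hsa-miR-1\tG1\t0.5", "broken1", "broken2"), p)
  expect_error(suppressWarnings(read_predictions(p, "generic")), "malformed")
  empty <- file.path(dir, "empty.tsv")
  writeLines(character(), empty)
  expect_warning(dbe <- read_predictions(empty, "generic"), "no prediction")
  expect_identical(nrow(dbe$pairs), 0L)
})

test_that("beta-miRNA selection applies a strict fold-change bound", {
  t1 <- table1_rows()
  t1 <- rbind(t1, data.frame(miRNA = "miR-boundary", score_d = 2.5,
                             q_percent = 0, fold_change = 3.0,
                             direction = "beta"),
              data.frame(miRNA = "miR-alpha", score_d = -2.5,
                         q_percent = 0, fold_change = 9,
                         direction = "alpha"))
  sel <- filter_beta_mirnas(t1, min_fc = 3)
  expect_true("miR-125b" %in% sel)   # FC 27.70
  expect_true("miR-204" %in% sel)    # FC 108.42
  expect_false("miR-375" %in% sel)   # FC 2.01
  expect_false("miR-boundary" %in% sel)  # FC exactly 3: strict bound
  expect_false("miR-alpha" %in% sel)
  # min_fc = 0 returns every beta-direction row
  expect_setequal(filter_beta_mirnas(t1, min_fc = 0),
                  t1$miRNA[t1$direction == "beta"])
})

test_that("target intersection reports group hits with consensus counts", {
  db1 <- prediction_db(data.frame(mirna = c("mir-200c", "mir-200c"),
                                  gene = c("MAF", "GCG")),
                       source = "pictar")
  groups <- gene_group_set(aTF = c("MAF", "ZFPM2"))
  rep1 <- intersect_targets("hsa-miR-200c", list(pictar = db1), groups)
  expect_identical(nrow(rep1), 1L)
  expect_identical(rep1$gene, "MAF")
  expect_identical(rep1$group, "aTF")
  expect_identical(rep1$consensus, 1L)

  db2 <- prediction_db(data.frame(mirna = "mir-200c", gene = "MAF"),
                       source = "targetscan")
  db3 <- prediction_db(data.frame(mirna = "mir-200c", gene = "MAF"),
                       source = "microcosm")
  rep3 <- intersect_targets("miR-200c", list(db1, db2, db3), groups)
  expect_identical(nrow(rep3), 3L)
  expect_true(all(rep3$consensus == 3L))
  # brute-force recount of the consensus over the raw pair lists
  for (i in seq_len(nrow(rep3))) {
    n <- sum(vapply(list(db1, db2, db3), function(db)
      any(db$pairs$mirna == rep3$mirna[i] & db$pairs$gene == rep3$gene[i]),
      logical(1)))
    expect_identical(rep3$consensus[i], n)
  }
})

test_that("intersection is invariant to row and input order", {
  set.seed(29)
  pairs <- data.frame(mirna = sample(c("mir-1", "mir-2", "mir-3"), 30, TRUE),
                      gene = sample(sprintf("G%02d", 1:12), 30, TRUE))
  groups <- gene_group_set(aG = sprintf("G%02d", 1:4),
                           bTF = sprintf("G%02d", 9:12))
  dbA <- prediction_db(pairs, "pictar")
  dbB <- prediction_db(pairs[sample(nrow(pairs)), ], "pictar")
  r1 <- intersect_targets(c("mir-1", "mir-2", "mir-3"),
                          list(p = dbA), groups)
  r2 <- intersect_targets(c("mir-3", "mir-1", "mir-2"),
                          list(p = dbB), groups)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # every reported gene really is in its claimed group and in the db
  for (i in seq_len(nrow(r1))) {
    expect_true(r1$gene[i] %in% groups[[r1$group[i]]])
    expect_true(any(dbA$pairs$mirna == r1$mirna[i] &
                      dbA$pairs$gene == r1$gene[i]))
  }
})

test_that("miRNAs absent from all databases are listed, not errors", {
  db <- prediction_db(data.frame(mirna = "mir-1", gene = "G1"), "pictar")
  groups <- gene_group_set(aG = "G1")
  r <- intersect_targets(c("mir-1", "mir-404"), list(p = db), groups)
  expect_identical(attr(r, "unmatched"), "mir-404")
  expect_identical(nrow(r), 1L)
})

test_that("gene-group files are read with comments stripped", {
  dir <- withr::local_tempdir()
  nm <- c("aG", "bG", "abTF", "aTF", "bTF")
  for (g in nm)
    writeLines(c("# comment", paste0(g, "_GENE1"), "",
                 paste0(g, "_gene2  ")), file.path(dir, paste0(g, ".txt")))
  gs <- read_gene_groups(dir)
  expect_s3_class(gs, "gene_group_set")
  expect_identical(gs$aTF, c("ATF_GENE1", "ATF_GENE2"))
  expect_error(read_gene_groups(paths = list(aG = "x")), "missing")
})
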