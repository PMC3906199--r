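test_that("generator is deterministic and honours the study design", {
  cfg <- synth_config(n_genes = 150, module_sizes = c(40, 30), seed = 9)
  d1 <- synth_dataset(cfg)
  d2 <- synth_dataset(cfg)
  expect_identical(d1$expr, d2$expr)
  expect_identical(d1$design, d2$design)
  expect_identical(d1$truth, d2$truth)
  expect_identical(synth_promoters(cfg, d1$truth),
                   synth_promoters(cfg, d2$truth))
  expect_identical(synth_annotations(cfg, d1$truth),
                   synth_annotations(cfg, d2$truth))

  des <- d1$design
  # one heat array (5 h, replicate C) is dropped; controls are triplicate
  expect_false(any(des$stress == "heat" & des$timepoint_h == 5 &
                     des$replicate == "C"))
  expect_equal(sum(des$stress == "heat"), 14)
  expect_equal(sum(des$is_control), 15)
  expect_equal(ncol(d1$expr), nrow(des))
  expect_false(anyDuplicated(des$sample_id) > 0)
  # RMA-scale baseline: grand level near 8 with spread of a few units
  expect_gt(mean(d1$expr), 6)
  expect_lt(mean(d1$expr), 10)
})

test_that("degenerate and invalid configurations are handled", {
  empty <- synth_dataset(synth_config(n_genes = 0, module_sizes = integer(),
                                      n_tfs = 0, n_class = 0,
                                      n_plastic_pairs = 0, seed = 1))
  expect_equal(nrow(empty$expr), 0)
  expect_equal(nrow(empty$truth$modules), 0)

  expect_error(synth_config(n_genes = 50, module_sizes = c(30, 30),
                            n_tfs = 5), "exceeding")
  expect_error(synth_config(n_genes = 100, module_sizes = 30, n_tfs = 5,
                            timepoints_h = c(2, 1, 5)), "increasing")
  expect_error(synth_config(n_genes = 100, module_sizes = 30, n_tfs = 200),
               "n_tfs")
  expect_error(synth_config(
    n_genes = 100, module_sizes = c(30, 30), n_tfs = 5,
    planted_motifs = tibble::tibble(motif = c("AACGG", "AACGG"),
                                    module = c(1L, 1L), rate = c(1, 1))),
    "duplicate")
  expect_error(synth_config(
    n_genes = 100, module_sizes = 30, n_tfs = 5,
    planted_motifs = tibble::tibble(motif = "AANGG", module = 1L, rate = 1)),
    "ACGT")
  expect_error(synth_config(
    n_genes = 100, module_sizes = 30, n_tfs = 5,
    planted_motifs = tibble::tibble(motif = "ACGT", module = 1L, rate = 1)),
    "5-8")
  expect_error(synth_config(
    n_genes = 100, module_sizes = 30, n_tfs = 5,
    planted_motifs = tibble::tibble(motif = "AACGG", module = 1L, rate = 0)),
    "rate")
})

test_that("high signal-to-noise forces high within-module correlation", {
  cfg <- synth_config(n_genes = 200, module_sizes = c(40, 35, 30),
                      de_effect_rma = 2, noise_sd_rma = 0.3, seed = 5)
  ds <- synth_dataset(cfg)
  stress_cols <- ds$design$sample_id[!ds$design$is_control]
  rs <- vapply(1:3, function(m) {
    g <- ds$truth$modules$gene_id[ds$truth$modules$module == m]
    cm <- cor(t(ds$expr[g, stress_cols]))
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  expect_gt(mean(rs), 0.8)

  # within-module correlations exceed between-module correlations
  g1 <- ds$truth$modules$gene_id[ds$truth$modules$module == 1]
  g2 <- ds$truth$modules$gene_id[ds$truth$modules$module == 2]
  between <- mean(abs(cor(t(ds$expr[g1, stress_cols]),
                          t(ds$expr[g2, stress_cols]))))
  expect_gt(mean(rs), between)
})

test_that("ground truth is consistent with the emitted data", {
  fx <- shared_fixture()
  tr <- fx$ds$truth
  # planted plastic pairs: |r_a - r_b| >= 1 in the generating model, and
  # realised correlations close to the recorded truth
  expect_true(all(abs(tr$plastic_pairs$r_a - tr$plastic_pairs$r_b) >= 1))
  cols_a <- fx$ds$design$sample_id[fx$ds$design$stress == "drought"]
  cols_b <- fx$ds$design$sample_id[fx$ds$design$stress == "salt"]
  for (i in seq_len(nrow(tr$plastic_pairs))) {
    ra <- cor(fx$ds$expr[tr$plastic_pairs$tf[i], cols_a],
              fx$ds$expr[tr$plastic_pairs$tg[i], cols_a])
    rb <- cor(fx$ds$expr[tr$plastic_pairs$tf[i], cols_b],
              fx$ds$expr[tr$plastic_pairs$tg[i], cols_b])
    expect_equal(ra, tr$plastic_pairs$r_a[i], tolerance = 0.12)
    expect_equal(rb, tr$plastic_pairs$r_b[i], tolerance = 0.12)
  }
  # module truth: per-module profile peaks at or above 1 RMA for responsive
  # stresses
  peaks <- tapply(abs(tr$module_profiles$delta_rma),
                  list(tr$module_profiles$module, tr$module_profiles$stress),
                  max)
  expect_true(all(peaks[peaks > 0] >= 1))
})

test_that("promoter planting at rate 1 places the motif at recorded offsets", {
  cfg <- synth_config(n_genes = 60, module_sizes = 10, n_tfs = 5,
                      n_class = 5, n_plastic_pairs = 0,
                      planted_motifs = tibble::tibble(
                        motif = "AACGGTC", module = 1L, rate = 1),
                      seed = 3)
  ds <- synth_dataset(cfg)
  pr <- synth_promoters(cfg, ds$truth)
  members <- ds$truth$modules$gene_id[ds$truth$modules$module == 1]
  expect_setequal(pr$placements$gene_id, members)
  for (i in seq_len(nrow(pr$placements))) {
    seq <- pr$promoters$sequence[
      pr$promoters$gene_id == pr$placements$gene_id[i]]
    expect_equal(substr(seq, pr$placements$start[i],
                        pr$placements$start[i] + 6), "AACGGTC")
  }
  expect_true(all(nchar(pr$promoters$sequence) == 500))
  expect_true(all(grepl("^[ACGT]+$", pr$promoters$sequence)))
})

test_that("promoter length equal to motif length forces start 1", {
  cfg <- synth_config(n_genes = 60, module_sizes = 10, n_tfs = 5,
                      n_class = 5, n_plastic_pairs = 0,
                      promoter_length_nt = 5,
                      planted_motifs = tibble::tibble(
                        motif = "AACGG", module = 1L, rate = 1),
                      seed = 3)
  ds <- synth_dataset(cfg)
  pr <- synth_promoters(cfg, ds$truth)
  expect_true(all(pr$placements$start == 1))
})

test_that("unplanted motif frequency matches the i.i.d. background rate", {
  cfg <- synth_config(n_genes = 10000, module_sizes = 100, n_tfs = 5,
                      n_class = 5, n_plastic_pairs = 0,
                      promoter_length_nt = 100,
                      planted_motifs = tibble::tibble(motif = character(),
                                                      module = integer(),
                                                      rate = double()),
                      seed = 17)
  ds_truth <- list(modules = tibble::tibble(
    gene_id = sprintf("g%05d", 1:10000), module = 0L))
  pr <- synth_promoters(cfg, ds_truth)
  motif <- "AACGGTC"
  n_hits <- sum(Biostrings::vcountPattern(
    motif, Biostrings::DNAStringSet(pr$promoters$sequence)))
  # length-adjusted binomial expectation: (L - w + 1) * 4^-w per promoter
  expected <- 10000 * (100 - 7 + 1) * 4^-7
  se <- sqrt(expected)                    # Poisson-scale Monte-Carlo error
  expect_lt(abs(n_hits - expected), 4 * se)
})

test_that("annotations cover the planted structures", {
  fx <- shared_fixture()
  expect_true(all(fx$ds$truth$plastic_tfs %in% fx$ann$tf_genes))
  expect_equal(length(fx$ann$tf_genes), fx$cfg$n_tfs)
  # planted term covers exactly module 1
  m1 <- fx$ds$truth$modules$gene_id[fx$ds$truth$modules$module == 1]
  expect_setequal(fx$ann$term_map$gene_id[fx$ann$term_map$term == "TERM:0001"],
                  m1)
  # the non-modular class is sampled preferentially outside modules
  in_mod <- fx$ann$class_genes %in%
    fx$ds$truth$modules$gene_id[fx$ds$truth$modules$module > 0]
  expect_lt(mean(in_mod), 0.5)

  # n_tfs = n_genes makes the TF list the whole universe
  cfg <- synth_config(n_genes = 60, module_sizes = 10, n_tfs = 60,
                      n_class = 5, n_plastic_pairs = 0, seed = 2)
  ds <- synth_dataset(cfg)
  ann <- synth_annotations(cfg, ds$truth)
  expect_setequal(ann$tf_genes, rownames(ds$expr))
})

test_that("fixture bundles round-trip through the writers", {
  fx <- shared_fixture()
  dir <- withr::local_tempdir()
  write_synth_bundle(fx$ds, promoters = fx$pr, annotations = fx$ann, dir = dir)
  back <- read_expression(file.path(dir, "expression.tsv"),
                          file.path(dir, "design.tsv"))
  expect_equal(back$expr, fx$ds$expr)
  expect_equal(back$design$sample_id, fx$ds$design$sample_id)
  pr2 <- read_promoters(file.path(dir, "promoters.fasta"))
  expect_equal(pr2$sequence, fx$pr$promoters$sequence)
  expect_equal(read_gene_list(file.path(dir, "tf_genes.txt")),
               fx$ann$tf_genes)
})
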