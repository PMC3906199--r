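test_that("pair correlations split DE-in-both genes into TF and TG groups", {
  fx <- shared_fixture()
  pc <- pair_correlations(fx$ds$expr, fx$ds$design, fx$de, fx$ann$tf_genes,
                          "drought", "salt")
  both <- intersect(de_genes(fx$de, "drought"), de_genes(fx$de, "salt"))
  expect_setequal(c(pc$tf, pc$tg), intersect(both, c(pc$tf, pc$tg)))
  expect_true(all(pc$tf %in% fx$ann$tf_genes))
  expect_false(any(pc$tg %in% fx$ann$tf_genes))
  expect_equal(dim(pc$r_a), c(length(pc$tf), length(pc$tg)))
  expect_true(all(abs(pc$r_a) <= 1 + 1e-12))

  # planted pairs are recovered within +/- 0.1 of the generating correlation
  tr <- fx$ds$truth$plastic_pairs
  for (i in seq_len(nrow(tr))) {
    if (tr$tf[i] %in% pc$tf && tr$tg[i] %in% pc$tg) {
      expect_equal(pc$r_a[tr$tf[i], tr$tg[i]], tr$r_a[i], tolerance = 0.12)
      expect_equal(pc$r_b[tr$tf[i], tr$tg[i]], tr$r_b[i], tolerance = 0.12)
    }
  }
})

test_that("a TF identical to a target gives correlation 1; constants drop", {
  design <- tibble::tibble(
    sample_id = paste0("s", 1:8),
    stress = rep(c("cold", "heat"), each = 4),
    timepoint_h = rep(c(1, 2, 1, 2), 2), replicate = rep(c("A", "B"), 4),
    is_control = FALSE)
  set.seed(5)
  base <- rnorm(8)
  m <- rbind(tf1 = base, tg1 = base, tg2 = c(rep(1, 4), rnorm(4)))
  colnames(m) <- design$sample_id
  de <- structure(list(by_stress = tibble::tibble(
    stress = rep(c("cold", "heat"), each = 3),
    gene_id = rep(c("tf1", "tg1", "tg2"), 2),
    direction = "up", both_directions = FALSE)), class = "de_calls")
  expect_warning(
    pc <- pair_correlations(m, design, de, "tf1", "cold", "heat"),
    "zero-variance")
  expect_equal(pc$r_a["tf1", "tg1"], 1)
  expect_false("tg2" %in% pc$tg)       # constant in cold, dropped
})

test_that("null exceedance counts behave at the grid boundaries", {
  set.seed(6)
  m <- matrix(rnorm(20 * 40), 20, 40,
              dimnames = list(paste0("g", 1:20), NULL))
  nl <- plasticity_null(m, paste0("g", 1:5), paste0("g", 6:20),
                        n_permutations = 30, subset_n = 15)
  expect_equal(nl$n_pairs, 75)
  # cutoff 0 counts every pairing; cutoff 2 counts none
  expect_true(all(nl$counts[, 1] == 75))
  expect_true(all(nl$counts[, ncol(nl$counts)] == 0))
  # monotone non-increasing in the cutoff, per permutation
  expect_true(all(apply(nl$counts, 1, \(x) all(diff(x) <= 0))))

  expect_error(plasticity_null(m[, 1:20], paste0("g", 1:5), paste0("g", 6:20),
                               n_permutations = 5, subset_n = 15),
               "exceeds")
})

test_that("cutoff selection is the minimal grid point meeting the FDR", {
  null <- structure(list(cutoffs = seq(0, 2, 0.5),
                         mean_exceed = c(100, 5, 0, 0, 0)),
                    class = "plasticity_null")
  sel <- select_cutoff(c(rep(0.6, 100), rep(1.2, 20)), null,
                       target_fdr = 0.05)
  expect_false(sel$no_signal)
  # at 0: 100/120 fails; at 0.5: 5/120 = 0.042 passes and is minimal
  expect_equal(sel$cutoff, 0.5)
  expect_equal(sel$n_plastic, 120L)
  expect_equal(sel$fdr, 5 / 120)

  # all-null observations: no signal
  none <- select_cutoff(numeric(0), null, target_fdr = 0.05)
  expect_true(none$no_signal)
  expect_equal(none$n_plastic, 0L)

  # zero null exceedances above 0.5 with 100 observed: fdr 0 at cutoff <= 0.5
  sel0 <- select_cutoff(rep(0.7, 100),
                        structure(list(cutoffs = seq(0, 2, 0.5),
                                       mean_exceed = c(50, 0, 0, 0, 0)),
                                  class = "plasticity_null"), 0.05)
  expect_lte(sel0$cutoff, 0.5)
  expect_equal(sel0$fdr, 0)
})

test_that("planted plastic pairs are detected; stable pairs are not", {
  fx <- shared_fixture()
  cmp <- shared_plasticity()
  expect_false(cmp$cutoff$no_signal)
  expect_lte(cmp$cutoff$fdr, cmp$target_fdr)

  # minimality: the next-smaller grid cutoff violates the target
  i <- which(abs(cmp$null$cutoffs - cmp$cutoff$cutoff) < 1e-9)
  if (i > 1) {
    obs_prev <- sum(abs(cmp$pairs$r_a - cmp$pairs$r_b) >=
                      cmp$null$cutoffs[i - 1] - 1e-12)
    expect_gt(cmp$null$mean_exceed[i - 1] / max(obs_prev, 1),
              cmp$target_fdr)
  }

  tab <- tidy(cmp)
  tr <- fx$ds$truth$plastic_pairs
  planted_key <- paste(tr$tf, tr$tg)
  tab_key <- paste(tab$tf, tab$tg)
  planted <- tab[tab_key %in% planted_key, ]
  expect_gte(nrow(planted), 8)           # nearly all pairs eligible
  expect_gte(mean(planted$plastic), 0.9) # sensitivity

  background <- tab[!tab_key %in% planted_key, ]
  expect_lte(mean(background$plastic), 2 * cmp$target_fdr)
})

test_that("non-plastic genes are the eligible genes with no plastic pairing", {
  cmp <- shared_plasticity()
  np <- nonplastic_genes(list(cmp))
  tab <- tidy(cmp)
  eligible <- unique(c(tab$tf, tab$tg))
  plastic_genes <- unique(c(tab$tf[tab$plastic], tab$tg[tab$plastic]))
  expect_setequal(np, setdiff(eligible, plastic_genes))
  expect_true(all(np %in% eligible))

  # all pairs plastic leaves nothing non-plastic
  forced <- cmp
  forced$cutoff$cutoff <- 0
  expect_equal(length(nonplastic_genes(list(forced))), 0)

  expect_error(nonplastic_genes(list()), "no comparisons")
})

test_that("glance lays out the comparison like the plasticity report table", {
  cmp <- shared_plasticity()
  g <- glance(cmp)
  expect_named(g, c("stress_a", "stress_b", "gene_pairings", "plastic_pairs",
                    "plastic_pct", "mean_false_positives", "fdr",
                    "delta_r_cutoff", "no_signal"))
  expect_equal(g$gene_pairings,
               length(cmp$pairs$tf) * length(cmp$pairs$tg))
  expect_equal(g$plastic_pct,
               100 * g$plastic_pairs / g$gene_pairings)
  expect_lte(g$plastic_pairs, g$gene_pairings)
})
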