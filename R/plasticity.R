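#' TF-target correlation matrices for a condition pair
#'
#' Genes differentially expressed in both conditions of the pair are split
#' into a transcription-factor (TF) group and a non-TF target (TG) group;
#' all TF x TG Pearson correlations are computed separately over each
#' condition's stress arrays (all timepoints and replicates). Genes with zero
#' variance within a condition are dropped with a warning.
#'
#' @param expr Numeric matrix, genes x arrays.
#' @param design Design tibble.
#' @param de A `de_calls` object from [sam_call_all()].
#' @param tf_genes Character vector of transcription-factor gene ids.
#' @param cond_a,cond_b Stress labels of the two conditions.
#'
#' @return List of class `pair_cor`: `tf`, `tg` (gene ids), `r_a`, `r_b`
#'   (TF x TG correlation matrices), `cond_a`, `cond_b`, `n_a`, `n_b`
#'   (array counts). Empty TF or TG groups yield an empty comparison.
#' @export
pair_correlations <- function(expr, design, de, tf_genes, cond_a, cond_b) {
  de_a <- de_genes(de, cond_a)
  de_b <- de_genes(de, cond_b)
  both <- intersect(de_a, de_b)
  tf <- intersect(both, tf_genes)
  tg <- setdiff(both, tf_genes)
  cols_a <- design$sample_id[design$stress == cond_a & !design$is_control]
  cols_b <- design$sample_id[design$stress == cond_b & !design$is_control]

  drop_const <- function(genes, cols, cond) {
    if (!length(genes)) return(genes)
    sds <- apply(expr[genes, cols, drop = FALSE], 1, sd)
    if (any(sds == 0)) {
      warn(sprintf("dropping %d zero-variance gene(s) in condition '%s'",
                   sum(sds == 0), cond))
    }
    genes[sds > 0]
  }
  tf <- drop_const(drop_const(tf, cols_a, cond_a), cols_b, cond_b)
  tg <- drop_const(drop_const(tg, cols_a, cond_a), cols_b, cond_b)

  if (!length(tf) || !length(tg)) {
    return(structure(list(tf = tf, tg = tg,
                          r_a = matrix(0, length(tf), length(tg)),
                          r_b = matrix(0, length(tf), length(tg)),
                          cond_a = cond_a, cond_b = cond_b,
                          n_a = length(cols_a), n_b = length(cols_b)),
                     class = "pair_cor"))
  }
  r_a <- cor(t(expr[tf, cols_a, drop = FALSE]),
             t(expr[tg, cols_a, drop = FALSE]))
  r_b <- cor(t(expr[tf, cols_b, drop = FALSE]),
             t(expr[tg, cols_b, drop = FALSE]))
  structure(list(tf = tf, tg = tg, r_a = r_a, r_b = r_b,
                 cond_a = cond_a, cond_b = cond_b,
                 n_a = length(cols_a), n_b = length(cols_b)),
            class = "pair_cor")
}

#' Permutation null for TF-target correlation changes
#'
#' Each gene's profile across the supplied arrays is independently
#' Fisher-Yates shuffled; two disjoint column subsets of size `subset_n` are
#' drawn, all TF x TG Pearson correlations are computed in each subset, and
#' the number of pairs whose absolute correlation difference reaches each
#' cutoff on a `[0, 2]` grid is recorded per permutation.
#'
#' @param expr Numeric matrix restricted to the arrays forming the shuffle
#'   pool (typically all stress arrays).
#' @param tf_genes,tg_genes Row names forming the TF and target groups.
#' @param n_permutations Number of permutations (the full-scale analysis
#'   uses 7200; smaller counts give the same null in expectation).
#' @param subset_n Size of each of the two disjoint subsets (default 15).
#' @param grid_step Cutoff grid step in delta-r units (default 0.01).
#'
#' @return Object of class `plasticity_null`: `cutoffs` (grid), `counts`
#'   (permutations x cutoffs exceedance matrix), `mean_exceed` (column
#'   means), `n_pairs`.
#' @export
plasticity_null <- function(expr, tf_genes, tg_genes, n_permutations = 200,
                            subset_n = 15, grid_step = 0.01) {
  ncols <- ncol(expr)
  if (2 * subset_n > ncols) {
    abort(sprintf("2 * subset_n = %d exceeds the %d available arrays",
                  2 * subset_n, ncols))
  }
  x <- expr[c(tf_genes, tg_genes), , drop = FALSE]
  ntf <- length(tf_genes)
  ntg <- length(tg_genes)
  cutoffs <- seq(0, 2, by = grid_step)
  counts <- matrix(0L, n_permutations, length(cutoffs))
  ia <- seq_len(subset_n)
  ib <- subset_n + seq_len(subset_n)
  for (p in seq_len(n_permutations)) {
    shuffled <- t(apply(x, 1, sample))    # per-gene Fisher-Yates shuffle
    ra <- row_cor(shuffled[seq_len(ntf), ia, drop = FALSE],
                  shuffled[ntf + seq_len(ntg), ia, drop = FALSE])
    rb <- row_cor(shuffled[seq_len(ntf), ib, drop = FALSE],
                  shuffled[ntf + seq_len(ntg), ib, drop = FALSE])
    dr <- abs(ra - rb)
    counts[p, ] <- exceed_counts(dr, cutoffs)
  }
  structure(list(cutoffs = cutoffs, counts = counts,
                 mean_exceed = colMeans(counts),
                 n_pairs = ntf * ntg, n_permutations = n_permutations,
                 subset_n = subset_n),
            class = "plasticity_null")
}

# Pearson correlations between all rows of a and all rows of b.
row_cor <- function(a, b) {
  za <- a - rowMeans(a)
  zb <- b - rowMeans(b)
  za <- za / sqrt(rowSums(za^2))
  zb <- zb / sqrt(rowSums(zb^2))
  r <- tcrossprod(za, zb)
  r[!is.finite(r)] <- 0                   # constant rows contribute nothing
  pmin(pmax(r, -1), 1)
}

# number of values >= each cutoff, via a single sorted pass
exceed_counts <- function(values, cutoffs) {
  n <- length(values)
  n - findInterval(cutoffs - 1e-12, sort(values))
}

#' Select the delta-r cutoff controlling permutation FDR
#'
#' Chooses the smallest grid cutoff `c` such that the mean number of null
#' pairs exceeding `c` per permutation, divided by the number of observed
#' pairs exceeding `c`, is at or below `target_fdr`. When no cutoff
#' qualifies (or nothing is observed above any qualifying cutoff) the
#' comparison is marked as having no signal.
#'
#' @param observed_dr Numeric vector of observed `|r_a - r_b|` values.
#' @param null A [plasticity_null()] object.
#' @param target_fdr Target FDR (default 0.05).
#'
#' @return One-row tibble: `cutoff`, `n_plastic`, `mean_false_positives`,
#'   `fdr`, `no_signal`.
#' @export
select_cutoff <- function(observed_dr, null, target_fdr = 0.05) {
  obs <- exceed_counts(observed_dr, null$cutoffs)
  fdr <- null$mean_exceed / pmax(obs, 1)
  ok <- which(fdr <= target_fdr & obs > 0)
  if (!length(ok)) {
    return(tibble::tibble(cutoff = NA_real_, n_plastic = 0L,
                          mean_false_positives = NA_real_, fdr = NA_real_,
                          no_signal = TRUE))
  }
  i <- ok[1]
  tibble::tibble(cutoff = null$cutoffs[i], n_plastic = as.integer(obs[i]),
                 mean_false_positives = null$mean_exceed[i],
                 fdr = null$mean_exceed[i] / obs[i], no_signal = FALSE)
}

#' Differential-correlation (plasticity) analysis for one condition pair
#'
#' Full pipeline for one comparison: build the TF/TG groups and per-condition
#' correlation matrices ([pair_correlations()]), generate the permutation
#' null over the pooled stress arrays ([plasticity_null()]), select the
#' delta-r cutoff at the target FDR ([select_cutoff()]), and tabulate
#' plastic pairs.
#'
#' @inheritParams pair_correlations
#' @param n_permutations Permutations for the null (default 200).
#' @param subset_n Null subset size (default 15).
#' @param target_fdr Target FDR (default 0.05).
#' @param grid_step Cutoff grid step (default 0.01).
#'
#' @return Object of class `plasticity_cmp`; see [tidy.plasticity_cmp()] and
#'   [glance.plasticity_cmp()].
#' @export
plasticity_comparison <- function(expr, design, de, tf_genes, cond_a, cond_b,
                                  n_permutations = 200, subset_n = 15,
                                  target_fdr = 0.05, grid_step = 0.01) {
  pc <- pair_correlations(expr, design, de, tf_genes, cond_a, cond_b)
  stress_cols <- design$sample_id[!design$is_control]
  if (!length(pc$tf) || !length(pc$tg)) {
    cut <- tibble::tibble(cutoff = NA_real_, n_plastic = 0L,
                          mean_false_positives = NA_real_, fdr = NA_real_,
                          no_signal = TRUE)
    return(structure(list(pairs = pc, cutoff = cut, null = NULL,
                          cond_a = cond_a, cond_b = cond_b,
                          target_fdr = target_fdr),
                     class = "plasticity_cmp"))
  }
  null <- plasticity_null(expr[, stress_cols, drop = FALSE],
                          pc$tf, pc$tg,
                          n_permutations = n_permutations,
                          subset_n = subset_n, grid_step = grid_step)
  cut <- select_cutoff(abs(pc$r_a - pc$r_b), null, target_fdr)
  structure(list(pairs = pc, cutoff = cut, null = null,
                 cond_a = cond_a, cond_b = cond_b, target_fdr = target_fdr),
            class = "plasticity_cmp")
}

#' @describeIn plasticity_comparison Per-pair table (`tf`, `tg`, `r_a`,
#'   `r_b`, `delta_r`, `plastic`).
#' @param x A `plasticity_cmp` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.plasticity_cmp <- function(x, ...) {
  pc <- x$pairs
  if (!length(pc$tf) || !length(pc$tg)) {
    return(tibble::tibble(tf = character(), tg = character(), r_a = double(),
                          r_b = double(), delta_r = double(),
                          plastic = logical()))
  }
  tab <- tibble::tibble(
    tf = rep(pc$tf, times = length(pc$tg)),
    tg = rep(pc$tg, each = length(pc$tf)),
    r_a = as.vector(pc$r_a), r_b = as.vector(pc$r_b))
  tab$delta_r <- abs(tab$r_a - tab$r_b)
  tab$plastic <- !x$cutoff$no_signal & tab$delta_r >= (x$cutoff$cutoff %||% Inf)
  tab
}

#' @describeIn plasticity_comparison One-row comparison summary in the shape
#'   of the plasticity report table (pairings, plastic pairs, mean false
#'   positives, FDR, cutoff).
#' @exportS3Method generics::glance
glance.plasticity_cmp <- function(x, ...) {
  n_pairs <- length(x$pairs$tf) * length(x$pairs$tg)
  tibble::tibble(
    stress_a = x$cond_a, stress_b = x$cond_b,
    gene_pairings = n_pairs,
    plastic_pairs = x$cutoff$n_plastic,
    plastic_pct = if (n_pairs > 0) 100 * x$cutoff$n_plastic / n_pairs else NA_real_,
    mean_false_positives = x$cutoff$mean_false_positives,
    fdr = x$cutoff$fdr,
    delta_r_cutoff = x$cutoff$cutoff,
    no_signal = x$cutoff$no_signal)
}

#' @export
print.plasticity_cmp <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<plasticity_cmp> %s vs %s: %d pairings, %d plastic (cutoff %.2f, FDR %.3g)\n",
              g$stress_a, g$stress_b, g$gene_pairings, g$plastic_pairs,
              g$delta_r_cutoff %||% NA, g$fdr %||% NA))
  invisible(x)
}

#' Genes with no plastic TF relationship in any comparison
#'
#' A gene is non-plastic when it appears (as TF or target) in at least one
#' comparison and none of its TF pairings reaches the comparison's delta-r
#' cutoff in any comparison. Genes eligible in no comparison are excluded
#' entirely.
#'
#' @param comparisons List of `plasticity_cmp` objects.
#' @return Character vector of gene ids.
#' @export
nonplastic_genes <- function(comparisons) {
  if (!length(comparisons)) abort("no comparisons supplied")
  eligible <- character(); plastic <- character()
  for (cmp in comparisons) {
    tab <- tidy(cmp)
    eligible <- union(eligible, c(cmp$pairs$tf, cmp$pairs$tg))
    bad <- tab[tab$plastic, ]
    plastic <- union(plastic, c(bad$tf, bad$tg))
  }
  sort(setdiff(eligible, plastic))
}
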