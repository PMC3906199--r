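# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture_config <- function() {
  synth_config(
    n_genes = 400,
    module_sizes = c(60, 45, 35),
    n_tfs = 60,
    n_plastic_pairs = 10,
    n_class = 40,
    planted_motifs = tibble::tibble(motif = "CAACGGTC", module = 2L,
                                    rate = 0.6),
    seed = 101)
}

# dataset + annotations + promoters + DE calls on the shared config
shared_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    cfg <- fixture_config()
    ds <- synth_dataset(cfg)
    ann <- synth_annotations(cfg, ds$truth)
    pr <- synth_promoters(cfg, ds$truth)
    de <- sam_call_all(ds$expr, ds$design)
    .fixture_cache$fx <- list(cfg = cfg, ds = ds, ann = ann, pr = pr, de = de)
  }
  .fixture_cache$fx
}

# network module assignment detected from the shared fixture's DE genes
shared_modules <- function() {
  if (is.null(.fixture_cache$mod)) {
    fx <- shared_fixture()
    genes <- intersect(de_genes(fx$de), rownames(fx$ds$expr))
    genes <- genes[apply(fx$ds$expr[genes, , drop = FALSE], 1, sd) > 0]
    nt <- adjacency_tom(fx$ds$expr[genes, , drop = FALSE], power = 23)
    asg <- detect_modules(nt$dissimilarity, cut_height = 0.91, min_size = 25)
    asg <- merge_modules(asg, fx$ds$expr[genes, , drop = FALSE])
    .fixture_cache$mod <- list(net = nt, assignment = asg, genes = genes)
  }
  .fixture_cache$mod
}

# drought-salt plasticity comparison on the shared fixture
shared_plasticity <- function() {
  if (is.null(.fixture_cache$plas)) {
    fx <- shared_fixture()
    set.seed(202)
    .fixture_cache$plas <- plasticity_comparison(
      fx$ds$expr, fx$ds$design, fx$de, fx$ann$tf_genes,
      "drought", "salt", n_permutations = 100)
  }
  .fixture_cache$plas
}

# brute-force TOM oracle: direct triple loop over the defining formula
tom_dissimilarity_oracle <- function(a) {
  n <- nrow(a)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      tom <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
      d[i, j] <- 1 - tom
    }
  }
  d
}

# step-up BH oracle over the full family of m tests (absent tests have p = 1)
bh_oracle <- function(p, m) {
  full <- c(p, rep(1, m - length(p)))
  o <- order(full)
  ranked <- full[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  pmin(adj, 1)[order(o)][seq_along(p)]
}

# exact hypergeometric upper-tail by direct pmf summation
hyper_tail_oracle <- function(q, white, black, drawn) {
  sum(vapply(q:min(white, drawn), function(x) {
    choose(white, x) * choose(black, drawn - x) / choose(white + black, drawn)
  }, numeric(1)))
}

# adjusted Rand index between two label vectors (contingency-table formula)
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# A significant motif is attributable to a planted word when it shares a
# core of >= 5 consecutive bases with it: that covers sub/super-words and
# the junction words formed where a planted insert meets random flanks.
related_to_planted <- function(motif, planted, core = 5) {
  if (grepl(motif, planted, fixed = TRUE) ||
      grepl(planted, motif, fixed = TRUE)) return(TRUE)
  for (len in seq(nchar(planted), core)) {
    for (at in seq_len(nchar(planted) - len + 1)) {
      if (grepl(substr(planted, at, at + len - 1), motif, fixed = TRUE)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

reverse_complement_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}
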