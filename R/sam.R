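#' SAM-style two-class unpaired permutation test
#'
#' Computes, for every gene, the regularised difference statistic
#' `d = (mean(B) - mean(A)) / (s + s0)` where `s` is the pooled-SD standard
#' error of the difference and `s0` a fudge factor stabilising low-variance
#' genes. Permutations of the group labels give expected order statistics;
#' a gene at sorted rank `i` is called when `|d_(i) - dbar_(i)| >= delta`,
#' and the median false discovery rate at a given `delta` is the median over
#' permutations of the number of permuted `d` values beyond the observed call
#' cutoffs, divided by the number of observed calls. When `delta` is `NULL`
#' the smallest value on a 0.01-step grid whose median FDR is at or below
#' `target_fdr` is selected.
#'
#' For small balanced designs all distinct label assignments are enumerated
#' and resampled with replacement up to `n_permutations`, so the full
#' exchangeable space is always covered.
#'
#' @param expr Numeric matrix, genes x arrays.
#' @param group_a,group_b Column names (or indices) of the two groups;
#'   disjoint, each of size >= 2. `group_a` is the reference (e.g. control).
#' @param n_permutations Number of label permutations (default 100).
#' @param target_fdr Target median FDR used for automatic `delta` selection.
#' @param s0 Fudge factor; estimated by the standard percentile procedure
#'   when `NULL`.
#' @param delta Call threshold on `|d - dbar|`; selected automatically when
#'   `NULL`.
#'
#' @return Object of class `sam_fit`; see [tidy.sam_fit()] and
#'   [glance.sam_fit()].
#' @export
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(600), 100, 6,
#'             dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
#' m[1:5, 4:6] <- m[1:5, 4:6] + 4
#' fit <- sam_test(m, paste0("s", 1:3), paste0("s", 4:6))
#' glance(fit)
sam_test <- function(expr, group_a, group_b, n_permutations = 100,
                     target_fdr = 0.01, s0 = NULL, delta = NULL) {
  if (is.character(group_a)) group_a <- match(group_a, colnames(expr))
  if (is.character(group_b)) group_b <- match(group_b, colnames(expr))
  if (anyNA(group_a) || anyNA(group_b)) abort("unknown sample id(s) in groups")
  if (length(intersect(group_a, group_b))) abort("groups must be disjoint")
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group must contain at least 2 arrays")
  }
  x <- expr[, c(group_a, group_b), drop = FALSE]
  na <- length(group_a); nb <- length(group_b)
  n <- nrow(x)
  if (n == 0) abort("empty expression matrix")

  dstat <- function(cols_a, cols_b, s0) {
    ma <- rowMeans(x[, cols_a, drop = FALSE])
    mb <- rowMeans(x[, cols_b, drop = FALSE])
    ssa <- rowSums((x[, cols_a, drop = FALSE] - ma)^2)
    ssb <- rowSums((x[, cols_b, drop = FALSE] - mb)^2)
    s <- sqrt((1 / na + 1 / nb) * (ssa + ssb) / (na + nb - 2))
    denom <- s + s0
    d <- ifelse(denom > 0, (mb - ma) / denom, 0)
    list(d = d, s = s)
  }

  obs0 <- dstat(seq_len(na), na + seq_len(nb), 0)
  if (is.null(s0)) s0 <- estimate_s0(x, na, nb, obs0$s)
  obs <- dstat(seq_len(na), na + seq_len(nb), s0)

  # permutation assignments: enumerate the exchangeable space when small,
  # then resample with replacement to the requested count
  total <- choose(na + nb, na)
  if (total <= n_permutations) {
    combos <- combn(na + nb, na)
    take <- c(seq_len(ncol(combos)),
              sample.int(ncol(combos), n_permutations - ncol(combos),
                         replace = TRUE))
    assign_a <- combos[, take, drop = FALSE]
  } else {
    assign_a <- replicate(n_permutations, sample.int(na + nb, na))
  }

  perm_sorted <- matrix(0, n, n_permutations)
  perm_all <- matrix(0, n, n_permutations)
  for (p in seq_len(n_permutations)) {
    ca <- assign_a[, p]
    dp <- dstat(ca, setdiff(seq_len(na + nb), ca), s0)$d
    perm_all[, p] <- dp
    perm_sorted[, p] <- sort(dp)
  }
  dbar <- rowMeans(perm_sorted)              # expected order statistics

  ord <- order(obs$d)
  dev <- obs$d[ord] - dbar                   # per-rank deviation

  # directional calling: up where the sorted d exceeds its expected order
  # statistic by delta, down where it falls short by delta; the observed d
  # cutoffs then close the call sets monotonically
  eval_delta <- function(delta) {
    up_ranks <- which(dev >= delta & dbar >= 0)
    dn_ranks <- which(dev <= -delta & dbar <= 0)
    cutup <- if (length(up_ranks)) min(obs$d[ord][up_ranks]) else Inf
    cutlo <- if (length(dn_ranks)) max(obs$d[ord][dn_ranks]) else -Inf
    sign_call <- integer(n)
    sign_call[obs$d >= cutup] <- 1L
    sign_call[obs$d <= cutlo] <- -1L
    fp <- colSums(perm_all >= cutup) + colSums(perm_all <= cutlo)
    n_called <- sum(sign_call != 0)
    med_fdr <- if (n_called == 0) 0 else median(fp) / n_called
    list(sign_call = sign_call, n_called = n_called, med_fdr = med_fdr,
         cutup = cutup, cutlo = cutlo)
  }

  if (is.null(delta)) {
    grid <- seq(0, max(abs(dev)) + 0.01, by = 0.01)
    delta <- grid[length(grid)]
    for (g in grid) {
      if (eval_delta(g)$med_fdr <= target_fdr) { delta <- g; break }
    }
  }
  res <- eval_delta(delta)

  expected_d <- numeric(n)
  expected_d[ord] <- dbar

  structure(list(
    stats = tibble::tibble(gene_id = rownames(x) %||% as.character(seq_len(n)),
                           d = unname(obs$d), s = unname(obs$s),
                           expected_d = expected_d,
                           called = res$sign_call),
    delta = delta, s0 = s0, median_fdr = res$med_fdr,
    n_called = res$n_called, cutup = res$cutup, cutlo = res$cutlo,
    n_permutations = n_permutations, target_fdr = target_fdr
  ), class = "sam_fit")
}

# Standard percentile search for the fudge factor: among the 0,5,...,95
# percentiles of s, choose the candidate minimising the coefficient of
# variation of mad(d) across s-quintiles.
estimate_s0 <- function(x, na, nb, s) {
  if (all(s == 0)) return(0)
  cand <- unique(quantile(s, probs = seq(0, 0.95, by = 0.05), names = FALSE))
  ma <- rowMeans(x[, seq_len(na), drop = FALSE])
  mb <- rowMeans(x[, na + seq_len(nb), drop = FALSE])
  diff <- mb - ma
  qs <- quantile(s, probs = seq(0, 1, 0.2), names = FALSE)
  bins <- cut(s, breaks = unique(qs), include.lowest = TRUE)
  cv <- vapply(cand, function(a) {
    d <- ifelse(s + a > 0, diff / (s + a), 0)
    mads <- tapply(d, bins, mad)
    mads <- mads[is.finite(mads) & mads > 0]
    if (length(mads) < 2) return(Inf)
    sd(mads) / mean(mads)
  }, numeric(1))
  cand[which.min(cv)]
}

#' @describeIn sam_test Per-gene statistics as a tibble.
#' @param x A `sam_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sam_fit <- function(x, ...) x$stats

#' @describeIn sam_test One-row model summary (delta, s0, median FDR,
#'   call counts).
#' @exportS3Method generics::glance
glance.sam_fit <- function(x, ...) {
  tibble::tibble(delta = x$delta, s0 = x$s0, median_fdr = x$median_fdr,
                 n_called = x$n_called,
                 n_up = sum(x$stats$called > 0),
                 n_down = sum(x$stats$called < 0),
                 n_permutations = x$n_permutations)
}

#' @export
print.sam_fit <- function(x, ...) {
  cat(sprintf("<sam_fit> %d genes; delta = %.2f, s0 = %.3g, median FDR = %.3g, %d called\n",
              nrow(x$stats), x$delta, x$s0, x$median_fdr, x$n_called))
  invisible(x)
}

#' Call differential expression for every stress and timepoint
#'
#' Runs one [sam_test()] per (stress, timepoint) pair, comparing the stress
#' arrays against the matched control arrays of the same timepoint, and
#' aggregates per-stress up/down gene sets as unions over timepoints. A gene
#' up-regulated at one time and down-regulated at another appears in both
#' per-stress sets and is flagged.
#'
#' @param expr Numeric matrix, genes x arrays.
#' @param design Design tibble (`sample_id`, `stress`, `timepoint_h`,
#'   `replicate`, `is_control`).
#' @inheritParams sam_test
#'
#' @return Object of class `de_calls` with elements `per_test` (gene-level
#'   calls per stress/timepoint), `by_stress` (union sets with direction and
#'   a `both_directions` flag), and `diagnostics` (per-test delta, s0 and
#'   median FDR).
#' @export
sam_call_all <- function(expr, design, n_permutations = 100,
                         target_fdr = 0.01) {
  stresses <- setdiff(unique(design$stress[!design$is_control]), character())
  empty <- function() structure(list(
    per_test = tibble::tibble(stress = character(), timepoint_h = double(),
                              gene_id = character(), direction = character(),
                              d = double()),
    by_stress = tibble::tibble(stress = character(), gene_id = character(),
                               direction = character(),
                               both_directions = logical()),
    diagnostics = tibble::tibble(stress = character(), timepoint_h = double(),
                                 delta = double(), s0 = double(),
                                 median_fdr = double(), n_up = integer(),
                                 n_down = integer())
  ), class = "de_calls")
  if (nrow(expr) == 0 || length(stresses) == 0) return(empty())

  ctrl <- design[design$is_control, ]
  if (nrow(ctrl) == 0) abort("design contains no control arrays")

  per_test <- list(); diagnostics <- list()
  for (s in stresses) {
    tps <- sort(unique(design$timepoint_h[design$stress == s]))
    if (!length(tps)) abort(sprintf("stress '%s' has no arrays", s))
    for (t in tps) {
      ga <- ctrl$sample_id[ctrl$timepoint_h == t]
      gb <- design$sample_id[design$stress == s & design$timepoint_h == t]
      if (length(ga) < 2 || length(gb) < 2) {
        warn(sprintf("skipping %s %sh: fewer than 2 arrays in a group", s, t))
        next
      }
      fit <- sam_test(expr, ga, gb, n_permutations = n_permutations,
                      target_fdr = target_fdr)
      called <- fit$stats[fit$stats$called != 0, ]
      if (nrow(called)) {
        per_test[[length(per_test) + 1]] <- tibble::tibble(
          stress = s, timepoint_h = t, gene_id = called$gene_id,
          direction = ifelse(called$called > 0, "up", "down"),
          d = called$d)
      }
      diagnostics[[length(diagnostics) + 1]] <- tibble::tibble(
        stress = s, timepoint_h = t, delta = fit$delta, s0 = fit$s0,
        median_fdr = fit$median_fdr,
        n_up = sum(fit$stats$called > 0),
        n_down = sum(fit$stats$called < 0))
    }
  }
  per_test <- dplyr::bind_rows(per_test)
  if (nrow(per_test) == 0) {
    out <- empty()
    out$diagnostics <- dplyr::bind_rows(diagnostics)
    return(out)
  }
  by_stress <- per_test |>
    dplyr::distinct(.data$stress, .data$gene_id, .data$direction) |>
    dplyr::group_by(.data$stress, .data$gene_id) |>
    dplyr::mutate(both_directions = dplyr::n() > 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$stress, .data$direction, .data$gene_id)

  structure(list(per_test = per_test, by_stress = by_stress,
                 diagnostics = dplyr::bind_rows(diagnostics)),
            class = "de_calls")
}

#' @export
print.de_calls <- function(x, ...) {
  cat(sprintf("<de_calls> %d per-test calls over %d stress/timepoint tests\n",
              nrow(x$per_test), nrow(x$diagnostics)))
  invisible(x)
}

#' @describeIn sam_call_all Per-stress union call table.
#' @param x A `de_calls` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.de_calls <- function(x, ...) x$by_stress

#' @describeIn sam_call_all Per-test diagnostics.
#' @exportS3Method generics::glance
glance.de_calls <- function(x, ...) x$diagnostics

#' Extract a per-stress differential-expression gene set
#'
#' @param de A `de_calls` object.
#' @param stress Stress label, or `NULL` for all stresses combined.
#' @param direction `"up"`, `"down"` or `"any"`.
#' @return Character vector of gene ids.
#' @export
de_genes <- function(de, stress = NULL, direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  tab <- de$by_stress
  if (!is.null(stress)) tab <- tab[tab$stress %in% stress, ]
  if (direction != "any") tab <- tab[tab$direction == direction, ]
  unique(tab$gene_id)
}

#' Partition four per-stress gene sets into the 15 Venn regions
#'
#' Every gene in the union of the four per-stress sets is assigned to exactly
#' one region by its membership signature; counts over the 15 non-empty
#' signatures are returned and always sum to the size of the union.
#'
#' @param de A `de_calls` object (or a named list of four character vectors).
#' @param direction `"up"` or `"down"` (ignored when `de` is already a list
#'   of sets).
#' @return Tibble with columns `region` (ampersand-joined stress names) and
#'   `count`, one row per region, zero counts included.
#' @export
venn_partition <- function(de, direction = c("up", "down")) {
  if (inherits(de, "de_calls")) {
    direction <- match.arg(direction)
    stresses <- sort(unique(de$by_stress$stress))
    sets <- purrr::map(stresses, \(s) de_genes(de, s, direction))
    names(sets) <- stresses
  } else {
    sets <- de
  }
  if (length(sets) != 4) abort("venn_partition() requires exactly four sets")
  labs <- names(sets)
  all_genes <- unique(unlist(sets))
  memb <- vapply(sets, \(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1) memb <- matrix(memb, nrow = 1)
  sig <- apply(memb, 1, \(row) paste(labs[row], collapse = "&"))
  regions <- unlist(purrr::map(1:4, \(k)
    apply(combn(labs, k), 2, paste, collapse = "&")))
  counts <- table(factor(sig, levels = regions))
  tibble::tibble(region = regions, count = as.integer(counts))
}
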