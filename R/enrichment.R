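#' Gene-set overlap test (permutation or hypergeometric)
#'
#' Tests whether an observed overlap between a gene class and a member set
#' (e.g. module members) within a common universe is larger or smaller than
#' expected by chance. The permutation method draws class-sized random
#' subsets of the universe and records their overlap with the member set;
#' the Z-score is `(observed - mean) / sd` with a two-tailed normal p-value.
#' The hypergeometric method uses the closed-form mean `n K / N` and SD.
#'
#' @param universe Character vector of all genes, or a single integer size
#'   (in which case `members` and `class_set` must be integer counts and
#'   `observed` must be given).
#' @param members Member gene set (character) or its size.
#' @param class_set Class gene set (character) or its size.
#' @param observed Observed overlap; computed from the sets when omitted.
#' @param method `"permutation"` or `"hypergeometric"`.
#' @param n_permutations Number of permutations (default 10000).
#'
#' @return Object of class `overlap_test`; [glance.overlap_test()] returns
#'   the one-row summary.
#' @export
#' @examples
#' ot <- overlap_test(9496, 6399, 600, observed = 369,
#'                    method = "hypergeometric")
#' glance(ot)
overlap_test <- function(universe, members, class_set, observed = NULL,
                         method = c("permutation", "hypergeometric"),
                         n_permutations = 10000) {
  method <- match.arg(method)
  if (is.character(universe)) {
    if (!all(members %in% universe) || !all(class_set %in% universe)) {
      abort("member and class sets must be subsets of the universe")
    }
    n_u <- length(universe)
    n_m <- length(members)
    n_c <- length(class_set)
    if (is.null(observed)) observed <- length(intersect(members, class_set))
    member_flag <- universe %in% members
  } else {
    n_u <- universe; n_m <- members; n_c <- class_set
    if (n_m > n_u || n_c > n_u) abort("set sizes exceed the universe")
    if (is.null(observed)) abort("`observed` is required with size inputs")
    member_flag <- c(rep(TRUE, n_m), rep(FALSE, n_u - n_m))
  }
  if (method == "permutation") {
    draws <- vapply(seq_len(n_permutations), function(i) {
      sum(member_flag[sample.int(n_u, n_c)])
    }, numeric(1))
    mu <- mean(draws)
    sdev <- sd(draws)
  } else {
    mu <- n_c * n_m / n_u
    sdev <- sqrt(n_c * (n_m / n_u) * (1 - n_m / n_u) * (n_u - n_c) / (n_u - 1))
  }
  z <- if (sdev > 0) (observed - mu) / sdev else NA_real_
  p <- if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z))
  structure(list(universe_n = n_u, members_n = n_m, class_n = n_c,
                 observed = observed, expected = mu, sd = sdev,
                 z = z, p = p, method = method,
                 n_permutations = if (method == "permutation") n_permutations else NA_integer_),
            class = "overlap_test")
}

#' @describeIn overlap_test One-row summary tibble.
#' @param x An `overlap_test` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.overlap_test <- function(x, ...) {
  tibble::tibble(universe_n = x$universe_n, members_n = x$members_n,
                 class_n = x$class_n, observed = x$observed,
                 expected = x$expected, sd = x$sd, z = x$z, p = x$p,
                 method = x$method)
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("<overlap_test> observed %d vs expected %.1f (sd %.2f), Z = %.3f, p = %.3g [%s]\n",
              x$observed, x$expected, x$sd, x$z, x$p, x$method))
  invisible(x)
}

#' Term enrichment for a gene set
#'
#' Hypergeometric tail test per term against a background, with
#' Benjamini-Hochberg correction. A term is significant only when its
#' corrected p-value is below `fdr_threshold` AND it maps more than
#' `min_mapped` genes of the set.
#'
#' @param genes Gene set (character).
#' @param background Background gene set (superset of `genes`).
#' @param term_map Tibble `term`, `gene_id` (flat term-to-gene annotation).
#' @param fdr_threshold Corrected p-value threshold (default 0.05).
#' @param min_mapped A significant term must map strictly more than this
#'   many set genes (default 5).
#'
#' @return Tibble `term`, `set_hits`, `bg_hits`, `p`, `fdr`, `significant`.
#' @export
term_enrichment <- function(genes, background, term_map,
                            fdr_threshold = 0.05, min_mapped = 5) {
  if (!length(genes) || !nrow(term_map)) {
    return(tibble::tibble(term = character(), set_hits = integer(),
                          bg_hits = integer(), p = double(), fdr = double(),
                          significant = logical()))
  }
  if (!all(genes %in% background)) {
    abort("gene set must be a subset of the background")
  }
  term_map <- term_map[term_map$gene_id %in% background, ]
  n_bg <- length(unique(background))
  n_set <- length(unique(genes))
  res <- term_map |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(set_hits = sum(unique(.data$gene_id) %in% genes),
                     bg_hits = dplyr::n_distinct(.data$gene_id),
                     .groups = "drop")
  res$p <- phyper(res$set_hits - 1, res$bg_hits, n_bg - res$bg_hits, n_set,
                  lower.tail = FALSE)
  res$fdr <- p.adjust(res$p, method = "BH")
  res$significant <- res$fdr < fdr_threshold & res$set_hits > min_mapped
  dplyr::arrange(res, .data$fdr, .data$p)
}

#' Classify genes as functionally undefined
#'
#' A gene is "defined" when it has at least one alignment with identity and
#' query coverage both at or above 70% to a target carrying an informative
#' annotation, or an informative domain-scan flag; all other genes are
#' undefined. Matches the homology-transfer rule of annotating proteins by
#' alignment at >= 70% identity over >= 70% of their length, with
#' descriptions like "expressed protein" treated as uninformative.
#'
#' @param alignments Tibble `gene_id`, `identity` (fraction or percent),
#'   `coverage` (fraction of query length, in `[0, 1]`),
#'   `target_informative` (logical). One row per alignment; genes may have
#'   several or none.
#' @param domain_flags Optional tibble `gene_id`, `informative` from domain
#'   scans.
#' @param genes Gene universe to classify; defaults to the genes appearing
#'   in the inputs.
#' @param identity_min,coverage_min Inclusive thresholds (default 0.7; a
#'   value above 1 is interpreted as a percentage).
#'
#' @return Tibble `gene_id`, `defined`, `undefined`.
#' @export
classify_undefined <- function(alignments, domain_flags = NULL, genes = NULL,
                               identity_min = 0.7, coverage_min = 0.7) {
  aln <- tibble::as_tibble(alignments)
  if (nrow(aln)) {
    if (any(aln$coverage > 1)) abort("alignment coverage above 1")
    if (any(aln$identity > 1)) aln$identity <- aln$identity / 100
  }
  genes <- genes %||% unique(c(aln$gene_id,
                               if (!is.null(domain_flags)) domain_flags$gene_id))
  by_homology <- if (nrow(aln)) {
    unique(aln$gene_id[aln$identity >= identity_min &
                         aln$coverage >= coverage_min &
                         aln$target_informative])
  } else character()
  by_domain <- if (!is.null(domain_flags) && nrow(domain_flags)) {
    unique(domain_flags$gene_id[domain_flags$informative])
  } else character()
  defined_set <- union(by_homology, by_domain)
  is_defined <- genes %in% defined_set
  tibble::tibble(gene_id = genes, defined = is_defined,
                 undefined = !is_defined)
}
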