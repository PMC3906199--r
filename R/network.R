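#' Unsigned soft-threshold adjacency and topological overlap dissimilarity
#'
#' The unsigned adjacency between genes i and j is
#' `a_ij = |cor(x_i, x_j)|^power` over all supplied arrays. The topological
#' overlap of the pair is
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k_i = sum_{u != i} a_iu` and the sum over `u != i, j`;
#' the returned dissimilarity is `1 - TOM` with a zero diagonal.
#'
#' @param expr Numeric matrix, genes x arrays (at least 3 of each).
#' @param power Soft-threshold exponent (default 23).
#'
#' @return List with `adjacency` and `dissimilarity` (both genes x genes).
#' @export
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(60), 6, 10, dimnames = list(paste0("g", 1:6), NULL))
#' nt <- adjacency_tom(m, power = 6)
#' range(nt$dissimilarity)
adjacency_tom <- function(expr, power = 23) {
  if (nrow(expr) < 3 || ncol(expr) < 3) {
    abort("need at least 3 genes and 3 arrays")
  }
  sds <- apply(expr, 1, sd)
  if (any(sds == 0)) {
    abort(sprintf("zero-variance gene(s): %s",
                  paste(rownames(expr)[sds == 0], collapse = ", ")))
  }
  a <- abs(cor(t(expr)))^power
  diag(a) <- 1
  d <- tom_dissimilarity(a)
  list(adjacency = a, dissimilarity = d)
}

#' Topological overlap dissimilarity of an adjacency matrix
#'
#' @param adjacency Symmetric adjacency in `[0, 1]` with unit diagonal.
#' @return Symmetric dissimilarity matrix `1 - TOM`, zero diagonal.
#' @export
tom_dissimilarity <- function(adjacency) {
  a <- adjacency
  k <- rowSums(a) - diag(a)
  # (A %*% A)_ij counts u = i and u = j terms, each equal to a_ij when the
  # diagonal is 1; remove them to sum over shared neighbours only
  l <- a %*% a - 2 * a
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  d <- 1 - tom
  diag(d) <- 0
  d
}

#' Detect co-expression modules by static dendrogram cut
#'
#' Builds an average-linkage dendrogram from the TOM dissimilarity and cuts
#' it statically at `cut_height`; each resulting branch with at least
#' `min_size` genes becomes a module, smaller branches are left unassigned
#' (label 0). Module labels are dense integers ordered by decreasing size.
#'
#' @param dissimilarity Symmetric dissimilarity matrix (e.g. from
#'   [adjacency_tom()]).
#' @param cut_height Static cut height on the dendrogram (default 0.91).
#' @param min_size Minimum module size in genes (default 25).
#'
#' @return Tibble `gene_id`, `module` (0 = unassigned), with the `hclust`
#'   tree attached as attribute `"tree"`.
#' @export
detect_modules <- function(dissimilarity, cut_height = 0.91, min_size = 25) {
  genes <- rownames(dissimilarity) %||% as.character(seq_len(nrow(dissimilarity)))
  tree <- hclust(as.dist(dissimilarity), method = "average")
  # exact ties can leave merge heights non-monotone at machine precision,
  # which cutree(h = ...) refuses; clamp to the running maximum
  if (is.unsorted(tree$height)) tree$height <- cummax(tree$height)
  raw <- cutree(tree, h = cut_height)
  out <- relabel_by_size(raw, min_size)
  res <- tibble::tibble(gene_id = genes, module = out)
  attr(res, "tree") <- tree
  res
}

# Drop branches below min_size to label 0 and relabel the rest densely by
# decreasing size (ties by first occurrence); input label 0 always stays
# unassigned.
relabel_by_size <- function(labels, min_size) {
  valid <- !is.na(labels) & labels != 0
  sizes <- table(labels[valid])
  keep <- names(sizes)[sizes >= min_size]
  out <- integer(length(labels))
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], match(keep, names(sizes)))]
    for (i in seq_along(ord)) out[valid & labels == ord[i]] <- i
  }
  out
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of the
#' standardised member-gene expression, sign-oriented to correlate
#' positively with the module mean profile; it is returned with unit norm.
#'
#' @param assignment Tibble `gene_id`, `module` (as from [detect_modules()]).
#' @param expr Numeric matrix, genes x arrays.
#' @return Tibble `module`, `sample_id`, `eigengene`.
#' @export
module_eigengenes <- function(assignment, expr) {
  mods <- sort(setdiff(unique(assignment$module), 0L))
  purrr::map_dfr(mods, function(m) {
    rows <- assignment$gene_id[assignment$module == m]
    e <- eigengene_vector(expr[rows, , drop = FALSE])
    tibble::tibble(module = m, sample_id = colnames(expr), eigengene = e)
  })
}

eigengene_vector <- function(x) {
  z <- t(scale(t(x)))
  z[!is.finite(z)] <- 0
  sv <- svd(z, nu = 0, nv = 1)
  v <- sv$v[, 1]
  if (cor(v, colMeans(z)) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Merge modules with highly correlated eigengenes
#'
#' Modules whose eigengene dissimilarity `1 - cor` falls below `merge_height`
#' are merged, iterating (closest pair first) until no pair qualifies.
#' Plain (signed) correlation is used, so anticorrelated modules are never
#' merged. Labels are re-assigned densely by decreasing size.
#'
#' @inheritParams module_eigengenes
#' @param merge_height Eigengene dissimilarity below which modules merge
#'   (default 0.1).
#' @return Tibble `gene_id`, `module`.
#' @export
merge_modules <- function(assignment, expr, merge_height = 0.1) {
  module <- assignment$module
  repeat {
    mods <- sort(setdiff(unique(module), 0L))
    if (length(mods) < 2) break
    eg <- vapply(mods, function(m) {
      eigengene_vector(expr[assignment$gene_id[module == m], , drop = FALSE])
    }, numeric(ncol(expr)))
    dis <- 1 - cor(eg)
    diag(dis) <- Inf
    if (min(dis) >= merge_height) break
    pair <- which(dis == min(dis), arr.ind = TRUE)[1, ]
    keep <- mods[min(pair)]; drop <- mods[max(pair)]
    module[module == drop] <- keep
  }
  tibble::tibble(gene_id = assignment$gene_id,
                 module = relabel_by_size(module, 1))
}

#' Module stress-response profiles and module-level DE calls
#'
#' For every module, stress and timepoint, computes the mean over member
#' genes of the per-gene delta-RMA (mean over the stress arrays of that
#' timepoint minus mean over the matched control arrays) and its standard
#' error over genes. A module is flagged responsive to a stress when the
#' maximum absolute mean delta over timepoints reaches `de_threshold`
#' (1 RMA unit by default).
#'
#' @inheritParams module_eigengenes
#' @param design Design tibble.
#' @param de_threshold Module response criterion in RMA units (default 1).
#' @return Object of class `module_profiles`: tibble `module`, `stress`,
#'   `timepoint_h`, `mean_delta_rma`, `se`, `n`, with the per-module
#'   responsiveness table as attribute `"responses"` (see
#'   [module_responses()]).
#' @export
module_profiles <- function(assignment, expr, design, de_threshold = 1) {
  stresses <- unique(design$stress[!design$is_control])
  tps <- sort(unique(design$timepoint_h))
  mods <- sort(setdiff(unique(assignment$module), 0L))
  rows <- list()
  for (m in mods) {
    members <- assignment$gene_id[assignment$module == m]
    members <- intersect(members, rownames(expr))
    if (!length(members)) {
      warn(sprintf("module %d has no members in the matrix; skipped", m))
      next
    }
    for (s in stresses) {
      for (t in tps) {
        sc <- design$sample_id[design$stress == s & design$timepoint_h == t]
        cc <- design$sample_id[design$is_control & design$timepoint_h == t]
        if (!length(sc) || !length(cc)) next
        delta <- rowMeans(expr[members, sc, drop = FALSE]) -
          rowMeans(expr[members, cc, drop = FALSE])
        rows[[length(rows) + 1]] <- tibble::tibble(
          module = m, stress = s, timepoint_h = t,
          mean_delta_rma = mean(delta),
          se = stats::sd(delta) / sqrt(length(delta)),
          n = length(members))
      }
    }
  }
  prof <- dplyr::bind_rows(rows)
  if (nrow(prof) == 0) {
    prof <- tibble::tibble(module = integer(), stress = character(),
                           timepoint_h = double(), mean_delta_rma = double(),
                           se = double(), n = integer())
  }
  responses <- prof |>
    dplyr::group_by(.data$module, .data$stress) |>
    dplyr::summarise(max_abs_delta = max(abs(.data$mean_delta_rma)),
                     responsive = max(abs(.data$mean_delta_rma)) >= de_threshold,
                     .groups = "drop")
  structure(prof, responses = responses, de_threshold = de_threshold,
            class = c("module_profiles", class(prof)))
}

#' Per-module stress responsiveness
#'
#' @param profiles A [module_profiles()] result.
#' @return Tibble `module`, `stress`, `max_abs_delta`, `responsive`.
#' @export
module_responses <- function(profiles) attr(profiles, "responses")

#' Export a weighted co-expression edge list
#'
#' Edges with adjacency at or above `export_threshold` are returned; a
#' `display` flag marks those at or above `display_threshold` (the stricter
#' filter used for graph rendering).
#'
#' @param adjacency Symmetric adjacency matrix.
#' @param assignment Optional module assignment tibble; adds module labels
#'   for both endpoint genes.
#' @param export_threshold Minimum adjacency to include (default 0.35).
#' @param display_threshold Adjacency at which an edge is display-flagged
#'   (default 0.45).
#' @return Tibble `gene_a`, `gene_b`, `adjacency`, `display` (plus
#'   `module_a`, `module_b` when an assignment is given).
#' @export
export_edge_list <- function(adjacency, assignment = NULL,
                             export_threshold = 0.35,
                             display_threshold = 0.45) {
  if (export_threshold > display_threshold) {
    abort("`export_threshold` must not exceed `display_threshold`")
  }
  genes <- rownames(adjacency) %||% as.character(seq_len(nrow(adjacency)))
  idx <- which(upper.tri(adjacency) & adjacency >= export_threshold,
               arr.ind = TRUE)
  weight <- adjacency[idx]
  out <- tibble::tibble(
    gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
    adjacency = weight,
    display = weight >= display_threshold)
  if (!is.null(assignment)) {
    lk <- setNames(assignment$module, assignment$gene_id)
    out$module_a <- unname(lk[out$gene_a])
    out$module_b <- unname(lk[out$gene_b])
  }
  dplyr::arrange(out, dplyr::desc(.data$adjacency))
}
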