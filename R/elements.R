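#' Count 5-8 nt motif occurrences in promoter sequences
#'
#' Tallies every observed k-mer, for each k in `k`, on the given strand only,
#' counting overlapping occurrences. Words spanning a non-ACGT base (e.g. N)
#' are never counted. Returns total hit counts and the number of promoters
#' containing at least one hit.
#'
#' @param promoters Promoter tibble (`gene_id`, `sequence`) or a character
#'   vector of sequences.
#' @param k Integer vector of word sizes (default `5:8`).
#' @param chunk_size Number of promoters processed per block (memory
#'   control for the 4^8-column count matrices).
#'
#' @return Tibble `motif`, `k`, `hits`, `promoters`, restricted to motifs
#'   observed at least once; the number of promoters scanned is attached as
#'   attribute `"n_promoters"`.
#' @export
#' @examples
#' count_kmers(tibble::tibble(gene_id = "g1", sequence = "AAAAAA"), k = 5)
count_kmers <- function(promoters, k = 5:8, chunk_size = 200) {
  seqs <- if (is.character(promoters)) promoters else promoters$sequence
  if (!length(seqs)) abort("no promoters supplied")
  if (any(k < 1)) abort("`k` must be positive")
  x <- Biostrings::DNAStringSet(seqs)
  out <- purrr::map_dfr(sort(unique(k)), function(kk) {
    hits <- prom <- numeric(4^kk)
    nm <- NULL
    for (i in seq(1, length(x), by = chunk_size)) {
      block <- x[i:min(i + chunk_size - 1, length(x))]
      f <- Biostrings::oligonucleotideFrequency(block, width = kk, step = 1)
      if (is.null(nm)) nm <- colnames(f)
      hits <- hits + colSums(f)
      prom <- prom + colSums(f > 0)
    }
    keep <- hits > 0
    tibble::tibble(motif = nm[keep], k = kk,
                   hits = as.integer(hits[keep]),
                   promoters = as.integer(prom[keep]))
  })
  attr(out, "n_promoters") <- length(x)
  out
}

#' Motif enrichment of a promoter set against a genome-wide background
#'
#' For every motif, a one-sided hypergeometric tail probability on promoter
#' presence: the chance of observing at least as many set promoters
#' containing the motif, drawing `set_n` promoters from a background in which
#' `bg_promoters` of `background_n` contain it. P-values are
#' Benjamini-Hochberg corrected across the full family of tested motifs
#' (all `4^k` words for each k, by default), and elements with corrected
#' p below `fdr_threshold` are flagged significant.
#'
#' @param set_counts Count table from [count_kmers()] on the gene-set
#'   promoters.
#' @param background_counts Count table from [count_kmers()] on all
#'   promoters (a superset of the set).
#' @param set_n,background_n Promoter counts for set and background; taken
#'   from the count tables' attributes when omitted.
#' @param fdr_threshold Significance threshold on the corrected p-value
#'   (default 0.01).
#' @param n_motifs_tested Size of the multiple-testing family; defaults to
#'   `sum(4^k)` over the word sizes present in the background table.
#'
#' @return Tibble `motif`, `k`, `hits`, `promoters`, `bg_hits`,
#'   `bg_promoters`, `p`, `fdr`, `significant`, sorted by `fdr`.
#' @export
enrich_motifs <- function(set_counts, background_counts,
                          set_n = NULL, background_n = NULL,
                          fdr_threshold = 0.01, n_motifs_tested = NULL) {
  set_n <- set_n %||% attr(set_counts, "n_promoters")
  background_n <- background_n %||% attr(background_counts, "n_promoters")
  if (is.null(set_n) || is.null(background_n)) {
    abort("`set_n` and `background_n` must be supplied or attached")
  }
  if (set_n > background_n) abort("set larger than background")
  if (is.null(n_motifs_tested)) {
    n_motifs_tested <- sum(4^sort(unique(background_counts$k)))
  }
  merged <- dplyr::left_join(
    set_counts,
    dplyr::rename(background_counts, bg_hits = "hits",
                  bg_promoters = "promoters"),
    by = c("motif", "k"))
  if (any(is.na(merged$bg_promoters)) ||
      any(merged$promoters > merged$bg_promoters)) {
    abort("set promoters are not a subset of the background")
  }
  merged$p <- phyper(merged$promoters - 1, merged$bg_promoters,
                     background_n - merged$bg_promoters, set_n,
                     lower.tail = FALSE)
  merged$fdr <- p.adjust(merged$p, method = "BH", n = n_motifs_tested)
  merged$significant <- merged$fdr < fdr_threshold
  dplyr::arrange(merged, .data$fdr, .data$p, .data$motif)
}

#' Per-module motif enrichment over a shared background
#'
#' Convenience wrapper: counts k-mers once over all promoters as the
#' background, then runs [enrich_motifs()] for the promoter set of every
#' module in the assignment.
#'
#' @param promoters Promoter tibble for the whole gene universe.
#' @param assignment Module assignment tibble (`gene_id`, `module`).
#' @param k Word sizes (default `5:8`).
#' @param fdr_threshold Significance threshold (default 0.01).
#' @return Combined tibble with a leading `module` column.
#' @export
module_motif_enrichment <- function(promoters, assignment, k = 5:8,
                                    fdr_threshold = 0.01) {
  bg <- count_kmers(promoters, k = k)
  mods <- sort(setdiff(unique(assignment$module), 0L))
  purrr::map_dfr(mods, function(m) {
    members <- assignment$gene_id[assignment$module == m]
    pr <- promoters[promoters$gene_id %in% members, ]
    if (!nrow(pr)) return(NULL)
    sc <- count_kmers(pr, k = k)
    res <- enrich_motifs(sc, bg, fdr_threshold = fdr_threshold)
    dplyr::bind_cols(tibble::tibble(module = m), res)
  })
}

#' Unique and total significant elements per module
#'
#' `total` counts the motifs significant in a module; `unique` those
#' significant in that module and in no other.
#'
#' @param tables Combined per-module enrichment table (with `module`,
#'   `motif`, `significant` columns), or a list of per-module tables named
#'   by module.
#' @return Tibble `module`, `unique_elements`, `total_elements`.
#' @export
unique_total_summary <- function(tables) {
  if (is.list(tables) && !is.data.frame(tables)) {
    tables <- purrr::imap_dfr(tables, \(tab, m)
      dplyr::bind_cols(tibble::tibble(module = as.integer(m)), tab))
  }
  sig <- tables[tables$significant, c("module", "motif")]
  shared <- sig |>
    dplyr::count(.data$motif, name = "n_modules")
  sig <- dplyr::left_join(sig, shared, by = "motif")
  tables |>
    dplyr::distinct(.data$module) |>
    dplyr::left_join(
      sig |>
        dplyr::group_by(.data$module) |>
        dplyr::summarise(unique_elements = sum(.data$n_modules == 1),
                         total_elements = dplyr::n(), .groups = "drop"),
      by = "module") |>
    tidyr::replace_na(list(unique_elements = 0L, total_elements = 0L)) |>
    dplyr::arrange(.data$module)
}

#' Query one core motif in a module's promoters
#'
#' Same counting and test as [enrich_motifs()], restricted to a single
#' 5-8 nt core; the corrected p-value comes from the full-table correction,
#' so it matches the value the motif would receive in an exhaustive scan.
#'
#' @param core Motif string, 5-8 nt over ACGT.
#' @param module_promoters Promoter tibble for the module.
#' @param background_counts Background count table from [count_kmers()]
#'   (must include `core`'s word size).
#' @param background_n Background promoter count (taken from the attribute
#'   when omitted).
#' @return One-row tibble `motif`, `hits`, `promoters`, `p`, `fdr`.
#' @export
query_core <- function(core, module_promoters, background_counts,
                       background_n = NULL) {
  w <- nchar(core)
  if (w < 5 || w > 8) abort("core motif must be 5-8 nt long")
  if (!grepl("^[ACGT]+$", core)) abort("core motif must be ACGT only")
  if (!nrow(module_promoters)) {
    return(tibble::tibble(motif = core, hits = 0L, promoters = 0L,
                          p = 1, fdr = 1))
  }
  sc <- count_kmers(module_promoters, k = sort(unique(background_counts$k)))
  res <- enrich_motifs(sc, background_counts, background_n = background_n)
  row <- res[res$motif == core, ]
  if (!nrow(row)) {
    return(tibble::tibble(motif = core, hits = 0L, promoters = 0L,
                          p = 1, fdr = 1))
  }
  tibble::tibble(motif = core, hits = row$hits, promoters = row$promoters,
                 p = row$p, fdr = row$fdr)
}
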