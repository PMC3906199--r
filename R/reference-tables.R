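#' Published reference summary tables
#'
#' Small summary tables from a genome-wide abiotic-stress microarray study
#' of *Brachypodium distachyon* (raw data: PLEXDB accession BD2), shipped
#' with the package as plain TSV so that cross-checks of the statistical
#' machinery (module-size/enrichment correlations, overlap expectations,
#' plasticity-table arithmetic) can be reproduced without the raw arrays.
#'
#' \describe{
#'   \item{`ref_module_summary()`}{Per co-expression module: size (`n_genes`),
#'     undefined member genes, unique/total enriched GO terms and unique/total
#'     enriched promoter DNA elements (22 modules).}
#'   \item{`ref_plasticity_summary()`}{Per condition pair: TF-target gene
#'     pairings, plastic pairs, mean false positives per permutation, FDR and
#'     the selected delta-r cutoff.}
#'   \item{`ref_stress_de_counts()`}{Per stress: up-/down-regulated gene
#'     counts, their total, and the number of genes unique to that stress.}
#' }
#'
#' @return A tibble.
#' @name reference_tables
NULL

ref_table <- function(file) {
  readr::read_tsv(system.file("extdata", file, package = "stressnet",
                              mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname reference_tables
#' @export
ref_module_summary <- function() ref_table("module_summary.tsv")

#' @rdname reference_tables
#' @export
ref_plasticity_summary <- function() ref_table("plasticity_summary.tsv")

#' @rdname reference_tables
#' @export
ref_stress_de_counts <- function() ref_table("stress_de_counts.tsv")
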