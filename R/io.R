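#' Read an expression matrix and its sample design
#'
#' Reads a tab-separated expression table (gene ids in the first column,
#' one column per array, RMA/log2 scale) together with a sample-design table
#' (`sample_id`, `stress`, `timepoint_h`, `replicate`, `is_control`), and
#' validates them against each other: duplicate gene or sample ids and
#' non-numeric cells are errors; matrix columns missing from the design are
#' errors; design rows without a matrix column are dropped with a warning.
#'
#' @param matrix_path Path to the expression TSV.
#' @param design_path Path to the design TSV.
#'
#' @return List with `expr` (numeric matrix, genes x arrays) and `design`
#'   (tibble).
#' @export
read_expression <- function(matrix_path, design_path) {
  tab <- readr::read_tsv(matrix_path, show_col_types = FALSE,
                         progress = FALSE)
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicate gene id(s) in %s: %s", matrix_path,
                  paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  vals <- tab[-1]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    abort(sprintf("non-numeric expression column(s): %s",
                  paste(names(vals)[bad], collapse = ", ")))
  }
  expr <- as.matrix(vals)
  rownames(expr) <- genes
  if (anyDuplicated(colnames(expr))) abort("duplicate sample id(s) in matrix")
  if (any(!is.finite(expr))) abort("non-finite expression values")

  design <- readr::read_tsv(design_path, show_col_types = FALSE,
                            progress = FALSE)
  design <- tibble::as_tibble(design)
  if (anyDuplicated(design$sample_id)) abort("duplicate sample id(s) in design")
  missing_in_design <- setdiff(colnames(expr), design$sample_id)
  if (length(missing_in_design)) {
    abort(sprintf("matrix sample(s) missing from design: %s",
                  paste(missing_in_design, collapse = ", ")))
  }
  extra <- setdiff(design$sample_id, colnames(expr))
  if (length(extra)) {
    warn(sprintf("dropping %d design row(s) without matrix columns",
                 length(extra)))
    design <- design[design$sample_id %in% colnames(expr), ]
  }
  design <- design[match(colnames(expr), design$sample_id), ]
  list(expr = expr, design = design)
}

#' Write an expression matrix and design to TSV
#'
#' @param expr Numeric matrix, genes x arrays.
#' @param design Design tibble matching `colnames(expr)`.
#' @param matrix_path,design_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(expr, design, matrix_path, design_path) {
  tab <- tibble::as_tibble(expr, rownames = "gene_id")
  readr::write_tsv(tab, matrix_path)
  readr::write_tsv(design, design_path)
  invisible(matrix_path)
}

#' Read/write promoter sets as FASTA
#'
#' Promoter tables are tibbles with columns `gene_id`, `sequence` and
#' optionally `truncated` and `provenance`.
#'
#' @param path FASTA path.
#' @return `read_promoters()` returns a promoter tibble.
#' @export
read_promoters <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble::tibble(gene_id = names(x),
                 sequence = unname(as.character(x)),
                 truncated = FALSE,
                 provenance = "file")
}

#' @param promoters Promoter tibble.
#' @rdname read_promoters
#' @export
write_promoters <- function(promoters, path) {
  x <- Biostrings::DNAStringSet(promoters$sequence)
  names(x) <- promoters$gene_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read/write plain gene lists (one id per line)
#'
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @param genes Character vector of gene ids.
#' @rdname read_gene_list
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Extract promoter sequences from a genome and gene models
#'
#' For each gene feature in the GFF3, takes the `length` bases immediately
#' upstream of the gene (excluding the first gene base): for `+`-strand genes
#' the bases ending just before the gene start, for `-`-strand genes the
#' bases starting just after the gene end, reverse-complemented. Promoters
#' running off a contig edge are truncated and flagged. GFF3 coordinates are
#' treated as 1-based inclusive.
#'
#' @param genome_fasta Path to the genome FASTA.
#' @param gff3 Path to gene models in GFF3 (features of type `gene` are used).
#' @param length Promoter length in nucleotides (default 500).
#'
#' @return Tibble `gene_id`, `sequence`, `truncated`, `provenance`.
#' @export
extract_promoters <- function(genome_fasta, gff3, length = 500) {
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gff3)
  gr <- gr[gr$type == "gene"]
  if (!base::length(gr)) {
    return(tibble::tibble(gene_id = character(), sequence = character(),
                          truncated = logical(), provenance = character()))
  }
  ids <- gr$ID %||% gr$Name
  if (is.null(ids) || any(is.na(ids))) {
    ids <- paste0("gene", seq_along(gr))
  }
  chr <- as.character(GenomicRanges::seqnames(gr))
  missing <- setdiff(unique(chr), names(genome))
  if (base::length(missing)) {
    bad <- ids[chr %in% missing]
    abort(sprintf("gene(s) on contig(s) missing from FASTA: %s",
                  paste(bad, collapse = ", ")))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    abort(sprintf("gene(s) without strand: %s",
                  paste(ids[strand == "*"], collapse = ", ")))
  }
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  contig_len <- setNames(Biostrings::width(genome), names(genome))
  out <- purrr::map_dfr(seq_along(gr), function(i) {
    clen <- contig_len[[chr[i]]]
    if (strand[i] == "+") {
      from <- starts[i] - length
      to <- starts[i] - 1L
    } else {
      from <- ends[i] + 1L
      to <- ends[i] + length
    }
    truncated <- from < 1L || to > clen
    from <- max(from, 1L)
    to <- min(to, clen)
    seq <- if (to < from) "" else
      as.character(Biostrings::subseq(genome[[chr[i]]], from, to))
    if (strand[i] == "-" && nzchar(seq)) {
      seq <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    }
    tibble::tibble(gene_id = ids[i], sequence = seq, truncated = truncated)
  })
  out$provenance <- "extracted"
  out
}
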