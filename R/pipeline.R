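#' Run the full stress-transcriptome analysis pipeline
#'
#' Executes the analysis stages in order — differential expression, network
#' module detection, plasticity, promoter elements, set/term enrichment —
#' on either files named in the configuration or a simulated dataset, and
#' writes all report tables to `out_dir`. Identical configuration and seed
#' give identical outputs; each stage is re-seeded independently so that
#' disabling one stage never changes another's results.
#'
#' @param config A configuration list, or the path of a YAML file holding
#'   one. Recognised keys: `expression`/`design`/`promoters`/`tf_genes`/
#'   `term_map`/`class_genes` (input paths), `simulate` (`TRUE` or a list of
#'   [synth_config()] overrides; replaces the input paths), `out_dir`,
#'   `seed`, `stages` (character subset of `c("diffexpr", "network",
#'   "plasticity", "elements", "enrichment")`), and per-stage parameter
#'   lists `sam`, `network`, `plasticity`, `elements`, `enrichment` whose
#'   entries override the corresponding function defaults.
#'
#' @return Invisibly, a named list with the stage results (`de`, `modules`,
#'   `profiles`, `edges`, `plasticity`, `motifs`, `element_summary`,
#'   `overlap`, `terms`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    simulate = NULL, expression = NULL, design = NULL, promoters = NULL,
    tf_genes = NULL, term_map = NULL, class_genes = NULL,
    out_dir = "stressnet_out", seed = 1,
    stages = c("diffexpr", "network", "plasticity", "elements", "enrichment"),
    sam = list(), network = list(), plasticity = list(), elements = list(),
    enrichment = list()
  ), config)

  paths <- purrr::compact(cfg[c("expression", "design", "promoters",
                                "tf_genes", "term_map", "class_genes")])
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing)) {
    abort(sprintf("input file(s) not found: %s",
                  paste(unlist(missing), collapse = ", ")))
  }
  if (is.null(cfg$simulate) && (is.null(cfg$expression) || is.null(cfg$design))) {
    abort("config must name `expression` and `design` files or set `simulate`")
  }

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  stage_on <- function(s) s %in% cfg$stages
  run_stage <- function(name, offset, fn) {
    set.seed(cfg$seed + offset)
    tryCatch(fn(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  results <- list()

  # ---- inputs -------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    overrides <- if (isTRUE(cfg$simulate)) list() else cfg$simulate
    scfg <- do.call(synth_config,
                    utils::modifyList(list(seed = cfg$seed), overrides))
    ds <- synth_dataset(scfg)
    expr <- ds$expr; design <- ds$design
    promoters <- synth_promoters(scfg, ds$truth)$promoters
    ann <- synth_annotations(scfg, ds$truth)
    tf_genes <- ann$tf_genes
    class_genes <- ann$class_genes
    term_map <- ann$term_map
  } else {
    dat <- read_expression(cfg$expression, cfg$design)
    expr <- dat$expr; design <- dat$design
    promoters <- if (!is.null(cfg$promoters)) read_promoters(cfg$promoters)
    tf_genes <- if (!is.null(cfg$tf_genes)) read_gene_list(cfg$tf_genes) else character()
    class_genes <- if (!is.null(cfg$class_genes)) read_gene_list(cfg$class_genes) else character()
    term_map <- if (!is.null(cfg$term_map)) {
      readr::read_tsv(cfg$term_map, show_col_types = FALSE, progress = FALSE)
    }
  }

  log_lines <- c(sprintf("seed: %d", cfg$seed),
                 sprintf("genes: %d, arrays: %d", nrow(expr), ncol(expr)),
                 sprintf("stages: %s", paste(cfg$stages, collapse = ", ")))

  # ---- differential expression -------------------------------------------
  de <- NULL
  if (stage_on("diffexpr")) {
    de <- run_stage("diffexpr", 101L, function() {
      do.call(sam_call_all, c(list(expr = expr, design = design), cfg$sam))
    })
    results$de <- de
    readr::write_tsv(de$diagnostics, out("sam_diagnostics.tsv"))
    for (s in unique(de$by_stress$stress)) {
      write_gene_list(de_genes(de, s, "up"), out(sprintf("%s.up.txt", s)))
      write_gene_list(de_genes(de, s, "down"), out(sprintf("%s.down.txt", s)))
    }
    if (length(unique(de$by_stress$stress)) == 4) {
      venn <- dplyr::bind_rows(
        dplyr::mutate(venn_partition(de, "up"), direction = "up"),
        dplyr::mutate(venn_partition(de, "down"), direction = "down"))
      readr::write_tsv(venn, out("venn_regions.tsv"))
      results$venn <- venn
    }
    log_lines <- c(log_lines, sprintf("diffexpr: %d union calls",
                                      nrow(de$by_stress)))
  }

  # ---- network ------------------------------------------------------------
  assignment <- NULL
  if (stage_on("network")) {
    if (is.null(de)) abort("network stage requires the diffexpr stage")
    netres <- run_stage("network", 202L, function() {
      genes <- intersect(de_genes(de), rownames(expr))
      genes <- genes[apply(expr[genes, , drop = FALSE], 1, sd) > 0]
      np <- utils::modifyList(list(power = 23, cut_height = 0.91,
                                   min_size = 25, merge_height = 0.1,
                                   export_threshold = 0.35,
                                   display_threshold = 0.45,
                                   de_threshold = 1), cfg$network)
      if (length(genes) < max(3, np$min_size)) {
        return(list(assignment = tibble::tibble(gene_id = genes, module = 0L),
                    profiles = NULL, edges = NULL))
      }
      nt <- adjacency_tom(expr[genes, , drop = FALSE], power = np$power)
      asg <- detect_modules(nt$dissimilarity, cut_height = np$cut_height,
                            min_size = np$min_size)
      asg <- merge_modules(asg, expr[genes, , drop = FALSE],
                           merge_height = np$merge_height)
      prof <- module_profiles(asg, expr, design,
                              de_threshold = np$de_threshold)
      edges <- export_edge_list(nt$adjacency, asg,
                                export_threshold = np$export_threshold,
                                display_threshold = np$display_threshold)
      list(assignment = asg, profiles = prof, edges = edges)
    })
    assignment <- netres$assignment
    results$modules <- assignment
    results$profiles <- netres$profiles
    results$edges <- netres$edges
    readr::write_tsv(assignment, out("module_membership.tsv"))
    if (!is.null(netres$profiles)) {
      readr::write_tsv(tibble::as_tibble(netres$profiles),
                       out("module_profiles.tsv"))
      readr::write_tsv(module_responses(netres$profiles),
                       out("module_responses.tsv"))
    }
    if (!is.null(netres$edges)) {
      readr::write_tsv(netres$edges, out("edge_list.tsv"))
    }
    log_lines <- c(log_lines, sprintf("network: %d modules over %d genes",
                                      max(assignment$module, 0),
                                      sum(assignment$module > 0)))
  }

  # ---- plasticity ---------------------------------------------------------
  if (stage_on("plasticity")) {
    if (is.null(de)) abort("plasticity stage requires the diffexpr stage")
    plas <- run_stage("plasticity", 303L, function() {
      pp <- utils::modifyList(list(n_permutations = 200, subset_n = 15,
                                   target_fdr = 0.05, grid_step = 0.01),
                              cfg$plasticity)
      stresses <- sort(unique(design$stress[!design$is_control]))
      pairs <- combn(stresses, 2)
      cmps <- purrr::map(seq_len(ncol(pairs)), function(i) {
        plasticity_comparison(expr, design, de, tf_genes,
                              pairs[1, i], pairs[2, i],
                              n_permutations = pp$n_permutations,
                              subset_n = pp$subset_n,
                              target_fdr = pp$target_fdr,
                              grid_step = pp$grid_step)
      })
      cmps
    })
    results$plasticity <- plas
    summary_tab <- purrr::map_dfr(plas, glance)
    readr::write_tsv(summary_tab, out("plasticity_summary.tsv"))
    pair_tab <- purrr::map_dfr(plas, function(cmp) {
      dplyr::bind_cols(tibble::tibble(stress_a = cmp$cond_a,
                                      stress_b = cmp$cond_b),
                       tidy(cmp))
    })
    readr::write_tsv(pair_tab, out("plasticity_pairs.tsv"))
    np <- tryCatch(nonplastic_genes(plas), error = function(e) character())
    write_gene_list(np, out("nonplastic_genes.txt"))
    results$nonplastic <- np
    log_lines <- c(log_lines,
                   sprintf("plasticity: %d comparisons, %d nonplastic genes",
                           length(plas), length(np)))
  }

  # ---- promoter elements --------------------------------------------------
  if (stage_on("elements") && !is.null(promoters) && !is.null(assignment)) {
    motifs <- run_stage("elements", 404L, function() {
      ep <- utils::modifyList(list(k = 5:8, fdr = 0.01), cfg$elements)
      module_motif_enrichment(promoters, assignment, k = ep$k,
                              fdr_threshold = ep$fdr)
    })
    results$motifs <- motifs
    readr::write_tsv(motifs, out("motif_enrichment.tsv"))
    results$element_summary <- unique_total_summary(motifs)
    readr::write_tsv(results$element_summary, out("element_summary.tsv"))
    log_lines <- c(log_lines, sprintf("elements: %d significant motif calls",
                                      sum(motifs$significant)))
  }

  # ---- set / term enrichment ----------------------------------------------
  if (stage_on("enrichment") && !is.null(assignment)) {
    enr <- run_stage("enrichment", 505L, function() {
      ep <- utils::modifyList(list(n_permutations = 10000, fdr = 0.05,
                                   min_mapped = 5), cfg$enrichment)
      universe <- assignment$gene_id
      members <- assignment$gene_id[assignment$module > 0]
      overlap <- if (length(class_genes)) {
        cls <- intersect(class_genes, universe)
        if (length(cls)) {
          glance(overlap_test(universe, members, cls,
                              method = "permutation",
                              n_permutations = ep$n_permutations))
        }
      }
      terms <- if (!is.null(term_map)) {
        mods <- sort(setdiff(unique(assignment$module), 0L))
        purrr::map_dfr(mods, function(m) {
          set <- assignment$gene_id[assignment$module == m]
          res <- term_enrichment(set, universe, term_map,
                                 fdr_threshold = ep$fdr,
                                 min_mapped = ep$min_mapped)
          if (nrow(res)) dplyr::bind_cols(tibble::tibble(module = m), res)
        })
      }
      list(overlap = overlap, terms = terms)
    })
    if (!is.null(enr$overlap)) {
      results$overlap <- enr$overlap
      readr::write_tsv(enr$overlap, out("class_overlap.tsv"))
    }
    if (!is.null(enr$terms)) {
      results$terms <- enr$terms
      readr::write_tsv(enr$terms, out("term_enrichment.tsv"))
    }
  }

  writeLines(log_lines, out("run_log.txt"))
  invisible(results)
}
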