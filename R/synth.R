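#' Configuration for the synthetic stress-transcriptome generator
#'
#' Builds and validates the parameter set from which [synth_dataset()],
#' [synth_promoters()] and [synth_annotations()] produce a complete synthetic
#' study: an RMA-scale (log2) expression matrix on a multi-stress time-course
#' design, promoter sequences with planted cis-elements, and gene-class
#' annotations, all with recorded ground truth.
#'
#' The default configuration emulates a four-stress (cold, heat, salt,
#' drought) by five-timepoint (1, 2, 5, 10, 24 h) design with biological
#' triplicates, matched triplicate control arrays at every timepoint, and a
#' single dropped stress array (heat, 5 h, replicate C). Genes are organised
#' into 22 co-expression modules of geometrically decaying size covering about
#' two thirds of the universe; each module responds to a module-specific
#' subset of stresses with its own random temporal shape, peaking between
#' 0.7 and 1 times `de_effect_rma`.
#'
#' @param n_genes Number of genes in the universe.
#' @param module_sizes Integer vector of module sizes (largest first). When
#'   `NULL`, 22 modules with geometrically decaying sizes (minimum 25) covering
#'   ~67% of `n_genes` are used.
#' @param stresses Stress condition labels.
#' @param timepoints_h Sampling times in hours after stress onset, strictly
#'   increasing.
#' @param n_replicates Biological replicates per condition/timepoint.
#' @param de_effect_rma Peak differential-expression effect, in RMA (log2)
#'   units (default 4, the saturation scale of severe stress responses on
#'   log2 expression displays).
#' @param noise_sd_rma Residual standard deviation in RMA units.
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline
#'   expression (RMA units).
#' @param n_tfs Number of genes annotated as transcription factors.
#' @param n_class Size of the planted non-modular gene class (e.g. a
#'   calcium-binding-like class sampled preferentially outside modules).
#' @param n_plastic_pairs Number of planted plastic TF-target pairs whose
#'   correlation flips sign between `plastic_conditions`.
#' @param plastic_amp Amplitude of the shared latent driver behind each
#'   plastic pair; with the default noise this yields per-condition
#'   correlations of about +/-0.92 and a true |delta r| of about 1.8.
#' @param plastic_conditions Length-2 character vector naming the condition
#'   pair across which planted pairs rewire.
#' @param de_frac_nonmodular Fraction of non-module genes given an
#'   idiosyncratic (non-co-expressed) stress response.
#' @param promoter_length_nt Promoter length in nucleotides.
#' @param planted_motifs Data frame with columns `motif`, `module`, `rate`:
#'   each motif (5-8 nt over ACGT) is inserted in the given fraction of the
#'   target module's promoters.
#' @param dropouts Data frame with columns `stress`, `timepoint_h`,
#'   `replicate` naming stress arrays to drop (quality-control failures).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#'
#' @return A validated list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_genes = 200, module_sizes = c(40, 30), seed = 1)
#' cfg$n_genes
synth_config <- function(n_genes = 2000,
                         module_sizes = NULL,
                         stresses = c("cold", "heat", "salt", "drought"),
                         timepoints_h = c(1, 2, 5, 10, 24),
                         n_replicates = 3,
                         de_effect_rma = 4,
                         noise_sd_rma = 0.25,
                         baseline_mean = 8,
                         baseline_sd = 2,
                         n_tfs = 150,
                         n_class = 60,
                         n_plastic_pairs = 25,
                         plastic_amp = 1,
                         plastic_conditions = c("drought", "salt"),
                         de_frac_nonmodular = 0.5,
                         promoter_length_nt = 500,
                         planted_motifs = NULL,
                         dropouts = NULL,
                         seed = 1) {
  if (is.null(module_sizes)) {
    module_sizes <- default_module_sizes(n_genes)
  }
  if (is.null(planted_motifs)) {
    planted_motifs <- if (length(module_sizes) >= 2) {
      tibble::tibble(motif = c("CAACGGTC", "ACGTGGC"),
                     module = c(2L, min(7L, length(module_sizes))),
                     rate = c(0.6, 0.5))
    } else {
      tibble::tibble(motif = character(), module = integer(), rate = double())
    }
  }
  if (is.null(dropouts)) {
    dropouts <- tibble::tibble(stress = "heat", timepoint_h = 5, replicate = "C")
  }
  cfg <- structure(list(
    n_genes = as.integer(n_genes),
    module_sizes = as.integer(module_sizes),
    stresses = stresses,
    timepoints_h = timepoints_h,
    n_replicates = as.integer(n_replicates),
    de_effect_rma = de_effect_rma,
    noise_sd_rma = noise_sd_rma,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    n_tfs = as.integer(n_tfs),
    n_class = as.integer(n_class),
    n_plastic_pairs = as.integer(n_plastic_pairs),
    plastic_amp = plastic_amp,
    plastic_conditions = plastic_conditions,
    de_frac_nonmodular = de_frac_nonmodular,
    promoter_length_nt = as.integer(promoter_length_nt),
    planted_motifs = tibble::as_tibble(planted_motifs),
    dropouts = tibble::as_tibble(dropouts),
    seed = as.integer(seed)
  ), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

# Geometrically decaying module sizes (ratio 0.85, min 25) covering ~67% of
# the universe, clipped so they always fit.
default_module_sizes <- function(n_genes, n_modules = 22,
                                 frac_assigned = 0.67, ratio = 0.85) {
  if (n_genes < 50) return(integer())
  raw <- ratio^(seq_len(n_modules) - 1)
  sizes <- pmax(25L, as.integer(round(raw / sum(raw) * frac_assigned * n_genes)))
  sizes <- sizes[cumsum(sizes) <= n_genes]
  sizes
}

validate_synth_config <- function(cfg) {
  if (cfg$n_genes < 0) abort("`n_genes` must be non-negative")
  if (sum(cfg$module_sizes) > cfg$n_genes) {
    abort(sprintf("module sizes sum to %d, exceeding n_genes = %d",
                  sum(cfg$module_sizes), cfg$n_genes))
  }
  if (any(cfg$module_sizes < 1)) abort("module sizes must be positive")
  if (is.unsorted(cfg$timepoints_h, strictly = TRUE)) {
    abort("`timepoints_h` must be strictly increasing")
  }
  if (cfg$n_replicates < 1) abort("`n_replicates` must be >= 1")
  if (cfg$n_tfs > cfg$n_genes) abort("`n_tfs` cannot exceed `n_genes`")
  pm <- cfg$planted_motifs
  if (nrow(pm)) {
    if (anyDuplicated(pm[c("motif", "module")])) {
      abort("duplicate motif/module planting in `planted_motifs`")
    }
    if (any(!grepl("^[ACGT]+$", pm$motif))) {
      abort("planted motifs must be uppercase ACGT strings")
    }
    if (any(nchar(pm$motif) < 5 | nchar(pm$motif) > 8)) {
      abort("planted motifs must be 5-8 nt long")
    }
    if (any(pm$rate <= 0 | pm$rate > 1)) abort("planting rates must be in (0, 1]")
    if (any(pm$module > length(cfg$module_sizes))) {
      abort("planted motif targets a module that does not exist")
    }
    if (cfg$promoter_length_nt < max(nchar(pm$motif))) {
      abort("`promoter_length_nt` shorter than the longest planted motif")
    }
  }
  if (!all(cfg$plastic_conditions %in% cfg$stresses) ||
      length(cfg$plastic_conditions) != 2) {
    abort("`plastic_conditions` must name two of the configured stresses")
  }
  invisible(cfg)
}

#' Generate a synthetic stress time-course expression dataset
#'
#' Simulates an RMA-scale expression matrix on the configured design together
#' with its sample table and full ground truth. Module member genes share a
#' latent stress-response profile (a monotone onset reaching the configured
#' effect at the last timepoint, under a module-specific subset of stresses)
#' plus independent Gaussian noise; a configurable fraction of non-module
#' genes receive idiosyncratic (mutually uncorrelated) responses; planted
#' plastic TF-target pairs share a latent driver whose coupling flips sign
#' between the two plastic conditions, so their Pearson correlation rewires
#' from about +0.9 to -0.9.
#'
#' @param config A [synth_config()] object.
#'
#' @return A list of class `synth_dataset` with elements
#'   \describe{
#'     \item{expr}{numeric matrix, genes x arrays, RMA (log2) scale.}
#'     \item{design}{tibble: `sample_id`, `stress`, `timepoint_h`,
#'       `replicate`, `is_control`.}
#'     \item{truth}{list with `modules` (gene to module label, 0 = none),
#'       `module_profiles` (true delta-RMA per module/stress/timepoint),
#'       `gene_profiles` (idiosyncratic responses), `plastic_pairs` (planted
#'       TF-target rewiring with true per-condition correlations), and
#'       `plastic_tfs`.}
#'   }
#' @export
#' @examples
#' cfg <- synth_config(n_genes = 120, module_sizes = c(40, 30), seed = 7)
#' ds <- synth_dataset(cfg)
#' dim(ds$expr)
synth_dataset <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  design <- synth_design(config)
  n <- config$n_genes
  genes <- synth_gene_ids(n)

  if (n == 0) {
    return(structure(list(
      expr = matrix(numeric(), 0, nrow(design),
                    dimnames = list(NULL, design$sample_id)),
      design = design,
      truth = list(modules = tibble::tibble(gene_id = character(),
                                            module = integer()),
                   module_profiles = tibble::tibble(module = integer(),
                                                    stress = character(),
                                                    timepoint_h = double(),
                                                    delta_rma = double()),
                   gene_profiles = tibble::tibble(gene_id = character(),
                                                  stress = character(),
                                                  timepoint_h = double(),
                                                  delta_rma = double()),
                   plastic_pairs = tibble::tibble(tf = character(),
                                                  tg = character(),
                                                  cond_a = character(),
                                                  cond_b = character(),
                                                  r_a = double(),
                                                  r_b = double()),
                   plastic_tfs = character())
    ), class = "synth_dataset", seed = config$seed))
  }

  k <- length(config$module_sizes)
  module_of <- integer(n)                     # 0 = unassigned
  idx <- 1L
  for (m in seq_len(k)) {
    module_of[idx:(idx + config$module_sizes[m] - 1L)] <- m
    idx <- idx + config$module_sizes[m]
  }

  # A responder (module or idiosyncratic gene) carries one random temporal
  # shape, shared by all its responsive stresses and scaled by a per-stress
  # positive amplitude factor. Sharing the shape across stresses keeps a
  # gene pair's correlation consistent between conditions (so only planted
  # pairs rewire), while distinct shapes keep different modules separable.
  random_shape <- function() {
    w <- rnorm(length(config$timepoints_h))
    w / max(abs(w))
  }

  # Module truth: each module responds to drought (if configured) with high
  # probability and to each other stress sparsely; at least one stress each.
  module_profiles <- purrr::map_dfr(seq_len(k), function(m) {
    p_resp <- ifelse(config$stresses == "drought", 0.9, 0.3)
    resp <- runif(length(config$stresses)) < p_resp
    if (!any(resp)) resp[sample.int(length(config$stresses), 1)] <- TRUE
    shape <- random_shape()
    amp <- runif(length(config$stresses), 0.7, 1) * config$de_effect_rma
    purrr::map_dfr(seq_along(config$stresses), function(s) {
      tibble::tibble(
        module = m, stress = config$stresses[s],
        timepoint_h = config$timepoints_h,
        delta_rma = if (resp[s]) amp[s] * shape else 0
      )
    })
  })

  # Idiosyncratic non-module responders: same model with per-gene shapes, so
  # they are differentially expressed without co-expressing with anything.
  free <- which(module_of == 0L)
  n_idio <- as.integer(round(config$de_frac_nonmodular * length(free)))
  idio <- if (n_idio > 0) sort(sample(free, n_idio)) else integer()
  gene_profiles <- purrr::map_dfr(idio, function(g) {
    resp <- runif(length(config$stresses)) < 0.5
    if (!any(resp)) resp[sample.int(length(config$stresses), 1)] <- TRUE
    shape <- random_shape()
    amp <- runif(length(config$stresses), 0.7, 1) * config$de_effect_rma
    purrr::map_dfr(which(resp), function(s) {
      tibble::tibble(gene_id = genes[g], stress = config$stresses[s],
                     timepoint_h = config$timepoints_h,
                     delta_rma = amp[s] * shape)
    })
  })
  if (nrow(gene_profiles) == 0) {
    gene_profiles <- tibble::tibble(gene_id = character(), stress = character(),
                                    timepoint_h = double(), delta_rma = double())
  }

  # Plastic TF-target pairs live outside modules and outside the
  # idiosyncratic set; each pair shares a latent per-array driver whose
  # coupling to the target flips sign between the two plastic conditions.
  pool <- setdiff(free, idio)
  n_pp <- min(config$n_plastic_pairs, length(pool) %/% 2)
  plastic_tf <- plastic_tg <- integer()
  if (n_pp > 0) {
    picked <- sample(pool, 2L * n_pp)
    plastic_tf <- picked[seq_len(n_pp)]
    plastic_tg <- picked[n_pp + seq_len(n_pp)]
  }

  # Assemble the expression matrix.
  expr <- matrix(rnorm(n * nrow(design), 0, config$noise_sd_rma),
                 n, nrow(design),
                 dimnames = list(genes, design$sample_id))
  baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
  expr <- expr + baseline

  col_key <- paste(design$stress, design$timepoint_h)
  add_profile <- function(rows, prof) {
    # prof: tibble(stress, timepoint_h, delta_rma) on stress arrays only
    delta <- setNames(prof$delta_rma, paste(prof$stress, prof$timepoint_h))
    cols <- which(!design$is_control & col_key %in% names(delta))
    if (length(cols) && length(rows)) {
      expr[rows, cols] <<- expr[rows, cols] +
        rep(delta[col_key[cols]], each = length(rows))
    }
  }
  for (m in seq_len(k)) {
    add_profile(which(module_of == m),
                dplyr::filter(module_profiles, .data$module == m))
  }
  for (i in seq_along(idio)) {
    add_profile(idio[i],
                dplyr::filter(gene_profiles, .data$gene_id == genes[idio[i]]))
  }

  conds <- config$plastic_conditions
  amp <- config$plastic_amp
  r_true <- amp^2 / (amp^2 + config$noise_sd_rma^2)
  if (n_pp > 0) {
    cols_a <- which(design$stress == conds[1] & !design$is_control)
    cols_b <- which(design$stress == conds[2] & !design$is_control)
    for (i in seq_len(n_pp)) {
      za <- rnorm(length(cols_a))
      zb <- rnorm(length(cols_b))
      expr[plastic_tf[i], cols_a] <- expr[plastic_tf[i], cols_a] + amp * za
      expr[plastic_tg[i], cols_a] <- expr[plastic_tg[i], cols_a] + amp * za
      expr[plastic_tf[i], cols_b] <- expr[plastic_tf[i], cols_b] + amp * zb
      expr[plastic_tg[i], cols_b] <- expr[plastic_tg[i], cols_b] - amp * zb
      # constant offset on both conditions' arrays makes the pair
      # differentially expressed there without touching its correlations
      expr[c(plastic_tf[i], plastic_tg[i]), c(cols_a, cols_b)] <-
        expr[c(plastic_tf[i], plastic_tg[i]), c(cols_a, cols_b)] +
        config$de_effect_rma
    }
  }

  truth <- list(
    modules = tibble::tibble(gene_id = genes, module = module_of),
    module_profiles = module_profiles,
    gene_profiles = gene_profiles,
    plastic_pairs = tibble::tibble(
      tf = genes[plastic_tf], tg = genes[plastic_tg],
      cond_a = conds[1], cond_b = conds[2],
      r_a = rep(r_true, n_pp), r_b = rep(-r_true, n_pp)),
    plastic_tfs = genes[plastic_tf]
  )
  structure(list(expr = expr, design = design, truth = truth),
            class = "synth_dataset", seed = config$seed)
}

synth_gene_ids <- function(n) sprintf("g%05d", seq_len(n))

synth_design <- function(config) {
  reps <- LETTERS[seq_len(config$n_replicates)]
  grid <- tidyr::expand_grid(stress = c(config$stresses, "control"),
                             timepoint_h = config$timepoints_h,
                             replicate = reps)
  grid$is_control <- grid$stress == "control"
  if (nrow(config$dropouts)) {
    grid <- dplyr::anti_join(grid, config$dropouts,
                             by = c("stress", "timepoint_h", "replicate"))
  }
  grid$sample_id <- sprintf("%s_%02dh_%s", grid$stress,
                            as.integer(grid$timepoint_h), grid$replicate)
  dplyr::select(grid, "sample_id", "stress", "timepoint_h", "replicate",
                "is_control")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("<synth_dataset> %d genes x %d arrays; %d modules, %d plastic pairs\n",
              nrow(x$expr), ncol(x$expr),
              max(x$truth$modules$module, 0),
              nrow(x$truth$plastic_pairs)))
  invisible(x)
}

#' Generate synthetic promoter sequences with planted motifs
#'
#' Produces one uppercase ACGT sequence of the configured length per gene,
#' with i.i.d. uniform background composition, and inserts each configured
#' motif at a uniformly drawn offset in the stated fraction of its target
#' module's promoters. Placements are recorded so downstream enrichment can
#' be validated against ground truth.
#'
#' @param config A [synth_config()] object.
#' @param truth The `truth` element of a [synth_dataset()] (module labels are
#'   needed to target planting).
#'
#' @return List of class `synth_promoters`: `promoters` (tibble `gene_id`,
#'   `sequence`, `truncated`, `provenance`) and `placements` (tibble
#'   `gene_id`, `motif`, `start` with 1-based start positions).
#' @export
synth_promoters <- function(config, truth) {
  validate_synth_config(config)
  set.seed(config$seed + 1L)
  genes <- truth$modules$gene_id
  L <- config$promoter_length_nt
  n <- length(genes)
  seqs <- if (n > 0) {
    chars <- sample(c("A", "C", "G", "T"), n * L, replace = TRUE)
    apply(matrix(chars, n, L), 1, paste0, collapse = "")
  } else character()

  placements <- tibble::tibble(gene_id = character(), motif = character(),
                               start = integer())
  pm <- config$planted_motifs
  for (i in seq_len(nrow(pm))) {
    members <- which(truth$modules$module == pm$module[i])
    n_plant <- ceiling(pm$rate[i] * length(members))
    if (n_plant == 0) next
    target <- sort(sample(members, n_plant))
    w <- nchar(pm$motif[i])
    starts <- sample.int(L - w + 1L, n_plant, replace = TRUE)
    for (j in seq_along(target)) {
      substr(seqs[target[j]], starts[j], starts[j] + w - 1L) <- pm$motif[i]
    }
    placements <- dplyr::bind_rows(placements, tibble::tibble(
      gene_id = genes[target], motif = pm$motif[i], start = starts))
  }
  structure(list(
    promoters = tibble::tibble(gene_id = genes, sequence = seqs,
                               truncated = FALSE, provenance = "synthetic"),
    placements = placements
  ), class = "synth_promoters")
}

#' Generate synthetic gene-class annotations
#'
#' Emits a transcription-factor list (always containing the planted plastic
#' TFs), a non-modular gene class sampled preferentially outside modules
#' (emulating, e.g., calcium-binding loci that escape co-expression modules),
#' and a term-to-gene annotation map in which one term covers exactly module 1
#' so that term enrichment has a planted positive control.
#'
#' @inheritParams synth_promoters
#'
#' @return List of class `synth_annotations`: `tf_genes`, `class_genes`
#'   (character vectors) and `term_map` (tibble `term`, `gene_id`).
#' @export
synth_annotations <- function(config, truth) {
  validate_synth_config(config)
  set.seed(config$seed + 2L)
  genes <- truth$modules$gene_id
  n <- length(genes)
  if (n == 0) {
    return(structure(list(tf_genes = character(), class_genes = character(),
                          term_map = tibble::tibble(term = character(),
                                                    gene_id = character())),
                     class = "synth_annotations"))
  }
  tf <- unique(c(truth$plastic_tfs,
                 sample(genes, min(config$n_tfs, n))))[seq_len(min(config$n_tfs, n))]

  in_mod <- truth$modules$module > 0
  out_pool <- genes[!in_mod]
  in_pool <- genes[in_mod]
  n_out <- min(length(out_pool), ceiling(0.85 * config$n_class))
  n_in <- min(length(in_pool), config$n_class - n_out)
  class_genes <- c(if (n_out) sample(out_pool, n_out),
                   if (n_in) sample(in_pool, n_in))

  term_map <- tibble::tibble(
    term = "TERM:0001",
    gene_id = genes[truth$modules$module == 1L])
  for (t in 2:4) {
    term_map <- dplyr::bind_rows(term_map, tibble::tibble(
      term = sprintf("TERM:%04d", t),
      gene_id = sample(genes, min(n, sample(10:40, 1)))))
  }
  structure(list(tf_genes = tf, class_genes = class_genes,
                 term_map = term_map),
            class = "synth_annotations")
}

#' Write a synthetic fixture bundle to disk
#'
#' Writes the expression TSV (genes in rows), sample-design TSV, promoters
#' FASTA, gene-class lists (one id per line), truth tables as TSV and a JSON
#' sidecar recording the seed, into `dir`.
#'
#' @param dataset A [synth_dataset()] result.
#' @param promoters Optional [synth_promoters()] result.
#' @param annotations Optional [synth_annotations()] result.
#' @param dir Output directory (created if needed).
#'
#' @return `dir`, invisibly.
#' @export
write_synth_bundle <- function(dataset, promoters = NULL, annotations = NULL,
                               dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(dataset$expr, dataset$design,
                   file.path(dir, "expression.tsv"),
                   file.path(dir, "design.tsv"))
  readr::write_tsv(dataset$truth$modules, file.path(dir, "truth_modules.tsv"))
  readr::write_tsv(dataset$truth$module_profiles,
                   file.path(dir, "truth_module_profiles.tsv"))
  readr::write_tsv(dataset$truth$plastic_pairs,
                   file.path(dir, "truth_plastic_pairs.tsv"))
  if (!is.null(promoters)) {
    write_promoters(promoters$promoters, file.path(dir, "promoters.fasta"))
    readr::write_tsv(promoters$placements,
                     file.path(dir, "truth_motif_placements.tsv"))
  }
  if (!is.null(annotations)) {
    writeLines(annotations$tf_genes, file.path(dir, "tf_genes.txt"))
    writeLines(annotations$class_genes, file.path(dir, "class_genes.txt"))
    readr::write_tsv(annotations$term_map, file.path(dir, "term_map.tsv"))
  }
  s <- attr(dataset, "seed")
  writeLines(sprintf('{"seed": %s}',
                     if (is.null(s) || is.na(s)) "null" else as.integer(s)),
             file.path(dir, "seed.json"))
  invisible(dir)
}
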