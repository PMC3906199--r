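test_that("soft-threshold adjacency follows |cor|^power", {
  # x and z orthogonal with equal norms give y = 0.9 x + sqrt(1-0.81) z an
  # exact correlation of 0.9 with x
  x <- rep(c(1, -1), 8)
  z <- rep(c(1, 1, -1, -1), 4)
  y <- 0.9 * x + sqrt(1 - 0.81) * z
  w <- rep(c(1, -1, -1, 1), 4)
  m <- rbind(g1 = x, g2 = y, g3 = w)
  nt <- adjacency_tom(m, power = 23)
  expect_equal(nt$adjacency["g1", "g2"], 0.9^23, tolerance = 1e-12)
  expect_equal(0.9^23, 0.0886, tolerance = 1e-3)

  # perfectly correlated genes have adjacency 1 at any power
  m2 <- rbind(g1 = x, g2 = 2 * x + 5, g3 = w)
  nt2 <- adjacency_tom(m2, power = 23)
  expect_equal(nt2$adjacency["g1", "g2"], 1)

  expect_error(adjacency_tom(rbind(g1 = x, g2 = rep(1, 16), g3 = w)), "g2")
})

test_that("TOM dissimilarity equals the brute-force oracle", {
  set.seed(12)
  for (rep in 1:3) {
    m <- matrix(rnorm(6 * 10), 6, 10,
                dimnames = list(paste0("g", 1:6), NULL))
    nt <- adjacency_tom(m, power = 6)
    expect_equal(nt$dissimilarity, tom_dissimilarity_oracle(nt$adjacency),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(nt$dissimilarity >= 0 & nt$dissimilarity <= 1))
    expect_equal(nt$dissimilarity, t(nt$dissimilarity))
    expect_true(all(diag(nt$dissimilarity) == 0))
  }

  # isolated pair: k_i = k_j = a_ij, so dissimilarity reduces to 1 - a_ij
  a <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  expect_equal(tom_dissimilarity(a)[1, 2], 1 - 0.4, tolerance = 1e-12)
})

test_that("static cut calls planted blocks and applies the size floor", {
  block_dissim <- function(sizes, within = 0.1, between = 0.99) {
    n <- sum(sizes)
    d <- matrix(between, n, n)
    at <- 1
    for (s in sizes) {
      d[at:(at + s - 1), at:(at + s - 1)] <- within
      at <- at + s
    }
    diag(d) <- 0
    rownames(d) <- colnames(d) <- paste0("g", seq_len(n))
    d
  }
  asg <- detect_modules(block_dissim(c(30, 30)), cut_height = 0.91,
                        min_size = 25)
  expect_equal(as.vector(table(asg$module)), c(30L, 30L))
  expect_setequal(unique(asg$module), c(1L, 2L))

  # all pairs above the cut: everything unassigned
  far <- detect_modules(block_dissim(c(30, 30), within = 0.99),
                        cut_height = 0.91, min_size = 25)
  expect_true(all(far$module == 0))

  # a cohesive block below the minimum size stays unassigned
  small <- detect_modules(block_dissim(c(10, 30)), cut_height = 0.91,
                          min_size = 25)
  expect_true(all(small$module[1:10] == 0))
  expect_true(all(small$module[11:40] == 1))
})

test_that("eigengene merging joins duplicated latent profiles only", {
  set.seed(13)
  latent <- rnorm(20)
  m <- rbind(
    matrix(rep(latent, each = 30), 30, byrow = FALSE) + rnorm(600, sd = 0.1),
    matrix(rep(latent, each = 30), 30, byrow = FALSE) + rnorm(600, sd = 0.1),
    matrix(rep(-latent, each = 30), 30, byrow = FALSE) + rnorm(600, sd = 0.1))
  rownames(m) <- paste0("g", 1:90)
  asg <- tibble::tibble(gene_id = rownames(m),
                        module = rep(1:3, each = 30))

  merged <- merge_modules(asg, m, merge_height = 0.1)
  # modules 1 and 2 share a latent profile (eigengene cor ~ 1): merged;
  # module 3 is anticorrelated (cor ~ -1, dissimilarity ~ 2): kept apart
  expect_equal(length(unique(merged$module)), 2)
  expect_equal(merged$module[1], merged$module[31])
  expect_false(merged$module[1] == merged$module[61])

  # idempotence: merging the merged assignment changes nothing
  expect_equal(merge_modules(merged, m, merge_height = 0.1), merged)

  # a single module passes through unchanged
  one <- tibble::tibble(gene_id = rownames(m)[1:30], module = 1L)
  expect_equal(merge_modules(one, m[1:30, ], merge_height = 0.1)$module,
               rep(1L, 30))
})

test_that("planted modules are recovered with high adjusted Rand index", {
  fx <- shared_fixture()
  mod <- shared_modules()
  truth <- fx$ds$truth$modules$module[
    match(mod$assignment$gene_id, fx$ds$truth$modules$gene_id)]
  ari <- ari_oracle(mod$assignment$module, truth)
  expect_gte(ari, 0.8)
  # and agrees with an independent ARI implementation
  expect_equal(ari, mclust::adjustedRandIndex(mod$assignment$module, truth),
               tolerance = 1e-12)
})

test_that("module profiles flag responses at the 1-RMA criterion", {
  # module whose genes all sit exactly +1 RMA above control at 24 h
  design <- tibble::tibble(
    sample_id = c("c1", "c2", "s1", "s2"),
    stress = c("control", "control", "cold", "cold"),
    timepoint_h = 24, replicate = c("A", "B", "A", "B"),
    is_control = c(TRUE, TRUE, FALSE, FALSE))
  m <- rbind(g1 = c(5, 5, 6, 6), g2 = c(7, 7, 8, 8))
  colnames(m) <- design$sample_id
  asg <- tibble::tibble(gene_id = c("g1", "g2"), module = 1L)
  prof <- module_profiles(asg, m, design)
  expect_equal(prof$mean_delta_rma, 1)
  expect_equal(prof$se, 0)
  expect_true(module_responses(prof)$responsive)

  # flat module responds to nothing
  m0 <- rbind(g1 = c(5, 5, 5, 5), g2 = c(7, 7, 7, 7))
  colnames(m0) <- design$sample_id
  prof0 <- module_profiles(asg, m0, design)
  expect_false(any(module_responses(prof0)$responsive))
})

test_that("detected module responses match the generating truth", {
  fx <- shared_fixture()
  mod <- shared_modules()
  prof <- module_profiles(mod$assignment, fx$ds$expr, fx$ds$design)
  resp <- module_responses(prof)
  tr <- fx$ds$truth

  # map detected modules to the dominant true module of their members
  for (m in sort(unique(resp$module))) {
    members <- mod$assignment$gene_id[mod$assignment$module == m]
    truem <- tr$modules$module[match(members, tr$modules$gene_id)]
    dom <- as.integer(names(which.max(table(truem[truem > 0]))))
    if (length(dom) == 0) next
    tp <- tr$module_profiles[tr$module_profiles$module == dom, ]
    true_resp <- tapply(abs(tp$delta_rma), tp$stress, max) >= 1
    got <- resp[resp$module == m, ]
    expect_equal(got$responsive, as.vector(true_resp[got$stress]))
  }
})

test_that("edge-list export applies both thresholds and conserves pairs", {
  a <- matrix(c(1, 0.5, 0.4, 0.2,
                0.5, 1, 0.3, 0.1,
                0.4, 0.3, 1, 0.05,
                0.2, 0.1, 0.05, 1), 4, 4,
              dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  edges <- export_edge_list(a, export_threshold = 0.35,
                            display_threshold = 0.45)
  expect_equal(nrow(edges), 2)
  expect_equal(sum(edges$display), 1)

  none <- export_edge_list(a * 0.3, export_threshold = 0.35)
  expect_equal(nrow(none), 0)

  all_edges <- export_edge_list(a, export_threshold = 0,
                                display_threshold = 0)
  expect_equal(nrow(all_edges), 4 * 3 / 2)

  expect_error(export_edge_list(a, export_threshold = 0.5,
                                display_threshold = 0.4), "exceed")
})
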