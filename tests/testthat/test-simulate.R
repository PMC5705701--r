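test_that("the generator is deterministic given a seed", {
  d <- small_design(seed = 101L)
  b1 <- simulate_annotation(d)
  b2 <- simulate_annotation(d)
  expect_identical(b1$exons, b2$exons)
  expect_identical(b1$circ_layout, b2$circ_layout)
  s1 <- simulate_counts(d, b1)
  s2 <- simulate_counts(d, b2)
  expect_identical(s1$circ_evidence, s2$circ_evidence)
  expect_identical(simulate_clinical(d, s1$truth),
                   simulate_clinical(d, s2$truth))
})

test_that("clinical events and censorings partition the cohort", {
  d <- small_design(seed = 102L)
  b <- simulate_annotation(d)
  sim <- simulate_counts(d, b)
  cl <- simulate_clinical(d, sim$truth)
  expect_equal(sum(cl$progressed) + sum(cl$progressed == 0L), nrow(cl))
  expect_equal(nrow(cl), sum(d$n_class))
  expect_true(all(cl$time_months > 0))
  expect_true(all(cl$eortc >= 0 & cl$eortc <= 23))
  # EORTC is monotone (non-decreasing) in latent risk
  z_order <- order(sim$truth$samples$latent_risk)
  expect_true(all(diff(cl$eortc[z_order]) >= 0))
})

test_that("extreme planting probabilities are recovered exactly downstream", {
  # every planted circle gets an inverted pair; no background Alus
  d <- small_design(seed = 103L, alu_planting = 1, alu_background_per_kb = 0)
  b <- simulate_annotation(d)
  planted <- b$circ_layout[planted == TRUE]
  res <- nearest_inverted_alu_pair(
    planted[, list(chrom, start, end)], b$alus, 20000L)
  expect_true(all(is.finite(res$distance)))
  expect_true(all(res$distance <= 20000))
  # the nearest pair is the planted one, unless a neighbouring planted
  # circle in the same gene contributed an even closer homologous pair
  expect_true(all(res$distance <= planted$planted_alu_distance))
  # zero background SCE density: only planted circles' exons carry SCEs
  d2 <- small_design(seed = 104L, sce_rate_background = 0)
  b2 <- simulate_annotation(d2)
  if (nrow(b2$sce)) {
    pl <- b2$circ_layout[planted == TRUE]
    inside <- outer(b2$sce$start, pl$start, ">=") &
      outer(b2$sce$end, pl$end, "<=")
    expect_true(all(rowSums(inside) > 0))
  }
})

test_that("planted fold changes and the null both show in group means", {
  # 2-fold planted down in class 2: mean ratio of group means near 2
  d <- simulation_design(n_class = c(class1 = 100L, class2 = 100L,
                                     class3 = 0L),
                         n_genes = 80L, n_planted_enriched = Inf,
                         frac_de = 0.5, frac_up_in_class2 = 0,
                         de_fold_change = 2, n_prognostic = 0L,
                         prognostic_effect = 0, seed = 105L)
  b <- simulate_annotation(d)
  sim <- simulate_counts(d, b)
  ev <- sim$circ_evidence
  cts <- build_catalog(filter_junctions(ev, 35L), 2L, 2L)$counts
  truth <- sim$truth
  cls <- truth$samples$class[match(colnames(cts), truth$samples$sample_id)]
  act <- truth$samples$circ_activity *
    truth$samples$lib_size / mean(truth$samples$lib_size)
  norm <- sweep(cts, 2L, act, "/")  # remove known per-sample factors
  de_ids <- intersect(truth$circles[is_de == TRUE, circ_id], rownames(norm))
  ratio <- rowMeans(norm[de_ids, cls == 1, drop = FALSE]) /
    rowMeans(norm[de_ids, cls == 2, drop = FALSE])
  expect_gt(mean(ratio), 1.7)
  expect_lt(mean(ratio), 2.3)
  null_ids <- intersect(truth$circles[is_de == FALSE, circ_id],
                        rownames(norm))
  ratio0 <- rowMeans(norm[null_ids, cls == 1, drop = FALSE]) /
    rowMeans(norm[null_ids, cls == 2, drop = FALSE])
  expect_gt(mean(ratio0), 0.9)
  expect_lt(mean(ratio0), 1.1)
})

test_that("QKI expression tracks total circular output across seeds", {
  pos <- vapply(1:25, function(s) {
    d <- small_design(seed = 400L + s, n_prognostic = 0L)
    b <- simulate_annotation(d)
    sim <- simulate_counts(d, b)
    cts <- build_catalog(filter_junctions(sim$circ_evidence, 35L),
                         2L, 2L)$counts
    tot <- colSums(cts)
    qki <- sim$gene_expression["QKI", colnames(cts)]
    cor(tot, qki, method = "spearman") > 0
  }, logical(1L))
  expect_gte(mean(pos), 0.95)
})

test_that("equal library sizes make CPM proportional to raw counts", {
  counts <- matrix(rpois(20, 5), 4, 5,
                   dimnames = list(letters[1:4], paste0("S", 1:5)))
  lib <- stats::setNames(rep(2e6, 5), paste0("S", 1:5))
  cpm <- cpm_matrix(counts, lib)
  expect_equal(cpm, counts / 2e6 * 1e6)
})
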