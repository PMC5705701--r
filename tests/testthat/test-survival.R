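test_that("median split puts ties in the low group and flags degeneracy", {
  sp <- median_split(c(0, 0, 1, 2))
  expect_equal(as.character(sp$group), c("low", "low", "high", "high"))
  sp2 <- median_split(c(5, 5, 5, 9))
  expect_equal(sum(sp2$group == "low"), 3L)
  expect_false(sp2$degenerate)
  expect_true(median_split(c(1, 1, 1, 1))$degenerate)
  expect_error(median_split(c(1, 2, 3)), "4 samples")
})

test_that("product-limit estimator matches hand computation", {
  # two subjects, events at t = 1 and 2
  km <- km_estimate(c(1, 2), c(1L, 1L))
  expect_equal(km$survival, c(0.5, 0))
  # all censored: survival stays at 1
  km2 <- km_estimate(c(3, 5, 7), c(0L, 0L, 0L))
  expect_equal(km2$survival, c(1, 1, 1))
  # 10-subject mixed fixture, worked by hand
  time <- c(1, 2, 2, 3, 4, 5, 6, 7, 8, 10)
  event <- c(1L, 1L, 0L, 1L, 0L, 1L, 1L, 0L, 1L, 0L)
  km3 <- km_estimate(time, event)
  hand <- cumprod(c(1 - 1 / 10, 1 - 1 / 9, 1 - 1 / 7, 1, 1 - 1 / 5,
                    1 - 1 / 4, 1, 1 - 1 / 2, 1))
  expect_equal(km3$survival, hand, tolerance = 1e-12)
  expect_equal(km3$n_risk, c(10L, 9L, 7L, 6L, 5L, 4L, 3L, 2L, 1L))
  expect_error(km_estimate(c(0, 1), c(1L, 1L)), "positive")
})

test_that("product-limit estimator agrees with survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(21)
  time <- round(rexp(40, 0.05), 2) + 0.01
  event <- rbinom(40, 1, 0.6)
  group <- rep(c("a", "b"), 20)
  km <- km_estimate(time, event, group)
  sf <- summary(survival::survfit(survival::Surv(time, event) ~ group))
  for (g in c("a", "b")) {
    ours <- km[km$group == g & km$n_event > 0, ]
    ref <- sf$surv[sf$strata == paste0("group=", g)]
    expect_equal(ours$survival, ref, tolerance = 1e-12)
  }
})

test_that("log-rank matches the hand-computed hypergeometric tables", {
  # 8-subject fixture worked by hand over event times 1,2,3,6,7
  time <- c(1, 3, 5, 7, 2, 4, 6, 8)
  event <- c(1L, 1L, 0L, 1L, 1L, 0L, 1L, 0L)
  group <- rep(c("A", "B"), each = 4)
  lr <- logrank_test(time, event, group)
  E <- 1 / 2 + 3 / 7 + 1 / 2 + 1 / 3 + 1 / 2
  V <- 1 / 4 + 12 / 49 + 1 / 4 + 2 / 9 + 1 / 4
  expect_equal(lr$statistic, (3 - E)^2 / V, tolerance = 1e-12)
  expect_equal(lr$p_value, pchisq((3 - E)^2 / V, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(lr$observed, c(3, 2))
  # identical event patterns in the two groups: statistic 0, p 1
  lr0 <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(1L, 6),
                      rep(c("A", "B"), each = 3))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)
  # degenerate and error cases
  expect_true(logrank_test(c(1, 2), c(0L, 0L), c("A", "B"))$degenerate)
  expect_error(logrank_test(c(1, 2), c(1L, 1L), c("A", "A")), "two groups")
})

test_that("log-rank is label-symmetric and grows with group separation", {
  skip_if_not_installed("survival")
  set.seed(22)
  n <- 60
  group <- rep(c("A", "B"), each = n / 2)
  stats <- sapply(c(0, 0.5, 1, 1.5), function(shift) {
    rate <- ifelse(group == "A", 0.1 * exp(shift), 0.1)
    time <- rexp(n, rate) + 0.01
    event <- rep(1L, n)
    s1 <- logrank_test(time, event, group)$statistic
    s2 <- logrank_test(time, event, rev(group))$statistic
    expect_equal(s1, s2, tolerance = 1e-12)
    sd_ref <- survival::survdiff(survival::Surv(time, event) ~ group)
    expect_equal(s1, unname(sd_ref$chisq), tolerance = 1e-9)
    s1
  })
  expect_true(all(diff(stats) > 0))
})

test_that("prognostic triage flags circle-specific survival signal only", {
  d <- small_design(seed = 31L, n_class = c(class1 = 60L, class2 = 60L,
                                            class3 = 0L),
                    n_prognostic = 2L, base_hazard = 2e-3)
  b <- simulate_annotation(d)
  sim <- simulate_counts(d, b)
  cl <- simulate_clinical(d, sim$truth)
  ct <- build_catalog(filter_junctions(sim$circ_evidence, 35L), 2L, 2L,
                      samples = cl$sample_id)
  lib <- stats::setNames(cl$library_size, cl$sample_id)
  cpm <- cpm_matrix(ct$counts, lib)
  lin <- cpm_matrix(linear_counterpart(sim$linear_evidence,
                                       ct$catalog[robust == TRUE],
                                       cl$sample_id), lib)
  gmap <- dt(circ_id = sim$truth$circles$circ_id,
             gene_id = sim$truth$circles$gene_id)
  tr <- prognostic_triage(cpm, lin, sim$gene_expression, gmap, cl, 0.1)
  # structural invariants
  expect_lte(sum(tr$independent_prognostic),
             sum(tr$q_circ < 0.1, na.rm = TRUE))
  expect_true(all(tr$q_circ >= tr$p_circ, na.rm = TRUE))
  expect_true(all(tr$independent_prognostic %in% c(TRUE, FALSE)))
})
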