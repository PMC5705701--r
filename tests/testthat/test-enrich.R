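# shared fixture: two genes, fully coding internal exons, one abundant and
# one non-abundant circle
enrich_fixture <- function() {
  exons <- rbind(
    exon_row("chr1", 0L, 100L, region = "UTR5"),
    exon_row("chr1", 1000L, 1100L, region = "CDS"),
    exon_row("chr1", 2000L, 2100L, region = "CDS"),
    exon_row("chr1", 3000L, 3100L, region = "UTR3"),
    exon_row("chr1", 10000L, 10100L, gene = "G2", tx = "G2.t1",
             region = "UTR5"),
    exon_row("chr1", 11000L, 11100L, gene = "G2", tx = "G2.t1",
             region = "CDS"),
    exon_row("chr1", 12000L, 12100L, gene = "G2", tx = "G2.t1",
             region = "UTR3"))
  catalog <- rbind(cat_row("chr1", 1000L, 2100L),   # contains 2 CDS exons
                   cat_row("chr1", 11000L, 11100L)) # contains 1 CDS exon
  list(exons = exons, catalog = catalog,
       abundant = catalog$circ_id[1])
}

test_that("coding exons require >= 90% CDS bases, boundary inclusive", {
  exons <- rbind(
    exon_row("chr1", 0L, 90L, region = "CDS"),      # 90 of 100 bp coding
    exon_row("chr1", 0L, 100L, region = "UTR3"),
    exon_row("chr1", 200L, 289L, region = "CDS"),   # 89 of 100 bp coding
    exon_row("chr1", 200L, 300L, region = "UTR3"))
  g <- build_coding_exon_groups(exons, cat_row("chr1", 90000L, 90100L),
                                character())
  expect_equal(nrow(g$exons), 1L)
  expect_equal(g$exons$start, 0L)
})

test_that("exon group assignment follows abundant > non-abundant > linear", {
  fx <- enrich_fixture()
  # the G2 CDS exon is inside both circles when we add a wide abundant circle
  wide <- cat_row("chr1", 10500L, 11600L)
  catalog <- rbind(fx$catalog, wide)
  g <- build_coding_exon_groups(fx$exons, catalog, wide$circ_id)
  g2exon <- g$exons[start == 11000L]
  expect_equal(g2exon$group, "abundant")  # abundant containment wins
  g_no <- build_coding_exon_groups(fx$exons, catalog, character())
  expect_equal(g_no$exons[start == 11000L]$group, "nonabundant")
  # disjointness and totality
  expect_true(all(g$exons$group %in% c("abundant", "nonabundant", "linear")))
  expect_equal(nrow(g$exons),
               length(unique(paste(g$exons$start, g$exons$end))))
})

test_that("containment fractions and merged-interval semantics", {
  fx <- enrich_fixture()
  g <- build_coding_exon_groups(fx$exons, fx$catalog, fx$abundant)
  # elements covering one of the abundant group's two exons
  sce <- dt(chrom = "chr1", start = 1010L, end = 1020L)
  cf <- containment_fractions(g, sce)
  expect_equal(cf$fractions[group == "abundant", fraction], 0.5)
  expect_equal(cf$fractions[group == "nonabundant", fraction], 0)
  # touching intervals merge to one 20 bp block, overlapping to 15 bp
  expect_equal(circprog:::merged_length(
    dt(chrom = "c", start = c(10L, 20L), end = c(20L, 30L))), 20L)
  expect_equal(circprog:::merged_length(
    dt(chrom = "c", start = c(10L, 15L), end = c(20L, 25L))), 15L)
})

test_that("SCE observed-vs-expected matches the direct formula", {
  fx <- enrich_fixture()
  g <- build_coding_exon_groups(fx$exons, fx$catalog, fx$abundant)
  # abundant group: exons [1000,1100) and [2000,2100) -> L_coding_exons 200
  sce <- dt(chrom = "chr1", start = 1000L, end = 1050L)  # 50 bp overlap
  oe <- sce_observed_vs_expected(g, sce)
  expect_equal(oe$expectation$L_coding_exons, 200L)
  expect_equal(oe$expectation$L_SCE, 50L)
  expect_equal(oe$expectation$P_SCE, 0.25)
  expect_equal(oe$table$observed_bp, 50L)
  expect_equal(oe$table$expected_bp, 0.25 * 200)
  # SCE covering everything -> observed equals the coding length
  all_sce <- dt(chrom = "chr1", start = 0L, end = 20000L)
  oe2 <- sce_observed_vs_expected(g, all_sce)
  expect_equal(oe2$table$observed_bp, oe2$table$l_coding)
  # no abundant coding exons -> error
  expect_error(
    sce_observed_vs_expected(
      build_coding_exon_groups(fx$exons, fx$catalog, character()), sce),
    "abundant")
})

test_that("miRNA observed-vs-expected applies length rules and exclusions", {
  fx <- enrich_fixture()
  cat <- rbind(fx$catalog[1L],
               cat_row("chr1", 100000L, 112000L),  # non-exonic, 12 kb
               cat_row("chr1", 200000L, 200500L))  # non-exonic, 500 bp
  sites <- dt(chrom = "chr1",
              start = c(1010L, 2050L, 200100L, 105000L),
              end = c(1018L, 2058L, 200108L, 105008L),
              mirna_id = "miR-001", experiment_id = "exp01")
  oe <- mirna_observed_vs_expected(cat, fx$exons, sites, 10000L)
  expect_false(cat$circ_id[2] %in% oe$table$circ_id)  # >= 10 kb non-exonic
  tab <- oe$table[match(c(cat$circ_id[1], cat$circ_id[3]), circ_id)]
  expect_equal(tab$length_bp, c(200L, 500L))  # exonic length vs span
  expect_equal(tab$observed_sites, c(2L, 1L))
  expect_equal(oe$expectation$P_miRNA, 3 / 700)
  expect_equal(tab$expected_sites, 3 / 700 * c(200, 500))
})

test_that("sponge statistic returns the maximal same-miRNA count", {
  fx <- enrich_fixture()
  sites <- dt(chrom = "chr1",
              start = c(1010L, 1030L, 2050L, 1060L),
              end = c(1018L, 1038L, 2058L, 1068L),
              mirna_id = c("miR-7", "miR-7", "miR-7", "miR-124"),
              experiment_id = c("brain", "brain", "brain", "HeLa"))
  sp <- sponge_statistic(fx$catalog[1L], fx$exons, sites)
  expect_equal(sp$best_mirna, "miR-7")
  expect_equal(sp$best_experiment, "brain")
  expect_equal(sp$max_same_mirna_sites, 3L)
  # no sites
  sp0 <- sponge_statistic(fx$catalog[2L], fx$exons, sites)
  expect_equal(sp0$max_same_mirna_sites, 0L)
  expect_true(is.na(sp0$best_mirna))
})

test_that("sponge statistic equals a brute-force recount on random sites", {
  set.seed(5)
  fx <- enrich_fixture()
  sites <- dt(chrom = "chr1",
              start = sample(900:2300, 200L, replace = TRUE))
  sites$end <- sites$start + 8L
  sites$mirna_id <- sample(sprintf("miR-%02d", 1:5), 200L, replace = TRUE)
  sites$experiment_id <- sample(c("e1", "e2"), 200L, replace = TRUE)
  sp <- sponge_statistic(fx$catalog[1L], fx$exons, sites)
  # brute force: sites overlapping the circle's two exons
  inexon <- sites[(sites$end > 1000L & sites$start < 1100L) |
                    (sites$end > 2000L & sites$start < 2100L), ]
  cnt <- table(paste(inexon$mirna_id, inexon$experiment_id))
  expect_equal(sp$max_same_mirna_sites, as.integer(max(cnt)))
})
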