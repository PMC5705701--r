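test_that("splice-site classification honours the region hierarchy", {
  exons <- rbind(exon_row("chr1", 100L, 200L, region = "CDS"),
                 exon_row("chr1", 198L, 300L, region = "UTR3"),
                 exon_row("chr1", 1000L, 1100L, region = "ncRNA"))
  sites <- dt(chrom = "chr1", pos = c(199L, 1050L, 5000L, 299L))
  lab <- classify_splice_site(sites, exons, 6L)
  expect_equal(lab, c("CDS", "ncRNA", "none", "UTR3"))
  expect_error(classify_splice_site(sites, exons, 5L), "even")
})

test_that("origin fractions sum to one and the chi-square matches by hand", {
  exons <- rbind(exon_row("chr1", 0L, 1000L, region = "CDS"),
                 exon_row("chr1", 5000L, 6000L, region = "ncRNA"))
  # 10 circular sites entirely in CDS, 10 linear sites entirely in ncRNA
  circ <- dt(chrom = "chr1", pos = seq(100L, 550L, by = 50L), reads = 10)
  lin <- dt(chrom = "chr1", pos = seq(5100L, 5550L, by = 50L), reads = 1)
  suppressWarnings(of <- origin_fractions(circ, lin, exons))
  expect_equal(sum(of$site_fractions$circular), 1, tolerance = 1e-9)
  expect_equal(sum(of$site_fractions$linear), 1, tolerance = 1e-9)
  expect_equal(of$site_fractions[region == "CDS", circular], 1)
  expect_equal(of$site_fractions[region == "ncRNA", linear], 1)
  # contingency table [[10,0],[0,10]]: Pearson statistic sum((O-E)^2/E) = 20
  expect_equal(of$chisq$statistic, 20, tolerance = 1e-9)
  # identical distributions give statistic 0
  suppressWarnings(of0 <- origin_fractions(circ, circ, exons))
  expect_equal(of0$chisq$statistic, 0, tolerance = 1e-12)
})

test_that("exon structure collapses overlaps and clips to the circle", {
  exons <- rbind(exon_row("chr1", 100L, 200L), exon_row("chr1", 150L, 250L),
                 exon_row("chr1", 400L, 500L))
  circ <- rbind(cat_row("chr1", 100L, 250L),    # two overlapping exons
                cat_row("chr1", 100L, 500L),    # union + a disjoint exon
                cat_row("chr1", 10000L, 11000L))
  es <- exon_structure(circ, exons)
  expect_equal(es$n_exons, c(1L, 2L, 0L))
  expect_equal(es$exonic_length, c(150L, 250L, 1000L))
  expect_equal(es$exonic, c(TRUE, TRUE, FALSE))
  expect_true(all(es$exonic_length <= circ$end - circ$start))
})

test_that("internal exon controls drop short transcripts and terminal exons", {
  ex3 <- rbind(exon_row("chr1", 0L, 10L, tx = "t3"),
               exon_row("chr1", 100L, 110L, tx = "t3"),
               exon_row("chr1", 200L, 210L, tx = "t3"))
  ex2 <- rbind(exon_row("chr1", 300L, 310L, tx = "t2"),
               exon_row("chr1", 400L, 410L, tx = "t2"))
  ex5 <- do.call(rbind, lapply(0:4, function(i)
    exon_row("chr1", 1000L + i * 100L, 1010L + i * 100L, tx = "t5")))
  out <- internal_exon_controls(rbind(ex3, ex2, ex5))
  expect_equal(nrow(out), 4L)
  expect_true(all(c(100L, 1100L, 1200L, 1300L) %in% out$start))
  expect_false(any(c(0L, 200L, 300L, 1000L, 1400L) %in% out$start))
})

test_that("inverted Alu pair search matches the worked example and rules", {
  feature <- dt(chrom = "chr1", start = 50000L, end = 51000L)
  alus <- dt(chrom = "chr1",
             start = c(49200L, 51300L, 48000L, 51200L),
             end = c(49500L, 51600L, 48300L, 51500L),
             strand = c("+", "-", "+", "-"),
             subfamily = c("AluS", "AluS", "AluJ", "AluY"))
  res <- nearest_inverted_alu_pair(feature, alus, 20000L)
  expect_equal(res$distance, 800)  # 500 upstream gap + 300 downstream gap
  expect_equal(res$subfamily, "AluS")
  # subfamily mismatch between the flanks -> no pair
  res2 <- nearest_inverted_alu_pair(feature, alus[3:4, ], 20000L)
  expect_true(is.na(res2$distance))
  # same strand -> no pair
  alus_same <- data.table::copy(alus[1:2, ]); alus_same$strand <- "+"
  expect_true(is.na(nearest_inverted_alu_pair(feature, alus_same)$distance))
  # Alu overlapping the feature edge clamps its gap to zero
  alus_ov <- dt(chrom = "chr1", start = c(49900L, 51100L),
                end = c(50100L, 51400L), strand = c("+", "-"),
                subfamily = "AluS")
  expect_equal(nearest_inverted_alu_pair(feature, alus_ov)$distance, 100)
})

test_that("Alu distances are invariant under coordinate mirroring", {
  set.seed(42)
  G <- 1000000L
  feats <- dt(chrom = "chrM", start = sort(sample.int(G - 2000L, 30L)))
  feats$end <- feats$start + 1000L
  alus <- dt(chrom = "chrM", start = sample.int(G - 300L, 400L))
  alus$end <- alus$start + 300L
  alus$strand <- sample(c("+", "-"), 400L, replace = TRUE)
  alus$subfamily <- sample(c("AluJ", "AluS", "AluY"), 400L, replace = TRUE)
  d1 <- nearest_inverted_alu_pair(feats, alus)$distance
  mirror <- function(x) {
    y <- data.table::copy(x)
    y$start2 <- G - x$end; y$end <- G - x$start; y$start <- y$start2
    y$start2 <- NULL
    if ("strand" %in% names(y))
      y$strand <- ifelse(y$strand == "+", "-", "+")
    y
  }
  d2 <- nearest_inverted_alu_pair(mirror(feats), mirror(alus))$distance
  expect_equal(d2, d1)
})

test_that("splice-site conservation averages the four core bases", {
  feat <- dt(chrom = "chr1", start = 100L, end = 200L)
  track <- dt(chrom = "chr1", start = c(98L, 99L, 200L, 201L),
              end = c(99L, 100L, 201L, 202L), score = c(2, 2, 4, 4))
  res <- splice_site_conservation(feat, track)
  expect_equal(res$mean_score, 3.0)
  expect_equal(res$n_scored, 4L)
  # uniform 6.15 track reproduces a 6.15 mean
  track2 <- data.table::copy(track); track2$score <- 6.15
  expect_equal(splice_site_conservation(feat, track2)$mean_score, 6.15)
  # missing positions are skipped; all-missing is flagged undefined
  res3 <- splice_site_conservation(feat, track[1:3, ])
  expect_equal(res3$n_scored, 3L)
  expect_equal(res3$mean_score, (2 + 2 + 4) / 3)
  far <- dt(chrom = "chr1", start = 5000L, end = 6000L)
  res4 <- splice_site_conservation(far, track)
  expect_equal(res4$n_scored, 0L)
  expect_true(is.na(res4$mean_score))
  # exonic-side alternative uses the first/last bases inside the feature
  track5 <- dt(chrom = "chr1", start = c(100L, 101L, 198L, 199L),
               end = c(101L, 102L, 199L, 200L), score = 7)
  expect_equal(splice_site_conservation(feat, track5,
                                        side = "exonic")$mean_score, 7)
})
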