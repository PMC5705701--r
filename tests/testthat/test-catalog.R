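test_that("anchor MAPQ filter is inclusive at the cutoff", {
  ev <- rbind(jrow("chr1", 10L, 100L, "+", "S1", 2L, 40L, 35L),
              jrow("chr1", 10L, 100L, "+", "S2", 2L, 40L, 34L),
              jrow("chr1", 200L, 300L, "+", "S1", 5L, 35L, 35L))
  out <- filter_junctions(ev, 35L)
  expect_equal(nrow(out), 2L)
  expect_true(all(pmin(out$mapq_anchor1, out$mapq_anchor2) >= 35L))
  expect_equal(nrow(filter_junctions(ev, 0L)), 3L)
  expect_error(filter_junctions(jrow("c", 1L, 2L, "+", "S", 1L, -1L, 40L), 35L),
               "negative")
  expect_error(filter_junctions(ev[, 1:6], 35L), "MAPQ")
})

test_that("catalog tiers follow the read/sample support rules", {
  ev <- rbind(
    jrow("chr1", 10L, 100L, "+", "S1", 2L),    # 2 reads, 1 sample
    jrow("chr1", 200L, 300L, "+", "S1", 2L),   # 2 reads in 2 samples
    jrow("chr1", 200L, 300L, "+", "S2", 2L),
    jrow("chr1", 400L, 500L, "+", "S1", 1L),   # 1 read in 5 samples
    jrow("chr1", 400L, 500L, "+", "S2", 1L),
    jrow("chr1", 400L, 500L, "+", "S3", 1L),
    jrow("chr1", 400L, 500L, "+", "S4", 1L),
    jrow("chr1", 400L, 500L, "+", "S5", 1L))
  res <- build_catalog(ev, min_reads = 2L, min_samples = 2L)
  cat <- res$catalog
  one <- cat[cat$start == 10L, ]
  expect_true(one$detected && !one$robust)
  two <- cat[cat$start == 200L, ]
  expect_true(two$detected && two$robust)
  low <- cat[cat$start == 400L, ]
  expect_true(!low$detected && !low$robust)
  expect_equal(rownames(res$counts), two$circ_id)
  # empty evidence is an empty catalog, not an error
  expect_equal(nrow(build_catalog(ev[0, ])$catalog), 0L)
})

test_that("abundance flags respect both thresholds at their boundaries", {
  mk <- function(n_expressed, max_count, n_samples = 400L) {
    v <- integer(n_samples)
    if (n_expressed > 0L) v[seq_len(n_expressed)] <- 2L
    v[1L] <- max_count
    v
  }
  m <- rbind(a = mk(30L, 20L), b = mk(29L, 100L), c = mk(400L, 19L))
  colnames(m) <- sprintf("S%03d", seq_len(ncol(m)))
  expect_equal(flag_abundant(m, 30L, 20L, expressed_min = 2L), "a")
})

test_that("linear counterparts sum reads at both splice sites", {
  cat <- cat_row("chr1", 1000L, 2000L)
  lin <- rbind(
    dt(chrom = "chr1", start = 500L, end = 1000L, strand = "+",
       sample_id = "S1", n_reads = 5L),                       # acceptor side
    dt(chrom = "chr1", start = 2000L, end = 2500L, strand = "+",
       sample_id = "S1", n_reads = 4L))                       # donor side
  m <- linear_counterpart(lin, cat, "S1")
  expect_equal(unname(m[1, 1]), 9L)
  # no reads at either site
  m0 <- linear_counterpart(lin[0, ], cat, "S1")
  expect_equal(unname(m0[1, 1]), 0L)
  # one record touching both sites counts once per site listing
  both <- dt(chrom = "chr1", start = 1000L, end = 2000L, strand = "+",
             sample_id = "S1", n_reads = 3L)
  expect_equal(unname(linear_counterpart(both, cat, "S1")[1, 1]), 6L)
})

test_that("circ-to-lin ratios follow the pseudocount formula", {
  c_m <- matrix(c(0, 19, 0), 3, 1); l_m <- matrix(c(0, 9, 99), 3, 1)
  r <- circ_to_lin(c_m, l_m)
  expect_equal(as.numeric(r), c(1.0, 2.0, 0.01))
  expect_true(all(r > 0))
  expect_equal(as.logical(r > 1), as.logical(c_m > l_m))
  expect_error(circ_to_lin(c_m, l_m[1:2, , drop = FALSE]), "mismatch")
})

test_that("CPM uses library sizes and round-trips to raw counts", {
  counts <- matrix(c(10L, 0L, 5L, 2L), 2, 2,
                   dimnames = list(c("a", "b"), c("S1", "S2")))
  lib <- c(S1 = 2e6, S2 = 4e6)
  cpm <- cpm_matrix(counts, lib)
  expect_equal(cpm["a", "S1"], 10 / 2e6 * 1e6)
  back <- sweep(cpm, 2, lib, "*") / 1e6
  expect_equal(back, counts + 0)   # exact round trip
  expect_warning(cpm_matrix(counts, NULL), "column sums")
  expect_error(cpm_matrix(counts, c(S1 = 1e6)), "missing")
})

test_that("per-gene profiles count distinct circles and reads per gene", {
  exons <- rbind(exon_row("chr1", 0L, 10000L, gene = "GA"),
                 exon_row("chr1", 20000L, 30000L, gene = "GB"),
                 exon_row("chr1", 9000L, 21000L, gene = "GC"))
  cat <- rbind(cat_row("chr1", 100L, 400L), cat_row("chr1", 500L, 900L),
               cat_row("chr1", 1000L, 2000L),
               cat_row("chr1", 9500L, 20500L),   # overlaps GA, GB and GC
               cat_row("chr1", 50000L, 60000L))  # intergenic
  counts <- matrix(10L, nrow(cat), 2,
                   dimnames = list(cat$circ_id, c("S1", "S2")))
  prof <- per_gene_profile(cat, counts, exons)
  ga <- prof$genes[gene_id == "GA"]
  expect_equal(ga$n_distinct_circ, 4L)   # three inside + the spanning one
  expect_equal(ga$total_circ_reads, 80)
  expect_true("intergenic" %in% prof$genes$gene_id)
  amb <- prof$assignment[circ_id == cat$circ_id[4]]
  expect_setequal(amb$gene_id, c("GA", "GB", "GC"))
  expect_true(all(amb$ambiguous))
  # brute-force overlap check of every assignment
  for (k in seq_len(nrow(prof$assignment))) {
    row <- prof$assignment[k]
    if (row$gene_id == "intergenic") next
    ci <- cat[cat$circ_id == row$circ_id, ]
    ge <- exons[exons$gene_id == row$gene_id, ]
    expect_true(any(ci$start < ge$end & ge$start < ci$end))
  }
})
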