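options(circprog.verbose = FALSE)

# data.table shorthand used throughout the suite
dt <- data.table::data.table

# junction evidence rows
jrow <- function(chrom, start, end, strand, sample, reads,
                 mq1 = 40L, mq2 = 40L) {
  dt(chrom = chrom, start = start, end = end, strand = strand,
     sample_id = sample, n_reads = reads,
     mapq_anchor1 = mq1, mapq_anchor2 = mq2)
}

# minimal exon annotation table
exon_row <- function(chrom, start, end, strand = "+", gene = "G1",
                     tx = "G1.t1", region = "CDS") {
  dt(chrom = chrom, start = start, end = end, strand = strand,
     gene_id = gene, transcript_id = tx, region = region)
}

# catalog row keyed like build_catalog output
cat_row <- function(chrom, start, end, strand = "+") {
  dt(circ_id = paste0(chrom, ":", start, "-", end, ":", strand),
     chrom = chrom, start = start, end = end, strand = strand)
}

# small cohort design used by several pipeline-level tests
small_design <- function(seed = 11L, ...) {
  args <- list(n_class = c(class1 = 25L, class2 = 35L, class3 = 15L),
               n_genes = 50L, n_planted_enriched = 15L,
               n_prognostic = 2L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_design, args)
}

# brute-force oracle for the inverted Alu pair search: exhaustive pair scan
alu_pair_bruteforce <- function(features, alus, window_bp = 20000L) {
  vapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    up <- alus[alus$chrom == f$chrom &
                 alus$end > f$start - window_bp & alus$start < f$start, ]
    dn <- alus[alus$chrom == f$chrom &
                 alus$end > f$end & alus$start < f$end + window_bp, ]
    best <- Inf
    if (nrow(up) && nrow(dn)) {
      for (a in seq_len(nrow(up))) for (b in seq_len(nrow(dn))) {
        if (is.na(up$subfamily[a]) || is.na(dn$subfamily[b])) next
        if (up$subfamily[a] != dn$subfamily[b]) next
        if (up$strand[a] == dn$strand[b]) next
        d <- max(0L, f$start - up$end[a]) + max(0L, dn$start[b] - f$end)
        if (d < best) best <- d
      }
    }
    if (is.finite(best)) as.numeric(best) else NA_real_
  }, numeric(1L))
}

# naive step-up BH oracle
bh_naive <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    idx <- o[i]
    val <- min(prev, p[idx] * n / i)
    q[idx] <- val
    prev <- val
  }
  q
}

# full-enumeration two-sided rank-sum p oracle (no ties assumed)
ranksum_enum_p <- function(x, y) {
  vals <- c(x, y)
  n <- length(x)
  r <- rank(vals)
  obs <- sum(r[seq_len(n)])
  combs <- utils::combn(length(vals), n)
  sums <- colSums(matrix(r[combs], nrow = n))
  mu <- n * (length(vals) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}
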