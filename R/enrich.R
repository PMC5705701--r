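# Synonymous-constraint-element and miRNA-target-site enrichment analyses
# over hierarchically assigned coding exon groups, plus the same-miRNA
# "sponge" statistic.

# Collapsed (union) exonic regions clipped to each circRNA span; non-exonic
# circles fall back to their genomic span. Returns one row per region.
circ_regions <- function(catalog, exons) {
  es <- exon_structure(catalog, exons)
  out <- vector("list", 2L)
  cg <- gr(catalog)
  eg <- gr(exons)
  ov <- GenomicRanges::findOverlaps(cg, eg, ignore.strand = TRUE)
  if (length(ov)) {
    clipped <- IRanges::pintersect(eg[S4Vectors::subjectHits(ov)],
                                   cg[S4Vectors::queryHits(ov)],
                                   ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(ov)
    grl <- GenomicRanges::reduce(
      GenomicRanges::split(GenomicRanges::granges(clipped),
                           factor(qi, levels = seq_len(nrow(catalog)))),
      ignore.strand = TRUE)
    flat <- unlist(grl, use.names = FALSE)
    reg <- dt_from_gr(flat)
    reg$circ_id <- rep(catalog$circ_id, S4Vectors::elementNROWS(grl))
    out[[1L]] <- reg[, list(circ_id, chrom, start, end)]
  }
  nonex <- !es$exonic
  if (any(nonex))
    out[[2L]] <- data.table(circ_id = catalog$circ_id[nonex],
                            chrom = catalog$chrom[nonex],
                            start = catalog$start[nonex],
                            end = catalog$end[nonex])
  reg <- rbindlist(out[!vapply(out, is.null, logical(1L))])
  reg <- merge(reg, es[, list(circ_id, exonic, exonic_length)],
               by = "circ_id", sort = FALSE)
  reg[]
}

#' Hierarchical coding exon groups
#'
#' Collapses the exon annotation (union of overlapping exons), defines coding
#' exons as collapsed exons with at least `min_cds_frac` of their bases in
#' CDS annotation, and assigns each coding exon to exactly one group by
#' circRNA containment with precedence abundant > non-abundant > linear-only:
#' an exon is "circularized" by a circle when it lies fully within the
#' circle's backsplice span.
#'
#' @param exons region-labelled exon annotation.
#' @param catalog robust-tier catalog.
#' @param abundant_ids circ_ids in the abundant tier.
#' @param min_cds_frac minimum CDS fraction for a coding exon (default 0.9,
#'   boundary inclusive).
#' @return list with `exons` (collapsed coding exons + `group`) and
#'   `abundant_map` (circ_id to contained coding-exon row).
#' @export
build_coding_exon_groups <- function(exons, catalog, abundant_ids,
                                     min_cds_frac = 0.9) {
  coll <- GenomicRanges::reduce(gr(exons), ignore.strand = TRUE)
  cds <- GenomicRanges::reduce(gr(exons[exons$region == "CDS"]),
                               ignore.strand = TRUE)
  cds_bp <- rep(0L, length(coll))
  ov <- GenomicRanges::findOverlaps(coll, cds, ignore.strand = TRUE)
  if (length(ov)) {
    w <- IRanges::width(IRanges::pintersect(coll[S4Vectors::queryHits(ov)],
                                            cds[S4Vectors::subjectHits(ov)]))
    agg <- rowsum(w, S4Vectors::queryHits(ov))
    cds_bp[as.integer(rownames(agg))] <- agg[, 1L]
  }
  coding <- cds_bp / IRanges::width(coll) >= min_cds_frac
  ce <- dt_from_gr(coll[coding])
  ce[, exon_idx := .I]
  if (nrow(ce) == 0L)
    return(list(exons = cbind(ce, data.table(group = character())),
                abundant_map = data.table(circ_id = character(),
                                          exon_idx = integer())))
  # containment: exon fully within circle span
  cov <- GenomicRanges::findOverlaps(gr(ce), gr(catalog),
                                     ignore.strand = TRUE, type = "within")
  cmap <- data.table(exon_idx = S4Vectors::queryHits(cov),
                     circ_id = catalog$circ_id[S4Vectors::subjectHits(cov)])
  cmap[, abundant := circ_id %in% abundant_ids]
  grp <- rep("linear", nrow(ce))
  grp[unique(cmap$exon_idx[!cmap$abundant])] <- "nonabundant"
  grp[unique(cmap$exon_idx[cmap$abundant])] <- "abundant"
  ce$group <- grp
  list(exons = ce[],
       abundant_map = cmap[abundant == TRUE, list(circ_id, exon_idx)])
}

# overlap bp of each 0-based interval row in `x` with the merged element set
overlap_bp <- function(x, elements) {
  out <- rep(0L, nrow(x))
  if (nrow(x) == 0L || nrow(elements) == 0L) return(out)
  mg <- GenomicRanges::reduce(gr(elements), ignore.strand = TRUE)
  xg <- gr(x)
  ov <- GenomicRanges::findOverlaps(xg, mg, ignore.strand = TRUE)
  if (length(ov)) {
    w <- IRanges::width(IRanges::pintersect(xg[S4Vectors::queryHits(ov)],
                                            mg[S4Vectors::subjectHits(ov)]))
    agg <- rowsum(w, S4Vectors::queryHits(ov))
    out[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out
}

#' Element containment fractions per coding exon group
#'
#' For merged element intervals (SCEs or unioned miRNA target regions),
#' reports per group the fraction of exons containing at least 1 bp of
#' element, pairwise Pearson chi-square tests (no continuity correction) on
#' the containment counts, and per-exon coverage (overlap bp / exon bp)
#' compared pairwise by Wilcoxon rank-sum.
#'
#' @param groups result of [build_coding_exon_groups()].
#' @param elements element interval table (merged internally).
#' @return list `fractions`, `pairwise`, `coverage`.
#' @export
containment_fractions <- function(groups, elements) {
  ex <- copy(groups$exons)
  ex[, ov_bp := overlap_bp(ex, elements)]
  ex[, len := end - start]
  ex[, coverage := ov_bp / len]
  ex[, contains := ov_bp > 0L]
  frac <- ex[, list(n = .N, n_overlapping = sum(contains),
                    fraction = mean(contains),
                    mean_coverage = mean(coverage)), by = "group"]
  setorder(frac, group)
  gs <- frac$group[frac$n > 0L]
  pw <- NULL
  if (length(gs) >= 2L) {
    cmb <- utils::combn(gs, 2L)
    pw <- data.table(group1 = cmb[1L, ], group2 = cmb[2L, ],
                     chisq_p = NA_real_, wilcox_p = NA_real_)
    for (i in seq_len(ncol(cmb))) {
      a <- ex[group == cmb[1L, i]]
      b <- ex[group == cmb[2L, i]]
      tab <- rbind(c(sum(a$contains), sum(!a$contains)),
                   c(sum(b$contains), sum(!b$contains)))
      if (all(colSums(tab) > 0))
        pw$chisq_p[i] <- suppressWarnings(
          stats::chisq.test(tab, correct = FALSE)$p.value)
      pw$wilcox_p[i] <- suppressWarnings(
        stats::wilcox.test(a$coverage, b$coverage)$p.value)
    }
  }
  list(fractions = frac[], pairwise = pw,
       coverage = ex[, list(chrom, start, end, group, ov_bp, len, coverage)])
}

#' Observed versus expected SCE overlap per abundant circRNA
#'
#' The per-bp SCE probability is the total merged-SCE overlap of the unique
#' abundant circularized coding exons divided by their total length; each
#' circle's expected overlap is that probability times the length of its own
#' circularized coding exons, compared with the observed overlap.
#'
#' @param groups result of [build_coding_exon_groups()].
#' @param sce SCE interval table.
#' @return list with `table` (circ_id, l_coding, observed_bp, expected_bp)
#'   and `expectation` (P_SCE, L_SCE, L_coding_exons).
#' @export
sce_observed_vs_expected <- function(groups, sce) {
  abex <- groups$exons[group == "abundant"]
  L_coding_exons <- sum(abex$end - abex$start)
  if (L_coding_exons == 0L)
    stop("no abundant circularized coding exons; cannot form SCE expectation")
  abex_ov <- overlap_bp(abex, sce)
  L_SCE <- sum(abex_ov)
  P_SCE <- L_SCE / L_coding_exons
  ovmap <- data.table(exon_idx = abex$exon_idx, len = abex$end - abex$start,
                      ov = abex_ov)
  m <- merge(groups$abundant_map, ovmap, by = "exon_idx")
  tab <- m[, list(l_coding = sum(len), observed_bp = sum(ov)), by = "circ_id"]
  tab[, expected_bp := P_SCE * l_coding]
  setorder(tab, circ_id)
  list(table = tab[],
       expectation = list(P_SCE = P_SCE, L_SCE = L_SCE,
                          L_coding_exons = L_coding_exons))
}

#' Observed versus expected miRNA target sites per abundant circRNA
#'
#' Counts unmerged AGO-CLIP sites overlapping each included circle's region:
#' exonic circles use their collapsed exonic regions (introns spliced out),
#' non-exonic circles their genomic span, and non-exonic circles of at least
#' `max_len_bp` are excluded. The per-bp site rate is the total counted
#' sites over the total included length; expectations are rate times length.
#'
#' @param catalog catalog restricted upstream to the abundant set.
#' @param exons exon annotation.
#' @param sites miRNA site table (rows counted as-is, unmerged).
#' @param max_len_bp exclusion size for non-exonic circles (default 10 kb).
#' @return list with `table` (circ_id, length_bp, observed_sites,
#'   expected_sites, exonic) and `expectation` (P_miRNA, T_miRNAs, L_exons).
#' @export
mirna_observed_vs_expected <- function(catalog, exons, sites,
                                       max_len_bp = 10000L) {
  reg <- circ_regions(catalog, exons)
  reg[, span := end - start]
  drop <- reg[exonic == FALSE & (end - start) >= max_len_bp, unique(circ_id)]
  reg <- reg[!circ_id %in% drop]
  if (nrow(reg) == 0L)
    return(list(table = data.table(circ_id = character(),
                                   length_bp = integer(),
                                   observed_sites = integer(),
                                   expected_sites = numeric(),
                                   exonic = logical()),
                expectation = list(P_miRNA = NA_real_, T_miRNAs = 0L,
                                   L_exons = 0L)))
  sg <- gr(as.data.table(sites))
  ov <- GenomicRanges::findOverlaps(gr(reg), sg, ignore.strand = TRUE)
  # a site may straddle two regions of one circle; count once per circle
  hits <- unique(data.table(circ_id = reg$circ_id[S4Vectors::queryHits(ov)],
                            site = S4Vectors::subjectHits(ov)))
  cnt <- hits[, list(observed_sites = .N), by = "circ_id"]
  tab <- reg[, list(length_bp = sum(end - start), exonic = exonic[1L]),
             by = "circ_id"]
  tab <- merge(tab, cnt, by = "circ_id", all.x = TRUE)
  tab[is.na(observed_sites), observed_sites := 0L]
  T_miRNAs <- sum(tab$observed_sites)
  L_exons <- sum(tab$length_bp)
  P_miRNA <- T_miRNAs / L_exons
  tab[, expected_sites := P_miRNA * length_bp]
  setorder(tab, circ_id)
  list(table = tab[],
       expectation = list(P_miRNA = P_miRNA, T_miRNAs = T_miRNAs,
                          L_exons = L_exons))
}

#' Same-miRNA sponge statistic
#'
#' For each circRNA, counts target sites per (miRNA, experiment) pair within
#' the circle's region and returns the maximal count with its labels — the
#' signature of a miRNA sponge is many sites for one miRNA. Ties are broken
#' lexicographically by miRNA id, then experiment id.
#'
#' @param catalog catalog of circles to score.
#' @param exons exon annotation (defines exonic regions).
#' @param sites miRNA site table with `mirna_id` and `experiment_id`.
#' @return data.table: circ_id, best_mirna, best_experiment,
#'   max_same_mirna_sites (0 and `NA` labels when no site overlaps).
#' @export
sponge_statistic <- function(catalog, exons, sites) {
  reg <- circ_regions(catalog, exons)
  sites <- as.data.table(sites)
  out <- data.table(circ_id = catalog$circ_id, best_mirna = NA_character_,
                    best_experiment = NA_character_,
                    max_same_mirna_sites = 0L)
  if (nrow(sites) == 0L || nrow(reg) == 0L) return(out)
  ov <- GenomicRanges::findOverlaps(gr(reg), gr(sites), ignore.strand = TRUE)
  hits <- unique(data.table(circ_id = reg$circ_id[S4Vectors::queryHits(ov)],
                            site = S4Vectors::subjectHits(ov)))
  if (nrow(hits) == 0L) return(out)
  hits[, `:=`(mirna_id = sites$mirna_id[site],
              experiment_id = sites$experiment_id[site])]
  cnt <- hits[, list(n = .N), by = c("circ_id", "mirna_id", "experiment_id")]
  best <- cnt[order(-n, mirna_id, experiment_id), .SD[1L], by = "circ_id"]
  idx <- match(best$circ_id, out$circ_id)
  out$best_mirna[idx] <- best$mirna_id
  out$best_experiment[idx] <- best$experiment_id
  out$max_same_mirna_sites[idx] <- best$n
  out[]
}
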