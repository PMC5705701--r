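# Genomic annotation of circRNAs and control exon sets: origin hierarchy,
# exon structure, inverted homologous Alu repeat pairs, splice-site
# conservation.

REGION_PRIORITY <- c(CDS = 1L, UTR3 = 2L, UTR5 = 3L, ncRNA = 4L)

#' Assign genomic origin to splice sites
#'
#' Intersects a symmetric window around each splice-site position with the
#' region-labelled exon annotation and returns the highest-priority label
#' overlapped, under the fixed hierarchy CDS > 3'-UTR > 5'-UTR > ncRNA;
#' `"none"` when the window overlaps no annotated exon.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based position of
#'   the splice site).
#' @param exons exon annotation table with `region` labels.
#' @param window_bp even window width centred on the site (default 6).
#' @return character vector of labels, one per site.
#' @export
classify_splice_site <- function(sites, exons, window_bp = 6L) {
  if (window_bp %% 2L != 0L) stop("window_bp must be even")
  sites <- as.data.table(sites)
  if (nrow(sites) == 0L) return(character())
  half <- window_bp %/% 2L
  win <- data.table(chrom = sites$chrom,
                    start = pmax(0L, sites$pos - half),
                    end = sites$pos + half)
  ov <- GenomicRanges::findOverlaps(gr(win), gr(exons), ignore.strand = TRUE)
  lab <- rep("none", nrow(sites))
  if (length(ov)) {
    hits <- data.table(q = S4Vectors::queryHits(ov),
                       pri = REGION_PRIORITY[exons$region[S4Vectors::subjectHits(ov)]])
    best <- hits[, list(pri = min(pri)), by = "q"]
    lab[best$q] <- names(REGION_PRIORITY)[best$pri]
  }
  lab
}

#' Genomic origin of circular versus linear splicing
#'
#' Classifies every circular and linear splice site, and reports two
#' contrasts: the fraction of splice sites per region class and the fraction
#' of reads (each site weighted by the total reads using it across samples).
#' The circular and linear site-count distributions are compared with a
#' Pearson chi-square test (no continuity correction); region classes with
#' zero total sites in both sets are excluded from the test with a warning.
#'
#' @param circ_sites data.table with `chrom`, `pos`, `reads`.
#' @param linear_sites data.table with `chrom`, `pos`, `reads`.
#' @param exons region-labelled exon annotation.
#' @param window_bp origin window width.
#' @return list with `site_fractions`, `read_fractions` (data.tables with
#'   one row per region class) and `chisq` (htest-like list with `statistic`,
#'   `p_value`).
#' @export
origin_fractions <- function(circ_sites, linear_sites, exons,
                             window_bp = 6L) {
  circ_sites <- as.data.table(circ_sites)
  linear_sites <- as.data.table(linear_sites)
  labs <- c(names(REGION_PRIORITY), "none")
  lc <- factor(classify_splice_site(circ_sites, exons, window_bp), levels = labs)
  ll <- factor(classify_splice_site(linear_sites, exons, window_bp), levels = labs)
  site_tab <- rbind(circular = table(lc), linear = table(ll))
  rw <- function(lab, reads) {
    s <- tapply(reads, lab, sum, default = 0)
    s[is.na(s)] <- 0
    s
  }
  read_tab <- rbind(circular = rw(lc, circ_sites$reads),
                    linear = rw(ll, linear_sites$reads))
  frac <- function(tab) {
    data.table(region = colnames(tab),
               circular = as.numeric(tab["circular", ] /
                                       max(1, sum(tab["circular", ]))),
               linear = as.numeric(tab["linear", ] /
                                     max(1, sum(tab["linear", ]))))
  }
  keep <- colSums(site_tab) > 0
  if (any(!keep))
    warning("region class(es) with zero sites excluded from chi-square: ",
            paste(colnames(site_tab)[!keep], collapse = ", "))
  test_tab <- site_tab[, keep, drop = FALSE]
  chisq <- if (ncol(test_tab) >= 2L && all(rowSums(test_tab) > 0)) {
    ht <- suppressWarnings(stats::chisq.test(test_tab, correct = FALSE))
    list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
         df = unname(ht$parameter))
  } else if (ncol(test_tab) == 1L && all(rowSums(test_tab) > 0)) {
    # both site sets fall in a single region class: identical distributions
    list(statistic = 0, p_value = 1, df = 0L)
  } else list(statistic = NA_real_, p_value = NA_real_, df = NA_real_)
  list(site_fractions = frac(site_tab), read_fractions = frac(read_tab),
       chisq = chisq)
}

#' Exon structure of circRNAs
#'
#' Clips annotated exons to each circRNA's backsplice span, collapses
#' overlapping exons (union) and reports the exon count and total exonic
#' length; introns are assumed spliced out. CircRNAs overlapping no exon are
#' flagged non-exonic and assigned their genomic span length.
#'
#' @param catalog catalog data.table (`circ_id`, coordinates).
#' @param exons exon annotation table.
#' @return data.table: `circ_id`, `n_exons`, `exonic_length`, `exonic`.
#' @export
exon_structure <- function(catalog, exons) {
  out <- data.table(circ_id = catalog$circ_id, n_exons = 0L,
                    exonic_length = catalog$end - catalog$start,
                    exonic = FALSE)
  if (nrow(catalog) == 0L || nrow(exons) == 0L) return(out)
  cg <- gr(catalog)
  eg <- gr(exons)
  ov <- GenomicRanges::findOverlaps(cg, eg, ignore.strand = TRUE)
  if (length(ov)) {
    clipped <- IRanges::pintersect(eg[S4Vectors::subjectHits(ov)],
                                   cg[S4Vectors::queryHits(ov)],
                                   ignore.strand = TRUE)
    grl <- GenomicRanges::reduce(
      GenomicRanges::split(GenomicRanges::granges(clipped),
                           factor(S4Vectors::queryHits(ov),
                                  levels = seq_len(nrow(catalog)))),
      ignore.strand = TRUE)
    n <- S4Vectors::elementNROWS(grl)
    len <- sum(IRanges::width(grl))
    hit <- n > 0L
    out$n_exons[hit] <- n[hit]
    out$exonic_length[hit] <- len[hit]
    out$exonic[hit] <- TRUE
  }
  out[]
}

#' Internal spliced exons (control set)
#'
#' From the transcript-grouped exon annotation, removes all transcripts with
#' fewer than three exons and then strips every transcript's first and last
#' exon, returning the unique internal spliced exons. These serve as the
#' linear-splicing control set for Alu and conservation contrasts.
#'
#' @param exons exon annotation table with `transcript_id`.
#' @return data.table of unique internal exon intervals.
#' @export
internal_exon_controls <- function(exons) {
  ex <- as.data.table(exons)
  ex <- ex[, if (.N >= 3L) .SD[order(start)][2:(.N - 1L)],
           by = "transcript_id"]
  if (nrow(ex) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  out <- unique(ex[, list(chrom, start, end, strand)])
  setorder(out, chrom, start, end, strand)
  out[]
}

#' Closest inverted homologous Alu pair flanking each feature
#'
#' Searches the two flanks (`window_bp` each side, the feature itself
#' excluded) for the pair of Alu repeats that (i) share a subfamily class
#' (AluJ/AluS/AluY), (ii) lie on opposite strands, and (iii) sit one in each
#' flank, minimising the summed gap
#' `max(0, start - upstream_end) + max(0, downstream_start - end)` — the
#' distance between the pair omitting the feature's own span. An Alu belongs
#' to a flank when at least 1 bp falls inside it; Alus overlapping the
#' feature edge contribute a clamped gap of 0.
#'
#' @param features data.table with `chrom`, `start`, `end` (any extra
#'   columns, e.g. an id, are carried through).
#' @param alus Alu table with `strand` and `subfamily`.
#' @param window_bp flank width (default 20 kb).
#' @return data.table, one row per feature: pair coordinates, subfamily and
#'   `distance` (`NA` when no valid pair exists).
#' @export
nearest_inverted_alu_pair <- function(features, alus, window_bp = 20000L) {
  features <- as.data.table(features)
  n <- nrow(features)
  res <- data.table(distance = rep(NA_real_, n),
                    subfamily = NA_character_,
                    up_start = NA_integer_, up_end = NA_integer_,
                    up_strand = NA_character_,
                    down_start = NA_integer_, down_end = NA_integer_,
                    down_strand = NA_character_)
  if (n == 0L || nrow(alus) == 0L) return(cbind(features, res))
  al <- as.data.table(alus)[!is.na(subfamily) & strand %in% c("+", "-")]
  if (nrow(al) == 0L) return(cbind(features, res))

  flank_hits <- function(fl) {
    ov <- GenomicRanges::findOverlaps(gr(fl), gr(al), ignore.strand = TRUE)
    data.table(f = S4Vectors::queryHits(ov), a = S4Vectors::subjectHits(ov))
  }
  up <- flank_hits(data.table(chrom = features$chrom,
                              start = pmax(0L, features$start - window_bp),
                              end = features$start))
  dn <- flank_hits(data.table(chrom = features$chrom,
                              start = features$end,
                              end = features$end + window_bp))
  if (nrow(up) == 0L || nrow(dn) == 0L) return(cbind(features, res))
  up[, `:=`(gap = pmax(0L, features$start[f] - al$end[a]),
            sub = al$subfamily[a], str = al$strand[a])]
  dn[, `:=`(gap = pmax(0L, al$start[a] - features$end[f]),
            sub = al$subfamily[a], str = al$strand[a])]
  # minimal gap per (feature, subfamily, strand), with the achieving Alu
  best_up <- up[order(gap, a), .SD[1L], by = c("f", "sub", "str")]
  setnames(best_up, c("a", "gap", "str"), c("a_up", "gap_up", "up_str"))
  best_dn <- dn[order(gap, a), .SD[1L], by = c("f", "sub", "str")]
  setnames(best_dn, c("a", "gap", "str"), c("a_dn", "gap_dn", "dn_str"))
  best_dn[, up_str := ifelse(dn_str == "+", "-", "+")]
  pairs <- merge(best_up, best_dn, by = c("f", "sub", "up_str"),
                 allow.cartesian = TRUE)
  if (nrow(pairs) == 0L) return(cbind(features, res))
  pairs[, total := gap_up + gap_dn]
  win <- pairs[order(total, sub, up_str), .SD[1L], by = "f"]
  res$distance[win$f] <- as.numeric(win$total)
  res$subfamily[win$f] <- win$sub
  res$up_start[win$f] <- al$start[win$a_up]
  res$up_end[win$f] <- al$end[win$a_up]
  res$up_strand[win$f] <- win$up_str
  res$down_start[win$f] <- al$start[win$a_dn]
  res$down_end[win$f] <- al$end[win$a_dn]
  res$down_strand[win$f] <- win$dn_str
  cbind(features, res)
}

#' Conservation of the core splice-site bases
#'
#' Averages the per-base conservation scores (e.g. PhyloP) of the four core
#' nucleotides involved in the two splice sites of each feature: the two
#' bases immediately upstream of the feature start and the two immediately
#' downstream of its end (the intronic dinucleotides of the acceptor and
#' donor). Positions absent from the track are treated as missing and
#' skipped; features with no scored position are flagged undefined.
#'
#' @param features data.table with `chrom`, `start`, `end`.
#' @param track conservation track as a GRanges with a `score` column
#'   (bedGraph), or a data.table with `chrom`, `start`, `end`, `score`.
#' @param side `"intronic"` (default: bases outside the feature) or
#'   `"exonic"` (first/last two bases inside it).
#' @return data.table: four per-base scores, `mean_score`, `n_scored`.
#' @export
splice_site_conservation <- function(features, track,
                                     side = c("intronic", "exonic")) {
  side <- match.arg(side)
  features <- as.data.table(features)
  n <- nrow(features)
  if (!inherits(track, "GRanges")) {
    track <- as.data.table(track)
    track <- gr(track, keep = "score")
  }
  pos <- if (side == "intronic") {
    cbind(features$start - 2L, features$start - 1L,
          features$end, features$end + 1L)
  } else {
    cbind(features$start, features$start + 1L,
          features$end - 2L, features$end - 1L)
  }
  scores <- matrix(NA_real_, n, 4L)
  q <- data.table(chrom = rep(features$chrom, 4L),
                  start = as.integer(pos), end = as.integer(pos) + 1L)
  valid <- q$start >= 0L
  qg <- gr(q[valid])
  ov <- GenomicRanges::findOverlaps(qg, track, ignore.strand = TRUE,
                                    select = "first")
  sc <- rep(NA_real_, nrow(q))
  sc[valid] <- S4Vectors::mcols(track)$score[ov]
  scores[] <- sc
  out <- data.table(score_up2 = scores[, 1L], score_up1 = scores[, 2L],
                    score_down1 = scores[, 3L], score_down2 = scores[, 4L])
  out$n_scored <- rowSums(!is.na(scores))
  out$mean_score <- ifelse(out$n_scored > 0, rowMeans(scores, na.rm = TRUE),
                           NA_real_)
  cbind(features[, intersect(c("circ_id", "chrom", "start", "end"),
                             names(features)), with = FALSE], out)
}
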