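# Catalog construction and quantification from backsplice junction evidence.
# A circRNA is keyed by (chrom, start, end, strand) of its backsplice; strand
# "." is kept as a distinct key. Catalog ordering is lexicographic in
# (chrom, start, end, strand) so outputs are reproducible.

log_stage <- function(...) {
  if (isTRUE(getOption("circprog.verbose", TRUE))) message(...)
}

#' Filter backsplice evidence on anchor mapping quality
#'
#' Retains records whose two anchor alignments both reach the MAPQ cutoff
#' (inclusive). Records lacking the quality columns are assumed pre-filtered
#' and pass only when `allow_missing_mapq` is set.
#'
#' @param evidence junction evidence from [read_junction_table()].
#' @param mapq_cutoff minimum anchor MAPQ (applied to both anchors, `>=`).
#' @param allow_missing_mapq pass records without quality fields.
#' @return filtered evidence data.table.
#' @export
filter_junctions <- function(evidence, mapq_cutoff = 35L,
                             allow_missing_mapq = FALSE) {
  evidence <- as.data.table(evidence)
  has_cols <- all(c("mapq_anchor1", "mapq_anchor2") %in% names(evidence))
  if (!has_cols) {
    if (!allow_missing_mapq)
      stop("evidence has no anchor MAPQ columns; set allow_missing_mapq ",
           "if the input was pre-filtered")
    return(evidence)
  }
  if (nrow(evidence) &&
      any(stats::na.omit(c(evidence$mapq_anchor1, evidence$mapq_anchor2)) < 0))
    stop("negative anchor MAPQ encountered")
  ok_na <- is.na(evidence$mapq_anchor1) & is.na(evidence$mapq_anchor2) &
    allow_missing_mapq
  keep <- (!is.na(evidence$mapq_anchor1) & !is.na(evidence$mapq_anchor2) &
             evidence$mapq_anchor1 >= mapq_cutoff &
             evidence$mapq_anchor2 >= mapq_cutoff) | ok_na
  out <- evidence[keep]
  log_stage("filter_junctions: ", nrow(evidence), " -> ", nrow(out),
            " records at MAPQ >= ", mapq_cutoff)
  out
}

#' Build the circRNA catalog and raw count matrix
#'
#' Unique backsplice keys are tiered: a circRNA is *detected* when supported
#' by at least `min_reads` reads in at least one sample, and *robust* when
#' supported by at least `min_reads` reads in at least `min_samples`
#' different samples. The count matrix covers the robust tier by default (the
#' set carried through all downstream analyses).
#'
#' @param evidence filtered circular junction evidence.
#' @param min_reads per-sample read support threshold.
#' @param min_samples number of supporting samples for the robust tier.
#' @param samples optional character vector fixing the sample (column) set.
#' @param tier which tier the count matrix should cover.
#' @return list with `catalog` (data.table: circ_id, chrom, start, end,
#'   strand, n_samples_expressed, max_reads, total_reads, detected, robust)
#'   and `counts` (integer matrix circRNAs x samples).
#' @export
build_catalog <- function(evidence, min_reads = 2L, min_samples = 2L,
                          samples = NULL, tier = c("robust", "detected")) {
  tier <- match.arg(tier)
  evidence <- as.data.table(evidence)
  if (nrow(evidence) == 0L) {
    cat0 <- data.table(circ_id = character(), chrom = character(),
                       start = integer(), end = integer(), strand = character(),
                       n_samples_expressed = integer(), max_reads = integer(),
                       total_reads = integer(), detected = logical(),
                       robust = logical())
    return(list(catalog = cat0,
                counts = matrix(0L, 0, length(samples),
                                dimnames = list(NULL, samples))))
  }
  # collapse duplicate (junction, sample) rows by summing read support
  ev <- evidence[, list(n_reads = sum(n_reads)),
                 by = c("chrom", "start", "end", "strand", "sample_id")]
  ev[, circ_id := circ_id(chrom, start, end, strand)]
  cat <- ev[, list(
    n_samples_expressed = sum(n_reads >= min_reads),
    max_reads = max(n_reads),
    total_reads = sum(n_reads)
  ), by = c("circ_id", "chrom", "start", "end", "strand")]
  cat[, detected := max_reads >= min_reads]
  cat[, robust := n_samples_expressed >= min_samples]
  setorder(cat, chrom, start, end, strand)
  keep_ids <- if (tier == "robust") cat$circ_id[cat$robust] else
    cat$circ_id[cat$detected]
  if (is.null(samples)) samples <- sort(unique(ev$sample_id))
  counts <- matrix(0L, nrow = length(keep_ids), ncol = length(samples),
                   dimnames = list(keep_ids, samples))
  sub <- ev[circ_id %in% keep_ids & sample_id %in% samples]
  if (nrow(sub))
    counts[cbind(match(sub$circ_id, keep_ids),
                 match(sub$sample_id, samples))] <- as.integer(sub$n_reads)
  log_stage("build_catalog: ", nrow(cat), " detected-or-better keys; ",
            sum(cat$detected), " detected (>=", min_reads, " reads); ",
            sum(cat$robust), " robust (>=", min_reads, " reads in >=",
            min_samples, " samples)")
  list(catalog = cat[], counts = counts)
}

#' Flag abundant circRNAs
#'
#' The abundant tier of the catalog: expressed (count at or above the
#' detection support threshold) in at least `min_samples` samples and
#' supported by at least `min_reads` reads in at least one sample.
#'
#' @param counts raw count matrix (robust tier).
#' @param min_samples minimum number of expressing samples.
#' @param min_reads minimum read count required in at least one sample.
#' @param expressed_min count at which a circRNA counts as expressed in a
#'   sample (defaults to the catalog detection threshold of 2).
#' @return character vector of abundant circ_ids (catalog order).
#' @export
flag_abundant <- function(counts, min_samples = 30L, min_reads = 20L,
                          expressed_min = 2L) {
  if (nrow(counts) == 0L) return(character())
  n_expr <- rowSums(counts >= expressed_min)
  max_reads <- apply(counts, 1L, max)
  ids <- rownames(counts)[n_expr >= min_samples & max_reads >= min_reads]
  log_stage("flag_abundant: ", length(ids), " of ", nrow(counts),
            " circRNAs abundant (>=", min_samples, " samples, >=",
            min_reads, " reads in one sample)")
  ids
}

#' Linear-counterpart counts for each circRNA
#'
#' For every circRNA and sample, sums the linearly spliced reads that use the
#' circle's two backsplice splice sites: reads from linear junctions touching
#' the circle's start coordinate plus reads from junctions touching its end
#' coordinate. A single linear junction record whose two ends hit both sites
#' contributes once per site listing.
#'
#' @param linear_evidence linear junction evidence table.
#' @param catalog catalog data.table from [build_catalog()].
#' @param samples sample (column) set of the result.
#' @return integer matrix aligned to `catalog` rows and `samples` columns.
#' @export
linear_counterpart <- function(linear_evidence, catalog, samples) {
  lv <- as.data.table(linear_evidence)
  out <- matrix(0L, nrow = nrow(catalog), ncol = length(samples),
                dimnames = list(catalog$circ_id, samples))
  if (nrow(lv) == 0L || nrow(catalog) == 0L) return(out)
  # long table of (circ, site) keys; a site is matched by either junction end
  sites <- rbindlist(list(
    data.table(circ_id = catalog$circ_id, chrom = catalog$chrom,
               pos = catalog$start),
    data.table(circ_id = catalog$circ_id, chrom = catalog$chrom,
               pos = catalog$end)
  ))
  ends <- rbindlist(list(
    lv[, list(chrom, pos = start, sample_id, n_reads)],
    lv[, list(chrom, pos = end, sample_id, n_reads)]
  ))
  ends <- ends[sample_id %in% samples]
  hit <- merge(sites, ends, by = c("chrom", "pos"), allow.cartesian = TRUE)
  if (nrow(hit)) {
    agg <- hit[, list(n = sum(n_reads)), by = c("circ_id", "sample_id")]
    out[cbind(match(agg$circ_id, rownames(out)),
              match(agg$sample_id, samples))] <- as.integer(agg$n)
  }
  out
}

#' Counts-per-million normalisation
#'
#' Divides each column by the per-sample library size (total mapped reads
#' from the clinical table) and scales to one million. When no library sizes
#' are supplied the column sums of the matrix itself are used, with a
#' warning, since backsplice reads alone understate sequencing depth.
#'
#' @param counts raw count matrix.
#' @param library_sizes named numeric vector (names = sample ids) or `NULL`.
#' @return numeric CPM matrix of the same shape.
#' @export
cpm_matrix <- function(counts, library_sizes = NULL) {
  if (is.null(library_sizes)) {
    warning("no library sizes supplied; falling back to matrix column sums")
    library_sizes <- colSums(counts)
  }
  ls <- library_sizes[colnames(counts)]
  if (anyNA(ls)) stop("library sizes missing for sample(s): ",
                      paste(colnames(counts)[is.na(ls)], collapse = ", "))
  if (any(ls <= 0)) stop("library sizes must be positive")
  sweep(counts, 2L, ls, "/") * 1e6
}

#' Circular-to-linear expression ratios
#'
#' Elementwise `(circular reads + 1) / (linear reads + 1)`; the pseudocount
#' avoids division by zero and keeps the ordering of circular versus linear
#' support (ratio > 1 iff circular reads exceed linear reads).
#'
#' @param circ_counts raw circular count matrix.
#' @param linear_counts aligned linear-counterpart matrix.
#' @return numeric ratio matrix.
#' @export
circ_to_lin <- function(circ_counts, linear_counts) {
  if (!identical(dim(circ_counts), dim(linear_counts)))
    stop("circular and linear matrices have mismatched dimensions")
  (circ_counts + 1) / (linear_counts + 1)
}

#' Per-gene circRNA production profile
#'
#' Assigns each circRNA to the gene(s) its backsplice span overlaps and
#' tabulates, per gene, the number of distinct circRNAs and the total
#' backsplice reads. CircRNAs overlapping no gene are grouped under
#' `"intergenic"`; circRNAs overlapping several genes count for each and are
#' flagged ambiguous.
#'
#' @param catalog catalog data.table.
#' @param counts raw count matrix aligned with `catalog`.
#' @param exons exon annotation table (needs `gene_id`).
#' @return list with `genes` (gene_id, n_distinct_circ, total_circ_reads) and
#'   `assignment` (circ_id, gene_id, ambiguous).
#' @export
per_gene_profile <- function(catalog, counts, exons) {
  if (nrow(catalog) == 0L)
    return(list(genes = data.table(gene_id = character(),
                                   n_distinct_circ = integer(),
                                   total_circ_reads = numeric()),
                assignment = data.table(circ_id = character(),
                                        gene_id = character(),
                                        ambiguous = logical())))
  genes_gr <- gr(exons, keep = "gene_id")
  circ_gr <- gr(catalog, keep = "circ_id")
  ov <- GenomicRanges::findOverlaps(circ_gr, genes_gr, ignore.strand = TRUE)
  asg <- unique(data.table(
    circ_id = catalog$circ_id[S4Vectors::queryHits(ov)],
    gene_id = exons$gene_id[S4Vectors::subjectHits(ov)]
  ))
  orphan <- setdiff(catalog$circ_id, asg$circ_id)
  if (length(orphan))
    asg <- rbindlist(list(asg, data.table(circ_id = orphan,
                                          gene_id = "intergenic")))
  asg[, ambiguous := .N > 1L, by = "circ_id"]
  reads <- rowSums(counts)[asg$circ_id]
  tab <- data.table(gene_id = asg$gene_id, reads = reads)[
    , list(n_distinct_circ = .N, total_circ_reads = sum(reads)),
    by = "gene_id"]
  setorder(tab, gene_id)
  setorder(asg, circ_id, gene_id)
  list(genes = tab[], assignment = asg[])
}
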