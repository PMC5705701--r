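#' Pipeline run configuration
#'
#' Bundles the filtering thresholds, input file paths and the random seed
#' used by [run_pipeline()] and the individual analysis stages. Defaults
#' follow the catalog stringency and annotation windows used throughout the
#' package: backsplice anchors must map at MAPQ >= 35, a circRNA enters the
#' robust catalog with >= 2 reads in >= 2 samples, the abundant tier requires
#' expression in >= 30 samples and >= 20 reads in at least one sample,
#' significance is declared at FDR < 0.1, Alu pairs are searched in 20 kb
#' flanks, splice-site origin uses a 6 bp window, and non-exonic circRNAs
#' longer than 10 kb are excluded from the miRNA observed-vs-expected
#' analysis.
#'
#' @param paths named list of input file paths. Recognised names:
#'   `circ_junctions`, `linear_junctions`, `exons` (GTF), `repeats` (TSV),
#'   `conservation` (bedGraph), `sce` (BED), `mirna_sites` (TSV),
#'   `gene_expression` (TSV matrix), `clinical` (TSV).
#' @param min_reads minimum backsplice reads for a circRNA to count as
#'   expressed in a sample.
#' @param min_samples_robust minimum number of samples with `min_reads`
#'   support for the robust catalog tier.
#' @param abundant_min_samples minimum number of expressing samples for the
#'   abundant tier.
#' @param abundant_min_reads minimum read count in at least one sample for
#'   the abundant tier.
#' @param mapq_cutoff minimum anchor mapping quality (both anchors).
#' @param fdr_level Benjamini-Hochberg false discovery rate threshold.
#' @param alu_window_bp flank width searched for inverted Alu pairs.
#' @param splice_window_bp window intersected with exon annotation when
#'   assigning genomic origin to a splice site; must be even.
#' @param mirna_max_circ_len_bp non-exonic circRNAs at least this long are
#'   excluded from the miRNA observed-vs-expected analysis.
#' @param log2fc_pseudocount pseudocount (CPM units) in log2 fold changes.
#' @param seed integer random seed for any stage that randomises.
#' @param outdir output directory for pipeline tables.
#' @return a list of class `circ_config`.
#' @export
circ_config <- function(paths = list(),
                        min_reads = 2L,
                        min_samples_robust = 2L,
                        abundant_min_samples = 30L,
                        abundant_min_reads = 20L,
                        mapq_cutoff = 35L,
                        fdr_level = 0.1,
                        alu_window_bp = 20000L,
                        splice_window_bp = 6L,
                        mirna_max_circ_len_bp = 10000L,
                        log2fc_pseudocount = 1,
                        seed = 1L,
                        outdir = ".") {
  cfg <- list(
    paths = paths,
    min_reads = as.integer(min_reads),
    min_samples_robust = as.integer(min_samples_robust),
    abundant_min_samples = as.integer(abundant_min_samples),
    abundant_min_reads = as.integer(abundant_min_reads),
    mapq_cutoff = as.integer(mapq_cutoff),
    fdr_level = as.numeric(fdr_level),
    alu_window_bp = as.integer(alu_window_bp),
    splice_window_bp = as.integer(splice_window_bp),
    mirna_max_circ_len_bp = as.integer(mirna_max_circ_len_bp),
    log2fc_pseudocount = as.numeric(log2fc_pseudocount),
    seed = as.integer(seed),
    outdir = outdir
  )
  thr <- c("min_reads", "min_samples_robust", "abundant_min_samples",
           "abundant_min_reads", "alu_window_bp", "splice_window_bp",
           "mirna_max_circ_len_bp")
  for (nm in thr) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] <= 0L)
      stop("config threshold '", nm, "' must be positive")
  }
  if (cfg$mapq_cutoff < 0L) stop("mapq_cutoff must be non-negative")
  if (!(cfg$fdr_level > 0 && cfg$fdr_level < 1))
    stop("fdr_level must lie in (0, 1)")
  if (cfg$splice_window_bp %% 2L != 0L)
    stop("splice_window_bp must be even (split symmetrically around the site)")
  class(cfg) <- "circ_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' The file may contain any of the arguments of [circ_config()]; `paths` is a
#' nested mapping of input names to file paths (resolved relative to the YAML
#' file's directory unless absolute).
#'
#' @param path YAML file.
#' @return a `circ_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  if (!is.null(raw$paths)) {
    raw$paths <- lapply(raw$paths, function(p) {
      if (startsWith(p, "/")) p else file.path(base, p)
    })
  }
  known <- names(formals(circ_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(circ_config, raw)
}
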