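ALLOWED_REGIONS <- c("CDS", "UTR3", "UTR5", "ncRNA")

#' Read a junction evidence table
#'
#' Junction tables are tab-separated with a header and one row per
#' (junction, sample) pair:
#' `chrom  start  end  strand  sample_id  n_reads  mapq_anchor1  mapq_anchor2`.
#' Coordinates are 0-based half-open. The two anchor mapping-quality columns
#' are optional and normally only present for backsplice (circular) evidence,
#' where they feed the anchor-quality filter; linear splice junctions are
#' usually consumed pre-filtered.
#'
#' @param path TSV file.
#' @param kind `"circular"` or `"linear"`; recorded on the result.
#' @return data.table of validated junction evidence.
#' @export
read_junction_table <- function(path, kind = c("circular", "linear")) {
  kind <- match.arg(kind)
  x <- fread(path, sep = "\t", header = TRUE, colClasses = list(
    character = "chrom"))
  need <- c("chrom", "start", "end", "strand", "sample_id", "n_reads")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("junction table ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(x)) {
    # header is line 1, so data row i sits on file line i + 1
    bad <- which(is.na(x$start) | is.na(x$end) | x$start < 0 | x$start >= x$end)
    if (length(bad))
      stop("junction table ", path, ": start >= end (or missing) on line(s) ",
           paste(utils::head(bad + 1L, 10L), collapse = ", "))
    bad <- which(!x$strand %in% c("+", "-", "."))
    if (length(bad))
      stop("junction table ", path, ": bad strand on line(s) ",
           paste(utils::head(bad + 1L, 10L), collapse = ", "))
    bad <- which(is.na(x$n_reads) | x$n_reads < 0)
    if (length(bad))
      stop("junction table ", path, ": negative or missing n_reads on line(s) ",
           paste(utils::head(bad + 1L, 10L), collapse = ", "))
    for (mq in c("mapq_anchor1", "mapq_anchor2")) {
      if (mq %in% names(x)) {
        bad <- which(!is.na(x[[mq]]) & x[[mq]] < 0)
        if (length(bad))
          stop("junction table ", path, ": negative ", mq, " on line(s) ",
               paste(utils::head(bad + 1L, 10L), collapse = ", "))
      }
    }
  }
  x$sample_id <- as.character(x$sample_id)
  attr(x, "kind") <- kind
  x[]
}

#' Write a junction evidence table
#'
#' Inverse of [read_junction_table()]; a write/read round trip preserves all
#' records.
#'
#' @param x junction evidence data.table.
#' @param path output TSV.
#' @export
write_junction_table <- function(x, path) {
  fwrite(x, path, sep = "\t")
  invisible(path)
}

#' Map RepeatMasker repeat names to Alu subfamily classes
#'
#' The subfamily class is the leading `Alu` prefix through the family letter:
#' `AluJb` and `AluJo` are both class `AluJ`; `AluSx1` is `AluS`; `AluYk11`
#' is `AluY`. Two Alu repeats are considered homologous when they share this
#' class. Non-Alu repeat names map to `NA` and are excluded from the Alu set.
#'
#' @param repeat_name character vector of RepeatMasker repeat names.
#' @return character vector of subfamily classes (`NA` for non-Alu repeats).
#' @export
alu_subfamily <- function(repeat_name) {
  m <- regmatches(repeat_name, regexpr("^Alu[A-Z]", repeat_name))
  out <- rep(NA_character_, length(repeat_name))
  out[regexpr("^Alu[A-Z]", repeat_name) > 0] <- m
  out
}

# --- annotation bundle -------------------------------------------------------

#' Read all annotation tracks into a bundle
#'
#' Reads the exon model (GTF, attributes `gene_id`, `transcript_id`,
#' `region`), the repeat table (TSV: chrom, start, end, strand, repeat_name;
#' 0-based), the conservation track (bedGraph, per-base scores), synonymous
#' constraint elements (BED) and the AGO-CLIP miRNA target site table (TSV:
#' chrom, start, end, mirna_id, experiment_id, optionally `conserved`).
#' GTF coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention on read; BED and bedGraph are already 0-based.
#'
#' @param config a [circ_config()] whose `paths` name the input files; paths
#'   for absent tracks may be omitted, leaving that slot `NULL`.
#' @return a list of class `annotation_bundle` with elements `exons`,
#'   `repeats`, `alus`, `conservation`, `sce`, `mirna_sites`.
#' @export
read_annotation_bundle <- function(config) {
  p <- config$paths
  bundle <- list(exons = NULL, repeats = NULL, alus = NULL,
                 conservation = NULL, sce = NULL, mirna_sites = NULL)

  if (!is.null(p$exons)) {
    g <- rtracklayer::import(p$exons, format = "gtf")
    g <- g[S4Vectors::mcols(g)$type == "exon"]
    ex <- dt_from_gr(g)
    ex$gene_id <- S4Vectors::mcols(g)$gene_id
    ex$transcript_id <- S4Vectors::mcols(g)$transcript_id
    ex$region <- S4Vectors::mcols(g)$region
    badlab <- setdiff(unique(ex$region), ALLOWED_REGIONS)
    if (length(badlab))
      stop("unknown region label(s) ", paste(badlab, collapse = ", "),
           "; allowed labels are: ", paste(ALLOWED_REGIONS, collapse = ", "))
    bundle$exons <- validate_intervals(ex, "exon")
  }
  if (!is.null(p$repeats)) {
    rp <- fread(p$repeats, sep = "\t", header = TRUE,
                colClasses = list(character = "chrom"))
    rp <- validate_intervals(rp, "repeat")
    rp$subfamily <- alu_subfamily(rp$repeat_name)
    bundle$repeats <- rp
    bundle$alus <- rp[!is.na(rp$subfamily)]
  }
  if (!is.null(p$conservation)) {
    bundle$conservation <- rtracklayer::import(p$conservation,
                                               format = "bedGraph")
  }
  if (!is.null(p$sce)) {
    sce <- dt_from_gr(rtracklayer::import(p$sce, format = "bed"))
    bundle$sce <- validate_intervals(sce, "SCE")
  }
  if (!is.null(p$mirna_sites)) {
    mi <- fread(p$mirna_sites, sep = "\t", header = TRUE,
                colClasses = list(character = "chrom"))
    need <- c("chrom", "start", "end", "mirna_id", "experiment_id")
    miss <- setdiff(need, names(mi))
    if (length(miss))
      stop("miRNA site table lacks column(s): ", paste(miss, collapse = ", "))
    bundle$mirna_sites <- validate_intervals(mi, "miRNA site")
  }
  class(bundle) <- "annotation_bundle"
  bundle
}

# --- matrices and tables -----------------------------------------------------

#' Write a numeric matrix as TSV with row identifiers
#' @param m matrix with rownames and colnames.
#' @param path output TSV.
#' @param id_col name of the identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "circ_id") {
  dt <- data.table(id = rownames(m))
  setnames(dt, "id", id_col)
  dt <- cbind(dt, as.data.table(m))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a numeric matrix written by [write_matrix_tsv()]
#' @param path TSV file; first column holds row identifiers.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- as.character(dt[[1]])
  m
}

#' Read the clinical table
#'
#' Expected columns: `sample_id`, `class` (risk class 1/2/3), `stage`,
#' `grade`, `eortc` (EORTC progression score), `library_size` (total mapped
#' reads), `time_months` (progression-free time), `progressed` (1 =
#' progression to muscle-invasive disease, 0 = censored).
#'
#' @param path TSV file.
#' @return data.table keyed by `sample_id`.
#' @export
read_clinical_table <- function(path) {
  cl <- fread(path, sep = "\t", header = TRUE)
  need <- c("sample_id", "class", "library_size", "time_months", "progressed")
  miss <- setdiff(need, names(cl))
  if (length(miss))
    stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(cl$time_months <= 0))
    stop("clinical table: time_months must be positive")
  if (!all(cl$progressed %in% c(0L, 1L)))
    stop("clinical table: progressed must be 0/1")
  cl$sample_id <- as.character(cl$sample_id)
  cl[]
}
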