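#' @importFrom data.table data.table as.data.table setDT setorder := .N .SD fread fwrite rbindlist setnames copy
#' @import GenomicRanges
#' @import IRanges
NULL

# Internal coordinate convention: all tables carry 0-based half-open
# [start, end) intervals. GRanges (1-based closed) are only built transiently
# for overlap machinery; `gr()` and `dt_from_gr()` do the +1/-1 shifts.

#' Validate a table of genomic intervals
#'
#' Checks the 0-based half-open invariant (`0 <= start < end`, non-empty
#' chromosome, strand in `+`, `-`, `.`) and reports offending rows by index.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` and optionally
#'   `strand`.
#' @param what label used in error messages.
#' @return `x` as a data.table, invisibly validated.
#' @export
validate_intervals <- function(x, what = "interval") {
  x <- as.data.table(x)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(what, " table lacks required column(s): ", paste(miss, collapse = ", "))
  bad <- which(is.na(x$start) | is.na(x$end) | x$start < 0 | x$start >= x$end |
                 is.na(x$chrom) | x$chrom == "")
  if (length(bad))
    stop(what, " rows violate 0-based half-open invariant (0 <= start < end, ",
         "chrom non-empty) at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  if ("strand" %in% names(x)) {
    badstr <- which(!x$strand %in% c("+", "-", "."))
    if (length(badstr))
      stop(what, " rows have strand outside {+, -, .} at row(s): ",
           paste(utils::head(badstr, 10L), collapse = ", "))
  }
  x
}

# Build a GRanges from a 0-based half-open table. Strand "." becomes "*".
gr <- function(x, keep = character()) {
  strand <- if ("strand" %in% names(x)) {
    s <- as.character(x$strand); s[s == "."] <- "*"; s
  } else "*"
  g <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
  for (k in keep) S4Vectors::mcols(g)[[k]] <- x[[k]]
  g
}

# Back-convert a GRanges to the 0-based half-open table convention.
dt_from_gr <- function(g) {
  s <- as.character(GenomicRanges::strand(g))
  s[s == "*"] <- "."
  data.table(
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g) - 1L,
    end = GenomicRanges::end(g),
    strand = s
  )
}

# Total length of the union of a set of 0-based intervals.
merged_length <- function(x) {
  if (nrow(x) == 0L) return(0L)
  sum(IRanges::width(GenomicRanges::reduce(gr(x), ignore.strand = TRUE)))
}

# Union (merge) of intervals, strand-blind; returns 0-based table.
merge_intervals <- function(x) {
  if (nrow(x) == 0L) return(data.table(chrom = character(), start = integer(),
                                       end = integer(), strand = character()))
  dt_from_gr(GenomicRanges::reduce(gr(x), ignore.strand = TRUE))
}

# Stable circRNA identifier from the backsplice key.
circ_id <- function(chrom, start, end, strand) {
  paste0(chrom, ":", start, "-", end, ":", strand)
}
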