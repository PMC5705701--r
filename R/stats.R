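# Class-wise differential expression and correlation statistics with
# Benjamini-Hochberg control. The two-sided rank-sum p-value is exact
# (permutation distribution) when the smaller group has at most 8 samples
# and there are no ties, and otherwise uses the normal approximation with
# tie and continuity corrections — the branch rule is fixed so p-values are
# reproducible bit for bit.

EXACT_MAX_N <- 8L

# two-sided rank-sum p for x vs y under the package branch rule
ranksum_p <- function(x, y) {
  exact <- min(length(x), length(y)) <= EXACT_MAX_N &&
    !anyDuplicated(c(x, y))
  stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return q-values (adjusted p-values), capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(stats::na.omit(p) < 0 | stats::na.omit(p) > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Wilcoxon rank-sum differential expression between two risk classes
#'
#' Tests every matrix row (circRNA) for a difference between class `class_a`
#' and `class_b` samples with a two-sided rank-sum test, adjusts across rows
#' with Benjamini-Hochberg, and reports
#' `log2FC = log2((mean_a + eps) / (mean_b + eps))`, so a positive fold
#' change means higher expression in `class_a`. Rows constant across both
#' groups get p = 1 and a `constant` flag.
#'
#' @param mat expression matrix (CPM or ratios), circRNAs x samples.
#' @param classes vector of class labels aligned with `colnames(mat)`.
#' @param class_a,class_b the two classes compared (default classes 1 and 2;
#'   the basal-like class 3 is excluded by default).
#' @param fdr_level FDR threshold for the `significant` flag.
#' @param pseudocount epsilon in the fold-change (expression units).
#' @return data.table: circ_id, log2_fold_change, p_value, q_value,
#'   significant, constant.
#' @export
wilcoxon_de <- function(mat, classes, class_a = 1, class_b = 2,
                        fdr_level = 0.1, pseudocount = 1) {
  sel_a <- which(classes == class_a)
  sel_b <- which(classes == class_b)
  if (length(sel_a) < 2L || length(sel_b) < 2L)
    stop("each compared class needs at least 2 samples")
  a <- mat[, sel_a, drop = FALSE]
  b <- mat[, sel_b, drop = FALSE]
  n <- nrow(mat)
  p <- numeric(n)
  const <- logical(n)
  for (i in seq_len(n)) {
    xi <- a[i, ]; yi <- b[i, ]
    if (length(unique(c(xi, yi))) == 1L) {
      p[i] <- 1; const[i] <- TRUE
    } else {
      p[i] <- ranksum_p(xi, yi)
    }
  }
  lfc <- log2((rowMeans(a) + pseudocount) / (rowMeans(b) + pseudocount))
  q <- bh_adjust(p)
  data.table(circ_id = rownames(mat), log2_fold_change = lfc,
             p_value = p, q_value = q, significant = q < fdr_level,
             constant = const)
}

#' Differential circular-to-linear ratios between risk classes
#'
#' [wilcoxon_de()] applied to the ratio matrix: detects shifts in the
#' relative circular output of a locus that raw-level tests confound with
#' host-gene expression changes.
#'
#' @inheritParams wilcoxon_de
#' @param ratios circular-to-linear ratio matrix from [circ_to_lin()].
#' @return as [wilcoxon_de()].
#' @export
ratio_de <- function(ratios, classes, class_a = 1, class_b = 2,
                     fdr_level = 0.1, pseudocount = 0) {
  wilcoxon_de(ratios, classes, class_a = class_a, class_b = class_b,
              fdr_level = fdr_level, pseudocount = pseudocount)
}

#' Total circRNA expression per sample, compared across classes
#'
#' Sums each sample's circRNA CPM and compares the totals between every pair
#' of classes with two-sided rank-sum tests.
#'
#' @param cpm CPM matrix.
#' @param classes class labels aligned with columns.
#' @return list with `totals` (sample, class, total_cpm), `summary`
#'   (per-class n/median/mean) and `pairwise` (class pair, p_value; `NA`
#'   with `insufficient_n` flag when a class has fewer than 2 samples).
#' @export
total_expression_comparison <- function(cpm, classes) {
  totals <- data.table(sample_id = colnames(cpm), class = classes,
                       total_cpm = colSums(cpm))
  summ <- totals[, list(n = .N, median_total = stats::median(total_cpm),
                        mean_total = mean(total_cpm)), by = "class"]
  setorder(summ, class)
  cls <- summ$class
  pw <- NULL
  if (length(cls) >= 2L) {
    cmb <- utils::combn(as.character(cls), 2L)
    pw <- data.table(class1 = cmb[1L, ], class2 = cmb[2L, ],
                     p_value = NA_real_, insufficient_n = FALSE)
    for (i in seq_len(ncol(cmb))) {
      x <- totals$total_cpm[totals$class == cmb[1L, i]]
      y <- totals$total_cpm[totals$class == cmb[2L, i]]
      if (length(x) < 2L || length(y) < 2L) {
        pw$insufficient_n[i] <- TRUE
      } else {
        pw$p_value[i] <- ranksum_p(x, y)
      }
    }
  }
  list(totals = totals[], summary = summ[], pairwise = pw)
}

# Spearman rho and p; returns NAs with a flag when either vector is constant
spearman_pair <- function(x, y) {
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p = NA_real_, degenerate = TRUE))
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ht$estimate), p = ht$p.value, degenerate = FALSE)
}

#' Correlation of circRNA expression with circRNA-biogenesis regulators
#'
#' Spearman correlation of every circRNA's CPM with the expression of each
#' regulator gene (typically the RNA-editing enzyme ADAR and the splicing
#' factor Quaking/QKI), BH-adjusted per regulator, plus the global
#' correlation of total circRNA output with each regulator.
#'
#' @param cpm circRNA CPM matrix.
#' @param gene_expr gene expression matrix (genes x samples) containing the
#'   regulator rows.
#' @param regulators character vector of regulator gene ids.
#' @param fdr_level FDR threshold for the `significant` flag.
#' @return list with `per_circ` and `global` data.tables.
#' @export
regulator_correlation <- function(cpm, gene_expr,
                                  regulators = c("ADAR", "QKI"),
                                  fdr_level = 0.1) {
  shared <- intersect(colnames(cpm), colnames(gene_expr))
  if (length(shared) < 3L)
    stop("need at least 3 matched samples for correlation")
  missing_reg <- setdiff(regulators, rownames(gene_expr))
  if (length(missing_reg))
    stop("regulator(s) absent from gene expression matrix: ",
         paste(missing_reg, collapse = ", "))
  cpm <- cpm[, shared, drop = FALSE]
  per <- list()
  glob <- list()
  tot <- colSums(cpm)
  for (rg in regulators) {
    rv <- gene_expr[rg, shared]
    res <- lapply(seq_len(nrow(cpm)), function(i) spearman_pair(cpm[i, ], rv))
    dt <- data.table(circ_id = rownames(cpm), partner = rg,
                     spearman_rho = vapply(res, `[[`, 0, "rho"),
                     p_value = vapply(res, `[[`, 0, "p"),
                     degenerate = vapply(res, `[[`, TRUE, "degenerate"))
    dt[, q_value := bh_adjust(p_value)]
    dt[, significant := !is.na(q_value) & q_value < fdr_level]
    per[[rg]] <- dt
    g <- spearman_pair(tot, rv)
    glob[[rg]] <- data.table(partner = rg, spearman_rho = g$rho,
                             p_value = g$p)
  }
  list(per_circ = rbindlist(per), global = rbindlist(glob))
}

#' Correlation of circRNA expression with the EORTC progression score
#'
#' Spearman correlation of each circRNA's CPM with the per-sample EORTC
#' score, BH-adjusted; a constant score vector yields flagged undefined
#' results.
#'
#' @param cpm circRNA CPM matrix.
#' @param eortc named numeric vector of EORTC scores (names = sample ids).
#' @param fdr_level FDR threshold.
#' @return data.table as the `per_circ` slot of [regulator_correlation()].
#' @export
eortc_correlation <- function(cpm, eortc, fdr_level = 0.1) {
  shared <- intersect(colnames(cpm), names(eortc))
  if (length(shared) < 3L)
    stop("need at least 3 matched samples for correlation")
  cpm <- cpm[, shared, drop = FALSE]
  ev <- eortc[shared]
  res <- lapply(seq_len(nrow(cpm)), function(i) spearman_pair(cpm[i, ], ev))
  dt <- data.table(circ_id = rownames(cpm), partner = "EORTC",
                   spearman_rho = vapply(res, `[[`, 0, "rho"),
                   p_value = vapply(res, `[[`, 0, "p"),
                   degenerate = vapply(res, `[[`, TRUE, "degenerate"))
  dt[, q_value := bh_adjust(p_value)]
  dt[, significant := !is.na(q_value) & q_value < fdr_level]
  dt[]
}
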