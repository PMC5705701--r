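# Median-split Kaplan-Meier / log-rank machinery and the triage that flags
# circRNAs whose expression correlates with progression independently of the
# linear counterpart and the parent gene.

#' Median split of an expression vector
#'
#' `high` means strictly greater than the median; ties (including the heavy
#' zero mass typical of circRNA counts) fall in the `low` group. An
#' all-equal vector is a degenerate split.
#'
#' @param values per-sample expression.
#' @return list with `group` (factor low/high) and `degenerate` flag.
#' @export
median_split <- function(values) {
  if (length(values) < 4L) stop("median split needs at least 4 samples")
  med <- stats::median(values)
  grp <- factor(ifelse(values > med, "high", "low"), levels = c("low", "high"))
  degenerate <- length(unique(grp[!is.na(grp)])) < 2L
  list(group = grp, degenerate = degenerate)
}

#' Kaplan-Meier product-limit estimate per group
#'
#' Standard product-limit estimator: at each distinct event time t,
#' `S(t) = S(t-) * (1 - d_t / n_t)` with `n_t` the number at risk (subjects
#' censored at t are still at risk at t).
#'
#' @param time positive event/censoring times.
#' @param event 1 = event, 0 = censored.
#' @param group optional group labels; one table per group.
#' @return data.table: group, time, n_risk, n_event, n_censor, survival.
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (any(time <= 0)) stop("times must be positive")
  if (is.null(group)) group <- rep("all", length(time))
  out <- list()
  for (g in unique(group)) {
    ti <- time[group == g]; ev <- event[group == g]
    tt <- sort(unique(ti))
    n_risk <- vapply(tt, function(t) sum(ti >= t), 0L)
    n_event <- vapply(tt, function(t) sum(ti == t & ev == 1L), 0L)
    n_censor <- vapply(tt, function(t) sum(ti == t & ev == 0L), 0L)
    surv <- cumprod(1 - n_event / n_risk)
    out[[length(out) + 1L]] <- data.table(group = g, time = tt,
                                          n_risk = n_risk, n_event = n_event,
                                          n_censor = n_censor,
                                          survival = surv)
  }
  rbindlist(out)
}

#' Two-group log-rank test
#'
#' Sums, over distinct event times, the observed minus hypergeometric-
#' expected events in group 1 and the hypergeometric variance; the squared
#' standardised sum is referred to the chi-square distribution with 1 df.
#'
#' @param time positive times.
#' @param event 1 = event, 0 = censored.
#' @param group two-level group labels.
#' @return list: statistic, p_value, observed/expected per group,
#'   `degenerate` (TRUE when there are no events or a group is empty, in
#'   which case statistic and p are `NA`).
#' @export
logrank_test <- function(time, event, group) {
  grp <- as.factor(group)
  if (nlevels(grp) != 2L) stop("log-rank test requires exactly two groups")
  if (any(table(grp) == 0L)) stop("one group is empty")
  g1 <- grp == levels(grp)[1L]
  tt <- sort(unique(time[event == 1L]))
  if (length(tt) == 0L)
    return(list(statistic = NA_real_, p_value = NA_real_,
                observed = c(0, 0), expected = c(0, 0), degenerate = TRUE))
  O1 <- E1 <- V <- 0
  for (t in tt) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(time == t & event == 1L)
    d1 <- sum(time == t & event == 1L & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1L) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1L)
  }
  if (V <= 0)
    return(list(statistic = NA_real_, p_value = NA_real_,
                observed = c(O1, sum(event) - O1),
                expected = c(E1, sum(event) - E1), degenerate = TRUE))
  stat <- (O1 - E1)^2 / V
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       observed = c(O1, sum(event) - O1),
       expected = c(E1, sum(event) - E1),
       degenerate = FALSE)
}

# median-split log-rank p for one expression vector; NA when degenerate
split_logrank_p <- function(values, time, event) {
  sp <- median_split(values)
  if (sp$degenerate) return(NA_real_)
  lr <- logrank_test(time, event, sp$group)
  if (lr$degenerate) return(NA_real_)
  lr$p_value
}

#' Prognostic triage of circRNAs
#'
#' For each circRNA, runs three median-split log-rank tests against
#' progression-free survival — on the circular expression, on the
#' linear-counterpart expression at the same splice sites, and on the parent
#' gene's mRNA expression — adjusts each measurement family separately with
#' Benjamini-Hochberg, and flags a circle as independently prognostic when
#' the circular test is significant while neither the linear nor the mRNA
#' test is. Degenerate splits (constant expression, or no events in either
#' group) are excluded from their family's adjustment and noted.
#'
#' @param circ_cpm circRNA CPM matrix.
#' @param linear_cpm aligned linear-counterpart CPM matrix.
#' @param gene_expr gene expression matrix (genes x samples).
#' @param gene_map data.table `circ_id` -> `gene_id` (first/unambiguous
#'   assignment used; circles without a measured parent gene get `NA`).
#' @param clinical clinical table with `sample_id`, `time_months`,
#'   `progressed`.
#' @param fdr_level FDR threshold (default 0.1).
#' @return data.table: circ_id, p/q for circ, linear and mRNA families,
#'   independent_prognostic flag, notes on degenerate tests.
#' @export
prognostic_triage <- function(circ_cpm, linear_cpm, gene_expr, gene_map,
                              clinical, fdr_level = 0.1) {
  samples <- intersect(colnames(circ_cpm), clinical$sample_id)
  if (length(samples) < 4L) stop("too few matched samples for survival")
  cl <- clinical[match(samples, clinical$sample_id), ]
  time <- cl$time_months
  event <- as.integer(cl$progressed)
  ids <- rownames(circ_cpm)
  gmap <- gene_map[!duplicated(circ_id)]
  gene_of <- gmap$gene_id[match(ids, gmap$circ_id)]
  gene_of[!gene_of %in% rownames(gene_expr)] <- NA
  p_circ <- p_lin <- p_mrna <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    p_circ[i] <- split_logrank_p(circ_cpm[ids[i], samples], time, event)
    if (ids[i] %in% rownames(linear_cpm))
      p_lin[i] <- split_logrank_p(linear_cpm[ids[i], samples], time, event)
    if (!is.na(gene_of[i]) && all(samples %in% colnames(gene_expr)))
      p_mrna[i] <- split_logrank_p(gene_expr[gene_of[i], samples], time, event)
  }
  q_circ <- bh_adjust(p_circ)
  q_lin <- bh_adjust(p_lin)
  q_mrna <- bh_adjust(p_mrna)
  res <- data.table(circ_id = ids, gene_id = gene_of,
                    p_circ = p_circ, q_circ = q_circ,
                    p_linear = p_lin, q_linear = q_lin,
                    p_mrna = p_mrna, q_mrna = q_mrna)
  res[, independent_prognostic :=
        !is.na(q_circ) & q_circ < fdr_level &
        (is.na(q_linear) | q_linear >= fdr_level) &
        (is.na(q_mrna) | q_mrna >= fdr_level)]
  res[, degenerate_circ := is.na(p_circ)]
  res[]
}
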