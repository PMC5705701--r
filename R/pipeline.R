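# Orchestration: reads configured inputs, runs the analysis stages in order
# (catalog -> annotate -> enrich -> de -> survival -> report), writes one
# TSV per result and a combined per-circRNA property ledger. Stages that
# need the clinical table (class-wise DE, survival) are skipped with a
# warning when it is not configured; any other failure aborts with the
# stage name and cause.

PIPELINE_STAGES <- c("catalog", "annotate", "enrich", "de", "survival",
                     "report")

#' Run the circRNA analysis pipeline
#'
#' @param config a [circ_config()] with input paths and thresholds.
#' @param stages subset of stages to run (dependencies are run implicitly:
#'   every stage needs `catalog`, the report needs everything before it).
#' @return invisibly, a list with all stage results (`catalog`, `counts`,
#'   `cpm`, `linear_counts`, `ratios`, `abundant`, `annotation`,
#'   `enrichment`, `de`, `survival`, `profile`, `summary`).
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  set.seed(config$seed)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- new.env(parent = emptyenv())
  fp <- function(x) file.path(config$outdir, x)
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  bundle <- run_stage("io", function() read_annotation_bundle(config))
  clinical <- NULL
  if (!is.null(config$paths$clinical))
    clinical <- run_stage("io", function()
      read_clinical_table(config$paths$clinical))
  gene_expr <- NULL
  if (!is.null(config$paths$gene_expression))
    gene_expr <- run_stage("io", function()
      read_matrix_tsv(config$paths$gene_expression))

  ## --- catalog ---------------------------------------------------------
  run_stage("catalog", function() {
    ev <- read_junction_table(config$paths$circ_junctions, "circular")
    has_mapq <- all(c("mapq_anchor1", "mapq_anchor2") %in% names(ev))
    ev <- filter_junctions(ev, config$mapq_cutoff,
                           allow_missing_mapq = !has_mapq)
    samples <- if (!is.null(clinical)) clinical$sample_id else NULL
    cat <- build_catalog(ev, config$min_reads, config$min_samples_robust,
                         samples = samples)
    out$catalog <- cat$catalog
    out$counts <- cat$counts
    lib <- if (!is.null(clinical))
      stats::setNames(clinical$library_size, clinical$sample_id) else NULL
    out$cpm <- cpm_matrix(out$counts, lib)
    lin_ev <- read_junction_table(config$paths$linear_junctions, "linear")
    robust_cat <- out$catalog[robust == TRUE]
    out$linear_counts <- linear_counterpart(lin_ev, robust_cat,
                                            colnames(out$counts))
    out$linear_cpm <- cpm_matrix(out$linear_counts, lib)
    out$ratios <- circ_to_lin(out$counts, out$linear_counts)
    out$abundant <- flag_abundant(out$counts, config$abundant_min_samples,
                                  config$abundant_min_reads,
                                  expressed_min = config$min_reads)
    out$gene_profile <- per_gene_profile(robust_cat, out$counts,
                                         bundle$exons)
    out$linear_evidence <- lin_ev
    cat_out <- copy(out$catalog)
    cat_out[, abundant := circ_id %in% out$abundant]
    fwrite(cat_out, fp("catalog.tsv"), sep = "\t")
    write_matrix_tsv(out$counts, fp("circ_counts.tsv"))
    write_matrix_tsv(out$cpm, fp("circ_cpm.tsv"))
    write_matrix_tsv(out$linear_counts, fp("linear_counts.tsv"))
    write_matrix_tsv(out$ratios, fp("ratios.tsv"))
    fwrite(out$gene_profile$genes, fp("gene_profile.tsv"), sep = "\t")
  })
  robust_cat <- out$catalog[robust == TRUE]
  abundant_cat <- robust_cat[circ_id %in% out$abundant]

  ## --- annotate --------------------------------------------------------
  if (any(c("annotate", "enrich", "report") %in% stages))
    run_stage("annotate", function() {
      reads_by_site <- function(tab, weights) {
        s <- rbindlist(list(
          data.table(chrom = tab$chrom, pos = tab$start, w = weights),
          data.table(chrom = tab$chrom, pos = tab$end, w = weights)))
        s[, list(reads = sum(w)), by = c("chrom", "pos")]
      }
      circ_sites <- reads_by_site(robust_cat,
                                  rowSums(out$counts)[robust_cat$circ_id])
      lin_agg <- out$linear_evidence[, list(n = sum(n_reads)),
                                     by = c("chrom", "start", "end")]
      lin_sites <- reads_by_site(lin_agg, lin_agg$n)
      orig <- origin_fractions(circ_sites, lin_sites, bundle$exons,
                               config$splice_window_bp)
      out$origin <- orig
      est <- exon_structure(robust_cat, bundle$exons)
      controls <- internal_exon_controls(bundle$exons)
      feat_sets <- rbindlist(list(
        data.table(set = "abundant_circ", abundant_cat[, list(chrom, start, end)],
                   feature_id = abundant_cat$circ_id),
        data.table(set = "nonabundant_circ",
                   robust_cat[!circ_id %in% out$abundant,
                              list(chrom, start, end)],
                   feature_id = robust_cat$circ_id[!robust_cat$circ_id %in%
                                                     out$abundant]),
        data.table(set = "internal_exons", controls[, list(chrom, start, end)],
                   feature_id = paste0(controls$chrom, ":", controls$start,
                                       "-", controls$end))))
      alu <- nearest_inverted_alu_pair(feat_sets, bundle$alus,
                                       config$alu_window_bp)
      cons <- cbind(feat_sets[, list(set, feature_id)],
                    splice_site_conservation(
                      feat_sets[, list(chrom, start, end)],
                      bundle$conservation)[, list(mean_score, n_scored)])
      out$exon_struct <- est
      out$alu <- alu
      out$conservation <- cons
      orig_tab <- merge(orig$site_fractions, orig$read_fractions,
                        by = "region", suffixes = c("_sites", "_reads"))
      fwrite(orig_tab, fp("origin_fractions.tsv"), sep = "\t")
      fwrite(est, fp("exon_structure.tsv"), sep = "\t")
      fwrite(alu, fp("alu_pairs.tsv"), sep = "\t")
      fwrite(cons, fp("conservation.tsv"), sep = "\t")
    })

  ## --- enrich ----------------------------------------------------------
  if (any(c("enrich", "report") %in% stages))
    run_stage("enrich", function() {
      groups <- build_coding_exon_groups(bundle$exons, robust_cat,
                                         out$abundant)
      out$groups <- groups
      sce_frac <- containment_fractions(groups, bundle$sce)
      mir_frac <- containment_fractions(groups, bundle$mirna_sites)
      out$sce_frac <- sce_frac
      out$mirna_frac <- mir_frac
      out$sce_oe <- tryCatch(sce_observed_vs_expected(groups, bundle$sce),
                             error = function(e) NULL)
      out$mirna_oe <- mirna_observed_vs_expected(
        abundant_cat, bundle$exons, bundle$mirna_sites,
        config$mirna_max_circ_len_bp)
      out$sponge <- sponge_statistic(abundant_cat, bundle$exons,
                                     bundle$mirna_sites)
      fwrite(groups$exons, fp("exon_groups.tsv"), sep = "\t")
      fwrite(sce_frac$fractions, fp("containment_sce.tsv"), sep = "\t")
      fwrite(mir_frac$fractions, fp("containment_mirna.tsv"), sep = "\t")
      if (!is.null(out$sce_oe))
        fwrite(out$sce_oe$table, fp("sce_enrichment.tsv"), sep = "\t")
      fwrite(out$mirna_oe$table, fp("mirna_enrichment.tsv"), sep = "\t")
      fwrite(out$sponge, fp("sponge_stats.tsv"), sep = "\t")
    })

  ## --- de --------------------------------------------------------------
  if (any(c("de", "report") %in% stages)) {
    if (is.null(clinical)) {
      warning("clinical table not configured; skipping class-wise DE stage")
    } else run_stage("de", function() {
      classes <- clinical$class[match(colnames(out$cpm),
                                      clinical$sample_id)]
      ab_cpm <- out$cpm[rownames(out$cpm) %in% out$abundant, , drop = FALSE]
      ab_rat <- out$ratios[rownames(out$ratios) %in% out$abundant, ,
                           drop = FALSE]
      out$de_levels <- wilcoxon_de(ab_cpm, classes,
                                   fdr_level = config$fdr_level,
                                   pseudocount = config$log2fc_pseudocount)
      out$de_ratios <- ratio_de(ab_rat, classes,
                                fdr_level = config$fdr_level)
      out$totals <- total_expression_comparison(out$cpm, classes)
      if (!is.null(gene_expr) &&
          all(c("ADAR", "QKI") %in% rownames(gene_expr)))
        out$regcor <- regulator_correlation(ab_cpm, gene_expr,
                                            fdr_level = config$fdr_level)
      if ("eortc" %in% names(clinical))
        out$eortc <- eortc_correlation(
          ab_cpm, stats::setNames(clinical$eortc, clinical$sample_id),
          fdr_level = config$fdr_level)
      fwrite(out$de_levels, fp("de_levels.tsv"), sep = "\t")
      fwrite(out$de_ratios, fp("de_ratios.tsv"), sep = "\t")
      fwrite(out$totals$summary, fp("totals_by_class.tsv"), sep = "\t")
      cors <- rbindlist(list(
        if (!is.null(out$regcor)) out$regcor$per_circ,
        out$eortc), use.names = TRUE, fill = TRUE)
      if (nrow(cors)) fwrite(cors, fp("correlations.tsv"), sep = "\t")
    })
  }

  ## --- survival --------------------------------------------------------
  if (any(c("survival", "report") %in% stages)) {
    if (is.null(clinical)) {
      warning("clinical table not configured; skipping survival stage")
    } else run_stage("survival", function() {
      ab_cpm <- out$cpm[rownames(out$cpm) %in% out$abundant, , drop = FALSE]
      lin_cpm <- out$linear_cpm[rownames(ab_cpm), , drop = FALSE]
      gmap <- out$gene_profile$assignment[gene_id != "intergenic"]
      ge <- if (is.null(gene_expr))
        matrix(0, 0, ncol(ab_cpm), dimnames = list(NULL, colnames(ab_cpm)))
      else gene_expr
      out$triage <- prognostic_triage(ab_cpm, lin_cpm, ge, gmap, clinical,
                                      config$fdr_level)
      fwrite(out$triage, fp("survival_triage.tsv"), sep = "\t")
    })
  }

  ## --- report ----------------------------------------------------------
  if ("report" %in% stages)
    run_stage("report", function() {
      out$profile <- build_circ_profile(out, abundant_cat, config)
      fwrite(out$profile, fp("circ_profile.tsv"), sep = "\t")
      out$summary <- pipeline_summary(out, config)
      sm <- data.table(metric = names(out$summary),
                       value = unlist(lapply(out$summary, format,
                                             digits = 15)))
      fwrite(sm, fp("pipeline_summary.tsv"), sep = "\t")
    })

  invisible(as.list(out))
}

# Combined per-circRNA property ledger over the abundant set. Properties
# needing external resources not part of the pipeline inputs (known cancer
# genes, cell-line and cross-tissue detection) are reported as NA columns.
build_circ_profile <- function(out, abundant_cat, config) {
  prof <- data.table(circ_id = abundant_cat$circ_id)
  gmap <- out$gene_profile$assignment[!duplicated(circ_id)]
  prof[, gene_id := gmap$gene_id[match(circ_id, gmap$circ_id)]]
  cons <- out$conservation[set == "abundant_circ"]
  prof[, conservation_mean := cons$mean_score[match(circ_id,
                                                    cons$feature_id)]]
  alu <- out$alu[set == "abundant_circ"]
  prof[, alu_pair_distance := alu$distance[match(circ_id, alu$feature_id)]]
  prof[, known_cancer_gene := NA]
  prof[, circ_to_lin_gt1 :=
         rowMeans(out$ratios)[match(circ_id, rownames(out$ratios))] > 1]
  if (!is.null(out$sce_oe)) {
    prof[, sce_obs_gt_exp := {
      m <- out$sce_oe$table
      (m$observed_bp > m$expected_bp)[match(circ_id, m$circ_id)]
    }]
  } else prof[, sce_obs_gt_exp := NA]
  prof[, mirna_obs_gt_exp := {
    m <- out$mirna_oe$table
    (m$observed_sites > m$expected_sites)[match(circ_id, m$circ_id)]
  }]
  addcor <- function(tab) {
    if (is.null(tab)) return(rep(NA, nrow(prof)))
    tab$significant[match(prof$circ_id, tab$circ_id)]
  }
  if (!is.null(out$regcor)) {
    prof[, adar_correlated := addcor(out$regcor$per_circ[partner == "ADAR"])]
    prof[, qki_correlated := addcor(out$regcor$per_circ[partner == "QKI"])]
  } else prof[, `:=`(adar_correlated = NA, qki_correlated = NA)]
  prof[, detected_in_cell_lines := NA]
  prof[, eortc_correlated := addcor(out$eortc)]
  de_flag <- function(tab) {
    if (is.null(tab)) return(rep(NA, nrow(prof)))
    tab$significant[match(prof$circ_id, tab$circ_id)]
  }
  prof[, de_class1_vs_2 := de_flag(out$de_levels)]
  prof[, ratio_de_class1_vs_2 := de_flag(out$de_ratios)]
  if (!is.null(out$triage)) {
    tr <- out$triage
    i <- match(prof$circ_id, tr$circ_id)
    prof[, `:=`(km_circ_q = tr$q_circ[i], km_linear_q = tr$q_linear[i],
                km_mrna_q = tr$q_mrna[i],
                independent_prognostic = tr$independent_prognostic[i])]
  } else {
    prof[, `:=`(km_circ_q = NA_real_, km_linear_q = NA_real_,
                km_mrna_q = NA_real_, independent_prognostic = NA)]
  }
  prof[, n_tissues_expressed := NA_integer_]
  prof[, mean_cpm := rowMeans(out$cpm)[match(circ_id, rownames(out$cpm))]]
  setorder(prof, circ_id)
  prof[]
}

# Key-value summary of the run for the top-level report.
pipeline_summary <- function(out, config) {
  s <- list(
    n_detected = sum(out$catalog$detected),
    n_robust = sum(out$catalog$robust),
    n_abundant = length(out$abundant),
    origin_chisq_p = if (!is.null(out$origin)) out$origin$chisq$p_value else NA
  )
  if (!is.null(out$de_levels)) {
    sig <- out$de_levels[significant == TRUE]
    s$n_de_significant <- nrow(sig)
    s$frac_de_up_in_class1 <- if (nrow(sig)) mean(sig$log2_fold_change > 0)
      else NA_real_
  }
  if (!is.null(out$de_ratios))
    s$n_ratio_de_significant <- sum(out$de_ratios$significant)
  if (!is.null(out$regcor))
    s$qki_total_expression_rho <-
      out$regcor$global[partner == "QKI"]$spearman_rho
  if (!is.null(out$eortc))
    s$n_eortc_negative_significant <-
      sum(out$eortc$significant & out$eortc$spearman_rho < 0, na.rm = TRUE)
  if (!is.null(out$triage))
    s$n_independent_prognostic <- sum(out$triage$independent_prognostic)
  if (!is.null(out$conservation)) {
    cons <- out$conservation
    s$mean_conservation_abundant <-
      mean(cons[set == "abundant_circ"]$mean_score, na.rm = TRUE)
    s$mean_conservation_exons <-
      mean(cons[set == "internal_exons"]$mean_score, na.rm = TRUE)
  }
  s
}
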