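# Synthetic study generator. Produces a full cohort — gene models, repeat /
# conservation / SCE / miRNA annotation tracks, backsplice and linear
# junction counts, gene expression, and clinical outcomes — with planted
# effects recorded in a ground-truth object, so each analysis stage can be
# validated against known answers. Cohort composition defaults follow the
# study design the pipeline targets: 96 class-1, 232 class-2 and 129
# class-3 samples (457 NMIBC tumors, 348 Ta / 109 T1).

#' Synthetic cohort design
#'
#' All knobs of the generator with their defaults. Counts are negative
#' binomial (overdispersed, zero-inflation arising from low means);
#' class-wise differential expression is planted mostly as downregulation in
#' class 2; prognostic circles carry a latent-risk expression gradient and
#' the progression hazard is multiplied by `hazard_ratio` for every
#' prognostic circle whose (median-split) expression puts a sample in the
#' low group; censoring is independent and uniform.
#'
#' @param n_class named integer vector of samples per risk class.
#' @param n_genes number of genes on the synthetic chromosome.
#' @param exons_per_gene inclusive range of exon counts per gene.
#' @param exon_len,intron_len inclusive bp ranges.
#' @param gene_spacing bp between consecutive genes.
#' @param frac_ncrna fraction of genes labelled non-coding.
#' @param circ_per_gene_lambda Poisson mean of circles per gene.
#' @param n_planted_enriched circles given abundant-tier baseline expression
#'   and planted annotation enrichment (`Inf` = all circles).
#' @param circ_meanlog,circ_sdlog log-normal baseline mean distribution for
#'   background circles.
#' @param planted_meanlog,planted_sdlog same for planted (abundant-like)
#'   circles.
#' @param dispersion negative binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param frac_de fraction of planted circles that are differentially
#'   expressed between classes 1 and 2.
#' @param de_fold_change fold change applied in class 2.
#' @param frac_up_in_class2 fraction of DE circles whose direction is up in
#'   class 2 (the remainder are downregulated there).
#' @param lin_mean_factor linear-junction mean relative to the circle mean.
#' @param frac_high_ratio fraction of circles with weak linear splicing
#'   (circ-to-lin ratio above 1).
#' @param n_prognostic number of prognostic circles.
#' @param prognostic_mode `"circ"` plants the survival signal in the
#'   circular expression only; `"gene"` co-varies circle, linear counterpart
#'   and parent gene (a host-gene-driven effect the triage must reject).
#' @param prognostic_effect latent-risk log-expression slope.
#' @param hazard_ratio per-low-group multiplier on the progression hazard.
#' @param base_hazard baseline progression hazard per month.
#' @param censor_horizon_months uniform censoring horizon.
#' @param qki_effect exponent tying QKI expression to the per-sample
#'   circRNA-production factor (0 = uncoupled).
#' @param lib_size_range per-sample total mapped reads range.
#' @param alu_planting probability a planted circle receives an inverted
#'   homologous Alu pair in its flanks.
#' @param alu_planted_max_gap maximal gap (bp) between a planted Alu and the
#'   circle edge.
#' @param alu_background_per_kb background Alu density.
#' @param cons_planted_mean,cons_planted_sd conservation score distribution
#'   at planted circle core splice bases.
#' @param cons_exon_mean,cons_exon_sd same at all other exon boundaries.
#' @param sce_rate_planted,sce_rate_background SCE block start rate per bp in
#'   exons of planted circles versus background exons.
#' @param sce_len SCE block length (15 codons).
#' @param mirna_rate_planted,mirna_rate_background miRNA site start rates.
#' @param mirna_len site length.
#' @param n_mirnas,n_experiments sizes of the miRNA and experiment pools.
#' @param sponge_k extra same-miRNA sites given to one designated circle.
#' @param n_decoy_junctions junk backsplice records with sub-threshold
#'   anchor MAPQ (removed by the quality filter).
#' @param seed integer random seed.
#' @return list of class `simulation_design`.
#' @export
simulation_design <- function(n_class = c(class1 = 96L, class2 = 232L,
                                          class3 = 129L),
                              n_genes = 200L,
                              exons_per_gene = c(4L, 8L),
                              exon_len = c(150L, 400L),
                              intron_len = c(800L, 3000L),
                              gene_spacing = 60000L,
                              frac_ncrna = 0.1,
                              circ_per_gene_lambda = 1.2,
                              n_planted_enriched = 40L,
                              circ_meanlog = log(2), circ_sdlog = 1.2,
                              planted_meanlog = log(25), planted_sdlog = 0.6,
                              dispersion = 0.3,
                              frac_de = 0.4,
                              de_fold_change = 2,
                              frac_up_in_class2 = 0.12,
                              lin_mean_factor = 4,
                              frac_high_ratio = 0.15,
                              n_prognostic = 3L,
                              prognostic_mode = c("circ", "gene"),
                              prognostic_effect = 1,
                              hazard_ratio = 3,
                              base_hazard = 1.2e-4,
                              censor_horizon_months = 120,
                              qki_effect = 1,
                              lib_size_range = c(15e6, 45e6),
                              alu_planting = 0.9,
                              alu_planted_max_gap = 2000L,
                              alu_background_per_kb = 0.05,
                              cons_planted_mean = 6.15, cons_planted_sd = 0.5,
                              cons_exon_mean = 5.8, cons_exon_sd = 1.5,
                              sce_rate_planted = 1 / 300,
                              sce_rate_background = 1 / 3000,
                              sce_len = 45L,
                              mirna_rate_planted = 1 / 250,
                              mirna_rate_background = 1 / 2500,
                              mirna_len = 8L,
                              n_mirnas = 30L, n_experiments = 8L,
                              sponge_k = 10L,
                              n_decoy_junctions = 50L,
                              seed = 1L) {
  d <- as.list(environment())
  d$prognostic_mode <- match.arg(prognostic_mode)
  stopifnot(all(d$n_class >= 0L), d$n_genes > 0L, d$dispersion > 0,
            d$hazard_ratio > 0, d$frac_de >= 0, d$frac_de <= 1,
            d$frac_up_in_class2 >= 0, d$frac_up_in_class2 <= 1,
            d$alu_planting >= 0, d$alu_planting <= 1,
            d$frac_ncrna >= 0, d$frac_ncrna < 1)
  class(d) <- "simulation_design"
  d
}

ri <- function(n, range) {
  if (range[1L] == range[2L]) rep(as.integer(range[1L]), n)
  else sample(range[1L]:range[2L], n, replace = TRUE)
}

#' Simulate the genome annotation and circRNA layout
#'
#' Lays genes with at least three exons (so internal-exon controls always
#' exist) on one synthetic chromosome, defines circRNAs over internal exon
#' runs, selects the planted (abundant-intended) subset, and builds every
#' annotation track: inverted homologous Alu pairs in the flanks of planted
#' circles plus uniform background Alus, a conservation track elevated at
#' the four core splice bases of planted circles, and SCE / miRNA sites at
#' higher densities inside planted circles' exons.
#'
#' @param design a [simulation_design()].
#' @return an `annotation_bundle` with two extra elements: `circ_layout`
#'   (the circRNA ground-truth layout) and `genes`.
#' @export
simulate_annotation <- function(design) {
  d <- design
  set.seed(d$seed)
  if (d$exons_per_gene[2L] < 3L)
    stop("design yields no internal exons: genes need at least 3 exons")
  chrom <- "chrS1"
  genes <- data.table(gene_id = sprintf("G%04d", seq_len(d$n_genes)))
  genes$n_exons <- pmax(3L, ri(d$n_genes, d$exons_per_gene))
  genes$strand <- sample(c("+", "-"), d$n_genes, replace = TRUE)
  genes$ncrna <- stats::runif(d$n_genes) < d$frac_ncrna
  # exon coordinates
  exl <- list()
  cursor <- 100000L
  for (i in seq_len(d$n_genes)) {
    ne <- genes$n_exons[i]
    lens <- ri(ne, d$exon_len)
    gaps <- ri(ne - 1L, d$intron_len)
    starts <- cursor + cumsum(c(0L, lens[-ne] + gaps))
    region <- if (genes$ncrna[i]) rep("ncRNA", ne) else
      c("UTR5", rep("CDS", ne - 2L), "UTR3")
    exl[[i]] <- data.table(chrom = chrom, start = starts,
                           end = starts + lens, strand = genes$strand[i],
                           gene_id = genes$gene_id[i],
                           transcript_id = paste0(genes$gene_id[i], ".t1"),
                           region = region, exon_rank = seq_len(ne))
    cursor <- starts[ne] + lens[ne] + d$gene_spacing
  }
  exons <- rbindlist(exl)
  genome_len <- cursor + 100000L

  # circRNAs over internal exon runs
  ncirc <- pmin(stats::rpois(d$n_genes, d$circ_per_gene_lambda),
                genes$n_exons - 2L)
  circl <- list()
  for (i in which(ncirc > 0L)) {
    ex <- exl[[i]]
    internal <- 2L:(genes$n_exons[i] - 1L)
    pick1 <- function(v) v[sample.int(length(v), 1L)]
    for (k in seq_len(ncirc[i])) {
      fe <- pick1(internal)
      le <- pick1(internal[internal >= fe])
      circl[[length(circl) + 1L]] <- data.table(
        gene_id = genes$gene_id[i], chrom = chrom,
        start = ex$start[fe], end = ex$end[le], strand = genes$strand[i],
        first_exon = fe, last_exon = le)
    }
  }
  layout <- unique(rbindlist(circl), by = c("chrom", "start", "end", "strand"))
  setorder(layout, chrom, start, end, strand)
  layout[, circ_id := circ_id(chrom, start, end, strand)]
  n_circ <- nrow(layout)

  n_pl <- min(n_circ, d$n_planted_enriched)
  coding_circ <- which(!genes$ncrna[match(layout$gene_id, genes$gene_id)])
  planted <- if (length(coding_circ) >= n_pl)
    sort(sample(coding_circ, n_pl)) else sort(sample(n_circ, n_pl))
  layout[, planted := FALSE]
  layout$planted[planted] <- TRUE
  layout[, sponge := FALSE]
  if (length(planted)) layout$sponge[planted[1L]] <- TRUE

  # --- Alu repeats ---
  n_bg <- max(1L, round(genome_len / 1000 * d$alu_background_per_kb))
  subfams <- c("AluJb", "AluJo", "AluSx", "AluSz", "AluSg", "AluYa5", "AluYb8")
  bg <- data.table(chrom = chrom,
                   start = sort(sample.int(genome_len - 400L, n_bg)),
                   repeat_name = sample(subfams, n_bg, replace = TRUE),
                   strand = sample(c("+", "-"), n_bg, replace = TRUE))
  bg[, end := start + 300L]
  planted_alu <- list()
  layout[, planted_alu_distance := NA_real_]
  for (j in which(layout$planted)) {
    if (stats::runif(1L) > d$alu_planting) next
    fam <- sample(subfams, 1L)
    gap_up <- sample.int(d$alu_planted_max_gap, 1L)
    gap_dn <- sample.int(d$alu_planted_max_gap, 1L)
    ori <- sample(c("+", "-"), 1L)
    planted_alu[[length(planted_alu) + 1L]] <- data.table(
      chrom = chrom,
      start = c(layout$start[j] - gap_up - 300L, layout$end[j] + gap_dn),
      end = c(layout$start[j] - gap_up, layout$end[j] + gap_dn + 300L),
      repeat_name = fam,
      strand = c(ori, setdiff(c("+", "-"), ori)))
    layout$planted_alu_distance[j] <- gap_up + gap_dn
  }
  repeats <- rbindlist(c(list(bg[, list(chrom, start, end, strand,
                                        repeat_name)]),
                         planted_alu), use.names = TRUE)
  setorder(repeats, chrom, start, end, strand, repeat_name)

  # --- conservation at exon boundaries, elevated at planted backsplices ---
  core <- function(s, e) c(s - 2L, s - 1L, e, e + 1L)
  bound <- unique(data.table(
    pos = as.integer(unlist(Map(core, exons$start, exons$end)))))
  bound[, score := round(stats::rnorm(.N, d$cons_exon_mean, d$cons_exon_sd), 3)]
  pl_pos <- unique(as.integer(unlist(
    Map(core, layout$start[layout$planted], layout$end[layout$planted]))))
  pl <- data.table(pos = pl_pos,
                   score = round(stats::rnorm(length(pl_pos),
                                              d$cons_planted_mean,
                                              d$cons_planted_sd), 3))
  cons <- rbindlist(list(bound[!pos %in% pl$pos], pl))
  setorder(cons, pos)
  conservation <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = cons$pos + 1L, width = 1L),
    score = cons$score)

  # --- SCE and miRNA sites over exons, denser inside planted circles ---
  planted_gr <- gr(layout[planted == TRUE])
  ex_in_planted <- rep(FALSE, nrow(exons))
  if (length(planted_gr)) {
    ov <- GenomicRanges::findOverlaps(gr(exons), planted_gr,
                                      ignore.strand = TRUE, type = "within")
    ex_in_planted[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  scatter <- function(rate_planted, rate_background, elen, cds_only) {
    use <- if (cds_only) exons$region == "CDS" else rep(TRUE, nrow(exons))
    rate <- ifelse(ex_in_planted, rate_planted, rate_background)
    rows <- list()
    for (i in which(use)) {
      w <- exons$end[i] - exons$start[i]
      k <- stats::rpois(1L, w * rate[i])
      if (k == 0L) next
      st <- exons$start[i] + sort(sample.int(max(1L, w - elen), k,
                                             replace = TRUE)) - 1L
      rows[[length(rows) + 1L]] <- data.table(chrom = chrom, start = st,
                                              end = st + elen)
    }
    if (!length(rows)) data.table(chrom = character(), start = integer(),
                                  end = integer()) else rbindlist(rows)
  }
  sce <- scatter(d$sce_rate_planted, d$sce_rate_background, d$sce_len, TRUE)
  sce[, strand := "."]
  mir <- scatter(d$mirna_rate_planted, d$mirna_rate_background,
                 d$mirna_len, FALSE)
  if (nrow(mir)) {
    mir[, mirna_id := sprintf("miR-%03d", sample.int(d$n_mirnas, .N,
                                                     replace = TRUE))]
    mir[, experiment_id := sprintf("exp%02d", sample.int(d$n_experiments, .N,
                                                         replace = TRUE))]
  } else {
    mir[, `:=`(mirna_id = character(), experiment_id = character())]
  }
  sp <- which(layout$sponge)
  if (length(sp) == 1L && d$sponge_k > 0L) {
    fe <- layout[sp]
    gexons <- exons[gene_id == fe$gene_id & start >= fe$start & end <= fe$end]
    if (nrow(gexons)) {
      host <- gexons[1L]
      w <- host$end - host$start
      st <- host$start + sort(sample.int(max(1L, w - d$mirna_len),
                                         d$sponge_k, replace = TRUE)) - 1L
      mir <- rbindlist(list(mir, data.table(
        chrom = chrom, start = st, end = st + d$mirna_len,
        mirna_id = "miR-sponge", experiment_id = "exp01")), use.names = TRUE)
    }
  }
  setorder(mir, chrom, start, end, mirna_id, experiment_id)

  bundle <- list(
    exons = exons,
    repeats = cbind(repeats, subfamily = alu_subfamily(repeats$repeat_name)),
    alus = NULL,
    conservation = conservation,
    sce = sce,
    mirna_sites = mir,
    circ_layout = layout[],
    genes = genes[]
  )
  bundle$alus <- bundle$repeats[!is.na(subfamily)]
  class(bundle) <- "annotation_bundle"
  bundle
}

#' Simulate junction counts, gene expression and ground truth
#'
#' Negative-binomial backsplice counts with per-sample library-size offsets
#' and a shared circRNA-production factor; planted circles get abundant-tier
#' baselines; DE circles are scaled by the class fold change in class 2
#' (direction mostly down there); prognostic circles carry a latent-risk
#' expression gradient; linear junction counts at each circle's two splice
#' sites give the circ-to-lin structure, with a configurable subset of
#' circles exceeding ratio 1; QKI expression is coupled to the per-sample
#' circRNA-production factor.
#'
#' @param design a [simulation_design()].
#' @param bundle result of [simulate_annotation()] for the same design.
#' @return list: `circ_evidence`, `linear_evidence` (junction tables),
#'   `gene_expression` (matrix), `truth` (list with `circles`, `samples`,
#'   `prog_groups`).
#' @export
simulate_counts <- function(design, bundle) {
  d <- design
  set.seed(d$seed + 1L)
  layout <- copy(bundle$circ_layout)
  n_circ <- nrow(layout)
  samples <- data.table(
    sample_id = sprintf("S%03d", seq_len(sum(d$n_class))),
    class = rep(seq_along(d$n_class), d$n_class))
  ns <- nrow(samples)
  samples[, lib_size := stats::runif(ns, d$lib_size_range[1L],
                                     d$lib_size_range[2L])]
  samples[, circ_activity := stats::rlnorm(ns, 0, 0.25)]
  samples[, latent_risk := stats::rnorm(ns) +
            c(0, 0.8, 0.4)[pmin(class, 3L)]]

  layout[, base_mean := ifelse(planted,
                               stats::rlnorm(n_circ, d$planted_meanlog,
                                             d$planted_sdlog),
                               stats::rlnorm(n_circ, d$circ_meanlog,
                                             d$circ_sdlog))]
  # DE planting (among planted circles; classes 1 vs 2)
  layout[, is_de := FALSE]
  layout[, de_direction := NA_character_]
  pl_idx <- which(layout$planted)
  n_de <- round(d$frac_de * length(pl_idx))
  if (n_de > 0L) {
    de_idx <- sort(sample(pl_idx, n_de))
    layout$is_de[de_idx] <- TRUE
    up2 <- stats::runif(n_de) < d$frac_up_in_class2
    layout$de_direction[de_idx] <- ifelse(up2, "up_in_class2",
                                          "down_in_class2")
  }
  # prognostic planting
  layout[, is_prognostic := FALSE]
  n_prog <- min(d$n_prognostic, length(pl_idx))
  prog_idx <- if (n_prog > 0L) sort(sample(pl_idx, n_prog)) else integer()
  layout$is_prognostic[prog_idx] <- TRUE
  # circ-to-lin structure
  layout[, high_ratio := stats::runif(n_circ) < d$frac_high_ratio]
  layout[, lin_mean := ifelse(high_ratio, base_mean / d$lin_mean_factor,
                              base_mean * d$lin_mean_factor)]

  libfac <- samples$lib_size / mean(samples$lib_size)
  act <- samples$circ_activity
  z <- samples$latent_risk
  size <- 1 / d$dispersion

  mu <- outer(layout$base_mean, libfac * act)
  defac <- matrix(1, n_circ, ns)
  cls2 <- samples$class == 2L
  if (n_de > 0L) {
    dn <- layout$is_de & layout$de_direction == "down_in_class2"
    up <- layout$is_de & layout$de_direction == "up_in_class2"
    defac[dn, cls2] <- 1 / d$de_fold_change
    defac[up, cls2] <- d$de_fold_change
  }
  progfac <- matrix(1, n_circ, ns)
  if (length(prog_idx))
    progfac[prog_idx, ] <- exp(-d$prognostic_effect *
                                 matrix(z, length(prog_idx), ns, byrow = TRUE))
  mu <- mu * defac * progfac
  counts <- matrix(stats::rnbinom(n_circ * ns, mu = mu, size = size),
                   n_circ, ns, dimnames = list(layout$circ_id,
                                               samples$sample_id))

  # linear junction counts at the two splice sites of each circle
  lin_mu <- outer(layout$lin_mean, libfac)
  if (d$prognostic_mode == "gene" && length(prog_idx))
    lin_mu[prog_idx, ] <- lin_mu[prog_idx, ] * progfac[prog_idx, ]
  lin_a <- matrix(stats::rnbinom(n_circ * ns, mu = lin_mu / 2, size = size),
                  n_circ, ns)
  lin_b <- matrix(stats::rnbinom(n_circ * ns, mu = lin_mu / 2, size = size),
                  n_circ, ns)

  # junction evidence tables (zero-count cells omitted)
  ev_from <- function(cnt, coords, mapq = TRUE) {
    idx <- which(cnt > 0L, arr.ind = TRUE)
    ev <- data.table(chrom = coords$chrom[idx[, 1L]],
                     start = coords$start[idx[, 1L]],
                     end = coords$end[idx[, 1L]],
                     strand = coords$strand[idx[, 1L]],
                     sample_id = samples$sample_id[idx[, 2L]],
                     n_reads = cnt[idx])
    if (mapq) {
      ev[, mapq_anchor1 := sample(35:42, .N, replace = TRUE)]
      ev[, mapq_anchor2 := sample(35:42, .N, replace = TRUE)]
    }
    setorder(ev, chrom, start, end, strand, sample_id)
    ev
  }
  circ_ev <- ev_from(counts, layout)
  if (d$n_decoy_junctions > 0L) {
    dec <- data.table(
      chrom = layout$chrom[1L],
      start = sample.int(max(layout$end), d$n_decoy_junctions),
      strand = sample(c("+", "-"), d$n_decoy_junctions, replace = TRUE),
      sample_id = sample(samples$sample_id, d$n_decoy_junctions,
                         replace = TRUE),
      n_reads = sample(2:5, d$n_decoy_junctions, replace = TRUE),
      mapq_anchor1 = sample(5:34, d$n_decoy_junctions, replace = TRUE),
      mapq_anchor2 = sample(20:42, d$n_decoy_junctions, replace = TRUE))
    dec[, end := start + sample(200:5000, .N, replace = TRUE)]
    circ_ev <- rbindlist(list(circ_ev, dec), use.names = TRUE)
    setorder(circ_ev, chrom, start, end, strand, sample_id)
  }
  # linear junctions: upstream intron (ending at circle start) and
  # downstream intron (starting at circle end)
  exons <- bundle$exons
  up_coord <- dn_coord <- copy(layout)
  for (j in seq_len(n_circ)) {
    gex <- exons[gene_id == layout$gene_id[j]][order(start)]
    fe <- layout$first_exon[j]; le <- layout$last_exon[j]
    up_coord$start[j] <- gex$end[fe - 1L]
    up_coord$end[j] <- gex$start[fe]
    dn_coord$start[j] <- gex$end[le]
    dn_coord$end[j] <- gex$start[le + 1L]
  }
  lin_ev <- rbindlist(list(ev_from(lin_a, up_coord, mapq = FALSE),
                           ev_from(lin_b, dn_coord, mapq = FALSE)))
  lin_ev <- lin_ev[, list(n_reads = sum(n_reads)),
                   by = c("chrom", "start", "end", "strand", "sample_id")]
  setorder(lin_ev, chrom, start, end, strand, sample_id)

  # gene expression: host genes + regulators QKI and ADAR
  genes <- bundle$genes
  gbase <- stats::rlnorm(nrow(genes), log(50), 1)
  gexpr <- outer(gbase, libfac / libfac) *
    matrix(stats::rlnorm(nrow(genes) * ns, 0, 0.3), nrow(genes), ns)
  rownames(gexpr) <- genes$gene_id
  colnames(gexpr) <- samples$sample_id
  if (d$prognostic_mode == "gene" && length(prog_idx)) {
    pg <- unique(layout$gene_id[prog_idx])
    gexpr[pg, ] <- gexpr[pg, , drop = FALSE] *
      matrix(exp(-d$prognostic_effect * z), length(pg), ns, byrow = TRUE)
  }
  qki <- 100 * act^d$qki_effect * stats::rlnorm(ns, 0, 0.15)
  adar <- 100 * stats::rlnorm(ns, 0, 0.3)
  gexpr <- rbind(gexpr, QKI = qki, ADAR = adar)

  # prognostic groups from the realized CPM (median split; ties low)
  cpm <- sweep(counts, 2L, samples$lib_size, "/") * 1e6
  prog_groups <- NULL
  if (length(prog_idx)) {
    prog_groups <- matrix(FALSE, length(prog_idx), ns,
                          dimnames = list(layout$circ_id[prog_idx],
                                          samples$sample_id))
    for (k in seq_along(prog_idx)) {
      v <- cpm[prog_idx[k], ]
      prog_groups[k, ] <- v <= stats::median(v)  # TRUE = low group
    }
  }
  truth <- list(
    circles = layout[, list(circ_id, gene_id, chrom, start, end, strand,
                            planted, base_mean, is_de, de_direction,
                            is_prognostic, high_ratio,
                            is_enriched_sce = planted,
                            is_enriched_mirna = planted,
                            planted_alu_distance, sponge)],
    samples = samples[],
    prog_groups = prog_groups
  )
  list(circ_evidence = circ_ev, linear_evidence = lin_ev,
       gene_expression = gexpr, truth = truth)
}

#' Simulate the clinical table
#'
#' Progression times are exponential: each sample's hazard is the base
#' hazard multiplied by the design hazard ratio once for every prognostic
#' circle whose median-split expression puts the sample in the low group
#' (low circRNA expression marks aggressive disease here). Censoring is
#' independent uniform over the follow-up horizon. The EORTC score is
#' monotone increasing in the latent risk; stage and grade are drawn with
#' risk-dependent probabilities.
#'
#' @param design a [simulation_design()].
#' @param truth ground-truth list from [simulate_counts()].
#' @return clinical data.table (`sample_id`, `class`, `stage`, `grade`,
#'   `eortc`, `library_size`, `time_months`, `progressed`).
#' @export
simulate_clinical <- function(design, truth) {
  d <- design
  set.seed(d$seed + 2L)
  s <- truth$samples
  ns <- nrow(s)
  k_low <- if (is.null(truth$prog_groups)) rep(0L, ns) else
    colSums(truth$prog_groups)
  hazard <- d$base_hazard * d$hazard_ratio^k_low
  t_event <- stats::rexp(ns, rate = hazard)
  censor <- stats::runif(ns, 0, d$censor_horizon_months)
  time <- pmin(t_event, censor)
  progressed <- as.integer(t_event <= censor)
  time <- pmax(time, 0.01)  # strictly positive follow-up
  z <- s$latent_risk
  eortc <- as.integer(floor(23 * (rank(z, ties.method = "first") - 0.5) / ns))
  p_t1 <- stats::plogis(z - 1.5)
  stage <- ifelse(stats::runif(ns) < p_t1, "T1", "Ta")
  grade <- ifelse(stats::runif(ns) < stats::plogis(z - 1), "high", "low")
  data.table(sample_id = s$sample_id, class = s$class, stage = stage,
             grade = grade, eortc = eortc, library_size = s$lib_size,
             time_months = time, progressed = progressed)
}

#' Generate and write a complete synthetic cohort
#'
#' Runs [simulate_annotation()], [simulate_counts()] and
#' [simulate_clinical()], writes every input file the pipeline readers
#' consume (junction tables, exon GTF, repeat TSV, conservation bedGraph,
#' SCE BED, miRNA TSV, gene expression matrix, clinical table) plus the
#' ground truth (never read by analysis stages), and returns a ready
#' [circ_config()].
#'
#' @param design a [simulation_design()].
#' @param outdir output directory (created if missing).
#' @param ... further arguments passed to [circ_config()].
#' @return a `circ_config` whose paths point at the written files; the
#'   ground truth is attached as attribute `"truth"`.
#' @export
simulate_cohort <- function(design, outdir, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  bundle <- simulate_annotation(design)
  sim <- simulate_counts(design, bundle)
  clinical <- simulate_clinical(design, sim$truth)
  fp <- function(x) file.path(outdir, x)

  write_junction_table(sim$circ_evidence, fp("circ_junctions.tsv"))
  write_junction_table(sim$linear_evidence, fp("linear_junctions.tsv"))
  eg <- gr(bundle$exons)
  S4Vectors::mcols(eg) <- S4Vectors::DataFrame(
    type = "exon", gene_id = bundle$exons$gene_id,
    transcript_id = bundle$exons$transcript_id,
    region = bundle$exons$region)
  rtracklayer::export(eg, fp("exons.gtf"), format = "gtf")
  fwrite(bundle$repeats[, list(chrom, start, end, strand, repeat_name)],
         fp("repeats.tsv"), sep = "\t")
  rtracklayer::export(bundle$conservation, fp("conservation.bedGraph"),
                      format = "bedGraph")
  rtracklayer::export(gr(bundle$sce), fp("sce.bed"), format = "bed")
  fwrite(bundle$mirna_sites, fp("mirna_sites.tsv"), sep = "\t")
  write_matrix_tsv(sim$gene_expression, fp("gene_expression.tsv"),
                   id_col = "gene_id")
  fwrite(clinical, fp("clinical.tsv"), sep = "\t")

  fwrite(sim$truth$circles, fp("ground_truth_circles.tsv"), sep = "\t")
  fwrite(sim$truth$samples, fp("ground_truth_samples.tsv"), sep = "\t")

  cfg <- circ_config(paths = list(
    circ_junctions = fp("circ_junctions.tsv"),
    linear_junctions = fp("linear_junctions.tsv"),
    exons = fp("exons.gtf"),
    repeats = fp("repeats.tsv"),
    conservation = fp("conservation.bedGraph"),
    sce = fp("sce.bed"),
    mirna_sites = fp("mirna_sites.tsv"),
    gene_expression = fp("gene_expression.tsv"),
    clinical = fp("clinical.tsv")
  ), seed = design$seed, outdir = outdir, ...)
  attr(cfg, "truth") <- sim$truth
  cfg
}
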