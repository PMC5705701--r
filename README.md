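# circprog

Circular RNAs (circRNAs) are covalently closed transcripts produced when a
downstream splice donor joins an upstream acceptor (a backsplice). Their
stability makes them attractive prognostic biomarkers, but their signal is
confounded by the host gene: a circle whose expression merely tracks its
parent mRNA adds nothing to what the linear transcript already tells the
clinician. `circprog` implements the full analysis chain for a bulk
RNA-seq tumor cohort — non-muscle-invasive bladder cancer (NMIBC) being the
motivating setting — that takes per-sample backsplice junction evidence to
a ranked set of circRNAs whose association with progression-free survival
is *independent* of both the linear counterpart and the parent gene.

The pipeline stages:

1. **Catalog** — backsplice calls are filtered on both anchor mapping
   qualities (MAPQ ≥ 35) and tiered: *detected* (≥2 reads), *robust*
   (≥2 reads in ≥2 samples), *abundant* (expressed in ≥30 samples, ≥20
   reads in at least one). Counts are CPM-normalised by library size, and
   each circle gets a per-sample circular-to-linear ratio
   `(c+1)/(l+1)`, where `l` sums the linear junction reads using the same
   two splice sites.
2. **Annotation** — genomic origin of splice sites under the hierarchy
   CDS > 3′-UTR > 5′-UTR > ncRNA (6 bp window); collapsed exon structure;
   the closest pair of inverted homologous Alu repeats (same subfamily
   class, opposite strands, one per 20 kb flank, distance = summed gaps);
   mean conservation of the four core splice-site bases.
3. **Enrichment** — synonymous constraint elements (SCEs) and AGO-CLIP
   miRNA target sites, as containment fractions over hierarchically
   assigned coding-exon groups (abundant > non-abundant > linear) and as
   per-circle observed-versus-expected statistics under a
   proportional-length null; plus the same-miRNA "sponge" statistic.
4. **Differential expression** — two-sided Wilcoxon rank-sum tests between
   risk classes 1 and 2 on CPM and on circ-to-lin ratios, BH-corrected at
   FDR < 0.1; Spearman correlations with the biogenesis regulators ADAR
   and QKI and with the EORTC progression score.
5. **Prognosis** — per circle, three median-split log-rank tests
   (circular, linear counterpart, parent mRNA) against progression to
   muscle-invasive disease, BH within each family; a circle is flagged
   independently prognostic when only the circular test survives.

A synthetic-cohort generator (`simulation_design()` / `simulate_cohort()`)
reproduces the study design — 96/232/129 samples in risk classes 1/2/3,
negative-binomial junction counts, ~31 progression events among 457
patients — with planted DE, enrichment and survival effects, so every
stage is validated against ground truth.

## Worked example

```r
library(circprog)

design <- simulation_design(seed = 1)        # the default 457-sample cohort
cfg    <- simulate_cohort(design, "cohort")  # writes all pipeline inputs
res    <- run_pipeline(cfg)                  # writes TSVs to cfg$outdir
str(res$summary)
```

```
List of 12
 $ n_detected                  : int 187
 $ n_robust                    : int 187
 $ n_abundant                  : int 102
 $ origin_chisq_p              : num 6.6e-16
 $ n_de_significant            : int 16
 $ frac_de_up_in_class1        : num 1
 $ n_ratio_de_significant      : int 18
 $ qki_total_expression_rho    : num 0.795
 $ n_eortc_negative_significant: int 11
 $ n_independent_prognostic    : int 4
 $ mean_conservation_abundant  : num 6
 $ mean_conservation_exons     : num 5.8
```

Of 187 cataloged circles, 102 reach the abundant tier; 16 are
differentially expressed between risk classes (all upregulated in the
good-prognosis class 1, consistent with the planted direction), total
circRNA output correlates with QKI expression (Spearman ρ = 0.795), and
abundant circles' splice sites score higher conservation (6.0) than
internal exons (5.8). The triage flags 4 circles as prognostic
independently of their linear transcript and parent gene:

```r
res$triage[res$triage$independent_prognostic, c("circ_id", "q_circ", "q_linear")]
#                      circ_id       q_circ  q_linear
# 1:   chrS1:1026115-1027510:+ 5.068807e-04 0.9624503
# 2:   chrS1:7628580-7628952:- 2.765046e-02 0.9935361
# 3: chrS1:10166609-10166778:+ 9.607950e-06 0.9754934
# 4: chrS1:13955093-13961656:+ 2.759440e-05 0.9624503
```

(three of the four are the generator's planted prognostic circles; the
fourth is a planted-DE circle whose class-linked expression genuinely
tracks the latent risk).

A thin CLI wraps the same functions:

```sh
exec/circprog simulate --outdir cohort --seed 1
exec/circprog all --config cohort/config.yaml --outdir results
```

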