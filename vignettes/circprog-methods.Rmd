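---
title: "circprog: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circprog: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`circprog` analyses circular RNA (circRNA) expression in a tumor cohort from
backsplice junction evidence. The pipeline covers catalog construction and
filtering, circular-to-linear quantification, genomic and evolutionary
annotation, element-enrichment statistics, class-wise differential
expression, and a Kaplan–Meier/log-rank triage that asks whether a circRNA's
prognostic signal is independent of its linear counterpart and parent gene.
A synthetic-cohort generator with planted effects provides ground truth for
every stage. This vignette records the models, the parameter choices, and
the design decisions that were genuinely open.

# The catalog model

A circRNA is identified by its backsplice key `(chrom, start, end, strand)`
in 0-based half-open coordinates; strand `"."` is allowed and treated as a
distinct key, and backsplice calls are preserved with whatever strand the
upstream caller reported. Three nested tiers structure all analyses:

* **detected** — at least 2 backsplice reads in at least one sample;
* **robust** — at least 2 reads in at least 2 different samples (the working
  set for annotation, ratios, and per-gene profiles);
* **abundant** — expressed in at least 30 samples and supported by at least
  20 reads in at least one sample (the set carried into enrichment, DE and
  survival).

Backsplice evidence is pre-filtered on the mapping quality of both anchor
alignments (MAPQ ≥ 35, inclusive). "Expressed in a sample" for the abundance
filter is not defined by the tier quotes themselves; we use count ≥ 2, the
same support level as detection, and expose it as `expressed_min`.

The linear counterpart of a circle is the sum of linearly spliced reads
using the circle's two splice sites (donor-side plus acceptor-side
junctions). A single sequenced fragment whose junction touches both sites
cannot be disambiguated from count tables; it contributes once per site
listing, a documented approximation. Circular-to-linear ratios are
`(circ + 1)/(lin + 1)` per sample; the pseudocount avoids division by zero
and preserves the ordering circ > lin ⇔ ratio > 1.

CPM normalisation divides by the per-sample total mapped library size from
the clinical table (not by total backsplice reads, which would understate
depth); when no clinical table is supplied the column sums are used with a
warning.

# Genomic annotation

**Origin.** A 6 bp window (±3 bp) around each splice site is intersected
with region-labelled exons under the fixed hierarchy
CDS > 3′-UTR > 5′-UTR > ncRNA; windows hitting nothing are `none`. Both
site-count and read-weighted fractions are reported, and the circular
versus linear site distributions are compared with a Pearson chi-square
without continuity correction (multi-class table); classes empty in both
sets are dropped with a warning.

**Exon structure.** Exons are clipped to the backsplice span, unioned, and
counted; introns are assumed spliced out. Non-exonic circles fall back to
their genomic span length.

**Inverted Alu pairs.** The Alu subfamily class is the leading
`Alu` + family-letter prefix of the RepeatMasker name (`AluJ`, `AluS`,
`AluY`); same-class repeats are treated as homologous. For each feature the
two 20 kb flanks are searched for the opposite-strand same-class pair
minimising `max(0, start − up_end) + max(0, down_start − end)` — the summed
gap, i.e. the pair distance omitting the feature itself. We interpret
"closest distance" as this sum (the span the pairing stem must bridge)
rather than the smaller of the two gaps; an Alu belongs to a flank if ≥1 bp
falls inside it, and gaps of edge-overlapping Alus clamp to 0. The search is
validated against an exhaustive pair scan. Internal spliced exons (all
transcripts with ≥3 exons, first and last exon removed) are the
linear-splicing control set.

**Conservation.** The score of a feature is the mean per-base conservation
(PhyloP-style track) over the four core splice nucleotides. "Two bases
upstream and downstream" is directionally ambiguous; we default to the
intronic dinucleotides (positions `start−2`, `start−1`, `end`, `end+1`),
where the canonical GT/AG signals sit, and expose `side = "exonic"` as the
alternative. Missing positions are skipped and the coverage reported; the
four scores of one feature are averaged jointly (not per site first).

# Element enrichment

Coding exons are collapsed exon unions with ≥90% of their bases in CDS
annotation (boundary inclusive). A coding exon is circularized by a circle
when it lies fully within the circle's span — full containment is the only
observable notion of "100% overlap" given that internal transcript
structure is not measured. Exons are assigned to exactly one group with
precedence abundant > non-abundant > linear-only.

Two deliberately different statistics are used, mirroring the two
procedures they feed:

* containment/coverage uses **merged** element intervals (a length), with
  per-group containment fractions compared pairwise by Pearson chi-square
  and per-bp coverage by Wilcoxon rank-sum;
* the observed-vs-expected miRNA analysis counts **unmerged** sites (a
  count), since distinct overlapping sites are distinct binding events.

Expectations are proportional-length null models: `P_SCE` is total SCE
overlap per bp of unique abundant circularized coding exons, and a circle's
expected overlap is `P_SCE ×` its own coding length; the miRNA analogue
uses sites per bp over included circles (exonic circles with introns
spliced out; non-exonic circles shorter than 10 kb). On a partition fixture
(each exon in exactly one circle) the expected and observed totals agree
identically, which the tests verify to 1e-9. Observed site counts are not
deduplicated across experiments (the atlas records each experiment's
evidence separately); the sponge statistic then reports the maximal number
of sites for one (miRNA, experiment) pair within a circle, ties broken
lexicographically. Restriction to conserved miRNAs is an input-table
filter, not a computation.

# Cohort statistics

Differential expression between risk classes 1 and 2 (class 3, the
basal-like group, is excluded by default) uses the two-sided Wilcoxon
rank-sum test on CPM rows, with BH adjustment across tested circles and
significance at FDR < 0.1. The p-value branch is fixed for bit-level
reproducibility: exact permutation p when the smaller group has ≤8 samples
and no ties, else the normal approximation with tie and continuity
corrections. `log2FC = log2((mean₁+1)/(mean₂+1))` so positive values mean
higher in class 1; the 1-CPM pseudocount is configurable. Whether to test
CPM or raw counts was open; we default to CPM so that library size does not
drive the ranks, and note that rank tests on raw counts are the
alternative. The same machinery applied to ratio rows separates
circle-specific regulation from host-gene effects. Each analysis (levels,
ratios, each correlation partner) forms its own BH family.

Spearman correlations link each circle's CPM to regulator expression (ADAR,
QKI) and to the EORTC progression score, plus a global correlation of total
circRNA output with each regulator.

# Prognostic triage

For each circle, samples are median-split (high = strictly greater than the
median, so the heavy zero mass of circRNA counts falls in the low group —
the tie rule was open and this choice keeps zero-inflated vectors
testable), and two-group log-rank tests are run on progression-free
survival for (i) the circular CPM, (ii) the linear-counterpart CPM at the
same splice sites, and (iii) the parent gene's expression. The log-rank
statistic is the standard hypergeometric observed-minus-expected sum
referred to χ²(1); the Kaplan–Meier estimator is the product-limit form
with censorings at an event time still at risk at that time. Each of the
three measurement families is BH-adjusted separately over all
non-degenerate tests (degenerate splits are excluded and noted; the
testable family size is reported rather than assumed). A circle is
*independently prognostic* when the circular test is significant
(q < 0.1) while neither the linear nor the mRNA test is; an untestable
linear/mRNA vector cannot veto. The progression event is transition to
muscle-invasive disease; no multivariate adjustment or optimal-cutoff
search is attempted — the median split is used as-is.

# The synthetic cohort

The generator emulates the targeted study design: 96 class-1, 232 class-2
and 129 class-3 samples (457 in total), and a baseline progression hazard
calibrated so that roughly 31 of 457 samples progress before censoring,
matching the event scarcity such cohorts exhibit. One synthetic chromosome
carries 200 genes (4–8 exons of 150–400 bp, introns 0.8–3 kb, 60 kb
spacing, 10% non-coding); circRNAs arise over internal exon runs so that
internal-exon controls always exist.

Counts are negative binomial (dispersion 0.3 by default) with per-sample
library-size offsets and a shared log-normal circRNA-production factor;
zero-inflation emerges from low means rather than a separate parameter,
keeping the model minimal. A planted subset of circles (default 40)
receives abundant-tier baselines (log-normal around 25 reads) and carries
the planted annotation: inverted homologous Alu pairs within 2 kb of the
flanks (probability 0.9), conservation ~N(6.15, 0.5) at the four core
splice bases versus ~N(5.8, 1.5) at other exon boundaries, and denser
SCE/miRNA tracks; one designated circle receives 10 same-miRNA sites as a
sponge positive control. Differential expression is planted in 40% of the
planted circles as a 2-fold change, 88% of it downregulation in class 2.
QKI expression is coupled to the circRNA-production factor; ADAR is
independent. Three prognostic circles carry an expression gradient in a
latent per-sample risk variable; the hazard is multiplied by 3 for every
prognostic circle whose median-split group puts the sample low (linking
hazard to the group, not the continuous value, keeps the triage target
well-defined). In `prognostic_mode = "gene"` the linear counterpart and the
parent gene co-vary too — the negative control the triage must reject. The
EORTC score is a deterministic monotone transform of the latent risk.

What the generator does **not** emulate: read-level errors and mappability
(junction records are consumed, not reads), correlated gene networks,
isoform structure inside circles, batch effects, and real genome repeat or
conservation landscapes. Passing tests therefore demonstrate the
correctness and calibration of the statistical machinery under the stated
generative model, not performance on real sequencing data.

# Numerical choices and degenerate inputs

* All coordinates are normalised once at the readers (GTF 1-based
  inclusive → 0-based half-open; BED/bedGraph pass through) and validated.
* Catalog ordering and all outputs are sorted lexicographically so reruns
  are byte-identical; `set.seed(config$seed)` anchors any randomised stage.
* Constant expression rows: DE reports p = 1 with a flag; median splits are
  flagged degenerate and excluded from their BH family.
* Chi-square contrasts drop region classes empty in both groups (warning);
  a single shared class yields statistic 0 rather than an error.
* Conservation positions outside the track are missing, skipped in the
  mean, with the per-feature coverage reported; all-missing features are
  flagged undefined rather than given a score.
* BH is the standard step-up, capped at 1; p-values are validated to
  [0, 1].

# Problem sizes used in validation

The shipped test-suite and acceptance checks run at desk scale, chosen to
exercise every code path while completing in minutes: the Alu oracle
comparison uses 1,000 features against 10,000 repeats; DE recovery uses 20
seeded cohorts of ~300 circles at 100 samples per class with 2-fold planted
effects; triage recovery uses 20 seeded cohorts of 300 samples with ~30
progression events; type-I checks pool 200 null replicates per statistic;
and the determinism check reruns the full default 457-sample pipeline
twice. The catalog sizes these runs produce (hundreds of circles rather
than tens of thousands) reflect the synthetic genome's size, not an
algorithmic limit; all interval machinery is overlap-indexed and scales to
genome-wide annotation.

# Known limitations

* The linear-counterpart sum can double-count fragments spanning both
  sites of very short circles (documented approximation).
* Spearman p-values with heavily tied (zero-inflated) rows use the
  asymptotic approximation; exact tie-corrected permutation p-values are
  not implemented.
* The triage is univariate by construction; covariate adjustment (stage,
  grade, EORTC) is deliberately out of scope.
* Whether a minus-strand backsplice caller flips coordinates is
  caller-specific; keys are taken as given, so mixed-caller inputs should
  be harmonised upstream.
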