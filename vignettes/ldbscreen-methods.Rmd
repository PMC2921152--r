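---
title: "Methods: target-gene selection, binding-site enrichment and modifier-screen statistics"
author: "ldbscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target-gene selection, binding-site enrichment and modifier-screen statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldbscreen)
```

# Scope and scientific setting

The CHIP/LDB nuclear adaptors assemble tissue-specific transcription
complexes in *Drosophila* — with the LIM-homeodomain factor APTEROUS (AP)
in the wing, and with the GATA factor PANNIER (PNR) in the thorax. SSDP, a
single-stranded-DNA-binding cofactor, stabilises these complexes and is
rate-limiting for their activity. `ldbscreen` implements the three
computational stages used to characterise downstream targets of these
complexes:

1. **Expression screen** — select candidate target genes from two-channel
   microarray comparisons of *ssdp* trans-heteroallelic mutants against
   their corresponding single heterozygotes.
2. **Binding-site enrichment** — test whether upstream regions of the
   candidates are enriched for binding sites of SSDP, AP, PNR or any other
   supplied matrix, by two independent algorithms (threshold scan +
   hypergeometric test; HMM promoter scoring + rank test).
3. **Modifier-screen statistics** — quantify dominant genetic interactions
   in sensitized backgrounds: ordinal wing-notching severity
   distributions, and binomial scutellar-bristle duplication counts, with
   the calling rules used to build gene-by-sensitizer interaction tables.

Because the original raw hybridizations and genome assembly are not
packaged, every stage is paired with a seeded synthetic-data generator
(`simulation_config()` and friends) that reproduces the statistical
structure each stage assumes. This keeps the whole pipeline runnable and
testable offline; the packaged replica of the published interaction table
is the only real data shipped.

# Synthetic-data generator

The generator is first-class, tested code, not a fixture. Its defaults
describe the study design being emulated: 22 two-channel hybridizations
over ~14,000 transcripts, two replicate spots per gene (duplicate array
elements are a feature of these arrays and are never averaged), 16
print-tip groups, and 500 bp upstream regions. Sizes are freely scaled
down in examples and tests; the structure does not change.

* **Promoters** are order-0 sequences parameterized only by GC content
  (default 0.43, typical of fly non-coding sequence). An order-0
  background keeps the enrichment null analytically computable, which the
  threshold-scan method exploits. Real promoters have higher-order
  composition, CpG-like heterogeneity and repeats; passing tests on this
  background therefore validates the statistics, not robustness to
  genomic sequence quirks.
* **Planted sites** are sampled column-wise from a motif's probability
  matrix (optionally flattened toward uniform by `affinity_jitter`, giving
  sites of varying affinity), written at non-overlapping uniform positions
  on a random strand, with a Poisson site count per promoter. Overlapping
  placements are resampled up to 100 times, then dropped with a warning,
  so the annotation table is always an exact record of what was written.
* **Expression** is generated on the log2 scale and exponentiated:
  channel intensities are base expression + per-array dye bias + a
  per-print-tip quadratic intensity-dependent ratio distortion + genotype
  effect + noise. Arrays alternate mutant / heterozygote-control labels
  across two contrast pairs, mirroring the mutant-vs-heterozygote design.
  A chosen fraction of genes carries ±`de_log2_effect` in mutant arrays;
  the truth table records the signs.
* **Crosses**: wing severity counts are multinomial draws from
  exponentially tilted control class probabilities
  (p_c ∝ p^ctrl_c · e^{shift·c}), so `shift` moves mass smoothly toward
  severe (enhancer) or mild (suppressor) classes; bristle-duplication
  counts are binomial. Vial-level structure is flattened, as the original
  crosses were pooled across vials.

All generators are pure functions of (config, seed); randomness is
confined to a local RNG so callers' streams are untouched.

# Expression screen

Normalisation follows standard two-colour practice: within arrays, a
loess fit of M = log2(ch1/ch2) on A = mean log2 intensity is subtracted
per print-tip group (span 0.3, degree-1 local regression with tricube
weights via `limma::loessFit`); between arrays, the two log2 channel
vectors of every array are quantile-normalised jointly onto the mean of
the order statistics (`limma::normalizeQuantiles`) and M/A are recomputed.
Quantile normalisation is idempotent, which the tests assert.

Elements whose intensity is strictly below the per-array median in *both*
channels are flagged and excluded downstream; ties with the median are
retained ("lower than" is read strictly), and no other background
correction is applied.

Per gene, a fixed-effect linear model of M with a genotype-class factor
(mutant vs control) — plus a contrast-pair covariate when more than one
pair is present — is fitted across all hybridizations; the F-test of the
genotype term gives the raw p-value. This is the minimal fixed model
consistent with comparing each heteroallelic combination with its own
heterozygote controls; whether dye or array should enter as covariates is
genuinely open, and the minimal model was chosen and is recorded in the
output metadata. Duplicate spots enter as independent replicates. Genes
with fewer than two usable observations in either class are reported with
missing p and excluded from correction rather than imputed. A constant
response (zero variance) is reported as F = 0, p = 1; a zero-residual fit
with a real effect as F = ∞, p = 0. Benjamini–Hochberg correction
(`p.adjust`, validated against a brute-force step-up oracle) and a q < 0.05
cut select targets, partitioned by the sign of the mutant-minus-control
effect (down = lower in mutants; an exactly zero effect — a measure-zero
event — is excluded).

# Binding-site enrichment

## Motif matrices

Matrices are 4×W column-stochastic probability matrices. A single
published site (the poly-pyrimidine SSDP element) is converted to a
matrix by indicator columns corrected with a symmetric pseudocount ε
(default 0.1): the observed base gets (1+ε)/(1+4ε), others ε/(1+4ε). The
exact SSDP site sequence is not redistributed; the packaged
`ssdp_placeholder_matrix()` is a synthetic poly-pyrimidine stand-in,
clearly labelled non-canonical and meant to be replaced by the user's own
site. TRANSFAC-format flat files are parsed with a configurable count
pseudocount; curated TRANSFAC releases are licensed and not shipped, so
the packaged matrix file contains synthetic records for testing the
parser and pipeline.

## Threshold-scan method (PRIMA-style)

Window scores are log2-odds against an order-0 background,
discretised to a grain of 0.001 bits. The discretisation lets the *exact*
null score distribution be computed by dynamic programming (a dense
convolution over matrix columns), and the scan threshold is then an exact
null quantile (default 0.999) rather than an estimate. Both strands are
scanned — binding sites are double-stranded features — and a gene is a
hit if any window reaches the threshold; windows containing ambiguous
bases are skipped and counted. Enrichment of hit genes in the target set
against the background set (of which the targets are a subset) is the
upper-tail hypergeometric probability. Within each method × gene-set
stratum, BH correction runs across the matrix library, mirroring the
practice of testing one full matrix collection at a time.

## HMM method (DEMON-style)

The published description of the HMM scorer fixes its intent — one HMM
per binding site, a score per HMM–promoter pair reflecting how likely the
motif appears in the promoter, tolerance of multiple sites of varying
affinity, and a set-vs-background p-value — but not its topology or
p-value mechanism. The package's realisation is the minimal model
matching every stated property: a single background state B (emitting
background base frequencies) plus a left-to-right match block M1..MW
(emitting the matrix columns), with transitions B→B (1−τ), B→M1 (τ),
Mi→Mi+1 (1), MW→B (1) and initial distribution (1−τ, τ, 0, …). The
return transition lets one promoter harbour several sites; τ defaults to
1/promoter-length (one expected site entry per promoter). The score is
the forward-algorithm log-likelihood ratio against the background-only
model, computed in log space (zero-probability emissions propagate as
−Inf without numeric fault), on both strands with the larger taken.
Whether a single-stranded binder like SSDP should be scanned
single-stranded is not settled; both-strand scanning is applied uniformly
and is configurable at the scan level. Set-level enrichment is a
one-sided rank-sum test of target scores against non-target background
scores (exact enumeration when both sets have ≤ 8 promoters, else the
normal approximation with tie correction).

The forward pass is validated exhaustively: for a width-3 motif HMM its
likelihood matches an independent path-enumeration oracle over **all**
4^8 sequences of length 8 to 1e-9, and the null score DP matches
enumeration of all 4^W windows for W ≤ 5.

# Modifier-screen statistics

## Wing-notching severity

Severity classes are ordinal (class 1 = wild-type wings … class 6 =
partial dorsoventral detachment). Two independent fly samples are
compared by expanding class counts to per-fly values and applying the
rank-sum statistic with tie correction (normal approximation; ties are
ubiquitous with six classes). The original study names its rank test
after Wilcoxon; the signed-rank form requires paired observations, which
independent test and control crosses are not, so the rank-sum
(Mann–Whitney) form is implemented and the naming is preserved in the
output metadata. Direction: enhancer if the test sample is stochastically
more severe. No multiplicity correction is applied across the wing screen
(configurable), matching the original reporting; the significance
threshold α = 0.05 is likewise an assumption made explicit.

A gene becomes an interactor only under the concordance rules: every
significant result must agree in direction, and either every allele is
significant in both sexes, or one allele is significant in both sexes and
the remaining alleles in at least one sex with the same direction.
Conflicting significant directions yield "0" with a conflict flag.

The two-class / three-class wing assay variant is handled by the same
machinery: classes are compared after mapping to their printed order, a
pragmatic choice given that the genotypes' class schemes differ by
construction.

## Scutellar-bristle duplication

The control duplication rate is the pseudocounted frequency
p̂ = (d+1)/(n+1). A test cross of m flies with d duplicated is compared to
Binomial(m, p̂) by exact tails: enhancement P(X ≥ d), suppression
P(X ≤ d). Which tail the original screen used is not stated; both are
computed and the smaller reported with its direction, matching the fact
that both enhancers and suppressors were reported. The two tails always
satisfy P(X≥d) + P(X≤d) − P(X=d) = 1. BH correction runs across the
screen and calls "+" / "−" at q < 0.05.

## Interaction-table summaries

`summarize_screen()` reproduces, per sensitizer column: tested (≠ "n"),
interacting ("+"/"−"), enhancer and suppressor counts with percentages to
one decimal; and for the bristle sensitizer pair, distinct-gene counts by
role. A gene may be an enhancer of one sensitizer and a suppressor of the
other (M(2)21AB in the packaged table), so role counts are reported both
as distinct genes per role and per column. The packaged table yields six
genes interacting with both bristle sensitizers where the accompanying
published text reports five; the summariser reports the table-derived
count and emits a discrepancy note rather than silently matching either.

# Pipeline

`run_pipeline()` executes simulate → expression → motifs → screen →
report in a single process; stages communicate only via files, and each
writes a JSON manifest (parameters, inputs, seed, output checksums)
sufficient to re-run it in isolation. Configuration files are YAML with
per-stage sections — the natural key-value format in this ecosystem, with
a parser available everywhere the package runs. Input files are checked
before any stage executes; a stage failure halts the run naming the
stage, retaining completed outputs. `make_report()` assembles whatever
outputs exist and marks missing sections absent.

# Numerical choices and problem sizes

* PRIMA score grain 0.001 bits: fine enough that the discrete 0.999-null
  quantile's achieved tail sits close to 0.001 (the tests assert the
  realised per-window false-hit rate), coarse enough that the DP support
  stays small.
* Sentinel handling: matrix entries of probability zero map to a large
  negative integer score; windows touching them collapse into a single
  floor atom of the null distribution whose probability mass is retained.
* Rank tests switch from exact enumeration to the tie-corrected normal
  approximation at n, m > 8.
* Validation problem sizes (chosen as the smallest sizes at which the
  asserted 3-SD bounds are meaningful): null calibration uses 50 matrices
  × 20 seeds with 100 target / 300 extra background promoters; power uses
  100 target / 1000 background promoters at planting rates 2 vs 0.2 over
  50 seeds; expression recovery uses 1000 genes × 8 arrays over 20 seeds.
  Recovery is evaluated without the median-intensity filter: on these
  synthetic arrays the two channels are strongly correlated, so the
  both-channels-below-median rule removes roughly the dimmer half of the
  spots regardless of differential expression, and recall is a property
  of the selection statistics, not of that deliberate censoring.

# Known limitations

* The synthetic background is order-0; conclusions about real-genome
  false-positive behaviour (repeats, composition bias, conservation) are
  out of reach of these tests.
* The HMM topology and τ, and the rank-sum p-value mechanism, are this
  package's own minimal realisation of the published description of the
  HMM scorer; other realisations (e.g. per-strand models for
  single-stranded binders) are plausible.
* The published genome-scale numbers (the 189-gene list and the printed
  enrichment p-values) depend on the original deposited arrays, genome
  assembly and licensed matrix library, none of which are packaged; the
  package validates the methods on synthetic data and reproduces exactly
  the interaction-table arithmetic instead.

# A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  seed = 1, out_dir = "run1",
  simulate = list(n_genes = 500, n_arrays = 8, n_printtips = 4,
                  de_fraction = 0.1),
  n_promoter_background = 300,
  motifs = list(n_library = 5, methods = c("prima", "demon"), fdr = 0.05))
run_pipeline(cfg)
cat(readLines(file.path("run1", "report.txt")), sep = "\n")
```

```{r screen}
summarize_screen(ldb_screen_table())
```
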