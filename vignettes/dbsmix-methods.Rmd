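---
title: "Single-allele methylation analysis of germ-cell/somatic mixtures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-allele methylation analysis of germ-cell/somatic mixtures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Deep bisulfite sequencing (DBS) of targeted amplicons reads the methylation
state of individual DNA molecules: each sequencing read is one allele, and at
the loci in this package's panel an allele is, to very good approximation,
either fully methylated or fully unmethylated across its CpGs. That
single-allele resolution is what makes testicular cell-culture fractions
analysable even when germ cells are a minority: a germ-cell-derived allele is
recognizable *per read*, not only as a shift in a bulk average.

The panel mirrors the assay this package models:

* **Germ-cell marker promoters** (*FGFR3*, *VASA/DDX4*, *RHOXF1*): fully
  methylated in somatic cells, fully unmethylated in male germ cells. The
  proportion of unmethylated reads at these loci *is* the germ-cell fraction
  of the sample.
* **Imprinted DMRs**: maternally methylated DMRs (*MEST*:alt-TSS-DMR,
  *KCNQ1OT1*/*LIT1*:TSS-DMR) are ~50% methylated in soma (one parental
  allele) and unmethylated in sperm; the paternally methylated *H19/IGF2*
  IG-DMR is ~50% in soma and fully methylated in sperm.
* ***MEG3*:TSS-DMR** is a special case. The locus is paternally imprinted,
  but its TSS-DMR is a *secondary* DMR that acquires paternal methylation
  only after fertilization: in sperm it is unmethylated. The panel therefore
  carries an explicit `germ_level` field per locus — 1 for the H19 IG-DMR, 0
  for everything else including MEG3 — and every expectation downstream
  (mixture prediction, shift direction) is derived from `germ_level`, not
  from the imprint-class label. Germ-cell enrichment is thus expected to
  *decrease* MEG3 methylation, matching its behaviour in normal germ-cell
  fractions.
* ***XIST* promoter CpG island**: fully methylated on the active X, so 100%
  in 46,XY soma, ~50% in 46,XX or 47,XXY soma (one inactive X), and
  unmethylated in the male germline.

Two questions drive the analysis of a germ-cell-enriched supernatant (SN)
fraction and its somatic attached (AT) counterpart from the same patient:

1. *How many germ cells are in the fraction?* — estimated from unmethylated
   reads at the marker loci.
2. *Do the imprinted loci shift as the mixture predicts?* — germ-cell
   enrichment must move each locus toward its germline level by an amount
   proportional to the germ-cell fraction, and a locus that moves the wrong
   way, fails to move, or moves far too much carries an imprinting
   epimutation.

# The generative model

`simulate_sample_reads()` / `simulate_cohort()` draw reads in three stages.

**Allele identity.** Each read is germ-cell-derived with probability $f$
(the sample's true germ-cell fraction). Compartment baselines give the
allele-methylation probability $P$: germ markers 1 in soma / 0 in germ;
imprinted DMRs 0.5 in soma and `germ_level` in germ; XIST 1 (46,XY soma),
0.5 (46,XX and 47,XXY soma), 0 in germ. An injected epimutation of magnitude
$e \in [-1, 1]$ shifts the *germ* compartment's probability to
$\mathrm{clamp}(P + e, 0, 1)$.

**Epiallele coherence.** One Bernoulli draw per read sets *all* CpGs of that
allele identically. This is deliberately all-or-none: it reproduces the
fully-methylated/fully-unmethylated read structure seen in single-allele DBS
data at these loci and makes read classification well-posed. Intermediate
epialleles can only be produced collectively, through an epimutation acting
on the germ compartment's probability.

**Chemistry and sequencing noise.** Each non-CpG cytosine converts to
thymine with probability `conversion_rate` (default 0.995); a CpG cytosine
converts when the allele is unmethylated and is retained when methylated,
each with the same `conversion_rate` — a single parameter covers both
failure modes (inappropriate retention and over-conversion) for parsimony.
Every base is then substituted uniformly to another base with probability
`seq_error_rate` (default 0.002). No indels are simulated, and FASTQ quality
strings are constant: homopolymer/flowgram artifacts of legacy
pyrosequencing chemistry are out of scope, and quality is not used
downstream. The defaults were chosen once so that read-level classification
is near-perfect while the conversion filter still has something to do.

The generator also accepts `exact_proportions = TRUE`, which replaces the
Bernoulli draws for compartment membership and allele methylation with
deterministic rounded allocations. This is a variance-reduction switch used
for algebraic identity checks (below); the default is fully stochastic.

What the generator does **not** emulate — PCR amplification bias, chimeric
reads, bisulfite-induced degradation, real primer/barcode sequences, indels
— bounds what passing tests can show: they validate the inference given the
mixture-with-noise model, not robustness to every artifact of real
libraries.

# The caller

**Alignment.** Reads are aligned to the *unconverted* reference by a
Needleman–Wunsch variant (compiled code): global in the read, end-gap-free
in the reference, with bisulfite-asymmetric substitution — reference C
aligned to read T (expected conversion) or read C (methylated or
unconverted) both score as matches. Methylation state therefore never
influences the alignment score, which keeps M/U calling unbiased; this is
why the reference is not three-letter-collapsed. Scoring defaults are match
+1, mismatch −1, gap −2; ties resolve diagonal > up > left, end-cell ties
toward the larger reference coordinate. Both orientations are tried:
bisulfite PCR amplifies the converted top strand only, so a
reverse-orientation read is the reverse complement of a converted-top
molecule and is re-complemented before alignment under the same expectation
(the higher score wins, ties prefer forward). Orientation is detected from
the data, never from metadata. Reads identical in length to the reference
that match the conversion expectation at every base take a provably-optimal
shortcut past the dynamic program.

**Calls and QC.** Each CpG becomes M (C), U (T) or N (gap/other). The
per-read conversion rate is the fraction of aligned non-CpG reference
cytosines read as T — every amplicon is generated with at least five non-CpG
cytosines so this rate is estimable. Reads pass QC when conversion ≥
`min_conversion` (default 0.95, common DBS practice) and aligned reference
fraction ≥ `min_aligned` (default 0.8); reads with no aligned non-CpG
cytosine fail. A read is classified *unmethylated* when its M-fraction over
non-N calls is ≤ `read_class_max_minor` (default 0.1, tolerating one miscall
on a 10-CpG amplicon), *methylated* when ≥ 0.9, otherwise *mosaic*.
`mean_methylation` averages per-read M-fractions (per-read-then-average,
matching the single-allele framing). A locus with zero passing reads is
reported as missing, never as 0%. Coordinates are 0-based internally and
1-based in every report.

# Mixture inference

**Purity gate.** A germ-cell fraction whose VASA/DDX4 methylation exceeds
4% contains appreciable somatic DNA and is excluded — the boundary itself
(exactly 4.0%) is retained, since the rule is strictly "higher than". The
gate applies to normal-group SN fractions declared gated in the sample
sheet; Klinefelter SN fractions bypass it, because for those samples only
enrichment, not complete separation, is achievable, and discarding them
would discard the patients.

**Germ-cell fraction.** At each marker locus $\hat f_\ell$ = proportion of
unmethylated passing reads; the sample estimate $\hat f$ is the
read-count-weighted mean over the three markers (all three are used, with
per-locus values reported alongside). Uncertainty is a seeded nonparametric
bootstrap over reads; because the per-locus statistic is a mean of binary
read labels, the resampled statistic is drawn as a binomial, which is
distributionally identical to index resampling and much faster.

**Expected shift.** With germline level $g$ (0 or 100 by `germ_level`) and
somatic level $s$, a fraction with germ-cell proportion $f$ has expectation
$(1-f)\,s + f\,g$. The somatic level is *not* taken from a 50%/100% prior:
it is inverted from the patient's own AT fraction,
$s = (m_{AT} - f_{AT}\, g)/(1 - f_{AT})$, which absorbs residual germ cells
in AT (hence $f_{AT} < 1$ is required, and $f_{AT}$ is estimated exactly
like $f_{SN}$). The prediction is clamped to $[0, 100]$.

**Aberration rules.** The anomalies this pipeline must detect are
qualitative — a locus moving against the expected direction, a locus not
moving at all, a locus overshooting — so `assess_shift()` operationalizes
them as three explicit rules, checked in order, all gated on the expected
shift being material (|expected shift| > `tolerance_delta`, default 10
percentage points, exposed in config):

1. **wrong_direction** — the observed AT→SN shift opposes the expected
   sign;
2. **no_shift** — the observed shift is within the bootstrap 95% null width
   (the 95th percentile of the centred bootstrap AT−SN difference; whether
   any formal threshold underlay the original qualitative "no change" calls
   is unknowable, so this construction is this package's own);
3. **magnitude** — $|m_{SN} - m_{expected}|$ > `tolerance_delta` *and* the
   bootstrap 95% CI of $m_{SN}$ excludes the expectation.

The three rules map one-to-one onto the three anomaly archetypes the demo
cohort injects: H19 losing germline methylation ($e = -1$, falls instead of
rising), MEG3 gaining it ($e = +0.8$, rises instead of falling), MEST
pinned at the somatic level ($e = +0.5$ with $f_{SN} = 0.5$, no shift);
LIT1 is left intact everywhere. The flat-MEST case is typically caught by
rule 2 or rule 3 — both fire on it, and the rule order decides the recorded
reason.

# Group statistics

Per locus, per-sample mean methylation is compared across fractions by
one-way ANOVA followed by all pairwise two-sided t tests (Welch by default
— group sizes and variances differ across fractions; poolable-variance t
tests are available by `welch = FALSE`) with Holm's step-down correction.
The multiple-testing family is the set of pairwise comparisons within one
locus panel — per-gene families, matching how such panels are displayed.
Normality is checked per group by Shapiro–Wilk (the test the original
workflow left unnamed; groups with n < 3 are skipped); if any group fails
at $\alpha = 0.05$ all groups are transformed $x \mapsto \log(x + 0.5)$,
the offset handling exact zeros, and reported summaries stay on the raw
percent scale. Significance letters follow the box-plot convention: one
letter per reference group, repeated once/twice/thrice for Holm-adjusted
p < 0.05 / 0.005 / 0.001, concatenated in reference order.

# Numerical and design choices

* **Determinism.** Every stochastic operation takes a seed; the pipeline
  fans one master seed out to per-stage child seeds by a stable integer
  derivation, so stages are independently rerunnable and full runs are
  byte-identical. Seeded code saves and restores the caller's RNG state.
* **Degenerate inputs.** Empty reads, empty cohorts, zero-variance groups,
  missing AT/SN pair members, missing marker summaries and $f_{AT} \ge 1$
  all fail loudly or are reported as explicit missing/skip states — never
  silently imputed.
* **Identity checks.** With noise off and `exact_proportions = TRUE`, read
  counts of 400 make every compartment and allele allocation integral, so
  the SN methylation equals the mixture expectation *exactly* (delta = 0 to
  floating-point precision) at every locus class and $f \in
  \{0, 0.25, 0.5, 0.75, 1\}$.
* **Problem sizes in the test suite.** Estimator properties are exercised
  at 2000 reads/locus (50 replicates per $f \in \{0.1, 0.5, 0.9\}$ for
  bias; 200 replicates at $f = 0.25$ for 95% CI coverage ≥ 93%);
  specificity on 20 aberration-free patients at 500 reads/locus (per-locus
  flag rate ≤ 5%); the demo cohort at its full 39 samples × 8 loci × 500
  reads; alignment against an exhaustive-enumeration oracle on hundreds of
  instances ≤ 8 bp; Holm against hand-computed step-down values and a
  1000-replicate null simulation of the letter display (family-wise error ≤
  0.065 at the 0.05 tier). These sizes are the package's chosen design
  points for stable yet fast checks.
* **Demo cohort composition.** Sample counts mirror the modelled study's
  included samples (normal: 5 SN, 4 AT, 3 SCO, 5 blood, 6 sperm; KS: 7
  blood, 3 SN + 3 AT with germ cells, 3 AT without). Normal SN germ
  fractions are drawn near 0.97–0.99 (post-gate purity), AT fractions
  retain ~2–6% germ cells, KS+ SN fractions sit at 0.4–0.5 (enrichment
  without separation). These are realistic settings chosen once; none of
  them is tuned to test outcomes.

# Limitations

* The synthetic amplicons are random stand-ins with the right CpG
  structure, not the real assay sequences; per-locus quantitative claims
  about the real amplicons cannot be checked against them.
* The estimator and the aberration rules inherit the all-or-none epiallele
  assumption; partially methylated epialleles (e.g. mosaic imprint erosion
  *within* alleles) would appear as the mosaic read class and are not
  modelled by the mixture expectation.
* The bootstrap null-width and CI rules control per-locus error under the
  simulation model only; they are not calibrated against biological
  replicate variation, which desk-scale simulation cannot supply.
* Single-cell methylation, sperm-level aberration calling and any clinical
  interpretation are out of scope.
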