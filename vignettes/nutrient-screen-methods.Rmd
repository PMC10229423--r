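---
title: "Methods: scoring nutrient-sensitized screens and correcting tracer data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring nutrient-sensitized screens and correcting tracer data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriscreen)
```

# The scientific setting

When glucose is withdrawn, some cells survive by catabolizing alternative
substrates — notably the ribose moiety of uridine, cleaved by uridine
phosphorylase (UPP1/UPP2) into ribose-1-phosphate and routed through the
non-oxidative pentose phosphate pathway into glycolysis. Asking *which
genes* confer or gate that ability leads to a family of pooled competition
experiments read out by barcode sequencing:

1. a **gain-of-function ORF screen** — thousands of barcoded
   open-reading-frame constructs compete during growth on glucose versus a
   poor substrate (galactose); enrichment of a barcode means the encoded
   protein improved fitness;
2. a **genome-wide CRISPR knockout screen** — sgRNA abundance after weeks
   of growth on glucose versus uridine reveals which genes are essential
   in each nutrient;
3. a **multiplexed cell-line competition assay** (PRISM-style) — hundreds
   of stably barcoded cancer cell lines pooled in one well, grown on
   glucose or uridine, asking which lineages and which molecular features
   (transcripts, proteins, copy number) track with uridine tolerance;
4. **¹³C₅-uridine tracing** — mass-isotopomer distributions of downstream
   metabolites show whether uridine-derived ribose actually reaches
   glycolysis; raw MIDs must first be stripped of naturally occurring ¹³C.

This package implements the statistics of all four read-outs as reusable,
separately testable functions, plus negative-binomial simulators that
plant known ground truth so each stage can be validated end to end
without any external download.

# Normalization and fold change

Counts are normalized per sample to reads per million and
log2-transformed with a pseudocount:

$$v_{es} = \log_2\!\left(\frac{r_{es}}{\sum_e r_{es}} \times 10^6 + 1\right)$$

The pseudocount pins zero counts at exactly 0 and attenuates fold changes
of very low-abundance elements; per sample, $\sum_e (2^{v_{es}}-1) = 10^6$
holds identically, which the tests exploit as an invariant. The same
formula is used for every screen type — the one printed normalization,
one code path. A log2 fold change is simply $v_{e,\text{sample}} -
v_{e,\text{reference}}$, so it is antisymmetric by construction.

For the ORF screen the contrast at a chosen day is the difference of
condition means of $v$, with a **pooled-variance (Student's) two-sided
t-test** across replicates. With $n = 2$ per arm this test is blunt; we
deliberately do not adjust these p-values for multiplicity — ranking by
fold change with the p-value as a supporting annotation is the intended
reading, and the volcano table renders $-\log_{10} p$ capped at 300 so
the degenerate $p = 0$ convention stays finite. When the pooled variance
is exactly zero (possible in noise-free synthetic fixtures) the
convention is $p = 1$ if the means agree and $p = 0$ otherwise, emitted
with a warning; this keeps degenerate fixtures deterministic instead of
erroring.

An alternative contrast — per-replicate LFCs versus day 0 rather than
normalized values at the final day — is statistically equivalent for a
two-arm design at $n = 2$ up to the shared day-0 term; we score
normalized values at the contrasted day, which needs no day-0 sample.

# CRISPR essentiality z-scores

Per replicate, each gene's LFC is the arithmetic mean of its (typically
four) sgRNAs' log2 fold changes against the **pre-swap reference** (the
sample harvested before the nutrient switch). Gene LFCs are then averaged
across replicates — mean-then-standardize, in that printed order. Genes
with low expression (log2 FPKM < 0, strict inequality: a gene exactly at
0 is retained) are removed from scoring, since a knockout of an
unexpressed gene cannot have an on-target effect.

Those same unexpressed genes are, however, exactly what calibrates the
score: the **empirical null** is the set of the $k$ lowest-expressed
genes, whose LFC spread estimates the technical noise floor. With null
mean $\mu$ and sample standard deviation $\sigma$ (ddof 1),

$$z_g = \frac{\overline{\mathrm{LFC}}_g - \mu}{\sigma}.$$

Two null modes are provided because the two natural calibrations differ:
`expression` (default — the procedural description) and `noncutting`,
which uses the non-cutting control pseudo-genes instead. Both satisfy the
self-consistency identity that null members z-scored against their own
null have mean 0 and sample sd 1 to machine precision; the tests enforce
this at 1e-12. $k$ is an opaque parameter: genome-scale analyses in this
tradition use $k = 3726$; for synthetic screens the default is 20% of
the scoreable genes, matching the generator's low-expression fraction.
Ties at the $k$-th expression rank are broken lexicographically by gene
id so the member set is reproducible.

Differential essentiality between conditions is $dz = z_u - z_{glu}$.
The class labels (`shared_essential`, condition-specific, `neutral`) use
reporting conventions, not estimated thresholds: essential at $z \le -3$,
spared at $z > -1$. A gene essential in one condition whose other-condition
z falls in the gap $(-3, -1]$ is labelled `neutral`; the gap is
deliberate — such genes are neither convincingly specific nor shared.
Ranking by $dz$, not the labels, is the quantitative output.

# Multiplexed growth metrics

For the barcoded cell-line pool, replicate-level counts below a floor
(default 20 raw counts — a conservative sequencing-noise threshold,
configurable) are masked so that spurious near-zero reads do not depress
a line's mean. Remaining replicates are **mean-collapsed first**, then
the two closed-form metrics are computed on collapsed counts, mirroring
the printed order of operations:

$$\mathrm{LFC} = \log_2(n_u / n_g), \qquad
  \mathrm{growth\ rate} = \frac{\log_2(n_f / n_0)}{t}$$

with $t = 6$ days as the assay default. Counts that are zero or missing
after collapse yield missing metrics, never $\pm\infty$; missingness
propagates, it is never imputed as 0. Counts enter the equations raw —
the equations are ratios within a well, so depth cancels to first order;
an RPM pre-scaling is available but off by default.

Lineage enrichment is a members-versus-rest pooled t-test on per-line
LFCs with the effect reported as the difference of group means, BH-adjusted
across lineages; lineages with fewer than 3 scored members are flagged
untested. The members-vs-rest t-test is the simplest defensible choice
for this design and is documented as such. Biomarker discovery is a
Pearson correlation (Spearman behind a flag) between each feature and
the LFC vector with pairwise-complete missing handling, p-values from
the exact t-transform of r, BH within feature class, ranked by |r|.
Constant features are excluded with a warning rather than reported with
an undefined r.

# Natural-abundance correction of MIDs

A measured isotopologue vector mixes tracer-derived labeling with
naturally occurring ¹³C (abundance $p \approx 1.07\%$). For a metabolite
with $n$ carbons the measured MID is the true MID convolved with a
lower-triangular binomial matrix

$$C_{ij} = \binom{n-j}{\,i-j\,} p^{\,i-j} (1-p)^{\,n-i}, \quad i \ge j,$$

whose columns each sum to 1 (signal is conserved). Correction solves
$Cx = b$ for the normalized measurement $b$. Two solvers are exposed:
`inverse`, the exact triangular solve — the right oracle for round-trip
tests, but capable of small negative fractions on noisy data — and
`nnls` (default for real data), nonnegative least squares via
`pracma::lsqnonneg`, which guarantees a proper distribution. Results are
renormalized to sum to 1. Only carbon is corrected: the tracer is
¹³C₅-uridine, and N/H/O isotopes and tracer impurity are out of scope,
as is any absolute pool-size quantification. The summaries are the
percentage labelled, $100(1 - M_0)$, and mean fractional enrichment
$\sum_i i M_i / n$.

The upstream correction this replaces was performed manually and its
constants are not recorded; the binomial-matrix method with $p = 0.0107$
(IUPAC representative ¹³C abundance) is the standard formulation and is
documented as this package's choice.

# What the simulators emulate — and what they do not

All generators are pure functions of (parameters, seed): a master seed
derives fixed substreams per stage, so identical calls are byte-identical
down to the written TSVs.

* **CRISPR / ORF screens**: lognormal baseline abundances (sdlog 0.5 —
  typical library skew), negative-binomial counts with dispersion 0.1
  (CRISPR; overdispersed sequencing) or 0.01 (ORF; a clean screen at
  ~10% CV), planted condition-specific effects applied as $2^{\mathrm{effect}}$
  to the final-timepoint mean. Defaults follow the screen designs the
  package targets: 4 sgRNAs/gene, 2 replicates, depth 500 reads/sgRNA,
  effect −4 log2 for knockout depletion; one barcode per ORF, effect +3
  log2 for enrichment. Expression values are drawn so planted genes are
  always expressed and 20% of genes form the low-expression null pool.
* **Cell-line pool**: 482 lines across 22 lineages, 3 replicate wells,
  6-day assay, 200-count seeding scale, glucose-arm growth rates
  N(0.7, 0.15) doublings/day, latent per-line differential growth
  N(0, 0.5) plus a +2 log2 shift in one 20-member lineage, and one of
  2000 features constructed with true correlation 0.6 to the latent
  values.
* **MIDs**: exact binomial convolution times a lognormal multiplicative
  noise at 2% CV by default.

These emulate the *statistical* structure the estimators rely on. They do
not model lentiviral infection dynamics, guide-efficiency heterogeneity,
PCR jackpotting, barcode collisions, copy-number confounding of CRISPR
scores, or batch structure in the feature matrices. Passing recovery
tests on these simulations therefore demonstrates that the estimators
are implemented correctly and are well calibrated under their stated
noise model — not that real screens are free of the artifacts listed
above.

# Numerical choices and problem sizes

* Zero-total samples, all-zero MIDs, sub-2-member nulls and zero-spread
  nulls are errors, not silent NA propagation.
* The BH adjustment and the pooled t-test are delegated to
  `stats::p.adjust(method = "BH")` and `stats::t.test(var.equal = TRUE)`
  behind validated surfaces; the test suite checks them against a
  brute-force step-up implementation and the closed-form pooled-t
  arithmetic, and the vectorized row-wise t used in matrix scoring is
  cross-checked against the scalar path.
* Tie-breaks are always lexicographic (null membership, output ordering)
  so outputs are reproducible; writers emit 6-significant-digit floats
  and a comment header carrying version and parameters.
* Test and validation runs use 300–2000 genes, 2000 ORFs, and the full
  482-line / 22-lineage / 2000-feature pool size with 100 seeded
  repetitions for the recovery-rate checks; these sizes give the
  recovery statistics comfortable margins (e.g. the null AUROC sampling
  sd is ~0.03 at 1000 genes) while keeping a full run in tens of
  seconds.

# Known limitations

* The lineage test assumes approximately exchangeable per-line LFCs
  within and across lineages; strongly unequal lineage variances would
  call for Welch or a permutation test.
* The expression-mode null assumes knockouts of unexpressed genes are
  fitness-neutral; bystander effects (e.g. cutting toxicity scaling with
  copy number) are not modelled, which is one reason the non-cutting
  mode is also provided.
* MID correction assumes the instrument resolves only mass shifts from
  carbon and that the tracer is isotopically pure.
* The classification thresholds in `differential_essentiality` are
  conventions for labelling, not inference.
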