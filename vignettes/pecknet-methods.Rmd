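---
title: "Methods: SV/TR association, networks and motif enrichment in pecknet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SV/TR association, networks and motif enrichment in pecknet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pecknet)
```

## Scope and model

`pecknet` implements the computational pipeline of a structural-variant (SV)
and tandem-repeat (TR) association study of feather-pecking behaviour in
chickens: two mapping designs (an F2 cross and half-sib families from lines
divergently selected for high/low feather pecking), a behavioural phenotype
on a Box-Cox-transformed count scale (`fpd_bc`), and brain gene expression
for a panel of differentially expressed genes. Stages:

1. multi-caller SV call-set merging and genotype filtering,
2. mixed-linear-model (MLM) GWAS with leave-one-chromosome-out (LOCO)
   genomic relationship matrices (GRMs),
3. sample-size-weighted meta-analysis across the two designs,
4. expression GWAS (eGWAS), an association weight matrix (AWM) and PCIT
   partial-correlation network inference,
5. position-weight-matrix (PWM) promoter scanning with gene-coverage
   enrichment.

Every stage is exercised end-to-end on synthetic data whose statistical
structure mirrors the study; nothing requires external downloads.

## The association model

For each tested variant the model is

$$y = W\alpha + X\beta + u + \varepsilon,\qquad
  u \sim N(0, A^{-}\sigma_g^2),\quad \varepsilon \sim N(0, I\sigma_e^2),$$

with $W$ the fixed effects (hatch for the F2 design; hatch and line for the
half-sib design), $X$ the dosage at the tested locus, and $A^{-}$ the GRM
built from all chip markers *except* the chromosome being analysed (LOCO),
so a tested variant never contributes to its own covariance correction. The
GRM is the standard frequency-standardized cross-product
$A_{jk} = m^{-1}\sum_i (x_{ij}-2p_i)(x_{ik}-2p_i)/(2p_i(1-p_i))$; missing
dosages are mean-imputed and monomorphic markers skipped.

Variance components are estimated once per LOCO chromosome (not per
variant) by REML. Because the model has a single genetic component, we do
not iterate average-information updates: after one eigendecomposition
$A = UDU'$ the restricted likelihood is profiled down to the variance
ratio $\delta = \sigma_e^2/\sigma_g^2$ and maximized exactly by Brent
search on $\log\delta \in [-6\ln 10,\ 8\ln 10]$ (relative tolerance
$10^{-6}$). The boundary $\sigma_g^2 \to 0$ is the edge of the interval, so
degenerate fits are flagged rather than divergent; components are floored
at $10^{-10}\,\mathrm{Var}(y)$. Each variant is then tested by generalized
least squares with $V = A_{loco}\hat\sigma_g^2 + I\hat\sigma_e^2$ treated
as known: $\hat\beta = \tilde x'V^{-1}\tilde y / \tilde x'V^{-1}\tilde x$,
$se^2 = (\tilde x'V^{-1}\tilde x)^{-1}$, and $p$ from
$(\hat\beta/se)^2 \sim \chi^2_1$ — the convention of standard MLM-LOCO
tools. Variants with minor allele frequency below 0.01 (the study's
threshold) or call rate below 0.5 are skipped.

The variance explained by one variant uses the decomposition
$\mathrm{Var}(Y) = \beta^2\mathrm{Var}(X) + \sigma^2$, i.e.
$PVE = \beta^2\mathrm{Var}(X)/\mathrm{Var}(Y)$, clipped to $[0,1]$.
Genome-wide significance is Bonferroni, $\alpha/m$; with the study's
$m = 35{,}571$ screened SVs/TRs and $\alpha = 0.05$ this is
$1.41\times10^{-6}$.

Meta-analysis follows the sample-size-weighted (Stouffer) scheme:
$Z_i = \Phi^{-1}(1-p_i/2)\,\mathrm{sign}(\beta_i)$, weights $\sqrt{n_i}$,
$Z = \sum w_iZ_i/\sqrt{\sum w_i^2}$. Variants present in one study carry
their Z through; zero p-values are clamped to the smallest positive double.

## Call-set merging and filters

Merging emulates SURVIVOR's behaviour with the study's settings: records
cluster across callers when both breakpoints lie within 1,000 bp and SV
type and strand pair match; clusters need at least 2 supporting callers;
the minimum SV length is 30 bp (translocations carry no length and are
exempt). Clustering is greedy single linkage seeded by coordinate-sorted
order, comparing each record to the cluster's *seed* record — this matches
merge-tool behaviour and is order-stable because the pooled records are
sorted before clustering. The emitted representative is the member from the
highest-priority caller; the default priority is the sorted caller
identifier so that results are invariant to the order in which call sets
are supplied. Consensus genotypes start from the representative and fill
missing entries from other members in priority order; the merged QUAL is
the cluster maximum.

Merged SVs keep only records with QUAL $\ge$ 1000 and call rate $\ge$ 0.8.
TR genotypes are masked per sample at depth DP < 10 (inclusive threshold)
or quality Q $\le$ 0.8 (strict, "higher than 0.8"), then variants with call
rate < 0.8 are removed; both filters are idempotent. Multiallelic variants
are split into one biallelic record per alternate allele with dosages equal
to that allele's copy count, conserving total allele counts.

## AWM and PCIT

A variant enters the AWM if its main-trait p-value is below $10^{-4}$ *or*
it reaches $p < 10^{-4}$ in at least ten eGWAS scans. AWM entries are
signed z-scores $\beta/se$; a cell whose scan did not test the variant
(e.g. MAF-filtered there) is 0, column standardization is optional, and
each variant row is annotated with its nearest gene by TSS distance. These
conventions beyond the two selection rules are documented flags: the
original AWM construction defers details to an external script, so they
are this package's own choices.

PCIT operates on the correlation matrix of AWM columns. For every trio
$(x,y,z)$ the three first-order partial correlations are computed, the
trio tolerance $\varepsilon$ is the mean of the partial-to-direct ratios,
and edge $(x,y)$ is non-significant if some $z$ gives
$|r_{xy}| < \varepsilon|r_{xz}|$ and $|r_{xy}| < \varepsilon|r_{yz}|$.
Trio enumeration is exhaustive (the trait panels here are $\le$ a few
hundred). Direct correlations below $10^{-12}$ are pruned outright;
$|r| = 1$ denominators are treated as a perfect proxy dominating the edge.
Note a property worth knowing: for a mediated chain with
$r_{xy} = r_{yz} = r$ and $r_{xz} = r^2$, the indirect edge is pruned only
for $r < \sqrt{4/5}$ at which the tolerance $2/(3\sqrt{1+r^2})$ crosses
$r$; at $r = 0.8$ the chain tolerance equals 0.52 and the indirect edge
survives. The significant edge list exports as a viewer-ready TSV.

## PWM scanning and enrichment

JASPAR frequency matrices are converted to log-odds with pseudocount 0.25
and configurable background; scanning covers the window
$[TSS-1500,\ TSS+500)$ on both strands (reverse strand = the
reverse-complemented matrix at the same coordinates). A position is a hit
when its score reaches `threshold_frac` (default 0.85) of the attainable
score range — the original enrichment tool's internal match cut-off is not
published, so this knob is a documented stand-in, and an exact
convolution of the per-column score distribution
(`pecknet:::pwm_score_distribution`) is provided to translate any
threshold into expected hit rates.

Coverage enrichment compares the fraction of foreground vs background
genes with $\ge 1$ hit by a one-sided Fisher exact test (two-sided
available) and reports $\log_2$ enrichment. Exact-test p-values are
discrete and conservative by construction, so the result also carries the
Lancaster mid-p, which is the quantity to inspect in null-calibration
diagnostics; the decision statistic remains the exact p. With 23
foreground genes the mid-p is approximately uniform under the null while
the raw exact p is visibly super-uniform — this is a property of exact
tests on small sets, not an implementation artefact.

## The synthetic-data generator

The generator's defaults encode the emulated study conditions: 500
half-sib-like samples (two lines, four hatches), 2,000 markers on five
chromosomes, polygenic heritability 0.15, an optional lead QTL at target
PVE 0.047, 86 expression traits on 167 samples with a TF hub regulating 20
targets, three noisy callers over 200 true SVs, and promoters of 2,001 bp
with the TSS at position 1,501 (window $-1500/+500$). Specifics:

* **Genotypes.** Haplotypes follow a first-order copying process on latent
  uniforms; with matched allele frequencies the copy probability
  `ld_decay` *is* the adjacent-marker correlation (default 0.3, chip-like
  spacing). Dosages are haplotype sums; frequencies are uniform on
  `maf_range`.
* **Phenotype.** Unit non-fixed variance by construction: QTL effects are
  solved from $\beta = \sqrt{PVE/\mathrm{Var}(x)}$, the infinitesimal
  polygenic term is rescaled so its realized variance equals
  `h2_polygenic` exactly (making REML recovery targets well-defined), and
  QTL markers are excluded from the polygenic sum. Hatch effects are
  $N(0, 0.5^2)$ and the line difference is 0.5 — modest batch/selection
  effects on a unit trait scale. Phenotypes are emitted on the
  already-transformed (Gaussian) scale; the Box-Cox step itself is out of
  scope.
* **Expression.** Every gene gets a distinct cis-eQTL (effect 1, noise 1);
  hub targets additionally receive `effect` $\times$ the hub's expression,
  so target eGWAS hit the hub's eQTL variant.
* **Caller outputs.** Per caller: false-negative thinning, rounded
  Gaussian breakpoint jitter, Poisson false positives with random
  type/position, caller-specific genotype missingness, and QUAL drawn
  higher for true events than false positives so the QUAL filter is
  informative. True SV starts are kept $\ge$ 3,001 bp apart so distinct
  true events can never fall within the 1,000-bp merge distance — merged
  counts are then identifiable against the truth.
* **Promoters.** I.i.d. background (default uniform composition, a knob
  because enrichment power depends on it); foreground genes receive a
  motif instance sampled column-wise from the frequency matrix with
  probability 0.6, background genes with 0.2, at uniform positions on
  random strands.

One master seed expands into fixed per-component child seeds, so each
stage is a pure function of its configuration and stages can be
regenerated independently.

What the generator does **not** emulate: realistic long-range LD or
demography, read-level errors, expression normalization pipelines
(expression is emitted already-Gaussian; the study's normalization is
unspecified upstream), multi-breakend SV notation, or genome-scale marker
densities. Passing tests therefore demonstrate correctness of the
statistical machinery under the assumed generative model, not performance
on real chicken data.

## Validation scenarios and problem sizes

The test suite fixes these desk-scale scenarios (chosen once, as the
package's own design):

* **Type-I error.** Null MLMA-LOCO with the polygenic background and GRM
  from a chip-like panel and an independent, effect-free tested panel —
  mirroring the study's separation of chip markers (GRM) from tested
  SVs/TRs. 20 genotype draws $\times$ 10 phenotype replicates at
  $n = 500$, 2,000 tested variants, independent markers; the nested design
  reuses each draw's eigendecompositions. Rejection at $\alpha = 0.05$ is
  checked against $[0.04, 0.06]$ and pooled p-values against uniformity.
* **Recovery.** $h^2$: 100 replicates at $n = 1000$, target 0.15. PVE: 200
  replicates at $n = 500$, target 0.047 via `estimate_pve` on a
  covariate-adjusted fit.
* **Oracle equivalence.** PCIT vs exhaustive trio enumeration (50 random
  matrices, sizes 3-40, exact match); scanning vs per-base brute force;
  Fisher p vs the hypergeometric closed form to $10^{-12}$; MLMA at
  $\sigma_g^2 = 0$ vs ordinary least squares to $10^{-8}$.
* **Merging.** Exact truth recovery without noise; count equality with an
  independent connected-components oracle under jitter and dropout; order
  invariance and filter idempotence.
* **Enrichment.** 23 foreground vs 500 background genes, plant
  probabilities 0.6/0.2. The shipped synthetic ETS-like motif is 12 bp
  with sharp columns; by the exact score-distribution computation this
  gives planted-instance detection 0.94 and background coverage 0.009 at
  the default threshold, hence power $\approx 0.94$ and a per-null-motif
  flag rate $\approx 0.02$ in the 7-motif specificity panel. The null
  calibration scenario scans at `threshold_frac = 0.7` (background
  coverage $\approx 0.8$), a regime where coverage counts are far from
  degenerate and the mid-p is verifiably uniform.

## Known limitations

* The eGWAS/AWM stage at desk scale selects few variants under the default
  thresholds (the synthetic world has one hub); the pipeline skips network
  inference when fewer than three variants are selected rather than
  correlating degenerate columns.
* GLS p-values treat the REML variance components as known
  ($\chi^2_1$ reference); at $n \ge 500$ the finite-sample distortion is
  negligible relative to the acceptance bands, but very small samples
  would need an exact F reference.
* PCIT is $O(n^3)$ in the number of traits; fine for hundreds, not for
  thousands.
* The merge representative's breakpoints are a single caller's call;
  no breakpoint averaging is attempted (matching the emulated tool).
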