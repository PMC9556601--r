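---
title: "Within-sample genotype calling with a bivariate normal mixture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-sample genotype calling with a bivariate normal mixture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Infinium-style SNP bead arrays report, for every assayed SNP, a mean signal
intensity for each of the two alleles (in Illumina's abstract A/B
nomenclature), together with the number of beads averaged into each mean and
a per-allele standard deviation. Plotted in log space, the intensities of
the three genotype groups AA, AB and BB form the characteristic three-lobed
"butterfly" scatter: AA is A-high/B-low, BB the mirror image, and AB sits on
the diagonal. Genotype calling amounts to deciding which lobe a SNP belongs
to — and, crucially for forensic and clinical use, deciding when *not* to
call.

`butterflycall` performs this calling **within a single sample**: the model
for a sample is estimated from that sample's own ~millions of SNPs, so calls
are never influenced by other samples of possibly different quality (the
main caveat of across-sample clustering approaches, which also tend not to
expose per-call posterior probabilities).

## The model

Let $A$ and $B$ be the raw mean intensities of alleles A and B. Because a
mean intensity can be exactly 0, both are transformed as

$$A' = \ln(A + 1), \qquad B' = \ln(B + 1),$$

which is finite everywhere and maps 0 to 0. The transformed pairs are
modelled as a three-component mixture of bivariate normal distributions,

$$f(A', B') = \sum_{i=1}^{3} \tau_i \, \phi_i(A', B'),$$

where $i$ indexes the genotype groups AA, AB, BB, $\phi_i$ is a bivariate
normal density with its own unconstrained mean vector and full $2 \times 2$
covariance (the "VVV" structure: every component has its own volume, shape
and orientation), and the prior weights satisfy $\sum_i \tau_i = 1$. Given a
fitted model, the genotype posterior is

$$P(k \mid A', B') = \frac{\tau_k \, \phi_k(A', B')}
       {\sum_{i=1}^{3} \tau_i \, \phi_i(A', B')},$$

and a SNP is called as the maximum a posteriori genotype unless a no-call
rule fires.

Three model variants are provided by `call_sample()`: one model per sample
(`"per_sample"`); separate models for type I and type II probes of one
sample (`"per_sample_per_probe_type"`, guarding against probe-type bias);
and a single model fitted on the pooled intensities of several samples
(`"ensemble"`).

## No-call rules

The no-call (NC) rules are applied in a fixed order, and the first matching
rule is recorded per SNP:

1. **Zero intensity** — both raw means are exactly 0 (scanner dropout).
   Always a no-call, at any threshold.
2. **Too few beads** — a bead count below `beads_min` makes the mean
   unreliable. Type II probes have a single count (the same beads capture
   both alleles); type I probes have one count per allele and *both* must
   pass. The rule is strictly-below, so a count equal to `beads_min`
   passes; `beads_min = 0` disables the rule. The default of 5 reflects the
   observed bead-count distribution (median 13, central 95% within
   [5, 23]): counts below 5 sit in the unreliable lower tail.
3. **Degenerate posterior** — all three component log densities underflow
   (a point astronomically far from every component); flagged rather than
   propagating `NaN`.
4. **Low posterior** — the maximum posterior is strictly below
   `posterior_min`. Useful thresholds range from 0.5 to 0.999; because the
   three posteriors sum to 1, any threshold of at least 0.5 can be exceeded
   by at most one genotype. A call at exactly the threshold is made; an
   exact argmax tie (only possible at 0.5/0.5) is a no-call.

Raising either threshold trades call rate for reliability:
`threshold_sweep()` fits the model once and tabulates the call rate over a
threshold grid, and its call rate is monotone non-increasing in each
threshold.

## Fitting: EM, initialisation, numerics

The mixture is fitted by expectation-maximisation on the transformed
intensities. Design choices that matter:

* **Initialisation** is deterministic by default: points are split into
  three groups at the 1/3 and 2/3 quantiles of $B' - A'$ (the coordinate
  that orders the butterfly lobes), followed by one M-step. This matches
  the cluster geometry, makes fits reproducible without a seed, and in
  practice converges in a handful of iterations on well-separated data. A
  k-means initialiser is available (`mixture_config(init = "kmeans")`) and
  is used automatically for restarts.
* **Convergence** is declared when the relative log-likelihood change drops
  below `tol = 1e-8`, with a cap of 500 iterations. The log-likelihood
  trace is recorded and is non-decreasing (a property the test suite
  asserts on every fit it makes).
* **Regularisation**: if a component covariance becomes numerically
  singular or its condition number exceeds `1e12` (which can happen with
  saturated intensity ties), a ridge of `1e-6` times its mean diagonal is
  added. A covariance that collapses to exactly zero (all points of a
  component identical) is an error, not something to paper over.
* **Component collapse**: a mixing weight below `1e-6` triggers a restart
  with a different initialisation, and a classed fit error after
  `max_restarts` failures. Degenerate inputs should fail loudly.
* **Origin exclusion**: points at raw $(0, 0)$ are excluded from fitting by
  default (`exclude_origin = TRUE`). They are forced no-calls anyway, and
  at non-trivial dropout rates they form a point mass at the origin that
  the normal mixture would otherwise have to absorb. The exclusion is
  configurable for sensitivity analysis.
* **Posteriors in log space**: responsibilities and posteriors are
  accumulated as log densities with a max-shift, so no finite point
  produces `NaN`; full underflow is flagged as degenerate instead.
* **Labelling**: nothing in the likelihood orders the fitted components, so
  they are sorted by the mean of $B' - A'$ ascending and assigned AA, AB,
  BB in that order; exact ties (essentially impossible on real data) are
  broken by ascending mean $A'$ and reported.

Component labelling, and the model's ability to run on millions of SNPs,
are what make the within-sample design workable: a full-array fit involves
only a few dozen vectorised E/M iterations over an $n \times 3$ matrix.

## Manifest filtering and allele bookkeeping

`filter_probes()` applies seven rules **sequentially**, each acting on the
survivors of the previous one, and reports per-step removal counts (the
counts are order-dependent by construction; a probe matching several rules
is attributed to the first): named problem probes; chromosome "0"
(unmapped); X/Y/mitochondrial probes (autosomal analyses only); probes with
a non-empty mapping comment; indels; all probes of any rsID carried by more
than one remaining probe; and all probes of any probe name associated with
more than one remaining rsID. For the two duplicate rules we remove *every*
involved probe rather than keeping one representative: there is no
principled tie-break between probes of unknown relative quality, and the
choice is configurable in spirit via the exposed report (users can rejoin
removed rows if they disagree). Chromosome labels are normalised
case-insensitively, with "MT", "M" and "chrM" all accepted for the
mitochondrion.

`ab_to_bases()` translates A/B calls to plus-strand nucleotides: allele A
is the first SNP base of the probe, allele B the second, both complemented
for minus-strand probes, and heterozygotes are emitted in lexicographic
order so that comparisons against VCF-derived genotypes are deterministic.

`assemble_from_raw()` encodes the colour-channel bookkeeping: red detects
A/T bases and green detects C/G. Type II probes read both channels at one
address; a type II probe whose two bases sit on the same channel is
unassignable and dropped with a count. Type I probes read two addresses on
the probe's designated channel; for the unusual case of a type I probe
whose bases would sit on different channels, allele A's channel is used and
a warning is issued.

## The simulator, and what passing tests do and do not show

`simulate_sample()` generates per-SNP intensities with ground truth: an
allele A frequency $p$ is drawn from a Beta prior (default Beta(1, 1) —
array content is ascertained towards common variants, so no rare-variant
skew is imposed); the genotype follows Hardy–Weinberg proportions
$(p^2,\, 2p(1-p),\, (1-p)^2)$; the transformed intensity pair is drawn from
that genotype's bivariate normal cluster; and the transform is inverted
(`exp(value) - 1`, clamped at 0) to raw units. Defaults:

* cluster means $(7.5, 3.5)$, $(7.0, 7.0)$, $(3.5, 7.5)$ in ln-intensity
  units with diagonal-dominant covariances — an illustrative,
  well-separated butterfly (the geometry is a package default, not an
  empirical claim, and is fully configurable);
* type I probe fraction 135419/4055428 ≈ 3.3%, the type I share of a
  filtered high-density manifest;
* bead counts from `1 + NegBin(size = 17.5, mu = 11.9)`, calibrated by
  `calibrate_bead_dist()` so that a million draws have median 13 and
  central-95% quantiles exactly [5, 23], matching the empirical bead-count
  distribution;
* dropout probability 0.002 (both raw means set to 0) and outlier
  probability 0.001 with a 4× inflated deviation, both independent
  Bernoulli per SNP — the simplest testable contamination model.

Because the simulator draws in transformed space, the mixture family is
*exactly* correct under defaults. That is deliberate: it enables clean
parameter-recovery tests and a meaningful Bayes bound
(`bayes_bound()` samples labelled points from the generating process —
including the outlier contamination, excluding dropouts, which both routes
force to no-calls — and classifies them with the true-parameter posterior
at the same threshold; no caller can beat it in expectation). It also means
that passing these tests demonstrates correctness of the machinery, not
robustness to real-data pathologies: real arrays show asymmetric lobes,
intensity-dependent variance, batch effects and non-Gaussian tails that the
defaults do not emulate. The t-tail contamination knob (`outlier_prob`,
`outlier_scale`) provides a first robustness probe, no more.

Problem sizes used by the shipped checks — 50,000-SNP samples for
parameter recovery and end-to-end concordance, 200,000 Monte-Carlo draws
for the Bayes bound, $10^6$ draws for the bead calibration — were chosen so
that sampling noise is far below the asserted tolerances (e.g. the
binomial standard error of a 99.99% concordance at $n = 5 \times 10^4$ is
~0.004 pp against a 0.2 pp tolerance).

## Evaluation semantics

`concordance()` compares a call set with a reference (e.g. PCR-free WGS
calls loaded by `load_reference_calls()`, which keeps biallelic SNVs with
per-sample depth ≥ 25 and drops everything else with counts). The
**call rate** is the fraction of reference-called SNPs the method did not
no-call; the **concordance** is computed among SNPs called by both,
comparing unordered genotypes; discordant pairs populate a
reference × method cross-tab and a hom/het 2×2 summary. Reference no-calls
are excluded from the universe entirely. Genotypes are compared as
unordered plus-strand base pairs (or, against simulator truth, as A/B
genotypes), which sidesteps phasing and A/B orientation. SNPs are matched
to the reference by rsID, with `chrom:pos` as the identifier when a VCF
record has no ID. `conditional_on_nc()` tabulates one caller's calls on the
SNPs another caller refused, the standard way to compare no-call policies.

## Known limitations

* Binary scanner formats (IDAT) and binary manifests (BPM) are out of
  scope; inputs are delimited tables (a configurable column map accepts
  Illumina-style manifest headers).
* Signal standard deviations are carried through but unused by the model.
* The mixture assumes three genotype clusters; somatic mosaicism, CNVs and
  sex chromosomes (filtered out) violate that.
* No scanner normalisation or background correction is applied; raw means
  are modelled as exported.
* Whether to keep one representative probe of a duplicated rsID (instead
  of removing all) is a genuinely open bookkeeping choice; the remove-all
  default is the conservative one.
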