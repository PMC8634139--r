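---
title: "Methods: differential TMT phosphoproteomic screening for kinase substrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential TMT phosphoproteomic screening for kinase substrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoscreen)
```

## The problem

A kinase-substrate discovery screen compares the phosphoproteome of cells
expressing an active kinase (WT) against cells expressing a catalytically
dead point mutant (KD). Both populations are processed as five biological
replicates, multiplexed with TMT10 isobaric labels, fractionated (60
fractions concatenated to 20) and quantified by reporter ions at the PSM
level. Phosphopeptides more abundant under WT are substrate candidates;
their sequence context is then checked against the kinase's consensus
motif, validated by targeted MS with Bonferroni-corrected t-tests and by
in-vitro peptide kinase assays, and interpreted through GO
over-representation and PPI confidence binning. This package implements
every computational step of that workflow and a synthetic-data generator
that emulates the screen's statistical structure, so the pipeline can be
exercised, benchmarked and regression-tested without any raw MS data.

## Generative model of the synthetic screen

For peptide $k$ with latent abundance $\mu_k > 0$ and log2 effect
$\delta_k$ (non-zero only for substrates), the reporter intensity in
channel $i$ and fraction $f$ is

$$y_{kif} = a_i + b_i\,\mu_k\,2^{\delta_k [i \in WT] c_f} e^{\varepsilon_m}
  + \varepsilon_a,\qquad
  \varepsilon_m \sim N(0, \sigma_m^2),\ \varepsilon_a \sim N(0, \sigma_a^2),$$

truncated at zero, where $a_i$ is an additive channel background, $b_i > 0$
a multiplicative channel gain, and $c_f \in (0, 1]$ an optional
fraction-specific co-isolation compression of the effect. This
additive-multiplicative error structure is exactly the assumption under
which the arsinh variance-stabilizing transform is the natural
normalization, so normalization recovery is a well-posed benchmark.

Defaults, chosen once as a realistic desk-scale version of the screen and
recorded in every truth JSON: 2,000 peptides; 5% substrates with $\delta =
1.5$ (one-sided, WT > KD, with a flag for bidirectional effects since a
screen can contain the occasional peptide lower under WT); $\mu_k \sim
\mathrm{lognormal}(\log 10^4, 1)$; $\sigma_m = 0.25$ (natural-log scale),
$\sigma_a = 50$ intensity units; $b_i \sim \mathrm{lognormal}(0, 0.2)$,
$a_i \sim U(20, 100)$; 20 fractions with each peptide observed in 1-3 of
them and a Poisson(0.3) count of duplicate PSMs per fraction. PTM
localization probabilities are a two-component mixture: a 10% ambiguous
share drawn as $0.75\,\mathrm{Beta}(2, 2)$ (always below the gate) and a
well-localized share drawn as $0.75 + 0.25\,\mathrm{Beta}(21, 1)$, which
places roughly 40% of well-localized sites above the 0.994 flag, so both
the 75% gate and the 1%-FLR flag are exercised. 15% of peptides carry a
second phospho mark and are thus excluded from hits by the
single-unique-site rule. Substrate peptides embed a consensus context
around the phosphosite; null peptides have K at $-3$, which can never
match. One root seed drives label-derived substreams per generator, so
adding draws to one stage never perturbs another.

What the generator does **not** emulate: isotope-impurity crosstalk
between TMT channels, retention-time or charge-state effects, peptide-level
missingness correlated with abundance, and the long-tailed contaminant
populations of real searches. Passing recovery benchmarks on these
synthetic data therefore demonstrates correctness of the computation, not
performance on any real acquisition.

## Aggregation and localization filtering

PSMs are averaged per (peptide, fraction) first, and fraction-level values
are then combined by an **unweighted** mean across fractions. The
fraction-first order equalizes the contribution of fractions whose
co-isolation populations differ; weighting by PSM count would re-introduce
exactly the bias the two-step procedure avoids. With equal per-fraction
quality the two-step mean provably equals the global PSM mean, which the
tests verify. Zero intensities are kept as zeros (the transform's offset
absorbs background); missing channels propagate and reduce the per-row
degrees of freedom downstream. Rows below 75% localization probability
are removed; rows at or above 0.994 (1% false localization rate) are
flagged, and the flag is annotation only.

## Variance-stabilizing normalization

The calibration $h_i(y) = \operatorname{arsinh}(a_i + b_i y)$ is fitted by
minimizing the negative profile log-likelihood (row means and the common
variance profiled out, Jacobian included) under the model that transformed
row values are Normal with a common variance. The offset sits inside the
arsinh and gains are log-parameterized, giving a single smooth
unconstrained optimization (BFGS). Robustness against differentially
abundant rows comes from a least-trimmed-squares outer loop: rows are
ranked by residual sum of squares and the worst 10% (trim quantile 0.9,
the conventional default, exposed as a parameter) are excluded from the
next iteration, iterating to a $10^{-4}$ parameter tolerance with a
`converged` flag on the result. Initialization puts channel medians at
zero ($b_i = 1/\mathrm{MAD}_i$, $a_i = -b_i\,\mathrm{median}_i$). Channels
with zero MAD are rejected; a matrix of identical channels short-circuits
to the symmetric initial calibration (the residuals vanish there, so the
likelihood is degenerate). Reported values are
$\operatorname{arsinh}(a_i + b_i y)/\ln 2$, a generalized-log2 scale whose
large-intensity asymptote differs from $\log_2 y$ by a channel constant.

A note on identifiability: the profile likelihood is nearly flat along the
direction where all $(a_i, b_i)$ grow jointly and the transform approaches
a pure log — two parameter vectors far apart can induce almost the same
transform. Recovery is therefore assessed on gain *ratios*
($b_1/b_i$ against the generative $b_i/b_1$), which are well identified;
the tests compare fits by achieved likelihood and by the induced
transform, not by raw parameter values.

QC mirrors the screen's own diagnostics: a normal Q-Q deviation statistic,
the SD-versus-intensity-rank curve (flat after a successful fit; the
package also reports a dimensionless slope — SD change across the full
rank range relative to the mean row SD — so raw and transformed scales are
comparable), and per-channel median summaries (no channel should deviate
from the global median).

## Moderated testing and hit selection

Per row, the WT-minus-KD effect, pooled variance $s_g^2$ and residual df
$d_g = n_{WT} + n_{KD} - 2$ (reduced by missing values; rows with fewer
than two finite values per group are skipped and reported) feed an
empirical-Bayes layer: sample variances are modelled as
$s_g^2 \sim s_0^2 F(d_g, d_0)$, with $(d_0, s_0^2)$ estimated by moment
matching on $z = \log s_g^2$ using the digamma/trigamma identities for
log-chi-square moments, $d_0$ obtained from a Newton inversion of the
trigamma function. Identical variances yield the zero-dispersion limit
$d_0 = \infty$, $s_0^2$ the common value.

The robust variant winsorizes $z$ at the (5%, 10%) tails and matches the
winsorized moments against the *theoretical* winsorized moments of
$\log F(d_g, d_0)$, computed on a fine quantile grid, so a small share of
hypervariable rows cannot inflate the prior. Rows beyond the upper
winsorization limit are variance outliers and receive an individually
*reduced* prior df — scaled by the ratio of their upper-tail probability
under the fitted prior to that of the limit itself, down to zero
(no moderation) for extreme rows — so a genuinely hypervariable row keeps
its large variance instead of having it shrunk away and surfacing as a
false positive.

The moderated statistic uses
$\tilde s^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$,
$t = \mathrm{effect}/\sqrt{\tilde s^2 (1/n_{WT} + 1/n_{KD})}$ with
$d_0 + d_g$ df (normal when $d_0 = \infty$; ordinary t when $d_0 = 0$).
Both limits are verified against closed forms, and the whole layer is
cross-checked against an independent reference implementation of moderated
statistics in the test suite.

Hits require all of: $p < 5\times10^{-4}$ (strict inequality; the
"cluster" of the volcano plot is operationalized as this threshold, which
is how the screen states it), effect in the WT direction (configurable,
since enrichment foregrounds may admit both directions), a single unique
phosphosite, and the 75% localization gate. The FLR flag and the
consensus-motif match are annotations, never filters. An optional
Benjamini-Hochberg column is emitted but unused by default, matching the
screen's stated rule. Recovery metrics define sensitivity over substrates
*eligible* for selection (single-site, localized): the localization filter
is an upstream data-quality gate, and counting its casualties against the
test would conflate two different error sources.

## Consensus motif

The motif R-P-X-[S/T]-[A/G/P/S] is represented as allowed residue sets at
positions relative to the acceptor (R at $-3$, P at $-2$ — the positions
occupied in the actual substrate sequences), with X admitting all 20
residues. Windows are $\pm 7$ residues (the common phosphosite-window
convention; configurable) padded with `-` at termini, and padding never
matches. The scanner is property-tested against an independent regular
expression oracle, and the in-vitro percent-of-control quantitation
normalizes background-subtracted counts to the wild-type control peptide
(= 100%), clipping negatives to zero with a warning; KD-background
subtraction is on by default because the kinase-dead lane is the assay's
specificity control.

## Enrichment and network binning

GO over-representation uses the one-sided hypergeometric upper tail
$P[X \ge k]$ against the full background of leading razor proteins, the
enrichment factor $(k/n)/(K/N)$, and the significance rule $p \le 0.01$
with at least 3 foreground proteins — deliberately with no additional
multiple-testing correction, since that is the screen's stated rule.
Annotations are consumed as pre-fetched tables with no ontology
propagation (a pre-propagated table can be supplied). PPI edges below a
combined score of 150 are dropped and the rest binned at 400/700/900; the
legend's ranges touch, so the half-open convention ([150,400) low,
[400,700) medium, [700,900] high, (900,1000] very high) is this package's
choice, tested as a partition.

## Targeted validation, masses, ddCt

Repeated observations of a phosphopeptide are collapsed by per-channel
medians before testing. Per-peptide two-sample t-tests (Welch by default —
the validation protocol says only "t-test", and unequal variances are the
safer default; a pooled option is provided) are compared against
$\alpha/m$ with $\alpha = 0.05$ and $m$ the number of peptides tested;
thresholds are reported rounded to 3 significant figures (0.0125, 0.00833)
while comparisons use the exact value. Peptide m/z is computed from a
versioned monoisotopic constants file (water 18.010565, proton 1.007276,
phospho +79.966331, TMT10 +229.162932 Da) with default labelling at the
N-terminus plus every lysine; the doubly-TMT, singly-phospho validation
peptide lands at 628.3311 Th at $z = 3$, within a part in $10^6$ of the
instrument's printed inclusion mass — and $z = 3$ is confirmed as the
intended charge because it is the value this mass computation places
inside the 350-1,500 scan range near the printed number. Inclusion lists
enumerate (peptide, charge) pairs inside the scan range. The ddCt helper
evaluates $2^{-\Delta\Delta C_t}$ against a housekeeping reference.

## Imaging quantification

Recruitment after spot micro-irradiation is
$(\overline{I}_{in} - \overline{I}_{near})\cdot|in|$ per frame, after a
5x5 Gaussian blur. The "nearby" region is an equal-area annulus around the
ROI (unspecified in the protocol; equal area balances the variance of the
two means). Spot tracking is a light-weight intensity-weighted centroid
re-estimated within a search radius — deliberately not a re-implementation
of a full spot-tracker — and when no excess intensity is found the trace
falls back to the static initial ROI and says so, reproducing the
negative-result handling. Because the y-axis normalization of recruitment
plots varies, the trace reports raw, baseline-subtracted (pre-irradiation
frame exactly 0) and fold-over-pre forms. Track quantification subtracts
the nuclear background outside the segmented tracks; chromatin retention
is a masked mean over the DAPI region excluding the nucleolar mask. All
mask formulas are tested against brute-force per-pixel loops; masks are
binary with no soft weighting. Segmentation itself (nuclei, tracks) is out
of scope — masks are inputs.

## Pipeline, configuration, problem sizes

`run_pipeline()` executes simulate → aggregate → normalize → test → hits →
motif → enrich from a single YAML-serializable configuration holding every
threshold (5e-4, 0.75, 0.994, 0.01, 3, 150, 0.05). Unknown keys are
rejected; every output table carries the configuration hash, and equal
hashes reproduce byte-identical tables. Errors name the failing stage.
The order aggregate-then-normalize is fixed and recorded in provenance
(the alternative, normalizing per fraction before averaging, is not
supported); the calibration is fitted once on the collapsed matrix.

Benchmarks in the tests and the acceptance script use the package's
standard problem sizes: 2,000-peptide screens for calibration recovery and
hit selection, 5,000 simulated variances for prior recovery, 50,000 null
rows for type-I error, 1,000 sequences for the scan oracle, 64x64 phantoms
for imaging. At these sizes every documented recovery criterion is met
with margin (gain ratios within ~2%, prior parameters within ~3%, type-I
error within the binomial CI, sensitivity above 90% at $\delta = 1.5$).

## Known limitations

Two-group contrasts only (no general design matrices, array weights or
variance trends); no PSM-level FDR estimation, isotope-impurity correction
or charge deconvolution; no GO graph propagation; no real-image
segmentation or stitching; synthetic data idealize the error structure as
described above. The acceptor T is treated symmetrically with S throughout
the motif code, as the printed consensus does, although the underlying
assays probed +1 preferences on an S acceptor.
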