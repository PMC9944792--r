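---
title: "Quantifying CpG and non-CpG methylation from bisulfite Sanger traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CpG and non-CpG methylation from bisulfite Sanger traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sangermeth)
```

## The measurement model

Direct bisulfite Sanger sequencing estimates per-site methylation from the
relative fluorescence of the two channels that can appear at a converted
cytosine call. After bisulfite treatment, an unmethylated cytosine reads as
T and a methylated one as C, so a population of molecules with methylated
fraction $m$ produces superimposed C and T peaks, and

$$ \hat m = 100 \cdot \frac{H_C}{H_C + H_T} $$

on a forward read. A reverse read runs along the complement, where the
same information sits in the G and A channels; `flip_chromatogram()`
reverses the call order, complements the basecalls and swaps the A/T and
C/G channels so the downstream arithmetic is identical. Non-CpG (CpH)
sites — cytosines followed by A, T or C, the contexts of the neural
mCA/mCT/mCC methylation — are treated exactly like CpG sites.

Two idealisations are worth stating. First, the ratio assumes the two
dyes' responses are comparable at a given call; systematic dye bias would
need an instrument-specific calibration that is out of scope. Second,
basecalls are taken as input (the trace table carries basecalls plus the
four channel heights); raw electropherogram processing is not modelled.

## Site naming

CpG sites are numbered 1..k from the start of each region (`CpG-45` is the
45th CpG of intron 1). CpH candidates are named by the local index of the
nearest upstream CpG plus a letter in positional order: `CpG-4I` is the
ninth CpH candidate after CpG-4. Candidates upstream of the first CpG get
index 0 (`CpG-0A`) — a convention this package defines, since the
published tables never show the case. All CpH candidates are labelled,
whether or not they turn out to be methylated; the gaps in published
tables (4B listed, 4A not) are then simply undetected candidates. Runs of
more than 26 candidates roll over to double letters (`AA`, `AB`, ...).

Coordinates are 0-based half-open internally (the BED convention);
reports print 1-based positions. Minus-strand regions are
reverse-complemented at load time, so enumeration always walks the
analysed strand 5'→3'.

## Conversion efficiency and correction

Incomplete bisulfite conversion leaves a fraction $1-\varepsilon$ of
unmethylated cytosines reading as C, inflating $\hat m$. CpH candidates
that are *not* genuinely methylated are natural controls: any C signal
there is residual non-conversion, so
$\hat\varepsilon = 1 - \overline{\hat m_{\mathrm{ctrl}}}/100$ (at least 3
controls required). The correction inverts the mixture:

$$ m = 100 \cdot \max\!\left(0, \frac{\hat m / 100 - (1-\varepsilon)}
{\varepsilon}\right), $$

capped at 100. Because some CpH sites are genuinely methylated (notably in
the MSA promoter), cohort quantification runs two passes: estimate
efficiency with all CpH candidates, discover methylated CpH sites from the
raw matrix (group median above 5% in at least one group), then re-estimate
on the reduced control set and correct. Without the exclusion, samples
with true non-CpG methylation would be wrongly penalised. Profiles with
$\hat\varepsilon < 0.90$ (configurable) are excluded rather than
corrected. The specific correction formula is this package's explicit
stand-in for an unpublished normalisation in the original assay software;
`correction = FALSE` reproduces raw ratios.

## Alignment

Sanger amplicons are short and fixed, so alignment is ungapped: the offset
maximising matching calls against the in-silico converted reference is
chosen, with every panel cytosine rendered as the IUPAC code Y (its C/T
identity depends on methylation). Ties in match count go to the
higher-identity window. A best identity below 90% over the overlap rejects
the trace — permissive, because the converted sequence is effectively
three-letter; indels are treated as QC failures, not modelled. The chosen
offset is provably score-maximal (the test suite verifies it against an
exhaustive scorer).

## Statistics

Group summaries are `median [Q1; Q3]` with type-7 quantiles (the R
default; the original analysis software's rule is undocumented, so the
type is selectable). Two-group comparisons use the Mann–Whitney U test:
exact p by full null enumeration when there are no ties and
$n_x n_y \le 400$, otherwise the tie-corrected normal approximation
without continuity correction. K-group comparisons use Kruskal–Wallis;
correlations use Spearman's rank test with the conventional clinical
bands — below 0.3 negligible, 0.3–0.5 weak (screened out), 0.5–0.7
moderate, 0.7–0.9 strong — and a retention rule $|\rho| \ge 0.5$.

Multiplicity is handled per region and site kind: promoter CpG, promoter
CpH, intron-1 CpG and intron-2 CpG form separate Bonferroni families, one
family per pairwise comparison, with significance decided by
$p < \alpha/m$ at full precision (strict inequality). Printed thresholds
truncate rather than round — $0.05/7 = 0.00714 \to$ `0.007`,
$0.05/28 = 0.00179 \to$ `0.0017`, $0.05/2 \to$ `0.025` — implemented as
truncation to 3 decimals at or above 0.005 and 4 below; the truncated
string is display-only. (The published methods text pairs the 0.007 and
0.0017 thresholds with swapped family descriptions relative to its own
region definitions; this package maps thresholds by family size.)

Sites that are essentially unmethylated in every group carry no
comparative information: a site is dropped before testing when its value
is at most 5% in at least 95% of each group's samples. On the shipped
scenario this removes exactly the intron-1 CpG 1–20 block, the promoter
CpG-1/2 sites outside the analysed window and the conversion-control CpH
candidates, leaving families of 7, 28, 28 and 2 tests.

## The synthetic study generator

No patient-level data are available for studies of this design, so the
generator produces cohorts with the statistical structure the analysis
assumes, making every stage testable end to end.

**Marginals.** Published per-site summaries are `median [Q1; Q3]`, several
of which sit on a boundary (`0 [0; 10]`, `100 [87; 100]`) — impossible for
any continuous beta. Each site × group marginal is therefore a three-part
distribution on [0, 100]: point masses $p_0$ and $p_{100}$ plus a
location-scale beta body. Quantile geometry fixes the minimal boundary
mass (a boundary median forces mass ≥ 0.5, a boundary quartile ≥ 0.25; a
0.05 buffer is added so the boundary quantile is attained robustly), and
the body's four parameters are optimised to the interior quantile targets
(weakly regularised where underdetermined). The location-scale freedom
matters: a skewed triplet like `50 [40; 55]` cannot be matched within a
point by a plain two-parameter beta. Fits reproduce their targets to well
under one percentage point; simulated cohorts of 5000 reproduce them
within 1.5 points.

**Correlations.** Clinical correlations are injected through a Gaussian
copula. A target Spearman $\rho_S$ maps to the latent Pearson correlation
$\rho_P = 2\sin(\pi\rho_S/6)$, exact for continuous margins; for that
reason the sites carrying correlation targets are given interior
(boundary-free) marginals, since boundary atoms introduce ties that
attenuate rank correlations. Sites sharing a target covariate receive a
mutual latent correlation of 0.5 — neighbouring sites are co-methylated in
real data, and without this block the latent matrix of four sites each at
$\rho \approx 0.52$–0.56 with one covariate is not positive definite. Any
residual non-PD matrix is repaired with `Matrix::nearPD()`.

**Covariates.** Age at onset, disease duration and UPDRS-III are drawn by
monotone piecewise-linear interpolation of the published `median [Q1; Q3]`
(linear tails out to the 1st/99th percentiles, clamped to plausible
ranges) — monotone, hence Spearman-preserving, while reproducing the
printed quartiles exactly. Patient age is onset + duration by
construction, which reproduces the published MSA age almost exactly and
sits about three years under the published PD median — accepted as the
cost of enforcing the consistency invariant. Hoehn–Yahr stages and sex
follow the published frequencies; treatment flags are independent
Bernoulli draws at the published prevalences with no methylation effect,
mirroring the published null finding.

**Unpublished marginals.** Only a subset of sites has printed summaries.
The remaining sites use deterministic defaults, identical across groups so
they contribute no spurious effects: mid-range triplets varying by site
index for analysed CpG/CpH sites, and a near-zero marginal (70% exact
zeros plus a thin beta tail of mean 0.7%) for the persistently
demethylated blocks — "demethylated" is modelled as essentially always
below the 5% information threshold. The truth tables written with every
scenario make all assumed shapes explicit.

**Traces.** The generative inverse of the peak ratio: at a site with
methylation fraction $m$, $H_C \propto m + (1-\varepsilon)(1-m)$ and
$H_T \propto \varepsilon(1-m)$, each scaled by the total signal (default
1000 RFU) and an independent multiplicative noise factor
$1+\epsilon,\ \epsilon \sim N(0, \sigma)$ truncated at −0.9; silent
channels carry a 1% cross-talk baseline. Defaults: $\sigma = 0.02$,
$\varepsilon = 0.98$. With $\sigma = 0$ the pipeline inverts the generator
exactly at every site, including through the conversion correction — an
algebraic identity the tests assert. The synthetic reference is a
deterministic minus-strand gene fragment (clearly labelled synthetic)
whose site geometry mirrors the analysed regions: 9 promoter CpGs with 28
clustered elevated CpH candidates — including an adjacent C-C-C run
(4I/4J/4K) and 7A three bases downstream of CpG-7 — plus unmethylated CpH
conversion controls; 48 intron-1 CpGs with CpG 1–20 near zero; 2 intron-2
CpGs (written as reverse-direction reads to exercise the channel flip).
Electropherogram raw signal, PCR bias and batch effects are *not*
simulated, so passing tests validate the quantification arithmetic and
statistical machinery, not robustness to those real-world artefacts.

## Problem sizes and determinism

The shipped full scenario is 82 PD + 24 MSA + 50 control samples × 3
amplicons (468 traces, ~100 sites); the test suite exercises it once end
to end and uses reduced cohorts (typically 3–25 samples per group, and
200 replicates for generator-fidelity and null-error checks) elsewhere.
All generators are seeded: a fixed seed gives byte-identical study
directories, and every simulation run writes a manifest with its seed and
input fingerprints.

## Known limitations

- The conversion correction is an assumption, not a reconstruction of the
  original software's normalisation; raw-ratio mode is provided.
- Ungapped alignment cannot rescue traces with indels; they are excluded.
- The copula reproduces pairwise rank correlations, not the full joint
  dependence of real methylation profiles; between-site correlation is
  modelled only within correlated blocks.
- Small subgroups (n near 10) routinely produce spurious
  $|\rho| \ge 0.5$ correlations in the screen, as the README example
  shows; the retention rule is a screen, not an inference guarantee.
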