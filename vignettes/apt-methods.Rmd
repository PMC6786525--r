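---
title: "Methods: content scoring, APT prediction, and citation editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: content scoring, APT prediction, and citation editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptscore)
```

# The problem

Most biomedical research is funded in the hope that it will eventually
improve human health, yet the first externally visible marker of that
transfer — citation of a paper by a clinical trial or guideline — often
arrives a decade or more after publication. `aptscore` operationalises a
simple question: given what the literature has done with a paper in its
first few years, what are the odds it will ever receive a clinical
citation? The package covers the full chain: content classification from
MeSH, the triangle-of-biomedicine embedding, citing-network feature
engineering, a calibrated random-forest predictor (the APT score), and
counterfactual perturbation of citing networks.

# Content classification

Every MeSH descriptor carries one or more *tree addresses* — dot-separated
paths such as `B01.050` — and category membership is decided purely by
address prefix tests:

| Category | Rule |
|---|---|
| Human | the single `Humans` address (`B01.050.150.900.649.801.400.112.400.400`) or anything under `M01` (Persons) |
| Animal | anything under `B01` (Eukaryota) except the Humans address |
| Molecular/Cellular | anything under `A11`, `B02`, `B03`, `B04`, `G02.111.570`, or `G02.149` |
| Disease | the `C` branch except `C22` (Animal Diseases) |
| Therapeutic/Diagnostic | the `E` branch except `E07` (Equipment and Supplies) |
| Chemical/Drug | the `D` branch |

Three conventions matter and are fixed throughout the package:

- **Descriptor-level set semantics.** A descriptor counts at most once per
  category however many of its addresses match, because articles are indexed
  with descriptors, not addresses. A descriptor *may* belong to several
  categories (e.g. `Tumor Cells, Cultured` is both Molecular/Cellular and
  Disease); nothing in the address algebra forbids that and the union is the
  natural reading.
- **Qualifier stripping.** Subheading suffixes (`"Neoplasms/drug therapy"`)
  are removed before lookup; classification concerns the descriptor.
- **Strict-by-default lookup.** An unknown descriptor is an error unless the
  vocabulary was built with `lenient = TRUE`, in which case it is dropped
  with a warning. Silent empty sets hide data corruption.

The vocabulary is an input artifact: `read_mesh_ascii()` parses the NLM
ASCII descriptor format (`MH = ` / `MN = ` lines), `read_mesh_tsv()` a flat
two-column dialect. The packaged miniature vocabulary
(`toy_mesh_vocabulary()`, ~50 descriptors spanning all six systems) is a
test and simulation substrate, not a substitute for a full NLM baseline;
vocabularies evolve (addresses move between releases), so analyses should
pin a vocabulary version alongside their corpus.

# Fractional HAMC scores and the triangle

With distinct-descriptor counts $(n_H, n_A, n_{MC})$, the fractional score
is $h = n_H / N$, $a = n_A / N$, $mc = n_{MC} / N$ with
$N = n_H + n_A + n_{MC}$. When $N = 0$ the score is *undefined* — the
article cannot be placed on the triangle — and such articles are excluded
from triangle plots and curve groups rather than silently mapped anywhere.
Binary scoring (`binary_hamc()`) is retained as the coarser baseline: it
collapses any mixed article onto equal fractions of its present categories,
which is exactly why fractional counting is the default.

The trilinear embedding is

$$x = a\frac{\sqrt3}{2} - mc\frac{\sqrt3}{2}, \qquad
  y = h - \frac{a}{2} - \frac{mc}{2},$$

whose constants are the coordinates of the equilateral triangle's vertices:
Human $(0, 1)$, Animal $(\sqrt3/2, -1/2)$, Molecular/Cellular
$(-\sqrt3/2, -1/2)$. $\sqrt3/2$ is always computed, never the decimal
`0.866`; the simplex constraint is checked to `1e-9`. The transform is
affine, so mixtures of scores map to mixtures of coordinates — the property
the test suite uses as its oracle.

Focus classes partition articles by term presence: *fundamental* (no Human
terms, at least one Animal or Mol/Cell term), *human-focused* (Human terms
only), *mixed*, *unclassified*. The "fundamental" label is operational
shorthand for indexing patterns, not a judgment about the science. For
articles with $0 < h < 1$, `human_fraction_band()` splits at thirds with
left-closed intervals (`h = 1/3` is LOW), matching the convention that the
low band is "≤ 33.3% Human".

# Data profiles

The classifier input is a fixed 22-vector per article:

1. article block (7): `H, A, MC, D, E, CD, CPY`;
2. network block (15): `maxH, meanH, sdH, maxA, meanA, sdA, maxMC, meanMC,
   sdMC, meanD, sdD, meanE, sdE, meanCD, sdCD` over the article's citing
   set.

Feature order and names are frozen in `APT_FEATURES`; training and
prediction both align columns by name and refuse mismatches, so a profile
matrix is portable across sessions and the persisted-model sidecar can
detect drift.

Numerical conventions, chosen where the underlying procedure is
underdetermined:

- **Window boundary.** "Two years post publication" retains citation years
  `pub_year .. pub_year + 2` (inclusive), consistent with end-of-calendar-
  year snapshots; callers wanting the half-open variant pass
  `window_years - 1`.
- **Citation rate.** `CPY = n / max(1, as_of_year − pub_year + 1)`:
  elapsed calendar years plus one, floored at one so same-year citations do
  not divide by zero. When the network is windowed, both the count and the
  denominator use the same window; `rate_full_history = TRUE` overrides to
  full-history counts for sensitivity analyses.
- **Standard deviations.** Population SD (divide by $n$), with $n \le 1$
  giving 0. This keeps singleton and empty networks finite and makes the SD
  a pure dispersion summary rather than an estimator.
- **Undefined citers.** A citing article with no HAMC terms contributes
  `(0, 0, 0)` to the HAMC summaries but still counts in every denominator
  and in `CPY`, so $n$ is consistent across all fifteen network features.
- **Duplicates.** Duplicate edges are kept as distinct observations; the
  citation-editing "Originals" control depends on duplication being
  representable.
- **Empty networks** produce an all-zero network block plus `CPY = 0` — a
  representable, meaningful state (a so-far-uncited paper), not a missing
  value.

# The APT classifier

A probability random forest (`ranger`, 100 trees by default, seeded,
single-threaded for bit reproducibility) is trained after randomly
downsampling the majority class — in realistic corpora, the clinically
uncited — to twice the minority count. Downsampling never touches minority
rows. The raw output is the ensemble vote fraction for the positive class.

Because vote fractions need not be linear in actual outcome rates, they are
*binned, not reported raw*. `apt_calibrate_bins()` seeks four strictly
increasing thresholds cutting the calibration scores into five contiguous
bins whose empirical positive rates sit as close as possible to
$(0.05, 0.25, 0.50, 0.75, 0.95)$ — the five APT bins <5%, 25%, 50%, 75%,
>95%. The objective (sum of squared deviations of per-bin rates from the
targets) is minimised exactly by dynamic programming over a quantile grid of
candidate cut positions (default 256, placed only where the sorted raw
score strictly increases so thresholds are well defined). "Centred on the
actual distribution of positive cases in each bin" admits more than one
formalisation; a least-squares threshold scan is the one implemented here,
and the calibration object always reports the achieved rates so users can
judge the fit. Degenerate inputs (constant raw scores, too few distinct
values for five bins) are errors, not silent single-bin output.

Calibration is fitted on a split held out from forest training: fitting the
bins on training-set votes would inherit the forest's optimism and shift
every threshold.

`apt_evaluate()` reports accuracy, F1 for the positive class, the ROC curve
and AUC (via `pROC`), the precision-recall curve, and the chance rate
(test-set prevalence) that any accuracy figure must be read against.
Feature importance is the forest's mean decrease in Gini impurity,
normalised to sum one; the fundamental-only and human-focused-only
importance rankings are obtained by retraining on the corresponding focus
subset rather than by post-hoc masking.

Article-only baselines (content features without the network block) are a
feature-subset exercise on the same profile matrix, not a separate code
path.

# Temporal experiments

`apt_trajectory()` scores articles with one fixed classifier on cumulative
yearly snapshots of their citing networks. Two controls disentangle *why* a
score moves:

- **Growing network, fixed classifier** (default): any change reflects new
  information entering the citing network.
- **Fixed network** (`freeze_network_year`): the profile — network block
  *and* the citation-rate clock — is frozen, so re-scoring at later years,
  or with classifiers retrained on other draws of a stationary corpus, must
  return (nearly) the same score. Freezing the rate clock matters: a frozen
  edge set with a running clock would mechanically decay `CPY` and smuggle
  a trend into the control.

# Citation editing

For articles whose APT bin rose between two windows (default: bin 25% at
two years, any higher bin at three), `edit_network()` deletes the citation
increment and appends an equal number of synthetic citers:

- `ORIGINALS` — resampled (with replacement, seeded) from the earlier
  network: the size-only control;
- `MOLCELL`, `ANIMAL`, `HUMAN` — homogeneous citers with the named score 1
  and everything else 0;
- `HUMAN_PLUS` — citers with `h = 1` and `d = e = cd = 1`, the most
  clinically-flavoured admissible citer.

Every edit conserves the natural later-snapshot size, so the citation rate
is held fixed across edit types and only composition varies (except for
`ORIGINALS`, where composition is held and only size-vs-natural-composition
varies). Synthetic citers carry the increment year. A `replace_all` flag
implements the variant in which the whole network is replaced. ΔAPT is
reported both as raw vote-fraction difference (high resolution) and as
bin-centre difference (comparable across calibrations). Vertex strata
(articles with ≥95% of HAMC content in one category) allow the effect of an
edit to be read conditionally on the edited article's own content.

# The synthetic corpus

`generate_corpus()` is first-class, tested code, not a fixture dump. It
emulates the statistical structure the pipeline assumes:

- **Content**: articles draw a simplex position from a four-region mixture
  (human-focused, animal, mol/cell, mixed; Dirichlet concentrations 8:1:1
  per dominant region, 3:3:3 mixed), realised as descriptor lists from the
  miniature vocabulary with Poisson($5$)+1 HAMC terms. A small fraction
  (2%) of articles carry no HAMC terms, so the undefined-score path is
  exercised.
- **Modifier flags**: $p_D = 0.15 + 0.55h + 0.35a$,
  $p_E = 0.10 + 0.60h$, $p_{CD} = 0.20 + 0.30h + 0.20mc$ (clamped to
  $[0,1]$). The Disease flag deliberately rises with *animal* as well as
  human content: animal disease-model literature is heavily indexed with
  C-branch terms, and this is what gives animal-flavoured citations a
  genuine, learnable association with translation in the simulated world.
- **Citations**: grown year by year; each new article cites
  Poisson($8$) earlier articles, with attachment probability proportional
  to $(1 + \text{prior citations})^{0.8} \cdot e^{-d/0.6}$ where $d$ is
  Euclidean distance on the triangle. The similarity kernel encodes the
  observation that knowledge flows preferentially between nearby content
  regions; candidate subsampling (8 per reference slot) keeps generation
  linear in corpus size, and the weighted choice uses the Gumbel-max trick
  so it is exact and vectorised.
- **Clinical-article flags**: probability $0.08 (0.4 + 1.2h)$, so clinical
  citers concentrate near the Human vertex and the `exclude_clinical`
  robustness control has something to exclude.
- **Outcome**: the planted mechanism
  $\Pr(\text{clinical citation}) = \sigma(-3.9 + 4.0\,\overline{H}_{cit} +
  1.5\log(1 + CPY) + 1.5\,\overline{D}_{cit})$ evaluated on each article's
  realised full-history network. The per-article probability is stored, so
  `bayes_auc()` gives the exact discrimination ceiling against which a
  trained forest can be judged. The default coefficients were fixed once so
  that the simulated prevalence of clinically cited articles lands near the
  0.2–0.3 range typical of long-horizon bibliometric corpora.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real literature: field- and journal-level effects,
review articles' distinct citation kinetics, indexing lag and vocabulary
drift, self-citation, and any direct coupling between being *flagged*
clinical and *receiving* clinical citations beyond the planted mechanism.
Synthetic results validate the machinery, not the headline numbers
obtainable on a bulk bibliographic corpus.

# Problem sizes and determinism

The shipped tests run the method at the sizes the checks need and nothing
larger: bin calibration on $10^5$ Bernoulli draws, planted-mechanism
recovery and citation editing on a 50,000-article corpus (editing on a
250-article subsample of APT-up papers), classifier-stability on three
8,000-article corpora, oracle equivalences on 1,000 random networks. Every
stochastic step takes an explicit integer seed — corpus generation,
downsampling, forest fitting, ORIGINALS resampling, the workbench's named
substreams — and the test suite asserts byte-level reproducibility where it
is promised (corpus generation, editing, workbench tables).

# Rendering

Triangle density maps accumulate articles as unit point sources on a
nearest-pixel raster (default 512², conserving total weight exactly), then
apply a separable Gaussian blur (σ in pixels, zero-padded; σ = 0 is the
identity) and a perceptually uniform pseudocolour palette. Ratio maps —
e.g. the fraction of articles per pixel with a clinical citation — divide
two smoothed rasters and mask zero-denominator pixels to `NA` rather than
inventing values. Blur width and raster size are configuration, not
science; no attempt is made to replicate any particular legacy palette.

# Known limitations

- The category rules are tied to a vocabulary snapshot; re-running with a
  newer MeSH baseline can move descriptors between categories.
- The APT bin boundaries are only as good as the calibration split;
  strongly non-stationary corpora need re-calibration per era.
- Vote fractions from a finite forest are discrete; with very few trees the
  calibration grid may not find five well-separated bins.
- The workbench is a reproducibility harness, not a scheduler: one
  directory per run, artifacts overwritten in place.
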