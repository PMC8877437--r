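---
title: "Discovering microbial biotransformations with biotransnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering microbial biotransformations with biotransnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biotransnet)
```

## The problem

Gut microbes chemically transform dietary molecules: a decarboxylase strips
CO2 from a hydroxycinnamic acid, a reductase saturates a double bond, a
methyltransferase caps a catechol. Each such biotransformation consumes a
substrate and produces a product, and both leave traces in untargeted LC-MS/MS
metabolomics, while the responsible organism leaves traces in 16S or shotgun
metagenomics of the same stool samples. Association testing alone — correlate
every molecular feature with every microbial feature — recovers these
relationships but buries them under enormous numbers of spurious
correlations, because co-occurring features need not interact.

`biotransnet` filters associations through two orthogonal lines of chemical
evidence. A candidate biotransformation must form a **golden triangle**:

1. the microbial feature is **negatively** correlated with the substrate
   (the reaction consumes it),
2. the microbial feature is **positively** correlated with the product
   (the reaction makes it), and
3. the substrate and product are connected by an edge of the **molecular
   network**, i.e. their tandem mass spectra are similar, implying
   structural similarity.

A fourth, optional filter demands that the precursor mass difference between
substrate and product equals the mass delta of a known chemical
transformation (e.g. −43.9898 Da for a CO2 loss) within tolerance.

## The statistical model

**Association network.** For molecular feature $x$ with intensities
$FI(x, s)$ and microbial feature $y$ with counts $OTU(y, s)$ over shared
samples $s$, the null hypothesis is that the two series are independent.
The test is Spearman's rank correlation: $\rho$ is the Pearson correlation
of average-ranked values, so zeros participate as true zero measurements and
the statistic is invariant under monotone transforms (no normalization model
is imposed on either platform). An edge $(x, y)$ is kept when
$p < 10^{-4}$ and $|\rho| > 0.1$ (both configurable; the defaults are the
standard screening thresholds for cohorts of thousands of subjects and
should be tightened or loosened with sample size). Raw p-values are
thresholded by default — the screening threshold is an integration device,
not a family-wise error claim, and the triangle constraint is the real false
positive filter — but a Benjamini–Hochberg mode is available
(`adjust = "BH"`).

For $n > 9$ paired samples the p-value uses the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ with $n-2$ degrees of freedom; for
$n \le 9$ the exact permutation null over all $n!$ rank permutations is
enumerated. The exact null assumes untied ranks (the function receives only
$\rho$ and $n$, and a tie-aware exact null would need the tie structure);
tied data at $n \le 9$ therefore see a mildly conservative reference
distribution. Perfect correlations never return $p = 0$: the exact path
yields $2/n!$ and the approximate path the smallest positive double.

**Molecular network.** Spectra are first merged into consensus nodes by a
deterministic greedy pass: descending total-intensity order (ties on id), a
spectrum joins the earliest node whose precursor is within 0.02 Da and whose
representative spectrum reaches plain cosine 0.7, otherwise it seeds a node.
Node pairs are then scored with the **modified cosine**: square-root
intensities, unit-normalized per spectrum, with a fragment of one spectrum
allowed to match a fragment of the other either directly or shifted by the
precursor difference, and the score taken over an exact maximum-weight
one-to-one assignment of candidate peak pairs (branch-and-bound over the
sparse candidate list, verified against brute-force enumeration in the test
suite). Edges require cosine ≥ 0.7 — the conventional molecular-networking
default — and ≥ 6 matched peaks, which suppresses one-peak coincidences.
All precursor arithmetic is on the m/z axis under a uniform singly charged
[M+H]⁺ assumption; multiply charged species are out of scope.

**Cohort merging.** When both a host (gut) and a diet (food) cohort are
supplied, their networks are merged: nodes agreeing within 0.02 Da in
precursor mass *and* 0.7 in cosine are unified into intersection nodes
(a mass-only mode exists for libraries without informative fragments), and
each surviving node is labeled intersection, gut-unique or food-unique.
Products observed only in the gut are flagged `gut_unique_product` on the
reported triangles — a molecule absent from food but present in the host is
a stronger candidate for in-host production. It is a flag, not a filter.

**Rules and dereplication.** A biotransformation rule is a named signed
monoisotopic mass delta. The built-ins cover the common gut-microbial
phenolic transformations (decarboxylation −CO2, dehydroxylation −O, catechol
O-methylation +CH2, double-bond reduction +H2, beta-oxidation −C2H4,
glucuronidation +C6H8O6); deltas are always computed from element
monoisotopic masses, never copied from rounded literature prints, and the
0.02 Da matching tolerance absorbs print rounding. Substrates are annotated
by parent-mass dereplication against a compound table at 0.002 Da against
the computed [M+H]⁺ adduct mass; fragmentation-level identity scoring is not
performed, so annotations are level-4 style parent-mass hypotheses (below
200 Da parent-mass matching is the only applicable level regardless).

**Triangle extraction.** For every molecular-network edge and every microbe
associated with both endpoints, the correlation signs orient the undirected
edge: the negative endpoint is the substrate. `mode = "same_sign"`
additionally admits triplets whose two correlations share a sign —
substrate-limited reactions where more substrate also means more product —
oriented by compound-database annotation, then by larger precursor mass as
substrate. When several molecular features map to the same node, the
(microbe, node) pair is represented by the feature with the smallest
p-value (then largest $|\rho|$, then feature id). Output is sorted by
$\max(|\rho_s|, |\rho_p|)$ descending and is deterministic.

## A worked run on synthetic data

The package ships a generator whose defaults define the reference study
conditions used throughout the tests: 200 samples, 30 microbes, 100
molecular features, 5 planted biotransformations.

```{r example}
cohort <- simulate_cohort(n_samples = 200, n_microbes = 30,
                          n_molecules = 100, n_planted = 5,
                          noise_sd = 0, seed = 42)
result <- discover_biotransformations(
  cohort$molecules, cohort$microbes,
  cohort$spectra_gut, cohort$spectra_food,
  compound_db = cohort$compound_db)
result$triangles[, c("microbial_feature_id", "substrate_name",
                     "matched_rules", "rho_s", "rho_p", "edge_cosine")]
evaluate_recovery(cohort$truth, result$triangles)
```

On the noise-free cohort all five planted triplets are recovered with no
false positives (precision = recall = 1).

## What the generator emulates — and what it does not

Planted structure follows the golden-triangle hypothesis generatively.
Microbial abundances are lognormal per sample (log-mean drawn uniform on
log 20–log 200, log-sd 1), observed as Poisson counts of those means —
positive, right-skewed, with realistic mean–variance coupling. For a planted
triplet with microbe abundance $a$, substrate intensity is
$b\,(1 - e\,g(a))$ and product intensity $b\,e\,g(a)$ with baseline
$b$ lognormal around $10^5$, effect strength $e = 0.8$ by default, and
$g(a) = a^2 / (a^2 + K^2)$ a Hill-type saturating function with
half-saturation $K$ at the microbe's median abundance — Spearman only
requires monotonicity, so the exact saturating form is a free choice fixed
once. Intensity noise is multiplicative lognormal of scale `noise_sd`
(mass-spectrometric intensities are positive and right-skewed). Substrate
and product spectra share eight fragments with the upper half shifted by the
rule's delta, so their modified cosine is ~1 with 8 matched peaks; unplanted
molecules get independent random fragments and intensities. Food spectra
contain substrates and unplanted molecules but never planted products. Rules
are assigned to substrates cyclically, skipping assignments whose product
m/z would fall within 0.06 Da of an existing feature, so every synthetic
molecule is mass-resolvable at the 0.02 Da tolerance.

The generator does **not** emulate instrument artifacts (retention-time
drift, in-source fragmentation, adduct heterogeneity, isotopologues),
compositionality of relative abundances, zero inflation beyond what Poisson
sampling produces, or realistic taxonomic covariance between microbes.
Passing tests therefore demonstrate correctness of the integration logic and
its statistical calibration under the stated generative model — not
field performance on real cohorts, where feature extraction quality and
confounding dominate.

## Numerical choices and degenerate inputs

* Tolerances: 0.02 Da for precursors, fragments, feature↔node matching and
  rule matching; 0.002 Da for dereplication. All configurable.
* Constant features are skipped in association testing (rank correlation is
  undefined), with a reported count; blank CSV cells read as zero with a
  reported count; "present in a sample" means strictly positive.
* Clustering and matching tie-breaks are deterministic everywhere (documented
  per function), so a fixed-seed cohort yields byte-identical reports across
  runs.
* An empty filtered matrix, an empty rule set, an empty compound table and a
  triangle-less result are all legal and propagate to empty (header-only)
  outputs rather than errors.
* Peak binning when building consensus spectra is a single ascending sweep
  that starts a new bin when the gap to the current bin's intensity-weighted
  mean exceeds the fragment tolerance.

## Design decisions taken where the design was open

* **Enzyme features need no special path**: a `count_matrix` with
  `feature_kind = "enzyme"` (e.g. predicted KEGG enzyme abundances) flows
  through the identical pipeline; only the interpretation of the microbial
  feature changes.
* **Orientation of an undirected spectral edge** is decided by correlation
  signs first; annotation and mass order are tie-breakers only (used in
  same-sign mode).
* **min_matched_peaks = 6** is the conventional molecular-networking default;
  the consensus-merge heuristic (descending total intensity, earliest
  compatible node) was chosen for determinism, since published clustering
  tools do not specify their tie-breaking.
* **All candidates are reported** (with `rule_unmatched` and
  `gut_unique_product` flags) rather than imposing an opaque ranking;
  `require_rule = TRUE` gives the strict rule-filtered view.
* Reference problem sizes in the test suite (cohorts of 100–200 samples and
  100 molecular features, spectra of 6–8 fragments) keep exhaustive oracle
  comparisons — permutation nulls, brute-force peak assignments, full triple
  enumeration — tractable while exercising every code path.

## Known limitations

* Mass-only rule matching cannot check structural applicability (whether the
  substrate even has a carboxyl group to lose); SMILES strings are carried
  through compound tables for downstream structure-aware filtering.
* Parent-mass dereplication cannot distinguish isomers.
* Spearman screening ignores compositionality; on relative-abundance data
  consider the caveats of correlation-based microbiome analysis.
* A single [M+H]⁺ charge assumption; negative mode and multimers are out of
  scope.
* The exact permutation p-value at $n \le 9$ assumes untied ranks.
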