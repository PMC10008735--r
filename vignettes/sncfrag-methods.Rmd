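---
title: "Methods: models, defaults and design choices in sncfrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults and design choices in sncfrag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the generative model behind the synthetic data, the annotation and
characterization rules, the count model used for differential expression,
the marker-selection and classification protocol, and the numerical and
design choices made where several defensible options existed.

## The problem

Small-RNA sequencing of cell-free compartments (blood serum, bone-marrow
supernatant) over a 15–45 nt window captures, besides mature miRNAs, large
populations of fragments of longer parental RNAs: rRNA-derived (rsRNA),
YRNA-derived (ysRNA) and tRNA-derived (tsRNA) small RNAs, plus piRNAs and
other small ncRNAs. Analysis of such libraries needs (i) a class
assignment for every read, (ii) fragment-level descriptions (where on the
parent a fragment comes from), (iii) case-control differential expression
on counts, (iv) marker-panel selection with honest validation, and (v) a
measure of agreement between paired compartments. The deposited cohorts
behind this design are controlled-access, so the package ships a
generative model with known ground truth instead of data; every stage is
validated by parameter recovery against that truth.

## Synthetic reference

`build_default_reference()` creates a miniature but structurally faithful
parental-RNA universe: nuclear rRNAs (5S, 5.8S, 18S at 1,869 nt, 28S at
2,920 nt, and a 45S precursor embedding 18S/5.8S/28S between transcribed
spacers), mitochondrial 12S/16S, the four YRNAs at real gene lengths
(83–113 nt), 22 cytoplasmic tRNAs labelled amino-acid/anticodon (with
longer bodies for Leu/Ser, which carry a variable arm), six mitochondrial
tRNAs, 55 mature miRNAs (19–25 nt), 24 piRNAs (26–32 nt), ten other small
ncRNAs and one exogenous spike-in.

Sequences are drawn from a uniform base model under **15-mer uniqueness
rejection sampling**: every 15-mer occurs at exactly one reference location
except inside the deliberate 45S nesting, and tRNA 15-mers are checked on
the CCA-appended mature sequence. Two consequences matter:

* any 15–45 nt read has at most one exact origin (plus its 45S shadow), so
  annotation accuracy against generator truth is exactly measurable and
  should be 100% at zero mismatches;
* first-15-mer lookup plus verification enumerates *all* exact hits, which
  makes the k-mer index a complete exact-matching algorithm, not a
  heuristic (the test suite cross-checks it against a brute-force substring
  scan).

A uniform base model is a simplification: real references carry repeats,
homopolymers and compositional bias, so real-data annotation is harder
than the synthetic benchmark. Passing the recovery tests demonstrates the
machinery is correct, not that real serum reads are unambiguous.

## Fragment mixture and its defaults

`default_mixture()` fixes the healthy-serum conditions:

| parameter | default | meaning |
|---|---|---|
| class proportions | rsRNA 0.6286, ysRNA 0.1497, tsRNA 0.0422, miRNA 0.0309, piRNA 0.0743, other 0.0743 | serum composition; the piRNA/other split of the 0.1486 remainder is an even split, chosen once |
| rsRNA parents | 28S 0.88, 18S 0.10, rest 0.02 | 28S/18S dominance; the 2% remainder is spread over 5S/5.8S/45S/12S/16S |
| 18S peaks | 674–692, 897–919, 1194–1223, 1838–1862 (equal weights) | positional hotspots of 18S fragments |
| 28S peaks | 1336–1355, 1963–1982, 2895–2920 | idem for 28S |
| off-peak background | 0.10 | fraction of rsRNA reads placed uniformly |
| cyto tsRNA positional model | 5' 0.70, inner 0.20, 3' 0.05, 3'CCA 0.05 | 5'-dominant cleavage |
| mito tsRNA positional model | 0.15 / 0.70 / 0.10 / 0.05 | inner-skewed |
| cyto : mito tsRNA | 0.85 : 0.15 | mt-tsRNAs are a minor component; exact share chosen once |
| ysRNA gene weights | RNY4 0.55, RNY1 0.20, RNY3 0.15, RNY5 0.10 | RNY4-dominant |
| ysRNA 5' fraction | 0.90 | 5'-end dominance |
| length models | discretized normals: ysRNA 30±2.5, tsRNA 32±4, rsRNA 28±6 nt | class-typical lengths; miRNA/piRNA reads are full-length parents |

Peak reads are sampled wholly inside their interval (length truncated to
the interval width), so the planted coverage is near-rectangular; the 10%
background adds a low uniform floor. 45S-only reads are drawn from spacer
regions so that most-specific-parent assignment leaves them on 45S, keeping
parent-level ground truth exact.

Out of scope by design: sequencing errors beyond an optional uniform
substitution rate (`mutation_rate`, default 0), UMIs, and adapter
artefacts.

## Annotation engine

Matching is ungapped, full-read, forward-strand, exact by default
(`max_mismatch = 0`); a 1-mismatch fallback scan exists behind the flag but
is quadratic and intended for small inputs. The category priority (miRNA
first, then rRNA, YRNA, tRNA, mt-tRNA, piRNA, other, spike-in) prevents
mature miRNAs embedded in longer transcripts from being claimed by broader
classes; within the winning category, multi-parent ties split the read's
count equally (fractional counts are kept throughout and rounded only at
export). Class proportions are reported over annotated reads with the
spike-in excluded, since the spike-in is a technical control.

Count-matrix features are fragment identities, not just parents: miRNAs by
mature id, tsRNAs by parent × cleavage group (5', inner', 3'+3'CCA), rsRNAs
by parent × called-peak bin (`RNA18S#3` style, with a background bin), and
ysRNAs by gene × 5'/3'. Peak bins default to peaks called on the library's
own 18S/28S profiles; multi-sample runs should pass one shared peak set
(as `run_pipeline()` does via its first library).

## tsRNA subtype rule

On CCA-appended coordinates, with body length `L` and boundary tolerance
`delta = 3`: `s ≤ delta` → 5'; else `e ≥ L+1` → 3'CCA; else
`e ≥ L−delta+1` → 3'; else inner. The tolerance absorbs ragged cleavage
ends while keeping the inner class meaningful; it is configurable, and the
partition is exhaustive and mutually exclusive by construction (property
tested over random spans). 3' and 3'CCA are merged into one reported group
in composition tables, reflecting that the CCA tail is a maturation state
rather than a distinct cleavage site.

## Peak caller

`detect_peaks()` keeps maximal runs with depth at or above
`threshold_frac = 0.25` of the profile maximum, merges runs separated by
fewer than `merge_gap = 10` nt and drops runs narrower than
`min_width = 10` nt. There is no published detection rule to match, only
printed intervals; these defaults are the package's own and were set so
that the planted defaults yield exactly four 18S and three 28S peaks with
high interval overlap. The caller is invariant to positive rescaling of
depth and reports each peak's summit, mean height and share of parent
coverage.

## Cohort model

`simulate_cohort()` draws feature counts as Poisson around
`library_size × proportion × latent`, with a lognormal latent of variance
`log(1 + phi)`; marginally this matches a negative binomial with
`variance = μ + φμ²`, which the moment-based dispersion estimator recovers.
Defaults: φ = 0.1 (a biological CV of ~0.32, appropriate for deep,
well-controlled serum libraries), library sizes uniform in 0.8–1.2 million,
spike-in exactly 10,000 reads per library. AML samples multiply the
configured features' proportions by `2^log2FC` without renormalization, so
planted fold changes are exact in expectation.

Within-class base abundances follow a symmetric Dirichlet with
concentration 200, i.e. close to even. This is deliberately idealized: it
makes the class-level composition exactly interpretable and keeps
within-class abundance spread from dominating paired-compartment
correlations. Real libraries have heavy-tailed within-class abundances;
concordance estimates on real data therefore mix abundance structure with
subject-level agreement in a way the synthetic model intentionally avoids.

For paired designs, each subject's latent vector decomposes as
`z = sqrt(rho) · u_subject + sqrt(1 − rho) · e_sample` with
`rho = bms_shared_signal_fraction` (default 0.8). Blood/marrow correlation
of `log10(RPM+1)` then rises smoothly from ~0 at `rho = 0` to ~1 at
`rho = 1`, passing ~0.8 at the default — the regime reported for real
paired AML compartments. Correlations are evaluated within fragment class;
pooled across classes they are dominated by between-class abundance
differences, which both compartments share by construction.

## Differential expression

The DE stage is written in the package rather than delegated, so the
procedure is testable standalone:

* **Normalization** — weighted trimmed mean of M-values against a
  reference sample (the one whose upper quartile is closest to the mean),
  trimming 30% of M- and 5% of A-values. The weights are inverse
  asymptotic variances on the *proportion* scale
  (`(N−x)/x + (Nr−r)/r`), which are scale-free per library: rescaling all
  counts of one sample leaves every factor, and hence every p-value,
  exactly unchanged. Depth-dependent weight variants break that exact
  invariance while moving factors only marginally.
* **Dispersion** — per-feature moment estimates `(v − m)/m²` on
  counts scaled to a common size, combined across groups and summarized by
  the median of the positive values (0 if none). Simulation tests verify
  recovery at φ = 0 and φ = 0.4.
* **Exact test** — counts are scaled to the reference library's effective
  size, rounded, and summed per group; conditional on the total, the
  two-sided p sums the probabilities of all group-A outcomes no more
  probable than the observed one, with group sums NB (size `n_g/φ`). At
  φ = 0 with balanced groups this is exactly the two-sided
  Binomial(total, ½) test, checked exhaustively for totals ≤ 20. The
  conditional pmf is log-concave, so for large totals the computation
  windows around the mode (±60 SD) without approximating the p-value
  beyond machine precision. P-values are floored at the smallest positive
  double so they remain in (0, 1].
* **Calls** — significant means `p ≤ 0.05` and `|log2FC| ≥ 1`, with the
  fold change computed on mean RPM with pseudocount 1 (finite for
  zero-count groups) and AML over control by convention (label swaps
  negate it). No multiple-testing correction enters the call, matching the
  stated criterion; a Benjamini–Hochberg column is emitted for
  information. The mean-expression filter used downstream is interpreted
  as mean RPM > 10 (the unit of every other expression statement here).

## Marker selection and classification

A feature of a given class enters the panel if it (1) is DE-significant on
the discovery cohort, (2) has mean RPM > 10 across discovery samples, and
(3) achieves `p < 0.05` in a univariate logistic regression of group on
`log2(RPM+1)` (IRLS, ≤ 50 iterations, tolerance 1e-8, two-sided Wald
test). Complete separation — non-convergence, slope beyond ±20, or a
saturated fit with residual deviance ≈ 0 (the Albert–Anderson condition,
under which the MLE diverges even though IRLS may stop early with a finite
slope) — is flagged and treated as maximally significant: a perfectly
separating marker is the strongest possible candidate, and its Wald p is
an artifact of a divergent standard error. The univariate form is used
because the criterion acts as a per-feature filter.

A known property of this filter shapes the default simulation: markers of
*intermediate* strength can fall into the Hauck–Donner window
(quasi-separation inflates the Wald standard error, so p rises as the
effect grows), where a Wald filter loses power non-monotonically. The
default study therefore plants its six tsRNA markers deep in the
complete-separation regime (|log2FC| 3.0–3.4 at φ = 0.1, i.e. 8–10-fold
changes, as seen for top serum markers), where detection is reliable, and
its sixteen miRNA markers at a moderate |log2FC| = 1.25, producing the
qualitative contrast of interest: a compact, strong tsRNA panel versus a
broader, weaker miRNA panel.

The classifier is specified by contract — bootstrap-aggregated decision
trees, `floor(sqrt(p))` candidate features per split, per-sample OOB score
= fraction of OOB trees voting case, OOB error at threshold 0.5 — and
implemented with the `randomForest` package under a fixed seed. Selection
and training see only discovery data; validation samples must be disjoint
and their labels verifiably never influence the model (tested by mutating
them). The shuffled-label control keeps the selected panel but permutes the
training labels; because the planted panel makes the feature space strongly
two-clustered, a single permutation has a highly variable validation AUC,
so the null control is reported as an average over ten permutation seeds.
With no planted effects at all the selection correctly returns an empty
panel, and no classifier is trained (NA AUC with a warning).

## Problem sizes used by the tests

The packaged checks run at desk scale, chosen to keep every statistic
stable: composition, subtype, parent-share and peak recovery on one
100,000-read library (shares resolve to ±0.3 percentage points); the exact
test's null calibration on 5,000 NB features with 10 + 10 samples at
φ = 0.2; the classifier protocol on discovery 30 + 12 / validation 20 + 10
cohorts over a 205-feature panel; concordance on 20 paired subjects at
shared-signal fractions {0, 0.4, 0.8, 1}; oracle equivalence suites at
1,000 reads / 200 score sets / 20 logistic datasets.

## Known limitations

* Exact (or 1-mismatch) full-length matching only: no gapped or spliced
  alignment, no genome fallback — unmatched reads stay unannotated rather
  than being rescued.
* The uniform-base, k-mer-unique reference makes annotation unambiguous by
  construction; real references are not, and multi-mapping policy beyond
  equal tie-splitting is not modelled.
* The common-dispersion estimator is a moment estimator without shrinkage
  or tagwise variation; it is adequate for calibration at the simulated
  depths but is not a replacement for likelihood-based dispersion
  machinery on real data.
* The paired-compartment model shares a single latent fraction across all
  features; it does not model feature-specific compartment biology
  (e.g. marrow-restricted transcripts).
* No survival or clinical-risk modelling is included.
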