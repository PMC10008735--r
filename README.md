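# sncfrag

Profiling and biomarker analysis of circulating small non-coding RNA
(sncRNA) fragments.

Cell-free compartments such as blood serum and bone-marrow supernatant carry
a rich population of 15–45 nt RNA fragments. Most of them are not the
familiar miRNAs but fragments of longer parental RNAs: rRNA-derived small
RNAs (**rsRNA**, dominated by 28S and 18S fragments that pile up at a few
discrete positional peaks), YRNA-derived small RNAs (**ysRNA**, ~30 nt
5'-end fragments of RNY1/3/4/5, with RNY4 most abundant), and tRNA-derived
small RNAs (**tsRNA/tRF**, classified by cleavage position on the
CCA-appended mature tRNA as 5', inner', 3' or 3'CCA fragments). These
fragment classes shift in acute myeloid leukaemia (AML) and are candidate
liquid-biopsy markers; compact tsRNA panels can separate AML cases from
controls at least as well as larger miRNA panels, and paired blood/marrow
profiles are strongly correlated.

`sncfrag` implements the full analysis as a tested, reusable R pipeline:

* **Hierarchical annotation** — reads are collapsed, then matched ungapped
  and full-length against a curated parental-RNA reference via a 15-mer
  index, and assigned to the *first* matching category in the priority
  order miRNA → rRNA → YRNA → tRNA → mt-tRNA → piRNA → other ncRNA →
  spike-in. Ties within a category split counts equally; reads inside the
  45S pre-rRNA nesting are attributed to the most specific mature subunit.
* **Fragment characterization** — tsRNA cleavage subtypes (a span `[s, e]`
  on a tRNA of body length `L` is 5' if `s ≤ 3`, 3'CCA if `e ≥ L+1`, 3' if
  `e ≥ L−2`, else inner), positional coverage profiles, and a peak caller
  (runs above 25% of maximum depth, merged across gaps < 10 nt, minimum
  width 10 nt).
* **Differential expression** — trimmed-mean (TMM-style) normalization, a
  moment estimate of the common negative-binomial dispersion φ
  (`variance = μ + φμ²`), and a conditional exact test on group sums that
  reduces to the two-sided Binomial(total, ½) test in the Poisson limit.
  Features are called at `p ≤ 0.05` and `|log2FC| ≥ 1`.
* **Marker panels** — three-criterion selection (significant DE, mean
  expression > 10 RPM, univariate logistic Wald `p < 0.05` with complete
  separation flagged), bagged-tree classification with out-of-bag error,
  and ROC/AUC (`AUC = P(score_case > score_control) + ½P(tie)`) on disjoint
  discovery and validation cohorts.
* **Compartment concordance** — pooled and per-subject Pearson correlation
  of paired blood/marrow `log10(RPM+1)` profiles, per fragment class.
* **Synthetic ground truth** — a k-mer-unique synthetic reference and a
  generative fragment/cohort model whose defaults encode the serum
  composition above, so every stage is testable by parameter recovery.

## Worked example

```r
library(sncfrag)
library(dplyr)

ref   <- build_default_reference(seed = 1)
frags <- sample_fragments(ref, n = 50000, seed = 42)   # healthy-serum mixture
lib   <- annotate_library(frags$sequence, ref)

compute_class_proportions(lib)
#> # A tibble: 6 × 3
#>   class       count proportion
#> 1 rsRNA       31358     0.627
#> 2 ysRNA        7394     0.148
#> 3 other_ncRNA  3792     0.0758
#> 4 piRNA        3689     0.0738
#> 5 tsRNA        2140     0.0428
#> 6 miRNA        1627     0.0325
```

rsRNA dominates (~63% of annotated reads), followed by ysRNA (~15%), with
tsRNA slightly ahead of miRNA — the serum fingerprint the generator encodes.
The 18S coverage profile shows four discrete peaks at the expected loci:

```r
prof <- coverage_profile(lib$annotations, "RNA18S", build_kmer_index(ref))
detect_peaks(prof)
#>    peak start   end summit mean_height share
#> 1     1   674   692    689        754. 0.191
#> 2     2   897   919    903        706. 0.217
#> 3     3  1194  1223   1208        621. 0.249
#> 4     4  1838  1862   1846        677. 0.226
```

A simulated AML case-control study, end to end:

```r
study <- default_aml_study(ref, seed = 42)    # discovery 30+12, validation 20+10
de <- run_de(study$discovery$counts, study$discovery$samples,
             feature_meta = select(study$discovery$features, feature_id, class))
glance(de)
#>   n_features n_significant  n_up n_down frac_up frac_down
#> 1        205            20    12      8  0.0585    0.0390

rep <- evaluate_panels(study$discovery, study$validation, de = de, seed = 42)
glance(rep)
#>   class panel_size oob_error auc_discovery auc_validation
#> 1 tsRNA          6         0             1              1
#> 2 miRNA         11        0             1              1
```

The selected tsRNA panel is exactly the six planted markers — smaller than
the miRNA panel with equal validation AUC. Paired blood/marrow profiles at
the default shared-signal fraction (0.8) correlate class-wise around 0.8:

```r
paired <- simulate_cohort(default_cohort(n_control = 4, n_aml = 16,
                                         paired_bms = TRUE, seed = 7), ref)
concordance_by_class(paired, c("miRNA", "tsRNA", "ysRNA", "rsRNA"))
#>   class     r mean_subject_r n_features n_subjects
#> 1 miRNA 0.805          0.800         50         20
#> 2 tsRNA 0.781          0.784         40         20
#> 3 ysRNA 0.825          0.820         20         20
#> 4 rsRNA 0.810          0.810         60         20
```

`run_pipeline()` chains all stages from a YAML configuration (see
`inst/extdata/demo_config.yaml`; a CLI wrapper lives in
`inst/cli/sncfrag.R`), writing TSV/BED/JSON outputs with provenance
headers; identical configurations reproduce identical files.

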