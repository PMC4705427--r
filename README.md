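# peaksig

Integrative analysis of inducible transcription-factor ChIP-Seq and
expression data, for regulatory genomicists studying systems in which a
factor's activity can be switched on (hormone-inducible fusions such as
PuER in myeloid leukaemia models). From two-condition peak calls, read
pileups and expression arrays, the package derives which binding events
are *functional*, which genes they drive, and whether the resulting
gene signature stratifies independent expression datasets such as an
AML patient cohort.

## The method

For each merged region \(r\) (union of the two conditions' peaks,
merged at ≥ 1 bp overlap), coverage scores are normalised read counts

\[ s_r = n_r \cdot \frac{10^6}{N} \cdot \frac{10^3}{L_r} \]

(reads per kb per million mapped reads; H3K27ac over fixed 800 bp
midpoint windows), and condition fold changes are pseudocounted ratios
\((s_r^{+}+1)/(s_r^{-}+1)\). Regions are classified:

* **Group I** — factor fold change ≥ 4 **and** H3K27ac fold change ≥ 4
  **and** induced H3K27ac raw count ≥ 50 (functional induced binding);
* **Group II** — factor fold change ≥ 4, remaining (binding without
  chromatin response);
* **Group III** — factor fold change within a symmetric 2-fold band
  (unchanged binding); everything else stays unclassified.

Regions map to genes by promoter → intragenic → intergenic cascade
(both flanking genes within 50 kb). The **target-gene signature** is
the intersection of Group I-linked genes with genes significantly
up-regulated on the array (quantile normalisation, equal-variance
t-test, BH-adjusted p ≤ 0.05, fold change > 1.2). Expression datasets
are stratified by average-linkage clustering on 1 − Pearson correlation
over the signature genes, with gene-resampling bootstrap node support,
and clusters are summarised by marker expression and label composition
(karyotype, FAB, cell type). A synthetic-data module generates
annotation, peaks, reads and expression matrices with planted,
recorded ground truth; the methods vignette
(`vignettes/peak-groups-and-signatures.Rmd`) documents every modelling
choice.

## Worked example

```r
library(peaksig)
res <- run_pipeline(default_config(seed = 1), outdir = "results/run")
```

The run narrates each stage; with the packaged study conditions
(300 planted regions, 8-fold induction, triplicate arrays) it prints:

```
group sizes: I=100, II=140, III=60, unclassified=0
mean fold increase 6.67; TF~histone r = 0.346 (p = 7.1e-10, n = 300)
25 significant probes of 300 (25 planted)
  group  n mean_fold_change
1     I 24         2.096470
2   III  1         0.713434
Target gene set: 23 genes ( 86 group genes ∩ 23 up-regulated )
```

meaning: every planted region is recovered into its true group; factor
and H3K27ac fold changes are positively coupled; genes linked to
Group I regions respond strongly to induction (mean 2.1-fold) while
genes of the unchanged groups do not; and 23 of the up-regulated genes
are high-confidence targets. Clustering a labelled synthetic cohort by
that signature recovers the planted sample partition exactly and
concentrates the planted translocation label in the low-marker
cluster:

```
t_15_17 in lowest-marker cluster 1: 13/15 (86.7%)
```

The numbered scripts under `analysis/` run the same workflow
stage-by-stage from the serialised fixtures (simulate → merge/score →
classify → assign → expression/targets → co-binding → cohort
clustering), writing every table under `results/`.

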