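# clonocomp

Pairwise statistical comparison of immune-repertoire clonotype sets.

Adaptive immune repertoires — immunoglobulin (IG) and T cell receptor
(TR) rearrangements sequenced at depth — are summarized as tables of
amino-acid clonotypes: unique V-(D)-J rearrangements with a unique CDR3
junction, each with the number of sequences assigned to it. Given two
such tables (two cell subsets, two time points, vaccine versus
baseline), `clonocomp` answers the question *which V, D and J genes —
and which of their alleles — are used significantly differently*, and
provides the comparative CDR and gene-association views that give those
differences context. It is aimed at immunogenetics and AIRR-seq
analysts working from annotated clonotype tables, not raw reads.

## The statistic at its core

For gene $k$ with counts $x_{1k}$ of $n_1$ (set 1) and $x_{2k}$ of
$n_2$ (set 2), the difference in usage proportions
$p_{1k} - p_{2k}$ is tested with the pooled two-proportion z-score

$$z_k = \frac{p_{1k}-p_{2k}}{\sqrt{\hat p_k(1-\hat p_k)(1/n_1+1/n_2)}},
\qquad \hat p_k=\frac{x_{1k}+x_{2k}}{n_1+n_2},$$

falling back to Fisher's exact test whenever any expected cell count
drops below 5. Raw p-values are adjusted seven ways in parallel
(Bonferroni, Holm, Hochberg, Šidák SS/SD, Benjamini-Hochberg,
Benjamini-Yekutieli) over the joint V+D+J family, and alleles of genes
validated by all seven procedures are tested in a follow-up family.
Around this sit CDR length distributions, per-position amino-acid and
amino-acid-class profiles under the IMGT unique numbering (Shannon,
Wu-Kabat and Simpson variability), V-J/V-D/D-J association tables with
double Ward clustering, per-10,000 normalization and locus-ordered
synthesis tables, and a synthetic-repertoire generator used for
calibration and power benchmarking.

## Worked example

Simulate a pair of clonotype tables with two genes genuinely shifted,
then run the comparison:

```r
library(clonocomp)

cfg  <- sim_config(n1 = 8000, n2 = 6000,
                   effects = c("IGHV4-34" = -0.012, "IGHV1-8" = 0.015),
                   seed = 42)
pair <- generate_pair(cfg)
s1 <- filter_cdr3_range(pair$set1, label = "set1")
s2 <- filter_cdr3_range(pair$set2, label = "set2")
s1
#> <repertoire_set> set1
#>   CDR3 length range: 4-45 AA
#>   clonotypes (diversity): 8000
#>   assigned sequences (expression): 10674
#>   length outliers excluded: 0

rows <- run_comparison(count_family(s1, s2, level = "gene"))
nrow(rows)
#> [1] 72
rows[order(rows$rawp)[1:3],
     c("item", "x1", "x2", "diff", "z", "rawp", "adj_BH", "interpretation")]
#>      item  x1  x2     diff     z     rawp   adj_BH                                      interpretation
#>   IGHV1-8  36 133 -0.01767 -9.47 2.73e-21 1.97e-19 rawp;bonferroni;holm;hochberg;sidakSS;sidakSD;BH;BY
#>  IGHV4-34 152  31  0.01383  7.13 9.93e-13 3.57e-11 rawp;bonferroni;holm;hochberg;sidakSS;sidakSD;BH;BY
#>  IGHD5-18 100 103 -0.00467 -2.29 2.23e-02 4.28e-01                                                rawp
```

72 hypotheses were tested (41 V + 25 D + 6 J genes). The two injected
genes are recovered with every procedure agreeing (their
`interpretation` lists all seven), while the best null gene reaches
only an unadjusted `rawp` — exactly the false-positive behaviour the
adjustment exists to absorb. The allele follow-up then tests only
alleles of the all-procedure-validated genes:

```r
al <- allele_followup(rows, s1, s2)
unique(sub("\\*.*", "", al$item))
#> [1] "IGHV1-8"  "IGHV4-34"
```

The same pipeline runs from the shell via the installed `exec/clonocomp`
script (`simulate`, `compare`, `cdr-lengths`, `aa-properties`,
`associations` subcommands), writing the results tables, rejection
curves, scatter tables, synthesis tables, plots and a JSON run
manifest; identical configurations produce byte-identical outputs.

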