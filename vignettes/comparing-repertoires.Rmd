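---
title: "Comparing clonotype repertoires: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing clonotype repertoires: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonocomp)
```

## The problem

High-throughput sequencing of immunoglobulin (IG) and T cell receptor
(TR) rearrangements yields, after annotation, a table of amino-acid
clonotypes: unique V-(D)-J rearrangements with a unique CDR3 junction
sequence, each carrying the number of sequencing reads unambiguously
assigned to it. Two such tables — say, two cell subsets, two time
points, or patient versus control — differ in **diversity** (how many
distinct clonotypes use each V, D or J gene) and **expression** (how
many sequences those clonotypes account for). `clonocomp` quantifies
those differences gene by gene and allele by allele, with explicit
multiple-testing control, and adds comparative CDR-length,
amino-acid-property and V-D-J-association views of the same data.

## The statistical procedure

For a gene $k$, let $x_{1k}$ of the $n_1$ clonotypes of set 1 and
$x_{2k}$ of the $n_2$ clonotypes of set 2 carry $k$ (or, in expression
mode, the analogous sequence counts). The null hypothesis is equality
of the usage proportions $p_{1k} = x_{1k}/n_1$ and $p_{2k} = x_{2k}/n_2$.

**Test statistic.** The pooled (score-form) two-proportion z-statistic

$$z_k = \frac{p_{1k} - p_{2k}}
{\sqrt{\hat p_k (1 - \hat p_k)\left(\tfrac1{n_1} + \tfrac1{n_2}\right)}},
\qquad \hat p_k = \frac{x_{1k} + x_{2k}}{n_1 + n_2},$$

with a two-sided normal p-value. The confidence interval for the
difference uses the unpooled Wald standard error
$\sqrt{p_{1k}(1-p_{1k})/n_1 + p_{2k}(1-p_{2k})/n_2}$ — the standard
pairing of a pooled test with an unpooled interval. With the exact
formula variant of the underlying procedure not fully reprinted
anywhere accessible, borderline items could shift slightly under an
unpooled-test variant; the pooled score form was chosen as the
textbook default and is what the calibration benchmarks validate.

**Small occurrences.** The normal approximation needs the four
expected cells $n_1 p_{1k}$, $n_1(1-p_{1k})$, $n_2 p_{2k}$,
$n_2(1-p_{2k})$ — equivalently $x_{1k}$, $n_1 - x_{1k}$, $x_{2k}$,
$n_2 - x_{2k}$ — to be at least 5. When **any** of the four falls
below 5, `small_count_guard()` routes the item to Fisher's exact test
(two-sided by the probability-mass rule) and no z-score is reported.
The "any" reading, rather than "all four", is the classical validity
rule; an all-four rule would almost never trigger for genuinely rare
genes, defeating the purpose of a small-occurrence list.

**Multiple testing.** All items of one level form a single family
spanning the V, D and J gene types jointly (a typical deep IGH
comparison tests 72 gene hypotheses: 41 V + 25 D + 6 J). Seven
adjustments are always computed side by side — Bonferroni, Holm,
Hochberg, Šidák single-step and step-down, Benjamini-Hochberg and
Benjamini-Yekutieli — deliberately without electing one: conservative
familywise procedures suit confirmatory settings, the FDR procedures
exploratory ones, and showing all seven lets the analyst make that
call. `rejection_curves()` tabulates rejected hypotheses over an
$\alpha$ grid (default 0.001 to 0.25 in steps of 0.001) and
`scatter_table()` gives the volcano-style $-\log_{10} p$ versus $z$
view; a $p$ of exactly zero is capped at the smallest positive double
rather than mapped to infinity.

**Allele follow-up.** Alleles are only informative where their gene
moved: by default `allele_followup()` tests alleles of genes validated
by **all seven** procedures, with the allele family size set to the
number of such alleles across gene types; `all_alleles = TRUE`
overrides this, since the restriction is a design default, not a
statistical necessity. Calls carrying a gene but no allele never
invent an allele: they accumulate in a "(no allele)" remainder, so
single plus remainder counts always reconcile with the set totals.
The same conservation bookkeeping places ambiguous multi-gene
("several") calls in an explicit bucket; they remain part of the
$n_1, n_2$ totals — they are clonotypes of the set even if their gene
identity is ambiguous.

## CDR analyses

CDR3 length outliers (outside 4-45 AA by default, bounds inclusive)
are excluded from every statistic but retained for reporting.
Positions within a CDR3 of length $L$ follow the IMGT unique
numbering: base positions 105-117, shorter loops losing positions
symmetrically at the loop top between 111 and 112 (right side first),
longer loops gaining insertion labels there (112.1 first, then 111.1,
112.2, ...). `imgt_cdr3_positions(L)` returns exactly $L$ labels for
any $L$; CDR1 (27-38) and CDR2 (56-65) use the same symmetric rule
within their fixed germline spans, and lengths beyond those spans are
an error rather than an extrapolation.

Per-position variability of amino acids, or of amino-acid classes, is
summarized three ways: Shannon entropy in bits
($H = -\sum_i p_i \log_2 p_i$; above 2 bits conventionally variable,
below 1 highly conserved — thresholds that only make sense on the
$\log_2$ scale, which is why bits are used), the Wu-Kabat coefficient
$k\,N/n_{\max}$, and the Simpson index $1 - \sum_i p_i^2$. The class
schemes (hydropathy, volume, chemical, charge, hydrogen
donor/acceptor, polarity) ship as an editable TSV
(`extdata/aa_classes.tsv`), so a membership can be corrected against
the published IMGT classification without touching code. The combined
"physicochemical" scheme is implemented as the identity over the 20
residues: the authoritative combined table was not available for
transcription, and an identity scheme is transparent rather than
wrong. Profiles default to diversity weighting (one count per
clonotype) with an expression flag, keeping the profile insensitive
to a single highly expanded clone unless expansion is the question.

## Gene associations

`association_matrix()` cross-tabulates single-by-single gene calls of
two types (V-J, V-D, D-J); ambiguous calls are excluded and counted,
so the cell total always reconciles. `ward_cluster()` applies Ward's
minimum-variance criterion on Euclidean distances — the
squared-updating variant (`hclust` method `"ward.D2"`), which is the
variant consistent with feeding unsquared Euclidean distances — to
rows and columns independently. Merge heights are therefore
non-decreasing and tie-breaks follow the input order deterministically;
clustering operates on raw counts by default (normalized per 10,000 on
request, no row scaling), since the display is about occurrence
structure, not profile shape. Heatmaps default to diversity counts,
with expression as a flag.

## The synthetic generator

`sim_config()`/`generate_pair()` define the study conditions the test
suite and the acceptance script run under, emulating a deep human IGH
comparison:

* panels of 41 V, 25 D and 6 J genes (matching the family sizes a
  real IGH comparison tests), with long-tailed baseline usage spanning
  roughly a 20-fold range plus two rare V genes whose expected counts
  sit below the small-occurrence guard, so the Fisher path is always
  exercised;
* set sizes defaulting to 27,730 and 17,302 clonotypes — the scale of
  a deep memory-B-cell comparison;
* CDR3 lengths from a shifted Poisson (mean 11 over a support of
  4-45), peaking at 14-15 AA as deep IGH repertoires do;
* clonotype expression dominated by single-copy clonotypes (75%),
  with a geometric tail giving a mean near 1.33 sequences per
  clonotype, matching the expression/diversity ratio of such data;
* a 2% fraction of ambiguous two-gene V calls, and optional CDR3
  length outliers to exercise the filter;
* injected effects as absolute usage shifts in set 2, with the
  remaining genes rescaled so probabilities still sum to one.

What the generator deliberately does **not** model: real junction
sequence composition (CDR3 residues are uniform random letters),
biological V(D)J pairing preferences (gene draws are independent, so
association heatmaps of synthetic data show noise), somatic
hypermutation, and sequencing error. Green tests therefore demonstrate
the statistical machinery — calibration, recovery, conservation,
determinism — not biological realism of the inputs.

## Numerical choices and problem sizes

* Type-I calibration is checked by Monte Carlo: 500 null replicates at
  10,000 clonotypes per set, comparing the raw z-test rejection rate
  to a three-binomial-SD band around $\alpha = 0.05$. The band applies
  to the z-tested items; items on the exact-test path are discrete and
  conservative by construction, so they are checked one-sidedly
  (rate $\le \alpha$). Familywise-error estimates are compared to
  $\alpha$ allowing three Monte-Carlo standard errors.
* Recovery benchmarks inject shifts of at least four pooled standard
  errors at 20,000 clonotypes per set and require all-procedure
  recovery of every shifted gene.
* Oracle checks run the seven adjustments against reference
  implementations on 1,000 random p-vectors, Fisher's two-sided
  p-value against exhaustive table enumeration for all margins up to
  12, and Ward merges against a brute-force agglomerative oracle on
  up to 6 items.
* Reports round proportions and p-values to 6 significant digits;
  counts stay exact. The run manifest records configuration, package
  version and key counts — and nothing volatile — so identical
  configurations produce byte-identical output files.

## Limitations

* The two sets are treated as independent, and items within a family
  as independent tests; paired or longitudinal designs need different
  machinery.
* The canonical input dialect is this package's own definition;
  genuine annotation exports are adapted via the column map rather
  than auto-detected.
* The bundled IGH locus ordering is approximate and editable; D and J
  display order in particular should be checked against the reference
  gene database for publication-grade figures.
* Allele-level conclusions inherit the annotator's allele calls;
  poorly supported allele assignments upstream propagate here.
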