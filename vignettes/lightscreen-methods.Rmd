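---
title: "Methods: robust domain-abundance screening of light ecotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust domain-abundance screening of light ecotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lightscreen)
```

## The scientific problem

*Prochlorococcus marinus*, the smallest and most abundant marine
phototroph, splits into high-light (HL) ecotypes of the upper photic zone
and low-light (LL) ecotypes adapted to depth. Which protein-domain content
separates the two? `lightscreen` works at the level of Pfam protein-domain
families detected by profile-HMM search in predicted proteomes: the unit of
analysis is not the gene but the domain family, which is robust to the
gene gain/loss and phage-mediated acquisition that dominate this genus.

The pipeline moves through seven stages, each usable on its own:

1. parse HMMER3 per-domain tables (`parse_domtblout`, `filter_hits`),
2. build a genomes x domains sum-bit-score matrix (`build_matrix`,
   `normalize_matrix`),
3. screen every family for HL/LL differences with outlier- and
   FDR-corrected robust tests (`response_screen`),
4. order genomes and families by bi-clustering and PLS
   (`hierarchical_cluster`, `bicluster`, `pls_ordination`),
5. classify ecotype membership with a boosted TanH network (`ann_fit`),
6. count endogenous viral-element (VFam) signatures co-occurring with the
   classifier's domains (`codomain_counts`, `group_difference`), and
7. run domain-centric GO enrichment (`enrich_pfam_go`) and design Gateway
   attL ORFeome constructs (`orf_design`).

A synthetic-data module generates every input with known ground truth, so
the whole pipeline is testable without genome downloads.

## The abundance matrix and its normalization

A cell of the matrix is the sum of HMM bit scores of one domain family in
one genome, after discarding hits with full-sequence E-value above 1e-9
(the strict threshold used for both Pfam and VFam calls; the filter applies
to HMMER's full-sequence E-value, matching the semantics of the `-E` flag
the searches are run with). Summed bit scores behave as a copy-number
proxy weighted by match quality.

Raw sums confound domain content with genome size and annotation depth, so
the default normalization is a per-genome rate: each row is divided by its
total and rescaled to 1000. Per-feature z-scoring was considered and
rejected as the default because it erases the non-negative,
abundance-like character of the data that the fold-change interpretation
relies on; the raw-sum matrix remains available (`normalization`
attribute records which one you have).

## The response screen

For each domain family the HL and LL groups are compared with a construction
that protects against both outliers and multiplicity:

* **Outlier correction.** Each group is Huber M-reweighted:
  `w_i = min(1, k s / |x_i - mu|)` with `k = 1.345` (95% Gaussian
  efficiency; the method prescribes no constant, so the conventional one is
  used) and the MAD as the fixed scale `s`. The test statistics are computed
  on the pseudo-observations `mu + w_i (x_i - mu)`, which pull gross
  outliers toward the robust location and leave clean data untouched.
* **Welch t tests** throughout, because the groups are unbalanced (25 HL vs
  15 LL) and variances need not match.
* **Practical difference.** The robust spread is estimated as
  `sigma_hat = IQR / 1.3489795` (the standard-normal IQR; type-7
  linear-interpolation quantiles — the quantile rule is a free choice and
  is recorded here). The practical-difference threshold is
  `6 * 0.10 * sigma_hat`: 10% of a six-sigma spread. A one-sided t test
  asks whether |mean difference| exceeds this threshold.
* **Practical equivalence (TOST).** Two one-sided t tests against the
  nulls "difference >= +threshold" and "difference <= -threshold"; the
  equivalence p-value is the larger of the two, so equivalence requires
  rejecting both.
* **Call trichotomy.** At `alpha = 0.05`: `practical_difference` if the
  practical-difference test rejects, else `practical_equivalence` if the
  TOST rejects, else `inconclusive`. The three calls are exclusive and
  exhaustive.
* **FDR.** Raw two-sided p-values are Benjamini-Hochberg adjusted across
  the batch of families; rankings and top-k selections use the adjusted
  values, with ties broken by |mean difference| (descending) then
  accession, for reproducibility.

Note an asymmetry users should expect: at n = 25 vs 15 the screen has high
power to *detect* three-fold effects but limited power to *certify
equivalence*, because the TOST margin `0.6 sigma_hat` is only about 1.5
standard errors wide at these group sizes. Identically distributed groups
are therefore mostly called `inconclusive` at this n, and reliably called
equivalent only for larger panels. This is a property of the design, not a
defect of the implementation.

## Bi-clustering and PLS ordination

Both Pearson-correlation distance (`1 - r`) and Euclidean distance are
available for the hierarchical bi-clustering, with average linkage, because
the two metrics answer slightly different questions (profile shape vs
absolute abundance) and both are legitimate on this matrix; `pearson` is
the default and the choice is an explicit argument, not a hidden constant.
Constant profiles, which have no defined correlation, sit at the neutral
distance 1 with a warning.

The ordination is a two-component PLS of the centered matrix against the
binary ecotype label, computed by SVD of the cross-covariance with
deflation. PLS is preferred over PCA here because the contrast of interest
is known: the first component is the domain-content direction that best
covaries with the HL/LL label, and separation of the score clusters is the
visual summary of how much ecotype signal the matrix carries. Constant
feature columns are dropped with a warning.

## The boosted TanH classifier

The classifier is a boosted additive ensemble of four single-hidden-layer
networks with three TanH nodes each, trained on the top-20 screened
families with a randomly selected, label-stratified 20% holdout removed
before any training computation (per-class counts round up; 25 + 15
genomes give a 5 + 3 holdout). Covariates are z-standardized with
training-set statistics.

Each stage is a penalized maximum-likelihood logistic fit: given the
running ensemble logit as offset, stage parameters minimize the logistic
negative log-likelihood of `offset + learning_rate * g(x)` plus an L2
("squared") penalty `lambda * ||theta||^2` on the stage weights, and the
shrunk contribution `learning_rate * g(x)` is added to the ensemble. The
learning rate thus lives inside the stage objective; fitting stages to
loss-gradient residuals by least squares and shrinking afterwards was
tried and discarded, because four stages at rate 0.1 then cap the ensemble
logit near 0.4 and the fit can never become confident — incompatible with
the near-unit entropy R-squared this architecture demonstrably reaches on
separable domain profiles. `penalty_lambda = 1e-3` was fixed once from a
small grid on synthetic data; `n_models = 1` recovers a single unboosted
network.

Stage optimization is full-batch BFGS with analytic gradients from random
normal initial weights (sd 0.5), deterministic per seed; a stage whose
final penalized loss exceeds its initial loss aborts with diagnostics.
Reported fit metrics are the misclassification rate (0.5 probability
threshold) and the entropy R-squared, one minus the ratio of model to
null binomial deviance.

**Variable importance** is variance-based: features are resampled
independently from their empirical marginals (pick-freeze design), the
first-order (main-effect) index uses the Saltelli/Janon estimator and the
total index uses Jansen's, both on the predicted HL probability. Negative
estimates, which can only arise from Monte-Carlo noise, are clamped to
zero. Dependent-input variants are out of scope. **Marginal profiles** are
partial-dependence curves over the observed range of one feature.

## VFam co-domain statistics

VFam profile HMMs (built from clustered viral RefSeq proteins) flag
endogenous viral elements. Hits are called at the same strict 1e-9
E-value, deduplicated on genome + ORF + model + coordinates, and
intersected with the classifier's Pfam set at the ORF level. Per genome
the pipeline counts VFam-bearing ORFs, co-domain ORFs (VFam and
discriminant Pfam on the same ORF), and VFam hits on co-domain ORFs; the
last is the default field for the group test, with the others selectable,
since "VFams per genome" could reasonably mean hits or ORFs. The group
difference is a Welch two-tailed t test reported as LL minus HL.

## GO enrichment and ORF design

Enrichment is the dcGO-style pairing of a one-sided hypergeometric
upper-tail p-value with its normal-approximation Z-score, per GO term
reachable from the background (by default all families observed in the
matrix) through a pfam2go mapping, BH-adjusted across terms. No GO-graph
propagation is attempted.

Construct design treats each cDNA as a frame-0 CDS: a terminal in-frame
stop codon (TAA/TAG/TGA) is removed — internal stops and non-multiple-of-3
lengths are warned about but never edited — and the insert is flanked with
the attL1/attL2 Gateway recombination sites (emitted lowercase; the
insert's case is preserved; all comparisons are case-insensitive). The
Uni9 universal primers anneal in the vector outside the attL sites, so
they match no bare construct — `find_primer` reports exact matches on both
strands for any primer/sequence pair. Plate maps fill row-major in input
order. Codon optimization for synthesis is vendor-specific and excluded.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, at
the study's group sizes:

* **Matrix**: 25 HL + 15 LL genomes, 200 families. Cells are log-normal
  (`sdlog = 0.5`, baseline `meanlog = log(50)`) — non-negative and
  right-skewed, the shape of summed bit scores; 20 families carry planted
  fold-changes of 2-10x, among them the four effect sizes reported for the
  real panel: PF00288 5x LL-higher, PF02421 2x LL-higher, PF16881 10x
  HL-higher, PF06182 3x HL-higher. 200 families (rather than the real
  panel's ~1200) keeps full-pipeline test runs fast while preserving the
  informative-to-null ratio that matters for FDR behavior.
* **domtblout decomposition**: each nonzero cell is split into hit rows
  whose printed one-decimal bit scores sum exactly to the cell, with
  E-values drawn below 1e-10, so parse-and-rebuild round-trips the matrix
  at writer precision.
* **VFam overlay**: Poisson co-domain hit counts with HL mean 10.8 and a
  planted LL - HL difference of 12, giving a panel-wide expectation of
  15.3 co-domain VFams per genome, plus Poisson background hits on
  non-discriminant ORFs.
* **cDNAs**: ATG + random sense codons + one stop, lengths log-normal with
  mean 767 bp and `sdlog = 0.6`, which puts ~92% of sequences under
  1.5 kb.

Everything is deterministic per seed, and the truth records score every
downstream stage. What the generator does *not* emulate: phylogenetic
correlation among genomes (cells are independent given the group),
correlated domain families, realistic HMM score distributions, or
annotation-depth artifacts. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to every pathology of real comparative-genomics data.

## Numerical choices and degenerate inputs

* Huber IRLS converges when successive locations differ by < 1e-8 (100
  iteration cap, error on failure); a fully degenerate spread returns the
  median with unit weights.
* Zero-variance groups: the TOST returns 0 when the observed difference
  lies strictly inside the margin and 1 otherwise; the Welch t degenerates
  to p = 1 at equal means, 0 otherwise; the co-domain group test reports
  t = 0, p = 1 on exact ties.
* All-zero matrix rows pass through normalization unchanged (no 0/0).
* Dendrogram tie-breaks follow `stats::hclust`'s deterministic merge
  order; screen rank ties break by effect size then accession.

## Worked example

```{r example, eval = FALSE}
sc  <- simulation_scenario(seed = 7)
gm  <- generate_matrix(sc)
m   <- normalize_matrix(gm$matrix)
scr <- response_screen(m)
summary(scr)

feat <- unclass(m)[, top_features(scr, 20)$model_acc]
fit  <- ann_fit(feat, matrix_labels(m), ann_config(seed = 17))
print(fit)
head(variable_importance(fit, feat, n_mc = 2000, seed = 1))
```

At these defaults the screen recovers the planted families at the top of
the FDR ranking and the classifier reaches zero holdout misclassification
with entropy R-squared above 0.99 — the qualitative behavior expected when
ecotype-diagnostic domain content is as separable as it is in this genus.

## Known limitations

* The screen's robust t construction (pseudo-observation Welch t) is one
  reasonable implementation of "outlier-corrected batch t tests"; other
  software makes different internal choices, so agreement is expected at
  the level of calls and rankings, not digits.
* Equivalence calls are underpowered at small n (see above).
* GO enrichment ignores the GO graph; parent terms are tested only if
  directly mapped.
* The PLS ordination is descriptive; no component-count selection or
  cross-validated Q2 is computed.
* Per-strain pairwise screening (all genome pairs rather than HL vs LL) is
  not implemented.
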