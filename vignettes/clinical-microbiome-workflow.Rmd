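---
title: "Downstream analysis of clinical microbiome cohorts with clinmicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Downstream analysis of clinical microbiome cohorts with clinmicro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In retrospective clinical 16S studies, the microbial data arrive as relative
abundance tables at up to six taxonomic ranks (phylum through species), and
the clinical side arrives as a wide, partially missing table of mixed
continuous and categorical variables — age, BMI, disease status, dietary
frequencies, medication history. Three recurring obstacles stand between
these tables and a defensible analysis: the grouping of subjects is often
not given a priori (dietary pattern, for instance, confounds disease
contrasts unless subjects are stratified by it); low-abundance,
low-prevalence taxa inflate false discoveries in classification and network
models; and every step needs to stay reproducible when the sample set is
revised. `clinmicro` packages this downstream workflow: align the abundance
table to a mapping file so only the mapping ever needs editing, summarize
and regroup the clinical table, filter to core taxa, and run diversity,
network, biomarker and correlation analyses per group with a single seeded
configuration.

# Subject regrouping by a cluster-validity vote

Subjects are clustered on a chosen block of continuous clinical features
(z-scored, so items on different scales weigh equally) with k-means
(k-means++ initialization, 25 restarts, best within-cluster sum of squares
kept), PAM, or Ward linkage; Gower dissimilarity is available for mixed
feature blocks. The number of clusters is not chosen by one index but by a
majority vote over a battery of cluster-validity indices evaluated at every
candidate k:

* arg-max indices: Calinski–Harabasz, mean silhouette width, Dunn,
  point-biserial (the correlation between the pairwise-distance vector and
  the different-cluster indicator), Ratkowsky–Lance;
* arg-min indices: Davies–Bouldin, C-index, McClain–Rao, Xie–Beni;
* sequence indices, which compare the within-cluster sum of squares
  \(W_k\) at neighboring k: Ball–Hall (\(W_k/k\), nominated at the largest
  drop between successive k), Hartigan
  (\(H(k) = (W_k/W_{k+1} - 1)(n-k-1)\), nominated at the smallest k with
  \(H(k) \le 10\), abstaining when no k qualifies), and Krzanowski–Lai
  (\(KL(k) = |DIFF_k| / |DIFF_{k+1}|\) with
  \(DIFF_k = (k-1)^{2/p} W_{k-1} - k^{2/p} W_k\), nominated at the
  arg-max).

Each index nominates one k (or abstains when it is undefined, e.g. distance
ratios on all-singleton clusterings); the winner is the modal nomination
with ties broken toward the smallest k — parsimony is the only defensible
deterministic tie-break. The index set is configurable; twelve indices is
enough for the majority to be robust to any single index's pathologies
(several indices are biased toward large k on well-separated data, which
the vote absorbs). Subjects with a missing value in any clustering feature
are excluded from the vote and reported rather than imputed; this keeps the
clustering honest about the data it saw and matches the exclusion-first
style of clinical workflows. The chosen clustering is then crossed with the
clinical status into composite labels (`Cases_1`, `Control_2`, ...), which
drive every downstream per-group analysis through the mapping file alone.

# Core-taxon filtering

A taxon qualifies in a group when its group-mean relative abundance (zeros
included) is at least `min_abund` and its prevalence (fraction of the
group's samples where it is non-zero) is at least `min_prev`; defaults are
0.001 and 0.7, the common 1-per-mille / 70% decontamination rule. The
phrase "qualifies in a group" admits two readings, and both are exposed:
`mode = "any"` (default) retains a taxon that qualifies in at least one
group — the permissive reading that keeps group-specific organisms —
while `mode = "all"` demands qualification everywhere. Both comparisons are
inclusive (`>=`), and boundary cases are visible in the exclusion report,
which lists each dropped taxon with its best group-mean, best prevalence
and the failed criterion. Raising either threshold can only shrink the
retained set, and the `all` set is always nested in the `any` set; both
facts are enforced by property tests.

# Diversity and ordination

Alpha diversity (Shannon, Simpson, inverse Simpson, Pielou evenness) is
computed on each sample renormalized over its non-zero taxa; Pielou is
undefined for single-taxon samples and reported as missing rather than
zero. Because the input tables are relative abundances, rarefaction is not
applied to them — subsampling fractions is undefined — but a seeded
multi-draw rarefaction is available for integer count tables.

Group comparisons use the Welch t test for two groups (the classic
pooled-variance test is a flag; Welch is the safer default when group
spreads differ) and one-way ANOVA with Fisher LSD pairwise p-values from
the pooled mean square error for more groups, mirroring standard clinical
reporting; a BH-adjusted variant of the pairwise table is available.

Beta diversity uses Bray–Curtis dissimilarity, principal coordinates
(Gower double-centering of \(-D^2/2\), symmetric eigendecomposition, axes
scaled by the square root of the positive eigenvalues; negative eigenvalues
are reported, never embedded), and a one-factor permutational MANOVA with
\(F\) and \(R^2\) computed from the within/total squared-distance sums.
The permutation p-value uses the add-one convention
\((1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})\), which cannot return
zero; when the design is small enough that the distinct label arrangements
number at most `n_perm`, the test enumerates them all and the p-value is
exact. Group-label permutation is seeded, so a configuration reproduces
bit-identically.

# Co-occurrence networks

Within each composite group, taxa are correlated by Spearman's rank
correlation on the shared core-taxon set, so the vertex universe is
comparable across groups. P-values use the t approximation
\(t = r\sqrt{(n-2)/(1-r^2)}\); an exact permutation p over all orderings is
available for very small groups and doubles as the test oracle.
Zero-variance taxa are flagged and excluded from edges. Edges require
`|r| > 0.3` and `p < 0.05` (both strict, both configurable); the vertex set
defaults to edge-incident taxa only, because isolated vertices change every
whole-graph statistic, and `keep_isolated` exposes the other convention.
The reported statistics are transitivity (3 × triangles / connected
triples), degree centralization (\(\sum_i (d_{max}-d_i)/((n-1)(n-2))\)) and
density (\(2E/(n(n-1))\)), all undefined below three vertices and reported
as missing there.

# Random-forest biomarker selection

For each of (by default) ten seeds, a stratified five-fold cross-validation
is run. Within every fold, features are ranked by random-forest importance
computed on the training folds only — ranking on the full data would leak
test information into the subset curve — and the held-out error is
evaluated for nested top-m subsets with m halving from all features to one
(the conventional schedule). Permutation importance (mean decrease in
accuracy) is the default ranking; impurity importance is a flag, since it
is biased toward features with many split points. Per seed, the selected
size m* is the smallest m whose mean CV error is within one standard
deviation (taken at the curve's minimum) of that minimum — the standard
parsimony rule; the plain minimum rule is a flag. Each seed's marker set is
its top-m* taxa by mean within-fold rank, and the final marker set is the
union across seeds, which is deliberately inclusive: a taxon that any
repeat finds necessary is worth reporting. Pooled out-of-fold class
probabilities (averaged over seeds per sample) give the ROC curve and the
trapezoidal AUC, which equals the normalized Mann–Whitney statistic.

Two properties of compositional data are worth knowing when reading the
curves. First, closure spreads a planted shift in a few taxa into every
renormalized abundance, so on strongly structured data the error curve can
be flat or even minimized at the full feature set; the one-SD rule then
selects large subsets and the union approaches the full core set, which is
correct behavior, not a selection failure. Second, random forests are
robust to uninformative features, so removing noise features often does
not lower the error; the reliable signature of a planted subset is that
the error rises once m falls below it.

Defaults: 500 trees per forest for analyses; the simulation-based checks
shipped with the package use 200 trees, 60 subjects, 20 taxa and 10 seeds,
sizes chosen to exercise the full repeated-CV machinery at a scale a
laptop runs in minutes. All forests are seeded per (seed, fold, subset),
so every number is bit-reproducible.

# Taxa–metadata correlation

Core taxa are correlated against the continuous clinical columns
(categorical features are excluded — a correlation coefficient is
undefined for them; group comparisons cover that case) with Pearson,
Spearman, or Kendall's tau-b (tie-corrected). Every cell uses its
pairwise-complete observations, with a minimum of four; p-values use the t
approximation for Pearson/Spearman and the normal approximation for
tau-b. Raw p-values remain primary in all exports, and BH q-values over
the full matrix are reported alongside, because a 20-taxa-by-20-feature
screen is a multiplicity problem whether or not one adjusts; the heat
export marks the two significance levels distinctly.

# The synthetic cohort generator

The generator emulates the statistical shape the workflow assumes: taxon
intensities are log-normal (taxon base log-means N(0, 1.2), unit log
noise), with a configurable log shift added to planted taxa in one status
group, exponentiated and closed to sum one — relative abundances of the
kind a standard amplicon pipeline exports. The clinical table carries the
binary status, age and sex columns, and a dietary block drawn from k
Gaussian clusters whose centers sit a configurable number of noise
standard deviations apart (default 8, a cleanly separated regime), with a
configurable fraction of cells masked missing. Planted taxon–feature
associations share a latent standard-normal driver. A multinomial count
mode at a stated depth exercises the rarefaction path. Everything is a
deterministic function of the specification and one seed, and the planted
truth is written as machine-readable JSON next to the tables.

What the generator does not emulate — and therefore what passing tests do
not certify about real data — includes phylogenetic correlation among
taxa, zero inflation beyond what closure and log-normal tails produce,
sequencing error and batch effects, and non-Gaussian dietary structure.
The recovery checks (vote recovers the planted k; the marker union
recovers planted differential taxa; null labels give chance-level AUC) are
statements about the machinery, not about any particular cohort.

# Numerical conventions and degenerate inputs

Percent-scaled abundance tables (columns summing near 100) are rescaled to
fractions with a warning; genuinely missing abundance cells are an error,
never a silent zero. Duplicate lineages merge by summation on read. Files
annotated at mixed taxonomic depths are rejected rather than guessed at.
Sample ids match case-sensitively after whitespace trimming. Constant
clinical features are flagged with p = 1 instead of producing NaN
statistics. All-zero sample pairs get Bray–Curtis 0 with a warning.
Eigenvalues below 1e-10 of the spectral radius count as null space in the
PCoA. The chi-square test for clinical contingency tables falls back to
Fisher's exact test when any expected cell is below five. Seeds derive
from one global seed through a fixed integer recurrence recorded in the
pipeline manifest, and every stochastic routine restores the caller's RNG
state.

# Known limitations

Only one-factor PERMANOVA is provided (no strata, no covariates);
phylogenetic diversity and UniFrac are out of scope, as are
compositionality-aware network estimators (SparCC-style) — the Spearman
network inherits the usual caveat that closure can induce spurious
negative correlations. The cluster vote assumes the feature block is
meaningfully Euclidean after z-scoring; heavily skewed dietary scores may
deserve a transformation first. The pipeline's stage cache keys on the
configuration hash, not on input file contents; feeding different data to
the same output directory should use a fresh directory.
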