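---
title: "Network-based group variable selection for eQTL mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based group variable selection for eQTL mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngvs)
```

## The problem

Expression quantitative trait locus (eQTL) mapping regresses the
expression levels of `G` gene traits on the genotypes of `p` markers
measured in the same `n` individuals.  In an F2 intercross each marker
takes three states (aa, Aa, AA); linkage makes nearby markers strongly
correlated; sample sizes are small; and expression traits are noisy and
themselves correlated.  Penalized regression handles `p > n`, but the
plain lasso ignores two kinds of structure a geneticist usually has:

* **loci structure** — markers fall into linkage-disequilibrium (LD)
  blocks, and a locus acts through both an additive and a dominant
  effect, which should be selected together; and
* **trait structure** — co-expressed genes that share function tend to
  be regulated by the same loci.

This package selects *marker sets* (groups of markers) jointly across a
*trait co-expression network*.

## The penalized criterion

Markers are partitioned into `J` disjoint marker sets; each set `j`
contributes a block of regressor columns per trait (its markers' dummy
columns, interaction columns, or kernel columns).  With the regressors
standardized (centered, unit Euclidean norm) and each response centered,
the coefficient vector `beta` (trait blocks stacked) minimises

```
||Y - X beta||^2
  + lambda1 * sum_g sum_j w_j || beta_{j,g} ||_2
  + lambda2 * sum_{u~v} || beta_u / sqrt(d_u) - beta_v / sqrt(d_v) ||^2
```

The first penalty is a group lasso over marker sets within every trait,
with the Yuan–Lin weights `w_j = sqrt(#columns in set j)` so that each
group is penalized in proportion to its parameter count; a whole set
enters or leaves a trait's model at once.  The second penalty is a
quadratic form `beta' L beta` in the normalized Laplacian of the trait
network (`d_u` is the degree of trait `u`): it shrinks the degree-scaled
coefficient blocks of linked traits toward each other, encoding the
assumption that strongly co-expressed traits share eQTLs.  With
`lambda2 = 0` the traits decouple into independent group-lasso problems.

Two structural facts drive the implementation:

* **Augmentation.**  Because `L = S S'` for the edge incidence factor
  `S`, the criterion equals an ordinary group lasso on an artificial
  dataset with `Ep` extra rows:
  `X* = (1+lambda2)^{-1/2} [X; sqrt(lambda2) S']`, `Y* = [Y; 0]`, at
  penalty level `lambda1 / sqrt(1+lambda2)`; the solution maps back by
  `beta = beta* / sqrt(1+lambda2)`.  Reported coefficients are finally
  rescaled by `1 + lambda2` to counteract the double shrinkage, as in
  the elastic net; selection orders are invariant to that factor, so it
  is applied only to reported coefficients, never inside the path.
  `augment_dataset()` implements this, and the test suite verifies on
  random tiny instances that the augmented route and direct minimisation
  of the criterion by an independent proximal-gradient solver agree.
* **Saturation lifting.**  A group lasso on `Gn` rows can select at most
  `Gn` variables.  The augmented problem has `Gn + Ep` rows, so whenever
  the network satisfies `E > G(p - n)/p` the saturation bound exceeds
  the parameter count.  `build_network()` evaluates this inequality and
  flags infeasible networks.

Both `L` and `S` consist of `p x p` scalar-multiple-of-identity blocks,
so only their `G x G` (or `G x E`) scalar cores are stored
(`laplacian_operator()`); nothing of size `Gp x Gp` is ever
materialised, and the augmented design is held sparse.

## The solver

`group_lasso()` implements block co-ordinate gradient descent: starting
from zero, each group's objective is replaced by a quadratic surrogate
with Hessian `h_j I` (`h_j` = largest eigenvalue of the group's Gram
matrix), whose exact minimiser is a group soft-threshold; an Armijo line
search (halving, sufficient-decrease constant 0.1) guarantees descent.
Convergence is declared on the Karush–Kuhn–Tucker residual: inactive
groups must satisfy `||X_j' r|| <= lambda w_j (1 + tol)`, active groups
the stationarity condition within `tol` (default `1e-8`; the
selection-order drivers default to `1e-6`, since entry orders do not
depend on the last digits of the coefficients).  The implementation
iterates on a *work set* (active groups plus current KKT violators) and
re-verifies the full KKT system between rounds, which keeps the cost per
`lambda` close to the size of the active set; the small per-group Gram
matrices are precomputed once per path.

`entry_path()` descends a log-spaced `lambda1` grid (default 100 points
down to `0.001 * lambda_max`) with warm starts and records each group's
first entry.  The grid step must be small enough that marker sets enter
one at a time; whenever two or more groups enter between consecutive
grid points the interval is bisected recursively (up to 12 levels) until
entries separate.  Groups still tied after refinement are ordered by
their gradient norm `||X_j' r|| / w_j` just above the entry point, and
groups that never enter are appended in order of their end-of-path
gradient norms — both natural gradient-magnitude rankings; the reference
method leaves these corners unspecified.  Two computational shortcuts
preserve the consumed part of the order exactly: the path stops early
once every group (or a requested number per trait) has entered, and
bisection is only spent on simultaneous entries within the same trait,
because the downstream procedure never compares entry ranks across
traits.

## The three-stage selection-order procedure

`ngvs_order()` produces, per trait, a ranked list of loci:

1. **Big scale.**  The networked multi-trait fit is pathed over
   `lambda1` at a fixed `lambda2` (default 10; big-scale orders are
   stable over a wide range of `lambda2`, so it is not tuned), and each
   trait's marker sets are ranked by first entry of their coefficient
   block.
2. **Small scale.**  Within each marker set, a single-trait group lasso
   over the set's loci (one group per locus: its additive and dominant
   dummies) ranks the loci, ignoring the set structure and the network
   — at small scale, trait-specific differences are allowed.
3. **Combination.**  Single-QTL likelihood-ratio p-values (simple
   regression of the trait on each locus's additive code, `chi^2_1`
   reference) glue the two scales into one final order under three
   criteria: each set's leading locus appears in big-scale set order;
   loci within a set keep their small-scale order; and whenever several
   loci are permitted by those constraints, the smallest p-value goes
   first.

The three criteria define only a partial order, and the exact
linearisation is a design choice.  `combine_orders()` uses the greedy
linear extension: at each step, among the loci whose within-set
predecessors are placed (and, for set leaders, all higher-ranked sets'
leaders), the smallest p-value wins.  A block interleaving that
exhausts one set before the next — or takes exactly one locus per set
per round — was rejected: either rule caps the attainable top-`k`
accuracy whenever two causal loci share a set, which contradicts the
reported behaviour of the reference procedure on its own low-dimensional
study; the greedy extension satisfies all three criteria and lets a
strong set contribute several top loci while weak sets wait.

`consensus_sets()` supports the trait-class view: marker sets ranked in
the top `m` (default 3) of at least a threshold fraction (default 0.5)
of traits.  `epistasis_scan()` is the post-hoc interaction scan: within
the consensus sets, each trait gets a group-lasso entry order over
per-locus two-effect groups plus one singleton group per adjacent-locus
interaction (product of additive codes), and interactions appearing in
the top `k` are reported with their supporting trait counts.

## Model variants, kernels, covariates

`build_model()` assembles six variants: (1) additive coding; (2)
two-effect coding (AA and Aa indicator dummies against the aa baseline
— the pair is one group, so a locus is selected as a unit); (3)/(4)
either coding plus adjacent-marker interaction columns (products of
additive codes, appended to the set's group — only adjacent pairs, since
distant pairs within sparsely genotyped low-LD maps carry little
information); (5) the two-effect model with a covariate (e.g. sex) as
one additional group, optionally with per-set covariate-by-marker
interaction groups; and (6) kernel models.

For the kernel models, each marker set's columns are replaced by the `n`
columns of its kernel matrix (the representer expansion of the set's
epistatic relationship function), giving `J x n` correlated new
variables whose big-scale order is computed exactly as before.  Five
kernels are provided (`kernel_matrix()`): linear `X_j X_j'`; polynomial
`(1 + X_j X_j')^q` (default order 2); Gaussian
`exp(-||x_i - x_i'||^2 / (d p_j))`, with the bandwidth scaled by the set
size so `d = 1` is comparable across sets; identity-by-state (IBS),
the fraction of shared alleles; and weighted IBS, which up-weights rare
alleles by `1 / sqrt(MAF)` (monomorphic markers are an error — their
weight is infinite).  Exact published forms of these kernels vary in
normalisation; the implementation follows the SNP-set association
literature, and the properties the package tests (positive
semi-definiteness; IBS-type values in `[0, 1]` with unit diagonal;
weighted IBS reducing to IBS under equal frequencies) are
convention-independent.  Kernel selection is left to the user; the
package compares kernels, it does not auto-select one.

## The synthetic-data generators

Both generators draw latent Gaussians, trichotomize them at the
standard-normal quartiles into codes −1/0/1 (so marginally ¼, ½, ¼ — an
F2 intercross), build trait signals from additive + dominant effects of
a few causal loci, and add correlated Gaussian noise scaled to a target
signal-to-noise ratio:

* `simulate_large_n()`: 7 markers with `Cov(Z1, Z2) = 0.8` and
  `0.4^|i-j|` otherwise; 2 linked traits driven by loci 1–3; marker-set
  layouts `"proper"` (`{Z1, Z2}` + singletons) and `"tangled"`
  (`{Z1, Z2, Z4}, {Z3, Z5}, {Z6, Z7}` — every causal locus diluted by a
  null one).
* `simulate_large_p()`: 60 samples, 200 markers with latent covariance
  `0.4^|i-j|` truncated beyond lag 10 (eigenvalue-clipped if the
  truncation breaks positive definiteness), 5 traits on the full
  network, causal loci {3, 4, 13, 27}, SNR 5.

Choices the source description leaves open, fixed here once:

* **Sample size of the low-dimensional design.**  Not stated; fixed at
  `n = 60`, the sample size of the linkage study both simulations
  emulate (and of the high-dimensional design).
* **Effect sizes.**  The per-locus regression coefficients are not
  recoverable from the source; the default effect table sets the AA and
  Aa dummy coefficients to 1.0 for every causal locus and trait (a
  complete-dominance pattern), perturbed per dataset by
  `r ~ U(0.9, 1.1)` drawn independently per (locus, dummy, trait) and
  held constant across samples — a per-sample draw would change the
  model class from fixed effects with noise to random coefficients.
  The table is overridable (`effects =`).  Note one consequence: under
  equal dummy coefficients the additive code still captures about two
  thirds of each locus's signal variance, so additive-only selectors
  are less handicapped here than in the reference study, whose printed
  comparisons imply dominance patterns that additive coding misses.
* **SNR convention.**  `sigma_g^2 = mean-square(signal_g) / SNR`, with
  the mean square taken of the *centered* signal.  The dummy coding
  gives the raw signal a large constant mean that response centering
  removes; including it would make the nominal SNR almost entirely
  intercept and the SNR = 5 setting behave like SNR < 1, which is
  inconsistent with every reported detection rate.  Noise correlation
  between traits is 0.5.

What the generators emulate: LD-like marker correlation, three-state
genotypes, shared causal loci across correlated traits, controlled
noise.  What they do not: real LD block structure (correlation decays
geometrically and is banded), genotyping error and missingness,
expression normalisation artefacts, hub structure in co-expression
networks, or causal effects that differ across traits.  Passing the
simulation benchmarks therefore demonstrates correctness of the
machinery and the qualitative value of the structural penalties under
the stated model — not performance on any particular real dataset.

## Benchmarks and their problem sizes

`run_benchmark("large_n")` reproduces the low-dimensional study: four
settings (proper/tangled sets × SNR 1/5), 50 datasets each, top-3
declared significant, methods NGVS / per-locus group lasso / additive
lasso.  `run_benchmark("large_p")` reproduces the high-dimensional
study: 20 datasets of 60 × 200 × 5, fixed windows `r ∈ {1, 2, 5, 10}`,
total true/false positives at `k ∈ {2, 3, 4, 5}` for NGVS, single-trait
selection (same machinery, `lambda2 = 0`), single-QTL regression and
the lasso.  The large-p driver runs the big-scale path on a 40-point
grid down to `0.2 * lambda_max` and stops once every trait has 8
entered sets — far deeper than the top-5 loci the scores consume — at
path tolerance `1e-5`; these are accuracy-neutral for the reported
quantities and keep the full benchmark within minutes on one core.

## Numerical choices and degenerate inputs

* Standardization scales columns to unit *norm*, not unit variance,
  making `lambda1` comparable across problem sizes.
* Zero-variance design columns (monomorphic markers, constant
  covariates) are an error naming the offending column; missing
  genotype codes are an error (no imputation).
* Degree-0 traits are reported by `build_network()` and are an error
  when the Laplacian is actually built — lower the correlation cutoff
  or supply a larger network.
* `fixed_size(r)` keeps the remainder markers as a trailing smaller
  set; `r = 1` means no grouping.
* Ties: simultaneous path entries are bisected apart; residual ties and
  never-entering groups rank by gradient norm; equal p-values in the
  final merge fall back to set rank, then within-set rank.
* The truncated latent covariance of the high-dimensional generator is
  repaired by eigenvalue clipping at `1e-8` if needed (with a warning).

## Limitations

Gaussian responses only (the BCGD framework extends to generalized
linear models; this implementation does not).  No VCF/PLINK input; no
missing-genotype handling; no automatic tuning of `lambda1`/`lambda2`
(the procedure's output is a selection *order*, cut by the user);
kernel designs do not support prediction on new samples; and arbitrary
(non-adjacent) two-locus interactions are out of scope.
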