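---
title: "Likelihood-free admixture inference: model, algorithm, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-free admixture inference: model, algorithm, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfadmix)
```

## The model

`lfadmix` estimates global ancestry under the structure/admixture model.
An m x n genotype matrix $X$ (m biallelic SNPs, n diploid individuals,
$x_{ij} \in \{0,1,2\}$ counting copies of the A1 allele) is generated from
an individual allele frequency matrix $F = PQ$:

* $P$ (m x k): allele frequencies of k latent ancestral populations,
  $0 \le p_{il} \le 1$;
* $Q$ (k x n): admixture proportions, each column on the probability
  simplex;
* $x_{ij} \mid f_{ij} \sim \mathrm{Binomial}(2, f_{ij})$, independently.

The model assumes unlinked SNPs (no linkage disequilibrium), Hardy–Weinberg
sampling within an individual's mosaic ancestry, and a fixed, user-chosen
number of populations k.

## The estimator

### Latent subspace estimation

Writing $D = \mathrm{diag}(d_j)$ with
$d_j = \tfrac1m \sum_i (2x_{ij} - x_{ij}^2)$ — the fraction of heterozygous
calls of individual j, since $2x - x^2$ is 1 for a heterozygote and 0
otherwise — the operator

$$G = \tfrac1m X^\top X - D$$

has the property that its top k eigenvectors $V$ span (asymptotically in m)
the row space of $Q$. The heterozygosity correction $D$ removes the
binomial-noise inflation of the diagonal of $X^\top X$; without it the
leading eigenvectors would be biased by per-individual noise levels.

$G$ is n x n and $F$ is m x n; at biobank scale neither fits in memory as a
dense real matrix. The package therefore never forms either: the only
primitives are $Xv$, $X^\top w$ and $d \circ v$, combined as
$Gv = \tfrac1m X^\top (Xv) - d\circ v$.

**Eigensolver.** Eigenpairs are computed by a Lanczos recurrence with full
(two-pass) reorthogonalisation, followed by Rayleigh–Ritz extraction from
the explicit projection $H = B^\top G B$ with exact residuals
$\lVert Gv - \lambda v\rVert$ computed from the stored operator images.
The Krylov basis starts at $\max(2k+10, 20)$ vectors and grows by a factor
1.6 until every requested pair has residual below $10^{-8}\,|\lambda_1|$
(the returned contract is $10^{-6}\,|\lambda_1|$; a cap of $1000k$ operator
products guards against pathological spectra). Because the basis may grow
to the full dimension n, at which point the extraction is exact,
convergence is guaranteed. If an invariant subspace is hit early (exact
breakdown), a fresh random direction is injected and orthogonalised; the
explicit projection keeps the extraction correct in that case. The starting
vector is drawn uniform(-1, 1) from the user's seed, making the estimate
deterministic; since only the subspace is identified, all downstream code
is invariant to sign flips or rotations of individual eigenvectors, which a
dedicated test asserts.

If any of the top-k eigenvalues is non-positive the estimate is still
returned, with a warning that k likely exceeds the structure detectable in
the data ($G$ is not guaranteed positive semidefinite at finite m).

### Finite-alphabet (Mailman) multiplication

Genotypes are stored packed at 2 bits per call, in PLINK bed geometry, so a
dataset occupies mn/4 bytes and bed files translate by recoding rather than
repacking. Products exploit the three-letter alphabet: rows are grouped
into segments of $d = \lceil \log_3 n \rceil$ SNPs, each column of a
segment is encoded once as a d-digit base-3 integer, and a segment product
then costs $O(n + 3^d) = O(n)$ — bucket-accumulate the input by code, then
peel digits — instead of $O(dn)$. Both $Xv$ and $X^\top w$ reuse the same
row-segment codes (the transpose direction builds a $3^d$ lookup of digit
sums and scatters it through the codes), giving $O(mn/\log_3 n)$ per
product with one shared $O(mn)$ preprocessing. Rows left after the last
full segment are multiplied naively, as are matrices with fewer than 27
rows or columns, where the encoding cannot pay off. ALS needs products
against k-column blocks, so batched kernels read the code array once for
all k right-hand sides; this is a memory-traffic optimisation only and
changes nothing numerically beyond summation order.

### Truncated alternating least squares

With $\hat F = \tfrac12 X V V^\top$ held implicitly, the factors solve the
constrained least-squares problem by alternation:

$$\hat Q = \tfrac12 (\hat P^\top \hat P)^{-1} \hat P^\top X V V^\top,
\qquad
\hat P = \tfrac12 X V V^\top \hat Q^\top (\hat Q \hat Q^\top)^{-1},$$

each evaluated right-to-left so only k-column intermediates exist, followed
by projection: every column of $\hat Q$ is mapped to its Euclidean
projection on the simplex (sort-based algorithm), every entry of $\hat P$
is truncated to [0, 1]. $\hat P$ is initialised i.i.d. uniform(0, 1) from
the seed; $\hat Q$ is updated first, matching the order in which the
normal equations are written. Iteration stops when the change between
successive admixture estimates,
$\lVert \hat Q_t - \hat Q_{t-1}\rVert_F / \sqrt{nk}$, falls below the
tolerance (default $10^{-5}$) or after `max_iter` (default 1000)
iterations. The $\sqrt{nk}$ normalisation makes the criterion a proper
root-mean-square over entries; a per-entry reading of the same formula
would only rescale the tolerance. Factor constraints are re-asserted after
every iteration, not just at exit.

**Degenerate factors.** If two latent populations collapse during ALS, the
Gram matrix $\hat P^\top \hat P$ (or $\hat Q\hat Q^\top$) becomes
numerically singular. The updates then switch to the Moore–Penrose
pseudoinverse — but a pseudoinverse step cannot re-separate populations that
have already merged, so inside `admix_fit()` a detected singular Gram
matrix triggers a fresh uniform(0, 1) re-initialisation from the seeded
stream (at most 10 times, counted against the iteration budget). The
standalone `update_q()`/`update_p()` functions keep the
pseudoinverse-with-warning behaviour so exploratory large-k use degrades
gracefully. Without the restart, the fit can converge to a merged-population
fixed point even on noiseless rank-k data.

**Supervised mode.** Given reference allele frequencies (an aligned matrix
or a panel file), $\hat P$ is fixed and $\hat Q$ is obtained by a single
constrained update after LSE; the subspace can be shared between a
supervised and an unsupervised fit of the same data via the `subspace`
argument (LSE depends only on the data and k, so recomputing it would waste
the dominant cost).

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | — | latent populations; no automatic selection is attempted |
| `tol` | 1e-5 | RMSE change between successive $\hat Q$ that counts as converged |
| `max_iter` | 1000 | ALS iteration cap |
| `seed` | 1 | drives the eigensolver start and the $\hat P$ init |
| LSE residual tol | 1e-8 (relative) | eigenpair residual target; contract 1e-6 |
| `eps` (metrics) | 1e-9 | zero replacement in KL/JSD |
| `sigma2` (spatial sim) | 4 | spatial kernel variance |
| `fst`, `alpha` (PSD sim) | 0.1, 1 | differentiation and admixture concentration |

## Simulators and what they do (not) emulate

`sim_psd()` draws $p_{il} \sim \mathrm{Beta}(c\,p_A, c\,(1-p_A))$ with
$c = (1-F_{ST})/F_{ST}$ (the Balding–Nichols model: mean $p_A$, variance
$F_{ST}\,p_A(1-p_A)$), one $(p_A, F_{ST})$ pair per SNP shared across
populations; admixture columns $\sim \mathrm{Dirichlet}(\alpha 1_k)$; and
genotypes binomially from $PQ$. `sim_spatial()` replaces the Dirichlet by a
1-D geography: populations at positions $1,\dots,k$, individuals at
$y_j \sim \mathrm{Uniform}(0, k+1)$, proportions equal to normalised
$N(z_l, \sigma^2)$ densities at $y_j$ — a deliberate violation of the PSD
prior used as a robustness probe.

Defaults are chosen once: $\alpha = 1$ (uniform on the simplex — the
neutral choice when no concentration is specified), $F_{ST} = 0.1$
(continental-scale differentiation), $p_A \sim \mathrm{Uniform}(0.1, 0.9)$
(a download-free stand-in for frequencies estimated from a reference
cohort; per-SNP vectors can be passed to reproduce a real frequency
spectrum), $\sigma^2 = 4$. Everything is reproducible from `(params, seed)`
to the byte.

What the simulators do **not** emulate: linkage disequilibrium (SNPs are
independent), missing genotypes (simulated data are complete; real-data
missingness is handled at load time, see below), allele-frequency spectra
of real panels (unless supplied), relatedness, and genotyping error.
Passing recovery tests on these simulations therefore demonstrates
correctness of the estimator under its own model and robustness to the
spatial violation — not performance on LD-rich or artefact-laden cohorts,
which should be LD-pruned and quality-controlled upstream.

## Evaluation metrics

Estimates are identifiable only up to population relabelling, so
evaluation first solves an assignment problem: cost of matching inferred
population b to reference population a is the mean absolute difference of
their admixture rows, minimised exactly by a Hungarian-class solver (an LP
would find the same optimum; the mean-absolute-difference score is this
package's concrete choice of row distance). Metrics on matched matrices:
$\mathrm{RMSE} = \lVert Q - \hat Q\rVert_F/\sqrt{nk}$;
$\mathrm{KL} = \tfrac1n\sum_{j,l} q_{lj}\log(q_{lj}/\hat q_{lj})$ with
zeros replaced by $10^{-9}$ and natural logarithm;
$\mathrm{JSD} = \tfrac12[\mathrm{KL}(Q, M) + \mathrm{KL}(\hat Q, M)]$ with
$M = (Q+\hat Q)/2$. Reports can be scaled by 100, the convention used in
simulation-accuracy tables. The log base is a genuine convention choice;
natural log is used consistently, and only cross-package comparisons of
absolute JSD values would notice the difference.

## Input handling and degenerate cases

* **Missing genotypes.** The matrix-free machinery requires the exact
  alphabet {0,1,2}, so missing bed calls are imputed at load time to the
  rounded per-SNP mean genotype, with the count reported; a SNP with no
  observed calls at all is imputed to 0 and flagged. Imputation is a
  loader policy, not part of the estimator.
* **Reference panels.** TSV with header `SNP A1 A2 <pop...>`; frequencies
  refer to A1. Alignment intersects on SNP id, flips $p \to 1-p$ where the
  allele pair is swapped, and drops incompatible pairs. Strand ambiguity
  (A/T, C/G) is deliberately not resolved — silent strand guessing corrupts
  supervised estimates — so ambiguous SNPs should be filtered upstream.
* **k = 1** degenerates correctly: the simplex in one dimension is the
  point {1}.
* **Rank-deficient reference panels** (duplicate populations) solve via
  pseudoinverse with a warning rather than failing.

## Problem sizes used by the test suite

Oracle comparisons (dense eigendecomposition, naive products, brute-force
simplex/assignment enumeration) run at dimensions up to 200 x 200, where
dense references are exact and cheap. Statistical recovery runs use
m = 5000, n = 500, k = 3 (PSD, five replicate seeds) and m = 5000,
n = 1000, k = 6 (spatial); the trend test over SNP count uses
m in {1000, 5000, 20000} at n = 500. The memory-contract check fits
m = 20000, n = 2000 and asserts that peak R allocation stays far below the
size of a single dense m x n double matrix. These sizes keep the full suite
in the order of a minute while leaving each effect (recovery accuracy,
supervision gain, trend in m, allocation bound) well outside noise.

## Known limitations

* No criterion for choosing k is provided; replicate fits across a range
  of k are the intended workflow.
* ALS minimises a non-convex objective; different seeds can reach
  different local optima (replicate-consistency is tested on simulated
  data, and the degeneracy restart removes the most common failure mode,
  but multimodality at large k is inherent).
* Linkage disequilibrium is ignored; dense LD can masquerade as structure.
  LD-prune upstream.
* The supervised mode is only as good as the supplied panel: biased or
  misaligned reference frequencies propagate directly into $\hat Q$.
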