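# lfadmix

Scalable, likelihood-free inference of population structure from biallelic
genotype data: individual admixture proportions and ancestral allele
frequencies, estimated without ever forming any dense SNP-by-individual
real matrix.

## The model and the estimator

Under the structure/admixture (PSD) model, an m SNP x n individual genotype
matrix **X** (entries x_ij in {0,1,2}, counts of the A1 allele) is linked to
an individual allele frequency matrix **F** = **PQ**, where

* **P** (m x k) holds ancestral allele frequencies, 0 <= p_il <= 1,
* **Q** (k x n) holds admixture proportions, q_lj >= 0 and sum_l q_lj = 1
  for every individual j,
* x_ij | f_ij ~ Binomial(2, f_ij) independently.

The estimator is likelihood-free and two-staged:

1. **Latent subspace estimation (LSE).** The row space of **Q** is spanned
   by the top k eigenvectors **V** of
   `G = (1/m) X'X − D`, where D is diagonal with
   `d_j = (1/m) Σ_i (2 x_ij − x_ij²)` (the per-individual heterozygosity
   fraction). `lfadmix` computes these eigenvectors matrix-free with a
   Lanczos/Rayleigh–Ritz iteration whose only primitive is multiplication
   by **X** and **X'**.
2. **Truncated alternating least squares (ALS).** The implied frequency
   estimate `F̂ = (1/2) X V V'` is factorised into **P̂** and **Q̂** by
   alternating the closed-form least-squares updates
   `Q̂ = (1/2)(P̂'P̂)⁻¹ P̂'X V V'` and `P̂ = (1/2) X V V' Q̂'(Q̂Q̂')⁻¹`,
   truncating **P̂** to [0,1] and projecting each column of **Q̂** onto the
   probability simplex after every update. Iteration stops after 1000
   rounds or when the RMSE between successive **Q̂** drops below 1e-5.
   `F̂` is only ever applied, never stored.

All products against **X** use the Mailman finite-alphabet algorithm on
2-bit-packed genotypes: row segments of ceil(log3 n) SNPs are encoded once
as base-3 column codes, after which every product costs O(mn / log3 n).

A **supervised mode** fixes **P̂** at reference panel allele frequencies and
solves for **Q̂** in a single constrained step after LSE.

The package also ships generative simulators with ground truth (PSD model:
Balding–Nichols Beta frequencies x Dirichlet admixture; spatial model:
normal-density weights on a 1-D geography), permutation-matched accuracy
metrics (RMSE, Jensen–Shannon and Kullback–Leibler divergence), and PLINK 1
bed/bim/fam input/output.

## Worked example

```r
library(lfadmix)

# simulate an admixed cohort: 2000 SNPs, 200 individuals, 3 populations
sim <- sim_psd(m = 2000, n = 200, k = 3, seed = 42)

fit <- admix_fit(sim$X, k = 3, seed = 1)
fit
#> Admixture model fit (unsupervised): 2000 SNPs x 200 individuals, k = 3
#> ALS iterations: 148 (converged, final change 9.93e-06, tol 1e-05)
#> Top eigenvalues of G: 245.2, 1.459, 1.262
#> Mean admixture proportions: pop1 0.351, pop2 0.340, pop3 0.308

evaluate_admixture(sim$Q, coef(fit), percent = TRUE)
#> RMSE 4.751%  JSD 0.6283%  KL 6.256%  (populations matched: 2 3 1)

# supervised: fix P at the true frequencies, reuse the subspace estimate
sup <- admix_fit(sim$X, ref = sim$P, seed = 1, subspace = fit$subspace)
evaluate_admixture(sim$Q, coef(sup), percent = TRUE)
#> RMSE 4.438%  JSD 0.5674%  KL 7.81%  (populations matched: 1 2 3)
```

The print method reports the ALS convergence state and the eigenvalue gap
(one dominant eigenvalue plus k−1 structure eigenvalues here). The
evaluation line gives permutation-matched error metrics in percent:
RMSE ~4.8% of admixture mass misassigned per entry on average, and the
supervised fit improves on the unsupervised one.

A command-line interface with the same functionality installs to
`exec/lfadmix` (subcommands `simulate`, `fit`, `supervised`, `evaluate`;
each writes a JSON run manifest with configuration, seeds and input
checksums).

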