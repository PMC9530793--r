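---
title: "Decomposing host trait variance over genome, microbiome and their interaction"
author: "hologreml"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing host trait variance over genome, microbiome and their interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hologreml)
```

## The question

Quantitative traits of a host animal — fat deposition in livestock is the
motivating case — are shaped by host genetics, by the gut microbial
community the host carries, and potentially by the interplay of the two:
the same microbes may matter more on some genetic backgrounds than on
others. hologreml quantifies these contributions as fractions of
phenotypic variance using individual-by-individual similarity kernels:

* **GRM** `G` — genomic relationship from SNP genotypes,
* **MRM** `M` — microbial relationship from OTU relative abundances,
* **interaction kernel** `A = G ∘ M` — the elementwise (Hadamard)
  product, the natural covariance structure of a genome-by-microbiome
  interaction effect (positive semi-definite whenever `G` and `M` are,
  by the Schur product theorem).

The working model for a trait vector `y` over `n` individuals is

```
y = Xb + g + m + a + e,
g ~ N(0, G sg2),  m ~ N(0, M sm2),  a ~ N(0, A sa2),  e ~ N(0, I se2)
```

and the reported quantities are the fractions `sx2 / sp2` with
`sp2 = sg2 + sm2 + sa2 + se2`. Single-kernel versions of the same model
define heritability (`h2`, GRM only, with sex and body weight as fixed
covariates) and microbiability (`m2`, MRM only, with a BIC-selected
covariate set).

## Kernels

**GRM.** Two standard dialects are implemented, both using in-sample
coded-allele frequencies `p_i`. The VanRaden form divides the
cross-product of centered genotypes by a single genome-wide constant,
`G = ZZ' / (2 Σ p_i(1 − p_i))`; the GCTA form standardizes each SNP to
unit variance before averaging. They coincide when all SNPs share the
same allele frequency (a tested identity) and in practice differ little;
the VanRaden form is the default, and the GCTA form is used by the
heritability front-end. Missing genotypes are mean-imputed to `2 p_i`,
which makes their centered contribution exactly zero — the standard,
HWE-unbiased choice. With in-sample frequencies every row of `G` sums to
zero; this identity and the allele-flip invariance are tested.

**MRM.** Microbial similarity is the average over OTUs of the product of
standardized relative abundances:
`m_ij = (1/N) Σ_o (X_io − X̄_o)(X_jo − X̄_o) / s2_o`. Abundances enter
raw (no log or centered-log-ratio transform): the construction
standardizes each OTU across individuals, so any per-OTU rescaling —
which is what a log transform would change monotonically — leaves the
standardized scores' covariance structure to carry the signal, and
per-OTU scale is provably irrelevant (a tested invariance). The variance
`s2_o` uses the `n − 1` sample convention; the paper-facing consequence
is the exact identity `trace(M) = n − 1`, which the tests assert to
1e-8. OTUs constant across individuals are undefined under
standardization and are dropped, with `N` counting the survivors.

**Scaling.** Before multi-kernel fitting every kernel is divided by its
mean diagonal, so each variance component is on the phenotypic-variance
scale and fractions are directly comparable across kernels. Raw-scale
fitting is available by skipping `standardize_kernel()`.

## REML engine

`reml_fit()` maximizes the restricted likelihood of
`y ~ N(Xb, Σ_k sk2 K_k + se2 I)`. Two numerical choices matter:

* **Fixed effects are absorbed, not profiled.** With `Q` an orthonormal
  basis of the complement of `col(X)`, the restricted likelihood is the
  ordinary likelihood of `Q'y ~ N(0, Σ_k sk2 Q'K_kQ + se2 I)`. Working
  in this `(n − p)`-dimensional space makes the projection matrix simply
  `V^{-1}` and removes a genuine failure mode: when a kernel's null
  space lies inside `col(X)` (a centered GRM's all-ones direction and
  the intercept, for instance) the textbook `y'Py` form computes a tiny
  number as the difference of two enormous ones and can go negative,
  sending the optimizer to garbage. In the absorbed space the offending
  direction never appears.
* **Active-set average-information updates.** The first step is an EM
  step; subsequent steps solve the AI system restricted to components
  not pinned at the lower bound (`1e-8 · var(y)`) with a non-positive
  gradient, with step-halving and an EM fallback whenever a step fails
  to improve the likelihood. Pinned components re-enter automatically
  when their gradient turns positive. Convergence requires
  `|Δ logL| < 1e-6` and a small free-component gradient, within 200
  iterations; non-convergence is flagged, never silent. On the
  three-kernel recovery benchmark this scheme converges in a median of
  ~6 iterations where a naive clamped AI loop oscillated for hundreds.

With a single kernel the absorbed kernel is eigendecomposed once and
every iteration is `O(n)` — this is what makes the simulation studies
(hundreds of single-kernel fits) cheap. A `constrain = FALSE` option
removes the positivity bound (the analogue of GCTA's unconstrained
mode); see *Limitations* for why one might want it.

Standard errors come from the inverse AI matrix at the optimum, with the
delta method for fractions. A fit whose AI matrix is numerically
singular — an identity-like kernel makes the kernel/residual split
unidentifiable — is flagged and its SEs set to `NA`. Per-component
p-values use the likelihood-ratio statistic against the model with that
kernel removed, referred to the 50:50 mixture of a point mass at zero
and chi-square(1), the correct null when a variance sits on the boundary
of its parameter space; `Λ = 0` gives p = 0.5 and the null rejection
rate is verified below 7% by simulation. A `grid` algorithm evaluates
the single-kernel likelihood on a 21 × 21 grid and serves as a
brute-force oracle in the tests: the AI optimum must match or beat it.

## Covariate selection and BIC

Microbiability is sensitive to what the fixed effects absorb, so six
candidate covariate sets are screened — all contain body weight and they
differ in sex, the first five genome-wide PCs (population structure) and
the first two PCs computed at a user-supplied trait-associated SNP
subset (the scan that would identify those SNPs is out of scope; without
a subset only the two sets free of subset PCs are screened). The
selection statistic is `BIC = k ln(n) − 2 ln(L)` with `k` counting
variance parameters plus fixed effects and `L` the restricted
likelihood; the smallest BIC wins, ties to fewer parameters. Because the
restricted likelihood is defined on the absorbed space, comparisons
across different `X` are comparisons of different data transformations —
a known, accepted property of REML-based information criteria that all
GREML software shares; the simulation check (a real sex effect is
planted; the sets containing sex win in 100% of replicates) shows it
selects correctly where it matters.

## Candidate-genus screens

Genera are OTU-proportion sums above 0.01% mean relative abundance
(strict inequality; OTUs without genus annotation pool into an
`unclassified` bucket that never enters scans).

**Divergent groups.** The top and bottom `round(0.2 n)` individuals
(half rounds up — 239 individuals give 48 per extreme, matching the
cohort convention the method comes from) are compared by two-sided
Wilcoxon rank-sum tests in both directions: genus abundance between
extreme-trait groups, and trait between extreme-abundance groups. A
genus is a divergent-screen candidate when both p-values fall below
0.05. The two p-values are strongly dependent (they probe the same
underlying genus-trait association; log-p correlation ≈ 0.6 under the
null), so the double-significance null rate is about 1.5–2% — far below
the 5% of either test alone, but well above the 0.25% naive independence
product. Exact-mode Wilcoxon p-values are enumeration-exact (tested
against full enumeration for all configurations up to combined n = 10);
the normal approximation with continuity and tie correction is reliable
only once both groups have at least 3 members (worst-case deviation
0.037 there, versus 0.13 for singleton groups), which the group sizes in
practice always satisfy.

**Association scan (MWAS).** Per genus, `y = Xb + u + e` with `X`
holding intercept, genus abundance, sex and body weight, and `u` an
optional polygenic effect with covariance `G su2`. With a kinship
kernel, variance components are estimated once under the genus-free null
model and each genus is then tested by generalized least squares with
`V` held fixed — the standard two-stage mixed-model association
strategy — using a 1-df F-test on the genus coefficient. Without
kinship the scan reduces exactly to per-genus ordinary regression (a
tested identity), and its null rejection rate at α = 0.05 is calibrated
within [0.035, 0.065]. Raw p-values drive the significance call, as in
the source method; a Benjamini–Hochberg column is emitted for
information only. Genera flagged by both screens form the final
candidate list.

## The synthetic hologenome generator

`simulate_hologenome()` is the package's acceptance surface: it draws
data whose true variance fractions are known, so the whole pipeline can
be audited end to end.

* **Genotypes:** independent biallelic SNPs, allele frequencies
  `U(0.05, 0.5)`, calls `Binomial(2, p)`. Defaults: 300 individuals,
  3,000 SNPs — kernels, not marker count, drive estimator behaviour, so
  a desk-scale marker panel stands in for sequencing-scale data. SNPs
  fixed by sampling are excluded from the generator's kernel but kept in
  the emitted files for QC to catch.
* **Microbiome:** per-OTU log-abundance locations `N(0, 2)` with
  individual noise SD 1, exponentiated and renormalized per individual
  to proportions. The location SD of 2 concentrates the community in a
  few dominant taxa — the heavy-tailed, few-dominant-phyla shape real
  16S profiles show. 300 OTUs in 30 synthetic genera.
* **Trait:** `y = mu + 0.5·male + 0.02·(BW − mean BW) + g + m + a + e`,
  the four random draws taken from the realized standardized kernels
  with user-chosen fractions (default 0.5/0.2/0.1/0.2) summing to unit
  variance; body weight `N(100, 10)` kg, sexes alternating. Everything
  is reproducible from one seed.

What the generator does **not** emulate — and what passing tests
therefore do not certify about real data: linkage disequilibrium and
family structure (SNPs are independent, individuals unrelated),
compositional zero-inflation (every OTU is present in every individual,
so `Sobs` is flat and Chao1/ACE add nothing over observed richness),
sequencing depth variation, and any mechanistic genotype-dependent
microbe effect — the interaction draw comes directly from the Hadamard
kernel, matching the statistical model being tested rather than a
biological mechanism.

## Numerical conventions and edge cases

* Internal abundance unit is the proportion; thresholds quoted in
  percent are converted (0.01% → 1e-4). All filter inequalities are
  strict except the HWE boundary, where a SNP at exactly the threshold
  p-value is kept (removal is `p < threshold`).
* PLINK bed 2-bit codes map 00→2, 01→missing, 10→1, 11→0 copies of the
  A1 allele (PLINK 1.9 counting); the decoder is tested against a
  hand-decoded byte.
* GCTA-dialect kernel files store the row-order lower triangle as
  float32; round trips are exact to float32 precision (~1e-7), which is
  far below any quantity of interest here.
* Exact HWE p-values enumerate the conditional distribution of the
  heterozygote count in log space (no mid-p), and agree with brute-force
  enumeration for every configuration up to n = 10.
* Missing phenotypes or covariates: complete-case per fitted model, with
  the dropped count reported. Ties at a divergent-group cut resolve by
  stable input order, and the two groups are disjoint by construction
  even under mass ties.

## Known limitations

* **Constrained REML near boundaries is biased.** At the default study
  scale (n = 300, weakly structured GRM, near-diagonal interaction
  kernel) single-replicate fraction SDs are 0.1–0.24. Truths near zero
  (the interaction fraction especially) then truncate at the bound in a
  sizable minority of replicates, inflating their average and — through
  the strong negative correlation among estimates — depressing the
  genetic fraction's average by about 0.05–0.07. This is a property of
  the estimator at this information level, not of the implementation:
  the optimizer verifiably reaches the REML optimum (grid and
  multi-start checks), and the unconstrained mode trades this bias for
  fraction distortions of similar size through negative components. At
  these scales, read three-kernel point estimates with their standard
  errors, not as unbiased measurements.
* REML-based BIC comparisons across covariate sets inherit the usual
  caveat about comparing restricted likelihoods under different fixed
  designs (above).
* The normal-mode Wilcoxon approximation is unreliable for groups
  smaller than 3; exact mode is automatic there.
* Alpha-diversity estimators needing singleton/doubleton counts (Chao1,
  ACE) require integer read counts; tables that only carry proportions
  report them as `NA`.
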