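---
title: "Auditing codon-specific dihedral-angle signals with null codon-usage models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing codon-specific dihedral-angle signals with null codon-usage models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonangles)
```

## The question this package addresses

Reports of statistically significant differences between the backbone
dihedral-angle (Ramachandran) distributions of synonymous codons are
surprising: synonymous codons encode the same amino acid, so any such
difference would have to arise through the translation process itself.
Before accepting that interpretation, two mundane explanations must be
ruled out:

1. **Test noise.** Distances between estimated angle distributions are
   positive even when the underlying distributions are identical, and the
   magnitude of that noise varies across amino acids and secondary
   structures (sample sizes and basin shapes differ). A method that
   conflates this noise with signal will "find" codon effects where none
   exist.
2. **Gene expression.** Codon usage varies strongly across genes, driven
   by mutation bias and by selection for translation efficiency whose
   strength scales with expression. Any per-gene property that also
   co-varies with expression (amino-acid usage, structure composition)
   can then masquerade as a codon-specific effect.

The audit strategy implemented here is simulation-based: keep a study's
structural observations fixed, replace the codon labels with sequences
simulated under a null codon-usage model that contains no position- or
angle-specific information, re-run the codon-pair angle test, and compare
the two analyses. If the null-resimulated data reproduce the "signal",
the signal was never about angles.

## The codon-usage model

For an amino acid with $n_a$ synonymous codons, the probability that gene
$g$ (expression $\phi_g > 0$) uses codon $i$ is

$$
p_{i,g} \;=\;
\frac{e^{-\Delta M_i - \Delta\eta_i\,\phi_g}}
     {\sum_{j=1}^{n_a} e^{-\Delta M_j - \Delta\eta_j\,\phi_g}},
$$

the selection–mutation–drift equilibrium (SMDE) form used by
ROC-SEMPPR-style models of codon usage. $\Delta M_i$ is the mutation-bias
offset and $\Delta\eta_i$ the selection offset of codon $i$, both
log-scale and relative to a **reference codon** per family. We fix the
reference to the lexicographically last codon of each family
(`genetic_code()$reference`); the formula is invariant to a common
within-family shift, so any fixed convention is equivalent — ours is
simply documented and stable.

Four simulation regimes are supported (`model_spec()`):

* **UNIFORM** — every synonym equally likely ($1/n_a$);
* **MUTATION_ROC** — $\Delta\eta \equiv 0$, usage set by fitted
  mutation-bias offsets;
* **MUTATION_EMPIRICAL** — $\Delta\eta \equiv 0$ with $\Delta M$ derived
  from a measured 4×4 single-nucleotide mutation-rate table: we take the
  stationary base frequencies $\pi$ of the rate matrix, give each codon
  weight $w = \pi_{b_1}\pi_{b_2}\pi_{b_3}$ (independent sites, no context
  dependence — the simplest defensible conversion, chosen because a
  context-aware conversion is not identifiable from a 4×4 table), and set
  $\Delta M_i = -\ln(w_i / w_{\mathrm{ref}})$;
* **SMDE** — the full expression-dependent model.

Serine is one 6-codon family by default; `genetic_code(split_serine =
TRUE)` splits it into the TCN and AGY blocks (labelled `S` and `Z`),
which are not connected by single synonymous substitutions. Both
treatments are supported because analyses in this area have used both;
results tables carry the family label.

## Fitting the model

`fit_smde()` is a Metropolis-within-Gibbs sampler on the multinomial
likelihood implied by the formula above, intended for parameter recovery
on simulated data (it makes no attempt at feature parity with genome-scale
codon-model software). Design choices that matter:

* **Identifiability.** $\phi$ and $\Delta\eta$ trade off scale for scale,
  so $\phi$ is renormalised to geometric mean 1 after every sweep with
  $\Delta\eta$ rescaled inversely (likelihood-invariant).
* **Priors.** $\Delta M, \Delta\eta \sim N(0,1)$ and
  $\ln\phi \sim N(0, 2^2)$ — weakly informative; the lognormal form
  mirrors the empirical distribution of expression levels.
* **Proposals.** Component-wise Gaussian random walks, scales adapted
  during burn-in towards ~0.3 acceptance; the per-gene $\phi$ updates are
  proposed and accepted in parallel since the likelihood factorises over
  genes.
* **Mode flipping.** The posterior has an approximate reflection mode
  ($\ln\phi \to -\ln\phi$, $\Delta\eta \to -\Delta\eta$,
  $\Delta M \to \Delta M + 2\Delta\eta$; exact to first order in
  $\ln\phi$). A chain started at the symmetric point
  ($\phi \equiv 1, \Delta\eta \equiv 0$) can settle in the mirrored mode,
  which manifests as sign-flipped expression estimates. Every sweep the
  sampler proposes the deterministic involution and accepts it by
  Metropolis-Hastings (unit Jacobian), which reliably moves chains into
  the dominant mode and makes estimates invariant to gene relabelling.
* **Initialisation.** $\Delta M$ starts at pooled-frequency moment
  estimates (pseudo-count 0.5), $\Delta\eta$ at 0, $\phi$ at 1.

On data simulated from the model (500 genes, mean 300 codons, lognormal
expression with `sdlog = 1`, `sd_deltaM = 0.5`, `sd_deltaEta = 0.3`),
1200 sweeps recover $\Delta M$ and $\Delta\eta$ with correlation
$\ge 0.9$ against truth and expression with Spearman $\ge 0.8$ — the
package's acceptance bar for the sampler, exercised by the test suite and
`scripts/acceptance.R`.

## The angle test

`torus_kde()` estimates a density on the $(\phi, \psi)$ torus with a
wrapped Gaussian kernel, computed by periodic bilinear binning on a
$G \times G$ grid followed by circular FFT convolution — exactly
periodic, so mass near $-180^\circ$ leaks correctly to $+180^\circ$.
Defaults: bandwidth 15°, $G = 64$ (5.6° cells). The bandwidth resolves
the α and β basins without extreme over-fitting; both knobs are exposed
in `angle_test_config()` precisely because over-smoothing and
over-fitting change the noise behaviour of the statistic, which is the
phenomenon under audit. Points of exactly $+180^\circ$ are remapped to
$-180^\circ$ on ingest.

The distance statistic **DDist** (`ddist()`) is the total-variation
distance between two grid densities, $\tfrac12\sum|d_1-d_2|\,\Delta A
\in [0,1]$. The original pipeline this audit re-examines did not publish
its metric in a reproducible form; total variation was chosen as a
bounded, symmetric, interpretable re-specification. Qualitative
behaviour, not bit-level agreement with any particular pipeline, is the
design target.

`pair_test()` compares two synonymous codons within one (amino acid,
secondary structure) stratum: the null distribution is built by randomly
permuting the codon labels between the two groups (sizes preserved),
`n_perm = 999` by default, with the add-one estimator
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n_\mathrm{perm})$,
so the smallest reportable p-value is $1/(n_\mathrm{perm}+1)$. Pairs with
fewer than `min_n = 50` records per codon are reported untested rather
than tested on noise. Benjamini–Hochberg q-values are computed across the
full results table (`multiple_testing()`, $\alpha = 0.05$); the exact
correction used by prior analyses in this area is unstated, so BH across
all tested pairs is our documented choice, with a per-class breakdown
available downstream. Unlike distance-threshold heuristics, a label
permutation test is valid under the null regardless of bandwidth — a
deliberate strengthening relative to the audited approach, and the reason
null studies here show *controlled* error rates rather than the inflated
counts that motivated the audit.

`self_distance()` quantifies pure noise: random half-splits of one
codon's own records, KDE per half, DDist recorded. The companion
diagnostic `noise_signal_correlation()` rank-correlates, across amino
acids within each structure class, the mean self-distance with the mean
between-codon distance. A strong positive correlation says the
between-codon statistic tracks stratum noise (sample size, basin
roughness) rather than codon identity.

## The synthetic-study generator

`make_study()` composes the generator stages so every pipeline stage is
testable without external data. Its defaults define the study conditions
used throughout the tests and the acceptance script:

* 150 genes, geometric lengths with mean 300 amino acids (floor 30) —
  typical bacterial coding-sequence scale, held at a size the full
  permutation analysis completes in minutes on one core;
* amino-acid frequencies follow a bacterial-proteome-like table (leucine
  ~11%, tryptophan ~1.5%): the resulting spread of per-stratum sample
  sizes is what gives different amino acids genuinely different noise
  levels, a feature of real structural data the noise diagnostic needs;
* secondary structure per site: HELIX 0.35, SHEET 0.25, TURN 0.20,
  OTHER 0.20;
* expression lognormal with `sdlog = 1`; codon parameters
  $\Delta M \sim N(0, 0.5^2)$, $\Delta\eta \sim N(0, 0.3^2)$ — magnitudes
  in the range reported for enteric bacteria;
* angles per (amino acid, structure): a two-component mixture of
  independent-axis wrapped normals, an α basin at $(-63, -43)$ and a β
  basin at $(-120, 135)$, helix-dominated or sheet-dominated weights per
  class, with per-residue width scaling (glycine broad, proline narrow).
  Under the null the draw ignores the codon entirely, so **any**
  downstream significant pair is a false positive by construction;
  `effect_injection` shifts $\psi$ (wrapped) for one codon's sites to
  create known positives for power studies.

What the generator does **not** emulate: position-dependent structure
(sites are i.i.d. given the amino acid), real Ramachandran fine structure
beyond two basins, correlated angles along the chain, missing residues,
or any true codon–angle mechanism. Passing tests therefore demonstrate
properties of the *method* (calibration, power, noise behaviour,
concordance under resimulation), not statements about real proteins.

## The audit itself

`relabel_codons()` performs the central manipulation: keep every
structural record, substitute the codon at each (gene, position) from a
re-simulated sequence set. `spearman_concordance()`,
`significance_overlap()` and `positional_agreement()` then mirror the
comparison metrics used in this literature: rank correlations of DDist
and p-values over shared tested pairs, counts of significant pairs in
both runs or only one (percentages relative to the observed run), and the
per-amino-acid percentage of sites keeping the same codon (with the
$100/n_a$ random-expectation reference; two independent uniform draws of
a 4-codon amino acid agree at ~25%, and independent draws from usage $p,
q$ agree at $100\sum_i p_i q_i$ %).

Because the permutation test is calibrated, a *null* synthetic study
yields few or no BH-significant pairs in either the observed or the
resimulated analysis; their DDist vectors nevertheless remain strongly
rank-correlated (the noise structure — per-stratum sample sizes and
densities — is shared), and an SMDE resimulation tracks the observed run
more closely per structure class than a uniform resimulation does,
because it preserves the per-codon sample sizes. That ordering is the
qualitative fingerprint the audit looks for; the overlap bookkeeping
reports empty significant sets as consistent runs, which is the correct
reading under FDR control.

## Numerical and degenerate-input policy

* Angles live in degrees on $[-180, 180)$; $+180$ remaps to $-180$.
* Probability evaluation uses a max-stabilised softmax; the likelihood
  returns $-\infty$ (flagged) if a structurally zero probability faces a
  positive count.
* The KDE clips FFT round-off negatives (magnitude ~1e-16) to zero and
  renormalises; grid integrals are exact to 1e-9.
* Permutation ties (`null >= observed`) count toward the p-value,
  keeping it conservative; `n_perm = 0` computes distances only.
* Strata below `min_n` are flagged untested and excluded from BH;
  untested pairs propagate `NA` statistics, never zeros.
* `empirical_mutation_params()` rejects reducible rate matrices (no
  unique positive stationary distribution).
* All stochastic stages draw per-gene / per-pair sub-seeds from one
  top-level seed, so results are byte-reproducible and independent of
  evaluation order.

## Problem sizes used by the tests and acceptance script

The packaged checks run the full pipeline at a deliberate desk scale,
chosen once as the smallest sizes at which the targeted properties are
statistically decidable: a 150-gene study (~45,000 residue records) for
the calibration and resimulation-concordance checks, which need the full
999-permutation analysis; a 300-gene study for the noise-correlation
diagnostic, which needs only distances and is otherwise underpowered in
the smallest structure class; 500 genes for sampler recovery; $10^5$
sites per family for simulation-frequency checks; 50 replicates of a
4-codon stratum (500 records per codon) for power. Headline numbers from genome-scale analyses of real structural
data (e.g. specific significant-pair counts) are not reproducible at this
scale and are not targets; the qualitative properties — calibration,
noise-signal correlation, SMDE-closest ordering — are.

## Known limitations

* The sampler is plain R and sized for hundreds of genes, not genomes.
* The angle test is a re-specification (TV distance + permutation), not
  a reimplementation of any published pipeline's internals; quantitative
  statistics are not comparable bit-for-bit with such pipelines.
* The mutation-empirical conversion ignores context-dependent mutation.
* Single-codon families (ATG, TGG) are structurally untestable and are
  excluded from pair enumeration.
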