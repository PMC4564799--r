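---
title: "Whole-plastome phylogenomics and molecular-clock dating with plastochron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-plastome phylogenomics and molecular-clock dating with plastochron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastochron)
```

## The analysis this package implements

plastochron re-implements, as one tested toolchain, the analysis design used
to resolve shallow plant phylogenies from whole chloroplast genomes — the
setting of the rice (*Oryza*) AA-genome group, where ten plastomes of
~134.6 kb differ by only a few hundred substitutions and the questions are
(i) the species tree, (ii) its robustness, and (iii) absolute divergence
times on a Pleistocene scale. The chain is:

1. **Alignment site statistics** — constant / variable /
   parsimony-informative / singleton counts and pairwise difference counts,
   with the out-group excluded and with two gap policies (gaps as missing
   data, or every gapped column deleted).
2. **Model selection** — AIC over nested time-reversible nucleotide models
   (JC, K80, HKY, GTR, each optionally +Γ and +I).
3. **Tree inference** — neighbour joining on model-based (GTR+Γ) distances,
   maximum parsimony with random-addition starts and
   tree-bisection–reconnection (TBR) branch swapping, and maximum likelihood
   by NNI search under GTR+G+I; nonparametric bootstrap, majority-rule
   consensus and out-group rooting.
4. **Bayesian divergence dating** — on the fixed rooted topology, a
   calibrated-Yule tree prior, strict or lognormal-relaxed clock,
   partitioned HKY + 4Γ likelihood, Metropolis–Hastings MCMC, and
   posterior summaries (mean, 95% HPD, ESS) per node.
5. **A synthetic plastome generator** providing ground truth for all of the
   above.

Everything methodological — NJ, Fitch parsimony and TBR, the pruning
likelihood with discrete-Γ and invariant sites, AIC counting, the Yule
prior, the MCMC and the HPD/ESS estimators — is implemented in this package.
`ape` supplies tree containers and Newick parsing, `IRanges` interval
algebra for GenBank-derived partitions, and `phangorn` appears only inside
the test suite as an independent cross-check.

## Models and conventions

**Substitution models.** A model is a scaled reversible rate matrix
`Q = S diag(π)` with exchangeabilities `S` and stationary frequencies `π`,
normalized so one unit of branch length is one expected substitution per
site; with a proportion `p_inv` of invariant sites the matrix is rescaled by
`1/(1 - p_inv)` so branch lengths keep that meaning. Transition
probabilities come from one symmetric eigendecomposition path for all
families (JC through GTR); the JC/K80 closed forms are used as oracles in
the tests rather than as a second code path. Discrete-gamma rates use the
mean-of-quantile-interval scheme (the convention of mainstream likelihood
software), renormalized to mean exactly 1. Gaps, `N` and IUPAC ambiguity
codes are missing data throughout: they contribute a partial-likelihood row
of ones, count as missing in site classification and pairwise differences,
and contribute their full compatible state set in Fitch parsimony.

**Coordinates.** All intervals exposed by the package are 0-based half-open;
GenBank's 1-based inclusive locations are converted exactly once, at parse
time. NEXUS-style `charset` lines (1-based inclusive) are likewise converted
on input.

**Distances.** The JC distance uses its closed form; K80/HKY/GTR (+Γ)
distances maximize the two-sequence likelihood over the divergence time
numerically, with base frequencies taken empirically from each pair and
exchangeabilities/shape from the supplied (typically pre-fitted) model.
Saturation (p ≥ 3/4 under JC, or no optimum below the search bound) raises
an error rather than returning infinities, and neighbour joining refuses
non-finite matrices.

**Neighbour joining** is the canonical Saitou–Nei agglomeration with
deterministic lexicographic tie-breaking; negative branch lengths are
clamped to zero with the total deficit recorded on the tree. **Parsimony
search** uses random-order stepwise addition followed by strict-improvement
TBR (bisect every edge; reconnect across all edge pairs), keeping all
equally parsimonious trees; ties anywhere break on a canonical topology
key, so a seed fully determines the result. **ML search** re-optimizes
branch lengths coarsely for each NNI neighbour and fully on acceptance;
branch optimization itself is exact coordinate-wise Brent search on the
single-branch likelihood, which cannot decrease the objective.

## The dating model

Node ages `t` (Myr, tips at 0), a birth rate λ, clock parameters and the
substitution parameters are sampled by Metropolis–Hastings. The Yule prior
on a labelled history is `(n−1)·log λ − λ·L` with `L` the summed branch
durations; the forward simulator draws waiting times `Exp(kλ)` while `k`
lineages exist, taking the present at the moment the `(n+1)`-th lineage
would arise, which is exactly the density above (for two tips the root age
is `Exp(2λ)`; simulator and prior agree by construction, and the tests
check the forward mean root age against `Σ_{k=2..n} 1/(kλ)`).

**Calibrations.** A calibration places a normal, lognormal or uniform
density on the age of a clade's MRCA. When that MRCA is the root — the
design of the mirrored study, which calibrates the split spanned by two
deep outgroup taxa at ~50 Myr — the package uses the exact conditional
construction: given the root age `t` and `n` tips, the non-root node ages of
a Yule tree are iid truncated-Exponential(λ) on `[0, t]` (this drops out of
the labelled-history density), so the prior factorizes as
`f_cal(t_root) × Yule(rest | root)` and the prior marginal of the root age
*is* the calibration density. Prior-only MCMC runs verify this to within
Monte-Carlo error. For non-root calibrations the standard multiplicative
approximation (Yule density times calibration density) is used; its root
marginal is only approximately the calibration.

**Clocks.** The strict clock has one rate `r` (substitutions/site/Myr); the
relaxed clock draws branch rates iid LogNormal(M, S), with S = 0 collapsing
to strict. Branch lengths passed to the pruning likelihood are
`duration × rate`, so doubling rates and halving ages leaves the likelihood
unchanged — the classic rate–time ridge. The move set therefore includes,
besides per-node uniform age slides, root and parameter scale moves, a
joint "up-down" move that scales all ages up and all rates down; it leaves
the likelihood exactly invariant and is what lets the chain travel along
the ridge to wherever the calibration pins it. Without it the sampler can
stall far from the calibration (we observed exactly this during
development), so it is on by default with a weight comparable to the age
moves.

**Parameter priors** (all overridable in spirit by editing the config):
λ ∝ 1/λ on [1e−6, 1e3], r ∝ 1/r on [1e−9, 1e2], κ ~ LogNormal(1, 1.25),
α ~ Exp(1), relaxed-clock S ~ Exp(1). These are the weakly informative
choices common in Bayesian dating software; the data dominate all of them
at plastome scale.

**Summaries.** The HPD is the narrowest contiguous window of sorted samples
holding ⌈0.95 n⌉ of them; the ESS is `n / (1 + 2 Σ ρ_k)` with Geyer's
initial-positive-sequence truncation. Because the topology is fixed, clade
summaries are exact and no MCC-tree search is needed.

**Fixed topology.** Unlike a full BEAST run, the topology is not co-sampled:
the mirrored study reports one topology congruent across NJ/MP/ML/Bayesian
criteria, and fixing it makes the dating stage fast and its calibration
experiments testable. This is a deliberate scope decision, not a
limitation of the MCMC machinery.

## The synthetic-data generator

`make_fixture("aa_like")` emulates the statistical shape of the mirrored
study's data:

* quadripartite plastomes (LSC 80,700 bp; SSC 12,400 bp; IR 20,800 bp;
  total 134,700 bp, inside the 134,563–134,911 bp band observed across the
  assembled genomes), with IRb emitted as the exact reverse complement of
  IRa after substitution sampling (perfect IR homogenization, matching the
  near-identity of real inverted repeats);
* a 10-taxon ingroup on a Yule tree rescaled to a 1.0 Myr crown, an
  outgroup diverging at 4.4 Myr, and a calibration pair spanning a 50 Myr
  root — the geometry of the published chronogram;
* a strict clock at 0.0016 substitutions/site/Myr, anchored on the printed
  pair of facts that two cultivated-rice plastomes separated ~0.68 Myr ago
  differ at ~296 positions over ~134.6 kb (and consistent with general
  plastome rates of 1–3 × 10⁻³ /site/Myr);
* HKY with κ = 3.5 and Γ shape 0.5 — transition-biased, moderately
  heterogeneous, typical fitted values for plastome data;
* indels as per-branch Poisson events (8 × 10⁻⁵ events/site/Myr, geometric
  lengths of mean 3 bp, insertions:deletions 1:1), restricted to branch
  segments younger than 5 Myr. The age cutoff stands in for the strong
  length conservation of plastomes over deep time: without it, tens of
  millions of years of unconstrained random indel drift would move total
  genome lengths far outside the narrow band real plastomes occupy.
  Ingroup node ages are additionally kept at least 0.05 Myr apart (then
  rescaled to the 1 Myr crown): the published divergence times are spaced
  by ~0.1 Myr and larger, whereas an unconstrained Yule draw occasionally
  places two splits so close that the intervening edge carries ~1 expected
  substitution genome-wide — an edge no method, on any data, could resolve.

Substitutions and indels are driven by two independent RNG streams derived
from the one seed, so switching indels off changes nothing about the
substitution outcomes at shared columns — an invariant the tests assert
directly. The generator does **not** emulate: alignment error (the emitted
alignment is the true one), rate variation among lineages beyond the chosen
clock, IR boundary shifts, sequencing or assembly artefacts, and
chloroplast capture / introgression. Passing tests on these fixtures
therefore demonstrate correctness of the inference machinery under the
stated generative model, not robustness to real-data pathologies such as
alignment ambiguity — which is why the site-count and dating comparisons
against the published numbers are kept as a separate, real-data validation
path that requires the deposited genomes.

## Problem sizes and numerical choices

The bundled analyses and tests use deliberately scaled problem sizes chosen
as the smallest that still exercise each claim: 6-taxon × 20 kb alignments
for clock-recovery experiments (20 replicates; every true node age should
fall in the 95% HPD in ≥ 90% of node × replicate cases), 50 kb for
parameter-recovery checks (κ within ±0.5, branch lengths within 10%),
exhaustive 105-topology parsimony oracles at 6 taxa, chains of 2–5 × 10⁴
Metropolis moves with thinning 10–20 for the synthetic datasets, and 50–100
bootstrap replicates in scripts (the package default follows the mirrored
study's 1000). MCMC defaults in `mcmc_config()` mirror the only chain
settings printed in that study (1.1 × 10⁶ steps, sampling every 200,
10⁵ burn-in). Branch-length optimization uses bounded Brent search with
tolerance 1e−8 per branch, cycling until the log-likelihood gains less than
the stated pass tolerance; all ties in search break lexicographically so
results are bit-reproducible across runs and platforms.

Degenerate inputs are defined errors, not silent results: saturated
distances, alignments left empty by gap stripping, exclusion below two
taxa, non-ultrametric age vectors, non-monophyletic calibration clades
(except pairs spanning the root, which legitimately calibrate the root age)
and unbalanced Newick all raise messages naming the offender.

## Known limitations

* ML topology search is NNI from an NJ start, not TBR-in-likelihood; at ten
  to thirteen taxa with genome-scale signal this reliably reaches the
  MP/NJ-congruent topology, but it is a local search.
* The relaxed clock is uncorrelated lognormal only, and relaxed-clock runs
  mix more slowly than strict ones (each branch rate is a parameter); the
  shipped chain lengths are sized for the synthetic datasets.
* The multiplicative calibrated-Yule construction for non-root calibrations
  is approximate (its prior marginal is tilted by the Yule density); only
  root calibrations get the exact treatment.
* `classify_sites` treats ambiguity codes as missing everywhere; software
  that partially resolves ambiguities may count a handful of sites
  differently on real data.
* The pipeline consumes pre-aligned FASTA; `align_with_mafft()` is an
  untested convenience hook around an external aligner, not part of the
  validated core.
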