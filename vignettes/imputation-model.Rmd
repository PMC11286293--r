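---
title: "Reference-free imputation for F2 crosses: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free imputation for F2 crosses: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossimpute)
```

## The problem

Structured crosses of inbred lines — a handful of founder lines, their F1
hybrids, and a large F2 cohort — are a standard design for mapping
phenotypes to genotypes. Sequencing every F2 individual deeply is wasteful:
the cohort carries only a small number of founder haplotypes, each of which
is collectively covered at high depth even when every individual is
sequenced at a fraction of 1x. Genotype imputation exploits this: it
reconstructs the founder-like haplotypes from the pooled low-coverage reads
and infers each individual's diploid genotype from them, without any
reference panel.

`crossimpute` packages this analysis end to end on synthetic data: a
simulator for multi-parent F2 cohorts, the imputation engine itself, the
iterative refinement of the imputable SNP set, concordance evaluation
against held-out high-coverage ("truth") samples, and the design-space
machinery — depth/sample/cross downsampling and a sequencing cost model —
needed to answer the practical question "how much coverage do I buy for how
many samples?".

## The copying model

The engine is a diploid Li–Stephens haplotype-copying hidden Markov model
combined with EM re-estimation of a panel of `K` ancestral haplotypes.

The parameters are a `K x T` matrix $\theta$, with $\theta_{k,t}$ the
probability that ancestral haplotype $k$ carries the alternate allele at
SNP $t$, and a weight vector $\alpha$ over haplotypes. Each sample's two
chromosomes are modelled as two independent copying chains over the $K$
haplotypes, giving a joint state space of $K^2$ ordered pairs. Across the
interval between adjacent SNPs, each chain jumps (resamples its haplotype
from $\alpha$, current haplotype included) with probability

$$\rho_t = 1 - \exp(-n_\mathrm{gen}\, r\, d_t / 100),$$

where $r$ is the recombination rate in cM/Mb, $d_t$ the interval length in
Mb, and $n_\mathrm{gen}$ the number of meioses separating the cohort from
the founders (2 for an F2). This is a Haldane-style conversion of the
accumulated genetic distance into a jump probability; chromosome boundaries
get $\rho = 1$ so chains reset between chromosomes.

**Emission.** At a site with state $(k_1, k_2)$, the two allele copies are
latent Bernoulli draws $a_c \sim \mathrm{Bern}(\theta_{k_c,t})$ and the
read stack depends on their sum: each of the $r + a$ reads is an alternate
read with probability $\tfrac{g}{2}(1-\varepsilon) +
(1-\tfrac{g}{2})\varepsilon$ given genotype $g = a_1 + a_2$, with
$\varepsilon$ the per-read error. The emission marginalises $a_1, a_2$.
An alternative found in this model family treats every read independently
with success probability $(\theta_{k_1} + \theta_{k_2})/2$; the two forms
coincide whenever a site carries at most one read (the majority of sites at
~1x coverage). We use the marginalised form deliberately: with explicit
latent allele copies, the alternation below is an *exact* EM, so the total
log-likelihood is provably non-decreasing — a property we test.

**E-step.** A scaled forward–backward pass per sample yields the joint
state posteriors $\gamma_t(k_1,k_2)$ and the exact log-likelihood. The
recursion exploits the product structure of the transition kernel, so a
pass costs $O(K^2)$ per site rather than $O(K^4)$. Correctness is checked
against exhaustive enumeration over all $(K^2)^T$ state paths on small
instances.

**M-step.** Each haplotype's dosage is re-estimated as the expected number
of alternate alleles carried by chains copying it, divided by the expected
number of copying chains:
$\theta'_{k,t} = \sum_i \mathbb{E}[a\,\mathbb{1}(\text{chain copies }k)] /
\sum_i \mathbb{E}[\mathbb{1}(\text{chain copies }k)]$, where the allele
responsibilities condition on the site's reads. Sites at which a haplotype
receives no posterior mass keep their previous value, and $\theta$ is
clipped to $[10^{-4}, 1-10^{-4}]$ to avoid degenerate likelihoods. For
$\alpha$, the default update is the exact M-step — normalised expected
landings of the copying jumps (plus the initial draws) — which preserves
the monotonicity guarantee; a classical "mean marginal usage" update and a
fixed-uniform mode are also available (`alpha_update` in [hmm_params()]).
$\theta$ is initialised Uniform(0.1, 0.9) from one explicit seed that
governs all randomness of a run.

**Output.** A final E-pass converts posteriors into per-sample genotype
probabilities $P(g)= \sum_{k_1,k_2}\gamma(k_1,k_2)\,P(g \mid
\theta_{k_1},\theta_{k_2})$, dosages $P(1) + 2P(2) \in [0,2]$, and an
IMPUTE-style per-site info score
$1 - \overline{\mathrm{Var}(g)} / (2\hat f(1-\hat f))$ with $\hat f$ the
estimated allele frequency; the score is reported as `NA` where $\hat f$ is
0 or 1. The info score formula is our choice of the standard
posterior-variance measure; the family of pipelines this follows names the
metric without fixing a formula.

**Refill heuristic (off by default).** At one quarter and one half of the
iterations, haplotypes with mean usage below $1/(4K)$ can be re-seeded from
the most-used haplotype plus Uniform(−0.1, 0.1) noise. This is a simplified
stand-in for the re-seeding heuristics of mature imputation software; it
breaks the monotone-likelihood guarantee and is therefore excluded from the
monotonicity tests. The block-shuffling heuristics of that software
(proposing segment swaps between haplotype pairs) are deliberately not
implemented.

## What the simulator emulates

The generator mirrors the structure of a real multi-parent medaka F2
cohort:

* **Founders.** `n_lines` inbred lines; at each SNP a population
  alternate-allele frequency is drawn Uniform(0.05, 0.95) and each line's
  consensus allele is sampled from it, with sites redrawn until every site
  is polymorphic across the panel. The uniform prior is chosen so the
  cohort exhibits the full minor-allele-frequency spectrum needed for
  MAF-binned evaluation. A fraction `residual_het` (default 0.01) of
  (line, site) pairs is made heterozygous: inbred lines are never perfectly
  homozygous, and no measured value exists for the real lines, so 1% is a
  fixed, configurable choice.
* **Cross structure.** The reference design ([medaka_cross_design()]) is
  the 10-cross, 8-line design with its published per-cross F2 counts
  (2209 F2, of which 2 are high-coverage, leaving 2207 low-coverage
  samples) and 12 truth samples (one F1 per cross plus two F2 from the
  first cross). F1s are formed from one gamete of each parental line, F2s
  from two gametes of two distinct F1s, so two meioses separate every F2
  haplotype from the founders. Crossovers are Poisson
  (`exp_rate x Mb / 100`) with uniform positions.
* **Reads.** Per-sample depths are Gamma-distributed (CV 0.5) around the
  target mean to emulate the heterogeneous depths of multiplexed
  sequencing; truth samples get a fixed 40x (the real truth samples were
  sequenced at 33–61x). Read counts are Poisson per site; alternate-read
  probabilities incorporate a per-read error of 0.01, a typical post-filter
  short-read error rate. A fixed-depth mode (`depth_cv = 0`) exists for
  tests.

What it does *not* emulate: read-level sequences (no FASTQ), alignment or
duplication artefacts, library-preparation bias, depth correlation along
the genome, genotyping error in the truth samples, or segmental
duplications and partially inbred regions. Passing tests on this generator
therefore demonstrate the statistical machinery under the model's own
assumptions, not robustness to those real-data artefacts.

The default genome is desk-scale — one 5 Mb chromosome with 1000–2000 SNPs
— chosen so a full pipeline run completes in minutes; a genome of
real-medaka scale (24 chromosomes, 734 Mb) is expressible but not a
default.

## SNP-set refinement and evaluation

The imputable SNP set starts from sites polymorphic among the truth
samples (minor allele count ≥ 1). Each refinement round thins the truth
samples' reads to 0.5x, imputes the whole cohort jointly, scores every SNP
by the squared Pearson correlation between the truth samples' imputed
dosages and their true genotypes, and drops SNPs below the round's
threshold. The default schedule is five rounds at 0.5, 0.5, 0.75, 0.9,
0.9. SNPs with undefined r² (monomorphic among truth samples after
thinning) cannot be validated and are dropped. r² is computed on dosages,
not hard calls, matching dosage-based concordance tooling.

Evaluation reports the squared Pearson correlation per truth sample across
sites (averaged into one figure per run) and pooled within MAF bins of
width 0.05, where within a bin all (site, sample) pairs enter one
correlation and the bin is labelled by the mean observed MAF of its member
sites. Observed MAF comes from the truth samples' genotypes by default
(the imputed cohort's dosages are an alternative source); with 12 truth
samples the MAF grid is coarse, which is visible in the bin occupancy of
small runs.

## Design exploration

* **Depth downsampling** is per-read binomial thinning with factor
  `f = d_target / d_original`, capped at 1 (samples already below target
  are untouched) — the in-simulation analogue of subsampling alignments.
  When a cohort keeps its original depth, truth samples are still thinned
  to 0.5x before joint imputation so their evaluation is not inflated by
  their high coverage.
* **Sample downsampling** retains all truth samples and fills the rest
  uniformly at random, ignoring cross membership.
* **Cross downsampling** removes whole crosses (truth samples included) in
  a configurable line order; with the reference design and default order
  the (lines, crosses) sequence is (7,9), (6,7), (5,6), (4,4), (3,3),
  (2,1), ending at the single 72-2 x 55-2 cross.
* **K rule.** `K = 2 x` number of founder lines (16 for eight lines, 4 for
  a single cross), re-applied whenever lines are removed.
* **Cost model.** `cost(n, d) = (n d g / f) cf + n cp` with genome size
  `g`, per-flow-cell output `f`, and flow-cell/library unit costs
  `cf`, `cp`. Defaults are the reference constants (g = 734,040,372 bp,
  f = 273,542,732,637 bp, cf/cp = 683.89, costs in per-library units);
  sequencing is treated as continuously divisible — no flow-cell packing.
  At these constants, sequencing a 2177-sample cohort at 0.5x instead of
  1.4x costs 53.7% of the original.
* **Sweep.** [sweep_design()] crosses a grid of cohort sizes and target
  depths (replicated over random subsamples), imputes each scenario, and
  reports mean per-truth-sample r² against relative cost.

## Numerical choices and degenerate inputs

* Scaled (normalised) forward–backward recursions; log-likelihood from the
  scaling constants, exact to machine precision against enumeration.
* Zero-variance guards: r² and info score return `NA` rather than a value
  wherever a correlation or frequency is degenerate; `NA` r² counts as
  "below threshold" during refinement.
* K-scan ties break toward the smaller `K` (cheaper and less prone to
  overfitting); label assignment in haplotype-recovery diagnostics breaks
  ties by total absolute error.
* EM runs a fixed number of iterations (default 100) by default;
  `tol > 0` enables early stopping on the relative log-likelihood
  increase, which the sweep machinery uses.
* Empty read stacks are exact no-ops throughout (emission 1, dosage driven
  by the copying posterior alone).

## Problem sizes used by the test suite

The suite simulates every fixture: typical unit-test cohorts are 10–50
samples x 40–300 sites; the property tests use a 400-F2 single cross at
2000 sites (parameter recovery), a 50 x 200 cohort (EM monotonicity), a
10-cross scaled design of ~130 samples x 500 sites (refinement), and an
18-run sweep over five 2 Mb chromosomes with 400 SNPs each (trade-off
shape; the dense 200 SNPs/Mb map keeps the scaled-down cohort in the
information regime where accuracy plateaus with depth, and nine truth
samples stabilise the per-scenario mean). These sizes are the package's
chosen desk scale: large enough for the statistical assertions'
tolerances, small enough to run routinely.

## Known limitations

* **Haplotype point recovery.** With more ancestral haplotypes than
  distinct founder haplotypes (e.g. K = 4 on a two-line cross), plain EM
  converges to local optima in which founders are represented by
  complementary blends or label-switched mosaics of haplotype pairs. The
  imputed genotypes are essentially unaffected (mean per-sample r² stays
  above 0.97 in that regime) because the blend spans the same space, but
  the point estimate $\theta$ of individual founder haplotypes can differ
  from any single founder by a mean absolute error of ~0.1 or more. The
  segment-shuffling heuristics that mature imputation software uses to
  escape these optima are out of scope here, and the optional refill
  heuristic does not trigger in this regime (all haplotypes retain
  usage above its 1/(4K) threshold). Users who need founder haplotypes as
  point estimates, rather than imputed genotypes, should treat
  `theta_final` with caution.
* The diploid chain is exact over the $K^2$ joint space, which is the
  right trade-off up to K ≈ 24; far larger K calls for the factorised
  approximations used by production tools.
* **Refinement at small scale.** With only a dozen truth samples, per-SNP
  r² is a noisy statistic, and the 0.9-threshold rounds of the default
  schedule discard many adequately imputed SNPs in small cohorts; the
  dropout is then not MAF-neutral (rare or oddly configured SNPs have
  noisier r²). MAF-neutral dropout, as observed in well-powered cohorts,
  should not be expected below roughly a thousand samples.
* **Short single-chromosome genomes.** With a 2 cM/Mb map, a single 5 Mb
  chromosome carries ~0.1 crossovers per meiosis, so a large fraction of
  simulated F2s inherit one intact chromosome from each parent and are
  heterozygous at almost every site. Such samples have (nearly) constant
  true genotypes and a degenerate per-sample r². Multi-chromosome genomes
  (used by the heavier tests) avoid this.
* **Where the depth plateau lives.** Accuracy as a function of coverage
  plateaus only once the cohort is large enough that the ancestral
  haplotypes are deeply covered in aggregate; for a 400-sample cross at
  desk scale the curve is still rising at 1×, and whether the marginal
  gain of the second depth doubling falls below the first depends on the
  cohort draw. Expect clear flattening only for cohorts of roughly a
  thousand samples or more.
* The cost model knows nothing about flow-cell granularity, batching or
  price breaks; it is a smooth guide, not a quote.
* All accuracy statements are on synthetic data from the generator above;
  absolute r² values on real cohorts depend on founder divergence,
  inbreeding completeness and sequencing artefacts that the generator does
  not model.
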