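---
title: "Methods: a probabilistic model of transcription-network evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a probabilistic model of transcription-network evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnevo)
```

## The inference problem

Given N species with known phylogeny, each orthologous gene group
carries a hidden binary vector Z: whether the gene is a target of the
focal transcription factor in each species. Three kinds of evidence bear
on Z, and the package's likelihood combines them under one assumption:
*conditional on Z, a gene's promoter sequence and its expression are
independent*. The likelihood of group m is

    P(S_m, E_m) = sum over configs z of
        P(z | T, lambda, mu, pi) *
        prod over species i of P(S_mi | z_i) * P(E_mi | z_i)^w

and the dataset likelihood is the product over groups. Everything
downstream — EM fitting, MAP decoding, rewiring rates, permutation
nulls — is built on this sum, which `group_loglik()` evaluates in log
space with log-sum-exp (the 20 kb-scale sequence terms make linear-space
products underflow).

## The phylogenetic prior

Z evolves along the tree as a two-state continuous-time Markov chain
with gain rate `lam` and loss rate `mu` per unit divergence time; branch
lengths are taken from the Newick input as-is, so rates are implicitly in
the same time unit. The 2x2 transition matrix has the closed form
P(0->1, t) = (lam/(lam+mu)) (1 - e^-(lam+mu)t); we use the closed form
for speed and keep a scaling-and-squaring matrix exponential in the test
suite as an independent oracle.

The probability of a leaf configuration marginalizes ancestral states by
Felsenstein pruning. On a star tree this reduces to a root-weighted
product of per-path transition probabilities; on shared-branch
topologies only the ancestral-state summation yields a normalized
distribution over the 2^N configurations, and an exhaustive-enumeration
oracle (`leaf_config_probability_bruteforce()`) pins this semantics in
the tests. The root prior `pi` is a free parameter by default and can be
tied to the stationary distribution lam/(lam+mu) (`tie_root = TRUE`). On
short trees with few taxa, `pi` and the stationary fraction are nearly
confounded (the data constrain the leaf marginals, which either can
produce), so recovery experiments use the tied parameterization; free
`pi` remains the default for data analysis, where the root state is a
quantity of interest.

## The sequence likelihood

Rather than a full HMM forward pass, the sequence model summarizes each
window by a motif scan — the approximation is part of the model. The
scan scores every offset on both strands with the PSSM's log
likelihood-ratio against the background composition, calls segments that
reach a threshold, and resolves overlaps greedily by descending score
(ties: leftmost, then forward strand). Greedy non-overlap keeps
N_b + N_m * width an exact partition of the window, which the likelihood
requires. With q the probability that a hidden position-state in a
*target* promoter is a motif,

    log P(S | Z=1) - log P(S | Z=0) = N_b log(1-q) + N_m log q + log R.

Choices a user can tune, with defaults and rationale:

* **Calling threshold** — 60% of the PSSM's maximum achievable score.
  A fraction of the maximum is scale-free across motifs of different
  width and information content; an absolute threshold is accepted too.
  For an 8-mer this admits roughly 0.3 chance calls per 500 bp of random
  background, which the q-aware likelihood absorbs; raising the fraction
  to 0.8 drives false calls to near zero at the cost of sensitivity.
* **Window selection** — the representative 500 bp window of a long
  regulatory region is the one maximizing the target-vs-background
  log-likelihood difference above, evaluated every 250 bp (half-overlap)
  plus a flush-to-end window; ties go leftmost. The selected window's
  statistics stand in for the whole region.
* **Strands and ambiguity** — both strands are scanned (binding is
  strand-agnostic; a hit's strand is recorded but not modeled); `N` bases
  score zero and count as background.
* **Multiple TFs** — `pool_scans()` sums N_m and log R across per-motif
  scans and recomputes N_b, following the product form of the
  multi-matrix likelihood. Natural logarithms are used throughout.

## The expression likelihood

Expression enters "softly", through cluster membership: each species'
genes are clustered independently (the built-in route is per-gene
z-scored profiles + `stats::kmeans`; externally produced labels are
accepted as TSV, and cluster counts K may differ per species — 27/22/26
in the motivating mammalian analysis). A target's cluster index follows
theta1, a non-target's theta0, per species. The weight w is a fixed
exponent on this term, never estimated: it compensates for the gross
scale difference between a 500 bp sequence log-likelihood and a single
categorical log-probability. w = 1 is the default; w = 0 removes
expression entirely.

Genes in singleton clusters carry no co-expression information and can
be dropped (`drop_singletons`); the CV filter (`filter_by_cv()`, default
threshold 1.26) removes groups with no clear expression change before
clustering, mirroring standard practice for developmental time courses.

## EM estimation

The E-step computes each group's posterior over all 2^N configurations
(one vectorized matrix operation per dataset). The M-step updates

* `q` in closed form: expected motif count over expected motif-plus-
  background count among targets;
* `theta0`, `theta1` in closed form from posterior-weighted label counts
  with a pseudocount (default 0.5 per cluster) that keeps empty clusters
  off the log(0) boundary. The pseudocount is divided by w so that the
  update exactly maximizes the penalized objective block;
* `lam`, `mu`, `pi` by bounded Nelder-Mead (log / logit scale, rates
  clamped to [1e-6, 1e3]) on the expected log configuration-prior,
  started from the current values and accepted only on improvement.

Treating the leaf configurations as the hidden variables makes every
step a proper (generalized) EM step, so the objective — the data
log-likelihood plus the theta pseudocount regularizer — is monotone
non-decreasing; `tn_fit()` records it as `$trace` and reports the raw
log-likelihood separately. A closed-form `pi` update from root-state
posteriors is possible under the all-node-states decomposition, but
mixing it with a configuration-marginal rate step would forfeit the
monotonicity guarantee, so the package optimizes the three rate
parameters jointly. Convergence is declared when the objective gains
less than `tol` (default 1e-6, 100-iteration cap). Initialization is
data-driven (marginal scan counts for q, sequence-evidence-weighted
label frequencies for theta); `n_restarts` adds seeded jittered restarts
for multimodal surfaces, though the simulated scenarios converge from
the default start in well under 20 iterations.

Degenerate inputs are handled explicitly: non-finite likelihoods abort
with a diagnostic, empty clusters are absorbed by the pseudocount, and
MAP ties break toward the lexicographically smallest configuration so
decoding is deterministic.

## Rewiring statistics

`classify_conservation()` maps a MAP configuration to conserved-in-all /
conserved-in-all-but-one / species-specific / non-target (plus `mixed`
for N > 4). The rewiring rate is 1 minus the conserved-in-all fraction;
the denominator is explicit because two conventions are defensible — all
analyzed groups (the default, matching the published 100% - 55.3% =
44.7% arithmetic) or only groups with at least one link (matching the
verbal "among all TF-target links" reading). `permutation_null()`
shuffles PSSM rows and columns independently (once each per replicate),
rescans, refits, and re-decodes through the identical code path, so the
identity permutation reproduces the observed rate exactly; the null mode
is read from a 0.05-wide histogram.

## What the simulator emulates

`tn_scenario()` crosses two sequence-signal levels with three
expression-signal levels — the six canonical scenarios. Defaults, chosen
once as a realistic desk-scale testbed: 3 species on
`((sp1:0.25,sp2:0.25):0.15,sp3:0.40)` with lam = mu = 0.5 and pi = 0.5
(target fraction 1/2 and appreciable per-branch turnover, so every
conservation category is populated); an 8 bp motif with consensus
probability 0.85 (strong) / 0.75 (weak); target motif rate q = 0.012 /
0.008; K = 6 clusters with theta1 diverging from uniform theta0 by
total-variation 0.6 / 0.3 / 0.1 (strong/medium/weak); 500 bp windows.
The weak levels were calibrated once so that weak/weak decoding accuracy
is intermediate — clearly above the ~0.52 majority-state baseline and
clearly below the ~0.96 of strong/strong; at these settings it sits near
0.7.

Motifs are planted by letting each background position open a PSSM draw
with probability q (overlapping candidates dropped left-to-right) — a
first-order approximation of the segment chain whose adequacy the
round-trip suites bound. Expression is simulated at the label level
because the model only consumes labels; a Gaussian profile generator
exercises the clustering path separately. All randomness flows through a
scenario seed and derived per-component streams, so regeneration is
bit-identical.

What passing simulations do *not* show about real data: real promoters
are not i.i.d. background (repeats, CpG islands, composition gradients
inflate false motif calls), real motif instances are not independent
PSSM draws, real co-expression clusters are neither uniform nor equally
sized across species, and the true generative process for regulatory
evolution need not be a homogeneous two-state chain. The simulation
validates the inference machinery, not the biological adequacy of the
model.

## Weight limits and cross-validation

At w = 0 the expression term vanishes and fitting/decoding coincides
exactly with the sequence-only model. At large w (checked at w = 50) the
decoded states coincide with the expression-only model *run at the same
exponent*: that comparator isolates the presence of the sequence term as
the only difference. An expression-only fit at w = 1 is a genuinely
different estimator — the weighted theta updates sharpen toward hard
cluster assignments as w grows — and agrees with the w = 50 joint fit on
only ~71% of states, which is why the package compares like with like.

`crossvalidate()` partitions groups into seeded folds, fits on the
training folds at each weight in the grid, and scores MAP decodings
against the simulation truth on both sides. Across the six scenarios at
M = 500 and five folds the train/test accuracy gap stays within 0.05 at
every weight — the model's resistance to overfitting, which follows from
its small parameter count relative to M.

## Problem sizes and numerical conventions

The shipped suites run the six scenarios at M = 500 groups, parameter
recovery at M = 2000, permutation nulls at M = 200 with 50 replicates,
and distributional checks at M = 20000 draws; these sizes make the
Monte-Carlo error small relative to the tolerances while keeping a full
run on one CPU in minutes. Probabilities are computed in log space with
log-sum-exp wherever sequence terms appear; config-prior pruning over at
most 2^6 configurations is done in linear space, where magnitudes are
benign. Exported coordinates are 0-based half-open (BED convention);
internal hit positions are 1-based R indices.

## Known limitations

Two regulatory states only (no activator/repressor distinction, no
combinatorial TF states); no missing-data imputation — groups must be
complete across species; the scan approximation discards sub-threshold
motif evidence, biasing fitted q below a generative motif rate when
instances straddle the threshold; ancestral states are marginalized, not
reconstructed; and divergence times are taken as known, not estimated.
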