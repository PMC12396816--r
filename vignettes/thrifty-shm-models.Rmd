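---
title: "Modeling somatic hypermutation with thrifty convolutional models"
author: "thriftySHM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling somatic hypermutation with thrifty convolutional models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thriftySHM)
```

## The modeling problem

Somatic hypermutation (SHM) introduces point mutations into B-cell receptor
(BCR) genes at a rate far above background, and those mutations are strongly
biased by local nucleotide context (the classic AID hot- and cold-spot
motifs). A neutral model of this process is the substrate for almost every
downstream repertoire analysis: detecting selection, forecasting the
accessibility of antibody mutations, and interpreting affinity maturation.

The data unit is a *parent-child pair* (PCP): two aligned, gap-free
nucleotide sequences corresponding to one edge of a clonal-family phylogeny,
with the rootward (ancestral) sequence as parent. Because productive
receptors are shaped by germinal-center selection, neutral training data
come from out-of-frame rearrangements, or--for in-frame sequences--from
fourfold-degenerate synonymous sites only.

For each site $i$ of a parent we model mutation as an exponential waiting
time with rate $\lambda_i$ and, conditional on a mutation, a categorical
choice among the three non-parent bases with probabilities $\mathbf p_i$
(the *conditional substitution probability*, CSP). Sites are independent
given the parent sequence, and all mutations on a branch are treated as
simultaneous: every site's context is read from the parent. A pair's
evolutionary time enters through a branch length $t \ge 0$, giving the
offset-scaled parameter $\tilde\lambda_i = t\lambda_i$ and the per-site
substitution probability

$$ p_i = 1 - e^{-t\lambda_i}. $$

By default $t$ is the *normalized mutation count*: mutated informative
sites divided by informative sites, with masked sites excluded from both
numerator and denominator. It can also be re-optimized per pair by maximum
likelihood (`optimizeBranchLength()`), which evaluation always does so that
scores are comparable across pairs.

## Thrifty architectures

A $k$-mer rate table needs $4^k$ parameters, so widening the context
explodes exponentially. The thrifty construction instead embeds each
overlapping 3-mer of the parent into a trainable $E$-dimensional space
(`tokenize3mers()`; 64 unambiguous 3-mers plus one ambiguity token for
windows touching N or a sequence boundary), slides a biased width-$K$
convolution with $F$ filters over the embedded sequence (symmetric zero
padding, so every site gets a prediction), applies a rectifier, and feeds
two affine heads: a scalar rate head (exponentiated, so rates are
log-linear and the offset acts additively in log space) and a 5-output CSP
head (softmax after forcing the ambiguity column and the parent base to
$-\infty$). Because the outer 3-mers extend one base beyond the kernel
span, the effective context is $K + 2$ nucleotides -- kernel 11 is a
13-mer model. Parameters grow *linearly* in $K$.

The rate and CSP outputs can share structure in three ways:

* **joined** -- one embedding + convolution stack feeds both heads;
* **hybrid** -- a shared embedding with one convolution per head;
* **independent** -- a rate sub-model and a CSP sub-model with two
  embedding + convolution branches combined by element-wise addition
  before the CSP head.

With a 65-row embedding table ($65E$), a biased convolution ($EFK + F$),
and heads of $F+1$ and $5F+5$ scalars, these wirings reproduce the
reference parameter counts exactly: 2057 for the joined (11, 7, 19) model
and 4539 / 5931 for the independent (9, 7, 16) and (11, 7, 19) models
(`countParams()`, verified against exhaustive weight enumeration). The
allocation of the independent wiring's third stack to the CSP sub-model,
combined by addition before the head, is our choice among the
under-determined alternatives: it is the simple decomposition that
reproduces all three printed counts while keeping the CSP head input width
$F$. The rectifier nonlinearity and the placement of dropout (after the
nonlinearity, before the heads) are likewise conventional choices; both
are parameter-free, so counts are unaffected.

Two table baselines are included: `buildFivemerModel()` (1024 unambiguous
5-mers plus an ambiguity token; lookup is the whole forward pass) and
`buildSitewiseFivemerModel()`, which multiplies a 5-mer table by a
per-site factor over a fixed site range. The per-site log factors carry a
squared-magnitude penalty with coefficient $10^{-4}$, enough to keep the
per-site component from absorbing context effects without visibly biasing
a well-identified fit. These baselines use their own parameterization and
document their own counts; no externally reported count is claimed for them.

## Training

The loss for one pair sums two parts over loss-masked sites
(`pcpLoss()`):

* placement: the Bernoulli negative log-likelihood of the mutation
  indicators under $p_i = 1 - e^{-t\lambda_i}$, computed with `expm1` so
  small rates do not lose precision ($\log(1-p_i)$ is exactly
  $-t\lambda_i$);
* base identity: cross-entropy of the observed child base under the CSP
  row, weighted by `cspWeight = 0.01` to approximately even out the two
  contributions. A CSP that assigns zero mass to an observed base yields
  an explicit infinite loss, never a clipped one.

Losses are summed per pair and averaged over the pairs of a mini-batch;
`trainModel()` minimizes them with Adam (default learning rate $10^{-3}$,
100 epochs, batch 32) through a hand-written backward pass whose analytic
gradients are verified against finite differences in the test suite.
Pairs with zero observed substitutions are excluded from training -- their
offset is 0, so they contribute no gradient -- but retained for
evaluation. Dropout (probability from the model configuration) is active
only during training; every evaluation pass is deterministic. With
`jointBranchOpt = TRUE` each gradient epoch is followed by per-pair
branch-length re-optimization; the once-per-epoch alternation schedule is
our choice. The per-pair-summed (rather than per-site-averaged) loss is
also a choice; it only rescales the effective learning rate. Training
with `lossSites = "fourfold_synonymous"` first restricts every loss mask
to fourfold-degenerate third codon positions (`fourfoldDegenerateMask()`,
derived from the standard genetic code; codons containing N and trailing
partial codons are wholly masked).

## Evaluation

`evaluateModel()` pools informative sites whose 0-based index lies in an
inclusive window (default 80-319, a region well covered by typical bulk
IgH libraries; the coordinate base of the window is our convention, stated
once). Scores are substitution probabilities under per-pair
likelihood-optimized branch lengths. The report contains:

* **AUROC** via the rank-sum identity (exactly the all-pairs statistic,
  ties counted 1/2);
* **AUPRC** as uninterpolated average precision with a deterministic
  (pair, site) tie-break -- linear interpolation is known to flatter
  classifiers. Its random baseline is the prevalence $\rho$;
* **R-precision**, micro-averaged as total hits over total $R$ across
  pairs ($R$ = the pair's observed mutation count); the aggregation rule
  is our choice, as only the per-pair definition is standard;
* **substitution accuracy** (argmax of the CSP row vs the observed base,
  alphabetical tie-break);
* a **binned observed/expected fit**: 20 bins, equal width in
  $\log_{10}$ probability across the pooled score range (zero scores fall
  in the lowest bin), with the overlap statistic
  $\sum_b \min(O_b, E_b) / \tfrac12(\sum_b O_b + \sum_b E_b)$;
* the mean per-site log-likelihood (placement over all window sites plus
  CSP at mutated sites, divided by window sites) and $\rho$ itself.

Whether sites should be ranked by $\lambda$ or by $p$ is not determined a
priori; we rank $p$ with optimized $t^\ast$ because the calibration
assessment is defined on per-site substitution probabilities, and
monotone-transform invariance makes the choice irrelevant within a pair.

## The simulator and what passing tests mean

`simulateDataset()` draws parents (i.i.d. uniform bases, an optional fixed
germline, or in-frame parents that start with ATG and avoid in-frame stop
codons), branch lengths from a configurable law, and children site by site
under a known `TrueModel` (a $k$-mer rate table plus CSP rows). Contexts
are always read from the parent, matching the simultaneity assumption of
the likelihood. Boundary and ambiguous contexts fall back to the table's
geometric-mean rate and a uniform CSP -- a neutral, documented choice.
Stored branch lengths are recomputed as normalized mutation counts, as in
the real pipeline, with the true branch lengths kept in the provenance.

Defaults are chosen to resemble repertoire data: rates log-normal with
$\mathrm{sd}(\log\lambda) = 1$ (hot and cold contexts separated by roughly
two orders of magnitude, as in empirical mutability tables), CSP rows
Dirichlet with a transition-biased base measure $(12, 2, 2)$, and branch
lengths log-uniform on $[0.005, 0.1]$, spanning the per-pair mutation
loads typical of clonal-family edges.

The simulator emulates the *assumed* generative process. It does not
emulate sequencing error, UMI effects, selection leaking into out-of-frame
data, spatially correlated mutation, indels, or phylogenetic
reconstruction error in ancestral sequences. Passing recovery and
calibration tests therefore demonstrates correctness of the estimator
under its own assumptions -- not that real SHM obeys those assumptions.

### The parameter-recovery experiment

The recovery experiment trains a K=1 thrifty model (an effective 3-mer
model) on 50,000 simulated sites (125 pairs of 400 nt) from a seeded 3-mer
truth and asks for per-3-mer rate rank correlation above 0.95 and mean CSP
total-variation distance below 0.05. Its design was fixed by an a-priori
power analysis: with 50,000 sites, the CSP criterion needs on the order of
100+ observed mutations per 3-mer before even the maximum-likelihood
estimator meets it, so the experiment uses a fixed branch length
$t = 0.4$ -- deliberately above the simulator's default law, which models
field-typical mutation loads, because a recovery experiment is powered for
identifiability, not for data realism. The experiment uses the
independent wiring: with a shared trunk, placement gradients (unweighted)
dominate the $0.01$-weighted CSP gradients, and CSP convergence within 100
epochs becomes erratic; a dedicated CSP stack removes the competition
because Adam's per-parameter scaling is invariant to the uniform $0.01$
factor. The experiment's optimizer settings (learning rate 0.02, batch 8)
were likewise chosen for convergence of this small model; package-wide
training defaults are unchanged.

## Numerical and degenerate-input choices

* Coordinates are 0-based and ranges inclusive throughout (tokens,
  windows, site ranges); one convention, stated once.
* `substitutionProbability()` uses `-expm1(-t*lambda)`; the small-rate
  limit is exact to first order.
* Branch-length optimization root-finds the strictly decreasing derivative
  of the log-likelihood on $[0, 5]$ (tolerance $10^{-10}$ on $t$); pairs
  with no mutations return $t^\ast = 0$, and a derivative still positive
  at the bracket edge returns $t_{\max}$.
* Gapped sequences are rejected at load time; sequences with N anywhere
  have those sites force-masked, and a pair with zero informative sites is
  an error wherever $t$ must be computed.
* Argmax and ranking ties break deterministically (alphabetical bases;
  (pair, site) order for ranking), so reports are reproducible.
* All stochastic entry points (weight initialization, simulation,
  training, scans) take explicit seeds, save and restore the caller's RNG
  state, and are bit-reproducible on one device; model serialization
  writes doubles as 17-significant-digit text so save/load round-trips
  exactly.

## Problem sizes used by the test suite

The suite exercises full training only at small scale: the recovery
experiment above (50,000 sites, ~100 seconds), a separable toy problem
whose loss must approach its analytic entropy floor, and short smoke runs
elsewhere. Metric oracles use exhaustive enumeration at $n \le 50$ and
Monte Carlo with closed-form finite-sample expectations at $n = 2000$.
These sizes are the package's choices for a reproducible desk-scale suite.

## Known limitations

* No GPU or multi-device training; the backward pass is plain R matrix
  algebra, entirely adequate for models with a few thousand parameters but
  not for transformer-scale variants (which are out of scope).
* The 5-mer and per-site baselines use this package's parameterization;
  externally reported parameter counts for third-party implementations of those
  baselines are not reproduced.
* Clonal-family inference, multiple alignment, phylogenetic inference and
  ancestral reconstruction are upstream of this package; trees and node
  sequences must be supplied.
* Real-data headline metrics require the original repertoire datasets and
  are not part of the test suite.
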