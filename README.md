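# thriftySHM

Context-dependent models of somatic hypermutation (SHM), the process that
diversifies B-cell receptor (BCR) genes during affinity maturation. The
package is for immunologists and computational biologists who need a
neutral SHM model: to quantify selection in repertoires, to score the
accessibility of antibody mutations, or to study the context dependence of
the mutation process itself.

## The model

Training data are *parent-child pairs* (PCPs): aligned ancestral/descendant
sequences from the edges of clonal-family phylogenies (the edge carrying
the naive germline outgroup is excluded). Each site *i* of a parent
carries an exponential mutation clock with rate λᵢ and, conditional on
mutation, a categorical distribution **p**ᵢ over the three non-parent
bases (the conditional substitution probability, CSP). With a per-pair
branch length *t* (by default the normalized mutation count), the
probability that site *i* differs in the child is

    p_i = 1 − exp(−t λ_i)

and the training loss is the Bernoulli likelihood of the mutation
locations plus 0.01 × the cross-entropy of the mutated bases.

A k-mer rate table costs 4^k parameters. The *thrifty* architecture gets
wide context at linear cost: each overlapping 3-mer is embedded into a
trainable E-dimensional space, a width-K convolution with F filters runs
over the embeddings, and affine heads produce the rate and the CSP. The
effective context is K + 2 nucleotides (kernel 11 → a 13-mer model), and
the rate/CSP outputs can share everything but the heads ("joined"), only
the embedding ("hybrid"), or nothing ("independent"). A classical 5-mer
table model and a per-site × 5-mer variant are included as baselines, and
a seeded simulator generates PCP data from known truth models for
calibration and recovery experiments.

## Worked example

Simulate PCPs from a known 3-mer truth model, train a small thrifty model,
and evaluate it on held-out pairs:

```r
library(thriftySHM)

cfg <- thriftyConfig(kernel = 11, embed = 7, filters = 19,
                     dropout = 0.3, wiring = "joined")
countParams(cfg)    # 2057  (trainable scalars)
receptiveField(cfg) # 13    (effective k-mer context)

tm    <- randomTrueModel(k = 3, seed = 1)
train <- simulateDataset(simConfig(60, 300, "loguniform", seed = 2), tm)
test  <- simulateDataset(simConfig(30, 300, "loguniform", seed = 3), tm)
train
#> PcpSet with 60 parent-child pairs
#>   sequence lengths: 300-300
#>   samples: 1, families: 60
#>   median mutations per pair: 12

model <- buildThriftyModel(thriftyConfig(3, 4, 8, 0, "joined"), seed = 4)
fit <- trainModel(model, train, config = trainingConfig(
  epochs = 30, learningRate = 0.01, batchSize = 8, seed = 5))

evaluateModel(fit$model, test, siteWindow = c(80, 319))
#> MetricReport
#>   sites evaluated: 6600 (286 mutated, prevalence rho = 0.04333)
#>   AUROC:                 0.7959
#>   AUPRC:                 0.1759
#>   R-precision:           0.1993
#>   substitution accuracy: 0.4336
#>   overlap:               0.9275
#>   mean per-site loglik:  -0.19898
```

Reading the report: the model ranks a mutated site above an unmutated one
about 80% of the time (AUROC); AUPRC and R-precision sit well above the
random-classifier baseline ρ = 0.043; the predicted most-likely base
matches the observed mutation 43% of the time (a uniform CSP would give
33%); and the binned observed/expected histograms overlap by 93%,
indicating good calibration. For reference, the generative truth model
itself reaches AUROC 0.82 on this test set — the ceiling imposed by the
stochasticity of mutation.

A command-line interface over the same functions (train / evaluate /
simulate / extract) is installed at `inst/cli/thriftyshm.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","thriftyshm.R",package="thriftySHM"))')" \
    simulate --config sim.cfg
```

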