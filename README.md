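# sctopic

Topic modelling for single-cell RNA-seq with an interpretable linear
decoder, batch-effect correction, and a transferable neural encoder.

## The problem

Integrative analysis of scRNA-seq data has to separate biology from batch:
cells measured in different samples, donors or protocols carry systematic
technical shifts that confound clustering and annotation. Deep embeddings
correct batch effects well but are hard to interpret; linear factor models
are interpretable but struggle with batch effects and transfer. `sctopic`
implements an embedded topic model that keeps both properties: a
neural-network encoder infers each cell's topic mixture (so the model
scales and transfers), while the decoder is a linear tri-factorization
whose pieces are directly readable.

## The model

Each cell `d` has latent topic activities `δ_d ~ N(0, I)` and topic
proportions `θ_d = softmax(δ_d)`. Counts follow a multinomial whose rate
over genes is

```
r_d = softmax( θ_d α ρ + λ_{s(d)} )
```

with `α` (topics x L) the topic embedding, `ρ` (L x genes) the gene
embedding, and `λ` (batches x genes) additive batch intercepts inside the
gene softmax. The rows of `β = α ρ` score every gene under every topic.
Inference is amortized variational: a two-hidden-layer encoder maps
normalized profiles to `[μ_d, log σ²_d]`, and the ELBO (with a linearly
annealed KL weight) is maximized by Adam, with manually derived gradients
— the package has no deep-learning dependency.

Variants: `batch_intercept = FALSE` ablates `λ`; `adversarial = TRUE` adds
a batch discriminator on the cell embedding for stronger mixing;
`rho_fixed` freezes `ρ` to a standardized pathways-by-genes membership
matrix so the learned `α` scores pathways per topic directly. A trained
encoder applies zero-shot to any gene-aligned dataset
(`align_to_reference()` + `predict()`), including cross-species via a
user-supplied ortholog map.

Also included: a generative-process simulator with planted cell types and
batch effects; clustering/batch-mixing evaluation (Leiden-sweep ARI, NMI,
kBET-style acceptance, silhouette); weighted GSEA over topic-gene scores
with a gene-shuffle permutation null and BH correction; differential-topic
permutation tests with Bonferroni correction.

## Worked example

Simulate a small dataset from the model's own generative process (5
planted cell types, 2 batches), fit, and evaluate:

```r
library(sctopic)

sim <- simulate_sc_dataset(D = 1000, V = 200, K = 5, L = 16, S = 2, seed = 7)
fit <- sctopic(sim$data, K = 5, L = 16, hidden = 32, epochs = 150,
               minibatch = 125, seed = 1)
fit
#> Embedded topic model: K = 5 topics, L = 16, V = 200 genes, S = 2 batch(es)
#> Trained 150 epochs (final loss 4.47448, reconstruction 4.47447)

emb <- predict(fit, sim$data)            # cells x K variational means
evaluate_embeddings(emb, cell_type = sim$data$cell_type,
                    batch = sim$data$batch, seed = 1)
#> ARI 0.978 | NMI 0.967 | kBET acceptance 0.836 | ASW 0.588 (Leiden res 0.1)
```

The planted clusters are recovered (ARI 0.98 against the simulator's
labels) and batches are well mixed in the embedding (84% of sampled
neighborhoods accept the kBET test at α = 0.05). Topic-gene scores are
read off the decoder, and the planted gene sets are recovered as enriched:

```r
top_genes(fit, topic = 1, n = 5)
#> [1] "gene27"  "gene53"  "gene1"   "gene153" "gene5"

res <- gsea_topics(fit, sim$gene_sets, topics = 1, n_perm = 500, seed = 1)
head(res[order(res$q), c("set", "es", "p", "q")], 3)
#>              set        es           p          q
#> 2 planted_topic2 0.8624438 0.001996008 0.02994012
#> 4 planted_topic4 0.4586736 0.003992016 0.02994012
#> 6          null1 0.3331212 0.057884232 0.28942116
```

(Fitted topics need not preserve the planted indexing: this run's topic 1
captured planted topic 2's gene program, at p = 1/501 — the smallest value
500 permutations can resolve.)

A command-line interface covering `simulate`, `train`, `transfer`,
`evaluate`, `gsea` and `de-topics` is installed at `cli/sctopic` inside
the package directory (`system.file("cli", "sctopic", package =
"sctopic")`); see `--help`.

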