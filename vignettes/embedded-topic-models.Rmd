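---
title: "Embedded topic models for single-cell transcriptomes: model, training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedded topic models for single-cell transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`sctopic()` fits a topic model to a cells-by-genes count matrix
$Y \in \mathbb{N}^{D \times V}$. Each cell $d$ carries a latent
$K$-dimensional activity vector $\delta_d$ with prior
$\mathcal{N}(0, I)$; its topic proportions are
$\theta_d = \mathrm{softmax}(\delta_d)$. The decoder is linear and
tri-factorized: a topic embedding $\alpha \in \mathbb{R}^{K \times L}$ and a
gene embedding $\rho \in \mathbb{R}^{L \times V}$ give unnormalized
topic-gene scores $\beta = \alpha\rho$, and the per-cell transcription rate
over genes is

$$ r_{d\cdot} = \mathrm{softmax}\!\left(\theta_d\,\alpha\rho +
\lambda_{s(d)\cdot}\right), $$

where $\lambda \in \mathbb{R}^{S \times V}$ is a per-batch gene intercept
($s(d)$ is cell $d$'s batch). Counts are multinomial:
$y_{d\cdot} \sim \mathrm{Multinomial}(N_d, r_{d\cdot})$ with $N_d$ the
library size. The gene-wise softmax is what lets a *linear* decoder absorb
additive technical shifts: $\lambda$ captures batch-specific composition
changes so that $\delta$ is free to encode biology.

Inference is amortized and variational: a two-hidden-layer encoder (ReLU,
1D batch normalization, dropout 0.1) maps the library-size-normalized
profile $\tilde{y}_d = y_d / N_d$ to $[\mu_d, \log\sigma^2_d]$, the
parameters of a Gaussian posterior over $\delta_d$. Training maximizes the
ELBO with one reparameterized draw per cell,

$$ \mathcal{L} = \frac{1}{B}\sum_d \Big[ \textstyle\sum_g \tilde{y}_{dg}
\log r_{dg} - w \cdot \mathrm{KL}\big(q(\delta_d \mid y_d)\,\|\,
\mathcal{N}(0, I)\big) \Big], $$

by Adam on all parameters jointly. The multinomial combinatorial constant
is omitted (it does not depend on any parameter); the held-out NLL reported
by `heldout_nll()` omits it identically, so numbers are comparable across
models but are not full multinomial likelihoods.

Two reconstruction targets are supported. The default reconstructs the
normalized profile $\tilde{y}_d$ (matching what the encoder consumes); the
token-level multinomial view weights the same cross-entropy by raw counts
instead (`recon_target = "counts"`), which up-weights deeply sequenced
cells. The two differ only by per-cell factors $N_d$.

The evaluation embedding is the variational mean $\mu_d$ — unnormalized,
so distances are not compressed by the simplex — and is a deterministic
function of the input: in evaluation mode dropout is off and batch
normalization uses running statistics (momentum 0.1). That determinism is
what makes zero-shot transfer well defined: `predict()` on a gene-aligned
foreign dataset runs the frozen encoder, and `align_to_reference()`
reorders, translates (via a user ortholog map) and zero-fills the target's
genes so the input dimension is preserved.

For transfer to data whose technical shifts were *not* seen in training,
`predict(..., bn_stats = "dataset")` recomputes the batch-normalization
statistics over the target dataset instead of reusing the training-time
running averages (adaptive normalization, the standard batch-norm
domain-adaptation recipe). The pass is still deterministic — full-dataset
means and variances, dropout off — but cells are no longer encoded
independently: a cell's embedding depends on which dataset it is encoded
with. On the packaged transfer benchmark (fresh draw from the training
truth with redrawn batch intercepts) this closes roughly half of the
zero-shot clustering gap, because the unseen intercepts act as an input
distribution shift that the normalization layers can re-standardize away.
The CLI `transfer` subcommand uses this mode. Zero-filling is a deliberate
extension beyond training on common genes: it keeps a pretrained encoder
applicable when the target misses reference genes, and the returned
coverage fraction makes the missingness explicit.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `K` | 50 | number of topics |
| `L` | 400 | embedding dimension of $\alpha$ and $\rho$ |
| `hidden` | 128 | encoder hidden width |
| `lr` | 0.005 | Adam learning rate (generator) |
| `minibatch` | 2000 | cells per step; last short batch kept |
| `kl_max_weight` | 1e-7 | KL plateau weight |
| `kl_warmup_fraction` | 1/3 | fraction of epochs ramping the KL weight |
| `adv_weight` | 1 | adversarial term weight |
| `adv_warmup` | (1/3, 2/3) | adversarial ramp, fractions of training |
| `disc_lr` | 0.02 | discriminator learning rate |
| `disc_updates` | 8 | discriminator steps per generator step |

The KL weight is linearly annealed from zero to `kl_max_weight` and then
held constant. The default plateau of 1e-7 follows the reference training
recipe and renders the KL term nearly inert — the model behaves almost
like a regularization-free autoencoder, which is empirically what makes
the multinomial reconstruction informative; set `kl_max_weight = 1` for a
conventionally weighted ELBO. Whether the weight should keep rising after
the warm-up is unspecified in the recipe; this implementation holds it
constant.

The number of *steps*, not epochs, governs convergence (typically a few
thousand). The `minibatch` default of 2000 is calibrated to datasets of
$10^5$–$10^6$ cells; on small data, keep the step count in that range by
reducing the minibatch (the benchmark below uses 250 on 3000 cells, i.e.
~3.6k steps over 300 epochs) rather than inflating epochs.

## The adversarial variant

`adversarial = TRUE` adds a two-layer discriminator that predicts the
batch from the sampled $\delta_d$; each iteration performs one generator
update followed by `disc_updates` discriminator updates (cross-entropy,
Adam). Three design choices here are the package's own, made after the
naive formulation failed in measurable ways:

* **Objective.** A generator that *maximizes* the discriminator's label
  cross-entropy has no fixed point: once the discriminator is fooled, the
  gradient keeps pushing until the discriminator is confidently *wrong*
  (cross-entropy above $\log S$), a label-flip equilibrium in which batches
  remain perfectly separable. The default `"confusion"` objective instead
  minimizes the cross-entropy between the discriminator's prediction and
  the uniform distribution; its fixed point is an uninformative
  discriminator. The literal form is available as
  `adv_objective = "gated_ce"`, made bounded by applying it only while the
  discriminator beats chance.
* **Warm-up.** Applying adversarial pressure from the first epoch removes
  the globally decodable batch signal while the topic structure is still
  forming, and the generator learns to hide batch information in
  per-cluster displacements that a global classifier cannot express —
  local batch mixing (what kBET measures) gets *worse*. Ramping the
  adversarial weight from zero over the middle third of training lets the
  clusters form first; the pressure then removes the batch displacement
  without reshaping the clusters.
* **Discriminator learning rate.** The discriminator must track a moving
  embedding; at the generator's learning rate it lags and the adversarial
  gradient points at stale boundaries. Its default is 4x the generator's.

## The pathway-informed variant

`rho_fixed` freezes the gene embedding to a pathways-by-genes matrix built
by `build_pathway_rho()`: binary membership (sets smaller than five genes
should be filtered at load time, `read_gmt(min_size = 5)`), then each gene
column standardized to mean 0, sd 1 across pathways; zero-variance columns
(genes in no pathway) are set to zero. With $\rho$ fixed, $L$ equals the
number of pathways and each row of the learned $\alpha$ scores pathways
directly — `pathway_topic_report()` reads topic-pathway associations
straight off the fit.

## The simulator

`simulate_truth()` / `simulate_cells()` generate data from exactly the
generative process above, with two extensions that make recovery testable:
planted cell types (cluster $c$ draws $\delta \sim \mathcal{N}(t\,e_c, I)$,
a Gaussian mixture that reduces to the model's prior at separation
$t = 0$) and batch intercepts drawn $\mathcal{N}(0,
\texttt{batch\_scale}^2)$. $\alpha$ is scaled by $1/\sqrt{L}$ so rows of
$\beta$ have unit variance regardless of $L$, making `topic_separation`
the only separation knob. Defaults — 3000 cells, 500 genes, 8 topics, 2
batches, separation 4 (dominant-topic proportion about 0.9), unit batch
scale, Poisson(1500) library sizes — describe a modestly sized, clearly
clustered, strongly batched dataset: separation 4 leaves adjacent clusters
in latent space slightly overlapping (Leiden on the *true* $\delta$
attains ARI about 0.96, not 1.0), and the batch intercepts are on the same
scale as the biological topic-gene scores.

What the simulator does *not* emulate: overdispersion beyond multinomial
sampling (no negative-binomial noise), dropout inflation, library-size
biology correlation, or any real dataset's gene-gene correlation. Passing
recovery tests on these data shows the estimator inverts its own
generative process — a necessary check that says nothing about robustness
to model misspecification on real tissue.

## Evaluation choices

* **ARI** via `mclust`; **NMI** normalized by the arithmetic mean of the
  entropies (one of several conventions; chosen and fixed here).
* **kBET-style acceptance**: for 500 sampled cells, the batch composition
  of the 15 nearest neighbors (Euclidean, self excluded) is tested against
  the global composition by a Pearson chi-square test with $S - 1$ degrees
  of freedom (no continuity correction, expected counts floored at 1e-12);
  the acceptance rate is the fraction with $p > 0.05$. Under an
  exchangeable null the expected acceptance is slightly above $1 - \alpha$
  because of the discreteness of counts at $k = 15$ (about 0.965 for two
  equal batches).
* **Leiden sweep**: unweighted 15-NN graph, modularity objective,
  resolutions {0.1, 0.25, 0.5, 0.75, 1, 1.5, 2} by default; the clustering
  with the best ARI against the reference labels is reported, ties going
  to the smallest resolution.
* **Silhouette** via `cluster::silhouette`; the label-restricted variant
  averages the same per-cell widths over one label's cells.

## Interpretation statistics

Gene ranking within a topic sorts $\beta_{k\cdot}$ descending with ties
broken lexicographically by gene identifier, so rankings are reproducible
across input orders. The enrichment score of a gene set walks this ranked
list accumulating the set's share of (absolute) score mass minus the
non-set share — note both hits *and misses* are score-weighted, which
follows the description this implementation adheres to and differs from
classic GSEA's unweighted misses (`classic = TRUE` restores that
convention). ES is the signed one-sided maximum of the difference. The
null shuffles gene symbols over the fixed sorted scores; since only hit
positions matter, null draws depend on a set only through its size and
are shared across same-sized sets. Empirical p-values are
$(N' + 1)/(N + 1)$ with $N'$ counting strictly greater null scores; BH
correction is applied within each topic by default (each topic's Manhattan
plot is a family), with a global option.

The differential-topic test compares mean topic activity between cells
with and without a label against a label-shuffling null, one-sided for
upregulation, Bonferroni-corrected by the number of (topic, label) pairs.
Activities are the unnormalized $\mu$ embedding, not $\theta$: the
conventional effect-size thresholds (mean difference > 2 for cell types,
> 0.2 for conditions) are impossible on a simplex whose coordinates are
bounded by 1, and only meaningful on the $\delta$ scale. Permutation
exceedance uses $\geq$ (conservative under ties; `strict = TRUE` matches
the strictly-greater reading).

## Numerical choices and degenerate inputs

Softmax subtracts the row maximum; logarithms floor their argument at
1e-30 (with a warning when a positive-weight entry hits the floor); batch
normalization uses variance floor 1e-5 and biased batch variance, with
unbiased running variance (as the common deep-learning convention).
Zero-library cells are dropped with a message by default
(`drop_empty = FALSE` to error). Cells from batches unseen at training
time decode with a zero intercept and a warning. A non-finite training
loss aborts with diagnostics rather than continuing. All training
randomness — initialization, shuffling, dropout, reparameterization —
derives from the single `seed`, making two same-seed fits bit-identical on
a fixed BLAS thread count.

## Benchmark problem sizes

The packaged benchmark (tests and `scripts/acceptance.R`) trains on 3000
cells x 500 genes with K = 8, L = 32, hidden 64, 300 epochs, minibatch
250 — chosen so each variant trains in a few minutes on one CPU while
landing in the step-count regime where the optimizer converges. Smaller
configurations (hundreds of cells, tens of epochs) are used for
interface-level and determinism tests where recovery quality is not the
point.

## Known limitations

* Multinomial-only likelihood: real scRNA-seq overdispersion is absorbed
  by the latent space rather than modeled.
* The adversarial comparison is intrinsically noisy: kBET acceptance on a
  fitted embedding varies by tens of points across training seeds, so
  single-seed orderings between variants should be read as trends.
* One categorical batch variable; no continuous or crossed batch designs.
* The permutation GSEA shares one null per set size; sets of equal size
  receive correlated (identical) null draws within a topic, which is
  exactly what symbol-shuffling implies but differs from set-specific
  resampling schemes.
* `de_topic_test()` at its publication-grade default (1e5 permutations) is
  O(`n_perm` x cells x topics) in time; scale `n_perm` to the precision
  actually needed.
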