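---
title: "Cascade flexible neural forests: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascade flexible neural forests: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfnforest)
```

## The problem

Cancer subtype classification from bulk RNA-seq expression matrices is a
small-n, large-p problem: a few hundred patients, thousands of genes, strong
gene-gene correlation, and continuous-valued inputs that decision-tree
ensembles discretize away. This package implements a cascade of *flexible
neural tree* (FNT) ensembles for this setting: a neural model whose
architecture is not fixed by hand but searched, and whose small parameter
count per tree suits small cohorts.

## The flexible neural tree

An FNT is a rooted tree. A leaf emits one input feature $x_j$. A non-leaf
node of arity $M$ ("+M") emits

$$ y = \sigma\!\Big(\sum_{j=1}^{M} \omega_j I_j + \theta\Big), \qquad
   \sigma(z) = \frac{1}{1 + e^{-z}}, $$

where $I_j$ are its children's outputs, $\omega_j$ the edge weights and
$\theta$ the node bias. Leaves carry no weights of their own; weights live on
the parent's incoming edges. Output is computed bottom-up; with a function
node at the root it lies strictly in $(0,1)$. The permitted arities form the
*function set* (for example $\{+2,+3,+4\}$); varying the function set across
ensemble members is the model's main source of structural diversity, so it is
user-configurable everywhere and never hard-coded.

Two searches train an FNT in alternation:

* **Structure** — grammar-guided genetic programming (GGGP). The grammar
  (`fnt_grammar()`) admits exactly the trees whose non-leaf arities are in
  the function set, whose leaves index valid features, and whose depth stays
  within a bound; generation, subtree crossover and subtree mutation are all
  restricted to grammar-valid results, so no invalid individual is ever
  constructed. Selection is by tournament (size 3, sampling without
  replacement) with elitism of one, minimizing the root-mean-square error of
  the tree output against the coded target; the best-ever fitness is
  therefore monotone non-increasing over generations.
* **Parameters** — particle swarm optimization (PSO) over the flattened
  weight/bias vector. Velocities follow
  $v \leftarrow \omega v + c_1 r_1 (p_{best} - x) + c_2 r_2 (g_{best} - x)$
  with the velocity clamped to $[-v_{max}, v_{max}]$ componentwise, and
  positions follow $x \leftarrow x + v$. The swarm is seeded at the
  incumbent tree's parameters (one particle exactly there, the rest
  perturbed by $U(-1,1)$), so PSO refines rather than restarts, and the
  returned fitness never exceeds the incumbent's.

`train_fnt()` alternates the two (default three rounds, stopping early on
absolute fitness below `1e-4` or relative improvement below `1e-3`), keeping
the best post-PSO tree seen.

## From one tree to a multi-class cascade

**M-ary decomposition.** A single FNT has one output, so an $M$-class
problem is decomposed into $L = \lceil \log_2 M \rceil$ binary problems:
class $i$ (0-based, in class-list order) is coded as the $L$-bit big-endian
binary representation of $i$ (`class_codec()`). One FNT per bit forms an
*FNT Group*. Decoding returns the class whose code is nearest in Euclidean
distance; for $M$ not a power of two the unused codes never compete, and
ties resolve to the smallest class index.

**Bagging.** `train_forest()` draws $K$ bootstrap samples (n draws with
replacement, redrawn — boundedly — if a class present in the labels is
missing) and trains one group per draw; the forest output is the
componentwise mean of its groups' code vectors, clamped to $[0,1]$ to guard
against degenerate single-leaf trees whose raw feature output can leave the
sigmoid range.

**Cascade.** `cfnforest()` stacks layers of three forests with pairwise
distinct function sets (defaults $\{2,3,4\}$, $\{2,3,5\}$, $\{2,4,5\}$).
Each layer's three outputs are fused by componentwise mean into the layer
score $y_i$. A *confidence region* $[0, \text{low}] \cup [\text{high}, 1]$
(closed; defaults 0.2 / 0.8) gates the flow: a sample whose every fused
component lies in the region exits the cascade at that layer; the rest
continue, with the three forests' $3L$ code outputs appended to the original
features as the next layer's input (so every layer past the first sees
base + $3L$ columns). Setting low = high disables the gate. By default
deeper layers train only on the still-uncertain samples
(`train_on = "uncertain"`), trading sample size for focus on the hard
region; `train_on = "all"` is available.

**Depth and fusion.** A stratified holdout (`validation_fraction`, default
0.25) scores the whole cascade after each added layer; growth stops when
accuracy improves by less than `min_gain` (0.005) for `patience` (1)
consecutive layers, when too few uncertain samples remain to train on, or at
`max_layers` (5), and the model is trimmed to the best-validated depth. The
final score of a sample exiting at layer $j$ is the weighted fusion
$y_f = \sum_{i \le j} \omega_i y_i / \sum_{i \le j} \omega_i$ with
$\omega_i = i / (1 + 2 + \cdots + N)$: increasing in depth and summing to
one, so later, more refined layers dominate and $y_f$ stays a convex
combination. The printed triangular form $i/(1+2+\cdots+i)$, which
simplifies to $2/(i+1)$ and is decreasing, is available as
`weights = "literal"` for comparison.

## Preprocessing

`read_expression()` reads delimited matrices (samples x genes, `NA`/empty
cells missing). The chain mirrors standard expression practice:

1. `filter_missing_samples()` removes samples missing strictly more than 20%
   of genes (a sample at exactly the threshold is retained);
2. `knn_impute()` replaces each missing cell with the mean of the k (default
   5) nearest samples that observe the gene, with Euclidean distance over
   mutually observed genes;
3. `zscore_normalize()` standardizes each gene by its population standard
   deviation, mapping constant genes to zero. The statistics transfer to
   held-out data via `apply_normalization()`, so cross-validation never
   leaks test-fold information into preprocessing. Division by the variance
   (a literal reading of the standardization formula that changes feature
   scale pathologically) is preserved under `divisor = "var"`.

## The synthetic study

`make_dataset()` generates class-conditional Gaussian expression data: class
$c$ of $M$ shifts its own disjoint block of
$\lfloor n_{inf}/M \rfloor$ informative genes upward by `shift`, all other
genes are pure noise, and cells go missing uniformly at random. The defaults
(4 balanced classes of 50 samples; 40 genes, 10 informative; shift 2.0; unit
noise; 5% missingness) define the reference study used by the tests and the
acceptance script. Separation grows with `shift`: at 3 the classes are
essentially linearly separable, at 2 they overlap enough that the Bayes
accuracy of the generative model is about 0.94 and any finite-sample
classifier sits well below it, and at 0 there is no signal at all (a
nearest-centroid reader scores at chance, which the tests verify).

What the generator deliberately does *not* emulate: negative-binomial count
noise (the model consumes z-scored values, so Gaussian blocks suffice),
gene-gene correlation beyond the shared class shift, batch effects, and
class imbalance beyond what `n_per_class` encodes. Passing tests on this
generator therefore demonstrate the machinery — decomposition, search,
bagging, gating, fusion, leakage-free evaluation — not performance on real
RNA-seq cohorts.

## Evaluation

`stratified_kfold()` deals each class round-robin across folds (per-class
counts differ by at most one); `run_cv()` runs the full
filter/impute/standardize/fit/predict pipeline per fold, fitting every
statistic on the training split only, and reports per-class and macro
one-vs-rest precision, recall and F1 plus accuracy, with across-fold means
and sample (n-1) standard deviations. "Average precision" is read as
macro-averaged one-vs-rest precision, the standard choice in multi-class
subtype work.

## Numerical and design notes

* Sigmoid pre-activations are clamped to $[-500, 500]$; this prevents
  floating overflow and perturbs nothing above $10^{-200}$.
* PSO's random factors $r_1, r_2$ are drawn per dimension (canonical PSO).
  The scalar per-update convention, a literal reading of the update
  equation's notation, is available via `per_dimension = FALSE`; it makes
  every velocity update a rank-one combination of three fixed vectors and
  stalls in higher dimensions, which is why it is not the default.
* PSO defaults ($\omega = 0.729$, $c_1 = c_2 = 1.49445$, swarm 30,
  $v_{max} = 4$) are the standard constriction-equivalent values; the
  inertia is constant (no schedule).
* GGGP scores every individual with its current weights plus two fresh
  $U(-1,1)$ draws, keeping the best (`weight_draws = 3`). A topology judged
  under one arbitrary weight setting is mostly weight luck; a few restarts
  let selection see structure quality. The initial population is
  depth-ramped (target depths cycle over 2..max depth) so small and large
  structures compete from the start.
* Tournament sampling is without replacement, which makes a full-population
  tournament deterministically return the best individual.
* `optimize_params()` with zero iterations returns the tree bit-unchanged;
  a single-leaf tree (no parameters) is returned unchanged with a notice.
* Ties in decoding go to the smallest class index; confidence-region bounds
  are closed at both ends.
* All randomness flows through R's RNG, so any top-level seed makes fits,
  forests, fold plans and datasets bit-reproducible; with a fixed seed,
  growing K only appends bootstrap groups (the first groups are unchanged).

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run the reference study at 200
samples x 40 genes with 2-fold cross-validation and deliberately small
search budgets (K = 3 groups, population 20 over 10 generations, swarm 30
over 20 iterations, at most 3 layers), chosen so the whole evaluation
completes in minutes on one core while still exercising every stage. At
these budgets and at this sample size (100 training rows per fold) the
model sits well below the generative model's asymptotic accuracy: the
binding constraints are the small per-fold sample, the tiny evolutionary
budget for picking informative genes out of the matrix, and the short swarm
runs per tree. The acceptance script prints the exact cross-validated
metrics obtained for a given seed; raising the budgets (and `shift` in the
generator) moves the model toward the separable regime shown in the README
example.

## Known limitations

* No gene selection: the model consumes the matrix it is given; the
  preprocessing chain does not reduce dimensionality.
* The minimal $\lceil \log_2 M \rceil$-bit decomposition has no redundancy;
  a single wrong bit is a wrong class. Error-correcting (longer) codes are
  out of scope.
* Deeper cascade layers trained only on uncertain samples can see very few
  rows; growth stops rather than trains degenerate forests, and the final
  depth is chosen on validation accuracy.
* Evolutionary budgets dominate accuracy; the defaults favor turnaround
  over exhaustive search and should be raised for real analyses.
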