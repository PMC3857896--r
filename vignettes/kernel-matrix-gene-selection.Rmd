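---
title: "Kernel-matrix gene selection: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-matrix gene selection: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the statistic

Support vector machines are sample-based classifiers: the decision function
is a weighted combination of training *samples* in the kernel-induced
feature space, not of features. A gene set chosen because each gene is
individually differential (a t-test, Fisher's ratio, ...) therefore
optimizes the wrong object — it makes *features* discriminant, with no
guarantee that the resulting training *samples* are easy to separate. The
selection criterion implemented here scores gene subsets by how discriminant
they make the samples, using only the kernel (Gram) matrix the SVM itself
would consume, and without ever training an SVM during selection.

Column $j$ of an $n \times n$ kernel matrix holds the similarities between
sample $j$ and all $n$ samples (self-similarity included). Splitting those
$n$ values by the class of the other sample gives a same-class population
$P_{same}$ and an opposite-class population $P_{opp}$, and the
**separability of sample $j$** is the t-like statistic

$$S_j \;=\; \frac{\operatorname{mean}(P_{same}) - \operatorname{mean}(P_{opp})}
{\operatorname{sd}(P_{same}) + \operatorname{sd}(P_{opp})},$$

with sample ($n-1$) standard deviations. A large positive $S_j$ marks a
sample statistically more similar to its own class than to the other (a
"discriminant sample"); a negative $S_j$ marks a sample whose similarities
contradict its label. The **problem separability** is the sum
$M = \sum_j S_j$, and a gene (or gene subset) is scored by the $M$ of the
classification problem it induces.

Two kernels are supported:

* **linear**, $K_{ij} = \langle x_i, x_j\rangle$, with each column divided
  by its diagonal entry $K_{jj}$ so that self-similarity is exactly 1
  (the matrix need not stay symmetric after this column normalization);
* **Gaussian RBF**, $K_{ij} = \exp(-\lVert x_i - x_j\rVert^2/\sigma)$,
  which has unit diagonal by construction. $\sigma$ is a tuning parameter.

The denominator of $S_j$ is a *sum* of standard deviations, not a pooled
variance, and no stabilizing epsilon is added: for well-posed two-class
problems with the kernels above the sum cannot vanish. When a degenerate
input (e.g. a constant gene under the RBF kernel, where every similarity is
1) does drive both standard deviations to zero, the column's score is
defined as 0, the column index is recorded, and a warning is emitted — a
guard, not a model change, so that batch pipelines survive pathological
candidates.

Two further numerical conventions, chosen where the published description is
ambiguous and isolated behind single internal functions so they can be
swapped: self-similarity is included in $P_{same}$ (the statistic scores all
$n$ measurements of a column, and the normalizations above engineer
$K_{jj} = 1$ specifically); and a similarity population with a single member
has standard deviation 0, the only consistent value under the $n-1$
convention (reachable only when one class has a single sample). The RBF
exponent uses $\sigma$ itself; any monotone reparameterization
($\sigma^2$, $2\sigma^2$) merely relabels the tuning grid.

## The two selectors

**KMGS** (kernel-matrix gene selection) ranks genes independently: gene $g$
induces the one-dimensional problem given by its expression vector, and its
score is that problem's $M$. Ranking is by descending score, ties toward the
lower gene index (the published procedure is silent on ties; determinism is
required for reproducible traces). Because scores are real-valued, the tie
problem that plagues count-based wrappers (many subsets with identical
leave-one-out error) essentially does not arise.

**KMSFS** (kernel-matrix sequential forward selection) grows a set greedily.
An $n \times n$ accumulator $A$ carries the pairwise statistic of the genes
selected so far — accumulated inner products for the linear kernel,
accumulated squared coordinate differences for the RBF kernel. Each
remaining candidate $k$ is scored by converting $A + C_k$ (its
contribution) into a Gram matrix (linear: column-normalize; RBF:
$\exp(-\cdot/\sigma)$) and evaluating $M$; the argmax joins the set and its
contribution folds into $A$. The per-kernel accumulator semantics are the
only reading under which a single-pass update keeps every candidate
evaluation at $O(n^2)$, and the test suite verifies the incremental trace is
*exactly* (to $10^{-10}$) the trace of naively rebuilding every candidate
Gram matrix from scratch. Only the chronological selected list is part of
the contract; internal bookkeeping (the published pseudocode swaps selected
indices to the front of a working array) is not reproduced.

**Fisher's ratio**, $F_g = (\mu_g^+ - \mu_g^-)^2 / ((\sigma_g^+)^2 +
(\sigma_g^-)^2)$, is provided as the filter baseline and as the prescreen
used before the wrappers on large arrays (top 1000 genes by default in the
published protocol). When both class variances are zero the score is defined
as $+\infty$ for unequal means and 0 otherwise.

## Preprocessing

Two standard preparations are implemented in `data_io`:

* `standardize_rows_then_columns()`: z-score each sample (row), then each
  gene (column). The second pass leaves every gene with mean 0 and sd 1
  (tolerance $10^{-9}$), which is what gene-wise kernel scoring consumes;
  the row-then-column order is a documented convention (the source
  description's matrix orientation is ambiguous), chosen because it ends
  with exactly-standardized genes. Any zero-variance row or column raises an
  error naming the offending index. Note that a $2\times 2$ matrix always
  degenerates (both rows z-score to the same pair, leaving constant
  columns), so the smallest meaningful input is $3\times 3$.
* `dudoit_preprocess()`: clamp to $[100, 16000]$, remove genes with
  max/min $\le 5$ or max $-$ min $\le 500$ across samples, then $\log_{10}$.
  The thresholds are the standard Dudoit values and are exposed as
  parameters. On the classic 72-sample leukemia array this retains 3571 of
  7129 genes.

Sample standard deviations use the $n-1$ denominator throughout (the
t-statistic convention), configurable to $n$.

## Error estimation: external B.632+

Selection bias is the dominant pitfall when evaluating gene selection:
selecting genes on the full dataset and cross-validating only the classifier
leaks the held-out labels into the gene list. The estimator here is the
**external** B.632+ bootstrap: for each of $B$ bootstrap sets, gene
selection is run on the in-bag samples *only*, a linear SVM (`e1071::svm`,
i.e. LIBSVM, cost parameter $C$) is trained on the in-bag samples restricted
to the top-$g$ genes, and errors are recorded on the out-of-bag samples, for
every $g = 1..G$. The test suite asserts that each per-set gene list is
re-derivable from in-bag data alone, and that the whole estimator collapses
to a standalone B.632+ oracle (to $10^{-12}$) when the selector ignores its
input.

The resampling design is the **balanced bootstrap**: the multiset holding
each sample index exactly $B$ times is permuted and cut into $B$ blocks of
$n$, so every sample occurs exactly $B$ times overall, reducing variance.
Blocks with an empty out-of-bag complement or single-class in-bag labels
trigger a bounded re-permutation (at most 1000 attempts; with $B = 1$ the
single balanced block is a permutation of all samples and the design is
provably unsatisfiable, which raises an error). Plans are deterministic
given their seed.

Per gene count $g$, the components are combined as in the standard .632+
definition: the apparent error $\overline{err}_g$ and no-information rate
$\gamma_g = \sum_k p_k(1-q_k)$ come from the full-data pipeline
($\gamma$ is recomputed per gene count — whether the published protocol
recomputed it or fixed it per dataset is unstated; per-count is the
conservative choice); the leave-one-out bootstrap error $err^{(1)}_g$
averages each sample's out-of-bag misclassification rate; and

$$err^{.632+} = (1-w)\,\overline{err} + w\,\min(err^{(1)}, \gamma), \qquad
w = \frac{0.632}{1 - 0.368 R},$$

with $R$ the relative overfitting rate, clipped to $[0,1]$. Defaults are
$B = 200$ and $G = 100$, the published protocol's values.

## Parameter tuning

`grid_search()` evaluates each $(\sigma, C)$ setting (defaults
$\sigma \in 10^{-5..5}$, $C \in 10^{-3..3}$; linear-kernel selectors grid
over $C$ alone) on the *same* bootstrap plan, giving a $G \times k$ matrix
of B.632+ errors treated as repeated measures. `friedman_test()` ranks the
$k$ settings within each gene count (smaller error = rank 1, average ranks
on ties) and refers
$\chi^2 = \frac{12N}{k(k+1)}\sum_j(\bar R_j - \tfrac{k+1}{2})^2$ to a
chi-square with $k-1$ df; the statistic is implemented without tie
correction, matching its textbook form, and agrees exactly with
`stats::friedman.test` on tie-free data. On rejection, `holm_select()`
compares the best-ranked setting against the other $k-1$
(best-vs-rest, matching the protocol's narrative, rather than all-pairs)
with $z_j = (\bar R_j - \bar R_{best})/\sqrt{k(k+1)/(6N)}$, two-sided
normal p-values and Holm's step-down at level $\alpha$ (default 0.05,
exposed as a parameter since sensitivity analyses at other confidence
levels are standard). The reported per-setting "score" is the mean rank —
bounded by $k$, best lowest. Returned best setting: the best-ranked member
of the selected set, ties toward smaller $\sigma$, then smaller $C$.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` produces the minimal structure exhibiting the two
regimes the method distinguishes:

* **null genes** — standard normal in both classes;
* **linear (mean-shift) DEGs** — class means $\pm\delta/2$, unit spread:
  the regime any mean-based statistic detects;
* **nonlinear (variance-shift) DEGs** — equal means, class spreads 1 and
  $\rho$: invisible to mean-based statistics and to the normalized linear
  kernel, visible to the RBF kernel.

Effect sizes are in within-class sd units for interpretability. The matrix
is then row/column standardized exactly as real data would be. Defaults
(30 + 30 samples, 5 mean-shift DEGs at $\delta = 3$ among 200 nulls) are the
validation conditions used throughout the tests; the variance-shift checks
use a single $\rho = 3$ gene among 50 nulls, scored with $\sigma = 1$, a
width of the order of the typical squared distance between standardized
single-gene values. The generator does **not** emulate gene–gene
correlation, batch effects, heavy-tailed noise or probe-level artifacts, so
passing tests demonstrate correctness of the machinery and detectability of
planted signal — not performance claims on real arrays, where correlated
nulls make selection strictly harder.

Test problem sizes (e.g. $B = 50$ bootstrap sets and $G = 10$ gene counts
for the synthetic error-curve study, $8 \times 6$ instances for the
exhaustive oracle comparisons) were chosen as the smallest designs that
exercise every code path with non-trivial statistics.

## Degenerate inputs and tie-breaking, in one place

* Degenerate kernel column (both sds zero): score 0, recorded, warned.
* Linear column with $K_{jj} < 10^{-12}$: column zeroed and recorded.
* Zero-variance row/column at standardization: error naming the index.
* All genes fully degenerate in `kmgs_rank()`: error.
* Ties — gene ranking, forward selection, Fisher prescreen, frequency
  tables: lower gene index wins; tuning: smaller $\sigma$, then smaller
  $C$.
* Labels: first-seen category recodes to $+1$ (already-$\pm 1$ numeric
  labels are kept as given).

## Known limitations

* Two-class problems only; no multi-class extension.
* KMSFS is $O(T\,m\,n^2)$; for arrays with tens of thousands of genes the
  intended use (as in the published protocol) is a Fisher-ratio prescreen
  to ~1000 genes first.
* The MAT-format loader shells out to the system `python` (scipy) and
  supports v5 archives with one expression matrix and one two-valued label
  vector; it is a convenience for the published supplementary datasets, not
  a general MATLAB reader.
* `render_heatmap()` z-scores genes for display only; constant genes in the
  display selection would produce undefined display rows.
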