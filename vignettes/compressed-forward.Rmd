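---
title: "The compressed-sequence forward algorithm: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The compressed-sequence forward algorithm: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfhmm)
```

## The model and the matrix-chain view

A discrete HMM over `N` hidden states and `M` observable symbols is
parameterised by an initial distribution $\pi$, a row-stochastic transition
matrix $A$ and a row-stochastic emission matrix $B$. The forward algorithm
computes $\Pr(Y_{1:T} \mid \lambda)$ column by column:
$\alpha_1(i) = \pi_i b_{i,y_1}$,
$\alpha_t(j) = b_{j,y_t} \sum_i \alpha_{t-1}(i)\, a_{ij}$.
Writing $C_o = B_o A^{*}$ (with $B_o$ the diagonal matrix of column $o$ of
$B$ and $A^{*}$ the transpose of $A$) and $C_1 = B_{y_1}\pi$, the whole
computation is the right-to-left matrix chain

$$\alpha_T = C_{y_T} C_{y_{T-1}} \cdots C_{y_2} C_1 .$$

Matrix multiplication is associative, so the chain may be regrouped freely
— and every repeated substring of $Y$ is a repeated sub-product that needs
computing only once. That observation, not any change to the model, is the
entire speedup: the likelihood returned is algebraically identical to the
classical recursion, and `forward_scaled()` (the classical algorithm) is
kept in the package as a permanent cross-check.

## Pair-substitution preprocessing

`preprocess()` compresses the token stream by repeatedly finding the most
frequent adjacent pair and replacing its non-overlapping occurrences with a
fresh composite symbol. Design choices that the algorithm itself leaves
open were fixed as follows:

* **Counting and replacement semantics.** Greedy left-to-right,
  non-overlapping. For a pair of distinct symbols adjacent occurrences can
  never overlap, so the count is the plain number of adjacent matches; for
  a pair of identical symbols a run of length $L$ contributes
  $\lfloor L/2 \rfloor$. Counts are recomputed on the rewritten sequence
  after each round, which is exactly what a fused count-while-replacing
  scan yields.
* **Tie-break.** Among pairs with maximal count the lexicographically
  smallest $(l, r)$ wins. Any fixed rule works (the evaluated product is
  the same chain regrouped); a deterministic one makes preprocessing
  reproducible byte for byte.
* **Sequence boundary.** The first symbol $y_1$ is stored apart and never
  substituted: its term in the chain is the vector $C_1$, not a square
  matrix, so folding it into a composite would have no well-formed matrix.
  Positions $2..T$ are what gets compressed.
* **Stopping.** Each substitution converts $p$ matrix–vector products into
  one matrix–matrix product per future evaluation, at a one-off
  preprocessing cost. With measured unit costs $t_{mv}, t_{mm}$ for the
  smallest state count $N_{\min}$ the preprocessing will serve, an
  expected reuse count $e$ (default 1: a single likelihood evaluation),
  and $pre_{i-1}$ the previous round's duration as the estimate of the
  next round's cost, compression stops before the first round $i$ with
  $e\,(t_{mv}\, p_{i-1} - t_{mm}) - pre_{i-1} \le 0$. When a list of
  $N_{\min}$ thresholds is given, each threshold is calibrated separately
  and snapshotted when its own criterion fires, largest threshold first
  (larger states mean costlier matrix products and an earlier stop);
  compression then continues for the smaller thresholds. With no
  thresholds at all, no timings are needed: compression stops the first
  time a round finds the same maximal pair count as the round before.
  The no-threshold snapshot is stored under threshold key 1, so the
  loading rule ("largest stored $N_{\min} \le N$") always selects it.
* **Reproducible timing.** Wall-clock round durations make
  threshold-mode stopping environment-dependent by design. For exact
  reproducibility, `compression_calibration()` accepts explicit `t_mv` /
  `t_mm` overrides and an optional `fixed_round_time`; the package's own
  tests use these to pin stopping points.

The substitution table is a flat list of `(new, left, right)` rules with
constituents always predating composites, so expansion is acyclic and the
round trip back to the original sequence is exact — a property tested on
hundreds of random sequences at every stored threshold. The saved
directory layout is plain text (metadata, rules, one token file per
threshold), human-diffable and exactly reconstructable.

## Two-stage evaluation and numerical stability

All matrices hold probabilities, so raw chain products decay exponentially
and underflow IEEE doubles within a few thousand positions. Stage 1
therefore normalises every per-symbol matrix by its entry sum $c_o$ and
tracks log scales: $\tilde{s}_o = \log c_o$ for original symbols and
$\tilde{s}_o = \log c_o + \tilde{s}_l + \tilde{s}_r$ for a composite
$(l, r)$, accumulated along the rule-dependency chain. Stage 2 starts from
the raw $C_1$, multiplies one normalised matrix per compressed token,
normalises each resulting vector by its sum $d_j$, and returns

$$\log \Pr(Y_{1:T} \mid \lambda) = \sum_{t=2}^{T'} \tilde{s}_{y'_t}
  + \sum_j \log d_j .$$

Natural logarithms are used throughout — the convention optimisers expect.
Numerical decisions worth recording:

* **Orientation.** The chain applies right-to-left, so the composite for
  the in-sequence pair "$l$ then $r$" is $\bar{C}_r \bar{C}_l$.
  Correctness is enforced by oracle-equivalence tests against the
  classical forward algorithm, not by notation.
* **Degenerate mass.** A zero entry sum ($c_o = 0$, possible with
  structural zeros in $A$ or $B$) flags the symbol degenerate; any
  sequence using it, or any stage-2 step with $d_j = 0$, returns
  $-\infty$ rather than raising an error, because optimisers routinely
  probe impossible parameter regions. $C_1$ is used unnormalised; its
  mass enters through the first $d_j$ (equivalent algebra).
* **Edge cases.** $T = 1$ sequences are evaluated from $C_1$ alone. Model
  validation uses an absolute row-sum tolerance of $10^{-9}$ — loose
  enough for parsed decimals, tight enough to catch construction bugs —
  and the HMM text format prints 17 significant digits so file round
  trips are exact.
* **Blocked stage 2.** `forward_compressed(..., n_blocks = k)` partitions
  the compressed sequence into contiguous blocks, evaluates each block as
  a normalised matrix product and combines right-to-left with $C_1$. The
  contract is value equality with the sequential sweep (within $10^{-9}$;
  associativity again); blocks are independent, so a parallel runtime
  could process them concurrently. Stage 1 is sequential by nature: rule
  $i$ may depend on any earlier rule.

Operation counts are first-class outputs (`stage2_steps`, the compressed
length; `stage1_products`, one per composite symbol), because the method's
benefit is exactly the gap between `stage2_steps + stage1_products` and
the $T - 1$ products of the classical sweep. On highly repetitive input —
e.g. the all-zeros sequence of length 1024 — the total drops from 1023 to
a few dozen; the package's tests assert this, and assert that mean
compressed lengths increase monotonically with the 1-frequency of random
binary sequences, the complexity dial the method is sensitive to.

## Synthetic data and training

The generators exist to exercise exactly the regimes the method cares
about. `random_binary_sequence(length, one_frequency, seed)` draws i.i.d.
tokens with $\Pr(1) = f$: low $f$ gives long zero-runs and high
compressibility, high $f$ approaches incompressible noise. The package's
sweeps use $T = 10^5$ and $f \in \{10^{-4}, 10^{-3}, 0.01, 0.05\}$, sizes
chosen so the whole suite runs in well under a minute per property while
still forcing underflow in any unscaled implementation.
`sample_sequence()` draws from the HMM generative process itself. What
these do **not** emulate: real alignment columns are neither i.i.d. nor
stationary, their repeat structure is patchy (isochores, repeat families),
and their alphabets carry missing-data codes. Passing tests therefore
certify algorithmic correctness and the direction of the complexity
response, not wall-clock performance on genomes.

`train_nelder_mead()` maximises the compressed-forward log likelihood
through a user-supplied parameterization (unconstrained vector to `"hmm"`),
because structured applications map a handful of scientific parameters to
full matrices; `softmax_parameterization()` is the generic default.
Nelder–Mead is derivative-free and tolerates the $-\infty$ plateaus of
impossible regions, which are mapped to a large finite penalty. One caveat
the tests document: in label-symmetric models the fully symmetric
parameter point is a stationary plateau where any simplex method stalls,
so recovery runs start from a mildly asymmetric point. The recovery check
— a two-state symmetric switch model, true rate 0.1, $T = 5000$, estimate
within 0.05 absolute — uses optimizer defaults (`maxit = 500`, `optim`'s
relative tolerance); these are documented, not tuned.

## Limitations

* Preprocessing pays off only when reused ($e > 1$) or when the sequence
  is compressible; on incompressible input the stopping rule quits after
  few rounds and evaluation degenerates gracefully to near-classical
  cost plus a small stage-1 overhead.
* The compressed representation cannot serve Viterbi or posterior
  decoding — the max-sum semiring does not distribute over the grouped
  products the way sum-product does — so the decoders run on the
  uncompressed sequence.
* Emissions are categorical; continuous or higher-order models are out of
  scope, as is Baum–Welch (training is generic likelihood search).
* `ScaledMatrixSet` objects are model-specific ($C_o$ depends on $A$ and
  $B$) and are deliberately rebuilt per evaluation; only the sequence
  preprocessing is cached across models.
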