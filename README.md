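# cfhmm — compressed-sequence forward algorithm for hidden Markov models

Likelihood evaluation is the bottleneck of HMM analysis on genome-scale
data: the forward algorithm costs one `N x N` matrix–vector product per
observation, sequences run to 10⁸ positions, and maximum-likelihood training
evaluates the likelihood hundreds of times. `cfhmm` attacks this with a
model-independent preprocessing of the observation sequence: because the
forward recursion is the right-to-left matrix chain

    alpha_T = C_{y_T} C_{y_{T-1}} ... C_{y_2} C_1,
    C_o = B_o A*,   C_1 = B_{y_1} pi,

(`A` the transition matrix, `B_o` the diagonal emission matrix of symbol
`o`, `A*` the transpose), every repeated substring of the observations is a
repeated sub-product. The preprocessing repeatedly replaces the most
frequent non-overlapping adjacent pair of symbols by a fresh composite
symbol (digram / re-pair compression); at evaluation time each composite's
matrix `C_{(l,r)} = C_r C_l` is computed once (stage 1) and the shortened
sequence is swept with one matrix–vector product per compressed token
(stage 2). A cost-model stopping criterion — stop before round `i` when
`e (t_mv p_{i-1} - t_mm) - pre_{i-1} <= 0`, with `t_mv`/`t_mm` measured unit
costs, `p` the pair count and `e` the expected number of reuses — keeps the
preprocessing from outrunning its payoff. All products are entry-sum
normalised with log-space scale bookkeeping, so likelihoods that underflow
any floating-point format are returned exactly as `log Pr(Y | lambda)`.

The compression depends only on the sequence, never on the model, so one
saved preprocessing serves a whole training run. The package is for anyone
fitting discrete-emission HMMs to long, repetitive sequences — alignment
columns, chromatin states, binary site classifications — and also ships the
classical scaled forward algorithm, an exact path-enumeration oracle,
Viterbi and posterior decoding, HMM simulation, and generic Nelder–Mead
likelihood training.

## Worked example

The 14-symbol binary sequence `1 0 1 0 0 0 1 0 0 1 1 0 0 1` compresses in
three rounds; the most frequent pair `(0,1)` occurs 4 times, so its matrix
is computed once and reused — 3 matrix–vector products saved in every
subsequent likelihood evaluation:

```r
library(cfhmm)
s <- obs_seq(c(1,0,1,0,0,0,1,0,0,1,1,0,0,1), alphabet_size = 2)
p <- preprocess(s)
p$rounds[, c("round", "left", "right", "pair_count")]
#>   round left right pair_count
#> 1     0    0     1          4
#> 2     1    0     2          3
#> 3     2    0     3          1

h <- hmm(c(0.5, 0.5),
         matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
         matrix(c(0.8, 0.2, 0.2, 0.8), 2, byrow = TRUE))
forward_compressed(p, h)
#> log Pr(Y | lambda) = -11.3778889534
#>   stage 2 matrix-vector steps: 5
#>   stage 1 matrix-matrix products: 3
forward_scaled(s, h)                 # classical oracle, same value
#> [1] -11.37789
```

The compressed evaluation used 5 matrix–vector plus 3 matrix–matrix
products instead of 13 matrix–vector products, and agrees with the
classical algorithm to machine precision. For reuse across a training run:

```r
save_preprocessing(preprocess(s, compression_calibration(thresholds = c(4, 16), e = 500)), "prep_dir")
pre <- load_preprocessing("prep_dir", n_states = 4)   # best stored threshold
fit <- train_nelder_mead(pre, softmax_parameterization(4, 2), start = rep(0, 16))
```

A shell interface covering preprocessing, likelihood, decoding, simulation,
calibration and training is installed as `exec/cfhmm`
(`cfhmm likelihood --hmm model.txt --dir prep_dir`), with a `--reference`
flag that forces the classical algorithm for self-auditing runs.

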