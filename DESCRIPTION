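Package: cfhmm
Title: Compressed-Sequence Forward Algorithm for Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast likelihood evaluation for discrete hidden Markov models on
    long observation sequences. A model-independent preprocessing step
    compresses the observed sequence by repeated most-frequent-pair
    substitution with a cost-model stopping criterion; the forward algorithm
    is then evaluated in two numerically stable stages that reuse one matrix
    product per repeated substring, so one preprocessing serves many
    likelihood evaluations during training. Includes the classical scaled
    forward algorithm, a brute-force path-enumeration oracle, Viterbi and
    posterior decoding, HMM-based sequence simulation, generic Nelder-Mead
    likelihood training, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
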