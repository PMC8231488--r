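Package: mcdecode
Title: Robust Neural Decoding with a Maximum Correntropy Information Filter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: State estimation of low-dimensional movement intention from noisy
    high-dimensional neural recordings. Implements a nonlinear maximum
    correntropy information filter - an information-form Kalman-type recursion
    whose measurement update maximises a Gaussian-kernel correntropy cost by
    fixed-point (iteratively reweighted least squares) iteration, making it
    robust to heavy-tailed non-Gaussian observation noise and to near-total
    initial uncertainty. Also provides the nonlinear information filter and
    covariance-form Kalman filter baselines, a multilayer-perceptron
    pseudo-observation model mapping lagged multi-channel firing rates to the
    behavioural state, a synthetic two-lever-task data generator with outlier
    contamination, and evaluation tooling with tidy outputs and ggplot2
    figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
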