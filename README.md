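# hlrnet

Sparse logistic regression with the hybrid L1/2+L2 penalty, for feature
(gene) selection and classification in high-dimensional, low-sample-size
data such as microarray and RNA-seq expression matrices.

Plain logistic regression cannot be fit when the number of features far
exceeds the number of samples, and the lasso — the standard remedy — is
biased and tends to pick one arbitrary representative from each group of
correlated genes. `hlrnet` fits the penalized model

    min over beta:  -sum_i [ y_i log f(X_i'beta) + (1-y_i) log(1 - f(X_i'beta)) ]
                    + lambda * ( alpha * ||beta||_{1/2} + (1-alpha) * ||beta||_2^2 )

with `f(x) = e^x / (1 + e^x)` and `||beta||_{1/2} = sum_j |beta_j|^(1/2)`.
The non-convex L1/2 norm gives very sparse, nearly unbiased solutions; the
ridge term is strictly convex and gives the grouping effect (highly
correlated features move in and out of the model together). `alpha = 1` is
pure L1/2, `alpha = 0` is ridge; lasso and elastic-net baselines run
through the same coordinate-descent engine.

The workhorse is the closed-form half-thresholding operator

    Half(omega, lambda) = (2/3) * omega * (1 + cos(2*(pi - phi)/3)),
    phi = arccos( (lambda/8) * (|omega|/3)^(-3/2) ),

applied when `|omega| > (3/4) * lambda^(2/3)` and zero otherwise, embedded
in an IRLS + cyclic coordinate descent solver with warm-started
regularization paths and two-dimensional `(lambda, alpha)`
cross-validation.

## Worked example

Simulate the grouped-predictor benchmark (scenario 1: 5 true coefficients
out of 1000, group correlation 0.9), tune the penalty by 10-fold
cross-validation, and score the held-out test block:

```r
library(hlrnet)
dat <- generate_scenario(scenario_spec(1, 0.9), seed = 1)
cv  <- cv_hlr(dat$X_train, dat$y_train, family = "hlr", k = 10, seed = 1,
              intercept = FALSE)
cv
#> <hlr_cv> family=hlr, 10-fold CV over 30 lambda x 6 alpha (accuracy, rule=min)
#>   best: lambda=0.39621 alpha=1 (accuracy 1.0000)

pred <- predict(cv$fit, dat$X_test, type = "class")
selection_metrics(dat$beta_true, cv$fit$beta, dat$y_test, pred)
#> <selection_metrics> TP=1 FP=2 TN=993 FN=4  sens=0.200 spec=0.998 acc=0.9800
```

Reading the output: cross-validation chose `lambda = 0.396` at the
pure-L1/2 endpoint `alpha = 1`, a 3-gene model that classifies 98% of the
test samples correctly. The support tells the grouping story — at
correlation 0.9 the five true features are nearly interchangeable, so the
sparse endpoint keeps a single representative (TP=1, sensitivity 0.2) with
no accuracy cost; cells at smaller `alpha` recover the whole group when
they tie on accuracy. Single fits are available directly:

```r
fit <- hlr_fit(dat$X_train, dat$y_train,
               penalty_spec("hlr", lambda = 0.4, alpha = 0.5))
coef(fit)[coef(fit) != 0]
half_threshold(2, 1)
#> [1] 1.814402
```

The full simulation study (scenarios x correlations x methods, with
support-recovery sensitivity/specificity and test accuracy averaged over
seeded repeats) runs through `run_benchmark()`, and delimited expression
matrices come in through `read_expression_table()`.

## Command line

A thin CLI wraps the same functions
(`system.file("cli", "hlr", package = "hlrnet")`):

```sh
hlr simulate  --scenario 1 --rho 0.9 --seed 7 --out sim/
hlr cv        --data sim/train.csv --label-column y --penalty hlr --out tuned/
hlr predict   --data sim/test.csv --label-column y --model tuned/model.tsv --out preds/
hlr benchmark --scenarios 1 --rhos 0.3,0.9 --methods lasso,hlr --repeats 50 --out bench/
```

Every run writes a `config.json` snapshot sufficient to reproduce it.

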