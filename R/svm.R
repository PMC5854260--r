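## Thin wrappers around the libsvm linear classifier (e1071), converting
## the fitted support-vector expansion into explicit weights/bias so the
## decision function is portable and the positive class orientation is
## fixed: decision(x) = x %*% weights + bias, positive => label 1.

defaultRegularizationGrid <- function() 10^seq(-4, 3, length.out = 50L)

fitLinearSVM <- function(X, y, cost, classWeights = NULL) {
  yf <- factor(y, levels = c(0, 1))
  fit <- e1071::svm(X, yf, kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = classWeights)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  ## libsvm orients the decision function toward the class seen first in
  ## the data; flip so that positive decision always means label 1
  if (y[1] == 0) {
    w <- -w
    b <- -b
  }
  list(weights = w, bias = b)
}

decisionValues <- function(model, X) drop(X %*% model$weights + model$bias)

predictLabels <- function(model, X) as.numeric(decisionValues(model, X) > 0)

## subjects -> fold assignment (seeded shuffle, round robin)
assignFolds <- function(subjects, folds, seed) {
  subjects <- unique(subjects)
  if (folds < 2L) stopInvalidArgument("at least 2 folds required")
  if (length(subjects) < folds)
    stopInvalidSplit("fewer subjects than folds")
  shuffled <- withSeed(seed, sample(subjects))
  stats::setNames(rep(seq_len(folds), length.out = length(shuffled)),
                  shuffled)
}

## run expr with a temporary RNG state
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
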