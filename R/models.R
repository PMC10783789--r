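# Thin uniform interface over the four classifiers and ridge regression used
# for decoding. Regularization follows the inverse-strength C convention for
# logistic regression / SVC and the additive penalty alpha for ridge, with
# logistic regression mapped onto glmnet via lambda = 1 / (C * n).

fit_classifier <- function(x, y, model = c("logistic", "svc", "ridge", "gnb"),
                           C = 0.01, cost = 1, alpha = 50) {
  model <- match.arg(model)
  y <- factor(y)
  stop_if_not(nlevels(y) == 2, "classifier: need exactly 2 classes, got ",
              nlevels(y))
  if (model == "logistic") {
    lam <- 1 / (C * nrow(x))
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lam,
                          standardize = FALSE, thresh = 1e-6)
    return(structure(list(fit = fit, levels = levels(y)), class = "cm_logistic"))
  }
  if (model == "svc") {
    fit <- e1071::svm(x, y, type = "C-classification", kernel = "linear",
                      cost = cost, scale = FALSE)
    return(structure(list(fit = fit, levels = levels(y)), class = "cm_svc"))
  }
  if (model == "ridge") {
    # least squares on +/-1 targets with unpenalized intercept (via centering)
    yy <- ifelse(y == levels(y)[2], 1, -1)
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    w <- solve(crossprod(xc) + alpha * diag(ncol(x)), crossprod(xc, yy))
    b <- mean(yy) - sum(mu * w)
    return(structure(list(w = w, b = b, levels = levels(y)), class = "cm_ridgec"))
  }
  df <- as.data.frame(x)
  fit <- e1071::naiveBayes(df, y)
  structure(list(fit = fit, levels = levels(y), names = names(df)),
            class = "cm_gnb")
}

predict_classifier <- function(obj, x) {
  if (inherits(obj, "cm_logistic")) {
    as.character(predict(obj$fit, x, type = "class"))
  } else if (inherits(obj, "cm_svc")) {
    as.character(predict(obj$fit, x))
  } else if (inherits(obj, "cm_ridgec")) {
    score <- as.numeric(x %*% obj$w + obj$b)
    obj$levels[(score > 0) + 1L]
  } else {
    df <- as.data.frame(x)
    names(df) <- obj$names
    as.character(predict(obj$fit, df))
  }
}

# ridge regression, exact closed form with unpenalized intercept
fit_ridge_regression <- function(x, y, alpha = 50) {
  mu <- colMeans(x)
  my <- mean(y)
  xc <- sweep(x, 2, mu)
  w <- solve(crossprod(xc) + alpha * diag(ncol(x)), crossprod(xc, y - my))
  list(w = w, b = my - sum(mu * w))
}

predict_ridge_regression <- function(obj, x) {
  as.numeric(x %*% obj$w + obj$b)
}
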