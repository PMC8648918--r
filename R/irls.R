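# Ridge-stabilised iteratively reweighted least squares for logistic
# regression. The tiny ridge term keeps coefficients finite under complete
# separation, which both the categorical encoder and the logistic baseline
# rely on. The intercept is never penalised.

irls_logistic <- function(X, y, lambda = 1e-6, max_iter = 100L, tol = 1e-8,
                          intercept = TRUE) {
  X <- as.matrix(X)
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- rep(lambda, p)
  if (intercept) pen[1L] <- 0
  converged <- FALSE
  iter <- 0L
  deviance <- function(b) {
    eta <- pmin(pmax(drop(X %*% b), -30), 30)
    -2 * sum(y * eta - log1p(exp(eta)))
  }
  dev <- deviance(beta)
  for (iter in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    H <- XtW %*% X + diag(pen, p)
    beta_new <- tryCatch(drop(solve(H, XtW %*% z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    # step-halving keeps the (penalised) deviance monotone; plain IRLS can
    # oscillate once fitted probabilities saturate
    dev_new <- deviance(beta_new)
    half <- 0L
    while (dev_new > dev + 1e-10 && half < 25L) {
      beta_new <- (beta + beta_new) / 2
      dev_new <- deviance(beta_new)
      half <- half + 1L
    }
    step_ok <- max(abs(beta_new - beta)) < tol ||
      abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol
    beta <- beta_new
    dev <- dev_new
    if (step_ok) { converged <- TRUE; break }
  }
  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  list(coefficients = setNames(beta, colnames(X)),
       fitted = plogis(eta), iterations = iter, converged = converged,
       intercept = intercept)
}
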