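# The four classifier families of the evaluation protocol, behind one
# fit/score interface. Labels are passed as 0/1 (1 = deteriorated); all
# score functions return a continuous decision score oriented so that
# larger means "deteriorated", with the decision threshold at
# `score_threshold()` (0 for margin models, 0.5 for probability models).

#' Model specification for the evaluation protocol
#'
#' Encodes the family, its hyperparameter grid and whether features are
#' standardized before fitting (all families except random forest):
#' `C in {0.01, 0.1, 1, 10, 100, 1000}` for the linear SVM and logistic
#' regression, tree depth `{3, 4, 5, 6}` (Gini splits) for the random
#' forest, and `{1, 2, 3}` hidden layers of 100 ReLU units (Adam,
#' learning rate 0.001) for the multi-layer perceptron.
#'
#' @param family one of `"LR"`, `"SVM"`, `"RF"`, `"MLP"`.
#' @return a list of class `model_spec` with `family`, `grid`,
#'   `standardize`.
#' @export
model_spec <- function(family = c("LR", "SVM", "RF", "MLP")) {
  family <- match.arg(family)
  grid <- switch(family,
    LR = data.frame(C = c(0.01, 0.1, 1, 10, 100, 1000)),
    SVM = data.frame(C = c(0.01, 0.1, 1, 10, 100, 1000)),
    RF = data.frame(depth = 3:6),
    MLP = data.frame(n_layers = 1:3))
  structure(list(family = family, grid = grid,
                 standardize = family != "RF"),
            class = "model_spec")
}

score_threshold <- function(family) {
  if (family %in% c("LR", "SVM", "MLP")) 0 else 0.5
}

fit_model <- function(family, params, X, y, seed = 1) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), length(unique(y)) == 2L)
  fit <- switch(family,
    LR = fit_ridge_logistic(X, y, C = params$C),
    SVM = {
      yf <- factor(y, levels = c(0, 1))
      m <- e1071::svm(X, yf, kernel = "linear", cost = params$C,
                      scale = FALSE)
      list(svm = m)
    },
    RF = {
      df <- as.data.frame(X)
      df$.y <- factor(y, levels = c(0, 1))
      m <- ranger::ranger(.y ~ ., data = df, num.trees = 500,
                          mtry = max(1L, floor(sqrt(ncol(X)))),
                          max.depth = params$depth, splitrule = "gini",
                          probability = TRUE, seed = seed,
                          num.threads = 1)
      list(rf = m)
    },
    MLP = fit_mlp(X, y, layers = rep(100L, params$n_layers), seed = seed))
  structure(list(family = family, params = params, fit = fit),
            class = "coldperf_model")
}

predict_scores <- function(model, X) {
  X <- as.matrix(X)
  switch(model$family,
    LR = drop(cbind(1, X) %*% model$fit$beta),
    SVM = {
      pr <- stats::predict(model$fit$svm, X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # e1071 orients the margin toward the first label of the colname pair
      if (startsWith(colnames(dv)[1L], "0")) -drop(dv) else drop(dv)
    },
    RF = {
      p <- stats::predict(model$fit$rf, data = as.data.frame(X),
                          num.threads = 1)$predictions
      p[, "1"]
    },
    MLP = drop(mlp_forward(model$fit, X)$logit))
}

# ---- L2-penalized logistic regression (IRLS) --------------------------------

# Minimizes -loglik + (1/(2C)) ||w||^2 (intercept unpenalized) by Newton
# iterations; exact for the C parameterization used by the protocol.
fit_ridge_logistic <- function(X, y, C, max_iter = 50, tol = 1e-10) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  beta <- numeric(p)
  pen <- c(0, rep(1 / C, p - 1L))
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Xd, y - mu)) - pen * beta
    H <- crossprod(Xd * w, Xd) + diag(pen, p)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta)
}

# ---- multi-layer perceptron -------------------------------------------------

# Fully connected ReLU network with sigmoid output, trained full-batch with
# Adam (lr 0.001, beta1 0.9, beta2 0.999) on binary cross-entropy for a
# fixed 200 epochs; He-initialized, seeded.
fit_mlp <- function(X, y, layers = c(100L), lr = 0.001, epochs = 200L,
                    seed = 1) {
  n <- nrow(X); d <- ncol(X)
  sizes <- c(d, layers, 1L)
  nl <- length(sizes) - 1L
  W <- vector("list", nl); b <- vector("list", nl)
  with_seed(seed, {
    for (l in seq_len(nl)) {
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                    sd = sqrt(2 / sizes[l])),
                       nrow = sizes[l])
      b[[l]] <- numeric(sizes[l + 1L])
    }
  })
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (ep in seq_len(epochs)) {
    # forward
    a <- vector("list", nl + 1L)
    a[[1L]] <- X
    for (l in seq_len(nl - 1L)) {
      z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
      a[[l + 1L]] <- pmax(z, 0)
    }
    logit <- drop(sweep(a[[nl]] %*% W[[nl]], 2, b[[nl]], "+"))
    mu <- 1 / (1 + exp(-logit))
    # backward (BCE with sigmoid: dL/dlogit = mu - y)
    delta <- matrix((mu - y) / n, ncol = 1L)
    gW <- vector("list", nl); gb <- vector("list", nl)
    for (l in nl:1L) {
      gW[[l]] <- crossprod(a[[l]], delta)
      gb[[l]] <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
      }
    }
    # Adam update
    for (l in seq_len(nl)) {
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW[[l]]
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW[[l]]^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb[[l]]
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb[[l]]^2
      mhW <- mW[[l]] / (1 - b1^ep); vhW <- vW[[l]] / (1 - b2^ep)
      mhb <- mb[[l]] / (1 - b1^ep); vhb <- vb[[l]] / (1 - b2^ep)
      W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
      b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
    }
  }
  list(W = W, b = b)
}

mlp_forward <- function(fit, X) {
  nl <- length(fit$W)
  a <- X
  for (l in seq_len(nl - 1L)) {
    a <- pmax(sweep(a %*% fit$W[[l]], 2, fit$b[[l]], "+"), 0)
  }
  logit <- drop(sweep(a %*% fit$W[[nl]], 2, fit$b[[nl]], "+"))
  list(logit = logit, prob = 1 / (1 + exp(-logit)))
}
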