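## Small multilayer perceptron: logistic activations throughout, one
## logistic output unit per class, 1..5 hidden layers of equal width,
## trained by batch BFGS on the cross-entropy with an L2 penalty.
## Deterministic given the initialisation seed.

.mlpSizes <- function(p, layers, neurons, K) {
  c(p, rep(neurons, layers), K)
}

.mlpInit <- function(sizes, seed) {
  set.seed(as.integer(seed %% 2147483647))
  unlist(lapply(seq_len(length(sizes) - 1L), function(l) {
    fanIn <- sizes[l]
    c(stats::rnorm(fanIn * sizes[l + 1L], 0, 1 / sqrt(fanIn)),
      rep(0, sizes[l + 1L]))
  }))
}

.mlpUnflatten <- function(par, sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  off <- 0L
  for (l in seq_len(L)) {
    nw <- sizes[l] * sizes[l + 1L]
    W[[l]] <- matrix(par[off + seq_len(nw)], sizes[l], sizes[l + 1L])
    off <- off + nw
    b[[l]] <- par[off + seq_len(sizes[l + 1L])]
    off <- off + sizes[l + 1L]
  }
  list(W = W, b = b)
}

.mlpForward <- function(par, sizes, X) {
  wb <- .mlpUnflatten(par, sizes)
  L <- length(sizes) - 1L
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% wb$W[[l]], 2L, wb$b[[l]], "+")
    A[[l + 1L]] <- stats::plogis(Z)
  }
  list(A = A, wb = wb)
}

.mlpLoss <- function(par, sizes, X, Y, lambda) {
  O <- .mlpForward(par, sizes, X)$A[[length(sizes)]]
  O <- pmin(pmax(O, 1e-12), 1 - 1e-12)
  wb <- .mlpUnflatten(par, sizes)
  penalty <- lambda / 2 * sum(vapply(wb$W, function(w) sum(w^2), numeric(1)))
  -sum(Y * log(O) + (1 - Y) * log(1 - O)) / nrow(X) + penalty
}

.mlpGrad <- function(par, sizes, X, Y, lambda) {
  fw <- .mlpForward(par, sizes, X)
  A <- fw$A
  wb <- fw$wb
  L <- length(sizes) - 1L
  n <- nrow(X)
  grads <- vector("list", L)
  delta <- (A[[L + 1L]] - Y) / n
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(A[[l]], delta) + lambda * wb$W[[l]],
                       b = colSums(delta))
    if (l > 1L)
      delta <- (delta %*% t(wb$W[[l]])) * A[[l]] * (1 - A[[l]])
  }
  unlist(lapply(grads, function(g) c(as.numeric(g$W), g$b)))
}

.mlpTrain <- function(X, Y, layers, neurons, seed, maxit = 300,
                      lambda = 1e-4) {
  sizes <- .mlpSizes(ncol(X), layers, neurons, ncol(Y))
  par0 <- .mlpInit(sizes, seed)
  fit <- stats::optim(par0, fn = .mlpLoss, gr = .mlpGrad, sizes = sizes,
                      X = X, Y = Y, lambda = lambda, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  list(par = fit$par, sizes = sizes, layers = layers, neurons = neurons,
       value = fit$value)
}

.mlpPredictProb <- function(fit, X) {
  .mlpForward(fit$par, fit$sizes, X)$A[[length(fit$sizes)]]
}
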