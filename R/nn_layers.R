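## Internal neural-network primitives: dilated 1-D convolution (im2col over
## BLAS matmul), batch/layer normalisation, activations, linear maps, and
## softmax -- each with a hand-derived backward pass. Finite-difference
## gradient checks in the test suite cover every layer.

## ---- initialisers (draw from the current RNG stream) ----------------------

.init_matrix <- function(nin, nout, scale = sqrt(2 / nin)) {
  matrix(stats::rnorm(nin * nout, sd = scale), nin, nout)
}

## ---- dilated conv1d -------------------------------------------------------

## weights stored im2col-style: W is (cin*k) x cout, taps stacked rowwise
conv1d_init <- function(k, cin, cout) {
  stopifnot(k %% 2L == 1L)
  list(W = .init_matrix(cin * k, cout), b = numeric(cout),
       k = k, cin = cin, cout = cout)
}

## gather indices for im2col are pure geometry (window length, kernel,
## dilation, channels), so they are built once and memoised
.conv_idx_cache <- new.env(parent = emptyenv())

.im2col_idx <- function(L, k, dil, cin) {
  key <- paste(L, k, dil, cin, sep = "_")
  idx <- .conv_idx_cache[[key]]
  if (is.null(idx)) {
    idx <- matrix(0L, L, cin * k)
    for (t in seq_len(k)) {
      r <- seq_len(L) + (t - (k + 1L) %/% 2L) * dil
      r[r < 1L | r > L] <- L + 1L  # the appended zero row
      idx[, ((t - 1L) * cin + 1L):(t * cin)] <-
        outer(r, (seq_len(cin) - 1L) * (L + 1L), `+`)
    }
    .conv_idx_cache[[key]] <- idx
  }
  idx
}

.im2col <- function(X, k, dil) {
  L <- nrow(X); cin <- ncol(X)
  idx <- .im2col_idx(L, k, dil, cin)
  Xz <- rbind(X, 0)  # out-of-window taps read the zero row
  Xs <- Xz[idx]
  dim(Xs) <- dim(idx)
  Xs
}

## broadcast a length-C vector over the rows of an L x C matrix
.add_col <- function(Y, b) Y + rep(b, each = nrow(Y))
.mul_col <- function(Y, s) Y * rep(s, each = nrow(Y))

conv1d_forward <- function(par, X, dil) {
  Xs <- .im2col(X, par$k, dil)
  Y <- .add_col(Xs %*% par$W, par$b)
  list(Y = Y, cache = list(Xs = Xs, dil = dil, k = par$k, cin = par$cin,
                           L = nrow(X)))
}

conv1d_backward <- function(par, cache, dY) {
  dW <- crossprod(cache$Xs, dY)
  db <- colSums(dY)
  ## dX is the correlation of dY with the tap-reversed, transposed kernel:
  ## one im2col plus one BLAS multiply instead of a per-tap scatter-add
  k <- cache$k; cin <- cache$cin
  cout <- ncol(dY)
  Wb <- matrix(0, cout * k, cin)
  for (t in seq_len(k)) {
    src <- ((k - t) * cin + 1L):((k - t + 1L) * cin)
    Wb[((t - 1L) * cout + 1L):(t * cout), ] <- t(par$W[src, , drop = FALSE])
  }
  dX <- .im2col(dY, k, cache$dil) %*% Wb
  list(grads = list(W = dW, b = db), dX = dX)
}

## ---- batch normalisation (positions act as the batch dimension) -----------

bn_init <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C),
       rm = numeric(C), rv = rep(1, C))
}

bn_forward <- function(par, X, train, momentum = 0.1, eps = 1e-5) {
  if (train) {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    par$rm <- (1 - momentum) * par$rm + momentum * mu
    par$rv <- (1 - momentum) * par$rv + momentum * v
  } else {
    mu <- par$rm; v <- par$rv
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- .add_col(.mul_col(X, inv), -mu * inv)
  Y <- .add_col(.mul_col(xhat, par$gamma), par$beta)
  list(Y = Y, par = par, cache = list(xhat = xhat, inv = inv, train = train))
}

bn_backward <- function(par, cache, dY) {
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  if (cache$train) {
    N <- nrow(dY)
    t1 <- .add_col(dY, -colMeans(dY))
    t2 <- .mul_col(xhat, colSums(dY * xhat) / N)
    dX <- .mul_col(t1 - t2, par$gamma * cache$inv)
  } else {
    dX <- .mul_col(dY, par$gamma * cache$inv)
  }
  list(grads = list(gamma = dgamma, beta = dbeta), dX = dX)
}

## ---- layer normalisation (over the feature dimension, rowwise) ------------

ln_init <- function(C) list(gamma = rep(1, C), beta = numeric(C))

ln_forward <- function(par, X, eps = 1e-5) {
  mu <- rowMeans(X)
  v <- rowMeans(X^2) - mu^2
  inv <- 1 / sqrt(v + eps)
  xhat <- (X - mu) * inv
  Y <- sweep(sweep(xhat, 2L, par$gamma, "*"), 2L, par$beta, "+")
  list(Y = Y, cache = list(xhat = xhat, inv = inv))
}

ln_backward <- function(par, cache, dY) {
  xhat <- cache$xhat; inv <- cache$inv
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, par$gamma, "*")
  C <- ncol(dY)
  dX <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(grads = list(gamma = dgamma, beta = dbeta), dX = dX)
}

## ---- activations ----------------------------------------------------------

relu_forward <- function(X) list(Y = pmax(X, 0), cache = X > 0)
relu_backward <- function(cache, dY) dY * cache

leaky_relu_forward <- function(X, slope = 0.01) {
  pos <- X > 0
  Y <- X
  Y[!pos] <- slope * X[!pos]
  list(Y = Y, cache = list(pos = pos, slope = slope))
}
leaky_relu_backward <- function(cache, dY) {
  dX <- dY
  dX[!cache$pos] <- cache$slope * dY[!cache$pos]
  dX
}

gelu_forward <- function(X) {
  Phi <- stats::pnorm(X)
  list(Y = X * Phi, cache = list(X = X, Phi = Phi))
}
gelu_backward <- function(cache, dY) {
  dY * (cache$Phi + cache$X * stats::dnorm(cache$X))
}

## ---- linear ---------------------------------------------------------------

linear_init <- function(nin, nout, scale = sqrt(1 / nin)) {
  list(W = .init_matrix(nin, nout, scale), b = numeric(nout))
}

linear_forward <- function(par, X) {
  list(Y = .add_col(X %*% par$W, par$b), cache = X)
}

linear_backward <- function(par, cache, dY) {
  list(grads = list(W = crossprod(cache, dY), b = colSums(dY)),
       dX = tcrossprod(dY, par$W))
}

## ---- softmax --------------------------------------------------------------

softmax_rows <- function(Z) {
  m <- do.call(pmax, c(lapply(seq_len(ncol(Z)), function(j) Z[, j]),
                       list(na.rm = FALSE)))
  E <- exp(Z - m)
  E / rowSums(E)
}

## backward of Y = softmax_rows(Z): dZ = Y * (dY - rowSums(dY * Y))
softmax_rows_backward <- function(Y, dY) {
  Y * (dY - rowSums(dY * Y))
}

## ---- parameter tree utilities ---------------------------------------------

## Walk the gradient tree (whose leaves are exactly the optimisable
## parameters) and apply f(param_leaf, grad_leaf, state_leaf) -> list(par,
## state). Non-gradient leaves of `params` (e.g. batch-norm running stats,
## integer shape fields) are left untouched.
.tree_map <- function(params, grads, state, f) {
  if (is.null(state) || length(state) < length(grads)) {
    state <- vector("list", length(grads))
    names(state) <- names(grads)
  }
  keys <- if (is.null(names(grads))) seq_along(grads) else names(grads)
  for (nm in keys) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st <- state[[nm]]
    if (is.list(g)) {
      res <- .tree_map(params[[nm]], g, st, f)
      params[[nm]] <- res$par
      state[[nm]] <- res$state
    } else {
      res <- f(params[[nm]], g, st)
      params[[nm]] <- res$par
      state[[nm]] <- res$state
    }
  }
  list(par = params, state = state)
}

## elementwise accumulate two gradient trees with identical structure
.tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(b)) {
    keys <- if (is.null(names(b))) seq_along(b) else names(b)
    for (nm in keys) a[[nm]] <- .tree_add(a[[nm]], b[[nm]])
    a
  } else {
    a + b
  }
}

.tree_scale <- function(a, s) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- .tree_scale(a[[nm]], s)
    a
  } else {
    a * s
  }
}
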