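# Broad Learning System: random feature-mapping and enhancement nodes with a
# closed-form ridge pseudo-inverse output solve. In ensemble mode the feature
# nodes read the shallow vector x_d and the enhancement nodes read the deep
# vector x_e; in classic mode the enhancement layer reads the feature-node
# block itself, as in the original BLS.

activation_fn <- function(name) {
  switch(name,
         identity = function(x) x,
         linear   = function(x) x,
         tanh     = tanh,
         relu     = relu,
         sigmoid  = function(x) 1 / (1 + exp(-x)),
         stop("unknown activation '", name, "'"))
}

SWEEP_RANGES <- list(n_feature_nodes = c(500, 4000),
                     n_enh_nodes = c(100, 1000),
                     sparsity = c(0.4, 0.7))

#' Configuration of the broad learner
#'
#' @param n_feature_nodes Total number of feature-mapping nodes; the
#'   hyperparameter sweep explores 500-4000.
#' @param n_enh_nodes Total number of enhancement nodes; sweep range 100-1000.
#' @param n_feature_groups,n_enh_groups Number of equal-width node groups the
#'   totals are split into (each group has its own random weights).
#' @param phi Feature-node activation; `"identity"` by default (a selectable
#'   linear or non-linear map).
#' @param delta Enhancement-node activation; `"tanh"` by default.
#' @param sparsity L1 coefficient of the optional sparse auto-coding of the
#'   mapping weights; 0 (default) disables it. Sweep range 0.4-0.7.
#' @param lam Ridge regularizer of the output solve. The pseudo-inverse is
#'   defined as the limit lambda -> 0; a tiny positive value keeps the solve
#'   numerically safe.
#' @param seed RNG seed for the random node weights.
#' @param mode `"ensemble"` (enhancement nodes read the deep vector) or
#'   `"classic"` (they read the feature-node block).
#' @param sweep_mode If `TRUE`, node counts and sparsity are validated
#'   against the sweep ranges above; outside sweep mode arbitrary values are
#'   allowed.
#' @return A list of class `bls_config`.
#' @export
bls_config <- function(n_feature_nodes = 1000L, n_enh_nodes = 500L,
                       n_feature_groups = 1L, n_enh_groups = 1L,
                       phi = "identity", delta = "tanh",
                       sparsity = 0, lam = 1e-8, seed = 1L,
                       mode = c("ensemble", "classic"),
                       sweep_mode = FALSE) {
  mode <- match.arg(mode)
  n_feature_nodes <- as.integer(n_feature_nodes)
  n_enh_nodes <- as.integer(n_enh_nodes)
  stopifnot(n_feature_nodes >= 1L, n_enh_nodes >= 1L, lam > 0, sparsity >= 0)
  if (n_feature_nodes %% n_feature_groups != 0L ||
      n_enh_nodes %% n_enh_groups != 0L)
    stop("group counts must divide the node totals")
  activation_fn(phi); activation_fn(delta)   # fail fast on unknown names
  if (isTRUE(sweep_mode)) {
    chk <- function(val, key) {
      r <- SWEEP_RANGES[[key]]
      if (val < r[1] || val > r[2])
        stop(key, " = ", val, " outside sweep range [", r[1], ", ", r[2], "]")
    }
    chk(n_feature_nodes, "n_feature_nodes")
    chk(n_enh_nodes, "n_enh_nodes")
    if (sparsity > 0) chk(sparsity, "sparsity")
  }
  structure(list(n_feature_nodes = n_feature_nodes, n_enh_nodes = n_enh_nodes,
                 n_feature_groups = as.integer(n_feature_groups),
                 n_enh_groups = as.integer(n_enh_groups),
                 phi = phi, delta = delta, sparsity = sparsity, lam = lam,
                 seed = as.integer(seed), mode = mode,
                 sweep_mode = isTRUE(sweep_mode)),
            class = "bls_config")
}

#' Compute the feature-node block D
#'
#' `D = phi(X W_e + b_e)`, with columns grouped as the concatenation of the
#' per-group node outputs.
#'
#' @param X Sample-by-dimension input matrix.
#' @param W_e Mapping weights: a matrix or a list of per-group matrices.
#' @param b_e Mapping biases: a vector or list matching `W_e`.
#' @param phi Activation name.
#' @return `n x n_feature_nodes` matrix.
#' @export
feature_nodes <- function(X, W_e, b_e, phi = "identity") {
  f <- activation_fn(phi)
  if (!is.list(W_e)) { W_e <- list(W_e); b_e <- list(b_e) }
  blocks <- mapply(function(W, b) {
    if (ncol(X) != nrow(W))
      stop("dimension mismatch: X has ", ncol(X), " columns, W_e expects ",
           nrow(W))
    f(sweep(X %*% W, 2L, b, "+"))
  }, W_e, b_e, SIMPLIFY = FALSE)
  do.call(cbind, blocks)
}

#' Compute the enhancement-node block E
#'
#' `E = delta(S W_h + b_h)` where the source `S` is the deep feature matrix
#' in ensemble mode and the feature-node block `D` in classic mode; the
#' caller passes the source explicitly.
#'
#' @param S Source matrix.
#' @param W_h Enhancement weights (matrix or list of group matrices).
#' @param b_h Enhancement biases.
#' @param delta Activation name.
#' @return `n x n_enh_nodes` matrix.
#' @export
enhancement_nodes <- function(S, W_h, b_h, delta = "tanh") {
  f <- activation_fn(delta)
  if (!is.list(W_h)) { W_h <- list(W_h); b_h <- list(b_h) }
  blocks <- mapply(function(W, b) {
    if (ncol(S) != nrow(W))
      stop("dimension mismatch: source has ", ncol(S), " columns, W_h expects ",
           nrow(W))
    f(sweep(S %*% W, 2L, b, "+"))
  }, W_h, b_h, SIMPLIFY = FALSE)
  do.call(cbind, blocks)
}

#' Ridge pseudo-inverse
#'
#' `G+ = (lambda I + G'G)^-1 G'`, the regularized Moore-Penrose limit, via a
#' numerically stable solve. When `n < p` the algebraically identical dual
#' form `G'(lambda I + GG')^-1` is used, so wide state matrices (many nodes,
#' few samples) stay cheap.
#'
#' @param G State matrix (`n x p`).
#' @param lam Positive ridge coefficient.
#' @return `p x n` matrix.
#' @export
ridge_pinv <- function(G, lam) {
  G <- as.matrix(G)
  stopifnot(lam > 0)
  if (!all(is.finite(G))) stop("non-finite entries in G")
  n <- nrow(G); p <- ncol(G)
  if (n <= p) t(G) %*% solve(tcrossprod(G) + diag(lam, n))
  else solve(crossprod(G) + diag(lam, p), t(G))
}

#' Solve the BLS output weights in closed form
#'
#' `W = G+ Y`, the minimizer of `||Y - G W||^2 + lambda ||W||^2`. The product
#' is formed without materialising the pseudo-inverse.
#'
#' @param G State matrix (`n x p`).
#' @param Y Target matrix (`n x k`), typically one-hot labels.
#' @param lam Positive ridge coefficient.
#' @return `p x k` weight matrix.
#' @export
fit_output_weights <- function(G, Y, lam) {
  G <- as.matrix(G); Y <- as.matrix(Y)
  if (nrow(G) != nrow(Y)) stop("row counts of G and Y differ")
  if (!all(is.finite(G))) stop("non-finite entries in G")
  stopifnot(lam > 0)
  n <- nrow(G); p <- ncol(G)
  if (n <= p) t(G) %*% solve(tcrossprod(G) + diag(lam, n), Y)
  else solve(crossprod(G) + diag(lam, p), crossprod(G, Y))
}

#' Ridge training objective
#'
#' `||Y - G W||_F^2 + lambda ||W||_F^2`, the quantity minimized by
#' [fit_output_weights()].
#'
#' @param G,Y,W,lam State matrix, targets, output weights, ridge coefficient.
#' @return Scalar objective value.
#' @export
ridge_objective <- function(G, Y, W, lam) {
  sum((Y - G %*% W)^2) + lam * sum(W^2)
}

#' Sparse auto-coding of mapping weights
#'
#' Refines an initial random mapping by solving the lasso problem
#' `min_W ||Z W - X||_F^2 + sparsity * ||W||_1` with `Z = phi(X W_init +
#' b_init)`, by ISTA (iterative soft-thresholding). With `sparsity = 0` the
#' exact least-squares solution is returned. The transpose of the solution is
#' used as the refined mapping weight.
#'
#' @param X Input matrix (`n x d`).
#' @param W_init Initial random mapping (`d x k`).
#' @param b_init Initial bias (length `k`).
#' @param sparsity Non-negative L1 coefficient.
#' @param phi Activation used to form `Z`.
#' @param max_iter,tol ISTA iteration cap and relative-change tolerance; if
#'   the tolerance is not reached a warning is raised and the best iterate
#'   returned.
#' @return `k x d` coefficient matrix.
#' @export
sparse_autoencode_weights <- function(X, W_init, b_init = numeric(ncol(W_init)),
                                      sparsity, phi = "identity",
                                      max_iter = 50L, tol = 1e-6) {
  stopifnot(sparsity >= 0)
  f <- activation_fn(phi)
  Z <- f(sweep(X %*% W_init, 2L, b_init, "+"))
  if (sparsity == 0) {
    # minimum-norm least squares; Z is typically rank-deficient (more nodes
    # than input dimensions), so solve through the SVD
    sv <- svd(Z)
    pos <- sv$d > max(dim(Z)) * .Machine$double.eps * sv$d[1]
    return(sv$v[, pos, drop = FALSE] %*%
             ((t(sv$u[, pos, drop = FALSE]) %*% X) / sv$d[pos]))
  }
  L <- 2 * norm(Z, "2")^2            # Lipschitz constant of the gradient
  step <- 1 / L
  W <- matrix(0, ncol(Z), ncol(X))
  ZtZ <- crossprod(Z)
  ZtX <- crossprod(Z, X)
  soft <- function(M, t) sign(M) * pmax(abs(M) - t, 0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    grad <- 2 * (ZtZ %*% W - ZtX)
    W_new <- soft(W - step * grad, step * sparsity)
    delta <- norm(W_new - W, "F") / max(1, norm(W, "F"))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("sparse auto-coding did not converge in ", max_iter,
            " iterations; returning best iterate")
  W
}

one_hot <- function(y, classes) {
  Y <- matrix(0, length(y), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(y), match(as.character(y), classes))] <- 1
  Y
}

#' Fit a Broad Learning System
#'
#' Draws the random mapping and enhancement weights from the seeded RNG
#' (uniform on \[-1, 1\]), optionally refines the mapping weights by sparse
#' auto-coding, builds the state matrix `G = [D | E]`, and solves the output
#' weights in closed form. Only `W_out` is learned; everything else stays
#' fixed.
#'
#' @param X_d Shallow feature matrix (`n x d`), the feature-node input.
#' @param y Class labels (factor or character), length `n`.
#' @param X_e Deep feature matrix (`n x e`), the enhancement-node source in
#'   ensemble mode; ignored (may be `NULL`) in classic mode.
#' @param config A [bls_config()].
#' @return An object of class `bls_model`.
#' @export
bls_fit <- function(X_d, y, X_e = NULL, config = bls_config()) {
  stopifnot(inherits(config, "bls_config"))
  X_d <- as.matrix(X_d)
  n <- nrow(X_d)
  if (length(y) != n) stop("label length does not match row count")
  if (config$mode == "ensemble") {
    if (is.null(X_e)) stop("ensemble mode requires the deep feature matrix X_e")
    X_e <- as.matrix(X_e)
    if (nrow(X_e) != n) stop("X_d and X_e row counts differ")
  }
  classes <- if (is.factor(y)) levels(droplevels(y)) else sort(unique(as.character(y)))
  Y <- one_hot(y, classes)

  gw_f <- config$n_feature_nodes %/% config$n_feature_groups
  gw_e <- config$n_enh_nodes %/% config$n_enh_groups

  params <- with_local_seed(config$seed, {
    W_e <- vector("list", config$n_feature_groups)
    b_e <- vector("list", config$n_feature_groups)
    for (g in seq_len(config$n_feature_groups)) {
      W_e[[g]] <- matrix(runif(ncol(X_d) * gw_f, -1, 1), ncol(X_d), gw_f)
      b_e[[g]] <- runif(gw_f, -1, 1)
    }
    if (config$sparsity > 0) {
      for (g in seq_len(config$n_feature_groups)) {
        W_s <- sparse_autoencode_weights(X_d, W_e[[g]], b_e[[g]],
                                         config$sparsity, config$phi)
        W_e[[g]] <- t(W_s)
        b_e[[g]] <- numeric(gw_f)
      }
    }
    src_dim <- if (config$mode == "ensemble") ncol(X_e)
               else config$n_feature_nodes
    W_h <- vector("list", config$n_enh_groups)
    b_h <- vector("list", config$n_enh_groups)
    for (g in seq_len(config$n_enh_groups)) {
      W_h[[g]] <- matrix(runif(src_dim * gw_e, -1, 1), src_dim, gw_e)
      b_h[[g]] <- runif(gw_e, -1, 1)
    }
    list(W_e = W_e, b_e = b_e, W_h = W_h, b_h = b_h)
  })

  D <- feature_nodes(X_d, params$W_e, params$b_e, config$phi)
  S <- if (config$mode == "ensemble") X_e else D
  E <- enhancement_nodes(S, params$W_h, params$b_h, config$delta)
  G <- cbind(D, E)
  W_out <- fit_output_weights(G, Y, config$lam)

  model <- structure(list(config = config, classes = classes,
                          W_e = params$W_e, b_e = params$b_e,
                          W_h = params$W_h, b_h = params$b_h,
                          W_out = W_out, input_dims = c(d = ncol(X_d),
                            e = if (config$mode == "ensemble") ncol(X_e) else NA_integer_),
                          fitted = TRUE),
                     class = "bls_model")
  model
}

#' @export
print.bls_model <- function(x, ...) {
  cat("<bls_model> mode", x$config$mode, "|", x$config$n_feature_nodes,
      "feature +", x$config$n_enh_nodes, "enhancement nodes | classes:",
      paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' Predict with a fitted Broad Learning System
#'
#' Linear scores are `G W_out` per sample; the label is the argmax over
#' classes (first index on ties). `prob` is the softmax of the scores — a
#' monotone, calibration-free convenience view; ROC analysis uses the raw
#' scores.
#'
#' @param object A fitted `bls_model`.
#' @param X_d Shallow feature matrix.
#' @param X_e Deep feature matrix (ensemble mode).
#' @param ... Unused.
#' @return List with `scores`, `prob` (both `n x k`, columns named by class)
#'   and `labels` (character vector).
#' @export
predict.bls_model <- function(object, X_d, X_e = NULL, ...) {
  if (!isTRUE(object$fitted) || is.null(object$W_out))
    stop("model has not been fitted")
  X_d <- as.matrix(X_d)
  D <- feature_nodes(X_d, object$W_e, object$b_e, object$config$phi)
  S <- if (object$config$mode == "ensemble") {
    if (is.null(X_e)) stop("ensemble mode requires X_e")
    as.matrix(X_e)
  } else D
  E <- enhancement_nodes(S, object$W_h, object$b_h, object$config$delta)
  G <- cbind(D, E)
  scores <- G %*% object$W_out
  colnames(scores) <- object$classes
  m <- apply(scores, 1L, max)
  ex <- exp(scores - m)
  prob <- ex / rowSums(ex)
  labels <- object$classes[max.col(scores, ties.method = "first")]
  list(scores = scores, prob = prob, labels = labels)
}
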