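#' Fit a partial-least-squares projection of the summary statistics
#'
#' Orthogonal-scores (NIPALS) PLS2 regression of the simulation
#' parameters (responses, typically on their log prior scale) on the 13
#' transformed summary statistics, fitted to a prior-predictive batch of
#' simulations. Columns of both blocks are centred and scaled to unit
#' variance. The fitted object stores the centring/scaling constants and
#' the rotation matrix `R = W (P'W)^-1`, so that projecting new data is a
#' plain affine map applied identically to empirical and simulated
#' statistics.
#'
#' @param X Numeric matrix `n x 13` of transformed summary statistics.
#' @param Y Numeric matrix `n x q` of (transformed) parameter draws.
#' @param k Number of components to extract (default 6).
#' @return A `pls_projection`: list with `center`, `scale`, `W`, `P`,
#'   `rotation`, `Q`, `y_center`, `y_scale`, `k`, and the training scores
#'   `scores`.
#' @export
fit_projection <- function(X, Y, k = 6) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), nrow(X) > ncol(X), k <= ncol(X))
  sx <- apply(X, 2, sd)
  if (any(sx == 0))
    stop("constant statistic column(s): ",
         paste(colnames(X)[sx == 0], collapse = ", "))
  cx <- colMeans(X)
  cy <- colMeans(Y)
  sy <- apply(Y, 2, sd)
  sy[sy == 0] <- 1
  E <- sweep(sweep(X, 2, cx), 2, sx, "/")
  F_ <- sweep(sweep(Y, 2, cy), 2, sy, "/")
  p <- ncol(E); q <- ncol(F_); n <- nrow(E)
  W <- matrix(0, p, k); P <- matrix(0, p, k)
  Q <- matrix(0, q, k); TT <- matrix(0, n, k)
  for (h in seq_len(k)) {
    u <- F_[, which.max(apply(F_, 2, var))]
    w <- rep(0, p)
    for (it in 1:500) {
      w_new <- drop(crossprod(E, u))
      w_new <- w_new / sqrt(sum(w_new^2))
      tt <- drop(E %*% w_new)
      qq <- drop(crossprod(F_, tt)) / sum(tt^2)
      u_new <- drop(F_ %*% qq) / sum(qq^2)
      if (sqrt(sum((w_new - w)^2)) < 1e-12) { w <- w_new; u <- u_new; break }
      w <- w_new; u <- u_new
    }
    tt <- drop(E %*% w)
    pp <- drop(crossprod(E, tt)) / sum(tt^2)
    qq <- drop(crossprod(F_, tt)) / sum(tt^2)
    E <- E - tcrossprod(tt, pp)
    F_ <- F_ - tcrossprod(tt, qq)
    W[, h] <- w; P[, h] <- pp; Q[, h] <- qq; TT[, h] <- tt
  }
  R <- W %*% solve(crossprod(P, W))
  dimnames(R) <- list(colnames(X), paste0("comp", seq_len(k)))
  structure(list(center = setNames(cx, colnames(X)),
                 scale = setNames(sx, colnames(X)),
                 W = W, P = P, rotation = R, Q = Q,
                 y_center = cy, y_scale = sy, y_names = colnames(Y),
                 k = k, scores = TT),
            class = "pls_projection")
}

#' @export
print.pls_projection <- function(x, ...) {
  cat("PLS projection: ", length(x$center), " statistics -> ", x$k,
      " components (", nrow(x$scores), " training simulations)\n",
      sep = "")
  invisible(x)
}

#' Project transformed statistics onto the fitted PLS components
#'
#' @param x Named 13-vector of transformed statistics, or a matrix with
#'   one row per observation (columns matching the training statistics).
#' @param proj A [fit_projection()] object.
#' @return Score vector (or matrix) with `proj$k` columns; rows
#'   containing `NA` sentinels project to `NA` scores.
#' @export
project_scores <- function(x, proj) {
  stopifnot(inherits(proj, "pls_projection"))
  xm <- if (is.null(dim(x))) matrix(x, 1, dimnames = list(NULL, names(x)))
        else as.matrix(x)
  if (ncol(xm) != length(proj$center)) stop("dimension mismatch")
  if (!is.null(colnames(xm))) xm <- xm[, names(proj$center), drop = FALSE]
  xs <- sweep(sweep(xm, 2, proj$center), 2, proj$scale, "/")
  sc <- xs %*% proj$rotation
  if (is.null(dim(x))) drop(sc) else sc
}

# standardized-scale regression coefficients for k components
pls_coef <- function(proj, k = proj$k) {
  proj$rotation[, seq_len(k), drop = FALSE] %*%
    t(proj$Q[, seq_len(k), drop = FALSE])
}

#' Predict responses from a fitted projection
#'
#' @param object A `pls_projection`.
#' @param newdata Matrix of transformed statistics.
#' @param k Number of components to use.
#' @param ... Unused.
#' @return Matrix of predicted responses on their original scale.
#' @export
predict.pls_projection <- function(object, newdata, k = object$k, ...) {
  xm <- as.matrix(newdata)
  if (!is.null(colnames(xm))) xm <- xm[, names(object$center), drop = FALSE]
  xs <- sweep(sweep(xm, 2, object$center), 2, object$scale, "/")
  yh <- xs %*% pls_coef(object, k)
  yh <- sweep(sweep(yh, 2, object$y_scale, "*"), 2, object$y_center, "+")
  colnames(yh) <- object$y_names
  yh
}

#' Choose the number of PLS components by leave-one-out cross-validation
#'
#' Refits the projection with each observation left out and accumulates
#' the squared prediction error of the responses (on their standardised
#' scale) for every component count up to `k_max`. The chosen `k` is the
#' smallest count whose error is within a relative tolerance of the
#' minimum (a parsimony rule: cross-validation curves typically flatten
#' once the informative rank is reached, and the flat tail should not
#' drag the choice upward).
#'
#' @param X,Y As in [fit_projection()].
#' @param k_max Largest component count considered.
#' @param tol Relative tolerance for the parsimony rule (default 0.05).
#' @return List with the chosen `k` and the per-`k` error curve `press`.
#' @export
select_components <- function(X, Y, k_max = min(10, ncol(X)),
                              tol = 0.05) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  sy <- apply(Y, 2, sd); sy[sy == 0] <- 1
  press <- numeric(k_max)
  for (i in seq_len(n)) {
    fit <- fit_projection(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                          k = k_max)
    for (k in seq_len(k_max)) {
      yh <- predict(fit, X[i, , drop = FALSE], k = k)
      press[k] <- press[k] + sum(((Y[i, ] - yh) / sy)^2)
    }
  }
  list(k = which(press <= min(press) * (1 + tol))[1], press = press)
}

#' Serialize / restore a PLS projection
#'
#' JSON round-trip so empirical and simulated data can be projected with
#' identical constants across processes.
#'
#' @param proj A `pls_projection`.
#' @param path File path.
#' @return `read_projection` returns the restored `pls_projection`.
#' @export
write_projection <- function(proj, path) {
  obj <- proj[c("center", "scale", "rotation", "W", "P", "Q",
                "y_center", "y_scale", "y_names", "k")]
  obj$stat_names <- names(proj$center)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_projection
#' @export
read_projection <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  proj <- list(center = setNames(obj$center, obj$stat_names),
               scale = setNames(obj$scale, obj$stat_names),
               W = as.matrix(obj$W), P = as.matrix(obj$P),
               rotation = as.matrix(obj$rotation), Q = as.matrix(obj$Q),
               y_center = obj$y_center, y_scale = obj$y_scale,
               y_names = obj$y_names, k = obj$k, scores = NULL)
  dimnames(proj$rotation) <- list(obj$stat_names,
                                  paste0("comp", seq_len(obj$k)))
  class(proj) <- "pls_projection"
  proj
}
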