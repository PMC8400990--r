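#' Fit canonical correlation analysis between two feature sets
#'
#' Solves the canonical correlation eigenproblem
#' `Sxx^-1 Sxy Syy^-1 Syx Wx = Delta^2 Wx` for matched samples, via the
#' numerically equivalent whitened form: the singular value decomposition of
#' `Sxx^-1/2 Sxy Syy^-1/2`. Canonical transforms are scaled so the
#' canonical variates have unit variance (`diag(Wx' Sxx Wx) = 1`), and the
#' canonical correlations are returned in decreasing order. Near-singular
#' within-set covariances are ridge-regularized (`eps = 1e-8 trace/p`) with
#' a warning.
#'
#' @param X p x n matrix (p features, n matched samples). A plain vector is
#'   treated as 1 x n.
#' @param Y q x n matrix.
#' @return Object of class `cca_model`: `Wx` (p x d), `Wy` (q x d),
#'   `correlations` (length d, each in [0, 1]), `d`, `x_mean`, `y_mean`.
#'   `d` is the numerical rank of the whitened cross-covariance (singular
#'   values > 1e-10 of the largest), floored at 1 so a zero cross-covariance
#'   still yields one (zero-correlation) variate.
#' @export
cca_fit <- function(X, Y) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1L)
  n <- ncol(X)
  if (ncol(Y) != n) stop("X and Y must have the same number of samples")
  if (n < 3L) stop("need at least 3 samples")
  p <- nrow(X); q <- nrow(Y)
  x_mean <- rowMeans(X); y_mean <- rowMeans(Y)
  Xc <- X - x_mean; Yc <- Y - y_mean
  Sxx <- Xc %*% t(Xc) / (n - 1)
  Syy <- Yc %*% t(Yc) / (n - 1)
  Sxy <- Xc %*% t(Yc) / (n - 1)

  inv_sqrt <- function(S, label) {
    pdim <- nrow(S)
    eg <- eigen(S, symmetric = TRUE)
    vals <- eg$values
    # ridge only when (near-)singular, so well-conditioned problems stay exact
    if (min(vals) < 1e-10 * max(abs(vals), 1e-300)) {
      warning("near-singular within-set covariance (", label,
              "); ridge-regularized")
      eps <- 1e-8 * sum(diag(S)) / pdim
      if (eps <= 0) eps <- 1e-12
      vals <- vals + eps
    }
    eg$vectors %*% diag(1 / sqrt(vals), pdim) %*% t(eg$vectors)
  }
  Wxx <- inv_sqrt(Sxx, "X")
  Wyy <- inv_sqrt(Syy, "Y")
  K <- Wxx %*% Sxy %*% Wyy
  sv <- svd(K)
  d_rank <- sum(sv$d > 1e-10 * max(sv$d[1], 1e-300))
  d <- max(1L, min(d_rank, p, q, n - 1L))
  Wx <- Wxx %*% sv$u[, seq_len(d), drop = FALSE]
  Wy <- Wyy %*% sv$v[, seq_len(d), drop = FALSE]
  # deterministic sign: largest-magnitude element of each Wx column positive
  for (j in seq_len(d)) {
    s <- sign(Wx[which.max(abs(Wx[, j])), j])
    if (s < 0) { Wx[, j] <- -Wx[, j]; Wy[, j] <- -Wy[, j] }
  }
  structure(list(Wx = Wx, Wy = Wy,
                 correlations = pmin(1, pmax(0, sv$d[seq_len(d)])),
                 d = d, p = p, q = q, x_mean = x_mean, y_mean = y_mean),
            class = "cca_model")
}

#' @export
print.cca_model <- function(x, ...) {
  cat("<cca_model> p=", x$p, " q=", x$q, " d=", x$d, "; correlations: ",
      paste(signif(x$correlations, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Transform matched feature sets into fused canonical variates
#'
#' Applies the fitted canonical transforms and vertically concatenates the
#' variates: `Z = [Wx'(X - x_mean); Wy'(Y - y_mean)]`, a 2d x n matrix.
#' Applied to the training data this reproduces the fitted variates
#' exactly, and the sample covariance of Z equals the block matrix with
#' identity diagonal blocks and `diag(delta)` off-diagonal blocks.
#'
#' @param model A [cca_fit()] result.
#' @param X p x n matrix (or length-n vector when p = 1).
#' @param Y q x n matrix.
#' @return 2d x n fused matrix.
#' @export
cca_transform <- function(model, X, Y) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1L)
  if (nrow(X) != model$p || nrow(Y) != model$q)
    stop("feature dimensions do not match the fitted model")
  rbind(t(model$Wx) %*% (X - model$x_mean),
        t(model$Wy) %*% (Y - model$y_mean))
}

#' Sequentially fuse the five regional features
#'
#' Pairwise chained fusion over the fixed feature order: `Z1 = fuse(f1, f2)`
#' then `Zk = fuse(Z(k-1), f(k+1))` for k = 2..4, two features at a time
#' until a single fused vector per region remains. With scalar features each
#' step has d = 1, so Z stays two-dimensional and the final per-region fused
#' representation is 2 x n. The four fitted models are returned so held-out
#' subjects can be transformed by replay ([sequential_transform()]); the
#' chain is never refit on test data.
#'
#' @param columns List of 5 numeric vectors (one per feature, each length
#'   n >= 6), already min-max normalized.
#' @param order Permutation of 1:5 giving the pairing order (default the
#'   canonical feature order).
#' @return Object of class `cca_chain`: `Z` (2 x n), `models` (list of 4
#'   [cca_fit()] models), `order`, `feature_names`.
#' @export
sequential_fuse <- function(columns, order = 1:5) {
  stopifnot(length(columns) == 5L, length(order) == 5L,
            all(sort(order) == 1:5))
  n <- unique(vapply(columns, length, 1L))
  if (length(n) != 1L) stop("all feature vectors must share subject count")
  if (n < 6L) stop("need at least 6 subjects for a stable fusion chain")
  cols <- columns[order]
  Z <- matrix(cols[[1]], nrow = 1L)
  models <- vector("list", 4L)
  for (k in 1:4) {
    models[[k]] <- cca_fit(Z, matrix(cols[[k + 1]], nrow = 1L))
    Z <- cca_transform(models[[k]], Z, matrix(cols[[k + 1]], nrow = 1L))
  }
  structure(list(Z = Z, models = models, order = order,
                 feature_names = region_feature_names()[order]),
            class = "cca_chain")
}

#' Replay a fitted fusion chain on new subjects
#'
#' @param chain A [sequential_fuse()] result.
#' @param columns List of 5 numeric vectors in the original feature order,
#'   normalized with the training statistics.
#' @return 2 x n fused matrix.
#' @export
sequential_transform <- function(chain, columns) {
  stopifnot(inherits(chain, "cca_chain"), length(columns) == 5L)
  cols <- columns[chain$order]
  Z <- matrix(cols[[1]], nrow = 1L)
  for (k in 1:4)
    Z <- cca_transform(chain$models[[k]], Z,
                       matrix(cols[[k + 1]], nrow = 1L))
  Z
}

#' Serialize a fusion chain to JSON
#'
#' @param chain A [sequential_fuse()] result (the fitted models; the
#'   training variates `Z` are not stored).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cca_chain <- function(chain, path) {
  payload <- list(
    order = chain$order,
    feature_names = chain$feature_names,
    models = lapply(chain$models, function(m)
      list(Wx = m$Wx, Wy = m$Wy, correlations = m$correlations, d = m$d,
           p = m$p, q = m$q, x_mean = m$x_mean, y_mean = m$y_mean)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a fusion chain serialized by [write_cca_chain()]
#'
#' @param path JSON path.
#' @return A `cca_chain` (without training variates).
#' @export
read_cca_chain <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  models <- lapply(payload$models, function(m) {
    p <- as.integer(m$p); q <- as.integer(m$q); d <- as.integer(m$d)
    structure(list(
      Wx = matrix(unlist(m$Wx), nrow = p, ncol = d, byrow = TRUE),
      Wy = matrix(unlist(m$Wy), nrow = q, ncol = d, byrow = TRUE),
      correlations = as.numeric(unlist(m$correlations)),
      d = d, p = p, q = q,
      x_mean = as.numeric(unlist(m$x_mean)),
      y_mean = as.numeric(unlist(m$y_mean))), class = "cca_model")
  })
  structure(list(Z = NULL, models = models,
                 order = as.integer(unlist(payload$order)),
                 feature_names = as.character(unlist(payload$feature_names))),
            class = "cca_chain")
}
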