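#' Stepwise variable selection by partial F-tests
#'
#' The classical SWLDA feature selector: an ordinary-least-squares regression
#' of the class label on the selected features (with intercept) is grown and
#' pruned by alternating forward and backward phases. In the forward phase
#' the partial F statistic for adding each excluded variable is
#' `F = (RSS_reduced - RSS_full) / (RSS_full / (n - p_full - 1))` on
#' `(1, n - p_full - 1)` degrees of freedom; the variable with the smallest
#' p-value enters if that p-value is below `p_in`. In the backward phase the
#' included variable with the largest partial-F p-value leaves if that
#' p-value exceeds `p_out`. Phases alternate until a full pass changes
#' nothing (or `max_features` is reached). Ties are broken by the lowest
#' column index. Degenerate (constant) columns are skipped with a warning;
#' the forward phase halts when the residual degrees of freedom would be
#' exhausted.
#'
#' @param X n x D numeric feature matrix.
#' @param y Numeric class labels (conventionally +1 target / -1 non-target;
#'   selection is invariant to affine recoding). A logical vector is accepted.
#' @param p_in Entry threshold (p-value), default 0.10.
#' @param p_out Removal threshold (p-value), default 0.15; `p_in <= p_out`
#'   avoids add/remove cycles.
#' @param max_features Optional cap on the number of selected variables
#'   (default unlimited).
#' @return An object of class `stepwise_model`: `selected` (ordered column
#'   indices), `p_in`, `p_out`, `max_features`, `D`, and `trace`, a
#'   data.frame of per-step `(action, index, p_value)`.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(50 * 6), 50, 6)
#' y <- X[, 3] + 0.01 * rnorm(50)
#' stepwise_select(X, y, p_in = 0.05)$selected # 3
stepwise_select <- function(X, y, p_in = 0.10, p_out = 0.15,
                            max_features = Inf) {
  X <- as.matrix(X)
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  y <- as.numeric(y)
  n <- nrow(X); D <- ncol(X)
  stopifnot(n > 2, length(y) == n, 0 < p_in, p_in < 1, 0 < p_out, p_out < 1)
  if (length(unique(y)) < 2) stop("y must contain both classes")

  Xc <- scale(X, center = TRUE, scale = FALSE) # intercept absorbed
  yc <- y - mean(y)
  ss0 <- colSums(Xc^2)
  tol <- max(ss0, 1) * 1e-12
  degenerate <- ss0 <= tol
  if (any(degenerate))
    warning(sprintf("%d constant column(s) skipped: %s", sum(degenerate),
                    paste(utils::head(which(degenerate), 5), collapse = ", ")))

  selected <- integer(0)
  trace <- list()
  # residuals of Xc / yc after projecting out the selected columns
  Xr <- Xc; yr <- yc
  orthogonalize <- function(Xr, yr, j) {
    u <- Xr[, j]
    q <- u / sqrt(sum(u^2))
    yr <- yr - q * sum(q * yr)
    Xr <- Xr - q %o% as.vector(crossprod(q, Xr))
    list(Xr = Xr, yr = yr)
  }
  rebuild <- function(sel) {
    Xr <- Xc; yr <- yc
    for (j in sel) {
      st <- orthogonalize(Xr, yr, j)
      Xr <- st$Xr; yr <- st$yr
    }
    list(Xr = Xr, yr = yr)
  }

  forward_pvals <- function() {
    m <- length(selected)
    df2 <- n - m - 2L # model would have m + 1 predictors plus intercept
    if (df2 <= 0) return(NULL)
    ssr <- colSums(Xr^2)
    elig <- !degenerate & !(seq_len(D) %in% selected) & ssr > tol
    if (!any(elig)) return(NULL)
    gain <- rep(NA_real_, D)
    gain[elig] <- colSums(Xr[, elig, drop = FALSE] * yr)^2 / ssr[elig]
    rss_new <- sum(yr^2) - gain
    p <- stats::pf(gain / (rss_new / df2), 1, df2, lower.tail = FALSE)
    p[!elig] <- NA_real_
    p
  }
  backward_pvals <- function() {
    m <- length(selected)
    df2 <- n - m - 1L
    if (m == 0 || df2 <= 0) return(NULL)
    fit <- stats::lm.fit(Xc[, selected, drop = FALSE], yc)
    R <- qr.R(fit$qr)
    xtx_inv_diag <- diag(chol2inv(R))[order(fit$qr$pivot)]
    rss <- sum(fit$residuals^2)
    tstat2 <- fit$coefficients[order(fit$qr$pivot)]^2 /
      (xtx_inv_diag * rss / df2)
    stats::pf(tstat2, 1, df2, lower.tail = FALSE)
  }

  max_passes <- 4L * max(D, 1L)
  pass <- 0L
  repeat {
    pass <- pass + 1L
    changed <- FALSE
    # FORWARD
    repeat {
      if (length(selected) >= max_features) break
      p <- forward_pvals()
      if (is.null(p) || all(is.na(p))) break
      j <- which.min(p) # ties -> lowest index
      if (!(p[j] < p_in)) break
      st <- orthogonalize(Xr, yr, j)
      Xr <- st$Xr; yr <- st$yr
      selected <- c(selected, j)
      trace[[length(trace) + 1L]] <-
        data.frame(action = "add", index = j, p_value = p[j])
      changed <- TRUE
    }
    # BACKWARD
    repeat {
      p <- backward_pvals()
      if (is.null(p)) break
      j <- which.max(p) # ties -> lowest index
      if (!(p[j] > p_out)) break
      removed <- selected[j]
      selected <- selected[-j]
      st <- rebuild(selected)
      Xr <- st$Xr; yr <- st$yr
      trace[[length(trace) + 1L]] <-
        data.frame(action = "remove", index = removed, p_value = p[j])
      changed <- TRUE
    }
    if (!changed) break
    if (pass >= max_passes) {
      warning("stepwise selection did not stabilize; aborting after ",
              max_passes, " passes")
      break
    }
  }
  trace <- if (length(trace)) do.call(rbind, trace)
    else data.frame(action = character(0), index = integer(0),
                    p_value = numeric(0))
  structure(list(selected = as.integer(selected), p_in = p_in, p_out = p_out,
                 max_features = max_features, D = D, trace = trace),
            class = "stepwise_model")
}

#' Apply a fitted stepwise model
#'
#' Restricts a feature matrix to the selected columns, in selection order.
#' Train and test transforms therefore use identical column sets.
#'
#' @param model A [stepwise_select()] fit.
#' @param X n x D matrix with the same D the model was fitted on.
#' @return n x |selected| matrix.
#' @export
apply_stepwise <- function(model, X) {
  stopifnot(inherits(model, "stepwise_model"), ncol(X) == model$D)
  if (length(model$selected) == 0L)
    stop("stepwise model selected zero features; the ensemble treats such a ",
         "weak learner as contributing nothing (see train_ensemble)")
  X[, model$selected, drop = FALSE]
}

#' Fit principal components
#'
#' Eigendecomposition of the covariance matrix of the mean-centered data; the
#' top M orthonormal eigenvectors (descending eigenvalue) are retained. The
#' sign of each component is fixed so its largest-magnitude element is
#' positive, making transforms reproducible.
#'
#' @param X n x D matrix.
#' @param M Number of components, 1 <= M <= min(n - 1, D).
#' @return An object of class `pca_model`: `mean`, `components` (D x M),
#'   `eigenvalues` (length M), `M`, `total_variance` (sum of all
#'   eigenvalues = total variance of the centered data).
#' @export
pca_fit <- function(X, M) {
  X <- as.matrix(X)
  n <- nrow(X); D <- ncol(X)
  M <- as.integer(M)
  if (M < 1L || M > min(n - 1L, D))
    stop(sprintf("M must be in 1..min(n - 1, D) = %d", min(n - 1L, D)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc) / (n - 1)
  ee <- eigen(S, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  comps <- ee$vectors[, seq_len(M), drop = FALSE]
  for (j in seq_len(M)) {
    i0 <- which.max(abs(comps[, j]))
    if (comps[i0, j] < 0) comps[, j] <- -comps[, j]
  }
  structure(list(mean = mu, components = comps,
                 eigenvalues = vals[seq_len(M)], M = M,
                 total_variance = sum(vals)),
            class = "pca_model")
}

#' Project data onto fitted principal components
#'
#' @param model A [pca_fit()] model.
#' @param X n x D matrix.
#' @return n x M score matrix (centered data projected onto the components).
#' @export
pca_transform <- function(model, X) {
  stopifnot(inherits(model, "pca_model"), ncol(X) == length(model$mean))
  sweep(as.matrix(X), 2, model$mean) %*% model$components
}

#' Identity (no dimension reduction)
#'
#' The control condition: features pass through unchanged.
#'
#' @param X Any matrix.
#' @return `X`.
#' @export
no_reduction <- function(X) X

#' Fit a dimension-reduction transform for one partition
#'
#' Dispatches to [stepwise_select()], [pca_fit()] or the identity, giving the
#' three per-partition conditions a single surface for the ensemble trainer.
#'
#' @param X Partition feature matrix.
#' @param y Class labels (`is_target` logical or +1/-1) -- used by the
#'   stepwise condition only.
#' @param condition "stepwise", "pca" or "none".
#' @param p_in,p_out,max_features Stepwise thresholds (see
#'   [stepwise_select()]).
#' @param n_pcs PCA component count; default `min(n - 1, floor(D / 4))`.
#' @return A fitted transform (`stepwise_model`, `pca_model`, or
#'   `dimred_none`), usable with [transform_dimred()].
#' @export
fit_dimred <- function(X, y, condition = c("none", "stepwise", "pca"),
                       p_in = 0.10, p_out = 0.15, max_features = Inf,
                       n_pcs = NULL) {
  condition <- match.arg(condition)
  switch(condition,
    none = structure(list(D = ncol(X)), class = "dimred_none"),
    stepwise = stepwise_select(X, y, p_in = p_in, p_out = p_out,
                               max_features = max_features),
    pca = {
      if (is.null(n_pcs))
        n_pcs <- max(1L, min(nrow(X) - 1L, ncol(X) %/% 4L))
      pca_fit(X, n_pcs)
    })
}

#' Apply a fitted dimension-reduction transform
#'
#' @param model A [fit_dimred()] result.
#' @param X Feature matrix with the training dimension D.
#' @return The reduced matrix; a zero-feature stepwise model yields an
#'   n x 0 matrix.
#' @export
transform_dimred <- function(model, X) UseMethod("transform_dimred")

#' @export
transform_dimred.dimred_none <- function(model, X) {
  stopifnot(ncol(X) == model$D)
  X
}

#' @export
transform_dimred.stepwise_model <- function(model, X) {
  if (length(model$selected) == 0L)
    return(matrix(0, nrow(X), 0L))
  apply_stepwise(model, X)
}

#' @export
transform_dimred.pca_model <- function(model, X) pca_transform(model, X)
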