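# LASSO screening on independent contrasts. Contrasts force regression
# through the origin, so there is no intercept anywhere and columns are
# standardized without centering (unit root-mean-square). The objective is
#   (1/(2m)) ||y - X b||^2 + lambda * sum |b_j|
# with m = number of contrast rows; coefficients are reported back on the
# original predictor scale.

# RMS standardization (no centering). Zero columns get scale 1 and are
# masked out of the fit.
.lasso_standardize <- function(X) {
  m <- nrow(X)
  s <- sqrt(colSums(X^2) / m)
  zero <- s == 0
  s[zero] <- 1
  list(Xs = sweep(X, 2L, s, "/"), s = s, zero = zero)
}

#' Through-origin lasso at a fixed penalty
#'
#' Solves the penalized least-squares problem above by coordinate descent.
#' At `lambda = 0` with a full-rank design this is ordinary least squares
#' through the origin (solved directly); above the null threshold
#' `max_j |x_j' y| / m` (standardized scale) the solution is exactly zero.
#'
#' @param X Numeric predictor matrix (contrast rows; no intercept column).
#' @param y Numeric response vector of contrasts.
#' @param lambda Nonnegative penalty.
#' @param standardize Standardize columns to unit RMS internally (default
#'   `TRUE`); coefficients are always returned on the input scale.
#' @param tol Convergence tolerance on coefficient updates.
#' @param maxit Maximum coordinate-descent sweeps.
#' @return Named numeric coefficient vector (length `ncol(X)`); columns that
#'   are identically zero get coefficient 0 with a warning.
#' @export
lasso_fit <- function(X, y, lambda, standardize = TRUE,
                      tol = 1e-11, maxit = 100000L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), is.finite(lambda), lambda >= 0)
  if (ncol(X) < 1L) stop("no predictors")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  std <- .lasso_standardize(X)
  if (any(std$zero))
    warning("all-zero predictor column(s) forced to coefficient 0: ",
            paste(colnames(X)[std$zero], collapse = ", "))
  keep <- !std$zero
  beta <- numeric(ncol(X))
  names(beta) <- colnames(X)
  if (!any(keep)) return(beta)
  Xs <- if (standardize) std$Xs[, keep, drop = FALSE]
        else X[, keep, drop = FALSE]
  if (lambda == 0) {
    q <- qr(Xs)
    if (q$rank == ncol(Xs)) {
      b <- qr.coef(q, y)
    } else {
      b <- cd_lasso(Xs, y, 0, numeric(ncol(Xs)), tol, as.integer(maxit))
    }
  } else {
    b <- cd_lasso(Xs, y, lambda, numeric(ncol(Xs)), tol, as.integer(maxit))
  }
  beta[keep] <- if (standardize) b / std$s[keep] else b
  beta
}

#' Maximum Karush-Kuhn-Tucker violation of a lasso solution
#'
#' On the standardized scale the stationarity conditions are
#' `|x_j' r / m| <= lambda` for zero coefficients and
#' `x_j' r / m = lambda * sign(b_j)` for active ones. Returns the largest
#' absolute violation; a correct solution is at numerical zero.
#'
#' @param X,y The design and response passed to [lasso_fit()].
#' @param beta Coefficients on the original scale.
#' @param lambda The penalty they were fitted at.
#' @return Maximum KKT residual (nonnegative scalar).
#' @export
lasso_kkt_residual <- function(X, y, beta, lambda) {
  X <- as.matrix(X)
  std <- .lasso_standardize(X)
  keep <- !std$zero
  Xs <- std$Xs[, keep, drop = FALSE]
  b <- (beta * std$s)[keep]
  m <- nrow(X)
  g <- as.numeric(crossprod(Xs, y - Xs %*% b)) / m
  active <- b != 0
  viol <- pmax(0, abs(g) - lambda)
  viol[active] <- abs(g[active] - lambda * sign(b[active]))
  if (length(viol)) max(viol) else 0
}

# Descending log-spaced lambda grid from the null threshold.
.lasso_grid <- function(Xs, y, nlambda, lambda_min_ratio) {
  m <- nrow(Xs)
  lmax <- max(abs(crossprod(Xs, y))) / m
  if (lmax == 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

# Warm-started solution path on an already-standardized design, using the
# sequential strong rule to restrict coordinate descent to plausible
# coordinates at each penalty, with a full KKT check (and refit on any
# violators) before a solution is accepted.
.lasso_path_std <- function(Xs, y, lambda, tol = 1e-8, maxit = 100000L) {
  p <- ncol(Xs)
  m <- nrow(Xs)
  B <- matrix(0, p, length(lambda))
  b <- numeric(p)
  r <- y
  for (l in seq_along(lambda)) {
    g <- abs(as.numeric(crossprod(Xs, r))) / m
    lam_prev <- if (l == 1L) max(g) else lambda[l - 1L]
    cand <- which(b != 0 | g >= 2 * lambda[l] - lam_prev)
    repeat {
      if (length(cand)) {
        bc <- cd_lasso(Xs[, cand, drop = FALSE], y, lambda[l], b[cand],
                       tol, as.integer(maxit))
        b[cand] <- bc
      }
      r <- y - as.numeric(Xs %*% b)
      viol <- which(abs(as.numeric(crossprod(Xs, r))) / m >
                      lambda[l] + 1e-10 & b == 0)
      viol <- setdiff(viol, cand)
      if (!length(viol)) break
      cand <- union(cand, viol)
    }
    B[, l] <- b
  }
  B
}

#' Cross-validated lasso screen on contrasts
#'
#' Fits the through-origin lasso along a grid of `nlambda` log-spaced
#' penalties from the null threshold down by `lambda_min_ratio`, estimates
#' mean squared prediction error by k-fold cross-validation (folds assigned
#' from `seed`), picks a penalty by the chosen rule, refits on the full
#' data, and reports the predictors with nonzero coefficients -- the
#' screened candidates passed on to phylogenetic GLS.
#'
#' The default `"min"` rule takes the CV-error minimizer; `"1se"` takes
#' the sparsest model within one standard error of the minimum. Both
#' solutions are always returned so callers (notably the pipeline, which
#' screens hundreds of categories and prefers the sparser rule) can apply
#' either without refitting.
#'
#' @param X Contrast predictor matrix (no intercept column).
#' @param y Contrast response vector.
#' @param nfolds Number of CV folds (default 10); must be between 2 and
#'   `nrow(X)`.
#' @param seed Integer seed controlling fold assignment; results are
#'   deterministic given the seed.
#' @param nlambda,lambda_min_ratio Penalty grid controls.
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @param cv_repeats Number of independent fold assignments averaged into
#'   the CV curve (default 1, plain k-fold CV). With few contrast rows the
#'   CV curve is noisy in any single assignment; averaging over repeats
#'   stabilizes both selection rules.
#' @return An object of class `"lasso_screen"`: list with `lambda` (grid),
#'   `cvm`, `cvsd` (CV mean error and its standard error), `lambda_min`,
#'   `lambda_1se`, `lambda_sel` (the one the rule picked), `beta`
#'   (full-data coefficients at `lambda_sel`, original scale), `selected`
#'   (names of nonzero coefficients), `foldid`, `seed`, `rule`.
#' @export
lasso_screen <- function(X, y, nfolds = 10L, seed = 1L,
                         nlambda = 100L, lambda_min_ratio = 1e-4,
                         lambda_rule = c("min", "1se"),
                         cv_repeats = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  cv_repeats <- as.integer(cv_repeats)
  stopifnot(cv_repeats >= 1L)
  X <- as.matrix(X)
  y <- as.numeric(y)
  m <- nrow(X)
  if (ncol(X) < 1L) stop("no predictors to screen")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  nfolds <- as.integer(nfolds)
  if (nfolds < 2L || nfolds > m)
    stop("'nfolds' must be between 2 and the number of contrast rows (",
         m, ")")
  std <- .lasso_standardize(X)
  keep <- !std$zero
  Xs <- std$Xs[, keep, drop = FALSE]
  lambda <- .lasso_grid(Xs, y, nlambda, lambda_min_ratio)

  set.seed(as.integer(seed))
  foldid <- sample(rep_len(seq_len(nfolds), m))
  fold_mse <- matrix(NA_real_, nfolds * cv_repeats, length(lambda))
  for (rep_i in seq_len(cv_repeats)) {
    fid <- if (rep_i == 1L) foldid else sample(rep_len(seq_len(nfolds), m))
    for (k in seq_len(nfolds)) {
      tr <- fid != k
      Xtr <- X[tr, keep, drop = FALSE]
      str_ <- .lasso_standardize(Xtr)
      # CV fits only feed prediction error, so a looser tolerance suffices
      B <- .lasso_path_std(str_$Xs, y[tr], lambda, tol = 1e-7)
      B <- B / str_$s                      # back to original scale
      pred <- X[!tr, keep, drop = FALSE] %*% B
      fold_mse[(rep_i - 1L) * nfolds + k, ] <- colMeans((y[!tr] - pred)^2)
    }
  }
  cvm <- colMeans(fold_mse)
  # the curve is averaged over repeats, but the one-SE band keeps the
  # single-assignment scale: repeats remove fold-assignment noise from the
  # curve, while the band reflects the data noise of one k-fold estimate
  cvsd <- apply(fold_mse, 2L, stats::sd) / sqrt(nfolds)
  i_min <- which.min(cvm)
  # grid is descending, so the first index within one s.e. of the minimum
  # is the sparsest such model
  i_1se <- which(cvm <= cvm[i_min] + cvsd[i_min])[1L]
  i_sel <- if (lambda_rule == "1se") i_1se else i_min

  B <- .lasso_path_std(Xs, y, lambda)
  unpack <- function(i) {
    b <- numeric(ncol(X))
    names(b) <- colnames(X)
    b[keep] <- B[, i] / std$s[keep]
    b
  }
  beta_min <- unpack(i_min)
  beta_1se <- unpack(i_1se)
  beta <- if (lambda_rule == "1se") beta_1se else beta_min
  structure(
    list(lambda = lambda, cvm = cvm, cvsd = cvsd,
         lambda_min = lambda[i_min], lambda_1se = lambda[i_1se],
         lambda_sel = lambda[i_sel], rule = lambda_rule, beta = beta,
         selected = names(beta)[beta != 0],
         beta_min = beta_min, selected_min = names(beta_min)[beta_min != 0],
         beta_1se = beta_1se,
         selected_1se = names(beta_1se)[beta_1se != 0],
         foldid = foldid, seed = as.integer(seed)),
    class = "lasso_screen")
}

#' @export
print.lasso_screen <- function(x, ...) {
  cat("Cross-validated lasso screen (", length(x$beta), " predictors, ",
      max(x$foldid), " folds, seed ", x$seed, ")\n", sep = "")
  cat("lambda (", x$rule, " rule) = ", format(x$lambda_sel, digits = 4),
      "; selected: ",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}
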