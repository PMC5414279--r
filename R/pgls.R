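# Phylogenetic generalized least squares under Brownian-motion covariance,
# with all-subsets AICc model selection and multimodel averaging over the
# 95% confidence set. The likelihood is maximum likelihood (ML) by default
# so AICc values are comparable across models with different fixed effects;
# REML is available for single-model reporting.

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`, where `k` counts every
#' estimated parameter (regression coefficients plus the residual
#' variance).
#'
#' @param logLik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations.
#' @return The AICc value; `NA` with a warning when `n - k - 1 <= 0`.
#' @export
aicc <- function(logLik, k, n) {
  if (n - k - 1 <= 0) {
    warning("AICc undefined: n - k - 1 <= 0")
    return(NA_real_)
  }
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Whiten y and X against C via its Cholesky factor; shared across all
# subset fits of one model search. C = t(R) %*% R with R upper triangular,
# so backsolve(R, ., transpose = TRUE) maps a vector v to t(R)^{-1} v and
# crossprods of whitened quantities are C^{-1} inner products.
.pgls_prepare <- function(y, X, tree = NULL, C = NULL) {
  if (is.null(names(y))) stop("'y' must be a named (species) vector")
  if (is.null(X)) {
    Xm <- matrix(numeric(0), nrow = length(y), ncol = 0,
                 dimnames = list(names(y), NULL))
  } else if (is.list(X) && !is.data.frame(X)) {
    if (is.null(names(X))) stop("predictor list must be named")
    Xm <- do.call(cbind, lapply(X, function(v) v[names(y)]))
    colnames(Xm) <- names(X)
    rownames(Xm) <- names(y)
  } else {
    Xm <- as.matrix(X)
    if (is.null(rownames(Xm))) rownames(Xm) <- names(y)
  }
  if (!is.null(tree)) {
    joined <- .join_species(tree, c(list(y = y),
                                    lapply(seq_len(ncol(Xm)), function(j)
                                      stats::setNames(Xm[, j], rownames(Xm)))),
                            min_n = 3L)
    sp <- joined$species
    y <- y[sp]
    Xm <- Xm[sp, , drop = FALSE]
    C <- brownian_covariance(joined$tree, sp)
  } else {
    if (is.null(C)) stop("supply 'tree' or 'C'")
    sp <- names(y)
    C <- C[sp, sp, drop = FALSE]
  }
  if (anyNA(y) || anyNA(Xm)) stop("missing trait values after join")
  R <- tryCatch(chol(C), error = function(e)
    stop("Brownian covariance matrix is not positive definite: ",
         conditionMessage(e)))
  n <- length(y)
  Xfull <- cbind(`(Intercept)` = 1, Xm)
  list(y = y, X = Xfull, species = sp,
       yw = backsolve(R, y, transpose = TRUE),
       Xw = backsolve(R, Xfull, transpose = TRUE),
       logdetC = 2 * sum(log(diag(R))), n = n)
}

# Fit one coefficient subset on pre-whitened data. cols indexes columns of
# prep$X (the intercept is column 1 and is always included).
.pgls_fit_core <- function(prep, cols, method = "ML") {
  Xw <- prep$Xw[, cols, drop = FALSE]
  colnames(Xw) <- colnames(prep$X)[cols]
  n <- prep$n
  k <- ncol(Xw)
  if (n <= k + 1) stop("too few species (", n, ") for ", k, " coefficients")
  q <- qr(Xw)
  if (q$rank < k) {
    drop_cols <- colnames(Xw)[q$pivot[(q$rank + 1):k]]
    stop("singular design: collinear column(s) ",
         paste(drop_cols, collapse = ", "))
  }
  beta <- qr.coef(q, prep$yw)
  res <- prep$yw - Xw %*% beta
  rss <- sum(res^2)
  sigma2_ml <- rss / n
  XtX <- crossprod(Xw)
  XtXinv <- chol2inv(chol(XtX))
  sigma2_adj <- rss / (n - k)
  se <- sqrt(diag(XtXinv) * sigma2_adj)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - k)
  if (method == "REML") {
    ll <- -0.5 * ((n - k) * log(2 * pi * sigma2_adj) + prep$logdetC +
                    determinant(XtX, logarithm = TRUE)$modulus[1] + (n - k))
    sigma2 <- sigma2_adj
  } else {
    ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + prep$logdetC + n)
    sigma2 <- sigma2_ml
  }
  kpar <- k + 1  # coefficients + residual variance
  structure(
    list(coefficients = stats::setNames(as.numeric(beta), colnames(Xw)),
         se = stats::setNames(as.numeric(se), colnames(Xw)),
         t = stats::setNames(as.numeric(tval), colnames(Xw)),
         p = stats::setNames(as.numeric(pval), colnames(Xw)),
         sigma2 = sigma2, logLik = as.numeric(ll),
         k = kpar, n = n, df_residual = n - k,
         AICc = aicc(as.numeric(ll), kpar, n),
         method = method,
         predictors = setdiff(colnames(Xw), "(Intercept)")),
    class = "pgls_fit")
}

#' Phylogenetic generalized least squares under Brownian motion
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma^2 C)` with `C` the Brownian
#' covariance of the tree ([brownian_covariance()]) and an intercept always
#' included. Estimation is by maximum likelihood: `beta` is the GLS
#' estimator, `sigma^2` its profile ML estimate; standard errors carry the
#' conventional `n/(n - k)` small-sample adjustment and p-values are
#' two-sided t on `n - k` degrees of freedom (`k` = number of
#' coefficients). On a star phylogeny the fit reduces exactly to ordinary
#' least squares.
#'
#' @param y Named numeric response vector (species names).
#' @param X Named list of trait vectors, a matrix with species rownames, or
#'   `NULL` for the intercept-only model.
#' @param tree A rooted `"phylo"` object; species present in only one of
#'   tree/traits are dropped with a warning.
#' @param C Optionally, a precomputed covariance matrix instead of `tree`.
#' @param method `"ML"` (default; AICc-comparable across fixed effects) or
#'   `"REML"` for single-model reporting.
#' @return An object of class `"pgls_fit"` with elements `coefficients`,
#'   `se`, `t`, `p`, `sigma2`, `logLik`, `k` (parameters incl. variance),
#'   `n`, `AICc`, `predictors`.
#' @export
pgls_fit <- function(y, X = NULL, tree = NULL, C = NULL,
                     method = c("ML", "REML")) {
  method <- match.arg(method)
  prep <- .pgls_prepare(y, X, tree, C)
  .pgls_fit_core(prep, seq_len(ncol(prep$X)), method)
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS (Brownian), ", x$method, ", n = ", x$n, "\n",
      sep = "")
  tab <- data.frame(estimate = x$coefficients, s.e. = x$se,
                    t = x$t, p.value = x$p)
  print(format(tab, digits = 3))
  cat("logLik = ", format(x$logLik, digits = 6),
      ", k = ", x$k, ", AICc = ", format(x$AICc, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Enumerate all predictor subsets
#'
#' All `2^p` subsets of the full predictor set, including the
#' intercept-only model, in a deterministic order (by subset size, then
#' lexicographic within size).
#'
#' @param full Character vector of predictor names.
#' @param max_p Guard against combinatorial blow-up (default 16).
#' @return List of character vectors (the empty vector is the
#'   intercept-only model).
#' @export
enumerate_models <- function(full, max_p = 16L) {
  p <- length(full)
  if (p > max_p)
    stop(p, " predictors would give 2^", p, " models; raise 'max_p' only ",
         "if you mean it")
  if (anyDuplicated(full)) stop("duplicate predictor names")
  out <- list(character(0))
  for (size in seq_len(p)) {
    sets <- utils::combn(sort(full), size, simplify = FALSE)
    out <- c(out, sets)
  }
  out
}

#' Fit phylogenetic GLS for every predictor subset
#'
#' Whitening against the tree covariance is done once and shared across all
#' subset fits, so the all-subsets search is cheap.
#'
#' @inheritParams pgls_fit
#' @param X Named list or matrix of the full predictor set.
#' @param max_p Passed to [enumerate_models()].
#' @return List of `"pgls_fit"` objects, in [enumerate_models()] order.
#' @export
fit_all_subsets <- function(y, X, tree = NULL, C = NULL,
                            method = c("ML", "REML"), max_p = 16L) {
  method <- match.arg(method)
  prep <- .pgls_prepare(y, X, tree, C)
  vars <- setdiff(colnames(prep$X), "(Intercept)")
  subsets <- enumerate_models(vars, max_p = max_p)
  lapply(subsets, function(s) {
    cols <- c(1L, which(colnames(prep$X) %in% s))
    .pgls_fit_core(prep, cols, method)
  })
}

#' Select the AICc-best model
#'
#' Minimum AICc; exact ties are broken in favour of fewer parameters, then
#' by lexicographic predictor names. Fits whose AICc is undefined
#' (`n - k - 1 <= 0`) are excluded with a warning.
#'
#' @param fits List of `"pgls_fit"` objects on identical species sets.
#' @return The winning `"pgls_fit"`.
#' @export
select_best <- function(fits) {
  stopifnot(length(fits) >= 1L)
  a <- vapply(fits, function(f) f$AICc, numeric(1))
  if (anyNA(a)) {
    warning(sum(is.na(a)), " fit(s) dropped: AICc undefined (n - k - 1 <= 0)")
    fits <- fits[!is.na(a)]
    a <- a[!is.na(a)]
    if (!length(fits)) stop("no fit has a defined AICc")
  }
  k <- vapply(fits, function(f) f$k, numeric(1))
  key <- vapply(fits, function(f) paste(sort(f$predictors), collapse = "+"),
                character(1))
  fits[[order(a, k, key)[1L]]]
}

#' Multimodel averaging over the AICc confidence set
#'
#' Akaike weights `w_i = exp(-delta_i/2) / sum exp(-delta_j/2)` are computed
#' over all fits; the confidence set is the smallest weight-ordered prefix
#' with cumulative weight `>= conf`, within which weights are renormalized.
#' Two averages are reported per coefficient: the *full* (zero-substitution)
#' average, where a model not containing the term contributes zero, and the
#' *conditional* average over only the models containing it. Unconditional
#' standard errors follow
#' `sqrt(sum w_i (se_i^2 + (b_i - bbar)^2))`, and p-values are two-sided
#' normal on `estimate / se` (no single model supplies residual df).
#'
#' @param fits List of `"pgls_fit"` objects on identical species sets.
#' @param conf Cumulative-weight level of the confidence set, in (0, 1].
#' @return An object of class `"averaged_model"`: `table` (one row per
#'   coefficient: full and conditional estimates, s.e., p, number of
#'   containing models), `models` (per-model AICc, delta, weight,
#'   cumulative weight, set membership), `conf`.
#' @export
model_average <- function(fits, conf = 0.95) {
  stopifnot(length(fits) >= 1L)
  if (!is.numeric(conf) || length(conf) != 1L || conf <= 0 || conf > 1)
    stop("'conf' must be in (0, 1]")
  a <- vapply(fits, function(f) f$AICc, numeric(1))
  if (anyNA(a)) {
    fits <- fits[!is.na(a)]
    a <- a[!is.na(a)]
    if (!length(fits)) stop("no fit has a defined AICc")
  }
  delta <- a - min(a)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  ord <- order(w, decreasing = TRUE)
  cum <- cumsum(w[ord])
  set_size <- which(cum >= conf)[1L]
  in_set <- logical(length(fits))
  in_set[ord[seq_len(set_size)]] <- TRUE
  wset <- ifelse(in_set, w, 0)
  wset <- wset / sum(wset)

  terms <- unique(unlist(lapply(fits, function(f) names(f$coefficients))))
  rows <- lapply(terms, function(tm) {
    b <- vapply(fits, function(f)
      if (tm %in% names(f$coefficients)) f$coefficients[[tm]] else 0,
      numeric(1))
    s <- vapply(fits, function(f)
      if (tm %in% names(f$coefficients)) f$se[[tm]] else 0, numeric(1))
    has <- vapply(fits, function(f) tm %in% names(f$coefficients),
                  logical(1))
    if (!any(has & in_set)) return(NULL)
    bf <- sum(wset * b)
    sef <- sqrt(sum(wset * (s^2 + (b - bf)^2)))
    wc <- wset * has
    wc <- wc / sum(wc)
    bc <- sum(wc * b)
    sec <- sqrt(sum(wc * (s^2 + (b - bc)^2)))
    data.frame(term = tm,
               estimate = bf, se = sef,
               p = 2 * stats::pnorm(-abs(bf / sef)),
               estimate_cond = bc, se_cond = sec,
               p_cond = 2 * stats::pnorm(-abs(bc / sec)),
               n_models = sum(has & in_set),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  models <- data.frame(
    model = vapply(fits, function(f)
      if (length(f$predictors)) paste(sort(f$predictors), collapse = "+")
      else "(intercept)", character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    AICc = a, delta = delta, weight = w,
    in_set = in_set, stringsAsFactors = FALSE)
  models <- models[order(-models$weight), ]
  models$cum_weight <- cumsum(models$weight)
  rownames(models) <- NULL
  structure(list(table = tab, models = models, conf = conf),
            class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, ...) {
  cat("Model-averaged estimates (", sum(x$models$in_set), " of ",
      nrow(x$models), " models in the ", 100 * x$conf,
      "% confidence set)\n", sep = "")
  print(format(x$table, digits = 3))
  invisible(x)
}

#' Significance gate for a reported association
#'
#' An association is accepted only when its p-value is strictly below
#' `alpha` (default 0.01).
#'
#' @param p P-value(s) in \[0, 1\].
#' @param alpha Strict acceptance threshold.
#' @return Logical, `TRUE` where `p < alpha`.
#' @export
significance_gate <- function(p, alpha = 0.01) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  p < alpha
}
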