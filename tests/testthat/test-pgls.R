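test_that("phylogenetic GLS reduces to OLS on a star phylogeny", {
  n <- 20
  star <- ape::stree(n, "star")
  star$edge.length <- rep(1, n)
  star$tip.label <- paste0("t", 1:n)
  set.seed(1)
  x <- setNames(rnorm(n), star$tip.label)
  y <- 2 + 1.5 * x + setNames(rnorm(n), star$tip.label)
  fit <- pgls_fit(y, list(x = x), tree = star)
  ref <- summary(lm(y ~ x))
  expect_equal(unname(fit$coefficients), unname(ref$coefficients[, 1]),
               tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(ref$coefficients[, 2]),
               tolerance = 1e-8)
  expect_equal(unname(fit$p), unname(ref$coefficients[, 4]),
               tolerance = 1e-8)
  expect_equal(fit$logLik, as.numeric(logLik(lm(y ~ x))),
               tolerance = 1e-8)
})

test_that("the PGLS slope equals the through-origin contrast slope", {
  for (seed in 1:25) {
    n <- sample(4:32, 1)
    tr <- rand_tree(n, seed + 400)
    x <- bm_trait(tr, seed = seed)
    y <- 1.2 * x + bm_trait(tr, seed = seed + 1000)
    # AICc is undefined at the smallest n here, which is irrelevant to the
    # slope identity being checked
    fit <- suppressWarnings(pgls_fit(y, list(x = x), tree = tr))
    px <- as.numeric(pic_contrasts(tr, x))
    py <- as.numeric(pic_contrasts(tr, y))
    slope_pic <- sum(px * py) / sum(px^2)
    expect_equal(unname(fit$coefficients["x"]), slope_pic,
                 tolerance = 1e-8)
  }
})

test_that("PGLS agrees with the reference GLS implementation", {
  # ultrametric tree so nlme's unit-diagonal correlation matrix describes
  # the same model as the Brownian covariance
  set.seed(31)
  tr <- ape::rcoal(16)
  x <- bm_trait(tr, seed = 31)
  y <- 0.8 * x + bm_trait(tr, seed = 32)
  fit <- pgls_fit(y, list(x = x), tree = tr, method = "ML")
  d <- data.frame(y = y[tr$tip.label], x = x[tr$tip.label],
                  sp = tr$tip.label)
  ref <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corBrownian(1, tr, form = ~sp),
                   method = "ML")
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$p), unname(summary(ref)$tTable[, 4]),
               tolerance = 1e-6)
})

test_that("noiseless responses are recovered exactly", {
  tr <- rand_tree(12, 77)
  x <- bm_trait(tr, seed = 77)
  y <- 3 + 2 * x
  fit <- pgls_fit(y, list(x = x), tree = tr)
  expect_equal(unname(fit$coefficients), c(3, 2), tolerance = 1e-8)
  expect_lt(fit$sigma2, 1e-16)
})

test_that("singular designs and tiny samples are rejected informatively", {
  tr <- rand_tree(10, 5)
  x <- bm_trait(tr, seed = 5)
  expect_error(pgls_fit(x + 0, list(a = x, b = 2 * x), tree = tr),
               "collinear")
  tr3 <- rand_tree(4, 6)
  x3 <- bm_trait(tr3, seed = 6)
  nm <- names(x3)
  expect_error(pgls_fit(x3, list(a = setNames(rnorm(4), nm),
                                 b = setNames(rnorm(4), nm),
                                 c = setNames(rnorm(4), nm)), tree = tr3),
               "too few")
})

test_that("AICc stored on fits matches independent arithmetic", {
  tr <- rand_tree(18, 9)
  x <- bm_trait(tr, seed = 9)
  y <- x + bm_trait(tr, seed = 10)
  fit <- pgls_fit(y, list(x = x), tree = tr)
  k <- fit$k; n <- fit$n
  expect_equal(fit$AICc,
               -2 * fit$logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1),
               tolerance = 1e-12)
  expect_warning(aicc(-10, 5, 6), "undefined")
})

test_that("model enumeration covers all subsets deterministically", {
  expect_length(enumerate_models(c("a", "b")), 4L)
  expect_length(enumerate_models(character(0)), 1L)
  expect_length(enumerate_models(letters[1:6]), 64L)
  expect_identical(enumerate_models(c("b", "a"))[[1]], character(0))
  expect_error(enumerate_models(letters[1:17]), "models")
})

test_that("best-model selection minimizes AICc with stated tie-breaks", {
  mk <- function(aicc, k, preds) structure(
    list(AICc = aicc, k = k, predictors = preds,
         coefficients = c(`(Intercept)` = 0), se = c(`(Intercept)` = 1),
         p = c(`(Intercept)` = 1)), class = "pgls_fit")
  f1 <- mk(97.5, 7, letters[1:6])
  f2 <- mk(84.7, 3, "a")
  expect_identical(select_best(list(f1, f2)), f2)
  expect_identical(select_best(list(f2)), f2)
  # exact tie: fewer parameters wins
  f3 <- mk(84.7, 2, character(0))
  expect_identical(select_best(list(f2, f3)), f3)
})

test_that("Akaike weights and the confidence-set prefix rule are exact", {
  tr <- rand_tree(20, 15)
  X <- simulate_bm(tr, n_traits = 3, seed = 15)
  y <- X[, 1] + bm_trait(tr, seed = 16)
  preds <- lapply(1:3, function(j) setNames(X[, j], rownames(X)))
  names(preds) <- c("a", "b", "c")
  fits <- fit_all_subsets(setNames(y, rownames(X)), preds, tree = tr)
  avg <- model_average(fits, conf = 0.95)
  expect_equal(sum(avg$models$weight), 1, tolerance = 1e-12)
  # the closed-form two-model case
  w <- exp(-c(0, 2) / 2); w <- w / sum(w)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  # prefix rule against exhaustive enumeration for <= 5 models
  for (seed in 1:20) {
    set.seed(seed)
    nm <- sample(2:5, 1)
    ws <- sort(runif(nm), decreasing = TRUE); ws <- ws / sum(ws)
    sizes <- which(cumsum(ws) >= 0.95)
    aiccs <- -2 * log(ws)   # weights reconstruct these AICc deltas
    mocks <- lapply(seq_len(nm), function(i) structure(
      list(AICc = aiccs[i], k = 2, predictors = paste0("p", i),
           coefficients = setNames(c(0, 1), c("(Intercept)", paste0("p", i))),
           se = setNames(c(1, 1), c("(Intercept)", paste0("p", i))),
           p = setNames(c(1, 1), c("(Intercept)", paste0("p", i)))),
      class = "pgls_fit"))
    av <- model_average(mocks, conf = 0.95)
    expect_equal(sum(av$models$in_set), sizes[1])
    expect_equal(av$models$weight[order(av$models$AICc)], ws,
                 tolerance = 1e-10)
  }
  expect_error(model_average(fits, conf = 1.5), "conf")
})

test_that("averaging a single model returns that model's estimates", {
  tr <- rand_tree(14, 21)
  x <- bm_trait(tr, seed = 21)
  y <- x + bm_trait(tr, seed = 22)
  fit <- pgls_fit(y, list(x = x), tree = tr)
  av <- model_average(list(fit))
  expect_equal(av$table$estimate,
               unname(fit$coefficients[av$table$term]), tolerance = 1e-12)
  expect_equal(av$table$se, unname(fit$se[av$table$term]),
               tolerance = 1e-12)
})

test_that("the significance gate is strict at its threshold", {
  expect_true(significance_gate(0.009))
  expect_false(significance_gate(0.01))
  expect_false(significance_gate(0.5))
  expect_error(significance_gate(1.2), "0, 1")
  expect_error(significance_gate(0.5, alpha = 0), "alpha")
})
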