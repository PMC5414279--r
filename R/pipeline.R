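# End-to-end orchestration: niche-breadth scores -> genomic predictors ->
# independent contrasts -> lasso screen -> phylogenetic GLS with all-subsets
# AICc selection and confidence-set averaging -> significance gate. The
# report mirrors the usual three-column layout (full model / best model /
# averaged model).

#' Pipeline configuration
#'
#' @param grid_n1,grid_n2 Envelope grid bins along PC1/PC2 (defaults 981 and
#'   15, i.e. 14 715 cells weighting the axes by their variance
#'   contributions).
#' @param grid_from_pca Derive the bin counts from the fitted PCA's variance
#'   fractions ([grid_bins_from_pca()]) instead of the fixed defaults.
#' @param pca_scale Scale bioclim columns to unit variance before the PCA
#'   (default `FALSE`: covariance PCA).
#' @param sqrt_response Square-root transform the climate envelope before
#'   all regressions (default `TRUE`).
#' @param log_transform Character vector of covariate names to log10
#'   transform before analysis (default none).
#' @param lasso_folds,lasso_seed,nlambda,lambda_min_ratio,lambda_rule,cv_repeats
#'   Passed to [lasso_screen()]; the pipeline defaults to the sparser
#'   `"1se"` rule, which keeps the screen conservative when categories
#'   vastly outnumber contrast rows.
#' @param covariates Covariates always present in the phylogenetic
#'   regression stage alongside the screened categories.
#' @param conf Cumulative Akaike-weight level of the averaging confidence
#'   set.
#' @param alpha Strict significance gate on averaged-model p-values.
#' @param max_model_predictors All-subsets guard passed to
#'   [enumerate_models()]; if the screen returns more categories than fit,
#'   the largest-coefficient ones are kept with a warning.
#' @param method `"ML"` (default) or `"REML"` likelihood for the GLS fits.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(grid_n1 = 981L, grid_n2 = 15L,
                            grid_from_pca = FALSE,
                            pca_scale = FALSE,
                            sqrt_response = TRUE,
                            log_transform = character(0),
                            lasso_folds = 10L, lasso_seed = 1L,
                            nlambda = 100L, lambda_min_ratio = 1e-4,
                            lambda_rule = c("1se", "min"),
                            cv_repeats = 1L,
                            covariates = c("G", "N_g", "N_d", "M", "B_c"),
                            conf = 0.95, alpha = 0.01,
                            max_model_predictors = 16L,
                            method = c("ML", "REML")) {
  method <- match.arg(method)
  lambda_rule <- match.arg(lambda_rule)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  structure(list(grid_n1 = as.integer(grid_n1),
                 grid_n2 = as.integer(grid_n2),
                 grid_from_pca = isTRUE(grid_from_pca),
                 pca_scale = isTRUE(pca_scale),
                 sqrt_response = isTRUE(sqrt_response),
                 log_transform = log_transform,
                 lasso_folds = as.integer(lasso_folds),
                 lasso_seed = as.integer(lasso_seed),
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 lambda_rule = lambda_rule,
                 cv_repeats = as.integer(cv_repeats),
                 covariates = covariates,
                 conf = conf, alpha = alpha,
                 max_model_predictors = as.integer(max_model_predictors),
                 method = method),
            class = "pipeline_config")
}

# Envelope scores for all species from pooled climate samples.
.envelope_scores <- function(climate, config) {
  bio <- paste0("bio", 1:19)
  miss <- setdiff(c("species", bio), names(climate))
  if (length(miss))
    stop("climate table missing column(s): ", paste(miss, collapse = ", "))
  pca <- fit_climate_pca(climate[bio], scale = config$pca_scale)
  scores <- project_climate(climate[bio], pca)
  bins <- if (config$grid_from_pca) grid_bins_from_pca(pca)
          else c(config$grid_n1, config$grid_n2)
  grid <- envelope_grid(scores, n1 = bins[1L], n2 = bins[2L])
  sp <- unique(climate$species)
  env <- vapply(sp, function(s)
    climate_envelope(scores[climate$species == s, , drop = FALSE], grid),
    numeric(1))
  list(envelope = stats::setNames(as.numeric(env), sp), pca = pca,
       grid = grid)
}

#' Run the full habitat-variability analysis
#'
#' Stages, in order: (1) niche-breadth scores -- the climate envelope from
#' pooled-PCA grid occupancy (square-root transformed) and, when class
#' counts are supplied, Brillouin habitat diversity; (2) genomic predictors
#' -- duplicated-gene counts from the hit table and per-category gene
#' counts from the gene map, merged with the supplied covariates; (3)
#' independent contrasts of every variable on the tree; (4) cross-validated
#' lasso screen of the contrasts; (5) phylogenetic GLS over the screened
#' categories plus the fixed covariates, with all-subsets AICc selection
#' and confidence-set model averaging; (6) strict significance gate on the
#' averaged-model p-values. Deterministic given the config's seed.
#'
#' @param tree A rooted binary `"phylo"` tree.
#' @param traits Data frame with a `species` column and the covariates
#'   (`G`, `N_g`, `M`, `B_c`, plus `N_d` and per-category counts when
#'   `hits`/`gene_map` are not supplied, and `envelope` when `climate` is
#'   not supplied).
#' @param climate Optional pooled climate sample table (`species`,
#'   `bio1`..`bio19`); when given, envelopes are computed from it.
#' @param hits Optional homology hit table for
#'   [count_duplicated_genes()].
#' @param gene_map,catalogue Optional gene-to-category map and catalogue
#'   for [count_nogf()]; without a map, every non-covariate numeric column
#'   of `traits` named in `catalogue` is used as a category count.
#' @param class_counts Optional habitat class counts (`species`, `class`,
#'   `count`) for Brillouin diversity.
#' @param config A [pipeline_config()].
#' @return An object of class `"habitat_report"`; see Details in the
#'   package vignette. Key elements: `scores`, `screen`, `screened_nogf`,
#'   `full_fit`, `best_fit`, `averaged`, `table1`, `gated`, `gated_nogf`,
#'   `no_candidates`, `provenance`.
#' @export
run_pipeline <- function(tree, traits, climate = NULL, hits = NULL,
                         gene_map = NULL, catalogue = NULL,
                         class_counts = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!"species" %in% names(traits)) stop("'traits' needs a species column")
  if (anyDuplicated(traits$species)) stop("duplicate species in traits")
  rownames(traits) <- traits$species

  ## stage 1: niche-breadth scores
  pca <- NULL; grid <- NULL
  if (!is.null(climate)) {
    es <- .envelope_scores(climate, config)
    envelope <- es$envelope; pca <- es$pca; grid <- es$grid
  } else {
    if (!"envelope" %in% names(traits))
      stop("supply 'climate' or an 'envelope' column in traits")
    envelope <- stats::setNames(as.numeric(traits$envelope), traits$species)
  }
  response <- if (config$sqrt_response) sqrt_transform(envelope)
              else envelope
  diversity <- NULL
  if (!is.null(class_counts)) {
    diversity <- vapply(split(class_counts$count, class_counts$species),
                        brillouin_index, numeric(1))
  }

  ## stage 2: genomic predictors
  if (!is.null(hits)) {
    nd <- count_duplicated_genes(hits)
    N_d <- stats::setNames(rep(0, nrow(traits)), traits$species)
    N_d[names(nd)] <- nd
  } else if ("N_d" %in% names(traits)) {
    N_d <- stats::setNames(as.numeric(traits$N_d), traits$species)
  } else stop("supply 'hits' or an 'N_d' column in traits")

  if (!is.null(gene_map)) {
    if (is.null(catalogue)) stop("'catalogue' is required with 'gene_map'")
    nogf_m <- count_nogf(gene_map, catalogue)
    nogf <- matrix(0, nrow(traits), length(catalogue),
                   dimnames = list(traits$species, catalogue))
    nogf[rownames(nogf_m), ] <- nogf_m
  } else {
    if (is.null(catalogue))
      catalogue <- setdiff(names(traits),
                           c("species", "envelope", "diversity",
                             config$covariates))
    miss <- setdiff(catalogue, names(traits))
    if (length(miss))
      stop("category column(s) absent from traits: ",
           paste(head(miss, 5L), collapse = ", "))
    nogf <- as.matrix(traits[, catalogue, drop = FALSE])
    rownames(nogf) <- traits$species
  }

  cov_miss <- setdiff(config$covariates, c(names(traits), "N_d"))
  if (length(cov_miss))
    stop("covariate column(s) missing from traits: ",
         paste(cov_miss, collapse = ", "))
  covs <- lapply(config$covariates, function(v) {
    val <- if (v == "N_d") N_d
           else stats::setNames(as.numeric(traits[[v]]), traits$species)
    if (v %in% config$log_transform) {
      if (any(val <= 0)) stop("cannot log-transform nonpositive ", v)
      val <- log10(val)
    }
    val
  })
  names(covs) <- config$covariates

  ## join species across every data source
  vars <- c(list(.response = response), covs,
            lapply(seq_len(ncol(nogf)), function(j)
              stats::setNames(nogf[, j], rownames(nogf))))
  names(vars) <- c(".response", names(covs), colnames(nogf))
  joined <- .join_species(tree, vars, min_n = 4L)
  tree <- joined$tree
  vars <- joined$vectors
  n <- length(joined$species)

  ## stage 3: independent contrasts
  pics <- lapply(vars, function(v) as.numeric(pic_contrasts(tree, v)))
  y_pic <- pics[[".response"]]
  X_pic <- do.call(cbind, pics[-1L])
  colnames(X_pic) <- names(vars)[-1L]

  ## stage 4: lasso screen (over categories and covariates alike)
  screen <- suppressWarnings(lasso_screen(
    X_pic, y_pic, nfolds = min(config$lasso_folds, n - 1L),
    seed = config$lasso_seed, nlambda = config$nlambda,
    lambda_min_ratio = config$lambda_min_ratio,
    lambda_rule = config$lambda_rule, cv_repeats = config$cv_repeats))
  screened_nogf <- intersect(screen$selected, colnames(nogf))
  # The conservative 1-se rule can be unable to distinguish any model from
  # the null on a shallow CV curve; the screen then falls back to the CV
  # minimizer so the gate, not the screen, arbitrates weak candidates.
  screen_fallback <- FALSE
  if (!length(screened_nogf) && config$lambda_rule == "1se" &&
      length(screen$selected_min)) {
    screened_nogf <- intersect(screen$selected_min, colnames(nogf))
    screen_fallback <- length(screened_nogf) > 0L
  }
  no_candidates <- length(screened_nogf) == 0L

  ## stage 5: phylogenetic GLS, all subsets, averaging
  max_nogf <- config$max_model_predictors - length(config$covariates)
  screen_beta <- if (screen_fallback) screen$beta_min else screen$beta
  if (length(screened_nogf) > max_nogf) {
    keep <- order(-abs(screen_beta[screened_nogf]))[seq_len(max_nogf)]
    warning("screen returned ", length(screened_nogf), " categories; ",
            "keeping the ", max_nogf, " with largest screened coefficients ",
            "to bound the all-subsets search")
    screened_nogf <- screened_nogf[keep]
  }
  predictors <- c(screened_nogf, config$covariates)
  X_fit <- vars[predictors]
  fits <- fit_all_subsets(vars[[".response"]], X_fit, tree = tree,
                          method = config$method,
                          max_p = config$max_model_predictors)
  full_fit <- fits[[length(fits)]]   # largest subset is last in order
  best_fit <- select_best(fits)
  averaged <- model_average(fits, conf = config$conf)

  ## stage 6: significance gate on averaged estimates
  avg_tab <- averaged$table
  gate_rows <- avg_tab$term != "(Intercept)"
  gated <- avg_tab$term[gate_rows & significance_gate(avg_tab$p,
                                                      config$alpha)]
  gated_nogf <- intersect(gated, colnames(nogf))

  table1 <- .report_table(full_fit, best_fit, averaged)
  scores <- data.frame(species = joined$species,
                       envelope = envelope[joined$species],
                       response = vars[[".response"]],
                       stringsAsFactors = FALSE)
  if (!is.null(diversity))
    scores$diversity <- diversity[joined$species]
  rownames(scores) <- NULL

  structure(list(scores = scores, pca = pca, grid = grid,
                 screen = screen, screened_nogf = screened_nogf,
                 no_candidates = no_candidates,
                 screen_fallback = screen_fallback,
                 full_fit = full_fit, best_fit = best_fit,
                 averaged = averaged, table1 = table1,
                 weights = averaged$models,
                 gated = gated, gated_nogf = gated_nogf,
                 provenance = list(
                   package = "habvar",
                   version = as.character(utils::packageVersion("habvar")),
                   n_species = n, species = joined$species,
                   config = unclass(config))),
            class = "habitat_report")
}

# Three-column report table: full / best / averaged estimates per variable.
.report_table <- function(full_fit, best_fit, averaged) {
  terms <- union(names(full_fit$coefficients), averaged$table$term)
  get3 <- function(fit, tm)
    if (tm %in% names(fit$coefficients))
      c(fit$coefficients[[tm]], fit$se[[tm]], fit$p[[tm]])
    else rep(NA_real_, 3L)
  rows <- lapply(terms, function(tm) {
    f <- get3(full_fit, tm); b <- get3(best_fit, tm)
    ai <- match(tm, averaged$table$term)
    a <- if (is.na(ai)) rep(NA_real_, 3L) else
      unlist(averaged$table[ai, c("estimate", "se", "p")], use.names = FALSE)
    data.frame(variable = tm,
               estimate_full = f[1L], se_full = f[2L], p_full = f[3L],
               estimate_best = b[1L], se_best = b[2L], p_best = b[3L],
               estimate_avg = a[1L], se_avg = a[2L], p_avg = a[3L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "AICc") <- c(full = full_fit$AICc, best = best_fit$AICc)
  out
}

#' @export
print.habitat_report <- function(x, ...) {
  cat("Habitat-variability analysis report (", x$provenance$n_species,
      " species)\n", sep = "")
  cat("screened categories: ",
      if (length(x$screened_nogf)) paste(x$screened_nogf, collapse = ", ")
      else "(none)", "\n", sep = "")
  cat("AICc: full ", format(attr(x$table1, "AICc")[["full"]], digits = 4),
      ", best ", format(attr(x$table1, "AICc")[["best"]], digits = 4),
      "\n", sep = "")
  print(format(x$table1, digits = 3))
  cat("gated at p < ", x$provenance$config$alpha, ": ",
      if (length(x$gated)) paste(x$gated, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

#' Write a report to TSV + JSON
#'
#' `report.tsv` mirrors the three-column model table; `report.json` holds
#' the machine-readable object (weights, confidence set, gate outcome,
#' provenance).
#'
#' @param report A `"habitat_report"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "habitat_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(report$table1, file.path(dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$scores, file.path(dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(screened = report$screened_nogf,
         no_candidates = report$no_candidates,
         gated = report$gated, gated_nogf = report$gated_nogf,
         aicc = as.list(attr(report$table1, "AICc")),
         weights = report$weights,
         averaged = report$averaged$table,
         provenance = report$provenance[c("package", "version",
                                          "n_species", "config")]),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Contrast correlation between two traits
#'
#' Through-origin regression of the contrasts of `y` on the contrasts of
#' `x`: slope, the through-origin coefficient of determination
#' `R^2 = 1 - RSS / sum(y_i^2)` (no mean-centering -- contrasts have mean
#' zero by construction), and a two-sided t test on `n - 2` degrees of
#' freedom (`n - 1` contrasts, one slope). This is the single-predictor
#' summary used for scatter-plot panels.
#'
#' @param x,y Named trait vectors.
#' @param tree A rooted binary `"phylo"` tree; at least 4 shared species.
#' @return List with `slope`, `r_squared`, `p_value`, `n_contrasts`.
#' @export
pic_correlation_report <- function(x, y, tree) {
  joined <- .join_species(tree, list(x = x, y = y), min_n = 4L)
  px <- as.numeric(pic_contrasts(joined$tree, joined$vectors$x))
  py <- as.numeric(pic_contrasts(joined$tree, joined$vectors$y))
  sxx <- sum(px^2)
  if (sxx == 0) stop("predictor contrasts are all zero")
  slope <- sum(px * py) / sxx
  rss <- sum((py - slope * px)^2)
  r2 <- 1 - rss / sum(py^2)
  df <- length(px) - 1L
  se <- sqrt(rss / df / sxx)
  tval <- slope / se
  list(slope = slope, r_squared = r2,
       p_value = 2 * stats::pt(-abs(tval), df = df),
       n_contrasts = length(px))
}
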