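# Habitat-variability scores. The climate envelope summarises a species'
# climatic niche breadth as the number of occupied cells in a 2-D grid laid
# over the first two principal components of the 19 bioclim variables, with
# the grid deliberately anisotropic (default 981 x 15 = 14 715 cells) to
# weigh the two axes by their variance contributions. The Brillouin index
# scores the diversity of categorical habitat climate classes.

#' Fit a shared principal-component space to pooled climate samples
#'
#' All species are projected into one PC space fitted to the pooled per-cell
#' bioclim rows, so that envelope counts are comparable across species.
#' Covariance PCA (no unit-variance scaling) is the default: the bioclim
#' variables carry meaningful, very unequal variances and unscaled PCA is
#' what concentrates ~98% of variance on PC1 for such data; set
#' `scale = TRUE` for correlation PCA.
#'
#' @param x Numeric matrix or data frame of climate samples (rows = occupied
#'   map cells pooled over species, columns = bioclim variables).
#' @param scale Logical; scale columns to unit variance before the
#'   decomposition (default `FALSE`, covariance PCA).
#' @return An object of class `"climate_pca"`: list with `center`, `scale`,
#'   `rotation` (orthonormal loadings), `sdev`, and `var_frac` (explained
#'   variance fractions, non-increasing).
#' @export
fit_climate_pca <- function(x, scale = FALSE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("climate samples must be numeric")
  if (nrow(x) < 3L) stop("need at least 3 sample rows to fit a PCA")
  if (ncol(x) < 2L) stop("need at least 2 climate variables")
  if (anyNA(x) || any(!is.finite(x))) stop("climate samples must be finite")
  if (scale) {
    v <- apply(x, 2L, stats::var)
    if (any(v == 0))
      stop("constant column(s) cannot be scaled to unit variance: ",
           paste(colnames(x)[v == 0], collapse = ", "))
  }
  p <- stats::prcomp(x, center = TRUE, scale. = scale)
  structure(
    list(center = p$center,
         scale = if (scale) p$scale else NULL,
         rotation = p$rotation,
         sdev = p$sdev,
         var_frac = p$sdev^2 / sum(p$sdev^2)),
    class = "climate_pca")
}

#' @export
print.climate_pca <- function(x, ...) {
  cat("Climate PCA (", length(x$center), " variables, ",
      if (is.null(x$scale)) "covariance" else "correlation", ")\n", sep = "")
  k <- min(4L, length(x$var_frac))
  cat("explained variance:",
      paste0(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$var_frac[seq_len(k)]),
             collapse = ", "), "\n")
  invisible(x)
}

#' Project climate samples onto the first two principal components
#'
#' @param x Numeric matrix/data frame with the same columns the model was
#'   fitted on.
#' @param model A `"climate_pca"` object from [fit_climate_pca()].
#' @return Numeric matrix with columns `PC1`, `PC2`.
#' @export
project_climate <- function(x, model) {
  stopifnot(inherits(model, "climate_pca"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$center))
    stop("column mismatch: model was fitted on ", length(model$center),
         " variables, data has ", ncol(x))
  xc <- sweep(x, 2L, model$center)
  if (!is.null(model$scale)) xc <- sweep(xc, 2L, model$scale, "/")
  s <- xc %*% model$rotation[, 1:2, drop = FALSE]
  colnames(s) <- c("PC1", "PC2")
  s
}

#' Define the envelope grid over PC space
#'
#' The grid should be built once from the pooled PC scores of *all* species
#' so each species' occupancy count refers to the same cells. The default
#' 981 x 15 split encodes the relative variance contributions of PC1 and PC2
#' (98.1% and 1.5%, at ten cells per percent) and yields 14 715 cells.
#'
#' @param scores Two-column matrix of pooled PC scores used for the axis
#'   ranges; alternatively pass `xlim`/`ylim` directly.
#' @param n1,n2 Number of bins along PC1 and PC2.
#' @param xlim,ylim Optional explicit axis ranges `(min, max)`.
#' @return An object of class `"envelope_grid"`.
#' @seealso [grid_bins_from_pca()] to derive `n1`, `n2` from a fitted PCA.
#' @export
envelope_grid <- function(scores = NULL, n1 = 981L, n2 = 15L,
                          xlim = NULL, ylim = NULL) {
  if (is.null(xlim) || is.null(ylim)) {
    if (is.null(scores)) stop("supply 'scores' or explicit xlim/ylim")
    scores <- as.matrix(scores)
    stopifnot(ncol(scores) >= 2L, nrow(scores) >= 1L)
    if (is.null(xlim)) xlim <- range(scores[, 1L])
    if (is.null(ylim)) ylim <- range(scores[, 2L])
  }
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  stopifnot(n1 >= 1L, n2 >= 1L,
            is.finite(xlim), is.finite(ylim),
            xlim[2L] > xlim[1L], ylim[2L] > ylim[1L])
  structure(list(xlim = xlim, ylim = ylim, n1 = n1, n2 = n2,
                 cells = n1 * n2),
            class = "envelope_grid")
}

#' Bin counts proportional to PC variance contributions
#'
#' Returns `round(cells_per_percent * 100 * var_frac)` for the first two
#' components, the rule that turns contributions of 98.1% and 1.5% into a
#' 981 x 15 grid.
#'
#' @param model A `"climate_pca"` object.
#' @param cells_per_percent Cells per percentage point of explained variance.
#' @return Integer vector `c(n1, n2)`.
#' @export
grid_bins_from_pca <- function(model, cells_per_percent = 10) {
  stopifnot(inherits(model, "climate_pca"))
  n <- as.integer(round(cells_per_percent * 100 * model$var_frac[1:2]))
  if (any(n < 1L)) stop("derived bin count below 1; increase cells_per_percent")
  n
}

# Half-open bin index: cell k covers [lo + (k-1) w, lo + k w), except the
# last cell which is closed so the axis maximum is counted once. Points
# outside the range are clipped into the edge cells.
.grid_bin <- function(v, lim, n) {
  i <- floor((v - lim[1L]) / (lim[2L] - lim[1L]) * n) + 1
  i[i < 1] <- 1
  i[i > n] <- n
  as.integer(i)
}

#' Climate envelope: occupied cells of the PC grid
#'
#' Counts the distinct grid cells containing at least one of the species'
#' score points. The count is a niche-breadth score: it grows with the area
#' of climate space the species occupies and is invariant to duplicated
#' sample points.
#'
#' @param scores Two-column matrix of the species' (PC1, PC2) scores.
#' @param grid An `"envelope_grid"`.
#' @return Nonnegative integer count of occupied cells.
#' @export
climate_envelope <- function(scores, grid) {
  stopifnot(inherits(grid, "envelope_grid"))
  scores <- as.matrix(scores)
  if (nrow(scores) < 1L) stop("empty score table")
  if (ncol(scores) < 2L) stop("scores must have two columns (PC1, PC2)")
  if (anyNA(scores)) stop("scores contain NA")
  i1 <- .grid_bin(scores[, 1L], grid$xlim, grid$n1)
  i2 <- .grid_bin(scores[, 2L], grid$ylim, grid$n2)
  length(unique((i1 - 1L) * grid$n2 + i2))
}

#' Square-root transform for the climate envelope
#'
#' The envelope is an occupancy count; its square root is the scale on which
#' all regressions are run.
#'
#' @param envelope Nonnegative numeric value(s).
#' @return `sqrt(envelope)`.
#' @export
sqrt_transform <- function(envelope) {
  if (any(!is.finite(envelope)) || any(envelope < 0))
    stop("envelope must be finite and nonnegative")
  sqrt(envelope)
}

#' Brillouin diversity index
#'
#' `H = (ln N! - sum ln n_i!) / N` for class counts `n_i` with total `N`,
#' computed through the log-gamma function so large counts do not overflow.
#' Unlike Shannon entropy this index describes the realised collection
#' itself and is robust to sample size. `H >= 0`, with equality iff a single
#' class holds all counts.
#'
#' @param counts Nonnegative integer vector of per-class counts (zeros are
#'   allowed and contribute nothing); total must be at least 1.
#' @return The Brillouin index, a nonnegative real number.
#' @examples
#' brillouin_index(c(2, 2))  # log(6)/4
#' @export
brillouin_index <- function(counts) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("class counts must be finite and nonnegative")
  N <- sum(counts)
  if (N < 1) stop("total count must be at least 1")
  (lgamma(N + 1) - sum(lgamma(counts + 1))) / N
}

#' Read a per-cell climate sample table
#'
#' Expects a TSV with a `species` column and the 19 bioclim columns
#' `bio1`..`bio19`, one row per occupied map cell.
#'
#' @param path File path.
#' @return Data frame with `species` and `bio1`..`bio19`.
#' @export
read_climate_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("species", paste0("bio", 1:19))
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("climate table missing column(s): ", paste(miss, collapse = ", "))
  d[need]
}

#' Read a habitat class count table
#'
#' TSV with columns `species`, `class`, `count` (occupied cells per climate
#' class per species), the input to [brillouin_index()].
#'
#' @param path File path.
#' @return Data frame with columns `species`, `class`, `count`.
#' @export
read_class_counts <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  miss <- setdiff(c("species", "class", "count"), names(d))
  if (length(miss))
    stop("class count table missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(d$count < 0)) stop("negative class counts")
  d
}
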