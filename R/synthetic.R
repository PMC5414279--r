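# Synthetic study generator. Emulates the statistical structure the
# comparative analysis assumes -- a Yule tree, Brownian trait evolution,
# per-species climate sample clouds whose breadth carries the planted
# signal, homology hit tables with threshold-boundary decoys, and a
# gene-to-category map consistent with the simulated per-category counts --
# so that every pipeline stage can be tested without external downloads.
# All generators are pure functions of (config, seed): a single master seed
# fans out to fixed per-component substreams.

.sub_seed <- function(seed, offset) {
  as.integer(((as.numeric(seed) %% 599999) * 3571 + offset * 7919) %%
               2147483647)
}

#' Configuration of a synthetic study
#'
#' Defaults emulate the target study scale: 32 species, 384 gene-function
#' categories, one category ("Exosome-like") causally linked to niche
#' breadth with an effect size calibrated so that the contrast-level signal
#' strength sits near R^2 = 0.5. See the methods vignette for the rationale
#' behind each default.
#'
#' @param n_species Number of tips (default 32).
#' @param n_categories Number of functional categories incl. the planted one
#'   (default 384).
#' @param planted_category Name of the causal category.
#' @param planted_effect Slope of latent sqrt-envelope on the planted
#'   category's gene count.
#' @param response_noise_rate Brownian rate of the residual sqrt-envelope
#'   noise.
#' @param birth_rate Yule speciation rate for the tree.
#' @param bm_rate Brownian rate of the latent predictor processes.
#' @param nogf_base_mean,nogf_base_sdlog Lognormal parameters for catalogue
#'   base gene counts.
#' @param nogf_planted_base Base gene count of the planted category.
#' @param nogf_spread Lognormal spread of per-species category counts
#'   around their base.
#' @param target_sqrt_env Baseline sqrt-envelope at the planted category's
#'   base count.
#' @param min_sqrt_env Floor on the latent sqrt-envelope (keeps niche
#'   breadths positive).
#' @param n_cells Climate sample rows per species.
#' @param axis_sd Latent climate-axis standard deviations (length 19; the
#'   steep decay concentrates pooled variance on two PCs).
#' @param center_spread Species-center spread along the first two axes, in
#'   multiples of `axis_sd`.
#' @param breadth_scale Cloud standard deviation per unit latent breadth,
#'   in multiples of `axis_sd`.
#' @param n_classes,class_samples,class_decay Habitat class-count model:
#'   number of classes, cells sampled per species, and the evenness decay
#'   (smaller latent breadth concentrates cells in fewer classes).
#' @param n_genes Genes per species in the homology hit tables.
#' @param dup_base,dup_spread Base count and lognormal spread of duplicate
#'   gene pairs per species.
#' @param seed Master seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_species = 32L,
                       n_categories = 384L,
                       planted_category = "Exosome-like",
                       planted_effect = 0.37,
                       response_noise_rate = 3,
                       birth_rate = 1,
                       bm_rate = 1,
                       nogf_base_mean = 25,
                       nogf_base_sdlog = 0.6,
                       nogf_planted_base = 50,
                       nogf_spread = 0.1,
                       target_sqrt_env = 16,
                       min_sqrt_env = 2,
                       n_cells = 4000L,
                       axis_sd = c(10, sqrt(10), rep(0.5, 17)),
                       center_spread = c(3, 0.5),
                       breadth_scale = 0.045,
                       n_classes = 13L,
                       class_samples = 500L,
                       class_decay = 6,
                       n_genes = 400L,
                       dup_base = 60,
                       dup_spread = 0.3,
                       seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              n_categories = as.integer(n_categories),
              planted_category = planted_category,
              planted_effect = planted_effect,
              response_noise_rate = response_noise_rate,
              birth_rate = birth_rate, bm_rate = bm_rate,
              nogf_base_mean = nogf_base_mean,
              nogf_base_sdlog = nogf_base_sdlog,
              nogf_planted_base = nogf_planted_base,
              nogf_spread = nogf_spread,
              target_sqrt_env = target_sqrt_env,
              min_sqrt_env = min_sqrt_env,
              n_cells = as.integer(n_cells),
              axis_sd = axis_sd, center_spread = center_spread,
              breadth_scale = breadth_scale,
              n_classes = as.integer(n_classes),
              class_samples = as.integer(class_samples),
              class_decay = class_decay,
              n_genes = as.integer(n_genes),
              dup_base = dup_base, dup_spread = dup_spread,
              seed = as.integer(seed))
  stopifnot(cfg$n_species >= 2L, cfg$n_categories >= 1L,
            cfg$n_cells >= 50L, cfg$n_genes >= 4L,
            length(cfg$axis_sd) == 19L, all(cfg$axis_sd > 0))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a Yule (pure-birth) tree
#'
#' @param n Number of tips (at least 2).
#' @param birth_rate Speciation rate.
#' @param seed Integer seed; the tree is deterministic given it.
#' @return A rooted binary `"phylo"` tree with positive branch lengths and
#'   tips `t1..tn`.
#' @export
simulate_tree <- function(n, birth_rate = 1, seed = 1L) {
  n <- as.integer(n)
  if (n < 2L) stop("need at least 2 tips")
  set.seed(as.integer(seed))
  tree <- ape::rphylo(n, birth = birth_rate, death = 0)
  tree$tip.label <- paste0("t", seq_len(n))
  tree
}

#' Simulate Brownian traits on a tree
#'
#' Draws `n_traits` independent Brownian-motion realisations (root value 0)
#' from the tree's Brownian covariance via its Cholesky factor.
#'
#' @param tree A rooted `"phylo"` tree with branch lengths.
#' @param rate Brownian rate (variance per unit branch length).
#' @param n_traits Number of independent traits.
#' @param seed Optional integer seed.
#' @return Matrix (tips x traits) with species rownames.
#' @export
simulate_bm <- function(tree, rate = 1, n_traits = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  C <- brownian_covariance(tree)
  R <- chol(C)
  n <- nrow(C)
  Z <- matrix(stats::rnorm(n * n_traits), n, n_traits)
  X <- sqrt(rate) * crossprod(R, Z)
  rownames(X) <- rownames(C)
  X
}

#' Simulate the species trait table and ground truth
#'
#' Every predictor evolves as independent Brownian motion on the tree and
#' is mapped to a plausible positive scale (count-like traits by
#' exponentiation and rounding, which keeps the Brownian structure on the
#' log scale). The response is planted on the category named in the
#' config: latent sqrt-envelope
#' `= target + beta * (NOGF_planted - base) + Brownian noise`, floored at
#' `min_sqrt_env`. Mass-specific metabolic rate scales allometrically with
#' body mass (exponent -1/4) plus lognormal noise.
#'
#' @param tree A `"phylo"` tree whose tips are the species.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `traits` (data frame: `species`, `envelope`, `G`,
#'   `N_g`, `N_d`, `M`, `B_c`, then one column per category), `catalogue`,
#'   and `ground_truth` (planted category and effect, latent breadths,
#'   expected duplicate counts, per-category base counts).
#' @export
simulate_traits <- function(tree, config = sim_config(), seed = 1L) {
  n <- length(tree$tip.label)
  K <- config$n_categories
  set.seed(.sub_seed(seed, 11))
  base <- pmax(3, round(stats::rlnorm(K, log(config$nogf_base_mean),
                                      config$nogf_base_sdlog)))
  catalogue <- c(config$planted_category,
                 sprintf("cat%03d", seq_len(K - 1L)))
  if (anyDuplicated(catalogue))
    stop("planted category collides with an auto-generated catalogue name")
  base[1L] <- config$nogf_planted_base

  Z <- simulate_bm(tree, rate = config$bm_rate, n_traits = K + 6L,
                   seed = .sub_seed(seed, 12))
  nogf <- sapply(seq_len(K), function(k)
    pmax(0L, as.integer(round(base[k] * exp(config$nogf_spread * Z[, k])))))
  colnames(nogf) <- catalogue

  G <- round(2.6e9 * exp(0.04 * Z[, K + 1L]))
  N_g <- round(2.1e4 * exp(0.05 * Z[, K + 2L]))
  M <- round(exp(log(3000) + 1.3 * Z[, K + 3L]), 1)
  B_c <- signif(0.0035 * (M / 3000)^(-0.25) * exp(0.2 * Z[, K + 4L]), 4)
  pairs <- pmax(0L, as.integer(round(config$dup_base *
                                       exp(config$dup_spread * Z[, K + 5L]))))
  pairs <- pmin(pairs, (config$n_genes - 4L) %/% 2L)
  N_d <- 2L * pairs

  noise <- simulate_bm(tree, rate = config$response_noise_rate,
                       n_traits = 1L, seed = .sub_seed(seed, 13))[, 1L]
  latent <- config$target_sqrt_env +
    config$planted_effect * (nogf[, 1L] - base[1L]) + noise
  latent <- pmax(config$min_sqrt_env, latent)

  traits <- data.frame(species = tree$tip.label,
                       envelope = as.integer(round(latent^2)),
                       G = G, N_g = N_g, N_d = N_d, M = M, B_c = B_c,
                       stringsAsFactors = FALSE)
  traits <- cbind(traits, as.data.frame(nogf, check.names = FALSE))
  rownames(traits) <- NULL

  list(traits = traits,
       catalogue = catalogue,
       ground_truth = list(
         planted_category = config$planted_category,
         planted_effect = config$planted_effect,
         latent_breadth = stats::setNames(latent, tree$tip.label),
         expected_n_d = stats::setNames(N_d, tree$tip.label),
         dup_pairs = stats::setNames(pairs, tree$tip.label),
         base_counts = stats::setNames(base, catalogue)))
}

# Fixed orthogonal rotation mixing the 19 latent climate axes into the
# observed bioclim-like columns, derived deterministically from the seed.
.climate_rotation <- function(seed) {
  set.seed(.sub_seed(seed, 21))
  Q <- qr.Q(qr(matrix(stats::rnorm(19 * 19), 19, 19)))
  Q * sign(diag(Q))[col(Q)]  # fix column signs for reproducibility
}

#' Simulate per-species climate sample clouds
#'
#' Each species receives `n_cells` rows drawn from a 19-dimensional
#' Gaussian: a species-specific center (spread along the first two latent
#' axes) plus a cloud whose standard deviation along every axis scales with
#' the species' latent niche breadth. The latent axis variances decay
#' steeply (defaults 100, 10, then 0.25), so a pooled PCA concentrates
#' ~98% of variance on the first two components; a fixed orthogonal
#' rotation then mixes the axes into the 19 observed columns. Larger
#' breadth yields a stochastically larger climate envelope.
#'
#' @param breadths Named positive vector of latent niche breadths (on the
#'   sqrt-envelope scale).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Data frame: `species`, `bio1`..`bio19`, `n_cells` rows per
#'   species.
#' @export
simulate_niche_samples <- function(breadths, config = sim_config(),
                                   seed = 1L) {
  if (is.null(names(breadths))) stop("'breadths' must be named by species")
  if (any(!is.finite(breadths)) || any(breadths <= 0))
    stop("niche breadths must be positive")
  nsp <- length(breadths)
  set.seed(.sub_seed(seed, 22))
  centers <- matrix(0, nsp, 19)
  centers[, 1L] <- stats::rnorm(nsp, 0,
                                config$axis_sd[1L] * config$center_spread[1L])
  centers[, 2L] <- stats::rnorm(nsp, 0,
                                config$axis_sd[2L] * config$center_spread[2L])
  Q <- .climate_rotation(config$seed)
  nc <- config$n_cells
  z <- matrix(stats::rnorm(nsp * nc * 19), ncol = 19)
  sdv <- outer(rep(config$breadth_scale * breadths, each = nc),
               config$axis_sd)
  pts <- (z * sdv + centers[rep(seq_len(nsp), each = nc), ]) %*% Q
  colnames(pts) <- paste0("bio", 1:19)
  out <- data.frame(species = rep(names(breadths), each = nc), pts,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a homology hit table for one species
#'
#' Emits `n_dup_pairs` passing intra-species hits (E-value strictly below
#' 1e-5 and coverage strictly above 30%), plus decoy hits among the
#' remaining genes that each fail exactly one threshold -- including hits
#' exactly at the E = 1e-5 and coverage = 30 boundaries, which the strict
#' filter must exclude -- plus a self-hit for every gene. The genes of
#' passing pairs are disjoint from decoy genes, so the recoverable
#' duplicated-gene count is exactly `2 * n_dup_pairs`.
#'
#' @param n_genes Total genes of the species (`>= 2 * n_dup_pairs`).
#' @param n_dup_pairs Number of true duplicate pairs.
#' @param species Species label.
#' @param seed Integer seed.
#' @return List with `hits` (data frame for
#'   [count_duplicated_genes()]) and `n_d` (the planted duplicated-gene
#'   count).
#' @export
simulate_hit_table <- function(n_genes, n_dup_pairs, species = "sp1",
                               seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_dup_pairs <- as.integer(n_dup_pairs)
  if (2L * n_dup_pairs > n_genes)
    stop("infeasible: 2 * n_dup_pairs exceeds n_genes")
  set.seed(.sub_seed(seed, 31))
  genes <- sprintf("%s_g%04d", species, seq_len(n_genes))
  rows <- list()
  if (n_dup_pairs > 0L) {
    qi <- genes[seq(1L, 2L * n_dup_pairs, by = 2L)]
    si <- genes[seq(2L, 2L * n_dup_pairs, by = 2L)]
    rows$pass <- data.frame(
      species = species, query = qi, subject = si,
      evalue = 10^stats::runif(n_dup_pairs, -30, -6),
      coverage = stats::runif(n_dup_pairs, 35, 100),
      stringsAsFactors = FALSE)
  }
  rest <- genes[seq_len(n_genes) > 2L * n_dup_pairs]
  if (length(rest) >= 2L) {
    nd <- length(rest) %/% 2L
    qd <- rest[seq_len(nd) * 2L - 1L]
    sd_ <- rest[seq_len(nd) * 2L]
    kind <- rep_len(c("e_boundary", "cov_boundary", "e_fail", "cov_fail"), nd)
    ev <- ifelse(kind == "e_boundary", 1e-5,
                 ifelse(kind == "e_fail", 10^stats::runif(nd, -4, -1),
                        10^stats::runif(nd, -30, -6)))
    cv <- ifelse(kind == "cov_boundary", 30,
                 ifelse(kind == "cov_fail", stats::runif(nd, 1, 29),
                        stats::runif(nd, 35, 100)))
    rows$decoy <- data.frame(species = species, query = qd, subject = sd_,
                             evalue = ev, coverage = cv,
                             stringsAsFactors = FALSE)
  }
  rows$self <- data.frame(species = species, query = genes, subject = genes,
                          evalue = 0, coverage = 100,
                          stringsAsFactors = FALSE)
  hits <- do.call(rbind, rows)
  rownames(hits) <- NULL
  list(hits = hits, n_d = 2L * n_dup_pairs)
}

#' Simulate habitat class counts
#'
#' Species with larger latent niche breadth spread their occupied cells
#' more evenly over the climate classes (multinomial with exponentially
#' decaying class probabilities whose decay rate is `class_decay /
#' breadth`), so the Brillouin index increases stochastically with breadth.
#'
#' @param breadths Named positive vector of latent niche breadths.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Data frame `species`, `class`, `count`.
#' @export
simulate_class_counts <- function(breadths, config = sim_config(),
                                  seed = 1L) {
  if (is.null(names(breadths))) stop("'breadths' must be named by species")
  if (any(breadths <= 0)) stop("niche breadths must be positive")
  set.seed(.sub_seed(seed, 41))
  K <- config$n_classes
  cls <- sprintf("class%02d", seq_len(K))
  out <- lapply(names(breadths), function(sp) {
    p <- exp(-(seq_len(K) - 1L) * config$class_decay / breadths[[sp]])
    cnt <- as.integer(stats::rmultinom(1L, config$class_samples, p / sum(p)))
    data.frame(species = sp, class = cls, count = cnt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a complete synthetic study
#'
#' Fans the master seed out to per-component substreams and generates every
#' input the pipeline consumes: tree, trait table, climate samples,
#' homology hit tables, gene-to-category map, habitat class counts, plus
#' the ground truth needed for recovery tests. The gene map is built to
#' reproduce the simulated per-category counts exactly, and the hit tables
#' reproduce the trait table's duplicated-gene counts exactly.
#'
#' @param config A [sim_config()]; the master seed lives in it.
#' @return List of class `"synthetic_study"` with elements `tree`,
#'   `traits`, `climate`, `hits`, `gene_map`, `class_counts`, `catalogue`,
#'   `ground_truth`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  tree <- simulate_tree(config$n_species, config$birth_rate,
                        .sub_seed(seed, 1))
  tr <- simulate_traits(tree, config, .sub_seed(seed, 2))
  gt <- tr$ground_truth
  climate <- simulate_niche_samples(gt$latent_breadth, config,
                                    .sub_seed(seed, 3))
  hits <- do.call(rbind, lapply(seq_along(tree$tip.label), function(i) {
    simulate_hit_table(config$n_genes, gt$dup_pairs[[i]],
                       species = tree$tip.label[i],
                       seed = .sub_seed(seed, 100 + i))$hits
  }))
  class_counts <- simulate_class_counts(gt$latent_breadth, config,
                                        .sub_seed(seed, 4))
  nogf <- as.matrix(tr$traits[, tr$catalogue, drop = FALSE])
  rownames(nogf) <- tr$traits$species
  gene_map <- .gene_map_from_counts(nogf, tr$catalogue)
  structure(list(tree = tree, traits = tr$traits, climate = climate,
                 hits = hits, gene_map = gene_map,
                 class_counts = class_counts, catalogue = tr$catalogue,
                 ground_truth = gt, config = config),
            class = "synthetic_study")
}

# Deterministic gene-to-category map whose per-category distinct-gene
# counts equal the given NOGF matrix.
.gene_map_from_counts <- function(nogf, catalogue) {
  sp <- rownames(nogf)
  species <- rep(rep(sp, times = ncol(nogf)), times = as.vector(nogf))
  category <- rep(rep(catalogue, each = nrow(nogf)), times = as.vector(nogf))
  idx <- sequence(as.vector(nogf))
  gene <- paste0(species, ".", rep(rep(seq_along(catalogue), each = nrow(nogf)),
                                   times = as.vector(nogf)), ".g", idx)
  data.frame(species = species, gene = gene, category = category,
             stringsAsFactors = FALSE)
}

#' Write a synthetic study to plain-text files
#'
#' Emits exactly the formats the analysis functions read: `tree.nwk`
#' (Newick), `traits.tsv`, `climate.tsv`, `hits.tsv`, `gene_map.tsv`,
#' `class_counts.tsv`, `catalogue.txt`, and `ground_truth.json`.
#'
#' @param study A `"synthetic_study"` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_newick(study$tree, file.path(dir, "tree.nwk"))
  wt(study$traits, "traits.tsv")
  wt(study$climate, "climate.tsv")
  wt(study$hits, "hits.tsv")
  wt(study$gene_map, "gene_map.tsv")
  wt(study$class_counts, "class_counts.tsv")
  writeLines(study$catalogue, file.path(dir, "catalogue.txt"))
  gt <- study$ground_truth
  jsonlite::write_json(
    list(planted_category = gt$planted_category,
         planted_effect = gt$planted_effect,
         latent_breadth = as.list(gt$latent_breadth),
         expected_n_d = as.list(gt$expected_n_d)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
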