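test_that("tree simulation is valid and deterministic", {
  t2 <- simulate_tree(2, seed = 1)
  expect_length(t2$tip.label, 2L)
  expect_true(all(t2$edge.length > 0))

  ta <- simulate_tree(32, seed = 42)
  tb <- simulate_tree(32, seed = 42)
  expect_identical(write_newick(ta), write_newick(tb))
  expect_error(simulate_tree(1), "at least 2")

  for (s in 1:50) {
    tr <- simulate_tree(sample(2:40, 1), seed = s)
    expect_true(is_binary_tree(tr))
    expect_true(all(tr$edge.length > 0))
  }
})

test_that("Brownian simulation honours the tree covariance", {
  tr <- simulate_tree(8, seed = 3)
  C <- brownian_covariance(tr)
  X <- simulate_bm(tr, rate = 2, n_traits = 4000, seed = 3)
  expect_equal(unname(cov(t(X))), unname(2 * C), tolerance = 0.15)
})

test_that("trait simulation is reproducible and internally consistent", {
  tr <- simulate_tree(16, seed = 5)
  cfg <- sim_config(n_species = 16L, n_categories = 40L)
  a <- simulate_traits(tr, cfg, seed = 9)
  b <- simulate_traits(tr, cfg, seed = 9)
  expect_identical(a$traits, b$traits)
  expect_true(all(a$traits$N_d <= a$traits$N_g))
  expect_true(all(a$traits$N_d == 2 * a$ground_truth$dup_pairs))
  expect_length(a$catalogue, 40L)
  expect_identical(a$catalogue[1], "Exosome-like")
  expect_true(all(a$traits$envelope >= 0))
})

test_that("without a planted effect the contrast correlation is null", {
  cors <- sapply(1:60, function(s) {
    tr <- simulate_tree(20, seed = s)
    cfg <- sim_config(n_species = 20L, n_categories = 5L,
                      planted_effect = 0)
    sim <- simulate_traits(tr, cfg, seed = s)
    x <- setNames(sim$traits[["Exosome-like"]], sim$traits$species)
    y <- sim$ground_truth$latent_breadth
    cor(as.numeric(pic_contrasts(tr, x)), as.numeric(pic_contrasts(tr, y)))
  })
  expect_lt(abs(mean(cors)), 0.12)
})

test_that("niche clouds concentrate pooled variance on two components", {
  tr <- simulate_tree(12, seed = 7)
  cfg <- sim_config(n_species = 12L, n_cells = 300L)
  sim <- simulate_traits(tr, cfg, seed = 7)
  cl <- simulate_niche_samples(sim$ground_truth$latent_breadth, cfg,
                               seed = 7)
  expect_equal(nrow(cl), 12L * 300L)
  pca <- fit_climate_pca(cl[paste0("bio", 1:19)])
  expect_gt(sum(pca$var_frac[1:2]), 0.9)
  expect_error(simulate_niche_samples(c(a = -1), cfg), "positive")
})

test_that("larger niche breadth yields larger climate envelopes", {
  cfg <- sim_config(n_cells = 400L)
  wins <- sapply(1:40, function(s) {
    br <- c(small = 4, big = 16)
    cl <- simulate_niche_samples(br, cfg, seed = s)
    pca <- fit_climate_pca(cl[paste0("bio", 1:19)])
    sc <- project_climate(cl[paste0("bio", 1:19)], pca)
    grid <- envelope_grid(sc, n1 = 981, n2 = 15)
    e <- vapply(names(br), function(sp)
      climate_envelope(sc[cl$species == sp, ], grid), integer(1))
    e[["big"]] > e[["small"]]
  })
  expect_gt(mean(wins), 0.95)
})

test_that("a vanishing breadth collapses the envelope to one cell", {
  cfg <- sim_config(n_cells = 100L)
  cl <- simulate_niche_samples(c(a = 1e-9, b = 10), cfg, seed = 1)
  pca <- fit_climate_pca(cl[paste0("bio", 1:19)])
  sc <- project_climate(cl[paste0("bio", 1:19)], pca)
  grid <- envelope_grid(sc, n1 = 981, n2 = 15)
  expect_equal(climate_envelope(sc[cl$species == "a", ], grid), 1L)
})

test_that("hit tables plant an exactly recoverable duplicate count", {
  sim <- simulate_hit_table(10, 3, species = "sp1", seed = 2)
  expect_equal(count_duplicated_genes(sim$hits), c(sp1 = 6L))
  expect_equal(sim$n_d, 6L)
  # decoys include exact-boundary rows and never count
  expect_true(any(sim$hits$evalue == 1e-5) || any(sim$hits$coverage == 30))
  none <- simulate_hit_table(10, 0, species = "sp1", seed = 3)
  expect_equal(count_duplicated_genes(none$hits), c(sp1 = 0L))
  expect_error(simulate_hit_table(5, 3), "infeasible")
})

test_that("class counts become more even with breadth", {
  cfg <- sim_config()
  h <- sapply(1:30, function(s) {
    cc <- simulate_class_counts(c(narrow = 3, wide = 20), cfg, seed = s)
    vapply(split(cc$count, cc$species), brillouin_index, numeric(1))
  })
  expect_gt(mean(h["wide", ] > h["narrow", ]), 0.95)
})

test_that("a full study is deterministic and consistent across files", {
  cfg <- sim_config(n_species = 10L, n_categories = 15L, n_cells = 120L,
                    n_genes = 60L, seed = 11L)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$traits, s2$traits)
  expect_identical(s1$climate, s2$climate)
  expect_identical(write_newick(s1$tree), write_newick(s2$tree))

  # hit tables reproduce the trait table's duplicated-gene counts
  nd <- count_duplicated_genes(s1$hits)
  expect_equal(unname(nd[s1$traits$species]), s1$traits$N_d)
  # the gene map reproduces the per-category counts
  nogf <- count_nogf(s1$gene_map, s1$catalogue)
  expect_equal(unname(nogf[s1$traits$species, ]),
               unname(as.matrix(s1$traits[, s1$catalogue])))
})

test_that("studies round-trip through the plain-text writers", {
  cfg <- sim_config(n_species = 6L, n_categories = 8L, n_cells = 80L,
                    n_genes = 30L, seed = 13L)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(all(file.exists(file.path(dir,
    c("tree.nwk", "traits.tsv", "climate.tsv", "hits.tsv",
      "gene_map.tsv", "class_counts.tsv", "catalogue.txt",
      "ground_truth.json")))))
  tr <- read_newick(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, st$tree$tip.label)
  cl <- read_climate_table(file.path(dir, "climate.tsv"))
  expect_equal(nrow(cl), nrow(st$climate))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_identical(gt$planted_category, "Exosome-like")
})
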