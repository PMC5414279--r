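test_that("duplicated-gene filter applies both strict thresholds", {
  h <- data.frame(species = "sp1",
                  query = c("g1", "g3"), subject = c("g2", "g4"),
                  evalue = c(1e-6, 1e-3), coverage = c(40, 90))
  expect_equal(count_duplicated_genes(h), c(sp1 = 2L))

  # only self-hits -> nothing duplicated
  selfh <- data.frame(species = "sp1", query = "g1", subject = "g1",
                      evalue = 0, coverage = 100)
  expect_equal(count_duplicated_genes(selfh), c(sp1 = 0L))

  # exact threshold values are excluded (strict inequalities)
  bound <- data.frame(species = "sp1",
                      query = c("g1", "g3"), subject = c("g2", "g4"),
                      evalue = c(1e-5, 1e-9), coverage = c(80, 30))
  expect_equal(count_duplicated_genes(bound), c(sp1 = 0L))

  # cross-species hits never mark genes as duplicated
  cross <- data.frame(species = "sp1", subject_species = c("sp1", "sp2"),
                      query = c("g1", "g5"), subject = c("g2", "g6"),
                      evalue = 1e-9, coverage = 90)
  expect_equal(count_duplicated_genes(cross), c(sp1 = 2L))

  bad <- data.frame(species = "sp1", query = "g1", subject = "g2",
                    evalue = -1, coverage = 50)
  expect_error(count_duplicated_genes(bad), "row")
})

test_that("a passing hit marks both genes and order is irrelevant", {
  h <- data.frame(species = "sp1",
                  query = c("g1", "g2", "g9"),
                  subject = c("g2", "g1", "g1"),
                  evalue = c(1e-8, 1e-8, 1e-7), coverage = c(50, 50, 45))
  n1 <- count_duplicated_genes(h)
  n2 <- count_duplicated_genes(h[sample(nrow(h)), ])
  expect_equal(n1, c(sp1 = 3L))
  expect_equal(n1, n2)
})

test_that("tightening either threshold never increases counts", {
  set.seed(11)
  h <- data.frame(species = "sp1",
                  query = sprintf("g%02d", sample(30, 60, TRUE)),
                  subject = sprintf("g%02d", sample(30, 60, TRUE)),
                  evalue = 10^runif(60, -12, -2),
                  coverage = runif(60, 0, 100))
  base <- count_duplicated_genes(h)
  expect_true(count_duplicated_genes(h, e_max = 1e-8) <= base)
  expect_true(count_duplicated_genes(h, cov_min_pct = 60) <= base)
})

test_that("hit-table reader computes coverage from qlen or takes qcovs", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  std <- data.frame(q = "g1", s = "g2", pid = 90, len = 60, mm = 1, go = 0,
                    qs = 1, qe = 60, ss = 1, se = 60, ev = 1e-9, bs = 100)
  # 13th column as explicit coverage
  utils::write.table(cbind(std, qcov = 45), tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  hits <- read_blast_hits(tmp, species = "sp1")
  expect_equal(hits$coverage, 45)
  # header with qlen -> coverage = 100 * length / qlen
  names(std) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")
  utils::write.table(cbind(std, qlen = 120), tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  hits <- read_blast_hits(tmp, species = "sp1")
  expect_equal(hits$coverage, 50)
  # bare 12 columns carry no coverage at all
  utils::write.table(std, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  expect_error(read_blast_hits(tmp, species = "sp1"), "coverage")
})

test_that("category counting uses distinct genes and the full catalogue", {
  cat3 <- c("Exosome", "Ribosome", "Spliceosome")
  empty <- data.frame(species = character(), gene = character(),
                      category = character())
  expect_equal(unname(count_nogf(empty, cat3)),
               matrix(integer(0), 0, 3), ignore_attr = TRUE)

  map <- data.frame(species = "sp1",
                    gene = c("g1", "g2", "g2", "g2"),
                    category = c("Exosome", "Exosome", "Ribosome",
                                 "Ribosome"))
  m <- count_nogf(map, cat3)
  expect_equal(m["sp1", ], c(Exosome = 2L, Ribosome = 1L, Spliceosome = 0L))
  # membership-sum identity: column totals equal per-gene indicator sums
  genes <- unique(map[c("species", "gene", "category")])
  for (cc in cat3)
    expect_equal(m["sp1", cc], sum(genes$category == cc))

  expect_error(count_nogf(data.frame(species = "sp1", gene = "g1",
                                     category = "Nucleosome"), cat3),
               "Nucleosome")
})
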