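test_that("TRL sums footprint strengths and applies the strictly-over-1 floor", {
  fp <- make_footprints("tx1", anchor = c(100L, 300L), strength = c(0.5, 0.7))
  trl <- compute_trl(fp)
  expect_equal(trl$trl_0h, 1.2)
  expect_true(trl$retained)           # 1.2 > 1

  fp2 <- make_footprints("tx2", anchor = 100L, strength = 1.0)
  trl2 <- compute_trl(fp2)
  expect_equal(trl2$trl_0h, 1.0)
  expect_false(trl2$retained)         # exactly 1 is not "over 1"

  # transcripts with no footprints report zero load and are excluded
  trl3 <- compute_trl(fp, transcripts = c("tx1", "bare"))
  expect_equal(trl3$trl_0h[trl3$transcript_id == "bare"], 0)
  expect_false(trl3$retained[trl3$transcript_id == "bare"])

  # replicate averaging: strengths 1 and 3 in two replicates average to 2
  fp4 <- rbind(make_footprints("tx1", 100L, 1.0, replicate = "r1"),
               make_footprints("tx1", 100L, 3.0, replicate = "r2"))
  expect_equal(compute_trl(fp4)$trl_0h, 2)
})

test_that("TRL is additive over footprint lists", {
  set.seed(8)
  fp_a <- make_footprints("tx1", anchor = c(50L, 200L), strength = runif(2))
  fp_b <- make_footprints("tx1", anchor = c(400L, 600L), strength = runif(2))
  fp_b$footprint_id <- c("fx101", "fx102")
  total <- compute_trl(rbind(fp_a, fp_b))$trl_0h
  expect_equal(total, compute_trl(fp_a)$trl_0h + compute_trl(fp_b)$trl_0h)
})

test_that("profile matrices are log2, quantile-normalized, replicate-averaged", {
  grid <- expand.grid(id = sprintf("t%02d", 1:12),
                      time_point = c("0h", "1h", "36h", "48h"),
                      replicate = c("r1", "r2"), stringsAsFactors = FALSE)
  set.seed(10)
  grid$value <- 10 ^ runif(nrow(grid), 0.4, 2)
  mat <- build_matrix(grid, min_level = 2)
  expect_equal(dim(mat), c(12L, 4L))

  # identical libraries pass through quantile normalization unchanged
  flat <- grid
  flat$value <- rep(10 ^ runif(12, 0.4, 2), times = 8)
  fmat <- build_matrix(flat, min_level = 2)
  expect_equal(fmat[, "0h"], fmat[, "48h"])
  expect_equal(unname(fmat[, "0h"]),
               unname(log2(flat$value[1:12] + 0.1)))

  # after normalization all library columns share one sorted multiset
  libs <- expand.grid(tp = c("0h", "1h", "36h", "48h"), rep = c("r1", "r2"))
  raw <- matrix(10 ^ runif(96, 0.4, 2), 12, 8)
  lmat <- log2(raw + 0.1)
  qn <- limma::normalizeBetweenArrays(lmat, method = "quantile")
  for (j in 2:8) expect_equal(sort(qn[, 1]), sort(qn[, j]))
  # and quantile normalization is idempotent
  expect_equal(limma::normalizeBetweenArrays(qn, method = "quantile"), qn)

  # the expression floor drops rows below 2 RPKM at every time point
  low <- grid
  low$value[low$id == "t01"] <- 1.9
  expect_false("t01" %in% rownames(build_matrix(low, min_level = 2)))
  # strict floor: a row exactly at the floor is dropped only when strict
  at1 <- grid
  at1$value[at1$id == "t02"] <- 1
  expect_true("t02" %in% rownames(build_matrix(at1, min_level = 1)))
  expect_false("t02" %in% rownames(build_matrix(at1, min_level = 1, strict = TRUE)))
})

test_that("k-means profile clustering is deterministic and separates groups", {
  set.seed(2)
  g1 <- matrix(rep(c(0, 0, 2, 2), each = 15), 15, 4) + rnorm(60, 0, 0.05)
  g2 <- matrix(rep(c(2, 2, 0, 0), each = 15), 15, 4) + rnorm(60, 0, 0.05)
  mat <- rbind(g1, g2)
  rownames(mat) <- sprintf("t%02d", 1:30)
  colnames(mat) <- c("0h", "1h", "36h", "48h")

  fit <- kmeans_profiles(mat, k_range = c(2L, 6L), k_final = 2L, seed = 4L)
  truth <- rep(1:2, each = 15)
  # perfect recovery up to label switching
  expect_equal(length(unique(paste(fit$assignments, truth))), 2L)

  fit2 <- kmeans_profiles(mat, k_range = c(2L, 6L), k_final = 2L, seed = 4L)
  expect_identical(fit$assignments, fit2$assignments)

  # inertia shrinks (weakly) as k grows and hits 0 at k = nrow
  expect_true(all(diff(fit$inertia$tot_withinss) <= 1e-8))
  full <- kmeans_profiles(mat, k_range = c(30L, 30L), k_final = 30L, seed = 4L)
  expect_equal(full$inertia$tot_withinss, 0, tolerance = 1e-12)

  expect_error(kmeans_profiles(mat, k_final = 31L), "exceeds")
})

test_that("mRNA/TRL contrasts report peak lead-lag in hours", {
  tps <- c("0h", "1h", "36h", "48h")
  mrna <- matrix(c(0, 0, 0, 1), 1, 4, dimnames = list("g1", tps))
  trl <- matrix(c(0, 0, 1, 0), 1, 4, dimnames = list("g1", tps))
  out <- contrast_profiles("g1", mrna, trl)
  expect_equal(out$lags$lag_hours, -12)   # TRL peaks at 36h, mRNA at 48h

  same <- contrast_profiles("g1", mrna, mrna)
  expect_equal(same$lags$lag_hours, 0)

  out2 <- contrast_profiles(c("g1", "g2"), mrna, trl)
  expect_equal(out2$skipped, "g2")
})

test_that("cluster gene-set enrichment uses the hypergeometric tail", {
  universe <- sprintf("g%03d", 1:100)
  sets <- list(setA = universe[1:10])
  clusters <- list(cl1 = universe[1:10], cl2 = universe[51:60])
  res <- gene_set_enrichment(clusters, sets, universe)
  hit <- res[res$cluster == "cl1", ]
  # a cluster equal to the set achieves the smallest attainable p
  expect_equal(hit$p, oracle_hyper_tail(10, 10, 10, 100), tolerance = 1e-12)
  expect_equal(res$p[res$cluster == "cl2"], 1)   # disjoint: k = 0
  expect_error(gene_set_enrichment(clusters, sets, character(0)), "universe")
  empty <- gene_set_enrichment(list(cl = character(0)), sets, universe)
  expect_equal(nrow(empty), 0L)
})
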