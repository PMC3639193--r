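test_that("RPKM follows its definition", {
  models <- transcript_models(data.frame(
    transcript_id = c("tx1", "tx2"), gene_id = c("g1", "g2"),
    length = c(2000L, 1000L), stringsAsFactors = FALSE))
  counts <- data.frame(transcript_id = c("tx1", "tx2", "tx2"),
                       time_point = "0h", replicate = "r1",
                       raw_count = c(1000L, 0L, 10L),
                       library_size = c(1e7, 1e7, 1e7))
  expr <- compute_rpkm(counts, models)
  expect_equal(expr$rpkm[1], 50)   # 1000 / (2 kb x 10 M)
  expect_equal(expr$rpkm[2], 0)
  expect_equal(expr$rpkm[3], 1)    # 1 kb transcript, counts = lib / 1e6
  counts$transcript_id[1] <- "nope"
  expect_error(compute_rpkm(counts, models), "unknown transcript")
})

test_that("start indexing catalogues fragment 5' ends", {
  fr <- data.frame(transcript_id = "tx1", start = c(10L, 12L, 10L),
                   length = 30L, count = c(2L, 1L, 2L),
                   replicate = "r1", time_point = "0h")
  v <- index_starts(fr, 40L)
  expect_equal(v[11], 4L)
  expect_equal(v[13], 1L)
  expect_equal(sum(v), 5L)
  expect_equal(index_starts(fr[0, ], 40L), integer(40L))
})

test_that("greedy footprint calling matches the worked examples", {
  v <- integer(400)
  v[101] <- 10L; v[106] <- 3L; v[301] <- 7L
  fp <- call_footprints(v, min_reads = 5L, assign_window = 10L)
  expect_equal(fp$anchor, c(100L, 300L))
  expect_equal(fp$read_count, c(13L, 7L))
  expect_equal(fp$start, fp$anchor)
  expect_equal(fp$end, fp$anchor + 50L)

  # below the depth floor: nothing called
  v2 <- integer(100); v2[51] <- 4L
  expect_equal(nrow(call_footprints(v2)), 0L)

  # equal maxima far apart: both called, leftmost consumed first
  v3 <- integer(400); v3[51] <- 8L; v3[201] <- 8L
  fp3 <- call_footprints(v3)
  expect_equal(fp3$anchor, c(50L, 200L))

  # the footprint interval clips at the transcript end
  v4 <- integer(60); v4[41] <- 9L
  expect_equal(call_footprints(v4)$end, 60L)
})

test_that("greedy caller equals the brute-force reference on random vectors", {
  set.seed(99)
  for (i in 1:300) {
    L <- sample(30:500, 1)
    v <- integer(L)
    n_frag <- sample(0:100, 1)
    if (n_frag > 0) {
      pos <- sample(L, min(n_frag, L), replace = TRUE)
      tab <- table(pos)
      v[as.integer(names(tab))] <- as.integer(tab)
    }
    got <- call_footprints(v, min_reads = 3L, assign_window = 7L)
    ref <- oracle_footprints(v, min_reads = 3L, assign_window = 7L)
    expect_identical(got$anchor, ref$anchor)
    expect_identical(got$read_count, ref$read_count)
  }
})

test_that("reads are conserved between footprints and the residual vector", {
  set.seed(17)
  v <- integer(300)
  pos <- sample(300, 120, replace = TRUE)
  tab <- table(pos)
  v[as.integer(names(tab))] <- as.integer(tab)
  fp <- call_footprints(v, min_reads = 4L, assign_window = 10L)
  consumed <- logical(300)
  for (a in fp$anchor)
    consumed[max(1, a + 1 - 10):min(300, a + 1 + 10)] <- TRUE
  expect_equal(sum(fp$read_count) + sum(v[!consumed]), sum(v))
})

test_that("strengths divide footprint RPM by transcript RPKM with a floor", {
  conds <- data.frame(time_point = "0h", replicate = "r1")
  fp <- data.frame(footprint_id = "fp1", transcript_id = "tx1", anchor = 100L,
                   start = 100L, end = 150L, read_count = 50L,
                   time_point = "0h", replicate = "r1",
                   stringsAsFactors = FALSE)
  libs <- data.frame(time_point = "0h", replicate = "r1", library_size = 1e7)
  expr <- flat_expression("tx1", conds, rpkm = 10)
  out <- compute_strengths(fp, libs, expr)
  expect_equal(out$rpm, 5)          # 50 reads in a 10M library
  expect_equal(out$strength, 0.5)   # 5 RPM / 10 RPKM
  expect_true(out$strength_defined)

  # expression below the floor: strength undefined and flagged
  low <- expr; low$rpkm <- 0.05
  out2 <- compute_strengths(fp, libs, low)
  expect_false(out2$strength_defined)
  expect_true(is.na(out2$strength))

  # doubling CLIP counts and library size leaves the strength unchanged
  fp2 <- fp; fp2$read_count <- 100L
  libs2 <- libs; libs2$library_size <- 2e7
  expect_equal(compute_strengths(fp2, libs2, expr)$strength, out$strength)

  expect_error(compute_strengths(fp, libs, expr[0, ]), "missing expression")
})

test_that("footprints merge within 20 bp, transitively, summing strengths", {
  fp <- make_footprints("tx1", anchor = c(100L, 165L), strength = c(1.0, 0.4))
  fp$end <- c(150L, 215L)                      # gap 15 <= 20: merge
  m <- merge_footprints(fp, max_gap = 20L)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 100L)
  expect_equal(m$end, 215L)
  expect_equal(m$strength, 1.4)
  expect_equal(m$anchor, 100L)                 # anchor of strongest member

  fp2 <- fp; fp2$start <- c(100L, 171L); fp2$anchor <- c(100L, 171L)
  fp2$end <- c(150L, 221L)                     # gap 21: keep separate
  expect_equal(nrow(merge_footprints(fp2, max_gap = 20L)), 2L)

  # chained intervals merge transitively, matching a pairwise-closure oracle
  set.seed(5)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    starts <- sort(sample(0:400, n))
    ends <- starts + sample(20:60, n, replace = TRUE)
    fpc <- make_footprints("tx1", anchor = starts, strength = runif(n))
    fpc$start <- starts; fpc$end <- ends
    got <- merge_footprints(fpc, max_gap = 20L)
    ref <- oracle_merge_intervals(starts, ends, max_gap = 20L)
    expect_equal(got$start, ref$start)
    expect_equal(got$end, ref$end)
  }
})
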