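# Small loading-table factory: counts for 2 replicates x 4 time points.
loading_table <- function(counts_matrix, time_points = c("0h", "1h", "36h", "48h"),
                          replicates = c("r1", "r2")) {
  libs <- expand.grid(time_point = time_points, replicate = replicates,
                      stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(libs)), function(i) {
    data.frame(mirna_id = rownames(counts_matrix),
               time_point = libs$time_point[i], replicate = libs$replicate[i],
               raw_count = counts_matrix[, i], stringsAsFactors = FALSE)
  }))
}

test_that("RPM follows its definition and normalizes each library to 1e6", {
  counts <- data.frame(mirna_id = c("a", "b"), time_point = "0h",
                       replicate = "r1", raw_count = c(100L, 999900L))
  rpm <- compute_rpm(counts)
  expect_equal(rpm$rpm[1], 100)
  expect_equal(sum(rpm$rpm), 1e6)

  # scale invariance: doubling all counts (and hence the library) is a no-op
  doubled <- counts
  doubled$raw_count <- doubled$raw_count * 2L
  expect_equal(compute_rpm(doubled)$rpm, rpm$rpm)

  # single-miRNA library
  solo <- data.frame(mirna_id = "a", time_point = "0h", replicate = "r1",
                     raw_count = 5000L)
  expect_equal(compute_rpm(solo)$rpm, 1e6)

  bad <- data.frame(mirna_id = "a", time_point = "0h", replicate = "r1",
                    raw_count = 0L, library_size = 0L)
  expect_error(compute_rpm(bad), "library size")
})

test_that("loading detection is inclusive at the cutoff and monotone in it", {
  m <- matrix(1000L, 3, 8, dimnames = list(c("at100", "at99", "high"), NULL))
  lib <- 1e6
  # columns are (0h,1h,36h,48h) x (r1,r2); mean RPM is exactly 100 at 36h
  m["at100", ] <- c(50L, 50L, 100L, 50L, 50L, 50L, 100L, 50L)
  m["at99", ] <- 99L
  m["high", ] <- 5000L
  tbl <- loading_table(m)
  tbl$library_size <- lib
  rpm <- compute_rpm(tbl)
  detected <- detect_loaded(rpm, rpm_detect = 100)
  expect_true("at100" %in% detected)   # mean RPM exactly 100 at 36h
  expect_false("at99" %in% detected)
  expect_true("high" %in% detected)

  # monotone: raising the cutoff never adds miRNAs
  set.seed(3)
  rand <- matrix(rpois(160, 2000), 20, 8,
                 dimnames = list(sprintf("m%02d", 1:20), NULL))
  rrpm <- compute_rpm({
    t2 <- loading_table(rand); t2$library_size <- 1e6; t2
  })
  cuts <- c(50, 100, 500, 1000, 2000, 3000)
  sets <- lapply(cuts, function(ct) detect_loaded(rrpm, ct))
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("global normalization zeroes the median log-ratio to the reference", {
  set.seed(7)
  base <- round(10 ^ runif(40, 3, 5))
  m <- matrix(rep(base, 8), 40, 8,
              dimnames = list(sprintf("m%02d", 1:40), NULL))
  tbl <- loading_table(m)
  tbl$library_size <- 1e6
  rpm <- compute_rpm(tbl)

  # identical libraries: all scale factors 1
  norm <- global_normalize(rpm)
  sf <- attr(norm, "scale_factors")
  expect_equal(sf$scale, rep(1, 8), tolerance = 1e-12)
  expect_equal(norm$normalized_rpm, norm$rpm)

  # one library at exactly 2x the reference gets scale 0.5
  spiked <- rpm
  sel <- spiked$time_point == "1h" & spiked$replicate == "r1"
  spiked$rpm[sel] <- spiked$rpm[sel] * 2
  norm2 <- global_normalize(spiked)
  sf2 <- attr(norm2, "scale_factors")
  expect_equal(sf2$scale[sf2$time_point == "1h" & sf2$replicate == "r1"], 0.5,
               tolerance = 1e-3)

  # random perturbation: the output median log-ratio is 0 by construction
  pert <- rpm
  sel <- pert$time_point == "36h" & pert$replicate == "r2"
  pert$rpm[sel] <- pert$rpm[sel] * exp(rnorm(sum(sel), 0.4, 0.3))
  norm3 <- global_normalize(pert)
  ref <- norm3[norm3$time_point == "0h", ]
  ref_mean <- tapply(ref$rpm, ref$mirna_id, mean)
  out <- norm3[sel, ]
  med <- median(log((out$normalized_rpm + 0.5) / (ref_mean[out$mirna_id] + 0.5)))
  expect_equal(med, 0, tolerance = 1e-3)

  # too few high-abundance miRNAs: warns and no-ops
  low <- compute_rpm(data.frame(mirna_id = letters[1:3], time_point = "0h",
                                replicate = "r1", raw_count = c(10L, 20L, 30L)))
  expect_warning(nl <- global_normalize(low), "skipped")
  expect_equal(nl$normalized_rpm, nl$rpm)
})

test_that("differential loading finds a planted 5x recruitment and respects the floor", {
  set.seed(21)
  n <- 200
  base <- 10 ^ runif(n, 3, 4.5)
  ids <- sprintf("m%03d", 1:n)
  libs <- expand.grid(time_point = c("0h", "1h", "36h", "48h"),
                      replicate = c("r1", "r2"), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(libs)), function(i) {
    mu <- base
    if (libs$time_point[i] == "1h") mu[1] <- mu[1] * 5   # planted recruitment
    data.frame(mirna_id = ids, time_point = libs$time_point[i],
               replicate = libs$replicate[i],
               raw_count = rnbinom(n, mu = mu, size = 1 / 0.01),
               stringsAsFactors = FALSE)
  })
  tbl <- do.call(rbind, rows)
  norm <- global_normalize(compute_rpm(tbl))
  calls <- call_differential_loading(norm)
  hit <- calls[calls$mirna_id == "m001" & calls$time_point == "1h", ]
  expect_true(hit$called)
  expect_equal(hit$direction, "up")
  expect_equal(hit$fold_change, 5, tolerance = 0.25)
  # null miRNAs should be called at no more than the FDR ceiling on average
  null_calls <- calls[calls$mirna_id != "m001", ]
  expect_lt(mean(null_calls$called), 0.20)
})

test_that("identical loading everywhere yields zero differential calls", {
  m <- matrix(5000L, 10, 8, dimnames = list(sprintf("m%02d", 1:10), NULL))
  norm <- global_normalize(compute_rpm(loading_table(m)))
  calls <- call_differential_loading(norm)
  expect_true(all(!calls$called))
  # missing quiescent reference is an error
  no_ref <- norm[norm$time_point != "0h", ]
  expect_error(call_differential_loading(no_ref), "reference")
})
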