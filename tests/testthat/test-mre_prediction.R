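let7 <- c("miR-let7" = "UGAGGUAGUAGGUUGUAUAGUU")   # seed (nt 2-8) GAGGUAG

make_models <- function(seqs) {
  transcript_models(
    data.frame(transcript_id = names(seqs), gene_id = paste0("g_", names(seqs)),
               length = nchar(seqs), stringsAsFactors = FALSE),
    sequences = seqs)
}

test_that("the seed scanner classifies and places site types correctly", {
  # CTACCTC = reverse complement of seed nt 2-8; G suffix blocks the A1 class
  seqs <- c(tx1 = paste0(strrep("G", 30), "CTACCTC", strrep("G", 30)))
  hits <- seed_scan(let7, make_models(seqs))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$site_type, "7mer-m8")
  expect_equal(hits$mre_start, 30L)

  # a trailing A upgrades the same core occurrence to a single 8mer report
  seqs8 <- c(tx1 = paste0(strrep("G", 30), "CTACCTCA", strrep("G", 30)))
  hits8 <- seed_scan(let7, make_models(seqs8))
  expect_equal(nrow(hits8), 1L)
  expect_equal(hits8$site_type, "8mer")
  expect_equal(hits8$mre_start, 30L)

  # 6mer-only occurrences fall below the default reportable class
  seqs6 <- c(tx1 = paste0(strrep("G", 30), "TACCTC", strrep("G", 30)))
  expect_equal(nrow(seed_scan(let7, make_models(seqs6))), 0L)
  h6 <- seed_scan(let7, make_models(seqs6), min_class = "6mer")
  expect_equal(h6$site_type, "6mer")
  expect_equal(h6$mre_start, 30L)

  # no complementary 6mer anywhere: empty result
  none <- c(tx1 = strrep("A", 100))
  expect_equal(nrow(seed_scan(let7, make_models(none))), 0L)

  bad <- c("miR-x" = "UGAGGNAGU")
  expect_error(seed_scan(bad, make_models(seqs)), "non-nucleotide")
})

test_that("the seed scanner agrees with a brute-force oracle on random sequences", {
  set.seed(31)
  for (trial in 1:15) {
    mirna <- paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE),
                   collapse = "")
    seq <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                 collapse = "")
    got <- seed_scan(setNames(mirna, "mi"), make_models(c(tx = seq)),
                     min_class = "6mer")
    ref <- oracle_seed_sites(mirna, seq)
    ref <- ref[order(ref$mre_start), ]
    expect_equal(got$mre_start, ref$mre_start)
    expect_equal(got$site_type, ref$site_type)
  }
})

test_that("imported miRanda hits are re-filtered on score and energy", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna\ttranscript\tposition\tscore\tenergy",
               "miR-1\ttx1\t120\t139\t-15",    # score below 140: dropped
               "miR-1\ttx1\t200\t150\t-9.5",   # energy above -10: dropped
               "miR-2\ttx2\t300\t150\t-12"), tsv)
  hits <- read_miranda_hits(tsv)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$mirna_id, "miR-2")
  expect_equal(hits$mre_start, 300L)
  expect_equal(hits$site_type, "imported")

  writeLines(c("mirna\ttranscript\tposition\tscore\tenergy",
               "miR-1\ttx1\tNA\t150\t-12"), tsv)
  expect_error(read_miranda_hits(tsv), "malformed")
})

test_that("confirmation applies all three inclusive thresholds jointly", {
  conds <- data.frame(time_point = "0h", replicate = "r1")
  combos <- expand.grid(offset = c(4L, 5L, 43L, 44L),
                        strength = c(0.30, 0.31),
                        rpm = c(99, 100))
  pass <- logical(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    fp <- make_footprints("tx1", anchor = 100L, strength = combos$strength[i])
    pairs <- data.frame(mirna_id = "miR-1", transcript_id = "tx1",
                        mre_start = 100L + combos$offset[i],
                        site_type = "7mer-m8", score = 3, energy = NA_real_,
                        stringsAsFactors = FALSE)
    loading <- data.frame(mirna_id = "miR-1", time_point = "0h",
                          replicate = "r1", raw_count = 1L,
                          rpm = combos$rpm[i], stringsAsFactors = FALSE)
    res <- confirm_mres(pairs, fp, loading)
    pass[i] <- res$pairs$confirmed
  }
  expected <- combos$offset >= 5 & combos$offset <= 43 &
    combos$strength >= 0.31 & combos$rpm >= 100
  expect_identical(pass, expected)
  # of the corner combinations {4,44}x{0.30}x{99} vs {5,43}x{0.31}x{100},
  # confirmation holds exactly when all three inclusive bounds hold
  corner <- combos$offset %in% c(4L, 5L)
  expect_equal(sum(pass[combos$offset == 4L]), 0L)
  expect_equal(sum(pass), sum(expected))
})

test_that("confirmation is monotone when criteria are loosened", {
  set.seed(13)
  conds <- data.frame(time_point = "0h", replicate = "r1")
  fp <- make_footprints("tx1", anchor = c(100L, 400L), strength = c(0.4, 1.2))
  pairs <- data.frame(mirna_id = rep(c("miR-1", "miR-2"), each = 6),
                      transcript_id = "tx1",
                      mre_start = sample(80:460, 12),
                      site_type = "7mer-m8", score = 3, energy = NA_real_,
                      stringsAsFactors = FALSE)
  loading <- data.frame(mirna_id = c("miR-1", "miR-2"), time_point = "0h",
                        replicate = "r1", raw_count = 1L, rpm = c(150, 90),
                        stringsAsFactors = FALSE)
  strict <- confirm_mres(pairs, fp, loading,
                         confirmation_criteria(100, c(5L, 43L), 0.31))
  loose <- confirm_mres(pairs, fp, loading,
                        confirmation_criteria(80, c(3L, 60L), 0.2))
  expect_true(all(which(strict$pairs$confirmed) %in% which(loose$pairs$confirmed)))
})

test_that("refinement summary reports unique-pair counts and the ratio", {
  raw <- data.frame(mirna_id = rep("miR-1", 400),
                    transcript_id = sprintf("tx%03d", 1:400))
  conf <- raw
  conf$confirmed <- c(rep(TRUE, 20), rep(FALSE, 380))
  s <- summarize_refinement(raw, conf)
  expect_equal(s$n_raw, 400L)
  expect_equal(s$n_confirmed, 20L)
  expect_equal(s$refinement_ratio, 20)
  conf$confirmed <- TRUE
  expect_equal(summarize_refinement(raw, conf)$refinement_ratio, 1)
})
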