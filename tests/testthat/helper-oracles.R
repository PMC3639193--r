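# Independent reference implementations used as oracles. Each is written
# as a direct transliteration of the rule it checks, favouring clarity over
# speed, and shares no code with the package internals.

# Footprint coalescing by explicit re-sorting of positions by count
# (descending, then leftmost). Returns anchors (0-based) and read counts.
oracle_footprints <- function(v, min_reads = 5L, assign_window = 10L) {
  v <- as.integer(v)
  anchors <- integer(0)
  reads <- integer(0)
  repeat {
    ord <- order(-v, seq_along(v))
    top <- ord[1]
    if (v[top] < min_reads) break
    win <- max(1L, top - assign_window):min(length(v), top + assign_window)
    anchors <- c(anchors, top - 1L)
    reads <- c(reads, sum(v[win]))
    v[win] <- 0L
  }
  data.frame(anchor = anchors, read_count = reads)
}

# Transitive-closure merging of intervals by pairwise gap testing
# (quadratic sweep to a fixed point), independent of the package's
# single-pass sort-based implementation.
oracle_merge_intervals <- function(start, end, max_gap = 20L) {
  grp <- seq_along(start)
  repeat {
    changed <- FALSE
    for (i in seq_along(start)) for (j in seq_along(start)) {
      if (grp[i] == grp[j]) next
      gap <- max(start[i], start[j]) - min(end[i], end[j])
      if (gap <= max_gap) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- lapply(split(seq_along(start), grp), function(ix)
    c(start = min(start[ix]), end = max(end[ix]), n = length(ix)))
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$start), ]
}

# Brute-force seed-site search: walk every position of the transcript,
# compare substrings against explicitly constructed site strings, and
# classify each 6mer-core occurrence by its best extension.
oracle_seed_sites <- function(mirna, seq) {
  rc <- function(x) {
    x <- chartr("U", "T", x)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }
  site6 <- rc(substr(mirna, 2, 7))
  m8_base <- rc(substr(mirna, 8, 8))
  hits <- list()
  n <- nchar(seq)
  if (n >= 6) for (c0 in 0:(n - 6)) {          # 0-based core start
    if (substr(seq, c0 + 1, c0 + 6) != site6) next
    has_m8 <- c0 >= 1 && substr(seq, c0, c0) == m8_base
    has_a1 <- c0 + 6 < n && substr(seq, c0 + 7, c0 + 7) == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
            else if (has_a1) "7mer-A1" else "6mer"
    hits[[length(hits) + 1]] <- data.frame(
      mre_start = if (has_m8) c0 - 1 else c0, site_type = type,
      stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(mre_start = integer(), site_type = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

# Exhaustive hypergeometric upper tail: sum the pmf term by term from
# binomial coefficients (no distribution functions involved).
oracle_hyper_tail <- function(k, m, n, N) {
  if (k == 0) return(1)
  js <- k:min(m, n)
  sum(exp(lchoose(n, js) + lchoose(N - n, m - js) - lchoose(N, m)))
}

# Direct evaluation of the Benjamini-Hochberg step-up definition.
oracle_bh <- function(p) {
  M <- length(p)
  ord <- order(p)
  q <- numeric(M)
  for (i in seq_len(M)) {
    js <- i:M
    q[ord[i]] <- min(p[ord[js]] * M / js, 1)
  }
  q
}

# Small expression table covering every footprint condition at a flat RPKM.
flat_expression <- function(transcripts, conditions, rpkm = 10) {
  grid <- expand.grid(transcript_id = transcripts,
                      idx = seq_len(nrow(conditions)),
                      stringsAsFactors = FALSE)
  data.frame(transcript_id = grid$transcript_id,
             time_point = conditions$time_point[grid$idx],
             replicate = conditions$replicate[grid$idx],
             raw_count = 1L, library_size = 1e6, rpkm = rpkm,
             stringsAsFactors = FALSE)
}

# Hand-built footprint row(s) with strengths, for filter fixtures.
make_footprints <- function(transcript_id, anchor, strength,
                            time_point = "0h", replicate = "r1",
                            read_count = 10L, footprint_len = 50L) {
  n <- max(length(transcript_id), length(anchor), length(strength))
  data.frame(footprint_id = sprintf("fx%03d", seq_len(n)),
             transcript_id = rep_len(transcript_id, n),
             anchor = rep_len(anchor, n),
             start = rep_len(anchor, n),
             end = rep_len(anchor, n) + footprint_len,
             read_count = rep_len(read_count, n),
             time_point = rep_len(time_point, n),
             replicate = rep_len(replicate, n),
             rpm = rep_len(strength, n) * 10,
             rpkm = 10,
             strength_defined = !is.na(rep_len(strength, n)),
             strength = rep_len(strength, n),
             stringsAsFactors = FALSE)
}

# A hand-built single-hub study: 5 mRNAs each dominated by one footprint
# whose only strongly loaded confirmed miRNA is the hub; a decoy miRNA is
# confirmed on the same footprints but loaded below 10% of the hub.
hub_fixture <- function() {
  txs <- sprintf("tx%d", 1:5)
  fp <- do.call(rbind, lapply(seq_along(txs), function(i) {
    f <- make_footprints(txs[i], anchor = 100L, strength = 2.0,
                         time_point = "1h", replicate = "r1")
    f$footprint_id <- sprintf("fp%d", i)
    f
  }))
  support <- rbind(
    data.frame(pair_index = 1:5, mirna_id = "miR-hub", transcript_id = txs,
               mre_start = 110L, time_point = "1h", replicate = "r1",
               footprint_id = sprintf("fp%d", 1:5), offset = 10L,
               stringsAsFactors = FALSE),
    data.frame(pair_index = 6:10, mirna_id = "miR-decoy", transcript_id = txs,
               mre_start = 120L, time_point = "1h", replicate = "r1",
               footprint_id = sprintf("fp%d", 1:5), offset = 20L,
               stringsAsFactors = FALSE))
  loading <- data.frame(
    mirna_id = c("miR-hub", "miR-decoy"),
    time_point = "1h", replicate = "r1", raw_count = 1L,
    rpm = c(5000, 400), normalized_rpm = c(5000, 400),
    stringsAsFactors = FALSE)
  list(footprints = fp, confirmation = list(support = support),
       loading = loading, txs = txs)
}
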