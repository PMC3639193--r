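## miRNA regulatory element (MRE) handling: an internal seed-match scanner
## (nucleotides 2-8 of the miRNA; 8mer / 7mer-m8 / 7mer-A1 / 6mer site
## classes), an importer for miRanda-style prediction tables, and the
## footprint-based confirmation filter: a pair is confirmed when the miRNA
## is RISC-loaded at >= 100 RPM and its MRE lies 5-43 nt downstream of the
## anchor of a footprint with strength >= 0.31 RPM/RPKM, evaluated
## separately for each replicate at each time point.

SITE_RANK <- c("6mer" = 1L, "7mer-A1" = 2L, "7mer-m8" = 3L, "8mer" = 4L)

## DNA reverse complement of an RNA or DNA string (U treated as T)
revcomp_dna <- function(x) {
  x <- chartr("Uu", "Tt", x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## mRNA-side site matching miRNA nt 2-8 (the 7mer-m8 core written 5'->3')
seed_site_7m8 <- function(mirna) revcomp_dna(substr(mirna, 2L, 8L))

#' Scan transcript sequences for miRNA seed-match sites
#'
#' Finds perfect Watson-Crick complements of the miRNA seed in every
#' transcript region (5'UTR, CDS and 3'UTR alike). For each occurrence of
#' the 6mer core (complement of miRNA nt 2-7) the site is extended and
#' classified: an additional match to nt 8 on the 5' side gives 7mer-m8, an
#' adenosine opposite nt 1 on the 3' side gives 7mer-A1, both give 8mer.
#' Each core occurrence is reported once with its best class
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer). \code{mre_start} is the 5'-most
#' transcript coordinate of the classified site (0-based).
#'
#' @param mirnas named character vector of miRNA sequences (RNA or DNA
#'   alphabet).
#' @param models \code{\link{transcript_models}} carrying sequences.
#' @param min_class weakest reportable class (default "7mer-m8").
#' @return data.frame of candidate pairs: \code{mirna_id},
#'   \code{transcript_id}, \code{mre_start}, \code{site_type}, \code{score}
#'   (site-class rank), \code{energy} (NA for scanned sites).
#' @export
seed_scan <- function(mirnas, models, min_class = "7mer-m8") {
  if (is.null(models$sequences))
    stop("transcript models carry no sequences")
  if (!min_class %in% names(SITE_RANK))
    stop("min_class must be one of: ", paste(names(SITE_RANK), collapse = ", "))
  bad <- grepl("[^ACGTUacgtu]", mirnas)
  if (any(bad))
    stop("non-nucleotide characters in miRNA sequence(s): ",
         paste(names(mirnas)[bad], collapse = ", "))
  min_rank <- SITE_RANK[[min_class]]
  rows <- list()
  for (mi in names(mirnas)) {
    core <- revcomp_dna(substr(mirnas[[mi]], 2L, 7L))   # 6mer core
    m8 <- revcomp_dna(substr(mirnas[[mi]], 8L, 8L))     # 5' extension base
    for (tx in names(models$sequences)) {
      seq <- models$sequences[[tx]]
      hits <- gregexpr(core, seq, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      for (h in as.integer(hits)) {           # h is 1-based core start
        p <- h - 1L                           # 0-based core start
        has_m8 <- p >= 1L && substr(seq, h - 1L, h - 1L) == m8
        has_a1 <- p + 6L < nchar(seq) && substr(seq, h + 6L, h + 6L) == "A"
        type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
                else if (has_a1) "7mer-A1" else "6mer"
        if (SITE_RANK[[type]] < min_rank) next
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mi, transcript_id = tx,
          mre_start = if (has_m8) p - 1L else p,
          site_type = type, score = SITE_RANK[[type]], energy = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      mre_start = integer(), site_type = character(),
                      score = numeric(), energy = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$mirna_id, out$transcript_id, out$mre_start), ]
}

#' Import miRanda-style target predictions
#'
#' Reads a tabular export with columns \code{mirna}, \code{transcript},
#' \code{position} (5'-most mRNA coordinate of the site, 0-based),
#' \code{score}, \code{energy} (kcal/mol), and defensively re-applies the
#' prediction thresholds: alignment score at least \code{min_score} and
#' duplex energy at most \code{max_energy}.
#'
#' @param path TSV file with a header.
#' @param min_score minimum alignment score (default 140).
#' @param max_energy maximum (most positive) duplex energy (default -10).
#' @return data.frame in the same shape as \code{\link{seed_scan}} with
#'   \code{site_type = "imported"}.
#' @export
read_miranda_hits <- function(path, min_score = 140, max_energy = -10) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("mirna", "transcript", "position", "score", "energy")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("miRanda table missing column(s): ", paste(miss, collapse = ", "))
  bad <- !is.finite(df$position) | df$position < 0 |
    !is.finite(df$score) | !is.finite(df$energy)
  if (any(bad))
    stop("malformed miRanda row at line ", which(bad)[1] + 1L)
  keep <- df$score >= min_score & df$energy <= max_energy
  df <- df[keep, , drop = FALSE]
  out <- data.frame(mirna_id = df$mirna, transcript_id = df$transcript,
                    mre_start = as.integer(df$position),
                    site_type = "imported", score = df$score,
                    energy = df$energy, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Confirmation criteria for miRNA:mRNA pairs
#'
#' @param min_mirna_rpm minimum Ago-short loading, RPM (default 100,
#'   inclusive).
#' @param window inclusive offset window (nt) of the MRE downstream of the
#'   footprint anchor (default 5..43).
#' @param min_strength minimum footprint strength, RPM/RPKM (default 0.31,
#'   inclusive).
#' @return list of class \code{confirmation_criteria}.
#' @export
confirmation_criteria <- function(min_mirna_rpm = 100, window = c(5L, 43L),
                                  min_strength = 0.31) {
  stopifnot(window[1] <= window[2], min_mirna_rpm > 0, min_strength > 0)
  structure(list(min_mirna_rpm = min_mirna_rpm, window = window,
                 min_strength = min_strength),
            class = "confirmation_criteria")
}

#' Confirm candidate MREs against Ago footprints
#'
#' For each (time point, replicate) separately, a candidate pair is
#' confirmed when (a) the miRNA is present in that replicate's Ago-short
#' library at \code{min_mirna_rpm} or more, and (b) some footprint on the
#' transcript has a defined strength of at least \code{min_strength} with
#' the MRE start lying \code{window[1]}..\code{window[2]} nt downstream of
#' the footprint anchor (downstream = increasing transcript coordinate; the
#' footprint start is its anchor). The confirmed set is the union over all
#' conditions, with supporting evidence recorded.
#'
#' @param pairs candidate pairs (\code{\link{seed_scan}} or
#'   \code{\link{read_miranda_hits}}).
#' @param footprints footprints with strengths
#'   (\code{\link{compute_strengths}}).
#' @param loading miRNA loading table with \code{rpm}
#'   (\code{\link{compute_rpm}}).
#' @param criteria a \code{\link{confirmation_criteria}}.
#' @return list with \code{pairs} (input plus \code{confirmed} and
#'   \code{n_supporting_conditions}) and \code{support} (one row per
#'   confirmed pair x condition x footprint:
#'   condition labels, \code{footprint_id}, \code{offset}).
#' @export
confirm_mres <- function(pairs, footprints, loading,
                         criteria = confirmation_criteria()) {
  conds <- unique(footprints[c("time_point", "replicate")])
  lk <- paste(loading$mirna_id, loading$time_point, loading$replicate)
  support <- list()
  if (nrow(pairs)) for (i in seq_len(nrow(conds))) {
    tp <- conds$time_point[i]; rp <- conds$replicate[i]
    mi_rpm <- loading$rpm[match(paste(pairs$mirna_id, tp, rp), lk)]
    if (anyNA(mi_rpm))
      stop("loading table missing condition (", tp, ", ", rp,
           ") for some miRNA(s)")
    fp <- footprints[footprints$time_point == tp &
                       footprints$replicate == rp &
                       footprints$strength_defined &
                       !is.na(footprints$strength) &
                       footprints$strength >= criteria$min_strength, ,
                     drop = FALSE]
    if (!nrow(fp)) next
    cand <- which(mi_rpm >= criteria$min_mirna_rpm)
    for (j in cand) {
      hits <- fp[fp$transcript_id == pairs$transcript_id[j], , drop = FALSE]
      if (!nrow(hits)) next
      offset <- pairs$mre_start[j] - hits$anchor
      ok <- offset >= criteria$window[1] & offset <= criteria$window[2]
      if (any(ok)) {
        support[[length(support) + 1L]] <- data.frame(
          pair_index = j, mirna_id = pairs$mirna_id[j],
          transcript_id = pairs$transcript_id[j],
          mre_start = pairs$mre_start[j], time_point = tp, replicate = rp,
          footprint_id = hits$footprint_id[ok], offset = offset[ok],
          stringsAsFactors = FALSE)
      }
    }
  }
  support <- if (length(support)) do.call(rbind, support) else
    data.frame(pair_index = integer(), mirna_id = character(),
               transcript_id = character(), mre_start = integer(),
               time_point = character(), replicate = character(),
               footprint_id = character(), offset = integer(),
               stringsAsFactors = FALSE)
  pairs$confirmed <- seq_len(nrow(pairs)) %in% support$pair_index
  n_cond <- tapply(paste(support$time_point, support$replicate),
                   support$pair_index,
                   function(x) length(unique(x)))
  pairs$n_supporting_conditions <- 0L
  if (length(n_cond))
    pairs$n_supporting_conditions[as.integer(names(n_cond))] <-
      as.integer(n_cond)
  list(pairs = pairs, support = support)
}

#' Summarize the refinement of raw predictions by footprint confirmation
#'
#' @param raw_pairs candidate pair table.
#' @param confirmed_pairs pair table with a \code{confirmed} column.
#' @return list with \code{n_raw}, \code{n_confirmed} (unique
#'   miRNA:transcript pairs) and \code{refinement_ratio} = n_raw /
#'   n_confirmed (Inf when nothing is confirmed).
#' @export
summarize_refinement <- function(raw_pairs, confirmed_pairs) {
  uniq <- function(df) unique(df[c("mirna_id", "transcript_id")])
  n_raw <- nrow(uniq(raw_pairs))
  conf <- confirmed_pairs[confirmed_pairs$confirmed, , drop = FALSE]
  n_confirmed <- nrow(uniq(conf))
  list(n_raw = n_raw, n_confirmed = n_confirmed,
       refinement_ratio = if (n_confirmed > 0) n_raw / n_confirmed else Inf)
}
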