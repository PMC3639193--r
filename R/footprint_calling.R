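## Ago footprint calling: CLIP fragment 5' ends are catalogued per
## transcript, coalesced into footprints anchored at the locally strongest
## accumulation of starts, and weighted by transcript abundance
## (strength = footprint RPM / transcript RPKM).

#' Compute RPKM from an RNA-seq counts table
#'
#' RPKM = raw_count / (transcript length in kb x library size in millions).
#'
#' @param counts data.frame with \code{transcript_id}, \code{time_point},
#'   \code{replicate}, \code{raw_count} and \code{library_size}.
#' @param models \code{\link{transcript_models}} supplying lengths.
#' @return The input with an \code{rpkm} column.
#' @examples
#' models <- transcript_models(data.frame(transcript_id = "tx1",
#'                                        gene_id = "g1", length = 2000))
#' counts <- data.frame(transcript_id = "tx1", time_point = "0h",
#'                      replicate = "r1", raw_count = 1000,
#'                      library_size = 1e7)
#' compute_rpkm(counts, models)$rpkm  # 50
#' @export
compute_rpkm <- function(counts, models) {
  len <- models$transcripts$length[match(counts$transcript_id,
                                         models$transcripts$transcript_id)]
  if (anyNA(len))
    stop("unknown transcript_id in counts: ",
         paste(unique(counts$transcript_id[is.na(len)]), collapse = ", "))
  if (any(counts$library_size <= 0)) stop("library_size must be positive")
  counts$rpkm <- counts$raw_count / ((len / 1000) * (counts$library_size / 1e6))
  counts
}

#' Catalogue fragment start positions on one transcript
#'
#' @param fragments fragment alignments for a single transcript and
#'   condition (any other columns are ignored).
#' @param transcript_length length of the transcript in nt.
#' @return Integer vector \code{v} of length \code{transcript_length} where
#'   \code{v[p + 1]} is the total read count whose 5' end lies at 0-based
#'   position \code{p}.
#' @export
index_starts <- function(fragments, transcript_length) {
  v <- integer(transcript_length)
  if (nrow(fragments)) {
    if (any(fragments$start < 0 | fragments$start >= transcript_length))
      stop("fragment start outside transcript")
    agg <- tapply(fragments$count, fragments$start, sum)
    v[as.integer(names(agg)) + 1L] <- as.integer(agg)
  }
  v
}

#' Call footprints on one start-count vector
#'
#' Greedy coalescing: repeatedly take the position with the maximal start
#' count (ties broken leftmost); stop when that count falls below
#' \code{min_reads}; assign to the footprint all starts within
#' \code{assign_window} nt of the anchor; zero out the consumed positions;
#' record the footprint interval as \code{[anchor, anchor + footprint_len)}
#' clipped to the transcript. Consumed windows are disjoint by construction.
#'
#' @param start_counts integer vector from \code{\link{index_starts}}.
#' @param min_reads minimum start count at the anchor (default 5).
#' @param assign_window half-width (nt) of the read-assignment window
#'   (default 10).
#' @param footprint_len footprint extent downstream of the anchor (default
#'   50 nt, which contains the whole 5-43 nt MRE confirmation window).
#' @return data.frame with columns \code{anchor}, \code{start}, \code{end},
#'   \code{read_count}, ordered by decreasing anchor count at emission.
#' @examples
#' v <- integer(400); v[101] <- 10; v[106] <- 3; v[301] <- 7
#' call_footprints(v)  # anchors 100 (13 reads) and 300 (7 reads)
#' @export
call_footprints <- function(start_counts, min_reads = 5L, assign_window = 10L,
                            footprint_len = 50L) {
  v <- as.numeric(start_counts)
  L <- length(v)
  anchors <- integer(0); reads <- integer(0)
  repeat {
    top <- which.max(v)           # leftmost maximum
    if (v[top] < min_reads) break
    lo <- max(1L, top - assign_window)
    hi <- min(L, top + assign_window)
    anchors <- c(anchors, top - 1L)
    reads <- c(reads, as.integer(sum(v[lo:hi])))
    v[lo:hi] <- 0
  }
  data.frame(anchor = anchors,
             start = anchors,
             end = pmin(anchors + footprint_len, L),
             read_count = reads)
}

#' Call footprints for every transcript, time point and replicate
#'
#' @param fragments validated fragment alignments (all conditions).
#' @param models \code{\link{transcript_models}} supplying lengths.
#' @inheritParams call_footprints
#' @return data.frame with \code{footprint_id}, \code{transcript_id},
#'   \code{anchor}, \code{start}, \code{end}, \code{read_count},
#'   \code{time_point}, \code{replicate}.
#' @export
call_footprints_all <- function(fragments, models, min_reads = 5L,
                                assign_window = 10L, footprint_len = 50L) {
  lens <- setNames(models$transcripts$length, models$transcripts$transcript_id)
  unknown <- setdiff(unique(fragments$transcript_id), names(lens))
  if (length(unknown))
    stop("fragments refer to unknown transcript(s): ",
         paste(unknown, collapse = ", "))
  groups <- split(fragments,
                  list(fragments$transcript_id, fragments$time_point,
                       fragments$replicate), drop = TRUE, sep = "\r")
  out <- lapply(names(groups), function(g) {
    info <- strsplit(g, "\r", fixed = TRUE)[[1]]
    fr <- groups[[g]]
    fp <- call_footprints(index_starts(fr, lens[[info[1]]]),
                          min_reads = min_reads,
                          assign_window = assign_window,
                          footprint_len = footprint_len)
    if (!nrow(fp)) return(NULL)
    data.frame(transcript_id = info[1], fp, time_point = info[2],
               replicate = info[3], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(transcript_id = character(), anchor = integer(),
                      start = integer(), end = integer(),
                      read_count = integer(), time_point = character(),
                      replicate = character(), stringsAsFactors = FALSE)
  out <- out[order(out$time_point, out$replicate, out$transcript_id, out$anchor), ]
  rownames(out) <- NULL
  cbind(footprint_id = sprintf("fp%06d", seq_len(nrow(out))), out,
        stringsAsFactors = FALSE)
}

#' Compute expression-weighted footprint strengths
#'
#' Footprint RPM is the footprint's read count per million CLIP mRNA
#' library reads; strength divides that RPM by the transcript's RPKM in the
#' matching (time point, replicate) RNA-seq library. Transcripts whose RPKM
#' falls below \code{rpkm_floor} get an undefined strength
#' (\code{strength_defined = FALSE}, strength NA) and are excluded by
#' downstream consumers.
#'
#' @param footprints output of \code{\link{call_footprints_all}}.
#' @param clip_library_sizes data.frame (\code{time_point},
#'   \code{replicate}, \code{library_size}) of CLIP mRNA library sizes.
#' @param expression output of \code{\link{compute_rpkm}}.
#' @param rpkm_floor minimum RPKM for a defined strength (default 0.1).
#' @return \code{footprints} with \code{rpm}, \code{rpkm}, \code{strength},
#'   \code{strength_defined} columns.
#' @export
compute_strengths <- function(footprints, clip_library_sizes, expression,
                              rpkm_floor = 0.1) {
  key <- paste(footprints$time_point, footprints$replicate)
  lk <- paste(clip_library_sizes$time_point, clip_library_sizes$replicate)
  lib <- clip_library_sizes$library_size[match(key, lk)]
  if (anyNA(lib))
    stop("missing CLIP library size for some condition(s)")
  ek <- paste(expression$transcript_id, expression$time_point,
              expression$replicate)
  fk <- paste(footprints$transcript_id, footprints$time_point,
              footprints$replicate)
  rpkm <- expression$rpkm[match(fk, ek)]
  if (anyNA(rpkm))
    stop("missing expression record for: ",
         paste(unique(fk[is.na(rpkm)])[1:min(5, sum(is.na(rpkm)))],
               collapse = "; "))
  footprints$rpm <- footprints$read_count / lib * 1e6
  footprints$rpkm <- rpkm
  footprints$strength_defined <- rpkm >= rpkm_floor
  footprints$strength <- ifelse(footprints$strength_defined,
                                footprints$rpm / rpkm, NA_real_)
  footprints
}

#' Merge nearby footprints
#'
#' Within each (transcript, time point, replicate) group, footprints whose
#' intervals are separated by at most \code{max_gap} nt are unioned
#' (transitively). Read counts, RPM and strengths of the constituents are
#' summed; the merged anchor is the anchor of the strongest constituent.
#'
#' @param footprints footprint data.frame (with or without strengths).
#' @param max_gap maximum separation in nt (default 20).
#' @return Merged footprint data.frame; a \code{merged_from} column lists
#'   constituent footprint ids.
#' @export
merge_footprints <- function(footprints, max_gap = 20L) {
  if (!nrow(footprints)) return(footprints)
  has_strength <- "strength" %in% names(footprints)
  groups <- split(footprints,
                  list(footprints$transcript_id, footprints$time_point,
                       footprints$replicate), drop = TRUE)
  out <- lapply(groups, function(fp) {
    fp <- fp[order(fp$start, fp$end), , drop = FALSE]
    gap_ok <- c(FALSE, fp$start[-1] - cummax_end(fp$end)[-nrow(fp)] <= max_gap)
    cluster <- cumsum(!gap_ok)
    do.call(rbind, lapply(split(fp, cluster), function(cl) {
      strongest <- if (has_strength && any(!is.na(cl$strength)))
        which.max(ifelse(is.na(cl$strength), -Inf, cl$strength))
      else which.max(cl$read_count)
      res <- cl[strongest, , drop = FALSE]
      res$start <- min(cl$start)
      res$end <- max(cl$end)
      res$read_count <- sum(cl$read_count)
      if ("rpm" %in% names(cl)) res$rpm <- sum(cl$rpm)
      if (has_strength) {
        res$strength <- if (any(cl$strength_defined))
          sum(cl$strength[cl$strength_defined]) else NA_real_
        res$strength_defined <- any(cl$strength_defined)
      }
      res$merged_from <- paste(cl$footprint_id, collapse = ",")
      res
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$time_point, out$replicate, out$transcript_id, out$start), ]
  rownames(out) <- NULL
  out
}

## running maximum of interval ends, so chained merging is transitive
cummax_end <- function(end) cummax(end)
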