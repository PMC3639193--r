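## Total regulatory load (TRL): the sum of footprint strengths over all
## footprints on a transcript, averaged over biological replicates. TRL and
## mRNA time-course matrices are log2-transformed, quantile-normalized and
## clustered by k-means to expose shared regulation profiles.

#' Compute total regulatory load profiles
#'
#' Per (transcript, time point, replicate), TRL is the sum of defined
#' footprint strengths; the per-replicate loads are then averaged across
#' the replicates of each time point (a replicate with no footprints on a
#' transcript contributes 0). Transcripts whose maximum TRL does not exceed
#' \code{trl_min} are flagged \code{retained = FALSE} (the matrix builder
#' keeps transcripts with a load strictly over 1 by default).
#'
#' @param footprints footprints with strengths
#'   (\code{\link{compute_strengths}}).
#' @param trl_min retention floor; strictly-greater comparison (default 1).
#' @param transcripts optional character vector of transcript ids to report
#'   even when they carry no footprints (their TRL is 0).
#' @return data.frame with \code{transcript_id}, one \code{trl_<tp>} column
#'   per time point, \code{min}, \code{max}, \code{fold_change}
#'   (max/min; NA when min is 0) and \code{retained}.
#' @export
compute_trl <- function(footprints, trl_min = 1, transcripts = NULL) {
  tps <- unique(footprints$time_point)
  reps <- unique(footprints$replicate)
  ids <- unique(c(footprints$transcript_id, transcripts))
  per_tp <- matrix(0, length(ids), length(tps), dimnames = list(ids, tps))
  ok <- footprints$strength_defined & !is.na(footprints$strength)
  fp <- footprints[ok, , drop = FALSE]
  if (nrow(fp)) {
    for (tp in tps) {
      sub <- fp[fp$time_point == tp, , drop = FALSE]
      ## sum strengths per replicate, then average over the replicate set
      rep_sums <- matrix(0, length(ids), length(reps),
                         dimnames = list(ids, reps))
      if (nrow(sub)) {
        agg <- aggregate(strength ~ transcript_id + replicate, data = sub,
                         FUN = sum)
        rep_sums[cbind(agg$transcript_id, agg$replicate)] <- agg$strength
      }
      per_tp[, tp] <- rowMeans(rep_sums)
    }
  }
  mn <- apply(per_tp, 1, min)
  mx <- apply(per_tp, 1, max)
  out <- data.frame(transcript_id = ids, per_tp,
                    min = mn, max = mx,
                    fold_change = ifelse(mn > 0, mx / mn, NA_real_),
                    retained = mx > trl_min,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[seq_along(tps) + 1L] <- paste0("trl_", tps)
  rownames(out) <- NULL
  out
}

#' Build a normalized log2 time-course profile matrix
#'
#' Rows are filtered on replicate-mean raw values (at least one time point
#' must pass the floor: \code{>= min_level}, or \code{> min_level} when
#' \code{strict}), then log2(value + pseudocount) is taken per replicate
#' library, libraries are quantile-normalized
#' (\code{limma::normalizeBetweenArrays}), and replicates are averaged
#' within each time point.
#'
#' @param values long data.frame with columns \code{id},
#'   \code{time_point}, \code{replicate}, \code{value}; missing
#'   combinations count as 0.
#' @param min_level row filter floor (e.g. 2 RPKM for expression, 1 for TRL).
#' @param strict use strictly-greater comparison for the floor.
#' @param log_pseudocount added before log2 (default 0.1).
#' @param time_points column order; defaults to order of appearance.
#' @return Numeric matrix, rows = retained ids, columns = time points.
#' @export
build_matrix <- function(values, min_level, strict = FALSE,
                         log_pseudocount = 0.1, time_points = NULL) {
  stopifnot(all(c("id", "time_point", "replicate", "value") %in% names(values)))
  if (is.null(time_points)) time_points <- unique(values$time_point)
  reps_by_tp <- tapply(values$replicate, values$time_point,
                       function(r) length(unique(r)))
  if (any(reps_by_tp == 0) || !all(time_points %in% values$time_point))
    stop("every time point needs at least one replicate library")
  ids <- sort(unique(values$id))
  libs <- unique(values[c("time_point", "replicate")])
  libs <- libs[order(match(libs$time_point, time_points), libs$replicate), ]
  lib_key <- paste(libs$time_point, libs$replicate)
  mat <- matrix(0, length(ids), nrow(libs),
                dimnames = list(ids, lib_key))
  mat[cbind(match(values$id, ids),
            match(paste(values$time_point, values$replicate), lib_key))] <-
    values$value
  ## row filter on pre-normalization replicate means per time point
  tp_mean <- sapply(time_points, function(tp)
    rowMeans(mat[, libs$time_point == tp, drop = FALSE]))
  if (is.null(dim(tp_mean))) tp_mean <- matrix(tp_mean, nrow = length(ids))
  keep <- if (strict) apply(tp_mean > min_level, 1, any)
          else apply(tp_mean >= min_level, 1, any)
  mat <- mat[keep, , drop = FALSE]
  if (!nrow(mat)) return(matrix(numeric(0), 0, length(time_points),
                                dimnames = list(NULL, time_points)))
  lmat <- log2(mat + log_pseudocount)
  qn <- limma::normalizeBetweenArrays(lmat, method = "quantile")
  out <- sapply(time_points, function(tp)
    rowMeans(qn[, libs$time_point == tp, drop = FALSE]))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = nrow(qn), dimnames = list(rownames(qn), time_points))
  out
}

#' Cluster time-course profiles by k-means
#'
#' Profiles are row-mean-centered (shape, not level), then clustered with
#' \code{stats::kmeans} (Euclidean) over a range of K with multiple random
#' restarts, keeping the solution with the lowest within-cluster sum of
#' squares at each K. The seed schedule is fixed, so repeated runs are
#' bit-identical.
#'
#' @param mat profile matrix (rows = entities, columns = time points).
#' @param k_range inclusive range of K to scan (default 4..30).
#' @param k_final K of the returned assignment (default 12).
#' @param seed integer seed.
#' @param n_restarts random restarts per K (default 25).
#' @param center row-mean-center profiles first (default TRUE).
#' @return list with \code{assignments} (named integer vector at
#'   \code{k_final}), \code{centers}, \code{inertia} (data.frame of K and
#'   total within-cluster sum of squares), \code{k_final}.
#' @export
kmeans_profiles <- function(mat, k_range = c(4L, 30L), k_final = 12L,
                            seed = 1L, n_restarts = 25L, center = TRUE) {
  if (k_final > nrow(mat))
    stop("k_final (", k_final, ") exceeds number of rows (", nrow(mat), ")")
  m <- if (center) mat - rowMeans(mat) else mat
  ks <- k_range[1]:k_range[2]
  ks <- unique(c(ks[ks <= nrow(m)], k_final))
  inertia <- numeric(length(ks))
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    set.seed(seed + ks[i])
    if (ks[i] == nrow(m)) {
      ## every row its own cluster: the exact k = n solution
      fits[[i]] <- list(cluster = seq_len(nrow(m)), centers = m,
                        tot.withinss = 0)
    } else {
      fits[[i]] <- suppressWarnings(
        kmeans(m, centers = ks[i], nstart = n_restarts, iter.max = 50L))
    }
    inertia[i] <- fits[[i]]$tot.withinss
  }
  final <- fits[[match(k_final, ks)]]
  list(assignments = setNames(final$cluster, rownames(m)),
       centers = final$centers,
       inertia = data.frame(k = ks, tot_withinss = inertia),
       k_final = k_final)
}

#' Contrast mRNA and TRL time profiles for a gene set
#'
#' For each requested id present in both matrices, returns the paired
#' profiles and a lead/lag summary: the time (hours) of the TRL peak minus
#' the time of the mRNA peak. Negative lags mean regulatory load peaks
#' before the mRNA does.
#'
#' @param ids character vector of row ids.
#' @param mrna_matrix,trl_matrix matrices from \code{\link{build_matrix}}
#'   with identical column order.
#' @param time_hours numeric hours matching the columns (default
#'   c(0, 1, 36, 48)).
#' @return list with \code{profiles} (long data.frame), \code{lags}
#'   (data.frame of id and \code{lag_hours}), \code{skipped} (ids absent
#'   from either matrix).
#' @export
contrast_profiles <- function(ids, mrna_matrix, trl_matrix,
                              time_hours = c(0, 1, 36, 48)) {
  stopifnot(ncol(mrna_matrix) == ncol(trl_matrix),
            length(time_hours) == ncol(mrna_matrix))
  present <- ids[ids %in% rownames(mrna_matrix) & ids %in% rownames(trl_matrix)]
  skipped <- setdiff(ids, present)
  profiles <- do.call(rbind, lapply(present, function(id) {
    data.frame(id = id, time_hours = rep(time_hours, 2L),
               kind = rep(c("mrna", "trl"), each = length(time_hours)),
               level = c(mrna_matrix[id, ], trl_matrix[id, ]),
               stringsAsFactors = FALSE)
  }))
  lags <- data.frame(
    id = present,
    lag_hours = vapply(present, function(id)
      time_hours[which.max(trl_matrix[id, ])] -
        time_hours[which.max(mrna_matrix[id, ])], numeric(1)),
    stringsAsFactors = FALSE)
  rownames(lags) <- NULL
  list(profiles = profiles, lags = lags, skipped = skipped)
}

#' Hypergeometric gene-set enrichment of profile clusters
#'
#' For every (cluster, gene set) pair, tests over-representation of the set
#' within the cluster against the supplied universe with the one-sided
#' hypergeometric tail (\code{\link{fisher_one_sided}}) and adjusts across
#' all pairs with Benjamini-Hochberg.
#'
#' @param clusters named list of character vectors (cluster members) or a
#'   named assignment vector as returned by \code{\link{kmeans_profiles}}.
#' @param gene_sets named list of character vectors (e.g.
#'   \code{\link{read_gmt}}).
#' @param universe character vector of all eligible genes.
#' @return data.frame with \code{cluster}, \code{gene_set}, \code{k},
#'   \code{m}, \code{n}, \code{N}, \code{p}, \code{fdr}.
#' @export
gene_set_enrichment <- function(clusters, gene_sets, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  if (!is.list(clusters))
    clusters <- split(names(clusters), clusters)
  rows <- list()
  for (cl in names(clusters)) {
    members <- intersect(clusters[[cl]], universe)
    if (!length(members)) next
    for (gs in names(gene_sets)) {
      set <- intersect(gene_sets[[gs]], universe)
      k <- length(intersect(members, set))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, gene_set = gs, k = k, m = length(members),
        n = length(set), N = length(universe),
        p = fisher_one_sided(k, length(members), length(set),
                             length(universe)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cluster = character(), gene_set = character(),
                      k = integer(), m = integer(), n = integer(),
                      N = integer(), p = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out[order(out$p), ]
}
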