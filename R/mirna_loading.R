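## RISC-loading quantification of miRNAs from the Ago-short HITS-CLIP
## library: RPM computation, detection and differential cutoffs, global
## normalization, and differential-loading calls versus the quiescent liver.

#' Compute reads-per-million loading from an Ago-short counts table
#'
#' RPM expresses each miRNA's read count relative to all aligned miRNA reads
#' in the same replicate library, so RPM sums to 1e6 within every
#' (time point, replicate) library when the library size is the column sum.
#'
#' @param counts data.frame with columns \code{mirna_id}, \code{time_point},
#'   \code{replicate}, \code{raw_count}, and optionally \code{library_size}.
#' @param library_sizes optional data.frame (\code{time_point},
#'   \code{replicate}, \code{library_size}) overriding any column; when
#'   neither is supplied, per-library sums of \code{raw_count} are used.
#' @return The input with \code{library_size} and \code{rpm} columns.
#' @examples
#' counts <- data.frame(mirna_id = c("a", "b"), time_point = "0h",
#'                      replicate = "r1", raw_count = c(100L, 999900L))
#' compute_rpm(counts)$rpm
#' @export
compute_rpm <- function(counts, library_sizes = NULL) {
  need <- c("mirna_id", "time_point", "replicate", "raw_count")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("counts table missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(counts$time_point, counts$replicate)
  if (!is.null(library_sizes)) {
    lk <- paste(library_sizes$time_point, library_sizes$replicate)
    counts$library_size <- library_sizes$library_size[match(key, lk)]
  } else if (!"library_size" %in% names(counts)) {
    sums <- tapply(counts$raw_count, key, sum)
    counts$library_size <- as.numeric(sums[key])
  }
  if (anyNA(counts$library_size) || any(counts$library_size <= 0))
    stop("zero or missing library size for at least one library")
  counts$rpm <- counts$raw_count / counts$library_size * 1e6
  counts
}

#' Detect RISC-loaded miRNAs
#'
#' A miRNA counts as loaded when its replicate-mean RPM reaches
#' \code{rpm_detect} (inclusive) at one or more time points.
#'
#' @param loading output of \code{\link{compute_rpm}}.
#' @param rpm_detect detection cutoff in RPM (default 100).
#' @return Character vector of detected \code{mirna_id}s.
#' @export
detect_loaded <- function(loading, rpm_detect = 100) {
  mean_rpm <- aggregate(rpm ~ mirna_id + time_point, data = loading, FUN = mean)
  sort(unique(mean_rpm$mirna_id[mean_rpm$rpm >= rpm_detect]))
}

#' Globally normalize loading libraries to the quiescent reference
#'
#' Each library is rescaled so that, over the high-abundance miRNAs
#' (reference-mean RPM at or above \code{rpm_min}), the median log-ratio of
#' its RPM to the reference mean is zero; the reference libraries' scale
#' factors are then geometric-mean-centered to 1 and applied to all
#' libraries. A pseudocount (in RPM) guards the log-ratios only; reported
#' RPM values are untouched.
#'
#' @param loading output of \code{\link{compute_rpm}}.
#' @param reference_time label of the quiescent time point (default "0h").
#' @param rpm_min abundance floor for the miRNAs used to estimate scale
#'   factors (default 1000).
#' @param pseudocount RPM pseudocount used inside log-ratios (default 0.5).
#' @param min_mirnas minimum number of miRNAs above the floor; below it the
#'   function warns and returns the input with \code{normalized_rpm = rpm}.
#' @return The input with a \code{normalized_rpm} column; scale factors are
#'   attached as attribute \code{"scale_factors"}.
#' @export
global_normalize <- function(loading, reference_time = "0h", rpm_min = 1000,
                             pseudocount = 0.5, min_mirnas = 5L) {
  if (!reference_time %in% loading$time_point)
    stop("reference time point '", reference_time, "' absent from loading table")
  ref <- loading[loading$time_point == reference_time, ]
  ref_mean <- tapply(ref$rpm, ref$mirna_id, mean)
  high <- names(ref_mean)[ref_mean >= rpm_min]
  if (length(high) < min_mirnas) {
    warning("fewer than ", min_mirnas, " miRNAs above ", rpm_min,
            " RPM in the reference; normalization skipped")
    loading$normalized_rpm <- loading$rpm
    return(loading)
  }
  key <- paste(loading$time_point, loading$replicate)
  libs <- unique(data.frame(key = key, time_point = loading$time_point,
                            replicate = loading$replicate,
                            stringsAsFactors = FALSE))
  scale <- vapply(libs$key, function(k) {
    sub <- loading[key == k & loading$mirna_id %in% high, ]
    ratios <- log((sub$rpm + pseudocount) /
                    (ref_mean[sub$mirna_id] + pseudocount))
    exp(-median(ratios))
  }, numeric(1))
  ## center the reference libraries' factors at geometric mean 1
  ref_keys <- libs$key[libs$time_point == reference_time]
  scale <- scale / exp(mean(log(scale[ref_keys])))
  loading$normalized_rpm <- loading$rpm * scale[key]
  attr(loading, "scale_factors") <- data.frame(
    libs[c("time_point", "replicate")], scale = unname(scale),
    stringsAsFactors = FALSE)
  loading
}

#' Call differentially loaded miRNAs versus the quiescent time point
#'
#' Fold changes are ratios of replicate-mean normalized RPM at each
#' post-quiescent time point over the quiescent mean. With only two
#' replicates per condition the default significance test is a moderated t
#' on log2 normalized RPM (\code{limma::eBayes}; empirical-Bayes variance
#' shrinkage across miRNAs gives honest tail behaviour at this replicate
#' number); a plain z-test with a variance pooled across high-abundance
#' miRNAs is available as an alternative. P-values are Benjamini-Hochberg
#' adjusted within each time point. A miRNA is testable at a time point
#' only if its mean normalized RPM reaches \code{rpm_differential} there or
#' at the reference.
#'
#' @param loading output of \code{\link{global_normalize}} (must carry
#'   \code{normalized_rpm}).
#' @param reference_time quiescent label (default "0h").
#' @param fdr_max FDR ceiling for a call (default 0.20).
#' @param rpm_differential abundance floor in RPM (default 1000).
#' @param pseudocount RPM pseudocount inside log2 (default 0.5).
#' @param method "moderated_t" (default) or "pooled_z".
#' @return data.frame with one row per tested (miRNA, time point):
#'   \code{mirna_id}, \code{time_point}, \code{fold_change}, \code{log2fc},
#'   \code{p}, \code{fdr}, \code{direction} ("up"/"down"), \code{called}.
#' @export
call_differential_loading <- function(loading, reference_time = "0h",
                                      fdr_max = 0.20, rpm_differential = 1000,
                                      pseudocount = 0.5,
                                      method = c("moderated_t", "pooled_z")) {
  method <- match.arg(method)
  if (!"normalized_rpm" %in% names(loading))
    stop("loading table lacks normalized_rpm; run global_normalize() first")
  if (!reference_time %in% loading$time_point)
    stop("reference time point '", reference_time, "' absent from loading table")
  ids <- sort(unique(loading$mirna_id))
  tps <- unique(loading$time_point)
  other_tps <- setdiff(tps, reference_time)
  key <- paste(loading$time_point, loading$replicate)
  libk <- unique(key)
  lmat <- matrix(NA_real_, length(ids), length(libk),
                 dimnames = list(ids, libk))
  lmat[cbind(match(loading$mirna_id, ids), match(key, libk))] <-
    log2(loading$normalized_rpm + pseudocount)
  if (anyNA(lmat[, grepl(paste0("^", reference_time, " "), libk)]))
    stop("missing quiescent data for some miRNAs")
  mean_rpm <- tapply(loading$normalized_rpm,
                     list(loading$mirna_id, loading$time_point), mean)
  lib_tp <- sub(" .*$", "", libk)

  p_mat <- fc_mat <- matrix(NA_real_, length(ids), length(other_tps),
                            dimnames = list(ids, other_tps))
  if (method == "moderated_t") {
    design <- stats::model.matrix(~ 0 + factor(lib_tp, levels = tps))
    colnames(design) <- paste0("tp_", tps)
    fit <- limma::lmFit(lmat, design)
    contr <- vapply(other_tps, function(tp) {
      v <- numeric(length(tps))
      v[match(tp, tps)] <- 1
      v[match(reference_time, tps)] <- -1
      v
    }, numeric(length(tps)))
    rownames(contr) <- paste0("tp_", tps)
    fit2 <- limma::eBayes(limma::contrasts.fit(fit, contr))
    p_mat[] <- fit2$p.value
    fc_mat[] <- fit2$coefficients
  } else {
    ## pooled-variance z-test: one replicate variance shared by the
    ## high-abundance miRNAs
    grp_var <- grp_n <- matrix(NA_real_, length(ids), length(tps),
                               dimnames = list(ids, tps))
    for (tp in tps) {
      cols <- lib_tp == tp
      grp_var[, tp] <- apply(lmat[, cols, drop = FALSE], 1, var)
      grp_n[, tp] <- rowSums(!is.na(lmat[, cols, drop = FALSE]))
    }
    pool <- mean_rpm >= rpm_differential & grp_n[, colnames(mean_rpm)] >= 2
    s2 <- mean(grp_var[, colnames(mean_rpm)][pool], na.rm = TRUE)
    if (!is.finite(s2) || s2 <= 0) s2 <- 1e-8
    for (tp in other_tps) {
      d <- rowMeans(lmat[, lib_tp == tp, drop = FALSE]) -
        rowMeans(lmat[, lib_tp == reference_time, drop = FALSE])
      se <- sqrt(s2 / grp_n[, tp] + s2 / grp_n[, reference_time])
      p_mat[, tp] <- 2 * pnorm(-abs(d / se))
      fc_mat[, tp] <- d
    }
  }

  out <- list()
  for (tp in other_tps) {
    eligible <- mean_rpm[ids, tp] >= rpm_differential |
      mean_rpm[ids, reference_time] >= rpm_differential
    sel <- ids[eligible]
    if (!length(sel)) next
    p <- p_mat[sel, tp]
    fdr <- p.adjust(p, method = "BH")
    log2fc <- fc_mat[sel, tp]
    out[[tp]] <- data.frame(
      mirna_id = sel, time_point = tp,
      fold_change = (mean_rpm[sel, tp] + pseudocount) /
        (mean_rpm[sel, reference_time] + pseudocount),
      log2fc = unname(log2fc), p = unname(p), fdr = unname(fdr),
      direction = ifelse(log2fc >= 0, "up", "down"),
      called = unname(fdr <= fdr_max),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(mirna_id = character(), time_point = character(),
                      fold_change = numeric(), log2fc = numeric(),
                      p = numeric(), fdr = numeric(), direction = character(),
                      called = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$time_point, res$fdr, res$mirna_id), ]
}
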