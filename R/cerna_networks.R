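## Candidate ceRNA networks: mRNAs dominated by a single strong footprint
## that is in turn dominated by a single highly loaded miRNA. Footprints
## within 20 bp are merged first; rule 1 requires the second strongest
## distinct footprint to be less than 25% of the strongest (strict), rule 2
## requires the most loaded confirmed miRNA in that footprint to be at
## least 10x the second most loaded. Networks are built per time point and
## merged across time points into summary networks.

#' Select the dominant footprint of one mRNA
#'
#' @param footprints merged footprints of a single transcript at one time
#'   point (strengths present and replicate-reduced by the caller).
#' @param frac strict dominance fraction: dominant iff second strongest
#'   strength < \code{frac} x strongest (default 0.25). A single footprint
#'   passes vacuously.
#' @return The dominant footprint row, or \code{NULL}.
#' @export
select_dominant_footprint <- function(footprints, frac = 0.25) {
  fp <- footprints[footprints$strength_defined & !is.na(footprints$strength), ,
                   drop = FALSE]
  if (!nrow(fp)) return(NULL)
  ord <- order(-fp$strength)
  if (nrow(fp) == 1L) return(fp[1L, , drop = FALSE])
  if (fp$strength[ord[2]] < frac * fp$strength[ord[1]])
    fp[ord[1], , drop = FALSE]
  else NULL
}

#' Select the dominant miRNA of one footprint
#'
#' @param mirna_ids miRNAs with a confirmed MRE in the footprint.
#' @param loading_rpm named vector of loading (replicate-mean normalized
#'   RPM at the time point) covering \code{mirna_ids}.
#' @param ratio dominance ratio: dominant iff top loading >= \code{ratio} x
#'   second loading (default 10, inclusive). A single confirmed miRNA
#'   passes vacuously.
#' @return The dominant miRNA id, or \code{NULL}.
#' @export
select_dominant_mirna <- function(mirna_ids, loading_rpm, ratio = 10) {
  mirna_ids <- unique(mirna_ids)
  if (!length(mirna_ids)) return(NULL)
  rpm <- loading_rpm[mirna_ids]
  if (anyNA(rpm))
    stop("loading missing for miRNA(s): ",
         paste(mirna_ids[is.na(rpm)], collapse = ", "))
  if (length(rpm) == 1L) return(mirna_ids[1L])
  ord <- order(-rpm)
  if (rpm[ord[1]] >= ratio * rpm[ord[2]]) mirna_ids[ord[1]] else NULL
}

## Pool per-replicate footprints of one time point into replicate-mean
## merged footprints: constituents within max_gap are unioned and their
## strengths summed, then divided by the number of replicate libraries, so
## the merged strength is the replicate-mean footprint strength.
pool_replicate_footprints <- function(footprints, time_point, max_gap = 20L) {
  fp <- footprints[footprints$time_point == time_point, , drop = FALSE]
  if (!nrow(fp)) return(fp)
  n_reps <- length(unique(fp$replicate))
  fp$replicate <- "pooled"
  merged <- merge_footprints(fp, max_gap = max_gap)
  merged$strength <- merged$strength / n_reps
  merged$rpm <- merged$rpm / n_reps
  merged
}

#' Build per-time-point ceRNA networks
#'
#' Applies both dominance rules to every transcript: the transcript joins a
#' network when its merged footprints contain a strictly dominant one
#' (\code{\link{select_dominant_footprint}}) and the confirmed miRNAs in
#' that footprint contain a dominant one
#' (\code{\link{select_dominant_mirna}}). Edges are grouped by hub miRNA.
#'
#' @param footprints footprints with strengths, all replicates (merging and
#'   replicate pooling happen internally per time point).
#' @param confirmation result of \code{\link{confirm_mres}} (its
#'   \code{support} table links pairs to footprints and conditions).
#' @param loading loading table with \code{normalized_rpm} (or \code{rpm}).
#' @param models optional \code{\link{transcript_models}} for gene symbols.
#' @param frac rule-1 fraction (default 0.25, strict).
#' @param ratio rule-2 ratio (default 10, inclusive).
#' @param max_gap merge distance in nt (default 20).
#' @return data.frame of network edges: \code{time_point},
#'   \code{hub_mirna}, \code{transcript_id}, \code{gene_id},
#'   \code{footprint_id}, \code{strength}.
#' @export
build_networks <- function(footprints, confirmation, loading, models = NULL,
                           frac = 0.25, ratio = 10, max_gap = 20L) {
  rpm_col <- if ("normalized_rpm" %in% names(loading)) "normalized_rpm" else "rpm"
  support <- confirmation$support
  edges <- list()
  for (tp in unique(footprints$time_point)) {
    pooled <- pool_replicate_footprints(footprints, tp, max_gap = max_gap)
    ld <- loading[loading$time_point == tp, , drop = FALSE]
    loading_rpm <- tapply(ld[[rpm_col]], ld$mirna_id, mean)
    sup_tp <- support[support$time_point == tp, , drop = FALSE]
    for (tx in unique(pooled$transcript_id)) {
      dom_fp <- select_dominant_footprint(
        pooled[pooled$transcript_id == tx, , drop = FALSE], frac = frac)
      if (is.null(dom_fp)) next
      ## confirmed miRNAs whose supporting footprint (any replicate) was
      ## absorbed into the dominant merged footprint
      constituents <- strsplit(dom_fp$merged_from, ",", fixed = TRUE)[[1]]
      mi <- unique(sup_tp$mirna_id[sup_tp$transcript_id == tx &
                                     sup_tp$footprint_id %in% constituents])
      dom_mi <- select_dominant_mirna(mi, loading_rpm, ratio = ratio)
      if (is.null(dom_mi)) next
      edges[[length(edges) + 1L]] <- data.frame(
        time_point = tp, hub_mirna = dom_mi, transcript_id = tx,
        gene_id = if (!is.null(models))
          models$transcripts$gene_id[match(tx, models$transcripts$transcript_id)]
        else tx,
        footprint_id = dom_fp$footprint_id, strength = dom_fp$strength,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(edges))
    return(data.frame(time_point = character(), hub_mirna = character(),
                      transcript_id = character(), gene_id = character(),
                      footprint_id = character(), strength = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, edges)
  out[order(out$time_point, out$hub_mirna, out$transcript_id), ]
}

#' Merge per-time-point ceRNA networks into summary networks
#'
#' Per hub miRNA, the member set is the union across time points; each
#' edge records its supporting time points. Idempotent and independent of
#' time-point order.
#'
#' @param edges edge table from \code{\link{build_networks}} (or a
#'   previously merged table with a \code{time_points} column).
#' @return data.frame with \code{hub_mirna}, \code{transcript_id},
#'   \code{gene_id}, \code{time_points} (comma-joined, sorted),
#'   \code{n_time_points}, \code{max_strength}.
#' @export
merge_networks <- function(edges) {
  if (!nrow(edges))
    return(data.frame(hub_mirna = character(), transcript_id = character(),
                      gene_id = character(), time_points = character(),
                      n_time_points = integer(), max_strength = numeric(),
                      stringsAsFactors = FALSE))
  tp_col <- if ("time_points" %in% names(edges)) "time_points" else "time_point"
  str_col <- if ("strength" %in% names(edges)) "strength" else "max_strength"
  key <- paste(edges$hub_mirna, edges$transcript_id, sep = "\r")
  out <- do.call(rbind, lapply(split(edges, key), function(e) {
    tps <- sort(unique(unlist(strsplit(e[[tp_col]], ",", fixed = TRUE))))
    data.frame(hub_mirna = e$hub_mirna[1], transcript_id = e$transcript_id[1],
               gene_id = e$gene_id[1],
               time_points = paste(tps, collapse = ","),
               n_time_points = length(tps),
               max_strength = max(e[[str_col]]), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$hub_mirna, out$transcript_id), ]
  rownames(out) <- NULL
  out
}

#' Export a merged ceRNA network as igraph / GraphML / edge-list TSV
#'
#' @param merged output of \code{\link{merge_networks}}.
#' @return \code{cerna_igraph} returns a bipartite \code{igraph} object
#'   (vertex attribute \code{type}: "mirna" or "mrna").
#' @export
cerna_igraph <- function(merged) {
  g <- igraph::graph_from_data_frame(
    merged[c("hub_mirna", "gene_id", "time_points", "n_time_points",
             "max_strength")],
    directed = FALSE)
  igraph::V(g)$type <- ifelse(igraph::V(g)$name %in% merged$hub_mirna,
                              "mirna", "mrna")
  g
}

#' @rdname cerna_igraph
#' @param path output file.
#' @export
write_cerna_graphml <- function(merged, path) {
  igraph::write_graph(cerna_igraph(merged), path, format = "graphml")
  invisible(path)
}

#' @rdname cerna_igraph
#' @export
write_cerna_edges <- function(merged, path) {
  write_tsv_table(merged, path)
}
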