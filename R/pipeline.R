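#' Run the full HITS-CLIP analysis pipeline
#'
#' Convenience wrapper chaining the pipeline stages in their canonical
#' order: RPM loading + global normalization + differential-loading calls;
#' RPKM expression; footprint calling and expression-weighted strengths;
#' seed-match MRE prediction (or imported predictions) with footprint
#' confirmation; total regulatory load; and ceRNA network construction.
#'
#' @param models \code{\link{transcript_models}} (with sequences if
#'   \code{pairs} is not supplied).
#' @param fragments CLIP fragment alignments
#'   (\code{\link{read_fragment_table}} or a \code{synthetic_study}).
#' @param mirna_counts Ago-short miRNA counts table.
#' @param rnaseq_counts RNA-seq counts table (with \code{library_size}).
#' @param clip_library_sizes per-condition CLIP mRNA library sizes.
#' @param mirnas named miRNA sequences for the internal seed scanner;
#'   ignored when \code{pairs} is given.
#' @param pairs optional precomputed candidate pairs
#'   (\code{\link{read_miranda_hits}}).
#' @param config a \code{\link{riscprof_config}}.
#' @return list with elements \code{loading}, \code{detected},
#'   \code{differential}, \code{expression}, \code{footprints},
#'   \code{pairs}, \code{confirmation}, \code{refinement}, \code{trl},
#'   \code{network_edges}, \code{networks}.
#' @examples
#' study <- generate_study(synthetic_config(n_transcripts = 20,
#'                                          n_planted_footprints = 8,
#'                                          n_mirnas = 10, seed = 3))
#' res <- run_clip_pipeline(study$models, study$fragments,
#'                          study$mirna_counts, study$rnaseq_counts,
#'                          study$clip_library_sizes, study$mirnas)
#' res$refinement$n_confirmed
#' @export
run_clip_pipeline <- function(models, fragments, mirna_counts, rnaseq_counts,
                              clip_library_sizes, mirnas = NULL, pairs = NULL,
                              config = riscprof_config()) {
  loading <- global_normalize(compute_rpm(mirna_counts),
                              rpm_min = config$rpm_differential,
                              pseudocount = config$rpm_pseudocount)
  detected <- detect_loaded(loading, rpm_detect = config$rpm_detect)
  differential <- call_differential_loading(
    loading, fdr_max = config$fdr_loading,
    rpm_differential = config$rpm_differential,
    pseudocount = config$rpm_pseudocount)
  expression <- compute_rpkm(rnaseq_counts, models)
  footprints <- call_footprints_all(fragments, models,
                                    min_reads = config$min_reads,
                                    assign_window = config$assign_window,
                                    footprint_len = config$footprint_len)
  footprints <- compute_strengths(footprints, clip_library_sizes, expression,
                                  rpkm_floor = config$rpkm_floor)
  if (is.null(pairs)) {
    if (is.null(mirnas))
      stop("supply either miRNA sequences or a precomputed pair table")
    pairs <- seed_scan(mirnas, models)
  }
  criteria <- confirmation_criteria(min_mirna_rpm = config$rpm_detect,
                                    window = config$mre_window,
                                    min_strength = config$strength_min)
  confirmation <- confirm_mres(pairs, footprints, loading, criteria)
  refinement <- summarize_refinement(pairs, confirmation$pairs)
  trl <- compute_trl(footprints, trl_min = config$trl_min)
  network_edges <- build_networks(footprints, confirmation, loading, models,
                                  frac = config$cerna_second_fp_frac,
                                  ratio = config$cerna_mirna_ratio,
                                  max_gap = config$cerna_merge_bp)
  list(loading = loading, detected = detected, differential = differential,
       expression = expression, footprints = footprints, pairs = pairs,
       confirmation = confirmation, refinement = refinement, trl = trl,
       network_edges = network_edges, networks = merge_networks(network_edges))
}
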