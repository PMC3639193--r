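## Gene-set overlap statistics: one-sided Fisher exact (hypergeometric
## upper tail) significance of the overlap between predicted target sets
## and externally defined regulated-gene sets, with Benjamini-Hochberg
## correction across miRNAs.

#' One-sided Fisher exact p-value for a set overlap
#'
#' P(X >= k) where X ~ Hypergeometric(N, m, n): the chance of drawing at
#' least \code{k} members of an \code{n}-gene set when sampling \code{m}
#' genes from a universe of \code{N}. Computed via \code{stats::phyper} on
#' the log scale internally, which matches \code{fisher.test(...,
#' alternative = "greater")} exactly.
#'
#' @param k overlap count.
#' @param m size of the first set (e.g. predicted targets in the universe).
#' @param n size of the second set (e.g. regulated genes in the universe).
#' @param N universe size.
#' @return p-value in [0, 1].
#' @examples
#' fisher_one_sided(5, 10, 10, 100)
#' @export
fisher_one_sided <- function(k, m, n, N) {
  if (any(c(k, m, n, N) < 0) || m > N || n > N)
    stop("require 0 <= m, n <= N and k >= 0")
  if (k > min(m, n))
    stop("overlap k exceeds min(m, n)")
  if (k == 0) return(1)
  exp(phyper(k - 1, n, N - n, m, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment preserving input order (delegates to
#' \code{stats::p.adjust}).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Vector of adjusted values (same order).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Rank miRNAs by overlap of their confirmed targets with a gene set
#'
#' Pairs are collapsed to gene level (a gene is a target when any of its
#' transcripts carries a confirmed pair), intersected with the universe,
#' and each miRNA with at least one target in the universe is tested for
#' over-enrichment against the gene set with
#' \code{\link{fisher_one_sided}}; BH adjustment runs across miRNAs.
#'
#' @param pairs confirmed pair table carrying \code{mirna_id} and a gene
#'   column (\code{gene_id}; supply \code{models} to map transcript ids).
#' @param gene_set character vector of regulated genes; must be a subset of
#'   the universe.
#' @param universe character vector of eligible genes (e.g. all genes
#'   expressed at the time point).
#' @param models optional \code{\link{transcript_models}} used to map
#'   \code{transcript_id} to \code{gene_id} when the pair table lacks one.
#' @return data.frame sorted by p: \code{mirna_id}, \code{k}, \code{m},
#'   \code{n}, \code{N}, \code{p}, \code{fdr}.
#' @export
rank_mirnas_by_overlap <- function(pairs, gene_set, universe, models = NULL) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  missing_set <- setdiff(gene_set, universe)
  if (length(missing_set))
    stop("gene set members outside the universe: ",
         paste(missing_set[seq_len(min(5, length(missing_set)))],
               collapse = ", "))
  if (!"gene_id" %in% names(pairs)) {
    if (is.null(models))
      stop("pairs lack gene_id; supply transcript models for the mapping")
    pairs$gene_id <- models$transcripts$gene_id[
      match(pairs$transcript_id, models$transcripts$transcript_id)]
  }
  if ("confirmed" %in% names(pairs))
    pairs <- pairs[pairs$confirmed, , drop = FALSE]
  targets <- lapply(split(pairs$gene_id, pairs$mirna_id),
                    function(g) intersect(unique(g), universe))
  targets <- targets[lengths(targets) > 0]
  n <- length(intersect(gene_set, universe))
  N <- length(universe)
  out <- do.call(rbind, lapply(names(targets), function(mi) {
    m <- length(targets[[mi]])
    k <- length(intersect(targets[[mi]], gene_set))
    data.frame(mirna_id = mi, k = k, m = m, n = n, N = N,
               p = fisher_one_sided(k, m, n, N), stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(mirna_id = character(), k = integer(), m = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE))
  out$fdr <- bh_adjust(out$p)
  out <- out[order(out$p, out$mirna_id), ]
  rownames(out) <- NULL
  out
}
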