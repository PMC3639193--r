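## Synthetic HITS-CLIP study generator.
##
## Emulates the study design: 2 biological replicates at 4 time points
## (0h quiescent, 1h, 36h, 48h), Ago-short miRNA loading spanning roughly
## 10-1e5 RPM with a dynamically recruited subset (~5-fold changes), RNA-seq
## abundances spanning 0.1-1e3 RPKM, CLIP fragment starts concentrated at
## planted footprints over a uniform background, and planted seed-match MREs
## 5-43 nt downstream of footprint anchors. Every planted feature is
## recorded in a ground-truth object.

#' Configuration for the synthetic study generator
#'
#' @param n_transcripts number of transcripts.
#' @param n_mirnas number of miRNAs.
#' @param n_planted_footprints number of planted Ago footprints (at most one
#'   per transcript).
#' @param n_decoy_mres number of decoy seed-match sites planted far from any
#'   footprint (never inside the 5-43 nt confirmation window).
#' @param background_rate expected background CLIP fragment starts per nt
#'   per library.
#' @param footprint_depth expected CLIP fragment starts per planted
#'   footprint per library.
#' @param start_jitter_sd SD (nt) of the normal jitter of fragment starts
#'   around a planted anchor (rounded to integers).
#' @param fragment_len_range fragment lengths are uniform integers in this
#'   range (nt).
#' @param tx_len_range transcript lengths, uniform integers (nt).
#' @param rpm_range true baseline miRNA loading drawn log-uniform in this
#'   RPM range.
#' @param rpkm_range true baseline transcript abundance drawn log-uniform in
#'   this RPKM range.
#' @param frac_dynamic fraction of miRNAs whose RISC loading changes over
#'   the time course.
#' @param effect_fold fold change applied to dynamic miRNAs at one
#'   post-quiescent time point (up for half of them, down for the rest).
#' @param frac_dynamic_tx fraction of transcripts with a changing abundance.
#' @param tx_effect_fold_range fold-change range for dynamic transcripts.
#' @param dispersion negative-binomial dispersion of replicate counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson noise.
#' @param mirna_library_size nominal Ago-short library size (reads).
#' @param rnaseq_library_size nominal RNA-seq library size (reads).
#' @param mre_offset_range planted MRE offsets downstream of the anchor, nt.
#' @param mre_mirna_min_rpm planted MREs are assigned only to miRNAs whose
#'   baseline loading reaches this RPM (targeting statements in the pipeline
#'   concern RISC-loaded miRNAs).
#' @param time_points,replicates labels of the study design.
#' @param seed integer seed; the whole study is a deterministic function of
#'   the configuration.
#'
#' @return A named list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_transcripts = 100L,
                             n_mirnas = 50L,
                             n_planted_footprints = 50L,
                             n_decoy_mres = 25L,
                             background_rate = 0.005,
                             footprint_depth = 30,
                             start_jitter_sd = 2,
                             fragment_len_range = c(25L, 50L),
                             tx_len_range = c(500L, 3000L),
                             rpm_range = c(10, 1e5),
                             rpkm_range = c(0.1, 1e3),
                             frac_dynamic = 0.1,
                             effect_fold = 5,
                             frac_dynamic_tx = 0.2,
                             tx_effect_fold_range = c(2, 4),
                             dispersion = 0.05,
                             mirna_library_size = 1e6,
                             rnaseq_library_size = 1e7,
                             mre_offset_range = c(5L, 43L),
                             mre_mirna_min_rpm = 100,
                             time_points = TIME_POINTS,
                             replicates = c("r1", "r2"),
                             seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_planted_footprints > cfg$n_transcripts)
    stop("n_planted_footprints exceeds transcript capacity (one per transcript)")
  stopifnot(cfg$background_rate >= 0, cfg$footprint_depth > 0,
            cfg$start_jitter_sd >= 0, cfg$dispersion >= 0,
            cfg$mre_offset_range[1] <= cfg$mre_offset_range[2])
  class(cfg) <- "synthetic_config"
  cfg
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## NB draw parameterized by mean and dispersion; Poisson when dispersion 0
rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Generate a synthetic HITS-CLIP study with recorded ground truth
#'
#' Builds transcript models with random sequences and UTR/CDS annotation,
#' plants footprints and seed-match MREs (via \code{\link{plant_mres}}),
#' simulates CLIP mRNA fragment alignments (jittered starts around planted
#' anchors over a uniform background), and draws Ago-short miRNA and RNA-seq
#' replicate counts with overdispersed noise around the true loading and
#' expression trajectories.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return A list of class \code{synthetic_study} with elements
#'   \code{models} (\code{\link{transcript_models}}), \code{mirnas} (named
#'   RNA-alphabet sequences), \code{fragments}, \code{mirna_counts},
#'   \code{rnaseq_counts}, \code{clip_library_sizes} and \code{truth}
#'   (planted footprints, planted and decoy MREs, true loading and
#'   expression trajectories).
#' @examples
#' study <- generate_study(synthetic_config(n_transcripts = 20,
#'                                          n_planted_footprints = 10,
#'                                          seed = 7))
#' nrow(study$truth$planted_footprints)
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  tps <- config$time_points
  reps <- config$replicates

  ## --- transcripts -------------------------------------------------------
  n_tx <- config$n_transcripts
  tx_ids <- sprintf("tx%03d", seq_len(n_tx))
  gene_ids <- sprintf("gene%03d", seq_len(n_tx))
  lens <- sample(config$tx_len_range[1]:config$tx_len_range[2], n_tx,
                 replace = TRUE)
  seqs <- setNames(vapply(lens, rand_seq, character(1)), tx_ids)
  u <- pmax(1L, round(0.15 * lens))
  cds_end <- pmin(lens - 1L, round(0.75 * lens))
  regions <- data.frame(
    transcript_id = rep(tx_ids, each = 3L),
    region_kind = rep(c("five_prime_utr", "cds", "three_prime_utr"), n_tx),
    start = as.integer(rbind(0L, u, cds_end)),
    end = as.integer(rbind(u, cds_end, lens)),
    stringsAsFactors = FALSE)

  ## --- miRNAs (RNA alphabet, distinct seeds) -----------------------------
  n_mi <- config$n_mirnas
  mi_ids <- sprintf("miR-s%02d", seq_len(n_mi))
  mirnas <- character(n_mi)
  seen_seeds <- character(0)
  for (i in seq_len(n_mi)) {
    repeat {
      s <- rand_seq(22L, c("A", "C", "G", "U"))
      sd7 <- substr(s, 2L, 8L)
      if (!(sd7 %in% seen_seeds)) break
    }
    seen_seeds <- c(seen_seeds, sd7)
    mirnas[i] <- s
  }
  names(mirnas) <- mi_ids

  ## --- true loading trajectories (RPM) -----------------------------------
  base_rpm <- 10 ^ runif(n_mi, log10(config$rpm_range[1]),
                         log10(config$rpm_range[2]))
  loading <- matrix(base_rpm, n_mi, length(tps),
                    dimnames = list(mi_ids, tps))
  n_dyn <- round(config$frac_dynamic * n_mi)
  dyn_idx <- if (n_dyn > 0) sample(n_mi, n_dyn) else integer(0)
  dyn_tp <- sample(setdiff(tps, tps[1]), max(n_dyn, 1), replace = TRUE)[seq_len(n_dyn)]
  for (j in seq_along(dyn_idx)) {
    f <- if (j %% 2L == 1L) config$effect_fold else 1 / config$effect_fold
    loading[dyn_idx[j], dyn_tp[j]] <- loading[dyn_idx[j], dyn_tp[j]] * f
  }
  ## scale the static pool per column so each library's true RPM sums to 1e6
  ## (dynamic trajectories keep their exact planted fold changes)
  static <- setdiff(seq_len(n_mi), dyn_idx)
  for (tp in tps) {
    dyn_mass <- sum(loading[dyn_idx, tp])
    loading[static, tp] <- loading[static, tp] *
      (1e6 - dyn_mass) / sum(loading[static, tp])
  }

  ## --- true expression trajectories (RPKM) -------------------------------
  base_rpkm <- 10 ^ runif(n_tx, log10(config$rpkm_range[1]),
                          log10(config$rpkm_range[2]))
  expression <- matrix(base_rpkm, n_tx, length(tps),
                       dimnames = list(tx_ids, tps))
  n_dyn_tx <- round(config$frac_dynamic_tx * n_tx)
  if (n_dyn_tx > 0) {
    dyn_tx <- sample(n_tx, n_dyn_tx)
    for (i in dyn_tx) {
      tp <- sample(setdiff(tps, tps[1]), 1)
      f <- runif(1, config$tx_effect_fold_range[1], config$tx_effect_fold_range[2])
      if (runif(1) < 0.5) f <- 1 / f
      expression[i, tp] <- expression[i, tp] * f
    }
  }

  ## --- planted footprints -------------------------------------------------
  n_fp <- config$n_planted_footprints
  fp_tx <- sample(tx_ids[lens >= 200L], n_fp)
  fp_len <- lens[match(fp_tx, tx_ids)]
  anchors <- vapply(fp_len, function(L) sample(60:(L - 120L), 1L), integer(1))
  planted_fp <- data.frame(
    transcript_id = fp_tx, anchor = anchors,
    depth = config$footprint_depth,
    stringsAsFactors = FALSE)

  ## --- plant MREs (and decoys) into the sequences ------------------------
  loaded_pool <- mi_ids[base_rpm >= config$mre_mirna_min_rpm]
  if (!length(loaded_pool)) loaded_pool <- mi_ids
  truth <- list(planted_footprints = planted_fp)
  planted <- plant_mres(truth, seqs, mirnas[loaded_pool],
                        offset_range = config$mre_offset_range,
                        tx_lengths = setNames(lens, tx_ids))
  seqs <- planted$sequences
  truth <- planted$truth
  decoy <- plant_decoy_mres(seqs, mirnas[loaded_pool], truth$planted_footprints,
                            n_decoys = config$n_decoy_mres,
                            tx_lengths = setNames(lens, tx_ids))
  seqs <- decoy$sequences
  truth$decoy_mres <- decoy$decoys

  ## --- CLIP fragments -----------------------------------------------------
  frag_rows <- list()
  flr <- config$fragment_len_range
  for (tp in tps) for (rp in reps) {
    ## foreground: jittered starts around each planted anchor
    for (i in seq_len(n_fp)) {
      L <- fp_len[i]
      n <- rpois(1L, config$footprint_depth)
      if (n == 0L) next
      starts <- anchors[i] + as.integer(round(rnorm(n, 0, config$start_jitter_sd)))
      starts <- pmin(pmax(starts, 0L), L - flr[1])
      fraglen <- pmin(sample(flr[1]:flr[2], n, replace = TRUE), L - starts)
      frag_rows[[length(frag_rows) + 1L]] <- data.frame(
        transcript_id = fp_tx[i], start = starts, length = fraglen,
        count = 1L, replicate = rp, time_point = tp, stringsAsFactors = FALSE)
    }
    ## uniform background over every transcript
    if (config$background_rate > 0) {
      n_bg <- rpois(n_tx, config$background_rate * lens)
      for (i in which(n_bg > 0L)) {
        L <- lens[i]
        starts <- sample.int(L - flr[1] + 1L, n_bg[i], replace = TRUE) - 1L
        fraglen <- pmin(sample(flr[1]:flr[2], n_bg[i], replace = TRUE), L - starts)
        frag_rows[[length(frag_rows) + 1L]] <- data.frame(
          transcript_id = tx_ids[i], start = starts, length = fraglen,
          count = 1L, replicate = rp, time_point = tp, stringsAsFactors = FALSE)
      }
    }
  }
  fragments <- validate_fragments(do.call(rbind, frag_rows))
  clip_sizes <- aggregate(count ~ time_point + replicate, data = fragments,
                          FUN = sum)
  names(clip_sizes)[names(clip_sizes) == "count"] <- "library_size"

  ## --- Ago-short miRNA counts --------------------------------------------
  mirna_rows <- list()
  for (tp in tps) for (rp in reps) {
    mu <- loading[, tp] / 1e6 * config$mirna_library_size
    counts <- rcounts(n_mi, mu, config$dispersion)
    mirna_rows[[length(mirna_rows) + 1L]] <- data.frame(
      mirna_id = mi_ids, time_point = tp, replicate = rp,
      raw_count = counts, library_size = sum(counts), stringsAsFactors = FALSE)
  }
  mirna_counts <- do.call(rbind, mirna_rows)
  rownames(mirna_counts) <- NULL

  ## --- RNA-seq counts -----------------------------------------------------
  rna_rows <- list()
  for (tp in tps) for (rp in reps) {
    mu <- expression[, tp] * (lens / 1000) * (config$rnaseq_library_size / 1e6)
    counts <- rcounts(n_tx, mu, config$dispersion)
    rna_rows[[length(rna_rows) + 1L]] <- data.frame(
      transcript_id = tx_ids, time_point = tp, replicate = rp,
      raw_count = counts, library_size = config$rnaseq_library_size,
      stringsAsFactors = FALSE)
  }
  rnaseq_counts <- do.call(rbind, rna_rows)
  rownames(rnaseq_counts) <- NULL

  models <- transcript_models(
    data.frame(transcript_id = tx_ids, gene_id = gene_ids, length = lens,
               stringsAsFactors = FALSE),
    sequences = seqs, regions = regions)

  truth$true_loading <- loading
  truth$true_expression <- expression
  truth$dynamic_mirnas <- data.frame(
    mirna_id = mi_ids[dyn_idx],
    time_point = dyn_tp,
    fold = ifelse(seq_along(dyn_idx) %% 2L == 1L,
                  config$effect_fold, 1 / config$effect_fold),
    stringsAsFactors = FALSE)

  structure(list(models = models, mirnas = mirnas, fragments = fragments,
                 mirna_counts = mirna_counts, rnaseq_counts = rnaseq_counts,
                 clip_library_sizes = clip_sizes, truth = truth,
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic_study: %d transcripts, %d miRNAs, ",
                     "%d planted footprints, %d fragment records\n"),
              nrow(x$models$transcripts), length(x$mirnas),
              nrow(x$truth$planted_footprints), nrow(x$fragments)))
  invisible(x)
}

#' Plant seed-match MREs downstream of footprint anchors
#'
#' For each planted footprint, writes the DNA reverse complement of the
#' chosen miRNA's seed (nucleotides 2-8) into the transcript sequence at
#' \code{anchor + offset}, with the offset drawn uniformly from
#' \code{offset_range}. Sites that would run past the transcript end are
#' skipped with a warning.
#'
#' @param truth list carrying \code{planted_footprints} (data.frame with
#'   \code{transcript_id} and \code{anchor}).
#' @param sequences named character vector of transcript DNA sequences.
#' @param mirnas named character vector of miRNA sequences (RNA alphabet);
#'   one is drawn per footprint.
#' @param offset_range inclusive integer range of offsets downstream of the
#'   anchor.
#' @param tx_lengths optional named lengths (defaults to \code{nchar} of the
#'   sequences).
#' @return list with updated \code{sequences} and \code{truth} (gaining a
#'   \code{planted_mres} data.frame with \code{mirna_id},
#'   \code{transcript_id}, \code{mre_start}, \code{offset}).
#' @export
plant_mres <- function(truth, sequences, mirnas,
                       offset_range = c(5L, 43L), tx_lengths = NULL) {
  fp <- truth$planted_footprints
  if (is.null(tx_lengths)) tx_lengths <- nchar(sequences)
  mres <- list()
  for (i in seq_len(nrow(fp))) {
    tx <- fp$transcript_id[i]
    mi <- sample(names(mirnas), 1L)
    site <- seed_site_7m8(mirnas[[mi]])
    offset <- if (offset_range[1] == offset_range[2]) offset_range[1] else
      sample(offset_range[1]:offset_range[2], 1L)
    pos <- fp$anchor[i] + offset
    if (pos + nchar(site) > tx_lengths[[tx]]) {
      warning("skipping MRE on ", tx, ": site would exceed transcript bounds")
      next
    }
    substr(sequences[[tx]], pos + 1L, pos + nchar(site)) <- site
    mres[[length(mres) + 1L]] <- data.frame(
      mirna_id = mi, transcript_id = tx, mre_start = pos, offset = offset,
      stringsAsFactors = FALSE)
  }
  truth$planted_mres <- if (length(mres)) do.call(rbind, mres) else
    data.frame(mirna_id = character(), transcript_id = character(),
               mre_start = integer(), offset = integer(),
               stringsAsFactors = FALSE)
  list(sequences = sequences, truth = truth)
}

## Plant seed matches well away from every planted anchor: they can never
## satisfy the 5-43 nt downstream window of a genuine footprint.
plant_decoy_mres <- function(sequences, mirnas, planted_fp, n_decoys,
                             tx_lengths, exclusion = c(150L, 250L)) {
  decoys <- list()
  tx_ids <- names(sequences)
  tries <- 0L
  while (length(decoys) < n_decoys && tries < n_decoys * 50L) {
    tries <- tries + 1L
    tx <- sample(tx_ids, 1L)
    L <- tx_lengths[[tx]]
    if (L < 60L) next
    pos <- sample.int(L - 20L, 1L) - 1L
    anchors <- planted_fp$anchor[planted_fp$transcript_id == tx]
    if (length(anchors) &&
        any(pos > anchors - exclusion[1] & pos < anchors + exclusion[2])) next
    mi <- sample(names(mirnas), 1L)
    site <- seed_site_7m8(mirnas[[mi]])
    if (pos + nchar(site) > L) next
    substr(sequences[[tx]], pos + 1L, pos + nchar(site)) <- site
    decoys[[length(decoys) + 1L]] <- data.frame(
      mirna_id = mi, transcript_id = tx, mre_start = pos,
      stringsAsFactors = FALSE)
  }
  list(sequences = sequences,
       decoys = if (length(decoys)) do.call(rbind, decoys) else
         data.frame(mirna_id = character(), transcript_id = character(),
                    mre_start = integer(), stringsAsFactors = FALSE))
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Emits transcript FASTA, region BED, fragment/counts TSVs, CLIP library
#' sizes, miRNA FASTA (RNA alphabet), and a flat \code{truth.json} sidecar.
#'
#' @param study a \code{synthetic_study}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(study$models$sequences)
  names(seqs) <- paste0(names(study$models$sequences), " gene=",
                        study$models$transcripts$gene_id[
                          match(names(study$models$sequences),
                                study$models$transcripts$transcript_id)])
  Biostrings::writeXStringSet(seqs, file.path(dir, "transcripts.fa"))
  reg <- study$models$regions
  write.table(data.frame(reg$transcript_id, reg$start, reg$end, reg$region_kind,
                         0L, "+"),
              file.path(dir, "regions.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  mi <- Biostrings::RNAStringSet(study$mirnas)
  Biostrings::writeXStringSet(mi, file.path(dir, "mirnas.fa"))
  write_fragment_table(study$fragments, file.path(dir, "fragments.tsv"))
  write_tsv_table(study$mirna_counts, file.path(dir, "mirna_counts.tsv"))
  write_tsv_table(study$rnaseq_counts, file.path(dir, "rnaseq_counts.tsv"))
  write_tsv_table(study$clip_library_sizes, file.path(dir, "clip_library_sizes.tsv"))
  truth <- study$truth
  truth$true_loading <- as.data.frame(truth$true_loading)
  truth$true_expression <- as.data.frame(truth$true_expression)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), dataframe = "columns",
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
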