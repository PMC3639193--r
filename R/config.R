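#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#' Defaults are the study conventions: miRNAs count as RISC-loaded at a mean
#' of 100 RPM in the Ago-short library, differential loading uses a stricter
#' 1,000 RPM floor and an FDR ceiling of 20%, a miRNA regulatory element is
#' confirmed when it lies 5-43 nt downstream of a footprint anchor on a
#' footprint of strength at least 0.31 RPM/RPKM, ceRNA construction merges
#' footprints within 20 bp and requires a <25% second footprint and a 10x
#' dominant miRNA, expression matrices keep transcripts at >= 2 RPKM, TRL
#' matrices keep transcripts with a load over 1, and profile clustering
#' scans K = 4..30 with K = 12 as the reported partition.
#'
#' @param ... named overrides of any default listed below.
#'
#' @return A named list of class \code{riscprof_config}.
#' @examples
#' cfg <- riscprof_config(rpm_detect = 50)
#' cfg$rpm_detect
#' @export
riscprof_config <- function(...) {
  cfg <- list(
    rpm_detect          = 100,
    rpm_differential    = 1000,
    fdr_loading         = 0.20,
    mre_window          = c(5L, 43L),
    strength_min        = 0.31,
    cerna_merge_bp      = 20L,
    cerna_second_fp_frac = 0.25,
    cerna_mirna_ratio   = 10,
    rpkm_min            = 2,
    trl_min             = 1,
    kmeans_k_range      = c(4L, 30L),
    kmeans_k            = 12L,
    min_reads           = 5L,
    assign_window       = 10L,
    footprint_len       = 50L,
    rpkm_floor          = 0.1,
    log_pseudocount     = 0.1,
    rpm_pseudocount     = 0.5,
    seed                = 1L,
    coordinates         = "0-based-half-open"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(cfg)
  class(cfg) <- "riscprof_config"
  cfg
}

validate_config <- function(cfg) {
  num_pos <- c("rpm_detect", "rpm_differential", "fdr_loading",
               "strength_min", "cerna_merge_bp", "cerna_second_fp_frac",
               "cerna_mirna_ratio", "rpkm_min", "trl_min", "min_reads",
               "assign_window", "footprint_len", "rpkm_floor")
  for (f in num_pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("configuration field '", f, "' must be a positive scalar")
  if (length(cfg$mre_window) != 2L || cfg$mre_window[1] > cfg$mre_window[2])
    stop("mre_window must be (lower, upper) with lower <= upper")
  if (length(cfg$kmeans_k_range) != 2L ||
      cfg$kmeans_k_range[1] > cfg$kmeans_k_range[2])
    stop("kmeans_k_range must be (lower, upper) with lower <= upper")
  invisible(cfg)
}

#' Read or write a flat key=value configuration file
#'
#' The on-disk format is one \code{key = value} pair per line, with vector
#' values comma-separated; keys mirror the fields of
#' \code{\link{riscprof_config}}. Unknown keys are rejected.
#'
#' @param path file path.
#' @return \code{read_config} returns a \code{riscprof_config};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, function(x) length(x) != 2L, logical(1))
  if (any(bad))
    stop("malformed configuration line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  parsed <- lapply(vals, function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  })
  names(parsed) <- keys
  do.call(riscprof_config, parsed)
}

#' @rdname read_config
#' @param config a \code{riscprof_config}.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "riscprof_config"))
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", paste(config[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.riscprof_config <- function(x, ...) {
  cat("riscprof pipeline configuration\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, paste(x[[k]], collapse = ", ")))
  invisible(x)
}
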