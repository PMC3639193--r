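## Readers/writers for the transcript-space formats the pipeline touches.
## Internal convention everywhere: 0-based, half-open intervals on the
## transcript (sense) strand. GFF3 (1-based, inclusive) is converted on read.

REGION_KINDS <- c("five_prime_utr", "cds", "three_prime_utr")
TIME_POINTS <- c("0h", "1h", "36h", "48h")

#' Construct a set of transcript models
#'
#' @param transcripts data.frame with columns \code{transcript_id},
#'   \code{gene_id}, \code{length} (nt).
#' @param sequences optional named character vector of DNA sequences; names
#'   are transcript ids and lengths must match \code{length}.
#' @param regions optional data.frame with columns \code{transcript_id},
#'   \code{region_kind} (one of five_prime_utr, cds, three_prime_utr),
#'   \code{start}, \code{end} in 0-based half-open transcript coordinates.
#'
#' @return An object of class \code{transcript_models}: a list with elements
#'   \code{transcripts}, \code{sequences}, \code{regions}.
#' @export
transcript_models <- function(transcripts, sequences = NULL, regions = NULL) {
  stopifnot(is.data.frame(transcripts),
            all(c("transcript_id", "gene_id", "length") %in% names(transcripts)))
  transcripts$transcript_id <- as.character(transcripts$transcript_id)
  transcripts$gene_id <- as.character(transcripts$gene_id)
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicate transcript_id in transcript table")
  if (any(transcripts$length < 1))
    stop("transcript length must be >= 1")
  if (is.null(regions)) {
    regions <- data.frame(transcript_id = character(), region_kind = character(),
                          start = integer(), end = integer(),
                          stringsAsFactors = FALSE)
  }
  regions$transcript_id <- as.character(regions$transcript_id)
  unknown <- setdiff(regions$transcript_id, transcripts$transcript_id)
  if (length(unknown))
    stop("region refers to unknown transcript(s): ",
         paste(unique(unknown), collapse = ", "))
  bad_kind <- setdiff(unique(regions$region_kind), REGION_KINDS)
  if (length(bad_kind))
    stop("unknown region kind(s): ", paste(bad_kind, collapse = ", "))
  if (nrow(regions)) {
    len <- transcripts$length[match(regions$transcript_id, transcripts$transcript_id)]
    oob <- regions$start < 0 | regions$end > len | regions$start >= regions$end
    if (any(oob))
      stop("region outside transcript bounds for: ",
           paste(unique(regions$transcript_id[oob]), collapse = ", "))
    ## regions must be disjoint and ordered within each transcript
    sp <- split(regions[c("start", "end")], regions$transcript_id)
    for (tx in names(sp)) {
      r <- sp[[tx]][order(sp[[tx]]$start), , drop = FALSE]
      if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)]))
        stop("overlapping regions on transcript ", tx)
    }
    regions <- regions[order(regions$transcript_id, regions$start), , drop = FALSE]
    rownames(regions) <- NULL
  }
  if (!is.null(sequences)) {
    sequences <- vapply(sequences, as.character, character(1))
    missing_seq <- setdiff(names(sequences), transcripts$transcript_id)
    if (length(missing_seq))
      stop("sequence for unknown transcript(s): ",
           paste(missing_seq, collapse = ", "))
    idx <- match(names(sequences), transcripts$transcript_id)
    if (any(nchar(sequences) != transcripts$length[idx]))
      stop("sequence length disagrees with annotated transcript length")
  }
  structure(list(transcripts = transcripts, sequences = sequences,
                 regions = regions),
            class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("transcript_models: %d transcripts, %d annotated regions, sequences: %s\n",
              nrow(x$transcripts), nrow(x$regions),
              if (is.null(x$sequences)) "absent" else "present"))
  invisible(x)
}

#' Read transcript models from FASTA plus BED/GFF region annotation
#'
#' Sequences come from \code{fasta_path} (one record per transcript; the id
#' is the first whitespace-delimited token of the header, and a
#' \code{gene=...} token, when present, supplies the gene id). Region
#' annotation is BED (0-based half-open; the name column holds the region
#' kind) or GFF3 (1-based inclusive; the type column holds the kind),
#' expressed in transcript coordinates with the transcript id in the
#' chromosome column.
#'
#' @param fasta_path path to a FASTA file of transcript sequences.
#' @param annotation_path optional path to a BED or GFF3 file of UTR/CDS
#'   regions; \code{NULL} or an empty file yields models without regions.
#' @return A \code{\link{transcript_models}} object.
#' @export
read_transcript_models <- function(fasta_path, annotation_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate transcript_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gene_ids <- vapply(names(seqs), function(h) {
    m <- regmatches(h, regexpr("gene=[^[:space:]]+", h))
    if (length(m)) sub("^gene=", "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  gene_ids[is.na(gene_ids)] <- ids[is.na(gene_ids)]
  transcripts <- data.frame(transcript_id = ids, gene_id = gene_ids,
                            length = Biostrings::width(seqs),
                            stringsAsFactors = FALSE)
  sequences <- setNames(as.character(seqs), ids)
  regions <- NULL
  if (!is.null(annotation_path)) {
    regions <- read_region_annotation(annotation_path)
    if (nrow(regions) == 0L)
      warning("annotation file '", annotation_path, "' contains no regions")
  }
  transcript_models(transcripts, sequences, regions)
}

## BED or GFF3 -> region data.frame in 0-based half-open coordinates
read_region_annotation <- function(path) {
  empty <- data.frame(transcript_id = character(), region_kind = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  content <- readLines(path, warn = FALSE)
  content <- content[nzchar(trimws(content)) & !grepl("^#", content)]
  if (!length(content)) return(empty)
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE)
  gr <- rtracklayer::import(path, format = if (is_gff) "gff3" else "bed")
  kind <- if (is_gff) as.character(gr$type) else as.character(gr$name)
  ## GRanges carries 1-based inclusive coordinates for either source format;
  ## start-1 / end recovers 0-based half-open exactly.
  data.frame(transcript_id = as.character(GenomicRanges::seqnames(gr)),
             region_kind = tolower(kind),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Convert between 0-based half-open and 1-based inclusive coordinates
#'
#' Exact inverses: \code{from_gff_coords(to_gff_coords(s, e))} recovers
#' \code{(s, e)} for every interval.
#'
#' @param start,end 0-based half-open interval (vectorized).
#' @return A data.frame with columns \code{start} and \code{end} in the
#'   other convention.
#' @export
to_gff_coords <- function(start, end) {
  data.frame(start = start + 1L, end = end)
}

#' @rdname to_gff_coords
#' @param start1,end1 1-based inclusive interval (vectorized).
#' @export
from_gff_coords <- function(start1, end1) {
  data.frame(start = start1 - 1L, end = end1)
}

#' Read CLIP fragment alignments from a TSV
#'
#' Expected columns: \code{transcript_id}, \code{start} (0-based transcript
#' coordinate of the fragment 5' end), \code{length}, \code{count},
#' \code{replicate}, \code{time_point}. Rows sharing all key columns are
#' aggregated by summing counts.
#'
#' @param path TSV file with a header line.
#' @param models optional \code{transcript_models}; when given, fragment
#'   bounds are checked against transcript lengths.
#' @return data.frame of validated fragment alignments.
#' @export
read_fragment_table <- function(path, models = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(transcript_id = "character",
                                  replicate = "character",
                                  time_point = "character"))
  need <- c("transcript_id", "start", "length", "count", "replicate", "time_point")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("fragment table missing column(s): ", paste(miss, collapse = ", "))
  validate_fragments(df[need], models)
}

validate_fragments <- function(df, models = NULL) {
  for (col in c("start", "length", "count")) {
    v <- df[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != floor(v))) {
      bad <- which(!is.numeric(v) | is.na(v) | v != floor(v))[1]
      stop("fragment table: non-integer ", col, " at row ", bad)
    }
    df[[col]] <- as.integer(v)
  }
  if (any(df$start < 0))
    stop("fragment table: negative start at row ", which(df$start < 0)[1])
  if (any(df$length < 1))
    stop("fragment table: non-positive length at row ", which(df$length < 1)[1])
  if (any(df$count < 1))
    stop("fragment table: non-positive count at row ", which(df$count < 1)[1])
  if (!is.null(models)) {
    len <- models$transcripts$length[match(df$transcript_id,
                                           models$transcripts$transcript_id)]
    if (anyNA(len))
      stop("fragment table refers to unknown transcript(s): ",
           paste(unique(df$transcript_id[is.na(len)]), collapse = ", "))
    oob <- df$start + df$length > len
    if (any(oob))
      stop("fragment extends past transcript end at row ", which(oob)[1])
  }
  agg <- aggregate(count ~ transcript_id + start + length + replicate + time_point,
                   data = df, FUN = sum)
  agg <- agg[order(agg$transcript_id, agg$time_point, agg$replicate, agg$start), ]
  rownames(agg) <- NULL
  agg[c("transcript_id", "start", "length", "count", "replicate", "time_point")]
}

#' Write or read a fragment table TSV
#' @param fragments data.frame of fragment alignments.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_fragment_table <- function(fragments, path) {
  write.table(fragments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write footprints as BED6
#'
#' One line per footprint: transcript id, interval (0-based half-open),
#' footprint id, score = strength scaled by 1000 and capped at 1000
#' (undefined strengths score 0), strand "+" (transcript space is always the
#' sense strand). A single \code{track} header line precedes the records.
#'
#' @param footprints footprint data.frame (see \code{\link{call_footprints_all}}).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_footprints_bed <- function(footprints, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track name=riscprof_footprints description=\"Ago footprints\"", con)
  if (nrow(footprints)) {
    strength <- if ("strength" %in% names(footprints)) footprints$strength else NA_real_
    score <- ifelse(is.na(strength), 0, pmin(round(strength * 1000), 1000))
    lines <- paste(footprints$transcript_id, footprints$start, footprints$end,
                   footprints$footprint_id, score, "+", sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_footprints_bed
#' @return \code{read_footprints_bed} returns a data.frame with columns
#'   \code{transcript_id}, \code{start}, \code{end}, \code{footprint_id},
#'   \code{score}, \code{strand}.
#' @export
read_footprints_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), footprint_id = character(),
                      score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  df <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("transcript_id", "start", "end", "footprint_id", "score", "strand")
  df
}

#' Read a counts table TSV
#'
#' Expected columns: an id column (\code{mirna_id}, \code{transcript_id} or
#' \code{entity_id}), \code{time_point}, \code{replicate}, \code{raw_count},
#' and optionally \code{library_size}.
#'
#' @param path TSV file with a header.
#' @return data.frame.
#' @export
read_counts_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("time_point", "replicate", "raw_count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("counts table missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$raw_count < 0) || any(df$raw_count != floor(df$raw_count)))
    stop("counts table: raw_count must be a non-negative integer")
  if ("library_size" %in% names(df) && any(df$library_size <= 0))
    stop("counts table: library_size must be positive")
  df
}

#' Write a generic TSV table
#' @param df data.frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member genes, tab-separated.
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line: ", substr(l, 1, 60))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}
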