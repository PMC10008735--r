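## Readers and writers for the pipeline's plain-text interchange formats.

#' Read small-RNA reads from FASTA or FASTQ
#'
#' Format is inferred from the file name (`.fq`/`.fastq`, optionally
#' `.gz`); everything else is treated as FASTA.
#'
#' @param path Input path.
#' @return Character vector of read sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  as.character(Biostrings::readDNAStringSet(path, format = fmt))
}

#' Write reads as FASTA or FASTQ
#'
#' FASTQ qualities are a fixed "I" (Phred 40), marking the reads as
#' synthetic.
#'
#' @param reads Tibble with `read_id` and `sequence`, or character vector.
#' @param path Output path; `.gz` suffix gzips, `.fq`/`.fastq` selects
#'   FASTQ.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  if (!is.data.frame(reads)) {
    reads <- tibble(read_id = sprintf("read_%07d", seq_along(reads)), sequence = reads)
  }
  fastq <- grepl("\\.(fq|fastq)(\\.gz)?$", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (fastq) {
    writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                      strrep("I", nchar(reads$sequence))), con)
  } else {
    writeLines(paste0(">", reads$read_id, "\n", reads$sequence), con)
  }
  invisible(path)
}

provenance_header <- function(seed = NULL, config_hash = NULL) {
  paste0("# sncfrag ", as.character(packageVersion("sncfrag")),
         if (!is.null(seed)) paste0(" seed=", seed),
         if (!is.null(config_hash)) paste0(" config=", config_hash))
}

#' Write a tibble as TSV with a provenance header line
#'
#' @param x Data frame.
#' @param path Output path.
#' @param seed,config_hash Recorded in the leading `#` comment line.
#' @return `path`, invisibly.
#' @export
write_tsv_stamped <- function(x, path, seed = NULL, config_hash = NULL) {
  writeLines(provenance_header(seed, config_hash), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Export annotation records as a BED-like table
#'
#' Coordinates are converted to 0-based half-open intervals in this export
#' only (flagged in the header comment); everything else in the package is
#' 1-based inclusive.
#'
#' @param ann Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(ann, path) {
  bed <- ann |>
    mutate(chromStart = .data$start - 1L, chromEnd = .data$end) |>
    select(chrom = "parent_id", "chromStart", "chromEnd",
           name = "read_id", score = "count", "category")
  writeLines("# coordinates: 0-based half-open (BED)", path)
  readr::write_tsv(bed, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Export called peaks as BED
#'
#' @param peaks Named list of `snc_peaks` tibbles (parent -> peaks) or a
#'   single `snc_peaks`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  if (inherits(peaks, "snc_peaks")) {
    peaks <- setNames(list(peaks), attr(peaks, "parent_id") %||% "parent")
  }
  bed <- imap(peaks, function(pk, parent) {
    tibble(chrom = parent, chromStart = pk$start - 1L, chromEnd = pk$end,
           name = paste0(parent, "#", pk$peak), score = round(pk$mean_height, 2))
  }) |> bind_rows()
  writeLines("# coordinates: 0-based half-open (BED)", path)
  readr::write_tsv(bed, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
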