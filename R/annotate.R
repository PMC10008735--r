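#' Collapse reads to unique sequences
#'
#' Length-filters reads to the 15-45 nt window, drops sequences containing
#' characters outside A/C/G/T with a warning, and collapses identical
#' sequences to one record with a multiplicity count.
#'
#' @param reads A character vector of read sequences, or a data frame with a
#'   `sequence` column (an optional `count` column of prior multiplicities
#'   is honoured).
#' @param min_len,max_len Length filter bounds (default 15 and 45 nt).
#' @return A tibble with `read_id`, `sequence`, `count`; the counts sum to
#'   the number of input reads passing the filters.
#' @export
collapse_reads <- function(reads, min_len = 15L, max_len = 45L) {
  if (is.data.frame(reads)) {
    cnt <- if ("count" %in% names(reads)) reads$count else rep(1L, nrow(reads))
    seqs <- reads$sequence
  } else {
    seqs <- as.character(reads)
    cnt <- rep(1L, length(seqs))
  }
  if (length(seqs) == 0L) {
    return(tibble(read_id = character(), sequence = character(), count = integer()))
  }
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    warn(sprintf("dropping %d read(s) with non-ACGT characters", sum(bad)))
  }
  len <- nchar(seqs)
  keep <- !bad & len >= min_len & len <= max_len
  tibble(sequence = seqs[keep], count = cnt[keep]) |>
    group_by(.data$sequence) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(desc(.data$count), .data$sequence) |>
    mutate(read_id = sprintf("seq_%06d", row_number())) |>
    select("read_id", "sequence", "count")
}

#' Build a 15-mer index over a reference set
#'
#' tRNA and mt_tRNA parents are indexed on their CCA-appended mature
#' sequence, since circulating tRNA fragments frequently carry the
#' post-transcriptional tail. The index supports exact full-read lookup:
#' because any full-read match must contain the read's first 15-mer, looking
#' up that 15-mer and verifying the remainder enumerates all exact hits.
#'
#' @param ref An `snc_reference`.
#' @param k Seed k-mer length (default 15, the reference's uniqueness
#'   guarantee).
#' @return An object of class `snc_index` (kmer table plus the matching
#'   sequences); build once and reuse across libraries.
#' @export
build_kmer_index <- function(ref, k = 15L) {
  seqs <- ifelse(ref$category %in% c("tRNA", "mt_tRNA"),
                 paste0(ref$sequence, "CCA"), ref$sequence)
  n <- nchar(seqs)
  tab <- map_dfr(seq_along(seqs), function(i) {
    if (n[i] < k) return(NULL)
    tibble(
      kmer = substring(seqs[i], 1:(n[i] - k + 1L), k:n[i]),
      parent_id = ref$id[i],
      pos = 1:(n[i] - k + 1L)
    )
  })
  structure(
    list(kmers = tab, k = k,
         sequences = setNames(seqs, ref$id),
         category = setNames(ref$category, ref$id),
         subcategory = setNames(ref$subcategory, ref$id),
         body_length = setNames(ref$length, ref$id),
         nesting = attr(ref, "nesting")),
    class = "snc_index"
  )
}

# exact hits for a set of collapsed reads: first-kmer lookup + full verify
exact_hits <- function(collapsed, index) {
  if (nrow(collapsed) == 0L) {
    return(tibble(read_id = character(), parent_id = character(),
                  start = integer(), end = integer(), mismatches = integer()))
  }
  q <- collapsed |> mutate(kmer = substr(.data$sequence, 1L, index$k))
  cand <- inner_join(q, index$kmers, by = "kmer", relationship = "many-to-many")
  if (nrow(cand) == 0L) return(tibble(read_id = character(), parent_id = character(),
                                      start = integer(), end = integer(),
                                      mismatches = integer()))
  len <- nchar(cand$sequence)
  ok <- substring(index$sequences[cand$parent_id], cand$pos, cand$pos + len - 1L) ==
    cand$sequence
  cand[ok, ] |>
    mutate(start = .data$pos, end = .data$pos + len[ok] - 1L, mismatches = 0L) |>
    select("read_id", "parent_id", "start", "end", "mismatches")
}

# brute-force scan allowing up to max_mismatch substitutions; used only for
# reads left unmatched by the exact index when the 1-mismatch mode is on
mismatch_hits <- function(collapsed, index, max_mismatch) {
  if (nrow(collapsed) == 0L) return(NULL)
  subj <- Biostrings::DNAStringSet(index$sequences)
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  map_dfr(seq_len(nrow(collapsed)), function(i) {
    pat <- collapsed$sequence[i]
    map_dfr(names(subj), function(p) {
      m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj[[p]],
                                    max.mismatch = max_mismatch,
                                    with.indels = FALSE)
      if (length(m) == 0L) return(NULL)
      st <- Biostrings::start(m); en <- Biostrings::end(m)
      mm <- vapply(seq_along(m), function(j)
        hamming(pat, substring(index$sequences[[p]], st[j], en[j])), 0)
      tibble(read_id = collapsed$read_id[i], parent_id = p,
             start = st, end = en, mismatches = as.integer(mm))
    })
  })
}

# keep, per read, the first priority category containing a hit; resolve the
# 45S nesting (prefer the mature subunit) before splitting ties
resolve_hits <- function(hits, index, priority) {
  if (nrow(hits) == 0L) return(hits |> mutate(category = character(0), weight = numeric(0)))
  hits <- hits |>
    mutate(category = unname(index$category[.data$parent_id]),
           prio = match(.data$category, priority))
  hits <- hits |>
    group_by(.data$read_id) |>
    filter(.data$prio == min(.data$prio)) |>
    ungroup()
  # nesting consistency: a read matching both 45S and an embedded subunit is
  # counted only under the most specific mature parent
  hits <- hits |>
    group_by(.data$read_id) |>
    filter(!(.data$parent_id == "RNA45S" & any(.data$parent_id != "RNA45S") &
               .data$category[1] == "rRNA")) |>
    mutate(weight = 1 / n()) |>
    ungroup() |>
    select(-"prio")
  hits
}

#' Assign collapsed reads to sncRNA categories by hierarchical matching
#'
#' Each read is matched ungapped, full-length and forward-strand against the
#' reference (tRNAs on CCA-appended mature coordinates) and assigned to the
#' first category in `priority` containing a hit with at most `max_mismatch`
#' substitutions. Within the winning category, ties across parents split the
#' read's count equally; reads matching both the 45S precursor and one of
#' its embedded mature subunits are assigned to the subunit. Reads without
#' any hit are reported unannotated.
#'
#' @param collapsed Output of [collapse_reads()] (or any tibble with
#'   `read_id`, `sequence`, `count`).
#' @param index An `snc_index` from [build_kmer_index()] (or an
#'   `snc_reference`, which is indexed on the fly).
#' @param priority Ordered character vector of categories; defaults to
#'   miRNA first, then rRNA, YRNA, tRNA, mt_tRNA, piRNA, other_ncRNA,
#'   spike_in.
#' @param max_mismatch 0 (default, exact) or 1 (slow fallback scan).
#' @return A tibble of annotation records: `read_id`, `sequence`, `count`,
#'   `category`, `class`, `parent_id`, `start`, `end`, `mismatches`,
#'   `weight` (fraction of the read's count carried by each parent row).
#' @export
assign_category <- function(collapsed, index, priority = default_priority(),
                            max_mismatch = 0L) {
  if (inherits(index, "snc_reference")) index <- build_kmer_index(index)
  if (!all(unique(unname(index$category)) %in% priority)) {
    abort("priority must cover every category present in the reference")
  }
  hits <- exact_hits(collapsed, index)
  if (max_mismatch > 0L) {
    left <- collapsed |> filter(!(.data$read_id %in% hits$read_id))
    more <- mismatch_hits(left, index, max_mismatch)
    if (!is.null(more) && nrow(more)) hits <- bind_rows(hits, more)
  }
  resolve_hits(hits, index, priority) |>
    left_join(select(collapsed, "read_id", "sequence", "count"), by = "read_id") |>
    mutate(class = category_to_class(.data$category)) |>
    select("read_id", "sequence", "count", "category", "class", "parent_id",
           "start", "end", "mismatches", "weight")
}

# feature identity for each annotation row, per class:
# miRNA/piRNA/other/spike_in -> parent; tsRNA -> parent x reported subtype
# group; rsRNA -> specific parent x (peak index | background); ysRNA ->
# gene x 5'/3'
featurize_annotations <- function(ann, index, peaks = NULL) {
  if (nrow(ann) == 0L) return(mutate(ann, feature_id = character(0)))
  feature <- ann$parent_id
  i <- ann$class == "tsRNA"
  if (any(i)) {
    sub <- classify_tsrna_subtype(ann$start[i], ann$end[i],
                                  unname(index$body_length[ann$parent_id[i]]))
    grp <- dplyr::case_match(sub, "five_prime" ~ "5p", "inner" ~ "inner",
                             c("three_prime", "three_prime_cca") ~ "3pCCA")
    feature[i] <- paste0(ann$parent_id[i], "/", grp)
  }
  i <- ann$class == "ysRNA"
  if (any(i)) {
    feature[i] <- paste0(ann$parent_id[i], "/", ifelse(ann$start[i] <= 3L, "5p", "3p"))
  }
  i <- ann$class == "rsRNA" & ann$parent_id %in% names(peaks %||% list())
  if (any(i)) {
    feature[i] <- map_chr(which(i), function(j) {
      pk <- peaks[[ann$parent_id[j]]]
      ov <- pmin(ann$end[j], pk$end) - pmax(ann$start[j], pk$start) + 1L
      best <- which.max(ov)
      if (length(best) && ov[best] >= (ann$end[j] - ann$start[j] + 1L) / 2) {
        paste0(ann$parent_id[j], "#", best)
      } else paste0(ann$parent_id[j], "/background")
    })
  }
  i <- ann$class == "rsRNA" & !(ann$parent_id %in% names(peaks %||% list()))
  feature[i] <- ann$parent_id[i]
  mutate(ann, feature_id = feature)
}

#' Annotate one sequencing library
#'
#' Collapses, matches and featurizes a library of reads, producing one
#' count-matrix column keyed by category-specific fragment identities
#' (miRNA: mature id; tsRNA: parent x cleavage group; rsRNA: parent x peak
#' or background bin; ysRNA: gene x 5'/3'), plus the annotation records and
#' the unannotated read count. Fractional multi-hit counts are preserved;
#' rounding happens only at matrix export.
#'
#' @param reads Character vector or data frame of reads (see
#'   [collapse_reads()]).
#' @param index `snc_index` or `snc_reference`.
#' @param priority,max_mismatch Passed to [assign_category()].
#' @param peaks Optional named list (parent -> peak tibble from
#'   [detect_peaks()]) defining rsRNA bins; when `NULL`, peaks are called on
#'   the library's own 18S/28S coverage profiles.
#' @return A list of class `snc_library`: `column` (tibble feature_id,
#'   class, count), `annotations`, `unannotated`, `total` (collapsed input
#'   count), `peaks`.
#' @export
annotate_library <- function(reads, index, priority = default_priority(),
                             max_mismatch = 0L, peaks = NULL) {
  if (inherits(index, "snc_reference")) index <- build_kmer_index(index)
  collapsed <- if (is.data.frame(reads) && all(c("read_id", "count", "sequence") %in% names(reads)))
    reads else collapse_reads(reads)
  if (nrow(collapsed) == 0L) {
    warn("empty library")
    return(structure(list(
      column = tibble(feature_id = character(), class = character(), count = numeric()),
      annotations = tibble(), unannotated = 0, total = 0, peaks = peaks
    ), class = "snc_library"))
  }
  ann <- assign_category(collapsed, index, priority, max_mismatch)
  total <- sum(collapsed$count)
  annotated <- sum((ann |> distinct(.data$read_id, .data$count))$count)
  if (is.null(peaks)) {
    peaks <- purrr::compact(map(
      setNames(c("RNA18S", "RNA28S"), c("RNA18S", "RNA28S")),
      function(p) {
        prof <- coverage_profile(ann, p, index)
        pk <- detect_peaks(prof)
        if (nrow(pk)) pk else NULL
      }
    ))
  }
  ann <- featurize_annotations(ann, index, peaks)
  column <- ann |>
    group_by(.data$feature_id, .data$class) |>
    summarise(count = sum(.data$count * .data$weight), .groups = "drop") |>
    arrange(.data$feature_id)
  structure(list(column = column, annotations = ann,
                 unannotated = total - annotated, total = total, peaks = peaks),
            class = "snc_library")
}

#' Class proportions of an annotated library
#'
#' Fractions of annotated reads (spike-in excluded) per fragment class:
#' rsRNA, ysRNA, tsRNA, miRNA, piRNA, other_ncRNA. Proportions are computed
#' over annotated reads only, matching how serum composition is reported.
#'
#' @param x An `snc_library`, an annotation tibble, or a count column tibble
#'   with `class` and `count`.
#' @return A tibble `class`, `count`, `proportion` (summing to 1).
#' @export
compute_class_proportions <- function(x) {
  tab <- if (inherits(x, "snc_library")) x$annotations else x
  if (!"weight" %in% names(tab)) tab$weight <- 1
  tab <- filter(tab, .data$class != "spike_in")
  if (nrow(tab) == 0L || sum(tab$count * tab$weight) == 0) {
    abort("no annotated reads; class proportions undefined")
  }
  out <- tab |>
    group_by(class = .data$class) |>
    summarise(count = sum(.data$count * .data$weight), .groups = "drop") |>
    mutate(proportion = .data$count / sum(.data$count)) |>
    arrange(desc(.data$proportion))
  class(out) <- c("snc_proportions", class(out))
  out
}

#' Reads-per-million normalization
#'
#' @param counts Numeric vector of feature counts.
#' @param mapped_total Total mapped (annotated) reads of the sample.
#' @return `counts * 1e6 / mapped_total`.
#' @export
rpm_normalize <- function(counts, mapped_total) {
  if (length(mapped_total) != 1L || is.na(mapped_total) || mapped_total <= 0) {
    abort("mapped_total must be a single positive number")
  }
  counts * 1e6 / mapped_total
}

#' RPM-weighted read-length distribution of a fragment class
#'
#' @param ann Annotation tibble (e.g. from an `snc_library`).
#' @param class One of the fragment classes.
#' @param mapped_total Total annotated reads used as the RPM denominator;
#'   defaults to the annotated total of `ann`.
#' @return A tibble with `length` (15-45) and `rpm`; the 31 bins sum to the
#'   class RPM total.
#' @export
length_distribution <- function(ann, class, mapped_total = NULL) {
  if (!class %in% snc_classes()) abort(paste("unknown class:", class))
  if (is.null(mapped_total)) {
    mapped_total <- sum((ann |> distinct(.data$read_id, .data$count))$count)
  }
  sub <- filter(ann, .data$class == .env$class)
  h <- sub |>
    mutate(length = nchar(.data$sequence)) |>
    group_by(.data$length) |>
    summarise(count = sum(.data$count * .data$weight), .groups = "drop")
  out <- tibble(length = 15:45) |>
    left_join(h, by = "length") |>
    mutate(rpm = rpm_normalize(dplyr::coalesce(.data$count, 0), mapped_total)) |>
    select("length", "rpm")
  class(out) <- c("snc_lengthdist", class(out))
  attr(out, "fragment_class") <- class
  out
}
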