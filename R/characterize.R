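#' Classify a tsRNA fragment by cleavage position
#'
#' Operates on CCA-appended mature-tRNA coordinates: a fragment spanning
#' `[start, end]` of a tRNA with body length `L` (so mature length `L + 3`)
#' is `five_prime` when it starts within the first `delta` nucleotides,
#' otherwise `three_prime_cca` when it reaches into the appended tail
#' (`end >= L + 1`), otherwise `three_prime` when it ends within `delta`
#' of the body 3' end (`end >= L - delta + 1`), and `inner` otherwise.
#' The boundary tolerance `delta` absorbs ragged cleavage; the partition is
#' exhaustive and mutually exclusive. All arguments are vectorized.
#'
#' @param start,end 1-based inclusive span on the CCA-appended mature tRNA.
#' @param body_length Genomic (pre-CCA) tRNA length `L`.
#' @param delta Boundary tolerance in nt (default 3).
#' @return Character vector in
#'   `c("five_prime", "inner", "three_prime", "three_prime_cca")`.
#' @export
classify_tsrna_subtype <- function(start, end, body_length, delta = 3L) {
  n <- max(length(start), length(end), length(body_length))
  start <- rep_len(start, n); end <- rep_len(end, n)
  body_length <- rep_len(body_length, n)
  if (any(start < 1L | end > body_length + 3L | start > end)) {
    abort("fragment span outside [1, body_length + 3]")
  }
  dplyr::case_when(
    start <= delta ~ "five_prime",
    end >= body_length + 1L ~ "three_prime_cca",
    end >= body_length - delta + 1L ~ "three_prime",
    TRUE ~ "inner"
  )
}

# reported grouping used in composition figures: 3' and 3'CCA are combined
tsrna_reported_group <- function(subtype) {
  dplyr::case_match(subtype,
    "five_prime" ~ "5p", "inner" ~ "inner",
    c("three_prime", "three_prime_cca") ~ "3pCCA"
  )
}

#' Most-specific parent assignment within the nested rRNA hierarchy
#'
#' A read hitting both the 45S precursor and an embedded mature subunit
#' (18S, 5.8S, 28S) belongs to the subunit; only reads matching exclusively
#' precursor (spacer) sequence remain on 45S.
#'
#' @param parent_ids Character vector of rRNA parent hits for one read.
#' @return A single parent id.
#' @export
assign_rsrna_parent <- function(parent_ids) {
  if (length(parent_ids) == 0L) abort("empty rRNA hit list")
  mature <- setdiff(parent_ids, "RNA45S")
  if (length(mature)) mature[1] else "RNA45S"
}

# resolve the third argument of coverage_profile to a parent length
parent_length_of <- function(parent, where, ann) {
  if (is.numeric(where)) return(as.integer(where))
  if (inherits(where, "snc_index")) {
    L <- unname(nchar(where$sequences[parent]))
    if (!is.na(L)) return(L)
  }
  if (inherits(where, "snc_reference")) {
    L <- where$length[where$id == parent]
    if (length(L)) return(L)
  }
  max(ann$end)
}

#' Positional coverage profile of fragments on one parent RNA
#'
#' Depth at position p is the (weighted) count of fragments covering p, so
#' the profile integrates to the total covered nucleotides:
#' `sum(depth) = sum(fragment length x count x weight)`.
#'
#' @param ann Annotation tibble; rows are restricted to `parent`.
#' @param parent Parent id.
#' @param parent_length Parent length, an `snc_index`, or an
#'   `snc_reference`; defaults to the largest fragment end observed.
#' @return A tibble of class `snc_profile` with `pos` and `depth`.
#' @export
coverage_profile <- function(ann, parent, parent_length = NULL) {
  sub <- filter(ann, .data$parent_id == parent)
  if (!"weight" %in% names(sub)) sub$weight <- 1
  if (!"count" %in% names(sub)) sub$count <- 1
  L <- parent_length_of(parent, parent_length, if (nrow(sub)) sub else tibble(end = 1L))
  depth <- numeric(L + 1L)
  if (nrow(sub)) {
    w <- sub$count * sub$weight
    # difference-array accumulation of interval coverage
    add <- rowsum(w, pmin(sub$start, L))
    depth[as.integer(rownames(add))] <- add[, 1]
    ends <- pmin(sub$end, L) + 1L
    rem <- rowsum(w, ends)
    depth[as.integer(rownames(rem))] <- depth[as.integer(rownames(rem))] - rem[, 1]
    depth <- cumsum(depth)[1:L]
  } else {
    depth <- numeric(L)
  }
  out <- tibble(pos = seq_len(L), depth = depth)
  attr(out, "parent_id") <- parent
  attr(out, "total_fragments") <- sum(sub$count * sub$weight)
  class(out) <- c("snc_profile", class(out))
  out
}

#' Call positional peaks on a coverage profile
#'
#' Peaks are maximal runs of positions whose depth reaches
#' `threshold_frac` of the profile maximum, after merging runs separated by
#' fewer than `merge_gap` nt and discarding runs narrower than `min_width`.
#' The caller is invariant to rescaling the depth by any positive constant.
#'
#' @param profile An `snc_profile` (or tibble with `pos`, `depth`).
#' @param threshold_frac Fraction of the maximum depth (default 0.25).
#' @param merge_gap Merge runs separated by fewer than this many nt.
#' @param min_width Discard called runs narrower than this.
#' @return A tibble of class `snc_peaks`, sorted by start, with
#'   `peak` (index), `start`, `end`, `summit` (position of maximal depth),
#'   `mean_height` and `share` (fraction of total parent coverage inside the
#'   peak). Empty for an all-zero profile.
#' @export
detect_peaks <- function(profile, threshold_frac = 0.25, merge_gap = 10L,
                         min_width = 10L) {
  if (nrow(profile) == 0L) abort("empty profile")
  depth <- profile$depth
  empty <- tibble(peak = integer(), start = integer(), end = integer(),
                  summit = integer(), mean_height = numeric(), share = numeric())
  if (all(depth <= 0)) return(structure(empty, class = c("snc_peaks", class(empty))))
  thr <- threshold_frac * max(depth)
  above <- depth >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0L) return(structure(empty, class = c("snc_peaks", class(empty))))
  # merge runs separated by short gaps
  merged <- runs[1, ]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start[i] - merged$end[nrow(merged)] - 1L < merge_gap) {
      merged$end[nrow(merged)] <- runs$end[i]
    } else {
      merged <- bind_rows(merged, runs[i, ])
    }
  }
  merged <- filter(merged, .data$end - .data$start + 1L >= min_width)
  tot <- sum(depth)
  out <- merged |>
    mutate(
      peak = row_number(),
      summit = map_dbl(row_number(), function(i) {
        span <- merged$start[i]:merged$end[i]
        span[which.max(depth[span])]
      }),
      mean_height = map_dbl(row_number(), function(i)
        mean(depth[merged$start[i]:merged$end[i]])),
      share = map_dbl(row_number(), function(i)
        sum(depth[merged$start[i]:merged$end[i]]) / tot)
    ) |>
    select("peak", "start", "end", "summit", "mean_height", "share")
  attr(out, "parent_id") <- attr(profile, "parent_id")
  class(out) <- c("snc_peaks", class(out))
  out
}

#' YRNA fragment composition
#'
#' Per-gene (RNY1/3/4/5) fractions of ysRNA reads and the overall 5' share;
#' a fragment counts as 5' when it starts within the first 3 nt of its
#' YRNA.
#'
#' @param ann Annotation tibble.
#' @return A list with `genes` (tibble gene, count, fraction) and
#'   `five_prime_fraction`.
#' @export
ysrna_composition <- function(ann) {
  sub <- filter(ann, .data$class == "ysRNA")
  if (nrow(sub) == 0L) abort("no ysRNA reads")
  w <- sub$count * sub$weight
  genes <- sub |>
    group_by(gene = .data$parent_id) |>
    summarise(count = sum(.data$count * .data$weight), .groups = "drop") |>
    mutate(fraction = .data$count / sum(.data$count)) |>
    arrange(desc(.data$fraction))
  list(
    genes = genes,
    five_prime_fraction = sum(w[sub$start <= 3L]) / sum(w)
  )
}

#' tsRNA composition by anticodon and cleavage group
#'
#' RPM table of tsRNA fragments cross-classified by tRNA isoacceptor
#' (amino-acid/anticodon label) and reported cleavage group (5', inner',
#' 3'+3'CCA), split into cytoplasmic and mitochondrial compartments.
#'
#' @param ann Annotation tibble.
#' @param index `snc_index` (or `snc_reference`) supplying body lengths and
#'   anticodon labels.
#' @param mapped_total RPM denominator; defaults to the annotated total.
#' @return A tibble with `compartment` (cyto/mito), `anticodon`, `group`
#'   and `rpm`.
#' @export
tsrna_composition <- function(ann, index, mapped_total = NULL) {
  if (inherits(index, "snc_reference")) index <- build_kmer_index(index)
  if (is.null(mapped_total)) {
    mapped_total <- sum((ann |> distinct(.data$read_id, .data$count))$count)
  }
  sub <- filter(ann, .data$class == "tsRNA")
  if (nrow(sub) == 0L) {
    return(tibble(compartment = character(), anticodon = character(),
                  group = character(), rpm = numeric()))
  }
  sub |>
    mutate(
      compartment = unname(ifelse(index$category[.data$parent_id] == "tRNA", "cyto", "mito")),
      anticodon = unname(index$subcategory[.data$parent_id]),
      group = tsrna_reported_group(classify_tsrna_subtype(
        .data$start, .data$end, unname(index$body_length[.data$parent_id])
      ))
    ) |>
    group_by(.data$compartment, .data$anticodon, .data$group) |>
    summarise(rpm = rpm_normalize(sum(.data$count * .data$weight), mapped_total),
              .groups = "drop")
}
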