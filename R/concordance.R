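#' Pearson correlation with validity checks
#'
#' Standard product-moment correlation; errors on vectors shorter than 3 or
#' constant vectors, where r is undefined.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pairwise_pearson <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3L) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("correlation undefined for a constant vector")
  cor(x, y)
}

#' Paired blood/marrow expression profiles
#'
#' Extracts, per subject with both compartments, the `log10(RPM + 1)`
#' feature vectors of the PBS and BMS samples. Features detected (count >
#' 0) in fewer than half of the paired samples are dropped to avoid
#' zero-inflation artifacts.
#'
#' @param cohort A paired `snc_cohort` (or a list with `counts`, `samples`,
#'   `features` of the same shape).
#' @param classes Restrict to these fragment classes (default: all but
#'   spike-in).
#' @return Long tibble `subject`, `feature_id`, `class`, `pbs`, `bms`.
#' @export
paired_profiles <- function(cohort, classes = NULL) {
  s <- cohort$samples
  paired <- s |>
    group_by(.data$subject) |>
    filter(all(c("PBS", "BMS") %in% .data$compartment)) |>
    ungroup()
  if (length(unique(paired$subject)) < 3L) abort("need at least 3 paired subjects")
  lg <- log10(sweep(cohort$counts, 2, colSums(cohort$counts), "/") * 1e6 + 1)
  keep_cls <- classes %||% setdiff(unique(cohort$features$class), "spike_in")
  fids <- cohort$features$feature_id[cohort$features$class %in% keep_cls]
  fids <- intersect(fids, rownames(cohort$counts))
  detected <- rowMeans(cohort$counts[fids, paired$sample, drop = FALSE] > 0) >= 0.5
  fids <- fids[detected]
  cls <- setNames(cohort$features$class, cohort$features$feature_id)
  map_dfr(unique(paired$subject), function(su) {
    sp <- paired$sample[paired$subject == su & paired$compartment == "PBS"]
    sb <- paired$sample[paired$subject == su & paired$compartment == "BMS"]
    tibble(subject = su, feature_id = fids, class = unname(cls[fids]),
           pbs = lg[fids, sp], bms = lg[fids, sb])
  })
}

#' Blood/bone-marrow concordance of one fragment class
#'
#' Pools the `(feature, subject)` points of a class across paired samples
#' and reports the pooled Pearson correlation between PBS and BMS
#' `log10(RPM + 1)` values, together with the per-subject correlation
#' distribution.
#'
#' @param cohort A paired `snc_cohort`.
#' @param class Fragment class (e.g. "miRNA", "tsRNA", "ysRNA", "rsRNA"),
#'   or `NULL` for all classes pooled.
#' @return A list of class `snc_concordance`: `class`, `r` (pooled),
#'   `n_features`, `n_subjects`, `per_subject` (tibble subject, r).
#' @export
category_concordance <- function(cohort, class = NULL) {
  prof <- paired_profiles(cohort, classes = class)
  if (nrow(prof) == 0L) abort(paste("no features of class", class))
  if (length(unique(prof$feature_id)) < 3L) abort("fewer than 3 usable features")
  per_subject <- prof |>
    group_by(.data$subject) |>
    summarise(r = tryCatch(pairwise_pearson(.data$pbs, .data$bms),
                           error = function(e) NA_real_),
              .groups = "drop")
  structure(list(
    class = class %||% "all",
    r = pairwise_pearson(prof$pbs, prof$bms),
    n_features = length(unique(prof$feature_id)),
    n_subjects = length(unique(prof$subject)),
    per_subject = per_subject
  ), class = "snc_concordance")
}

#' @export
print.snc_concordance <- function(x, ...) {
  cat(sprintf("<snc_concordance> %s: pooled r = %.3f (%d features, %d subjects)\n",
              x$class, x$r, x$n_features, x$n_subjects))
  invisible(x)
}

#' Concordance across all fragment classes
#'
#' @param cohort A paired `snc_cohort`.
#' @param classes Classes to evaluate; defaults to those present (spike-in
#'   excluded).
#' @return Tibble `class`, `r`, `mean_subject_r`, `n_features`,
#'   `n_subjects`.
#' @export
concordance_by_class <- function(cohort, classes = NULL) {
  classes <- classes %||% setdiff(unique(cohort$features$class), "spike_in")
  map_dfr(classes, function(cl) {
    cc <- tryCatch(category_concordance(cohort, cl), error = function(e) NULL)
    if (is.null(cc)) return(NULL)
    tibble(class = cl, r = cc$r,
           mean_subject_r = mean(cc$per_subject$r, na.rm = TRUE),
           n_features = cc$n_features, n_subjects = cc$n_subjects)
  })
}
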