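#' Univariate logistic regression with Wald test
#'
#' Fits `label ~ value` with an intercept by iteratively reweighted least
#' squares (at most 50 iterations, tolerance 1e-8) and reports the slope
#' coefficient with its two-sided Wald p-value. Complete separation —
#' detected as non-convergence, a diverging slope (|coefficient| > 20 on
#' the log2-RPM scale) or a saturated fit — is flagged and assigned the
#' smallest representable
#' positive p, since a perfectly separating marker is maximally, not
#' minimally, informative. A constant feature yields coefficient 0, p = 1.
#'
#' @param values Numeric per-sample feature values (log2(RPM+1) in the
#'   selection pipeline).
#' @param labels Two-level vector; the second level is the event.
#' @return A list: `coefficient`, `se`, `p`, `separation`.
#' @export
logistic_wald <- function(values, labels) {
  y <- as.integer(factor(labels)) - 1L
  if (length(unique(y)) < 2L) abort("both classes must be present")
  if (var(values) == 0) {
    return(list(coefficient = 0, se = Inf, p = 1, separation = FALSE))
  }
  fit <- suppressWarnings(glm(y ~ values, family = binomial(),
                              control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  b <- unname(coef(fit)[2])
  se <- sqrt(diag(vcov(fit)))[2]
  # complete separation = divergent MLE: IRLS non-convergence, a runaway
  # slope, or a saturated fit (deviance ~ 0, the Albert-Anderson condition;
  # IRLS can stop "converged" there with the slope still finite)
  separation <- !fit$converged || !is.finite(b) || abs(b) > 20 ||
    fit$deviance < 1e-6
  if (separation) {
    return(list(coefficient = b, se = unname(se), p = .Machine$double.xmin,
                separation = TRUE))
  }
  z <- b / se
  list(coefficient = b, se = unname(se),
       p = unname(2 * stats::pnorm(-abs(z))), separation = FALSE)
}

#' Three-criterion marker-panel selection
#'
#' Selects, within one fragment class, the features satisfying all of:
#' (1) significant differential expression (`p <= 0.05` and
#' `|log2FC| >= 1` from the NB exact test), (2) mean expression above
#' `min_mean_expression` RPM across the discovery samples, and
#' (3) `p < logreg_alpha` in a univariate logistic regression of group on
#' `log2(RPM + 1)`. Selection is deterministic given its inputs and must be
#' run on the discovery cohort only.
#'
#' @param counts Count matrix or wide tibble (discovery cohort).
#' @param samples Discovery sample sheet (`sample`, `group`).
#' @param de `snc_de` results computed on the same discovery cohort.
#' @param class Fragment class to select within (e.g. "tsRNA", "miRNA").
#' @param feature_classes Tibble `feature_id`, `class` (defaults to the
#'   `class` column of `de` if present).
#' @param min_mean_expression Mean-RPM threshold (default 10).
#' @param logreg_alpha Logistic Wald significance level (default 0.05).
#' @return A tibble of selected features with the per-criterion columns
#'   (`de_significant`, `mean_rpm`, `logreg_p`, `separation`); zero rows
#'   (with a warning) when nothing passes.
#' @export
select_signature <- function(counts, samples, de, class,
                             feature_classes = NULL,
                             min_mean_expression = 10, logreg_alpha = 0.05) {
  m <- as_count_matrix(counts)
  samples <- as_tibble(samples)
  m <- m[, samples$sample, drop = FALSE]
  if (is.null(feature_classes)) {
    if (!"class" %in% names(de)) abort("feature_classes required when de lacks a class column")
    feature_classes <- select(as_tibble(de), "feature_id", "class")
  }
  ids <- feature_classes$feature_id[feature_classes$class == class]
  rpm <- sweep(m, 2, colSums(m), "/") * 1e6
  cand <- tibble(feature_id = intersect(ids, rownames(m))) |>
    left_join(select(as_tibble(de), "feature_id", "log2fc", "p", "significant"),
              by = "feature_id") |>
    mutate(
      de_significant = dplyr::coalesce(.data$significant, FALSE),
      mean_rpm = rowMeans(rpm)[.data$feature_id]
    )
  lw <- map(cand$feature_id, function(f) {
    logistic_wald(log2(rpm[f, ] + 1), samples$group == "AML")
  })
  cand <- cand |>
    mutate(
      logreg_p = map_dbl(lw, "p"),
      separation = purrr::map_lgl(lw, "separation"),
      selected = .data$de_significant &
        .data$mean_rpm > min_mean_expression &
        .data$logreg_p < logreg_alpha
    )
  out <- filter(cand, .data$selected) |>
    select("feature_id", "log2fc", "p", "de_significant", "mean_rpm",
           "logreg_p", "separation")
  if (nrow(out) == 0L) warn(sprintf("no %s features passed all three criteria", class))
  out
}

#' Train a bagged-tree classifier and report out-of-bag behaviour
#'
#' Bootstrap-aggregated decision trees with `floor(sqrt(panel size))`
#' candidate features per split; each sample's OOB score is the fraction of
#' trees not trained on it that vote AML, and the OOB error is the
#' misclassification rate at score 0.5. Deterministic given `seed`.
#'
#' @param x Matrix/data frame of per-sample feature values (samples x
#'   features, log2(RPM+1) in the pipeline).
#' @param labels Two-level vector (`control`/`AML`; AML is the event).
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return A list of class `snc_forest`: `model`, `oob_scores`,
#'   `oob_error`, `importance` (mean decrease in Gini impurity), `n_trees`.
#' @export
train_and_oob <- function(x, labels, n_trees = 500, seed = 1) {
  x <- as.data.frame(x)
  if (ncol(x) == 0L) abort("empty feature panel")
  y <- factor(ifelse(labels == "AML" | labels == TRUE | labels == 1, "AML", "control"),
              levels = c("control", "AML"))
  if (length(unique(y)) < 2L) abort("both classes must be present")
  withr::local_seed(seed)
  rf <- randomForest::randomForest(
    x = x, y = y, ntree = n_trees,
    mtry = max(1L, floor(sqrt(ncol(x)))), importance = FALSE
  )
  scores <- rf$votes[, "AML"]
  pred <- ifelse(scores >= 0.5, "AML", "control")
  structure(list(
    model = rf,
    oob_scores = unname(scores),
    oob_error = mean(pred != as.character(y)),
    importance = setNames(rf$importance[, "MeanDecreaseGini"], colnames(x)),
    n_trees = n_trees
  ), class = "snc_forest")
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a case outranks a control,
#' counting ties as one half; identical to the trapezoidal area under the
#' empirical ROC curve, and invariant under strictly increasing transforms
#' of the scores.
#'
#' @param scores Numeric classification scores.
#' @param labels Two-level vector; `AML`/`TRUE`/1 marks cases.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "AML" | labels == TRUE | labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @param scores,labels As in [roc_auc()].
#' @return Tibble `threshold`, `fpr`, `tpr` sorted for plotting.
#' @export
roc_points <- function(scores, labels) {
  pos <- labels == "AML" | labels == TRUE | labels == 1
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  map_dfr(thr, function(t) {
    tibble(threshold = t,
           fpr = sum(scores >= t & !pos) / sum(!pos),
           tpr = sum(scores >= t & pos) / sum(pos))
  })
}

#' Select and evaluate class-specific marker panels
#'
#' Runs the full discovery/validation protocol per fragment class: DE and
#' three-criterion selection on the discovery cohort only, bagged-tree
#' training with OOB scoring on discovery, and prediction on the held-out
#' validation cohort. The validation cohort must be sample-disjoint from
#' discovery and its labels never influence selection or training.
#' `shuffle_labels = TRUE` permutes the discovery training labels after
#' selection (the panel is kept), giving the null control for the AUC.
#'
#' @param discovery,validation `snc_cohort` objects sharing a feature
#'   panel.
#' @param classes Fragment classes to evaluate (default tsRNA and miRNA).
#' @param n_trees,seed Forest settings.
#' @param min_mean_expression,logreg_alpha Selection thresholds.
#' @param de Optional precomputed discovery `snc_de` (recomputed if NULL).
#' @param shuffle_labels Permute discovery training labels (null control).
#' @return A list of class `snc_panel_report`, one element per class, each
#'   with `panel`, `forest`, `oob_error`, `auc_discovery`,
#'   `auc_validation`, `validation_scores`, `importance`.
#' @export
evaluate_panels <- function(discovery, validation,
                            classes = c("tsRNA", "miRNA"),
                            n_trees = 500, seed = 1,
                            min_mean_expression = 10, logreg_alpha = 0.05,
                            de = NULL, shuffle_labels = FALSE) {
  if (length(intersect(discovery$samples$sample, validation$samples$sample))) {
    abort("validation cohort overlaps discovery cohort")
  }
  fm <- select(discovery$features, "feature_id", "class")
  if (is.null(de)) {
    de <- run_de(discovery$counts, discovery$samples, feature_meta = fm)
  }
  rpm_d <- cohort_rpm(discovery, log2 = TRUE)
  rpm_v <- cohort_rpm(validation, log2 = TRUE)
  lab_d <- discovery$samples$group
  lab_v <- validation$samples$group
  train_lab <- if (shuffle_labels) {
    withr::with_seed(derive_seed(seed, 99), sample(lab_d)) } else lab_d

  out <- map(setNames(classes, classes), function(cl) {
    panel <- select_signature(discovery$counts, discovery$samples, de, cl,
                              feature_classes = fm,
                              min_mean_expression = min_mean_expression,
                              logreg_alpha = logreg_alpha)
    if (nrow(panel) == 0L) {
      warn(sprintf("class %s: empty panel, no classifier trained", cl))
      return(list(class = cl, panel = panel, forest = NULL, oob_error = NA_real_,
                  auc_discovery = NA_real_, auc_validation = NA_real_,
                  validation_scores = NULL, importance = NULL))
    }
    xd <- t(rpm_d[panel$feature_id, , drop = FALSE])
    fit <- train_and_oob(xd, train_lab, n_trees = n_trees, seed = derive_seed(seed, 41))
    xv <- t(rpm_v[panel$feature_id, , drop = FALSE])
    sv <- predict(fit$model, as.data.frame(xv), type = "prob")[, "AML"]
    list(
      class = cl, panel = panel, forest = fit,
      oob_error = fit$oob_error,
      auc_discovery = roc_auc(fit$oob_scores, lab_d),
      auc_validation = roc_auc(sv, lab_v),
      validation_scores = unname(sv),
      validation_labels = lab_v,
      importance = fit$importance
    )
  })
  class(out) <- "snc_panel_report"
  out
}

#' @export
print.snc_panel_report <- function(x, ...) {
  print(glance.snc_panel_report(x))
  invisible(x)
}

#' One row per evaluated panel
#'
#' @param x `snc_panel_report`.
#' @param ... Unused.
#' @return Tibble `class`, `panel_size`, `oob_error`, `auc_discovery`,
#'   `auc_validation`.
#' @export
glance.snc_panel_report <- function(x, ...) {
  map_dfr(x, function(r) tibble(
    class = r$class, panel_size = nrow(r$panel), oob_error = r$oob_error,
    auc_discovery = r$auc_discovery, auc_validation = r$auc_validation
  ))
}

#' Per-feature rows of a panel report
#'
#' @param x `snc_panel_report`.
#' @param ... Unused.
#' @return Tibble with one row per selected feature and its importance.
#' @export
tidy.snc_panel_report <- function(x, ...) {
  map_dfr(x, function(r) {
    if (nrow(r$panel) == 0L) return(NULL)
    r$panel |>
      mutate(class = r$class,
             importance = unname(r$importance[.data$feature_id])) |>
      select("class", "feature_id", "log2fc", "mean_rpm", "logreg_p",
             "separation", "importance")
  })
}
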