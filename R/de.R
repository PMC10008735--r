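## Count-model differential expression: trimmed-mean normalization, a
## moment-based common dispersion, and a conditional negative-binomial exact
## test on group sums (Poisson/binomial limit at phi = 0). Written to stand
## alone so every step is testable against enumeration oracles.

# accept a features x samples matrix or a wide tibble with feature_id
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  if (is.data.frame(counts)) {
    fid <- counts[["feature_id"]]
    m <- as.matrix(counts[setdiff(names(counts), c("feature_id", "class"))])
    rownames(m) <- fid
    return(m)
  }
  abort("counts must be a matrix or a wide data frame with feature_id")
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes, per sample, the weighted trimmed mean of per-feature log2
#' ratios (M-values) against a reference sample, after trimming the most
#' extreme 30% of M-values and 5% of A-values; weights are inverse
#' asymptotic variances on the proportion scale (scale-free per library, so
#' rescaling a sample's counts leaves its factor — and downstream p-values —
#' exactly unchanged). Factors are rescaled to geometric mean 1;
#' `effective library size = raw total x factor`.
#'
#' @param counts Count matrix (features x samples) or wide tibble.
#' @param reference_sample Column name of the reference sample; by default
#'   the sample whose upper quartile of scaled counts is closest to the
#'   mean upper quartile.
#' @param trim_m,trim_a Two-sided trim fractions (defaults 0.30 and 0.05).
#' @return A tibble `sample`, `lib_size`, `factor`, `effective_size`.
#' @export
tmm_factors <- function(counts, reference_sample = NULL,
                        trim_m = 0.30, trim_a = 0.05) {
  m <- as_count_matrix(counts)
  if (ncol(m) < 2L) abort("need at least 2 samples")
  lib <- colSums(m)
  if (any(lib == 0)) abort("sample with all-zero counts")
  if (is.null(reference_sample)) {
    uq <- apply(sweep(m, 2, lib, "/"), 2, quantile, probs = 0.75)
    reference_sample <- colnames(m)[which.min(abs(uq - mean(uq)))]
  }
  r <- m[, reference_sample]
  Nr <- lib[reference_sample]
  f <- vapply(colnames(m), function(s) {
    x <- m[, s]; N <- lib[s]
    keep <- x > 0 & r > 0
    if (!any(keep)) return(1)
    M <- log2((x[keep] / N) / (r[keep] / Nr))
    A <- 0.5 * log2((x[keep] / N) * (r[keep] / Nr))
    # precision weights on the proportion scale; scale-free in each library
    # so that rescaling a whole sample leaves its factor unchanged
    w <- (N - x[keep]) / x[keep] + (Nr - r[keep]) / r[keep]
    loM <- quantile(M, trim_m); hiM <- quantile(M, 1 - trim_m)
    loA <- quantile(A, trim_a); hiA <- quantile(A, 1 - trim_a)
    in_trim <- M >= loM & M <= hiM & A >= loA & A <= hiA
    if (!any(in_trim) || all(w[in_trim] == 0)) return(1)
    2^(sum(M[in_trim] / w[in_trim]) / sum(1 / w[in_trim]))
  }, 1)
  f <- f / exp(mean(log(f)))   # geometric mean 1
  out <- tibble(sample = colnames(m), lib_size = unname(lib), factor = unname(f),
                effective_size = unname(lib * f))
  attr(out, "reference_sample") <- reference_sample
  out
}

#' Moment estimate of the common negative-binomial dispersion
#'
#' Counts are scaled to a common effective library size; within each group
#' the per-feature moment estimate `(variance - mean) / mean^2` is formed
#' and combined across groups (weights `n_g - 1`); the common dispersion is
#' the median of the positive per-feature estimates, or 0 when none is
#' positive. Under the count model `variance = mu + phi mu^2`.
#'
#' @param counts Count matrix or wide tibble.
#' @param groups Factor/character vector of group labels per sample.
#' @param factors Optional [tmm_factors()] output; computed when `NULL`.
#' @return A list with `phi` and the per-feature estimates `phi_feature`.
#' @export
estimate_common_dispersion <- function(counts, groups, factors = NULL) {
  m <- as_count_matrix(counts)
  groups <- as.character(groups)
  if (any(table(groups) < 2L)) abort("need at least 2 replicates per group")
  if (is.null(factors)) factors <- tmm_factors(m)
  eff <- setNames(factors$effective_size, factors$sample)[colnames(m)]
  y <- sweep(m, 2, median(eff) / eff, "*")
  num <- rep(0, nrow(m)); den <- 0
  for (g in unique(groups)) {
    yg <- y[, groups == g, drop = FALSE]
    n <- ncol(yg)
    mu <- rowMeans(yg)
    v <- apply(yg, 1, var)
    pf <- ifelse(mu > 0, (v - mu) / mu^2, 0)
    num <- num + (n - 1) * pf
    den <- den + (n - 1)
  }
  phi_f <- num / den
  pos <- phi_f[phi_f > 0 & is.finite(phi_f)]
  list(phi = if (length(pos)) median(pos) else 0, phi_feature = phi_f)
}

# conditional two-sided exact test on group sums: given total T, the
# distribution of the group-A sum under no difference is
# P(a) propto NB(a; nA/phi, nA*mu) NB(T-a; nB/phi, nB*mu), the Poisson /
# binomial limit at phi = 0. Two-sided p sums all outcomes no more probable
# than the observed one (log-concave, so the retained set is an interval).
exact_test_one <- function(sa, sb, na, nb, phi) {
  t_tot <- sa + sb
  if (t_tot == 0) return(1)
  mu <- t_tot / (na + nb)
  logp <- function(a) {
    if (phi > 0) {
      dnbinom(a, size = na / phi, mu = na * mu, log = TRUE) +
        dnbinom(t_tot - a, size = nb / phi, mu = nb * mu, log = TRUE)
    } else {
      dpois(a, na * mu, log = TRUE) + dpois(t_tot - a, nb * mu, log = TRUE)
    }
  }
  if (t_tot <= 2e5) {
    a <- 0:t_tot
    lp <- logp(a)
  } else {
    centre <- round(t_tot * na / (na + nb))
    sdev <- sqrt(t_tot * (na * nb) / (na + nb)^2 * (1 + phi * mu))
    a <- max(0, centre - ceiling(60 * sdev)):min(t_tot, centre + ceiling(60 * sdev))
    lp <- logp(a)
  }
  lp <- lp - max(lp)
  p <- exp(lp); p <- p / sum(p)
  pobs <- p[a == sa]
  if (!length(pobs)) return(.Machine$double.xmin)  # observed far outside window
  max(.Machine$double.xmin, min(1, 1 - sum(p[p > pobs * (1 + 1e-10)])))
}

#' Negative-binomial conditional exact test for one feature
#'
#' Counts are rescaled to a common effective library size and summed per
#' group; conditional on the total, the two-sided p-value is the summed
#' probability of all group-A outcomes no more probable than the observed
#' one, with group sums modelled as negative binomial with dispersion `phi`
#' (exactly `Binomial(total, 1/2)` when `phi = 0` and the groups are
#' balanced). The log2 fold change uses mean RPM with pseudocount 1.
#'
#' @param x Integer vector of counts for one feature (one per sample).
#' @param groups Two-level group vector; fold change is level 2 over
#'   level 1 (e.g. control, AML).
#' @param phi Common dispersion.
#' @param factors [tmm_factors()] tibble aligned to `x`'s samples (or
#'   `NULL` for equal libraries).
#' @return A list with `p` and `log2fc`.
#' @export
nb_exact_test <- function(x, groups, phi = 0, factors = NULL) {
  lev <- if (is.factor(groups)) levels(droplevels(groups)) else sort(unique(as.character(groups)))
  groups <- as.character(groups)
  if (length(lev) != 2L) abort("exactly two groups required")
  # baseline by name (control first when present) so that swapping the two
  # labels negates the fold change instead of silently re-anchoring it
  if ("control" %in% lev) lev <- c("control", setdiff(lev, "control"))
  eff <- if (is.null(factors)) rep(1, length(x)) else factors$effective_size
  # counts are expressed relative to the TMM reference library, so rescaling
  # any non-reference sample leaves the normalized pseudo-counts untouched
  anchor <- if (is.null(factors)) 1 else {
    rs <- attr(factors, "reference_sample")
    if (!is.null(rs) && rs %in% factors$sample) {
      factors$effective_size[factors$sample == rs]
    } else median(eff)
  }
  scl <- anchor / eff
  y <- round(x * scl)
  sa <- sum(y[groups == lev[1]]); sb <- sum(y[groups == lev[2]])
  na <- sum(groups == lev[1]); nb <- sum(groups == lev[2])
  if (sa + sb == 0) return(list(p = 1, log2fc = 0))
  rpm_a <- mean(x[groups == lev[1]] / eff[groups == lev[1]]) * 1e6
  rpm_b <- mean(x[groups == lev[2]] / eff[groups == lev[2]]) * 1e6
  list(
    p = exact_test_one(sa, sb, na, nb, phi),
    log2fc = log2((rpm_b + 1) / (rpm_a + 1))
  )
}

#' Differential expression across a count matrix
#'
#' Runs TMM normalization, common-dispersion estimation and the NB exact
#' test per feature, and calls significance at the case-control criterion
#' `p <= 0.05 & |log2FC| >= 1`. No multiple-testing correction is applied to
#' the call; a Benjamini-Hochberg `fdr` column is emitted for information.
#'
#' @param counts Count matrix or wide tibble (features x samples).
#' @param samples Sample sheet with columns `sample` and `group`; the first
#'   factor level (or first unique value) is the baseline group.
#' @param alpha,lfc_threshold Significance thresholds (defaults 0.05, 1).
#' @param phi Common dispersion; estimated when `NULL`.
#' @param feature_meta Optional tibble with `feature_id` (+ e.g. `class`)
#'   joined onto the result.
#' @return A tibble of class `snc_de`: `feature_id`, `log2fc`, `p`, `fdr`,
#'   `significant`, `direction` plus any metadata columns.
#' @export
run_de <- function(counts, samples, alpha = 0.05, lfc_threshold = 1,
                   phi = NULL, feature_meta = NULL) {
  m <- as_count_matrix(counts)
  samples <- as_tibble(samples)
  m <- m[, samples$sample, drop = FALSE]
  groups <- as.character(samples$group)
  factors <- tmm_factors(m)
  rs <- attr(factors, "reference_sample")
  factors <- factors[match(colnames(m), factors$sample), ]
  attr(factors, "reference_sample") <- rs
  if (is.null(phi)) phi <- estimate_common_dispersion(m, groups, factors)$phi
  res <- map_dfr(seq_len(nrow(m)), function(i) {
    r <- nb_exact_test(m[i, ], groups, phi, factors)
    tibble(feature_id = rownames(m)[i], log2fc = r$log2fc, p = r$p)
  })
  out <- res |>
    mutate(
      fdr = p.adjust(.data$p, "BH"),
      significant = .data$p <= alpha & abs(.data$log2fc) >= lfc_threshold,
      direction = dplyr::case_when(
        !.data$significant ~ "ns",
        .data$log2fc > 0 ~ "up",
        TRUE ~ "down"
      )
    )
  if (!is.null(feature_meta)) out <- left_join(out, feature_meta, by = "feature_id")
  attr(out, "phi") <- phi
  attr(out, "alpha") <- alpha
  attr(out, "lfc_threshold") <- lfc_threshold
  class(out) <- c("snc_de", class(out))
  out
}

#' Summarize differential-expression calls
#'
#' @param results An `snc_de` tibble (or any tibble with `significant` and
#'   `direction`).
#' @return A one-row tibble: `n_features`, `n_significant`, `n_up`,
#'   `n_down`, `frac_up`, `frac_down`.
#' @export
call_de <- function(results) {
  tibble(
    n_features = nrow(results),
    n_significant = sum(results$significant),
    n_up = sum(results$direction == "up"),
    n_down = sum(results$direction == "down"),
    frac_up = sum(results$direction == "up") / nrow(results),
    frac_down = sum(results$direction == "down") / nrow(results)
  )
}

#' @export
glance.snc_de <- function(x, ...) call_de(x)
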