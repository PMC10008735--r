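#' Cohort design configuration
#'
#' Parameters of the synthetic case-control (AML vs control) cohort
#' generator. Counts are simulated at the feature level with a lognormal
#' subject latent whose variance matches the negative-binomial dispersion
#' (`variance = mu + phi mu^2`), then expanded to reads on demand. In paired
#' designs the blood (PBS) and marrow (BMS) samples of a subject mix a
#' shared latent log-expression vector with compartment noise according to
#' `bms_shared_signal_fraction`.
#'
#' @param n_control,n_aml Subjects per group (each at least 2).
#' @param paired_bms When `TRUE`, every subject contributes a PBS and a BMS
#'   sample.
#' @param de_effects Named numeric vector: feature id -> log2 fold change
#'   applied in AML samples.
#' @param nb_dispersion Dispersion `phi` (squared biological CV).
#' @param library_size_range Uniform range of per-sample read totals.
#' @param spike_in_count Exact spike-in reads added to every library.
#' @param bms_shared_signal_fraction Fraction of the subject latent shared
#'   between compartments, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list of class `snc_cohort_config`.
#' @export
default_cohort <- function(n_control = 12, n_aml = 30, paired_bms = FALSE,
                           de_effects = numeric(0), nb_dispersion = 0.1,
                           library_size_range = c(8e5, 1.2e6),
                           spike_in_count = 1e4,
                           bms_shared_signal_fraction = 0.8, seed = 42) {
  cfg <- list(
    n_control = n_control, n_aml = n_aml, paired_bms = paired_bms,
    de_effects = de_effects, nb_dispersion = nb_dispersion,
    library_size_range = library_size_range, spike_in_count = spike_in_count,
    bms_shared_signal_fraction = bms_shared_signal_fraction, seed = seed
  )
  if (n_control < 2 || n_aml < 2) abort("n_control and n_aml must be >= 2")
  if (nb_dispersion < 0) abort("nb_dispersion must be >= 0")
  if (spike_in_count <= 0) abort("spike_in_count must be > 0")
  if (bms_shared_signal_fraction < 0 || bms_shared_signal_fraction > 1) {
    abort("bms_shared_signal_fraction must lie in [0, 1]")
  }
  class(cfg) <- "snc_cohort_config"
  cfg
}

#' Build the expressible fragment panel of a synthetic cohort
#'
#' Draws fragments from the mixture, deduplicates them by origin, keeps a
#' fixed number per class and assigns base expression proportions: the
#' class share from the mixture split within class by a symmetric Dirichlet
#' (concentration `alpha`, so within-class abundances are near-even and the
#' class totals reproduce the configured serum composition).
#'
#' @param ref `snc_reference`.
#' @param cfg `snc_mixture`.
#' @param n_per_class Named integer vector of features retained per class.
#' @param alpha Dirichlet concentration of within-class abundances.
#' @param seed Integer seed.
#' @return A tibble panel: `feature_id`, `class`, `parent_id`, `start`,
#'   `end`, `cca_appended`, `sequence`, `base_prop`.
#' @export
build_feature_panel <- function(ref, cfg = default_mixture(),
                                n_per_class = c(rsRNA = 60, ysRNA = 20, tsRNA = 40,
                                                miRNA = 50, piRNA = 24, other_ncRNA = 10),
                                alpha = 200, seed = 1) {
  frags <- sample_fragments(ref, cfg, n = 60L * sum(n_per_class), seed = derive_seed(seed, 11))
  panel <- frags |>
    distinct(.data$class, .data$parent_id, .data$start, .data$end,
             .data$cca_appended, .data$sequence) |>
    group_by(.data$class) |>
    slice_head(n = max(n_per_class)) |>
    ungroup()
  panel <- map_dfr(names(n_per_class), function(cl) {
    panel |> filter(.data$class == cl) |> slice_head(n = n_per_class[[cl]])
  })
  withr::local_seed(derive_seed(seed, 12))
  panel <- panel |>
    group_by(.data$class) |>
    mutate(base_prop = {
      g <- rgamma(n(), shape = alpha)
      unname(cfg$class_proportions[.data$class[1]]) * g / sum(g)
    }) |>
    ungroup() |>
    mutate(
      base_prop = .data$base_prop / sum(.data$base_prop),
      feature_id = paste0(.data$class, ":", .data$parent_id, ":",
                          .data$start, "-", .data$end)
    ) |>
    select("feature_id", "class", "parent_id", "start", "end",
           "cca_appended", "sequence", "base_prop")
  panel
}

#' Simulate a case-control (optionally paired-compartment) cohort
#'
#' Per sample, feature counts are Poisson draws around
#' `library_size x proportion x latent`, where the lognormal latent has
#' variance `log(1 + phi)` so the marginal count law matches a negative
#' binomial with dispersion `phi`; AML samples shift the configured DE
#' features by their log2 fold change. In paired designs the latent of a
#' subject's BMS sample shares a fraction `rho = bms_shared_signal_fraction`
#' of its variance with the PBS latent
#' (`z = sqrt(rho) u_subject + sqrt(1 - rho) e_sample`). Every library
#' additionally carries exactly `spike_in_count` spike-in reads.
#'
#' @param ccfg `snc_cohort_config` from [default_cohort()].
#' @param ref `snc_reference`.
#' @param mcfg `snc_mixture`.
#' @param panel Optional pre-built panel from [build_feature_panel()]
#'   (reuse it to simulate discovery and validation cohorts over the same
#'   feature space).
#' @param sample_prefix Prefix for sample ids (used to keep cohorts
#'   disjoint).
#' @return An object of class `snc_cohort`: `counts` (integer matrix
#'   features x samples), `samples` (sample sheet: sample, subject, group,
#'   compartment, lib_size), `features` (panel + `log2fc`, `is_de`), and
#'   `config`.
#' @export
simulate_cohort <- function(ccfg = default_cohort(), ref,
                            mcfg = default_mixture(), panel = NULL,
                            sample_prefix = "s") {
  if (is.null(panel)) panel <- build_feature_panel(ref, mcfg, seed = ccfg$seed)
  unknown <- setdiff(names(ccfg$de_effects), panel$feature_id)
  if (length(unknown)) {
    abort(paste("de_effects name unknown features:", paste(unknown, collapse = ", ")))
  }
  withr::local_seed(derive_seed(ccfg$seed, 21))

  lfc <- setNames(rep(0, nrow(panel)), panel$feature_id)
  lfc[names(ccfg$de_effects)] <- ccfg$de_effects

  subjects <- tibble(
    subject = c(sprintf("%s_ctrl_%02d", sample_prefix, seq_len(ccfg$n_control)),
                sprintf("%s_aml_%02d", sample_prefix, seq_len(ccfg$n_aml))),
    group = rep(c("control", "AML"), c(ccfg$n_control, ccfg$n_aml))
  )
  compartments <- if (ccfg$paired_bms) c("PBS", "BMS") else "PBS"
  samples <- tidyr::crossing(subjects, compartment = compartments) |>
    mutate(sample = paste0(.data$subject, "_", .data$compartment)) |>
    arrange(match(.data$subject, subjects$subject), desc(.data$compartment == "PBS"))

  nf <- nrow(panel)
  phi <- ccfg$nb_dispersion
  sigma <- sqrt(log1p(phi))
  rho <- ccfg$bms_shared_signal_fraction

  u_subj <- matrix(rnorm(nf * nrow(subjects)), nf, nrow(subjects),
                   dimnames = list(panel$feature_id, subjects$subject))
  counts <- matrix(0L, nf + 1L, nrow(samples),
                   dimnames = list(c(panel$feature_id, "spike_in:spike-cel-miR-39"),
                                   samples$sample))
  lib_drawn <- numeric(nrow(samples))
  for (j in seq_len(nrow(samples))) {
    lib <- round(runif(1, ccfg$library_size_range[1], ccfg$library_size_range[2]))
    lib_drawn[j] <- lib
    p <- panel$base_prop
    if (samples$group[j] == "AML") p <- p * 2^lfc
    z <- if (ccfg$paired_bms) {
      sqrt(rho) * u_subj[, samples$subject[j]] + sqrt(1 - rho) * rnorm(nf)
    } else {
      rnorm(nf)
    }
    mu <- lib * p * exp(sigma * z - sigma^2 / 2)
    counts[seq_len(nf), j] <- rpois(nf, mu)
    counts[nf + 1L, j] <- as.integer(ccfg$spike_in_count)
  }
  samples$lib_size <- colSums(counts)

  features <- panel |>
    bind_rows(tibble(feature_id = "spike_in:spike-cel-miR-39", class = "spike_in",
                     parent_id = "spike-cel-miR-39", start = 1L,
                     end = nchar(ref$sequence[ref$category == "spike_in"][1]),
                     cca_appended = FALSE,
                     sequence = ref$sequence[ref$category == "spike_in"][1],
                     base_prop = 0)) |>
    mutate(log2fc = unname(c(lfc, 0)[match(.data$feature_id, c(names(lfc), "spike_in:spike-cel-miR-39"))]),
           is_de = .data$log2fc != 0)

  structure(list(counts = counts, samples = as_tibble(samples),
                 features = features, config = ccfg),
            class = "snc_cohort")
}

#' Expand a simulated sample to individual reads
#'
#' @param cohort `snc_cohort`.
#' @param sample Sample id.
#' @return A tibble `read_id`, `sequence`, `feature_id` (feature order).
#' @export
cohort_reads <- function(cohort, sample) {
  if (!sample %in% colnames(cohort$counts)) abort("unknown sample")
  x <- cohort$counts[, sample]
  idx <- rep(seq_along(x), x)
  seqs <- cohort$features$sequence[idx]
  tibble(
    read_id = sprintf("%s_read_%07d", sample, seq_along(idx)),
    sequence = seqs,
    feature_id = cohort$features$feature_id[idx]
  )
}

#' Default synthetic AML study: discovery and validation cohorts
#'
#' Builds one feature panel, plants the study's marker effects (a compact
#' 6-feature tsRNA panel with strong effects, |log2FC| about 3.0-3.4, and a
#' broader 16-feature miRNA set with moderate effects, |log2FC| = 1.25) and
#' simulates disjoint discovery (30 AML + 12 control) and validation
#' (20 AML + 10 control) cohorts over the same feature space.
#'
#' @param ref `snc_reference`.
#' @param seed Integer seed.
#' @param mcfg `snc_mixture`.
#' @param n_discovery,n_validation Two-element vectors `(n_aml, n_control)`.
#' @return A list with `discovery`, `validation` (both `snc_cohort`),
#'   `panel`, and `effects` (named log2 fold changes).
#' @export
default_aml_study <- function(ref, seed = 42, mcfg = default_mixture(),
                              n_discovery = c(30, 12), n_validation = c(20, 10)) {
  panel <- build_feature_panel(ref, mcfg, seed = derive_seed(seed, 31))
  ts_ids <- panel$feature_id[panel$class == "tsRNA"][1:6]
  mi_ids <- panel$feature_id[panel$class == "miRNA"][1:16]
  effects <- c(
    setNames(c(3.2, 3.0, -3.0, 3.4, 3.2, -3.2), ts_ids),
    setNames(rep(c(1.25, -1.25), 8), mi_ids)
  )
  disc <- simulate_cohort(
    default_cohort(n_control = n_discovery[2], n_aml = n_discovery[1],
                   de_effects = effects, seed = derive_seed(seed, 32)),
    ref, mcfg, panel = panel, sample_prefix = "disc"
  )
  val <- simulate_cohort(
    default_cohort(n_control = n_validation[2], n_aml = n_validation[1],
                   de_effects = effects, seed = derive_seed(seed, 33)),
    ref, mcfg, panel = panel, sample_prefix = "val"
  )
  list(discovery = disc, validation = val, panel = panel, effects = effects)
}

#' @export
print.snc_cohort <- function(x, ...) {
  cat(sprintf("<snc_cohort> %d features x %d samples (%d AML / %d control)%s\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$group == "AML"), sum(x$samples$group == "control"),
              if (x$config$paired_bms) ", paired PBS/BMS" else ""))
  invisible(x)
}

#' Tidy a simulated cohort into a long count table
#'
#' @param x `snc_cohort`.
#' @param ... Unused.
#' @return Long tibble `feature_id`, `class`, `sample`, `group`,
#'   `compartment`, `subject`, `count`, `rpm`.
#' @export
tidy.snc_cohort <- function(x, ...) {
  as_tibble(x$counts, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample", values_to = "count") |>
    left_join(select(x$features, "feature_id", "class"), by = "feature_id") |>
    left_join(select(x$samples, "sample", "group", "compartment", "subject", "lib_size"),
              by = "sample") |>
    mutate(rpm = .data$count * 1e6 / .data$lib_size) |>
    select("feature_id", "class", "sample", "group", "compartment",
           "subject", "count", "rpm")
}

#' RPM matrix of a cohort
#'
#' @param cohort `snc_cohort`.
#' @param log2 Return `log2(RPM + 1)` when `TRUE`.
#' @return Numeric matrix features x samples.
#' @export
cohort_rpm <- function(cohort, log2 = FALSE) {
  m <- sweep(cohort$counts, 2, colSums(cohort$counts), "/") * 1e6
  if (log2) base::log2(m + 1) else m
}
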