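#' Default healthy-serum fragment mixture
#'
#' Encodes the composition of circulating sncRNA in healthy serum used by
#' the fragment generator: class proportions rsRNA 0.6286, ysRNA 0.1497,
#' tsRNA 0.0422, miRNA 0.0309, with the remaining 0.1486 split equally
#' between piRNA and other ncRNA; within rsRNA a 28S:18S:rest split of
#' 88:10:2; four 18S and three 28S positional peak intervals with a 10%
#' off-peak background; cytoplasmic tsRNA cleavage-position probabilities
#' 5':inner':3':3'CCA = 70:20:5:5 with mitochondrial tsRNAs skewed to
#' inner'; and 5'-dominant, RNY4-dominant ysRNAs peaking near 30 nt.
#'
#' @param seed Default seed used by [sample_fragments()] when none is given.
#' @return A list of class `snc_mixture`; see the fields in the source for
#'   the full parameterization.
#' @export
default_mixture <- function(seed = 42) {
  len_dist <- function(mean, sd) {
    p <- stats::dnorm(15:45, mean, sd)
    setNames(p / sum(p), 15:45)
  }
  cfg <- list(
    class_proportions = c(
      rsRNA = 0.6286, ysRNA = 0.1497, tsRNA = 0.0422, miRNA = 0.0309,
      piRNA = 0.0743, other_ncRNA = 0.0743
    ),
    rsrna_parent_weights = c(
      "RNA28S" = 0.88, "RNA18S" = 0.10, "RNA5S" = 0.005, "RNA5-8S" = 0.005,
      "RNA45S" = 0.004, "MT-RNR1" = 0.003, "MT-RNR2" = 0.003
    ),
    rsrna_peak_model = list(
      "RNA18S" = tibble(
        start = c(674L, 897L, 1194L, 1838L),
        end = c(692L, 919L, 1223L, 1862L),
        weight = rep(0.25, 4)
      ),
      "RNA28S" = tibble(
        start = c(1336L, 1963L, 2895L),
        end = c(1355L, 1982L, 2920L),
        weight = rep(1 / 3, 3)
      )
    ),
    rsrna_background_fraction = 0.10,
    tsrna_positional_model = list(
      cyto = c(five_prime = 0.70, inner = 0.20, three_prime = 0.05, three_prime_cca = 0.05),
      mito = c(five_prime = 0.15, inner = 0.70, three_prime = 0.10, three_prime_cca = 0.05)
    ),
    tsrna_cyto_fraction = 0.85,
    ysrna_five_prime_fraction = 0.90,
    ysrna_gene_weights = c(RNY4 = 0.55, RNY1 = 0.20, RNY3 = 0.15, RNY5 = 0.10),
    length_distribution = list(
      rsRNA = len_dist(28, 6),
      ysRNA = len_dist(30, 2.5),
      tsRNA = len_dist(32, 4),
      other_ncRNA = len_dist(30, 6)
    ),
    mutation_rate = 0,
    seed = seed
  )
  class(cfg) <- "snc_mixture"
  cfg
}

#' Validate a mixture configuration against a reference
#'
#' Checks that class proportions sum to one, all fractions lie in `[0, 1]`,
#' configured parents exist and peak intervals fall inside their parent.
#'
#' @param cfg An `snc_mixture` list.
#' @param ref An `snc_reference`.
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_mixture <- function(cfg, ref) {
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9) {
    abort("class_proportions must sum to 1")
  }
  fr <- c(cfg$rsrna_background_fraction, cfg$ysrna_five_prime_fraction,
          cfg$tsrna_cyto_fraction, unlist(cfg$tsrna_positional_model))
  if (any(fr < 0 | fr > 1)) abort("all fractions must lie in [0, 1]")
  for (m in cfg$tsrna_positional_model) {
    if (abs(sum(m) - 1) > 1e-9) abort("positional model probabilities must sum to 1")
  }
  missing_parents <- setdiff(
    c(names(cfg$rsrna_parent_weights), names(cfg$rsrna_peak_model),
      names(cfg$ysrna_gene_weights)),
    ref$id
  )
  if (length(missing_parents)) {
    abort(paste("mixture names parents absent from reference:",
                paste(missing_parents, collapse = ", ")))
  }
  for (p in names(cfg$rsrna_peak_model)) {
    pk <- cfg$rsrna_peak_model[[p]]
    L <- ref$length[ref$id == p]
    if (any(pk$start < 1 | pk$end > L | pk$start > pk$end)) {
      abort(sprintf("peak interval outside parent %s (length %d)", p, L))
    }
    if (any(pk$end - pk$start + 1 < 15)) {
      abort("peak intervals must be at least 15 nt wide to host fragments")
    }
  }
  invisible(cfg)
}
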