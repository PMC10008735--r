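## Fragment-level read generator: every read is an exact substring of its
## parent (on CCA-appended coordinates for tRNAs), with the recorded origin
## kept as ground truth for parameter-recovery tests.

# draw fragment lengths from a class length distribution truncated to
# [15, cap]; cap may be a scalar or per-draw vector
sample_lengths <- function(m, dist, cap) {
  if (m == 0L) return(integer(0))
  lens <- as.integer(names(dist))
  if (length(cap) == 1L) {
    keep <- lens <= cap
    if (!any(keep)) abort("no admissible fragment length under cap")
    sample(lens[keep], m, replace = TRUE, prob = dist[keep])
  } else {
    out <- sample(lens, m, replace = TRUE, prob = dist)
    pmin(out, as.integer(cap))
  }
}

# uniform random start for a fragment of length len inside [lo, hi] spans
runif_start <- function(lo, hi) {
  lo + floor(runif(length(lo)) * (hi - lo + 1))
}

#' Sample synthetic sncRNA fragments from a mixture configuration
#'
#' Draws `n` 15-45 nt reads from the configured fragment mixture: class
#' proportions, rsRNA parent weights and positional peak model (with
#' off-peak background), tsRNA cleavage-position model on CCA-appended
#' mature tRNAs, ysRNA gene weights and 5' dominance, and per-class length
#' distributions. Each read is an exact substring of its parent and carries
#' its true origin, so downstream annotation and characterization can be
#' scored against ground truth.
#'
#' @param ref An `snc_reference`.
#' @param cfg An `snc_mixture`, by default [default_mixture()].
#' @param n Number of reads to draw.
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return A tibble with columns `read_id`, `sequence`, `length`, `class`
#'   (true fragment class), `parent_id`, `start`, `end` (1-based inclusive
#'   on the parent, CCA-appended coordinates for tRNAs) and `cca_appended`.
#' @examples
#' ref <- build_default_reference(1)
#' frags <- sample_fragments(ref, n = 500, seed = 7)
#' table(frags$class)
#' @export
sample_fragments <- function(ref, cfg = default_mixture(), n, seed = cfg$seed) {
  stopifnot(n >= 1)
  validate_mixture(cfg, ref)
  withr::local_seed(seed)

  refseq <- setNames(ref$sequence, ref$id)
  reflen <- setNames(ref$length, ref$id)
  by_cat <- split(ref$id, ref$category)

  frag_tbl <- function(parent, start, len, cca = FALSE, seqsrc = NULL) {
    end <- start + len - 1L
    src <- if (is.null(seqsrc)) refseq[parent] else seqsrc
    tibble(
      sequence = unname(substring(src, start, end)),
      parent_id = parent, start = as.integer(start), end = as.integer(end),
      cca_appended = cca
    )
  }

  gen_background <- function(m, parents, weights, dist) {
    if (m == 0L) return(NULL)
    p <- sample(parents, m, replace = TRUE, prob = weights)
    len <- sample_lengths(m, dist, pmin(45L, reflen[p]))
    frag_tbl(p, runif_start(rep(1L, m), reflen[p] - len + 1L), len)
  }

  gen_rsrna <- function(m) {
    if (m == 0L) return(NULL)
    dist <- cfg$length_distribution$rsRNA
    w <- cfg$rsrna_parent_weights
    parent <- sample(names(w), m, replace = TRUE, prob = w)
    out <- vector("list", 0)
    for (p in unique(parent)) {
      mp <- sum(parent == p)
      if (p %in% names(cfg$rsrna_peak_model)) {
        pk <- cfg$rsrna_peak_model[[p]]
        in_peak <- runif(mp) >= cfg$rsrna_background_fraction
        npk <- sum(in_peak)
        if (npk > 0L) {
          idx <- sample(nrow(pk), npk, replace = TRUE, prob = pk$weight)
          width <- pk$end[idx] - pk$start[idx] + 1L
          len <- sample_lengths(npk, dist, width)
          out <- c(out, list(frag_tbl(rep(p, npk), runif_start(pk$start[idx], pk$end[idx] - len + 1L), len)))
        }
        if (mp - npk > 0L) out <- c(out, list(gen_background(mp - npk, p, 1, dist)))
      } else if (p == "RNA45S") {
        # precursor-only reads come from the transcribed spacers so that the
        # most-specific-parent rule leaves them on 45S
        nest <- attr(ref, "nesting")
        l45 <- reflen[["RNA45S"]]
        sub_len <- reflen[nest$unit]
        # spacer intervals: before 18S, between subunits, after 28S
        sp <- tibble(
          lo = c(1L, nest$offset + sub_len + 1L),
          hi = c(nest$offset, l45)
        )
        len <- sample_lengths(mp, dist, 45L)
        ok_width <- function(l) which(sp$hi - sp$lo + 1L >= l)
        rows <- map(len, function(l) {
          cand <- ok_width(l)
          i <- if (length(cand) > 1L) sample(cand, 1L) else cand
          s <- sp$lo[i] + floor(runif(1) * (sp$hi[i] - l + 1L - sp$lo[i] + 1L))
          c(s, l)
        })
        s <- map_dbl(rows, 1); l <- as.integer(map_dbl(rows, 2))
        out <- c(out, list(frag_tbl(rep(p, mp), as.integer(s), l)))
      } else {
        out <- c(out, list(gen_background(mp, p, 1, dist)))
      }
    }
    bind_rows(out) |> mutate(class = "rsRNA")
  }

  gen_ysrna <- function(m) {
    if (m == 0L) return(NULL)
    dist <- cfg$length_distribution$ysRNA
    w <- cfg$ysrna_gene_weights
    gene <- sample(names(w), m, replace = TRUE, prob = w)
    five <- runif(m) < cfg$ysrna_five_prime_fraction
    L <- reflen[gene]
    len <- sample_lengths(m, dist, pmin(45L, L))
    start <- integer(m)
    # 5' fragments start within the first 3 nt; 3' fragments end within the
    # last 3 nt but never start before position 4
    start[five] <- runif_start(rep(1L, sum(five)), pmin(3L, L[five] - len[five] + 1L))
    if (any(!five)) {
      e <- L[!five] - runif_start(rep(0L, sum(!five)), 2L)
      len[!five] <- pmin(len[!five], e - 3L)
      start[!five] <- e - len[!five] + 1L
    }
    frag_tbl(gene, start, len) |> mutate(class = "ysRNA")
  }

  gen_tsrna <- function(m) {
    if (m == 0L) return(NULL)
    dist <- cfg$length_distribution$tsRNA
    cyto <- runif(m) < cfg$tsrna_cyto_fraction
    pool <- ifelse(cyto, "cyto", "mito")
    parent <- character(m)
    parent[cyto] <- sample(by_cat$tRNA, sum(cyto), replace = TRUE)
    parent[!cyto] <- sample(by_cat$mt_tRNA, sum(!cyto), replace = TRUE)
    mature <- paste0(refseq[parent], "CCA")   # classification coordinates
    L <- reflen[parent]                        # body length
    subtype <- character(m)
    for (k in c("cyto", "mito")) {
      idx <- pool == k
      pm <- cfg$tsrna_positional_model[[k]]
      subtype[idx] <- sample(names(pm), sum(idx), replace = TRUE, prob = pm)
    }
    len <- sample_lengths(m, dist, 45L)
    start <- integer(m); end <- integer(m)
    i <- subtype == "five_prime"
    if (any(i)) {
      start[i] <- runif_start(rep(1L, sum(i)), 3L)
      len[i] <- pmin(len[i], L[i] - 3L - start[i] + 1L)  # keep clear of the 3' end
      end[i] <- start[i] + len[i] - 1L
    }
    i <- subtype == "inner"
    if (any(i)) {
      len[i] <- pmin(len[i], L[i] - 6L)
      start[i] <- runif_start(rep(4L, sum(i)), L[i] - 3L - len[i] + 1L)
      end[i] <- start[i] + len[i] - 1L
    }
    i <- subtype == "three_prime"
    if (any(i)) {
      end[i] <- L[i] - runif_start(rep(0L, sum(i)), 2L)
      len[i] <- pmin(len[i], end[i] - 3L)
      start[i] <- end[i] - len[i] + 1L
    }
    i <- subtype == "three_prime_cca"
    if (any(i)) {
      end[i] <- L[i] + runif_start(rep(1L, sum(i)), 3L)
      len[i] <- pmin(len[i], end[i] - 3L)
      start[i] <- end[i] - len[i] + 1L
    }
    tibble(
      sequence = unname(substring(mature, start, end)),
      parent_id = parent, start = start, end = end,
      cca_appended = end > L, class = "tsRNA"
    )
  }

  gen_full_length <- function(m, cat, cls) {
    if (m == 0L) return(NULL)
    p <- sample(by_cat[[cat]], m, replace = TRUE)
    frag_tbl(p, rep(1L, m), reflen[p]) |> mutate(class = cls)
  }

  props <- cfg$class_proportions
  cls_draw <- sample(names(props), n, replace = TRUE, prob = props)
  m_of <- function(cl) sum(cls_draw == cl)

  out <- bind_rows(
    gen_rsrna(m_of("rsRNA")),
    gen_ysrna(m_of("ysRNA")),
    gen_tsrna(m_of("tsRNA")),
    gen_full_length(m_of("miRNA"), "miRNA", "miRNA"),
    gen_full_length(m_of("piRNA"), "piRNA", "piRNA"),
    gen_background(m_of("other_ncRNA"), by_cat$other_ncRNA,
                   rep(1, length(by_cat$other_ncRNA)),
                   cfg$length_distribution$other_ncRNA) |>
      (\(x) if (is.null(x)) NULL else mutate(x, class = "other_ncRNA"))()
  )
  out <- out[sample.int(nrow(out)), ]

  if (cfg$mutation_rate > 0) {
    out$sequence <- mutate_sequences(out$sequence, cfg$mutation_rate)
  }
  out |>
    mutate(
      read_id = sprintf("read_%07d", row_number()),
      length = nchar(.data$sequence)
    ) |>
    select("read_id", "sequence", "length", "class", "parent_id",
           "start", "end", "cca_appended")
}

# optional uniform substitution noise (no indels, no adapter artefacts)
mutate_sequences <- function(seqs, rate) {
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1), "")
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}
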