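#' Synthetic parental-RNA reference
#'
#' Builds a self-contained reference set of parental RNAs covering every
#' fragment source profiled in 15-45 nt cell-free small-RNA libraries:
#' nuclear rRNAs (5S, 5.8S, 18S, 28S and a 45S precursor that embeds
#' 18S/5.8S/28S between transcribed spacers), mitochondrial 12S/16S rRNAs,
#' the four YRNAs (RNY1/3/4/5, 83-113 nt), cytoplasmic tRNAs labelled by
#' amino acid and anticodon, mitochondrial tRNAs, mature miRNAs (19-25 nt),
#' piRNAs, a handful of other small ncRNAs, and one exogenous spike-in
#' control. Sequences are drawn from a uniform base model under 15-mer
#' uniqueness rejection sampling, so every 15-mer occurs at a single
#' location in the reference except for the deliberate 45S nesting (and the
#' corresponding read is therefore unambiguous). tRNA 15-mers are checked on
#' the CCA-appended mature sequence, since matching is performed against it.
#'
#' @param seed Integer seed; the same seed always yields a byte-identical
#'   reference.
#' @return A tibble of class `snc_reference` with columns `id`, `category`,
#'   `subcategory`, `sequence`, `length` and `cca_appended`, plus attribute
#'   `nesting` describing the 45S layout (offsets of the embedded subunits).
#' @examples
#' ref <- build_default_reference(seed = 1)
#' dplyr::count(ref, category)
#' @export
build_default_reference <- function(seed = 1) {
  withr::local_seed(seed)

  kmers <- character(0)
  k <- 15L

  seq_kmers <- function(s, k. = k) {
    n <- nchar(s)
    if (n < k.) return(character(0))
    substring(s, 1:(n - k. + 1L), k.:n)
  }
  rand_seq <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }
  # rejection-sample a sequence whose 15-mers are internally unique and
  # absent from everything generated so far
  unique_seq <- function(len, max_try = 1000L) {
    for (i in seq_len(max_try)) {
      s <- rand_seq(len)
      km <- seq_kmers(s)
      if (anyDuplicated(km) == 0L && !any(km %in% kmers)) {
        kmers <<- c(kmers, km)
        return(s)
      }
    }
    abort("could not generate a k-mer-unique sequence; reference too dense")
  }

  rows <- list()
  add <- function(id, category, subcategory, sequence) {
    rows[[length(rows) + 1L]] <<- tibble(
      id = id, category = category, subcategory = subcategory,
      sequence = sequence, length = nchar(sequence)
    )
  }

  ## nuclear rRNAs ----------------------------------------------------------
  s18 <- unique_seq(1869L)
  s58 <- unique_seq(157L)
  s28 <- unique_seq(2920L)
  s5  <- unique_seq(121L)

  # 45S precursor: 5'ETS - 18S - ITS1 - 5.8S - ITS2 - 28S - 3'ETS.
  # Spacers are regenerated until every *new* 45S 15-mer (spacer bodies and
  # subunit junctions) is unique; the embedded subunit 15-mers are the one
  # sanctioned duplication in the reference.
  s45 <- NULL
  for (i in 1:1000) {
    ets5 <- rand_seq(300L); its1 <- rand_seq(250L)
    its2 <- rand_seq(350L); ets3 <- rand_seq(150L)
    cand <- paste0(ets5, s18, its1, s58, its2, s28, ets3)
    km_new <- setdiff(seq_kmers(cand), c(seq_kmers(s18), seq_kmers(s58), seq_kmers(s28)))
    full <- seq_kmers(cand)
    dup_ok <- sum(duplicated(full)) == 0L   # random subunits never repeat internally
    if (dup_ok && !any(km_new %in% kmers)) {
      kmers <- c(kmers, km_new)
      s45 <- cand
      nesting <- tibble(
        unit = c("RNA18S", "RNA5-8S", "RNA28S"),
        offset = c(300L, 300L + 1869L + 250L, 300L + 1869L + 250L + 157L + 350L)
      )
      break
    }
  }
  if (is.null(s45)) abort("failed to assemble a k-mer-consistent 45S precursor")

  add("RNA18S",  "rRNA", "18S",  s18)
  add("RNA5-8S", "rRNA", "5.8S", s58)
  add("RNA28S",  "rRNA", "28S",  s28)
  add("RNA5S",   "rRNA", "5S",   s5)
  add("RNA45S",  "rRNA", "45S",  s45)
  add("MT-RNR1", "rRNA", "12S",  unique_seq(954L))
  add("MT-RNR2", "rRNA", "16S",  unique_seq(1559L))

  ## YRNAs (83-113 nt) ------------------------------------------------------
  ylen <- c(RNY1 = 112L, RNY3 = 102L, RNY4 = 96L, RNY5 = 83L)
  for (g in names(ylen)) add(g, "YRNA", g, unique_seq(ylen[[g]]))

  ## tRNAs: store the genomic body; register 15-mers of the CCA-appended
  ## mature form because annotation matches against it
  trna_unique_seq <- function(len) {
    for (i in 1:1000) {
      s <- rand_seq(len)
      km <- seq_kmers(paste0(s, "CCA"))
      if (anyDuplicated(km) == 0L && !any(km %in% kmers)) {
        kmers <<- c(kmers, km)
        return(s)
      }
    }
    abort("could not generate a k-mer-unique tRNA")
  }
  cyto_trnas <- c(
    "Gly-GCC", "Gly-CCC", "Glu-CTC", "Glu-TTC", "Ala-TGC", "Leu-CAG",
    "Leu-CAA", "Lys-TTT", "Lys-CTT", "Ser-AGA", "Arg-CCT", "Thr-AGT",
    "Val-CAC", "Cys-GCA", "Asp-GTC", "His-GTG", "Gln-CTG", "Phe-GAA",
    "Pro-AGG", "Met-CAT", "Ile-AAT", "Tyr-GTA"
  )
  for (a in cyto_trnas) {
    len <- if (grepl("^(Leu|Ser)", a)) sample(82:88, 1) else sample(71:76, 1)
    add(paste0("tRNA-", a), "tRNA", a, trna_unique_seq(len))
  }
  mt_trnas <- c("Leu-TAA", "Lys-TTT", "Ser-TGA", "Met-CAT", "Phe-GAA", "Val-TAC")
  for (a in mt_trnas) {
    add(paste0("MT-tRNA-", a), "mt_tRNA", a, trna_unique_seq(sample(62:70, 1)))
  }

  ## mature miRNAs, piRNAs, other small ncRNAs, spike-in ---------------------
  for (i in 1:55) {
    add(sprintf("synmiR-%03d", i), "miRNA", "mature", unique_seq(sample(19:25, 1)))
  }
  for (i in 1:24) {
    add(sprintf("synpiR-%03d", i), "piRNA", "piRNA", unique_seq(sample(26:32, 1)))
  }
  other <- c("snRNA-U1L", "snRNA-U2L", "snRNA-U6L", "snoRNA-S1", "snoRNA-S2",
             "snoRNA-S3", "lncFrag-1", "lncFrag-2", "vaultRNA-L", "7SL-L")
  for (o in other) add(o, "other_ncRNA", o, unique_seq(sample(60:150, 1)))
  add("spike-cel-miR-39", "spike_in", "spike_in", unique_seq(22L))

  ref <- bind_rows(rows)
  ref$cca_appended <- FALSE
  attr(ref, "nesting") <- nesting
  class(ref) <- c("snc_reference", class(ref))
  ref
}

#' Append the post-transcriptional CCA tail to a tRNA
#'
#' Mature tRNAs carry a 3' CCA that is added post-transcriptionally and is
#' part of the coordinate system used for fragment classification. The tail
#' is appended unconditionally, even if the genomic sequence already happens
#' to end in CCA; appending twice is an error.
#'
#' @param trna A one-or-more-row tibble of tRNA or mt_tRNA parents (as in an
#'   `snc_reference`).
#' @return The same tibble with `CCA` appended to each sequence, `length`
#'   increased by 3 and `cca_appended = TRUE`.
#' @export
append_cca <- function(trna) {
  if (!all(trna$category %in% c("tRNA", "mt_tRNA"))) {
    abort("append_cca() only applies to tRNA and mt_tRNA parents")
  }
  if (any(isTRUE(trna$cca_appended) | trna$cca_appended)) {
    abort("CCA tail already appended")
  }
  trna$sequence <- paste0(trna$sequence, "CCA")
  trna$length <- trna$length + 3L
  trna$cca_appended <- TRUE
  trna
}

#' Write a reference set as FASTA plus an annotation table
#'
#' @param ref An `snc_reference`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (`fasta`, `annotation`).
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "reference.fasta")
  tsv <- file.path(dir, "reference_annotation.tsv")
  seqs <- Biostrings::DNAStringSet(setNames(ref$sequence, ref$id))
  Biostrings::writeXStringSet(seqs, fa)
  readr::write_tsv(dplyr::select(as_tibble(ref), "id", "category", "subcategory", "length"), tsv)
  invisible(list(fasta = fa, annotation = tsv))
}

#' Read a reference set from FASTA plus annotation table
#'
#' @param fasta Path to the reference FASTA.
#' @param annotation Path to the tab-separated annotation table with columns
#'   `id`, `category`, `subcategory`, `length`.
#' @return An `snc_reference` tibble.
#' @export
read_reference <- function(fasta, annotation) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  anno <- readr::read_tsv(annotation, show_col_types = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  ref <- anno |>
    mutate(sequence = unname(as.character(seqs)[match(.data$id, ids)])) |>
    mutate(length = nchar(.data$sequence), cca_appended = FALSE) |>
    select("id", "category", "subcategory", "sequence", "length", "cca_appended")
  bad <- setdiff(ref$category, parent_categories())
  if (length(bad)) abort(paste("unknown categories in annotation:", paste(bad, collapse = ", ")))
  class(ref) <- c("snc_reference", class(ref))
  ref
}
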