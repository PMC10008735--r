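# Lazily built fixtures shared across test files (one process per test run).
.shared <- new.env(parent = emptyenv())

shared_ref <- function() {
  if (is.null(.shared$ref)) .shared$ref <- build_default_reference(seed = 1)
  .shared$ref
}

shared_index <- function() {
  if (is.null(.shared$index)) .shared$index <- build_kmer_index(shared_ref())
  .shared$index
}

# the deep healthy-serum run used for composition / characterization checks
shared_serum_run <- function() {
  if (is.null(.shared$serum)) {
    frags <- sample_fragments(shared_ref(), default_mixture(), n = 1e5, seed = 42)
    lib <- annotate_library(frags$sequence, shared_index())
    .shared$serum <- list(frags = frags, lib = lib)
  }
  .shared$serum
}

shared_study <- function() {
  if (is.null(.shared$study)) {
    .shared$study <- default_aml_study(shared_ref(), seed = 42)
  }
  .shared$study
}

shared_study_de <- function() {
  if (is.null(.shared$study_de)) {
    study <- shared_study()
    fm <- dplyr::select(study$discovery$features, feature_id, class)
    .shared$study_de <- run_de(study$discovery$counts, study$discovery$samples,
                               feature_meta = fm)
  }
  .shared$study_de
}

# tiny hand-made reference for priority / tie-splitting tests
toy_reference <- function() {
  seqs <- c(
    mirA = "ACGTGGCTAACGTGCAAGTCC",                       # 21 nt miRNA
    rrnA = paste0("TTTTTCCCCCGGGGGAAAAATTTGGCACGTGGCTAACGTGCAAGTCCAT",
                  "GCGCATATATGCGCGCTTAAGGCCTTAA"),         # contains mirA
    trnA = paste0("GGGCGGGCGGGCGGGAAATTTCCCGGGAAACCCTTTGGGAAATTTCCC",
                  "GGGTTTAAACCCGGGTTTAAAGGGTTTA"),
    trnB = paste0("CATCATCATCATCATAAATTTCCCGGGAAACCCTTTGGGAAATTTCCC",
                  "TACTACTACTACTACTACTACTACGTAC")
  )
  ref <- tibble::tibble(
    id = names(seqs),
    category = c("miRNA", "rRNA", "tRNA", "tRNA"),
    subcategory = c("mature", "18S", "Gly-GCC", "Glu-CTC"),
    sequence = unname(seqs),
    length = nchar(unname(seqs)),
    cca_appended = FALSE
  )
  class(ref) <- c("snc_reference", class(ref))
  ref
}
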