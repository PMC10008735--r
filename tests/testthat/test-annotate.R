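test_that("collapse_reads tallies distinct sequences and filters junk", {
  r <- collapse_reads(c(rep(strrep("ACGA", 5), 3), strrep("TTGC", 5)))
  expect_identical(nrow(r), 2L)
  expect_identical(sort(r$count, decreasing = TRUE), c(3L, 1L))

  expect_identical(nrow(collapse_reads(character(0))), 0L)

  # brute-force tally oracle on 10,000 reads over 50 distinct sequences
  set.seed(1)
  pool <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = ""), "")
  reads <- sample(pool, 10000, replace = TRUE)
  col <- collapse_reads(reads)
  expect_identical(nrow(col), 50L)
  expect_identical(sum(col$count), 10000L)
  oracle <- table(reads)
  expect_identical(col$count[match(names(oracle), col$sequence)],
                   as.integer(oracle))

  expect_warning(out <- collapse_reads(c("ACGTNACGTACGTACGTA", strrep("AC", 10))),
                 "non-ACGT")
  expect_identical(nrow(out), 1L)
  # length filter: 14-mers and 46-mers are dropped
  expect_identical(nrow(collapse_reads(c(strrep("A", 14), strrep("A", 46)))), 0L)
})

test_that("priority order and tie-splitting follow the hierarchical rule", {
  toy <- toy_reference()
  idx <- build_kmer_index(toy)

  # a read present in both the miRNA and the rRNA goes to miRNA first
  shared_mir <- toy$sequence[toy$id == "mirA"]
  ann <- assign_category(collapse_reads(shared_mir), idx)
  expect_identical(unique(ann$category), "miRNA")

  # with rRNA prioritized ahead of miRNA the same read flips category
  ann_r <- assign_category(collapse_reads(shared_mir), idx,
                           priority = c("rRNA", "miRNA", "YRNA", "tRNA",
                                        "mt_tRNA", "piRNA", "other_ncRNA", "spike_in"))
  expect_identical(unique(ann_r$category), "rRNA")

  # a read matching two tRNA parents equally splits its count 0.5/0.5
  shared_tr <- substring(toy$sequence[toy$id == "trnA"], 16, 48)
  ann_t <- assign_category(collapse_reads(shared_tr), idx)
  expect_identical(nrow(ann_t), 2L)
  expect_setequal(ann_t$parent_id, c("trnA", "trnB"))
  expect_equal(ann_t$weight, c(0.5, 0.5))
})

test_that("annotation recovers generator truth exactly at max_mismatch = 0", {
  run <- shared_serum_run()
  frags <- run$frags
  ann <- run$lib$annotations
  expect_equal(run$lib$unannotated, 0)
  truth <- dplyr::distinct(frags, sequence, .keep_all = TRUE)
  m <- dplyr::inner_join(truth,
                         dplyr::distinct(ann, sequence, class2 = class),
                         by = "sequence")
  expect_identical(nrow(m), nrow(truth))
  expect_true(all(m$class == m$class2))

  # per-class totals equal the truth tallies exactly
  prop <- compute_class_proportions(run$lib)
  truth_tab <- table(frags$class)
  expect_equal(prop$count[match(names(truth_tab), prop$class)],
               as.numeric(truth_tab))
})

test_that("reads without any reference hit stay unannotated, conserving counts", {
  idx <- shared_index()
  real <- sample_fragments(shared_ref(), n = 200, seed = 21)$sequence
  set.seed(2)
  junk <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""), "")
  lib <- annotate_library(c(real, junk), idx)
  annotated <- sum(dplyr::distinct(lib$annotations, read_id, count)$count)
  expect_equal(annotated + lib$unannotated, lib$total)
  expect_equal(lib$total, 250)
  expect_gt(lib$unannotated, 0)

  # determinism: annotating the same library twice gives identical columns
  lib2 <- annotate_library(c(real, junk), idx)
  expect_identical(lib$column, lib2$column)
})

test_that("one-mismatch mode recovers substituted reads behind the flag", {
  idx <- shared_index()
  frag <- sample_fragments(shared_ref(), n = 5, seed = 33)
  s <- frag$sequence[1]
  ch <- strsplit(s, "")[[1]]
  ch[8] <- setdiff(c("A", "C", "G", "T"), ch[8])[1]
  mutated <- paste(ch, collapse = "")
  expect_identical(nrow(assign_category(collapse_reads(mutated), idx)), 0L)
  ann <- assign_category(collapse_reads(mutated), idx, max_mismatch = 1L)
  expect_gte(nrow(ann), 1L)
  expect_true(any(ann$parent_id == frag$parent_id[1] & ann$mismatches == 1L))
})

test_that("class proportions reproduce a printed serum composition from a toy tally", {
  tab <- tibble::tibble(
    class = c("rsRNA", "ysRNA", "tsRNA", "miRNA", "other_ncRNA"),
    count = c(6286, 1497, 422, 309, 1486),
    weight = 1
  )
  p <- compute_class_proportions(tab)
  expect_equal(p$proportion[match(c("rsRNA", "ysRNA", "tsRNA", "miRNA"), p$class)],
               c(0.6286, 0.1497, 0.0422, 0.0309))
  expect_equal(sum(p$proportion), 1, tolerance = 1e-9)

  # permutation invariance and single-class degenerate case
  p2 <- compute_class_proportions(tab[sample(nrow(tab)), ])
  expect_equal(dplyr::arrange(p, class), dplyr::arrange(p2, class))
  single <- compute_class_proportions(tab[1, ])
  expect_equal(single$proportion, 1)
  expect_error(compute_class_proportions(tab[0, ]), "no annotated reads")
})

test_that("RPM normalization is exact and guards its denominator", {
  expect_equal(rpm_normalize(10, 1e6), 10)
  expect_equal(rpm_normalize(0, 1e6), 0)
  expect_equal(rpm_normalize(37, 250000), 148)
  expect_error(rpm_normalize(5, 0), "positive")
})

test_that("per-sample RPM over annotated features sums to one million", {
  lib <- shared_serum_run()$lib
  rpm <- rpm_normalize(lib$column$count, sum(lib$column$count))
  expect_equal(sum(rpm), 1e6, tolerance = 0.5)
})

test_that("length distributions are 31-bin, RPM-conserving, ysRNA peaks near 30 nt", {
  lib <- shared_serum_run()$lib
  total <- sum(dplyr::distinct(lib$annotations, read_id, count)$count)
  ld <- length_distribution(lib$annotations, "ysRNA", total)
  expect_identical(nrow(ld), 31L)
  ys_total <- sum(lib$annotations$count[lib$annotations$class == "ysRNA"] *
                    lib$annotations$weight[lib$annotations$class == "ysRNA"])
  expect_equal(sum(ld$rpm), rpm_normalize(ys_total, total), tolerance = 1e-6)
  expect_lte(abs(ld$length[which.max(ld$rpm)] - 30), 1)

  one_len <- tibble::tibble(read_id = "r1", sequence = strrep("A", 30),
                            count = 7, class = "miRNA", weight = 1)
  h <- length_distribution(one_len, "miRNA", 7)
  expect_identical(sum(h$rpm > 0), 1L)
  expect_identical(h$length[h$rpm > 0], 30L)

  empty <- length_distribution(lib$annotations[0, ], "piRNA", 100)
  expect_true(all(empty$rpm == 0))
  expect_error(length_distribution(lib$annotations, "notaclass"), "unknown class")
})
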