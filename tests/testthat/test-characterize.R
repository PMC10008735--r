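test_that("tsRNA subtype rule matches the schematic cleavage classes", {
  # 76-nt tRNA body, CCA-appended coordinates
  expect_identical(classify_tsrna_subtype(1, 32, 76), "five_prime")
  expect_identical(classify_tsrna_subtype(45, 79, 76), "three_prime_cca")
  expect_identical(classify_tsrna_subtype(20, 50, 76), "inner")
  expect_identical(classify_tsrna_subtype(45, 75, 76), "three_prime")
  expect_error(classify_tsrna_subtype(0, 20, 76), "outside")
  expect_error(classify_tsrna_subtype(50, 80, 76), "outside")
})

test_that("subtype partition is exhaustive and mutually exclusive", {
  # property check over random spans: the classifier agrees with an
  # independent re-statement of the rule and always returns one class
  set.seed(7)
  for (i in 1:500) {
    L <- sample(60:95, 1)
    s <- sample(seq_len(L + 3), 1)
    e <- if (s == L + 3) s else s + sample.int(L + 3 - s + 1, 1) - 1L
    got <- classify_tsrna_subtype(s, e, L)
    oracle <- if (s <= 3) "five_prime"
      else if (e >= L + 1) "three_prime_cca"
      else if (e >= L - 2) "three_prime"
      else "inner"
    expect_identical(got, oracle)
  }
})

test_that("nested rRNA reads resolve to the most specific parent", {
  expect_identical(assign_rsrna_parent(c("RNA18S", "RNA45S")), "RNA18S")
  expect_identical(assign_rsrna_parent("RNA45S"), "RNA45S")
  expect_error(assign_rsrna_parent(character(0)), "empty")

  # in annotated libraries no read is counted under both 45S and a subunit
  ann <- shared_serum_run()$lib$annotations
  rr <- ann[ann$class == "rsRNA", ]
  per_read <- tapply(rr$parent_id, rr$read_id, unique)
  both <- vapply(per_read, function(p) "RNA45S" %in% p && length(p) > 1, TRUE)
  expect_false(any(both))
})

test_that("coverage profiles accumulate depth additively", {
  ann <- tibble::tibble(
    read_id = c("a", "b"), sequence = "", count = c(2, 1), weight = 1,
    class = "rsRNA", parent_id = "P", start = c(10L, 25L), end = c(29L, 34L)
  )
  prof <- coverage_profile(ann[1, ], "P", 50)
  expect_true(all(prof$depth[10:29] == 2))
  expect_true(all(prof$depth[c(1:9, 30:50)] == 0))

  prof2 <- coverage_profile(ann, "P", 50)
  expect_true(all(prof2$depth[25:29] == 3))
  expect_equal(sum(prof2$depth), 2 * 20 + 1 * 10)  # sum(len x count)
})

test_that("peak calling follows the threshold / merge / width rule", {
  empty <- detect_peaks(tibble::tibble(pos = 1:100, depth = 0))
  expect_identical(nrow(empty), 0L)

  depth <- numeric(1000)
  depth[674:692] <- 100
  pk <- detect_peaks(tibble::tibble(pos = 1:1000, depth = depth))
  expect_identical(nrow(pk), 1L)
  expect_identical(c(pk$start, pk$end), c(674L, 692L))
  expect_equal(pk$share, 1)

  # two plateaus at 100 split by a 20-nt valley at 40: one merged peak at
  # threshold 0.25 (40 >= 25), two peaks at threshold 0.5
  d2 <- numeric(200)
  d2[50:80] <- 100; d2[81:100] <- 40; d2[101:130] <- 100
  prof2 <- tibble::tibble(pos = 1:200, depth = d2)
  expect_identical(nrow(detect_peaks(prof2, threshold_frac = 0.25)), 1L)
  two <- detect_peaks(prof2, threshold_frac = 0.5)
  expect_identical(nrow(two), 2L)
  expect_identical(two$start, c(50L, 101L))

  # scale invariance: intervals unchanged under positive rescaling
  prof3 <- dplyr::mutate(prof2, depth = depth * 3.71)
  expect_identical(detect_peaks(prof2, 0.5)[, c("start", "end", "summit")],
                   detect_peaks(prof3, 0.5)[, c("start", "end", "summit")])
})

test_that("simulated 18S coverage concentrates in the configured peak intervals", {
  run <- shared_serum_run()
  idx <- shared_index()
  prof <- coverage_profile(run$lib$annotations, "RNA18S", idx)
  pkcfg <- default_mixture()$rsrna_peak_model$RNA18S
  inside <- unlist(purrr::map2(pmax(pkcfg$start - 5, 1), pkcfg$end + 5, seq))
  expect_gt(sum(prof$depth[inside]) / sum(prof$depth), 0.85)
})

test_that("ysRNA composition reports gene fractions and the 5' split", {
  ann <- shared_serum_run()$lib$annotations
  comp <- ysrna_composition(ann)
  expect_equal(sum(comp$genes$fraction), 1)
  expect_identical(comp$genes$gene[1], "RNY4")
  expect_equal(comp$five_prime_fraction, 0.9, tolerance = 0.02)

  only_rny4 <- ann[ann$parent_id == "RNY4", ]
  expect_equal(ysrna_composition(only_rny4)$genes$fraction, 1)
  expect_error(ysrna_composition(ann[ann$class == "miRNA", ]), "no ysRNA")
})

test_that("tsRNA composition table is keyed by anticodon and cleavage group", {
  idx <- shared_index()
  one <- tibble::tibble(read_id = "r", sequence = strrep("A", 30), count = 4,
                        weight = 1, class = "tsRNA",
                        parent_id = "tRNA-Gly-GCC", start = 1L, end = 30L)
  tab <- tsrna_composition(one, idx, mapped_total = 4)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$anticodon, "Gly-GCC")
  expect_identical(tab$group, "5p")
  expect_identical(tab$compartment, "cyto")
  expect_equal(tab$rpm, 1e6)

  full <- tsrna_composition(shared_serum_run()$lib$annotations, idx)
  cy <- full[full$compartment == "cyto", ]
  expect_equal(sum(cy$rpm[cy$group == "5p"]) / sum(cy$rpm), 0.70, tolerance = 0.03)
  mt <- full[full$compartment == "mito", ]
  mt_by_group <- tapply(mt$rpm, mt$group, sum)
  expect_identical(names(which.max(mt_by_group)), "inner")
})
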