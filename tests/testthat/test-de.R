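make_counts <- function(m, prefix = "s") {
  colnames(m) <- paste0(prefix, seq_len(ncol(m)))
  rownames(m) <- paste0("f", seq_len(nrow(m)))
  m
}

test_that("TMM factors are 1 for identical or proportionally scaled libraries", {
  set.seed(1)
  base <- rpois(200, 100)
  m <- make_counts(cbind(base, base, base))
  f <- tmm_factors(m)
  expect_equal(f$factor, rep(1, 3), tolerance = 1e-12)

  m2 <- make_counts(cbind(base, 2L * base))
  f2 <- tmm_factors(m2)
  expect_equal(f2$factor, rep(1, 2), tolerance = 1e-12)
  expect_equal(exp(mean(log(f2$factor))), 1, tolerance = 1e-6)
})

test_that("TMM matches an independent trimmed-mean recomputation", {
  set.seed(42)
  m <- make_counts(matrix(rpois(300, 200), ncol = 3))
  m[1, 1] <- 20000  # one inflated feature in sample 1
  got <- tmm_factors(m, reference_sample = "s2")

  # straight-line oracle recomputation of the doubly trimmed weighted mean
  oracle <- function(x, r) {
    N <- sum(x); Nr <- sum(r)
    keep <- x > 0 & r > 0
    M <- log2((x[keep] / N) / (r[keep] / Nr))
    A <- 0.5 * log2((x[keep] / N) * (r[keep] / Nr))
    w <- (N - x[keep]) / x[keep] + (Nr - r[keep]) / r[keep]
    qm <- quantile(M, c(0.3, 0.7)); qa <- quantile(A, c(0.05, 0.95))
    sel <- M >= qm[1] & M <= qm[2] & A >= qa[1] & A <= qa[2]
    2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
  }
  raw <- vapply(1:3, function(j) oracle(m[, j], m[, 2]), 1)
  raw <- raw / exp(mean(log(raw)))
  expect_equal(got$factor, raw, tolerance = 1e-10)

  expect_error(tmm_factors(make_counts(cbind(c(1, 2), c(0, 0)))), "all-zero")
})

test_that("common dispersion is recovered from simulated truth", {
  set.seed(5)
  g <- rep(c("A", "B"), each = 10)
  pois <- make_counts(matrix(rpois(50 * 20, 500), 50))
  expect_lte(estimate_common_dispersion(pois, g)$phi, 0.05)

  nb <- make_counts(matrix(rnbinom(400 * 20, mu = 800, size = 1 / 0.4), 400))
  phi_hat <- estimate_common_dispersion(nb, g)$phi
  expect_gte(phi_hat, 0.2)
  expect_lte(phi_hat, 0.6)

  const <- make_counts(matrix(50, 20, 20))
  expect_identical(estimate_common_dispersion(const, g)$phi, 0)
  expect_error(estimate_common_dispersion(pois, rep(c("A", "B"), c(19, 1))),
               "replicates")
})

test_that("exact test reduces to the two-sided binomial oracle at phi = 0", {
  # exhaustive over all totals <= 20 and all observed splits
  for (t_tot in 1:20) {
    pb <- dbinom(0:t_tot, t_tot, 0.5)
    for (a in 0:t_tot) {
      p_oracle <- sum(pb[pb <= pb[a + 1] * (1 + 1e-10)])
      p_got <- nb_exact_test(c(a, t_tot - a), c("A", "B"), phi = 0)$p
      expect_equal(p_got, p_oracle, tolerance = 1e-9)
    }
  }
})

test_that("exact test is symmetric and handles degenerate features", {
  x <- c(30, 25, 80, 90)
  g <- c("control", "control", "AML", "AML")
  r1 <- nb_exact_test(x, g, phi = 0.1)
  r2 <- nb_exact_test(x, rev(g), phi = 0.1)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-12)

  same <- nb_exact_test(c(50, 50, 50, 50), g, phi = 0)
  expect_gte(same$p, 0.99)
  expect_equal(same$log2fc, 0, tolerance = 1e-9)

  zero <- nb_exact_test(c(0, 0, 0, 0), g, phi = 0.2)
  expect_identical(zero$p, 1)
  expect_identical(zero$log2fc, 0)
})

test_that("significance calls apply the p and fold-change thresholds jointly", {
  res <- tibble::tibble(
    feature_id = c("a", "b", "c"),
    log2fc = c(0.9, -1.2, 2),
    p = c(0.04, 0.04, 0.2)
  )
  res <- dplyr::mutate(res,
    significant = p <= 0.05 & abs(log2fc) >= 1,
    direction = dplyr::case_when(!significant ~ "ns", log2fc > 0 ~ "up",
                                 TRUE ~ "down"))
  s <- call_de(res)
  expect_identical(s$n_significant, 1L)
  expect_identical(s$n_down, 1L)
  expect_identical(s$n_up, 0L)
})

test_that("type-I error of the full DE pipeline stays near nominal", {
  set.seed(17)
  g <- rep(c("control", "AML"), each = 8)
  m <- make_counts(matrix(rnbinom(800 * 16, mu = 300, size = 1 / 0.2), 800))
  de <- run_de(m, tibble::tibble(sample = colnames(m), group = g))
  expect_lte(mean(de$p <= 0.05), 0.08)
  expect_lte(mean(de$significant), 0.07)
})

test_that("power increases with planted effect size", {
  set.seed(23)
  g <- rep(c("control", "AML"), each = 4)
  mean_p <- vapply(c(0.5, 1, 2), function(lfc) {
    planted <- t(vapply(1:50, function(i) {
      c(rnbinom(4, mu = 60, size = 1 / 0.2),
        rnbinom(4, mu = 60 * 2^lfc, size = 1 / 0.2))
    }, numeric(8)))
    null_bg <- matrix(rnbinom(200 * 8, mu = 300, size = 1 / 0.2), 200)
    m <- make_counts(rbind(planted, null_bg))
    de <- run_de(m, tibble::tibble(sample = colnames(m), group = g), phi = 0.2)
    mean(de$p[seq_len(nrow(planted))])
  }, 1)
  expect_true(all(diff(mean_p) < 0))
})

test_that("p-values are invariant to proportional rescaling of one sample", {
  set.seed(31)
  g <- rep(c("control", "AML"), each = 4)
  m <- make_counts(matrix(rnbinom(200 * 8, mu = 250, size = 10), 200))
  de1 <- run_de(m, tibble::tibble(sample = colnames(m), group = g), phi = 0.1)
  # rescale a sample other than the normalization anchor
  scaled <- setdiff(colnames(m), attr(tmm_factors(m), "reference_sample"))[1]
  m2 <- m; m2[, scaled] <- m2[, scaled] * 2L
  de2 <- run_de(m2, tibble::tibble(sample = colnames(m2), group = g), phi = 0.1)
  expect_equal(de1$p, de2$p, tolerance = 1e-6)
})
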