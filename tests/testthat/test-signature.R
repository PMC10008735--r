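test_that("logistic Wald handles constant, separated and regular features", {
  const <- logistic_wald(rep(2, 10), rep(c("control", "AML"), 5))
  expect_identical(const$coefficient, 0)
  expect_identical(const$p, 1)

  sep <- logistic_wald(c(1:5, 11:15), rep(c("control", "AML"), each = 5))
  expect_true(sep$separation)
  expect_identical(sep$p, .Machine$double.xmin)

  expect_error(logistic_wald(1:5, rep("AML", 5)), "both classes")
})

test_that("logistic fit matches an independent Newton-Raphson oracle", {
  # oracle: direct maximization of the binomial log-likelihood
  nr_oracle <- function(x, y) {
    nll <- function(b) {
      eta <- b[1] + b[2] * x
      sum(log1p(exp(eta))) - sum(y * eta)
    }
    fit <- optim(c(0, 0), nll, method = "BFGS", hessian = TRUE,
                 control = list(reltol = 1e-14, maxit = 1000))
    se <- sqrt(diag(solve(fit$hessian)))[2]
    z <- fit$par[2] / se
    list(coefficient = fit$par[2], p = 2 * pnorm(-abs(z)))
  }
  set.seed(9)
  cases <- c(list(list(x = 1:8, y = c(0, 0, 0, 1, 0, 1, 1, 1))),
             lapply(1:20, function(i) {
               x <- rnorm(24)
               y <- rbinom(24, 1, plogis(0.3 + 0.8 * x))
               if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
               list(x = x, y = y)
             }))
  for (cs in cases) {
    got <- logistic_wald(cs$x, cs$y)
    if (got$separation) next
    ora <- nr_oracle(cs$x, cs$y)
    expect_equal(got$coefficient, ora$coefficient, tolerance = 1e-4)
    expect_lt(abs(got$p - ora$p), 1e-4)
  }
})

test_that("AUC equals the Mann-Whitney pairwise enumeration", {
  expect_identical(roc_auc(c(1, 2, 3, 10, 11, 12),
                           rep(c("control", "AML"), each = 3)), 1)
  expect_identical(roc_auc(c(10, 11, 12, 1, 2, 3),
                           rep(c("control", "AML"), each = 3)), 0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)

  enum_auc <- function(s, l) {
    pos <- which(l == 1); neg <- which(l == 0)
    pairs <- expand.grid(p = pos, n = neg)
    mean(ifelse(s[pairs$p] > s[pairs$n], 1, ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
  }
  set.seed(12)
  for (i in 1:200) {
    n <- sample(6:20, 1)
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # forces ties
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
    expect_equal(roc_auc(s, l), enum_auc(s, l), tolerance = 1e-12)
  }

  # invariance under strictly increasing transforms
  s <- rnorm(30); l <- rbinom(30, 1, 0.5); l[1:2] <- c(0, 1)
  expect_equal(roc_auc(exp(s), l), roc_auc(s, l))
  expect_equal(roc_auc(rank(s), l), roc_auc(s, l))
})

test_that("bagged-tree training is seeded, separable data give low OOB error", {
  set.seed(4)
  x <- data.frame(f1 = c(rnorm(20, 0), rnorm(20, 6)),
                  f2 = c(rnorm(20, 0), rnorm(20, 6)))
  y <- rep(c("control", "AML"), each = 20)
  fit1 <- train_and_oob(x, y, n_trees = 200, seed = 7)
  fit2 <- train_and_oob(x, y, n_trees = 200, seed = 7)
  expect_identical(fit1$oob_scores, fit2$oob_scores)
  expect_identical(fit1$oob_error, fit2$oob_error)
  expect_lte(fit1$oob_error, 0.05)
  expect_error(train_and_oob(x[, 0], y), "empty")
})

test_that("selection is a strict conjunction of the three criteria", {
  set.seed(11)
  n <- 16
  g <- rep(c("control", "AML"), each = n / 2)
  # f1: strong DE, abundant -> selected; f2: strong DE but rare (fails mean
  # RPM); f3: abundant, no effect
  f1 <- c(rnbinom(n / 2, mu = 500, size = 10), rnbinom(n / 2, mu = 3000, size = 10))
  f2 <- c(rnbinom(n / 2, mu = 2, size = 10), rnbinom(n / 2, mu = 14, size = 10))
  f3 <- rnbinom(n, mu = 500, size = 10)
  filler <- matrix(rnbinom(50 * n, mu = 60000, size = 10), ncol = n)
  m <- rbind(f1, f2, f3, filler)
  rownames(m) <- c("f1", "f2", "f3", paste0("bg", 1:50))
  colnames(m) <- paste0("s", 1:n)
  samples <- tibble::tibble(sample = colnames(m), group = g)
  fc <- tibble::tibble(feature_id = rownames(m),
                       class = c("tsRNA", "tsRNA", "tsRNA", rep("other_ncRNA", 50)))
  de <- run_de(m, samples, feature_meta = fc)
  sel <- suppressWarnings(select_signature(m, samples, de, "tsRNA"))
  expect_true("f1" %in% sel$feature_id)
  expect_false("f2" %in% sel$feature_id)   # mean RPM below threshold
  expect_false("f3" %in% sel$feature_id)   # not differentially expressed
})

test_that("discovery/validation firewall holds and overlap is rejected", {
  study <- shared_study()
  de <- shared_study_de()
  rep1 <- evaluate_panels(study$discovery, study$validation, de = de,
                          n_trees = 100, seed = 3)

  # mutating validation labels must change nothing about panels or scores
  mutated <- study$validation
  mutated$samples$group <- rev(mutated$samples$group)
  rep2 <- evaluate_panels(study$discovery, mutated, de = de,
                          n_trees = 100, seed = 3)
  for (cl in names(rep1)) {
    expect_identical(rep1[[cl]]$panel$feature_id, rep2[[cl]]$panel$feature_id)
    expect_identical(rep1[[cl]]$validation_scores, rep2[[cl]]$validation_scores)
  }

  expect_error(evaluate_panels(study$discovery, study$discovery, de = de),
               "overlaps")
})

test_that("planted markers dominate the fitted ensemble importances", {
  study <- shared_study()
  de <- shared_study_de()
  rep <- evaluate_panels(study$discovery, study$validation, de = de,
                         n_trees = 300, seed = 5)
  planted_ts <- names(study$effects)[1:6]
  imp <- sort(rep$tsRNA$importance, decreasing = TRUE)
  expect_setequal(names(imp)[seq_len(nrow(rep$tsRNA$panel))][1:6], planted_ts)
})
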