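test_that("pearson_r2 matches the direct formula and handles degeneracy", {
  y <- c(3, 7, 1, 9, 4, 6)
  yp <- c(2.5, 6, 2, 8, 5, 5.5)
  direct <- sum((y - mean(y)) * (yp - mean(yp)))^2 /
    (sum((y - mean(y))^2) * sum((yp - mean(yp))^2))
  expect_equal(pearson_r2(y, yp), direct)
  expect_equal(pearson_r2(y, y), 1)
  # affine sign-flip insensitivity is a property of the chosen formula
  expect_equal(pearson_r2(y, -2 * y + 5), 1)
  expect_true(is.na(pearson_r2(y, rep(1, 6))))
  expect_true(is.na(pearson_r2(y, c(yp[-1], NA))))
  expect_error(pearson_r2(rep(2, 6), yp), "constant")
  expect_error(pearson_r2(y, yp[-1]), "mismatch")
})

test_that("fold plans partition samples with balanced sizes", {
  plan <- make_fold_plan(40, 10, 9, 3, master_seed = 4)
  for (r in 1:3) {
    expect_equal(as.vector(table(plan$assignment[, r])), rep(4L, 10))
  }
  # n = 43: three folds of 5, seven of 4 (brute-force count)
  p43 <- make_fold_plan(43, 10, 9, 1, master_seed = 4)
  sizes <- sort(as.vector(table(p43$assignment[, 1])))
  expect_equal(sizes, c(rep(4L, 7), rep(5L, 3)))
  # reproducible from the master seed
  expect_identical(plan$assignment,
                   make_fold_plan(40, 10, 9, 3, master_seed = 4)$assignment)
  expect_error(make_fold_plan(5, 10), "fewer samples")
})

test_that("stratified folds spread every class across folds", {
  strata <- rep(letters[1:8], each = 5)
  plan <- make_fold_plan(40, 10, 9, 2, master_seed = 9, strata = strata)
  for (r in 1:2) {
    f <- plan$assignment[, r]
    expect_equal(as.vector(table(f)), rep(4L, 10))
    # no fold may hold two samples of the same 5-member class
    expect_true(all(table(strata, f) <= 1))
  }
})

test_that("nested CV recovers a noiseless linear signal", {
  X <- with_seed(1, matrix(stats::rnorm(40 * 3), 40))
  y <- 2 * X[, 1] + 1
  plan <- make_fold_plan(40, 10, 9, 2, master_seed = 5)
  cv <- nested_cv("ridge", X, y, plan)
  expect_gte(cv$r2, 0.999)
  expect_identical(cv$status, "ok")
  expect_false(anyNA(cv$predictions))
})

test_that("a single-row grid makes the inner loop a no-op", {
  X <- with_seed(2, matrix(stats::rnorm(40 * 3), 40))
  y <- with_seed(3, X[, 1] + stats::rnorm(40, 0, 0.3))
  plan <- make_fold_plan(40, 10, 9, 1, master_seed = 6)
  g1 <- data.frame(lambda = 0.1)
  cv_nested <- nested_cv("ridge", X, y, plan, grid = g1)
  # plain 10-fold CV at the same fixed hyperparameter, computed directly
  folds <- plan$assignment[, 1]
  preds <- rep(NA_real_, 40)
  for (f in 1:10) {
    fit <- fit_regression("ridge", X[folds != f, ], y[folds != f],
                          list(lambda = 0.1))
    preds[folds == f] <- predict(fit, X[folds == f, , drop = FALSE])
  }
  expect_equal(cv_nested$predictions, preds, tolerance = 1e-12)
  expect_equal(cv_nested$r2, pearson_r2(y, preds))
})

test_that("outer test folds cannot leak into hyperparameter selection", {
  X <- with_seed(4, matrix(stats::rnorm(40 * 4), 40))
  y <- with_seed(5, X[, 1] + stats::rnorm(40, 0, 0.5))
  plan <- make_fold_plan(40, 10, 9, 1, master_seed = 7)
  base <- nested_cv("ridge", X, y, plan)
  folds <- plan$assignment[, 1]
  for (f in c(1, 4)) {  # poison two different outer test folds
    y_poison <- y
    y_poison[folds == f] <- with_seed(50 + f, stats::rnorm(sum(folds == f),
                                                           100, 50))
    cv_p <- nested_cv("ridge", X, y_poison, plan)
    expect_identical(cv_p$chosen[[f]], base$chosen[[f]])
  }
})

test_that("NA-models propagate to NA cells with a reason, never zero", {
  X <- with_seed(6, matrix(stats::rnorm(40 * 3), 40))  # contains negatives
  y <- abs(with_seed(7, stats::rnorm(40))) + 1
  plan <- make_fold_plan(40, 10, 9, 2, master_seed = 8)
  cv <- repeat_cv("loglog", X, y, plan)
  expect_identical(cv$status, "NA")
  expect_true(is.na(cv$mean))
  expect_match(cv$reason, "NA-model")
})

test_that("benchmark tables carry families, NA reasons and the best marker", {
  b <- planted_bundle(seed = 51, n_genes = 120, n_linked = 4,
                      explained = 0.85)
  # shift log2 intensities below zero so the log-log family is inapplicable
  shifted <- b$expression - 20
  attr(shifted, "scale_tag") <- "log2"
  b <- study_bundle(shifted, b$annotation, b$residue, b$truth)
  rk <- correlation_rank(b$expression, b$residue)
  ps <- augment_with_extremes(predictor_set(character(0)), rk, 2, 2)
  fams <- c("ridge", "multivariate_ols", "loglog")
  tab <- benchmark(b, ps, families = fams, n_runs = 2, master_seed = 3)
  expect_s3_class(tab, "performance_table")
  expect_identical(tab$family, fams)
  expect_identical(tab$status[tab$family == "loglog"], "NA")
  expect_gt(tab$mean_r2[tab$family == "ridge"], 0.5)
  expect_identical(attr(tab, "best"),
                   tab$family[which.max(tab$mean_r2)])
  expect_equal(attr(tab, "predictor_size"), 4)
  expect_error(benchmark(b, character(0)), "empty")
})

test_that("benchmarks are reproducible to the last digit for a fixed seed", {
  b <- planted_bundle(seed = 52, n_genes = 80, n_linked = 2,
                      explained = 0.8)
  rk <- correlation_rank(b$expression, b$residue)
  ps <- augment_with_extremes(predictor_set(character(0)), rk, 1, 1)
  t1 <- benchmark(b, ps, families = "ridge", n_runs = 2, master_seed = 11)
  t2 <- benchmark(b, ps, families = "ridge", n_runs = 2, master_seed = 11)
  expect_identical(t1$mean_r2, t2$mean_r2)
  expect_identical(t1$sd_r2, t2$sd_r2)
})

test_that("reports render the wide table and round-trip the long TSV", {
  tab <- data.frame(family = c("ridge", "loglog"),
                    mean_r2 = c(0.81, NA), sd_r2 = c(0.03, NA),
                    n_runs = c(10L, 10L), status = c("ok", "NA"),
                    reason = c("", "domain"), stringsAsFactors = FALSE)
  class(tab) <- c("performance_table", "data.frame")
  attr(tab, "dataset") <- "HMX_D28"
  attr(tab, "predictor_size") <- 10
  attr(tab, "best") <- "ridge"
  path <- withr::local_tempfile()
  long <- report(tab, path)
  lines <- readLines(path)
  expect_match(lines[2], "Predictor size \\(gene #\\)")
  expect_match(lines[2], "10")
  expect_match(lines[grep("^ridge", lines)], "0.81 ± 0.03 \\*")
  expect_match(lines[grep("^loglog", lines)], "NA")
  back <- utils::read.delim(paste0(path, ".tsv"))
  expect_equal(back$mean_r2, tab$mean_r2)
  # best flag equals the independently computed argmax
  expect_identical(back$family[back$best],
                   tab$family[which.max(tab$mean_r2)])
})

test_that("honest benchmarking engages the selection fallback on nulls", {
  bn <- null_study(hmx_design(), n_genes = 60, duration = 4, seed = 61)
  rec <- default_selection_recipe(run_de = FALSE, cutoff = 0.99)
  ids <- rec(bn$expression, bn$annotation$class_label, bn$residue)
  expect_true(attr(ids, "fallback"))  # nothing passes |r| >= 0.99
  expect_length(ids, 4)
  tab <- honest_benchmark(bn, rec, families = "multivariate_ols",
                          n_runs = 1, master_seed = 2)
  expect_s3_class(tab, "performance_table")
  expect_identical(attr(tab, "mode"), "honest")
})
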