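test_that("pooled residual variances match the direct formula and aov", {
  x <- matrix(c(0, 2, 10, 12), 1)
  cl <- c("a", "a", "b", "b")
  rv <- residual_variances(x, cl)
  # direct pooled formula: SS_within = 2 + 2 = 4, m = 4 - 2 = 2
  expect_equal(unname(rv$s2), 2)
  expect_equal(rv$df, 2)
  # independent oracle: aov residual mean square
  ms <- summary(stats::aov(as.vector(x) ~ factor(cl)))[[1]]["Residuals",
                                                            "Mean Sq"]
  expect_equal(unname(rv$s2), unname(ms))
  # identical values within classes -> zero variance, m = n - k
  x0 <- matrix(rep(c(1, 5), each = 3), 1)
  rv0 <- residual_variances(x0, rep(c("a", "b"), each = 3))
  expect_equal(unname(rv0$s2), 0)
  expect_equal(rv0$df, 4)
  expect_error(residual_variances(x0, rep("a", 6)), "classes")
})

test_that("the prior fit recovers known hyperparameters and beats a grid", {
  m <- 6; a <- 3; b <- 1
  s2 <- with_seed(2, (1 / (a * b)) * stats::rf(10000, m, 2 * a))
  fit <- fit_random_variance_prior(s2, m)
  expect_lt(abs(fit$a - a) / a, 0.15)
  expect_lt(abs(fit$b - b) / b, 0.15)
  # grid oracle: optimizer must reach at least the best of a 50x50 grid
  grid_a <- 10^seq(-1, 2, length.out = 50)
  grid_b <- 10^seq(-2, 1, length.out = 50)
  ll <- function(a, b) sum(log(a * b) +
                             stats::df(a * b * s2, m, 2 * a, log = TRUE))
  best_grid <- max(outer(grid_a, grid_b, Vectorize(ll)))
  expect_gte(fit$loglik, best_grid)
})

test_that("degenerate all-equal variances yield a flagged capped-a fit", {
  expect_warning(fit <- fit_random_variance_prior(rep(2, 500), 6), "capped")
  expect_true(fit$boundary)
  expect_gte(fit$a, 1e5)
})

test_that("shrinkage pulls variances toward the prior point, fully as a grows", {
  s2 <- c(0.1, 0.5, 2, 10)
  pr <- rv_prior(a = 3, b = 1, m = 6)
  st <- shrink_variances(s2, pr)
  prior_point <- 1 / (pr$a * pr$b)
  expect_true(all((st >= pmin(s2, prior_point)) &
                    (st <= pmax(s2, prior_point))))
  big <- rv_prior(a = 1e6, b = 1 / (1e6 * 0.5), m = 6)
  expect_equal(unname(shrink_variances(s2, big)), rep(0.5, 4),
               tolerance = 1e-4)
})

test_that("the moderated statistic reduces to the ordinary test as a -> 0", {
  for (i in 1:5) {
    x <- two_class_matrix(n_genes = 200, seed = 40 + i)
    cl <- two_classes()
    mod <- moderated_statistic(x, cl, rv_prior(a = 1e-8, b = 1e12, m = 8))
    ord <- suppressWarnings(moderated_statistic(x, cl, prior = NULL))
    expect_lt(max(abs(mod$statistic - ord$statistic) / abs(ord$statistic)),
              1e-6)
  }
  # multi-class moderated F against the a->0 ordinary F from aov
  x3 <- with_seed(7, matrix(stats::rnorm(50 * 9), 50))
  cl3 <- rep(c("a", "b", "c"), each = 3)
  mod3 <- moderated_statistic(x3, cl3, rv_prior(a = 1e-8, b = 1e12, m = 6))
  f_aov <- apply(x3, 1, function(v) {
    summary(stats::aov(v ~ factor(cl3)))[[1]]["factor(cl3)", "F value"]
  })
  expect_equal(unname(mod3$statistic), unname(f_aov), tolerance = 1e-6)
})

test_that("equal class means give a zero F and p = 1", {
  x <- matrix(rep(c(1, 2, 3), 3), 1)  # every class sees values 1, 2, 3
  mod <- moderated_statistic(x, rep(c("a", "b", "c"), each = 3),
                             rv_prior(3, 1, m = 6))
  expect_equal(mod$statistic, 0)
  expect_equal(mod$p_value, 1)
})

test_that("a strongly shifted probe attains the smallest p-value", {
  x <- two_class_matrix(n_genes = 2000, shift_genes = 1, shift = 10,
                        seed = 77)
  rv <- residual_variances(x, two_classes())
  pr <- fit_random_variance_prior(rv$s2, rv$df)
  mod <- moderated_statistic(x, two_classes(), pr)
  expect_identical(mod$probe_id[which.min(mod$p_value)], "g0001")
})

test_that("sampled selection equals exhaustive enumeration on 3v3 designs", {
  x <- two_class_matrix(n_genes = 60, n_per = 3, shift_genes = 3,
                        shift = 8, seed = 12)
  cl <- two_classes(3)
  pr <- rv_prior(3, 1, m = 4)
  # the procedure must auto-switch to exhaustive mode: choose(6, 3) = 20
  sel <- multivariate_permutation_select(x, cl, n_permutations = 1000,
                                         seed = 5, prior = pr)
  expect_true(sel$exhaustive)
  expect_equal(sel$n_permutations, 20)
  sel2 <- multivariate_permutation_select(x, cl, n_permutations = 5000,
                                          seed = 99, prior = pr)
  expect_identical(sel$perm_p, sel2$perm_p)
  expect_identical(sel$probe_ids, sel2$probe_ids)
  # independent oracle: brute-force enumeration of all 20 label splits
  obs <- moderated_statistic(x, cl, pr)
  splits <- utils::combn(6, 3)
  perm_p_oracle <- rowMeans(apply(splits, 2, function(idx) {
    lab <- rep("b", 6); lab[idx] <- "a"
    moderated_statistic(x, lab, pr)$p_value
  }) <= obs$p_value + 1e-15)
  expect_equal(unname(sel$perm_p), unname(perm_p_oracle))
})

test_that("planted probes are selected with controlled false discoveries", {
  x <- two_class_matrix(n_genes = 2000, shift_genes = 20, shift = 10,
                        seed = 3)
  sel <- multivariate_permutation_select(x, two_classes(), seed = 3)
  planted <- sprintf("g%04d", 1:20)
  expect_true(all(planted %in% sel$probe_ids))
  fdp <- mean(!(sel$probe_ids %in% planted))
  expect_lte(fdp, 0.1)
})

test_that("selection is deterministic and refuses impossible permutations", {
  x <- two_class_matrix(n_genes = 120, seed = 8)
  s1 <- multivariate_permutation_select(x, two_classes(), seed = 11,
                                        exhaustive_limit = 1,
                                        n_permutations = 150)
  s2 <- multivariate_permutation_select(x, two_classes(), seed = 11,
                                        exhaustive_limit = 1,
                                        n_permutations = 150)
  expect_false(s1$exhaustive)
  expect_identical(s1$perm_p, s2$perm_p)
  expect_error(multivariate_permutation_select(x[, 1, drop = FALSE], "a"),
               "class")
})

test_that("compare_groups merges indistinguishable controls and proceeds", {
  b <- planted_bundle(seed = 31, n_genes = 300, n_linked = 4,
                      explained = 0.9, n_dose = 4)
  de <- compare_groups(b, n_permutations = 200, seed = 4)
  expect_true(attr(de, "controls_merged"))
  expect_equal(attr(de, "n_classes"), 6)  # merged control + five doses
  expect_identical(de$statistic_type, "F")
  # null bundle -> empty set with full audit metadata
  bn <- null_study(hmx_design(), n_genes = 200, duration = 4, seed = 6)
  den <- compare_groups(bn, n_permutations = 200, seed = 7)
  expect_length(den$probe_ids, 0)
  expect_s3_class(den, "de_gene_set")
  expect_gt(den$n_permutations, 0)
  expect_error(compare_groups(b, grouping = "no_such_column"),
               "configuration")
})

test_that("DE gene sets serialize to a TSV worksheet", {
  x <- two_class_matrix(n_genes = 30, shift_genes = 2, shift = 10, seed = 5)
  sel <- multivariate_permutation_select(x, two_classes(), seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_de_genes(sel, path)
  tab <- utils::read.delim(path)
  expect_equal(nrow(tab), 30)
  expect_setequal(tab$probe_id[tab$selected], sel$probe_ids)
})
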