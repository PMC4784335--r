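# Double-looped (nested) 10-fold cross-validation scored by squared Pearson
# correlation, repeated-run benchmark tables across the 18 families, and an
# honest mode that re-runs predictor selection inside every outer fold.

#' Squared Pearson correlation between measured and predicted values
#'
#' The accuracy metric of the benchmark: the square of the Pearson
#' correlation between pooled out-of-fold predictions and measured residues.
#' Note the caveat that any affine transform of the predictions (including a
#' sign flip) leaves this metric unchanged.
#'
#' @param y_measured measured values (length >= 3, non-constant).
#' @param y_predicted predicted values; NA or constant predictions give NA.
#' @return R-squared in `[0, 1]`, or NA.
#' @export
pearson_r2 <- function(y_measured, y_predicted) {
  if (length(y_measured) != length(y_predicted)) stop("length mismatch")
  if (length(y_measured) < 3) stop("need >= 3 observations")
  if (stats::sd(y_measured) == 0) {
    stop("degenerate-input error: measured values are constant")
  }
  if (anyNA(y_predicted) || stats::sd(y_predicted) == 0) return(NA_real_)
  stats::cor(y_measured, y_predicted)^2
}

# balanced (optionally stratified) fold assignment; sizes differ by <= 1
.fold_assign <- function(n, k, strata = NULL) {
  strata <- strata %||% rep(1, n)
  ord <- unlist(lapply(split(seq_len(n), strata), function(idx) {
    if (length(idx) > 1) idx[sample.int(length(idx))] else idx
  }), use.names = FALSE)
  folds <- integer(n)
  folds[ord] <- rep_len(sample.int(k), n)
  folds
}

#' Build a reproducible plan of repeated outer-fold partitions
#'
#' @param n number of samples.
#' @param k_outer outer folds (default 10).
#' @param k_inner inner folds used on each outer-training set (default 9).
#' @param n_runs repeated runs (default 10).
#' @param master_seed integer seed; per-run seeds are derived children.
#' @param strata optional stratification labels (e.g. treatment class) so
#'   every fold spans the dose range.
#' @return an object of class `fold_plan` with an `n x n_runs` assignment
#'   matrix of outer-fold ids.
#' @export
make_fold_plan <- function(n, k_outer = 10, k_inner = 9, n_runs = 10,
                           master_seed = 1, strata = NULL) {
  if (n < k_outer) stop("configuration error: fewer samples than outer folds")
  run_seeds <- child_seed(master_seed, seq_len(n_runs))
  assignment <- vapply(seq_len(n_runs), function(r) {
    with_seed(run_seeds[r], .fold_assign(n, k_outer, strata))
  }, integer(n))
  assignment <- matrix(assignment, nrow = n)
  structure(list(n = n, k_outer = k_outer, k_inner = k_inner,
                 n_runs = n_runs, master_seed = master_seed,
                 run_seeds = run_seeds, strata = strata,
                 assignment = assignment),
            class = "fold_plan")
}

# Inner-loop grid selection on one outer-training set. Returns the chosen
# grid row index (first row among ties: smallest complexity by grid order).
#
# Scoring note: candidates are ranked by the SIGNED Pearson correlation of
# pooled inner out-of-fold predictions with the response, not its square.
# Squared correlation cannot tell predictive from anti-predictive settings,
# and near-intercept-only configurations (huge ridge penalty, huge kernel
# bandwidth) produce out-of-fold predictions that anticorrelate with the
# held-out values through the training-mean-per-fold structure; selecting on
# the squared value would systematically prefer those degenerate settings on
# weak-signal data. The outer loop still reports the squared correlation.
.inner_select <- function(family, Xtr, ytr, grid, k_inner, strata_tr, seed) {
  if (nrow(grid) <= 1) return(1L)
  n_tr <- nrow(Xtr)
  k_in <- min(k_inner, n_tr)
  folds <- with_seed(seed, .fold_assign(n_tr, k_in, strata_tr))
  scores <- rep(-Inf, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    preds <- rep(NA_real_, n_tr)
    ok <- TRUE
    for (f in seq_len(k_in)) {
      tr <- folds != f
      fit <- tryCatch(
        fit_regression(family, Xtr[tr, , drop = FALSE], ytr[tr],
                       hyper = grid[g, , drop = FALSE],
                       seed = child_seed(seed, 100 + f)),
        error = function(e) NULL)
      if (is.null(fit) || is_na_model(fit)) { ok <- FALSE; break }
      preds[!tr] <- predict(fit, Xtr[!tr, , drop = FALSE])
    }
    if (!ok || anyNA(preds) || stats::sd(preds) == 0) next
    r <- stats::cor(ytr, preds)
    if (is.finite(r)) scores[g] <- r
  }
  if (all(!is.finite(scores))) return(1L)
  which.max(scores)  # first maximum = smallest complexity by grid order
}

#' One run of double-looped (nested) cross-validation
#'
#' For every outer fold, an inner `k_inner`-fold cross-validation over the
#' hyperparameter grid — run only on the outer-training samples — picks the
#' grid row whose pooled inner out-of-fold predictions correlate best
#' (signed Pearson r; ties resolved toward the most-regularized row); the
#' model is refit on the full outer-training set
#' and the held-out fold predicted. The run score is the squared Pearson
#' correlation of the pooled out-of-fold predictions against `y`.
#'
#' @param family regression family name.
#' @param X samples x predictors matrix.
#' @param y response vector.
#' @param plan a `fold_plan` covering `nrow(X)` samples.
#' @param run run index into the plan.
#' @param grid optional fixed hyperparameter grid; by default
#'   [default_grid()] is resolved per outer-training set.
#' @param feature_sets optional list (one element per outer fold) of
#'   predictor column indices to use in that fold — the hook used by the
#'   honest benchmark to nest feature selection.
#' @return list with `r2`, per-sample `predictions`, `chosen` hyperparameters
#'   per fold, `status` ("ok"/"NA") and `reason`.
#' @export
nested_cv <- function(family, X, y, plan, run = 1, grid = NULL,
                      feature_sets = NULL) {
  stopifnot(inherits(plan, "fold_plan"))
  X <- as.matrix(X)
  if (nrow(X) != plan$n) stop("plan does not match the data")
  folds <- plan$assignment[, run]
  run_seed <- plan$run_seeds[run]
  preds <- rep(NA_real_, plan$n)
  chosen <- vector("list", plan$k_outer)
  na_folds <- 0L
  for (f in seq_len(plan$k_outer)) {
    tr <- folds != f
    cols <- if (is.null(feature_sets)) seq_len(ncol(X)) else feature_sets[[f]]
    Xtr <- X[tr, cols, drop = FALSE]
    ytr <- y[tr]
    g <- if (is.null(grid)) default_grid(family, Xtr, ytr) else grid
    strata_tr <- if (is.null(plan$strata)) NULL else plan$strata[tr]
    gi <- .inner_select(family, Xtr, ytr, g, plan$k_inner, strata_tr,
                        seed = child_seed(run_seed, f))
    chosen[[f]] <- g[gi, , drop = FALSE]
    fit <- tryCatch(
      fit_regression(family, Xtr, ytr, hyper = g[gi, , drop = FALSE],
                     seed = child_seed(run_seed, 1000 + f)),
      error = function(e) NULL)
    if (is.null(fit) || is_na_model(fit)) { na_folds <- na_folds + 1L; next }
    preds[folds == f] <- predict(fit, X[folds == f, cols, drop = FALSE])
  }
  r2 <- tryCatch(pearson_r2(y, preds), error = function(e) NA_real_)
  status <- if (is.na(r2)) "NA" else "ok"
  reason <- if (is.na(r2)) {
    if (na_folds == plan$k_outer) "NA-model in every outer fold"
    else if (na_folds > 0 || anyNA(preds)) "NA predictions in some folds"
    else "constant predictions"
  } else ""
  list(run_seed = run_seed, predictions = preds, chosen = chosen,
       r2 = r2, status = status, reason = reason)
}

#' Repeated nested cross-validation for one family
#'
#' @inheritParams nested_cv
#' @param runs which runs of the plan to execute (default: all).
#' @return list with per-run `r2`, `mean`, `sd`, `status` and `reason`;
#'   a family returning NA in any run yields an NA cell.
#' @export
repeat_cv <- function(family, X, y, plan, grid = NULL, runs = NULL,
                      feature_sets = NULL) {
  runs <- runs %||% seq_len(plan$n_runs)
  res <- lapply(runs, function(r) {
    fs <- if (is.null(feature_sets)) NULL else feature_sets[[r]]
    nested_cv(family, X, y, plan, run = r, grid = grid, feature_sets = fs)
  })
  r2 <- vapply(res, `[[`, numeric(1), "r2")
  if (anyNA(r2)) {
    reasons <- unique(vapply(res, `[[`, character(1), "reason"))
    list(r2 = r2, mean = NA_real_, sd = NA_real_, status = "NA",
         reason = paste(reasons[nzchar(reasons)], collapse = "; "))
  } else {
    list(r2 = r2, mean = mean(r2), sd = stats::sd(r2), status = "ok",
         reason = "")
  }
}

.bundle_xy <- function(bundle, probe_ids) {
  missing <- setdiff(probe_ids, rownames(bundle$expression))
  if (length(missing)) {
    stop("predictor probes absent from the bundle: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  list(X = t(bundle$expression[probe_ids, , drop = FALSE]),
       y = as.numeric(bundle$residue))
}

#' Benchmark regression families on one study bundle
#'
#' The original-protocol ("faithful") benchmark: the predictor set is fixed
#' up-front, and each family is scored by `n_runs` runs of nested 10-fold
#' cross-validation on the predictor-restricted expression matrix. Folds are
#' stratified by treatment class so each fold spans the dose range.
#'
#' @param bundle a `study_bundle`.
#' @param predictor_ids character vector of predictor probe ids (or a
#'   `predictor_set`).
#' @param families families to benchmark (default: all 18).
#' @param n_runs repeated CV runs per family (default 10).
#' @param k_outer,k_inner fold counts.
#' @param master_seed seed for the fold plan.
#' @param stratify stratify folds by `class_label` (default TRUE).
#' @return a `performance_table`: data.frame (family, mean_r2, sd_r2, n_runs,
#'   status, reason) with attributes `dataset`, `predictor_size`, `best`.
#' @export
benchmark <- function(bundle, predictor_ids,
                      families = model_registry()$family,
                      n_runs = 10, k_outer = 10, k_inner = 9,
                      master_seed = 1, stratify = TRUE) {
  stopifnot(inherits(bundle, "study_bundle"))
  if (inherits(predictor_ids, "predictor_set")) {
    predictor_ids <- predictor_ids$probe_id
  }
  if (!length(predictor_ids)) stop("empty predictor set")
  xy <- .bundle_xy(bundle, predictor_ids)
  strata <- if (stratify) bundle$annotation$class_label else NULL
  plan <- make_fold_plan(length(xy$y), k_outer, k_inner, n_runs,
                         master_seed, strata)
  rows <- lapply(families, function(fam) {
    cv <- repeat_cv(fam, xy$X, xy$y, plan)
    data.frame(family = fam, mean_r2 = cv$mean, sd_r2 = cv$sd,
               n_runs = length(cv$r2), status = cv$status,
               reason = cv$reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("performance_table", "data.frame")
  attr(out, "dataset") <- sprintf("%s_D%g", bundle$annotation$compound[1],
                                  bundle$annotation$duration[1])
  attr(out, "predictor_size") <- length(predictor_ids)
  attr(out, "mode") <- "faithful"
  best <- which.max(out$mean_r2)
  attr(out, "best") <- if (length(best)) out$family[best] else NA_character_
  out
}

#' Default predictor-selection recipe for the honest benchmark
#'
#' Returns a closure mapping (expression, classes, residue) for a training
#' subset to predictor probe ids: permutation-selected DE genes augmented
#' with the top/bottom correlated extremes. When the DE test selects nothing
#' and no gene passes the correlation cutoff, the extremes are drawn from the
#' full ranking (fallback, flagged in attribute `fallback`).
#'
#' @param confidence,fdr_bound,n_permutations,seed DE-test settings.
#' @param cutoff |r| cutoff for the correlated-gene list.
#' @param n_top,n_bottom extreme genes per end.
#' @param run_de run the (comparatively costly) DE test at all; when FALSE
#'   the recipe uses correlation extremes only.
#' @return `function(x, classes, residue) -> character vector of probe ids`.
#' @export
default_selection_recipe <- function(confidence = 0.80, fdr_bound = 0.10,
                                     n_permutations = 200, seed = 1,
                                     cutoff = 0.6, n_top = 2, n_bottom = 2,
                                     run_de = TRUE) {
  function(x, classes, residue) {
    de_ids <- character(0)
    if (run_de && length(unique(classes)) >= 2) {
      de_ids <- tryCatch(
        multivariate_permutation_select(
          x, classes, confidence = confidence, fdr_bound = fdr_bound,
          n_permutations = n_permutations, seed = seed)$probe_ids,
        error = function(e) character(0))
    }
    ranking <- correlation_rank(x, residue)
    set <- augment_with_extremes(predictor_set(de_ids, "DE"), ranking,
                                 n_top, n_bottom, cutoff = cutoff)
    fallback <- FALSE
    if (nrow(set) == 0) {  # nothing significant, nothing past the cutoff
      set <- augment_with_extremes(predictor_set(character(0)), ranking,
                                   n_top, n_bottom, cutoff = NULL)
      fallback <- TRUE
    }
    structure(set$probe_id, fallback = fallback)
  }
}

#' Honest benchmark: predictor selection nested inside the outer loop
#'
#' Identical to [benchmark()] except that the predictor set is re-derived
#' from each outer-training split by `recipe`, so the selection step cannot
#' leak test-fold information into the reported R2. The gap between the
#' faithful and the honest table quantifies selection bias.
#'
#' @inheritParams benchmark
#' @param recipe a selection closure, e.g. [default_selection_recipe()].
#' @return a `performance_table` with attribute `mode = "honest"`.
#' @export
honest_benchmark <- function(bundle, recipe = default_selection_recipe(),
                             families = model_registry()$family,
                             n_runs = 10, k_outer = 10, k_inner = 9,
                             master_seed = 1, stratify = TRUE) {
  stopifnot(inherits(bundle, "study_bundle"))
  expr <- bundle$expression
  Xall <- t(expr)
  y <- as.numeric(bundle$residue)
  classes <- bundle$annotation$class_label
  strata <- if (stratify) classes else NULL
  plan <- make_fold_plan(length(y), k_outer, k_inner, n_runs,
                         master_seed, strata)
  # per (run, fold) predictor columns, shared across families
  feature_sets <- lapply(seq_len(plan$n_runs), function(r) {
    folds <- plan$assignment[, r]
    lapply(seq_len(plan$k_outer), function(f) {
      tr <- folds != f
      ids <- recipe(expr[, tr, drop = FALSE], classes[tr], y[tr])
      match(ids, rownames(expr))
    })
  })
  rows <- lapply(families, function(fam) {
    cv <- repeat_cv(fam, Xall, y, plan, feature_sets = feature_sets)
    data.frame(family = fam, mean_r2 = cv$mean, sd_r2 = cv$sd,
               n_runs = length(cv$r2), status = cv$status,
               reason = cv$reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("performance_table", "data.frame")
  attr(out, "dataset") <- sprintf("%s_D%g", bundle$annotation$compound[1],
                                  bundle$annotation$duration[1])
  attr(out, "predictor_size") <- NA_integer_
  attr(out, "mode") <- "honest"
  best <- which.max(out$mean_r2)
  attr(out, "best") <- if (length(best)) out$family[best] else NA_character_
  out
}

#' Cross-validated evaluator closure for the incremental scan
#'
#' @param bundle a `study_bundle`.
#' @param family regression family used for scoring (default "ridge").
#' @param n_runs CV runs averaged per evaluation.
#' @param master_seed fold-plan seed.
#' @return `function(probe_ids) -> mean nested-CV R2`.
#' @export
make_cv_evaluator <- function(bundle, family = "ridge", n_runs = 2,
                              master_seed = 1) {
  strata <- bundle$annotation$class_label
  n <- length(bundle$residue)
  plan <- make_fold_plan(n, 10, 9, n_runs, master_seed, strata)
  function(probe_ids) {
    if (!length(probe_ids)) return(NA_real_)
    xy <- .bundle_xy(bundle, probe_ids)
    cv <- repeat_cv(family, xy$X, xy$y, plan)
    cv$mean
  }
}

#' Write benchmark tables in the familiar wide layout
#'
#' Produces a human-readable table (one column per dataset, cells
#' "mean ± sd", NA cells rendered "NA", a "Predictor size (gene #)" header
#' row and the best family per dataset starred) plus a machine-readable long
#' TSV at `<path>.tsv`.
#'
#' @param tables a `performance_table` or a named list of them
#'   (one per dataset).
#' @param path output path for the pretty table.
#' @return invisibly, the long-format data.frame that was written.
#' @export
report <- function(tables, path) {
  if (inherits(tables, "performance_table")) tables <- list(tables)
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- vapply(tables, function(t) attr(t, "dataset"),
                            character(1))
  }
  fams <- tables[[1]]$family
  long <- do.call(rbind, lapply(names(tables), function(nm) {
    t <- tables[[nm]]
    data.frame(dataset = nm, family = t$family, mean_r2 = t$mean_r2,
               sd_r2 = t$sd_r2, n_runs = t$n_runs, status = t$status,
               reason = t$reason,
               best = !is.na(t$mean_r2) &
                 t$family == (attr(t, "best") %||% ""),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(long, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cell <- function(t, fam) {
    i <- match(fam, t$family)
    if (is.na(t$mean_r2[i])) return("NA")
    s <- sprintf("%.2f ± %.2f", t$mean_r2[i], t$sd_r2[i])
    if (identical(attr(t, "best"), fam)) s <- paste0(s, " *")
    s
  }
  header <- c("Regression method", names(tables))
  sizes <- c("Predictor size (gene #)",
             vapply(tables, function(t) {
               as.character(attr(t, "predictor_size") %||% NA)
             }, character(1)))
  body <- t(vapply(fams, function(fam) {
    c(fam, vapply(tables, cell, character(1), fam = fam))
  }, character(length(tables) + 1)))
  widths <- pmax(nchar(header),
                 apply(rbind(sizes, body), 2, function(cl) max(nchar(cl))))
  fmt <- function(row) paste(mapply(formatC, row, width = widths,
                                    flag = "-"), collapse = "  ")
  writeLines(c(fmt(header), fmt(sizes), apply(body, 1, fmt)), path)
  invisible(long)
}
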