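# Random-variance moderated t/F test and multivariate-permutation
# FDR-confidence gene selection.
#
# Hierarchical variance model: gene-wise precisions 1/sigma^2 are
# Gamma(shape a, scale b), i.e. sigma^2 is inverse-gamma. Marginally the
# pooled residual variance s^2 with m degrees of freedom then satisfies
#   a * b * s^2 ~ F(m, 2a),
# which is the cross-gene law fitted by maximum likelihood. The moderated
# denominator combines data and prior:
#   s_tilde^2 = (m * s^2 + 2/b) / (m + 2a),  df = m + 2a.
# As a -> 0 (with b large) this reduces to the ordinary pooled t/F test.

#' Per-probe pooled within-class residual variances
#'
#' @param x probes x samples matrix.
#' @param classes factor (or coercible) of length `ncol(x)`.
#' @return list with `s2` (per-probe pooled variance), `df` (n - k),
#'   `means` (probes x classes matrix of class means), `counts`.
#' @export
residual_variances <- function(x, classes) {
  classes <- droplevels(as.factor(classes))
  if (length(classes) != ncol(x)) stop("classes must match columns of x")
  counts <- table(classes)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    keep <- !(classes %in% small)
    warning("dropping singleton class(es): ", paste(small, collapse = ", "))
    x <- x[, keep, drop = FALSE]
    classes <- droplevels(classes[keep])
    counts <- table(classes)
  }
  k <- nlevels(classes)
  n <- ncol(x)
  if (k < 2) stop("degrees-of-freedom error: need >= 2 classes with >= 2 samples")
  m <- n - k
  if (m < 1) stop("degrees-of-freedom error: no residual degrees of freedom")
  Z <- stats::model.matrix(~ classes - 1)
  means <- x %*% Z %*% diag(1 / as.numeric(counts), k)
  colnames(means) <- levels(classes)
  resid <- x - means[, as.integer(classes), drop = FALSE]
  list(s2 = rowSums(resid^2) / m, df = m, means = means,
       counts = as.numeric(counts), classes = classes)
}

#' Construct a random-variance prior by hand
#'
#' @param a shape hyperparameter (> 0).
#' @param b scale hyperparameter (> 0).
#' @param m per-gene residual degrees of freedom.
#' @param loglik optional achieved log-likelihood.
#' @return an object of class `rv_prior`.
#' @export
rv_prior <- function(a, b, m = NA_real_, loglik = NA_real_) {
  if (a <= 0 || b <= 0) stop("a and b must be > 0")
  structure(list(a = a, b = b, m = m, loglik = loglik,
                 converged = NA, boundary = FALSE),
            class = "rv_prior")
}

.rv_loglik <- function(a, b, s2, m) {
  sum(log(a * b) + stats::df(a * b * s2, df1 = m, df2 = 2 * a, log = TRUE))
}

#' Fit the random-variance prior by maximum marginal likelihood
#'
#' Maximizes the scaled-F likelihood of the observed residual variances over
#' the inverse-gamma hyperparameters (a, b). Degenerate inputs with (nearly)
#' equal variances return a large-a capped fit flagged `boundary = TRUE`.
#'
#' @param s2 vector of per-probe pooled residual variances.
#' @param m shared residual degrees of freedom.
#' @return an `rv_prior` with fields a, b, m, loglik, converged, boundary.
#' @export
fit_random_variance_prior <- function(s2, m) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 10) stop("fit error: need >= 10 positive variances")
  mu <- mean(s2)
  if (stats::sd(s2) / mu < 1e-10) {
    a_cap <- 1e6
    fit <- rv_prior(a_cap, 1 / ((a_cap - 1) * mu), m = m)
    fit$boundary <- TRUE
    fit$converged <- TRUE
    fit$loglik <- .rv_loglik(a_cap, fit$b, s2, m)
    warning("all variances (nearly) equal; returning capped large-a fit")
    return(fit)
  }
  neg <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    if (!is.finite(a) || !is.finite(b) || a > 1e8) return(1e12)
    ll <- .rv_loglik(a, b, s2, m)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  starts <- lapply(c(0.5, 2, 5), function(a0) {
    c(log(a0), log(1 / (max(a0 - 0.5, 0.5) * mu)))
  })
  best <- NULL
  for (st in starts) {
    o <- stats::optim(st, neg, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (!is.finite(best$value) || best$value >= 1e12) {
    stop("fit error: random-variance likelihood optimization failed")
  }
  fit <- rv_prior(exp(best$par[1]), exp(best$par[2]), m = m)
  fit$loglik <- -best$value
  fit$converged <- best$convergence == 0
  fit
}

#' Shrunken (moderated) variance estimates
#'
#' @param s2 observed pooled variances.
#' @param prior an `rv_prior`.
#' @param m residual degrees of freedom (defaults to the prior's).
#' @return posterior-combined variances `(m*s2 + 2/b) / (m + 2a)`.
#' @export
shrink_variances <- function(s2, prior, m = prior$m) {
  (m * s2 + 2 / prior$b) / (m + 2 * prior$a)
}

.stat_from_rv <- function(rv, prior) {
  k <- length(rv$counts)
  n <- sum(rv$counts)
  if (is.null(prior)) {
    v <- rv$s2
    df2 <- rv$df
  } else {
    v <- shrink_variances(rv$s2, prior, m = rv$df)
    df2 <- rv$df + 2 * prior$a
  }
  gm <- as.numeric(rv$means %*% rv$counts) / n
  if (k == 2) {
    se2 <- v * (1 / rv$counts[1] + 1 / rv$counts[2])
    stat <- (rv$means[, 1] - rv$means[, 2]) / sqrt(se2)
    stat[se2 == 0] <- 0
    p <- 2 * stats::pt(-abs(stat), df2)
    list(statistic = stat, p_value = p, type = "t", df1 = 1, df2 = df2)
  } else {
    msb <- colSums(rv$counts * (t(rv$means) - rep(gm, each = k))^2) / (k - 1)
    stat <- ifelse(v > 0, msb / v, ifelse(msb > 0, Inf, 0))
    p <- stats::pf(stat, k - 1, df2, lower.tail = FALSE)
    list(statistic = stat, p_value = p, type = "F", df1 = k - 1, df2 = df2)
  }
}

#' Moderated t/F statistic with random-variance shrinkage
#'
#' Two classes give the moderated t; more give the moderated F. The
#' denominator is the shrunken variance with `m + 2a` degrees of freedom;
#' parametric p-values come from the corresponding t/F reference
#' distribution. Without a prior, the ordinary pooled test is used with a
#' warning.
#'
#' @param x probes x samples matrix.
#' @param classes class labels, length `ncol(x)`.
#' @param prior an `rv_prior`, or NULL for the ordinary test.
#' @return data.frame (probe_id, statistic, p_value) with attributes
#'   `type`, `df1`, `df2`.
#' @export
moderated_statistic <- function(x, classes, prior = NULL) {
  if (is.null(prior)) {
    warning("no random-variance prior supplied; using ordinary t/F test")
  } else stopifnot(inherits(prior, "rv_prior"))
  rv <- residual_variances(x, classes)
  st <- .stat_from_rv(rv, prior)
  out <- data.frame(probe_id = rownames(x) %||% seq_len(nrow(x)),
                    statistic = as.numeric(st$statistic),
                    p_value = as.numeric(st$p_value),
                    stringsAsFactors = FALSE)
  attr(out, "type") <- st$type
  attr(out, "df1") <- st$df1
  attr(out, "df2") <- st$df2
  out
}

# Count (on the log scale) the number of distinct label arrangements,
# stratified by batch when given.
.log_n_arrangements <- function(classes, batch = NULL) {
  strata <- if (is.null(batch)) rep(1, length(classes)) else batch
  tot <- 0
  for (s in unique(strata)) {
    cnt <- table(classes[strata == s])
    tot <- tot + lgamma(sum(cnt) + 1) - sum(lgamma(cnt + 1))
  }
  tot
}

# All distinct two-class assignments as a list of level-1 index sets.
.exhaustive_two_class <- function(classes) {
  n <- length(classes)
  n1 <- sum(classes == levels(classes)[1])
  asplit(utils::combn(n, n1), 2)
}

#' Multivariate permutation selection of differentially expressed genes
#'
#' Selects the largest rejection set (largest p-value cutoff over the ordered
#' observed parametric p-values) such that, with the stated confidence, the
#' false-discovery proportion estimated across label permutations stays below
#' `fdr_bound`. The prior is fitted once on the observed data and held fixed
#' across permutations. Two-class comparisons with at most
#' `exhaustive_limit` distinct label assignments are enumerated exhaustively;
#' otherwise `n_permutations` label permutations are sampled (stratified
#' within `batch`, since batches are not exchangeable).
#'
#' @param x probes x samples matrix.
#' @param classes class labels, length `ncol(x)`.
#' @param confidence confidence level for the FDP bound (default 0.80).
#' @param fdr_bound false-discovery-proportion bound (default 0.10).
#' @param n_permutations sampled permutations when not exhaustive.
#' @param seed integer seed for the sampled permutations.
#' @param batch optional batch labels; permutations are stratified within.
#' @param prior optional pre-fitted `rv_prior`.
#' @param comparison_label free-text label stored with the result.
#' @param exhaustive_limit enumerate exhaustively when the number of distinct
#'   two-class assignments is at most this (default 5000).
#' @return an object of class `de_gene_set`: selected `probe_ids`, per-probe
#'   `statistic`, `p_value` and permutation p-value `perm_p`, the cutoff used
#'   and procedure metadata.
#' @export
multivariate_permutation_select <- function(x, classes,
                                            confidence = 0.80,
                                            fdr_bound = 0.10,
                                            n_permutations = 1000,
                                            seed = 1,
                                            batch = NULL,
                                            prior = NULL,
                                            comparison_label = "",
                                            exhaustive_limit = 5000) {
  classes <- droplevels(as.factor(classes))
  if (nlevels(classes) < 2) stop("need >= 2 classes")
  if (confidence <= 0 || confidence >= 1 || fdr_bound <= 0 || fdr_bound >= 1) {
    stop("confidence and fdr_bound must be in (0, 1)")
  }
  if (exp(.log_n_arrangements(classes, batch)) < 2) {
    stop("procedure error: classes admit no distinct label permutation")
  }
  n <- ncol(x)
  rv <- residual_variances(x, classes)
  if (is.null(prior)) prior <- fit_random_variance_prior(rv$s2, rv$df)
  obs <- .stat_from_rv(rv, prior)
  p_obs <- obs$p_value

  one_batch <- is.null(batch) || length(unique(batch)) == 1
  exhaustive <- one_batch && nlevels(classes) == 2 &&
    choose(n, sum(classes == levels(classes)[1])) <= exhaustive_limit
  if (exhaustive) {
    sets <- .exhaustive_two_class(classes)
    perms <- lapply(sets, function(idx1) {
      lab <- factor(rep(levels(classes)[2], n), levels = levels(classes))
      lab[idx1] <- levels(classes)[1]
      lab
    })
  } else {
    if (n_permutations < 100) stop("n_permutations must be >= 100")
    strata <- if (is.null(batch)) rep(1, n) else batch
    perms <- with_seed(seed, lapply(seq_len(n_permutations), function(i) {
      ord <- seq_len(n)
      for (s in unique(strata)) {
        idx <- which(strata == s)
        ord[idx] <- idx[sample.int(length(idx))]
      }
      classes[ord]
    }))
  }
  B <- length(perms)
  P <- vapply(perms, function(lab) {
    rvp <- residual_variances(x, lab)
    .stat_from_rv(rvp, prior)$p_value
  }, numeric(nrow(x)))

  # per-gene permutation p-value (sampled mode: add-one correction)
  hits <- rowSums(P <= p_obs + 1e-15)
  perm_p <- if (exhaustive) hits / B else (hits + 1) / (B + 1)

  # cutoff scan over distinct observed p-values
  p_sorted <- sort(p_obs)
  cutoffs <- unique(p_sorted)
  n_reject <- findInterval(cutoffs, p_sorted)
  Psort <- apply(P, 2, sort)
  if (!is.matrix(Psort)) Psort <- matrix(Psort, ncol = B)
  Vmat <- vapply(seq_len(B), function(b) {
    as.numeric(findInterval(cutoffs, Psort[, b]))
  }, numeric(length(cutoffs)))
  Vmat <- matrix(Vmat, nrow = length(cutoffs))
  FDP <- pmin(sweep(Vmat, 1, n_reject, "/"), 1)
  qidx <- min(B, max(1, ceiling(confidence * B)))
  qconf <- apply(FDP, 1, function(z) sort.int(z, partial = qidx)[qidx])
  admissible <- which(qconf < fdr_bound)
  if (length(admissible)) {
    best <- admissible[which.max(n_reject[admissible])]
    cutoff <- cutoffs[best]
    selected <- (rownames(x) %||% as.character(seq_len(nrow(x))))[
      p_obs <= cutoff]
  } else {
    cutoff <- NA_real_
    selected <- character(0)
  }
  structure(list(probe_ids = selected,
                 statistic = stats::setNames(obs$statistic, rownames(x)),
                 p_value = stats::setNames(p_obs, rownames(x)),
                 perm_p = stats::setNames(perm_p, rownames(x)),
                 cutoff = cutoff,
                 confidence = confidence, fdr_bound = fdr_bound,
                 n_permutations = B, exhaustive = exhaustive,
                 statistic_type = obs$type,
                 prior = prior, seed = seed,
                 comparison_label = comparison_label),
            class = "de_gene_set")
}

#' @export
print.de_gene_set <- function(x, ...) {
  cat(sprintf(
    "de_gene_set '%s': %d/%d probes selected (%s-test, %s, conf %.2f, FDR < %.2f, B = %d)\n",
    x$comparison_label, length(x$probe_ids), length(x$p_value),
    x$statistic_type, if (x$exhaustive) "exhaustive" else "sampled",
    x$confidence, x$fdr_bound, x$n_permutations))
  invisible(x)
}

#' Run one named group comparison on a study bundle
#'
#' Wraps the full DE pipeline for a comparison defined by an annotation
#' column (default `class_label`) or a labeling function. Samples with role
#' `t0` are excluded unless the grouping selects them. When both a blank and
#' a solvent control are present, they are first tested against each other;
#' if that two-class comparison selects zero genes the two groups are merged
#' into one control class for the main comparison.
#'
#' @param bundle a `study_bundle`.
#' @param grouping annotation column name, or `function(annotation)` returning
#'   one label per sample (NA drops a sample).
#' @param confidence,fdr_bound,n_permutations,seed passed to
#'   [multivariate_permutation_select()].
#' @param merge_controls apply the control-merge rule (default TRUE).
#' @param include_t0 keep role `t0` samples (default FALSE).
#' @return a `de_gene_set`; attribute `controls_merged` records the merge
#'   decision, `n_classes` the class count used.
#' @export
compare_groups <- function(bundle, grouping = "class_label",
                           confidence = 0.80, fdr_bound = 0.10,
                           n_permutations = 1000, seed = 1,
                           merge_controls = TRUE, include_t0 = FALSE) {
  stopifnot(inherits(bundle, "study_bundle"))
  ann <- bundle$annotation
  labels <- if (is.function(grouping)) grouping(ann) else {
    if (!grouping %in% names(ann)) {
      stop("configuration error: grouping column '", grouping, "' absent")
    }
    ann[[grouping]]
  }
  keep <- !is.na(labels)
  if (!include_t0) keep <- keep & ann$role != "t0"
  ann <- ann[keep, , drop = FALSE]
  labels <- as.character(labels[keep])
  x <- bundle$expression[, ann$sample_id, drop = FALSE]
  batch <- if (length(unique(ann$batch)) > 1) ann$batch else NULL

  merged <- FALSE
  if (merge_controls &&
      all(c("blank_control", "solvent_control") %in% ann$role)) {
    ctrl <- ann$role %in% c("blank_control", "solvent_control")
    ctrl_de <- multivariate_permutation_select(
      x[, ctrl, drop = FALSE], ann$role[ctrl],
      confidence = confidence, fdr_bound = fdr_bound,
      n_permutations = n_permutations, seed = child_seed(seed, 1),
      batch = if (is.null(batch)) NULL else batch[ctrl],
      comparison_label = "blank_vs_solvent_controls")
    if (length(ctrl_de$probe_ids) == 0) {
      labels[ctrl] <- "control"
      merged <- TRUE
    }
  }
  if (length(unique(labels)) < 2) {
    stop("configuration error: grouping yields fewer than 2 classes")
  }
  de <- multivariate_permutation_select(
    x, labels, confidence = confidence, fdr_bound = fdr_bound,
    n_permutations = n_permutations, seed = child_seed(seed, 2),
    batch = batch,
    comparison_label = if (is.character(grouping)) grouping else "custom")
  attr(de, "controls_merged") <- merged
  attr(de, "n_classes") <- length(unique(labels))
  de
}

#' Serialize a DE gene set as TSV
#'
#' One row per tested probe: probe id, statistic, parametric p, permutation p
#' and a selected flag.
#'
#' @param de a `de_gene_set`.
#' @param path output path.
#' @export
write_de_genes <- function(de, path) {
  stopifnot(inherits(de, "de_gene_set"))
  out <- data.frame(probe_id = names(de$p_value),
                    statistic = as.numeric(de$statistic),
                    p_value = as.numeric(de$p_value),
                    perm_p = as.numeric(de$perm_p),
                    selected = names(de$p_value) %in% de$probe_ids)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
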