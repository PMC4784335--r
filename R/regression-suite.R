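# Uniform fit/predict interface over 18 regression families.
#
# Families marked "linear": multivariate_ols, robust, ridge, lasso,
# elastic_net, svr_linear. The remaining 12 are nonlinear. Families with
# domain restrictions (loglog needs y > 0 and X > 0; inverse needs |y|
# bounded away from 0) return an NA-model whose predictions are all NA,
# mirroring "NA" entries in benchmark tables.

.FAMILIES <- data.frame(
  family = c("multivariate_ols", "robust", "ridge", "lasso", "elastic_net",
             "svr_linear", "stepwise", "ridge_poly", "ridge_exponential",
             "ridge_gaussian", "svr_poly", "svr_gaussian", "svr_sigmoid",
             "nadaraya_watson", "inverse", "loglog", "regression_tree",
             "random_forest"),
  linear = c(rep(TRUE, 6), rep(FALSE, 12)),
  stringsAsFactors = FALSE)

#' Registry of the 18 regression families
#'
#' @return data.frame with columns `family` and `linear` (6 linear,
#'   12 nonlinear families).
#' @export
model_registry <- function() .FAMILIES

.check_family <- function(family) {
  if (!family %in% .FAMILIES$family) {
    stop("configuration error: unknown regression family '", family, "'")
  }
  family
}

# --- standardization helpers -------------------------------------------------

.std_fit <- function(X) {
  mu <- colMeans(X)
  sd <- sqrt(colMeans(sweep(X, 2, mu)^2))  # population sd (glmnet convention)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}

.std_apply <- function(X, std) sweep(sweep(X, 2, std$mu), 2, std$sd, "/")

.pairwise_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

.median_heuristic <- function(Xs) {
  d <- .pairwise_dist(Xs, Xs)
  med <- stats::median(d[upper.tri(d)])
  if (!is.finite(med) || med <= 0) med <- 1
  med
}

# --- hyperparameter grids ----------------------------------------------------

#' Default hyperparameter grid for a family
#'
#' Grids are returned as data.frames (one row per combination) ordered from
#' most- to least-regularized (smallest model complexity first), which is the
#' tie-breaking order of the inner cross-validation loop. Data-dependent
#' grids (median-heuristic kernel widths, sd(y)-scaled SVR epsilon) are
#' resolved from the supplied training data.
#'
#' @param family one of the 18 registered families.
#' @param X,y training data used to resolve data-dependent grid values;
#'   may be NULL for families with fixed grids.
#' @return data.frame of hyperparameter combinations (possibly zero columns
#'   for grid-free families).
#' @export
default_grid <- function(family, X = NULL, y = NULL) {
  .check_family(family)
  lam <- 10^seq(4, -4, length.out = 10)   # most regularized first
  lam_k <- 10^seq(3, -3, length.out = 7)
  med <- function() {
    if (is.null(X)) return(1)
    .median_heuristic(.std_apply(as.matrix(X), .std_fit(as.matrix(X))))
  }
  sdy <- if (is.null(y)) 1 else max(stats::sd(y), 1e-8)
  no_grid <- data.frame(matrix(nrow = 1, ncol = 0))
  svr_base <- expand.grid(epsilon = c(0.01, 0.1, 1) * sdy,
                          cost = 10^(-2:3))[, 2:1]
  switch(family,
    multivariate_ols = , robust = , stepwise = , inverse = ,
    loglog = no_grid,
    ridge = data.frame(lambda = lam),
    lasso = data.frame(lambda = lam),
    elastic_net = expand.grid(alpha = seq(0.1, 0.9, by = 0.1),
                              lambda = lam)[, 2:1],
    svr_linear = svr_base,
    svr_poly = merge(svr_base, data.frame(degree = c(2, 3))),
    svr_gaussian = merge(svr_base,
                         data.frame(sigma = med() * c(4, 2, 1, 0.5, 0.25))),
    svr_sigmoid = merge(svr_base, data.frame(coef0 = c(-1, 0, 1),
                                             sigma = med())),
    ridge_poly = expand.grid(degree = c(2, 3), lambda = lam_k)[, 2:1],
    ridge_exponential = expand.grid(sigma = med() * c(4, 2, 1, 0.5, 0.25),
                                    lambda = lam_k)[, 2:1],
    ridge_gaussian = expand.grid(sigma = med() * c(4, 2, 1, 0.5, 0.25),
                                 lambda = lam_k)[, 2:1],
    nadaraya_watson = data.frame(
      bandwidth = med() * c(3, 2, 1.5, 1, 0.75, 0.5, 0.25, 0.1)),
    regression_tree = expand.grid(maxdepth = 2:6, minbucket = c(5, 2))[, 2:1],
    random_forest = {
      p <- if (is.null(X)) 1 else ncol(as.matrix(X))
      data.frame(mtry = unique(c(ceiling(p / 3), ceiling(sqrt(p)))))
    })
}

# --- NA-model ----------------------------------------------------------------

.na_model <- function(family, reason) {
  structure(list(family = family, na_model = TRUE, reason = reason),
            class = "fitted_model")
}

#' Is a fitted model an NA-model?
#' @param model a `fitted_model`.
#' @export
is_na_model <- function(model) isTRUE(model$na_model)

# --- fitting -----------------------------------------------------------------

#' Fit one regression family with fixed hyperparameters
#'
#' @param family one of the 18 registered families (see [model_registry()]).
#' @param X samples x predictors numeric matrix (no missing values).
#' @param y numeric response (tissue residue).
#' @param hyper named list / one-row data.frame of hyperparameters; missing
#'   entries take the first (most regularized) row of [default_grid()].
#' @param seed integer seed for stochastic fits (random forest).
#' @return an object of class `fitted_model`; use [predict()] on it.
#'   Domain-violating inputs give an NA-model rather than an error.
#' @export
fit_regression <- function(family, X, y, hyper = list(), seed = NULL) {
  .check_family(family)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  colnames(X) <- paste0("V", seq_len(ncol(X)))  # predictors are positional
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y")
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  hyper <- as.list(hyper)
  defaults <- as.list(default_grid(family, X, y)[1, , drop = FALSE])
  for (nm in names(defaults)) {
    if (is.null(hyper[[nm]])) hyper[[nm]] <- defaults[[nm]]
  }
  fit <- switch(family,
    multivariate_ols = .fit_ols(X, y),
    robust = .fit_robust(X, y),
    ridge = .fit_ridge(X, y, hyper$lambda),
    lasso = .fit_glmnet(X, y, alpha = 1, lambda = hyper$lambda),
    elastic_net = .fit_glmnet(X, y, alpha = hyper$alpha,
                              lambda = hyper$lambda),
    svr_linear = .fit_svr(X, y, kernel = "linear", hyper),
    stepwise = .fit_stepwise(X, y),
    ridge_poly = .fit_krr(X, y, "poly", hyper),
    ridge_exponential = .fit_krr(X, y, "laplacian", hyper),
    ridge_gaussian = .fit_krr(X, y, "gaussian", hyper),
    svr_poly = .fit_svr(X, y, kernel = "polynomial", hyper),
    svr_gaussian = .fit_svr(X, y, kernel = "radial", hyper),
    svr_sigmoid = .fit_svr(X, y, kernel = "sigmoid", hyper),
    nadaraya_watson = .fit_nw(X, y, hyper$bandwidth),
    inverse = .fit_inverse(X, y),
    loglog = .fit_loglog(X, y),
    regression_tree = .fit_tree(X, y, hyper),
    random_forest = .fit_rf(X, y, hyper, seed))
  fit$family <- family
  fit$hyper <- hyper
  fit$p <- ncol(X)
  class(fit) <- "fitted_model"
  fit
}

#' @export
predict.fitted_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is_na_model(object)) return(rep(NA_real_, nrow(newdata)))
  if (ncol(newdata) != object$p) {
    stop("contract error: newdata has ", ncol(newdata),
         " predictors, model expects ", object$p)
  }
  storage.mode(newdata) <- "double"
  colnames(newdata) <- paste0("V", seq_len(ncol(newdata)))
  out <- object$predict_fun(object, newdata)
  out <- as.numeric(out)
  out[!is.finite(out)] <- NA_real_
  out
}

#' @export
print.fitted_model <- function(x, ...) {
  if (is_na_model(x)) {
    cat(sprintf("fitted_model <%s>: NA-model (%s)\n", x$family, x$reason))
  } else {
    cat(sprintf("fitted_model <%s>, p = %d\n", x$family, x$p))
  }
  invisible(x)
}

# ordinary least squares via SVD (minimum-norm solution on rank deficiency)
.fit_ols <- function(X, y) {
  mu <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2, mu); yc <- y - ybar
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * max(sv$d, 0) * .Machine$double.eps
  pos <- sv$d > tol
  beta <- if (any(pos)) {
    sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% yc) / sv$d[pos])
  } else matrix(0, ncol(X), 1)
  list(beta = as.numeric(beta),
       intercept = ybar - sum(mu * beta),
       min_norm = !all(pos),
       predict_fun = function(m, Xn) Xn %*% m$beta + m$intercept)
}

.fit_robust <- function(X, y) {
  df <- data.frame(y = y, X)
  fit <- tryCatch(
    suppressWarnings(MASS::rlm(y ~ ., data = df, psi = MASS::psi.huber,
                               k = 1.345, maxit = 50)),
    error = function(e) NULL)
  if (is.null(fit)) return(.na_model("robust", "IRLS fit failed"))
  list(fit = fit,
       predict_fun = function(m, Xn) {
         nd <- data.frame(Xn)
         colnames(nd) <- colnames(data.frame(X))
         unname(stats::predict(m$fit, newdata = nd))
       })
}

# Closed-form ridge in glmnet penalty units: predictors standardized with
# population sd, the response standardized internally (so the effective
# penalty on the original-scale problem is lambda / sd_n(y), matching what
# glmnet(alpha = 0) computes for the same lambda); lambda = 0 is exactly OLS.
.fit_ridge <- function(X, y, lambda) {
  std <- .std_fit(X)
  Xs <- .std_apply(X, std)
  yc <- y - mean(y)
  n <- nrow(X); p <- ncol(X)
  sdy <- sqrt(mean(yc^2))
  lam_eff <- if (sdy > 0) lambda / sdy else lambda
  A <- crossprod(Xs) / n + diag(lam_eff, p)
  bs <- tryCatch(solve(A, crossprod(Xs, yc) / n),
                 error = function(e) MASS::ginv(A) %*% (crossprod(Xs, yc) / n))
  beta <- as.numeric(bs) / std$sd
  list(beta = beta, intercept = mean(y) - sum(std$mu * beta),
       predict_fun = function(m, Xn) Xn %*% m$beta + m$intercept)
}

.fit_glmnet <- function(X, y, alpha, lambda) {
  X1 <- X
  if (ncol(X1) < 2) X1 <- cbind(X1, .const = 0)  # glmnet needs >= 2 columns
  lam_path <- sort(unique(c(lambda, lambda * c(16, 8, 4, 2))),
                   decreasing = TRUE)
  fit <- glmnet::glmnet(X1, y, alpha = alpha, lambda = lam_path,
                        standardize = TRUE, thresh = 1e-12, maxit = 1e6)
  list(fit = fit, lambda = lambda, pad = ncol(X1) > ncol(X),
       predict_fun = function(m, Xn) {
         if (m$pad) Xn <- cbind(Xn, .const = 0)
         as.numeric(stats::predict(m$fit, newx = Xn, s = m$lambda))
       })
}

.fit_svr <- function(X, y, kernel, hyper) {
  scale_cols <- apply(X, 2, stats::sd) > 0
  gamma <- if (!is.null(hyper$sigma)) 1 / (2 * hyper$sigma^2) else 1 / ncol(X)
  args <- list(x = X, y = y, type = "eps-regression", kernel = kernel,
               cost = hyper$cost %||% 1,
               epsilon = hyper$epsilon %||% 0.1,
               scale = scale_cols, fitted = FALSE)
  if (kernel == "polynomial") {
    args$degree <- hyper$degree %||% 2; args$gamma <- 1; args$coef0 <- 1
  } else if (kernel == "radial") {
    args$gamma <- gamma
  } else if (kernel == "sigmoid") {
    args$gamma <- gamma; args$coef0 <- hyper$coef0 %||% 0
  }
  fit <- tryCatch(suppressWarnings(do.call(e1071::svm, args)),
                  error = function(e) NULL)
  if (is.null(fit)) return(.na_model(paste0("svr_", kernel), "svm fit failed"))
  list(fit = fit,
       predict_fun = function(m, Xn) {
         if (m$fit$tot.nSV == 0) {
           # no support vectors (epsilon tube covers all residuals): the
           # regression function is the constant -rho on libsvm's scale
           v <- -m$fit$rho
           if (!is.null(m$fit$y.scale)) {
             v <- v * m$fit$y.scale$`scaled:scale` +
               m$fit$y.scale$`scaled:center`
           }
           return(rep(v, nrow(Xn)))
         }
         unname(stats::predict(m$fit, Xn))
       })
}

.fit_stepwise <- function(X, y) {
  df <- data.frame(y = y, X)
  preds <- setdiff(colnames(df), "y")
  scope <- stats::reformulate(preds, response = "y")
  base <- stats::lm(y ~ 1, data = df)
  fit <- tryCatch(
    suppressWarnings(stats::step(base,
                                 scope = list(lower = ~1, upper = scope),
                                 direction = "both", trace = 0, k = 2)),
    error = function(e) base)
  list(fit = fit, xnames = preds,
       predict_fun = function(m, Xn) {
         nd <- data.frame(Xn); colnames(nd) <- m$xnames
         unname(stats::predict(m$fit, newdata = nd))
       })
}

.kernel_matrix <- function(kind, A, B, hyper) {
  switch(kind,
    poly = (A %*% t(B) + 1)^(hyper$degree %||% 2),
    laplacian = exp(-.pairwise_dist(A, B) / (hyper$sigma %||% 1)),
    gaussian = exp(-.pairwise_dist(A, B)^2 / (2 * (hyper$sigma %||% 1)^2)))
}

# kernel ridge: alpha = (K + lambda I)^{-1} (y - ybar) on standardized X
.fit_krr <- function(X, y, kind, hyper) {
  std <- .std_fit(X)
  Xs <- .std_apply(X, std)
  K <- .kernel_matrix(kind, Xs, Xs, hyper)
  n <- nrow(X)
  A <- K + diag(hyper$lambda %||% 1, n)
  alpha <- tryCatch(solve(A, y - mean(y)),
                    error = function(e) MASS::ginv(A) %*% (y - mean(y)))
  list(std = std, Xs = Xs, alpha = as.numeric(alpha), ybar = mean(y),
       kind = kind, khyper = hyper,
       predict_fun = function(m, Xn) {
         Kn <- .kernel_matrix(m$kind, .std_apply(Xn, m$std), m$Xs, m$khyper)
         as.numeric(Kn %*% m$alpha) + m$ybar
       })
}

.fit_nw <- function(X, y, bandwidth) {
  std <- .std_fit(X)
  list(std = std, Xs = .std_apply(X, std), y = y, h = bandwidth,
       predict_fun = function(m, Xn) {
         D <- .pairwise_dist(.std_apply(Xn, m$std), m$Xs)
         W <- exp(-D^2 / (2 * m$h^2))
         tot <- rowSums(W)
         out <- as.numeric(W %*% m$y) / tot
         dead <- !is.finite(out) | tot < .Machine$double.xmin
         if (any(dead)) {  # bandwidth underflow: nearest training point
           nn <- apply(D[dead, , drop = FALSE], 1, which.min)
           out[dead] <- m$y[nn]
         }
         out
       })
}

.fit_inverse <- function(X, y) {
  if (min(abs(y)) <= 1e-6 * stats::sd(y)) {
    return(.na_model("inverse",
                     "response values too close to zero for 1/y regression"))
  }
  df <- data.frame(z = 1 / y, X)
  fit <- stats::lm(z ~ ., data = df)
  list(fit = fit, xnames = setdiff(colnames(df), "z"),
       predict_fun = function(m, Xn) {
         nd <- data.frame(Xn); colnames(nd) <- m$xnames
         1 / unname(stats::predict(m$fit, newdata = nd))
       })
}

.fit_loglog <- function(X, y) {
  if (any(y <= 0) || any(X <= 0)) {
    return(.na_model("loglog",
                     "log-log regression needs strictly positive y and X"))
  }
  df <- data.frame(ly = log(y), log(X))
  fit <- stats::lm(ly ~ ., data = df)
  list(fit = fit, xnames = setdiff(colnames(df), "ly"),
       predict_fun = function(m, Xn) {
         out <- rep(NA_real_, nrow(Xn))
         ok <- apply(Xn > 0, 1, all)
         if (any(ok)) {
           nd <- data.frame(log(Xn[ok, , drop = FALSE]))
           colnames(nd) <- m$xnames
           out[ok] <- exp(unname(stats::predict(m$fit, newdata = nd)))
         }
         out
       })
}

.fit_tree <- function(X, y, hyper) {
  if (nrow(X) < 2) {
    return(list(const = mean(y),
                predict_fun = function(m, Xn) rep(m$const, nrow(Xn))))
  }
  df <- data.frame(y = y, X)
  mb <- hyper$minbucket %||% 2
  fit <- rpart::rpart(y ~ ., data = df, method = "anova",
                      control = rpart::rpart.control(
                        maxdepth = hyper$maxdepth %||% 3,
                        minbucket = mb, minsplit = 2 * mb,
                        cp = 0, xval = 0))
  list(fit = fit, xnames = setdiff(colnames(df), "y"),
       predict_fun = function(m, Xn) {
         nd <- data.frame(Xn); colnames(nd) <- m$xnames
         unname(stats::predict(m$fit, newdata = nd))
       })
}

.fit_rf <- function(X, y, hyper, seed) {
  mtry <- min(hyper$mtry %||% max(1, floor(ncol(X) / 3)), ncol(X))
  fit <- with_seed(seed %||% 1,
                   randomForest::randomForest(X, y, ntree = 500, mtry = mtry))
  list(fit = fit,
       predict_fun = function(m, Xn) unname(stats::predict(m$fit, Xn)))
}
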