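# Synthetic study generator: dose/duration-dependent tissue residue,
# residue-linked transcripts, batch effects, inverse-gamma gene variances.

#' Describe a soil-exposure experimental design
#'
#' One design covers a compound amended into soil at several nominal
#' concentrations, sampled at one or more exposure durations, with replicate
#' arrays per treatment. Two zero-level concentrations are interpreted as a
#' blank control plus a solvent (carrier) control; a single zero is one
#' untreated control. An optional T = 0 group represents worms sampled before
#' exposure started.
#'
#' @param compound compound label, e.g. "HMX".
#' @param durations exposure durations in days.
#' @param concentrations nominal soil concentrations (mg/kg), including the
#'   0-level control(s). At most two zeros (blank + solvent control).
#' @param replicates replicate arrays per treatment (>= 2).
#' @param batches batch labels; separate exposures (e.g. "original", "repeat")
#'   each carry a full set of treatments.
#' @param include_t0 add a T = 0 sampling group per batch.
#' @return an object of class `exposure_design`.
#' @export
exposure_design <- function(compound = "HMX",
                            durations = c(4, 14, 28),
                            concentrations = c(0, 0, 8, 16, 32, 64, 128),
                            replicates = 5,
                            batches = "original",
                            include_t0 = TRUE) {
  .assert_finite_params(durations = durations, concentrations = concentrations,
                        replicates = replicates)
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  if (replicates < 2) stop("replicates must be >= 2")
  if (sum(concentrations == 0) < 1) {
    stop("design needs at least one 0-level control")
  }
  if (sum(concentrations == 0) > 2) {
    stop("at most two 0-level controls (blank + solvent) are supported")
  }
  if (length(batches) < 1) stop("at least one batch label required")
  structure(list(compound = as.character(compound),
                 durations = as.numeric(durations),
                 concentrations = as.numeric(concentrations),
                 replicates = as.integer(replicates),
                 batches = as.character(batches),
                 include_t0 = isTRUE(include_t0)),
            class = "exposure_design")
}

#' Tissue-residue uptake parameters
#'
#' Expected residue follows a saturating-in-time, power-in-concentration law:
#' `background + k * C^gamma * (1 - exp(-t / tau))`. Treated samples receive
#' multiplicative lognormal noise of coefficient of variation `cv_noise` on the
#' uptake term; control and T = 0 samples get additive half-normal detection
#' noise with sd `background * cv_noise`.
#'
#' @param k uptake scale (residue units per mg/kg).
#' @param gamma concentration exponent (> 0; 1 = proportional uptake).
#' @param tau uptake time constant in days.
#' @param background mean residue in unexposed controls (detection limit).
#' @param cv_noise lognormal coefficient of variation of the residue noise.
#' @return an object of class `uptake_params`.
#' @export
uptake_params <- function(k = 0.5, gamma = 1, tau = 7,
                          background = 0.1, cv_noise = 0.2) {
  .assert_finite_params(k = k, gamma = gamma, tau = tau,
                        background = background, cv_noise = cv_noise)
  if (k <= 0 || tau <= 0 || gamma <= 0) stop("k, gamma and tau must be > 0")
  if (background < 0 || cv_noise < 0) stop("background and cv_noise must be >= 0")
  structure(list(k = k, gamma = gamma, tau = tau,
                 background = background, cv_noise = cv_noise),
            class = "uptake_params")
}

#' Configuration of the planted expression signal
#'
#' Log2 intensity of probe g in sample i is
#' `baseline_g + beta_g * residue_i + dose offset + batch offset + noise`,
#' where only the configured probe subsets carry the respective terms and the
#' per-probe noise variance is drawn from an inverse-gamma prior (precision
#' Gamma(shape `variance_prior_a`, scale `variance_prior_b`)).
#'
#' @param n_genes number of probes on the simulated array.
#' @param n_residue_linked probes affine in tissue residue; slope magnitudes
#'   are uniform on `beta_range`, signs alternate (half positive, half
#'   negative) so positively and negatively correlated extremes both exist.
#' @param beta_range range of |slope| (log2 units per residue unit).
#' @param n_dose_responsive probes shifted by log-dose irrespective of residue.
#' @param dose_effect_range range of |shift| at the top dose (log2 units).
#' @param batch_effect_fraction fraction of probes with additive batch offsets
#'   (default 1/3: in multi-batch exposures roughly a third of the array
#'   separates the batches' control groups).
#' @param batch_effect_sd sd of the per-(probe, batch) offsets (log2 units).
#' @param variance_prior_a,variance_prior_b inverse-gamma hyperparameters of
#'   the gene-wise residual variances.
#' @param baseline_mean_range range of probe baseline log2 intensities.
#' @return an object of class `signal_config`.
#' @export
signal_config <- function(n_genes = 2000,
                          n_residue_linked = 10,
                          beta_range = c(0.02, 0.08),
                          n_dose_responsive = 20,
                          dose_effect_range = c(0.5, 2),
                          batch_effect_fraction = 1 / 3,
                          batch_effect_sd = 1,
                          variance_prior_a = 3,
                          variance_prior_b = 1,
                          baseline_mean_range = c(6, 12)) {
  .assert_finite_params(n_genes = n_genes, n_residue_linked = n_residue_linked,
                        beta_range = beta_range,
                        n_dose_responsive = n_dose_responsive,
                        dose_effect_range = dose_effect_range,
                        batch_effect_fraction = batch_effect_fraction,
                        batch_effect_sd = batch_effect_sd,
                        variance_prior_a = variance_prior_a,
                        variance_prior_b = variance_prior_b,
                        baseline_mean_range = baseline_mean_range)
  if (n_residue_linked < 0 || n_dose_responsive < 0) {
    stop("planted gene counts must be >= 0")
  }
  if (n_residue_linked + n_dose_responsive > n_genes) {
    stop("configuration error: more planted genes than probes")
  }
  if (batch_effect_fraction < 0 || batch_effect_fraction > 1) {
    stop("batch_effect_fraction must be in [0, 1]")
  }
  if (variance_prior_a <= 0 || variance_prior_b <= 0) {
    stop("variance prior hyperparameters must be > 0")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_residue_linked = as.integer(n_residue_linked),
                 beta_range = as.numeric(beta_range),
                 n_dose_responsive = as.integer(n_dose_responsive),
                 dose_effect_range = as.numeric(dose_effect_range),
                 batch_effect_fraction = batch_effect_fraction,
                 batch_effect_sd = batch_effect_sd,
                 variance_prior_a = variance_prior_a,
                 variance_prior_b = variance_prior_b,
                 baseline_mean_range = as.numeric(baseline_mean_range)),
            class = "signal_config")
}

#' Sample annotation table for one exposure duration of a design
#'
#' @param design an `exposure_design`.
#' @param duration one of `design$durations`.
#' @return data.frame with columns sample_id, compound, nominal_conc,
#'   duration, batch, class_label, role.
#' @export
build_annotation <- function(design, duration = design$durations[1]) {
  stopifnot(inherits(design, "exposure_design"))
  if (!duration %in% design$durations) {
    stop("duration not part of the design")
  }
  zeros <- which(design$concentrations == 0)
  rows <- list()
  for (batch in design$batches) {
    treats <- list()
    if (design$include_t0) {
      treats[[length(treats) + 1]] <- list(label = "T0", conc = 0, role = "t0")
    }
    for (j in seq_along(design$concentrations)) {
      conc <- design$concentrations[j]
      if (conc == 0) {
        if (length(zeros) == 2 && j == zeros[2]) {
          treats[[length(treats) + 1]] <-
            list(label = "SC", conc = 0, role = "solvent_control")
        } else {
          treats[[length(treats) + 1]] <-
            list(label = "BC", conc = 0, role = "blank_control")
        }
      } else {
        treats[[length(treats) + 1]] <-
          list(label = paste0("C", format(conc, trim = TRUE)),
               conc = conc, role = "treated")
      }
    }
    for (tr in treats) {
      cls <- tr$label
      if (length(design$batches) > 1) cls <- paste(batch, cls, sep = "_")
      for (r in seq_len(design$replicates)) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("%s_D%s_%s_%s_r%d", design$compound,
                              format(duration, trim = TRUE), batch,
                              tr$label, r),
          compound = design$compound,
          nominal_conc = tr$conc,
          duration = duration,
          batch = batch,
          class_label = cls,
          role = tr$role,
          stringsAsFactors = FALSE)
      }
    }
  }
  ann <- do.call(rbind, rows)
  rownames(ann) <- NULL
  ann
}

#' Closed-form expected tissue residue
#'
#' @param conc nominal soil concentration (mg/kg).
#' @param t exposure duration (days).
#' @param uptake an `uptake_params` object.
#' @return expected residue `background + k * C^gamma * (1 - exp(-t/tau))`.
#' @export
expected_residue <- function(conc, t, uptake) {
  stopifnot(inherits(uptake, "uptake_params"))
  uptake$background +
    uptake$k * conc^uptake$gamma * (1 - exp(-t / uptake$tau))
}

#' Simulate measured tissue residue for every sample of a design
#'
#' @param design an `exposure_design`, or an annotation data.frame from
#'   [build_annotation()].
#' @param uptake an `uptake_params` object.
#' @param seed integer seed.
#' @param duration duration to simulate when `design` is a design object.
#' @return named numeric vector (one residue per sample, units as configured).
#' @export
simulate_residue <- function(design, uptake, seed = 1,
                             duration = NULL) {
  stopifnot(inherits(uptake, "uptake_params"))
  ann <- if (is.data.frame(design)) design else {
    build_annotation(design, duration %||% design$durations[1])
  }
  t_eff <- ifelse(ann$role == "t0", 0, ann$duration)
  uptake_term <- uptake$k * ann$nominal_conc^uptake$gamma *
    (1 - exp(-t_eff / uptake$tau))
  with_seed(seed, {
    n <- nrow(ann)
    res <- numeric(n)
    treated <- uptake_term > 0
    if (uptake$cv_noise > 0) {
      sdlog <- sqrt(log(1 + uptake$cv_noise^2))
      noise <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      det_noise <- abs(stats::rnorm(n, 0, uptake$background * uptake$cv_noise))
    } else {
      noise <- rep(1, n)
      det_noise <- rep(0, n)
    }
    res[treated] <- uptake$background + uptake_term[treated] * noise[treated]
    res[!treated] <- uptake$background + det_noise[!treated]
    names(res) <- ann$sample_id
    pmax(res, 0)
  })
}

#' Simulate a log2 expression matrix with planted structure
#'
#' @param design an `exposure_design` or annotation data.frame.
#' @param signal a `signal_config`.
#' @param residue named residue vector covering all samples.
#' @param seed integer seed.
#' @param duration duration when `design` is a design object.
#' @return list with `expression` (probes x samples matrix, attribute
#'   `scale_tag = "log2"`) and `truth` (a `synthetic_truth` record).
#' @export
simulate_expression <- function(design, signal, residue, seed = 1,
                                duration = NULL) {
  stopifnot(inherits(signal, "signal_config"))
  ann <- if (is.data.frame(design)) design else {
    build_annotation(design, duration %||% design$durations[1])
  }
  if (!all(ann$sample_id %in% names(residue))) {
    stop("residue does not cover all samples in the design")
  }
  residue <- residue[ann$sample_id]
  G <- signal$n_genes
  n <- nrow(ann)
  probes <- sprintf("TA1-%06d", seq_len(G))
  with_seed(seed, {
    baseline <- stats::runif(G, signal$baseline_mean_range[1],
                             signal$baseline_mean_range[2])
    # disjoint planted subsets
    planted <- sample.int(G, signal$n_residue_linked + signal$n_dose_responsive)
    linked <- planted[seq_len(signal$n_residue_linked)]
    dosed <- setdiff(planted, linked)
    betas <- numeric(0)
    E <- matrix(baseline, nrow = G, ncol = n)
    if (length(linked)) {
      mag <- stats::runif(length(linked), signal$beta_range[1],
                          signal$beta_range[2])
      sgn <- rep(c(1, -1), length.out = length(linked))
      betas <- mag * sgn
      E[linked, ] <- E[linked, ] + betas %o% as.numeric(residue)
    }
    dose_scale <- numeric(0)
    if (length(dosed)) {
      cmax <- max(ann$nominal_conc)
      dshape <- if (cmax > 0) log2(1 + ann$nominal_conc) / log2(1 + cmax) else
        rep(0, n)
      mag <- stats::runif(length(dosed), signal$dose_effect_range[1],
                          signal$dose_effect_range[2])
      dose_scale <- mag * sample(c(-1, 1), length(dosed), replace = TRUE)
      E[dosed, ] <- E[dosed, ] + dose_scale %o% dshape
    }
    batch_ids <- integer(0)
    batch_offsets <- NULL
    n_batch_genes <- round(signal$batch_effect_fraction * G)
    batches <- unique(ann$batch)
    if (n_batch_genes > 0) {
      batch_ids <- sample.int(G, n_batch_genes)
      batch_offsets <- matrix(stats::rnorm(n_batch_genes * length(batches),
                                           0, signal$batch_effect_sd),
                              nrow = n_batch_genes,
                              dimnames = list(NULL, batches))
      bi <- match(ann$batch, batches)
      E[batch_ids, ] <- E[batch_ids, ] + batch_offsets[, bi, drop = FALSE]
    }
    sigma2 <- 1 / stats::rgamma(G, shape = signal$variance_prior_a,
                                scale = signal$variance_prior_b)
    X <- E + matrix(stats::rnorm(G * n, 0, sqrt(sigma2)), nrow = G)
    dimnames(X) <- list(probes, ann$sample_id)
    attr(X, "scale_tag") <- "log2"
    truth <- structure(list(
      residue_linked_ids = probes[linked],
      residue_linked_beta = stats::setNames(betas, probes[linked]),
      dose_responsive_ids = probes[dosed],
      dose_effect_scale = stats::setNames(dose_scale, probes[dosed]),
      batch_affected_ids = probes[batch_ids],
      true_gene_variances = stats::setNames(sigma2, probes),
      uptake = NULL, seed = as.integer(seed)),
      class = "synthetic_truth")
    list(expression = X, truth = truth)
  })
}

#' Generate one complete synthetic study bundle
#'
#' Composes annotation, residue and expression simulation for one exposure
#' duration of a design. Deterministic for a fixed seed; residue and
#' expression use independent child streams of `seed`.
#'
#' @param design an `exposure_design`.
#' @param uptake an `uptake_params`.
#' @param signal a `signal_config`.
#' @param duration one of `design$durations` (default: the first).
#' @param seed master integer seed.
#' @return a `study_bundle` (see [study_bundle()]) with a `truth` record.
#' @export
generate_study <- function(design,
                           uptake = uptake_params(),
                           signal = signal_config(),
                           duration = design$durations[1],
                           seed = 1) {
  ann <- build_annotation(design, duration)
  residue <- simulate_residue(ann, uptake, seed = child_seed(seed, 1))
  sim <- simulate_expression(ann, signal, residue,
                             seed = child_seed(seed, 2))
  sim$truth$uptake <- uptake
  sim$truth$seed <- as.integer(seed)
  study_bundle(sim$expression, ann, residue, truth = sim$truth)
}

#' Generate a null study bundle (no planted expression signal)
#'
#' Residue still follows the dose-response law, but expression is independent
#' of residue, dose and batch; the truth lists are empty.
#'
#' @inheritParams generate_study
#' @param n_genes probe count.
#' @export
null_study <- function(design, uptake = uptake_params(), n_genes = 2000,
                       duration = design$durations[1], seed = 1) {
  sig <- signal_config(n_genes = n_genes, n_residue_linked = 0,
                       n_dose_responsive = 0, batch_effect_fraction = 0)
  generate_study(design, uptake, sig, duration = duration, seed = seed)
}
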