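# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite runs at desk scale.

# a minimal HMX-like design: T0 + blank + solvent + five doses, 5 replicates
hmx_design <- function() exposure_design()

# a two-batch TNT-like design: one control + five doses per batch
tnt_design <- function() {
  exposure_design(compound = "TNT", durations = c(4, 14),
                  concentrations = c(0, 6, 12, 24, 48, 96),
                  replicates = 5, batches = c("original", "repeat"),
                  include_t0 = FALSE)
}

# small planted-signal bundle: n_linked residue-linked genes (signs
# alternating +,-) with slopes sized so each gene alone explains about
# `explained` of the residue variance given the default variance prior mean.
planted_bundle <- function(seed = 1, n_genes = 500, n_linked = 4,
                           explained = 0.8, duration = 14,
                           n_dose = 0) {
  des <- hmx_design()
  up <- uptake_params()
  ann <- build_annotation(des, duration)
  res <- simulate_residue(ann, up, seed = child_seed(seed, 1))
  sd_res <- stats::sd(res)
  sigma_typ <- sqrt(1 / (1 * (3 - 1)))  # prior mean sd at (a=3, b=1)
  beta <- sigma_typ * sqrt(explained / (1 - explained)) / sd_res
  sig <- signal_config(n_genes = n_genes, n_residue_linked = n_linked,
                       beta_range = c(beta, beta), n_dose_responsive = n_dose)
  generate_study(des, up, sig, duration = duration, seed = seed)
}

# tiny two-class matrix with optional planted mean shifts
two_class_matrix <- function(n_genes = 100, n_per = 5, shift_genes = 0,
                             shift = 0, seed = 1) {
  with_seed(seed, {
    x <- matrix(stats::rnorm(n_genes * 2 * n_per), n_genes,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)), NULL))
    if (shift_genes > 0) {
      x[seq_len(shift_genes), seq_len(n_per) + n_per] <-
        x[seq_len(shift_genes), seq_len(n_per) + n_per] + shift
    }
    x
  })
}

two_classes <- function(n_per = 5) rep(c("a", "b"), each = n_per)

# a fake de_gene_set over a given universe with a chosen selection
fake_de_set <- function(selected, universe, label = "fake") {
  structure(list(probe_ids = selected,
                 statistic = stats::setNames(rep(1, length(universe)), universe),
                 p_value = stats::setNames(rep(0.5, length(universe)), universe),
                 perm_p = stats::setNames(rep(0.5, length(universe)), universe),
                 cutoff = NA_real_, confidence = 0.8, fdr_bound = 0.1,
                 n_permutations = 0, exhaustive = FALSE,
                 statistic_type = "F", prior = NULL, seed = 1,
                 comparison_label = label),
            class = "de_gene_set")
}
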