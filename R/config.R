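#' Simulation configuration for a reference-design microarray experiment
#'
#' Builds and validates the configuration driving [simulate_truth()] and
#' [simulate_scans()]. Defaults emulate the study geometry the package is
#' designed around: a 44K two-colour salmonid oligo array hybridized in a
#' reference design (every fish vs. a pooled size-matched wild reference),
#' four genotype groups -- age-matched wild (`Wa`), size-matched wild (`Ws`),
#' domesticated (`D`) and F1 hybrid (`WD`) -- with six biological replicates
#' each (24 arrays).
#'
#' `mode_weights` is the marginal distribution of per-gene genotype effects
#' over the five modes `additive`, `D-dominant`, `D-recessive`,
#' `overdominant` and `no-effect`. The fraction of genes carrying a genotype
#' effect is therefore `1 - mode_weights["no-effect"]`; if
#' `fraction_affected` is supplied explicitly it must agree with that value.
#' A further `stage_effect_fraction` of genes differ between the two wild
#' groups only (a developmental-stage effect, mode `stage-only`); these are
#' drawn out of the no-effect mass.
#'
#' @param n_genes Number of distinct genes (default 40000; with the default
#'   `replicate_probe_fraction` this yields a 44K-probe array).
#' @param replicate_probe_fraction Fraction of genes spotted on a second
#'   probe sharing the gene name (default 0.1).
#' @param n_per_group Biological replicates per genotype group (default 6).
#' @param groups Ordered genotype labels; fixed to `c("Wa","Ws","D","WD")`.
#' @param mode_weights Named probabilities over the five genotype-effect
#'   modes; must sum to 1. Default: 98.2% no-effect, the rest split between
#'   additive (0.8%), D-dominant and D-recessive (0.5% each).
#' @param fraction_affected Optional; proportion of genes with a genotype
#'   effect. Derived from `mode_weights` when `NULL`; validated against them
#'   otherwise.
#' @param effect_size_log2 Magnitude of the true D-vs-W difference on the
#'   log2 scale for affected genes (default 2, i.e. 4-fold).
#' @param biological_cv Coefficient of variation of per-fish expression on
#'   the linear scale; converted internally to a log2 sd of `log2(1 + cv)`.
#' @param dye_bias_amplitude Amplitude (log2 units) of the smooth,
#'   intensity-dependent dye bias added to the channel ratio (default 0.5).
#' @param background_mean Additive fluorescence background per channel
#'   (default 50).
#' @param flagged_fraction Proportion of spots per array flagged non-good
#'   (default 0.05; split 4:1 between bad and absent).
#' @param stage_effect_fraction Proportion of genes with a Wa-vs-Ws offset
#'   only (default 0.002).
#' @param baseline_log2_mean,baseline_log2_sd Log2-scale mean and sd of the
#'   baseline expression of expressed genes (defaults 10 and 1.5).
#' @param expressed_fraction Overall fraction of genes expressed above
#'   background (default 0.25, matching typical liver present-call rates on
#'   a whole-genome array); affected and stage-effect genes are always
#'   expressed.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   truth tables and scan files.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 500, seed = 42)
#' cfg$fraction_affected
#' @export
sim_config <- function(n_genes = 40000,
                       replicate_probe_fraction = 0.1,
                       n_per_group = 6,
                       groups = c("Wa", "Ws", "D", "WD"),
                       mode_weights = c(additive = 0.008,
                                        `D-dominant` = 0.005,
                                        `D-recessive` = 0.005,
                                        overdominant = 0,
                                        `no-effect` = 0.982),
                       fraction_affected = NULL,
                       effect_size_log2 = 2,
                       biological_cv = 0.1,
                       dye_bias_amplitude = 0.5,
                       background_mean = 50,
                       flagged_fraction = 0.05,
                       stage_effect_fraction = 0.002,
                       baseline_log2_mean = 10,
                       baseline_log2_sd = 1.5,
                       expressed_fraction = 0.25,
                       seed = 1L) {
  stop_if_not_count(n_genes, "n_genes")
  stop_if_not_count(n_per_group, "n_per_group")
  stop_if_not_prop(replicate_probe_fraction, "replicate_probe_fraction")
  stop_if_not_prop(flagged_fraction, "flagged_fraction")
  stop_if_not_prop(stage_effect_fraction, "stage_effect_fraction")
  stop_if_not_prop(expressed_fraction, "expressed_fraction")
  if (!identical(groups, .groups))
    abort_config("`groups` must be c(\"Wa\", \"Ws\", \"D\", \"WD\")")

  if (!is.numeric(mode_weights) || is.null(names(mode_weights)) ||
      !setequal(names(mode_weights), .modes_truth))
    abort_config(paste0("`mode_weights` must be named probabilities over {",
                        paste(.modes_truth, collapse = ", "), "}"))
  mode_weights <- mode_weights[.modes_truth]
  if (any(mode_weights < 0) || abs(sum(mode_weights) - 1) > 1e-9)
    abort_config("`mode_weights` must be non-negative and sum to 1")
  w_ne <- unname(mode_weights["no-effect"])
  if (stage_effect_fraction > w_ne + 1e-12)
    abort_config("`stage_effect_fraction` exceeds the no-effect mass in `mode_weights`")

  derived_affected <- 1 - w_ne
  if (is.null(fraction_affected)) {
    fraction_affected <- derived_affected
  } else {
    stop_if_not_prop(fraction_affected, "fraction_affected")
    if (abs(fraction_affected - derived_affected) > 1e-9)
      abort_config("`fraction_affected` contradicts `mode_weights` (must equal 1 - no-effect weight)")
  }

  for (nm in c("effect_size_log2", "biological_cv", "dye_bias_amplitude",
               "background_mean", "baseline_log2_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      abort_config(sprintf("`%s` must be a single non-negative number", nm))
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    abort_config("`seed` must be a single integer")

  structure(list(
    n_genes = as.integer(n_genes),
    replicate_probe_fraction = replicate_probe_fraction,
    n_per_group = as.integer(n_per_group),
    groups = groups,
    mode_weights = mode_weights,
    fraction_affected = fraction_affected,
    effect_size_log2 = effect_size_log2,
    biological_cv = biological_cv,
    dye_bias_amplitude = dye_bias_amplitude,
    background_mean = background_mean,
    flagged_fraction = flagged_fraction,
    stage_effect_fraction = stage_effect_fraction,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    expressed_fraction = expressed_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d genes (+%.0f%% replicate probes), %d groups x %d fish\n",
              x$n_genes, 100 * x$replicate_probe_fraction,
              length(x$groups), x$n_per_group))
  cat(sprintf("  affected: %.1f%% (effect %.2g log2), stage-only: %.2f%%\n",
              100 * x$fraction_affected, x$effect_size_log2,
              100 * x$stage_effect_fraction))
  cat(sprintf("  cv %.2g, dye bias %.2g log2, background %.3g, flagged %.1f%%\n",
              x$biological_cv, x$dye_bias_amplitude, x$background_mean,
              100 * x$flagged_fraction))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Sample sheet for a simulated experiment
#'
#' @param config A [sim_config()].
#' @return A tibble with `sample_id`, `group` and `dose` (the
#'   domesticated-genome fraction in percent: wild 0, hybrid 50,
#'   domesticated 100).
#' @examples
#' sim_design(sim_config(n_genes = 10))
#' @export
sim_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tibble(
    sample_id = as.vector(vapply(config$groups, function(g)
      sprintf("%s_%d", g, seq_len(config$n_per_group)),
      character(config$n_per_group))),
    group = rep(config$groups, each = config$n_per_group),
    dose = unname(.dose_of[rep(config$groups, each = config$n_per_group)])
  )
}
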