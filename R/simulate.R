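# log2 centre/spread of not-expressed (near-background) genes
.low_log2_mean <- 6
.low_log2_sd <- 0.8

#' Simulate per-gene ground truth
#'
#' Draws, for every gene, an inheritance mode and the true mean log2
#' expression of the wild (`mu_W`), hybrid (`mu_WD`) and domesticated
#' (`mu_D`) genotypes, plus a developmental-stage offset `delta_stage`
#' between the two wild groups (age-matched wild mean = `mu_W +
#' delta_stage`; the size-matched wild group sits at `mu_W`, matching the
#' pooled reference). Group means obey the mode algebra exactly:
#' additive genes have the hybrid at the parental midpoint, D-dominant
#' genes have `mu_WD == mu_D`, D-recessive genes `mu_WD == mu_W`,
#' overdominant genes lie outside the parental range, and no-effect genes
#' have all three means equal with `delta_stage == 0`.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per gene: `gene_id`, `mode`, `expressed`,
#'   `mu_W`, `mu_WD`, `mu_D`, `delta_stage`.
#' @examples
#' truth <- simulate_truth(sim_config(n_genes = 100, seed = 1))
#' table(truth$mode)
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  w <- config$mode_weights
  stage_w <- config$stage_effect_fraction
  probs <- c(w[setdiff(.modes_truth, "no-effect")],
             `stage-only` = stage_w,
             `no-effect` = unname(w["no-effect"]) - stage_w)

  with_seed_(config$seed, {
    mode <- sample(names(probs), n, replace = TRUE, prob = probs)
    affected <- !(mode %in% c("no-effect", "stage-only"))

    # affected and stage-effect genes are always expressed; the remaining
    # expressed mass is spread over the no-effect pool
    forced <- affected | mode == "stage-only"
    p_rest <- (config$expressed_fraction - mean(forced)) /
      max(1 - mean(forced), .Machine$double.eps)
    expressed <- forced | runif(n) < min(max(p_rest, 0), 1)

    mu_W <- ifelse(expressed,
                   rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd),
                   rnorm(n, .low_log2_mean, .low_log2_sd))
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    delta <- sgn * config$effect_size_log2

    mu_D <- ifelse(affected, mu_W + delta, mu_W)
    mu_WD <- mu_W
    mu_WD[mode == "additive"] <- (mu_W + mu_D)[mode == "additive"] / 2
    mu_WD[mode == "D-dominant"] <- mu_D[mode == "D-dominant"]
    mu_WD[mode == "D-recessive"] <- mu_W[mode == "D-recessive"]
    od <- mode == "overdominant"
    mu_WD[od] <- pmax(mu_W, mu_D)[od] + config$effect_size_log2 / 2

    delta_stage <- ifelse(mode == "stage-only", sgn * config$effect_size_log2, 0)

    tibble(
      gene_id = sprintf("g%06d", seq_len(n)),
      mode = mode,
      expressed = expressed,
      mu_W = mu_W,
      mu_WD = mu_WD,
      mu_D = mu_D,
      delta_stage = delta_stage
    )
  })
}

# true group-mean log2 expression per gene (genes x groups)
.truth_group_means <- function(truth) {
  cbind(Wa = truth$mu_W + truth$delta_stage,
        Ws = truth$mu_W,
        D = truth$mu_D,
        WD = truth$mu_WD)
}

# smooth monotone low-intensity inflation of the log-ratio
.dye_bias <- function(A, amplitude) {
  amplitude / (1 + exp((A - 8) / 1.5))
}

#' Simulate two-channel reference-design scans
#'
#' Generates one quantified scan per fish: the sample channel (`ch2`, Cy5)
#' carries that fish's expression of each gene, the reference channel
#' (`ch1`, Cy3) carries a pooled size-matched-wild reference shared by all
#' arrays. Per-fish biological noise is normal on the log2 scale with sd
#' `log2(1 + biological_cv)`; per-spot technical noise has half that sd.
#' A smooth monotone intensity-dependent dye bias of amplitude
#' `dye_bias_amplitude` log2 units inflates the ratio at low mean
#' intensity, an additive background of `background_mean` is added to both
#' channels, a `flagged_fraction` of spots per array is flagged non-good,
#' and a `replicate_probe_fraction` of genes appear on a second probe with
#' the same gene name.
#'
#' @param truth Tibble from [simulate_truth()].
#' @param config The same [sim_config()].
#' @return A tibble in long scan form: `sample_id`, `group`, `probe_id`,
#'   `gene_name`, `ch1`, `ch2`, `flag` (`G`ood / `B`ad / `A`bsent). Probe
#'   order is identical within every sample.
#' @examples
#' cfg <- sim_config(n_genes = 50, seed = 7)
#' scans <- simulate_scans(simulate_truth(cfg), cfg)
#' dplyr::count(scans, sample_id)
#' @export
simulate_scans <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.data.frame(truth) || nrow(truth) == 0)
    abort_config("`truth` must be a non-empty tibble from simulate_truth()")

  n <- nrow(truth)
  sd_bio <- log2(1 + config$biological_cv)
  sd_spot <- sd_bio / 2

  with_seed_(config$seed + 1L, {
    n_rep <- round(config$replicate_probe_fraction * n)
    rep_idx <- if (n_rep > 0) sort(sample.int(n, n_rep)) else integer(0)
    gene_idx <- c(seq_len(n), rep_idx)   # probe -> gene, duplicates appended
    n_probes <- length(gene_idx)
    probe_id <- sprintf("P%06d", seq_len(n_probes))
    gene_name <- truth$gene_id[gene_idx]

    gm <- .truth_group_means(truth)
    design <- sim_design(config)

    # one physical reference pool: per-gene pooled value shared by all arrays
    ref_gene <- truth$mu_W + rnorm(n, 0, sd_bio / sqrt(config$n_per_group))

    scans <- purrr::map2(design$sample_id, design$group, function(sid, grp) {
      fish <- gm[, grp] + rnorm(n, 0, sd_bio)          # per-fish gene values
      s2 <- fish[gene_idx] + rnorm(n_probes, 0, sd_spot)
      s1 <- ref_gene[gene_idx] + rnorm(n_probes, 0, sd_spot)
      A <- (s1 + s2) / 2
      g <- .dye_bias(A, config$dye_bias_amplitude)
      ch2 <- 2^(s2 + g / 2) + config$background_mean
      ch1 <- 2^(s1 - g / 2) + config$background_mean
      u <- runif(n_probes)
      flag <- ifelse(u < 0.8 * config$flagged_fraction, "B",
                     ifelse(u < config$flagged_fraction, "A", "G"))
      tibble(sample_id = sid, group = grp, probe_id = probe_id,
             gene_name = gene_name, ch1 = ch1, ch2 = ch2, flag = flag)
    })
    dplyr::bind_rows(scans)
  })
}

#' Write scan tables to disk
#'
#' One tab-delimited file per sample, named `<sample_id>.tsv`, with header
#' `probe_id  gene_name  ch1  ch2  flag`. Intensities are written with
#' full round-trip precision so [read_scan()] recovers them exactly.
#'
#' @param scans Long scan tibble from [simulate_scans()] (or the same shape).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of file paths (one per
#'   sample, in first-appearance order).
#' @export
write_scans <- function(scans, dir) {
  if (!is.data.frame(scans) || nrow(scans) == 0) abort_format("no probes")
  need <- c("sample_id", "probe_id", "gene_name", "ch1", "ch2", "flag")
  if (!all(need %in% names(scans)))
    abort_format(paste("`scans` lacks columns:",
                       paste(setdiff(need, names(scans)), collapse = ", ")))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- unique(scans$sample_id)
  paths <- vapply(ids, function(sid) {
    one <- scans[scans$sample_id == sid,
                 c("probe_id", "gene_name", "ch1", "ch2", "flag")]
    if (nrow(one) == 0) abort_format("no probes")
    path <- file.path(dir, paste0(sid, ".tsv"))
    readr::write_tsv(one, path, progress = FALSE)
    path
  }, character(1))
  invisible(paths)
}
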