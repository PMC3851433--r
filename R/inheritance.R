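#' Genotype-dose regression fallback
#'
#' Decides between "resembling additive" and "no effect" for an entity
#' whose hybrid differs significantly from neither parent: ordinary
#' least-squares regression of the per-fish linear-scale (back-transformed)
#' expression values on the domesticated-genome dose (0, 50, 100%), with a
#' two-sided t-test on the slope. A perfect zero-residual fit with a
#' non-zero slope is declared significant (it arises only for noise-free
#' synthetic data, where the trend is unambiguous).
#'
#' @param values Per-fish expression values on the linear (non-log) scale.
#' @param dose Domesticated-genome dose per fish, in percent (0/50/100).
#' @param alpha Slope-test significance level (default 0.05).
#' @return One-row tibble `slope, slope_p, label` with label
#'   `"resembling-additive"` or `"no-effect"`.
#' @examples
#' regression_fallback(c(2, 3, 4), c(0, 50, 100))
#' @export
regression_fallback <- function(values, dose, alpha = 0.05) {
  stopifnot(is.numeric(values), length(values) == length(dose))
  if (length(unique(dose)) < 2)
    abort_config("`dose` must span at least two genotype levels")
  fit <- lm(values ~ dose)
  # summary.lm warns on zero-residual fits; that case is handled explicitly
  co <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(co["dose", "Estimate"])
  slope_p <- unname(co["dose", "Pr(>|t|)"])
  rss <- sum(fit$residuals^2)
  tss <- sum((values - mean(values))^2)
  if (!is.finite(slope_p) || (tss > 0 && rss <= 1e-12 * tss)) {
    # zero-residual (or df-exhausted) exact fit: significant iff sloped
    slope_p <- if (abs(slope) > 1e-12) 0 else 1
  }
  tibble(slope = slope, slope_p = slope_p,
         label = if (slope_p <= alpha) "resembling-additive" else "no-effect")
}

#' Classify the inheritance mode of each entity
#'
#' Re-runs the ANOVA / BH / Tukey machinery on the supplied entity set
#' (typically the combined list of entities differing between domesticated
#' and either wild group) and applies the decision tree per wild reference
#' group `r`:
#' * hybrid-vs-`r` and hybrid-vs-D both significant -> `additive`
#'   (hybrid intermediate between the parents);
#' * only hybrid-vs-`r` significant -> `D-dominant` (hybrid resembles the
#'   domesticated parent);
#' * only hybrid-vs-D significant -> `D-recessive` (hybrid resembles the
#'   wild parent);
#' * neither significant -> [regression_fallback()] on genotype dose
#'   decides `resembling-additive` (counted with additive) vs `no-effect`.
#'
#' A contrast counts as significant when the entity's BH-adjusted omnibus
#' q (across the supplied set) and its Tukey p for the contrast are both
#' at most `alpha`. The regression fallback runs only for entities whose
#' omnibus q is at most `alpha`: a gene with no detectable overall group
#' effect is called `no-effect` directly. The dose regression is a
#' confirmatory test for genes showing a group effect that neither
#' parental contrast resolves; gating it this way also keeps the
#' no-effect false-positive rate at the FDR level instead of adding an
#' unconditional alpha-level test per gene.
#'
#' @param em A preprocessed `expr_mat` containing all four groups.
#' @param entities Character vector of probe ids to classify (default:
#'   all entities in `em`).
#' @param reference Wild reference group(s): `"Wa"`, `"Ws"` or both
#'   (default both; each is evaluated independently).
#' @param alpha Significance level (default 0.05).
#' @return Tibble `probe_id, gene_name, probe_index, reference, label,
#'   basis, slope, slope_p` (slope columns are `NA` unless the fallback
#'   ran).
#' @export
classify_modes <- function(em, entities = NULL,
                           reference = c("Wa", "Ws"), alpha = 0.05) {
  stopifnot(inherits(em, "expr_mat"))
  reference <- match.arg(reference, c("Wa", "Ws"), several.ok = TRUE)
  stop_if_not_prop(alpha, "alpha")
  for (g in c(reference, "D", "WD"))
    if (!any(em$design$group == g))
      abort_config(sprintf("group '%s' missing from design", g))

  if (is.null(entities)) entities <- em$probes$probe_id
  idx <- match(entities, em$probes$probe_id)
  if (anyNA(idx))
    abort_config(paste("entities absent from matrix:",
                       paste(head(entities[is.na(idx)], 5), collapse = ", ")))

  vals <- em$values[idx, , drop = FALSE]
  an <- .row_anova(vals, em$design$group)
  q <- bh_adjust(an$p)
  pmat <- .row_tukey(an)
  pair_col <- function(g1, g2) {
    cn <- colnames(pmat)
    hit <- cn == paste(g1, g2, sep = "|") | cn == paste(g2, g1, sep = "|")
    pmat[, hit]
  }

  lin_vals <- 2^vals   # back-transformed per-fish values for the fallback
  purrr::map_dfr(reference, function(ref) {
    sig_wd_w <- pair_col("WD", ref) <= alpha & q <= alpha
    sig_wd_d <- pair_col("WD", "D") <= alpha & q <= alpha
    keep <- em$design$group %in% c(ref, "WD", "D")
    dose <- em$design$dose[keep]

    purrr::map_dfr(seq_along(idx), function(i) {
      basis <- sprintf("WD-%s:%s, WD-D:%s, omnibus:%s", ref,
                       if (sig_wd_w[i]) "sig" else "ns",
                       if (sig_wd_d[i]) "sig" else "ns",
                       if (q[i] <= alpha) "sig" else "ns")
      if (sig_wd_w[i] && sig_wd_d[i]) {
        lab <- "additive"; slope <- NA_real_; slope_p <- NA_real_
      } else if (sig_wd_w[i]) {
        lab <- "D-dominant"; slope <- NA_real_; slope_p <- NA_real_
      } else if (sig_wd_d[i]) {
        lab <- "D-recessive"; slope <- NA_real_; slope_p <- NA_real_
      } else if (q[i] <= alpha) {
        fb <- regression_fallback(lin_vals[i, keep], dose, alpha)
        lab <- fb$label; slope <- fb$slope; slope_p <- fb$slope_p
      } else {
        lab <- "no-effect"; slope <- NA_real_; slope_p <- NA_real_
      }
      tibble(probe_id = em$probes$probe_id[idx[i]],
             gene_name = em$probes$gene_name[idx[i]],
             probe_index = em$probes$probe_index[idx[i]],
             reference = ref, label = lab, basis = basis,
             slope = slope, slope_p = slope_p)
    })
  })
}

#' Partition D-vs-wild entity sets into shared and unique groups
#'
#' Group A holds entities differing between domesticated fish and both
#' wild groups, group B those unique to the age-matched comparison
#' (D vs Wa), group C those unique to the size-matched comparison
#' (D vs Ws).
#'
#' @param d_vs_wa,d_vs_ws Character vectors of entity ids (or entity-list
#'   tibbles with a `probe_id` column) for the two comparisons, built at
#'   the same alpha / fold-change settings.
#' @return Tibble `probe_id, partition` with partition in `A`, `B`, `C`.
#' @export
partition_groups <- function(d_vs_wa, d_vs_ws) {
  ids <- function(x) if (is.data.frame(x)) unique(x$probe_id) else unique(x)
  wa <- ids(d_vs_wa); ws <- ids(d_vs_ws)
  dplyr::bind_rows(
    tibble(probe_id = intersect(wa, ws), partition = "A"),
    tibble(probe_id = setdiff(wa, ws), partition = "B"),
    tibble(probe_id = setdiff(ws, wa), partition = "C")
  )
}

# map fine-grained call labels onto the four summary letters
.label_letter <- function(label) {
  c(additive = "a", `resembling-additive` = "a",
    `D-dominant` = "d", `D-recessive` = "r", `no-effect` = "Ne")[label]
}

#' Concordance of inheritance calls across the two wild references
#'
#' For each partition group (A/B/C) tabulates, per summary label
#' (r = D-recessive, d = D-dominant, a = additive incl.
#' resembling-additive, Ne = no effect), the counts under each wild
#' reference and the number of entities labelled identically under both.
#'
#' @param calls Classification tibble from [classify_modes()] covering
#'   both references.
#' @param partition Tibble from [partition_groups()].
#' @return Tibble `group, reference, r, d, a, Ne` where reference is
#'   `Wa`, `Ws` or `Concordance`.
#' @export
concordance <- function(calls, partition) {
  stopifnot(is.data.frame(calls), is.data.frame(partition))
  wide <- calls %>%
    dplyr::mutate(letter = .label_letter(.data$label)) %>%
    dplyr::select("probe_id", "reference", "letter") %>%
    tidyr::pivot_wider(names_from = "reference", values_from = "letter")
  if (!all(c("Wa", "Ws") %in% names(wide)))
    abort_config("`calls` must cover both references (Wa and Ws)")
  joined <- dplyr::inner_join(partition, wide, by = "probe_id")
  if (nrow(joined) < nrow(partition))
    abort_config("some partition entities were not classified under both references")
  if (anyNA(joined$Wa) || anyNA(joined$Ws))
    abort_config("some entities classified under one reference only")

  letters <- c("r", "d", "a", "Ne")
  count_row <- function(x) {
    cts <- table(factor(x, levels = letters))
    as.list(as.integer(cts)) %>% setNames(letters)
  }
  purrr::map_dfr(c("A", "B", "C"), function(grp) {
    g <- joined[joined$partition == grp, ]
    dplyr::bind_rows(
      tibble(group = grp, reference = "Wa", !!!count_row(g$Wa)),
      tibble(group = grp, reference = "Ws", !!!count_row(g$Ws)),
      tibble(group = grp, reference = "Concordance",
             !!!count_row(g$Wa[g$Wa == g$Ws]))
    )
  })
}

#' Percentage share of each inheritance mode
#'
#' Each label's share of the total, rounded half up to one decimal.
#'
#' @param counts Named numeric vector (or one-row data frame) of counts
#'   per label, e.g. `c(r = 36, d = 24, a = 32, Ne = 0)`.
#' @return Tibble `label, count, pct`.
#' @examples
#' summarize_percentages(c(r = 36, d = 24, a = 32, Ne = 0))
#' @export
summarize_percentages <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- unlist(counts[intersect(c("r", "d", "a", "Ne"), names(counts))])
  }
  if (!is.numeric(counts) || is.null(names(counts)) || any(counts < 0))
    abort_config("`counts` must be named non-negative counts")
  total <- sum(counts)
  if (total == 0) abort_config("all counts are zero")
  tibble(label = names(counts), count = as.numeric(counts),
         pct = percent_of(as.numeric(counts), total))
}
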