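# ---- vectorized row-wise ANOVA / Tukey ------------------------------------
# Classical equal-variance one-way ANOVA computed from group sums across the
# rows of `values` (entities x samples). Whole-matrix arithmetic keeps the
# 44K-entity case and simulation replicates fast.
.row_anova <- function(values, groups) {
  groups <- as.character(groups)
  glev <- unique(groups)
  k <- length(glev)
  n_per <- vapply(glev, function(g) sum(groups == g), integer(1))
  if (k < 2) abort_config("need >= 2 groups")
  if (any(n_per < 2)) abort_config("every group needs >= 2 observations")
  N <- ncol(values)

  gmat <- vapply(glev, function(g) as.numeric(groups == g), numeric(N))
  sums <- values %*% gmat                       # entities x k group sums
  means <- sweep(sums, 2, n_per, "/")
  grand <- rowSums(values) / N
  ss_between <- rowSums(sweep(means, 1, grand)^2 %*% diag(n_per, k))
  ss_total <- rowSums(values^2) - N * grand^2
  ss_within <- pmax(ss_total - ss_between, 0)
  df1 <- k - 1
  df2 <- N - k
  mse <- ss_within / df2
  f <- (ss_between / df1) / mse
  p <- pf(f, df1, df2, lower.tail = FALSE)
  # degenerate rows: zero within-group variance
  zero_w <- ss_within < 1e-12 * pmax(ss_total, 1)
  zero_b <- ss_between < 1e-12 * pmax(ss_total, 1) | ss_total < 1e-24
  f[zero_w & zero_b] <- 0
  p[zero_w & zero_b] <- 1
  f[zero_w & !zero_b] <- Inf
  p[zero_w & !zero_b] <- 0
  list(F = f, p = p, means = means, mse = mse, df2 = df2, k = k,
       n_per = n_per, levels = glev)
}

# Tukey-Kramer p-values for every group pair, from .row_anova output.
# Returns a matrix entities x pairs; pair labels "g1|g2".
.row_tukey <- function(an) {
  pairs <- utils::combn(an$levels, 2)
  pmat <- matrix(NA_real_, nrow = nrow(an$means), ncol = ncol(pairs))
  colnames(pmat) <- paste(pairs[1, ], pairs[2, ], sep = "|")
  for (j in seq_len(ncol(pairs))) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    diff <- an$means[, g1] - an$means[, g2]
    se <- sqrt(an$mse / 2 * (1 / an$n_per[[g1]] + 1 / an$n_per[[g2]]))
    q <- abs(diff) / se
    p <- ptukey(q, nmeans = an$k, df = an$df2, lower.tail = FALSE)
    p[se == 0] <- ifelse(abs(diff[se == 0]) < 1e-12, 1, 0)
    pmat[, j] <- p
  }
  pmat
}

#' One-way ANOVA (equal variance) for a single entity
#'
#' Classical fixed-effects one-way ANOVA assuming equal within-group
#' variance. By convention an entity with zero between- and within-group
#' variance gets `F = 0`, `p = 1`.
#'
#' @param values Numeric vector of observations.
#' @param groups Group label per observation (>= 2 groups, each with
#'   >= 2 observations).
#' @return One-row tibble: `F`, `p`, `df1`, `df2`.
#' @examples
#' anova_omnibus(c(1, 2, 3, 2, 3, 4, 3, 4, 5), rep(c("a", "b", "c"), each = 3))
#' @export
anova_omnibus <- function(values, groups) {
  stopifnot(is.numeric(values), length(values) == length(groups))
  an <- .row_anova(matrix(values, nrow = 1), groups)
  tibble(F = an$F, p = an$p, df1 = an$k - 1, df2 = an$df2)
}

#' Tukey HSD pairwise p-values for a single entity
#'
#' Studentized-range p-values with pooled within-group variance; unequal
#' group sizes use the Tukey-Kramer form.
#'
#' @inheritParams anova_omnibus
#' @return Tibble `group1, group2, p` covering every unordered pair.
#' @export
tukey_pairwise <- function(values, groups) {
  stopifnot(is.numeric(values), length(values) == length(groups))
  an <- .row_anova(matrix(values, nrow = 1), groups)
  pmat <- .row_tukey(an)
  pairs <- strsplit(colnames(pmat), "|", fixed = TRUE)
  tibble(group1 = vapply(pairs, `[`, "", 1),
         group2 = vapply(pairs, `[`, "", 2),
         p = as.numeric(pmat[1, ]))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: on sorted p-values,
#' `q(i) = min_{j >= i} min(1, p(j) * m / j)`, mapped back to input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of BH-adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    abort_config("`p` must be numeric in [0, 1] with no missing values")
  p.adjust(p, method = "BH")
}

#' Linear-scale fold change between two groups
#'
#' `fc = 2^(mean log2 of group1 - mean log2 of group2)`; direction is
#' `up` when `fc > 1` (ties count as up), else `down`.
#'
#' @param em An `expr_mat`.
#' @param pairing Character vector `c(group1, group2)`.
#' @return Tibble `probe_id, gene_name, fc, direction`.
#' @export
fold_change <- function(em, pairing) {
  stopifnot(inherits(em, "expr_mat"), length(pairing) == 2)
  for (g in pairing)
    if (!any(em$design$group == g))
      abort_config(sprintf("group '%s' absent from design", g))
  m1 <- rowMeans(em$values[, em$design$group == pairing[1], drop = FALSE])
  m2 <- rowMeans(em$values[, em$design$group == pairing[2], drop = FALSE])
  fc <- unname(2^(m1 - m2))
  tibble(probe_id = em$probes$probe_id, gene_name = em$probes$gene_name,
         fc = fc, direction = ifelse(fc >= 1, "up", "down"))
}

#' Group-pairwise differential-expression testing
#'
#' Runs, for every entity, the omnibus one-way ANOVA across all genotype
#' groups, Benjamini-Hochberg adjustment of the omnibus p-values across
#' entities, Tukey HSD p-values for every group pairing, and linear-scale
#' fold changes per pairing.
#'
#' @param em A preprocessed `expr_mat`.
#' @param pairwise Compute Tukey pairwise p-values (default `TRUE`). Set
#'   `FALSE` for omnibus-only screens (e.g. null calibrations); studentized
#'   range probabilities dominate the runtime on large matrices and the
#'   `tukey_p` column is then `NA`.
#' @return A `hybrid_de` object; `tidy()` gives the long per-entity
#'   per-pairing table, `glance()` a one-row summary.
#' @export
de_test <- function(em, pairwise = TRUE) {
  stopifnot(inherits(em, "expr_mat"))
  groups <- em$design$group
  if (!all(groups %in% .groups))
    abort_config(paste("unknown group(s) in design:",
                       paste(setdiff(groups, .groups), collapse = ", ")))
  an <- .row_anova(em$values, groups)
  q <- bh_adjust(an$p)
  pmat <- if (pairwise) .row_tukey(an) else {
    pairs <- utils::combn(an$levels, 2)
    matrix(NA_real_, nrow(an$means), ncol(pairs),
           dimnames = list(NULL, paste(pairs[1, ], pairs[2, ], sep = "|")))
  }

  pairs <- strsplit(colnames(pmat), "|", fixed = TRUE)
  pairwise <- purrr::map_dfr(seq_along(pairs), function(j) {
    g1 <- pairs[[j]][1]; g2 <- pairs[[j]][2]
    d <- an$means[, g1] - an$means[, g2]
    fc <- 2^d
    tibble(probe_id = em$probes$probe_id, group1 = g1, group2 = g2,
           tukey_p = as.numeric(pmat[, j]), fc = fc,
           direction = ifelse(fc >= 1, "up", "down"))
  })

  structure(list(
    omnibus = tibble(probe_id = em$probes$probe_id,
                     gene_name = em$probes$gene_name,
                     probe_index = em$probes$probe_index,
                     F = an$F, p = an$p, q = q),
    pairwise = pairwise,
    design = em$design
  ), class = "hybrid_de")
}

#' @export
print.hybrid_de <- function(x, ...) {
  cat(sprintf("<hybrid_de> %d entities, %d pairings\n",
              nrow(x$omnibus), length(unique(paste(x$pairwise$group1,
                                                   x$pairwise$group2)))))
  invisible(x)
}

#' @export
tidy.hybrid_de <- function(x, ...) {
  dplyr::left_join(x$pairwise,
                   x$omnibus[c("probe_id", "gene_name", "probe_index",
                               "p", "q")],
                   by = "probe_id") %>%
    dplyr::select("probe_id", "gene_name", "probe_index", "group1", "group2",
                  "p", "q", "tukey_p", "fc", "direction")
}

#' @export
glance.hybrid_de <- function(x, ...) {
  tibble(n_entities = nrow(x$omnibus),
         n_q05 = sum(x$omnibus$q <= 0.05),
         n_q01 = sum(x$omnibus$q <= 0.01))
}

#' Significant entity lists per group pairing
#'
#' An entity is a member for a pairing iff its BH-adjusted omnibus q is at
#' most `alpha`, its Tukey p for the pairing is at most `alpha`, and
#' `max(fc, 1/fc) >= fc_threshold`.
#'
#' @param de A `hybrid_de` from [de_test()].
#' @param alpha Significance level (0.05 or 0.01 in the study).
#' @param fc_threshold Minimum linear fold change (default 2; use 1 to
#'   disable).
#' @return Tibble `group1, group2, probe_id, gene_name, probe_index, fc,
#'   direction` with attributes `alpha` and `fc_threshold`.
#' @export
significant_entities <- function(de, alpha = 0.05, fc_threshold = 2) {
  stopifnot(inherits(de, "hybrid_de"))
  stop_if_not_prop(alpha, "alpha")
  out <- tidy(de) %>%
    dplyr::filter(.data$q <= alpha, .data$tukey_p <= alpha,
                  pmax(.data$fc, 1 / .data$fc) >= fc_threshold) %>%
    dplyr::select("group1", "group2", "probe_id", "gene_name", "probe_index",
                  "fc", "direction") %>%
    dplyr::arrange(.data$group1, .data$group2, .data$probe_index)
  attr(out, "alpha") <- alpha
  attr(out, "fc_threshold") <- fc_threshold
  out
}

#' Collapse replicate probes to the first per gene name
#'
#' Within each pairing, among members sharing an identical `gene_name`
#' only the first in array (probe) order is kept.
#'
#' @param lists Entity-list tibble from [significant_entities()].
#' @return The collapsed tibble (attributes preserved).
#' @export
collapse_replicates <- function(lists) {
  stopifnot(is.data.frame(lists),
            all(c("group1", "group2", "gene_name", "probe_index") %in% names(lists)))
  out <- lists %>%
    dplyr::group_by(.data$group1, .data$group2, .data$gene_name) %>%
    dplyr::arrange(.data$probe_index, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$group1, .data$group2, .data$probe_index)
  attributes(out)[c("alpha", "fc_threshold")] <-
    attributes(lists)[c("alpha", "fc_threshold")]
  out
}

#' Up/down counts per pairing
#'
#' @param lists Entity-list tibble (optionally collapsed).
#' @return Tibble `group1, group2, n_up, n_down, n`.
#' @export
de_counts <- function(lists) {
  stopifnot(is.data.frame(lists))
  lists %>%
    dplyr::group_by(.data$group1, .data$group2) %>%
    dplyr::summarise(n_up = sum(.data$direction == "up"),
                     n_down = sum(.data$direction == "down"),
                     n = dplyr::n(), .groups = "drop")
}

#' Venn partition of two or three entity sets
#'
#' Exact set-algebra decomposition of the identifier sets into their
#' disjoint regions (3 regions for two sets, 7 for three).
#'
#' @param sets Named list of 2 or 3 character vectors of identifiers.
#' @return Tibble `region, n, members` (list-column), one row per region;
#'   region names use the set names, e.g. `"A&B"`, `"A_only"`.
#' @examples
#' venn_partition(list(A = c("x", "y"), B = c("y", "z")))
#' @export
venn_partition <- function(sets) {
  stopifnot(is.list(sets), length(sets) %in% c(2, 3), !is.null(names(sets)))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 0)
    memb <- matrix(logical(0), ncol = length(sets),
                   dimnames = list(NULL, names(sets)))
  key <- apply(memb, 1, function(z) paste(ifelse(z, "1", "0"), collapse = ""))

  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, , drop = FALSE]
  names(combos) <- names(sets)
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    inc <- unlist(combos[i, ])
    k <- paste(ifelse(inc, "1", "0"), collapse = "")
    region <- if (sum(inc) == 1) paste0(names(sets)[inc], "_only")
              else paste(names(sets)[inc], collapse = "&")
    members <- universe[key == k]
    tibble(region = region, n = length(members), members = list(members))
  })
}
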