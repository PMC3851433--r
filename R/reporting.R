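#' Agglomerative hierarchical clustering on Euclidean distances
#'
#' @param em An `expr_mat`, or a plain numeric matrix (rows = items).
#' @param axis Cluster `"samples"` (columns of the expression matrix) or
#'   `"entities"` (rows). Ignored for a plain matrix.
#' @param linkage Linkage method: `"average"` (default), `"complete"`,
#'   `"single"` or `"ward"`.
#' @return A `hybrid_clust`: list with the `hclust` object, a `linkage`
#'   tibble of merge heights, the `leaf_order` permutation and labels.
#' @export
hierarchical_cluster <- function(em, axis = c("samples", "entities"),
                                 linkage = c("average", "complete",
                                             "single", "ward")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  x <- if (inherits(em, "expr_mat")) {
    if (axis == "samples") t(em$values) else em$values
  } else {
    as.matrix(em)
  }
  if (nrow(x) < 2) abort_config("need >= 2 items to cluster")
  method <- c(average = "average", complete = "complete",
              single = "single", ward = "ward.D2")[[linkage]]
  hc <- hclust(dist(x, method = "euclidean"), method = method)
  structure(list(
    hclust = hc,
    linkage = tibble(merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
                     height = hc$height),
    leaf_order = hc$order,
    labels = hc$labels,
    axis = axis,
    method = linkage
  ), class = "hybrid_clust")
}

#' @export
print.hybrid_clust <- function(x, ...) {
  cat(sprintf("<hybrid_clust> %d %s, %s linkage, Euclidean\n",
              length(x$leaf_order), x$axis, x$method))
  invisible(x)
}

#' Principal-component coordinates of the samples
#'
#' PCA of entity-centered data (no rescaling; the matrix is already on a
#' common normalized scale), reporting sample scores on the leading
#' components and the proportion of variance each explains.
#'
#' @param em An `expr_mat`.
#' @param n_components Number of components (default 3, the usual 3D view).
#' @return A `hybrid_pca`: `coordinates` tibble (`sample_id`, `group`,
#'   `PC1`..) and `variance_explained`.
#' @export
pca_coordinates <- function(em, n_components = 3) {
  stopifnot(inherits(em, "expr_mat"))
  stop_if_not_count(n_components, "n_components")
  x <- t(em$values)
  if (nrow(x) < n_components)
    abort_config("`n_components` exceeds the number of samples")
  if (all(apply(x, 2, var) < 1e-24))
    abort_config("matrix is constant; PCA undefined")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  structure(list(
    coordinates = dplyr::bind_cols(em$design[c("sample_id", "group")], coords),
    variance_explained = ve[seq_len(k)]
  ), class = "hybrid_pca")
}

#' @export
print.hybrid_pca <- function(x, ...) {
  cat("<hybrid_pca>", nrow(x$coordinates), "samples;",
      paste(sprintf("PC%d %.1f%%", seq_along(x$variance_explained),
                    100 * x$variance_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Functional-category up/down rollup
#'
#' Tabulates up- and down-regulated members of each entity list per
#' functional umbrella category; genes absent from the map fall under
#' `"unknown"`.
#'
#' @param lists Collapsed entity-list tibble ([collapse_replicates()]).
#' @param category_map Tibble `gene_name, category` (the study used 16
#'   umbrella terms such as "response to stimulus", "transport",
#'   "cell/tissue structure and development").
#' @return Tibble `group1, group2, category, n_up, n_down`.
#' @export
categorize_updown <- function(lists, category_map) {
  stopifnot(is.data.frame(lists))
  if (is.null(category_map) || nrow(category_map) == 0)
    category_map <- tibble(gene_name = character(), category = character())
  stopifnot(all(c("gene_name", "category") %in% names(category_map)))
  lists %>%
    dplyr::left_join(dplyr::distinct(category_map, .data$gene_name,
                                     .keep_all = TRUE),
                     by = "gene_name") %>%
    dplyr::mutate(category = dplyr::coalesce(.data$category, "unknown")) %>%
    dplyr::group_by(.data$group1, .data$group2, .data$category) %>%
    dplyr::summarise(n_up = sum(.data$direction == "up"),
                     n_down = sum(.data$direction == "down"),
                     .groups = "drop")
}

#' Run the whole pipeline on a simulated experiment
#'
#' simulate -> preprocess -> differential expression -> inheritance-mode
#' classification -> (optional) report rendering. Fully deterministic
#' under `config$seed`.
#'
#' @param config A [sim_config()].
#' @param category_map Optional `gene_name, category` tibble for the
#'   functional rollup.
#' @param alpha,fc_threshold Settings for the entity lists feeding the
#'   Venn partition and classification (defaults 0.05 and 2).
#' @param cutoff,span Preprocessing settings (see [preprocess_scans()]).
#' @param out_dir If given, [render_report()] writes the consolidated
#'   report there.
#' @return A `hybrid_run` list: `truth`, `design`, `matrix`,
#'   `filter_report`, `de`, entity lists at both alphas, `venn_d_vs_wild`,
#'   `venn_hybrid`, `calls`, `partition`, `concordance`,
#'   `mode_percentages`, `categories`.
#' @export
run_pipeline <- function(config, category_map = NULL, alpha = 0.05,
                         fc_threshold = 2, cutoff = 300, span = 0.3,
                         out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  truth <- simulate_truth(config)
  scans <- simulate_scans(truth, config)
  design <- sim_design(config)
  em <- preprocess_scans(scans, design, cutoff = cutoff, span = span)
  de <- de_test(em)

  lists05 <- collapse_replicates(significant_entities(de, alpha, fc_threshold))
  lists01 <- collapse_replicates(significant_entities(de, 0.01, fc_threshold))

  pick <- function(l, g1, g2) l$probe_id[l$group1 == g1 & l$group2 == g2 |
                                         l$group1 == g2 & l$group2 == g1]
  d_wa <- pick(lists05, "D", "Wa")
  d_ws <- pick(lists05, "D", "Ws")
  venn_dw <- venn_partition(list(D_vs_Wa = d_wa, D_vs_Ws = d_ws))
  venn_h <- venn_partition(list(WD_vs_Wa = pick(lists05, "WD", "Wa"),
                                WD_vs_Ws = pick(lists05, "WD", "Ws"),
                                WD_vs_D = pick(lists05, "WD", "D")))

  combined <- union(d_wa, d_ws)
  if (length(combined) > 0) {
    calls <- classify_modes(em, combined, reference = c("Wa", "Ws"),
                            alpha = alpha)
    part <- partition_groups(d_wa, d_ws)
    conc <- concordance(calls, part)
    concA <- conc[conc$group == "A" & conc$reference == "Concordance", ]
    pct <- if (sum(unlist(concA[c("r", "d", "a", "Ne")])) > 0)
      summarize_percentages(concA) else NULL
  } else {
    calls <- part <- conc <- pct <- NULL
  }

  cats <- if (!is.null(category_map)) categorize_updown(lists05, category_map)
          else NULL

  run <- structure(list(
    config = config, truth = truth, design = design, matrix = em,
    filter_report = filter_report(em), de = de,
    lists_alpha05 = lists05, lists_alpha01 = lists01,
    venn_d_vs_wild = venn_dw, venn_hybrid = venn_h,
    calls = calls, partition = part, concordance = conc,
    mode_percentages = pct, categories = cats
  ), class = "hybrid_run")
  if (!is.null(out_dir)) render_report(run, out_dir)
  run
}

#' @export
print.hybrid_run <- function(x, ...) {
  fr <- x$filter_report
  cat(sprintf("<hybrid_run> %d/%d entities present; %d DE members (alpha=%.2g)\n",
              fr$n_present, fr$n_total, nrow(x$lists_alpha05),
              attr(x$lists_alpha05, "alpha") %||% 0.05))
  invisible(x)
}

.tsv_block <- function(df) {
  c(paste(names(df), collapse = "\t"),
    apply(df, 1, function(r) paste(r, collapse = "\t")))
}

#' Render the consolidated run report
#'
#' Writes `report.md` plus machine-readable TSVs (filter report, per-pairing
#' significant counts at both alphas, Venn regions, the Table-1-shaped
#' concordance table, mode percentages, and category rollups when a map was
#' supplied). Deterministic: rerunning the same seeded pipeline reproduces
#' the files byte for byte.
#'
#' @param run A `hybrid_run` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(run, out_dir) {
  stopifnot(inherits(run, "hybrid_run"))
  for (stage in c("filter_report", "lists_alpha05", "lists_alpha01",
                  "venn_d_vs_wild", "venn_hybrid"))
    if (is.null(run[[stage]]))
      abort(sprintf("missing stage output: %s", stage))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(df, p, progress = FALSE)
    paths <<- c(paths, p)
    p
  }
  wr(run$filter_report, "filter_report.tsv")
  counts05 <- de_counts(run$lists_alpha05)
  counts01 <- de_counts(run$lists_alpha01)
  wr(dplyr::bind_rows(dplyr::mutate(counts05, alpha = 0.05, .before = 1),
                      dplyr::mutate(counts01, alpha = 0.01, .before = 1)),
     "de_counts.tsv")
  venn_flat <- function(v) dplyr::select(v, "region", "n")
  wr(venn_flat(run$venn_d_vs_wild), "venn_d_vs_wild.tsv")
  wr(venn_flat(run$venn_hybrid), "venn_hybrid.tsv")
  if (!is.null(run$concordance)) wr(run$concordance, "concordance.tsv")
  if (!is.null(run$mode_percentages)) wr(run$mode_percentages,
                                         "mode_percentages.tsv")
  if (!is.null(run$categories)) wr(run$categories, "categories.tsv")

  md <- c(
    "# Pipeline run report", "",
    "## Entity filtering",
    sprintf("%d of %d entities present (cutoff %g; %s).",
            run$filter_report$n_present, run$filter_report$n_total,
            run$filter_report$intensity_cutoff,
            run$filter_report$presence_rule), "",
    "## Significant entities per pairing (replicates collapsed)",
    "", "alpha = 0.05, fold change >= 2:", "",
    .tsv_block(counts05), "",
    "alpha = 0.01, fold change >= 2:", "",
    .tsv_block(counts01), "",
    "## Venn partition, D vs wild-type", "",
    .tsv_block(venn_flat(run$venn_d_vs_wild)), "",
    "## Venn partition, hybrid pairings", "",
    .tsv_block(venn_flat(run$venn_hybrid)), "")
  if (!is.null(run$concordance))
    md <- c(md, "## Inheritance-mode concordance (groups A/B/C)", "",
            .tsv_block(run$concordance), "")
  if (!is.null(run$mode_percentages))
    md <- c(md, "## Concordant mode percentages (group A)", "",
            .tsv_block(run$mode_percentages), "")
  if (!is.null(run$categories))
    md <- c(md, "## Functional-category rollup", "",
            .tsv_block(run$categories), "")
  p <- file.path(out_dir, "report.md")
  writeLines(md, p)
  invisible(c(paths, p))
}
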