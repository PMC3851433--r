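#' Read one quantified scan file
#'
#' Parses a tab-delimited scan table (`probe_id  gene_name  ch1  ch2  flag`)
#' as written by [write_scans()] or exported from an image-quantification
#' package mapped onto the same five columns.
#'
#' @param path Path to a scan file.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return A tibble `probe_id, gene_name, ch1, ch2, flag` with the sample id
#'   in attribute `"sample_id"`.
#' @export
read_scan <- function(path, sample_id = NULL) {
  if (!file.exists(path)) abort_format(sprintf("scan file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("probe_id", "gene_name", "ch1", "ch2", "flag")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    abort_format(sprintf("scan file %s is missing column(s): %s",
                         basename(path), paste(missing_cols, collapse = ", ")))
  if (nrow(raw) == 0) abort_format("no probes")
  for (ch in c("ch1", "ch2")) {
    v <- suppressWarnings(as.numeric(raw[[ch]]))
    bad <- which(is.na(v) & !is.na(raw[[ch]]))
    if (length(bad) > 0)
      abort_format(sprintf("non-numeric %s in %s at line(s) %s", ch,
                           basename(path),
                           paste(head(bad + 1L, 5), collapse = ", ")))
    if (anyNA(v) || any(v < 0) || any(!is.finite(v)))
      abort_format(sprintf("missing/negative %s in %s", ch, basename(path)))
    raw[[ch]] <- v
  }
  if (!all(raw$flag %in% c("G", "B", "A")))
    abort_format(sprintf("flags in %s must be G, B or A", basename(path)))
  out <- as_tibble(raw[need])
  attr(out, "sample_id") <- sample_id %||%
    sub("\\.[^.]*$", "", basename(path))
  out
}

#' Read a directory of scan files against a sample sheet
#'
#' @param paths Character vector of scan files, or a directory containing
#'   `<sample_id>.tsv` files.
#' @param design Sample sheet tibble (`sample_id`, `group`; see
#'   [sim_design()]). Only listed samples are read.
#' @return Long scan tibble (`sample_id`, `group`, `probe_id`, `gene_name`,
#'   `ch1`, `ch2`, `flag`) in design order.
#' @export
read_scans <- function(paths, design) {
  stopifnot(is.data.frame(design), all(c("sample_id", "group") %in% names(design)))
  if (length(paths) == 1 && dir.exists(paths))
    paths <- file.path(paths, paste0(design$sample_id, ".tsv"))
  names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  missing <- setdiff(design$sample_id, names(paths))
  if (length(missing) > 0)
    abort_format(paste("no scan file for sample(s):", paste(missing, collapse = ", ")))
  purrr::map_dfr(design$sample_id, function(sid) {
    sc <- read_scan(paths[[sid]], sample_id = sid)
    dplyr::mutate(sc,
                  sample_id = sid,
                  group = design$group[match(sid, design$sample_id)],
                  .before = 1)
  })
}

#' Threshold raw intensities and form M/A values
#'
#' Raw channel values below 1.0 are raised to 1.0, then per-spot
#' `M = log2(ch2/ch1)` (sample over reference) and
#' `A = (log2(ch2) + log2(ch1)) / 2` are computed. Thresholding guarantees
#' both are finite.
#'
#' @param scan A single-sample scan tibble (from [read_scan()] or one
#'   sample of [simulate_scans()]).
#' @return Tibble `probe_id, gene_name, M, A, flag`.
#' @examples
#' s <- tibble::tibble(probe_id = "P1", gene_name = "g", ch1 = 2, ch2 = 8,
#'                     flag = "G")
#' threshold_and_log(s) # M = 2, A = 2
#' @export
threshold_and_log <- function(scan) {
  stopifnot(is.data.frame(scan),
            all(c("probe_id", "gene_name", "ch1", "ch2", "flag") %in% names(scan)))
  l1 <- log2(pmax(scan$ch1, 1))
  l2 <- log2(pmax(scan$ch2, 1))
  tibble(probe_id = scan$probe_id, gene_name = scan$gene_name,
         M = l2 - l1, A = (l2 + l1) / 2, flag = scan$flag)
}

#' LOWESS-normalize M against A
#'
#' Fits a locally weighted regression of M on A using good-flagged spots
#' only and subtracts the fitted trend from every spot (flagged spots are
#' corrected but never influence the fit), removing intensity-dependent
#' dye bias.
#'
#' @param records Tibble from [threshold_and_log()].
#' @param span LOWESS smoother span as a fraction of good spots
#'   (default 0.3).
#' @return The input with `M` replaced by the corrected value.
#' @export
lowess_normalize <- function(records, span = 0.3) {
  stopifnot(is.data.frame(records), all(c("M", "A", "flag") %in% names(records)))
  good <- records$flag == "G"
  if (sum(good) < 10) abort(
    "insufficient spots for normalization (need >= 10 good-flagged spots)",
    class = "hybridmode_norm_error")
  fit <- lowess(records$A[good], records$M[good], f = span)
  corr <- approx(fit$x, fit$y, xout = records$A, rule = 2, ties = mean)$y
  dplyr::mutate(records, M = .data$M - corr)
}

# ---- ExpressionMatrix container ------------------------------------------

new_expr_mat <- function(values, probes, design, provenance,
                         filter_report = NULL) {
  structure(list(values = values, probes = probes, design = design,
                 provenance = provenance, filter_report = filter_report),
            class = "expr_mat")
}

#' Assemble per-sample normalized records into an expression matrix
#'
#' @param records Long tibble of normalized M/A records carrying a
#'   `sample_id` column (rows of every sample must list probes in the same
#'   order), or a named list of per-sample record tibbles.
#' @param design Sample sheet (`sample_id`, `group`, optionally `dose`).
#' @return An `expr_mat`: entities x samples matrix of normalized log2
#'   ratios plus probe and design tables and a provenance trail. Use
#'   [tidy()] for a long-tibble view.
#' @export
assemble_matrix <- function(records, design) {
  stopifnot(is.data.frame(design), all(c("sample_id", "group") %in% names(design)))
  if (is.data.frame(records)) {
    stopifnot("sample_id" %in% names(records))
    records <- split(records, factor(records$sample_id, levels = unique(records$sample_id)))
  }
  records <- records[design$sample_id]
  if (any(vapply(records, is.null, logical(1))))
    abort_format("records missing for some design samples")

  ref <- records[[1]]$probe_id
  offenders <- names(records)[!vapply(records, function(r)
    identical(r$probe_id, ref), logical(1))]
  if (length(offenders) > 0)
    abort_format(paste("probe set/order differs from first sample in:",
                       paste(offenders, collapse = ", ")))

  values <- vapply(records, function(r) r$M, numeric(length(ref)))
  dim(values) <- c(length(ref), length(records))
  dimnames(values) <- list(ref, design$sample_id)
  probes <- tibble(probe_id = ref,
                   gene_name = records[[1]]$gene_name,
                   probe_index = seq_along(ref))
  if (!"dose" %in% names(design))
    design$dose <- unname(.dose_of[design$group])
  new_expr_mat(values, probes, as_tibble(design),
               provenance = c("threshold_1.0", "log2", "lowess", "assemble"))
}

#' Baseline-center an expression matrix
#'
#' Subtracts from each entity its median across all samples (the median of
#' an even count is the mean of the two middle values), so every retained
#' entity has median 0. Idempotent.
#'
#' @param em An `expr_mat`.
#' @return The centered `expr_mat`.
#' @export
baseline_center <- function(em) {
  stopifnot(inherits(em, "expr_mat"))
  med <- apply(em$values, 1, median)
  em$values <- em$values - med
  em$provenance <- union(em$provenance, "baseline_center_median")
  em
}

#' Filter entities on intensity and flags
#'
#' An entity is retained iff (a) its raw sample-channel intensity is at or
#' above `cutoff` in every replicate of at least one genotype group
#' (protecting group-specific expression) and (b) it is flagged good in at
#' least `min_good_frac` of all samples. Intensity checks use the
#' pre-normalization raw values.
#'
#' @param em An `expr_mat` (normalized, centered).
#' @param scans The raw long scan tibble the matrix was built from.
#' @param cutoff Lower raw-intensity cut-off (default 300).
#' @param min_good_frac Minimum fraction of samples flagged good
#'   (default 0.75).
#' @return The filtered `expr_mat`; the filter report is available via
#'   [filter_report()].
#' @export
filter_entities <- function(em, scans, cutoff = 300, min_good_frac = 0.75) {
  stopifnot(inherits(em, "expr_mat"))
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0)
    abort_config("`cutoff` must be a single positive intensity")
  stop_if_not_prop(min_good_frac, "min_good_frac")

  samples <- em$design$sample_id
  np <- nrow(em$values)
  idx <- match(em$probes$probe_id, scans$probe_id[scans$sample_id == samples[1]])
  ch2 <- vapply(samples, function(sid) {
    one <- scans[scans$sample_id == sid, ]
    one$ch2[idx]
  }, numeric(np))
  flag_good <- vapply(samples, function(sid) {
    one <- scans[scans$sample_id == sid, ]
    one$flag[idx] == "G"
  }, logical(np))
  if (anyNA(ch2)) abort_format("raw scans lack probes present in the matrix")

  pass <- ch2 >= cutoff
  present <- rep(FALSE, np)
  for (g in unique(em$design$group)) {
    cols <- em$design$group == g
    present <- present | rowSums(pass[, cols, drop = FALSE]) == sum(cols)
  }
  good_ok <- rowMeans(flag_good) >= min_good_frac
  keep <- present & good_ok

  rule <- sprintf(
    "raw ch2 >= %g in all replicates of >= 1 group AND flag G in >= %d%% of samples",
    cutoff, round(100 * min_good_frac))
  report <- tibble(n_total = np, n_present = sum(keep),
                   intensity_cutoff = cutoff, presence_rule = rule)

  em$values <- em$values[keep, , drop = FALSE]
  em$probes <- em$probes[keep, ]
  em$provenance <- c(em$provenance, sprintf("filter(%s)", rule))
  em$filter_report <- report
  em
}

#' Retrieve the filter report of a filtered matrix
#'
#' @param em An `expr_mat` returned by [filter_entities()] or
#'   [preprocess_scans()].
#' @return A one-row tibble: `n_total`, `n_present`, `intensity_cutoff`,
#'   `presence_rule`.
#' @export
filter_report <- function(em) {
  stopifnot(inherits(em, "expr_mat"))
  em$filter_report %||%
    abort("matrix has not been filtered; run filter_entities()")
}

#' Full preprocessing pipeline
#'
#' Threshold to 1.0 and log2-transform, LOWESS-normalize each array,
#' assemble, baseline-center each entity to its across-sample median, and
#' filter on raw intensity and flags.
#'
#' @param scans Long raw scan tibble ([simulate_scans()] / [read_scans()]).
#' @param design Sample sheet.
#' @param cutoff,span,min_good_frac See [filter_entities()] and
#'   [lowess_normalize()].
#' @param filter Set `FALSE` to skip the intensity/flag filter.
#' @return A filtered, normalized `expr_mat`.
#' @export
preprocess_scans <- function(scans, design, cutoff = 300, span = 0.3,
                             min_good_frac = 0.75, filter = TRUE) {
  recs <- scans %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::group_modify(~ lowess_normalize(threshold_and_log(.x), span = span)) %>%
    dplyr::ungroup()
  em <- assemble_matrix(recs, design)
  em <- baseline_center(em)
  if (filter) em <- filter_entities(em, scans, cutoff = cutoff,
                                    min_good_frac = min_good_frac)
  em
}

# ---- expr_mat methods -----------------------------------------------------

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d entities x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  groups:", paste(sprintf("%s(%d)", unique(x$design$group),
                                 table(x$design$group)[unique(x$design$group)]),
                         collapse = " "), "\n")
  cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Tidy a normalized expression matrix into long form
#'
#' @param x An `expr_mat`.
#' @param ... Unused.
#' @return Long tibble `probe_id, gene_name, sample_id, group, value`.
#' @export
tidy.expr_mat <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "probe_id") %>%
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id", values_to = "value")
  long %>%
    dplyr::left_join(x$probes[c("probe_id", "gene_name")], by = "probe_id") %>%
    dplyr::left_join(x$design[c("sample_id", "group")], by = "sample_id") %>%
    dplyr::select("probe_id", "gene_name", "sample_id", "group", "value")
}

#' @export
glance.expr_mat <- function(x, ...) {
  tibble(n_entities = nrow(x$values), n_samples = ncol(x$values),
         n_groups = length(unique(x$design$group)),
         provenance = paste(x$provenance, collapse = " -> "))
}

#' Write / read an expression matrix as tab-delimited text
#'
#' The file carries `# provenance:` comment lines followed by a
#' `probe_id  gene_name  <sample...>` table.
#'
#' @param em An `expr_mat`.
#' @param path Output file.
#' @return `write_expr_matrix()`: the path, invisibly. `read_expr_matrix()`:
#'   an `expr_mat`.
#' @export
write_expr_matrix <- function(em, path) {
  stopifnot(inherits(em, "expr_mat"))
  hdr <- c(paste("# provenance:", paste(em$provenance, collapse = " -> ")),
           paste("# design:", paste(sprintf("%s=%s", em$design$sample_id,
                                            em$design$group), collapse = " ")))
  tab <- dplyr::bind_cols(em$probes[c("probe_id", "gene_name")],
                          as_tibble(em$values))
  writeLines(hdr, path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @param design Sample sheet used to re-attach group labels.
#' @rdname write_expr_matrix
#' @export
read_expr_matrix <- function(path, design) {
  lines <- readLines(path)
  prov_line <- grep("^# provenance:", lines, value = TRUE)
  tab <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         show_col_types = FALSE)
  samples <- setdiff(names(tab), c("probe_id", "gene_name"))
  values <- as.matrix(tab[samples])
  rownames(values) <- tab$probe_id
  design <- design[match(samples, design$sample_id), ]
  if (!"dose" %in% names(design)) design$dose <- unname(.dose_of[design$group])
  new_expr_mat(values,
               tibble(probe_id = tab$probe_id, gene_name = tab$gene_name,
                      probe_index = seq_len(nrow(tab))),
               as_tibble(design),
               provenance = sub("^# provenance: ?", "", prov_line))
}
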