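# Build an expr_mat from a plain entities x samples matrix through the
# public assembly path.
make_em <- function(values, design, gene_name = NULL, center = FALSE) {
  np <- nrow(values)
  probe_id <- sprintf("P%03d", seq_len(np))
  if (is.null(gene_name)) gene_name <- probe_id
  recs <- purrr::map_dfr(seq_len(ncol(values)), function(j) {
    tibble::tibble(sample_id = design$sample_id[j], probe_id = probe_id,
                   gene_name = gene_name, M = values[, j])
  })
  em <- assemble_matrix(recs, design)
  if (center) em <- baseline_center(em)
  em
}

# Standard 4-group x n design
make_design <- function(n = 6) {
  groups <- c("Wa", "Ws", "D", "WD")
  tibble::tibble(
    sample_id = as.vector(vapply(groups, function(g)
      sprintf("%s_%d", g, seq_len(n)), character(n))),
    group = rep(groups, each = n)
  )
}

# Entities x samples matrix with given per-group true means and iid noise
make_group_matrix <- function(mu, design, sd = 0.1) {
  # mu: entities x 4 matrix with columns Wa, Ws, D, WD
  vals <- mu[, design$group, drop = FALSE] +
    matrix(rnorm(nrow(mu) * nrow(design), 0, sd), nrow(mu))
  colnames(vals) <- design$sample_id
  vals
}

digest_file <- function(path) unname(tools::md5sum(path))

# Small config used by several generator tests
quick_config <- function(...) {
  defaults <- list(n_genes = 200, seed = 101, expressed_fraction = 1,
                   mode_weights = c(additive = 0.2, `D-dominant` = 0.15,
                                    `D-recessive` = 0.15, overdominant = 0,
                                    `no-effect` = 0.5))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
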