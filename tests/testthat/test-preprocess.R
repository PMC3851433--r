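test_that("thresholding and M/A arithmetic follow the log2 definitions", {
  s <- tibble::tibble(probe_id = c("P1", "P2", "P3"), gene_name = c("a", "b", "c"),
                      ch1 = c(0.5, 2, 1), ch2 = c(0.5, 8, 1),
                      flag = c("G", "G", "G"))
  r <- threshold_and_log(s)
  expect_equal(r$M, c(0, 2, 0))
  expect_equal(r$A, c(0, 2, 0))
})

test_that("read_scan rejects malformed files with informative errors", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "s1.tsv")
  writeLines(c("probe_id\tgene_name\tch1\tch2\tflag",
               "P1\tg1\t10\t20\tG",
               "P2\tg2\toops\t30\tG"), p)
  expect_error(read_scan(p), "non-numeric ch1.*line")

  writeLines("probe_id\tgene_name\tch1\tch2\tflag", p)
  expect_error(read_scan(p), "no probes")

  writeLines(c("probe_id\tch1\tch2", "P1\t1\t2"), p)
  expect_error(read_scan(p), "missing column")
})

test_that("LOWESS normalization removes a constant shift and needs good spots", {
  set.seed(1)
  rec <- tibble::tibble(probe_id = sprintf("P%04d", 1:2000),
                        gene_name = sprintf("g%04d", 1:2000),
                        A = runif(2000, 4, 14),
                        M = 0.5 + rnorm(2000, 0, 0.05),
                        flag = "G")
  out <- lowess_normalize(rec)
  expect_lt(abs(median(out$M)), 0.01)
  expect_equal(out$A, rec$A)

  few <- rec[1:20, ]
  few$flag <- c(rep("G", 9), rep("B", 11))
  expect_error(lowess_normalize(few), "insufficient spots")
})

test_that("LOWESS attenuates a simulated monotone dye bias", {
  cfg <- sim_config(n_genes = 10000, seed = 9, dye_bias_amplitude = 0.5,
                    replicate_probe_fraction = 0, flagged_fraction = 0,
                    expressed_fraction = 1, baseline_log2_sd = 2.5,
                    mode_weights = c(additive = 0, `D-dominant` = 0,
                                     `D-recessive` = 0, overdominant = 0,
                                     `no-effect` = 1))
  scans <- simulate_scans(simulate_truth(cfg), cfg)
  one <- scans[scans$sample_id == "Wa_1", ]
  raw <- threshold_and_log(one)
  norm <- lowess_normalize(raw)
  r_raw <- cor(raw$M, raw$A)
  r_norm <- cor(norm$M, norm$A)
  expect_lt(abs(r_norm), abs(r_raw) / 5)
})

test_that("flagged spots are corrected but never influence the fit", {
  set.seed(2)
  rec <- tibble::tibble(probe_id = sprintf("P%04d", 1:1000),
                        gene_name = sprintf("g%04d", 1:1000),
                        A = runif(1000, 4, 14),
                        M = rnorm(1000, 0, 0.05),
                        flag = rep(c("G", "B"), c(900, 100)))
  # huge outliers on flagged spots must not bend the fit
  rec$M[rec$flag == "B"] <- 50
  out <- lowess_normalize(rec)
  expect_lt(max(abs(out$M[rec$flag == "G"] - rec$M[rec$flag == "G"])), 0.2)
  expect_true(all(abs(out$M[rec$flag == "B"] - 50) < 0.2))
})

test_that("baseline centering uses the across-sample median and is idempotent", {
  design <- tibble::tibble(sample_id = c("s1", "s2", "s3", "s4"),
                           group = c("Wa", "Ws", "D", "WD"))
  vals <- rbind(c(1, 2, 3, 4), c(5, 5, 5, 5), c(1, 2, 3, 10))
  em <- make_em(vals, design)
  c1 <- baseline_center(em)
  expect_equal(unname(c1$values[1, ]), c(-1.5, -0.5, 0.5, 1.5))
  expect_equal(unname(c1$values[2, ]), c(0, 0, 0, 0))
  expect_equal(unname(apply(c1$values, 1, median)), rep(0, 3))
  c2 <- baseline_center(c1)
  expect_equal(c2$values, c1$values)
})

test_that("assemble_matrix aligns probes and rejects mismatched samples", {
  design <- tibble::tibble(sample_id = c("s1", "s2"), group = c("Wa", "D"))
  recs <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 3),
    probe_id = rep(c("P1", "P2", "P3"), 2),
    gene_name = rep(c("a", "b", "c"), 2),
    M = c(1, 2, 3, 4, 5, 6))
  em <- assemble_matrix(recs, design)
  expect_equal(dim(em), c(3L, 2L))
  expect_equal(unname(em$values[, "s2"]), c(4, 5, 6))

  extra <- dplyr::bind_rows(recs, tibble::tibble(sample_id = "s2",
                                                 probe_id = "P4",
                                                 gene_name = "d", M = 7))
  expect_error(assemble_matrix(extra, design), "s2")
})

test_that("entity filtering applies the presence rule on raw intensities", {
  cfg <- quick_config(flagged_fraction = 0)
  truth <- simulate_truth(cfg)
  scans <- simulate_scans(truth, cfg)
  design <- sim_design(cfg)
  em <- preprocess_scans(scans, design, filter = FALSE)

  low <- filter_entities(em, scans, cutoff = 1e7)
  expect_equal(filter_report(low)$n_present, 0)
  all_in <- filter_entities(em, scans, cutoff = 1e-3)
  expect_equal(filter_report(all_in)$n_present, nrow(em$values))
  expect_error(filter_entities(em, scans, cutoff = -1), "cutoff")

  # a gene expressed only in D must survive the in-every-sample-of-one-group rule
  fem <- filter_entities(em, scans, cutoff = 300)
  rep_tbl <- filter_report(fem)
  expect_true(rep_tbl$n_present > 0.8 * rep_tbl$n_total)
  expect_match(rep_tbl$presence_rule, "all replicates")
})

test_that("preprocessing is invariant to sample input order", {
  cfg <- quick_config(n_per_group = 2)
  scans <- simulate_scans(simulate_truth(cfg), cfg)
  design <- sim_design(cfg)
  em1 <- preprocess_scans(scans, design)
  perm <- scans[order(rev(scans$sample_id), method = "radix"), ]
  em2 <- preprocess_scans(perm, design)
  expect_equal(em1$values, em2$values)
})

test_that("bias-free preprocessing recovers true group differences", {
  # mostly-null gene population: LOWESS assumes most spots are unchanged,
  # so neutrality is only promised in that regime
  cfg <- sim_config(n_genes = 2000, seed = 101, expressed_fraction = 1,
                    mode_weights = c(additive = 0.02, `D-dominant` = 0.015,
                                     `D-recessive` = 0.015, overdominant = 0,
                                     `no-effect` = 0.95),
                    dye_bias_amplitude = 0, background_mean = 0,
                    flagged_fraction = 0, replicate_probe_fraction = 0)
  truth <- simulate_truth(cfg)
  scans <- simulate_scans(truth, cfg)
  em <- preprocess_scans(scans, sim_design(cfg), filter = FALSE)

  d <- rowMeans(em$values[, em$design$group == "D"]) -
    rowMeans(em$values[, em$design$group == "Ws"])
  true_d <- truth$mu_D - truth$mu_W
  # per-fish sd: biological + spot noise; group-difference SE over 2x6 fish
  sd_fish <- sqrt(log2(1.1)^2 + (log2(1.1) / 2)^2)
  se <- sd_fish * sqrt(2 / 6)
  expect_gt(mean(abs(d - true_d) < 3 * se), 0.97)
})

test_that("expression matrices round-trip through the TSV format", {
  cfg <- quick_config(n_per_group = 2)
  scans <- simulate_scans(simulate_truth(cfg), cfg)
  em <- preprocess_scans(scans, sim_design(cfg))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_expr_matrix(em, p)
  back <- read_expr_matrix(p, sim_design(cfg))
  expect_equal(back$values, em$values, tolerance = 1e-12)
  expect_equal(back$probes$gene_name, em$probes$gene_name)
})
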