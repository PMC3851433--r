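test_that("omnibus ANOVA matches hand computation and stats::oneway.test", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- anova_omnibus(vals, grp)
  # group means 2,3,4; SSB = 6 on 2 df, SSW = 6 on 6 df -> F = 3
  expect_equal(res$F, 3)
  expect_equal(res$p, pf(3, 2, 6, lower.tail = FALSE))

  set.seed(10)
  for (i in 1:5) {
    v <- rnorm(15)
    g <- rep(c("x", "y", "z"), each = 5)
    ours <- anova_omnibus(v, g)
    ref <- oneway.test(v ~ factor(g), var.equal = TRUE)
    expect_equal(ours$F, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-6)
  }
})

test_that("ANOVA degenerate cases follow the stated conventions", {
  v <- rep(c(1, 2, 3), each = 3)
  expect_error(anova_omnibus(1:3, c("a", "a", "b")), "2 observations")
  same <- anova_omnibus(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
})

test_that("two-group ANOVA equals the squared pooled t statistic", {
  set.seed(11)
  v <- rnorm(12)
  g <- rep(c("a", "b"), each = 6)
  ours <- anova_omnibus(v, g)
  tt <- t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)
  expect_equal(ours$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(ours$p, tt$p.value, tolerance = 1e-8)
})

test_that("Tukey pairwise p-values agree with TukeyHSD and are symmetric", {
  set.seed(12)
  v <- rnorm(18)
  g <- rep(c("a", "b", "c"), each = 6)
  ours <- tukey_pairwise(v, g)
  ref <- TukeyHSD(aov(v ~ factor(g)))$`factor(g)`
  ref_p <- ref[paste(ours$group2, ours$group1, sep = "-"), "p adj"]
  expect_equal(ours$p, unname(ref_p), tolerance = 1e-6)

  # relabelling two groups carries each pair's p-value along with it
  g2 <- ifelse(g == "a", "b", ifelse(g == "b", "a", "c"))
  swapped <- tukey_pairwise(v, g2)
  pair_key <- function(d, map = identity) {
    k <- purrr::map2_chr(d$group1, d$group2,
                         ~ paste(sort(map(c(.x, .y))), collapse = "-"))
    setNames(d$p, k)[sort(k)]
  }
  unswap <- function(x) ifelse(x == "a", "b", ifelse(x == "b", "a", x))
  expect_equal(pair_key(ours), pair_key(swapped, unswap), tolerance = 1e-12)

  same <- tukey_pairwise(rep(1, 9), rep(c("a", "b", "c"), each = 3))
  expect_true(all(same$p == 1))
})

test_that("a strongly shifted group is detected by Tukey at extreme p", {
  set.seed(13)
  sd <- 1
  v <- c(rnorm(6, 0, sd), rnorm(6, 0, sd), rnorm(6, 10 * sd, sd))
  g <- rep(c("a", "b", "c"), each = 6)
  res <- tukey_pairwise(v, g)
  p_ac <- res$p[(res$group1 == "a" & res$group2 == "c") |
                (res$group1 == "c" & res$group2 == "a")]
  p_ab <- res$p[(res$group1 == "a" & res$group2 == "b") |
                (res$group1 == "b" & res$group2 == "a")]
  expect_lt(p_ac, 1e-6)
  expect_gt(p_ab, 0.05)
})

test_that("BH adjustment reproduces the step-up formula", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- rev(cummin(rev(pmin(1, p[o] * m / seq_len(m)))))
    q <- numeric(m); q[o] <- q_sorted; q
  }
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(14)
  p <- runif(100)^2
  expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  expect_equal(order(bh_adjust(p)[order(p)]), seq_along(p)) # monotone
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fold changes are 2^(mean log2 difference) with reciprocal symmetry", {
  design <- tibble::tibble(sample_id = c("s1", "s2", "s3", "s4"),
                           group = c("Wa", "Wa", "D", "D"))
  vals <- rbind(c(5, 5, 3, 3), c(2, 2, 2, 2), c(1, 1, 4, 4))
  em <- make_em(vals, design)
  fc <- fold_change(em, c("Wa", "D"))
  expect_equal(fc$fc, c(4, 1, 1 / 8))
  expect_equal(fc$direction, c("up", "up", "down"))
  rev_fc <- fold_change(em, c("D", "Wa"))
  expect_equal(fc$fc * rev_fc$fc, rep(1, 3), tolerance = 1e-12)
  expect_error(fold_change(em, c("Wa", "nope")), "absent")
})

test_that("significant entity lists obey their membership invariants", {
  set.seed(15)
  design <- make_design(6)
  mu <- matrix(0, nrow = 60, ncol = 4,
               dimnames = list(NULL, c("Wa", "Ws", "D", "WD")))
  mu[1:10, "D"] <- 2   # spiked in D only
  em <- make_em(make_group_matrix(mu, design, sd = 0.2), design,
                center = TRUE)
  de <- de_test(em)
  lists <- significant_entities(de, alpha = 0.05, fc_threshold = 2)

  spiked <- sprintf("P%03d", 1:10)
  for (g in c("Wa", "Ws", "WD")) {
    members <- lists$probe_id[(lists$group1 == "D" & lists$group2 == g) |
                              (lists$group1 == g & lists$group2 == "D")]
    expect_true(all(spiked %in% members))
  }

  td <- generics::tidy(de)
  merged <- dplyr::inner_join(lists, td,
                              by = c("group1", "group2", "probe_id"))
  expect_true(all(merged$q <= 0.05 & merged$tukey_p <= 0.05 &
                  pmax(merged$fc.x, 1 / merged$fc.x) >= 2))

  strict <- significant_entities(de, alpha = 0.01, fc_threshold = 2)
  key <- function(l) paste(l$group1, l$group2, l$probe_id)
  expect_true(all(key(strict) %in% key(lists)))
})

test_that("q-values never fall below omnibus p and are FDR-scaled", {
  set.seed(16)
  design <- make_design(3)
  vals <- matrix(rnorm(50 * nrow(design)), 50)
  colnames(vals) <- design$sample_id
  de <- de_test(make_em(vals, design))
  expect_true(all(de$omnibus$q >= de$omnibus$p - 1e-12))
  expect_true(all(de$omnibus$q >= 0 & de$omnibus$q <= 1))
})

test_that("replicate collapse keeps the first probe in array order", {
  lists <- tibble::tibble(
    group1 = "D", group2 = "Wa",
    probe_id = c("P017", "P204", "P001", "P050", "P060"),
    gene_name = c("X", "X", "Y", "Z", "Z"),
    probe_index = c(17, 204, 1, 50, 60),
    fc = c(3, 3.1, 2.5, 4, 4.2),
    direction = "up")
  out <- collapse_replicates(lists)
  expect_equal(sort(out$probe_id), c("P001", "P017", "P050"))

  singles <- lists[c(1, 3), ]
  expect_equal(collapse_replicates(singles)$probe_id,
               singles$probe_id[order(singles$probe_index)])

  # 3 probes of one gene + 2 singletons -> 3 members
  lists2 <- tibble::tibble(
    group1 = "D", group2 = "Wa",
    probe_id = sprintf("P%03d", 1:5),
    gene_name = c("A", "A", "A", "B", "C"),
    probe_index = 1:5, fc = 2, direction = "up")
  expect_equal(nrow(collapse_replicates(lists2)), 3)
})

test_that("Venn partition is exact set algebra", {
  # sizes mirroring the study's D-vs-wild comparison: |A|=233, |B|=207,
  # shared 119 -> unique 114 and 88, union 321
  a <- sprintf("e%03d", 1:233)
  b <- sprintf("e%03d", 115:321)
  v <- venn_partition(list(D_vs_Wa = a, D_vs_Ws = b))
  get_n <- function(r) v$n[v$region == r]
  expect_equal(get_n("D_vs_Wa_only"), 114)
  expect_equal(get_n("D_vs_Ws_only"), 88)
  expect_equal(get_n("D_vs_Wa&D_vs_Ws"), 119)
  expect_equal(sum(v$n), length(union(a, b)))

  d <- venn_partition(list(A = c("x", "y"), B = c("p", "q")))
  expect_equal(d$n[d$region == "A&B"], 0)

  set.seed(17)
  s3 <- list(A = sample(letters, 10), B = sample(letters, 12),
             C = sample(letters, 8))
  v3 <- venn_partition(s3)
  expect_equal(nrow(v3), 7)
  expect_equal(sum(v3$n), length(unique(unlist(s3))))
  # brute-force check of every region against membership predicates
  for (i in seq_len(nrow(v3))) {
    for (el in v3$members[[i]]) {
      in_sets <- vapply(s3, function(s) el %in% s, logical(1))
      expected <- if (sum(in_sets) == 1) paste0(names(s3)[in_sets], "_only")
                  else paste(names(s3)[in_sets], collapse = "&")
      expect_equal(v3$region[i], expected)
    }
  }
})

test_that("permuting group labels destroys true-positive detections", {
  set.seed(18)
  design <- make_design(6)
  mu <- matrix(0, 100, 4, dimnames = list(NULL, c("Wa", "Ws", "D", "WD")))
  mu[1:30, "D"] <- 3
  em <- make_em(make_group_matrix(mu, design, sd = 0.2), design, center = TRUE)
  de_true <- de_test(em)
  expect_gt(sum(de_true$omnibus$q <= 0.05), 25)

  perm_design <- design
  perm_design$group <- sample(design$group)
  em_perm <- em
  em_perm$design <- perm_design
  de_perm <- de_test(em_perm)
  expect_lt(mean(de_perm$omnibus$q <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})
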