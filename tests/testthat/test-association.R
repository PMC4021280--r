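# small helper: random stratum sets for reference comparisons
random_strata <- function(K) {
  data.frame(a = rpois(K, 5) + 1, b = rpois(K, 8) + 1,
             c = rpois(K, 4) + 1, d = rpois(K, 20) + 1)
}

test_that("gene tables cross-classify with strict cutoffs", {
  # the published worked example: 3/10/4/57
  sites <- data.frame(
    E_w = c(rep(0.1, 3), rep(1.2, 10), rep(0.2, 4), rep(0.9, 57)),
    sensitivity = c(rep(0.5, 13), rep(0.01, 61)))
  expect_equal(gene_table(sites), c(a = 3, b = 10, c = 4, d = 57))
  # all sensitive and conserved
  allsc <- data.frame(E_w = rep(0, 5), sensitivity = rep(1, 5))
  expect_equal(gene_table(allsc), c(a = 5, b = 0, c = 0, d = 0))
  # boundary: E_w exactly 0.5 is non-conserved, sensitivity exactly 0.1 is
  # non-sensitive
  edge <- data.frame(E_w = c(0.5, 0.49), sensitivity = c(0.1, 0.1))
  expect_equal(gene_table(edge), c(a = 0, b = 0, c = 1, d = 1))
})

test_that("single-stratum Mantel-Haenszel equals the cross-product odds ratio", {
  m <- mantel_haenszel(c(a = 3, b = 10, c = 4, d = 57))
  expect_equal(m$or_mh, 171 / 40)  # = 4.275
  set.seed(20)
  for (i in 1:20) {
    tb <- random_strata(1)
    m1 <- mantel_haenszel(tb)
    expect_equal(m1$or_mh, tb$a * tb$d / (tb$b * tb$c))
  }
})

test_that("OR_MH is invariant to stratum replication and empty strata", {
  set.seed(21)
  tb <- random_strata(5)
  base <- mantel_haenszel(tb)$or_mh
  expect_equal(mantel_haenszel(rbind(tb, tb))$or_mh, base)
  expect_equal(mantel_haenszel(rbind(tb, tb, tb))$or_mh, base)
  # a stratum with no sensitive sites contributes nothing
  tb0 <- rbind(tb, data.frame(a = 0, b = 0, c = 7, d = 13))
  expect_equal(mantel_haenszel(tb0)$or_mh, base)
})

test_that("chi-square, p and CI match the textbook reference implementation", {
  set.seed(22)
  for (i in 1:200) {
    tb <- random_strata(sample(2:12, 1))
    arr <- array(0, c(2, 2, nrow(tb)))
    for (k in seq_len(nrow(tb)))
      arr[, , k] <- matrix(c(tb$a[k], tb$c[k], tb$b[k], tb$d[k]), 2, 2)
    ref <- stats::mantelhaen.test(arr, correct = TRUE)
    m <- mantel_haenszel(tb)
    expect_equal(m$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(m$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(m$or_mh, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(m$ci95, as.numeric(ref$conf.int), tolerance = 1e-8)
  }
})

test_that("degenerate denominators yield an infinite odds ratio", {
  m <- mantel_haenszel(data.frame(a = 5, b = 3, c = 0, d = 9))
  expect_identical(m$or_mh, Inf)
  expect_false(is.na(m$p_value))
  # strata below 2 sites are skipped and counted
  m2 <- mantel_haenszel(data.frame(a = c(3, 1), b = c(10, 0),
                                   c = c(4, 0), d = c(57, 0)))
  expect_identical(m2$n_strata_used, 1L)
  expect_equal(m2$or_mh, 171 / 40)
  expect_error(mantel_haenszel(data.frame(a = 1, b = 0, c = 0, d = 0)),
               "stratum")
})

test_that("the sliding-window schemes yield the published window counts", {
  w <- sliding_windows(36, 12, 109)
  expect_identical(nrow(w), 10L)
  expect_equal(unlist(w[1, ]), c(start = 1, end = 36))
  expect_equal(unlist(w[10, ]), c(start = 109, end = 144))
  w45 <- sliding_windows(45, 15, 121)
  expect_identical(nrow(w45), 9L)
  expect_equal(unlist(w45[9, ]), c(start = 121, end = 165))
  expect_identical(nrow(sliding_windows(36, 12, 1)), 1L)
})

test_that("sites join every overlapping window", {
  set.seed(30)
  sites <- data.frame(gene_id = rep(c("g1", "g2"), each = 40),
                      cds_pos = rep(seq(3, 120, by = 3), 2),
                      E_w = runif(80, 0, 2),
                      sensitivity = runif(80, 0, 0.3))
  win <- sliding_windows(36, 12, 109)
  res <- windowed_analysis(sites, win)
  expect_identical(nrow(res), 10L)
  # position 36 falls in windows [1,36], [13,48], [25,60] only
  member <- win$start <= 36 & win$end >= 36
  expect_identical(which(member), 1:3)
  # counted sites per window match direct interval arithmetic
  for (w in seq_len(10)) {
    expect_equal(res$n_sites[w],
                 sum(sites$cds_pos >= win$start[w] &
                       sites$cds_pos <= win$end[w]))
  }
})

test_that("windows without contrast report an undefined odds ratio", {
  sites <- data.frame(gene_id = "g1", cds_pos = c(3, 6, 9, 12),
                      E_w = c(0.1, 0.9, 0.2, 1.5),
                      sensitivity = rep(0.01, 4))  # nothing sensitive
  res <- windowed_analysis(sites, sliding_windows(36, 12, 1))
  expect_true(is.na(res$or_mh[1]))
  expect_identical(res$n_sites[1], 4L)
})

test_that("run_species_analysis combines per-gene tables and diagnostics", {
  set.seed(33)
  sites <- data.frame(gene_id = rep(c("g1", "g2", "g3"), each = 30),
                      cds_pos = rep(seq(3, 90, by = 3), 3),
                      ref_nt = sample(c("A", "C", "G", "T"), 90, TRUE),
                      E_w = runif(90, 0, 2),
                      sensitivity = runif(90, 0, 0.3))
  an <- run_species_analysis(sites)
  expect_s3_class(an$mh, "mh_result")
  expect_identical(nrow(an$tables), 3L)
  expect_equal(sum(unlist(an$tables[, c("a", "b", "c", "d")])), 90)
  expect_equal(unname(an$sensitive_fraction["g1"]),
               mean(sites$sensitivity[sites$gene_id == "g1"] > 0.1))
  # manual pooling of the same tables gives the same OR
  expect_equal(an$mh$or_mh, mantel_haenszel(an$tables)$or_mh)
})

test_that("stratified analysis splits genes and degenerates gracefully", {
  set.seed(34)
  sites <- data.frame(gene_id = rep(sprintf("g%02d", 1:6), each = 30),
                      cds_pos = rep(seq(3, 90, by = 3), 6),
                      ref_nt = sample(c("A", "C", "G", "T"), 180, TRUE),
                      E_w = runif(180, 0, 2),
                      sensitivity = runif(180, 0, 0.3))
  covar <- stats::setNames(1:6, sprintf("g%02d", 1:6))
  st <- stratified_analysis(sites, covar, "expression")
  expect_identical(st$groups$top, sprintf("g%02d", 4:6))
  # ENC' flips the labelling: strongest bias = lowest values
  st_enc <- stratified_analysis(sites, covar, "encprime")
  expect_identical(st_enc$groups$top, sprintf("g%02d", 1:3))
  # one-gene halves collapse to the single-stratum cross-product OR
  two <- sites[sites$gene_id %in% c("g01", "g02"), ]
  st2 <- stratified_analysis(two, covar[1:2], "expression")
  t2 <- gene_table(two[two$gene_id == "g02", ])
  expect_equal(st2$top$or_mh, t2[["a"]] * t2[["d"]] / (t2[["b"]] * t2[["c"]]))
  # genes without covariate values are excluded and counted
  st3 <- stratified_analysis(sites, covar[1:4], "expression")
  expect_identical(st3$n_excluded, 2L)
})

test_that("permutation p-values are valid and respect the add-one floor", {
  set.seed(35)
  sites <- data.frame(gene_id = rep("g1", 20),
                      cds_pos = seq(3, 60, by = 3),
                      ref_nt = rep(c("A", "C"), 10),
                      E_w = runif(20, 0, 2),
                      sensitivity = runif(20, 0, 0.3))
  # plant a perfect anticorrelation: observed should sit far left
  sites$E_w <- 2 - 6 * sites$sensitivity
  pt <- constrained_permutation_test(sites, n_perm = 99, seed = 1)
  expect_gte(pt$p_left, 1 / 100)
  expect_lte(pt$p_left, 1)
  expect_identical(length(pt$null_means), 99L)
  expect_lt(pt$mean_r, -0.99)
  # determinism under the same seed
  pt2 <- constrained_permutation_test(sites, n_perm = 99, seed = 1)
  expect_identical(pt$p_left, pt2$p_left)
  expect_identical(pt$null_means, pt2$null_means)
})

test_that("the reshuffle is constrained within reference-nucleotide classes", {
  # two nucleotide classes with very different E_w ranges: constrained
  # permutations can never mix them, so every null replicate keeps the
  # class-mean difference intact
  sites <- data.frame(gene_id = "g1",
                      cds_pos = seq(3, 36, by = 3),
                      ref_nt = rep(c("A", "G"), each = 6),
                      E_w = c(runif(6, 0, 0.2), runif(6, 1.8, 2)),
                      sensitivity = runif(12, 0, 0.3))
  pt <- constrained_permutation_test(sites, n_perm = 200, seed = 3)
  # compute the maximal |r| attainable when classes cannot mix: all null
  # means must stay within the envelope set by within-class shuffles;
  # verify against explicit enumeration on a small copy
  e <- sites$E_w; s <- sites$sensitivity
  cls <- rep(c(1, 2), each = 6)
  set.seed(4)
  brute <- replicate(500, {
    ee <- e
    ee[cls == 1] <- sample(ee[cls == 1])
    ee[cls == 2] <- sample(ee[cls == 2])
    cor(s, ee)
  })
  expect_gte(min(pt$null_means), min(brute) - 0.2)
  expect_lte(max(pt$null_means), max(brute) + 0.2)
})

test_that("genes without usable variance are excluded and counted", {
  sites <- data.frame(
    gene_id = c(rep("ok", 10), rep("flat", 10), rep("tiny", 2)),
    cds_pos = c(seq(3, 30, 3), seq(3, 30, 3), c(3, 6)),
    ref_nt = "A",
    E_w = c(runif(10), rep(0.5, 10), runif(2)),
    sensitivity = c(runif(10), runif(10), runif(2)))
  pt <- constrained_permutation_test(sites, n_perm = 50, seed = 2)
  expect_identical(pt$n_genes_used, 1L)
  expect_identical(pt$n_genes_excluded, 2L)
  expect_error(constrained_permutation_test(sites[11:22, ], 50, 1),
               "no gene")
})

test_that("regional tests restrict and degenerate correctly", {
  set.seed(36)
  sites <- data.frame(gene_id = rep(c("g1", "g2"), each = 50),
                      cds_pos = rep(seq(3, 150, by = 3), 2),
                      ref_nt = sample(c("A", "C", "G", "T"), 100, TRUE),
                      E_w = runif(100, 0, 2),
                      sensitivity = runif(100, 0, 0.3))
  whole <- constrained_permutation_test(sites, n_perm = 100, seed = 7)
  full_region <- regional_correlation_test(sites, c(1, 150),
                                           n_perm = 100, seed = 7)
  expect_identical(full_region$mean_r, whole$mean_r)
  expect_identical(full_region$p_left, whole$p_left)
  init <- regional_correlation_test(sites, c(1, 60), n_perm = 100, seed = 7)
  expect_identical(init$n_genes_used, 2L)
  expect_error(regional_correlation_test(sites, c(151, 200), 100, 7),
               "no 4-fold")
})
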