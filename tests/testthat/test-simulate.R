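test_that("tree generation respects shape, determinism and scale", {
  tr <- generate_tree(4, "balanced", 0.1, seed = 1)
  expect_identical(sort(tr$tip.label), paste0("sp", 1:4))
  # balanced 4-leaf topology: two cherries
  expect_identical(ape::write.tree(ape::compute.brlen(tr, 1)),
                   ape::write.tree(ape::compute.brlen(
                     ape::read.tree(text = "((sp1,sp2),(sp3,sp4));"), 1)))
  expect_true(all(tr$edge.length > 0))
  # byte-identical newick under the same seed
  expect_identical(ape::write.tree(generate_tree(6, "yule", 0.2, seed = 9)),
                   ape::write.tree(generate_tree(6, "yule", 0.2, seed = 9)))
  expect_error(generate_tree(3, "yule", 0.1, 1), "n_species")
})

test_that("yule trees have 2n-2 exponential branches of the right mean", {
  tot <- vapply(1:1000, function(s) {
    tr <- generate_tree(8, "yule", 0.2, seed = s)
    expect_identical(nrow(tr$edge), 14L)
    sum(tr$edge.length)
  }, numeric(1))
  # mean total length = 14 * 0.2; MC standard error = 0.2*sqrt(14)/sqrt(1000)
  expect_equal(mean(tot), 14 * 0.2, tolerance = 4 * 0.2 * sqrt(14 / 1000) / 2.8)
})

test_that("root CDS generation yields valid stop-free coding sequences", {
  cds <- generate_root_cds(20, 0.5, seed = 3)
  expect_identical(nchar(cds), 60L)
  expect_identical(substr(cds, 1, 3), "ATG")
  codons <- substring(cds, 3 * (1:20) - 2, 3 * (1:20))
  expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  expect_identical(cds, generate_root_cds(20, 0.5, seed = 3))
  # GC bias is honoured within a binomial envelope
  cds2 <- generate_root_cds(100, 0.7, seed = 3)
  gc <- mean(strsplit(cds2, "")[[1]] %in% c("G", "C"))
  expect_gt(gc, 0.6)
  expect_lt(gc, 0.8)
})

test_that("planted rates follow the 1/(1+beta) reduction", {
  sites <- data.frame(pos = c(6L, 9L, 12L), sensitive = c(TRUE, FALSE, TRUE))
  r0 <- plant_effect(sites, 0, 0.2)
  expect_equal(r0$rate, rep(0.2, 3))
  r1 <- plant_effect(sites, 1, 0.2)
  expect_equal(r1$rate, c(0.1, 0.2, 0.1))
  # region restriction: only position 6 is inside [1, 8]
  rr <- plant_effect(sites, 1, 0.2, region = c(1, 8))
  expect_equal(rr$rate, c(0.1, 0.2, 0.2))
  expect_error(plant_effect(sites, -1, 0.2), "effect_beta")
})

test_that("evolution is the identity at rate zero and saturates at high rate", {
  tr <- generate_tree(6, "yule", 0.2, seed = 2)
  root <- generate_root_cds(30, 0.5, seed = 4)
  sites <- fourfold_sites(ortholog_alignment(c(r = root)))
  zero <- evolve_alignment(root, tr,
                           data.frame(pos = sites$cds_pos, rate = 0), seed = 1)
  expect_true(all(zero$seqs == root))
  # enormous rate on long branches: the evolving column mixes all four bases
  tr_long <- generate_tree(8, "balanced", 0.2, seed = 3)  # all depths 3
  tr_long$edge.length <- rep(5, nrow(tr_long$edge))
  pos1 <- sites$cds_pos[1]
  set.seed(123)
  hits <- replicate(400, {
    a <- evolve_alignment(root, tr_long,
                          data.frame(pos = pos1, rate = 1e6),
                          seed = sample.int(1e6, 1))
    substr(a$seqs[["sp5"]], pos1, pos1)
  })
  freq <- table(factor(hits, c("A", "C", "G", "T"))) / 400
  expect_true(all(freq > 0.12 & freq < 0.40))
  expect_error(evolve_alignment(root, tr,
                                data.frame(pos = pos1, rate = -1), 1),
               "rate")
})

test_that("two-leaf divergence matches the closed-form mismatch probability", {
  t1 <- 0.3; t2 <- 0.7; r <- 1.2
  tr2 <- ape::read.tree(text = sprintf("(sp1:%f,sp2:%f);", t1, t2))
  root <- "ATGGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCT"
  sites <- fourfold_sites(ortholog_alignment(c(r = root)))
  rates <- data.frame(pos = sites$cds_pos, rate = r)
  p1 <- 1 - exp(-r * t1); p2 <- 1 - exp(-r * t2)
  p_diff <- 1 - ((1 - p1) * (1 - p2) + p1 * p2 / 3)
  set.seed(99)
  diffs <- replicate(1000, {
    a <- evolve_alignment(root, tr2, rates, seed = sample.int(1e6, 1))
    mean(substring(a$seqs[[1]], sites$cds_pos, sites$cds_pos) !=
           substring(a$seqs[[2]], sites$cds_pos, sites$cds_pos))
  })
  # ~19,000 site draws; Monte-Carlo envelope well above the standard error
  expect_equal(mean(diffs), p_diff, tolerance = 0.02)
})

test_that("evolution only touches 4-fold sites: the protein is invariant", {
  tr <- generate_tree(8, "yule", 0.3, seed = 11)
  root <- generate_root_cds(40, 0.5, seed = 11)
  sites <- fourfold_sites(ortholog_alignment(c(r = root)))
  aln <- evolve_alignment(root, tr,
                          data.frame(pos = sites$cds_pos, rate = 3), seed = 2)
  prots <- vapply(aln$seqs, function(s)
    as.character(Biostrings::translate(Biostrings::DNAString(s))),
    character(1))
  expect_identical(length(unique(prots)), 1L)
  expect_false(any(grepl("-", aln$seqs)))
  # and the frozen focal leaf keeps the root sequence exactly
  aln_f <- evolve_alignment(root, tr,
                            data.frame(pos = sites$cds_pos, rate = 3),
                            seed = 2, frozen_leaf = tr$tip.label[1])
  expect_identical(unname(aln_f$seqs[tr$tip.label[1]]), root)
})

test_that("expression values are log-normal, keyed and reproducible", {
  e <- generate_expression(1000, 0, 1, seed = 5)
  expect_identical(length(e), 1000L)
  expect_true(all(e > 0))
  expect_lt(abs(mean(log(e))), 3 / sqrt(1000))
  expect_identical(e, generate_expression(1000, 0, 1, seed = 5))
  # degenerate spread: all values collapse to exp(logmean)
  expect_equal(unname(generate_expression(5, 2, 0, seed = 1)),
               rep(exp(2), 5))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_species = 2), "n_species")
  expect_error(sim_config(gene_length = 10), "gene_length")
  expect_error(sim_config(effect_beta = -0.5), "effect_beta")
  expect_error(sim_config(branch_scale = 0), "branch_scale")
})

test_that("datasets carry coherent truth and support cheap re-evolution", {
  cfg <- sim_config(n_genes = 3, n_species = 5, gene_length = 25,
                    effect_beta = 2, seed = 42)
  ds <- simulate_dataset(cfg, fold_params(flank = 30))
  expect_s3_class(ds, "synthetic_dataset")
  for (g in ds$genes) {
    # truth labels cover every 4-fold site and rates obey the planting rule
    expect_identical(g$sites$cds_pos,
                     fourfold_sites(ortholog_alignment(
                       c(r = g$root_cds)))$cds_pos)
    expect_equal(g$sites$rate,
                 ifelse(g$sites$sensitive, 1 / 3, 1))
    # every alignment row has the same species set as the tree
    expect_identical(sort(g$alignment$species), sort(ds$tree$tip.label))
    # focal reference row is the root CDS
    expect_identical(unname(g$alignment$seqs[1]), g$root_cds)
  }
  # re-evolution changes alignments but nothing else
  ds2 <- resimulate_alignments(ds, seed = 77)
  expect_identical(ds2$genes[[1]]$sites, ds$genes[[1]]$sites)
  expect_false(identical(ds2$genes[[1]]$alignment$seqs,
                         ds$genes[[1]]$alignment$seqs))
  # same seed reproduces the whole dataset
  ds_b <- simulate_dataset(cfg, fold_params(flank = 30))
  expect_identical(ds_b$genes[[2]]$alignment$seqs,
                   ds$genes[[2]]$alignment$seqs)
  # effect swap: beta = 0 levels all rates without refolding
  ds0 <- set_planted_effect(ds, 0)
  expect_true(all(vapply(ds0$genes, function(g)
    all(g$sites$rate == 1), logical(1))))
})
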