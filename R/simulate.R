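# run expr with a local RNG stream seeded by `seed`, restoring the caller's
# stream afterwards.  `seed` is forced first: if its promise draws from the
# ambient RNG (e.g. seed = sample.int(...)), that draw must advance the
# caller's stream before we snapshot it.
.with_seed <- function(seed, expr) {
  seed <- as.integer(seed)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# per-gene substream seeds derived from one master seed (counter splitting,
# kept inside 32-bit integer range)
.derive_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 2147483629 * 48271 + index * 16807) %%
               2147483629) + 1L
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults define the
#' standard study conditions used throughout the package's examples and
#' checks: 200 genes of 150 codons across 8 species, a Yule tree with
#' exponential branch lengths of mean 0.15 expected substitutions per site,
#' a synonymous rate of 1 per unit branch length, and log-normal expression.
#' `effect_beta` is the planted effect: the synonymous rate at structurally
#' sensitive 4-fold sites is divided by `1 + effect_beta`, so `effect_beta
#' = 0` is the exchangeable null and larger values map monotonically to a
#' larger expected log odds ratio.
#'
#' @param n_genes number of genes.
#' @param n_species number of species (>= 4).
#' @param gene_length gene length in codons (>= 20).
#' @param tree_shape `"yule"` (random bifurcation order) or `"balanced"`.
#' @param branch_scale mean branch length, expected substitutions per site.
#' @param syn_rate_mean synonymous substitution rate per unit branch length
#'   at non-sensitive 4-fold sites.
#' @param effect_beta planted rate-reduction factor at sensitive sites
#'   (>= 0; 0 = null).
#' @param effect_region optional 1-based inclusive CDS interval
#'   `c(from, to)`; when given, the planted effect applies only to sensitive
#'   sites inside it (used for 5'-restricted effects).
#' @param gc_bias expected G+C fraction of generated root sequences.
#' @param expr_logmean,expr_logsd log-scale parameters of the log-normal
#'   expression values.
#' @param seed master seed; per-gene substreams are derived from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L, n_species = 8L, gene_length = 150L,
                       tree_shape = c("yule", "balanced"),
                       branch_scale = 0.15, syn_rate_mean = 1.0,
                       effect_beta = 0, effect_region = NULL, gc_bias = 0.5,
                       expr_logmean = 0, expr_logsd = 1, seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  if (n_species < 4) stop("invalid config: n_species must be >= 4")
  if (gene_length < 20) stop("invalid config: gene_length must be >= 20")
  if (effect_beta < 0) stop("invalid config: effect_beta must be >= 0")
  if (branch_scale <= 0) stop("invalid config: branch_scale must be > 0")
  if (expr_logsd < 0) stop("invalid config: expr_logsd must be >= 0")
  structure(list(n_genes = as.integer(n_genes),
                 n_species = as.integer(n_species),
                 gene_length = as.integer(gene_length),
                 tree_shape = tree_shape, branch_scale = branch_scale,
                 syn_rate_mean = syn_rate_mean, effect_beta = effect_beta,
                 effect_region = effect_region, gc_bias = gc_bias,
                 expr_logmean = expr_logmean, expr_logsd = expr_logsd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# balanced topology as a newick string over 1-based leaf indices
.balanced_newick <- function(idx) {
  n <- length(idx)
  if (n == 1) return(paste0("sp", idx))
  half <- ceiling(n / 2)
  paste0("(", .balanced_newick(idx[seq_len(half)]), ",",
         .balanced_newick(idx[(half + 1):n]), ")")
}

#' Generate a random rooted phylogeny
#'
#' Builds a rooted binary topology (balanced, or Yule: each split chooses a
#' current lineage uniformly at random) over leaves `sp1..spN` and draws
#' every branch length independently from an exponential distribution with
#' mean `branch_scale`.
#'
#' @param n_species number of leaves (>= 4).
#' @param tree_shape `"balanced"` or `"yule"`.
#' @param branch_scale mean branch length (expected substitutions per site).
#' @param seed RNG seed; the same seed reproduces the tree exactly.
#' @return An [ape::phylo] object.
#' @export
generate_tree <- function(n_species, tree_shape = c("yule", "balanced"),
                          branch_scale = 0.15, seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  if (n_species < 4) stop("invalid config: n_species must be >= 4")
  if (branch_scale <= 0) stop("invalid config: branch_scale must be > 0")
  .with_seed(seed, {
    if (tree_shape == "balanced") {
      nwk <- .balanced_newick(seq_len(n_species))
    } else {
      # Yule: repeatedly split a uniformly chosen current tip
      nwk <- "(sp1,sp2)"
      tips <- c("sp1", "sp2")
      while (length(tips) < n_species) {
        pick <- tips[sample.int(length(tips), 1)]
        newtip <- paste0("sp", length(tips) + 1L)
        nwk <- sub(paste0(pick, "(?=[,)])"),
                   paste0("(", pick, ",", newtip, ")"), nwk, perl = TRUE)
        tips <- c(tips, newtip)
      }
    }
    tree <- ape::read.tree(text = paste0(nwk, ";"))
    tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1 / branch_scale)
    tree
  })
}

#' Generate a random in-frame coding sequence
#'
#' Draws codons with independent nucleotides at the requested G+C bias,
#' starting with ATG, rejecting stop codons, and regenerating until at
#' least 10% of third codon positions are 4-fold degenerate (which a random
#' sequence virtually always satisfies).
#'
#' @param gene_length length in codons (>= 20).
#' @param gc_bias expected G+C fraction.
#' @param seed RNG seed.
#' @return A single nucleotide string of `3 * gene_length` characters.
#' @export
generate_root_cds <- function(gene_length, gc_bias = 0.5, seed = 1L) {
  if (gene_length < 20) stop("invalid config: gene_length must be >= 20")
  nt <- c("A", "C", "G", "T")
  prob <- c((1 - gc_bias) / 2, gc_bias / 2, gc_bias / 2, (1 - gc_bias) / 2)
  .with_seed(seed, {
    repeat {
      draw_codon <- function() {
        repeat {
          cod <- paste(sample(nt, 3, replace = TRUE, prob = prob),
                       collapse = "")
          if (!cod %in% .STOP_CODONS) return(cod)
        }
      }
      codons <- c("ATG",
                  vapply(seq_len(gene_length - 1), function(i) draw_codon(),
                         character(1)))
      frac4 <- mean(substr(codons, 1, 2) %in% .FOURFOLD_PREFIXES)
      if (frac4 >= 0.10) return(paste(codons, collapse = ""))
    }
  })
}

#' Plant a rate reduction at structurally sensitive sites
#'
#' Builds the per-site synonymous substitution rates used by
#' [evolve_alignment()]: every 4-fold site evolves at `syn_rate_mean`,
#' except sites labelled sensitive (optionally restricted to a CDS region),
#' whose rate is `syn_rate_mean / (1 + effect_beta)`. With `effect_beta =
#' 0` all 4-fold rates are identical, so conservation is exchangeable
#' across sites and the permutation null holds exactly.
#'
#' @param sites data.frame with columns `pos` and `sensitive` (as returned
#'   by [gene_sensitivity()]).
#' @param effect_beta planted effect size (>= 0).
#' @param syn_rate_mean baseline synonymous rate.
#' @param region optional `c(from, to)` CDS interval restricting the effect.
#' @return data.frame with columns `pos` and `rate`.
#' @export
plant_effect <- function(sites, effect_beta, syn_rate_mean, region = NULL) {
  if (effect_beta < 0) stop("invalid config: effect_beta must be >= 0")
  if (syn_rate_mean < 0) stop("invalid config: syn_rate_mean must be >= 0")
  hit <- sites$sensitive
  if (!is.null(region))
    hit <- hit & sites$pos >= region[1] & sites$pos <= region[2]
  rate <- ifelse(hit, syn_rate_mean / (1 + effect_beta), syn_rate_mean)
  data.frame(pos = as.integer(sites$pos), rate = rate)
}

#' Evolve an ortholog alignment along a tree
#'
#' Starting from the root CDS, each branch applies an independent
#' change/no-change draw per evolving site: the probability of a
#' substitution on a branch of length `t` at rate `r` is `1 - exp(-r t)`,
#' and a substituted site takes one of the other three nucleotides
#' uniformly. Only the listed (4-fold degenerate, third codon) positions
#' evolve; all other positions are frozen, so the translated protein is
#' identical across species and the alignment is gap-free. This single-draw
#' branch model deliberately ignores multiple hits within a branch; at the
#' default branch scale (<= ~0.3 expected substitutions per site) the
#' discrepancy from a full continuous-time chain is negligible and the
#' change probability has a closed form.
#'
#' @param root_cds ancestral coding sequence (string).
#' @param tree an [ape::phylo] phylogeny whose tips become the species.
#' @param site_rates data.frame with columns `pos`, `rate` (from
#'   [plant_effect()]).
#' @param seed RNG seed.
#' @param frozen_leaf optional tip label whose sequence is kept identical
#'   to `root_cds` (used to place the focal reference species at the
#'   ancestral sequence whose structure defined the planted labels).
#' @return An [ortholog_alignment()] with one row per tip, reference =
#'   first tip.
#' @export
evolve_alignment <- function(root_cds, tree, site_rates, seed = 1L,
                             frozen_leaf = NULL) {
  tree <- .as_phylo(tree)
  if (any(site_rates$rate < 0))
    stop("invalid config: negative substitution rate")
  nt <- c("A", "C", "G", "T")
  root <- strsplit(toupper(root_cds), "")[[1]]
  pos <- as.integer(site_rates$pos)
  rate <- site_rates$rate
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root_node <- n_tip + 1L
  S <- length(pos)
  states <- matrix(NA_integer_, nrow = n_node, ncol = S)
  states[root_node, ] <- match(root[pos], nt)
  # preorder: parents before children
  ord <- rev(ape::postorder(tree))
  .with_seed(seed, {
    for (e in ord) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      st <- states[parent, ]
      if (S > 0) {
        p_change <- 1 - exp(-rate * tree$edge.length[e])
        flip <- stats::runif(S) < p_change
        if (any(flip)) {
          # uniform draw over the three alternatives
          shift <- sample.int(3, sum(flip), replace = TRUE)
          st[flip] <- ((st[flip] - 1L + shift) %% 4L) + 1L
        }
      }
      states[child, ] <- st
    }
  })
  seqs <- vapply(seq_len(n_tip), function(i) {
    s <- root
    if (S > 0 && !identical(tree$tip.label[i], frozen_leaf))
      s[pos] <- nt[states[i, ]]
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- tree$tip.label
  ortholog_alignment(seqs, reference = tree$tip.label[1])
}

#' Generate log-normal expression values
#'
#' @param n_genes number of genes.
#' @param expr_logmean,expr_logsd log-scale mean and standard deviation.
#' @param seed RNG seed.
#' @param gene_ids optional gene identifiers (default `gene001`, ...).
#' @return Named numeric vector of positive expression values.
#' @export
generate_expression <- function(n_genes, expr_logmean = 0, expr_logsd = 1,
                                seed = 1L, gene_ids = NULL) {
  if (expr_logsd < 0) stop("invalid config: expr_logsd must be >= 0")
  if (is.null(gene_ids))
    gene_ids <- sprintf("gene%03d", seq_len(n_genes))
  .with_seed(seed, {
    x <- stats::rlnorm(n_genes, meanlog = expr_logmean, sdlog = expr_logsd)
    names(x) <- gene_ids
    x
  })
}

#' Simulate a full synthetic ortholog dataset
#'
#' Generates one tree, `n_genes` root coding sequences, per-site structural
#' sensitivities of every 4-fold degenerate site (by folding the root CDS),
#' planted per-site rates, evolved gap-free ortholog alignments, and
#' expression values. The focal reference species (`sp1`, first alignment
#' row) carries the root CDS itself: the planted sensitivity labels are
#' computed from exactly the sequence the analysis folds, and alignments
#' can be cheaply re-evolved without refolding (see
#' [resimulate_alignments()]).
#'
#' @param config a [sim_config()].
#' @param fp folding parameters; the default folds a 60-nt flank around
#'   each site, enough local context for hairpin-scale structure while
#'   keeping the mutation scan fast.
#' @return An object of class `synthetic_dataset`: list with `tree`,
#'   `weighted_tree`, `genes` (per gene: `gene_id`, `root_cds`, `alignment`,
#'   `sites` with truth columns `sensitivity`, `sensitive`, `rate`),
#'   `expression`, `config`, `fold_params`.
#' @export
simulate_dataset <- function(config = sim_config(),
                             fp = fold_params(flank = 60)) {
  tree <- generate_tree(config$n_species, config$tree_shape,
                        config$branch_scale, seed = config$seed)
  wt <- leaf_weights(tree)
  gene_ids <- sprintf("gene%03d", seq_len(config$n_genes))
  genes <- lapply(seq_len(config$n_genes), function(g) {
    gseed <- .derive_seed(config$seed, g)
    root <- generate_root_cds(config$gene_length, config$gc_bias, seed = gseed)
    sites <- fourfold_sites(ortholog_alignment(
      stats::setNames(root, "ref"), gene_id = gene_ids[g]))
    sens <- gene_sensitivity(root, sites$cds_pos, fp)
    sites$sensitivity <- sens$sensitivity
    sites$sensitive <- sens$sensitive
    rates <- plant_effect(
      data.frame(pos = sites$cds_pos, sensitive = sites$sensitive),
      config$effect_beta, config$syn_rate_mean, config$effect_region)
    sites$rate <- rates$rate
    aln <- evolve_alignment(root, tree, rates,
                            seed = .derive_seed(gseed, 1L),
                            frozen_leaf = tree$tip.label[1])
    aln$gene_id <- gene_ids[g]
    list(gene_id = gene_ids[g], root_cds = root, alignment = aln,
         sites = sites)
  })
  names(genes) <- gene_ids
  expr <- generate_expression(config$n_genes, config$expr_logmean,
                              config$expr_logsd,
                              seed = .derive_seed(config$seed, 0L),
                              gene_ids = gene_ids)
  structure(list(tree = tree, weighted_tree = wt, genes = genes,
                 expression = expr, config = config, fold_params = fp),
            class = "synthetic_dataset")
}

#' Re-evolve the alignments of a synthetic dataset
#'
#' Keeps the tree, root sequences, structural sensitivities and planted
#' rates of an existing dataset and redraws only the substitution process
#' with a new seed. This is the replication device for simulation studies:
#' folding (the expensive stage) is done once, while independent evolution
#' replicates are cheap.
#'
#' @param dataset a `synthetic_dataset`.
#' @param seed new master seed for the substitution draws.
#' @return A `synthetic_dataset` with re-evolved alignments.
#' @export
resimulate_alignments <- function(dataset, seed) {
  dataset$genes <- lapply(dataset$genes, function(g) {
    rates <- data.frame(pos = g$sites$cds_pos, rate = g$sites$rate)
    g$alignment <- evolve_alignment(
      g$root_cds, dataset$tree, rates,
      seed = .derive_seed(seed, match(g$gene_id, names(dataset$genes))),
      frozen_leaf = dataset$tree$tip.label[1])
    g$alignment$gene_id <- g$gene_id
    g
  })
  dataset
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic ortholog dataset: ", cfg$n_genes, " genes x ",
      cfg$n_species, " species x ", cfg$gene_length, " codons\n", sep = "")
  cat("  planted effect beta = ", cfg$effect_beta,
      if (!is.null(cfg$effect_region))
        paste0(" (region ", cfg$effect_region[1], "-", cfg$effect_region[2], ")"),
      ", seed = ", cfg$seed, "\n", sep = "")
  n_sites <- sum(vapply(x$genes, function(g) nrow(g$sites), integer(1)))
  n_sens <- sum(vapply(x$genes, function(g) sum(g$sites$sensitive), integer(1)))
  cat("  ", n_sites, " 4-fold degenerate sites, ",
      round(100 * n_sens / n_sites, 1), "% structurally sensitive\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes one aligned multi-FASTA per gene (reference species first), the
#' Newick tree, a TSV expression table and a TSV truth table with per-site
#' true rates and sensitivity labels.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aln_dir <- file.path(dir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  for (g in dataset$genes) {
    ss <- Biostrings::DNAStringSet(g$alignment$seqs)
    Biostrings::writeXStringSet(ss, file.path(aln_dir,
                                              paste0(g$gene_id, ".fasta")))
  }
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  utils::write.table(
    data.frame(gene_id = names(dataset$expression),
               expression = as.numeric(dataset$expression)),
    file.path(dir, "expression.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- do.call(rbind, lapply(dataset$genes, function(g)
    data.frame(gene_id = g$gene_id, cds_pos = g$sites$cds_pos,
               ref_nt = g$sites$ref_nt, sensitivity = g$sites$sensitivity,
               sensitive = g$sites$sensitive, rate = g$sites$rate)))
  rownames(truth) <- NULL
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Change the planted effect of an existing dataset
#'
#' Recomputes the per-site rates of a dataset from its stored structural
#' sensitivities under a new `effect_beta` (and optional region), without
#' redoing the folding. Together with [resimulate_alignments()] this lets a
#' power study sweep effect sizes over one fixed set of genes.
#'
#' @param dataset a `synthetic_dataset`.
#' @param effect_beta new planted effect size.
#' @param region optional `c(from, to)` CDS interval restricting the effect.
#' @param genes optional character vector of gene ids; the effect applies
#'   only to these genes (others revert to the flat rate), e.g. to couple
#'   the effect to high expression.
#' @return The dataset with updated `rate` columns and config; alignments
#'   are *not* re-evolved (call [resimulate_alignments()] afterwards).
#' @export
set_planted_effect <- function(dataset, effect_beta, region = NULL,
                               genes = NULL) {
  cfg <- dataset$config
  cfg$effect_beta <- effect_beta
  cfg$effect_region <- region
  dataset$config <- cfg
  dataset$genes <- lapply(dataset$genes, function(g) {
    beta_g <- if (is.null(genes) || g$gene_id %in% genes) effect_beta else 0
    rates <- plant_effect(
      data.frame(pos = g$sites$cds_pos, sensitive = g$sites$sensitive),
      beta_g, cfg$syn_rate_mean, region)
    g$sites$rate <- rates$rate
    g
  })
  dataset
}
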