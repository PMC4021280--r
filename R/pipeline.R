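#' Per-site records for a whole synthetic dataset
#'
#' Bridges simulation and statistics: for every gene, computes the weighted
#' entropy of each 4-fold site's alignment column (using the dataset's
#' equal-split leaf weights) and joins it with the site's structural
#' sensitivity. By construction the focal reference row is the folded root
#' CDS, so the stored sensitivities are exactly what folding the reference
#' sequence yields.
#'
#' @param dataset a `synthetic_dataset`.
#' @return data.frame of per-site records: `gene_id`, `cds_pos`, `aln_col`,
#'   `ref_nt`, `family`, `sensitivity`, `sensitive`, `rate`, `E_w`,
#'   `conserved`.
#' @export
analyze_dataset <- function(dataset) {
  w <- dataset$weighted_tree$weights
  rows <- lapply(dataset$genes, function(g) {
    rec <- site_entropies(g$alignment, g$sites, w)
    rec$conserved <- classify_conserved(rec$E_w)
    rec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.default_config <- function() {
  list(e_cut = 0.5, s_cut = 0.1, min_frac = 0.80, n_perm = 1000L,
       seed = 1L, flank = 60L, d_min_span = 10L, min_hairpin = 3L,
       window_win = 36L, window_step = 12L, window_last_start = 109L,
       region_init = c(1L, 60L), region_elong = c(91L, 150L))
}

#' Read a pipeline run configuration
#'
#' Reads a YAML configuration and merges it over the built-in defaults.
#' Recognized keys: paths (`alignments_dir`, `tree`, `expression`,
#' `out_dir`), thresholds (`e_cut`, `s_cut`, `min_frac`), folding
#' parameters (`flank`, `d_min_span`, `min_hairpin`), window scheme
#' (`window_win`, `window_step`, `window_last_start`), regions
#' (`region_init`, `region_elong`), `n_perm` and `seed`.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list overriding any key (CLI-style).
#' @return A configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- .default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg[names(overrides)] <- overrides
  cfg
}

#' Simulate a dataset to disk
#'
#' Generates a synthetic dataset from a [sim_config()] and writes the
#' per-gene alignments, tree, expression and truth tables plus a JSON run
#' manifest recording the configuration and seed.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param fp folding parameters for the sensitivity labels.
#' @return The `synthetic_dataset`, invisibly.
#' @export
pipeline_simulate <- function(config, out_dir, fp = fold_params(flank = 60)) {
  ds <- simulate_dataset(config, fp)
  write_dataset(ds, out_dir)
  manifest <- list(stage = "simulate",
                   config = unclass(config),
                   n_genes = length(ds$genes),
                   n_sites = sum(vapply(ds$genes, function(g) nrow(g$sites),
                                        integer(1))),
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(ds)
}

#' Run the full association analysis on alignment files
#'
#' Chains every stage on data read from disk: alignability filtering,
#' 4-fold site extraction, weighted entropy, structural sensitivity (by
#' folding the reference CDS of each gene), ENC', the overall
#' Mantel-Haenszel combination, expression- and codon-bias-stratified
#' reruns, the 5' sliding-window scan, and the constrained permutation
#' tests (whole-gene plus initiation and elongation regions). Every
#' stage's table is written as TSV and a JSON manifest records
#' configuration, seed, and per-stage gene counts including exclusions.
#'
#' @param alignments_dir directory of per-gene aligned multi-FASTA files
#'   (`*.fa`, `*.fasta`; reference species = first record).
#' @param tree_path Newick tree file covering all species.
#' @param out_dir output directory for result tables.
#' @param expression_path optional TSV with columns `gene_id`,
#'   `expression`.
#' @param config configuration list from [read_run_config()].
#' @param sensitivity_tsv optional TSV with columns `gene_id`, `cds_pos`,
#'   `sensitivity` from a previous run (e.g. its `site_records.tsv`);
#'   genes fully covered by it skip the folding stage.
#' @return list with `sites` (per-site records), `overall`
#'   (`species_analysis`), `stratified` (by expression and ENC', when
#'   available), `windows` (windowed table), `perm` / `perm_init` /
#'   `perm_elong` (permutation tests), `exclusions`.
#' @export
pipeline_run <- function(alignments_dir, tree_path, out_dir,
                         expression_path = NULL,
                         config = read_run_config(),
                         sensitivity_tsv = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sens_cache <- NULL
  if (!is.null(sensitivity_tsv)) {
    sens_cache <- utils::read.delim(sensitivity_tsv)
    stopifnot(all(c("gene_id", "cds_pos", "sensitivity") %in%
                    names(sens_cache)))
  }
  tree <- ape::read.tree(tree_path)
  wt <- leaf_weights(tree)
  fp <- fold_params(flank = config$flank, d_min_span = config$d_min_span,
                    min_hairpin = config$min_hairpin,
                    sens_cutoff = config$s_cut)
  files <- list.files(alignments_dir, pattern = "\\.(fa|fasta)$",
                      full.names = TRUE)
  if (!length(files)) stop("no alignment files found in ", alignments_dir)
  exclusions <- data.frame(gene_id = character(0), reason = character(0))
  site_list <- list()
  enc_values <- numeric(0)
  for (f in files) {
    aln <- read_alignment(f)
    gid <- aln$gene_id
    if (!all(aln$species %in% tree$tip.label)) {
      exclusions <- rbind(exclusions,
                          data.frame(gene_id = gid, reason = "species_not_in_tree"))
      next
    }
    filt <- alignability_filter(aln, config$min_frac)
    if (!filt$keep) {
      exclusions <- rbind(exclusions,
                          data.frame(gene_id = gid, reason = "alignability"))
      next
    }
    sites <- tryCatch(fourfold_sites(aln), error = function(e) e)
    if (inherits(sites, "error") || nrow(sites) == 0) {
      exclusions <- rbind(exclusions,
                          data.frame(gene_id = gid, reason = "no_fourfold_sites"))
      next
    }
    ref_cds <- gsub("-", "", aln$seqs[[aln$reference_index]], fixed = TRUE)
    # reuse cached per-site sensitivities when the cache covers the gene;
    # otherwise fold the reference CDS
    sens_vals <- NULL
    if (!is.null(sens_cache)) {
      cached <- sens_cache[sens_cache$gene_id == gid, ]
      hit <- match(sites$cds_pos, cached$cds_pos)
      if (!anyNA(hit)) sens_vals <- cached$sensitivity[hit]
    }
    if (is.null(sens_vals))
      sens_vals <- gene_sensitivity(ref_cds, sites$cds_pos, fp)$sensitivity
    rec <- site_entropies(aln, sites, wt$weights, sensitivity = sens_vals)
    rec$sensitive <- rec$sensitivity > config$s_cut
    rec$conserved <- classify_conserved(rec$E_w, config$e_cut)
    site_list[[gid]] <- rec
    enc_values[gid] <- suppressWarnings(encprime(ref_cds))
  }
  if (!length(site_list)) stop("no gene passed the filters")
  sites <- do.call(rbind, site_list)
  rownames(sites) <- NULL
  write_site_table(sites, file.path(out_dir, "site_records.tsv"))

  overall <- run_species_analysis(sites, config$e_cut, config$s_cut)
  .write_mh_tsv(list(overall = overall$mh), file.path(out_dir, "mh_overall.tsv"))

  stratified <- list()
  if (!is.null(expression_path)) {
    expr_tab <- utils::read.delim(expression_path)
    expr <- stats::setNames(expr_tab$expression, expr_tab$gene_id)
    stratified$expression <- stratified_analysis(sites, expr, "expression",
                                                 config$e_cut, config$s_cut)
  }
  if (any(!is.na(enc_values)))
    stratified$encprime <- stratified_analysis(sites, enc_values, "encprime",
                                               config$e_cut, config$s_cut)
  if (length(stratified)) {
    mh_list <- list()
    for (nm in names(stratified)) {
      mh_list[[paste0(nm, "_top")]] <- stratified[[nm]]$top
      mh_list[[paste0(nm, "_bottom")]] <- stratified[[nm]]$bottom
    }
    .write_mh_tsv(mh_list, file.path(out_dir, "mh_stratified.tsv"))
  }

  windows <- windowed_analysis(
    sites, sliding_windows(config$window_win, config$window_step,
                           config$window_last_start),
    config$e_cut, config$s_cut)
  utils::write.table(windows, file.path(out_dir, "mh_windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  perm <- constrained_permutation_test(sites, config$n_perm, config$seed)
  perm_init <- tryCatch(
    regional_correlation_test(sites, config$region_init, config$n_perm,
                              config$seed),
    error = function(e) NULL)
  perm_elong <- tryCatch(
    regional_correlation_test(sites, config$region_elong, config$n_perm,
                              config$seed),
    error = function(e) NULL)
  perm_tab <- do.call(rbind, lapply(
    Filter(Negate(is.null),
           list(whole_gene = perm, initiation = perm_init,
                elongation = perm_elong)),
    function(p) data.frame(mean_r = p$mean_r, p_left = p$p_left,
                           n_genes_used = p$n_genes_used,
                           n_genes_excluded = p$n_genes_excluded)))
  perm_tab <- cbind(analysis = rownames(perm_tab), perm_tab)
  utils::write.table(perm_tab, file.path(out_dir, "permutation_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(exclusions))
    utils::write.table(exclusions, file.path(out_dir, "exclusions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(stage = "run", config = config,
                   n_genes_analyzed = length(site_list),
                   n_genes_excluded = nrow(exclusions),
                   n_sites = nrow(sites),
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  list(sites = sites, overall = overall, stratified = stratified,
       windows = windows, perm = perm, perm_init = perm_init,
       perm_elong = perm_elong, enc = enc_values, exclusions = exclusions)
}

.write_mh_tsv <- function(mh_list, path) {
  tab <- do.call(rbind, lapply(names(mh_list), function(nm) {
    m <- mh_list[[nm]]
    data.frame(stratum = nm, or_mh = m$or_mh, chi2 = m$chi2,
               p_value = m$p_value, ci_low = m$ci95[1], ci_high = m$ci95[2],
               n_strata = m$n_strata_used, n_sites = m$n_sites)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
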