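#' Per-gene 2x2 contingency table
#'
#' Cross-classifies a gene's 4-fold degenerate sites as conserved
#' (weighted entropy strictly below `e_cut`) versus non-conserved and
#' structurally sensitive (sensitivity strictly above `s_cut`) versus
#' non-sensitive. Both thresholds are strict: a site exactly at a cutoff
#' falls in the non-conserved / non-sensitive cell. Sites with undefined
#' entropy are dropped.
#'
#' @param sites data.frame with columns `E_w` and `sensitivity` (all sites
#'   of one gene, optionally restricted to a window or region).
#' @param e_cut conservation cutoff on weighted entropy (bits).
#' @param s_cut sensitivity cutoff on mean d_max.
#' @return Named integer vector `c(a, b, c, d)`: a = sensitive & conserved,
#'   b = sensitive & non-conserved, c = non-sensitive & conserved,
#'   d = non-sensitive & non-conserved.
#' @export
gene_table <- function(sites, e_cut = 0.5, s_cut = 0.1) {
  sites <- sites[!is.na(sites$E_w), , drop = FALSE]
  cons <- sites$E_w < e_cut
  sens <- sites$sensitivity > s_cut
  c(a = sum(sens & cons), b = sum(sens & !cons),
    c = sum(!sens & cons), d = sum(!sens & !cons))
}

# strata as a data.frame with columns a, b, c, d
.as_strata <- function(tables) {
  if (is.data.frame(tables)) {
    stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
    return(tables[c("a", "b", "c", "d")])
  }
  if (is.numeric(tables) && length(tables) == 4)
    tables <- list(tables)
  as.data.frame(do.call(rbind, lapply(tables, function(t) t[c("a", "b", "c", "d")])))
}

#' Mantel-Haenszel combination of per-gene 2x2 tables
#'
#' Pools the per-gene odds ratios into one association estimate that is
#' robust to per-gene sparsity:
#' `OR_MH = sum(a_i d_i / s_i) / sum(b_i c_i / s_i)`.
#' Significance uses the Mantel-Haenszel chi-square with a 0.5 continuity
#' correction and a two-sided p-value from the 1-df chi-square upper tail;
#' the 95% confidence interval for `log OR_MH` uses the
#' Robins-Breslow-Greenland variance. Degenerate strata (fewer than 2
#' sites) are skipped and counted.
#'
#' @param tables a data.frame with columns `a`, `b`, `c`, `d` (one row per
#'   gene/stratum), a list of [gene_table()] vectors, or a single such
#'   vector.
#' @return Object of class `mh_result`: list with `or_mh`, `chi2`,
#'   `p_value`, `ci95`, `n_strata`, `n_strata_used`, `n_sites`.
#' @examples
#' mantel_haenszel(c(a = 3, b = 10, c = 4, d = 57))$or_mh  # 4.275
#' @export
mantel_haenszel <- function(tables) {
  tb <- .as_strata(tables)
  a <- tb$a; b <- tb$b; cc <- tb$c; d <- tb$d
  s <- a + b + cc + d
  use <- s >= 2
  if (!any(use)) stop("no stratum with at least 2 sites")
  a <- a[use]; b <- b[use]; cc <- cc[use]; d <- d[use]; s <- s[use]
  m1 <- a + b; m2 <- cc + d; n1 <- a + cc; n2 <- b + d
  num <- sum(a * d / s)
  den <- sum(b * cc / s)
  or_mh <- if (den > 0) num / den else if (num > 0) Inf else NA_real_
  # continuity-corrected MH chi-square; the 0.5 correction is not applied
  # past zero (standard Yates truncation)
  expect_a <- sum(m1 * n1 / s)
  delta <- abs(sum(a) - expect_a)
  cc_term <- if (delta >= 0.5) 0.5 else 0
  var_a <- sum(as.numeric(m1) * m2 * n1 * n2 / (s^2 * (s - 1)))
  chi2 <- if (var_a > 0) (delta - cc_term)^2 / var_a else NA_real_
  p <- if (is.na(chi2)) NA_real_ else stats::pchisq(chi2, df = 1,
                                                    lower.tail = FALSE)
  # Robins-Breslow-Greenland variance of log OR_MH
  ci <- c(NA_real_, NA_real_)
  if (is.finite(or_mh) && or_mh > 0 && num > 0 && den > 0) {
    P <- (a + d) / s; Q <- (b + cc) / s
    R <- a * d / s; S <- b * cc / s
    vlog <- sum(P * R) / (2 * num^2) +
      sum(P * S + Q * R) / (2 * num * den) +
      sum(Q * S) / (2 * den^2)
    ci <- exp(log(or_mh) + c(-1, 1) * stats::qnorm(0.975) * sqrt(vlog))
  }
  structure(list(or_mh = or_mh, chi2 = chi2, p_value = p, ci95 = ci,
                 n_strata = length(use), n_strata_used = sum(use),
                 n_sites = sum(s)),
            class = "mh_result")
}

#' @export
print.mh_result <- function(x, ...) {
  cat("Mantel-Haenszel association (", x$n_strata_used, " strata, ",
      x$n_sites, " sites)\n", sep = "")
  cat(sprintf("  OR_MH = %.4g  95%% CI [%.4g, %.4g]\n",
              x$or_mh, x$ci95[1], x$ci95[2]))
  cat(sprintf("  chi-square = %.4g, two-sided p = %.3g\n", x$chi2, x$p_value))
  invisible(x)
}

#' Genome-wide association between structural sensitivity and conservation
#'
#' Builds one 2x2 table per gene from the per-site records and combines
#' them with the Mantel-Haenszel procedure; also reports the per-gene
#' fraction of structurally sensitive sites (a power diagnostic: genes or
#' species with few sensitive sites yield weak tests).
#'
#' @param site_records data.frame with columns `gene_id`, `E_w`,
#'   `sensitivity` (one row per 4-fold site).
#' @param e_cut,s_cut classification cutoffs, see [gene_table()].
#' @return Object of class `species_analysis`: list with `mh` (an
#'   `mh_result`), `tables` (per-gene counts) and `sensitive_fraction`
#'   (named vector).
#' @export
run_species_analysis <- function(site_records, e_cut = 0.5, s_cut = 0.1) {
  stopifnot(all(c("gene_id", "E_w", "sensitivity") %in% names(site_records)))
  split_sites <- split(site_records, site_records$gene_id)
  tabs <- t(vapply(split_sites, gene_table, integer(4),
                   e_cut = e_cut, s_cut = s_cut))
  tabs <- as.data.frame(tabs)
  names(tabs) <- c("a", "b", "c", "d")
  tabs$gene_id <- rownames(tabs)
  frac <- vapply(split_sites, function(s)
    mean(s$sensitivity > s_cut, na.rm = TRUE), numeric(1))
  structure(list(mh = mantel_haenszel(tabs), tables = tabs,
                 sensitive_fraction = frac, e_cut = e_cut, s_cut = s_cut),
            class = "species_analysis")
}

#' @export
print.species_analysis <- function(x, ...) {
  cat("Association between structural sensitivity and conservation\n")
  cat(sprintf("  cutoffs: E_w < %.3g (conserved), sensitivity > %.3g (sensitive)\n",
              x$e_cut, x$s_cut))
  cat(sprintf("  median sensitive-site fraction per gene: %.3f\n",
              stats::median(x$sensitive_fraction)))
  print(x$mh)
  invisible(x)
}

#' Association analysis stratified by a gene-level covariate
#'
#' Splits genes at the covariate median ([median_split()]) and runs the
#' Mantel-Haenszel combination separately in each half. For expression,
#' `top` is the highest-expressed half; for codon bias, pass
#' `covariate_type = "encprime"` so that `top` denotes the strongest bias
#' (the *lowest* ENC' values).
#'
#' @param site_records per-site data.frame (see [run_species_analysis()]).
#' @param covariate named numeric vector over gene ids; genes missing from
#'   it are excluded from this analysis only.
#' @param covariate_type `"expression"` (top = largest values) or
#'   `"encprime"` (top = smallest values = strongest bias).
#' @param e_cut,s_cut classification cutoffs.
#' @return list of class `stratified_analysis` with `top`, `bottom`
#'   (`mh_result`s), `groups` (gene ids per half), `n_excluded`.
#' @export
stratified_analysis <- function(site_records, covariate,
                                covariate_type = c("expression", "encprime"),
                                e_cut = 0.5, s_cut = 0.1) {
  covariate_type <- match.arg(covariate_type)
  genes <- unique(site_records$gene_id)
  cov <- covariate[names(covariate) %in% genes]
  n_excluded <- length(genes) - length(cov[!is.na(cov)])
  halves <- median_split(cov)
  # "top" = high expression, or strongest codon bias (low ENC')
  top_ids <- if (covariate_type == "expression") halves$top else halves$bottom
  bottom_ids <- setdiff(c(halves$top, halves$bottom), top_ids)
  run_half <- function(ids)
    run_species_analysis(site_records[site_records$gene_id %in% ids, ,
                                      drop = FALSE], e_cut, s_cut)$mh
  structure(list(top = run_half(top_ids), bottom = run_half(bottom_ids),
                 groups = list(top = top_ids, bottom = bottom_ids),
                 covariate_type = covariate_type, n_excluded = n_excluded),
            class = "stratified_analysis")
}

#' @export
print.stratified_analysis <- function(x, ...) {
  lab <- if (x$covariate_type == "expression")
    c("high expression", "low expression")
  else c("strong codon bias (low ENC')", "weak codon bias (high ENC')")
  cat("Stratified association -- ", lab[1], ":\n", sep = "")
  print(x$top)
  cat("-- ", lab[2], ":\n", sep = "")
  print(x$bottom)
  invisible(x)
}

#' 5' sliding-window scheme
#'
#' Enumerates 1-based inclusive windows `[1 + step (k-1), win + step (k-1)]`
#' for `k = 1, 2, ...` while the window start does not exceed `last_start`.
#' The defaults (36-nt windows advanced in 12-nt steps up to start 109)
#' give 10 windows covering the first 144 coding nucleotides.
#'
#' @param win window length in nucleotides.
#' @param step step size in nucleotides.
#' @param last_start largest allowed window start.
#' @return data.frame with columns `start`, `end`.
#' @examples
#' nrow(sliding_windows(36, 12, 109))  # 10
#' nrow(sliding_windows(45, 15, 121))  # 9
#' @export
sliding_windows <- function(win = 36L, step = 12L, last_start = 109L) {
  stopifnot(win > 0, step > 0, last_start > 0)
  starts <- seq(1L, as.integer(last_start), by = as.integer(step))
  data.frame(start = starts, end = starts + as.integer(win) - 1L)
}

#' Windowed association analysis along the CDS
#'
#' Runs the Mantel-Haenszel combination within each window of a sliding
#' scheme. A site belongs to every window containing its CDS position, so
#' overlapping windows share sites; genes shorter than a window's end
#' simply contribute the sites they have. Windows with no sensitive (or no
#' conserved) contrast yield an undefined odds ratio, reported as `NA`.
#'
#' @param site_records per-site data.frame with `cds_pos`.
#' @param windows data.frame from [sliding_windows()].
#' @param e_cut,s_cut classification cutoffs.
#' @return data.frame: `start`, `end`, `or_mh`, `chi2`, `p_value`,
#'   `ci_low`, `ci_high`, `n_sites`, `sensitive_fraction`.
#' @export
windowed_analysis <- function(site_records, windows = sliding_windows(),
                              e_cut = 0.5, s_cut = 0.1) {
  res <- lapply(seq_len(nrow(windows)), function(w) {
    sel <- site_records$cds_pos >= windows$start[w] &
      site_records$cds_pos <= windows$end[w]
    sub <- site_records[sel, , drop = FALSE]
    out <- data.frame(start = windows$start[w], end = windows$end[w],
                      or_mh = NA_real_, chi2 = NA_real_, p_value = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      n_sites = nrow(sub),
                      sensitive_fraction = if (nrow(sub))
                        mean(sub$sensitivity > s_cut, na.rm = TRUE)
                      else NA_real_)
    if (nrow(sub) >= 2) {
      mh <- tryCatch(run_species_analysis(sub, e_cut, s_cut)$mh,
                     error = function(e) NULL)
      if (!is.null(mh)) {
        out$or_mh <- ifelse(is.finite(mh$or_mh), mh$or_mh, NA_real_)
        out$chi2 <- mh$chi2; out$p_value <- mh$p_value
        out$ci_low <- mh$ci95[1]; out$ci_high <- mh$ci95[2]
      }
    }
    out
  })
  do.call(rbind, res)
}

#' Constrained permutation test on continuous scores
#'
#' Dichotomizing both scores loses information; this test uses them as-is.
#' The observed statistic is the mean over genes of the per-gene Pearson
#' correlation between structural sensitivity and weighted entropy at
#' 4-fold sites. Its null distribution is obtained by reshuffling, within
#' each gene, the entropy values only among sites that share the same
#' reference nucleotide -- preserving each gene's amino acid sequence,
#' codon usage and nucleotide composition so compositional confounders
#' cannot create a spurious signal. The p-value is left-tailed (the
#' alternative is a *negative* mean correlation: sensitive sites more
#' conserved) and uses the add-one estimator
#' `(1 + #{null <= observed}) / (1 + n_perm)`, which can never be zero.
#'
#' Genes need at least 3 usable sites and nonzero variance in both scores;
#' others are excluded and counted. Nucleotide classes with fewer than 2
#' sites are fixed points of the reshuffle.
#'
#' @param site_records data.frame with `gene_id`, `ref_nt`, `E_w`,
#'   `sensitivity`.
#' @param n_perm number of permutation replicates.
#' @param seed RNG seed (per-gene substreams are derived from it, so
#'   results do not depend on gene order).
#' @return Object of class `perm_test_result`: `mean_r`, `null_means`,
#'   `p_left`, `n_genes_used`, `n_genes_excluded`.
#' @export
constrained_permutation_test <- function(site_records, n_perm = 1000L,
                                         seed = 1L) {
  stopifnot(all(c("gene_id", "ref_nt", "E_w", "sensitivity") %in%
                  names(site_records)))
  site_records <- site_records[!is.na(site_records$E_w), , drop = FALSE]
  split_sites <- split(site_records, site_records$gene_id)
  n_perm <- as.integer(n_perm)
  obs <- numeric(0)
  null_sum <- numeric(n_perm)
  used <- 0L
  for (gi in seq_along(split_sites)) {
    g <- split_sites[[gi]]
    if (nrow(g) < 3) next
    s <- g$sensitivity; e <- g$E_w
    if (stats::sd(s) == 0 || stats::sd(e) == 0) next
    used <- used + 1L
    obs[used] <- stats::cor(s, e)
    cls <- split(seq_len(nrow(g)), g$ref_nt)
    idx <- matrix(rep(seq_len(nrow(g)), n_perm), nrow = nrow(g))
    .with_seed(.derive_seed(seed, gi), {
      for (members in cls) {
        if (length(members) < 2) next
        for (b in seq_len(n_perm))
          idx[members, b] <- members[sample.int(length(members))]
      }
    })
    eperm <- matrix(e[idx], nrow = nrow(g))
    null_sum <- null_sum + as.numeric(stats::cor(s, eperm))
  }
  if (used == 0L) stop("no gene with enough usable sites for the test")
  mean_r <- mean(obs)
  null_means <- null_sum / used
  p_left <- (1 + sum(null_means <= mean_r)) / (1 + n_perm)
  structure(list(mean_r = mean_r, null_means = null_means, p_left = p_left,
                 n_perm = n_perm, n_genes_used = used,
                 n_genes_excluded = length(split_sites) - used),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat("Constrained permutation test (", x$n_genes_used, " genes, ",
      x$n_perm, " replicates; ", x$n_genes_excluded, " genes excluded)\n",
      sep = "")
  cat(sprintf("  mean per-gene Pearson r = %.4f\n", x$mean_r))
  cat(sprintf("  left-tailed p = %.4g\n", x$p_left))
  invisible(x)
}

#' Regional permutation test
#'
#' [constrained_permutation_test()] restricted to sites whose CDS position
#' lies in a 1-based inclusive interval -- typically the translation
#' initiation region (nucleotides 1-60) or the downstream elongation
#' region (91-150).
#'
#' @param site_records per-site data.frame.
#' @param region `c(from, to)`, 1-based inclusive.
#' @param n_perm,seed see [constrained_permutation_test()].
#' @return A `perm_test_result`.
#' @export
regional_correlation_test <- function(site_records, region,
                                      n_perm = 1000L, seed = 1L) {
  stopifnot(length(region) == 2, region[1] <= region[2])
  sel <- site_records$cds_pos >= region[1] & site_records$cds_pos <= region[2]
  if (!any(sel)) stop("region contains no 4-fold degenerate sites")
  constrained_permutation_test(site_records[sel, , drop = FALSE],
                               n_perm = n_perm, seed = seed)
}
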