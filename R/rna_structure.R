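#' Folding parameters for the partition-function engine
#'
#' Bundles the energy model and locality settings used by [partition_bpp()],
#' [d_max()] and [site_sensitivity()]. The default `simple_stack` model
#' assigns one free energy per canonical pair (AU/AT, GC, GU/GT) plus a
#' stacking bonus when a pair sits directly on another; Boltzmann factors are
#' `exp(-E / RT)` at the given temperature. The absolute scale is simpler
#' than a full nearest-neighbour parameter set: the downstream statistic
#' depends on *differences* between wild-type and mutant pairing
#' probabilities, not on absolute folding accuracy.
#'
#' @param e_au,e_gc,e_gu free energy of an AU, GC, GU pair (kcal/mol,
#'   negative = stabilizing).
#' @param e_stack additional stacking energy for directly nested pairs
#'   (kcal/mol).
#' @param temperature temperature in kelvin.
#' @param min_hairpin minimum number of unpaired bases in a hairpin loop;
#'   positions `i`, `j` can only pair when `j - i > min_hairpin`.
#' @param flank number of nucleotides of local context folded on each side of
#'   a site by [site_sensitivity()].
#' @param d_min_span minimum subinterval length in the [d_max()] scan.
#' @param sens_cutoff structural-sensitivity cutoff: a site is called
#'   sensitive when its mean d_max over the three point mutations is
#'   strictly greater than this value.
#' @return An object of class `fold_params`.
#' @examples
#' fp <- fold_params(flank = 40)
#' fp$min_hairpin
#' @export
fold_params <- function(e_au = -2.0, e_gc = -3.0, e_gu = -1.0,
                        e_stack = -1.0, temperature = 310.15,
                        min_hairpin = 3L, flank = 200L, d_min_span = 10L,
                        sens_cutoff = 0.1) {
  stopifnot(min_hairpin >= 3, flank >= d_min_span, d_min_span >= 2,
            temperature > 0)
  structure(list(e_au = e_au, e_gc = e_gc, e_gu = e_gu, e_stack = e_stack,
                 temperature = temperature, min_hairpin = as.integer(min_hairpin),
                 flank = as.integer(flank), d_min_span = as.integer(d_min_span),
                 sens_cutoff = sens_cutoff),
            class = "fold_params")
}

# gas constant in kcal/(mol K)
.RGAS <- 0.0019872

# Boltzmann factors for the current parameter set
.fold_weights <- function(fp) {
  rt <- .RGAS * fp$temperature
  list(wAU = exp(-fp$e_au / rt), wGC = exp(-fp$e_gc / rt),
       wGU = exp(-fp$e_gu / rt), wStack = exp(-fp$e_stack / rt))
}

# encode A/C/G/T/U as 0..3 (U == T); error on anything else
.encode_seq <- function(sequence) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  code <- match(ch, c("A", "C", "G", "T", "U"))
  if (anyNA(code))
    stop("invalid character(s) in sequence: ",
         paste(unique(ch[is.na(code)]), collapse = ", "))
  code[code == 5L] <- 4L
  as.integer(code - 1L)
}

#' Base-pair probability matrix by exact partition function
#'
#' Computes equilibrium base-pairing probabilities over the Boltzmann
#' ensemble of all nested secondary structures (McCaskill inside-outside
#' dynamic programming), with canonical pairs only and hairpin loops of at
#' least `min_hairpin` unpaired bases. Probabilities are exact for the
#' configured energy model (no sampling); partition functions are rescaled
#' internally so long, stable windows do not overflow.
#'
#' @param sequence a single DNA/RNA string (`U` is treated as `T`).
#' @param fp a [fold_params()] object.
#' @return An `n` x `n` numeric matrix of class `bpp_matrix`; entry `[i, j]`
#'   (`i < j`, 1-based) is the probability that bases `i` and `j` are paired.
#'   The lower triangle is zero.
#' @examples
#' P <- partition_bpp("GGGGAAAACCCC", fold_params())
#' P[1, 12]
#' @export
partition_bpp <- function(sequence, fp = fold_params()) {
  s <- .encode_seq(sequence)
  n <- length(s)
  if (n < fp$min_hairpin + 2L) {
    warning("sequence shorter than min_hairpin + 2; no structure possible")
    P <- matrix(0, n, n)
    class(P) <- c("bpp_matrix", class(P))
    return(P)
  }
  w <- .fold_weights(fp)
  P <- mccaskill_bpp_cpp(s, w$wAU, w$wGC, w$wGU, w$wStack, fp$min_hairpin)
  class(P) <- c("bpp_matrix", class(P))
  P
}

#' Extract the local folding window around a site
#'
#' Returns the subsequence `[max(1, pos - flank), min(n, pos + flank)]`
#' together with the offset mapping window coordinates back to sequence
#' coordinates. Wild-type and mutant are always folded over the identical
#' interval, so their probability matrices are directly comparable.
#'
#' @param sequence nucleotide string.
#' @param pos 1-based position the window is centred on.
#' @param flank context length on each side, in nucleotides.
#' @return list with `seq` (the window), `start`, `end` (1-based inclusive
#'   coordinates in `sequence`) and `offset` (`start - 1`; window position
#'   `k` corresponds to sequence position `k + offset`).
#' @export
local_window <- function(sequence, pos, flank) {
  n <- nchar(sequence)
  stopifnot(pos >= 1, pos <= n)
  a <- max(1L, as.integer(pos) - as.integer(flank))
  b <- min(n, as.integer(pos) + as.integer(flank))
  list(seq = substr(sequence, a, b), start = a, end = b, offset = a - 1L)
}

#' Maximum local structural distance between two pairing ensembles
#'
#' The disruption score for one mutation: over every subinterval `[a, b]` of
#' the window with `b - a + 1 >= d_min_span`, take the Euclidean distance
#' between the two matrices restricted to pairs inside the interval, divide
#' by the interval length, and return the maximum. Local normalization keeps
#' a short, completely rearranged hairpin from being drowned out by a long
#' unchanged context.
#'
#' @param p_wt,p_mut base-pair probability matrices over the same window.
#' @param d_min_span minimum subinterval length.
#' @return A single nonnegative number; 0 when the matrices are identical.
#' @export
d_max <- function(p_wt, p_mut, d_min_span = 10L) {
  if (!all(dim(p_wt) == dim(p_mut)))
    stop("base-pair probability matrices have different dimensions")
  dmax_scan_cpp(unclass(p_wt), unclass(p_mut), as.integer(d_min_span))
}

#' Structural sensitivity of a nucleotide site
#'
#' Folds the local window around the site for the wild type and for each of
#' the three possible point mutations, computes [d_max()] for every mutant,
#' and summarizes the site by the mean of the three scores. The site is
#' called structurally sensitive when the mean is strictly greater than the
#' cutoff.
#'
#' @param sequence the reference CDS (or any nucleotide string).
#' @param pos 1-based position to mutate (for the analysis proper this is a
#'   4-fold degenerate third codon position, so no mutation changes the
#'   protein).
#' @param fp a [fold_params()] object.
#' @return list with `pos`, `d_max` (named vector, one entry per mutant
#'   nucleotide), `sensitivity` (their mean) and `sensitive` (logical).
#' @export
site_sensitivity <- function(sequence, pos, fp = fold_params()) {
  win <- local_window(sequence, pos, fp$flank)
  p_wt <- partition_bpp(win$seq, fp)
  ref <- toupper(substr(sequence, pos, pos))
  muts <- setdiff(c("A", "C", "G", "T"), ref)
  k <- pos - win$offset
  d <- vapply(muts, function(nt) {
    mseq <- win$seq
    substr(mseq, k, k) <- nt
    d_max(p_wt, partition_bpp(mseq, fp), fp$d_min_span)
  }, numeric(1))
  sens <- mean(d)
  list(pos = pos, d_max = d, sensitivity = sens,
       sensitive = sens > fp$sens_cutoff)
}

#' Structural sensitivity for many sites of one gene
#'
#' Convenience wrapper over [site_sensitivity()]: scores each position and
#' returns a per-site data frame. When `flank` covers the whole sequence the
#' wild-type fold is shared across sites.
#'
#' @param sequence reference CDS.
#' @param positions integer vector of 1-based positions.
#' @param fp a [fold_params()] object.
#' @return data.frame with columns `pos`, `sensitivity`, `sensitive`.
#' @export
gene_sensitivity <- function(sequence, positions, fp = fold_params()) {
  n <- nchar(sequence)
  whole <- fp$flank >= n  # every window is the full sequence
  p_wt_full <- if (whole) partition_bpp(sequence, fp) else NULL
  sens <- vapply(positions, function(pos) {
    if (whole) {
      ref <- toupper(substr(sequence, pos, pos))
      muts <- setdiff(c("A", "C", "G", "T"), ref)
      d <- vapply(muts, function(nt) {
        mseq <- sequence
        substr(mseq, pos, pos) <- nt
        d_max(p_wt_full, partition_bpp(mseq, fp), fp$d_min_span)
      }, numeric(1))
      mean(d)
    } else {
      site_sensitivity(sequence, pos, fp)$sensitivity
    }
  }, numeric(1))
  data.frame(pos = as.integer(positions), sensitivity = sens,
             sensitive = sens > fp$sens_cutoff)
}

#' Calibrate the sensitivity cutoff to a target fraction of disruptive
#' mutations
#'
#' The absolute scale of [d_max()] depends on the locality convention, so
#' the dichotomizing cutoff can alternatively be set empirically: given
#' per-site sensitivity scores from a representative set of genes, pick the
#' cutoff as the `1 - target_fraction` quantile, so that `target_fraction`
#' of sites are called sensitive. Published screening experience suggests
#' that fewer than ~25% of sites have potentially disruptive mutations.
#'
#' @param sensitivities numeric vector of per-site mean d_max scores.
#' @param target_fraction desired fraction of sites called sensitive.
#' @return A cutoff value usable as `sens_cutoff` in [fold_params()].
#' @export
calibrate_sensitivity_cutoff <- function(sensitivities, target_fraction = 0.1) {
  stopifnot(target_fraction > 0, target_fraction < 1)
  as.numeric(stats::quantile(sensitivities, probs = 1 - target_fraction,
                             names = FALSE, type = 7))
}
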