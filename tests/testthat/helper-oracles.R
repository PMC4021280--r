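# Independent oracles used to validate the package's dynamic programs and
# statistics.  These deliberately use brute force / direct formulas and never
# call the code paths they check.

# Exhaustive Boltzmann-ensemble base-pair probabilities: enumerate every
# nested structure with hairpin loops >= min_hairpin, weight it as the
# product of its pair energies plus a stacking bonus for each directly
# nested pair, and accumulate the pair marginals.  Feasible up to ~20 nt.
enum_bpp_oracle <- function(seq, fp = fold_params()) {
  rt <- 0.0019872 * fp$temperature
  pair_w <- function(a, b) {
    p <- paste0(sort(c(a, b)), collapse = "")
    switch(p, AT = exp(-fp$e_au / rt), CG = exp(-fp$e_gc / rt),
           GT = exp(-fp$e_gu / rt), 0)
  }
  stack_w <- exp(-fp$e_stack / rt)
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  memo <- new.env(parent = emptyenv())
  structs <- function(i, j) {
    if (j - i < fp$min_hairpin + 1) return(list(list()))
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- structs(i, j - 1)
    for (k in i:(j - fp$min_hairpin - 1)) {
      if (pair_w(ch[k], ch[j]) > 0) {
        left <- if (k - 1 < i) list(list()) else structs(i, k - 1)
        inner <- structs(k + 1, j - 1)
        for (L in left) for (I in inner)
          out <- c(out, list(c(L, I, list(c(k, j)))))
      }
    }
    memo[[key]] <- out
    out
  }
  ss <- structs(1, n)
  P <- matrix(0, n, n)
  Z <- 0
  for (s in ss) {
    wgt <- 1
    if (length(s)) {
      pm <- do.call(rbind, s)
      for (r in seq_len(nrow(pm))) {
        wgt <- wgt * pair_w(ch[pm[r, 1]], ch[pm[r, 2]])
        if (any(pm[, 1] == pm[r, 1] + 1 & pm[, 2] == pm[r, 2] - 1))
          wgt <- wgt * stack_w
      }
    }
    Z <- Z + wgt
    if (length(s))
      for (r in seq_len(nrow(pm)))
        P[pm[r, 1], pm[r, 2]] <- P[pm[r, 1], pm[r, 2]] + wgt
  }
  P / Z
}

# Naive all-intervals maximum structural distance: explicit double loop,
# summing squared differences inside each interval from scratch.
dmax_naive_oracle <- function(p1, p2, min_span) {
  D <- (unclass(p1) - unclass(p2))^2
  n <- nrow(D)
  best <- 0
  for (a in seq_len(n)) {
    for (b in a:n) {
      if (b - a + 1 < min_span) next
      idx <- a:b
      sub <- D[idx, idx, drop = FALSE]
      d <- sqrt(sum(sub[upper.tri(sub)])) / (b - a + 1)
      if (d > best) best <- d
    }
  }
  best
}

# Plain (unweighted) Shannon entropy of a nucleotide column, in bits.
shannon_entropy_oracle <- function(column) {
  keep <- column %in% c("A", "C", "G", "T")
  p <- table(column[keep]) / sum(keep)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Codon third-position degeneracy from the genetic code itself: a third
# position is 4-fold degenerate iff all four third-position variants
# translate to the same amino acid.
fourfold_codon_oracle <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  variants <- paste0(substr(codon, 1, 2), c("A", "C", "G", "T"))
  aas <- gc[variants]
  !anyNA(aas) && length(unique(aas)) == 1 && gc[[codon]] != "*"
}

# Wright's classic effective number of codons from codon counts, using the
# homozygosity estimator F-hat = (n * sum p_i^2 - 1) / (n - 1) per family,
# count-weighted class averages, 3-fold interpolation, clipping -- mirrors
# the package's class combination but with Wright's F instead of the
# chi-square F'.
wright_enc_oracle <- function(counts) {
  fams <- list(
    k2 = list(c("TTT", "TTC"), c("TAT", "TAC"), c("TGT", "TGC"),
              c("CAT", "CAC"), c("CAA", "CAG"), c("AAT", "AAC"),
              c("AAA", "AAG"), c("GAT", "GAC"), c("GAA", "GAG")),
    k3 = list(c("ATT", "ATC", "ATA")),
    k4 = list(c("GTT", "GTC", "GTA", "GTG"), c("CCT", "CCC", "CCA", "CCG"),
              c("ACT", "ACC", "ACA", "ACG"), c("GCT", "GCC", "GCA", "GCG"),
              c("GGT", "GGC", "GGA", "GGG")),
    k6 = list(c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
              c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
              c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG")))
  class_f <- function(fam_list) {
    fs <- ns <- c()
    for (cods in fam_list) {
      n <- sum(counts[cods])
      if (n < 2) next
      p <- counts[cods] / n
      f <- (n * sum(p^2) - 1) / (n - 1)
      if (!is.finite(f) || f <= 1e-12) next
      fs <- c(fs, f); ns <- c(ns, n)
    }
    if (!length(fs)) return(NA_real_)
    sum(ns * fs) / sum(ns)
  }
  f2 <- class_f(fams$k2); f3 <- class_f(fams$k3)
  f4 <- class_f(fams$k4); f6 <- class_f(fams$k6)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
  if (anyNA(c(f2, f3, f4, f6))) return(NA_real_)
  min(61, max(20, 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6))
}

# Random nucleotide string.
random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A codon_counts object built directly from counts and background (for
# formula-level checks where the background must be controlled exactly).
make_codon_counts <- function(counts, background) {
  all_codons <- names(Biostrings::GENETIC_CODE)
  full <- stats::setNames(rep(0, length(all_codons)), all_codons)
  full[names(counts)] <- counts
  structure(list(counts = full, background = background),
            class = "codon_counts")
}
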