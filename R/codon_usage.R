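# Synonymous codon families of the standard genetic code, grouped by
# degeneracy class.  Met (ATG) and Trp (TGG) carry no synonymous signal and
# stop codons are excluded throughout.
.SYN_FAMILIES <- list(
  Phe = c("TTT", "TTC"), Tyr = c("TAT", "TAC"), Cys = c("TGT", "TGC"),
  His = c("CAT", "CAC"), Gln = c("CAA", "CAG"), Asn = c("AAT", "AAC"),
  Lys = c("AAA", "AAG"), Asp = c("GAT", "GAC"), Glu = c("GAA", "GAG"),
  Ile = c("ATT", "ATC", "ATA"),
  Val = c("GTT", "GTC", "GTA", "GTG"), Pro = c("CCT", "CCC", "CCA", "CCG"),
  Thr = c("ACT", "ACC", "ACA", "ACG"), Ala = c("GCT", "GCC", "GCA", "GCG"),
  Gly = c("GGT", "GGC", "GGA", "GGG"),
  Leu = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  Ser = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  Arg = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"))

.FAMILY_DEGENERACY <- vapply(.SYN_FAMILIES, length, integer(1))

#' Codon counts and background composition for one gene
#'
#' Tabulates codon usage over an in-frame CDS and records the background
#' nucleotide frequencies used to correct the effective number of codons.
#' The default background is the gene's own overall nucleotide composition;
#' `background = "third"` restricts it to third codon positions.
#'
#' @param cds in-frame coding sequence (string; `U` mapped to `T`).
#' @param background `"gene"` (all positions) or `"third"`.
#' @return list of class `codon_counts` with `counts` (named integer vector
#'   over the 61 sense codons) and `background` (frequencies of A, C, G, T).
#' @export
codon_counts <- function(cds, background = c("gene", "third")) {
  background <- match.arg(background)
  cds <- gsub("U", "T", toupper(cds), fixed = TRUE)
  if (nchar(cds) %% 3 != 0) stop("CDS length is not a multiple of 3")
  n <- nchar(cds) %/% 3
  codons <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
  codons <- codons[!codons %in% .STOP_CODONS & !grepl("[^ACGT]", codons)]
  all_codons <- unlist(.SYN_FAMILIES, use.names = FALSE)
  all_codons <- c(all_codons, "ATG", "TGG")
  counts <- table(factor(codons, levels = sort(all_codons)))
  chars <- if (background == "gene") strsplit(cds, "")[[1]]
           else substring(cds, 3 * seq_len(n), 3 * seq_len(n))
  chars <- chars[chars %in% c("A", "C", "G", "T")]
  bg <- table(factor(chars, levels = c("A", "C", "G", "T"))) / length(chars)
  structure(list(counts = c(unclass(counts)), background = c(unclass(bg))),
            class = "codon_counts")
}

# expected within-family codon frequencies from the background composition:
# product of background frequencies over the positions at which the family's
# codons differ, renormalized within the family
.family_expected <- function(codons, bg) {
  mat <- do.call(rbind, strsplit(codons, ""))
  varying <- which(apply(mat, 2, function(col) length(unique(col)) > 1))
  e <- vapply(seq_along(codons), function(i)
    prod(bg[mat[i, varying]]), numeric(1))
  e / sum(e)
}

#' Background-corrected effective number of codons (ENC')
#'
#' Wright-style effective number of codons with the homozygosity statistic
#' replaced by a chi-square deviation from background-derived expected
#' codon frequencies, so compositional bias (e.g. G+C content) is not
#' mistaken for selective codon bias. For each synonymous family with `k`
#' codons and `n` counted codons, `X2 = n * sum((p_i - e_i)^2 / e_i)` and
#' `F' = (X2 + n - k) / (k (n - 1))`; class averages (count-weighted over
#' families of equal degeneracy) combine as
#' `ENC' = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, a missing 3-fold class is
#' interpolated as `(F2 + F4)/2`, and the result is clipped to `[20, 61]`.
#' With a uniform background ENC' reduces exactly to Wright's classic ENC.
#'
#' @param x a `codon_counts` object or a CDS string.
#' @param averaging how family F' values combine into a class mean:
#'   `"count"` weights each family by its codon count (default);
#'   `"family"` averages families equally. Published ENC' variants differ
#'   in this detail.
#' @param ... passed to [codon_counts()] when `x` is a string.
#' @return ENC' in `[20, 61]` (20 = one codon per amino acid, 61 = no
#'   bias), or `NA` with a warning when the gene is too short (< 10 codons)
#'   or a required degeneracy class is unobserved.
#' @examples
#' encprime(generate_root_cds(100, gc_bias = 0.5, seed = 1))
#' @export
encprime <- function(x, averaging = c("count", "family"), ...) {
  averaging <- match.arg(averaging)
  cc <- if (inherits(x, "codon_counts")) x else codon_counts(x, ...)
  if (sum(cc$counts) < 10) {
    warning("gene shorter than 10 counted codons; ENC' undefined")
    return(NA_real_)
  }
  bg <- cc$background
  fam_stats <- lapply(names(.SYN_FAMILIES), function(fam) {
    codons <- .SYN_FAMILIES[[fam]]
    k <- length(codons)
    cnt <- cc$counts[codons]
    n <- sum(cnt)
    if (n < 2) return(NULL)
    p <- cnt / n
    e <- .family_expected(codons, bg)
    if (any(e == 0)) return(NULL)  # degenerate background composition
    x2 <- n * sum((p - e)^2 / e)
    fprime <- (x2 + n - k) / (k * (n - 1))
    # F' <= 0 (possible when n < k) carries no usable homozygosity signal;
    # the epsilon absorbs floating-point noise at the F' = 0 boundary
    if (!is.finite(fprime) || fprime <= 1e-12) return(NULL)
    list(k = k, n = n, fprime = fprime)
  })
  fam_stats <- Filter(Negate(is.null), fam_stats)
  kvec <- vapply(fam_stats, `[[`, numeric(1), "k")
  nvec <- vapply(fam_stats, `[[`, numeric(1), "n")
  fvec <- vapply(fam_stats, `[[`, numeric(1), "fprime")
  class_mean <- function(k) {
    sel <- kvec == k
    if (!any(sel)) return(NA_real_)
    if (averaging == "count") sum(nvec[sel] * fvec[sel]) / sum(nvec[sel])
    else mean(fvec[sel])
  }
  f2 <- class_mean(2); f3 <- class_mean(3)
  f4 <- class_mean(4); f6 <- class_mean(6)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
  if (anyNA(c(f2, f3, f4, f6))) {
    warning("a degeneracy class has no observed family; ENC' undefined")
    return(NA_real_)
  }
  enc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  min(61, max(20, enc))
}

#' Split genes into halves at the median of a covariate
#'
#' Genes are ordered by value with ties broken by gene id (stable), the
#' lower half takes any extra gene when the count is odd, and exact median
#' ties fall into the lower half. Used to stratify the association analysis
#' by expression level or codon bias.
#'
#' @param values named numeric vector (names = gene ids).
#' @return list with `bottom` and `top` character vectors of gene ids.
#' @export
median_split <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 genes with defined values")
  ord <- order(values, names(values))
  ids <- names(values)[ord]
  n_bottom <- ceiling(length(ids) / 2)
  list(bottom = ids[seq_len(n_bottom)], top = ids[-seq_len(n_bottom)])
}
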