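# Codon families whose third position is fully 4-fold degenerate: the first
# two codon nucleotides determine the amino acid (Ala, Arg4, Gly, Leu4, Pro,
# Ser4, Thr, Val).  AGR/AGY and TTR never qualify.
.FOURFOLD_PREFIXES <- c("GC", "CG", "GG", "CT", "CC", "TC", "AC", "GT")

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Construct an ortholog alignment object
#'
#' @param seqs named character vector of aligned nucleotide sequences
#'   (equal lengths; alphabet `A C G T - N`, `U` accepted and mapped to `T`).
#' @param gene_id gene identifier.
#' @param reference name of the focal (reference) species; defaults to the
#'   first record.
#' @return An object of class `ortholog_alignment`.
#' @export
ortholog_alignment <- function(seqs, gene_id = "gene",
                               reference = names(seqs)[1]) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named by species")
  seqs <- toupper(seqs)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (length(unique(nchar(seqs))) != 1)
    stop("ragged alignment: sequences have different lengths")
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("invalid characters in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  if (!reference %in% names(seqs))
    stop("reference species '", reference, "' not found in alignment")
  structure(list(gene_id = gene_id, seqs = seqs,
                 species = names(seqs),
                 reference = reference,
                 reference_index = match(reference, names(seqs))),
            class = "ortholog_alignment")
}

#' Read a multi-FASTA ortholog alignment
#'
#' Reads an aligned multi-FASTA file, uppercases, maps `U` to `T`, and
#' checks that all records have equal length.
#'
#' @param path path to a multi-FASTA file (>= 2 records).
#' @param reference reference species name; defaults to the first record.
#' @param gene_id gene identifier; defaults to the file name without
#'   extension.
#' @return An `ortholog_alignment`.
#' @export
read_alignment <- function(path, reference = NULL, gene_id = NULL) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 2) stop("alignment must contain at least 2 records")
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (is.null(gene_id))
    gene_id <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(reference)) reference <- names(seqs)[1]
  ortholog_alignment(seqs, gene_id = gene_id, reference = reference)
}

#' @export
print.ortholog_alignment <- function(x, ...) {
  cat("Ortholog alignment '", x$gene_id, "': ", length(x$seqs),
      " species, ", nchar(x$seqs[[1]]), " columns (reference: ",
      x$reference, ")\n", sep = "")
  invisible(x)
}

#' Pairwise alignability filter
#'
#' For the reference against every other species, the aligned fraction is
#' the number of columns where both sequences have a nucleotide, divided by
#' each sequence's ungapped length (both directions). A gene is kept only
#' when every pairwise fraction is at least `min_frac`; the boundary is
#' inclusive (exactly `min_frac` is kept).
#'
#' @param alignment an `ortholog_alignment`.
#' @param min_frac minimum aligned fraction (default 0.80).
#' @return list with `keep` (logical) and `fractions` (matrix: one row per
#'   non-reference species, columns `ref_covered` and `other_covered`).
#' @export
alignability_filter <- function(alignment, min_frac = 0.80) {
  chars <- .aln_matrix(alignment)
  ref <- chars[alignment$reference_index, ]
  others <- setdiff(seq_len(nrow(chars)), alignment$reference_index)
  fr <- t(vapply(others, function(i) {
    both <- sum(ref != "-" & chars[i, ] != "-")
    c(ref_covered = both / sum(ref != "-"),
      other_covered = both / sum(chars[i, ] != "-"))
  }, numeric(2)))
  rownames(fr) <- alignment$species[others]
  list(keep = all(fr >= min_frac), fractions = fr)
}

# alignment as a species x column character matrix
.aln_matrix <- function(alignment) {
  do.call(rbind, strsplit(unname(alignment$seqs), ""))
}

#' Locate 4-fold degenerate sites in the reference sequence
#'
#' A third codon position qualifies when the reference codon's first two
#' nucleotides form one of the eight fully degenerate families (`GC`, `CG`,
#' `GG`, `CT`, `CC`, `TC`, `AC`, `GT`), so that every third-position
#' substitution is synonymous. Only the reference row defines sites;
#' orthologs are free to differ at the column (that variation is what the
#' entropy score measures). Positions are reported both in ungapped
#' reference CDS coordinates (1-based; always multiples of 3) and as
#' alignment columns (1-based).
#'
#' @param alignment an `ortholog_alignment`.
#' @return data.frame with columns `gene_id`, `cds_pos`, `aln_col`,
#'   `ref_nt`, `family` (the two-nucleotide codon prefix).
#' @export
fourfold_sites <- function(alignment) {
  ref_row <- strsplit(alignment$seqs[[alignment$reference_index]], "")[[1]]
  cds_cols <- which(ref_row != "-")
  cds <- ref_row[cds_cols]
  if (length(cds) %% 3 != 0)
    stop("ungapped reference length is not a multiple of 3")
  n_codon <- length(cds) %/% 3
  codons <- paste0(cds[3 * seq_len(n_codon) - 2], cds[3 * seq_len(n_codon) - 1],
                   cds[3 * seq_len(n_codon)])
  internal <- codons[-n_codon]
  if (any(internal %in% .STOP_CODONS))
    stop("internal stop codon in reference CDS of gene ", alignment$gene_id)
  prefix <- substr(codons, 1, 2)
  third_known <- !substr(codons, 3, 3) %in% c("N")
  hit <- which(prefix %in% .FOURFOLD_PREFIXES & !grepl("N", prefix) &
                 third_known)
  cds_pos <- 3L * hit
  data.frame(gene_id = rep(alignment$gene_id, length(hit)),
             cds_pos = cds_pos,
             aln_col = cds_cols[cds_pos],
             ref_nt = cds[cds_pos],
             family = prefix[hit],
             stringsAsFactors = FALSE)
}

#' Write a per-site table as TSV
#'
#' @param sites data.frame of per-site records.
#' @param path output path.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
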