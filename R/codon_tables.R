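# Codon bookkeeping shared by the likelihood engine, the simulator and the
# validators. All state indices refer to the 61 sense codons of the universal
# genetic code, ordered alphabetically (AAA, AAC, ..., TTT minus stops).

.codon_env <- new.env(parent = emptyenv())

#' Sense codons of the universal genetic code
#'
#' @return Character vector of the 61 sense codons in alphabetical order
#'   (stop codons TAA, TAG, TGA excluded).
#' @export
sense_codons <- function() {
  if (is.null(.codon_env$codons)) .init_codon_tables()
  .codon_env$codons
}

#' Amino acid encoded by each sense codon
#'
#' @return Character vector of length 61, one-letter amino acid codes,
#'   parallel to [sense_codons()].
#' @export
codon_amino_acids <- function() {
  if (is.null(.codon_env$aa)) .init_codon_tables()
  .codon_env$aa
}

# 61x61 integer matrix classifying single-nucleotide codon exchanges:
# 0 = identical or >1 difference, 1 = synonymous transversion,
# 2 = synonymous transition, 3 = nonsynonymous transversion,
# 4 = nonsynonymous transition.
codon_substitution_types <- function() {
  if (is.null(.codon_env$types)) .init_codon_tables()
  .codon_env$types
}

.init_codon_tables <- function() {
  nt <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  all64 <- sort(all64)
  gc <- Biostrings::GENETIC_CODE  # keyed on DNA codons
  aa64 <- unname(gc[all64])
  keep <- aa64 != "*"
  codons <- all64[keep]
  aa <- aa64[keep]
  n <- length(codons)
  stopifnot(n == 61L)

  cmat <- do.call(rbind, strsplit(codons, ""))
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  types <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    diffs <- cmat[rep(i, n), , drop = FALSE] != cmat
    ndiff <- rowSums(diffs)
    for (j in which(ndiff == 1L)) {
      pos <- which(diffs[j, ])
      transition <- purine[cmat[i, pos]] == purine[cmat[j, pos]]
      syn <- aa[i] == aa[j]
      types[i, j] <- if (syn && !transition) 1L else if (syn && transition) 2L
        else if (!syn && !transition) 3L else 4L
    }
  }
  .codon_env$codons <- codons
  .codon_env$aa <- aa
  .codon_env$types <- types
  invisible(NULL)
}

# Map codon strings (vector of 3-mers) to 0-based engine state indices;
# NA for codons containing ambiguity (treated as missing downstream).
codon_state_index <- function(codons) {
  idx <- match(codons, sense_codons())
  idx - 1L
}
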