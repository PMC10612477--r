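# Protein multiple alignment, protein-guided codon back-translation, and the
# column-cleaning policy applied before likelihood computation.

AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                   "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# 21x21 substitution matrix: BLOSUM62 over the 20 residues plus a
# zero-scoring gap/unknown state in the last row/column.
.aln_submat <- function() {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  b <- get("BLOSUM62", envir = environment())[AA_ALPHABET20, AA_ALPHABET20]
  m <- matrix(0, 21, 21)
  m[1:20, 1:20] <- b
  m
}

# residue characters -> profile row indices (21 = gap/unknown)
.aa_index <- function(chars) {
  i <- match(chars, AA_ALPHABET20)
  i[is.na(i)] <- 21L
  i
}

# frequency profile (21 x L) of a set of equal-length gapped rows
.profile_of <- function(rows) {
  L <- nchar(rows[1])
  m <- matrix(0, 21, L)
  for (r in rows) {
    idx <- .aa_index(strsplit(r, "")[[1]])
    m[cbind(idx, seq_len(L))] <- m[cbind(idx, seq_len(L))] + 1
  }
  m / length(rows)
}

# apply a profile-alignment path (0 = inserted gap) to gapped rows
.apply_path <- function(rows, path) {
  vapply(rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    out <- rep("-", length(path))
    out[path != 0L] <- ch[path[path != 0L]]
    paste(out, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Progressive protein multiple sequence alignment
#'
#' Deterministic progressive alignment: pairwise global alignment distances
#' feed a neighbor-joining guide tree, and profiles are merged postorder by
#' global profile-profile alignment (BLOSUM62, affine gaps, gap open 10 /
#' extend 0.5; a gap of length g costs open + g * extend). An externally
#' produced protein alignment in FASTA can be supplied to the pipeline
#' instead (see [read_protein_alignment()]).
#'
#' @param peptides Named character vector (species -> peptide sequence),
#'   >= 2 sequences.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return An object of class `protein_alignment`: list with `taxa` and
#'   `rows` (named, equal-length gapped strings in input order).
#' @export
align_proteins <- function(peptides, gap_open = 10, gap_extend = 0.5) {
  taxa <- names(peptides)
  if (is.null(taxa) || any(taxa == "")) stop("peptides must be named by species")
  if (any(nchar(peptides) == 0L)) {
    stop("empty sequence for: ",
         paste(taxa[nchar(peptides) == 0L], collapse = ", "))
  }
  n <- length(peptides)
  if (n < 2L) stop("need at least 2 sequences to align")
  submat <- .aln_submat()

  if (n == 2L) {
    al <- cpp_profile_align(.profile_of(peptides[[1]]), .profile_of(peptides[[2]]),
                            submat, gap_open, gap_extend)
    rows <- c(.apply_path(peptides[[1]], al$path_a),
              .apply_path(peptides[[2]], al$path_b))
    return(structure(list(taxa = taxa, rows = setNames(rows, taxa)),
                     class = "protein_alignment"))
  }

  # guide tree from pairwise alignment distances (1 - identity fraction)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      al <- cpp_profile_align(.profile_of(peptides[[i]]),
                              .profile_of(peptides[[j]]),
                              submat, gap_open, gap_extend)
      ra <- .apply_path(peptides[[i]], al$path_a)
      rb <- .apply_path(peptides[[j]], al$path_b)
      ca <- strsplit(ra, "")[[1]]
      cb <- strsplit(rb, "")[[1]]
      shared <- ca != "-" & cb != "-"
      pid <- if (any(shared)) mean(ca[shared] == cb[shared]) else 0
      D[i, j] <- D[j, i] <- 1 - pid
    }
  }
  guide <- ape::nj(D)

  # postorder merge of sub-alignments
  po <- ape::reorder.phylo(ape::unroot(guide), "postorder")
  ntip <- length(po$tip.label)
  sub <- vector("list", ntip + po$Nnode)
  for (i in seq_len(ntip)) {
    sub[[i]] <- setNames(peptides[po$tip.label[i]], po$tip.label[i])
  }
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; child <- po$edge[e, 2]
    if (is.null(sub[[p]])) {
      sub[[p]] <- sub[[child]]
    } else {
      a <- sub[[p]]; b <- sub[[child]]
      al <- cpp_profile_align(.profile_of(a), .profile_of(b), submat,
                              gap_open, gap_extend)
      sub[[p]] <- c(setNames(.apply_path(a, al$path_a), names(a)),
                    setNames(.apply_path(b, al$path_b), names(b)))
    }
    sub[[child]] <- list()  # free
  }
  root <- po$edge[nrow(po$edge), 1]
  rows <- sub[[root]][taxa]
  structure(list(taxa = taxa, rows = rows), class = "protein_alignment")
}

#' Read an externally produced protein alignment (FASTA)
#'
#' @param path Aligned FASTA path (gap character `-`).
#' @return A `protein_alignment` object.
#' @export
read_protein_alignment <- function(path) {
  rows <- read_fasta(path)
  names(rows) <- .first_token(names(rows))
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows in ", path, " have unequal length")
  }
  structure(list(taxa = names(rows), rows = rows), class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("protein alignment: %d taxa x %d columns\n",
              length(x$taxa), nchar(x$rows[[1]])))
  invisible(x)
}

#' Back-translate a protein alignment to an in-frame codon alignment
#'
#' Each aligned residue is replaced by its source codon and each gap by
#' `---`, so gaps occur only as whole codons and degapping any row
#' reproduces the input CDS exactly.
#'
#' @param pa A `protein_alignment`.
#' @param cds Named character vector (species -> validated CDS, no terminal
#'   stop). `translate_cds(cds[s])` must equal the degapped row for every
#'   species.
#' @return An object of class `codon_alignment`: `taxa`, `rows` (gapped
#'   nucleotide strings), `n_codon_columns`, `site_map` (original 1-based
#'   codon coordinates of each column).
#' @export
back_translate <- function(pa, cds) {
  rows <- character(length(pa$taxa))
  for (i in seq_along(pa$taxa)) {
    s <- pa$taxa[i]
    if (is.null(cds[[s]])) stop("no CDS for species ", s)
    seq_cds <- toupper(cds[[s]])
    aa <- strsplit(pa$rows[[s]], "")[[1]]
    naa <- sum(aa != "-")
    if (nchar(seq_cds) != 3L * naa) {
      stop(sprintf("CDS length (%d) does not match %d aligned residues for %s",
                   nchar(seq_cds), naa, s))
    }
    tr <- translate_cds(seq_cds)
    deg <- paste(aa[aa != "-"], collapse = "")
    if (!.peptides_match(tr, deg)) {
      mism <- which(strsplit(tr, "")[[1]] != strsplit(deg, "")[[1]] &
                    strsplit(tr, "")[[1]] != "X" & strsplit(deg, "")[[1]] != "X")
      stop(sprintf("CDS/peptide translation mismatch for %s at residue %d",
                   s, if (length(mism)) mism[1] else naa))
    }
    starts <- seq(1L, nchar(seq_cds), 3L)
    codons <- substring(seq_cds, starts, starts + 2L)
    out <- rep("---", length(aa))
    out[aa != "-"] <- codons
    rows[i] <- paste(out, collapse = "")
  }
  ncol <- nchar(pa$rows[[1]])
  structure(list(taxa = pa$taxa, rows = setNames(rows, pa$taxa),
                 n_codon_columns = ncol, site_map = seq_len(ncol)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon alignment: %d taxa x %d codon columns\n",
              length(x$taxa), x$n_codon_columns))
  invisible(x)
}

#' Remove gapped/ambiguous codon columns before likelihood computation
#'
#' Under the default `complete_deletion` policy every codon column containing
#' a gap or an `N` in any taxon is removed (the cleandata analogue of the
#' likelihood stage). The returned `site_map` gives, for each surviving
#' column, its 1-based codon position in the original alignment, so reported
#' positively selected sites refer to original coordinates.
#'
#' @param ca A `codon_alignment`.
#' @param policy `"complete_deletion"` (default) or `"keep_all"`.
#' @param min_codons Minimum surviving codon columns; shorter alignments are
#'   flagged (attribute `too_short`), to be skipped by the caller.
#' @return A `codon_alignment` with updated `site_map` and logical attribute
#'   `too_short`.
#' @export
clean_columns <- function(ca, policy = c("complete_deletion", "keep_all"),
                          min_codons = 10L) {
  policy <- match.arg(policy)
  if (policy == "keep_all") {
    attr(ca, "too_short") <- ca$n_codon_columns < min_codons
    return(ca)
  }
  nc <- ca$n_codon_columns
  starts <- seq(1L, 3L * nc, 3L)
  codmat <- vapply(ca$rows, function(r) substring(r, starts, starts + 2L),
                   character(nc))
  if (nc == 1L) codmat <- matrix(codmat, nrow = 1L)
  bad <- apply(codmat, 1, function(col) any(!grepl("^[ACGT]{3}$", col)))
  keep <- which(!bad)
  rows <- apply(codmat[keep, , drop = FALSE], 2, paste, collapse = "")
  if (length(keep) == 0L) rows <- setNames(rep("", length(ca$taxa)), ca$taxa)
  out <- structure(list(taxa = ca$taxa, rows = setNames(rows, ca$taxa),
                        n_codon_columns = length(keep),
                        site_map = ca$site_map[keep]),
                   class = "codon_alignment")
  attr(out, "too_short") <- length(keep) < min_codons
  out
}

#' Write a codon alignment in sequential PHYLIP format
#'
#' CodeML-compatible layout: "ntaxa nchars" header, names padded to 30
#' characters, sequential sequences.
#'
#' @param ca A `codon_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(ca, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", length(ca$taxa), nchar(ca$rows[[1]])), con)
  for (s in ca$taxa) {
    nm <- substr(s, 1L, 30L)
    writeLines(sprintf("%-30s  %s", nm, ca$rows[[s]]), con)
  }
  invisible(path)
}

#' Write a protein or codon alignment as FASTA
#'
#' @param aln A `protein_alignment` or `codon_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  write_fasta(aln$rows, path)
}
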