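# Equilibrium codon frequency estimators (CodeML CodonFreq analogues).

#' Estimate equilibrium codon frequencies from codon sequences
#'
#' Computes the stationary frequencies pi of the 61 sense codons using one of
#' the standard estimators: `F3x4` (positional nucleotide frequencies,
#' the usual default), `F1x4` (pooled nucleotide frequencies), `F61`
#' (observed codon frequencies) or `equal` (uniform 1/61).
#'
#' Gapped codons (`---`) and codons containing ambiguity characters are
#' ignored when counting. Zero-frequency codons are floored at `1e-6` and the
#' vector renormalized so all entries are strictly positive, which the
#' reversible substitution model requires.
#'
#' @param sequences Character vector of in-frame nucleotide sequences (gaps
#'   allowed as `-`), e.g. the rows of a codon alignment.
#' @param method One of `"F3x4"`, `"F1x4"`, `"F61"`, `"equal"`.
#' @return An object of class `codon_frequencies`: list with `method` and
#'   `pi` (length-61 numeric, summing to 1, parallel to [sense_codons()]).
#' @export
codon_frequencies <- function(sequences, method = c("F3x4", "F1x4", "F61", "equal")) {
  method <- match.arg(method)
  codons <- sense_codons()
  n <- length(codons)
  if (method == "equal") {
    return(structure(list(method = method, pi = rep(1 / n, n)),
                     class = "codon_frequencies"))
  }
  seqs <- toupper(unlist(sequences, use.names = FALSE))
  if (any(nchar(seqs) %% 3 != 0)) {
    stop("codon_frequencies: sequence length not divisible by 3")
  }
  trip <- unlist(lapply(seqs, function(s) {
    substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  }), use.names = FALSE)
  trip <- trip[grepl("^[ACGT]{3}$", trip)]
  if (length(trip) == 0L) stop("codon_frequencies: no unambiguous codons found")

  if (method == "F61") {
    counts <- table(factor(trip, levels = codons))
    pi <- as.numeric(counts) / sum(counts)
  } else {
    cm <- do.call(rbind, strsplit(trip, ""))
    nt <- c("A", "C", "G", "T")
    if (method == "F3x4") {
      posfreq <- sapply(1:3, function(k) {
        tab <- table(factor(cm[, k], levels = nt))
        as.numeric(tab) / sum(tab)
      })  # 4 x 3
    } else {
      all_nt <- table(factor(as.vector(cm), levels = nt))
      posfreq <- matrix(rep(as.numeric(all_nt) / sum(all_nt), 3), ncol = 3)
    }
    rownames(posfreq) <- nt
    cmat <- do.call(rbind, strsplit(codons, ""))
    pi <- posfreq[cmat[, 1], 1] * posfreq[cmat[, 2], 2] * posfreq[cmat[, 3], 3]
    pi <- pi / sum(pi)
  }
  pi <- pmax(pi, 1e-6)
  pi <- pi / sum(pi)
  structure(list(method = method, pi = pi), class = "codon_frequencies")
}

#' @export
print.codon_frequencies <- function(x, ...) {
  cat(sprintf("codon frequencies (%s), 61 sense codons, sum = %.6f\n",
              x$method, sum(x$pi)))
  invisible(x)
}

.check_frequencies <- function(freqs) {
  if (!inherits(freqs, "codon_frequencies")) {
    stop("`freqs` must be a codon_frequencies object")
  }
  pi <- freqs$pi
  if (length(pi) != 61L || any(!is.finite(pi)) || any(pi <= 0) ||
      abs(sum(pi) - 1) > 1e-8) {
    stop("invalid codon frequencies: need 61 positive values summing to 1")
  }
  pi
}
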