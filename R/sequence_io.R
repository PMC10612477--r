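# FASTA input, CDS/peptide pairing and validation.

#' Read a FASTA file
#'
#' Reads plain or gzip-compressed FASTA. Sequence letters are folded to
#' upper case; headers are returned in full (pairing uses only the first
#' whitespace-delimited token, see [pair_and_validate()]).
#'
#' @param path Path to a FASTA file (optionally `.gz`).
#' @return Named character vector of sequences (names = headers), in file
#'   order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("no FASTA records in ", path)
  seqs <- toupper(as.character(set))
  headers <- names(set)
  if (anyDuplicated(headers)) {
    stop("duplicate FASTA header(s) in ", path, ": ",
         paste(unique(headers[duplicated(headers)]), collapse = ", "))
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence record(s) in ", path, ": ",
         paste(headers[nchar(seqs) == 0L], collapse = ", "))
  }
  setNames(seqs, headers)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector (names become headers).
#' @param path Output path.
#' @param width Line-wrapping width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  force(seqs)  # evaluate before truncating `path` (seqs may read from it)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Translate a coding sequence with the universal genetic code
#'
#' Codons containing `N` (or any non-ACGT character) translate to `X`;
#' stop codons translate to `*`.
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @return Amino-acid string of length `nchar(cds)/3`.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3 (", n, " nt)")
  if (n == 0L) return("")
  starts <- seq(1L, n, 3L)
  codons <- substring(cds, starts, starts + 2L)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Does `translated` match `peptide` under the X-wildcard rule?
.peptides_match <- function(translated, peptide) {
  if (nchar(translated) != nchar(peptide)) return(FALSE)
  a <- strsplit(translated, "")[[1]]
  b <- strsplit(peptide, "")[[1]]
  all(a == b | a == "X" | b == "X")
}

.first_token <- function(x) sub("\\s.*$", "", x)

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Pair and validate one species' CDS and peptide FASTA files
#'
#' Enforces the input contract: both files must contain the same number of
#' records with identical header sets (fatal otherwise). Each record is then
#' validated: terminal stop codons (TAA/TAG/TGA) on the CDS and a trailing
#' `*` on the peptide are stripped; the CDS must be in frame, free of
#' internal stop codons, and translate to the peptide (with `X` matching any
#' residue and N-containing codons translating to `X`). Records failing
#' per-record checks are moved to `rejected` with a machine-readable reason;
#' they do not abort the run.
#'
#' @param cds_path FASTA of coding sequences.
#' @param pep_path FASTA of the corresponding peptides.
#' @param species_id Species identifier; defaults to the shared file stem.
#' @return An object of class `proteome_pair`: list with `species_id`,
#'   `records` (data frame: header, cds, peptide) and `rejected`
#'   (data frame: header, reason).
#' @export
pair_and_validate <- function(cds_path, pep_path,
                              species_id = .file_stem(cds_path)) {
  cds <- read_fasta(cds_path)
  pep <- read_fasta(pep_path)
  names(cds) <- .first_token(names(cds))
  names(pep) <- .first_token(names(pep))
  if (anyDuplicated(names(cds)) || anyDuplicated(names(pep))) {
    stop("duplicate headers after truncation to first token (", species_id, ")")
  }
  if (length(cds) != length(pep)) {
    stop(sprintf("record counts differ for species '%s': %d CDS vs %d peptides",
                 species_id, length(cds), length(pep)))
  }
  if (!setequal(names(cds), names(pep))) {
    bad <- union(setdiff(names(cds), names(pep)), setdiff(names(pep), names(cds)))
    stop(sprintf("header sets differ between CDS and peptide files for '%s': %s",
                 species_id, paste(utils::head(bad, 5), collapse = ", ")))
  }
  pep <- pep[names(cds)]

  headers <- names(cds)
  keep <- character(0)
  rec_cds <- rec_pep <- character(0)
  rej <- list()
  for (i in seq_along(headers)) {
    h <- headers[i]
    s <- cds[[i]]
    p <- sub("\\*$", "", pep[[i]])
    if (nchar(s) %% 3L != 0L) {
      rej[[length(rej) + 1L]] <- c(h, "frame_error")
      next
    }
    last <- substring(s, nchar(s) - 2L, nchar(s))
    if (nchar(s) >= 3L && last %in% STOP_CODONS) {
      s <- substring(s, 1L, nchar(s) - 3L)
    }
    if (nchar(s) == 0L || !grepl("^[ACGTN]+$", s)) {
      rej[[length(rej) + 1L]] <- c(h, "invalid_characters")
      next
    }
    tr <- translate_cds(s)
    if (grepl("\\*", tr)) {
      rej[[length(rej) + 1L]] <- c(h, "internal_stop")
      next
    }
    if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]*$", p) || nchar(p) == 0L) {
      rej[[length(rej) + 1L]] <- c(h, "invalid_peptide")
      next
    }
    if (nchar(s) != 3L * nchar(p)) {
      rej[[length(rej) + 1L]] <- c(h, "length_mismatch")
      next
    }
    if (!.peptides_match(tr, p)) {
      rej[[length(rej) + 1L]] <- c(h, "translation_mismatch")
      next
    }
    keep <- c(keep, h)
    rec_cds <- c(rec_cds, s)
    rec_pep <- c(rec_pep, p)
  }
  rejected <- if (length(rej)) {
    data.frame(header = vapply(rej, `[`, "", 1L),
               reason = vapply(rej, `[`, "", 2L))
  } else {
    data.frame(header = character(0), reason = character(0))
  }
  structure(list(species_id = species_id,
                 records = data.frame(header = keep, cds = rec_cds,
                                      peptide = rec_pep),
                 rejected = rejected),
            class = "proteome_pair")
}

#' @export
print.proteome_pair <- function(x, ...) {
  cat(sprintf("proteome pair '%s': %d validated record(s), %d rejected\n",
              x$species_id, nrow(x$records), nrow(x$rejected)))
  invisible(x)
}

.file_stem <- function(path) {
  stem <- sub("\\.gz$", "", basename(path))
  tools::file_path_sans_ext(stem)
}

#' Discover and validate per-species input pairs
#'
#' Either pass two directories holding one CDS and one peptide FASTA per
#' species (matched by file name stem), or a manifest TSV with columns
#' `species_id`, `cds_path`, `pep_path`.
#'
#' @param cds_dir,pep_dir Directories of per-species FASTA files.
#' @param manifest Path to a manifest TSV (overrides the directories).
#' @return List of `proteome_pair` objects, named by species.
#' @export
load_proteomes <- function(cds_dir = NULL, pep_dir = NULL, manifest = NULL) {
  if (!is.null(manifest)) {
    m <- utils::read.table(manifest, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    need <- c("species_id", "cds_path", "pep_path")
    if (!all(need %in% names(m))) {
      stop("manifest must have columns: ", paste(need, collapse = ", "))
    }
    pairs <- Map(pair_and_validate, m$cds_path, m$pep_path, m$species_id)
    names(pairs) <- m$species_id
    return(pairs)
  }
  if (is.null(cds_dir) || is.null(pep_dir)) {
    stop("provide either cds_dir and pep_dir, or a manifest")
  }
  cds_files <- list.files(cds_dir, pattern = "\\.(fa|fasta|fna|fas)(\\.gz)?$",
                          full.names = TRUE)
  pep_files <- list.files(pep_dir, pattern = "\\.(fa|fasta|faa|fas)(\\.gz)?$",
                          full.names = TRUE)
  cds_stems <- vapply(cds_files, .file_stem, "")
  pep_stems <- vapply(pep_files, .file_stem, "")
  shared <- intersect(cds_stems, pep_stems)
  if (length(shared) == 0L) stop("no species with matching CDS/peptide file stems")
  pairs <- lapply(shared, function(s) {
    pair_and_validate(cds_files[match(s, cds_stems)],
                      pep_files[match(s, pep_stems)], s)
  })
  names(pairs) <- shared
  pairs
}

#' Write the per-record validation report
#'
#' @param proteomes List of `proteome_pair` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(proteomes, path) {
  rows <- do.call(rbind, lapply(proteomes, function(p) {
    rbind(
      if (nrow(p$records)) data.frame(species_id = p$species_id,
                                      header = p$records$header,
                                      status = "ok", reason = ""),
      if (nrow(p$rejected)) data.frame(species_id = p$species_id,
                                       header = p$rejected$header,
                                       status = "rejected",
                                       reason = p$rejected$reason)
    )
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
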