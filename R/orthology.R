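# Orthology prediction: all-vs-all protein similarity, reciprocal best hits,
# and one-to-one orthologous gene cluster (OGC) construction.
#
# OGC eligibility: a cluster is kept only if it (a) spans at least
# `min_species` species (default 3) and (b) contains exactly one gene per
# species; clusters with within-species paralogs are discarded entirely.

#' All-vs-all cross-species protein similarity
#'
#' Smith-Waterman local alignment (BLOSUM62, affine gaps) between every
#' cross-species protein pair. A hit is emitted when the alignment score and
#' percent identity pass the thresholds; scores are symmetric.
#'
#' @param proteomes List of `proteome_pair` objects (>= 2 species).
#' @param gap_open,gap_extend Affine gap penalties (defaults 11 / 1).
#' @param min_score Minimum local alignment score (default 50).
#' @param min_identity Minimum identity fraction over the local alignment
#'   (default 0.25).
#' @return Data frame of hits: `query_species`, `query`, `subject_species`,
#'   `subject`, `score`, `identity_fraction`. Both orientations of each
#'   passing pair are present.
#' @export
all_pairs_similarity <- function(proteomes, gap_open = 11, gap_extend = 1,
                                 min_score = 50, min_identity = 0.25) {
  if (length(proteomes) < 2L) stop("need at least 2 species for orthology")
  species <- names(proteomes)
  seqs <- lapply(proteomes, function(p) setNames(p$records$peptide,
                                                 p$records$header))
  hits <- list()
  for (i in seq_along(species)) {
    for (j in seq_along(species)) {
      if (i >= j) next
      a <- seqs[[i]]
      b <- seqs[[j]]
      if (length(a) == 0L || length(b) == 0L) next
      for (qi in seq_along(a)) {
        al_all <- Biostrings::pairwiseAlignment(
          pattern = Biostrings::AAStringSet(b),
          subject = Biostrings::AAString(a[[qi]]),
          type = "local", substitutionMatrix = "BLOSUM62",
          gapOpening = gap_open, gapExtension = gap_extend)
        scores <- Biostrings::score(al_all)
        idfs <- Biostrings::pid(al_all, type = "PID1") / 100
        for (sj in seq_along(b)) {
          sc <- scores[sj]
          idf <- idfs[sj]
          if (sc >= min_score && idf >= min_identity) {
            hits[[length(hits) + 1L]] <- data.frame(
              query_species = species[i], query = names(a)[qi],
              subject_species = species[j], subject = names(b)[sj],
              score = sc, identity_fraction = idf)
          }
        }
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(query_species = character(0), query = character(0),
                      subject_species = character(0), subject = character(0),
                      score = numeric(0), identity_fraction = numeric(0)))
  }
  h <- do.call(rbind, hits)
  # add the reverse orientation (local SW scores are symmetric)
  rev <- data.frame(query_species = h$subject_species, query = h$subject,
                    subject_species = h$query_species, subject = h$query,
                    score = h$score, identity_fraction = h$identity_fraction)
  out <- rbind(h, rev)
  rownames(out) <- NULL
  out
}

#' Read a precomputed tabular hit file
#'
#' Adapter for BLAST outfmt-6-like tables so the native similarity search can
#' be bypassed on large inputs. Expects columns query_species, query,
#' subject_species, subject, identity percent, score (TSV, no header).
#'
#' @param path TSV path.
#' @return Hit data frame as produced by [all_pairs_similarity()].
#' @export
read_hits_table <- function(path) {
  h <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(h) < 6L) stop("hits table needs 6 columns")
  names(h)[1:6] <- c("query_species", "query", "subject_species", "subject",
                     "identity_percent", "score")
  data.frame(query_species = h$query_species, query = h$query,
             subject_species = h$subject_species, subject = h$subject,
             score = as.numeric(h$score),
             identity_fraction = as.numeric(h$identity_percent) / 100)
}

#' Reciprocal-best-hit graph with adaptive best hits
#'
#' For each gene and each other species, the best-hit set contains every hit
#' whose score is within `best_factor` of the maximal score against that
#' species (adaptive best hits in the ProteinOrtho sense; `best_factor = 1`
#' keeps exact-maximum hits only). An undirected edge joins two genes iff
#' each lies in the other's best-hit set. The adaptive set is what lets a
#' recent within-species duplicate enter a cluster alongside its source gene
#' so the downstream paralog filter can reject the cluster.
#'
#' @param hits Hit data frame from [all_pairs_similarity()].
#' @param best_factor Score fraction of the per-species maximum that still
#'   counts as a best hit (default 0.95).
#' @return Data frame of edges: `species_a`, `gene_a`, `species_b`, `gene_b`,
#'   deterministically ordered.
#' @export
reciprocal_best_hits <- function(hits, best_factor = 0.95) {
  empty <- data.frame(species_a = character(0), gene_a = character(0),
                      species_b = character(0), gene_b = character(0))
  if (nrow(hits) == 0L) return(empty)
  stopifnot(best_factor > 0, best_factor <= 1)
  grp <- paste(hits$query_species, hits$query, hits$subject_species,
               sep = "\r")
  maxs <- stats::ave(hits$score, grp, FUN = max)
  best <- hits[hits$score >= best_factor * maxs, , drop = FALSE]
  fwd <- paste(best$query_species, best$query,
               best$subject_species, best$subject, sep = "\r")
  rev <- paste(best$subject_species, best$subject,
               best$query_species, best$query, sep = "\r")
  mutual <- best[fwd %in% rev, , drop = FALSE]
  if (nrow(mutual) == 0L) return(empty)
  # orient each unordered pair once, deterministically
  a_first <- paste(mutual$query_species, mutual$query) <=
    paste(mutual$subject_species, mutual$subject)
  out <- data.frame(
    species_a = ifelse(a_first, mutual$query_species, mutual$subject_species),
    gene_a = ifelse(a_first, mutual$query, mutual$subject),
    species_b = ifelse(a_first, mutual$subject_species, mutual$query_species),
    gene_b = ifelse(a_first, mutual$subject, mutual$query))
  out <- unique(out)
  out <- out[order(out$species_a, out$gene_a, out$species_b, out$gene_b), ]
  rownames(out) <- NULL
  out
}

#' Cluster the RBH graph into one-to-one orthologous gene clusters
#'
#' Connected components of the reciprocal-best-hit graph are candidate
#' clusters. A component becomes an OGC only if it spans at least
#' `min_species` species and contains exactly one gene per species;
#' components containing within-species paralogs are discarded entirely,
#' not trimmed. OGC identifiers are assigned in deterministic order (sorted
#' by lexicographic member list).
#'
#' @param edges RBH edge data frame from [reciprocal_best_hits()].
#' @param min_species Minimum number of species per OGC (default 3; values
#'   below 3 require `allow_small = TRUE`).
#' @param allow_small Expert override admitting `min_species < 3`.
#' @return List of `ogc` objects: `ogc_id`, `members` (named character
#'   vector, species -> gene header), `n_species`.
#' @export
cluster_and_filter <- function(edges, min_species = 3L, allow_small = FALSE) {
  if (min_species < 3L && !allow_small) {
    stop("min_species below 3 requires allow_small = TRUE")
  }
  if (nrow(edges) == 0L) return(list())
  va <- paste(edges$species_a, edges$gene_a, sep = "\r")
  vb <- paste(edges$species_b, edges$gene_b, sep = "\r")
  g <- igraph::graph_from_edgelist(cbind(va, vb), directed = FALSE)
  comp <- igraph::components(g)
  vnames <- igraph::V(g)$name
  clusters <- split(vnames, comp$membership)
  ogcs <- list()
  for (cl in clusters) {
    parts <- strsplit(cl, "\r", fixed = TRUE)
    sp <- vapply(parts, `[`, "", 1L)
    gene <- vapply(parts, `[`, "", 2L)
    if (anyDuplicated(sp)) next            # paralogs: discard whole cluster
    if (length(sp) < min_species) next     # too few species
    o <- order(sp)
    ogcs[[length(ogcs) + 1L]] <- setNames(gene[o], sp[o])
  }
  if (length(ogcs) == 0L) return(list())
  ord <- order(vapply(ogcs, function(m) {
    paste(names(m), m, sep = "=", collapse = ";")
  }, ""))
  ogcs <- ogcs[ord]
  lapply(seq_along(ogcs), function(i) {
    structure(list(ogc_id = sprintf("OGC%05d", i), members = ogcs[[i]],
                   n_species = length(ogcs[[i]])),
              class = "ogc")
  })
}

#' @export
print.ogc <- function(x, ...) {
  cat(sprintf("%s: %d species (%s)\n", x$ogc_id, x$n_species,
              paste(names(x$members), collapse = ", ")))
  invisible(x)
}

#' Predict orthologous gene clusters from validated proteomes
#'
#' Convenience wrapper: similarity search, reciprocal best hits, clustering
#' and eligibility filtering in one call.
#'
#' @inheritParams all_pairs_similarity
#' @inheritParams cluster_and_filter
#' @param hits Optional precomputed hit table (bypasses the native search).
#' @return List of `ogc` objects.
#' @export
predict_ogcs <- function(proteomes, min_species = 3L, hits = NULL, ...) {
  if (is.null(hits)) hits <- all_pairs_similarity(proteomes, ...)
  cluster_and_filter(reciprocal_best_hits(hits), min_species = min_species)
}

#' Write the orthology table
#'
#' One row per OGC: `ogc_id`, `n_species`, comma-separated species list, and
#' one column per species holding the member gene header or `*`.
#'
#' @param ogcs List of `ogc` objects.
#' @param path Output TSV path.
#' @param all_species Optional character vector fixing the species columns.
#' @return `path`, invisibly.
#' @export
write_orthology_table <- function(ogcs, path, all_species = NULL) {
  if (is.null(all_species)) {
    all_species <- sort(unique(unlist(lapply(ogcs, function(o) names(o$members)))))
  }
  rows <- lapply(ogcs, function(o) {
    mem <- setNames(rep("*", length(all_species)), all_species)
    mem[names(o$members)] <- o$members
    c(ogc_id = o$ogc_id, n_species = o$n_species,
      species = paste(names(o$members), collapse = ","), mem)
  })
  df <- if (length(rows)) {
    as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  } else {
    as.data.frame(matrix(character(0), 0, 3 + length(all_species),
                         dimnames = list(NULL, c("ogc_id", "n_species",
                                                 "species", all_species))))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
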