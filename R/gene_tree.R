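# Per-OGC gene trees: protein distances, neighbor joining, Newick ("dnd")
# and Nexus interconversion, foreground-branch labeling, and species-tree
# replacement for subgroup analyses.

#' Construct a gene tree object
#'
#' @param tree An `ape` phylo object (branch lengths required).
#' @param foreground Optional leaf label marking the foreground terminal
#'   branch.
#' @return An object of class `gene_tree`.
#' @export
gene_tree <- function(tree, foreground = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("gene tree requires branch lengths")
  if (any(tree$edge.length < 0)) tree$edge.length <- pmax(tree$edge.length, 0)
  if (!is.null(foreground)) {
    if (length(foreground) != 1L || !foreground %in% tree$tip.label) {
      stop("foreground must be a single leaf label of the tree")
    }
  }
  structure(list(tree = tree, foreground = foreground), class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("gene tree: %d leaves%s\n", length(x$tree$tip.label),
              if (!is.null(x$foreground))
                paste0(", foreground = ", x$foreground) else ""))
  invisible(x)
}

#' Protein distance matrix from a multiple alignment
#'
#' For each pair of rows, the p-distance over shared ungapped columns with
#' the Kimura protein correction `d = -ln(1 - p - 0.2 p^2)`. Saturated pairs
#' (p >= 0.85, where the correction diverges) are capped at `max_distance`.
#'
#' @param pa A `protein_alignment` (>= 3 taxa).
#' @param max_distance Cap for saturated pairs (default 5).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(pa, max_distance = 5) {
  n <- length(pa$taxa)
  if (n < 3L) stop("need at least 3 taxa")
  chars <- lapply(pa$rows, function(r) strsplit(r, "")[[1]])
  D <- matrix(0, n, n, dimnames = list(pa$taxa, pa$taxa))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      a <- chars[[i]]; b <- chars[[j]]
      shared <- a != "-" & b != "-"
      if (!any(shared)) {
        stop(sprintf("no shared ungapped columns between %s and %s",
                     pa$taxa[i], pa$taxa[j]))
      }
      p <- mean(a[shared] != b[shared])
      arg <- 1 - p - 0.2 * p^2
      d <- if (p >= 0.85 || arg <= 0) max_distance else min(-log(arg), max_distance)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining gene tree
#'
#' Saitou-Nei neighbor joining on a symmetric distance matrix (via
#' `ape::nj`); negative branch-length estimates are clamped at 0.
#'
#' @param distances Symmetric distance matrix with taxon dimnames.
#' @param foreground Optional foreground leaf label.
#' @return A `gene_tree`.
#' @export
nj_tree <- function(distances, foreground = NULL) {
  if (!is.matrix(distances) || !isTRUE(all.equal(distances, t(distances))) ||
      any(!is.finite(distances))) {
    stop("distances must be a finite symmetric matrix")
  }
  tr <- ape::nj(distances)
  tr$edge.length <- pmax(tr$edge.length, 0)
  gene_tree(tr, foreground = foreground)
}

.fmt_len <- function(x) sprintf("%.6g", x)

#' Emit a tree as Newick ("dnd"), optionally with the foreground mark
#'
#' Branch lengths are written with 6 significant digits. With
#' `labeled = TRUE` and a foreground set, the foreground terminal branch
#' carries the `" #1"` mark (the CodeML foreground convention); exactly one
#' such token appears.
#'
#' @param tree A `gene_tree` or phylo object.
#' @param labeled Add the foreground `#1` mark (default FALSE).
#' @return Newick string ending in `;`.
#' @export
to_newick <- function(tree, labeled = FALSE) {
  fg <- NULL
  if (inherits(tree, "gene_tree")) {
    fg <- tree$foreground
    phylo <- tree$tree
  } else {
    phylo <- tree
  }
  ntip <- length(phylo$tip.label)
  kids <- split(seq_len(nrow(phylo$edge)), phylo$edge[, 1])
  root <- setdiff(unique(phylo$edge[, 1]), phylo$edge[, 2])[1]
  rec <- function(node, elen) {
    is_fg_tip <- FALSE
    lab <- if (node <= ntip) {
      l <- phylo$tip.label[node]
      is_fg_tip <- labeled && !is.null(fg) && l == fg
      l
    } else {
      es <- kids[[as.character(node)]]
      paste0("(", paste(vapply(es, function(e) {
        rec(phylo$edge[e, 2], phylo$edge.length[e])
      }, ""), collapse = ","), ")")
    }
    out <- if (is.na(elen)) lab else paste0(lab, ":", .fmt_len(elen))
    if (is_fg_tip) paste0(out, " #1") else out  # CodeML foreground mark
  }
  paste0(rec(root, NA), ";")
}

#' Write a gene tree in Nexus format
#'
#' TREES block with a translate table (`ape::write.nexus`).
#'
#' @param tree A `gene_tree` or phylo object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genetree_nexus <- function(tree, path) {
  phylo <- if (inherits(tree, "gene_tree")) tree$tree else tree
  ape::write.nexus(phylo, file = path, translate = TRUE)
  invisible(path)
}

#' Parse a Nexus TREES block into a gene tree
#'
#' Accepts files with or without a translate table.
#'
#' @param path Nexus file path.
#' @return A `gene_tree` (first tree in the file).
#' @export
parse_nexus <- function(path) {
  tr <- ape::read.nexus(path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  gene_tree(tr)
}

#' Convert a Nexus tree file to a Newick ("dnd") string
#'
#' @param path Nexus file path.
#' @return Newick string.
#' @export
nexus_to_dnd <- function(path) {
  to_newick(parse_nexus(path))
}

#' Replace a per-OGC gene tree with a pruned species tree
#'
#' Implements the subgroup-validation workflow: the species tree is pruned
#' to the OGC's taxa and installed in place of the gene tree, rewriting both
#' the `.dnd` (Newick) and `.dnd.GenTree.nex` (Nexus) files in the OGC
#' bundle directory; downstream fits can then be re-run against it.
#'
#' @param bundle_dir Extracted per-OGC bundle directory containing
#'   `<ogc_id>.dnd` and `<ogc_id>.dnd.GenTree.nex`.
#' @param species_tree Newick string, file path, or phylo object whose leaf
#'   set covers the OGC's taxa.
#' @return The pruned `gene_tree`, invisibly.
#' @export
replace_tree <- function(bundle_dir, species_tree) {
  dnd <- list.files(bundle_dir, pattern = "\\.dnd$", full.names = TRUE)
  if (length(dnd) != 1L) stop("expected exactly one .dnd file in ", bundle_dir)
  current <- ape::read.tree(dnd)
  sp <- if (inherits(species_tree, "phylo")) {
    species_tree
  } else if (file.exists(species_tree)) {
    ape::read.tree(species_tree)
  } else {
    ape::read.tree(text = species_tree)
  }
  missing <- setdiff(current$tip.label, sp$tip.label)
  if (length(missing)) {
    stop("species tree is missing OGC taxa: ", paste(missing, collapse = ", "))
  }
  pruned <- ape::keep.tip(sp, current$tip.label)
  if (is.null(pruned$edge.length)) {
    pruned$edge.length <- rep(0.1, nrow(pruned$edge))
  }
  gt <- gene_tree(pruned)
  writeLines(to_newick(gt), dnd)
  nex <- paste0(dnd, ".GenTree.nex")
  write_genetree_nexus(gt, nex)
  cat(sprintf("tree replaced from species phylogeny on %s\n",
              format(Sys.time(), "%Y-%m-%d")),
      file = file.path(bundle_dir, "provenance.txt"), append = TRUE)
  invisible(gt)
}
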