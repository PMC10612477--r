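# helper: proteome_pair-like object from peptide vectors (CDS unused here)
fake_proteome <- function(species_id, peptides) {
  structure(list(species_id = species_id,
                 records = data.frame(header = names(peptides),
                                      cds = strrep("ATG", nchar(peptides)),
                                      peptide = unname(peptides)),
                 rejected = data.frame(header = character(0),
                                       reason = character(0))),
            class = "proteome_pair")
}

test_that("identical cross-species sequences score the BLOSUM62 self-score", {
  set.seed(11)
  pep <- random_peptide(50)
  pr <- list(A = fake_proteome("A", c(x = pep)),
             B = fake_proteome("B", c(y = pep)))
  hits <- all_pairs_similarity(pr)
  expect_equal(nrow(hits), 2L)  # both orientations
  data("BLOSUM62", package = "Biostrings", envir = environment())
  b62 <- get("BLOSUM62", envir = environment())
  self_score <- sum(diag(b62[strsplit(pep, "")[[1]], strsplit(pep, "")[[1]]]))
  expect_equal(hits$score[1], self_score)
  expect_equal(hits$identity_fraction[1], 1)
})

test_that("similarity scores match a hand-rolled Smith-Waterman oracle and are symmetric", {
  set.seed(12)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  b62 <- get("BLOSUM62", envir = environment())
  for (rep in 1:3) {
    p1 <- random_peptide(40)
    p2 <- paste0(substr(p1, 5, 30), random_peptide(10))
    pr <- list(A = fake_proteome("A", c(x = p1)),
               B = fake_proteome("B", c(y = p2)))
    hits <- all_pairs_similarity(pr, min_score = 1, min_identity = 0)
    oracle <- sw_score_oracle(p1, p2, b62)
    expect_equal(hits$score[hits$query == "x"], oracle)
    expect_equal(hits$score[hits$query == "x"], hits$score[hits$query == "y"])
  }
})

test_that("sub-threshold pairs yield no hit and <2 species errors", {
  set.seed(13)
  pr <- list(A = fake_proteome("A", c(x = random_peptide(30))),
             B = fake_proteome("B", c(y = random_peptide(30))))
  hits <- all_pairs_similarity(pr, min_score = 1e6)
  expect_equal(nrow(hits), 0L)
  expect_error(all_pairs_similarity(pr["A"]), "at least 2")
})

test_that("reciprocal best hits require mutual best-ness", {
  hits <- data.frame(
    query_species = c("A", "B", "A", "B"),
    query = c("g", "h", "g2", "h"),
    subject_species = c("B", "A", "B", "A"),
    subject = c("h", "g2", "h", "g2"),
    score = c(100, 120, 90, 120),
    identity_fraction = c(0.9, 0.95, 0.8, 0.95))
  # g's best in B is h, but h's best in A is g2 (score 120): no edge (g,h)
  edges <- reciprocal_best_hits(hits)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$gene_a, "g2")
  expect_equal(edges$gene_b, "h")
})

test_that("RBH graph on random toys equals a brute-force oracle", {
  set.seed(14)
  for (rep in 1:5) {
    n_sp <- sample(3:5, 1)
    species <- LETTERS[seq_len(n_sp)]
    genes <- lapply(species, function(s) paste0(s, "_g", 1:sample(2:4, 1)))
    names(genes) <- species
    rows <- list()
    for (i in seq_len(n_sp - 1)) for (j in (i + 1):n_sp) {
      for (q in genes[[i]]) for (s in genes[[j]]) {
        sc <- sample(50:150, 1)
        rows[[length(rows) + 1L]] <- data.frame(
          query_species = species[i], query = q,
          subject_species = species[j], subject = s,
          score = sc, identity_fraction = runif(1, 0.3, 1))
      }
    }
    h <- do.call(rbind, rows)
    h <- rbind(h, data.frame(query_species = h$subject_species,
                             query = h$subject,
                             subject_species = h$query_species,
                             subject = h$query, score = h$score,
                             identity_fraction = h$identity_fraction))
    edges <- reciprocal_best_hits(h)
    # oracle: direct enumeration of adaptive best-hit sets per
    # (gene, target species): every hit within 95% of the maximum
    bestset <- function(qs, q, ss) {
      cand <- h[h$query_species == qs & h$query == q & h$subject_species == ss, ]
      if (nrow(cand) == 0) return(character(0))
      cand$subject[cand$score >= 0.95 * max(cand$score)]
    }
    expected <- list()
    for (i in seq_len(n_sp - 1)) for (j in (i + 1):n_sp) {
      for (q in genes[[i]]) {
        for (s in bestset(species[i], q, species[j])) {
          if (q %in% bestset(species[j], s, species[i])) {
            expected[[length(expected) + 1L]] <- paste(species[i], q,
                                                       species[j], s)
          }
        }
      }
    }
    got <- paste(edges$species_a, edges$gene_a, edges$species_b, edges$gene_b)
    expect_setequal(got, unlist(expected))
  }
})

test_that("clustering enforces the two OGC eligibility rules", {
  # triangle of 3 species, one gene each -> one OGC
  tri <- data.frame(species_a = c("A", "A", "B"), gene_a = c("a1", "a1", "b1"),
                    species_b = c("B", "C", "C"), gene_b = c("b1", "c1", "c1"))
  ogcs <- cluster_and_filter(tri)
  expect_length(ogcs, 1L)
  expect_equal(ogcs[[1]]$n_species, 3L)
  expect_equal(ogcs[[1]]$ogc_id, "OGC00001")
  # component with a within-species paralog -> discarded entirely
  par <- rbind(tri, data.frame(species_a = "A", gene_a = "a2",
                               species_b = "B", gene_b = "b1"))
  expect_length(cluster_and_filter(par), 0L)
  # 2-species component -> discarded
  two <- data.frame(species_a = "A", gene_a = "a1",
                    species_b = "B", gene_b = "b1")
  expect_length(cluster_and_filter(two), 0L)
  expect_error(cluster_and_filter(tri, min_species = 2), "allow_small")
})

test_that("clustering matches a union-find oracle on a larger random graph", {
  set.seed(15)
  n_sp <- 5
  species <- LETTERS[1:n_sp]
  nodes <- unlist(lapply(species, function(s) paste0(s, ".", 1:40)))
  edges <- data.frame(a = sample(nodes, 200, replace = TRUE),
                      b = sample(nodes, 200, replace = TRUE))
  edges <- edges[edges$a != edges$b, ]
  sp_of <- function(x) sub("\\..*", "", x)
  e <- data.frame(species_a = sp_of(edges$a), gene_a = edges$a,
                  species_b = sp_of(edges$b), gene_b = edges$b)
  e <- e[e$species_a != e$species_b, ]
  ogcs <- cluster_and_filter(e)
  # union-find oracle
  parent <- setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(e))) {
    ra <- find(e$gene_a[i]); rb <- find(e$gene_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(unique(c(e$gene_a, e$gene_b)), find, "")
  comps <- split(names(roots), unname(roots))
  keep <- Filter(function(m) {
    sp <- sp_of(m)
    length(unique(sp)) >= 3 && !anyDuplicated(sp)
  }, comps)
  expected_members <- sort(vapply(keep, function(m) paste(sort(m), collapse = ","), ""))
  got_members <- sort(vapply(ogcs, function(o) paste(sort(unname(o$members)), collapse = ","), ""))
  expect_equal(unname(got_members), unname(expected_members))
})

test_that("OGC output is invariant to input row order", {
  set.seed(16)
  tri <- data.frame(species_a = c("A", "A", "B"), gene_a = c("a1", "a1", "b1"),
                    species_b = c("B", "C", "C"), gene_b = c("b1", "c1", "c1"))
  quad <- data.frame(species_a = c("A", "B", "C"),
                     gene_a = c("a9", "b9", "c9"),
                     species_b = c("B", "C", "D"),
                     gene_b = c("b9", "c9", "d9"))
  all_edges <- rbind(tri, quad)
  o1 <- cluster_and_filter(all_edges)
  o2 <- cluster_and_filter(all_edges[sample(nrow(all_edges)), ])
  expect_equal(lapply(o1, `[[`, "members"), lapply(o2, `[[`, "members"))
})

test_that("orthology table uses the ProteinOrtho-like layout", {
  tri <- data.frame(species_a = c("A", "A", "B"), gene_a = c("a1", "a1", "b1"),
                    species_b = c("B", "C", "C"), gene_b = c("b1", "c1", "c1"))
  ogcs <- cluster_and_filter(tri)
  d <- withr::local_tempdir()
  p <- file.path(d, "orth.tsv")
  write_orthology_table(ogcs, p, all_species = c("A", "B", "C", "D"))
  tab <- read.table(p, sep = "\t", header = TRUE)
  expect_equal(tab$ogc_id, "OGC00001")
  expect_equal(tab$D, "*")
  expect_equal(tab$A, "a1")
})
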