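# Shared fixtures and independent oracles used across test files.

EQ_FREQS <- codon_frequencies(method = "equal", sequences = NULL)

TREE3 <- ape::read.tree(text = "(spA:0.2,spB:0.2,spC:0.2);")
TREE5 <- ape::read.tree(text = "((a:0.3,b:0.4):0.2,(c:0.35,d:0.25):0.15,e:0.5);")

# write a FASTA fixture into a temp file, returning the path
tmp_fasta <- function(seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile("fx_", tmpdir = dir, fileext = ".fasta")
  write_fasta(seqs, path)
  path
}

# a small valid CDS/peptide pair for one species
fixture_species <- function(headers, cds) {
  pep <- vapply(cds, function(s) {
    s2 <- sub("(TAA|TAG|TGA)$", "", s)
    translate_cds(s2)
  }, "")
  list(cds = setNames(cds, headers), pep = setNames(pep, headers))
}

# Exhaustive-marginalization likelihood oracle for small trees: sums over
# all internal-node state assignments. Implements the engine's stated model
# (GY94 classes, per-branch scale = mixture-average rate) independently of
# the pruning code path.
brute_force_lnl <- function(tree, aln, spec) {
  cl <- orthoselect:::.resolve_classes(spec)
  pi <- spec$frequencies$pi
  et <- orthoselect:::.engine_tree(tree)
  po <- et$phylo
  ntip <- et$ntip
  states <- orthoselect:::.alignment_states(aln, taxa_order = po$tip.label)
  K <- length(cl$props)
  rates <- vapply(cl$bg, function(w) {
    orthoselect:::.gy94_rate(spec$kappa, w, spec$frequencies)
  }, 0)
  s_mix <- sum(cl$props * rates)
  Plist <- lapply(seq_len(K), function(k) {
    Q <- rate_matrix(spec$kappa, cl$bg[k], spec$frequencies)
    lapply(seq_len(nrow(po$edge)), function(e) {
      transition_probabilities(Q, po$edge.length[e] * rates[k] / s_mix)
    })
  })
  internals <- (ntip + 1):(ntip + po$Nnode)
  root <- po$edge[nrow(po$edge), 1]
  grid <- as.matrix(expand.grid(rep(list(1:61), length(internals))))
  total <- 0
  for (s in seq_len(ncol(states))) {
    sitelik <- 0
    for (k in seq_len(K)) {
      tot <- 0
      for (g in seq_len(nrow(grid))) {
        asg <- integer(ntip + po$Nnode)
        asg[1:ntip] <- states[, s] + 1L
        asg[internals] <- grid[g, ]
        pr <- pi[asg[root]]
        for (e in seq_len(nrow(po$edge))) {
          pr <- pr * Plist[[k]][[e]][asg[po$edge[e, 1]], asg[po$edge[e, 2]]]
        }
        tot <- tot + pr
      }
      sitelik <- sitelik + cl$props[k] * tot
    }
    total <- total + log(sitelik)
  }
  total
}

# Plain Smith-Waterman DP oracle (affine gaps, gap of length g costs
# open + g * extend), independent of Biostrings.
sw_score_oracle <- function(a, b, submat, gap_open = 11, gap_extend = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  na <- length(a); nb <- length(b)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, na + 1, nb + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(na + 1)) {
    for (j in 2:(nb + 1)) {
      sc <- submat[a[i - 1], b[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend, X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend, Y[i, j - 1] - gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# random peptide of length n (seeded by caller)
random_peptide <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"), n,
               replace = TRUE), collapse = "")
}

# random gap-free codon alignment (list form) for n taxa x n_codons
random_codon_alignment <- function(taxa, n_codons, tree = NULL, omega = 0.3) {
  if (is.null(tree)) {
    tree <- ape::read.tree(text = paste0(
      "(", paste(sprintf("%s:0.2", taxa), collapse = ","), ");"))
  }
  sc <- sim_scenario(tree = tree, n_codons = n_codons,
                     model = codon_model_spec("M0", EQ_FREQS, kappa = 2,
                                              params = list(omega = omega)))
  evolve_alignment(sc, seed = sample.int(1e6, 1))$alignment
}

# direct BH step-up oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}
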