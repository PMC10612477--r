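# Codon sequence simulator: evolves gap-free codon alignments along a tree
# under the engine's models and emits multi-species CDS/peptide FASTA inputs
# (with optional paralogs and gene losses) with known ground truth.

#' Define a simulation scenario
#'
#' Defaults describe the bundled toy data set: three moderately diverged
#' species, five gene families of 150 codons evolving under purifying
#' selection (M0, omega = 0.2, kappa = 2), uniform codon frequencies, no
#' paralogs and no losses.
#'
#' @param tree Newick string or phylo object with branch lengths.
#' @param model A [codon_model_spec()] giving the true parameters (its
#'   frequencies are the root/stationary distribution).
#' @param n_codons Codon sites per family (default 150).
#' @param n_families Number of gene families (default 5).
#' @param paralog_rate Probability that a family carries a within-species
#'   duplicate (default 0).
#' @param loss_rate Per-species, per-family gene loss probability
#'   (default 0).
#' @param seed Integer seed (default 1).
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(tree = "(spA:0.2,spB:0.2,spC:0.2);",
                         model = NULL, n_codons = 150L, n_families = 5L,
                         paralog_rate = 0, loss_rate = 0, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), n_codons >= 1L, n_families >= 1L,
            paralog_rate >= 0, paralog_rate <= 1,
            loss_rate >= 0, loss_rate <= 1)
  if (is.null(model)) {
    model <- codon_model_spec("M0", codon_frequencies(method = "equal",
                                                      sequences = NULL),
                              kappa = 2, params = list(omega = 0.2))
  }
  structure(list(tree = tree, model = model, n_codons = as.integer(n_codons),
                 n_families = as.integer(n_families),
                 paralog_rate = paralog_rate, loss_rate = loss_rate,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

# Evolve states down one branch: for each site, draw the child state from
# the row of P(t) given the parent state.
.evolve_branch <- function(states, P) {
  out <- integer(length(states))
  for (s in unique(states)) {
    idx <- which(states == s)
    out[idx] <- sample.int(61L, length(idx), replace = TRUE,
                           prob = P[s, ])
  }
  out
}

#' Simulate a codon alignment under a scenario's model
#'
#' Root codons are drawn from the stationary distribution; each site draws a
#' site class from the model's mixture; substitutions are then simulated
#' branch-wise from the class's transition probabilities (foreground
#' branches use the foreground omega for branch/branch-site models).
#'
#' @param scenario A [sim_scenario()].
#' @param seed Seed override (default: the scenario's seed).
#' @return List: `alignment` (gap-free `codon_alignment`), `site_classes`
#'   (true class index per site), `positive_sites` (1-based sites in the
#'   positive-selection class, if the model has one).
#' @export
evolve_alignment <- function(scenario, seed = scenario$seed) {
  set.seed(seed)
  spec <- scenario$model
  cl <- .resolve_classes(spec)
  K <- length(cl$props)
  pi <- spec$frequencies$pi
  phylo <- scenario$tree
  if (length(phylo$tip.label) >= 3L && ape::is.rooted(phylo)) {
    phylo <- ape::unroot(phylo)
  }
  et <- .engine_tree(phylo, foreground = spec$foreground)
  po <- et$phylo
  nsites <- scenario$n_codons

  site_class <- sample.int(K, nsites, replace = TRUE, prob = cl$props)
  node_states <- matrix(NA_integer_, et$nnode, nsites)
  root <- po$edge[nrow(po$edge), 1]
  node_states[root, ] <- sample.int(61L, nsites, replace = TRUE, prob = pi)

  # preorder = reversed postorder edges. Branch lengths are expected
  # substitutions per codon averaged over site classes, matching the
  # engine: class k on a branch with mixture rate s evolves for an
  # effective time t * rate_k / s under its unit-rate generator.
  rate_bg <- vapply(cl$bg, function(w) .gy94_rate(spec$kappa, w,
                                                  spec$frequencies), 0)
  rate_fg <- if (!is.null(cl$fg)) {
    vapply(cl$fg, function(w) .gy94_rate(spec$kappa, w, spec$frequencies), 0)
  } else {
    NULL
  }
  Qcache <- new.env(parent = emptyenv())
  getP <- function(omega, t_eff) {
    key <- sprintf("%.12g_%.12g", omega, t_eff)
    if (is.null(Qcache[[key]])) {
      Q <- rate_matrix(spec$kappa, omega, spec$frequencies)
      Qcache[[key]] <- transition_probabilities(Q, t_eff)
    }
    Qcache[[key]]
  }
  for (e in rev(seq_len(nrow(po$edge)))) {
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    t <- po$edge.length[e]
    is_fg <- !is.null(cl$fg) && !is.null(et$fg_edge) && e == et$fg_edge
    omegas <- if (is_fg) cl$fg else cl$bg
    rates <- if (is_fg) rate_fg else rate_bg
    s_mix <- sum(cl$props * rates)
    child_states <- integer(nsites)
    for (k in seq_len(K)) {
      idx <- which(site_class == k)
      if (length(idx) == 0L) next
      P <- getP(omegas[k], t * rates[k] / s_mix)
      child_states[idx] <- .evolve_branch(node_states[parent, idx], P)
    }
    node_states[child, ] <- child_states
  }

  codons <- sense_codons()
  rows <- setNames(vapply(seq_len(et$ntip), function(i) {
    paste(codons[node_states[i, ]], collapse = "")
  }, ""), po$tip.label)
  aln <- structure(list(taxa = po$tip.label, rows = rows,
                        n_codon_columns = nsites, site_map = seq_len(nsites)),
                   class = "codon_alignment")
  pos_class <- switch(spec$name, M2a = 3L, M8 = spec$n_beta_categories + 1L,
                      BSA = c(3L, 4L), NULL)
  list(alignment = aln, site_classes = site_class,
       positive_sites = if (!is.null(pos_class))
         which(site_class %in% pos_class) else integer(0))
}

#' Emit per-species CDS/peptide FASTA pipeline inputs with ground truth
#'
#' Each gene family is simulated independently (family f uses seed
#' `seed + f`), yielding one gene per species, minus simulated losses and
#' plus within-species duplicates at `paralog_rate` (duplicates evolve along
#' a short extra branch of 0.005 so the adaptive-best-hit step still clusters
#' them with the source gene and the one-to-one filter rejects the family
#' deterministically). CDS records carry a terminal stop codon (TAA);
#' peptides are exact translations. A ground-truth table maps family and
#' species to headers and the true selection regime.
#'
#' @param scenario A [sim_scenario()]. `scenario$model` may also be a list
#'   of specs, one per family.
#' @param out_dir Output directory (created); writes `cds/<sp>.fasta`,
#'   `pep/<sp>.fasta` and `ground_truth.tsv`.
#' @return Invisible list: `cds_dir`, `pep_dir`, `truth` (data frame).
#' @export
emit_pipeline_inputs <- function(scenario, out_dir) {
  dir.create(file.path(out_dir, "cds"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "pep"), recursive = TRUE, showWarnings = FALSE)
  species <- scenario$tree$tip.label
  models <- if (inherits(scenario$model, "codon_model_spec")) {
    rep(list(scenario$model), scenario$n_families)
  } else {
    stopifnot(length(scenario$model) == scenario$n_families)
    scenario$model
  }
  cds_out <- pep_out <- setNames(vector("list", length(species)), species)
  truth <- list()
  for (f in seq_len(scenario$n_families)) {
    fam <- sprintf("fam%03d", f)
    spec <- models[[f]]
    sc_f <- scenario
    sc_f$model <- spec
    sim <- evolve_alignment(sc_f, seed = scenario$seed + f)
    set.seed((as.numeric(scenario$seed) * 1000 + f) %% 2147483647)
    lost <- species[runif(length(species)) < scenario$loss_rate]
    dup_species <- if (runif(1) < scenario$paralog_rate) {
      sample(setdiff(species, lost), 1L)
    } else {
      character(0)
    }
    regime <- sprintf("%s_kappa%.3g", spec$name, spec$kappa)
    for (sp in setdiff(species, lost)) {
      h <- paste0(fam, "_", sp)
      cds <- paste0(sim$alignment$rows[[sp]], "TAA")
      cds_out[[sp]][[h]] <- cds
      pep_out[[sp]][[h]] <- translate_cds(sim$alignment$rows[[sp]])
      truth[[length(truth) + 1L]] <- data.frame(
        family = fam, species = sp, header = h, regime = regime,
        is_paralog = FALSE)
      if (sp %in% dup_species) {
        Q <- rate_matrix(spec$kappa, .resolve_classes(spec)$bg[1],
                         spec$frequencies)
        P <- transition_probabilities(Q, 0.005)
        st <- codon_state_index(substring(sim$alignment$rows[[sp]],
                                          seq(1, 3 * scenario$n_codons, 3),
                                          seq(3, 3 * scenario$n_codons, 3))) + 1L
        dup <- paste(sense_codons()[.evolve_branch(st, P)], collapse = "")
        hd <- paste0(h, "_dup")
        cds_out[[sp]][[hd]] <- paste0(dup, "TAA")
        pep_out[[sp]][[hd]] <- translate_cds(dup)
        truth[[length(truth) + 1L]] <- data.frame(
          family = fam, species = sp, header = hd, regime = regime,
          is_paralog = TRUE)
      }
    }
  }
  for (sp in species) {
    if (length(cds_out[[sp]]) == 0L) next  # species lost every family
    write_fasta(unlist(cds_out[[sp]]), file.path(out_dir, "cds",
                                                 paste0(sp, ".fasta")))
    write_fasta(unlist(pep_out[[sp]]), file.path(out_dir, "pep",
                                                 paste0(sp, ".fasta")))
  }
  truth_df <- do.call(rbind, truth)
  utils::write.table(truth_df, file.path(out_dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(cds_dir = file.path(out_dir, "cds"),
                 pep_dir = file.path(out_dir, "pep"), truth = truth_df))
}
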