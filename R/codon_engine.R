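# ML engine: GY94 rate matrices, transition probabilities, pruning
# likelihoods (via the compiled core) and model fitting.

#' GY94 codon rate matrix
#'
#' Builds the 61x61 generator of the Goldman-Yang codon model:
#' `q(i,j) = pi_j * m` for codon pairs differing at one nucleotide, where `m`
#' is 1 (synonymous transversion), `kappa` (synonymous transition), `omega`
#' (nonsynonymous transversion) or `omega*kappa` (nonsynonymous transition);
#' 0 for multi-nucleotide changes. The matrix is scaled so that the expected
#' substitution rate at stationarity, `-sum_i pi_i q_ii`, equals 1 (branch
#' lengths are then expected substitutions per codon).
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio dN/dS (>= 0).
#' @param freqs A [codon_frequencies()] object.
#' @return 61x61 generator matrix with attribute `"pi"`.
#' @export
rate_matrix <- function(kappa, omega, freqs) {
  if (kappa <= 0) stop("kappa must be > 0")
  if (omega < 0) stop("omega must be >= 0")
  pi <- .check_frequencies(freqs)
  types <- codon_substitution_types()
  mult <- matrix(0, 61, 61)
  mult[types == 1L] <- 1
  mult[types == 2L] <- kappa
  mult[types == 3L] <- omega
  mult[types == 4L] <- omega * kappa
  Q <- sweep(mult, 2, pi, "*")
  diag(Q) <- -rowSums(Q)
  s <- -sum(pi * diag(Q))
  if (s <= 0) s <- 1
  Q <- Q / s
  dimnames(Q) <- list(sense_codons(), sense_codons())
  attr(Q, "pi") <- pi
  Q
}

#' Codon transition probability matrix
#'
#' Computes `P(t) = exp(Qt)` by symmetric eigendecomposition (the GY94
#' generator is time-reversible). Rows sum to 1; negative round-off entries
#' are clamped at 0.
#'
#' @param Q Generator from [rate_matrix()] (must carry its `"pi"` attribute).
#' @param t Branch length (>= 0), expected substitutions per codon.
#' @return 61x61 stochastic matrix.
#' @export
transition_probabilities <- function(Q, t) {
  if (t < 0) stop("branch length t must be >= 0")
  pi <- attr(Q, "pi")
  if (is.null(pi)) stop("Q must be produced by rate_matrix()")
  sp <- sqrt(pi)
  A <- Q * (sp %o% (1 / sp))
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  V1 <- e$vectors / sp
  V2 <- t(e$vectors) * rep(sp, each = 61)
  P <- V1 %*% (exp(e$values * t) * V2)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

# Expected substitution rate of the UNSCALED GY94 generator at stationarity;
# the mixture average of these over site classes is the per-branch scale
# factor shared by the engine and the simulator.
.gy94_rate <- function(kappa, omega, freqs) {
  pi <- .check_frequencies(freqs)
  types <- codon_substitution_types()
  mult <- matrix(0, 61, 61)
  mult[types == 1L] <- 1
  mult[types == 2L] <- kappa
  mult[types == 3L] <- omega
  mult[types == 4L] <- omega * kappa
  sum(pi * rowSums(sweep(mult, 2, pi, "*")))
}

# ---- internal engine plumbing -------------------------------------------

# Canonicalize a tree for likelihood work: unroot, postorder, clamp branch
# lengths, resolve the foreground edge if any.
.engine_tree <- function(tree, foreground = NULL) {
  if (inherits(tree, "gene_tree")) {
    if (is.null(foreground)) foreground <- tree$foreground
    phylo <- tree$tree
  } else if (inherits(tree, "phylo")) {
    phylo <- tree
  } else {
    stop("tree must be a gene_tree or ape phylo object")
  }
  if (is.null(phylo$edge.length)) {
    phylo$edge.length <- rep(0.1, nrow(phylo$edge))
  }
  if (length(phylo$tip.label) >= 3L && ape::is.rooted(phylo)) {
    phylo <- ape::unroot(phylo)
  }
  po <- ape::reorder.phylo(phylo, "postorder")
  fg_edge <- NULL
  if (!is.null(foreground)) {
    i <- match(foreground, po$tip.label)
    if (is.na(i)) stop("foreground '", foreground, "' is not a leaf of the tree")
    fg_edge <- which(po$edge[, 2] == i)
  }
  list(phylo = po, edges = po$edge,
       lengths = pmin(pmax(po$edge.length, 1e-6), 50),
       ntip = length(po$tip.label),
       nnode = length(po$tip.label) + po$Nnode,
       tips = po$tip.label, foreground = foreground, fg_edge = fg_edge)
}

# Codon state matrix (tips x sites, 0-based) from a cleaned codon alignment.
.alignment_states <- function(ca, taxa_order = NULL) {
  rows <- ca$rows
  if (!is.null(taxa_order)) {
    if (!all(taxa_order %in% names(rows))) {
      stop("alignment is missing taxa: ",
           paste(setdiff(taxa_order, names(rows)), collapse = ", "))
    }
    rows <- rows[taxa_order]
  }
  nc <- unique(nchar(rows))
  if (length(nc) != 1L) stop("alignment rows have unequal length")
  starts <- seq(1L, nc, 3L)
  st <- t(vapply(rows, function(r) {
    codon_state_index(substring(r, starts, starts + 2L))
  }, integer(length(starts))))
  if (anyNA(st)) {
    stop("alignment contains gaps or ambiguous codons; apply clean_columns() first")
  }
  storage.mode(st) <- "integer"
  st
}

# Compress alignment columns into site patterns.
.pack_patterns <- function(states) {
  key <- apply(states, 2, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(tips = states[, first, drop = FALSE],
       weights = as.numeric(tabulate(map, sum(first))),
       pattern_of_site = map)
}

# Expand class omegas into the K x B matrix the core consumes.
.omega_matrix <- function(classes, nedge, fg_edge) {
  K <- length(classes$props)
  om <- matrix(rep(classes$bg, nedge), nrow = K)
  if (!is.null(classes$fg)) {
    if (is.null(fg_edge)) stop("model has foreground classes but no foreground branch")
    om[, fg_edge] <- classes$fg
  }
  om
}

.core_args <- function(et, ca, spec, blens = NULL) {
  classes <- .resolve_classes(spec)
  st <- .alignment_states(ca, taxa_order = et$tips)
  pat <- .pack_patterns(st)
  list(types = codon_substitution_types(),
       pi = spec$frequencies$pi,
       kappa = spec$kappa,
       edges = et$edges - 1L,
       blens = if (is.null(blens)) et$lengths else blens,
       tips = pat$tips, weights = pat$weights,
       props = classes$props,
       omegas = .omega_matrix(classes, nrow(et$edges), et$fg_edge),
       nnode = et$nnode, pattern_of_site = pat$pattern_of_site)
}

#' Log-likelihood of a codon alignment under a codon model
#'
#' Felsenstein pruning over the site-class mixture of `spec`, evaluated at
#' the fixed parameter values stored in the specification and the branch
#' lengths of `tree`.
#'
#' @param tree A `gene_tree` or `phylo` object whose leaves match the
#'   alignment taxa.
#' @param alignment A gap-free [codon_alignment] (apply [clean_columns()]
#'   first).
#' @param spec A [codon_model_spec()].
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(tree, alignment, spec) {
  et <- .engine_tree(tree, spec$foreground)
  a <- .core_args(et, alignment, spec)
  cpp_codon_lnl(a$types, a$pi, a$kappa, a$edges, a$blens, a$tips, a$weights,
                a$props, a$omegas, a$nnode)
}

# ---- fitting -------------------------------------------------------------

#' Fit a codon model by maximum likelihood
#'
#' Jointly optimizes branch lengths and model parameters by bounded
#' quasi-Newton (L-BFGS-B) with seeded multi-start. Rate parameters are
#' optimized on log scale; proportions through stick-breaking coordinates.
#' Box constraints: kappa in \[0.01, 100\], free omega in \[1e-4, 50\]
#' (positive-selection classes in \[1, 50\]), branch lengths in
#' \[1e-6, 50\].
#'
#' @param tree Starting tree (`gene_tree` or `phylo`); branch lengths are
#'   used as optimizer starting values and re-estimated.
#' @param alignment Cleaned (gap-free) codon alignment.
#' @param name Model name (see [codon_model_spec()]).
#' @param seed Integer seed controlling the multi-start jitter.
#' @param n_starts Number of optimizer starts (default 3).
#' @param frequencies Optional [codon_frequencies()]; default: F3x4
#'   estimated from the alignment.
#' @param foreground Foreground leaf label (BR2/BSA/BSA0 only).
#' @param init Optional warm start: list with elements `kappa`, `params`,
#'   `blens` taken from a previously fitted (nested) model.
#' @param control Overrides for `optim` control (`maxit`, `factr`).
#' @return An object of class `model_fit`: the filled-in spec plus `lnL`,
#'   `np` (free-parameter count, frequency parameters not counted),
#'   re-optimized `branch_lengths`, `converged`, `n_starts` and `seed`.
#' @export
fit_model <- function(tree, alignment, name, seed = 1L, n_starts = 3L,
                      frequencies = NULL, foreground = NULL, init = NULL,
                      control = list()) {
  name <- match.arg(name, CODON_MODELS)
  et <- .engine_tree(tree, foreground)
  if (et$ntip < 3L) stop("need at least 3 taxa to fit codon models")
  if (is.null(frequencies)) {
    frequencies <- codon_frequencies(unname(unlist(alignment$rows)), "F3x4")
  }
  pi <- .check_frequencies(frequencies)
  st <- .alignment_states(alignment, taxa_order = et$tips)
  pat <- .pack_patterns(st)
  pinfo <- .model_parinfo(name)
  nedge <- nrow(et$edges)
  types <- codon_substitution_types()
  edges0 <- et$edges - 1L

  needs_fg <- name %in% c("BR2", "BSA", "BSA0")
  if (needs_fg && is.null(et$fg_edge)) stop("model ", name, " requires a foreground leaf")

  lower <- c(rep(log(1e-6), nedge), pinfo$lower)
  upper <- c(rep(log(50), nedge), pinfo$upper)

  mkspec <- function(kappa, params) {
    codon_model_spec(name, frequencies, kappa = kappa, params = params,
                     foreground = if (needs_fg) et$foreground else NULL)
  }
  negll <- function(par) {
    blens <- exp(par[seq_len(nedge)])
    mp <- pinfo$unpack(par[-seq_len(nedge)])
    spec <- mkspec(mp$kappa, mp$params)
    cl <- .resolve_classes(spec)
    om <- .omega_matrix(cl, nedge, et$fg_edge)
    v <- cpp_codon_lnl(types, pi, mp$kappa, edges0, blens, pat$tips,
                       pat$weights, cl$props, om, et$nnode)
    if (!is.finite(v)) 1e10 else -v
  }

  bl_start <- log(pmin(pmax(et$lengths, 1e-4), 10))
  base_model_start <- pinfo$start
  starts <- list()
  if (!is.null(init)) {
    ms <- .pack_start(name, kappa = init$kappa, params = init$params)
    bs <- if (!is.null(init$blens) && length(init$blens) == nedge) {
      log(pmin(pmax(init$blens, 1e-6), 50))
    } else bl_start
    starts[[length(starts) + 1L]] <- c(bs, ms)
  }
  starts[[length(starts) + 1L]] <- c(bl_start, base_model_start)
  if (n_starts > length(starts)) {
    set.seed(seed)
    for (s in seq_len(n_starts - length(starts))) {
      jit <- c(bl_start, base_model_start) + rnorm(nedge + length(base_model_start), 0, 0.3)
      starts[[length(starts) + 1L]] <- pmin(pmax(jit, lower), upper)
    }
  }
  starts <- starts[seq_len(max(n_starts, if (is.null(init)) 1L else 2L))]

  ctl <- utils::modifyList(list(maxit = 300L, factr = 1e7), control)
  best <- NULL
  any_conv <- FALSE
  for (sv in starts) {
    fit <- tryCatch(
      optim(sv, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = ctl),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed for model ", name)

  blens <- exp(best$par[seq_len(nedge)])
  mp <- pinfo$unpack(best$par[-seq_len(nedge)])
  spec <- mkspec(mp$kappa, mp$params)
  structure(list(name = name, spec = spec, lnL = -best$value,
                 np = nedge + .np_extra(name),
                 kappa = mp$kappa, params = mp$params,
                 classes = .resolve_classes(spec),
                 branch_lengths = blens, tree = et,
                 frequencies = frequencies,
                 converged = any_conv && best$convergence == 0,
                 n_starts = length(starts), seed = seed),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, np = %d, kappa = %.3f%s\n",
              x$name, x$lnL, x$np, x$kappa,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("  proportions:", paste(sprintf("%.3f", x$classes$props), collapse = " "), "\n")
  cat("  omega:      ", paste(sprintf("%.3f", x$classes$bg), collapse = " "), "\n")
  if (!is.null(x$tree$foreground)) {
    cat(sprintf("  foreground: %s\n", x$tree$foreground))
  }
  invisible(x)
}

#' Fit the full set of site models for one alignment
#'
#' Fits M0, M3, M1a, M2a, M7, M8a and M8 with warm starting along the nested
#' chains (M0 to M3, M1a to M2a, M7 to M8a to M8), which both speeds up
#' convergence and guarantees the nested log-likelihood orderings.
#'
#' @inheritParams fit_model
#' @return Named list of `model_fit` objects.
#' @export
fit_site_models <- function(tree, alignment, seed = 1L, n_starts = 2L,
                            frequencies = NULL, control = list()) {
  if (is.null(frequencies)) {
    frequencies <- codon_frequencies(unname(unlist(alignment$rows)), "F3x4")
  }
  ff <- function(name, init = NULL) {
    fit_model(tree, alignment, name, seed = seed, n_starts = n_starts,
              frequencies = frequencies, init = init, control = control)
  }
  m0 <- ff("M0")
  m1a <- ff("M1a", init = list(kappa = m0$kappa, blens = m0$branch_lengths))
  m2a <- ff("M2a", init = list(kappa = m1a$kappa,
                               params = c(m1a$params, list(p2 = 0.05, omega2 = 1)),
                               blens = m1a$branch_lengths))
  m3 <- ff("M3", init = list(kappa = m0$kappa,
                             params = list(omegas = pmax(m0$params$omega * c(0.3, 1, 2.5), 1e-4),
                                           p0 = 1 / 3, p1 = 1 / 3),
                             blens = m0$branch_lengths))
  m7 <- ff("M7", init = list(kappa = m1a$kappa, blens = m1a$branch_lengths))
  m8a <- ff("M8a", init = list(kappa = m7$kappa,
                               params = c(m7$params, list(p_beta = 0.95)),
                               blens = m7$branch_lengths))
  m8 <- ff("M8", init = list(kappa = m8a$kappa,
                             params = c(m8a$params[c("beta_p", "beta_q", "p_beta")],
                                        list(omega_s = 1)),
                             blens = m8a$branch_lengths))
  list(M0 = m0, M3 = m3, M1a = m1a, M2a = m2a, M7 = m7, M8a = m8a, M8 = m8)
}

#' Branch test: two-ratio model against the one-ratio null
#'
#' Fits the one-ratio model M0 (null) and the two-ratio branch model BR2
#' (alternative; free foreground and background omega) with the given
#' terminal branch as foreground. The alternative is warm-started from the
#' null so the nested log-likelihood ordering holds by construction.
#'
#' @inheritParams fit_model
#' @param foreground Leaf label designated as foreground branch.
#' @param null_fit Optional previously fitted M0 to reuse as the null.
#' @return List with elements `null` and `alt` (`model_fit` objects).
#' @export
fit_branch_model <- function(tree, alignment, foreground, seed = 1L,
                             n_starts = 2L, frequencies = NULL,
                             null_fit = NULL, control = list()) {
  if (is.null(frequencies)) {
    frequencies <- codon_frequencies(unname(unlist(alignment$rows)), "F3x4")
  }
  if (is.null(null_fit)) {
    null_fit <- fit_model(tree, alignment, "M0", seed = seed,
                          n_starts = n_starts, frequencies = frequencies,
                          control = control)
  }
  alt <- fit_model(tree, alignment, "BR2", seed = seed, n_starts = n_starts,
                   frequencies = frequencies, foreground = foreground,
                   init = list(kappa = null_fit$kappa,
                               params = list(omega_bg = null_fit$params$omega,
                                             omega_fg = null_fit$params$omega),
                               blens = null_fit$branch_lengths),
                   control = control)
  list(null = null_fit, alt = alt)
}

#' Branch-site test: model A against its omega2 = 1 null
#'
#' Fits branch-site model A (site classes 0, 1, 2a, 2b; foreground omega2
#' free, >= 1) and its null with omega2 fixed at 1, for the given foreground
#' terminal branch. The alternative is warm-started from the null.
#'
#' @inheritParams fit_branch_model
#' @return List with elements `null` (BSA0 fit) and `alt` (BSA fit).
#' @export
fit_branch_site <- function(tree, alignment, foreground, seed = 1L,
                            n_starts = 2L, frequencies = NULL,
                            control = list()) {
  if (is.null(frequencies)) {
    frequencies <- codon_frequencies(unname(unlist(alignment$rows)), "F3x4")
  }
  null <- fit_model(tree, alignment, "BSA0", seed = seed, n_starts = n_starts,
                    frequencies = frequencies, foreground = foreground,
                    control = control)
  alt <- fit_model(tree, alignment, "BSA", seed = seed, n_starts = n_starts,
                   frequencies = frequencies, foreground = foreground,
                   init = list(kappa = null$kappa,
                               params = c(null$params[c("p0", "p1", "omega0")],
                                          list(omega2 = 1)),
                               blens = null$branch_lengths),
                   control = control)
  list(null = null, alt = alt)
}

#' Per-site posterior probabilities of positive selection
#'
#' Naive empirical Bayes (NEB): the posterior probability that a codon site
#' belongs to the positive-selection class, evaluated at the maximum
#' likelihood estimates:
#' `P(class k | site) = p_k L(site|k) / sum_j p_j L(site|j)`.
#' For branch-site model A the posteriors of classes 2a and 2b are summed.
#' Sites are reported in original (pre-cleaning) 1-based codon coordinates.
#'
#' @param fit A converged `model_fit` for M2a, M8 or BSA.
#' @param alignment The cleaned codon alignment the model was fitted to.
#' @param method Posterior method; `"NEB"` (naive empirical Bayes) is
#'   implemented.
#' @param threshold Posterior probability above which a site is flagged
#'   (default 0.95).
#' @return Data frame with columns `site`, `posterior`, `method`, `flagged`.
#' @export
site_posteriors <- function(fit, alignment, method = "NEB", threshold = 0.95) {
  method <- match.arg(method, "NEB")
  pos_class <- switch(fit$name,
    M2a = 3L,
    M8 = fit$spec$n_beta_categories + 1L,
    BSA = c(3L, 4L),
    stop("model ", fit$name, " has no positive-selection class"))
  et <- fit$tree
  a <- .core_args(et, alignment, fit$spec, blens = fit$branch_lengths)
  res <- cpp_codon_sitelik(a$types, a$pi, a$kappa, a$edges, a$blens, a$tips,
                           a$weights, a$props, a$omegas, a$nnode)
  ll <- res$class_loglik  # K x npat
  lp <- log(a$props)
  post <- apply(ll, 2, function(v) {
    w <- lp + v
    w <- exp(w - max(w))
    sum(w[pos_class]) / sum(w)
  })
  site_post <- post[a$pattern_of_site]
  orig <- if (!is.null(alignment$site_map)) alignment$site_map else seq_along(site_post)
  data.frame(site = orig, posterior = site_post, method = method,
             flagged = site_post >= threshold)
}
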