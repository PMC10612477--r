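test_that("rate matrix obeys the GY94 structure, scaling and reversibility", {
  set.seed(41)
  types <- orthoselect:::codon_substitution_types()
  for (rep in 1:3) {
    kappa <- runif(1, 0.5, 5)
    omega <- runif(1, 0.05, 3)
    # random frequencies
    x <- rexp(61) + 0.05
    fr <- structure(list(method = "F61", pi = x / sum(x)),
                    class = "codon_frequencies")
    Q <- rate_matrix(kappa, omega, fr)
    pi <- attr(Q, "pi")
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
    expect_equal(unname(rowSums(Q)), rep(0, 61), tolerance = 1e-12)
    # detailed balance
    expect_lt(max(abs(pi * Q - t(pi * Q))), 1e-14)
    # multi-nucleotide changes have rate zero
    expect_true(all(Q[types == 0L & row(Q) != col(Q)] == 0))
  }
  # omega = 0 silences all nonsynonymous rates
  Q0 <- rate_matrix(2, 0, EQ_FREQS)
  expect_true(all(Q0[types == 3L] == 0) && all(Q0[types == 4L] == 0))
  # kappa = 1, omega = 1, equal frequencies: all single-step rates equal
  Q1 <- rate_matrix(1, 1, EQ_FREQS)
  offd <- Q1[types != 0L]
  expect_equal(max(offd), min(offd))
})

test_that("transition probabilities are stochastic, stationary, and Taylor-consistent", {
  Q <- rate_matrix(2, 0.5, EQ_FREQS)
  pi <- attr(Q, "pi")
  expect_equal(transition_probabilities(Q, 0), diag(61), tolerance = 1e-12,
               ignore_attr = TRUE)
  for (t in c(0.05, 0.7, 3)) {
    P <- transition_probabilities(Q, t)
    expect_equal(unname(rowSums(P)), rep(1, 61), tolerance = 1e-10)
    expect_true(all(P >= 0))
    expect_equal(as.numeric(pi %*% P), pi, tolerance = 1e-10)
  }
  # small-t Taylor expansion P(t) ~ I + Qt
  t <- 1e-4
  expect_lt(max(abs(transition_probabilities(Q, t) - (diag(61) + Q * t))),
            10 * t^2)
  expect_error(transition_probabilities(Q, -1), ">= 0")
})

test_that("pruning likelihood hits analytic limits and model collapses", {
  set.seed(42)
  sc <- sim_scenario(tree = TREE3, n_codons = 30)
  sim <- evolve_alignment(sc, seed = 1)
  spec0 <- codon_model_spec("M0", EQ_FREQS, kappa = 2, params = list(omega = 0.3))
  ll0 <- log_likelihood(TREE3, sim$alignment, spec0)
  expect_true(is.finite(ll0))
  # identical sequences on a near-zero tree: lnL -> sum log pi(codon)
  tiny <- ape::read.tree(text = "(a:1e-9,b:1e-9,c:1e-9);")
  rows <- rep(sim$alignment$rows[[1]], 3)
  aln_id <- structure(list(taxa = c("a", "b", "c"),
                           rows = setNames(rows, c("a", "b", "c")),
                           n_codon_columns = 30L, site_map = 1:30),
                      class = "codon_alignment")
  st <- orthoselect:::.alignment_states(aln_id)[1, ] + 1L
  expect_equal(log_likelihood(tiny, aln_id, spec0),
               sum(log(EQ_FREQS$pi[st])), tolerance = 1e-4)
  # M3 with all omegas equal collapses to M0
  spec3 <- codon_model_spec("M3", EQ_FREQS, kappa = 2,
                            params = list(omegas = c(0.3, 0.3, 0.3),
                                          p0 = 0.25, p1 = 0.5))
  expect_equal(log_likelihood(TREE3, sim$alignment, spec3), ll0,
               tolerance = 1e-6)
})

test_that("likelihood is invariant to rerooting (time reversibility)", {
  set.seed(43)
  tr <- ape::read.tree(text = "((a:0.2,b:0.1):0.15,(c:0.3,d:0.2):0.1,e:0.25);")
  sc <- sim_scenario(tree = tr, n_codons = 25)
  sim <- evolve_alignment(sc, seed = 2)
  spec <- codon_model_spec("M1a", EQ_FREQS, kappa = 1.8,
                           params = list(omega0 = 0.15, p0 = 0.6))
  ll <- log_likelihood(tr, sim$alignment, spec)
  for (node in c("a", "d")) {
    rerooted <- ape::root(tr, outgroup = node, resolve.root = TRUE)
    expect_equal(log_likelihood(rerooted, sim$alignment, spec), ll,
                 tolerance = 1e-8)
  }
})

test_that("M8a holds omega_s fixed at 1 and np counts follow the CodeML convention", {
  set.seed(44)
  sc <- sim_scenario(tree = TREE3, n_codons = 60)
  sim <- evolve_alignment(sc, seed = 3)
  f8a <- fit_model(TREE3, sim$alignment, "M8a", seed = 1, n_starts = 1,
                   frequencies = EQ_FREQS)
  expect_equal(f8a$params$omega_s, 1)
  nedge <- 3L
  expect_equal(f8a$np, nedge + 4L)
  f0 <- fit_model(TREE3, sim$alignment, "M0", seed = 1, n_starts = 1,
                  frequencies = EQ_FREQS)
  expect_equal(f0$np, nedge + 2L)
})

test_that("branch model requires a valid foreground and detects elevated omega", {
  set.seed(45)
  spec_br <- codon_model_spec("BR2", EQ_FREQS, kappa = 2,
                              params = list(omega_bg = 0.2, omega_fg = 4),
                              foreground = "spB")
  sc <- sim_scenario(tree = TREE3, model = spec_br, n_codons = 250)
  sim <- evolve_alignment(sc, seed = 4)
  expect_error(fit_branch_model(TREE3, sim$alignment, "spX"), "spX")
  pair <- fit_branch_model(TREE3, sim$alignment, "spB", seed = 1, n_starts = 1,
                           frequencies = EQ_FREQS)
  expect_gte(pair$alt$lnL, pair$null$lnL - 1e-4)
  expect_gt(pair$alt$params$omega_fg, 1)
  expect_lt(pair$alt$params$omega_bg, 1)
})

test_that("branch-site alternative nests its null and respects the omega2 bound", {
  set.seed(46)
  sc <- sim_scenario(tree = TREE3, n_codons = 80)
  sim <- evolve_alignment(sc, seed = 5)
  pair <- fit_branch_site(TREE3, sim$alignment, "spA", seed = 1, n_starts = 1,
                          frequencies = EQ_FREQS)
  expect_gte(pair$alt$lnL, pair$null$lnL - 1e-4)
  expect_gte(pair$alt$params$omega2, 1)
  expect_equal(pair$null$params$omega2, 1)
  expect_equal(pair$alt$np - pair$null$np, 1L)
})

test_that("NEB posteriors follow Bayes' rule and sum to one across classes", {
  set.seed(47)
  spec <- codon_model_spec("M2a", EQ_FREQS, kappa = 2,
                           params = list(omega0 = 0.1, p0 = 0.4, p2 = 0.3,
                                         omega2 = 5))
  sc <- sim_scenario(tree = TREE3, model = spec, n_codons = 5)
  sim <- evolve_alignment(sc, seed = 6)
  fit <- fit_model(TREE3, sim$alignment, "M2a", seed = 1, n_starts = 1,
                   frequencies = EQ_FREQS)
  sp <- site_posteriors(fit, sim$alignment)
  expect_true(all(sp$posterior >= 0 & sp$posterior <= 1))
  expect_equal(sp$site, 1:5)
  # manual Bayes-rule oracle from the class-conditional likelihoods
  a <- orthoselect:::.core_args(fit$tree, sim$alignment, fit$spec,
                                blens = fit$branch_lengths)
  res <- orthoselect:::cpp_codon_sitelik(a$types, a$pi, a$kappa, a$edges,
                                         a$blens, a$tips, a$weights, a$props,
                                         a$omegas, a$nnode)
  manual <- apply(res$class_loglik, 2, function(v) {
    w <- exp(log(a$props) + v - max(log(a$props) + v))
    w <- w / sum(w)
    w[3]
  })
  expect_equal(sp$posterior, manual[a$pattern_of_site], tolerance = 1e-12)
  # models without a positive class are refused
  f0 <- fit_model(TREE3, sim$alignment, "M0", seed = 1, n_starts = 1,
                  frequencies = EQ_FREQS)
  expect_error(site_posteriors(f0, sim$alignment), "no positive-selection")
})

test_that("site posteriors are reported in original pre-cleaning coordinates", {
  set.seed(48)
  spec <- codon_model_spec("M2a", EQ_FREQS, kappa = 2,
                           params = list(omega0 = 0.1, p0 = 0.4, p2 = 0.3,
                                         omega2 = 5))
  sc <- sim_scenario(tree = TREE3, model = spec, n_codons = 10)
  sim <- evolve_alignment(sc, seed = 7)
  aln <- sim$alignment
  # gap one codon column in one row, then clean
  ch <- strsplit(aln$rows[["spA"]], "")[[1]]
  ch[4:6] <- "-"
  aln$rows[["spA"]] <- paste(ch, collapse = "")
  cc <- clean_columns(aln, min_codons = 1)
  expect_equal(cc$site_map, c(1L, 3:10))
  fit <- fit_model(TREE3, cc, "M2a", seed = 1, n_starts = 1,
                   frequencies = EQ_FREQS)
  sp <- site_posteriors(fit, cc)
  expect_equal(sp$site, c(1L, 3:10))
})
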