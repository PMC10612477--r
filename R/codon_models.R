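# Codon substitution model specifications (site, branch and branch-site
# models of the M-series) and their parameterizations for ML fitting.
#
# Site-class conventions:
#   M0   one ratio: omega
#   M1a  nearly neutral: (omega0 in (0,1), p0), (1, 1-p0)
#   M2a  positive selection: adds (omega2 >= 1, p2)
#   M3   discrete, 3 classes: free omegas and proportions
#   M7   beta: omega ~ Beta(p, q) discretized into equal-probability classes
#   M8   beta & omega: beta classes (weight p0) plus omega_s >= 1 (weight 1-p0)
#   M8a  M8 with omega_s fixed at 1 (null for the M8a-vs-M8 test)
#   BR2  two-ratio branch model: omega_fg on the foreground terminal branch,
#        omega_bg elsewhere
#   BSA  branch-site model A: classes 0, 1, 2a, 2b; foreground omega2 >= 1
#   BSA0 model A null: omega2 fixed at 1

CODON_MODELS <- c("M0", "M1a", "M2a", "M3", "M7", "M8", "M8a",
                  "BR2", "BSA", "BSA0")

#' Specify a codon substitution model with fixed parameter values
#'
#' Builds a fully parameterized model specification for likelihood evaluation
#' or simulation (for ML estimation see [fit_model()], which fills such a
#' specification with estimates).
#'
#' @param name Model name, one of `r paste(CODON_MODELS, collapse=", ")`.
#' @param frequencies A [codon_frequencies()] object.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param params Named list of model parameters; missing entries take the
#'   defaults of [default_model_params()]. Recognized entries by model:
#'   `omega` (M0), `omega0`/`p0` (M1a, M2a, BSA, BSA0), `omega2`/`p2` (M2a),
#'   `omegas`/`p0`/`p1` (M3), `beta_p`/`beta_q` (M7, M8, M8a),
#'   `p_beta`/`omega_s` (M8, M8a), `omega_bg`/`omega_fg` (BR2),
#'   `p1` (BSA, BSA0: proportion of class 1), `omega2` (BSA).
#' @param foreground Leaf label of the foreground terminal branch
#'   (required for BR2, BSA, BSA0; must be `NULL` otherwise).
#' @param n_beta_categories Number of equal-probability discretization
#'   categories for the beta distribution (default 10).
#' @return An object of class `codon_model_spec`.
#' @export
codon_model_spec <- function(name, frequencies, kappa = 2, params = list(),
                             foreground = NULL, n_beta_categories = 10L) {
  name <- match.arg(name, CODON_MODELS)
  .check_frequencies(frequencies)
  if (kappa <= 0) stop("kappa must be > 0")
  needs_fg <- name %in% c("BR2", "BSA", "BSA0")
  if (needs_fg && is.null(foreground)) {
    stop(sprintf("model %s requires a foreground branch", name))
  }
  if (!needs_fg && !is.null(foreground)) {
    stop(sprintf("model %s does not take a foreground branch", name))
  }
  p <- utils::modifyList(default_model_params(name), params)
  structure(list(name = name, kappa = kappa, params = p,
                 frequencies = frequencies, foreground = foreground,
                 n_beta_categories = as.integer(n_beta_categories)),
            class = "codon_model_spec")
}

#' Default parameter values per codon model
#'
#' @param name Model name.
#' @return Named list of default parameter values.
#' @export
default_model_params <- function(name) {
  switch(name,
    M0   = list(omega = 0.4),
    M1a  = list(omega0 = 0.2, p0 = 0.7),
    M2a  = list(omega0 = 0.2, p0 = 0.65, p2 = 0.1, omega2 = 2),
    M3   = list(omegas = c(0.1, 0.5, 1.5), p0 = 0.4, p1 = 0.3),
    M7   = list(beta_p = 1, beta_q = 2),
    M8   = list(beta_p = 1, beta_q = 2, p_beta = 0.9, omega_s = 2),
    M8a  = list(beta_p = 1, beta_q = 2, p_beta = 0.9, omega_s = 1),
    BR2  = list(omega_bg = 0.4, omega_fg = 0.8),
    BSA  = list(omega0 = 0.2, p0 = 0.6, p1 = 0.3, omega2 = 1.5),
    BSA0 = list(omega0 = 0.2, p0 = 0.6, p1 = 0.3, omega2 = 1),
    stop("unknown model: ", name)
  )
}

# Means of the ncat equal-probability categories of Beta(p, q).
.beta_cat_means <- function(p, q, ncat) {
  # extreme shape values during optimization can trip qbeta's precision
  # warning; the category means remain adequate for the discretization
  qs <- suppressWarnings(qbeta(seq(0, 1, length.out = ncat + 1L), p, q))
  m <- (p / (p + q)) * diff(suppressWarnings(pbeta(qs, p + 1, q))) * ncat
  pmin(pmax(m, 1e-8), 1 - 1e-12)
}

# Resolve a spec into mixture classes: proportions, background omegas and
# (for branch/branch-site models) foreground omegas.
.resolve_classes <- function(spec) {
  p <- spec$params
  ncat <- spec$n_beta_categories
  out <- switch(spec$name,
    M0  = list(props = 1, bg = p$omega, fg = NULL),
    M1a = list(props = c(p$p0, 1 - p$p0), bg = c(p$omega0, 1), fg = NULL),
    M2a = list(props = c(p$p0, 1 - p$p0 - p$p2, p$p2),
               bg = c(p$omega0, 1, p$omega2), fg = NULL),
    M3  = list(props = c(p$p0, p$p1, 1 - p$p0 - p$p1), bg = p$omegas, fg = NULL),
    M7  = list(props = rep(1 / ncat, ncat),
               bg = .beta_cat_means(p$beta_p, p$beta_q, ncat), fg = NULL),
    M8  = ,
    M8a = list(props = c(rep(p$p_beta / ncat, ncat), 1 - p$p_beta),
               bg = c(.beta_cat_means(p$beta_p, p$beta_q, ncat),
                      if (spec$name == "M8a") 1 else p$omega_s),
               fg = NULL),
    BR2 = list(props = 1, bg = p$omega_bg, fg = p$omega_fg),
    BSA = ,
    BSA0 = {
      w2 <- if (spec$name == "BSA0") 1 else p$omega2
      p2 <- 1 - p$p0 - p$p1
      share0 <- p$p0 / (p$p0 + p$p1)
      list(props = c(p$p0, p$p1, p2 * share0, p2 * (1 - share0)),
           bg = c(p$omega0, 1, p$omega0, 1),
           fg = c(p$omega0, 1, w2, w2))
    },
    stop("unknown model: ", spec$name)
  )
  if (any(out$props < -1e-9) || abs(sum(out$props) - 1) > 1e-8) {
    stop("invalid class proportions for model ", spec$name)
  }
  out$props <- pmax(out$props, 1e-12)
  out$props <- out$props / sum(out$props)
  out
}

# Number of free model parameters beyond branch lengths (CodeML convention:
# F3x4/F1x4/F61 frequency parameters are not counted).
.np_extra <- function(name) {
  switch(name, M0 = 2L, M1a = 3L, M2a = 5L, M3 = 6L, M7 = 3L, M8 = 5L,
         M8a = 4L, BR2 = 3L, BSA = 5L, BSA0 = 4L)
}

# Optimization parameterization: transformed parameter vectors with box
# bounds. Rate-like parameters live on log scale; proportions are raw (or
# stick-breaking) coordinates in [eps, 1-eps].
.model_parinfo <- function(name) {
  eps <- 1e-6
  LK <- list("lkappa", log(0.01), log(100), log(2))
  lw_free <- c(log(1e-4), log(50))      # unconstrained omega
  lw_01 <- c(log(1e-4), log(1 - 1e-7))  # omega in (0,1)
  lw_pos <- c(0, log(50))               # omega >= 1
  mk <- function(names, lower, upper, start, unpack) {
    list(names = names, lower = lower, upper = upper, start = start,
         unpack = unpack)
  }
  switch(name,
    M0 = mk(c("lkappa", "lomega"),
            c(LK[[2]], lw_free[1]), c(LK[[3]], lw_free[2]),
            c(LK[[4]], log(0.4)),
            function(v) list(kappa = exp(v[1]), params = list(omega = exp(v[2])))),
    M1a = mk(c("lkappa", "p0", "lomega0"),
             c(LK[[2]], eps, lw_01[1]), c(LK[[3]], 1 - eps, lw_01[2]),
             c(LK[[4]], 0.7, log(0.2)),
             function(v) list(kappa = exp(v[1]),
                              params = list(p0 = v[2], omega0 = exp(v[3])))),
    M2a = mk(c("lkappa", "a0", "p2", "lomega0", "lomega2"),
             c(LK[[2]], eps, eps, lw_01[1], lw_pos[1]),
             c(LK[[3]], 1 - eps, 1 - eps, lw_01[2], lw_pos[2]),
             c(LK[[4]], 0.7, 0.1, log(0.2), log(2)),
             function(v) {
               p2 <- v[3]
               list(kappa = exp(v[1]),
                    params = list(p0 = (1 - p2) * v[2], p2 = p2,
                                  omega0 = exp(v[4]), omega2 = exp(v[5])))
             }),
    M3 = mk(c("lkappa", "a1", "a2", "lomega_1", "lomega_2", "lomega_3"),
            c(LK[[2]], eps, eps, rep(lw_free[1], 3)),
            c(LK[[3]], 1 - eps, 1 - eps, rep(lw_free[2], 3)),
            c(LK[[4]], 0.4, 0.5, log(0.1), log(0.5), log(1.5)),
            function(v) list(kappa = exp(v[1]),
                             params = list(p0 = v[2], p1 = (1 - v[2]) * v[3],
                                           omegas = exp(v[4:6])))),
    M7 = mk(c("lkappa", "lbeta_p", "lbeta_q"),
            c(LK[[2]], log(0.005), log(0.005)),
            c(LK[[3]], log(99), log(99)),
            c(LK[[4]], log(1), log(2)),
            function(v) list(kappa = exp(v[1]),
                             params = list(beta_p = exp(v[2]), beta_q = exp(v[3])))),
    M8 = mk(c("lkappa", "lbeta_p", "lbeta_q", "p_beta", "lomega_s"),
            c(LK[[2]], log(0.005), log(0.005), eps, lw_pos[1]),
            c(LK[[3]], log(99), log(99), 1 - eps, lw_pos[2]),
            c(LK[[4]], log(1), log(2), 0.9, log(2)),
            function(v) list(kappa = exp(v[1]),
                             params = list(beta_p = exp(v[2]), beta_q = exp(v[3]),
                                           p_beta = v[4], omega_s = exp(v[5])))),
    M8a = mk(c("lkappa", "lbeta_p", "lbeta_q", "p_beta"),
             c(LK[[2]], log(0.005), log(0.005), eps),
             c(LK[[3]], log(99), log(99), 1 - eps),
             c(LK[[4]], log(1), log(2), 0.9),
             function(v) list(kappa = exp(v[1]),
                              params = list(beta_p = exp(v[2]), beta_q = exp(v[3]),
                                            p_beta = v[4], omega_s = 1))),
    BR2 = mk(c("lkappa", "lomega_bg", "lomega_fg"),
             c(LK[[2]], lw_free[1], lw_free[1]),
             c(LK[[3]], lw_free[2], lw_free[2]),
             c(LK[[4]], log(0.4), log(0.8)),
             function(v) list(kappa = exp(v[1]),
                              params = list(omega_bg = exp(v[2]),
                                            omega_fg = exp(v[3])))),
    BSA = mk(c("lkappa", "a0", "p2tot", "lomega0", "lomega2"),
             c(LK[[2]], eps, eps, lw_01[1], lw_pos[1]),
             c(LK[[3]], 1 - eps, 1 - eps, lw_01[2], lw_pos[2]),
             c(LK[[4]], 0.7, 0.1, log(0.2), log(1.5)),
             function(v) list(kappa = exp(v[1]),
                              params = list(p0 = (1 - v[3]) * v[2],
                                            p1 = (1 - v[3]) * (1 - v[2]),
                                            omega0 = exp(v[4]), omega2 = exp(v[5])))),
    BSA0 = mk(c("lkappa", "a0", "p2tot", "lomega0"),
              c(LK[[2]], eps, eps, lw_01[1]),
              c(LK[[3]], 1 - eps, 1 - eps, lw_01[2]),
              c(LK[[4]], 0.7, 0.1, log(0.2)),
              function(v) list(kappa = exp(v[1]),
                               params = list(p0 = (1 - v[3]) * v[2],
                                             p1 = (1 - v[3]) * (1 - v[2]),
                                             omega0 = exp(v[4]), omega2 = 1))),
    stop("unknown model: ", name)
  )
}

# Inverse of unpack for warm starts: map (kappa, params) to a transformed
# start vector, with missing entries taken from the default start.
.pack_start <- function(name, kappa = NULL, params = list()) {
  pinfo <- .model_parinfo(name)
  v <- pinfo$start
  names(v) <- pinfo$names
  set <- function(nm, val) {
    if (nm %in% names(v)) v[nm] <<- min(max(val, pinfo$lower[match(nm, pinfo$names)]),
                                        pinfo$upper[match(nm, pinfo$names)])
  }
  if (!is.null(kappa)) set("lkappa", log(kappa))
  p <- params
  if (!is.null(p$omega)) set("lomega", log(p$omega))
  if (!is.null(p$omega0)) set("lomega0", log(p$omega0))
  if (!is.null(p$omega2)) set("lomega2", log(max(p$omega2, 1)))
  if (!is.null(p$omega_s)) set("lomega_s", log(max(p$omega_s, 1)))
  if (!is.null(p$omega_bg)) set("lomega_bg", log(p$omega_bg))
  if (!is.null(p$omega_fg)) set("lomega_fg", log(p$omega_fg))
  if (!is.null(p$beta_p)) set("lbeta_p", log(p$beta_p))
  if (!is.null(p$beta_q)) set("lbeta_q", log(p$beta_q))
  if (!is.null(p$p_beta)) set("p_beta", p$p_beta)
  if (name == "M1a" && !is.null(p$p0)) set("p0", p$p0)
  if (name == "M2a" && !is.null(p$p0)) {
    p2 <- if (is.null(p$p2)) 0.05 else p$p2
    set("p2", p2)
    set("a0", p$p0 / max(1 - p2, 1e-9))
  }
  if (name == "M3") {
    if (!is.null(p$p0)) set("a1", p$p0)
    if (!is.null(p$p0) && !is.null(p$p1)) set("a2", p$p1 / max(1 - p$p0, 1e-9))
    if (!is.null(p$omegas)) for (i in 1:3) set(paste0("lomega_", i), log(p$omegas[i]))
  }
  if (name %in% c("BSA", "BSA0") && !is.null(p$p0) && !is.null(p$p1)) {
    p2tot <- 1 - p$p0 - p$p1
    set("p2tot", max(p2tot, 1e-6))
    set("a0", p$p0 / max(p$p0 + p$p1, 1e-9))
  }
  unname(v)
}

#' @export
print.codon_model_spec <- function(x, ...) {
  cl <- .resolve_classes(x)
  cat(sprintf("codon model %s: kappa = %.3f, %d site class(es)\n",
              x$name, x$kappa, length(cl$props)))
  cat("  proportions:", paste(sprintf("%.3f", cl$props), collapse = " "), "\n")
  cat("  omega:      ", paste(sprintf("%.3f", cl$bg), collapse = " "), "\n")
  if (!is.null(x$foreground)) {
    cat(sprintf("  foreground: %s (omega %s)\n", x$foreground,
                paste(sprintf("%.3f", cl$fg), collapse = " ")))
  }
  invisible(x)
}
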