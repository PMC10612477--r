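# Likelihood-ratio tests over the fixed model-comparison schedule, chi-square
# p-values, and FDR control across OGCs.

# comparison -> degrees of freedom
LRT_SCHEDULE <- c(M0_vs_M3 = 4L, M1a_vs_M2a = 2L, M7_vs_M8 = 2L,
                  M8a_vs_M8 = 1L, BR2_vs_M0 = 1L, BSA_vs_BSA0 = 1L)

# comparison -> (null model, alternative model)
LRT_PAIRS <- list(M0_vs_M3 = c("M0", "M3"), M1a_vs_M2a = c("M1a", "M2a"),
                  M7_vs_M8 = c("M7", "M8"), M8a_vs_M8 = c("M8a", "M8"),
                  BR2_vs_M0 = c("M0", "BR2"), BSA_vs_BSA0 = c("BSA0", "BSA"))

#' Degrees of freedom for a scheduled model comparison
#'
#' Returns the schedule constant; when the two fits are supplied, the
#' free-parameter difference `np(alt) - np(null)` is computed and asserted
#' equal to it (a disagreement indicates a model-wiring bug and is a hard
#' error).
#'
#' @param comparison One of `names(LRT_SCHEDULE)`.
#' @param null,alt Optional `model_fit` objects.
#' @return Integer degrees of freedom.
#' @export
dof_for <- function(comparison, null = NULL, alt = NULL) {
  if (!comparison %in% names(LRT_SCHEDULE)) {
    stop("unknown comparison: ", comparison)
  }
  dof <- LRT_SCHEDULE[[comparison]]
  if (!is.null(null) && !is.null(alt)) {
    got <- alt$np - null$np
    if (got != dof) {
      stop(sprintf("np difference for %s is %d, schedule says %d (model wiring bug)",
                   comparison, got, dof))
    }
  }
  dof
}

#' Likelihood-ratio test between two nested codon model fits
#'
#' `2dlnL = max(0, 2 (lnL_alt - lnL_null))` compared to the upper tail of
#' the chi-square distribution with the scheduled degrees of freedom.
#' Negative differences are clamped to 0; a difference below -0.01 triggers
#' a warning (optimizer-failure signal).
#'
#' @param null,alt `model_fit` objects (null nested in alternative).
#' @param comparison Schedule key; inferred from the model names if omitted.
#' @param boundary_mix Use the 50:50 mixture of chi-square(0) and
#'   chi-square(dof) null (appropriate when the tested parameter sits on the
#'   boundary, e.g. M8a-vs-M8); default FALSE (plain chi-square,
#'   conservative).
#' @return One-row data frame: comparison, lnl_null, lnl_alt, np_null,
#'   np_alt, two_delta_lnl, dof, p_value.
#' @export
lrt <- function(null, alt, comparison = NULL, boundary_mix = FALSE) {
  if (is.null(null) || is.null(alt)) stop("both fits are required")
  if (is.null(comparison)) {
    hit <- vapply(LRT_PAIRS, function(p) p[1] == null$name && p[2] == alt$name,
                  logical(1))
    if (!any(hit)) stop("no scheduled comparison for ", null$name, " vs ", alt$name)
    comparison <- names(LRT_PAIRS)[which(hit)[1]]
  }
  dof <- dof_for(comparison, null, alt)
  delta <- 2 * (alt$lnL - null$lnL)
  if (delta < -0.01) {
    warning(sprintf("%s: lnL(alt) < lnL(null) by %.4f - optimizer failure likely",
                    comparison, -delta / 2))
  }
  delta <- max(0, delta)
  p <- pchisq(delta, df = dof, lower.tail = FALSE)
  if (boundary_mix) p <- if (delta == 0) 1 else p / 2
  data.frame(comparison = comparison, lnl_null = null$lnL, lnl_alt = alt$lnL,
             np_null = null$np, np_alt = alt$np, two_delta_lnl = delta,
             dof = dof, p_value = p)
}

#' Benjamini-Hochberg FDR adjustment across OGCs
#'
#' Step-up FDR control applied within each comparison family (one family per
#' comparison type, across OGCs) by default, or pooled over all tests.
#'
#' @param lrt_table Data frame with at least `comparison` and `p_value`.
#' @param mode `"per_family"` (default) or `"pooled"`.
#' @param threshold Significance threshold on q (default 0.05).
#' @return The table with `q_value` and `significant` columns appended.
#' @export
fdr_adjust <- function(lrt_table, mode = c("per_family", "pooled"),
                       threshold = 0.05) {
  mode <- match.arg(mode)
  if (nrow(lrt_table) == 0L) {
    lrt_table$q_value <- numeric(0)
    lrt_table$significant <- logical(0)
    return(lrt_table)
  }
  if (any(lrt_table$p_value < 0 | lrt_table$p_value > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- if (mode == "pooled") {
    p.adjust(lrt_table$p_value, method = "BH")
  } else {
    stats::ave(lrt_table$p_value, lrt_table$comparison,
               FUN = function(p) p.adjust(p, method = "BH"))
  }
  lrt_table$q_value <- q
  lrt_table$significant <- !is.na(q) & q < threshold
  lrt_table
}

#' Site-model positive selection call for one OGC
#'
#' An OGC is called positively selected at the site-model layer when a
#' positive-selection comparison (M1a-vs-M2a or M7-vs-M8) is significant
#' after FDR *and* the corresponding positive-class omega estimate exceeds
#' 1 - this guards against significance driven by non-selection misfit.
#'
#' @param lrt_rows FDR-adjusted LRT rows for one OGC.
#' @param fits Named list of site-model fits for the OGC.
#' @return List with `selected` (logical) and `reasons` (character).
#' @export
positive_selection_call <- function(lrt_rows, fits) {
  reasons <- character(0)
  sel <- FALSE
  m2a_row <- lrt_rows[lrt_rows$comparison == "M1a_vs_M2a", ]
  if (nrow(m2a_row) && isTRUE(m2a_row$significant[1])) {
    w2 <- fits$M2a$params$omega2
    if (!is.null(w2) && w2 > 1) {
      sel <- TRUE
      reasons <- c(reasons, sprintf("M1a_vs_M2a significant, omega2 = %.3f", w2))
    } else {
      reasons <- c(reasons, "M1a_vs_M2a significant but omega2 <= 1")
    }
  }
  m8_row <- lrt_rows[lrt_rows$comparison == "M7_vs_M8", ]
  if (nrow(m8_row) && isTRUE(m8_row$significant[1])) {
    ws <- fits$M8$params$omega_s
    if (!is.null(ws) && ws > 1) {
      sel <- TRUE
      reasons <- c(reasons, sprintf("M7_vs_M8 significant, omega_s = %.3f", ws))
    } else {
      reasons <- c(reasons, "M7_vs_M8 significant but omega_s <= 1")
    }
  }
  if (length(reasons) == 0L) reasons <- "no significant site-model comparison"
  list(selected = sel, reasons = reasons)
}
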