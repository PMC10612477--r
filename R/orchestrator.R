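# Pipeline driver: runs orthology -> alignment -> gene tree -> model fits
# over all OGCs (optionally in parallel), applies the staged logic (branch
# and branch-site scans only for OGCs with significant site-model signal),
# and assembles the final CSV outputs and per-OGC archives.

#' Pipeline configuration
#'
#' @param cds_dir,pep_dir Input directories (one FASTA per species each).
#' @param manifest Optional manifest TSV (species_id, cds_path, pep_path);
#'   overrides the directories.
#' @param out_dir Output directory (created if absent).
#' @param min_species Minimum species per OGC (default 3).
#' @param models Analysis stages to run, subset of
#'   `c("ssm", "branch", "branchsite")`.
#' @param workers Number of parallel workers (default 1).
#' @param seed Global RNG seed; per-OGC seeds are derived from it and the
#'   OGC id, so results do not depend on scheduling order.
#' @param gap_policy Column-cleaning policy (see [clean_columns()]).
#' @param fdr_mode FDR family structure (see [fdr_adjust()]).
#' @param fdr_threshold Significance threshold on q (default 0.05).
#' @param n_starts Optimizer starts per model fit (default 2).
#' @param archive Compress per-OGC intermediates into
#'   `Results/<ogc_id>.tar.gz` (default TRUE).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cds_dir = NULL, pep_dir = NULL, manifest = NULL,
                            out_dir = "orthoselect_out", min_species = 3L,
                            models = c("ssm", "branch", "branchsite"),
                            workers = 1L, seed = 1L,
                            gap_policy = "complete_deletion",
                            fdr_mode = "per_family", fdr_threshold = 0.05,
                            n_starts = 2L, archive = TRUE) {
  models <- match.arg(models, c("ssm", "branch", "branchsite"),
                      several.ok = TRUE)
  stopifnot(workers >= 1L, fdr_threshold > 0, fdr_threshold < 1)
  structure(list(cds_dir = cds_dir, pep_dir = pep_dir, manifest = manifest,
                 out_dir = out_dir, min_species = as.integer(min_species),
                 models = models, workers = as.integer(workers),
                 seed = as.integer(seed), gap_policy = gap_policy,
                 fdr_mode = fdr_mode, fdr_threshold = fdr_threshold,
                 n_starts = as.integer(n_starts), archive = isTRUE(archive)),
            class = "pipeline_config")
}

# Deterministic per-OGC seed from the global seed and the OGC id, so results
# are independent of worker count and scheduling order.
.ogc_seed <- function(seed, ogc_id) {
  h <- as.numeric(seed) %% 2147483647
  for (c in utf8ToInt(ogc_id)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

.fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

.sites_string <- function(sites_df) {
  if (is.null(sites_df)) return("")
  f <- sites_df[sites_df$flagged, , drop = FALSE]
  if (nrow(f) == 0L) return("")
  paste(sprintf("%d:%s", f$site, .fmt_num(f$posterior, 4)), collapse = ";")
}

# Site-model analysis of one OGC. Returns fits, LRT rows (pre-FDR) and NEB
# site posteriors for the positive-selection models.
.run_ogc_ssm <- function(ogc, proteomes, cfg) {
  peptides <- setNames(vapply(names(ogc$members), function(sp) {
    rec <- proteomes[[sp]]$records
    rec$peptide[match(ogc$members[[sp]], rec$header)]
  }, ""), names(ogc$members))
  cds <- setNames(vapply(names(ogc$members), function(sp) {
    rec <- proteomes[[sp]]$records
    rec$cds[match(ogc$members[[sp]], rec$header)]
  }, ""), names(ogc$members))

  pa <- align_proteins(peptides)
  ca_full <- back_translate(pa, cds)
  ca <- clean_columns(ca_full, policy = cfg$gap_policy)
  if (isTRUE(attr(ca, "too_short"))) {
    return(list(status = "skipped:too_short", ogc = ogc))
  }
  gt <- nj_tree(pairwise_distances(pa))
  seed <- .ogc_seed(cfg$seed, ogc$ogc_id)
  fits <- fit_site_models(gt, ca, seed = seed, n_starts = cfg$n_starts)
  lrt_rows <- do.call(rbind, lapply(
    c("M0_vs_M3", "M1a_vs_M2a", "M7_vs_M8", "M8a_vs_M8"),
    function(cmp) {
      pair <- LRT_PAIRS[[cmp]]
      cbind(ogc_id = ogc$ogc_id,
            lrt(fits[[pair[1]]], fits[[pair[2]]], comparison = cmp))
    }))
  sites <- list(
    M2a = tryCatch(site_posteriors(fits$M2a, ca), error = function(e) NULL),
    M8 = tryCatch(site_posteriors(fits$M8, ca), error = function(e) NULL))
  list(status = "completed", ogc = ogc, alignment = ca,
       protein_alignment = pa, full_alignment = ca_full, tree = gt,
       fits = fits, lrt = lrt_rows, sites = sites, seed = seed)
}

#' Branch and branch-site scan over all terminal branches of one OGC
#'
#' Each terminal branch in turn is designated the foreground (all others
#' background); for each foreground the two-ratio branch test (BR2 vs M0)
#' and the branch-site model A test (BSA vs BSA0) are fitted.
#'
#' @param ogc An `ogc` object (used for its id).
#' @param tree The OGC's `gene_tree`.
#' @param alignment Cleaned codon alignment.
#' @param seed Integer seed.
#' @param models Which scans to run, subset of `c("branch", "branchsite")`.
#' @param n_starts Optimizer starts.
#' @param m0_fit Optional prefitted M0 to reuse as branch-test null.
#' @return Data frame of per-foreground LRT rows (pre-FDR) with `ogc_id`,
#'   `foreground`, `omega_fg` (BR2 rows) and `sites` (BSA rows) columns.
#' @export
branch_scan <- function(ogc, tree, alignment, seed = 1L,
                        models = c("branch", "branchsite"), n_starts = 2L,
                        m0_fit = NULL) {
  phylo <- if (inherits(tree, "gene_tree")) tree$tree else tree
  freqs <- codon_frequencies(unname(unlist(alignment$rows)), "F3x4")
  rows <- list()
  for (fg in sort(phylo$tip.label)) {
    if ("branch" %in% models) {
      br <- tryCatch({
        pair <- fit_branch_model(tree, alignment, fg, seed = seed,
                                 n_starts = n_starts, frequencies = freqs,
                                 null_fit = m0_fit)
        if (is.null(m0_fit)) m0_fit <- pair$null
        r <- lrt(pair$null, pair$alt, comparison = "BR2_vs_M0")
        r$omega_fg <- pair$alt$params$omega_fg
        r$omega_bg <- pair$alt$params$omega_bg
        r$sites <- ""
        r
      }, error = function(e) NULL)
      if (!is.null(br)) {
        rows[[length(rows) + 1L]] <- cbind(ogc_id = ogc$ogc_id,
                                           foreground = fg, br)
      }
    }
    if ("branchsite" %in% models) {
      bs <- tryCatch({
        pair <- fit_branch_site(tree, alignment, fg, seed = seed,
                                n_starts = n_starts, frequencies = freqs)
        r <- lrt(pair$null, pair$alt, comparison = "BSA_vs_BSA0")
        r$omega_fg <- pair$alt$params$omega2
        r$omega_bg <- pair$alt$params$omega0
        r$sites <- .sites_string(tryCatch(
          site_posteriors(pair$alt, alignment), error = function(e) NULL))
        r
      }, error = function(e) NULL)
      if (!is.null(bs)) {
        rows[[length(rows) + 1L]] <- cbind(ogc_id = ogc$ogc_id,
                                           foreground = fg, bs)
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

# One row of the site-model results CSV (all columns as strings so output
# bytes are reproducible).
.ssm_row <- function(res, threshold) {
  fits <- res$fits
  lr <- res$lrt
  row <- c(ogc_id = res$ogc$ogc_id,
           n_species = as.character(res$ogc$n_species),
           species = paste(names(res$ogc$members), collapse = ","),
           n_codons_used = as.character(res$alignment$n_codon_columns))
  for (m in names(fits)) {
    f <- fits[[m]]
    omega_summary <- switch(m,
      M0 = f$params$omega,
      M1a = f$params$omega0,
      M2a = f$params$omega2,
      M3 = max(f$params$omegas),
      M7 = f$params$beta_p / (f$params$beta_p + f$params$beta_q),
      M8a = ,
      M8 = f$params$omega_s)
    row <- c(row,
             setNames(.fmt_num(f$lnL, 8), paste0(m, "_lnL")),
             setNames(as.character(f$np), paste0(m, "_np")),
             setNames(.fmt_num(omega_summary), paste0(m, "_omega")))
  }
  for (i in seq_len(nrow(lr))) {
    cmp <- lr$comparison[i]
    row <- c(row,
             setNames(.fmt_num(lr$two_delta_lnl[i]), paste0(cmp, "_2dlnl")),
             setNames(as.character(lr$dof[i]), paste0(cmp, "_dof")),
             setNames(.fmt_num(lr$p_value[i]), paste0(cmp, "_p")),
             setNames(.fmt_num(lr$q_value[i]), paste0(cmp, "_q")),
             setNames(as.character(lr$significant[i]), paste0(cmp, "_significant")))
  }
  m2a_sig <- lr$significant[lr$comparison == "M1a_vs_M2a"]
  m8_sig <- lr$significant[lr$comparison == "M7_vs_M8"]
  sites <- if (isTRUE(m2a_sig[1]) && !is.null(res$sites$M2a)) {
    .sites_string(res$sites$M2a)
  } else if (isTRUE(m8_sig[1]) && !is.null(res$sites$M8)) {
    .sites_string(res$sites$M8)
  } else {
    ""
  }
  call <- positive_selection_call(lr, fits)
  c(row, positively_selected_sites = sites,
    positive_selection = as.character(call$selected))
}

.write_csv <- function(df, path) {
  utils::write.table(df, path, sep = ",", quote = TRUE, row.names = FALSE)
  invisible(path)
}

# Write per-OGC intermediates and optionally archive them.
.archive_ogc <- function(res, out_dir, archive) {
  id <- res$ogc$ogc_id
  res_dir <- file.path(out_dir, "Results")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  ogc_dir <- file.path(res_dir, id, "Orthology_Groups")
  dir.create(ogc_dir, recursive = TRUE, showWarnings = FALSE)
  write_alignment_fasta(res$protein_alignment,
                        file.path(ogc_dir, paste0(id, ".pep.aln.fasta")))
  write_alignment_fasta(res$full_alignment,
                        file.path(ogc_dir, paste0(id, ".codon.fasta")))
  write_phylip(res$alignment, file.path(ogc_dir, paste0(id, ".codon.phy")))
  writeLines(to_newick(res$tree), file.path(ogc_dir, paste0(id, ".dnd")))
  write_genetree_nexus(res$tree,
                       file.path(ogc_dir, paste0(id, ".dnd.GenTree.nex")))
  fit_report <- unlist(lapply(names(res$fits), function(m) {
    f <- res$fits[[m]]
    c(sprintf("model %s", m),
      sprintf("  lnL = %.8f  np = %d  kappa = %.6f  converged = %s",
              f$lnL, f$np, f$kappa, f$converged),
      sprintf("  proportions: %s", paste(.fmt_num(f$classes$props), collapse = " ")),
      sprintf("  omega:       %s", paste(.fmt_num(f$classes$bg), collapse = " ")))
  }))
  writeLines(fit_report, file.path(ogc_dir, paste0(id, ".fits.txt")))
  jsonlite::write_json(
    lapply(res$fits, function(f) {
      list(name = f$name, lnL = f$lnL, np = f$np, kappa = f$kappa,
           params = f$params, branch_lengths = f$branch_lengths,
           converged = f$converged)
    }),
    file.path(ogc_dir, paste0(id, ".fits.json")),
    auto_unbox = TRUE, digits = NA)
  for (m in c("M0", "M1a", "M2a", "M3", "M7", "M8", "M8a")) {
    writeLines(codeml_control_lines(id, m),
               file.path(ogc_dir, paste0(id, ".", m, ".ctl")))
  }
  if (archive) {
    old <- setwd(res_dir)
    on.exit(setwd(old))
    utils::tar(paste0(id, ".tar.gz"), files = id, compression = "gzip",
               tar = "internal")
    unlink(file.path(res_dir, id), recursive = TRUE)
  }
  invisible(NULL)
}

#' CodeML-style control file lines for manual re-runs
#'
#' Emits a minimal control file naming the bundled alignment and tree so the
#' corresponding model can be re-run manually in CodeML.
#'
#' @param ogc_id OGC identifier (file stem).
#' @param model Site model name.
#' @return Character vector of control-file lines.
#' @export
codeml_control_lines <- function(ogc_id, model) {
  ns <- switch(model, M0 = 0, M1a = 1, M2a = 2, M3 = 3, M7 = 7, M8 = 8,
               M8a = 8, stop("unsupported model for control file: ", model))
  c(sprintf("seqfile = %s.codon.phy", ogc_id),
    sprintf("treefile = %s.dnd", ogc_id),
    sprintf("outfile = %s.%s.mlc", ogc_id, model),
    "noisy = 0", "verbose = 1", "runmode = 0",
    "seqtype = 1", "CodonFreq = 2", "model = 0",
    sprintf("NSsites = %d", ns),
    "icode = 0", "fix_kappa = 0", "kappa = 2",
    if (model == "M8a") "fix_omega = 1" else "fix_omega = 0",
    if (model == "M8a") "omega = 1" else "omega = 0.4",
    "cleandata = 1")
}

#' Run the full positive-selection pipeline
#'
#' Executes the four workflow stages: (1) input validation and pairing,
#' (2) orthology prediction and OGC filtering, (3) per-OGC protein
#' alignment, codon back-translation, gene tree and site-model fits with
#' LRTs, (4) branch and branch-site scans for OGCs whose site-model tests
#' indicate diversifying selection (q < threshold for M1a-vs-M2a or
#' M7-vs-M8). FDR is controlled per comparison family across OGCs.
#'
#' OGCs are independent work units distributed over `workers` processes;
#' per-OGC seeds derive from the global seed and the OGC id, so all result
#' files are byte-identical across worker counts.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list: `ogcs`, `ssm_table`, `branch_table`, `manifest`
#'   (per-OGC status), `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  proteomes <- load_proteomes(config$cds_dir, config$pep_dir, config$manifest)
  write_validation_report(proteomes, file.path(out_dir, "validation_report.tsv"))
  if (length(proteomes) < config$min_species) {
    message(sprintf("only %d species provided; at least %d needed - no OGCs",
                    length(proteomes), config$min_species))
    ogcs <- list()
  } else {
    ogcs <- predict_ogcs(proteomes, min_species = config$min_species)
  }
  write_orthology_table(ogcs, file.path(out_dir, "orthology_groups.tsv"),
                        all_species = sort(names(proteomes)))
  if (length(ogcs) == 0L) {
    message("no eligible OGCs; writing empty result tables")
    .write_csv(data.frame(), file.path(out_dir, "ssm_results.csv"))
    .write_csv(data.frame(), file.path(out_dir, "branch_results.csv"))
    manifest <- list(seed = config$seed, n_ogcs = 0L, status = list())
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(list(ogcs = ogcs, ssm_table = NULL, branch_table = NULL,
                          manifest = manifest, out_dir = out_dir)))
  }

  run_one <- function(ogc) {
    tryCatch(.run_ogc_ssm(ogc, proteomes, config),
             error = function(e) list(status = paste0("failed:", conditionMessage(e)),
                                      ogc = ogc))
  }
  results <- if (config$workers > 1L) {
    parallel::mclapply(ogcs, run_one, mc.cores = config$workers,
                       mc.preschedule = FALSE)
  } else {
    lapply(ogcs, run_one)
  }
  names(results) <- vapply(ogcs, `[[`, "", "ogc_id")
  done <- results[vapply(results, function(r) r$status == "completed", TRUE)]

  # FDR across OGCs, per comparison family
  if (length(done)) {
    all_lrt <- do.call(rbind, lapply(done, `[[`, "lrt"))
    all_lrt <- fdr_adjust(all_lrt, mode = config$fdr_mode,
                          threshold = config$fdr_threshold)
    for (nm in names(done)) {
      done[[nm]]$lrt <- all_lrt[all_lrt$ogc_id == nm, , drop = FALSE]
    }
  }

  ssm_rows <- lapply(done, .ssm_row, threshold = config$fdr_threshold)
  ssm_table <- if (length(ssm_rows)) {
    as.data.frame(do.call(rbind, ssm_rows), stringsAsFactors = FALSE)
  } else {
    NULL
  }
  if (!is.null(ssm_table)) {
    ssm_table <- ssm_table[order(ssm_table$ogc_id), , drop = FALSE]
    rownames(ssm_table) <- NULL
    .write_csv(ssm_table, file.path(out_dir, "ssm_results.csv"))
  } else {
    .write_csv(data.frame(), file.path(out_dir, "ssm_results.csv"))
  }

  # stage 4: branch and branch-site scans for gated OGCs
  branch_table <- NULL
  want_branch <- intersect(config$models, c("branch", "branchsite"))
  if (length(want_branch) && length(done)) {
    gated <- Filter(function(r) {
      lr <- r$lrt
      any(lr$significant[lr$comparison %in% c("M1a_vs_M2a", "M7_vs_M8")])
    }, done)
    scan_one <- function(r) {
      branch_scan(r$ogc, r$tree, r$alignment, seed = r$seed,
                  models = want_branch,
                  n_starts = config$n_starts, m0_fit = r$fits$M0)
    }
    scans <- if (config$workers > 1L && length(gated) > 1L) {
      parallel::mclapply(gated, scan_one, mc.cores = config$workers,
                         mc.preschedule = FALSE)
    } else {
      lapply(gated, scan_one)
    }
    scans <- Filter(Negate(is.null), scans)
    if (length(scans)) {
      bt <- do.call(rbind, scans)
      bt <- fdr_adjust(bt, mode = config$fdr_mode,
                       threshold = config$fdr_threshold)
      bt <- bt[order(bt$ogc_id, bt$foreground, bt$comparison), , drop = FALSE]
      rownames(bt) <- NULL
      out_bt <- data.frame(
        ogc_id = bt$ogc_id, foreground = bt$foreground,
        comparison = bt$comparison,
        lnl_null = .fmt_num(bt$lnl_null, 8), lnl_alt = .fmt_num(bt$lnl_alt, 8),
        np_null = bt$np_null, np_alt = bt$np_alt,
        omega_fg = .fmt_num(bt$omega_fg), omega_bg = .fmt_num(bt$omega_bg),
        two_delta_lnl = .fmt_num(bt$two_delta_lnl), dof = bt$dof,
        p_value = .fmt_num(bt$p_value), q_value = .fmt_num(bt$q_value),
        significant = as.character(bt$significant),
        positively_selected_sites = bt$sites)
      branch_table <- out_bt
      .write_csv(out_bt, file.path(out_dir, "branch_results.csv"))
    }
  }
  if (is.null(branch_table)) {
    .write_csv(data.frame(ogc_id = character(0), foreground = character(0),
                          comparison = character(0)),
               file.path(out_dir, "branch_results.csv"))
  }

  for (r in done) .archive_ogc(r, out_dir, config$archive)

  status <- lapply(results, `[[`, "status")
  manifest <- list(
    package_version = as.character(utils::packageVersion("orthoselect")),
    seed = config$seed, workers = config$workers,
    models = config$models, fdr_mode = config$fdr_mode,
    fdr_threshold = config$fdr_threshold, gap_policy = config$gap_policy,
    n_ogcs = length(ogcs), status = status)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(ogcs = ogcs, ssm_table = ssm_table,
                 branch_table = branch_table, manifest = manifest,
                 out_dir = out_dir, results = done))
}

#' Re-run the codon-model fits for one archived OGC
#'
#' Extracts a per-OGC archive produced by [run_pipeline()], optionally
#' replaces its gene tree with a pruned species phylogeny
#' (see [replace_tree()]), and re-fits the site models on the bundled
#' alignment, reproducing the archived likelihoods when the tree is
#' unchanged.
#'
#' @param archive Path to `Results/<ogc_id>.tar.gz` (or the extracted
#'   directory).
#' @param species_tree Optional Newick string/file: replaces the gene tree
#'   before refitting.
#' @param models Site models to refit (default `"M0"`).
#' @param seed,n_starts Optimizer settings.
#' @return Named list of `model_fit` objects.
#' @export
rerun_ogc <- function(archive, species_tree = NULL, models = "M0",
                      seed = 1L, n_starts = 2L) {
  if (dir.exists(archive)) {
    root <- archive
  } else {
    root <- tempfile("ogc_rerun_")
    dir.create(root)
    utils::untar(archive, exdir = root)
  }
  grp <- list.files(root, pattern = "Orthology_Groups$", recursive = TRUE,
                    include.dirs = TRUE, full.names = TRUE)
  bundle <- if (length(grp)) grp[1] else root
  if (!is.null(species_tree)) replace_tree(bundle, species_tree)
  dnd <- list.files(bundle, pattern = "\\.dnd$", full.names = TRUE)
  fasta <- list.files(bundle, pattern = "\\.codon\\.fasta$", full.names = TRUE)
  if (length(dnd) != 1L || length(fasta) != 1L) {
    stop("bundle must contain one .dnd and one .codon.fasta file")
  }
  gt <- gene_tree(ape::read.tree(dnd))
  rows <- read_fasta(fasta)
  ca <- structure(list(taxa = names(rows), rows = rows,
                       n_codon_columns = nchar(rows[[1]]) / 3,
                       site_map = seq_len(nchar(rows[[1]]) / 3)),
                  class = "codon_alignment")
  ca <- clean_columns(ca)
  setNames(lapply(models, function(m) {
    fit_model(gt, ca, m, seed = seed, n_starts = n_starts)
  }), models)
}
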