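#' End-to-end run configuration
#'
#' Bundles the inputs and settings for [run_fit_pipeline()].  Inputs may be
#' given as file paths (read with the package readers) or as already-built
#' objects; an object wins over the corresponding path.  Defaults follow
#' the standard analysis: r2 threshold 0.1, genome-wide significance
#' `5e-8`, `m_star` 100000, grid -0.3..0.3 in steps of 0.005, 100
#' bootstrap replicates.
#'
#' @param summary_path,table summary statistics: path + `column_map`, or a
#'   [summary_table()].
#' @param column_map column map for [read_summary_table()] (when reading
#'   from `summary_path`).
#' @param n_cases,n_controls sample sizes (required with `summary_path`;
#'   taken from `table` otherwise).
#' @param ld_path,ld pairwise LD: path or [ld_table()].  Required: the
#'   model assumes a pruned, nearly independent SNP set.  Pass an empty
#'   `ld_table` for data known to be independent (e.g. synthetic).
#' @param panel_path,panel optional reference panel id list.
#' @param allele_map_path,allele_map optional ancestral/derived allele map.
#' @param r2_threshold LD pruning threshold.
#' @param em an [em_config()].
#' @param p_c significance level used downstream.
#' @param m_star assumed independent SNP count in a future study.
#' @param n_boot,level bootstrap settings.
#' @param seed master seed; stage seeds derive from it via [derive_seed()].
#' @param out_dir optional directory; when set, the fit, manifest, pruned
#'   ids and drop-report sidecar are written there.
#' @export
run_config <- function(summary_path = NULL, table = NULL, column_map = NULL,
                       n_cases = NULL, n_controls = NULL,
                       ld_path = NULL, ld = NULL,
                       panel_path = NULL, panel = NULL,
                       allele_map_path = NULL, allele_map = NULL,
                       r2_threshold = 0.1, em = em_config(),
                       p_c = 5e-8, m_star = 100000L,
                       n_boot = 100L, level = 0.95,
                       seed = 1L, out_dir = NULL) {
  if (is.null(table) && is.null(summary_path)) {
    stop("either `table` or `summary_path` must be given", call. = FALSE)
  }
  structure(list(summary_path = summary_path, table = table,
                 column_map = column_map, n_cases = n_cases,
                 n_controls = n_controls, ld_path = ld_path, ld = ld,
                 panel_path = panel_path, panel = panel,
                 allele_map_path = allele_map_path, allele_map = allele_map,
                 r2_threshold = r2_threshold, em = em, p_c = p_c,
                 m_star = as.integer(m_star), n_boot = as.integer(n_boot),
                 level = level, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    .stop_stage(stage, conditionMessage(e))
  })
}

#' Run the fitting pipeline
#'
#' Executes read -> harmonize (if an allele map is configured) -> panel
#' filter (if a panel is configured) -> LD prune -> EM fit, logging SNP
#' counts at every stage.  The returned manifest records every seed, count,
#' drop report and a content hash of the configuration, so any artifact is
#' reconstructible from the configuration and master seed alone.  Stage
#' failures are re-raised with the stage name prefixed.
#'
#' @param cfg a [run_config()].
#' @return an object of class `sphmm_run`: `fit` (an `sphmm_fit`),
#'   `pruned` (a `pruned_set`), `manifest`.
#' @export
run_fit_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  counts <- list()

  tab <- .stage("read", {
    if (!is.null(cfg$table)) {
      cfg$table
    } else {
      if (is.null(cfg$column_map) || is.null(cfg$n_cases) || is.null(cfg$n_controls)) {
        stop("summary_path requires column_map, n_cases and n_controls")
      }
      read_summary_table(cfg$summary_path, cfg$column_map,
                         cfg$n_cases, cfg$n_controls)
    }
  })
  counts$input <- nrow(tab)
  message(sprintf("[read] %d SNPs (seed %d)", nrow(tab), cfg$seed))

  if (!is.null(cfg$allele_map) || !is.null(cfg$allele_map_path)) {
    tab <- .stage("harmonize", {
      amap <- if (!is.null(cfg$allele_map)) cfg$allele_map else read_allele_map(cfg$allele_map_path)
      harmonize_to_derived(tab, amap)
    })
    message(sprintf("[harmonize] %d SNPs retained", nrow(tab)))
  }
  counts$harmonized <- nrow(tab)

  if (!is.null(cfg$panel) || !is.null(cfg$panel_path)) {
    tab <- .stage("panel_filter", {
      panel <- if (!is.null(cfg$panel)) cfg$panel else read_panel(cfg$panel_path)
      filter_to_panel(tab, panel)
    })
    message(sprintf("[panel_filter] %d SNPs retained", nrow(tab)))
  }
  counts$filtered <- nrow(tab)

  prune_seed <- derive_seed(cfg$seed, "prune")
  pruned <- .stage("ld_prune", {
    if (is.null(cfg$ld) && is.null(cfg$ld_path)) {
      stop("no LD table configured (set `ld` or `ld_path`)")
    }
    ld <- if (!is.null(cfg$ld)) cfg$ld else read_ld_table(cfg$ld_path)
    ld_prune(tab, ld, cfg$r2_threshold, seed = prune_seed)
  })
  counts$pruned <- nrow(pruned$table)
  message(sprintf("[ld_prune] %d of %d SNPs retained (r2 > %g removed, seed %d)",
                  counts$pruned, counts$filtered, cfg$r2_threshold, prune_seed))

  fit <- .stage("fit", fit_sphmm(pruned, cfg$em))
  message(sprintf("[fit] pi = %.4f after %d EM iterations (%s)",
                  fit$pi, fit$n_iter,
                  if (fit$converged) "converged" else "not converged"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("sphmm")),
    config_hash = .config_hash(unclass(cfg)[setdiff(names(unclass(cfg)),
                                                    c("table", "ld", "panel",
                                                      "allele_map"))]),
    master_seed = cfg$seed,
    stage_seeds = list(prune = prune_seed),
    counts = counts,
    drop_report = drop_report(tab),
    r2_threshold = cfg$r2_threshold,
    em = unclass(cfg$em),
    pi = fit$pi,
    loglik = fit$loglik,
    converged = fit$converged
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_sphmm_fit(fit, file.path(cfg$out_dir, "fit.json"))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    writeLines(pruned$table$snp_id, file.path(cfg$out_dir, "pruned_ids.txt"))
    jsonlite::write_json(drop_report(tab),
                         file.path(cfg$out_dir, "drop_report.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }

  structure(list(fit = fit, pruned = pruned, manifest = manifest),
            class = "sphmm_run")
}

#' Validate the discovery prediction on a current/future data pair
#'
#' Fits the model to a "current" study, predicts the number of significant
#' SNPs at the "future" study's sample sizes with `m_star` set to the size
#' of the future pruned set, attaches a parametric-bootstrap confidence
#' interval for the prediction and a bias-corrected prediction interval
#' for an observed count (see [bootstrap_k_ci()]), and compares against
#' the count actually observed in the future pruned set.
#'
#' @param current_cfg a [run_config()] for the current study.
#' @param future_table a [summary_table()] for the future study (its
#'   `n_cases`/`n_controls` attributes define the future sizes).
#' @param future_ld an [ld_table()] for the future study.
#' @return an object of class `validation_report`: `k_hat`, `k_ci`,
#'   `observed`, `m_star`, `pi`, sample sizes, and the underlying run.
#' @export
run_validation <- function(current_cfg, future_table, future_ld) {
  run <- run_fit_pipeline(current_cfg)

  fut_seed <- derive_seed(current_cfg$seed, "prune_future")
  fut_pruned <- .stage("ld_prune_future", {
    ld_prune(future_table, future_ld, current_cfg$r2_threshold, seed = fut_seed)
  })
  m_star <- nrow(fut_pruned$table)
  message(sprintf("[validate] future pruned set: %d SNPs -> m_star", m_star))

  pred_cfg <- prediction_config(
    p_c = current_cfg$p_c, m_star = m_star,
    n_r = attr(run$pruned$table, "n_cases"),
    n_s = attr(run$pruned$table, "n_controls"),
    n_r_star = attr(future_table, "n_cases"),
    n_s_star = attr(future_table, "n_controls")
  )
  k_hat <- predict_num_significant(run$fit, run$pruned, pred_cfg)
  boot <- bootstrap_k_ci(run$fit, run$pruned, current_cfg$em, pred_cfg,
                         n_boot = current_cfg$n_boot,
                         level = current_cfg$level,
                         seed = derive_seed(current_cfg$seed, "boot"))
  observed <- count_significant(fut_pruned, current_cfg$p_c)

  structure(list(
    k_hat = k_hat, k_ci = boot$k_ci,
    k_prediction_interval = boot$k_prediction_interval,
    observed = observed,
    m_star = m_star, pi = run$fit$pi, p_c = current_cfg$p_c,
    n_current = c(cases = pred_cfg$n_r, controls = pred_cfg$n_s),
    n_future = c(cases = pred_cfg$n_r_star, controls = pred_cfg$n_s_star),
    bootstrap = boot, run = run, future_pruned = fut_pruned
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Prediction validation (current -> future)\n")
  cat(sprintf("  current: %d/%d, future: %d/%d (cases/controls)\n",
              x$n_current[1], x$n_current[2], x$n_future[1], x$n_future[2]))
  cat(sprintf("  m_star = %d, p_c = %g, pi-hat = %.4f\n", x$m_star, x$p_c, x$pi))
  cat(sprintf("  predicted significant SNPs: %.2f  CI [%.2f, %.2f]\n",
              x$k_hat, x$k_ci[1], x$k_ci[2]))
  if (!is.null(x$k_prediction_interval)) {
    cat(sprintf("  prediction interval for an observed count: [%.2f, %.2f]\n",
                x$k_prediction_interval[1], x$k_prediction_interval[2]))
  }
  cat(sprintf("  observed in future pruned set: %d\n", x$observed))
  invisible(x)
}
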