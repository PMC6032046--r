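#' Simulate summary statistics from a fitted model
#'
#' One parametric-bootstrap draw: each SNP is non-null with probability
#' `fit$pi`; non-null SNPs draw their true effect from the fitted discrete
#' distribution, null SNPs have effect exactly zero; the observed estimate
#' is then normal around the true effect with the SNP's own variance.
#'
#' @param fit an `sphmm_fit` (or `list(pi =, g =)`).
#' @param variances per-SNP estimation variances, > 0.
#' @param seed integer seed; the draw is a pure function of
#'   `(fit, variances, seed)`.
#' @return numeric vector of simulated estimates, with the latent
#'   `beta_true` and `is_nonnull` attached as attributes.
#' @export
simulate_from_fit <- function(fit, variances, seed) {
  if (any(!is.finite(variances)) || any(variances <= 0)) {
    stop("variances must be positive", call. = FALSE)
  }
  m <- length(variances)
  with_local_seed(seed, {
    nonnull <- runif(m) < fit$pi
    beta <- numeric(m)
    if (any(nonnull)) {
      beta[nonnull] <- sample(fit$g$points, sum(nonnull), replace = TRUE,
                              prob = fit$g$masses)
    }
    y <- beta + sqrt(variances) * rnorm(m)
    structure(y, beta_true = beta, is_nonnull = nonnull)
  })
}

# simulate-and-refit engine shared by the bootstrap interfaces
.bootstrap_run <- function(fit, data, em_cfg, pred_cfg, n_boot, seed) {
  d <- .extract_yv(data)
  warm <- list(pi0 = fit$pi, g0 = fit$g)
  pi_reps <- rep(NA_real_, n_boot)
  k_reps <- if (is.null(pred_cfg)) NULL else rep(NA_real_, n_boot)
  count_reps <- k_reps
  params <- vector("list", n_boot)
  n_failed <- 0L
  if (!is.null(pred_cfg)) {
    v_star <- rescale_variance(d$v, pred_cfg$n_r, pred_cfg$n_s,
                               pred_cfg$n_r_star, pred_cfg$n_s_star)
    z_c <- rejection_threshold(pred_cfg$p_c)
  }
  for (b in seq_len(n_boot)) {
    rep_seed <- derive_seed(seed, paste0("boot", b))
    y_b <- as.numeric(simulate_from_fit(fit, d$v, rep_seed))
    rep_fit <- tryCatch(
      suppressWarnings(fit_sphmm(list(y = y_b, v = d$v), em_cfg, start = warm)),
      error = function(e) NULL
    )
    if (is.null(rep_fit)) {
      n_failed <- n_failed + 1L
      next
    }
    pi_reps[b] <- rep_fit$pi
    params[[b]] <- list(pi = rep_fit$pi, g = rep_fit$g)
    if (!is.null(pred_cfg)) {
      k_reps[b] <- predict_num_significant(rep_fit, data, pred_cfg)
      # a simulated future observed count: adds the binomial sampling
      # noise of an actual study on top of the estimation noise of the
      # refit (scaled from the m SNPs at hand to m_star)
      y_f <- simulate_from_fit(rep_fit, v_star,
                               derive_seed(seed, paste0("boot", b, "_future")))
      count_reps[b] <- sum(abs(as.numeric(y_f)) / sqrt(v_star) >= z_c) *
        pred_cfg$m_star / length(v_star)
    }
  }
  if (n_failed > 0.2 * n_boot) {
    stop(n_failed, " of ", n_boot, " bootstrap replicates failed to fit",
         call. = FALSE)
  }
  if (n_failed > 0) {
    message(n_failed, " bootstrap replicate(s) failed and were dropped")
  }
  ok <- !is.na(pi_reps)
  list(pi_reps = pi_reps[ok],
       k_reps = if (is.null(k_reps)) NULL else k_reps[ok],
       count_reps = if (is.null(count_reps)) NULL else count_reps[ok],
       params = params[ok], n_failed = n_failed)
}

.bootstrap_result <- function(run, n_boot, seed, level = NULL, k_hat = NULL) {
  structure(list(
    n_boot = as.integer(n_boot),
    n_used = length(run$pi_reps),
    n_failed = run$n_failed,
    pi_replicates = run$pi_reps,
    k_replicates = run$k_reps,
    pi_se = sd(run$pi_reps),
    k_ci = if (!is.null(run$k_reps) && !is.null(level)) {
      percentile_interval(run$k_reps, level)
    } else NULL,
    # bias-corrected prediction interval for an observed future count:
    # basic (reflected) interval of simulated counts around the point
    # prediction.  Reflection cancels the first-order bias the replicates
    # inherit from refitting a fitted model; the simulated counts carry
    # the future study's own sampling noise.
    k_prediction_interval = if (!is.null(run$count_reps) && !is.null(level) &&
                                  !is.null(k_hat)) {
      pmax(0, 2 * k_hat - rev(percentile_interval(run$count_reps, level)))
    } else NULL,
    k_hat = k_hat,
    count_replicates = run$count_reps,
    level = level,
    replicate_params = run$params,
    seed = as.integer(seed),
    warm_start = TRUE
  ), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Parametric bootstrap: %d replicates (%d failed), master seed %d\n",
              x$n_boot, x$n_failed, x$seed))
  cat(sprintf("  SE(pi) = %.4g\n", x$pi_se))
  if (!is.null(x$k_ci)) {
    cat(sprintf("  %g%% CI for predicted significant SNPs: [%.4g, %.4g]\n",
                100 * x$level, x$k_ci[1], x$k_ci[2]))
  }
  invisible(x)
}

#' Bootstrap standard error of the non-null proportion
#'
#' Repeats simulate-from-the-fit / refit `n_boot` times (default 100) using
#' the original per-SNP variances and reports the sample standard deviation
#' of the replicate `pi` estimates.  Replicate EMs are warm-started at the
#' original fit, which is recorded in the result; replicates whose EM
#' errors out are dropped and counted, and more than 20% failures is an
#' error.
#'
#' @param fit the original `sphmm_fit`.
#' @param data the fitted `pruned_set` (supplies the variances).
#' @param em_cfg the [em_config()] for refits.
#' @param n_boot number of replicates (>= 2).
#' @param seed master seed; every replicate seed derives from it.
#' @return a `bootstrap_result` with `pi_replicates` and `pi_se`.
#' @export
bootstrap_pi_se <- function(fit, data, em_cfg = fit$config, n_boot = 100L,
                            seed = 1L) {
  stopifnot(n_boot >= 2)
  run <- .bootstrap_run(fit, data, em_cfg, pred_cfg = NULL, n_boot, seed)
  .bootstrap_result(run, n_boot, seed)
}

#' Bootstrap confidence interval for the predicted number of discoveries
#'
#' As [bootstrap_pi_se()], but each replicate fit is pushed through
#' [predict_num_significant()] under `pred_cfg`; `k_ci` is the simple
#' percentile interval of the replicate predictions.  Each replicate also
#' simulates one future observed count from its refit (estimation noise
#' plus the future study's binomial sampling noise); the basic (reflected)
#' interval of those counts around the point prediction is returned as
#' `k_prediction_interval`.  The reflection cancels, to first order, the
#' upward bias that replicate refits inherit from simulating out of an
#' already-fitted model, so this is the interval to compare an actually
#' observed count against.
#'
#' @inheritParams bootstrap_pi_se
#' @param pred_cfg a [prediction_config()].
#' @param level confidence level (default 0.95).
#' @return a `bootstrap_result` with `k_replicates`, `k_ci`,
#'   `count_replicates`, `k_prediction_interval` (and the per-replicate
#'   `(pi, g)` in `replicate_params`, reusable for discovery-curve bands).
#' @export
bootstrap_k_ci <- function(fit, data, em_cfg = fit$config, pred_cfg,
                           n_boot = 100L, level = 0.95, seed = 1L) {
  stopifnot(n_boot >= 2, level > 0, level < 1)
  run <- .bootstrap_run(fit, data, em_cfg, pred_cfg, n_boot, seed)
  .bootstrap_result(run, n_boot, seed, level,
                    k_hat = predict_num_significant(fit, data, pred_cfg))
}
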