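#' Two-sided rejection threshold
#'
#' The standard-normal quantile `z_c` such that `|Z| >= z_c` has
#' probability `p_c` under the null: `z_c = qnorm(1 - p_c / 2)`, computed
#' through the upper tail for accuracy at genome-wide levels.
#'
#' @param p_c two-sided significance level in (0, 1\].
#' @return the threshold `z_c` (0 when `p_c = 1`).
#' @export
#' @examples
#' rejection_threshold(5e-8)  # about 5.4513
rejection_threshold <- function(p_c) {
  if (any(!is.finite(p_c)) || any(p_c <= 0) || any(p_c > 1)) {
    stop("p_c must lie in (0, 1]", call. = FALSE)
  }
  qnorm(p_c / 2, lower.tail = FALSE)
}

#' Power of the per-SNP Wald test
#'
#' Probability that a SNP with true log odds ratio `beta` and estimation
#' variance `v` is declared significant at threshold `z_c`: the Wald
#' statistic is normal with mean `beta / sqrt(v)` and unit variance, and
#' both tails count.  At `beta = 0` this returns the size of the test,
#' i.e. exactly the `p_c` from which `z_c` was derived.
#'
#' @param beta true log odds ratio(s).
#' @param v estimation variance(s), > 0.
#' @param z_c rejection threshold from [rejection_threshold()].
#' @return rejection probability in \[0, 1\].
#' @export
detection_power <- function(beta, v, z_c) {
  if (any(!is.finite(v)) || any(v <= 0)) stop("variance must be positive", call. = FALSE)
  mu <- beta / sqrt(v)
  pnorm(-z_c - mu) + pnorm(z_c - mu, lower.tail = FALSE)
}

#' Rescale a variance to a different study size
#'
#' The empirical variance of a log odds ratio estimate is approximately
#' proportional to `1/n_cases + 1/n_controls`, so a variance observed in a
#' current study transfers to a future study by the ratio of those sums.
#'
#' @param v variance(s) from the current study.
#' @param n_r,n_s current case and control counts.
#' @param n_r_star,n_s_star future case and control counts.
#' @return rescaled variance(s).
#' @export
rescale_variance <- function(v, n_r, n_s, n_r_star, n_s_star) {
  stopifnot(n_r >= 1, n_s >= 1, n_r_star >= 1, n_s_star >= 1)
  if (any(v <= 0)) stop("variance must be positive", call. = FALSE)
  v * (1 / n_r_star + 1 / n_s_star) / (1 / n_r + 1 / n_s)
}

#' Effective number of cases
#'
#' Since only `1/n_r + 1/n_s` enters the power calculation, an unbalanced
#' design is equivalent to a balanced one with `n_e = 2 / (1/n_r + 1/n_s)`
#' cases and as many controls (the harmonic mean of the two arms).
#'
#' @param n_r_star,n_s_star case and control counts.
#' @return the effective number of cases.
#' @export
#' @examples
#' effective_cases(100, 300)  # 150
effective_cases <- function(n_r_star, n_s_star) {
  stopifnot(n_r_star >= 1, n_s_star >= 1)
  2 / (1 / n_r_star + 1 / n_s_star)
}

#' Prediction configuration
#'
#' @param p_c significance level (default the genome-wide significant
#'   threshold `5e-8`; `1e-6` is the customary suggestive level).
#' @param m_star number of independent SNPs assumed in the future study
#'   (default 100000, the typical size of an LD-pruned genome-wide set).
#' @param n_r,n_s case/control counts of the study the model was fitted to.
#' @param n_r_star,n_s_star case/control counts of the future study.
#' @export
prediction_config <- function(p_c = 5e-8, m_star = 100000L,
                              n_r, n_s, n_r_star, n_s_star) {
  stopifnot(p_c > 0, p_c < 1, m_star >= 1,
            n_r >= 1, n_s >= 1, n_r_star >= 1, n_s_star >= 1)
  structure(list(p_c = p_c, m_star = m_star, n_r = n_r, n_s = n_s,
                 n_r_star = n_r_star, n_s_star = n_s_star),
            class = "prediction_config")
}

#' Per-SNP rejection probability under a fitted model
#'
#' Marginal probability that a SNP is significant in a study where its
#' estimation variance is `v_star`: the null component contributes the test
#' size, the non-null component the power averaged over the discrete
#' effect-size distribution (the integral over g collapses to an exact
#' finite sum).
#'
#' @param v_star variance(s) at the target study size.
#' @param fit an `sphmm_fit` (or any list with elements `pi` and `g`).
#' @param z_c rejection threshold.
#' @return probability/probabilities of significance.
#' @export
rejection_probability <- function(v_star, fit, z_c) {
  if (any(!is.finite(v_star)) || any(v_star <= 0)) {
    stop("variance must be positive", call. = FALSE)
  }
  pw <- 0
  pts <- fit$g$points
  ms <- fit$g$masses
  # components with essentially no mass cannot move the sum by more than
  # B * 1e-15; skipping them keeps the cost proportional to the support
  active <- which(ms > 1e-15)
  for (k in active) {
    pw <- pw + ms[k] * detection_power(pts[k], v_star, z_c)
  }
  (1 - fit$pi) * detection_power(0, v_star, z_c) + fit$pi * pw
}

#' Predicted number of significant SNPs in a future study
#'
#' `K = m_star x mean_j P_j`, where `P_j` is the rejection probability of
#' SNP j with its variance rescaled from the current to the future study
#' size.  The SNP set supplying the variances should be the set the model
#' was fitted to.
#'
#' @param fit an `sphmm_fit`.
#' @param data the fitted `pruned_set` (or `summary_table`).
#' @param cfg a [prediction_config()].
#' @return the expected count (not rounded).
#' @export
predict_num_significant <- function(fit, data, cfg) {
  d <- .extract_yv(data)
  v_star <- rescale_variance(d$v, cfg$n_r, cfg$n_s, cfg$n_r_star, cfg$n_s_star)
  z_c <- rejection_threshold(cfg$p_c)
  cfg$m_star * mean(rejection_probability(v_star, fit, z_c))
}

#' Discovery curve: expected significant SNPs versus study size
#'
#' Evaluates the predicted number of significant SNPs over a grid of
#' effective case numbers.  A balanced future design is assumed (only
#' `1/n_r + 1/n_s` matters, so any case:control ratio with the same
#' effective size gives the same curve).  If `replicate_fits` (e.g. the
#' `replicate_params` of a bootstrap result) is supplied, pointwise
#' percentile confidence bands are added.
#'
#' @param fit an `sphmm_fit`.
#' @param data the fitted `pruned_set`.
#' @param cfg a [prediction_config()]; its `n_r_star`/`n_s_star` are
#'   ignored in favour of the grid.
#' @param n_e_grid strictly increasing effective case numbers.
#' @param replicate_fits optional list of `list(pi =, g =)` replicates.
#' @param level confidence level for the optional bands.
#' @return a data frame of class `discovery_curve` with columns `n_e_star`,
#'   `k_hat` and optionally `ci_low`, `ci_high`.
#' @export
discovery_curve <- function(fit, data, cfg, n_e_grid,
                            replicate_fits = NULL, level = 0.95) {
  if (is.unsorted(n_e_grid, strictly = TRUE)) {
    stop("n_e_grid must be strictly increasing", call. = FALSE)
  }
  d <- .extract_yv(data)
  z_c <- rejection_threshold(cfg$p_c)
  cur <- 1 / cfg$n_r + 1 / cfg$n_s
  k_at <- function(f, n_e) {
    v_star <- d$v * (2 / n_e) / cur
    cfg$m_star * mean(rejection_probability(v_star, f, z_c))
  }
  k_hat <- vapply(n_e_grid, function(n_e) k_at(fit, n_e), numeric(1))
  out <- data.frame(n_e_star = n_e_grid, k_hat = k_hat)
  if (!is.null(replicate_fits)) {
    reps <- vapply(n_e_grid, function(n_e) {
      ks <- vapply(replicate_fits, function(f) k_at(f, n_e), numeric(1))
      percentile_interval(ks, level)
    }, numeric(2))
    out$ci_low <- reps[1, ]
    out$ci_high <- reps[2, ]
  }
  class(out) <- c("discovery_curve", "data.frame")
  out
}

#' @export
plot.discovery_curve <- function(x, log = "", ...) {
  graphics::plot(x$n_e_star, x$k_hat, type = "l", lwd = 2, log = log,
                 xlab = "effective number of cases",
                 ylab = "predicted significant SNPs", ...)
  if (!is.null(x$ci_low)) {
    graphics::lines(x$n_e_star, x$ci_low, lty = 2)
    graphics::lines(x$n_e_star, x$ci_high, lty = 2)
  }
  invisible(x)
}

#' Effective cases required for a target number of discoveries
#'
#' Inverts the (monotone) discovery curve by bisection: the smallest
#' effective number of cases at which the predicted count reaches
#' `k_target`, reported rounded up to `rounding` (default 1000, matching
#' how such requirements are usually quoted).  The bisection resolves the
#' unrounded crossing to within one effective case.
#'
#' @param fit an `sphmm_fit`.
#' @param data the fitted `pruned_set`.
#' @param cfg a [prediction_config()].
#' @param k_target target number of significant SNPs (>= 1 typically).
#' @param rounding reporting unit; use 1 for the raw crossing.
#' @param ceiling_n search ceiling; if the target is unachievable below it,
#'   the ceiling is returned with a warning.
#' @return required effective cases (a multiple of `rounding`), with the
#'   rounding unit attached as attribute `rounding`.
#' @export
required_effective_cases <- function(fit, data, cfg, k_target,
                                     rounding = 1000, ceiling_n = 1e7) {
  stopifnot(k_target > 0, rounding >= 1, ceiling_n > rounding)
  d <- .extract_yv(data)
  z_c <- rejection_threshold(cfg$p_c)
  cur <- 1 / cfg$n_r + 1 / cfg$n_s
  k_at <- function(n_e) {
    v_star <- d$v * (2 / n_e) / cur
    cfg$m_star * mean(rejection_probability(v_star, fit, z_c))
  }
  lo <- 2
  if (k_at(ceiling_n) < k_target) {
    warning("target of ", k_target, " discoveries not achievable below ",
            format(ceiling_n, scientific = FALSE), " effective cases; ",
            "returning the ceiling", call. = FALSE)
    return(structure(ceiling_n, rounding = rounding, capped = TRUE))
  }
  if (k_at(lo) >= k_target) {
    return(structure(rounding * ceiling(lo / rounding), rounding = rounding))
  }
  hi <- ceiling_n
  while (hi - lo > 1) {
    mid <- (hi + lo) / 2
    if (k_at(mid) >= k_target) hi <- mid else lo <- mid
  }
  structure(rounding * ceiling(hi / rounding), rounding = rounding)
}

#' Percentile interval from replicate values
#'
#' Order-statistic percentile interval: with `n` replicates and confidence
#' `level`, the lower bound is the `ceiling((n + 1) * (1 - level) / 2)`-th
#' smallest value and the upper bound its mirror image (for `n = 100`,
#' `level = 0.95`: the 3rd and 98th smallest).
#'
#' @param x numeric replicate values.
#' @param level confidence level in (0, 1).
#' @return length-2 numeric vector (lower, upper).
#' @export
percentile_interval <- function(x, level = 0.95) {
  stopifnot(level > 0, level < 1, length(x) >= 2)
  n <- length(x)
  xs <- sort(x)
  k_lo <- min(max(ceiling((n + 1) * (1 - level) / 2), 1L), n)
  k_hi <- max(n + 1 - k_lo, 1L)
  c(xs[k_lo], xs[k_hi])
}
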