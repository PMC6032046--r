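#' Define a synthetic GWAS scenario
#'
#' A scenario fixes everything the generator needs: the SNP count, the true
#' non-null proportion and effect-size distribution, case/control sizes, a
#' minor-allele-frequency model, and a seed.  The generated data have
#' exactly the statistical structure the mixture model assumes, so
#' parameter-recovery and calibration experiments have a well-defined
#' target.
#'
#' @param m number of SNPs.
#' @param pi_true true non-null proportion in \[0, 1\].
#' @param g_true an [effect_distribution()] (non-null effects are drawn
#'   from it exactly at its support, no jitter).
#' @param n_r,n_s case and control counts.
#' @param maf_model allele-frequency model; currently
#'   `list(dist = "uniform", min =, max =)` with default U(0.05, 0.5), a
#'   common-variant spectrum.
#' @param seed master seed; all generator stages derive sub-seeds from it.
#' @export
synthetic_scenario <- function(m, pi_true, g_true, n_r, n_s,
                               maf_model = list(dist = "uniform",
                                                min = 0.05, max = 0.5),
                               seed = 1L) {
  stopifnot(m >= 1, pi_true >= 0, pi_true <= 1, n_r >= 1, n_s >= 1,
            inherits(g_true, "effect_dist"))
  if (!identical(maf_model$dist, "uniform")) {
    stop("only the uniform maf_model is implemented", call. = FALSE)
  }
  if (!(maf_model$min > 0 && maf_model$max <= 0.5 &&
        maf_model$min < maf_model$max)) {
    stop("maf_model bounds must satisfy 0 < min < max <= 0.5", call. = FALSE)
  }
  structure(list(m = as.integer(m), pi_true = pi_true, g_true = g_true,
                 n_r = as.integer(n_r), n_s = as.integer(n_s),
                 maf_model = maf_model, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Draw per-SNP estimation variances
#'
#' Uses the asymptotic allele-count log odds ratio variance
#' `V_j = (1 / (2 f_j (1 - f_j))) * (1/n_r + 1/n_s)` with allele
#' frequencies `f_j` from the scenario's MAF model -- proportional to the
#' sum of inverse arm sizes, as the variance-rescaling step assumes.
#'
#' @param scenario a [synthetic_scenario()].
#' @return numeric vector of variances with the drawn frequencies attached
#'   as attribute `maf`.
#' @export
draw_variances <- function(scenario) {
  f <- with_local_seed(derive_seed(scenario$seed, "maf"), {
    runif(scenario$m, scenario$maf_model$min, scenario$maf_model$max)
  })
  if (any(f <= 0 | f >= 1)) stop("maf model produced f outside (0, 1)", call. = FALSE)
  v <- (1 / (2 * f * (1 - f))) * (1 / scenario$n_r + 1 / scenario$n_s)
  structure(v, maf = f)
}

#' Draw the latent truth layer
#'
#' Independent Bernoulli(`pi_true`) non-null labels; non-null effects drawn
#' i.i.d. from `g_true`, null effects exactly zero.
#'
#' @param scenario a [synthetic_scenario()].
#' @return data frame with columns `snp_id`, `is_nonnull`, `beta_true`.
#' @export
draw_truth <- function(scenario) {
  m <- scenario$m
  with_local_seed(derive_seed(scenario$seed, "truth"), {
    nonnull <- runif(m) < scenario$pi_true
    beta <- numeric(m)
    if (any(nonnull)) {
      beta[nonnull] <- sample(scenario$g_true$points, sum(nonnull),
                              replace = TRUE, prob = scenario$g_true$masses)
    }
    data.frame(snp_id = sprintf("snp%07d", seq_len(m)),
               is_nonnull = nonnull, beta_true = beta,
               stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic summary-statistics dataset
#'
#' Composes the variance, truth and observation layers:
#' `Y_j = beta_true_j + sqrt(V_j) * eps_j` with standard-normal noise.  The
#' result carries the truth sidecar for recovery experiments, and its table
#' round-trips through [write_summary_table()] / [read_summary_table()].
#'
#' @param scenario a [synthetic_scenario()].
#' @return an object of class `synthetic_dataset`: `table` (a
#'   [summary_table()]), `truth`, `scenario`.
#' @export
simulate_dataset <- function(scenario) {
  v <- draw_variances(scenario)
  truth <- draw_truth(scenario)
  eps <- with_local_seed(derive_seed(scenario$seed, "noise"), {
    rnorm(scenario$m)
  })
  y <- truth$beta_true + sqrt(as.numeric(v)) * eps
  z <- y / sqrt(as.numeric(v))
  rec <- data.frame(
    snp_id = truth$snp_id,
    effect_allele = "A", other_allele = "G",
    beta_hat = y, var_hat = as.numeric(v),
    p_value = 2 * pnorm(-abs(z)),
    maf = attr(v, "maf"),
    stringsAsFactors = FALSE
  )
  tab <- summary_table(rec, scenario$n_r, scenario$n_s,
                       provenance = sprintf("synthetic(pi=%g, m=%d, seed=%d)",
                                            scenario$pi_true, scenario$m,
                                            scenario$seed))
  structure(list(table = tab, truth = truth, scenario = scenario),
            class = "synthetic_dataset")
}

#' Write a summary table as tab-delimited text
#'
#' Numeric columns are written with full round-trip precision (`%.17g`),
#' with header names understood by [read_summary_table()]'s default
#' conventions (SNP, A1, A2, BETA, VAR, P, FRQ).
#'
#' @param table a [summary_table()].
#' @param path output path.
#' @return the column map needed to read the file back, invisibly.
#' @export
write_summary_table <- function(table, path) {
  df <- as.data.frame(table)
  out <- data.frame(SNP = df$snp_id, A1 = df$effect_allele,
                    A2 = df$other_allele,
                    BETA = sprintf("%.17g", df$beta_hat),
                    VAR = sprintf("%.17g", df$var_hat),
                    stringsAsFactors = FALSE)
  cmap <- c(snp = "SNP", effect_allele = "A1", other_allele = "A2",
            beta = "BETA", var = "VAR")
  if ("p_value" %in% names(df)) {
    out$P <- sprintf("%.17g", df$p_value)
    cmap <- c(cmap, p = "P")
  }
  if ("maf" %in% names(df)) {
    out$FRQ <- sprintf("%.17g", df$maf)
    cmap <- c(cmap, maf = "FRQ")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cmap)
}

#' Block-structured LD fixture
#'
#' SNP ids arranged in cliques: every pair within a block shares the same
#' r2, pairs across blocks are absent (independent).  Pruning such a table
#' at a threshold below `within_r2` must retain exactly one SNP per block.
#'
#' @param n_blocks number of blocks.
#' @param block_size SNPs per block.
#' @param within_r2 r2 shared by within-block pairs.
#' @param seed permutes the id order (the clique structure itself is
#'   deterministic).
#' @return `list(ld = ld_table, ids = character vector, block = integer
#'   vector mapping each id to its block)`.
#' @export
make_block_ld <- function(n_blocks, block_size, within_r2, seed = 1L) {
  stopifnot(n_blocks >= 1, block_size >= 1, within_r2 >= 0, within_r2 <= 1)
  ids <- character(0)
  block <- integer(0)
  pa <- character(0); pb <- character(0)
  for (blk in seq_len(n_blocks)) {
    bids <- sprintf("blk%03d_snp%02d", blk, seq_len(block_size))
    ids <- c(ids, bids)
    block <- c(block, rep(blk, block_size))
    if (block_size > 1) {
      cmb <- utils::combn(bids, 2)
      pa <- c(pa, cmb[1, ])
      pb <- c(pb, cmb[2, ])
    }
  }
  ord <- with_local_seed(seed, sample.int(length(ids)))
  pairs <- data.frame(id_a = pa, id_b = pb,
                      r2 = rep(within_r2, length(pa)),
                      stringsAsFactors = FALSE)
  list(ld = ld_table(pairs), ids = ids[ord], block = block[ord])
}

#' Read a scenario definition from a YAML file
#'
#' Keys mirror the [synthetic_scenario()] arguments; `g_true` is given
#' either as `{points: [...], masses: [...]}` or as
#' `{type: point_mass, at: [...], weights: [...]}` resolved against the
#' default grid (or a `grid: {b_min, b_max, step}` override).
#'
#' @param path YAML file path.
#' @return a [synthetic_scenario()].
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  grid <- if (!is.null(cfg$grid)) {
    make_grid(cfg$grid$b_min, cfg$grid$b_max, cfg$grid$step)
  } else {
    make_grid()
  }
  g <- if (!is.null(cfg$g_true$points)) {
    effect_distribution(cfg$g_true$points, cfg$g_true$masses)
  } else if (identical(cfg$g_true$type, "point_mass")) {
    point_mass_distribution(grid, unlist(cfg$g_true$at),
                            if (is.null(cfg$g_true$weights)) NULL
                            else unlist(cfg$g_true$weights))
  } else {
    stop("unrecognized g_true specification", call. = FALSE)
  }
  maf <- if (is.null(cfg$maf_model)) {
    list(dist = "uniform", min = 0.05, max = 0.5)
  } else {
    cfg$maf_model
  }
  synthetic_scenario(m = cfg$m, pi_true = cfg$pi_true, g_true = g,
                     n_r = cfg$n_r, n_s = cfg$n_s, maf_model = maf,
                     seed = if (is.null(cfg$seed)) 1L else cfg$seed)
}
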