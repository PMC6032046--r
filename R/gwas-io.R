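#' Construct a summary-statistics table
#'
#' The observable layer of the model: one row per SNP with the estimated
#' log odds ratio under the additive allele-dosage model (`beta_hat`), its
#' variance (`var_hat`), alleles, and optional p-value and allele
#' frequency, together with the study's case and control counts.
#'
#' @param records data frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta_hat`, `var_hat` and optionally `p_value`, `maf`.
#' @param n_cases,n_controls case and control sample sizes (>= 1).
#' @param provenance free-text label (source file, consortium, scenario).
#' @return an object of class `summary_table` (a data frame carrying
#'   `n_cases`, `n_controls` and `provenance` as attributes).
#' @export
summary_table <- function(records, n_cases, n_controls, provenance = "") {
  stopifnot(is.data.frame(records))
  need <- c("snp_id", "effect_allele", "other_allele", "beta_hat", "var_hat")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (n_cases < 1 || n_controls < 1) stop("sample sizes must be >= 1", call. = FALSE)
  if (anyDuplicated(records$snp_id)) stop("snp_id must be unique", call. = FALSE)
  if (any(!is.finite(records$beta_hat))) stop("beta_hat must be finite", call. = FALSE)
  if (any(!is.finite(records$var_hat)) || any(records$var_hat <= 0)) {
    stop("var_hat must be positive and finite", call. = FALSE)
  }
  if (any(records$effect_allele == records$other_allele)) {
    stop("effect and other allele must differ", call. = FALSE)
  }
  rownames(records) <- NULL
  structure(records, class = c("summary_table", "data.frame"),
            n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
            provenance = provenance)
}

# subset rows preserving summary_table attributes
.st_subset <- function(tab, keep) {
  out <- as.data.frame(tab)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("summary_table", "data.frame"),
            n_cases = attr(tab, "n_cases"), n_controls = attr(tab, "n_controls"),
            provenance = attr(tab, "provenance"),
            drop_report = attr(tab, "drop_report"))
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("GWAS summary table: %d SNPs, %d cases / %d controls  [%s]\n",
              nrow(x), attr(x, "n_cases"), attr(x, "n_controls"),
              attr(x, "provenance")))
  rep <- attr(x, "drop_report")
  if (!is.null(rep) && rep$n_dropped > 0) {
    cat(sprintf("  (%d input rows dropped: %s)\n", rep$n_dropped,
                paste(sprintf("%s=%d", names(rep$reasons), unlist(rep$reasons)),
                      collapse = ", ")))
  }
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Drop report of a table
#'
#' Filtering and harmonization steps drop rows that violate invariants and
#' record why; this accessor returns the accumulated counts.
#'
#' @param table a `summary_table`.
#' @return a list with `n_input`, `n_dropped` and per-reason `reasons`.
#' @export
drop_report <- function(table) {
  rep <- attr(table, "drop_report")
  if (is.null(rep)) list(n_input = nrow(table), n_dropped = 0L, reasons = list()) else rep
}

.make_report <- function(n_input, reasons) {
  reasons <- reasons[vapply(reasons, function(x) x > 0, logical(1))]
  list(n_input = as.integer(n_input),
       n_dropped = as.integer(sum(unlist(reasons), 0)),
       reasons = lapply(reasons, as.integer))
}

# guess the field separator of a delimited text file from its header line
.sniff_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

#' Read GWAS summary statistics from delimited text
#'
#' Consortium files differ in headers and in which uncertainty column they
#' publish, so the reader takes an explicit column map.  The effect column
#' may be a log odds ratio (`beta`) or an odds ratio (`or`, converted by
#' natural log).  Variance is taken from the least derived source
#' available: a variance column, else a standard error (squared), else
#' back-calculated from the p-value as `(beta / z)^2` with `z` the
#' two-sided standard-normal quantile of `p`.  Rows violating the record
#' invariants (non-positive or non-finite variance, non-finite beta, equal
#' alleles, duplicated id, or an undefined p-derived variance when `p` is 0
#' or `beta` is 0) are dropped and counted in the table's [drop_report()].
#'
#' @param path file path; tab-, comma- or whitespace-delimited with header.
#' @param column_map named character vector mapping roles to file columns.
#'   Mandatory roles: `snp`, `effect_allele`, `other_allele`, and `beta` or
#'   `or`; at least one of `var`, `se`, `p`.  Optional: `maf`.
#' @param n_cases,n_controls study sample sizes.
#' @param provenance label stored with the table; defaults to the path.
#' @return a [summary_table()].
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tA1\tA2\tOR\tSE",
#'              "rs1\tA\tG\t1.05\t0.02",
#'              "rs2\tC\tT\t0.98\t0.015"), tf)
#' tab <- read_summary_table(tf, c(snp = "SNP", effect_allele = "A1",
#'                                 other_allele = "A2", or = "OR", se = "SE"),
#'                           n_cases = 9240, n_controls = 9519)
read_summary_table <- function(path, column_map, n_cases, n_controls,
                               provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  column_map <- unlist(column_map)
  raw <- read.table(path, header = TRUE, sep = .sniff_sep(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", quote = "\"")
  need <- c("snp", "effect_allele", "other_allele")
  if (!all(need %in% names(column_map)) ||
      !any(c("beta", "or") %in% names(column_map)) ||
      !any(c("var", "se", "p") %in% names(column_map))) {
    stop("column_map must name snp, effect_allele, other_allele, beta|or, ",
         "and at least one of var/se/p", call. = FALSE)
  }
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols) > 0) {
    stop("columns not found in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  col <- function(role) if (role %in% names(column_map)) raw[[column_map[[role]]]] else NULL

  snp_id <- as.character(col("snp"))
  ea <- toupper(as.character(col("effect_allele")))
  oa <- toupper(as.character(col("other_allele")))
  beta <- if (!is.null(col("beta"))) as.numeric(col("beta")) else log(as.numeric(col("or")))

  reasons <- list(invalid_beta = 0L, invalid_variance = 0L,
                  undefined_p_variance = 0L, allele_conflict = 0L,
                  duplicate_id = 0L)
  n_input <- nrow(raw)

  # variance precedence: var > se > p-derived (least derived wins)
  undef_p <- rep(FALSE, n_input)
  if (!is.null(col("var"))) {
    var_hat <- as.numeric(col("var"))
  } else if (!is.null(col("se"))) {
    var_hat <- as.numeric(col("se"))^2
  } else {
    pval <- as.numeric(col("p"))
    undef_p <- !is.finite(pval) | pval <= 0 | pval > 1 | beta == 0
    z <- qnorm(pval / 2, lower.tail = FALSE)
    var_hat <- ifelse(undef_p, NA_real_, (beta / z)^2)
  }

  bad_beta <- !is.finite(beta)
  undef_p <- undef_p & !bad_beta
  bad_var <- !bad_beta & !undef_p &
    (is.na(var_hat) | !is.finite(var_hat) | var_hat <= 0)
  bad_allele <- !bad_beta & !undef_p & !bad_var &
    (is.na(ea) | is.na(oa) | ea == oa)
  keep <- !(bad_beta | undef_p | bad_var | bad_allele)
  dup <- duplicated(snp_id) & keep
  keep <- keep & !dup
  reasons$invalid_beta <- sum(bad_beta)
  reasons$undefined_p_variance <- sum(undef_p)
  reasons$invalid_variance <- sum(bad_var)
  reasons$allele_conflict <- sum(bad_allele)
  reasons$duplicate_id <- sum(dup)

  if (!any(keep)) stop("no usable rows in ", path, call. = FALSE)

  rec <- data.frame(snp_id = snp_id[keep], effect_allele = ea[keep],
                    other_allele = oa[keep], beta_hat = beta[keep],
                    var_hat = var_hat[keep], stringsAsFactors = FALSE)
  if (!is.null(col("p"))) rec$p_value <- as.numeric(col("p"))[keep]
  if (!is.null(col("maf"))) rec$maf <- as.numeric(col("maf"))[keep]

  out <- summary_table(rec, n_cases, n_controls, provenance)
  attr(out, "drop_report") <- .make_report(n_input, reasons)
  out
}

#' Orient effects to the derived allele
#'
#' Re-signs `beta_hat` so that the effect allele of every record is the
#' derived allele.  Records whose allele pair is inconsistent with the map
#' (neither orientation matches) or absent from it are dropped and counted;
#' ambiguous-strand SNPs are resolved only through the explicit map, never
#' by frequency matching.  Applying the operation twice is a no-op.
#'
#' @param table a [summary_table()].
#' @param allele_map data frame with columns `snp_id`, `ancestral`,
#'   `derived` (see [read_allele_map()]).
#' @return the harmonized `summary_table`.
#' @export
harmonize_to_derived <- function(table, allele_map) {
  stopifnot(is.data.frame(allele_map),
            all(c("snp_id", "ancestral", "derived") %in% names(allele_map)))
  idx <- match(table$snp_id, allele_map$snp_id)
  anc <- toupper(allele_map$ancestral[idx])
  der <- toupper(allele_map$derived[idx])
  ok_fwd <- !is.na(idx) & table$effect_allele == der & table$other_allele == anc
  ok_rev <- !is.na(idx) & table$effect_allele == anc & table$other_allele == der
  keep <- ok_fwd | ok_rev
  if (!any(keep)) {
    stop("no SNPs consistent with the allele map; nothing to harmonize",
         call. = FALSE)
  }
  out <- as.data.frame(table)
  flip <- which(ok_rev)
  out$beta_hat[flip] <- -out$beta_hat[flip]
  tmp <- out$effect_allele[flip]
  out$effect_allele[flip] <- out$other_allele[flip]
  out$other_allele[flip] <- tmp

  prev <- drop_report(table)
  res <- summary_table(out[keep, , drop = FALSE], attr(table, "n_cases"),
                       attr(table, "n_controls"), attr(table, "provenance"))
  reasons <- c(prev$reasons, list(allele_map_mismatch = sum(!keep)))
  attr(res, "drop_report") <- .make_report(prev$n_input, reasons)
  res
}

#' Restrict a table to a reference SNP panel
#'
#' Keeps only SNPs present in a reference panel id list (e.g. a HapMap 3
#' style panel restricting analysis to well-imputed variants), preserving
#' input order.
#'
#' @param table a [summary_table()].
#' @param panel_ids character vector of SNP ids.
#' @return the filtered `summary_table`; errors if the result is empty.
#' @export
filter_to_panel <- function(table, panel_ids) {
  keep <- table$snp_id %in% panel_ids
  if (!any(keep)) stop("no SNPs overlap the panel", call. = FALSE)
  prev <- drop_report(table)
  res <- .st_subset(table, keep)
  reasons <- c(prev$reasons, list(not_on_panel = sum(!keep)))
  attr(res, "drop_report") <- .make_report(prev$n_input, reasons)
  res
}

#' Pairwise LD table
#'
#' Symmetric r-squared values between SNP pairs.  A pair absent from the
#' table is treated as independent (r2 effectively 0): LD sources typically
#' report only pairs above some floor, so unknown pairs are kept by the
#' pruning step.
#'
#' @param pairs data frame with columns `id_a`, `id_b`, `r2`.
#' @return an object of class `ld_table`.
#' @export
ld_table <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0) {
    pairs <- data.frame(id_a = character(), id_b = character(), r2 = numeric())
  }
  if (!all(c("id_a", "id_b", "r2") %in% names(pairs))) {
    stop("pairs must have columns id_a, id_b, r2", call. = FALSE)
  }
  if (any(!is.finite(pairs$r2)) || any(pairs$r2 < 0) || any(pairs$r2 > 1)) {
    stop("r2 must lie in [0, 1]", call. = FALSE)
  }
  if (any(pairs$id_a == pairs$id_b)) stop("self-pairs are not allowed", call. = FALSE)
  structure(pairs[, c("id_a", "id_b", "r2")], class = c("ld_table", "data.frame"))
}

#' Read a pairwise LD table from delimited text
#'
#' Accepts a plain 3-column file (`id_a`, `id_b`, `r2`, with or without
#' header) and the common whitespace-separated pairwise-LD report dialect
#' whose header contains `SNP_A`, `SNP_B` and `R2` among other columns.
#'
#' @param path file path.
#' @return an [ld_table()].
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  toks <- strsplit(trimws(first), if (sep == "") "[[:space:]]+" else sep)[[1]]
  up <- toupper(toks)
  if (all(c("SNP_A", "SNP_B", "R2") %in% up)) {
    raw <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                      check.names = FALSE)
    names(raw) <- toupper(names(raw))
    pairs <- data.frame(id_a = as.character(raw$SNP_A),
                        id_b = as.character(raw$SNP_B),
                        r2 = as.numeric(raw$R2), stringsAsFactors = FALSE)
  } else {
    header <- is.na(suppressWarnings(as.numeric(toks[3])))
    raw <- read.table(path, header = header, sep = sep, stringsAsFactors = FALSE)
    pairs <- data.frame(id_a = as.character(raw[[1]]),
                        id_b = as.character(raw[[2]]),
                        r2 = as.numeric(raw[[3]]), stringsAsFactors = FALSE)
  }
  ld_table(pairs)
}

#' Read a SNP panel id list
#'
#' One record per line; the first whitespace- or comma-delimited token of
#' each line is taken as the id.
#'
#' @param path file path.
#' @return character vector of unique SNP ids.
#' @export
read_panel <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  unique(vapply(strsplit(lines, "[,[:space:]]+"), `[[`, character(1), 1L))
}

#' Read an ancestral/derived allele map
#'
#' Three columns: SNP id, ancestral allele, derived allele.  A header line
#' is detected by non-allele tokens in columns 2-3.
#'
#' @param path file path.
#' @return data frame with columns `snp_id`, `ancestral`, `derived`.
#' @export
read_allele_map <- function(path) {
  first <- strsplit(trimws(readLines(path, n = 1L)), "[,[:space:]]+")[[1]]
  header <- any(nchar(first[-1]) > 1)
  raw <- read.table(path, header = header, stringsAsFactors = FALSE,
                    sep = .sniff_sep(path))
  data.frame(snp_id = as.character(raw[[1]]),
             ancestral = toupper(as.character(raw[[2]])),
             derived = toupper(as.character(raw[[3]])),
             stringsAsFactors = FALSE)
}

#' Random LD pruning to a nearly independent SNP set
#'
#' Repeatedly selects one SNP uniformly at random from the remaining
#' candidates, irrespective of association strength, retains it, and
#' removes all candidates in LD with it (`r2 > r2_threshold`); this
#' continues until no candidates remain.  The selection is implemented as a
#' uniform random permutation processed in order, which draws from exactly
#' the same distribution over retained sets.  LD is treated as a global
#' graph (no chromosomal windows), and a pair absent from `ld` counts as
#' independent.  The result is deterministic given `seed`.
#'
#' @param table a [summary_table()].
#' @param ld an [ld_table()].
#' @param r2_threshold retain no pair with r2 above this (default 0.1).
#' @param seed integer seed for the random selection order.
#' @return an object of class `pruned_set`: `table` (retained records, in
#'   input order), `r2_threshold`, `seed`, `n_input`.
#' @export
ld_prune <- function(table, ld, r2_threshold = 0.1, seed = 1L) {
  stopifnot(inherits(ld, "ld_table"))
  if (!(r2_threshold > 0 && r2_threshold < 1)) {
    stop("r2_threshold must lie in (0, 1)", call. = FALSE)
  }
  ids <- table$snp_id
  m <- length(ids)
  strong <- ld[ld$r2 > r2_threshold, , drop = FALSE]
  ia <- match(strong$id_a, ids)
  ib <- match(strong$id_b, ids)
  ok <- !is.na(ia) & !is.na(ib)
  ia <- ia[ok]; ib <- ib[ok]
  adj <- split(c(ib, ia), c(ia, ib))  # symmetric adjacency, indices as names

  keep <- logical(m)
  alive <- rep(TRUE, m)
  perm <- with_local_seed(seed, sample.int(m))
  for (i in perm) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    nb <- adj[[as.character(i)]]
    if (!is.null(nb)) alive[nb] <- FALSE
  }
  structure(list(table = .st_subset(table, keep),
                 r2_threshold = r2_threshold, seed = as.integer(seed),
                 n_input = m),
            class = "pruned_set")
}

#' @export
print.pruned_set <- function(x, ...) {
  cat(sprintf("LD-pruned SNP set: %d of %d SNPs retained (r2 threshold %g, seed %d)\n",
              nrow(x$table), x$n_input, x$r2_threshold, x$seed))
  invisible(x)
}

#' Count observed significant SNPs
#'
#' Number of SNPs whose two-sided normal p-value for `beta_hat /
#' sqrt(var_hat)` reaches the significance level `p_c` (i.e. `|z| >= z_c`).
#'
#' @param pruned a `pruned_set` or [summary_table()].
#' @param p_c significance level in (0, 1\], e.g. `5e-8` (genome-wide
#'   significant) or `1e-6` (suggestive).
#' @return integer count.
#' @export
count_significant <- function(pruned, p_c) {
  if (!(p_c > 0 && p_c <= 1)) stop("p_c must lie in (0, 1]", call. = FALSE)
  tab <- if (inherits(pruned, "pruned_set")) pruned$table else pruned
  z <- abs(tab$beta_hat) / sqrt(tab$var_hat)
  sum(z >= rejection_threshold(p_c))
}
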