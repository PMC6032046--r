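write_lines_tmp <- function(lines) {
  tf <- tempfile(fileext = ".txt")
  writeLines(lines, tf)
  tf
}

test_that("reader parses delimited text and respects variance precedence", {
  tf <- write_lines_tmp(c(
    "SNP\tA1\tA2\tBETA\tVAR\tSE\tP",
    "rs1\tA\tG\t0.10\t0.0009\t0.05\t0.5",
    "rs2\tC\tT\t-0.02\t0.0004\t0.01\t0.3",
    "rs3\tG\tA\t0.00\t0.0001\t0.02\t0.9"
  ))
  tab <- read_summary_table(
    tf, c(snp = "SNP", effect_allele = "A1", other_allele = "A2",
          beta = "BETA", var = "VAR", se = "SE", p = "P"),
    n_cases = 100, n_controls = 100
  )
  expect_s3_class(tab, "summary_table")
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$var_hat > 0))
  # var column wins over se and p
  expect_equal(tab$var_hat, c(0.0009, 0.0004, 0.0001))

  # se wins when var is absent
  tab_se <- read_summary_table(
    tf, c(snp = "SNP", effect_allele = "A1", other_allele = "A2",
          beta = "BETA", se = "SE", p = "P"),
    n_cases = 100, n_controls = 100
  )
  expect_equal(tab_se$var_hat, c(0.05, 0.01, 0.02)^2)
})

test_that("p-derived variance matches the inverse-normal-quantile oracle", {
  tf <- write_lines_tmp(c("SNP,A1,A2,BETA,P", "rs1,A,G,0.1,0.05"))
  tab <- read_summary_table(
    tf, c(snp = "SNP", effect_allele = "A1", other_allele = "A2",
          beta = "BETA", p = "P"),
    n_cases = 50, n_controls = 50
  )
  # oracle: two-sided 5% quantile of the standard normal is 1.959964
  expect_equal(tab$var_hat, (0.1 / 1.959964)^2, tolerance = 1e-6)
})

test_that("odds-ratio column is converted by natural log", {
  tf <- write_lines_tmp(c("SNP A1 A2 OR SE", "rs1 A G 1.05 0.02"))
  tab <- read_summary_table(
    tf, c(snp = "SNP", effect_allele = "A1", other_allele = "A2",
          or = "OR", se = "SE"),
    n_cases = 50, n_controls = 50
  )
  expect_equal(tab$beta_hat, log(1.05))
})

test_that("rows violating record invariants are dropped and counted", {
  tf <- write_lines_tmp(c(
    "SNP\tA1\tA2\tBETA\tVAR",
    "rs1\tA\tG\t0.1\t0.0009",
    "rs2\tA\tG\t0.1\t0",       # zero variance
    "rs3\tA\tA\t0.1\t0.0009",  # equal alleles
    "rs1\tC\tT\t0.2\t0.0004"   # duplicate id
  ))
  cmap <- c(snp = "SNP", effect_allele = "A1", other_allele = "A2",
            beta = "BETA", var = "VAR")
  tab <- read_summary_table(tf, cmap, n_cases = 10, n_controls = 10)
  expect_equal(nrow(tab), 1)
  rep <- drop_report(tab)
  expect_equal(rep$n_input, 4)
  expect_equal(rep$n_dropped, 3)
  expect_equal(rep$reasons$invalid_variance, 1)
  expect_equal(rep$reasons$allele_conflict, 1)
  expect_equal(rep$reasons$duplicate_id, 1)

  # p-derived variance undefined at beta = 0 or p = 0
  tf2 <- write_lines_tmp(c("SNP\tA1\tA2\tBETA\tP",
                           "rs1\tA\tG\t0\t0.5",
                           "rs2\tA\tG\t0.1\t0",
                           "rs3\tA\tG\t0.1\t0.01"))
  tab2 <- read_summary_table(tf2, c(snp = "SNP", effect_allele = "A1",
                                    other_allele = "A2", beta = "BETA", p = "P"),
                             n_cases = 10, n_controls = 10)
  expect_equal(nrow(tab2), 1)
  expect_equal(drop_report(tab2)$reasons$undefined_p_variance, 2)
})

test_that("reader fails on missing mandatory columns or empty output", {
  tf <- write_lines_tmp(c("SNP\tA1\tA2\tBETA\tVAR", "rs1\tA\tG\t0.1\t0.0009"))
  expect_error(
    read_summary_table(tf, c(snp = "SNP", effect_allele = "A1",
                             other_allele = "A2", beta = "BETA"),
                       n_cases = 10, n_controls = 10),
    "column_map"
  )
  expect_error(
    read_summary_table(tf, c(snp = "SNP", effect_allele = "A1",
                             other_allele = "A2", beta = "NOPE", var = "VAR"),
                       n_cases = 10, n_controls = 10),
    "not found"
  )
  tf_bad <- write_lines_tmp(c("SNP\tA1\tA2\tBETA\tVAR", "rs1\tA\tG\t0.1\t0"))
  expect_error(
    read_summary_table(tf_bad, c(snp = "SNP", effect_allele = "A1",
                                 other_allele = "A2", beta = "BETA", var = "VAR"),
                       n_cases = 10, n_controls = 10),
    "no usable rows"
  )
})

test_that("harmonization orients effects to the derived allele", {
  tab <- toy_table(beta = c(0.1, -0.2, 0.3), var = rep(1e-3, 3))
  # rs001: A already derived; rs002: A ancestral (flip); rs003: absent
  amap <- data.frame(snp_id = c("rs001", "rs002"),
                     ancestral = c("G", "A"), derived = c("A", "G"),
                     stringsAsFactors = FALSE)
  out <- harmonize_to_derived(tab, amap)
  expect_equal(nrow(out), 2)
  expect_equal(out$beta_hat, c(0.1, 0.2))
  expect_equal(out$effect_allele, c("A", "G"))
  expect_equal(drop_report(out)$reasons$allele_map_mismatch, 1)

  # idempotent once oriented
  out2 <- harmonize_to_derived(out, amap)
  expect_equal(out2$beta_hat, out$beta_hat)
  expect_equal(out2$effect_allele, out$effect_allele)

  # allele pair inconsistent with the map is dropped, not guessed
  amap_bad <- data.frame(snp_id = "rs001", ancestral = "C", derived = "T",
                         stringsAsFactors = FALSE)
  expect_error(harmonize_to_derived(tab, amap_bad), "no SNPs")
})

test_that("panel filtering preserves order and errors on empty result", {
  tab <- toy_table(beta = c(0.1, 0.2, 0.3), var = rep(1e-3, 3))
  out <- filter_to_panel(tab, c("rs003", "rs001"))
  expect_equal(out$snp_id, c("rs001", "rs003"))  # input order kept
  ident <- filter_to_panel(tab, c(tab$snp_id, "rs999"))
  expect_equal(ident$snp_id, tab$snp_id)
  expect_equal(ident$beta_hat, tab$beta_hat)
  expect_error(filter_to_panel(tab, c("rsX", "rsY")), "panel")
})

test_that("LD pruning removes exactly the linked SNPs", {
  tab <- toy_table(beta = rep(0.01, 3), var = rep(1e-3, 3))
  ld <- ld_table(data.frame(id_a = "rs001", id_b = "rs002", r2 = 0.5))
  # the only conflict is rs001-rs002: retained size is 2 for every seed
  for (s in 1:8) {
    pr <- ld_prune(tab, ld, 0.1, seed = s)
    expect_equal(nrow(pr$table), 2)
    expect_true("rs003" %in% pr$table$snp_id)
    expect_equal(sum(c("rs001", "rs002") %in% pr$table$snp_id), 1)
  }
  # no pair above threshold: everything kept
  pr_all <- ld_prune(tab, ld, 0.6, seed = 1)
  expect_equal(nrow(pr_all$table), 3)
  # 5-SNP clique collapses to one
  tab5 <- toy_table(beta = rep(0.01, 5), var = rep(1e-3, 5))
  cmb <- combn(tab5$snp_id, 2)
  clique <- ld_table(data.frame(id_a = cmb[1, ], id_b = cmb[2, ], r2 = 0.9))
  expect_equal(nrow(ld_prune(tab5, clique, 0.1, seed = 3)$table), 1)
})

test_that("pruning satisfies the r2 contract, determinism, and idempotence", {
  set.seed(42)
  m <- 40
  tab <- toy_table(beta = rnorm(m, 0, 0.02), var = rep(1e-3, m))
  cmb <- combn(tab$snp_id, 2)
  sel <- sample(ncol(cmb), 150)
  ld <- ld_table(data.frame(id_a = cmb[1, sel], id_b = cmb[2, sel],
                            r2 = runif(150), stringsAsFactors = FALSE))
  pr <- ld_prune(tab, ld, 0.1, seed = 7)
  kept <- pr$table$snp_id
  # exhaustive pair check: no retained pair with r2 above the threshold
  bad <- ld$r2 > 0.1 & ld$id_a %in% kept & ld$id_b %in% kept
  expect_false(any(bad))
  # same seed => byte-identical id list
  expect_identical(kept, ld_prune(tab, ld, 0.1, seed = 7)$table$snp_id)
  # different seed is allowed to differ but must satisfy the same contract
  pr2 <- ld_prune(tab, ld, 0.1, seed = 8)
  kept2 <- pr2$table$snp_id
  expect_false(any(ld$r2 > 0.1 & ld$id_a %in% kept2 & ld$id_b %in% kept2))
  # idempotence: pruning a pruned set returns it unchanged, any seed
  expect_identical(ld_prune(pr$table, ld, 0.1, seed = 99)$table$snp_id, kept)
})

test_that("significance counting follows the two-sided normal threshold", {
  v <- 1e-4
  tab <- toy_table(beta = c(6 * sqrt(v), 5 * sqrt(v), 0), var = rep(v, 3))
  # |z| = 6 exceeds the genome-wide threshold (about 5.45); |z| = 5 does not
  expect_equal(count_significant(tab, 5e-8), 1)
  expect_equal(count_significant(toy_table(rep(0, 4), rep(v, 4)), 5e-8), 0)
  expect_equal(count_significant(tab, 1), 3)  # p_c = 1 counts everything
  # monotone nondecreasing in p_c
  pcs <- c(1e-12, 5e-8, 1e-6, 1e-3, 0.05, 0.5, 1)
  counts <- vapply(pcs, function(p) count_significant(tab, p), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("LD, panel and allele-map readers parse the standard dialects", {
  # bare 3-column file without header
  tf1 <- write_lines_tmp(c("rs1 rs2 0.45", "rs2 rs3 0.05"))
  ld1 <- read_ld_table(tf1)
  expect_equal(nrow(ld1), 2)
  expect_equal(ld1$r2, c(0.45, 0.05))
  # whitespace report dialect with extra columns
  tf2 <- write_lines_tmp(c(
    "CHR_A BP_A SNP_A CHR_B BP_B SNP_B R2",
    "1 1000 rs1 1 2000 rs2 0.45",
    "1 2000 rs2 1 3000 rs3 0.05"
  ))
  ld2 <- read_ld_table(tf2)
  expect_equal(ld2$id_a, c("rs1", "rs2"))
  expect_equal(ld2$r2, c(0.45, 0.05))
  # r2 out of range rejected
  tf3 <- write_lines_tmp(c("rs1 rs2 1.2"))
  expect_error(read_ld_table(tf3), "r2")

  panel <- read_panel(write_lines_tmp(c("rs1", "rs2 extra", "", "rs1")))
  expect_equal(panel, c("rs1", "rs2"))

  amap <- read_allele_map(write_lines_tmp(c("snp_id anc der", "rs1 a g")))
  expect_equal(amap$derived, "G")  # uppercased
  amap2 <- read_allele_map(write_lines_tmp(c("rs1 A G")))
  expect_equal(amap2$snp_id, "rs1")
})
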