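test_that("beta/M transform matches its closed form and round-trips", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  # clip boundary: beta = 0 maps to the logit of epsilon
  eps <- 1e-6
  expect_equal(beta_to_m(0, epsilon = eps), log2(eps / (1 - eps)))
  b <- seq(eps, 1 - eps, length.out = 201)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-12)
  expect_error(beta_to_m(1.2), "0, 1")
})

test_that("probe QC applies the over-5%-of-samples rule and flag/sex exclusions", {
  n_samp <- 16
  probes <- c("p_fail1", "p_border", "p_snp", "p_multi", "p_x", "p_ok")
  ann <- tibble::tibble(
    probe_id = probes,
    chrom = c("chr1", "chr1", "chr2", "chr2", "chrX", "chr3"),
    snp_flag = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    multimap_flag = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  samples <- paste0("s", seq_len(n_samp))
  mk <- function(fill) {
    m <- matrix(fill, length(probes), n_samp,
                dimnames = list(probes, samples))
    tibble::as_tibble(m, rownames = "probe_id")
  }
  beta <- mk(0.5)
  dp <- mk(1e-4)
  # failing 1 of 16 samples is 6.25% > 5% -> removed
  dp[dp$probe_id == "p_fail1", "s1"] <- 0.5
  bc <- mk(10)
  # p_border fails in exactly 5% of a 20-sample rule; with 16 samples use
  # bead failures: 0 failing samples -> retained
  res <- qc_filter_probes(beta, ann, dp, bc)
  expect_setequal(res$beta$probe_id, c("p_border", "p_ok"))
  expect_equal(sum(res$removal_log$n), nrow(beta) - nrow(res$beta))
  expect_equal(res$removal_log$n[res$removal_log$reason == "sex_chromosome"], 1L)

  # strict boundary: failing in exactly max_fail_fraction of samples is kept
  mk20 <- function(fill) {
    tibble::as_tibble(matrix(fill, 1, 20,
                             dimnames = list("pb", paste0("t", 1:20))),
                      rownames = "probe_id")
  }
  dp20 <- mk20(1e-4)
  dp20[1, 2] <- 0.5 # fails in 1 of 20 samples = exactly 5%
  ann1 <- tibble::tibble(probe_id = "pb", chrom = "chr1",
                         snp_flag = FALSE, multimap_flag = FALSE)
  res20 <- qc_filter_probes(mk20(0.5), ann1, dp20, mk20(10))
  expect_equal(res20$beta$probe_id, "pb")

  expect_error(qc_filter_probes(beta, ann["probe_id"], dp, bc), "chrom")
  expect_error(qc_filter_probes(beta, ann, NULL, bc), "detection_p")
})

test_that("ordinary paired test equals the direct paired-t formula", {
  set.seed(42)
  n_probes <- 50; n_pairs <- 6
  mu <- matrix(runif(n_probes, 0.2, 0.8), n_probes, 2 * n_pairs,
               dimnames = list(sprintf("p%02d", 1:n_probes),
                               sheet_fixture(n_pairs)$sample_id))
  beta <- beta_fixture(mu, seed = 42)
  sheet <- sheet_fixture(n_pairs)
  res <- paired_dmp(beta, sheet, moderated = FALSE)

  b <- as.matrix(beta[-1]); rownames(b) <- beta$probe_id
  d <- as_paired_design(sheet)
  m <- log2(pmin(pmax(b, 1e-6), 1 - 1e-6) /
              (1 - pmin(pmax(b, 1e-6), 1 - 1e-6)))
  diffs <- m[, d$on_treatment] - m[, d$baseline]
  for (i in c(1, 17, 50)) {
    tt <- t.test(diffs[i, ], mu = 0)
    expect_equal(res$statistic[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-10)
  }
  # BH adjustment is monotone in raw p and bounded by it from below
  ord <- order(res$p_value)
  expect_true(all(diff(res$p_adjusted[ord]) >= -1e-12))
  expect_true(all(res$p_adjusted >= res$p_value - 1e-12))
  expect_true(all(res$p_adjusted <= 1))
})

test_that("moderated paired test detects planted promoter-scale shifts", {
  set.seed(5)
  n_pairs <- 8; n_planted <- 300; n_null <- 1700
  sheet <- sheet_fixture(n_pairs)
  base_mu <- matrix(runif(n_planted + n_null, 0.35, 0.65),
                    n_planted + n_null, 2 * n_pairs)
  dimnames(base_mu) <- list(sprintf("p%04d", seq_len(nrow(base_mu))),
                            sheet$sample_id)
  d <- as_paired_design(sheet)
  base_mu[seq_len(n_planted), d$on_treatment] <-
    base_mu[seq_len(n_planted), d$on_treatment] - 0.30
  beta <- beta_fixture(base_mu, precision = 50, seed = 5)
  res <- paired_dmp(beta, sheet)
  sens <- mean(res$p_adjusted[seq_len(n_planted)] < 0.05)
  expect_gte(sens, 0.9)
})

test_that("zero within-pair variance probes are flagged with p = 1", {
  sheet <- sheet_fixture(3)
  b <- matrix(0.4, 2, 6, dimnames = list(c("pa", "pb"), sheet$sample_id))
  b["pb", ] <- runif(6, 0.2, 0.8)
  beta <- tibble::as_tibble(b, rownames = "probe_id")
  res <- paired_dmp(beta, sheet)
  expect_true(res$zero_variance[res$probe_id == "pa"])
  expect_equal(res$p_value[res$probe_id == "pa"], 1)
  expect_false(res$zero_variance[res$probe_id == "pb"])
})

test_that("promoter deltas average promoter probes and omit promoterless genes", {
  sheet <- sheet_fixture(2)
  b <- matrix(c(0.5, 0.5, 0.5, 0.5,  # baseline/on per column order of sheet
                0.5, 0.5, 0.5, 0.5,
                0.5, 0.5, 0.5, 0.5),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("pr1", "pr2", "body1"), sheet$sample_id))
  d <- as_paired_design(sheet)
  b["pr1", d$on_treatment[1]] <- 0.3   # delta -0.2 for P1
  b["pr2", d$on_treatment[1]] <- 0.1   # delta -0.4 for P1
  ann <- tibble::tibble(probe_id = c("pr1", "pr2", "body1"),
                        gene = c("G1", "G1", "G2"),
                        region = c("TSS200", "5UTR", "Body"))
  res <- promoter_delta(tibble::as_tibble(b, rownames = "probe_id"), sheet, ann)
  expect_equal(res$delta_beta[res$gene == "G1" & res$participant_id == "P1"], -0.3)
  expect_equal(res$delta_beta[res$gene == "G1" & res$participant_id == "P2"], 0)
  expect_false("G2" %in% res$gene) # no promoter probes -> absent, not zero
  expect_equal(res$n_probes[res$gene == "G1"], c(2L, 2L))
})

test_that("gene-level Z follows the Stouffer rule and its normal p", {
  z4 <- tibble::tibble(gene = "g", z = c(2, 2, 2, 2))
  res <- gene_level_z(z4)
  expect_equal(res$z, 4) # 8 / sqrt(4)
  z0 <- gene_level_z(tibble::tibble(gene = "g", z = c(0, 0)))
  expect_equal(z0$z, 0)
  expect_equal(z0$p_value, 1)
  z1 <- gene_level_z(tibble::tibble(gene = "g", z = 1.959964))
  expect_equal(z1$p_value, 0.05, tolerance = 1e-6)
  expect_equal(res$p_value, 2 * pnorm(-abs(res$z)))
})

test_that("global methylation summary counts strict >25-point decreases", {
  sheet <- sheet_fixture(1)
  mk <- function(shift) {
    b <- matrix(c(rep(0.6, 10), rep(0.6 + shift, 10)), 10,
                dimnames = list(sprintf("p%02d", 1:10), sheet$sample_id))
    tibble::as_tibble(b, rownames = "probe_id")
  }
  s1 <- global_methylation_summary(mk(-0.30), sheet)
  expect_equal(s1$frac_decreased, 1)
  expect_true(s1$global_decrease)
  s2 <- global_methylation_summary(mk(-0.20), sheet)
  expect_equal(s2$frac_decreased, 0) # strict inequality
  expect_true(s2$global_decrease)
  s3 <- global_methylation_summary(mk(0), sheet)
  expect_equal(s3$frac_decreased, 0)
  expect_false(s3$global_decrease)
})
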