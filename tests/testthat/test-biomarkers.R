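test_that("molecular responder calls apply the strict conjunction rule", {
  fc <- tibble::tibble(participant_id = c("A", "B", "C"),
                       ifng_fc = c(3.5, 2.0, 2.5),
                       cd274_fc = c(2.8, 2.5, 1.9))
  res <- call_molecular_responders(fc)
  expect_equal(res$responder, c(TRUE, FALSE, FALSE))
  res_dis <- call_molecular_responders(fc, rule = "disjunction")
  expect_equal(res_dis$responder, c(TRUE, TRUE, TRUE))
})

test_that("the BED rule uses inclusive thresholds on both criteria", {
  mk <- function(dec) tibble::tibble(participant_id = seq_along(dec),
                                     dose = "d1", decrease = dec)
  expect_true(assess_bed(mk(c(0.12, 0.15, 0.08, 0.11)))$bed_met)   # 3/4
  expect_false(assess_bed(mk(c(0.09, 0.09, 0.09, 0.20)))$bed_met)  # 1/4
  expect_true(assess_bed(mk(c(0.10, 0.05)))$bed_met)               # 1/2 = 50%
})

test_that("hypermethylated TSG selection requires promoter, delta and FDR", {
  tn <- tibble::tibble(
    probe_id = paste0("p", 1:4),
    gene = c("T1", "T2", "T3", "T4"),
    region = c("TSS200", "5UTR", "TSS200", "Body"),
    delta_beta = c(0.15, 0.08, -0.15, 0.30),
    fdr = c(0.01, 0.001, 0.001, 0.001))
  res <- tsg_hyper_dmps(tn, c("T1", "T2", "T3", "T4"))
  expect_equal(res$gene, "T1") # T2 below delta; T3 hypo; T4 not promoter
})

test_that("TSG reversal counts strict demethylation-and-re-expression", {
  pd <- tibble::tibble(participant_id = "P1", gene = c("T1", "T2", "T3"),
                       delta_beta = c(-0.30, -0.20, -0.40), n_probes = 2L)
  fc <- tibble::tibble(participant_id = "P1", gene_id = c("T1", "T2", "T3"),
                       fc = c(2.5, 3.0, 1.5))
  res <- tsg_reversal(c("T1", "T2", "T3"), pd, fc)
  expect_equal(res$n_reversed, 1L) # T2 fails delta; T3 fails FC
  expect_equal(res$mean_promoter_delta, -0.30)
})

test_that("NLR divides neutrophils by lymphocytes with a zero guard", {
  expect_equal(nlr(10, 2), 5)
  expect_equal(nlr(8.5, 0.1), 85)
  expect_equal(nlr(0, 1), 0)
  expect_warning(res <- nlr(c(5, 5), c(1, 0)), "zero lymphocyte")
  expect_equal(res, c(5, NA))
  clin <- tibble::tibble(neutrophils_baseline = c(10, 20),
                         lymphocytes_baseline = c(1, 2),
                         neutrophils_last = c(5, NA),
                         lymphocytes_last = c(1, NA))
  s <- nlr_summary(clin)
  expect_equal(s$n, c(2L, 1L)) # available-case summaries
  expect_equal(s$mean, c(10, 5))
})

test_that("H-score spans 0 to 300 and is linear in the percentages", {
  ihc <- tibble::tibble(pct_intensity_0 = c(0, 100, 0, 50),
                        pct_intensity_1 = c(0, 0, 0, 50),
                        pct_intensity_2 = c(0, 0, 0, 0),
                        pct_intensity_3 = c(100, 0, 0, 0))
  ihc$pct_intensity_2[3] <- 100
  res <- h_score(ihc)
  expect_equal(res$h_score, c(300, 0, 200, 50))
  expect_error(h_score(tibble::tibble(pct_intensity_0 = 50,
                                      pct_intensity_1 = 10,
                                      pct_intensity_2 = 10,
                                      pct_intensity_3 = 10)),
               "sum to 100")
})

test_that("exact rank-sum enumeration matches wilcox.test and its examples", {
  res <- wilcoxon_exact(c(3.5, 3.4, 3.6), c(0.8, 0.7, 0.9, 0.75, 0.85))
  expect_equal(res$p_value, 2 / 56)
  expect_equal(res$method, "enumeration")
  expect_equal(wilcoxon_exact(c(1, 2), c(1, 2))$p_value, 1)
  expect_equal(wilcoxon_exact(2, 1)$p_value, 1)
  # against the exact distribution in stats for tie-free samples, all
  # configurations with combined n <= 10
  set.seed(77)
  for (na in 2:5) {
    for (nb in 2:5) {
      a <- rnorm(na); b <- rnorm(nb)
      ours <- wilcoxon_exact(a, b)$p_value
      ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  }
})

test_that("Kaplan-Meier estimates follow the product-limit formula", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$table$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)
  km_c <- km_curve(c(5, 6, 7), c(0, 0, 0))
  expect_true(is.na(km_c$median)) # all censored: median not reached
  # large-sample median converges to the closed form ln(2)/lambda
  set.seed(12)
  lambda <- 0.1
  t <- rexp(500, lambda)
  km_e <- km_curve(t, rep(1, 500))
  expect_equal(km_e$median, log(2) / lambda, tolerance = 0.1)
  r <- km_rate(km_e, 10)
  expect_equal(r$surv, exp(-1), tolerance = 0.1)
  expect_true(r$lower < r$surv && r$surv < r$upper)
})

test_that("tidy/glance/autoplot accessors work on fitted objects", {
  km <- km_curve(c(1, 2, 3, 4), c(1, 1, 0, 1))
  expect_s3_class(tidy(km), "tbl_df")
  expect_equal(glance(km)$n_events, 3)
  expect_s3_class(autoplot(km), "ggplot")
  ref <- generate_reference(sim_config(seed = 2))
  cts <- setdiff(names(ref), "probe_id")
  f <- tibble::tibble(sample_id = "s1",
                      !!!setNames(as.list(rep(0.1, 10)), cts))
  dec <- deconvolve(mix_methylomes(ref, f, precision = Inf), ref)
  expect_equal(nrow(tidy(dec)), 10)
  expect_equal(glance(dec)$n_cell_types, 10)
  expect_s3_class(autoplot(dec), "ggplot")
})
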