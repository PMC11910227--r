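ref_fixture <- function(seed = 3) {
  generate_reference(sim_config(seed = seed))
}

fractions_fixture <- function(n, k_names, seed = 11) {
  set.seed(seed)
  f <- matrix(rgamma(n * length(k_names), 1), n)
  f <- f / rowSums(f)
  colnames(f) <- k_names
  dplyr::bind_cols(tibble::tibble(sample_id = paste0("s", seq_len(n))),
                   tibble::as_tibble(f))
}

test_that("reference intersection keeps shared probes and guards rank", {
  ref <- ref_fixture()
  co <- get_default_cohort()
  red <- intersect_reference(ref, co$beta)
  expect_equal(nrow(red), 933) # 933 of the 1197 reference CpGs are measured
  # full overlap leaves the reference unchanged
  expect_identical(intersect_reference(red, co$beta), red)
  expect_error(intersect_reference(ref, co$beta[1:50, ]), "at least")
})

test_that("constrained least squares recovers mixtures exactly", {
  ref <- ref_fixture()
  cts <- setdiff(names(ref), "probe_id")
  # one-hot: a pure cancer profile returns fraction 1 for Cancer
  onehot <- tibble::tibble(sample_id = "pure", !!!setNames(as.list(rep(0, 10)), cts))
  onehot$Cancer <- 1
  b1 <- mix_methylomes(ref, onehot, precision = Inf)
  r1 <- deconvolve(b1, ref)
  expect_equal(r1$Cancer, 1, tolerance = 1e-9)
  expect_equal(sum(as.matrix(r1[cts])), 1, tolerance = 1e-9)
  expect_equal(r1$residual, 0, tolerance = 1e-8)

  # 50/50 two-type mixture
  half <- onehot; half$Cancer <- 0.5; half$CD8T <- 0.5
  r2 <- deconvolve(mix_methylomes(ref, half, precision = Inf), ref)
  expect_equal(r2$Cancer, 0.5, tolerance = 1e-6)
  expect_equal(r2$CD8T, 0.5, tolerance = 1e-6)

  # random noiseless mixtures invert to machine precision
  f <- fractions_fixture(20, cts)
  r3 <- deconvolve(mix_methylomes(ref, f, precision = Inf), ref)
  expect_lt(max(abs(as.matrix(r3[cts]) - as.matrix(f[cts]))), 1e-6)
  expect_equal(qr(as.matrix(ref[cts]))$rank, 10) # identifiable reference
})

test_that("deconvolution is accurate on noisy mixtures", {
  ref <- ref_fixture()
  cts <- setdiff(names(ref), "probe_id")
  f <- fractions_fixture(100, cts)
  set.seed(21)
  noisy <- mix_methylomes(ref, f, precision = 50)
  est <- deconvolve(noisy, ref)
  rmse <- sqrt(colMeans((as.matrix(est[cts]) - as.matrix(f[cts]))^2))
  expect_true(all(rmse < 0.05))
  expect_true(all(est$residual > 0))
})

test_that("fractions are invariant to probe reordering and duplication", {
  ref <- ref_fixture()
  cts <- setdiff(names(ref), "probe_id")
  f <- fractions_fixture(3, cts)
  b <- mix_methylomes(ref, f, precision = Inf)
  r0 <- deconvolve(b, ref)
  perm <- sample(nrow(ref))
  r1 <- deconvolve(b[perm, ], ref[perm, ])
  expect_equal(as.matrix(r1[cts]), as.matrix(r0[cts]), tolerance = 1e-9)
  dup <- c(seq_len(nrow(ref)), 1:25)
  ref_dup <- ref[dup, ]; b_dup <- b[dup, ]
  ref_dup$probe_id <- b_dup$probe_id <- sprintf("d%05d", seq_along(dup))
  r2 <- deconvolve(b_dup, ref_dup)
  expect_equal(as.matrix(r2[cts]), as.matrix(r0[cts]), tolerance = 1e-9)
})

test_that("nu-SVR deconvolution approximates the mixing weights", {
  ref <- ref_fixture()
  cts <- setdiff(names(ref), "probe_id")
  f <- fractions_fixture(5, cts)
  b <- mix_methylomes(ref, f, precision = Inf)
  r <- deconvolve(b, ref, method = "nu_svr")
  expect_equal(attr(r, "method"), "nu_svr")
  expect_lt(max(abs(as.matrix(r[cts]) - as.matrix(f[cts]))), 0.05)
  expect_equal(rowSums(as.matrix(r[cts])), rep(1, 5), tolerance = 1e-9)
})

test_that("paired fraction changes report absolute and relative shifts", {
  sheet <- sheet_fixture(2)
  fr <- tibble::tibble(sample_id = sheet$sample_id,
                       Treg = c(0.10, 0.20, 0.065, 0.20),
                       Cancer = c(0.90, 0.80, 0.935, 0.80))
  # sheet rows: P1_b, P2_b, P1_t, P2_t
  ch <- fraction_change(fr, sheet)
  treg_p1 <- ch[ch$participant_id == "P1" & ch$cell_type == "Treg", ]
  expect_equal(treg_p1$rel_change, -0.35, tolerance = 1e-12)
  p2 <- ch[ch$participant_id == "P2", ]
  expect_equal(p2$abs_change, c(0, 0))
  # zero baseline: relative change missing, absolute change kept
  fr0 <- tibble::tibble(sample_id = sheet$sample_id,
                        A = c(0, 0.5, 0.2, 0.5), B = c(1, 0.5, 0.8, 0.5))
  ch0 <- fraction_change(fr0, sheet)
  a_p1 <- ch0[ch0$participant_id == "P1" & ch0$cell_type == "A", ]
  expect_true(is.na(a_p1$rel_change))
  expect_equal(a_p1$abs_change, 0.2)
  sm <- fraction_change_summary(ch)
  expect_equal(sm$mean_rel_change[sm$cell_type == "Treg"], -0.175)
})

test_that("deconvolution of the synthetic cohort recovers planted fractions", {
  co <- get_default_cohort()
  red <- intersect_reference(co$reference, co$beta)
  # noiseless forward model reproduces the truth to machine precision
  clean <- mix_methylomes(red, co$true_fractions, precision = Inf)
  cts <- setdiff(names(red), "probe_id")
  est <- deconvolve(clean, red)
  expect_lt(max(abs(as.matrix(est[cts]) -
                      as.matrix(co$true_fractions[cts]))), 1e-6)
  # with the cohort's observed (noisy) betas the planted Treg depletion in
  # responders is visible
  est_noisy <- deconvolve(co$beta[co$beta$probe_id %in% red$probe_id, ], red)
  ch <- fraction_change(est_noisy, co$sample_sheet)
  treg <- ch[ch$cell_type == "Treg", ]
  resp <- treg$participant_id %in% co$truth$responders
  expect_lt(mean(treg$rel_change[resp]), -0.2)
})
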