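counts_fixture <- function(m) {
  tibble::as_tibble(m, rownames = "gene_id")
}

test_that("rpkm matches its definition and the edgeR implementation", {
  m <- matrix(c(10, 90, 0, 900100,
                20, 80, 5, 1e6),
              nrow = 4,
              dimnames = list(c("g1", "g2", "g3", "g4"), c("s1", "s2")))
  storage.mode(m) <- "integer"
  lens <- c(g1 = 1000, g2 = 500, g3 = 2000, g4 = 1e4)
  # library of s1 is 900200; force the classic worked example instead:
  m2 <- matrix(c(10L, 999990L), 2, 1,
               dimnames = list(c("ga", "gb"), "s1"))
  r2 <- rpkm(counts_fixture(m2), c(ga = 1000, gb = 5000))
  expect_equal(r2$s1[r2$gene_id == "ga"], 10) # count 10, 1 kb, 1e6 library

  r <- rpkm(counts_fixture(m), lens)
  rm <- as.matrix(r[-1]); rownames(rm) <- r$gene_id
  expect_equal(rm, edgeR::rpkm(m, gene.length = lens, lib.size = colSums(m)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # zero count -> RPKM 0, log2 view = log2(pseudocount) = 0 at the default
  expect_equal(rm["g3", "s1"], 0)
  l2 <- log2_rpkm(r)
  expect_equal(l2$s1[l2$gene_id == "g3"], 0)
  # doubling all counts and the library leaves RPKM unchanged
  r_dbl <- rpkm(counts_fixture(m * 2L), lens)
  expect_equal(as.matrix(r_dbl[-1]), as.matrix(r[-1]), tolerance = 1e-12)
  expect_error(rpkm(counts_fixture(m), lens[1:2]), "lengths")
})

test_that("signature score is the geometric mean, symmetric and equivariant", {
  m <- matrix(c(2, 2, 2, 1, 4, 9), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expr <- counts_fixture(m)
  sc <- signature_score(expr, c("a", "b", "c"), offset = 0)
  expect_equal(sc$score[sc$sample_id == "s1"], 2) # constant input
  sc2 <- signature_score(expr, c("a", "b"), offset = 0)
  expect_equal(sc2$score[sc2$sample_id == "s2"], 2) # sqrt(1 * 4)
  # permutation symmetry
  sc3 <- signature_score(expr, c("c", "a", "b"), offset = 0)
  expect_equal(sc3$score, sc$score)
  # multiplicative equivariance at offset 0
  sc4 <- signature_score(counts_fixture(m * 7), c("a", "b", "c"), offset = 0)
  expect_equal(sc4$score, 7 * sc$score)
  expect_warning(signature_score(expr, c("a", "nope")), "absent")
  expect_error(signature_score(expr, "nope"), "no signature gene")
  # strictly positive with a positive offset, even at zero expression
  sc5 <- signature_score(counts_fixture(matrix(0, 1, 1,
                                               dimnames = list("a", "s"))),
                         "a", offset = 0.1)
  expect_true(all(sc5$score > 0))
})

test_that("paired fold changes obey their identities", {
  sheet <- sheet_fixture(2)
  m <- matrix(2, 3, 4, dimnames = list(c("a", "b", "c"), sheet$sample_id))
  d <- as_paired_design(sheet)
  m[, d$on_treatment[1]] <- 6
  expr <- counts_fixture(m)
  fc <- paired_fold_change(expr, sheet, "gene", offset = 0)
  expect_equal(fc$fc[fc$participant_id == "P1"], rep(3, 3)) # 6 / 2
  expect_equal(fc$fc[fc$participant_id == "P2"], rep(1, 3)) # identity
  # one-gene signature FC equals the gene FC
  fs <- paired_fold_change(expr, sheet, "signature", signature = "a", offset = 0)
  expect_equal(fs$fc, fc$fc[fc$gene_id == "a"])
})

test_that("planted signature effects are recovered at realistic noise", {
  co <- get_default_cohort()
  expr <- rpkm(co$counts, co$gene_lengths)
  fc <- paired_fold_change(expr, co$sample_sheet, "signature",
                           signature = co$gene_sets$ifng)
  resp <- fc$participant_id %in% co$truth$responders
  expect_true(mean(fc$fc[resp]) > 2.5 && mean(fc$fc[resp]) < 3.5)
  expect_true(all(fc$fc[!resp] < 2))
})

test_that("M1/M2 ratio compares the two signature scores", {
  m <- matrix(1, 4, 2, dimnames = list(c("m1a", "m1b", "m2a", "m2b"),
                                       c("s1", "s2")))
  m[c("m1a", "m1b"), ] <- 2
  r <- m1_m2_ratio(counts_fixture(m), c("m1a", "m1b"), c("m2a", "m2b"),
                   offset = 0)
  expect_equal(r$ratio, c(2, 2))
  # identical paired samples give ratio FC 1; a planted 1.3x M1 shift moves
  # the ratio FC to ~1.3 under multiplicative noise
  set.seed(9)
  sheet <- sheet_fixture(4)
  d <- as_paired_design(sheet)
  base <- matrix(rlnorm(40 * 8, log(5), 0.05), 40,
                 dimnames = list(sprintf("g%02d", 1:40), sheet$sample_id))
  base[1:20, d$on_treatment] <- base[1:20, d$on_treatment] * 1.3
  rc <- m1_m2_ratio_change(counts_fixture(base), sprintf("g%02d", 1:20),
                           sprintf("g%02d", 21:40), sheet, offset = 0)
  expect_equal(mean(rc$fc), 1.3, tolerance = 0.05)
})

test_that("set upregulation counts use a strict 2-fold rule", {
  fc <- tibble::tibble(participant_id = "P1",
                       gene_id = c("A", "B", "C"),
                       fc = c(2.5, 2.0, 1.9))
  res <- set_upregulation_count(fc, c("A", "B", "C"))
  expect_equal(res$n_up, 1L) # only the strictly-greater gene counts
  expect_warning(res0 <- set_upregulation_count(fc, "absent"), "no set gene")
  expect_equal(res0$n_up, 0L)
  # planted cancer-testis genes in the synthetic cohort are all recovered
  co <- get_default_cohort()
  expr <- rpkm(co$counts, co$gene_lengths)
  gfc <- paired_fold_change(expr, co$sample_sheet, "gene")
  for (p in names(co$truth$planted_cta)) {
    planted <- co$truth$planted_cta[[p]]
    res_p <- set_upregulation_count(gfc[gfc$participant_id == p, ], planted)
    expect_equal(res_p$n_up, length(planted))
  }
})
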