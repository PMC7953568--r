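# Minimal observed/imputed pair over 4 samples and a mix of array/hidden
# sites, for the statistic unit checks.
acc_fixture <- function(obs, dos, maf = 0.2) {
  n_site <- ncol(obs)
  sites <- variant_table("chr1", pos = seq_len(n_site + 1) * 1e5)
  sites$on_array <- c(TRUE, rep(FALSE, n_site))
  sites$maf <- c(0.4, rep_len(maf, n_site))
  sites$impact_class <- "modifier"
  ids <- sprintf("S%d", seq_len(nrow(obs)))
  og <- cbind(1L, obs)
  gm <- genotype_matrix(ids, og, sites)
  dosage <- cbind(1, dos)
  res <- imputation_result(ids, dosage,
                           imputeval:::hard_call(dosage, rep(FALSE, n_site + 1)),
                           imputeval:::rsq_from_dosage(dosage), sites, "lshmm")
  list(gm = gm, res = res, ids = ids)
}

test_that("balanced folds are seed-deterministic with the documented sizes", {
  plan <- make_folds(sprintf("A%03d", 1:151), 5, seed = 2)
  expect_equal(as.integer(sort(table(plan$fold_of), decreasing = TRUE)),
               c(31L, 30L, 30L, 30L, 30L))
  expect_identical(make_folds(sprintf("A%03d", 1:151), 5, seed = 2)$fold_of,
                   plan$fold_of)
  loo <- make_folds(sprintf("B%02d", 1:10), 10, seed = 1)
  expect_equal(as.integer(table(loo$fold_of)), rep(1L, 10))
  expect_error(make_folds(letters, 1), "n_folds")
  expect_error(make_folds(letters[1:3], 5), "exceeds")
})

test_that("masking hides exactly the non-array genotypes of the fold samples", {
  sites <- variant_table("chr1", pos = (1:4) * 1e5)
  sites$on_array <- c(TRUE, FALSE, TRUE, FALSE)
  g <- matrix(1L, 4, 4)
  gm <- genotype_matrix(sprintf("S%d", 1:4), g, sites)
  plan <- make_folds(gm$sample_ids, 2, seed = 1)
  fold1 <- names(plan$fold_of)[plan$fold_of == 1]
  masked <- mask_to_panel(gm, 1, plan)
  for (s in gm$sample_ids) {
    row <- masked$geno[match(s, gm$sample_ids), ]
    if (s %in% fold1) expect_identical(unname(is.na(row)), !sites$on_array)
    else expect_identical(unname(row), rep(1L, 4))
  }
  expect_error(mask_to_panel(gm, 9, plan), "not in plan")
})

test_that("the imputed-site percentage follows the printed two-decimal convention", {
  expect_equal(impute_fraction(100, 100), 0)
  expect_equal(impute_fraction(200, 3), 98.5)
  expect_error(impute_fraction(0, 0), "positive")
  expect_error(impute_fraction(10, 11), "<=")
})

test_that("per-SNP R2 and PERC match hand-computed cases with undefined flags", {
  fx <- acc_fixture(obs = rbind(c(0L, 0L, 0L), c(1L, 0L, 1L),
                                c(2L, 2L, 2L), c(1L, 2L, 1L)),
                    dos = rbind(c(0, 0, 1), c(1, 1, 1), c(2, 1, 1), c(1, 2, 1)))
  out <- per_snp_accuracy(fx$gm, fx$res, fx$ids)
  expect_equal(nrow(out), 3L)  # only the non-array sites are scored
  expect_equal(out$r2[1], 1)
  expect_equal(out$perc[1], 100)
  expect_equal(out$r2[2], 0.5)   # obs (0,0,2,2) vs dos (0,1,1,2)
  expect_equal(out$perc[2], 50)
  expect_true(is.na(out$r2[3]))  # constant imputed
  expect_equal(out$r2_reason[3], "constant_imputed")
  expect_equal(out$perc[3], 50)
})

test_that("constant observed truth and too-few calls carry their reason codes", {
  fx <- acc_fixture(obs = rbind(c(1L, NA), c(1L, NA), c(1L, 0L), c(1L, NA)),
                    dos = rbind(c(0, 1), c(1, 1), c(2, 0), c(1, 0)))
  out <- per_snp_accuracy(fx$gm, fx$res, fx$ids)
  expect_equal(out$r2_reason[1], "constant_observed")
  expect_equal(out$r2_reason[2], "too_few")
  expect_equal(out$n_called[2], 1L)
})

test_that("per-SNP statistics agree with the closed-form oracle on random draws", {
  withr::local_seed(99)
  for (rep in 1:5) {
    n <- 8L; m <- 40L
    obs <- matrix(sample(c(0:2, NA), n * m, replace = TRUE,
                         prob = c(0.4, 0.3, 0.25, 0.05)), n, m)
    dos <- matrix(round(runif(n * m, 0, 2), 2), n, m)
    fx <- acc_fixture(obs, dos)
    out <- per_snp_accuracy(fx$gm, fx$res, fx$ids)
    for (j in seq_len(m)) {
      r <- pearson_oracle(obs[, j], dos[, j])
      if (is.na(r)) expect_false(is.na(out$r2_reason[j]))
      else expect_equal(out$r2[j], r^2, tolerance = 1e-12)
    }
  }
})

test_that("per-animal accuracy is exact under perfection and skips empty truth", {
  obs <- rbind(c(0L, 1L, 2L), c(2L, 1L, 0L), c(NA, NA, NA), c(0L, 0L, 1L))
  fx <- acc_fixture(obs, dos = obs * 1.0)
  fx$gm$geno[3, ] <- NA_integer_
  expect_warning(out <- per_animal_accuracy(fx$gm, fx$res, fx$ids), "excluded")
  expect_equal(nrow(out), 3L)
  expect_true(all(out$r2 == 1))
  expect_true(all(out$perc == 100))
})

test_that("stratified summaries use interpolated quartiles and keep empty strata", {
  frame <- data.frame(chrom = "chr1", pos = seq_len(10) * 1e5,
                      maf = rep(c(0.01, 0.2), each = 5),
                      impact_class = rep(c("high", "modifier"), each = 5),
                      window = 0L, fold = 1L, engine = "lshmm",
                      n_called = 10L, r2 = c(1:5 / 5, 1:5 / 10),
                      r2_reason = NA_character_, perc = 50, rsq = 0.5)
  out <- stratify_accuracy(frame, "impact_class", "r2")
  high <- out[out$stratum == "high", ]
  expect_equal(high$q1, 0.4)    # quartiles of (0.2, 0.4, 0.6, 0.8, 1.0)
  expect_equal(high$median, 0.6)
  expect_equal(high$q3, 0.8)
  expect_equal(high$mean, 0.6)
  expect_equal(out[out$stratum == "moderate", "n"], 0L)
  two <- stratify_accuracy(frame, "maf_class", "r2")
  expect_equal(two[two$stratum == "maf<=0.03", "n"], 5L)
})

test_that("1-Mb windows are half-open with the documented boundary", {
  expect_equal(imputeval:::window_of(1e6), 0)
  expect_equal(imputeval:::window_of(1e6 + 1), 1)
  expect_equal(imputeval:::window_of(1), 0)
})

test_that("rsq calibration is exact in the trivial and degenerate cases", {
  frame <- data.frame(maf = runif(50, 0, 0.5), r2 = runif(50),
                      engine = "lshmm")
  frame$rsq <- frame$r2
  cal <- rsq_calibration(frame)
  expect_equal(cal$mean_signed_diff, 0)
  expect_equal(cal$correlation, 1)
  expect_equal(cal$curve$mean_r2, cal$curve$mean_rsq)
  one_bin <- rsq_calibration(frame, maf_bin_width = 1)
  expect_equal(nrow(one_bin$curve), 1L)
  empty <- data.frame(maf = 0.2, r2 = NA_real_, rsq = 0.5)
  expect_error(rsq_calibration(empty), "no sites")
})

test_that("fold-wise and pooled averaging agree for balanced folds on shared sites", {
  withr::local_seed(7)
  obs <- matrix(sample(0:2, 8 * 30, replace = TRUE), 8, 30)
  dos <- pmin(pmax(obs + matrix(rnorm(8 * 30, 0, 0.3), 8, 30), 0), 2)
  fx <- acc_fixture(obs, dos)
  f1 <- per_snp_accuracy(fx$gm, fx$res, fx$ids[1:2], fold = 1)
  f2 <- per_snp_accuracy(fx$gm, fx$res, fx$ids[3:4], fold = 2)
  both <- rbind(f1, f2)
  expect_equal(mean(c(mean(f1$perc), mean(f2$perc))), mean(both$perc))
})
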