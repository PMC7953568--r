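test_that("each constructed violator is removed by exactly its own rule", {
  fx <- make_fixture("qc-violations")
  out <- apply_site_filters(fx$variants, fx$genotypes)
  rm <- out$report$n_removed_by_rule
  for (rule in c("QD", "FS", "MQ", "ReadPosRankSum", "MQRankSum", "SOR"))
    expect_equal(unname(rm[[rule]]), 1L)
  expect_equal(unname(rm[["biallelic"]]), 0L)
  expect_equal(unname(rm[["missingness"]]), 2L)  # direct + via low GQ
  expect_equal(unname(rm[["maf"]]), 1L)
  expect_equal(out$report$n_genotypes_set_missing, 41L)
  expect_equal(out$report$n_sites_out, length(fx$clean_sites))
  expect_identical(out$variants$pos, fx$variants$pos[fx$clean_sites])
})

test_that("threshold boundaries are strict: a site sitting exactly on them survives", {
  sites <- variant_table("chr1", pos = c(1e5, 2e5),
                         site_stats = data.frame(
                           QD = c(2.0, 20), FS = c(60.0, 10), MQ = c(40.0, 55),
                           ReadPosRankSum = c(-8.0, 0), MQRankSum = c(-12.5, 0),
                           SOR = c(3.0, 1)))
  gm <- genotype_matrix(sprintf("A%02d", 1:10),
                        matrix(rep(c(0L, 1L, 2L), length.out = 20), 10, 2),
                        sites, gq = matrix(60L, 10, 2))
  out <- apply_site_filters(sites, gm, qc_thresholds(max_missing_individuals = 5L))
  expect_equal(out$report$n_sites_out, 2L)
})

test_that("genotype-quality and missingness rules use the printed cut-offs", {
  n <- 151L
  sites <- variant_table("chr1", pos = c(1e5, 2e5, 3e5))
  g <- matrix(rep(c(0L, 1L, 2L), length.out = n * 3), n, 3)
  gq <- matrix(60L, n, 3)
  gq[1, 1] <- 14L  # below: set missing
  gq[1, 2] <- 15L  # at cut-off: kept
  gm <- genotype_matrix(sprintf("A%03d", 1:n), g, sites, gq = gq)
  out <- apply_genotype_filters(gm)
  expect_true(is.na(out$genotypes$geno[1, 1]))
  expect_false(is.na(out$genotypes$geno[1, 2]))
  expect_equal(out$report$n_genotypes_set_missing, 1L)
  # 41 missing -> dropped, 40 -> kept
  g2 <- g
  g2[1:41, 1] <- NA_integer_
  g2[1:40, 2] <- NA_integer_
  gm2 <- genotype_matrix(sprintf("A%03d", 1:n), g2, sites,
                         gq = matrix(60L, n, 3))
  out2 <- apply_genotype_filters(gm2)
  expect_equal(out2$report$n_sites_out, 2L)
  expect_equal(out2$genotypes$sites$pos, c(2e5, 3e5))
})

test_that("dropping the GQ filter is the lenient scenario: never fewer sites survive", {
  fx <- make_fixture("qc-violations")
  strict <- apply_site_filters(fx$variants, fx$genotypes, qc_thresholds())
  lenient <- apply_site_filters(fx$variants, fx$genotypes,
                                qc_thresholds(apply_gq_filter = FALSE))
  expect_gte(lenient$report$n_sites_out, strict$report$n_sites_out)
  expect_equal(lenient$report$n_genotypes_set_missing, 0L)
})

test_that("filtering is idempotent and its report reconciles exactly", {
  fx <- make_fixture("qc-violations")
  pass1 <- apply_site_filters(fx$variants, fx$genotypes)
  expect_equal(pass1$report$n_sites_out,
               pass1$report$n_sites_in - sum(pass1$report$n_removed_by_rule))
  pass2 <- apply_site_filters(pass1$variants, pass1$genotypes)
  expect_identical(pass2$genotypes$geno, pass1$genotypes$geno)
  expect_equal(sum(pass2$report$n_removed_by_rule), 0L)
})

test_that("tightening any single threshold never increases the surviving site count", {
  cfg <- sim_config(n_founders = 20L, n_samples = 60L, n_chromosomes = 1L,
                    chrom_length_bp = 2e7, n_sites_per_chrom = 500L,
                    site_stat_fail = c(QD = 0.05, FS = 0.05, MQ = 0.05,
                                       ReadPosRankSum = 0.05, MQRankSum = 0.05,
                                       SOR = 0.05), seed = 17L)
  pop <- breed_population(simulate_founders(cfg), cfg)
  gm <- degrade_to_sequenced_genotypes(pop, cfg)
  base <- apply_site_filters(gm$sites, gm)
  tighter <- list(qc_thresholds(qd_min = 5), qc_thresholds(fs_max = 30),
                  qc_thresholds(mq_min = 50),
                  qc_thresholds(read_pos_rank_sum_min = -4),
                  qc_thresholds(mq_rank_sum_min = -6),
                  qc_thresholds(sor_max = 1.5),
                  qc_thresholds(maf_min = 0.05),
                  qc_thresholds(max_missing_individuals = 0L))
  for (th in tighter)
    expect_lte(apply_site_filters(gm$sites, gm, th)$report$n_sites_out,
               base$report$n_sites_out)
  # gq_min is monotone in the genotypes it blanks; the surviving site count
  # is not structurally monotone because MAF is recomputed afterwards
  expect_gte(apply_site_filters(gm$sites, gm,
                                qc_thresholds(gq_min = 40L))$report$n_genotypes_set_missing,
             base$report$n_genotypes_set_missing)
})

test_that("a missing site statistic disables that rule for the site", {
  sites <- variant_table("chr1", pos = c(1e5, 2e5),
                         site_stats = data.frame(QD = c(NA, 20), FS = c(10, 10),
                                                 MQ = c(55, 55)))
  gm <- genotype_matrix(sprintf("A%02d", 1:10),
                        matrix(rep(c(0L, 1L, 2L), length.out = 20), 10, 2),
                        sites, gq = matrix(60L, 10, 2))
  out <- apply_site_filters(sites, gm, qc_thresholds(max_missing_individuals = 5L))
  expect_equal(out$report$n_sites_out, 2L)
})

test_that("per-sample concordance counts identical codes over shared calls", {
  sites <- variant_table("chr1", pos = (1:4) * 1e5)
  a <- genotype_matrix(c("A", "B"), rbind(c(0L, 1L, 2L, 1L), c(0L, 0L, 0L, 0L)),
                       sites)
  expect_equal(unname(genotype_concordance(a, a)$per_sample), c(1, 1))
  b <- genotype_matrix(c("A", "B"), rbind(c(0L, 1L, 2L, 2L), c(0L, 0L, 0L, 0L)),
                       sites)
  cc <- genotype_concordance(a, b)
  expect_equal(unname(cc$per_sample["A"]), 0.75)
  expect_equal(cc$min, 0.75)
  expect_equal(cc$max, 1)
  miss <- genotype_matrix(c("A", "B"),
                          matrix(NA_integer_, 2, 4), sites)
  expect_error(genotype_concordance(a, miss), "no comparable")
  other <- genotype_matrix(c("A", "B"), rbind(c(0L, 1L), c(0L, 0L)),
                           variant_table("chr9", pos = c(1e5, 2e5)))
  expect_error(genotype_concordance(a, other), "no shared sites")
})
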