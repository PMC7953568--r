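fixture_catalogue <- c("tiny-panel", "exact-copy", "rare-variant-stress",
                       "qc-violations")

#' Deterministic fixtures for tests and documentation
#'
#' Small, fully reproducible datasets used throughout the test suite:
#' \describe{
#'   \item{tiny-panel}{4 reference haplotypes x 4 sites (2 array, 2 hidden)
#'     plus one phased target haplotype pair: small enough that HMM
#'     posteriors can be checked against exhaustive path enumeration.}
#'   \item{exact-copy}{a simulated reference panel whose first three samples
#'     are duplicated, error-free, as imputation targets; perfect recovery is
#'     expected from both engines.}
#'   \item{rare-variant-stress}{a simulated population with a strongly
#'     rare-skewed spectrum for stress-testing MAF stratification.}
#'   \item{qc-violations}{151 samples with constructed sites violating, one
#'     each, every site-statistic rule, the missingness rule directly, the
#'     missingness rule via low GQ, and the MAF rule, plus five clean sites.}
#' }
#'
#' @param name one of the catalogue names above.
#' @param dir optional directory: fixture files (VCF/TSV) are written there.
#' @return a named list of in-memory objects (contents depend on the
#'   fixture).
#' @export
make_fixture <- function(name, dir = NULL) {
  if (!name %in% fixture_catalogue)
    stop(sprintf("unknown fixture '%s'; catalogue: %s", name,
                 paste(fixture_catalogue, collapse = ", ")), call. = FALSE)
  fx <- switch(name,
               "tiny-panel" = fixture_tiny_panel(),
               "exact-copy" = fixture_exact_copy(),
               "rare-variant-stress" = fixture_rare_stress(),
               "qc-violations" = fixture_qc_violations())
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(fx$reference))
      write_panel_vcf(fx$reference, file.path(dir, paste0(name, "-reference.vcf")))
    gm <- fx$genotypes %||% fx$observed
    if (!is.null(gm))
      write_genotype_vcf(gm, file.path(dir, paste0(name, "-genotypes.vcf")))
  }
  fx
}

fixture_tiny_panel <- function() {
  sites <- variant_table(chrom = "chr1", pos = c(1e6, 2e6, 3e6, 4e6))
  sites$on_array <- c(TRUE, FALSE, FALSE, TRUE)
  H <- rbind(c(0L, 0L, 1L, 0L),
             c(1L, 0L, 0L, 1L),
             c(0L, 1L, 1L, 1L),
             c(1L, 1L, 0L, 0L))
  reference <- haplotype_panel(c("R1", "R2"), H, sites)
  arr <- which(sites$on_array)
  tsites <- sites[arr, , drop = FALSE]
  rownames(tsites) <- NULL
  target_haps <- haplotype_panel("T1", rbind(c(0L, 0L), c(1L, 1L)), tsites)
  list(reference = reference, target_haps = target_haps,
       array_idx = arr, sites = sites)
}

fixture_exact_copy <- function() {
  cfg <- sim_config(n_founders = 12L, n_samples = 12L, n_chromosomes = 1L,
                    chrom_length_bp = 2e7, n_sites_per_chrom = 400L,
                    array_fraction = 0.1, genotype_error_rate = 0,
                    mosaic_switch_rate = 0.02, seed = 42L)
  reference <- simulate_founders(cfg)
  reference$sites <- select_array_sites(reference$sites, cfg$array_fraction,
                                        seed = 43L)
  targets <- paste0("T", 1:3)
  src <- match(reference$sample_ids[1:3], reference$sample_ids)
  truth <- haplotype_panel(targets,
                           reference$haplotypes[hap_rows(src), , drop = FALSE],
                           reference$sites)
  observed <- genotype_matrix(targets, panel_genotypes(truth), reference$sites)
  arr <- which(reference$sites$on_array)
  asites <- reference$sites[arr, , drop = FALSE]
  rownames(asites) <- NULL
  target_arr <- genotype_matrix(targets,
                                panel_genotypes(truth)[, arr, drop = FALSE],
                                asites)
  list(reference = reference, truth = truth, observed = observed,
       target_arr = target_arr, array_idx = arr)
}

fixture_rare_stress <- function() {
  cfg <- sim_config(n_founders = 40L, n_samples = 80L, n_chromosomes = 1L,
                    chrom_length_bp = 5e7, n_sites_per_chrom = 2000L,
                    sfs_shape = 0.15, seed = 7L)
  pop <- breed_population(simulate_founders(cfg), cfg)
  pop$sites <- select_array_sites(pop$sites, 0.05, seed = 8L)
  list(population = pop, config = cfg)
}

fixture_qc_violations <- function() {
  n <- 151L
  m <- 14L
  pos <- seq(1e5, by = 1e5, length.out = m)
  sites <- variant_table(chrom = "chr1", pos = pos)
  pass <- list(QD = 20, FS = 10, MQ = 55, ReadPosRankSum = 0, MQRankSum = 0,
               SOR = 1)
  for (s in names(pass)) sites[[s]] <- pass[[s]]
  fail_vals <- c(QD = 1.5, FS = 75, MQ = 30, ReadPosRankSum = -9,
                 MQRankSum = -13, SOR = 3.5)
  for (j in seq_along(fail_vals)) sites[[names(fail_vals)[j]]][j] <- fail_vals[[j]]
  # genotypes: a deterministic common-variant pattern (MAF ~ 1/3)
  g <- matrix(rep_len(c(0L, 1L, 1L, 0L, 2L, 0L), n * m), nrow = n)
  gq <- matrix(60L, n, m)
  gq[seq_len(41L), 7L] <- 10L          # low-GQ genotypes -> 41 missing
  g[seq_len(41L), 8L] <- NA_integer_   # directly missing in 41 samples
  g[, 9L] <- 0L; g[1L, 9L] <- 1L       # MAF = 1/302 < 0.01
  gm <- genotype_matrix(sprintf("A%03d", seq_len(n)), g, sites, gq = gq)
  list(variants = sites, genotypes = gm,
       violating_sites = stats::setNames(seq_len(9L),
                                         c(names(fail_vals), "gq_missing",
                                           "missingness", "maf")),
       clean_sites = 10:14)
}
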