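#' Quality-control thresholds
#'
#' GATK-style site-statistic exclusion criteria plus genotype-level rules.
#' Removal uses strict inequalities exactly as printed in the defaults: a
#' site is removed when `QD < 2.0`, `FS > 60.0`, `MQ < 40.0`,
#' `ReadPosRankSum < -8.0`, `MQRankSum < -12.5` or `SOR > 3.0`; genotypes with
#' `GQ < 15` are set missing; sites missing in more than
#' `max_missing_individuals` samples are dropped; finally sites with
#' recomputed MAF below `maf_min` are dropped.
#'
#' @param qd_min,fs_max,mq_min,read_pos_rank_sum_min,mq_rank_sum_min,sor_max
#'   site-statistic thresholds.
#' @param maf_min minimum minor allele frequency in \[0, 0.5).
#' @param gq_min minimum phred-scaled genotype quality.
#' @param max_missing_individuals absolute missing-sample count above which a
#'   site is dropped; when NULL it is derived as
#'   `round(missing_fraction * n_samples)` at filter time.
#' @param missing_fraction companion fraction used when the cohort size
#'   differs from the one the absolute count was defined for (default 0.265).
#' @param apply_gq_filter set FALSE for the less strict genotype-filtering
#'   scenario in which GQ is ignored.
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(qd_min = 2.0, fs_max = 60.0, mq_min = 40.0,
                          read_pos_rank_sum_min = -8.0,
                          mq_rank_sum_min = -12.5, sor_max = 3.0,
                          maf_min = 0.01, gq_min = 15L,
                          max_missing_individuals = 40L,
                          missing_fraction = 0.265,
                          apply_gq_filter = TRUE) {
  th <- list(qd_min = qd_min, fs_max = fs_max, mq_min = mq_min,
             read_pos_rank_sum_min = read_pos_rank_sum_min,
             mq_rank_sum_min = mq_rank_sum_min, sor_max = sor_max,
             maf_min = maf_min, gq_min = gq_min,
             max_missing_individuals = max_missing_individuals,
             missing_fraction = missing_fraction,
             apply_gq_filter = isTRUE(apply_gq_filter))
  num <- unlist(th[1:8])
  if (any(!is.finite(num))) stop("qc_thresholds: all thresholds must be finite", call. = FALSE)
  if (!is_fraction(maf_min, 0, 0.5, open_hi = TRUE))
    stop("qc_thresholds: maf_min must lie in [0, 0.5)", call. = FALSE)
  class(th) <- "qc_thresholds"
  th
}

qc_report <- function(n_sites_in, removed, n_genotypes_set_missing, n_sites_out) {
  stopifnot(n_sites_out == n_sites_in - sum(removed))
  structure(list(n_sites_in = n_sites_in, n_removed_by_rule = removed,
                 n_genotypes_set_missing = n_genotypes_set_missing,
                 n_sites_out = n_sites_out),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d sites in -> %d out; %d genotypes set missing\n",
              x$n_sites_in, x$n_sites_out, x$n_genotypes_set_missing))
  rm <- x$n_removed_by_rule[x$n_removed_by_rule > 0]
  for (r in names(rm)) cat(sprintf("  removed by %s: %d\n", r, rm[[r]]))
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report a `qc_report` from [apply_site_filters()] or
#'   [apply_genotype_filters()].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

site_stat_violations <- function(sites, th) {
  viol <- cbind(
    QD = !is.na(sites$QD) & sites$QD < th$qd_min,
    FS = !is.na(sites$FS) & sites$FS > th$fs_max,
    MQ = !is.na(sites$MQ) & sites$MQ < th$mq_min,
    ReadPosRankSum = !is.na(sites$ReadPosRankSum) &
      sites$ReadPosRankSum < th$read_pos_rank_sum_min,
    MQRankSum = !is.na(sites$MQRankSum) & sites$MQRankSum < th$mq_rank_sum_min,
    SOR = !is.na(sites$SOR) & sites$SOR > th$sor_max)
  viol
}

#' Apply genotype-level quality filters
#'
#' Genotypes with `GQ < gq_min` are set missing (skipped entirely when
#' `apply_gq_filter` is FALSE, the less strict scenario); sites missing in
#' strictly more than `max_missing_individuals` samples are then dropped.
#'
#' @param genotypes a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list(genotypes = filtered [genotype_matrix()], report = [qc_report]).
#' @export
apply_genotype_filters <- function(genotypes, thresholds = qc_thresholds()) {
  th <- thresholds
  g <- genotypes$geno
  n_set <- 0L
  if (th$apply_gq_filter) {
    if (is.null(genotypes$gq))
      stop("apply_genotype_filters: GQ required when apply_gq_filter is TRUE", call. = FALSE)
    low <- !is.na(g) & genotypes$gq < th$gq_min
    n_set <- sum(low)
    g[low] <- NA_integer_
  }
  max_missing <- th$max_missing_individuals %||%
    round(th$missing_fraction * nrow(g))
  if (max_missing >= nrow(g))
    warning("max_missing_individuals >= n_samples: missingness rule is vacuous")
  keep <- colSums(is.na(g)) <= max_missing
  out <- genotype_matrix(genotypes$sample_ids, g[, keep, drop = FALSE],
                         {s <- genotypes$sites[keep, , drop = FALSE]; rownames(s) <- NULL; s},
                         gq = if (!is.null(genotypes$gq))
                           genotypes$gq[, keep, drop = FALSE])
  rep <- qc_report(ncol(genotypes$geno),
                   c(missingness = sum(!keep)), n_set, sum(keep))
  list(genotypes = out, report = rep)
}

#' Apply the full site and genotype quality-control cascade
#'
#' Removal order: site-statistic rules (each applied with strict inequality;
#' a missing statistic means that rule is skipped for that site), then the
#' non-biallelic rule, then the genotype rules (GQ-to-missing and the
#' missing-individuals site drop), and finally the MAF rule with MAF
#' recomputed on the post-missingness genotypes. A site violating several
#' statistic rules is counted under the first rule in the order
#' QD, FS, MQ, ReadPosRankSum, MQRankSum, SOR.
#'
#' @param variants a [variant_table()] (used for site statistics and alleles);
#'   must describe the same sites as `genotypes`.
#' @param genotypes a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list(variants, genotypes, report).
#' @export
apply_site_filters <- function(variants, genotypes,
                               thresholds = qc_thresholds()) {
  th <- thresholds
  stopifnot(nrow(variants) == ncol(genotypes$geno))
  n_in <- nrow(variants)
  viol <- site_stat_violations(variants, th)
  first_rule <- apply(viol, 1, function(v) if (any(v)) which(v)[1] else 0L)
  removed_stats <- vapply(seq_len(ncol(viol)), function(j) sum(first_rule == j), 0L)
  names(removed_stats) <- colnames(viol)
  keep <- first_rule == 0L
  nt <- c("A", "C", "G", "T")
  biallelic <- variants$ref_allele %in% nt & variants$alt_allele %in% nt &
    variants$ref_allele != variants$alt_allele
  removed_biallelic <- sum(keep & !biallelic)
  keep <- keep & biallelic
  gm <- genotype_matrix(genotypes$sample_ids,
                        genotypes$geno[, keep, drop = FALSE],
                        {s <- variants[keep, , drop = FALSE]; rownames(s) <- NULL; s},
                        gq = if (!is.null(genotypes$gq))
                          genotypes$gq[, keep, drop = FALSE])
  gstep <- apply_genotype_filters(gm, th)
  gm <- gstep$genotypes
  maf <- compute_maf(gm)
  keep_maf <- !is.na(maf) & maf >= th$maf_min
  removed_maf <- sum(!keep_maf)
  sites <- gm$sites[keep_maf, , drop = FALSE]
  rownames(sites) <- NULL
  sites$maf <- maf[keep_maf]
  out <- genotype_matrix(gm$sample_ids, gm$geno[, keep_maf, drop = FALSE],
                         sites,
                         gq = if (!is.null(gm$gq)) gm$gq[, keep_maf, drop = FALSE])
  removed <- c(removed_stats, biallelic = removed_biallelic,
               gstep$report$n_removed_by_rule, maf = removed_maf)
  if (ncol(out$geno) == 0L) {
    last <- names(removed)[max(which(removed > 0))]
    stop(sprintf("apply_site_filters: no sites survive; last removals by rule '%s'", last),
         call. = FALSE)
  }
  report <- qc_report(n_in, removed, gstep$report$n_genotypes_set_missing,
                      ncol(out$geno))
  list(variants = out$sites, genotypes = out, report = report)
}

#' Per-sample genotype concordance between two matrices
#'
#' Fraction of identical genotype codes at the shared, pairwise non-missing
#' sites of each shared sample, with a mean/min/max summary; the usual check
#' of array genotypes against sequencing-derived calls.
#'
#' @param a,b [genotype_matrix()] objects sharing samples and sites.
#' @return list(per_sample = named fractions, mean, min, max).
#' @export
genotype_concordance <- function(a, b) {
  samples <- intersect(a$sample_ids, b$sample_ids)
  if (length(samples) == 0L) stop("genotype_concordance: no shared samples", call. = FALSE)
  key_a <- paste(a$sites$chrom, a$sites$pos)
  key_b <- paste(b$sites$chrom, b$sites$pos)
  shared <- intersect(key_a, key_b)
  if (length(shared) == 0L) stop("genotype_concordance: no shared sites", call. = FALSE)
  ga <- a$geno[match(samples, a$sample_ids), match(shared, key_a), drop = FALSE]
  gb <- b$geno[match(samples, b$sample_ids), match(shared, key_b), drop = FALSE]
  ok <- !is.na(ga) & !is.na(gb)
  n_ok <- rowSums(ok)
  if (all(n_ok == 0L)) stop("genotype_concordance: no comparable genotype pairs", call. = FALSE)
  conc <- rowSums(ga == gb & ok, na.rm = TRUE) / n_ok
  names(conc) <- samples
  list(per_sample = conc, mean = mean(conc, na.rm = TRUE),
       min = min(conc, na.rm = TRUE), max = max(conc, na.rm = TRUE))
}
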