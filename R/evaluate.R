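#' Build a balanced cross-validation plan
#'
#' Randomly partitions samples into `n_folds` groups whose sizes differ by at
#' most one (the earliest folds take the remainder, e.g. 151 samples in five
#' folds gives sizes 31/30/30/30/30).
#'
#' @param sample_ids character vector of sample ids.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed; the plan is seed-deterministic.
#' @return a list of class `cv_plan` with `n_folds`, `fold_of` (named integer
#'   vector) and `seed`.
#' @export
make_folds <- function(sample_ids, n_folds = 5L, seed = 1L) {
  n <- length(sample_ids)
  if (!is_count(n_folds, 2)) stop("make_folds: n_folds must be >= 2", call. = FALSE)
  if (n_folds > n) stop("make_folds: n_folds exceeds number of samples", call. = FALSE)
  local_seed(seed)
  perm <- sample(sample_ids)
  sizes <- rep(n %/% n_folds, n_folds) + c(rep(1L, n %% n_folds),
                                           rep(0L, n_folds - n %% n_folds))
  fold_of <- stats::setNames(rep(seq_len(n_folds), times = sizes), perm)[sample_ids]
  structure(list(n_folds = as.integer(n_folds), fold_of = fold_of, seed = seed),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> %d folds over %d samples (sizes %s)\n", x$n_folds,
              length(x$fold_of), paste(table(x$fold_of), collapse = "/")))
  invisible(x)
}

#' Mask a fold's genotypes down to the array panel
#'
#' For every sample in the given fold, genotypes at non-array sites are set
#' missing; all other samples (the imputation reference for that fold) are
#' untouched.
#'
#' @param genotypes a [genotype_matrix()] whose sites carry `on_array` flags.
#' @param fold fold id present in the plan.
#' @param plan a [make_folds()] plan.
#' @return the masked [genotype_matrix()].
#' @export
mask_to_panel <- function(genotypes, fold, plan) {
  if (!fold %in% plan$fold_of)
    stop(sprintf("mask_to_panel: fold %s not in plan", fold), call. = FALSE)
  in_fold <- names(plan$fold_of)[plan$fold_of == fold]
  rows <- match(intersect(in_fold, genotypes$sample_ids), genotypes$sample_ids)
  g <- genotypes$geno
  g[rows, !genotypes$sites$on_array] <- NA_integer_
  genotype_matrix(genotypes$sample_ids, g, genotypes$sites, gq = genotypes$gq)
}

#' Percentage of sites to be imputed
#'
#' 100 x (n_reference_sites - n_array_sites) / n_reference_sites, reported to
#' two decimals: the fraction of sequence sites absent from the array panel.
#'
#' @param n_reference_sites number of sites in the sequenced reference.
#' @param n_array_sites number of those sites on the array panel.
#' @return percentage rounded to 2 decimals.
#' @export
impute_fraction <- function(n_reference_sites, n_array_sites) {
  if (n_reference_sites <= 0) stop("impute_fraction: n_reference_sites must be positive", call. = FALSE)
  if (n_array_sites < 0 || n_array_sites > n_reference_sites)
    stop("impute_fraction: need 0 <= n_array_sites <= n_reference_sites", call. = FALSE)
  round(100 * (n_reference_sites - n_array_sites) / n_reference_sites, 2)
}

window_of <- function(pos, width = 1e6) (pos - 1L) %/% as.integer(width)

# Vectorised per-column Pearson r between observed (with NA) and imputed.
col_pearson <- function(obs, imp) {
  ok <- !is.na(obs)
  n <- colSums(ok)
  o <- ifelse(ok, obs, 0)
  d <- ifelse(ok, imp, 0)
  sx <- colSums(o); sy <- colSums(d)
  sxx <- colSums(o * o); syy <- colSums(d * d); sxy <- colSums(o * d)
  vx <- n * sxx - sx^2
  vy <- n * syy - sy^2
  r <- (n * sxy - sx * sy) / sqrt(pmax(vx, 0) * pmax(vy, 0))
  list(n = n, vx = vx, vy = vy, r = r)
}

#' Per-SNP imputation accuracy
#'
#' For every imputed (non-array) site, computes the squared Pearson
#' correlation between observed genotype codes and imputed values across the
#' fold samples (pairwise-complete over missing truth) and PERC, the
#' percentage of hard-called genotypes identical to the observed ones. Sites
#' where either vector is constant, or with fewer than two called truth
#' genotypes, carry an undefined-R2 reason code (`constant_observed`,
#' `constant_imputed`, `too_few`); PERC is still reported for them.
#'
#' @param observed a [genotype_matrix()] holding the unmasked truth.
#' @param result an [imputation_result()] on the same site set.
#' @param fold_samples character vector: samples that were masked and imputed.
#' @param fold fold id recorded in the output (default NA).
#' @param compare `"dosage"` (default, when dosages exist) or `"best_guess"`:
#'   the imputed value entering the correlation.
#' @return a data.frame, one row per scored site: chrom, pos, maf,
#'   impact_class, window, fold, engine, n_called, r2, r2_reason, perc, rsq.
#' @export
per_snp_accuracy <- function(observed, result, fold_samples, fold = NA_integer_,
                             compare = c("dosage", "best_guess")) {
  compare <- match.arg(compare)
  scored <- which(!result$sites$on_array)
  orow <- match(fold_samples, observed$sample_ids)
  irow <- match(fold_samples, result$sample_ids)
  if (anyNA(orow) || anyNA(irow))
    stop("per_snp_accuracy: fold samples missing from inputs", call. = FALSE)
  obs <- observed$geno[orow, scored, drop = FALSE]
  imp <- if (compare == "dosage" && !is.null(result$dosage))
    result$dosage[irow, scored, drop = FALSE]
  else result$best_guess[irow, scored, drop = FALSE]
  bg <- result$best_guess[irow, scored, drop = FALSE]
  st <- col_pearson(obs, imp)
  r2 <- st$r^2
  reason <- rep(NA_character_, length(scored))
  reason[st$vy <= 1e-12] <- "constant_imputed"
  reason[st$vx <= 1e-12] <- "constant_observed"
  reason[st$n < 2L] <- "too_few"
  r2[!is.na(reason)] <- NA_real_
  ok <- !is.na(obs)
  perc <- ifelse(colSums(ok) > 0,
                 100 * colSums(bg == obs & ok, na.rm = TRUE) / colSums(ok),
                 NA_real_)
  s <- result$sites[scored, , drop = FALSE]
  data.frame(chrom = s$chrom, pos = s$pos, maf = s$maf,
             impact_class = s$impact_class, window = window_of(s$pos),
             fold = fold, engine = result$engine, n_called = st$n,
             r2 = r2, r2_reason = reason, perc = perc,
             rsq = result$rsq[scored], stringsAsFactors = FALSE)
}

#' Per-animal imputation accuracy
#'
#' The same two statistics computed across all imputed sites within each fold
#' sample. Animals with no called truth genotypes are excluded with a
#' warning.
#'
#' @inheritParams per_snp_accuracy
#' @return a data.frame, one row per fold sample: sample, fold, engine,
#'   n_called, r2, perc.
#' @export
per_animal_accuracy <- function(observed, result, fold_samples,
                                fold = NA_integer_,
                                compare = c("dosage", "best_guess")) {
  compare <- match.arg(compare)
  scored <- which(!result$sites$on_array)
  rows <- lapply(fold_samples, function(sid) {
    o <- observed$geno[match(sid, observed$sample_ids), scored]
    d <- if (compare == "dosage" && !is.null(result$dosage))
      result$dosage[match(sid, result$sample_ids), scored]
    else result$best_guess[match(sid, result$sample_ids), scored]
    bg <- result$best_guess[match(sid, result$sample_ids), scored]
    ok <- !is.na(o)
    if (!any(ok)) {
      warning(sprintf("per_animal_accuracy: %s has no called truth genotypes; excluded", sid))
      return(NULL)
    }
    r2 <- if (sum(ok) >= 2 && var(o[ok]) > 0 && var(d[ok]) > 0)
      cor(o[ok], d[ok])^2 else NA_real_
    data.frame(sample = sid, fold = fold, engine = result$engine,
               n_called = sum(ok), r2 = r2,
               perc = 100 * mean(bg[ok] == o[ok]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Mean/SD/min/max summary of per-animal accuracy
#'
#' @param per_animal a data.frame from [per_animal_accuracy()] (possibly
#'   several folds bound together).
#' @return a one-row data.frame per engine with r2 and perc summaries.
#' @export
per_animal_summary <- function(per_animal) {
  do.call(rbind, lapply(split(per_animal, per_animal$engine), function(d) {
    data.frame(engine = d$engine[1], n = nrow(d),
               r2_mean = mean(d$r2, na.rm = TRUE),
               r2_sd = stats::sd(d$r2, na.rm = TRUE),
               r2_min = min(d$r2, na.rm = TRUE),
               r2_max = max(d$r2, na.rm = TRUE),
               perc_mean = mean(d$perc, na.rm = TRUE),
               perc_sd = stats::sd(d$perc, na.rm = TRUE),
               perc_min = min(d$perc, na.rm = TRUE),
               perc_max = max(d$perc, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
}

#' Stratified accuracy summaries
#'
#' Summarises per-SNP accuracy by stratum: `maf_class` (the two-class split
#' at MAF 0.03), `maf_bin` (fine bins of the given width, for curves),
#' `impact_class`, or `window` (1-Mb half-open genomic windows per
#' chromosome). Each stratum row reports min, first quartile, median, mean,
#' third quartile and max (linear-interpolation quartiles) of the chosen
#' statistic over sites where it is defined; empty strata are emitted with
#' count 0.
#'
#' @param frame a per-SNP accuracy data.frame from [per_snp_accuracy()].
#' @param scheme stratification scheme.
#' @param statistic which per-site statistic to summarise.
#' @param maf_bin_width bin width for `scheme = "maf_bin"` (default 0.01).
#' @return a data.frame with one row per (engine, stratum).
#' @export
stratify_accuracy <- function(frame,
                              scheme = c("maf_class", "maf_bin",
                                         "impact_class", "window"),
                              statistic = c("r2", "perc", "rsq"),
                              maf_bin_width = 0.01) {
  scheme <- match.arg(scheme)
  statistic <- match.arg(statistic)
  stratum <- switch(scheme,
    maf_class = factor(ifelse(frame$maf <= 0.03, "maf<=0.03", "maf>0.03"),
                       levels = c("maf<=0.03", "maf>0.03")),
    maf_bin = {
      b <- floor(frame$maf / maf_bin_width) * maf_bin_width
      factor(sprintf("[%.2f,%.2f)", b, b + maf_bin_width))
    },
    impact_class = factor(frame$impact_class, levels = IMPACT_CLASSES),
    window = factor(paste0(frame$chrom, ":", frame$window)))
  out <- do.call(rbind, lapply(split(frame, list(frame$engine, stratum),
                                     drop = FALSE, sep = "\r"), function(d) {
    s <- six_num(d[[statistic]])
    s
  }))
  key <- strsplit(rownames(out), "\r", fixed = TRUE)
  out <- cbind(data.frame(engine = vapply(key, `[`, "", 1),
                          stratum = vapply(key, `[`, "", 2),
                          statistic = statistic, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out[order(out$engine, out$stratum), ]
}

#' Model Rsq against empirical accuracy by MAF bin
#'
#' Bins sites by MAF and reports the binned means of the empirical R2 and of
#' the model Rsq (a fixed-width binned-mean smoother), together with the
#' overall correlation between the two statistics and the mean signed
#' difference (Rsq minus R2); a negative mean difference indicates the model
#' statistic underestimates realised accuracy.
#'
#' @param frame a per-SNP accuracy data.frame with defined `r2` and `rsq`.
#' @param maf_bin_width MAF bin width (default 0.01).
#' @return list(curve = per-bin data.frame, correlation, mean_signed_diff, n).
#' @export
rsq_calibration <- function(frame, maf_bin_width = 0.01) {
  d <- frame[!is.na(frame$r2) & !is.na(frame$rsq), , drop = FALSE]
  if (nrow(d) == 0L)
    stop("rsq_calibration: no sites with both statistics defined", call. = FALSE)
  b <- floor(d$maf / maf_bin_width) * maf_bin_width
  curve <- do.call(rbind, lapply(split(d, b), function(x) {
    data.frame(maf_bin = floor(x$maf[1] / maf_bin_width) * maf_bin_width,
               n = nrow(x), mean_r2 = mean(x$r2), mean_rsq = mean(x$rsq))
  }))
  curve <- curve[order(curve$maf_bin), ]
  rownames(curve) <- NULL
  list(curve = curve,
       correlation = if (nrow(d) >= 2 && var(d$r2) > 0 && var(d$rsq) > 0)
         cor(d$r2, d$rsq) else NA_real_,
       mean_signed_diff = mean(d$rsq - d$r2), n = nrow(d))
}
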