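#' Full-run configuration
#'
#' Bundles the per-stage configurations of an end-to-end evaluation run:
#' simulation, quality control, reference selection, cross-validation and
#' the two imputation engines.
#'
#' @param sim a [sim_config()].
#' @param qc a [qc_thresholds()].
#' @param hmm an [hmm_params()].
#' @param osw an [osw_params()].
#' @param engines subset of c("lshmm", "osw").
#' @param n_sequenced number of animals selected (via GRM k-means) as the
#'   sequenced cohort over which cross-validation runs.
#' @param n_folds number of cross-validation folds.
#' @param folds fold ids to execute (default all); running a single fold is a
#'   legitimate scaled-down masking experiment.
#' @param per_snp_mode `"pooled"` (default): per-SNP statistics are computed
#'   once per site over all cross-validated animals, each imputed in its own
#'   fold, so a site is undefined only when truth or imputed values are
#'   constant over the whole cohort; `"foldwise"`: one record per site and
#'   fold, computed over that fold's animals only.
#' @param cv_seed seed of the fold plan (default `sim$seed + 3`).
#' @param verbose print stage-by-stage dimensions.
#' @return a list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), qc = qc_thresholds(),
                       hmm = hmm_params(), osw = osw_params(),
                       engines = c("lshmm", "osw"), n_sequenced = 150L,
                       n_folds = 5L, folds = NULL,
                       per_snp_mode = c("pooled", "foldwise"), cv_seed = NULL,
                       verbose = FALSE) {
  per_snp_mode <- match.arg(per_snp_mode)
  stopifnot(all(engines %in% c("lshmm", "osw")), length(engines) >= 1)
  if (!is_count(n_sequenced, 2)) stop_field("n_sequenced", "count >= 2 required")
  if (n_sequenced > sim$n_samples) stop_field("n_sequenced", "exceeds n_samples")
  structure(list(sim = sim, qc = qc, hmm = hmm, osw = osw, engines = engines,
                 n_sequenced = as.integer(n_sequenced),
                 n_folds = as.integer(n_folds),
                 folds = folds, per_snp_mode = per_snp_mode,
                 cv_seed = cv_seed %||% (sim$seed + 3L),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Serialise / restore a run configuration
#'
#' JSON round-trip: `read_run_config(write_run_config(cfg, path))` restores an
#' identical object (all stage configs are rebuilt through their validating
#' constructors).
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `write_run_config` the path; `read_run_config` a [run_config()].
#' @export
write_run_config <- function(config, path) {
  sim <- unclass(config$sim)
  # named vectors must serialise as objects, not bare arrays
  for (f in c("gq_distribution_params", "annotation_proportions",
              "site_stat_fail"))
    sim[[f]] <- as.list(sim[[f]])
  plain <- list(sim = sim, qc = unclass(config$qc),
                hmm = unclass(config$hmm)[c("n_states_cap", "mutation_rate",
                                            "recomb_scale")],
                osw = unclass(config$osw),
                engines = config$engines, n_sequenced = config$n_sequenced,
                n_folds = config$n_folds, folds = config$folds,
                per_snp_mode = config$per_snp_mode,
                cv_seed = config$cv_seed, verbose = config$verbose)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_named <- function(x) if (is.list(x)) unlist(x) else x
  run_config(
    sim = do.call(sim_config, lapply(p$sim, as_named)),
    qc = do.call(qc_thresholds, p$qc),
    hmm = do.call(hmm_params, p$hmm),
    osw = do.call(osw_params, p$osw),
    engines = p$engines, n_sequenced = p$n_sequenced, n_folds = p$n_folds,
    folds = p$folds, per_snp_mode = p$per_snp_mode, cv_seed = p$cv_seed,
    verbose = p$verbose)
}

#' Run the full evaluation pipeline
#'
#' Sequences the stages: simulate founders and breed a study population;
#' degrade truth to sequencing-style genotypes; apply the QC cascade; assign
#' functional annotations; ascertain array sites; select the sequenced cohort
#' by GRM k-means with progeny-count representatives; build the fold plan;
#' and, per fold and engine, mask, impute and score. Identical configuration
#' and seed yield byte-identical artifacts (asserted via manifest checksums).
#'
#' @param config a [run_config()].
#' @param out_dir directory for artifacts (created; default a fresh tempdir).
#' @return list of class `run_result`: accuracy tables, stratified summaries,
#'   calibration, the QC report, the fold plan, and a `manifest` with
#'   artifact paths and md5 checksums.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("impeval")) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (config$verbose) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  founders <- stage("simulate", simulate_founders(config$sim))
  pop <- stage("breed", breed_population(founders, config$sim))
  say("population: %d samples x %d sites", n_samples(pop), nrow(pop$sites))
  raw <- stage("degrade", degrade_to_sequenced_genotypes(pop, config$sim))
  qcres <- stage("qc", apply_site_filters(raw$sites, raw, config$qc))
  gm <- qcres$genotypes
  say("qc: %d -> %d sites", qcres$report$n_sites_in, qcres$report$n_sites_out)
  sites <- stage("annotate",
                 assign_annotations(gm$sites, config$sim, config$sim$seed + 4L))
  sites <- stage("array",
                 select_array_sites(sites, config$sim$array_fraction,
                                    config$sim$seed + 5L))
  gm$sites <- sites
  truth <- subset_panel(pop, site_idx = match(site_key(sites),
                                              site_key(pop$sites)))
  truth$sites <- sites
  say("array: %d of %d sites flagged (%.2f%% to impute)",
      sum(sites$on_array), nrow(sites),
      impute_fraction(nrow(sites), sum(sites$on_array)))

  arr_idx <- which(sites$on_array)
  gm_arr <- genotype_matrix(gm$sample_ids, gm$geno[, arr_idx, drop = FALSE],
                            {s <- sites[arr_idx, , drop = FALSE]; rownames(s) <- NULL; s},
                            gq = if (!is.null(gm$gq)) gm$gq[, arr_idx, drop = FALSE])
  seq_cohort <- stage("select-ref", {
    grm <- compute_grm(gm_arr)
    asg <- kmeans_reference_clusters(grm, k = config$n_sequenced,
                                     seed = config$sim$seed + 6L)
    local_seed(config$sim$seed + 7L)
    progeny <- stats::setNames(rpois(length(gm$sample_ids), 20), gm$sample_ids)
    asg <- pick_representatives(asg, progeny)
    sort(unname(asg$representatives))
  })
  say("sequenced cohort: %d animals", length(seq_cohort))
  plan <- make_folds(seq_cohort, config$n_folds, config$cv_seed)
  folds <- config$folds %||% seq_len(config$n_folds)
  per_snp <- list(); per_animal <- list()
  pooled <- list()  # engine -> stacked fold results
  for (fold in folds) {
    fold_samples <- names(plan$fold_of)[plan$fold_of == fold]
    ref_samples <- setdiff(seq_cohort, fold_samples)
    reference <- subset_panel(truth, ref_samples)
    masked <- mask_to_panel(gm, fold, plan)
    trow <- match(fold_samples, masked$sample_ids)
    target_arr <- genotype_matrix(fold_samples,
                                  masked$geno[trow, arr_idx, drop = FALSE],
                                  gm_arr$sites)
    for (eng in config$engines) {
      res <- stage(paste0("impute-", eng), switch(eng,
        lshmm = impute_ls_hmm(reference, prephase_target(target_arr, reference),
                              config$hmm),
        osw = impute_osw(reference, target_arr, config$osw)))
      if (config$per_snp_mode == "pooled")
        pooled[[eng]] <- c(pooled[[eng]], list(res))
      else
        per_snp[[paste(eng, fold)]] <-
          per_snp_accuracy(gm, res, fold_samples, fold)
      per_animal[[paste(eng, fold)]] <-
        per_animal_accuracy(gm, res, fold_samples, fold)
      say("fold %d engine %s scored", fold, eng)
    }
  }
  if (config$per_snp_mode == "pooled") {
    for (eng in names(pooled)) {
      parts <- pooled[[eng]]
      ids <- unlist(lapply(parts, `[[`, "sample_ids"))
      dosage <- do.call(rbind, lapply(parts, `[[`, "dosage"))
      bg <- do.call(rbind, lapply(parts, `[[`, "best_guess"))
      p_all <- colMeans(dosage) / 2
      combined <- imputation_result(ids, dosage, bg, rsq_from_dosage(dosage),
                                    parts[[1]]$sites, engine = eng)
      per_snp[[eng]] <- per_snp_accuracy(gm, combined, ids, fold = NA_integer_)
    }
  }
  per_snp <- do.call(rbind, per_snp); rownames(per_snp) <- NULL
  per_animal <- do.call(rbind, per_animal); rownames(per_animal) <- NULL
  strata <- list(maf_class = stratify_accuracy(per_snp, "maf_class"),
                 impact = stratify_accuracy(per_snp, "impact_class"),
                 window = stratify_accuracy(per_snp, "window"))
  calibration <- lapply(split(per_snp, per_snp$engine), rsq_calibration)

  paths <- c(per_snp = file.path(out_dir, "per_snp_accuracy.tsv"),
             per_animal = file.path(out_dir, "per_animal_accuracy.tsv"),
             maf_class = file.path(out_dir, "strata_maf_class.tsv"),
             impact = file.path(out_dir, "strata_impact.tsv"))
  write.table(per_snp, paths["per_snp"], sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(per_animal, paths["per_animal"], sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(strata$maf_class, paths["maf_class"], sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(strata$impact, paths["impact"], sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    seed = config$sim$seed, cv_seed = config$cv_seed,
    engines = config$engines, folds = folds,
    n_sites_qc = nrow(sites), n_array_sites = length(arr_idx),
    pct_to_impute = impute_fraction(nrow(sites), length(arr_idx)),
    sequenced_cohort = seq_cohort,
    artifacts = as.list(paths),
    checksums = as.list(tools::md5sum(paths)),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(config = config, qc_report = qcres$report, sites = sites,
                 plan = plan, sequenced = seq_cohort, per_snp = per_snp,
                 per_animal = per_animal, strata = strata,
                 calibration = calibration, manifest = manifest,
                 out_dir = out_dir),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %d scored site-records, %d animal-records; engines: %s\n",
              nrow(x$per_snp), nrow(x$per_animal),
              paste(x$config$engines, collapse = ", ")))
  print(per_animal_summary(x$per_animal), digits = 3)
  invisible(x)
}

#' Per-chromosome example site counts
#'
#' Loads the bundled per-chromosome autosomal site counts for a bovine
#' whole-genome-sequence reference panel of 151 sires and its overlap with
#' the ~777k HD array in the cross-validation targets, together with the
#' published percentage of sites to impute.
#'
#' @return a data.frame: chrom, length_mb, n_reference, n_target,
#'   pct_to_impute.
#' @export
load_site_counts <- function() {
  read.table(system.file("extdata", "bovine_hd_wgs_site_counts.tsv",
                         package = "imputeval"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
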