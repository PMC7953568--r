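vcf_header <- function(sites, sample_ids, format_defs, info_defs) {
  chroms <- unique(sites$chrom)
  lens <- vapply(chroms, function(cc) max(sites$pos[sites$chrom == cc]), 0L)
  c("##fileformat=VCFv4.2",
    "##source=imputeval",
    sprintf("##contig=<ID=%s,length=%d>", chroms, lens),
    info_defs, format_defs,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
}

info_field <- function(sites, extra = NULL) {
  parts <- lapply(SITE_STAT_COLS, function(s) {
    v <- sites[[s]]
    ifelse(is.na(v), NA_character_, sprintf("%s=%.4g", s, v))
  })
  parts <- c(parts, list(ifelse(is.na(sites$impact_class), NA_character_,
                                paste0("IMPACT=", sites$impact_class))))
  if (!is.null(extra)) parts <- c(parts, list(extra))
  apply(do.call(cbind, parts), 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0L) "." else paste(r, collapse = ";")
  })
}

vcf_info_defs <- c(
  sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="Site statistic">',
          SITE_STAT_COLS),
  '##INFO=<ID=IMPACT,Number=1,Type=String,Description="Functional impact class">',
  '##INFO=<ID=R2,Number=1,Type=Float,Description="Estimated imputation quality">')

#' Write a phased haplotype panel as VCF 4.2
#'
#' Genotypes are written phased (`a|b`); site statistics and impact classes
#' go to INFO.
#'
#' @param panel a [haplotype_panel()].
#' @param path output file path (plain text).
#' @return the path, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  s <- panel$sites
  gt1 <- panel$haplotypes[seq(1L, nrow(panel$haplotypes), 2L), , drop = FALSE]
  gt2 <- panel$haplotypes[seq(2L, nrow(panel$haplotypes), 2L), , drop = FALSE]
  gt <- matrix(paste0(t(gt1), "|", t(gt2)), nrow = nrow(s))
  body <- paste(s$chrom, s$pos, ".", s$ref_allele, s$alt_allele, ".", "PASS",
                info_field(s), "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(vcf_header(s, panel$sample_ids,
                          '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                          vcf_info_defs), body), path)
  invisible(path)
}

#' Write a genotype matrix as VCF 4.2 (unphased GT plus GQ)
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path (plain text).
#' @return the path, invisibly.
#' @export
write_genotype_vcf <- function(gm, path) {
  s <- gm$sites
  codes <- c("0/0", "0/1", "1/1")
  gt <- matrix(ifelse(is.na(t(gm$geno)), "./.", codes[t(gm$geno) + 1L]),
               nrow = nrow(s))
  fmt <- "GT"
  if (!is.null(gm$gq)) {
    gt <- matrix(paste0(gt, ":", t(gm$gq)), nrow = nrow(s))
    fmt <- "GT:GQ"
  }
  body <- paste(s$chrom, s$pos, ".", s$ref_allele, s$alt_allele, ".", "PASS",
                info_field(s), fmt,
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(vcf_header(s, gm$sample_ids,
                          c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                            '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">'),
                          vcf_info_defs), body), path)
  invisible(path)
}

#' Write an imputation result as VCF 4.2 (GT, DS and INFO R2)
#'
#' @param result an [imputation_result()].
#' @param path output file path (plain text).
#' @return the path, invisibly.
#' @export
write_imputed_vcf <- function(result, path) {
  s <- result$sites
  codes <- c("0/0", "0/1", "1/1")
  gt <- matrix(paste0(codes[t(result$best_guess) + 1L], ":",
                      sprintf("%.3f", t(result$dosage))), nrow = nrow(s))
  body <- paste(s$chrom, s$pos, ".", s$ref_allele, s$alt_allele, ".", "PASS",
                info_field(s, sprintf("R2=%.4f", result$rsq)), "GT:DS",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(vcf_header(s, result$sample_ids,
                          c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                            '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Alt-allele dosage">'),
                          vcf_info_defs), body), path)
  invisible(path)
}

gt_to_code <- function(gt) {
  gt <- sub(":.*", "", gt)
  map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
           "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  out <- map[gt]
  dim(out) <- dim(gt)
  dimnames(out) <- dimnames(gt)
  out
}

vcf_sites <- function(v) {
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  stats <- lapply(SITE_STAT_COLS, function(s)
    suppressWarnings(vcfR::extract.info(v, element = s, as.numeric = TRUE)))
  names(stats) <- SITE_STAT_COLS
  imp <- vcfR::extract.info(v, element = "IMPACT")
  variant_table(chrom = fix$CHROM, pos = as.integer(fix$POS),
                ref_allele = fix$REF, alt_allele = fix$ALT,
                impact_class = if (is.null(imp)) NA_character_ else imp,
                site_stats = as.data.frame(stats))
}

#' Read a VCF into a genotype matrix
#'
#' Parses GT (and GQ when present) with vcfR.
#'
#' @param path VCF file path.
#' @return a [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- t(gt_to_code(vcfR::extract.gt(v, element = "GT")))
  gq <- NULL
  if ("GQ" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    gq <- t(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
    storage.mode(gq) <- "integer"
  }
  genotype_matrix(rownames(gt), gt, vcf_sites(v), gq = gq)
}

#' Read a phased VCF into a haplotype panel
#'
#' @param path VCF file path; all genotypes must be phased (`|` separator).
#' @return a [haplotype_panel()].
#' @export
read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")  # variants x samples
  if (any(!grepl("|", gt, fixed = TRUE)))
    stop("read_panel_vcf: unphased genotypes present", call. = FALSE)
  a1 <- t(matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt)))
  a2 <- t(matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt)))
  H <- matrix(0L, nrow = 2L * ncol(gt), ncol = nrow(gt))
  H[seq(1L, nrow(H), 2L), ] <- a1
  H[seq(2L, nrow(H), 2L), ] <- a2
  haplotype_panel(colnames(gt), H, vcf_sites(v))
}

#' Import an externally imputed VCF as an imputation result
#'
#' Dosages come from the DS FORMAT field when available, otherwise from the
#' GT genotype codes; the per-site model quality is read from the INFO key
#' R2, Rsq or DR2 when present and otherwise recomputed from the dosages.
#'
#' @param vcf_path path to the imputed VCF.
#' @param field_priority order in which FORMAT fields are tried for dosage.
#' @param engine label recorded on the result (default "import").
#' @return an [imputation_result()].
#' @export
import_external <- function(vcf_path, field_priority = c("DS", "GT"),
                            engine = "import") {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fields <- tryCatch(vcfR::vcf_field_names(v, tag = "FORMAT")$ID,
                     error = function(e) character(0))
  dosage <- NULL
  for (f in field_priority) {
    if (f == "DS" && "DS" %in% fields) {
      dosage <- t(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE))
      break
    }
    if (f == "GT" && "GT" %in% fields) {
      dosage <- t(gt_to_code(vcfR::extract.gt(v, element = "GT")))
      storage.mode(dosage) <- "double"
      break
    }
  }
  if (is.null(dosage))
    stop("import_external: VCF has neither DS nor GT", call. = FALSE)
  sites <- vcf_sites(v)
  rsq <- NULL
  for (key in c("R2", "Rsq", "DR2")) {
    r <- suppressWarnings(vcfR::extract.info(v, element = key, as.numeric = TRUE))
    if (!is.null(r) && !all(is.na(r))) { rsq <- r; break }
  }
  if (is.null(rsq)) rsq <- rsq_from_dosage(dosage)
  p <- colMeans(dosage, na.rm = TRUE) / 2
  imputation_result(rownames(dosage), dosage, hard_call(dosage, p > 0.5),
                    rsq, sites, engine = engine)
}
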