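#' Overlapping-sliding-window parameters
#'
#' The window matcher mimics the deterministic long-haplotype-first strategy:
#' long windows capture exact sharing with close relatives, and successive
#' sweeps shrink the window to exploit shorter segments shared with more
#' distant relatives. Fills from earlier (longer-window) sweeps are never
#' overwritten.
#'
#' @param initial_window_sites window length of the first sweep, in array
#'   sites.
#' @param shrink_factor multiplicative window shrink per sweep, in (0, 1).
#' @param min_window_sites smallest window length swept.
#' @param min_match_fraction minimum agreement between a donor haplotype pair
#'   and the observed genotypes inside a window.
#' @return a list of class `osw_params`.
#' @export
osw_params <- function(initial_window_sites = 64L, shrink_factor = 0.5,
                       min_window_sites = 4L, min_match_fraction = 0.9) {
  if (!is_count(initial_window_sites, 1)) stop_field("initial_window_sites", "positive count required")
  if (!is_fraction(shrink_factor, 0, 1, open_lo = TRUE, open_hi = TRUE))
    stop_field("shrink_factor", "must lie in (0, 1)")
  if (!is_count(min_window_sites, 1)) stop_field("min_window_sites", "positive count required")
  if (initial_window_sites < min_window_sites)
    stop("osw_params: window schedule never reaches min_window_sites (initial < min)",
         call. = FALSE)
  if (!is_fraction(min_match_fraction)) stop_field("min_match_fraction", "must lie in [0, 1]")
  structure(list(initial_window_sites = as.integer(initial_window_sites),
                 shrink_factor = shrink_factor,
                 min_window_sites = as.integer(min_window_sites),
                 min_match_fraction = min_match_fraction),
            class = "osw_params")
}

osw_schedule <- function(params) {
  w <- params$initial_window_sites
  out <- integer(0)
  while (w >= params$min_window_sites) {
    out <- c(out, w)
    nxt <- as.integer(floor(w * params$shrink_factor))
    if (nxt >= w) stop("osw_schedule: window schedule does not shrink", call. = FALSE)
    w <- nxt
  }
  if (length(out) == 0L)
    stop("osw_schedule: window schedule never reaches min_window_sites", call. = FALSE)
  out
}

#' Impute to sequence density by overlapping sliding-window matching
#'
#' Operates directly on unphased genotypes. Each sweep slides half-overlapping
#' windows of the current length along the array sites of a chromosome;
#' within a window, reference haplotypes individually compatible with the
#' observed genotypes are paired, and the best pair whose implied genotypes
#' agree with the observations in at least `min_match_fraction` of the
#' window's called sites donates its alleles to every still-unfilled sequence
#' site spanned by the window. Sites never filled after the last sweep take
#' the reference expected dosage 2p. Observed genotypes at array sites are
#' never overwritten, and the per-site model Rsq uses the same
#' variance-ratio formula as the HMM engine.
#'
#' @param reference a phased [haplotype_panel()] over all sequence sites.
#' @param target a [genotype_matrix()] at array sites.
#' @param params an [osw_params()].
#' @return an [imputation_result()] over all reference sites.
#' @export
impute_osw <- function(reference, target, params = osw_params()) {
  if (nrow(reference$haplotypes) == 0L)
    stop("impute_osw: zero reference haplotypes", call. = FALSE)
  arr_in_ref <- match(site_key(target$sites), site_key(reference$sites))
  if (anyNA(arr_in_ref))
    stop("impute_osw: array sites must be a subset of reference sites", call. = FALSE)
  sched <- osw_schedule(params)
  n_t <- length(target$sample_ids)
  m_all <- nrow(reference$sites)
  dosage <- matrix(NA_real_, n_t, m_all)
  p_ref <- colMeans(reference$haplotypes)
  for (cc in unique(reference$sites$chrom)) {
    cidx <- which(reference$sites$chrom == cc)
    A <- reference$haplotypes[, cidx, drop = FALSE]
    S <- nrow(A)
    t_arr_cols <- which(arr_in_ref %in% cidx)
    arr_local <- match(arr_in_ref[t_arr_cols], cidx)
    J <- length(arr_local)
    if (J == 0L) next
    A_arr_all <- A[, arr_local, drop = FALSE]
    for (i in seq_len(n_t)) {
      g <- target$geno[i, t_arr_cols]
      filled <- rep(FALSE, length(cidx))
      dos_c <- rep(NA_real_, length(cidx))
      # chromosome-wide genotype compatibility per reference haplotype:
      # the closest-relative prior used to break within-window ties
      obs_all <- !is.na(g)
      gall <- g[obs_all]
      Aall <- A_arr_all[, obs_all, drop = FALSE]
      call_ok <- matrix(TRUE, S, length(gall))
      if (any(gall == 0L)) call_ok[, gall == 0L] <- Aall[, gall == 0L, drop = FALSE] == 0L
      if (any(gall == 2L)) call_ok[, gall == 2L] <- Aall[, gall == 2L, drop = FALSE] == 1L
      gscore <- rowMeans(call_ok)
      for (W in sched) {
        step <- max(1L, W %/% 2L)
        starts <- unique(c(seq(1L, max(1L, J - W + 1L), by = step),
                           max(1L, J - W + 1L)))
        for (s in starts) {
          e <- min(s + W - 1L, J)
          span_lo <- if (s == 1L) 1L else arr_local[s]
          span_hi <- if (e == J) length(cidx) else arr_local[e]
          span <- span_lo:span_hi
          if (all(filled[span])) next
          wj <- s:e
          obs <- !is.na(g[wj])
          if (!any(obs)) next
          gw <- g[wj][obs]
          Aw <- A[, arr_local[wj][obs], drop = FALSE]
          # single-haplotype genotype compatibility per window site
          compat <- matrix(TRUE, S, length(gw))
          hom0 <- gw == 0L; hom2 <- gw == 2L
          if (any(hom0)) compat[, hom0] <- Aw[, hom0, drop = FALSE] == 0L
          if (any(hom2)) compat[, hom2] <- Aw[, hom2, drop = FALSE] == 1L
          score <- rowMeans(compat)
          cand <- which(score >= params$min_match_fraction)
          if (length(cand) == 0L) next
          cand <- cand[order(-score[cand], -gscore[cand], cand)]
          cand <- cand[seq_len(min(12L, length(cand)))]
          best <- NULL; best_agr <- -1; best_g <- -1
          for (ai in seq_along(cand)) for (bi in ai:length(cand)) {
            h1 <- cand[ai]; h2 <- cand[bi]
            agr <- mean(Aw[h1, ] + Aw[h2, ] == gw)
            gsum <- gscore[h1] + gscore[h2]
            if (agr > best_agr + 1e-12 ||
                (agr > best_agr - 1e-12 && gsum > best_g + 1e-12)) {
              best_agr <- agr; best_g <- gsum; best <- c(h1, h2)
            }
          }
          if (is.null(best) || best_agr < params$min_match_fraction) next
          fill <- span[!filled[span]]
          dos_c[fill] <- A[best[1], fill] + A[best[2], fill]
          filled[fill] <- TRUE
        }
      }
      dosage[i, cidx] <- dos_c
    }
  }
  # fallback: reference expected dosage at sites never filled
  for (i in seq_len(n_t)) {
    nas <- is.na(dosage[i, ])
    if (any(nas)) dosage[i, nas] <- 2 * p_ref[nas]
  }
  obs_g <- target$geno
  keep <- !is.na(obs_g)
  dos_arr <- dosage[, arr_in_ref, drop = FALSE]
  dos_arr[keep] <- obs_g[keep]
  dosage[, arr_in_ref] <- dos_arr
  imputation_result(target$sample_ids, dosage,
                    hard_call(dosage, p_ref > 0.5),
                    rsq_from_dosage(dosage), reference$sites, engine = "osw")
}
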