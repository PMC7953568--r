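#' Li-Stephens HMM parameters
#'
#' The haplotype-copying model treats each target haplotype as an imperfect
#' mosaic of reference haplotypes: between adjacent observed (array) sites the
#' copied template switches with probability `1 - exp(-recomb_scale * dmap)`,
#' jumping uniformly over states, and at each observed site the copied allele
#' is misread with probability `mutation_rate`.
#'
#' @param n_states_cap maximum number of reference haplotypes used as copying
#'   states per target haplotype (the closest-matching are kept).
#' @param mutation_rate per-site miscopy probability in (0, 1).
#' @param recomb_scale expected template switches per Morgan per haplotype; a
#'   surrogate for effective population size / relatedness to the reference.
#'   Targets one meiosis away from the reference switch about once per
#'   Morgan; the default leaves headroom for more distant relationships.
#' @param map optional named list chrom -> numeric vector of genetic positions
#'   in Morgans (one per site); defaults to 1 cM/Mb from physical positions.
#' @return a list of class `hmm_params`.
#' @export
hmm_params <- function(n_states_cap = 300L, mutation_rate = 1e-3,
                       recomb_scale = 5, map = NULL) {
  if (!is_count(n_states_cap, 1)) stop_field("n_states_cap", "positive count required")
  if (!is_fraction(mutation_rate, 0, 1, open_lo = TRUE, open_hi = TRUE))
    stop_field("mutation_rate", "must lie in (0, 1)")
  if (!(is.numeric(recomb_scale) && recomb_scale >= 0))
    stop_field("recomb_scale", "non-negative real required")
  if (!is.null(map) && any(vapply(map, function(m) is.unsorted(m), TRUE)))
    stop_field("map", "genetic positions must be non-decreasing")
  structure(list(n_states_cap = as.integer(n_states_cap),
                 mutation_rate = mutation_rate, recomb_scale = recomb_scale,
                 map = map),
            class = "hmm_params")
}

genetic_map <- function(sites, params) {
  chroms <- unique(sites$chrom)
  out <- lapply(chroms, function(cc) {
    if (!is.null(params$map) && cc %in% names(params$map))
      params$map[[cc]]
    else sites$pos[sites$chrom == cc] * 1e-8  # 1 cM/Mb
  })
  stats::setNames(out, chroms)
}

site_key <- function(sites) paste(sites$chrom, sites$pos)

#' Phase target genotypes at array sites by greedy long matching
#'
#' Walks each chromosome left to right keeping, for both growing target
#' haplotypes, the length of the current exact suffix match against every
#' reference haplotype, plus a forward-looking run of compatibility with the
#' sample's homozygous genotypes (heterozygous and missing sites act as
#' wildcards). Homozygotes are phased trivially; at each heterozygote the
#' allele arrangement that extends the longest current-plus-lookahead
#' matches is chosen (ties resolved by placing the alternate allele on the
#' first haplotype); missing genotypes copy both alleles from the currently
#' best-matching reference haplotypes.
#'
#' @param target a [genotype_matrix()] restricted to array sites.
#' @param reference a phased [haplotype_panel()] whose sites contain all
#'   target sites.
#' @return a phased [haplotype_panel()] of the target samples at the target
#'   sites.
#' @export
prephase_target <- function(target, reference) {
  ridx <- match(site_key(target$sites), site_key(reference$sites))
  if (anyNA(ridx))
    stop("prephase_target: target sites must be a subset of reference sites", call. = FALSE)
  A <- reference$haplotypes[, ridx, drop = FALSE]
  S <- nrow(A)
  n <- length(target$sample_ids)
  m <- ncol(A)
  H <- matrix(0L, nrow = 2L * n, ncol = m)
  for (i in seq_len(n)) {
    g <- target$geno[i, ]
    if (all(is.na(g)))
      stop(sprintf("prephase_target: sample %s has no observed genotypes",
                   target$sample_ids[i]), call. = FALSE)
    h1 <- integer(m); h2 <- integer(m)
    for (cc in unique(target$sites$chrom)) {
      idx <- which(target$sites$chrom == cc)
      # forward compatibility runs under the homozygous constraints only
      # (het / missing sites are wildcards): Fwd[r, j] = number of
      # consecutive compatible sites starting at j for reference hap r
      hom <- matrix(rep(!is.na(g[idx]) & g[idx] != 1L, each = S), nrow = S)
      comp <- !hom | (A[, idx, drop = FALSE] ==
                        matrix(rep(g[idx] %/% 2L, each = S), nrow = S))
      Fwd <- matrix(0L, S, length(idx))
      Fwd[, length(idx)] <- as.integer(comp[, length(idx)])
      if (length(idx) > 1) for (jj in (length(idx) - 1L):1L)
        Fwd[, jj] <- ifelse(comp[, jj], Fwd[, jj + 1L] + 1L, 0L)
      L1 <- integer(S); L2 <- integer(S)
      for (jj in seq_along(idx)) {
        j <- idx[jj]
        a <- A[, j]
        gj <- g[j]
        ahead <- if (jj < length(idx)) Fwd[, jj + 1L] else integer(S)
        max_ext <- function(L, mask) if (any(mask))
          max(L[mask] + ahead[mask]) + 1L else 0L
        if (is.na(gj)) {
          h1[j] <- a[which.max(L1 + ahead)]
          h2[j] <- a[which.max(L2 + ahead)]
        } else if (gj == 0L) { h1[j] <- 0L; h2[j] <- 0L
        } else if (gj == 2L) { h1[j] <- 1L; h2[j] <- 1L
        } else {
          sA <- max_ext(L1, a == 1L) + max_ext(L2, a == 0L)
          sB <- max_ext(L1, a == 0L) + max_ext(L2, a == 1L)
          if (sA >= sB) { h1[j] <- 1L; h2[j] <- 0L } else { h1[j] <- 0L; h2[j] <- 1L }
        }
        L1 <- ifelse(a == h1[j], L1 + 1L, 0L)
        L2 <- ifelse(a == h2[j], L2 + 1L, 0L)
      }
    }
    H[2L * i - 1L, ] <- h1
    H[2L * i, ] <- h2
  }
  haplotype_panel(target$sample_ids, H, target$sites, phased = TRUE)
}

# Scaled forward-backward for the uniform-jump copying HMM.
# A_arr: S x J reference alleles at observed sites; t_hap: length-J target
# alleles (NA = uninformative); rho: length J-1 switch probabilities.
# Returns the J x S posterior state matrix (rows sum to 1).
ls_forward_backward <- function(A_arr, t_hap, rho, mu) {
  S <- nrow(A_arr); J <- ncol(A_arr)
  emis <- function(j) {
    if (is.na(t_hap[j])) rep(1, S)
    else ifelse(A_arr[, j] == t_hap[j], 1 - mu, mu)
  }
  f <- matrix(0, J, S)
  v <- rep(1 / S, S) * emis(1L)
  sv <- sum(v)
  if (sv <= 0 || !is.finite(sv)) stop("ls_forward_backward: non-finite forward probabilities", call. = FALSE)
  f[1L, ] <- v / sv
  if (J > 1) for (j in 2:J) {
    v <- ((1 - rho[j - 1L]) * f[j - 1L, ] + rho[j - 1L] / S) * emis(j)
    sv <- sum(v)
    if (sv <= 0 || !is.finite(sv)) stop("ls_forward_backward: non-finite forward probabilities", call. = FALSE)
    f[j, ] <- v / sv
  }
  b <- matrix(0, J, S)
  b[J, ] <- rep(1, S)
  if (J > 1) for (j in (J - 1L):1L) {
    eb <- emis(j + 1L) * b[j + 1L, ]
    v <- (1 - rho[j]) * eb + rho[j] * mean(eb)
    b[j, ] <- v / sum(v)
  }
  g <- f * b
  g / rowSums(g)
}

#' Impute to sequence density with the Li-Stephens copying HMM
#'
#' Runs the scaled forward-backward recursion per target haplotype over
#' reference-haplotype copying states, using the array sites as emissions.
#' Posterior state probabilities are linearly interpolated on the genetic map
#' at unobserved sites; the haplotype allele dosage at a site is the
#' posterior-weighted copied allele corrected for miscopy, and sample dosage
#' is the sum over its two haplotypes. Observed genotypes at array sites are
#' never overwritten. The per-site model quality is
#' Rsq = Var(d/2) / (p(1-p)) with p = mean(d)/2 (population variance,
#' clamped to \[0, 1\], zero where p is 0 or 1).
#'
#' @param reference a phased [haplotype_panel()] over all sequence sites.
#' @param target_haps a phased [haplotype_panel()] at array sites (from
#'   [prephase_target()]).
#' @param params an [hmm_params()].
#' @return an [imputation_result()] over all reference sites.
#' @export
impute_ls_hmm <- function(reference, target_haps, params = hmm_params()) {
  if (nrow(reference$haplotypes) == 0L)
    stop("impute_ls_hmm: zero reference haplotypes", call. = FALSE)
  if (!reference$phased || !target_haps$phased)
    stop("impute_ls_hmm: both panels must be phased", call. = FALSE)
  arr_in_ref <- match(site_key(target_haps$sites), site_key(reference$sites))
  if (anyNA(arr_in_ref))
    stop("impute_ls_hmm: array sites must be a subset of reference sites", call. = FALSE)
  mu <- params$mutation_rate
  n_t <- n_samples(target_haps)
  m_all <- nrow(reference$sites)
  hap_dos <- matrix(0, nrow = 2L * n_t, ncol = m_all)
  gmap <- genetic_map(reference$sites, params)
  for (cc in unique(reference$sites$chrom)) {
    cidx <- which(reference$sites$chrom == cc)
    A <- reference$haplotypes[, cidx, drop = FALSE]
    S_all <- nrow(A)
    map_c <- gmap[[cc]]
    t_arr_cols <- which(arr_in_ref %in% cidx)
    arr_local <- match(arr_in_ref[t_arr_cols], cidx)
    J <- length(arr_local)
    if (J == 0L) {
      # no observed sites on this chromosome: prior expectation
      base <- mu + (1 - 2 * mu) * colMeans(A)
      hap_dos[, cidx] <- matrix(base, 2L * n_t, length(cidx), byrow = TRUE)
      next
    }
    A_arr <- A[, arr_local, drop = FALSE]
    rho <- if (J > 1) 1 - exp(-params$recomb_scale * diff(map_c[arr_local])) else numeric(0)
    # hidden-site interpolation bookkeeping
    hidden <- setdiff(seq_along(cidx), arr_local)
    iv <- findInterval(hidden, arr_local)   # 0 = before first observed site
    w <- numeric(length(hidden))
    inside <- iv >= 1L & iv < J
    if (any(inside)) {
      j0 <- arr_local[iv[inside]]; j1 <- arr_local[iv[inside] + 1L]
      dd <- map_c[j1] - map_c[j0]
      w[inside] <- ifelse(dd > 0, (map_c[hidden[inside]] - map_c[j0]) / dd, 0)
    }
    for (h in seq_len(2L * n_t)) {
      t_hap <- target_haps$haplotypes[h, t_arr_cols]
      sel <- seq_len(S_all)
      if (S_all > params$n_states_cap) {
        obs <- !is.na(t_hap)
        mism <- A_arr[, obs, drop = FALSE] != matrix(t_hap[obs], S_all,
                                                     sum(obs), byrow = TRUE)
        sel <- order(rowSums(mism))[seq_len(params$n_states_cap)]
      }
      g <- ls_forward_backward(A_arr[sel, , drop = FALSE], t_hap, rho, mu)
      # copied-allele probability at every site of the chromosome
      pa <- numeric(length(cidx))
      pa[arr_local] <- rowSums(g * t(A[sel, arr_local, drop = FALSE]))
      if (length(hidden)) {
        lo <- pmax(iv, 1L); hi <- pmin(iv + 1L, J)
        P_lo <- g[lo, , drop = FALSE]; P_hi <- g[hi, , drop = FALSE]
        Ah <- A[sel, hidden, drop = FALSE]
        u_lo <- rowSums(P_lo * t(Ah))
        u_hi <- rowSums(P_hi * t(Ah))
        pa[hidden] <- (1 - w) * u_lo + w * u_hi
      }
      hap_dos[h, cidx] <- mu + (1 - 2 * mu) * pa
    }
  }
  dosage <- hap_dos[seq(1L, 2L * n_t, 2L), , drop = FALSE] +
    hap_dos[seq(2L, 2L * n_t, 2L), , drop = FALSE]
  # observed array genotypes are authoritative
  t_gen <- panel_genotypes(target_haps)
  dosage[, arr_in_ref] <- t_gen
  if (any(!is.finite(dosage)))
    stop("impute_ls_hmm: non-finite dosages", call. = FALSE)
  p_ref <- colMeans(reference$haplotypes)
  imputation_result(target_haps$sample_ids, dosage,
                    hard_call(dosage, p_ref > 0.5),
                    rsq_from_dosage(dosage), reference$sites, engine = "lshmm")
}
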