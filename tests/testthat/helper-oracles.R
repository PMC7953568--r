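# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force or closed form, without touching the package's
# computational paths.

# Exhaustive path-sum posteriors for the haplotype-copying HMM: sums the
# joint probability of every state path (uniform prior, stay probability
# (1 - rho) + rho/S, jump probability rho/S, emission 1-mu / mu, wildcard at
# missing target alleles) and accumulates per-site state marginals.
enumerate_posteriors <- function(A_arr, t_hap, rho, mu) {
  S <- nrow(A_arr)
  J <- ncol(A_arr)
  emis <- function(j, s) {
    if (is.na(t_hap[j])) 1
    else if (A_arr[s, j] == t_hap[j]) 1 - mu
    else mu
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), J)))
  post <- matrix(0, J, S)
  total <- 0
  for (p in seq_len(nrow(paths))) {
    path <- paths[p, ]
    w <- (1 / S) * emis(1L, path[1])
    if (J > 1) for (j in 2:J) {
      trans <- if (path[j] == path[j - 1L]) (1 - rho[j - 1L]) + rho[j - 1L] / S
               else rho[j - 1L] / S
      w <- w * trans * emis(j, path[j])
    }
    total <- total + w
    for (j in seq_len(J)) post[j, path[j]] <- post[j, path[j]] + w
  }
  post / total
}

# Closed-form Pearson r implemented directly from the definition.
pearson_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) return(NA_real_)
  sx <- sd(x) * sqrt((n - 1) / n)
  sy <- sd(y) * sqrt((n - 1) / n)
  if (sx == 0 || sy == 0) return(NA_real_)
  mean((x - mean(x)) * (y - mean(y))) / (sx * sy)
}

# A minimal hand-built panel: n_samples with explicit haplotype rows.
toy_panel <- function(haps, pos = seq_len(ncol(haps)) * 1e5,
                      chrom = "chr1", on_array = FALSE) {
  sites <- variant_table(chrom = chrom, pos = pos)
  sites$on_array <- rep_len(on_array, nrow(sites))
  sites$maf <- pmin(colMeans(haps), 1 - colMeans(haps))
  haplotype_panel(sprintf("H%02d", seq_len(nrow(haps) / 2)), haps, sites)
}
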