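#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = Z Z' / (2 * sum_j p_j (1 - p_j)), where Z is the genotype matrix
#' column-centred at twice the observed alt-allele frequency p_j. Missing
#' genotypes are mean-imputed per site for this computation only; monomorphic
#' sites contribute nothing (their centred column is zero).
#'
#' @param genotypes a [genotype_matrix()].
#' @return list of class `grm` with `sample_ids` and the symmetric `values`
#'   matrix.
#' @export
compute_grm <- function(genotypes) {
  g <- genotypes$geno
  p <- alt_freq(genotypes)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("compute_grm: all sites monomorphic", call. = FALSE)
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  mu <- rep(2 * p, each = nrow(g))
  z <- ifelse(is.na(g), 0, g - mu)  # mean imputation == centred zero
  denom <- 2 * sum(p * (1 - p))
  values <- tcrossprod(z) / denom
  dimnames(values) <- list(genotypes$sample_ids, genotypes$sample_ids)
  structure(list(sample_ids = genotypes$sample_ids, values = values),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d samples, mean diagonal %.3f\n",
              length(x$sample_ids), mean(diag(x$values))))
  invisible(x)
}

# k-means++ seeding: first centre uniform, subsequent centres sampled with
# probability proportional to squared distance to the nearest chosen centre.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  if (k > 1) for (i in 2:k) {
    if (all(d2 <= 0)) centers[i] <- sample.int(n, 1L)
    else centers[i] <- sample.int(n, 1L, prob = d2)
    di <- rowSums((x - matrix(x[centers[i], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, di)
  }
  x[centers, , drop = FALSE]
}

#' Cluster samples on the spectral embedding of the GRM
#'
#' Embeds samples in the leading `n_components` eigenvectors of the GRM,
#' scaled by the square roots of their (non-negative) eigenvalues, then runs
#' k-means with k-means++ seeding, keeping the best of `n_init` restarts in
#' which all clusters are non-empty (a restart producing an empty cluster is
#' re-seeded and noted).
#'
#' @param grm a [compute_grm()] result.
#' @param k number of clusters (<= n_samples).
#' @param n_components embedding dimension (default 20, capped at n_samples).
#' @param seed integer seed.
#' @param n_init number of restarts (default 10).
#' @return list of class `cluster_assignment` with `k`, `labels` (named
#'   integer vector) and `representatives` (filled by
#'   [pick_representatives()]).
#' @export
kmeans_reference_clusters <- function(grm, k, n_components = 20L, seed = 1L,
                                      n_init = 10L) {
  n <- length(grm$sample_ids)
  if (k > n) stop("kmeans_reference_clusters: k > n_samples", call. = FALSE)
  if (n_components > n) n_components <- n
  local_seed(seed)
  eig <- eigen(grm$values, symmetric = TRUE)
  d <- pmax(eig$values[seq_len(n_components)], 0)
  emb <- eig$vectors[, seq_len(n_components), drop = FALSE] *
    rep(sqrt(d), each = n)
  if (k == n) {
    labels <- stats::setNames(seq_len(n), grm$sample_ids)
    return(structure(list(k = k, labels = labels, representatives = NULL),
                     class = "cluster_assignment"))
  }
  best <- NULL
  tries <- 0L
  while (is.null(best) || tries < n_init) {
    tries <- tries + 1L
    fit <- tryCatch(
      kmeans(emb, centers = kmeanspp_centers(emb, k), iter.max = 100L),
      error = function(e) NULL)
    if (is.null(fit) || any(fit$size == 0L)) {
      message("kmeans restart produced an empty cluster; re-seeded")
      next
    }
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    if (tries > 5L * n_init) break
  }
  if (is.null(best)) stop("kmeans_reference_clusters: no valid clustering found", call. = FALSE)
  labels <- stats::setNames(as.integer(best$cluster), grm$sample_ids)
  structure(list(k = k, labels = labels, representatives = NULL),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k=%d over %d samples%s\n", x$k,
              length(x$labels),
              if (!is.null(x$representatives)) ", representatives chosen" else ""))
  invisible(x)
}

#' Pick one representative animal per cluster
#'
#' Within each cluster the sample with the largest number of genotyped
#' progeny is chosen (the sire most connected to the wider genotyped
#' population); ties are broken by lexicographic sample id.
#'
#' @param assignment a [kmeans_reference_clusters()] result.
#' @param progeny_counts named numeric vector, sample id -> progeny count;
#'   samples without an entry default to 0.
#' @return the assignment with `representatives` filled (cluster id ->
#'   sample id).
#' @export
pick_representatives <- function(assignment, progeny_counts = NULL) {
  ids <- names(assignment$labels)
  pc <- stats::setNames(rep(0, length(ids)), ids)
  if (!is.null(progeny_counts)) {
    known <- intersect(names(progeny_counts), ids)
    pc[known] <- progeny_counts[known]
  }
  reps <- vapply(sort(unique(assignment$labels)), function(cl) {
    members <- sort(ids[assignment$labels == cl])  # lexicographic tie-break
    members[which.max(pc[members])]
  }, "")
  names(reps) <- sort(unique(assignment$labels))
  assignment$representatives <- reps
  assignment
}
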