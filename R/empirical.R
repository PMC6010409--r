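#' Jaccard index of repertoire sharing
#'
#' Proportion of shared syllable types out of all types found in a pair
#' of repertoires: `|A intersect B| / |A union B|`.
#'
#' @param a,b Nonempty vectors of type labels.
#' @return Value in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty repertoire")
  length(intersect(a, b)) / length(union(a, b))
}

# all-pairs Jaccard and geographic distance for a repertoire sample
pairwise_tables <- function(sample) {
  n <- nrow(sample)
  types <- sort(unique(unlist(sample$syllables)))
  B <- matrix(0L, n, length(types), dimnames = list(NULL, types))
  for (i in seq_len(n)) B[i, sample$syllables[[i]]] <- 1L
  inter <- tcrossprod(B)
  sizes <- rowSums(B)
  un <- outer(sizes, sizes, "+") - inter
  J <- inter / un
  G <- as.matrix(dist(cbind(sample$x_m, sample$y_m)))
  list(jaccard = J, geo = G)
}

#' Mean repertoire sharing by geographic distance bin
#'
#' Assigns every unordered pair of individuals to a distance bin and
#' reports the mean Jaccard index and pair count per bin, separately for
#' within- and between-population pairs.
#'
#' @param sample A `repertoire_sample` with coordinates.
#' @param bin_edges Increasing numeric vector of bin edges in metres
#'   (pairs beyond the last edge are dropped).
#' @return Data frame with `bin` (factor of intervals), `scope`
#'   (`within`/`between`), `mean_jaccard` and `n_pairs`; empty bins have
#'   `n_pairs = 0` and `NA` mean.
#' @export
sharing_vs_distance <- function(sample, bin_edges) {
  stopifnot(nrow(sample) >= 2, all(is.finite(sample$x_m)),
            all(is.finite(sample$y_m)))
  pt <- pairwise_tables(sample)
  ut <- upper.tri(pt$geo)
  d <- pt$geo[ut]; j <- pt$jaccard[ut]
  same <- outer(sample$population, sample$population, "==")[ut]
  bin <- cut(d, bin_edges, include.lowest = TRUE)
  out <- expand.grid(bin = levels(bin), scope = c("within", "between"),
                     stringsAsFactors = FALSE)
  out$mean_jaccard <- NA_real_
  out$n_pairs <- 0L
  for (r in seq_len(nrow(out))) {
    sel <- !is.na(bin) & bin == out$bin[r] &
           (same == (out$scope[r] == "within"))
    out$n_pairs[r] <- sum(sel)
    if (any(sel)) out$mean_jaccard[r] <- mean(j[sel])
  }
  out
}

#' Mantel test of matrix correlation, optionally stratified
#'
#' Pearson correlation between the off-diagonal entries of two distance
#' (or dissimilarity) matrices, with a one-sided permutation p-value in
#' which items are permuted only within the given strata (so that, e.g.,
#' within-population structure can be tested without confounding from
#' between-population divergence). Backed by [vegan::mantel()].
#'
#' @param D1,D2 Square symmetric matrices (or `dist` objects) of equal
#'   size.
#' @param strata Optional factor partitioning the items; `NULL` gives the
#'   unstratified test.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return List with `r` (Mantel correlation) and `p` (one-sided
#'   permutation p-value).
#' @export
mantel_test <- function(D1, D2, strata = NULL, n_perm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d1 <- as.dist(D1); d2 <- as.dist(D2)
  stopifnot(attr(d1, "Size") == attr(d2, "Size"))
  if (sd(d1) == 0 || sd(d2) == 0)
    stop("constant matrix: Mantel correlation undefined")
  fit <- vegan::mantel(d1, d2, permutations = n_perm,
                       strata = if (is.null(strata)) NULL
                                else as.factor(strata))
  list(r = unname(fit$statistic), p = unname(fit$signif))
}

#' UPGMA (average-linkage) clustering of a dissimilarity matrix
#'
#' @param D Square symmetric nonnegative matrix with zero diagonal (or a
#'   `dist`).
#' @return An `hclust` merge tree with average-linkage heights.
#' @export
upgma <- function(D) {
  if (!inherits(D, "dist")) {
    D <- as.matrix(D)
    if (any(abs(D - t(D)) > 1e-8)) stop("dissimilarity matrix must be symmetric")
    if (any(diag(D) != 0)) stop("dissimilarity matrix must have zero diagonal")
    if (any(D < 0)) stop("dissimilarities must be nonnegative")
    D <- as.dist(D)
  }
  hclust(D, method = "average")
}

#' Export a dendrogram as Newick
#'
#' @param dendro An `hclust` tree (e.g. from [upgma()]).
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_dendrogram <- function(dendro, path) {
  ape::write.tree(ape::as.phylo(dendro), file = path)
  invisible(path)
}

# silhouette widths from a dissimilarity matrix and integer labels;
# singleton clusters get width 0 (cluster::silhouette convention)
silhouette_widths <- function(D, labels) {
  sil <- cluster::silhouette(labels, dmatrix = as.matrix(D))
  if (length(sil) == 1 && is.na(sil)) return(rep(0, length(labels)))
  sil[, "sil_width"]
}

#' Global silhouette index profile along a dendrogram
#'
#' Cuts the tree at each candidate number of clusters `k`, computes
#' silhouette widths from the dissimilarity matrix, and aggregates them
#' into the global silhouette index: the mean over clusters of the mean
#' per-item silhouette width (`method = "cluster_mean"`, the default), or
#' the plain mean over items (`method = "item_mean"`). The peak `k_star`
#' is the global argmax over `k_range`; local peaks are also reported.
#'
#' @param D Square symmetric dissimilarity matrix (or `dist`).
#' @param dendro An `hclust` tree of the same items (defaults to
#'   [upgma()] of `D`).
#' @param k_range Integer candidate cluster numbers within `[2, n - 1]`.
#' @param method Aggregation variant.
#' @return List with `k_star`, data frame `profile` (`k`, `gsi`) and
#'   integer vector `local_peaks`.
#' @export
gsi_profile <- function(D, dendro = upgma(D),
                        k_range = 2:(attr(as.dist(D), "Size") - 1),
                        method = c("cluster_mean", "item_mean")) {
  method <- match.arg(method)
  Dm <- as.matrix(D)
  n <- nrow(Dm)
  stopifnot(all(k_range >= 2), all(k_range <= n - 1))
  gsi <- vapply(k_range, function(k) {
    labels <- cutree(dendro, k = k)
    sw <- silhouette_widths(Dm, labels)
    if (method == "cluster_mean")
      mean(tapply(sw, labels, mean))
    else mean(sw)
  }, 0)
  d <- diff(gsi)
  local <- which(c(d, -1) < 0 & c(1, d) > 0)
  list(k_star = k_range[which.max(gsi)],
       profile = data.frame(k = k_range, gsi = gsi),
       local_peaks = k_range[local])
}

#' Normalised mutual information between two labelings
#'
#' `NMI = I(A; B) / N`, where the normaliser `N` is the arithmetic mean
#' of the two label entropies (default), their maximum, or the geometric
#' mean. A constant labeling has zero entropy and yields 0.
#'
#' @param a,b Label vectors of equal length.
#' @param normalization `"mean"`, `"max"` or `"sqrt"`.
#' @return Value in `[0, 1]`.
#' @export
nmi <- function(a, b, normalization = c("mean", "max", "sqrt")) {
  normalization <- match.arg(normalization)
  stopifnot(length(a) == length(b))
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  norm <- switch(normalization, mean = (ha + hb) / 2,
                 max = max(ha, hb), sqrt = sqrt(ha * hb))
  if (norm == 0) return(0)
  max(0, min(1, mi / norm))
}

#' Read / write a labelled dissimilarity matrix as CSV
#'
#' Labels are stored in the first row and column.
#'
#' @param D Square symmetric matrix with labels.
#' @param path File path.
#' @return `read_dissim` returns the labelled matrix.
#' @export
write_dissim <- function(D, path) {
  write.csv(as.matrix(D), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_dissim
#' @export
read_dissim <- function(path) {
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  colnames(m) <- rownames(m)
  m
}
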