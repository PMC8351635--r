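# Jaccard dissimilarity and principal coordinates ordination of the
# presence/absence matrix.

#' Binary Jaccard dissimilarity between genomes
#'
#' `d(i, j) = 1 - |A_i intersect A_j| / |A_i union A_j]` over the feature
#' sets of each genome pair. A pair of genomes with no features at all is
#' assigned distance 0 (identical emptiness) with a warning, since
#' feature-free genomes are degenerate inputs.
#'
#' @param matrix A binary `PresenceAbsenceMatrix` with >= 2 genomes.
#' @return A `DissimilarityMatrix`: symmetric numeric matrix in \[0, 1\]
#'   with zero diagonal, genome ids as dimnames.
#' @export
jaccard_dissimilarity <- function(matrix) {
  m <- unclass(matrix)
  if (nrow(m) < 2L) stop("need at least 2 genomes")
  if (!all(m %in% c(0L, 1L))) stop("matrix must be binary (0/1)")
  storage.mode(m) <- "double"
  inter <- m %*% t(m)
  sizes <- rowSums(m)
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / uni
  if (any(uni == 0)) {
    warning("feature-free genome pair(s); their distance is defined as 0")
    d[uni == 0] <- 0
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  class(d) <- c("DissimilarityMatrix", class(d))
  d
}

#' Principal coordinates ordination (classical metric MDS)
#'
#' Gower double-centering of `-0.5 * D^2` followed by a symmetric
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues. Negative eigenvalues — which
#' arise when the dissimilarity is not Euclidean-embeddable — are
#' reported but excluded from the variance-explained denominator, and no
#' correction is applied. Axis signs are fixed deterministically by
#' making the coordinate of largest absolute value positive on each axis.
#'
#' @param D A symmetric `DissimilarityMatrix` (or plain symmetric
#'   matrix with zero diagonal).
#' @param n_axes Number of axes to keep (default: all positive axes).
#' @return An `OrdinationResult`: list with `coordinates` (genomes x
#'   axes), `eigenvalues` (all, descending), `variance_explained`
#'   (percent per positive axis).
#' @export
pco <- function(D, n_axes = NULL) {
  D <- unclass(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("dissimilarity matrix must be symmetric")
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  pos <- which(ev > max(ev[1], 0) * 1e-9)
  keep <- if (is.null(n_axes)) pos else pos[seq_len(min(n_axes, length(pos)))]
  coords <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev[keep]), length(keep))
  # deterministic sign: largest-magnitude coordinate positive per axis
  for (j in seq_len(ncol(coords))) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCO", seq_len(ncol(coords)))
  pos_sum <- sum(ev[ev > 0])
  ve <- if (pos_sum > 0) 100 * ev[keep] / pos_sum else rep(NA_real_, length(keep))
  structure(list(coordinates = coords, eigenvalues = ev,
                 variance_explained = ve),
            class = "OrdinationResult")
}

#' Percent of variance explained by an ordination axis
#'
#' `100 * lambda_axis / sum(positive lambdas)`.
#'
#' @param result An `OrdinationResult` from [pco()].
#' @param axis Axis index (1-based, among all eigenvalues).
#' @return Percent.
#' @export
variance_explained <- function(result, axis) {
  ev <- result$eigenvalues
  if (axis < 1L || axis > length(ev)) stop("axis out of range")
  if (ev[axis] < 0) stop("axis ", axis, " has a negative eigenvalue; not a valid ordination axis")
  100 * ev[axis] / sum(ev[ev > 0])
}

#' Write ordination coordinates and axis variance to TSV
#' @param result An `OrdinationResult`.
#' @param coord_path,axis_path Output TSV paths.
#' @export
write_ordination <- function(result, coord_path, axis_path) {
  df <- data.frame(genome_id = rownames(result$coordinates),
                   result$coordinates, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, coord_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ax <- data.frame(axis = seq_along(result$variance_explained),
                   eigenvalue = result$eigenvalues[seq_along(result$variance_explained)],
                   variance_explained_pct = result$variance_explained)
  utils::write.table(ax, axis_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(coord_path)
}

#' Silhouette of a 1-D embedding against known labels
#'
#' Mean silhouette width of the axis coordinates with respect to a
#' two-or-more group labeling; used to quantify how cleanly an ordination
#' axis separates taxon groups.
#'
#' @param x Numeric vector (e.g. axis-1 coordinates).
#' @param labels Group labels, parallel to `x`.
#' @return Mean silhouette width in \[-1, 1\].
#' @export
axis_silhouette <- function(x, labels) {
  labels <- as.character(labels)
  n <- length(x)
  stopifnot(length(labels) == n, length(unique(labels)) >= 2L)
  dmat <- abs(outer(x, x, "-"))
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1L) mean(dmat[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(dmat[i, labels == g]), 0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  mean(s)
}
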