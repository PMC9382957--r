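# Multidimensional scaling of vignette co-naming dissimilarities.
# Classical (Torgerson) scaling provides a deterministic start; the
# configuration is then refined by SMACOF majorization, by default in
# nonmetric mode with disparities from monotone (isotonic) regression of
# the fitted distances on the dissimilarity order (primary approach to
# ties). Fit is reported as Kruskal's stress-1.

#' Convert a co-naming similarity matrix to dissimilarities
#'
#' Default transform: d[i, j] = 1 - s[i, j] / n_pairs[i, j], i.e. one
#' minus the fraction of participants (with codable answers to both
#' vignettes) who named the pair with the same word. Normalizing by
#' n_pairs keeps groups of different sizes comparable. The alternative
#' `"max_count"` transform divides by the largest off-diagonal count.
#'
#' @param sim a [similarity_matrix()].
#' @param method `"pair_fraction"` (default) or `"max_count"`.
#' @return An object of class `dissimilarity_matrix`: list with `d`
#'   (symmetric, zero diagonal, values in [0, 1]) and `source`.
#' @export
to_dissimilarity <- function(sim, method = c("pair_fraction", "max_count")) {
  stopifnot(inherits(sim, "similarity_matrix"))
  method <- match.arg(method)
  off <- row(sim$s) != col(sim$s)
  if (method == "pair_fraction") {
    if (any(sim$n_pairs[off] == 0))
      stop("n_pairs has zero off-diagonal entries; cannot normalize")
    d <- 1 - sim$s / sim$n_pairs
  } else {
    mx <- max(sim$s[off])
    if (mx == 0) stop("all off-diagonal co-naming counts are zero")
    d <- 1 - sim$s / mx
    d[d < 0] <- 0
  }
  diag(d) <- 0
  d <- (d + t(d)) / 2
  structure(list(d = d, source = method), class = "dissimilarity_matrix")
}

as_dist_matrix <- function(d) {
  if (inherits(d, "dissimilarity_matrix")) d <- d$d
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("dissimilarities must be symmetric")
  if (any(!is.finite(d))) stop("non-finite dissimilarities")
  d
}

#' Classical (Torgerson) metric scaling
#'
#' Double-centers the squared dissimilarities and takes the top-k
#' eigenvector scores; negative eigenvalues are truncated at zero. Used
#' as the deterministic initialization for [smacof()].
#'
#' @param d a `dissimilarity_matrix` or symmetric numeric matrix.
#' @param k target dimensionality.
#' @return n x k coordinate matrix, centered at the origin.
#' @export
classical_mds <- function(d, k = 2L) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  if (k >= n) stop("k must be smaller than the number of points")
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  ev <- pmax(e$values[seq_len(k)], 0)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
  rownames(coords) <- rownames(d)
  coords
}

edist <- function(x) {
  as.matrix(stats::dist(x))
}

#' Kruskal stress-1
#'
#' sqrt(sum((dhat - dist)^2) / sum(dist^2)) over the off-diagonal pairs.
#'
#' @param dhat disparities (target distances).
#' @param dist configuration distances.
#' @keywords internal
stress1 <- function(dhat, dist) {
  sqrt(sum((dhat - dist)^2) / sum(dist^2))
}

# monotone disparities: isotonic regression of distances on the
# dissimilarity order (primary approach: tied dissimilarities may take
# different disparities; within ties we order by distance, which lets the
# fit follow the data)
monotone_disparities <- function(d_vec, dist_vec) {
  ord <- order(d_vec, dist_vec, method = "radix")
  fit <- stats::isoreg(dist_vec[ord])
  dhat <- numeric(length(d_vec))
  dhat[ord] <- fit$yf
  dhat
}

#' SMACOF multidimensional scaling
#'
#' Minimizes stress by majorization (Guttman transform). In nonmetric
#' mode (default) disparities are re-fit each iteration by isotonic
#' regression of the configuration distances on the dissimilarity ranks
#' and rescaled to constant norm; in metric mode disparities are the
#' optimally scaled dissimilarities (ratio transformation). Iteration
#' stops when the stress decrease falls below `tol` or after `max_iter`
#' iterations. Stress is reported as Kruskal's stress-1, which is
#' invariant under rotation, reflection, translation and uniform scaling
#' of the configuration.
#'
#' @param d a `dissimilarity_matrix` or symmetric numeric matrix.
#' @param k target dimensionality (2 for the semantic-dimension maps).
#' @param init starting configuration (n x k); default classical
#'   scaling solution, making the whole fit deterministic.
#' @param tol convergence tolerance on the stress decrease.
#' @param max_iter iteration cap.
#' @param nonmetric logical; isotonic disparities (TRUE, default) or
#'   ratio-scaled metric disparities.
#' @return An object of class `mds_result`: `coords` (centered),
#'   `stress` (Kruskal stress-1), `stress_trace`, `n_iter`, `converged`,
#'   `config` (list of settings).
#' @export
smacof <- function(d, k = 2L, init = NULL, tol = 1e-9, max_iter = 1000L,
                   nonmetric = TRUE) {
  dm <- as_dist_matrix(d)
  n <- nrow(dm)
  if (is.null(init)) init <- classical_mds(dm, k)
  if (!all(dim(init) == c(n, k))) stop("init must be ", n, " x ", k)
  low <- lower.tri(dm)
  d_vec <- dm[low]
  m <- length(d_vec)
  x <- scale(init, center = TRUE, scale = FALSE)
  dist_m <- edist(x)
  # raw disparities: scale-equivariant in the distances, so the reported
  # stress-1 is invariant under similarity transforms of the coordinates
  disparity <- function(dist_vec) {
    if (nonmetric) {
      monotone_disparities(d_vec, dist_vec)
    } else {
      b <- sum(d_vec * dist_vec) / sum(d_vec^2)
      b * d_vec
    }
  }
  # update disparities: fixed norm, keeps the Guttman step well scaled
  normalize <- function(dhat) {
    nrm <- sqrt(sum(dhat^2))
    if (nrm == 0) dhat else dhat * sqrt(m) / nrm
  }
  dhat_raw <- disparity(dist_m[low])
  dhat_vec <- normalize(dhat_raw)
  stress_trace <- stress1(dhat_raw, dist_m[low])
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # Guttman transform with uniform weights (diagonal excluded)
    dhat <- matrix(0, n, n)
    dhat[low] <- dhat_vec
    dhat <- dhat + t(dhat)
    ratio <- ifelse(dist_m > 0, dhat / dist_m, 0)
    bmat <- -ratio
    diag(bmat) <- rowSums(ratio)
    x <- (bmat %*% x) / n
    x <- scale(x, center = TRUE, scale = FALSE)
    dist_m <- edist(x)
    dhat_raw <- disparity(dist_m[low])
    dhat_vec <- normalize(dhat_raw)
    s <- stress1(dhat_raw, dist_m[low])
    stress_trace <- c(stress_trace, s)
    prev <- stress_trace[length(stress_trace) - 1L]
    if (prev - s < tol) { converged <- TRUE; break }
  }
  rownames(x) <- rownames(dm)
  structure(list(coords = x[, , drop = FALSE], stress = stress_trace[length(stress_trace)],
                 stress_trace = stress_trace, n_iter = iter,
                 converged = converged,
                 config = list(mode = if (nonmetric) "nonmetric" else "metric",
                               init = "classical", tol = tol,
                               max_iter = max_iter, k = k)),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("<mds_result> %s, k=%d, stress-1 = %.4g (%d iterations%s)\n",
              x$config$mode, x$config$k, x$stress, x$n_iter,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Orient an MDS solution by valence
#'
#' MDS solutions are identified only up to rotation and reflection. This
#' normalizes the configuration so maps are comparable across age
#' groups: coordinates are rotated to their principal axes, the sign of
#' dimension 1 is chosen so the centroid of the positive-valence
#' vignettes lies on the positive side, and the sign of dimension 2 so
#' its largest-magnitude coordinate is positive.
#'
#' @param result an `mds_result`.
#' @param valence numeric vector of +1/-1 per point (vignette).
#' @return The `mds_result` with rotated/reflected `coords`; stress is
#'   unchanged.
#' @export
orient_mds <- function(result, valence) {
  stopifnot(inherits(result, "mds_result"))
  x <- result$coords
  if (length(valence) != nrow(x)) stop("one valence per point required")
  if (length(unique(sign(valence))) < 2L)
    stop("both valences must be present")
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  x <- x %*% sv$v  # principal axes
  if (mean(x[valence > 0, 1]) < 0) x[, 1] <- -x[, 1]
  if (ncol(x) >= 2L && x[which.max(abs(x[, 2])), 2] < 0)
    x[, 2] <- -x[, 2]
  dimnames(x) <- dimnames(result$coords)
  result$coords <- x
  result
}
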