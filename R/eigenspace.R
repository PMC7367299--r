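#' Principal coordinate analysis of a distance matrix
#'
#' Gower double-centering of \eqn{-\tfrac12 D^2} followed by a symmetric
#' eigendecomposition. Coordinates are returned for positive-eigenvalue axes
#' only, each axis scaled by the square root of its eigenvalue so that the
#' embedding reproduces the input distances when they are Euclidean.
#' Negative eigenvalues (possible for patristic distances) are recorded but
#' excluded from the coordinates and from explained fractions. Axis signs
#' are fixed by forcing the largest-magnitude loading on each axis to be
#' positive, making outputs reproducible across platforms.
#'
#' @param d Symmetric nonnegative distance matrix with zero diagonal;
#'   dimnames, if present, become the tip labels.
#' @return An object of class `eigen_basis`: a list with `eigenvalues` (all,
#'   descending), `coordinates` (species x positive axes, columns `EV1`,
#'   `EV2`, ...), `explained_fraction` (per positive axis, summing to 1),
#'   and `tip_labels`.
#' @export
phylo_pcoa <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square", call. = FALSE)
  if (any(is.na(d))) stop("distance matrix contains NA", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8 * max(1, max(abs(d)))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(d < 0)) stop("distance matrix has negative entries", call. = FALSE)
  n <- nrow(d)
  labels <- rownames(d) %||% paste0("item", seq_len(n))
  a <- -0.5 * d^2
  b <- a - matrix(rowMeans(a), n, n) - matrix(colMeans(a), n, n, byrow = TRUE) +
    mean(a)
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  vals <- eg$values
  tol <- max(abs(vals)) * 1e-10
  pos <- which(vals > tol)
  coords <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(vals[pos]), length(pos))
  for (k in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, k]))
    if (coords[i, k] < 0) coords[, k] <- -coords[, k]
  }
  dimnames(coords) <- list(labels, paste0("EV", seq_along(pos)))
  structure(
    list(
      eigenvalues = vals,
      coordinates = coords,
      explained_fraction = vals[pos] / sum(vals[pos]),
      tip_labels = labels
    ),
    class = "eigen_basis"
  )
}

#' @export
print.eigen_basis <- function(x, ...) {
  cat("<eigen_basis> ", length(x$tip_labels), " species, ",
      ncol(x$coordinates), " positive axes (",
      sum(x$eigenvalues < 0), " negative eigenvalues dropped)\n", sep = "")
  invisible(x)
}

#' Select leading eigenvectors by cumulative explained variation
#'
#' Retains the smallest prefix of positive-eigenvalue axes whose cumulative
#' explained fraction reaches `cum_threshold`. Axes are numbered by
#' descending eigenvalue, so "eigenvector 4" always means the fourth axis.
#'
#' @param basis An `eigen_basis` from [phylo_pcoa()].
#' @param cum_threshold Required cumulative fraction in `(0, 1]`. The
#'   default 0.99 retains axes explaining 99% of the phylogenetic structure;
#'   0.95 is the conventional floor for eigenvector regression.
#' @return An object of class `phylo_coords`: list with `scores` (a tibble:
#'   `species` plus `EV1..EVk`), `k`, and `cum_fraction` achieved.
#' @export
select_eigenvectors <- function(basis, cum_threshold = 0.99) {
  stopifnot(inherits(basis, "eigen_basis"))
  if (!is.numeric(cum_threshold) || cum_threshold <= 0 || cum_threshold > 1) {
    stop("cum_threshold must be in (0, 1]", call. = FALSE)
  }
  cum <- cumsum(basis$explained_fraction)
  k <- which(cum >= cum_threshold - 1e-9)[1]
  if (is.na(k)) {
    stop("cumulative explained fraction cannot reach ", cum_threshold,
         call. = FALSE)
  }
  scores <- tibble::as_tibble(basis$coordinates[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(tibble::tibble(species = basis$tip_labels),
                             scores)
  structure(
    list(scores = scores, k = k, cum_fraction = cum[k]),
    class = "phylo_coords"
  )
}

#' @export
print.phylo_coords <- function(x, ...) {
  cat("<phylo_coords> ", x$k, " eigenvectors, cumulative fraction ",
      format(x$cum_fraction, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write selected eigenvector scores and their metadata
#'
#' Writes the species-by-eigenvector score table as CSV and a JSON sidecar
#' holding the eigenvalues and cumulative explained fractions.
#'
#' @param basis An `eigen_basis`.
#' @param coords A `phylo_coords` selection from the same basis.
#' @param prefix Output path prefix; writes `<prefix>_eigenvectors.csv` and
#'   `<prefix>_eigenvalues.json`.
#' @return The two paths, invisibly.
#' @export
write_eigenvectors <- function(basis, coords, prefix) {
  csv <- paste0(prefix, "_eigenvectors.csv")
  js <- paste0(prefix, "_eigenvalues.json")
  readr::write_csv(coords$scores, csv)
  jsonlite::write_json(
    list(
      eigenvalues = basis$eigenvalues,
      explained_fraction = basis$explained_fraction,
      cumulative_fraction = cumsum(basis$explained_fraction),
      k_selected = coords$k
    ),
    js, auto_unbox = TRUE, digits = NA
  )
  invisible(c(csv, js))
}
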