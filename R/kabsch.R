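#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD of point
#' set `coordsB` onto `coordsA` (points paired row-to-row). Reflections are
#' suppressed: the returned rotation always has determinant +1. The
#' superposed copy of B is `coordsB %*% t(rotation) + translation` (row
#' vectors).
#'
#' @param coordsA,coordsB numeric N x 3 matrices, N >= 3, paired
#'   index-to-index.
#' @return list with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd` (Angstrom).
#' @examples
#' a <- matrix(rnorm(12), 4, 3)
#' fit <- kabschSuperpose(a, a)
#' stopifnot(fit$rmsd < 1e-12)
#' @export
kabschSuperpose <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (ncol(coordsA) != 3L || ncol(coordsB) != 3L)
    stop("coordinate matrices must be N x 3")
  if (nrow(coordsA) != nrow(coordsB))
    stop("coordinate sets must be paired index-to-index")
  if (nrow(coordsA) < 3L)
    stop("degenerate input: at least 3 paired points are required")
  # collinearity check: rank of either centered set < 2 leaves the rotation
  # about the line arbitrary; the canonical SVD solution is still returned
  sv <- svd(scale(coordsA, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    warning("points are (near-)collinear; rotation about the line is ",
            "arbitrary, returning the canonical SVD solution")
  fit <- .cpp_kabsch(coordsA, coordsB)
  fit$translation <- as.numeric(fit$translation)
  fit
}

#' Apply a rigid transform to row-vector coordinates
#'
#' @param coords numeric N x 3 matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector.
#' @return the transformed N x 3 matrix.
#' @export
applyTransform <- function(coords, rotation, translation) {
  sweep(coords %*% t(rotation), 2L, translation, `+`)
}
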