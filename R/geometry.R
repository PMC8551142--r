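#' The 24 proper rotations of the cube
#'
#' Brick orientations are restricted to the rotation group of the cube: 3x3
#' signed permutation matrices with determinant +1.  Reflections are rejected
#' because a physical brick cannot be mirrored.
#'
#' @return A list of 24 integer 3x3 matrices.
#' @export
#' @examples
#' length(cube_rotations())  # 24
cube_rotations <- function() {
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  out <- list()
  for (p in perms) {
    for (s1 in c(1L, -1L)) for (s2 in c(1L, -1L)) for (s3 in c(1L, -1L)) {
      m <- matrix(0L, 3L, 3L)
      sg <- c(s1, s2, s3)
      for (r in 1:3) m[r, p[r]] <- sg[r]
      if (det3(m) == 1L) out[[length(out) + 1L]] <- m
    }
  }
  out
}

det3 <- function(m) as.integer(round(det(m)))

#' Test whether a matrix is a valid brick orientation
#'
#' @param m A 3x3 matrix.
#' @param tol Largest tolerated deviation of the entries from integers.
#' @return `TRUE` if `m` rounds to a signed permutation matrix with
#'   determinant +1 (one of the 24 proper cube rotations).
#' @export
is_orientation <- function(m, tol = 1e-6) {
  if (!is.matrix(m) || !all(dim(m) == c(3L, 3L))) return(FALSE)
  r <- round(m)
  if (max(abs(m - r)) > tol) return(FALSE)
  if (!all(r %in% c(-1, 0, 1))) return(FALSE)
  if (any(rowSums(abs(r)) != 1) || any(colSums(abs(r)) != 1)) return(FALSE)
  det3(r) == 1L
}

# Canonical textual key for an orientation (column-major integer entries);
# used to deduplicate rotations into shared TR cards.
orientation_key <- function(m) paste(as.integer(round(m)), collapse = " ")

orientation_identity <- function() diag(3L)

is_identity_orientation <- function(m) all(round(m) == diag(3L))

# Minimum corner of the rotated brick box [0, dims] relative to the local
# origin: per world axis k, sum of the negative contributions of R %*% dims.
rot_box_min <- function(R, dims) {
  vapply(1:3, function(k) sum(pmin(R[k, ] * dims, 0)), numeric(1))
}

# Footprint (axis-aligned extents, in the same units as dims) of the rotated
# box: |R| %*% dims.
rot_box_dims <- function(R, dims) as.vector(abs(R) %*% dims)
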