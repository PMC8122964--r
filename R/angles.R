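#' Wrap an angle into the half-open interval (-180, 180]
#'
#' All torsion angles in the package live on the circle, represented in
#' degrees on the half-open interval (-180, 180]. Note the boundary
#' convention: +180 is kept, -180 maps to +180.
#'
#' @param theta numeric vector of angles in degrees. Must be finite;
#'   `NA` values are passed through (they mark undefined terminal torsions).
#' @return numeric vector congruent to `theta` modulo 360, in (-180, 180].
#' @examples
#' wrap_angle(c(180, -180, 370, 0))
#' @export
wrap_angle <- function(theta) {
  if (!is.numeric(theta)) {
    stop("`theta` must be numeric.", call. = FALSE)
  }
  if (any(!is.na(theta) & !is.finite(theta))) {
    stop("`theta` must be finite.", call. = FALSE)
  }
  theta - 360 * ceiling((theta - 180) / 360)
}

#' Shortest signed angular difference a - b on the circle
#'
#' Used for circular arithmetic in velocity updates: the attraction terms
#' toward personal and neighbourhood bests take the short way around the
#' circle, never the long way.
#'
#' @param a,b numeric vectors of angles in degrees.
#' @return signed difference in (-180, 180].
#' @export
angle_diff <- function(a, b) {
  wrap_angle(a - b)
}

# internal: 3-vector cross product
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("Cannot normalise a (near-)zero vector.", call. = FALSE)
  v / n
}

#' Dihedral angle defined by four points
#'
#' Standard IUPAC-signed torsion: looking down the p2->p3 axis, a clockwise
#' rotation of the far bond relative to the near bond is positive. A planar
#' cis arrangement gives 0 and trans gives 180.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return dihedral in degrees, wrapped to (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b2n <- unit3(p3 - p2)
  b3 <- p4 - p3
  v <- b0 - sum(b0 * b2n) * b2n
  w <- b3 - sum(b3 * b2n) * b2n
  if (sqrt(sum(v^2)) < 1e-10 || sqrt(sum(w^2)) < 1e-10) {
    stop("Degenerate geometry: collinear atoms in dihedral computation.",
         call. = FALSE)
  }
  wrap_angle(atan2(sum(cross3(b2n, v) * w), sum(v * w)) * 180 / pi)
}

# internal: bond angle a-b-c in degrees
bond_angle3 <- function(a, b, c) {
  u <- unit3(a - b)
  v <- unit3(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# internal: run code under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number.", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
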