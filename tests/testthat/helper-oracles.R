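# Independent oracles and small generators shared across the suite. These
# deliberately re-derive quantities from first principles (plane normals,
# exhaustive enumeration, O(n^2) scans) rather than calling the package's
# own implementation paths.

random_chain <- function(L, seed = NULL) {
  gen <- function() {
    torsion_chain(
      phi = c(NA, runif(L - 1, -179.9, 180)),
      psi = c(runif(L - 1, -179.9, 180), NA),
      omega = c(runif(L - 1, -179.9, 180), NA)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# dihedral via the two plane normals and an explicitly signed angle
# (parallel normals = planar cis = 0; antiparallel = trans = 180)
oracle_dihedral <- function(p1, p2, p3, p4) {
  n1 <- pracma::cross(p2 - p1, p3 - p2)
  n2 <- pracma::cross(p3 - p2, p4 - p3)
  axis <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  wrap_angle(atan2(sum(pracma::cross(n1, n2) * axis), sum(n1 * n2)) *
               180 / pi)
}

# brute-force non-dominated subset of the rows of a matrix, duplicates
# collapsed to their first occurrence
oracle_nondominated <- function(m) {
  dup <- duplicated(m)
  keep <- !dup
  for (i in which(keep)) {
    for (j in seq_len(nrow(m))) {
      if (i == j || dup[j]) next
      if (all(m[j, ] <= m[i, ]) && any(m[j, ] < m[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  m[keep, , drop = FALSE]
}

sort_rows <- function(m) m[do.call(order, as.data.frame(m)), , drop = FALSE]

# rigid motion helpers
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_structure <- function(s, R, shift) {
  xyz <- cbind(s$x, s$y, s$z) %*% t(R)
  s$x <- xyz[, 1] + shift[1]
  s$y <- xyz[, 2] + shift[2]
  s$z <- xyz[, 3] + shift[3]
  s
}

# circular absolute difference in degrees
circ_abs <- function(a, b) abs(wrap_angle(a - b))
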