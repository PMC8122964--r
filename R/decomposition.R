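#' Simplex-lattice weight vectors
#'
#' Generates the canonical simplex-lattice design: all vectors of M
#' non-negative components, each a multiple of 1/H, summing to 1. There are
#' exactly `choose(H + M - 1, M - 1)` such vectors; with H = 10 divisions and
#' M = 3 objectives this gives the engine's default 66 subproblems. Order is
#' deterministic: lexicographic in the integer compositions.
#'
#' @param H number of divisions along each objective axis (>= 1).
#' @param M number of objectives (>= 2).
#' @return an N x M numeric matrix, one weight vector per row.
#' @examples
#' nrow(simplex_lattice(10, 3)) # 66
#' @export
simplex_lattice <- function(H, M = 3L) {
  H <- as.integer(H)
  M <- as.integer(M)
  if (is.na(H) || H < 1L) stop("`H` must be a positive integer.", call. = FALSE)
  if (is.na(M) || M < 2L) stop("`M` must be at least 2.", call. = FALSE)
  compositions <- function(h, m) {
    if (m == 1L) return(matrix(h, 1L, 1L))
    do.call(rbind, lapply(0:h, function(k) {
      cbind(k, compositions(h - k, m - 1L))
    }))
  }
  w <- compositions(H, M) / H
  dimnames(w) <- NULL
  w
}

#' Neighborhoods of the decomposition subproblems
#'
#' For each weight vector, the indices of the `T` closest weight vectors by
#' Euclidean distance (the self-distance 0 means each subproblem is always in
#' its own neighborhood). Ties are broken toward lower indices.
#'
#' @param weights N x M weight matrix from [simplex_lattice()].
#' @param T_size neighborhood size, 1 <= T <= N.
#' @return an N x T integer matrix; row i is B(i).
#' @export
build_neighborhoods <- function(weights, T_size) {
  N <- nrow(weights)
  T_size <- as.integer(T_size)
  if (is.na(T_size) || T_size < 1L || T_size > N) {
    stop("`T_size` must be between 1 and the number of weight vectors.",
         call. = FALSE)
  }
  d <- as.matrix(stats::dist(weights))
  nb <- vapply(seq_len(N), function(i) {
    order(d[i, ], seq_len(N))[seq_len(T_size)]
  }, integer(T_size))
  t(matrix(nb, nrow = T_size))
}

#' Penalty-based boundary intersection (PBI) aggregation
#'
#' Scalarizes an objective vector for one subproblem: `d1` is the distance
#' travelled from the ideal point `z` along the ray through the weight vector
#' `lambda` (the convergence term), `d2` is the perpendicular distance of
#' `F - z` from that ray (the direction error), and the aggregate is
#' `g = d1 + theta * d2`.
#'
#' @param f objective vector (length M), or an n x M matrix of objective
#'   vectors scalarized against the same subproblem.
#' @param lambda weight vector of the subproblem (non-negative, nonzero).
#' @param z ideal point (component-wise minimum of observed objectives).
#' @param theta penalty parameter >= 0 balancing convergence vs direction.
#' @param nadir optional running nadir estimate (component-wise maximum of
#'   observed objectives). When supplied, objectives are min-max normalized
#'   to `(f - z) / (nadir - z)` before the PBI distances are computed;
#'   omitted by default so the distances act on raw energy scales exactly as
#'   the aggregation is defined.
#' @return list with numeric `d1`, `d2`, `g` (vectors if `f` is a matrix).
#' @export
pbi_aggregate <- function(f, lambda, z, theta, nadir = NULL) {
  if (is.matrix(f)) {
    fm <- f
  } else {
    fm <- matrix(f, nrow = 1L)
  }
  M <- ncol(fm)
  if (length(lambda) != M || length(z) != M) {
    stop("`f`, `lambda` and `z` must have matching dimension.", call. = FALSE)
  }
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta < 0) {
    stop("`theta` must be a single non-negative number.", call. = FALSE)
  }
  nl <- sqrt(sum(lambda^2))
  if (nl < 1e-12) stop("Weight vector must have nonzero norm.", call. = FALSE)
  diff <- sweep(fm, 2L, as.numeric(z))
  if (!is.null(nadir)) {
    scale <- pmax(as.numeric(nadir) - as.numeric(z), 1e-12)
    diff <- sweep(diff, 2L, scale, `/`)
  }
  d1 <- abs(as.vector(diff %*% lambda)) / nl
  proj <- outer(d1, lambda / nl)
  d2 <- sqrt(rowSums((diff - proj)^2))
  list(d1 = d1, d2 = d2, g = d1 + theta * d2)
}

#' Adaptive penalty schedule for PBI
#'
#' Linear ramp of the PBI penalty with the generation count: a small theta
#' early favours convergence toward the front, a large theta late enforces
#' adherence to each subproblem's direction and hence diversity.
#'
#' @param t current generation, 0 <= t <= max_iter.
#' @param max_iter total number of generations.
#' @param theta_min,theta_max endpoints of the ramp (defaults 5 and 20).
#' @return theta(t), affine in t.
#' @export
penalty_schedule <- function(t, max_iter, theta_min = 5, theta_max = 20) {
  if (any(t < 0) || any(t > max_iter)) {
    stop("`t` must lie in [0, max_iter].", call. = FALSE)
  }
  if (max_iter == 0) return(rep(theta_min, length(t)))
  theta_min + (theta_max - theta_min) * t / max_iter
}

#' Update the ideal point with a new objective vector
#'
#' @param z current ideal point (length M).
#' @param f newly observed objective vector (length M).
#' @return component-wise minimum of `z` and `f`.
#' @export
update_ideal <- function(z, f) {
  if (length(z) != length(f)) {
    stop("`z` and `f` must have the same length.", call. = FALSE)
  }
  pmin(z, f)
}
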