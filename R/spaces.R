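#' Search space over backbone torsion angles
#'
#' Flattens the defined torsions of an initial conformation into the PSO
#' decision vector. Phi and psi of every residue (where defined) are free
#' variables moving on the circle with wrap-around arithmetic; the
#' peptide-bond omega is held at its input value by default so sampling never
#' flips a trans peptide to cis (set `include_omega = TRUE` to free it).
#'
#' @param chain the initial [torsion_chain()] (defines dimension and omega).
#' @param geom covalent geometry used when decoding back to a chain.
#' @param include_omega also optimize omega torsions.
#' @return a `search_space` object with the encode/decode/arithmetic hooks
#'   the optimizer needs.
#' @export
torsion_space <- function(chain, geom = geometry_params(),
                          include_omega = FALSE) {
  validate_torsion_chain(chain)
  L <- nrow(chain)
  x0 <- c(chain$phi[-1L], chain$psi[-L])
  if (include_omega) x0 <- c(x0, chain$omega[-L])
  decode <- function(x) {
    phi <- c(NA_real_, x[seq_len(L - 1L)])
    psi <- c(x[L:(2L * (L - 1L))], NA_real_)
    omega <- chain$omega
    if (include_omega) {
      omega <- c(x[(2L * (L - 1L) + 1L):(3L * (L - 1L))], NA_real_)
    }
    new_torsion_chain(phi = phi, psi = psi, omega = omega,
                      resname = chain$resname)
  }
  structure(list(
    kind = "torsion",
    dim = length(x0),
    x0 = x0,
    wrap = wrap_angle,
    diff = angle_diff,
    decode = decode,
    perturb = function(x, sigma) wrap_angle(x + stats::rnorm(length(x), 0, sigma)),
    default_velocity_clamp = 60,
    default_sigma = 10,
    chain = chain,
    geom = geom
  ), class = "search_space")
}

#' Box-constrained real-vector search space
#'
#' Used with [benchmark_problem()] landscapes: plain Euclidean arithmetic,
#' positions clamped to `[lower, upper]`.
#'
#' @param lower,upper numeric bound vectors of equal length.
#' @param x0 starting point; defaults to the box centre.
#' @return a `search_space` object.
#' @export
vector_space <- function(lower, upper, x0 = NULL) {
  if (length(lower) != length(upper) || any(upper <= lower)) {
    stop("`lower` and `upper` must define a non-empty box.", call. = FALSE)
  }
  if (is.null(x0)) x0 <- (lower + upper) / 2
  rng <- upper - lower
  structure(list(
    kind = "vector",
    dim = length(x0),
    x0 = x0,
    wrap = function(x) pmin(pmax(x, lower), upper),
    diff = function(a, b) a - b,
    decode = identity,
    perturb = function(x, sigma) {
      pmin(pmax(x + stats::rnorm(length(x), 0, sigma), lower), upper)
    },
    default_velocity_clamp = 0.25 * max(rng),
    default_sigma = 0.2 * max(rng),
    lower = lower,
    upper = upper
  ), class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat(sprintf("<search_space: %s, %d free variables>\n", x$kind, x$dim))
  invisible(x)
}
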