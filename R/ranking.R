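#' Linear utility of an objective vector under one weight vector
#'
#' `U = w1*f1 + ... + wM*fM` with `w` on the probability simplex; lower is
#' better, since the objectives are energies.
#'
#' @param f objective vector.
#' @param w weight vector on the simplex (same length).
#' @return the scalar utility.
#' @export
utility <- function(f, w) {
  if (length(f) != length(w)) {
    stop("`f` and `w` must have the same length.", call. = FALSE)
  }
  sum(as.numeric(f) * as.numeric(w))
}

#' Sample weight vectors uniformly on the simplex
#'
#' Flat Dirichlet sampling (normalized unit-rate exponentials): uniform on
#' the (M-1)-simplex.
#'
#' @param S number of samples.
#' @param M dimension.
#' @param seed optional seed for reproducibility.
#' @return an S x M matrix of weight vectors, rows summing to 1.
#' @export
sample_simplex_weights <- function(S, M, seed = NULL) {
  draw <- function() {
    e <- matrix(stats::rexp(S * M), S, M)
    e / rowSums(e)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Expected utility of archive members under random weight sampling
#'
#' Monte-Carlo estimate of E[U(F, w)] over weights sampled uniformly on the
#' simplex. The same S weight samples are reused for every objective vector
#' (common random numbers), so sampling noise cancels in comparisons and a
#' dominated vector always has a strictly larger expected utility than its
#' dominator within one call.
#'
#' @param f an objective vector, or an n x M matrix of objective vectors.
#' @param n_samples number of weight samples S (default 20000).
#' @param seed RNG seed for the weight samples.
#' @param weight_samples optionally a precomputed S x M weight matrix
#'   (overrides `n_samples`/`seed`).
#' @return numeric vector of expected utilities (length n).
#' @export
expected_utility <- function(f, n_samples = 20000L, seed = 1L,
                             weight_samples = NULL) {
  fm <- if (is.matrix(f)) f else matrix(f, nrow = 1L)
  if (is.null(weight_samples)) {
    weight_samples <- sample_simplex_weights(n_samples, ncol(fm), seed = seed)
  }
  if (ncol(weight_samples) != ncol(fm)) {
    stop("Weight samples and objectives must have matching dimension.",
         call. = FALSE)
  }
  wbar <- colMeans(weight_samples)
  as.vector(fm %*% wbar)
}

#' Rank archived conformations by expected utility and select the top models
#'
#' Knee-oriented model selection: every archive member is scored by its
#' expected utility under S common random weight samples and ranked
#' ascending (lower expected energy first). Ties break toward the entry
#' found at an earlier generation, then the lower archive index. The top-k
#' entries are labelled `Model 1 .. Model k`.
#'
#' @param archive a `pareto_archive` (or a `swarm_run`).
#' @param top_k number of models to return (default 5).
#' @param n_samples number of weight samples S (default 20000).
#' @param seed RNG seed for the weight sampling.
#' @return tibble with `rank`, `model` label, `expected_utility`,
#'   `generation_found`, `entry` (archive index) and one column per
#'   objective; `min(top_k, archive size)` rows. The selected positions are
#'   attached as the `positions` attribute (a list).
#' @export
rank_select <- function(archive, top_k = 5L, n_samples = 20000L, seed = 1L) {
  if (inherits(archive, "swarm_run")) archive <- archive$archive
  n <- length(archive)
  if (n == 0L) stop("Cannot rank an empty archive.", call. = FALSE)
  eu <- expected_utility(archive$obj, n_samples = n_samples, seed = seed)
  ord <- order(eu, archive$gen, seq_len(n))
  k <- min(as.integer(top_k), n)
  sel <- ord[seq_len(k)]
  tab <- tidy.pareto_archive(archive)[sel, , drop = FALSE]
  out <- dplyr::bind_cols(
    tibble::tibble(rank = seq_len(k),
                   model = paste("Model", seq_len(k)),
                   expected_utility = eu[sel]),
    tab
  )
  attr(out, "positions") <- archive$pos[sel]
  out
}

#' Write ranked models to PDB files plus a ranking table
#'
#' Emits `Model_1.pdb .. Model_k.pdb` (decoding each selected conformation
#' through the search space) and `ranking.tsv` with rank, expected utility
#' and objective values.
#'
#' @param ranking output of [rank_select()].
#' @param space the [torsion_space()] the positions live in.
#' @param outdir output directory (created if needed).
#' @param geom covalent geometry for the conversion.
#' @return invisible character vector of the PDB paths written.
#' @export
write_ranked_models <- function(ranking, space, outdir,
                                geom = geometry_params()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  positions <- attr(ranking, "positions")
  paths <- character(nrow(ranking))
  for (i in seq_len(nrow(ranking))) {
    chain <- space$decode(positions[[i]])
    s <- torsions_to_cartesian(chain, geom)
    paths[i] <- file.path(outdir, sprintf("Model_%d.pdb", i))
    write_pdb(s, paths[i])
  }
  utils::write.table(as.data.frame(ranking), file.path(outdir, "ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
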