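#' Optimizer configuration
#'
#' Hyperparameters of the decomposition-guided particle swarm. Defaults are
#' the engine's standard settings: H = 10 weight-lattice divisions (66
#' subproblems/particles for 3 objectives), neighborhood size T = 8, inertia
#' decreasing linearly 1.3 to 0.7, learning coefficients c1 = c2 = 2, and a
#' PBI penalty ramped linearly from 5 to 20 over the run.
#'
#' @param max_iter number of generations (default 3000 at production scale;
#'   tests use far fewer).
#' @param divisions simplex-lattice divisions H (default 10).
#' @param T_size neighborhood size (default 8).
#' @param inertia_start,inertia_end linear inertia schedule endpoints.
#' @param c1,c2 cognitive and social learning coefficients.
#' @param theta_min,theta_max PBI penalty schedule endpoints.
#' @param perturb_sigma std-dev (degrees, or native units for vector spaces)
#'   of the perturbations creating particles 2..N from the initial model;
#'   `NULL` uses the space default.
#' @param velocity_clamp per-component velocity bound; `NULL` uses the space
#'   default (60 degrees/generation for torsion spaces), `Inf` disables.
#' @param per_angle_r draw the stochastic factors r1, r2 per angle rather
#'   than per particle (default `FALSE`: one scalar pair per particle per
#'   generation).
#' @param normalize_objectives min-max normalize objectives inside the PBI
#'   distances using running ideal/nadir estimates (default `FALSE`: raw
#'   energy scales, matching the aggregation as defined).
#' @param seed master RNG seed for the run.
#' @return a `pso_config` list.
#' @export
pso_config <- function(max_iter = 3000L, divisions = 10L, T_size = 8L,
                       inertia_start = 1.3, inertia_end = 0.7,
                       c1 = 2, c2 = 2, theta_min = 5, theta_max = 20,
                       perturb_sigma = NULL, velocity_clamp = NULL,
                       per_angle_r = FALSE, normalize_objectives = FALSE,
                       seed = 1L) {
  stopifnot(max_iter >= 0, divisions >= 1, T_size >= 1, c1 >= 0, c2 >= 0)
  structure(list(
    max_iter = as.integer(max_iter), divisions = as.integer(divisions),
    T_size = as.integer(T_size),
    inertia_start = inertia_start, inertia_end = inertia_end,
    c1 = c1, c2 = c2, theta_min = theta_min, theta_max = theta_max,
    perturb_sigma = perturb_sigma, velocity_clamp = velocity_clamp,
    per_angle_r = isTRUE(per_angle_r),
    normalize_objectives = isTRUE(normalize_objectives), seed = seed
  ), class = "pso_config")
}

#' Inertia weight at generation t
#'
#' Affine schedule from `inertia_start` at t = 0 to `inertia_end` at
#' t = `max_iter` (defaults 1.3 to 0.7).
#'
#' @param t generation, 0 <= t <= max_iter.
#' @param config a [pso_config()].
#' @return inertia weight w(t).
#' @export
inertia <- function(t, config) {
  if (any(t < 0) || any(t > config$max_iter)) {
    stop("`t` must lie in [0, max_iter].", call. = FALSE)
  }
  if (config$max_iter == 0L) return(rep(config$inertia_start, length(t)))
  config$inertia_start +
    (config$inertia_end - config$inertia_start) * t / config$max_iter
}

#' One particle's velocity update
#'
#' The canonical PSO velocity rule,
#' `v' = w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)`, with the attraction
#' differences taken by `diff_fn` (shortest signed angular difference on
#' torsion spaces) and the result clamped component-wise to
#' `[-velocity_clamp, velocity_clamp]`.
#'
#' @param v current velocity vector.
#' @param x current position vector.
#' @param pbest_x,gbest_x personal and neighborhood best positions.
#' @param w inertia weight.
#' @param c1,c2 learning coefficients.
#' @param r1,r2 stochastic factors in `[0, 1]`; scalars (shared across
#'   components) or vectors. Supplied explicitly in tests; drawn by the
#'   optimizer loop.
#' @param diff_fn difference function, default [angle_diff()].
#' @param velocity_clamp component-wise bound (default `Inf`).
#' @return the new velocity vector.
#' @export
update_velocity <- function(v, x, pbest_x, gbest_x, w, c1, c2, r1, r2,
                            diff_fn = angle_diff, velocity_clamp = Inf) {
  vnew <- w * v +
    c1 * r1 * diff_fn(pbest_x, x) +
    c2 * r2 * diff_fn(gbest_x, x)
  pmin(pmax(vnew, -velocity_clamp), velocity_clamp)
}

#' One particle's position update
#'
#' `x' = wrap(x + v)`: per-component addition followed by the space's wrap
#' (circular wrap for torsions, box clamp for vector spaces).
#'
#' @param x position vector.
#' @param v velocity vector.
#' @param wrap wrap/clamp function, default [wrap_angle()].
#' @return new position vector.
#' @export
update_position <- function(x, v, wrap = wrap_angle) {
  wrap(x + v)
}

# internal fast scalar PBI aggregate; `scale` (nadir - z) enables optional
# min-max normalization
g_pbi <- function(f, lambda, z, theta, lambda_norm, scale = NULL) {
  diff <- f - z
  if (!is.null(scale)) diff <- diff / scale
  d1 <- abs(sum(diff * lambda)) / lambda_norm
  resid <- diff - d1 * lambda / lambda_norm
  d1 + theta * sqrt(sum(resid * resid))
}

#' Initialize the swarm
#'
#' Builds the initial swarm state: particle 1 is the unperturbed initial
#' model, particles 2..N are random perturbations of it; velocities are drawn
#' uniformly in the clamp range; pbest and gbest start at each particle's own
#' position; the ideal point is the component-wise minimum of the initial
#' objective vectors; and all initial non-dominated particles enter the
#' archive. Uses the current RNG stream (seed it or use [run_swarm()]).
#'
#' @param space a [torsion_space()] or [vector_space()].
#' @param models list of [energy_model()]s (the objectives).
#' @param weights N x M weight matrix; one particle per row.
#' @param config a [pso_config()].
#' @return a `swarm_state` object.
#' @export
init_swarm <- function(space, models, weights, config) {
  N <- nrow(weights)
  if (N < 1L) stop("Need at least one weight vector/particle.", call. = FALSE)
  if (config$T_size > N) {
    stop("Neighborhood size exceeds the number of subproblems.", call. = FALSE)
  }
  sigma <- config$perturb_sigma %||% space$default_sigma
  clamp <- config$velocity_clamp %||% space$default_velocity_clamp
  vel_range <- if (is.finite(clamp)) clamp else space$default_velocity_clamp
  D <- space$dim
  X <- matrix(NA_real_, N, D)
  X[1L, ] <- space$x0
  if (N > 1L) {
    for (i in 2:N) X[i, ] <- space$perturb(space$x0, sigma)
  }
  V <- matrix(stats::runif(N * D, -vel_range, vel_range), N, D)
  F <- t(vapply(seq_len(N), function(i) {
    tryCatch(
      evaluate_all(models, space$decode(X[i, ])),
      error = function(e) {
        stop(sprintf("Objective evaluation failed for particle %d: %s",
                     i, conditionMessage(e)), call. = FALSE)
      }
    )
  }, numeric(length(models))))
  if (ncol(F) != ncol(weights)) {
    stop("Number of objectives must match the weight-vector dimension.",
         call. = FALSE)
  }
  z <- apply(F, 2L, min)
  archive <- new_archive()
  for (i in seq_len(N)) {
    archive <- archive_offer(archive, X[i, ], F[i, ], generation = 0L)
  }
  nbhd <- build_neighborhoods(weights, config$T_size)
  structure(list(
    X = X, V = V, F = F,
    pbest_X = X, pbest_F = F,
    gbest_X = X, gbest_F = F,
    z = z, nadir = apply(F, 2L, max), t = 0L, archive = archive,
    weights = weights, lambda_norms = sqrt(rowSums(weights^2)),
    nbhd = nbhd, space = space, clamp = clamp
  ), class = "swarm_state")
}

#' @export
print.swarm_state <- function(x, ...) {
  cat(sprintf("<swarm_state: %d particles, generation %d, archive %d>\n",
              nrow(x$X), x$t, length(x$archive)))
  invisible(x)
}

#' Advance the swarm by one generation
#'
#' For each particle in index order: move by the velocity/position rules
#' under the current inertia and PBI penalty, evaluate the objectives, update
#' the ideal point, update its own personal best under its subproblem's PBI
#' value (strict improvement only), update the neighborhood bests of every
#' subproblem in B(i), and offer the new conformation to the Pareto archive.
#' Best comparisons always use the current ideal point and penalty, so stored
#' bests are re-judged consistently as the ideal point drifts.
#'
#' @param state a `swarm_state` from [init_swarm()].
#' @param config the [pso_config()].
#' @param models the objective models.
#' @return the updated `swarm_state` (generation counter incremented).
#' @export
swarm_step <- function(state, config, models) {
  t_now <- state$t + 1L
  if (t_now > config$max_iter) {
    stop("Run already completed max_iter generations.", call. = FALSE)
  }
  w <- inertia(t_now, config)
  theta <- penalty_schedule(t_now, config$max_iter,
                            config$theta_min, config$theta_max)
  N <- nrow(state$X)
  D <- ncol(state$X)
  wts <- state$weights
  lnorm <- state$lambda_norms
  for (i in seq_len(N)) {
    r1 <- if (config$per_angle_r) stats::runif(D) else stats::runif(1L)
    r2 <- if (config$per_angle_r) stats::runif(D) else stats::runif(1L)
    v <- update_velocity(state$V[i, ], state$X[i, ],
                         state$pbest_X[i, ], state$gbest_X[i, ],
                         w, config$c1, config$c2, r1, r2,
                         diff_fn = state$space$diff,
                         velocity_clamp = state$clamp)
    x <- update_position(state$X[i, ], v, wrap = state$space$wrap)
    f <- tryCatch(
      evaluate_all(models, state$space$decode(x)),
      error = function(e) {
        stop(sprintf("Objective evaluation failed for particle %d: %s",
                     i, conditionMessage(e)), call. = FALSE)
      }
    )
    state$V[i, ] <- v
    state$X[i, ] <- x
    state$F[i, ] <- f
    state$z <- pmin(state$z, f)
    state$nadir <- pmax(state$nadir, f)
    z <- state$z
    scale <- if (config$normalize_objectives) {
      pmax(state$nadir - z, 1e-12)
    } else {
      NULL
    }
    if (g_pbi(f, wts[i, ], z, theta, lnorm[i], scale) <
        g_pbi(state$pbest_F[i, ], wts[i, ], z, theta, lnorm[i], scale)) {
      state$pbest_X[i, ] <- x
      state$pbest_F[i, ] <- f
    }
    for (j in state$nbhd[i, ]) {
      if (g_pbi(f, wts[j, ], z, theta, lnorm[j], scale) <
          g_pbi(state$gbest_F[j, ], wts[j, ], z, theta, lnorm[j], scale)) {
        state$gbest_X[j, ] <- x
        state$gbest_F[j, ] <- f
      }
    }
    state$archive <- archive_offer(state$archive, x, f, generation = t_now)
  }
  state$t <- t_now
  state
}

#' Run the full decomposition-guided particle swarm optimization
#'
#' The engine's main loop: generate the simplex-lattice weight vectors and
#' neighborhoods, initialize the swarm from the initial model, iterate
#' [swarm_step()] for `max_iter` generations, and return the final Pareto
#' archive with a per-generation log. Fully reproducible given `config$seed`.
#'
#' @param space a [torsion_space()] or [vector_space()] anchored at the
#'   initial model.
#' @param models list of [energy_model()]s.
#' @param config a [pso_config()].
#' @param weights optional weight matrix; by default the simplex lattice with
#'   `config$divisions` divisions and M = `length(models)` objectives.
#' @return a `swarm_run` object: `archive` (the Pareto archive), `log`
#'   (tibble: generation, ideal-point components, archive size, mean PBI
#'   aggregate), `state`, `config`, `weights`.
#' @export
run_swarm <- function(space, models, config = pso_config(), weights = NULL) {
  if (is.null(weights)) {
    weights <- simplex_lattice(config$divisions, length(models))
  }
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  state <- init_swarm(space, models, weights, config)
  nlog <- config$max_iter + 1L
  log_rows <- vector("list", nlog)
  snapshot <- function(state, theta) {
    g <- vapply(seq_len(nrow(state$X)), function(i) {
      g_pbi(state$F[i, ], weights[i, ], state$z, theta,
            state$lambda_norms[i])
    }, numeric(1L))
    c(generation = state$t, stats::setNames(state$z, paste0("z", seq_along(state$z))),
      archive_size = length(state$archive), mean_g = mean(g))
  }
  log_rows[[1L]] <- snapshot(state, config$theta_min)
  if (config$max_iter > 0L) {
    for (t in seq_len(config$max_iter)) {
      state <- swarm_step(state, config, models)
      theta <- penalty_schedule(t, config$max_iter,
                                config$theta_min, config$theta_max)
      log_rows[[t + 1L]] <- snapshot(state, theta)
    }
  }
  log <- tibble::as_tibble(as.data.frame(do.call(rbind, log_rows)))
  obj_names <- vapply(models, `[[`, character(1L), "name")
  colnames(state$archive$obj) <- obj_names
  structure(list(
    archive = state$archive, log = log, state = state,
    config = config, weights = weights, objective_names = obj_names
  ), class = "swarm_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.swarm_run <- function(x, ...) {
  cat(sprintf(
    "<swarm_run: %d particles x %d generations; archive of %d non-dominated conformations>\n",
    nrow(x$weights), x$config$max_iter, length(x$archive)))
  invisible(x)
}

#' Tidy the per-generation optimization log
#'
#' @param x a `swarm_run`.
#' @param ... unused.
#' @return tibble with one row per generation: `generation`, ideal-point
#'   components `z1..zM`, `archive_size`, `mean_g`.
#' @export
tidy.swarm_run <- function(x, ...) x$log

#' One-row summary of an optimization run
#'
#' @param x a `swarm_run`.
#' @param ... unused.
#' @return tibble with `n_particles`, `generations`, `archive_size`, final
#'   ideal-point components and final mean PBI aggregate.
#' @export
glance.swarm_run <- function(x, ...) {
  last <- x$log[nrow(x$log), , drop = FALSE]
  dplyr::bind_cols(
    tibble::tibble(n_particles = nrow(x$weights),
                   generations = x$config$max_iter,
                   archive_size = length(x$archive)),
    last[, setdiff(names(last), c("generation", "archive_size")), drop = FALSE]
  )
}

#' Plot the optimization trace of a run
#'
#' Ideal-point components and archive size per generation.
#'
#' @param object a `swarm_run`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.swarm_run <- function(object, ...) {
  log <- object$log
  zcols <- grep("^z[0-9]+$", names(log), value = TRUE)
  long <- tidyr::pivot_longer(
    log[, c("generation", zcols, "archive_size")],
    cols = -"generation", names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y") +
    ggplot2::labs(x = "generation", y = NULL,
                  title = "Swarm optimization trace")
}

#' Plot the Pareto front of an archive
#'
#' Pairwise scatter of the archived objective vectors.
#'
#' @param object a `pareto_archive` (or a `swarm_run`, whose archive is used).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pareto_archive <- function(object, ...) {
  df <- tidy.pareto_archive(object)
  objs <- setdiff(names(df), c("entry", "generation_found"))
  pairs <- utils::combn(objs, 2L, simplify = FALSE)
  long <- dplyr::bind_rows(lapply(pairs, function(p) {
    tibble::tibble(panel = paste(p[1L], "vs", p[2L]),
                   x = df[[p[1L]]], y = df[[p[2L]]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, title = "Pareto front (archive)")
}

#' Checkpoint and restore a swarm state
#'
#' Serializes the complete optimizer state (positions, velocities, bests,
#' ideal point, archive, search space) to a single file, so long runs can be
#' stopped and resumed with [swarm_step()]. Note the RNG stream is global:
#' to resume bit-for-bit, save and restore `.Random.seed` around the
#' checkpoint as well.
#'
#' @param state a `swarm_state`.
#' @param path checkpoint file path.
#' @return `path` (checkpoint) or the restored `swarm_state`.
#' @export
checkpoint_swarm <- function(state, path) {
  if (!inherits(state, "swarm_state")) {
    stop("`state` must be a swarm_state.", call. = FALSE)
  }
  saveRDS(state, path)
  invisible(path)
}

#' @rdname checkpoint_swarm
#' @export
restore_swarm <- function(path) {
  state <- readRDS(path)
  if (!inherits(state, "swarm_state")) {
    stop("File does not contain a swarm_state.", call. = FALSE)
  }
  state
}

#' Write the per-generation run log to TSV
#'
#' @param run a `swarm_run`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(run, path) {
  utils::write.table(run$log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
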