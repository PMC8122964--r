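# small helpers for swarm tests ------------------------------------------

quad_models <- function() {
  list(
    energy_model("f1", function(x) sum((x - 0.2)^2)),
    energy_model("f2", function(x) sum((x - 0.8)^2)),
    energy_model("f3", function(x) sum(x^2))
  )
}

test_that("inertia follows the linear 1.3 to 0.7 schedule", {
  cfg <- pso_config(max_iter = 3000)
  expect_equal(inertia(0, cfg), 1.3)
  expect_equal(inertia(3000, cfg), 0.7)
  expect_equal(inertia(1500, cfg), 1.0)
  expect_error(inertia(3001, cfg), "0, max_iter")
})

test_that("velocity update implements the PSO rule with circular diffs", {
  # stationary point: no attraction, no inertia contribution
  expect_equal(update_velocity(rep(0, 4), rep(10, 4), rep(10, 4), rep(10, 4),
                               w = 0.9, c1 = 2, c2 = 2, r1 = 0.5, r2 = 0.5),
               rep(0, 4))
  # r1 = r2 = 0 reduces to pure inertia
  expect_equal(update_velocity(c(3, -2), c(0, 0), c(50, 50), c(-50, -50),
                               w = 1.1, c1 = 2, c2 = 2, r1 = 0, r2 = 0),
               1.1 * c(3, -2))
  # hand evaluation: 1*10 + 2*0.5*20 + 2*0.5*(-10) = 20
  expect_equal(update_velocity(10, 0, 20, -10, w = 1, c1 = 2, c2 = 2,
                               r1 = 0.5, r2 = 0.5),
               20)
  # attraction takes the short way around the circle
  expect_equal(update_velocity(0, 170, -170, 170, w = 1, c1 = 2, c2 = 2,
                               r1 = 0.5, r2 = 0),
               20)  # -170 - 170 wraps to +20
  # clamping
  expect_equal(update_velocity(0, 0, 100, 100, w = 1, c1 = 2, c2 = 2,
                               r1 = 1, r2 = 1, velocity_clamp = 60),
               60)
})

test_that("position update adds velocity then wraps", {
  expect_equal(update_position(c(10, 20), c(0, 0)), c(10, 20))
  expect_equal(update_position(175, 10), -175)
  withr::with_seed(37, {
    x <- runif(20, -180, 180); v <- runif(20, -90, 90)
    want <- vapply(seq_along(x), function(i) wrap_angle(x[i] + v[i]),
                   numeric(1))
    expect_equal(update_position(x, v), want)
  })
})

test_that("swarm initialization follows the spec of particle 1 and bests", {
  w <- simplex_lattice(2, 3)  # 6 particles
  cfg <- pso_config(max_iter = 10, T_size = 3, perturb_sigma = 0, seed = 1)
  sp <- vector_space(rep(0, 4), rep(1, 4))
  set.seed(1)
  st <- init_swarm(sp, quad_models(), w, cfg)
  # sigma = 0: all particles identical to the initial model
  expect_true(all(st$X == matrix(sp$x0, 6, 4, byrow = TRUE)))
  expect_identical(st$pbest_X, st$X)
  expect_identical(st$gbest_X, st$X)
  expect_equal(st$z, apply(st$F, 2, min))
  expect_true(all(abs(st$V) <= sp$default_velocity_clamp))
  # determinism of the full initial state
  set.seed(1)
  expect_identical(init_swarm(sp, quad_models(), w, cfg), st)
  # 66 particles, one per weight vector, under the production lattice
  w66 <- simplex_lattice(10, 3)
  cfg2 <- pso_config(max_iter = 1, perturb_sigma = 0.1, seed = 2)
  set.seed(2)
  st66 <- init_swarm(sp, quad_models(), w66, cfg2)
  expect_equal(nrow(st66$X), 66)
  expect_equal(nrow(unique(w66)), 66)
  expect_error(init_swarm(sp, quad_models(), w66,
                          pso_config(T_size = 67)), "exceeds")
})

test_that("constant objectives never replace bests (strict improvement)", {
  const_models <- list(
    energy_model("a", function(x) 1),
    energy_model("b", function(x) 2),
    energy_model("c", function(x) 3)
  )
  w <- simplex_lattice(1, 3)
  cfg <- pso_config(max_iter = 5, T_size = 2, perturb_sigma = 0.1, seed = 3)
  sp <- vector_space(rep(0, 3), rep(1, 3))
  set.seed(3)
  st <- init_swarm(sp, const_models, w, cfg)
  pb0 <- st$pbest_X
  gb0 <- st$gbest_X
  for (k in 1:5) st <- swarm_step(st, cfg, const_models)
  expect_identical(st$pbest_X, pb0)
  expect_identical(st$gbest_X, gb0)
  expect_equal(length(st$archive), 1)  # one duplicate objective vector
})

test_that("one generation matches an independent re-implementation", {
  models <- quad_models()
  w <- diag(3)  # three axis subproblems
  cfg <- pso_config(max_iter = 4, T_size = 2, perturb_sigma = 0.3,
                    velocity_clamp = 0.5, seed = 5)
  sp <- vector_space(rep(0, 2), rep(1, 2))
  set.seed(5)
  st0 <- init_swarm(sp, models, w, cfg)
  nbhd <- st0$nbhd

  # reference: transparent loop over Algorithm-style updates using only
  # exported building blocks, with the same RNG draw order
  ref <- list(X = st0$X, V = st0$V, pbX = st0$pbest_X, pbF = st0$pbest_F,
              gbX = st0$gbest_X, gbF = st0$gbest_F, z = st0$z)
  offered <- st0$F
  set.seed(101)
  t_now <- 1
  wgt <- inertia(t_now, cfg)
  theta <- penalty_schedule(t_now, cfg$max_iter, cfg$theta_min, cfg$theta_max)
  for (i in 1:3) {
    r1 <- runif(1); r2 <- runif(1)
    v <- wgt * ref$V[i, ] + cfg$c1 * r1 * (ref$pbX[i, ] - ref$X[i, ]) +
      cfg$c2 * r2 * (ref$gbX[i, ] - ref$X[i, ])
    v <- pmin(pmax(v, -0.5), 0.5)
    x <- pmin(pmax(ref$X[i, ] + v, 0), 1)
    f <- vapply(models, function(m) m$evaluate(x), numeric(1))
    ref$z <- pmin(ref$z, f)
    g_of <- function(fv, lam) pbi_aggregate(fv, lam, ref$z, theta)$g
    if (g_of(f, w[i, ]) < g_of(ref$pbF[i, ], w[i, ])) {
      ref$pbX[i, ] <- x; ref$pbF[i, ] <- f
    }
    for (j in nbhd[i, ]) {
      if (g_of(f, w[j, ]) < g_of(ref$gbF[j, ], w[j, ])) {
        ref$gbX[j, ] <- x; ref$gbF[j, ] <- f
      }
    }
    ref$X[i, ] <- x; ref$V[i, ] <- v
    offered <- rbind(offered, f)
  }

  set.seed(101)
  st1 <- swarm_step(st0, cfg, models)
  expect_equal(st1$X, ref$X)
  expect_equal(st1$V, ref$V)
  expect_equal(st1$pbest_F, ref$pbF)
  expect_equal(st1$gbest_F, ref$gbF)
  expect_equal(st1$z, ref$z)
  expect_equal(sort_rows(st1$archive$obj),
               sort_rows(oracle_nondominated(offered)), ignore_attr = TRUE)
})

test_that("pbest is monotone under an effectively single-objective landscape", {
  # f1 convex in one variable; f2, f3 constant, so PBI comparisons reduce
  # to comparisons of f1 for every subproblem
  models <- list(
    energy_model("f1", function(x) (x[1] - 0.3)^2),
    energy_model("f2", function(x) 1),
    energy_model("f3", function(x) 2)
  )
  w <- simplex_lattice(2, 3)
  cfg <- pso_config(max_iter = 25, T_size = 2, perturb_sigma = 0.2, seed = 7)
  sp <- vector_space(0, 1)
  set.seed(7)
  st <- init_swarm(sp, models, w, cfg)
  traj <- st$pbest_F[, 1, drop = FALSE]
  for (k in 1:25) {
    st <- swarm_step(st, cfg, models)
    traj <- cbind(traj, st$pbest_F[, 1])
  }
  for (i in seq_len(nrow(w))) {
    expect_true(all(diff(traj[i, ]) <= 1e-14))
  }
})

test_that("full runs are reproducible bit for bit and handle MaxIt = 0", {
  bp <- benchmark_problem("convex-plane", dim = 5)
  sp <- vector_space(bp$lower, bp$upper)
  cfg <- pso_config(max_iter = 15, divisions = 3, T_size = 4, seed = 11)
  r1 <- run_swarm(sp, bp$models, cfg)
  r2 <- run_swarm(sp, bp$models, cfg)
  expect_identical(r1$archive$obj, r2$archive$obj)
  expect_identical(r1$log, r2$log)
  # MaxIt = 0: archive is the non-dominated subset of the initial particles
  cfg0 <- pso_config(max_iter = 0, divisions = 3, T_size = 4, seed = 13)
  r0 <- run_swarm(sp, bp$models, cfg0)
  expect_equal(sort_rows(unname(r0$archive$obj)),
               sort_rows(oracle_nondominated(r0$state$F)),
               ignore_attr = TRUE)
})

test_that("objective failures during a step name the particle", {
  bad <- list(
    energy_model("ok", function(x) sum(x^2)),
    energy_model("boom", function(x) if (x[1] > -Inf) NaN else 0),
    energy_model("ok2", function(x) sum(x))
  )
  w <- simplex_lattice(1, 3)
  sp <- vector_space(rep(0, 2), rep(1, 2))
  cfg <- pso_config(max_iter = 2, T_size = 1, perturb_sigma = 0.1, seed = 17)
  expect_error(run_swarm(sp, bad, cfg), "particle")
})

test_that("run results expose tidy, glance and autoplot interfaces", {
  bp <- benchmark_problem("dtlz2", dim = 4)
  sp <- vector_space(bp$lower, bp$upper)
  run <- run_swarm(sp, bp$models,
                   pso_config(max_iter = 5, divisions = 2, T_size = 2,
                              seed = 19))
  td <- tidy(run)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6)
  gl <- glance(run)
  expect_equal(gl$n_particles, 6)
  expect_s3_class(autoplot(run), "ggplot")
  expect_s3_class(autoplot(run$archive), "ggplot")
})

test_that("swarm state checkpoints restore and continue identically", {
  bp <- benchmark_problem("convex-plane", dim = 4)
  sp <- vector_space(bp$lower, bp$upper)
  cfg <- pso_config(max_iter = 6, divisions = 2, T_size = 2, seed = 29)
  set.seed(29)
  st <- init_swarm(sp, bp$models, simplex_lattice(2, 3), cfg)
  for (k in 1:3) st <- swarm_step(st, cfg, bp$models)
  path <- withr::local_tempfile(fileext = ".rds")
  rng <- .Random.seed
  checkpoint_swarm(st, path)
  st_direct <- st
  for (k in 1:3) st_direct <- swarm_step(st_direct, cfg, bp$models)
  st_resumed <- restore_swarm(path)
  assign(".Random.seed", rng, envir = globalenv())
  for (k in 1:3) st_resumed <- swarm_step(st_resumed, cfg, bp$models)
  expect_equal(st_resumed$X, st_direct$X)
  expect_equal(st_resumed$archive$obj, st_direct$archive$obj)
  expect_error(restore_swarm(withr::local_tempfile(lines = "x",
                                                   fileext = ".rds")))
})
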