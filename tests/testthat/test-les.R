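test_that("LES config enforces the exact 1/N scaling contract", {
  cfg <- les_config(n_copies = 14L)
  expect_identical(cfg$scaling, 1 / 14)
  expect_identical(les_config(n_copies = 1L)$scaling, 1)
  expect_error(les_config(n_copies = 0L), "n_copies")
})

test_that("N = 1 LES is bit-identical to the plain Langevin reference", {
  set.seed(3)
  sys <- toy_les_system(copy_pos = matrix(c(0.3, 0, 0), 1L, 3L),
                        env_pos = matrix(rnorm(9, sd = 2), 3L, 3L),
                        portal_dirs = rbind(c(1, 0, 0)))
  cfg <- les_config(n_copies = 1L, n_steps = 400L, seed = 77L)
  a <- simulate_les(sys, cfg)
  b <- simulate_langevin(sys, cfg)
  expect_identical(a$copy_traj, b$copy_traj)
  expect_identical(a$env_traj, b$env_traj)
  ## and the same seed twice reproduces the trajectory exactly
  expect_identical(simulate_les(sys, cfg)$copy_traj, a$copy_traj)
})

test_that("copy-copy forces vanish and coincident copies superpose linearly", {
  p <- c(0.7, -0.4, 0.2)
  env <- matrix(c(1.5, 0.2, -0.3), 1L, 3L)
  sys2 <- toy_les_system(copy_pos = rbind(p, p), env_pos = env)
  sys1 <- toy_les_system(copy_pos = rbind(p), env_pos = env)
  f2 <- les_forces(sys2, les_config(n_copies = 2L))
  f1 <- les_forces(sys1, les_config(n_copies = 1L))
  ## two copies at the same position, N = 2: each feels half the unscaled
  ## force; the environment feels the full single-copy pair force
  expect_equal(f2$copies[1L, ], f2$copies[2L, ])
  expect_equal(2 * f2$copies[1L, ], f1$copies[1L, ], tolerance = 1e-12)
  env_pair1 <- f1$env[1L, ] + sys1$tether_k * (env - sys1$env_sites)[1L, ]
  env_pair2 <- f2$env[1L, ] + sys2$tether_k * (env - sys2$env_sites)[1L, ]
  expect_equal(env_pair2, env_pair1, tolerance = 1e-12)
})

test_that("LES forces match a brute-force pairwise oracle on random systems", {
  set.seed(53)
  for (rep in 1:10) {
    N <- sample(c(1L, 3L, 14L), 1L)
    m <- sample(2:5, 1L)
    sys <- toy_les_system(copy_pos = matrix(rnorm(3 * N, sd = 2), N, 3L),
                          env_pos = matrix(rnorm(3 * m, sd = 2.5), m, 3L),
                          portal_dirs = rbind(c(0, 0, 1), c(1, 0, 0)),
                          uniform_field = c(0.2, 0, -0.1))
    sys$env_sites <- sys$env_pos + matrix(rnorm(3 * m, sd = 0.3), m, 3L)
    cfg <- les_config(n_copies = N)
    got <- les_forces(sys, cfg)
    ## independent scalar-loop oracle using the analytic force expressions
    Fc <- matrix(0, N, 3L); Fe <- matrix(0, m, 3L)
    for (i in seq_len(N)) {
      x <- sys$copy_pos[i, ]; r <- sqrt(sum(x^2))
      ew <- sys$well_depth * exp(-r^2 / (2 * sys$well_width^2))
      f <- -x * ew / sys$well_width^2
      eb <- sys$barrier_height * exp(-(r - sys$barrier_radius)^2 /
                                       (2 * sys$barrier_width^2))
      f <- f + eb * (r - sys$barrier_radius) / sys$barrier_width^2 * x / r
      for (k in seq_len(nrow(sys$portal_dirs))) {
        dx <- x - sys$barrier_radius * sys$portal_dirs[k, ]
        ep <- sys$portal_depth * exp(-sum(dx^2) / (2 * sys$portal_width^2))
        f <- f - dx * ep / sys$portal_width^2
      }
      f <- f + sys$uniform_field
      for (j in seq_len(m)) {
        dx <- x - sys$env_pos[j, ]
        den <- sum(dx^2) + 0.25 * sys$pair_sigma^2
        fp <- 12 * sys$pair_eps * (sys$pair_sigma^2 / den)^6 / den * dx
        f <- f + fp
        Fe[j, ] <- Fe[j, ] - fp / N
      }
      Fc[i, ] <- f / N
    }
    Fe <- Fe - sys$tether_k * (sys$env_pos - sys$env_sites)
    expect_equal(got$copies, Fc, tolerance = 1e-9)
    expect_equal(got$env, Fe, tolerance = 1e-9)
  }
})

test_that("a zero-temperature start at the cage minimum stays put", {
  sys <- toy_les_system(copy_pos = matrix(0, 1L, 3L), portal_dirs = NULL)
  cfg <- les_config(n_copies = 1L, n_steps = 200L, temperature = 0, friction = 0)
  run <- simulate_les(sys, cfg)
  expect_lt(max(abs(run$copy_traj)), 1e-12)
})

test_that("the thermostat holds the target temperature within 5 percent", {
  set.seed(91)
  sys <- toy_les_system(copy_pos = matrix(rnorm(36, sd = 0.3), 12L, 3L),
                        barrier_height = 60)   # keep all copies caged
  cfg <- les_config(n_copies = 12L, n_steps = 20000L, timestep = 0.005,
                    temperature = 1.2, friction = 4, seed = 19L)
  run <- simulate_les(sys, cfg)
  t_obs <- mean(run$kinetic_temperature[-seq_len(4000L)])
  expect_lt(abs(t_obs - 1.2) / 1.2, 0.05)
})

test_that("energy drift is bounded in the zero-friction, zero-noise limit", {
  sys <- toy_les_system(copy_pos = matrix(c(0.8, 0.2, -0.4), 1L, 3L),
                        env_pos = matrix(c(2, 0, 0), 1L, 3L))
  cfg <- les_config(n_copies = 1L, n_steps = 4000L, timestep = 0.002,
                    temperature = 0, friction = 0)
  run <- simulate_les(sys, cfg, record_energy = TRUE)
  drift <- max(abs(run$energy - run$energy[1L]))
  expect_lt(drift, 5e-3 * max(1, abs(run$energy[1L])))
})

test_that("non-finite and divergent states are reported", {
  sys <- toy_les_system(copy_pos = matrix(c(50, 0, 0), 1L, 3L), box_bound = 10)
  cfg <- les_config(n_copies = 1L, n_steps = 10L)
  expect_error(simulate_les(sys, cfg), "diverged")
})

test_that("a deterministic downhill run matches the closed-form passage time", {
  g <- 1.5; Fmag <- 2; L <- 5
  sys <- toy_les_system(copy_pos = matrix(0, 1L, 3L),
                        well_depth = 0, barrier_height = 0,
                        uniform_field = c(Fmag, 0, 0))
  dt <- 0.002
  cfg <- les_config(n_copies = 1L, n_steps = 6000L, timestep = dt,
                    temperature = 0, friction = g)
  run <- simulate_les(sys, cfg)
  xpos <- run$copy_traj[1L, 1L, ]
  step_hit <- which(xpos > L)[1L]
  ## x(t) = (F/g) t - (F/g^2)(1 - exp(-g t)) for x0 = v0 = 0
  xt <- function(t) (Fmag / g) * t - (Fmag / g^2) * (1 - exp(-g * t))
  t_star <- uniroot(function(t) xt(t) - L, c(1e-3, 50))$root
  expect_lt(abs(step_hit * dt - t_star), 0.03 * t_star + 5 * dt)
})

test_that("first-passage sampling flags censoring and a flat landscape is fast", {
  sys <- toy_les_system(copy_pos = matrix(0, 1L, 3L),
                        well_depth = 0, barrier_height = 0)
  cfg <- les_config(n_copies = 4L, n_steps = 2000L, temperature = 1.5,
                    friction = 1, timestep = 0.01)
  fp <- first_passage_stats(sys, cfg, escape_radius = 3, replicas = 10L, seed = 3L)
  expect_false(any(fp$censored))
  expect_lt(fp$median, 1000)
  ## an impossible budget censors every replica
  cfg2 <- les_config(n_copies = 1L, n_steps = 5L, temperature = 0.1)
  fp2 <- first_passage_stats(sys, cfg2, escape_radius = 50, replicas = 3L, seed = 3L)
  expect_true(all(fp2$censored))
  expect_identical(fp2$median, Inf)
})

test_that("LES runs convert into analyzable topology + trajectory", {
  set.seed(8)
  sys <- toy_les_system(copy_pos = matrix(0, 2L, 3L),
                        env_pos = matrix(rnorm(30, sd = 2), 10L, 3L),
                        well_depth = 0, barrier_height = 0,
                        uniform_field = c(1.5, 0, 0), box_bound = 500)
  cfg <- les_config(n_copies = 2L, n_steps = 2500L, temperature = 0.2,
                    friction = 1, timestep = 0.01, save_every = 10L)
  run <- simulate_les(sys, cfg)
  conv <- les_as_trajectory(run)
  expect_equal(n_ligand_copies(conv$atoms), 2L)
  tracks <- build_ligand_tracks(conv$trajectory, conv$atoms)
  ev <- detect_escape(tracks[[1L]], threshold = 5, persistence = 5)
  expect_false(is.null(ev))   # the field drags every copy away from the cluster
})
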