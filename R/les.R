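#' Locally-enhanced-sampling configuration
#'
#' The LES contract: the N ligand copies never interact with each other and
#' interact with the rest of the system (cage potential and environment
#' particles) at a scaling factor of exactly 1/N; each environment particle
#' feels the sum over copies of the 1/N-scaled interactions. Reduced units
#' throughout (k_B = 1, unit masses).
#'
#' @param n_copies number of ligand copies N (>= 1).
#' @param timestep integration timestep (reduced units).
#' @param temperature target temperature (reduced, k_B = 1).
#' @param friction Langevin friction gamma (1/time).
#' @param n_steps number of integration steps.
#' @param seed RNG seed.
#' @param save_every store every k-th step (default 1).
#' @return An `les_config`; `scaling` is fixed at `1/n_copies`.
#' @export
les_config <- function(n_copies = 14L, timestep = 0.005, temperature = 1,
                       friction = 1, n_steps = 1000L, seed = 1L,
                       save_every = 1L) {
  assert_that(n_copies >= 1L, "n_copies must be >= 1, got %s", n_copies)
  structure(list(n_copies = as.integer(n_copies),
                 scaling = 1 / as.integer(n_copies),
                 timestep = timestep, temperature = temperature,
                 friction = friction, n_steps = as.integer(n_steps),
                 seed = as.integer(seed), save_every = as.integer(save_every)),
            class = "les_config")
}

#' Toy cage system for LES demonstrations
#'
#' The "protein" stand-in is a radially symmetric cage potential: a Gaussian
#' well of depth `well_depth` at the origin, a spherical Gaussian barrier
#' ridge of height `barrier_height` at radius `barrier_radius`, and optional
#' portal wells (3-D Gaussian depressions of depth `portal_depth` centred on
#' `barrier_radius * portal_dirs[k,]`) that locally lower the ridge.
#' Optional environment particles are harmonically tethered to sites and
#' repel the copies through a softened inverse-12 pair potential.
#'
#' @param copy_pos `N x 3` initial copy positions.
#' @param env_pos `m x 3` environment particle positions (may be 0 rows).
#' @param well_depth,well_width cage well parameters.
#' @param barrier_height,barrier_radius,barrier_width ridge parameters.
#' @param portal_dirs `k x 3` unit directions of portal depressions (or NULL).
#' @param portal_depth,portal_width portal well parameters.
#' @param pair_eps,pair_sigma copy-environment repulsion parameters.
#' @param tether_k environment tether stiffness.
#' @param uniform_field constant external force on copies (length 3),
#'   useful for closed-form integrator checks.
#' @param box_bound integration aborts when any coordinate exceeds this.
#' @return A `toy_les_system`.
#' @export
toy_les_system <- function(copy_pos, env_pos = matrix(numeric(), 0L, 3L),
                           well_depth = 4, well_width = 1.5,
                           barrier_height = 4, barrier_radius = 3,
                           barrier_width = 0.6,
                           portal_dirs = NULL, portal_depth = 1.5,
                           portal_width = 0.8,
                           pair_eps = 1, pair_sigma = 0.8, tether_k = 10,
                           uniform_field = c(0, 0, 0), box_bound = 100) {
  copy_pos <- as_xyz(copy_pos); env_pos <- as_xyz(env_pos)
  if (!is.null(portal_dirs)) {
    portal_dirs <- as_xyz(portal_dirs)
    portal_dirs <- portal_dirs / sqrt(rowSums(portal_dirs^2))
  }
  sys <- structure(list(copy_pos = copy_pos, env_pos = env_pos,
                        env_sites = env_pos,
                        well_depth = well_depth, well_width = well_width,
                        barrier_height = barrier_height,
                        barrier_radius = barrier_radius,
                        barrier_width = barrier_width,
                        portal_dirs = portal_dirs, portal_depth = portal_depth,
                        portal_width = portal_width,
                        pair_eps = pair_eps, pair_sigma = pair_sigma,
                        tether_k = tether_k,
                        uniform_field = as.numeric(uniform_field),
                        box_bound = box_bound),
                   class = "toy_les_system")
  e0 <- les_energy(sys, scaling = 1)
  assert_that(is.finite(e0), "initial energy is not finite")
  sys
}

## cage force/energy on one position (unscaled)
cage_force_energy <- function(x, sys) {
  r2 <- sum(x * x); r <- sqrt(r2)
  ew <- sys$well_depth * exp(-r2 / (2 * sys$well_width^2))
  U <- -ew
  F <- -x * ew / sys$well_width^2
  eb <- sys$barrier_height * exp(-(r - sys$barrier_radius)^2 / (2 * sys$barrier_width^2))
  U <- U + eb
  if (r > 1e-12)
    F <- F + eb * (r - sys$barrier_radius) / sys$barrier_width^2 * (x / r)
  if (!is.null(sys$portal_dirs)) {
    for (k in seq_len(nrow(sys$portal_dirs))) {
      c_k <- sys$barrier_radius * sys$portal_dirs[k, ]
      dx <- x - c_k
      ep <- sys$portal_depth * exp(-sum(dx * dx) / (2 * sys$portal_width^2))
      U <- U - ep
      F <- F - dx * ep / sys$portal_width^2
    }
  }
  U <- U - sum(sys$uniform_field * x)
  F <- F + sys$uniform_field
  list(U = U, F = F)
}

## softened repulsion between one copy and one environment particle
pair_force_energy <- function(xc, xe, sys) {
  dx <- xc - xe
  s2 <- sys$pair_sigma^2 / (sum(dx * dx) + 0.25 * sys$pair_sigma^2)
  U <- sys$pair_eps * s2^6
  F <- 12 * sys$pair_eps * s2^6 / (sum(dx * dx) + 0.25 * sys$pair_sigma^2) * dx
  list(U = U, F = F)
}

#' LES forces on copies and environment
#'
#' Copy-copy forces are identically zero. Each copy feels the cage and the
#' environment particles scaled by `1/N`; each environment particle feels
#' its tether (unscaled, it belongs to the environment) plus the reaction
#' sum over copies of the `1/N`-scaled pair interactions.
#'
#' @param system a [toy_les_system()].
#' @param config an [les_config()] (supplies the 1/N scaling).
#' @param copy_pos,env_pos optional position overrides.
#' @return list(`copies` `N x 3`, `env` `m x 3`).
#' @export
les_forces <- function(system, config, copy_pos = system$copy_pos,
                       env_pos = system$env_pos) {
  s <- config$scaling
  N <- nrow(copy_pos); m <- nrow(env_pos)
  X <- as_xyz(copy_pos)
  ## cage forces, vectorized over copies
  r2 <- rowSums(X^2); r <- sqrt(r2)
  ew <- system$well_depth * exp(-r2 / (2 * system$well_width^2))
  Fc <- -X * (ew / system$well_width^2)
  eb <- system$barrier_height * exp(-(r - system$barrier_radius)^2 /
                                      (2 * system$barrier_width^2))
  rs <- ifelse(r > 1e-12, 1 / r, 0)
  Fc <- Fc + X * (eb * (r - system$barrier_radius) / system$barrier_width^2 * rs)
  if (!is.null(system$portal_dirs)) {
    for (k in seq_len(nrow(system$portal_dirs))) {
      dx <- X - matrix(system$barrier_radius * system$portal_dirs[k, ], N, 3L, byrow = TRUE)
      ep <- system$portal_depth * exp(-rowSums(dx^2) / (2 * system$portal_width^2))
      Fc <- Fc - dx * (ep / system$portal_width^2)
    }
  }
  Fc <- Fc + matrix(system$uniform_field, N, 3L, byrow = TRUE)
  Fc <- s * Fc
  Fe <- matrix(0, max(m, 0L), 3L)
  if (m > 0L) {
    sig2 <- system$pair_sigma^2
    for (j in seq_len(m)) {
      dx <- X - matrix(env_pos[j, ], N, 3L, byrow = TRUE)
      denom <- rowSums(dx^2) + 0.25 * sig2
      fmag <- 12 * system$pair_eps * (sig2 / denom)^6 / denom
      Fp <- dx * fmag
      Fc <- Fc + s * Fp
      Fe[j, ] <- Fe[j, ] - s * colSums(Fp)
    }
    Fe <- Fe - system$tether_k * (env_pos - system$env_sites)
  }
  bad <- !is.finite(Fc)
  if (any(bad))
    stopf("non-finite force on copy %d", which(rowSums(bad) > 0)[1L])
  if (m > 0L && any(!is.finite(Fe)))
    stopf("non-finite force on environment particle %d",
          which(rowSums(!is.finite(Fe)) > 0)[1L])
  list(copies = Fc, env = Fe)
}

#' Total potential + kinetic energy of a toy LES system
#' @param system a [toy_les_system()].
#' @param scaling copy-environment scaling factor.
#' @param copy_pos,env_pos,copy_vel,env_vel optional state overrides.
#' @return Numeric scalar energy (reduced units).
#' @export
les_energy <- function(system, scaling = 1, copy_pos = system$copy_pos,
                       env_pos = system$env_pos, copy_vel = NULL, env_vel = NULL) {
  U <- 0
  for (i in seq_len(nrow(copy_pos))) {
    U <- U + scaling * cage_force_energy(copy_pos[i, ], system)$U
    for (j in seq_len(nrow(env_pos)))
      U <- U + scaling * pair_force_energy(copy_pos[i, ], env_pos[j, ], system)$U
  }
  if (nrow(env_pos) > 0L)
    U <- U + 0.5 * system$tether_k * sum((env_pos - system$env_sites)^2)
  K <- 0
  if (!is.null(copy_vel)) K <- K + 0.5 * sum(copy_vel^2)
  if (!is.null(env_vel)) K <- K + 0.5 * sum(env_vel^2)
  U + K
}

#' Run a BAOAB Langevin LES simulation
#'
#' BAOAB splitting (kick / drift / Ornstein-Uhlenbeck / drift / kick) with a
#' single uniform thermostat over copies and environment. Reproducible given
#' the seed; with `friction = 0` and `temperature = 0` the integrator
#' reduces to velocity Verlet.
#'
#' @param system a [toy_les_system()].
#' @param config an [les_config()].
#' @param record_energy also record the total (scaled) energy per saved
#'   step; used by the zero-friction drift checks.
#' @return list with `copy_traj` (`N x 3 x n_saved`), `env_traj`,
#'   `kinetic_temperature` (per saved step), `energy` (or NULL), `config`,
#'   `system`.
#' @export
simulate_les <- function(system, config, record_energy = FALSE) {
  set.seed(config$seed)
  dt <- config$timestep; g <- config$friction; Tt <- config$temperature
  c1 <- exp(-g * dt); c2 <- sqrt((1 - c1^2) * Tt)
  N <- nrow(system$copy_pos); m <- nrow(system$env_pos)
  x <- rbind(system$copy_pos, system$env_pos)   # all particles, copies first
  v <- matrix(0, N + m, 3L)
  nsave <- config$n_steps %/% config$save_every
  traj <- array(NA_real_, dim = c(N + m, 3L, nsave))
  ktemp <- numeric(nsave)
  ener <- if (record_energy) numeric(nsave) else NULL
  forces <- function(x) {
    f <- les_forces(system, config, copy_pos = x[seq_len(N), , drop = FALSE],
                    env_pos = x[N + seq_len(m), , drop = FALSE])
    rbind(f$copies, f$env)
  }
  F <- forces(x)
  si <- 0L
  for (step in seq_len(config$n_steps)) {
    v <- v + 0.5 * dt * F
    x <- x + 0.5 * dt * v
    if (g > 0 || Tt > 0) {
      xi <- matrix(stats::rnorm(3L * (N + m)), N + m, 3L)
      v <- c1 * v + c2 * xi
    }
    x <- x + 0.5 * dt * v
    F <- forces(x)
    v <- v + 0.5 * dt * F
    if (any(abs(x) > system$box_bound))
      stopf("integration diverged at step %d (|x| > %g)", step, system$box_bound)
    if (step %% config$save_every == 0L) {
      si <- si + 1L
      traj[, , si] <- x
      ktemp[si] <- sum(v * v) / (3 * (N + m))
      if (record_energy)
        ener[si] <- les_energy(system, scaling = config$scaling,
                               copy_pos = x[seq_len(N), , drop = FALSE],
                               env_pos = x[N + seq_len(m), , drop = FALSE]) +
          0.5 * sum(v * v)
    }
  }
  list(copy_traj = traj[seq_len(N), , , drop = FALSE],
       env_traj = if (m > 0L) traj[N + seq_len(m), , , drop = FALSE] else NULL,
       kinetic_temperature = ktemp, energy = ener, config = config, system = system)
}

#' Plain (unscaled) Langevin reference simulation
#'
#' Identical integrator, but forces are computed directly from the unscaled
#' potential for a single ligand; used as the independent reference for the
#' N = 1 LES limit (bit-identical trajectories given the same seed).
#'
#' @param system a [toy_les_system()] with exactly one copy.
#' @param config an [les_config()] (its `n_copies` is ignored; scaling 1).
#' @return Same shape as [simulate_les()].
#' @export
simulate_langevin <- function(system, config) {
  assert_that(nrow(system$copy_pos) == 1L,
              "plain Langevin reference expects exactly one copy")
  cfg1 <- config
  cfg1$n_copies <- 1L
  cfg1$scaling <- 1
  class(cfg1) <- "les_config"
  simulate_les(system, cfg1)
}

#' First-passage statistics for "any copy escapes"
#'
#' Runs `replicas` independent LES simulations (seeds derived from `seed`)
#' and records, per replica, the first saved step at which any copy crosses
#' the spherical barrier surface of radius `escape_radius`. Replicas with no
#' escape within the step budget are censored (`NA`, flagged) and treated as
#' +Inf in the median.
#'
#' @param system a [toy_les_system()] template (copy count taken from
#'   `config`; the template's first copy position is replicated).
#' @param config an [les_config()].
#' @param escape_radius barrier surface radius (default: ridge radius plus
#'   two ridge widths).
#' @param replicas number of replicas (>= 1).
#' @param seed master seed; replica r uses `seed + r`.
#' @return list(`first_passage` numeric vector (saved-step index, `NA` if
#'   censored), `censored` logical vector, `median`, `mean` (censored
#'   replicas excluded from the mean, counted as +Inf in the median)).
#' @export
first_passage_stats <- function(system, config, escape_radius = NULL,
                                replicas = 100L, seed = 1L) {
  assert_that(replicas >= 1L, "replicas must be >= 1")
  if (is.null(escape_radius))
    escape_radius <- system$barrier_radius + 2 * system$barrier_width
  start <- matrix(rep(system$copy_pos[1L, ], each = config$n_copies),
                  config$n_copies, 3L)
  sys <- system
  sys$copy_pos <- start
  fp <- rep(NA_real_, replicas)
  for (r in seq_len(replicas)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    class(cfg) <- "les_config"
    run <- simulate_les(sys, cfg)
    rad2 <- apply(run$copy_traj, 3L, function(fr) max(rowSums(fr^2)))
    hit <- which(rad2 > escape_radius^2)
    if (length(hit)) fp[r] <- hit[1L]
  }
  censored <- is.na(fp)
  med <- stats::median(ifelse(censored, Inf, fp))
  list(first_passage = fp, censored = censored, median = med,
       mean = if (all(censored)) NA_real_ else mean(fp[!censored]))
}

#' Convert an LES run into analyzable topology + trajectory
#'
#' Builds an [atom_table()] (environment particles as protein pseudo-atoms,
#' copies as single-atom ligand residues) and an [md_trajectory()] so the
#' ligand-tracking stack can analyze toy LES output end-to-end.
#'
#' @param run result of [simulate_les()].
#' @param timestep_ps nominal time between saved frames, ps.
#' @return list(`atoms`, `trajectory`).
#' @export
les_as_trajectory <- function(run, timestep_ps = 1) {
  N <- dim(run$copy_traj)[1L]
  m <- if (is.null(run$env_traj)) 0L else dim(run$env_traj)[1L]
  assert_that(m > 0L, "LES run has no environment particles to act as protein")
  nfr <- dim(run$copy_traj)[3L]
  atoms <- atom_table(data.frame(
    serial = seq_len(m + N),
    name = c(rep("CA", m), rep("O1", N)),
    element = c(rep("C", m), rep("O", N)),
    resname = c(rep("ENV", m), rep("O2", N)),
    resid = c(seq_len(m), seq_len(N)),
    chain = "A",
    role = c(rep("protein", m), rep("ligand", N)),
    copy = c(rep(NA_integer_, m), seq_len(N)),
    stringsAsFactors = FALSE))
  coords <- array(NA_real_, dim = c(m + N, 3L, nfr))
  coords[seq_len(m), , ] <- run$env_traj
  coords[m + seq_len(N), , ] <- run$copy_traj
  list(atoms = atoms, trajectory = md_trajectory(coords, timestep_ps = timestep_ps))
}

#' Read an LES config file (flat key-value dialect)
#'
#' One `key value` pair per line; keys are the arguments of [les_config()].
#' @param path config file.
#' @return An [les_config()].
#' @export
read_les_config <- function(path) {
  toks <- read_config_lines(path)
  kv <- list()
  for (tk in toks) {
    assert_that(length(tk) == 2L, "bad LES config line in %s: need 'key value'", path)
    kv[[tk[1L]]] <- as.numeric(tk[2L])
  }
  do.call(les_config, kv)
}
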