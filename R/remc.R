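# Replica-exchange Monte Carlo docking of an anchored flexible lid: the lid
# is parameterized by a rigid-body orientation about its anchor atom plus
# the rotatable torsion angles; bond lengths and angles never change. The
# receptor is held rigid (binding-site side chains may be relaxed separately
# with the self-consistent rotamer optimizer).

# ---- quaternions -----------------------------------------------------------

.quat_normalize <- function(q) q / sqrt(sum(q^2))

.quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

.quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

.axis_angle_quat <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

.random_unit_quat <- function() .quat_normalize(rnorm(4))

# ---- pose state ------------------------------------------------------------

#' Anchored-lid pose in rigid-body + torsion coordinates
#'
#' A pose is the orientation of the whole lid about its anchor atom (unit
#' quaternion), the anchor-atom position (fixed during docking), and the
#' values of the rotatable torsions. Realizing a pose is a pure function of
#' these coordinates and the lid's reference geometry.
#'
#' @param translation 3-vector: the anchor atom position (A)
#' @param quaternion unit quaternion (w, x, y, z) orienting the lid about
#'   the anchor
#' @param torsions target angles (radians) for the rotatable torsions, in
#'   torsion-table order
#' @param anchor_idx index of the anchored atom in the lid
#' @param replica_id,temperature_id provenance labels
#' @param energy optional cached `energy_breakdown`
#' @return object of class `pose_state`
#' @export
pose_state <- function(translation, quaternion = c(1, 0, 0, 0), torsions,
                       anchor_idx = 1L, replica_id = NA_integer_,
                       temperature_id = NA_integer_, energy = NULL) {
  quaternion <- .quat_normalize(quaternion)
  stopifnot(length(translation) == 3L, abs(sum(quaternion^2) - 1) < 1e-9)
  structure(list(translation = as.numeric(translation),
                 quaternion = quaternion, torsions = as.numeric(torsions),
                 anchor_idx = as.integer(anchor_idx),
                 replica_id = replica_id, temperature_id = temperature_id,
                 energy = energy),
            class = "pose_state")
}

# connected component containing `from` after deleting bond (j, k)
.moving_side <- function(n, bonds, j, k, from) {
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    bi <- bonds$i[b]; bj <- bonds$j[b]
    if ((bi == j && bj == k) || (bi == k && bj == j)) next
    adj[[bi]] <- c(adj[[bi]], bj); adj[[bj]] <- c(adj[[bj]], bi)
  }
  seen <- logical(n); seen[from] <- TRUE
  frontier <- from
  while (length(frontier) > 0L) {
    nxt <- setdiff(unique(unlist(adj[frontier])), which(seen))
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

# rotate points about the axis through p0 with unit direction u (Rodrigues)
.rotate_about_axis <- function(X, p0, u, theta) {
  u <- u / sqrt(sum(u^2))
  V <- sweep(X, 2L, p0)
  ct <- cos(theta); st <- sin(theta)
  Vu <- as.vector(V %*% u)
  crossm <- cbind(u[2] * V[, 3] - u[3] * V[, 2],
                  u[3] * V[, 1] - u[1] * V[, 3],
                  u[1] * V[, 2] - u[2] * V[, 1])
  sweep(V * ct + crossm * st + outer(Vu * (1 - ct), u), 2L, p0, `+`)
}

#' Set one torsion of a structure to a target angle
#'
#' Rotates the atoms on the far side of the central bond so that the
#' dihedral i-j-k-l equals `target`; bond lengths and bond angles are
#' untouched.
#'
#' @param s a `lidstruct` with bonds and torsions
#' @param row row index into `s$torsions`
#' @param target target dihedral (radians)
#' @return the structure with the torsion set
#' @export
set_torsion <- function(s, row, target) {
  tt <- s$torsions[row, ]
  xyz <- coords(s)
  cur <- .dihedral(xyz[tt$i, ], xyz[tt$j, ], xyz[tt$k, ], xyz[tt$l, ])
  delta <- target - cur
  if (abs(delta) < 1e-12) return(s)
  cache_pos <- match(row, s$metadata$rot_rows %||% integer(0))
  mov <- if (!is.na(cache_pos)) s$metadata$moving_sides[[cache_pos]]
  else .moving_side(natoms(s), s$bonds, tt$j, tt$k, tt$k)
  axis <- xyz[tt$k, ] - xyz[tt$j, ]
  xyz2 <- xyz
  xyz2[mov, ] <- .rotate_about_axis(xyz[mov, , drop = FALSE], xyz[tt$j, ],
                                    axis, delta)
  new <- .dihedral(xyz2[tt$i, ], xyz2[tt$j, ], xyz2[tt$k, ], xyz2[tt$l, ])
  if (abs(sin(new - target)) > 1e-8 || cos(new - target) < 0) {
    xyz2 <- xyz
    xyz2[mov, ] <- .rotate_about_axis(xyz[mov, , drop = FALSE], xyz[tt$j, ],
                                      axis, -delta)
  }
  set_coords(s, xyz2)
}

#' Realize a pose as Cartesian lid coordinates
#'
#' Applies the pose's rotatable-torsion values to the lid's reference
#' geometry, then rotates the whole lid about the anchor atom by the pose
#' quaternion and places the anchor at the pose translation. The anchor
#' atom's coordinates are exactly the pose translation for every pose.
#'
#' @param pose a `pose_state`
#' @param lid the reference lid `lidstruct`
#' @return a `lidstruct` with the realized coordinates
#' @export
realize_pose <- function(pose, lid) {
  s <- lid
  rot_rows <- which(s$torsions$rotatable %||% logical(0))
  if (length(rot_rows) != length(pose$torsions))
    stop("pose has ", length(pose$torsions), " torsions but the lid has ",
         length(rot_rows), " rotatable torsions")
  for (k in seq_along(rot_rows))
    s <- set_torsion(s, rot_rows[k], pose$torsions[k])
  xyz <- coords(s)
  R <- .quat_to_matrix(pose$quaternion)
  anchor <- xyz[pose$anchor_idx, ]
  xyz <- sweep(sweep(xyz, 2L, anchor) %*% t(R), 2L, pose$translation, `+`)
  set_coords(s, xyz)
}

# ---- ladder and search box -------------------------------------------------

#' Arithmetic temperature ladder
#'
#' Temperature levels uniformly distributed between `t_min` and `t_max`
#' inclusive (the replica-exchange default; a geometric ladder is available
#' via `spacing = "geometric"`).
#'
#' @param t_min,t_max endpoint temperatures (K), `t_min <= t_max`
#' @param n number of levels (>= 1; `n = 1` requires `t_min == t_max`)
#' @param spacing `"arithmetic"` (default) or `"geometric"`
#' @return list of class `temperature_ladder` with ascending `levels`
#' @export
make_temperature_ladder <- function(t_min, t_max, n,
                                    spacing = c("arithmetic", "geometric")) {
  spacing <- match.arg(spacing)
  if (n < 1L) stop("ladder needs at least one level")
  if (t_min > t_max) stop("t_min must not exceed t_max")
  if (t_min <= 0) stop("temperatures must be positive")
  if (n == 1L) {
    if (t_min != t_max) stop("n = 1 requires t_min == t_max")
    levels <- t_min
  } else {
    levels <- if (spacing == "arithmetic") seq(t_min, t_max, length.out = n)
    else exp(seq(log(t_min), log(t_max), length.out = n))
  }
  structure(list(levels = levels), class = "temperature_ladder")
}

#' Axis-aligned search box around a binding interface
#'
#' The bounding box of the reference coordinates expanded by `cushion` on
#' every face; lid poses proposed outside the box are rejected before the
#' Metropolis step.
#'
#' @param reference a `lidstruct`, a list of them, or an n x 3 coordinate
#'   matrix
#' @param cushion expansion on every side (A, default 10)
#' @return list of class `search_box` with `lo` and `hi` 3-vectors
#' @export
define_search_box <- function(reference, cushion = 10) {
  xyz <- if (is.matrix(reference)) reference
  else if (inherits(reference, "lidstruct")) coords(reference)
  else do.call(rbind, lapply(reference, coords))
  if (is.null(xyz) || nrow(xyz) == 0L) stop("empty selection for search box")
  structure(list(lo = apply(xyz, 2L, min) - cushion,
                 hi = apply(xyz, 2L, max) + cushion),
            class = "search_box")
}

.in_box <- function(xyz, box) {
  if (is.null(box)) return(TRUE)
  all(sweep(xyz, 2L, box$lo, `>=`)) && all(sweep(xyz, 2L, box$hi, `<=`))
}

#' Coarse reference grid over anchored-lid pose space
#'
#' Enumerates poses on a regular 6-DOF grid: rigid-body orientation about
#' the anchor as z-y-z Euler angles (`n_euler` points per axis; the middle
#' angle spans `[0, pi]`, the outer two span `[0, 2*pi)`) crossed with every
#' rotatable torsion on `n_torsion` points over `[0, 2*pi)`. With
#' `offset = TRUE` (the default) every axis is shifted by half a grid
#' spacing, making the grid a reference set of poses that is independent of
#' any axis-aligned construction; with `offset = FALSE` the grid contains
#' the identity orientation and torsions at exact multiples of the spacing.
#'
#' @param lid reference lid (`lidstruct`)
#' @param anchor_idx anchored lid atom (default 1)
#' @param n_euler grid points per Euler axis (default 8)
#' @param n_torsion grid points per rotatable torsion (default 4)
#' @param offset logical: shift all axes by half a spacing (default TRUE)
#' @return list of [pose_state()] objects
#' @export
reference_pose_grid <- function(lid, anchor_idx = 1L, n_euler = 8L,
                                n_torsion = 4L, offset = TRUE) {
  stopifnot(n_euler >= 1L, n_torsion >= 1L)
  anchor_xyz <- coords(lid)[anchor_idx, ]
  n_tor <- sum(lid$torsions$rotatable %||% logical(0))
  half <- if (offset) 0.5 else 0
  alpha <- (seq_len(n_euler) - 1 + half) * 2 * pi / n_euler
  beta <- (seq_len(n_euler) - 1 + half) * pi / n_euler
  tor <- (seq_len(n_torsion) - 1 + half) * 2 * pi / n_torsion
  tor <- atan2(sin(tor), cos(tor))
  axes <- as.matrix(expand.grid(c(list(alpha, beta, alpha),
                                  rep(list(tor), n_tor))))
  ez <- c(0, 0, 1); ey <- c(0, 1, 0)
  lapply(seq_len(nrow(axes)), function(r) {
    a <- axes[r, ]
    q <- .quat_multiply(.axis_angle_quat(ez, a[1]),
                        .quat_multiply(.axis_angle_quat(ey, a[2]),
                                       .axis_angle_quat(ez, a[3])))
    pose_state(anchor_xyz, q,
               if (n_tor > 0L) a[3L + seq_len(n_tor)] else numeric(0),
               anchor_idx)
  })
}

# ---- Monte Carlo kernel ----------------------------------------------------

#' Propose a symmetric Monte Carlo move in pose space
#'
#' With equal probability either perturbs the rigid-body orientation about
#' the anchor (random axis, Gaussian angle) or one randomly chosen torsion
#' (Gaussian increment). Increments are symmetric, so forward and reverse
#' proposals are equally probable. The anchor atom never moves. If a search
#' box is given and the realized proposal leaves it, the unchanged pose is
#' returned with attribute `rejected_oob = TRUE`.
#'
#' @param pose current `pose_state`
#' @param lid reference lid
#' @param box optional `search_box`
#' @param rot_step s.d. of the rigid rotation angle (radians; default 4
#'   degrees)
#' @param tor_step s.d. of a torsion increment (radians; default 10 degrees)
#' @return a proposed `pose_state`
#' @export
propose_move <- function(pose, lid, box = NULL, rot_step = 4 * pi / 180,
                         tor_step = 10 * pi / 180) {
  new <- pose
  if (length(pose$torsions) == 0L || runif(1) < 0.5) {
    dq <- .axis_angle_quat(rnorm(3), rnorm(1, 0, rot_step))
    new$quaternion <- .quat_normalize(.quat_multiply(dq, pose$quaternion))
  } else {
    k <- sample.int(length(pose$torsions), 1L)
    phi <- pose$torsions[k] + rnorm(1, 0, tor_step)
    new$torsions[k] <- atan2(sin(phi), cos(phi))
  }
  if (!is.null(box) && !.in_box(coords(realize_pose(new, lid)), box)) {
    attr(pose, "rejected_oob") <- TRUE
    return(pose)
  }
  new
}

#' Metropolis acceptance test
#'
#' Accepts with probability min(1, exp(-dE / (kB T))), kB the gas constant
#' 0.0019872041 kcal/mol/K.
#'
#' @param delta_e energy change (kcal/mol)
#' @param t temperature (K, > 0)
#' @return logical, TRUE to accept
#' @export
metropolis_accept <- function(delta_e, t) {
  if (t <= 0) stop("temperature must be positive")
  if (delta_e <= 0) return(TRUE)
  runif(1) < exp(-delta_e / (.kB * t))
}

#' Replica-swap acceptance test
#'
#' Exchanges the configurations of two replicas with probability
#' min(1, exp((beta_i - beta_j)(E_i - E_j))); temperatures stay attached to
#' the ladder levels.
#'
#' @param e_i,e_j current energies of the two replicas (kcal/mol)
#' @param t_i,t_j their temperatures (K)
#' @return logical, TRUE to swap
#' @export
swap_attempt <- function(e_i, e_j, t_i, t_j) {
  arg <- (1 / (.kB * t_i) - 1 / (.kB * t_j)) * (e_i - e_j)
  if (arg >= 0) return(TRUE)
  runif(1) < exp(arg)
}

# ---- exact kernels on discrete state spaces (validation machinery) ---------

#' Exact Metropolis transition matrix on a discrete state space
#'
#' @param energies state energies (kcal/mol)
#' @param t temperature (K)
#' @param proposal row-stochastic symmetric proposal matrix (default:
#'   uniform over the other states)
#' @return row-stochastic transition matrix whose stationary distribution is
#'   the Boltzmann distribution at `t`
#' @export
metropolis_kernel_matrix <- function(energies, t, proposal = NULL) {
  n <- length(energies)
  if (is.null(proposal)) {
    proposal <- matrix(1 / (n - 1), n, n); diag(proposal) <- 0
  }
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    K[i, j] <- proposal[i, j] * min(1, exp(-(energies[j] - energies[i]) /
                                             (.kB * t)))
  diag(K) <- 1 - rowSums(K)
  K
}

#' Exact two-replica exchange kernel on a discrete state space
#'
#' Product-space kernel for two replicas at `t1` and `t2`: independent
#' Metropolis moves at each level followed by a swap attempt. Its stationary
#' distribution is the product of the Boltzmann distributions at the two
#' temperatures.
#'
#' @param energies state energies (kcal/mol)
#' @param t1,t2 replica temperatures (K)
#' @param proposal per-level proposal matrix (see
#'   [metropolis_kernel_matrix()])
#' @return an n^2 x n^2 row-stochastic matrix over states (a, b), indexed
#'   `(a - 1) * n + b`
#' @export
remc_kernel_matrix <- function(energies, t1, t2, proposal = NULL) {
  n <- length(energies)
  K1 <- metropolis_kernel_matrix(energies, t1, proposal)
  K2 <- metropolis_kernel_matrix(energies, t2, proposal)
  Kmove <- kronecker(K1, K2)
  b1 <- 1 / (.kB * t1); b2 <- 1 / (.kB * t2)
  S <- matrix(0, n * n, n * n)
  idx <- function(a, b) (a - 1L) * n + b
  for (a in seq_len(n)) for (b in seq_len(n)) {
    p <- min(1, exp((b1 - b2) * (energies[a] - energies[b])))
    S[idx(a, b), idx(b, a)] <- S[idx(a, b), idx(b, a)] + p
    S[idx(a, b), idx(a, b)] <- S[idx(a, b), idx(a, b)] + 1 - p
  }
  Kmove %*% S
}

#' Boltzmann distribution over discrete states
#' @param energies state energies (kcal/mol)
#' @param t temperature (K)
#' @return probability vector
#' @export
boltzmann_weights <- function(energies, t) {
  w <- exp(-(energies - min(energies)) / (.kB * t))
  w / sum(w)
}

# ---- the sampler -----------------------------------------------------------

#' Replica-exchange Monte Carlo docking of an anchored lid
#'
#' Runs `length(ladder$levels)` replicas of the anchored lid against the
#' rigid receptor. Each cycle performs `moves_per_cycle` Metropolis moves
#' per replica at its own temperature, then `swaps_per_cycle` random
#' adjacent-pair swap attempts. The pose at the coldest level is recorded
#' after every cycle. Fully reproducible from `seed`.
#'
#' @param receptor rigid receptor (`lidstruct`)
#' @param lid flexible lid (`lidstruct`) in its reference geometry
#' @param params energy parameters ([default_energy_params()])
#' @param ladder a [make_temperature_ladder()] object
#' @param cycles number of simulation cycles (>= 1)
#' @param moves_per_cycle Metropolis moves per replica per cycle
#' @param swaps_per_cycle swap attempts after each cycle (default 100)
#' @param seed integer RNG seed
#' @param anchor_idx anchored lid atom (default 1)
#' @param box search box (default: receptor plus reference lid, 10 A
#'   cushion)
#' @param rot_step,tor_step move step sizes (radians)
#' @param init `"random"` (random orientations and torsions) or
#'   `"reference"` (all replicas start at the reference pose)
#' @return object of class `remc_dock`: the cold-chain pose trace,
#'   `best_pose`/`best_energy`, per-replica acceptance rates, the swap
#'   acceptance rate and an energy matrix (cycles x replicas)
#' @export
run_remc_docking <- function(receptor, lid, params = default_energy_params(),
                             ladder = make_temperature_ladder(300, 5300, 8),
                             cycles = 20L, moves_per_cycle = 50L,
                             swaps_per_cycle = 100L, seed = 1L,
                             anchor_idx = 1L, box = NULL,
                             rot_step = 4 * pi / 180,
                             tor_step = 10 * pi / 180,
                             init = c("random", "reference")) {
  init <- match.arg(init)
  if (cycles < 1L) stop("cycles must be >= 1")
  temps <- ladder$levels
  n_rep <- length(temps)
  receptor <- assign_vdw_params(receptor, params)
  lid <- prepare_topology(assign_vdw_params(lid, params))
  if (is.null(box)) box <- define_search_box(list(receptor, lid), 10)
  set.seed(seed)
  rot_rows <- which(lid$torsions$rotatable %||% logical(0))
  ref_tors <- vapply(rot_rows, function(r)
    measure_dihedral(lid, unlist(lid$torsions[r, c("i", "j", "k", "l")])),
    numeric(1))
  anchor_xyz <- coords(lid)[anchor_idx, ]
  replicas <- lapply(seq_len(n_rep), function(r) {
    pose <- if (init == "random")
      pose_state(anchor_xyz, .random_unit_quat(),
                 runif(length(rot_rows), -pi, pi), anchor_idx,
                 replica_id = r, temperature_id = r)
    else pose_state(anchor_xyz, c(1, 0, 0, 0), ref_tors, anchor_idx,
                    replica_id = r, temperature_id = r)
    e <- total_docking_energy(realize_pose(pose, lid), receptor, params)
    list(pose = pose, energy = e$total)
  })
  acc <- integer(n_rep); tries <- integer(n_rep)
  swap_acc <- 0L; swap_tries <- 0L
  energies <- matrix(NA_real_, cycles, n_rep)
  cold_trace <- vector("list", cycles)
  best_energy <- Inf; best_pose <- NULL
  # hot replicas take proportionally larger steps so they traverse the box
  # while the cold replica refines within its basin
  step_scale <- sqrt(temps / temps[1L])
  for (cy in seq_len(cycles)) {
    for (r in seq_len(n_rep)) {
      st <- replicas[[r]]
      for (mv in seq_len(moves_per_cycle)) {
        prop <- propose_move(st$pose, lid, box, rot_step * step_scale[r],
                             tor_step * step_scale[r])
        tries[r] <- tries[r] + 1L
        if (isTRUE(attr(prop, "rejected_oob"))) next
        e_new <- total_docking_energy(realize_pose(prop, lid), receptor,
                                      params)$total
        if (metropolis_accept(e_new - st$energy, temps[r])) {
          st$pose <- prop; st$energy <- e_new
          acc[r] <- acc[r] + 1L
          if (e_new < best_energy) {
            best_energy <- e_new
            best_pose <- prop
          }
        }
      }
      replicas[[r]] <- st
    }
    if (n_rep >= 2L) for (sw in seq_len(swaps_per_cycle)) {
      k <- sample.int(n_rep - 1L, 1L)
      swap_tries <- swap_tries + 1L
      if (swap_attempt(replicas[[k]]$energy, replicas[[k + 1L]]$energy,
                       temps[k], temps[k + 1L])) {
        tmp <- replicas[[k]]; replicas[[k]] <- replicas[[k + 1L]]
        replicas[[k + 1L]] <- tmp
        replicas[[k]]$pose$temperature_id <- k
        replicas[[k + 1L]]$pose$temperature_id <- k + 1L
        swap_acc <- swap_acc + 1L
      }
    }
    energies[cy, ] <- vapply(replicas, `[[`, numeric(1), "energy")
    cold_trace[[cy]] <- replicas[[1L]]
  }
  structure(list(
    cold_poses = lapply(cold_trace, `[[`, "pose"),
    cold_energies = vapply(cold_trace, `[[`, numeric(1), "energy"),
    best_pose = best_pose, best_energy = best_energy,
    energies = energies, ladder = ladder,
    acceptance = ifelse(tries > 0, acc / tries, NA_real_),
    swap_rate = if (swap_tries > 0) swap_acc / swap_tries else NA_real_,
    receptor = receptor, lid = lid, params = params, seed = seed),
    class = "remc_dock")
}

#' @export
print.remc_dock <- function(x, ...) {
  cat("Replica-exchange Monte Carlo docking\n")
  cat(sprintf("  %d replicas, %d cycles; T = %.0f ... %.0f K\n",
              length(x$ladder$levels), nrow(x$energies),
              min(x$ladder$levels), max(x$ladder$levels)))
  cat(sprintf("  best energy: %.4f kcal/mol\n", x$best_energy))
  cat(sprintf("  acceptance (cold -> hot): %s\n",
              paste(sprintf("%.2f", x$acceptance), collapse = " ")))
  cat(sprintf("  swap acceptance: %.2f\n", x$swap_rate))
  invisible(x)
}

#' @export
summary.remc_dock <- function(object, ...) {
  out <- list(best_energy = object$best_energy,
              cold_energy_mean = mean(object$cold_energies),
              cold_energy_min = min(object$cold_energies),
              acceptance = object$acceptance,
              swap_rate = object$swap_rate)
  class(out) <- "summary.remc_dock"
  out
}

#' @export
print.summary.remc_dock <- function(x, ...) {
  cat(sprintf("best energy       %10.4f kcal/mol\n", x$best_energy))
  cat(sprintf("cold-chain mean   %10.4f kcal/mol\n", x$cold_energy_mean))
  cat(sprintf("cold-chain min    %10.4f kcal/mol\n", x$cold_energy_min))
  cat(sprintf("swap acceptance   %10.2f\n", x$swap_rate))
  invisible(x)
}

#' @export
plot.remc_dock <- function(x, ...) {
  matplot(x$energies, type = "l", lty = 1, xlab = "cycle",
          ylab = "energy (kcal/mol)",
          main = "replica energies per cycle", ...)
  lines(x$cold_energies, lwd = 2)
  invisible(x)
}

# ---- rotamer optimization --------------------------------------------------

#' Load the bundled coarse side-chain rotamer library
#'
#' A compact chi-angle library (common gauche/trans combinations per residue
#' type) shipped with the package; angles in degrees, in (-180, 180].
#'
#' @return named list: residue type -> matrix of chi-angle rows (degrees)
#' @export
load_rotamer_library <- function() {
  f <- system.file("extdata", "rotamers.csv", package = "liddock")
  if (!nzchar(f)) f <- file.path("inst", "extdata", "rotamers.csv")
  tab <- read.csv(f, stringsAsFactors = FALSE, comment.char = "#")
  out <- lapply(split(tab, tab$resid), function(d) {
    m <- as.matrix(d[, grep("^chi", names(d)), drop = FALSE])
    m[, colSums(!is.na(m)) > 0, drop = FALSE]
  })
  out
}

#' Self-consistent rotamer optimization of selected side chains
#'
#' Iterates single-residue passes: for each listed residue, every candidate
#' rotamer (chi-angle tuple) is applied to that residue's chi torsions and
#' the configuration of lowest total energy is kept; passes repeat until a
#' full pass changes no assignment or `max_passes` is reached. The final
#' energy never exceeds the initial energy.
#'
#' Chi torsions are identified by optional `resno` and `chi` columns in
#' `s$torsions`; residues without rotamer entries raise an error.
#'
#' @param s a `lidstruct` whose torsion table carries `resno`/`chi` labels
#' @param residues integer vector of residue numbers to optimize
#' @param rotamers named list: residue type (3-letter code) -> matrix of
#'   chi-angle rows in degrees (see [load_rotamer_library()])
#' @param params energy parameters
#' @param energy_fn objective, default [system_energy()]; supply a closure
#'   including receptor interactions for in-site optimization
#' @param max_passes pass cap (reported if hit)
#' @return list with `structure`, `assignments` (chosen rotamer row per
#'   residue), `passes`, `converged`, `energy_initial`, `energy_final`
#' @export
self_consistent_rotamer_optimization <- function(
    s, residues, rotamers, params = default_energy_params(),
    energy_fn = NULL, max_passes = 20L) {
  if (is.null(energy_fn)) energy_fn <- function(x) system_energy(x, params)
  if (length(residues) == 0L)
    return(list(structure = s, assignments = integer(0), passes = 0L,
                converged = TRUE, energy_initial = energy_fn(s),
                energy_final = energy_fn(s)))
  tt <- s$torsions
  if (is.null(tt$resno) || is.null(tt$chi))
    stop("torsion table needs resno and chi columns for rotamer moves")
  chi_rows <- lapply(residues, function(rn) {
    rows <- which(tt$resno == rn)
    rows[order(tt$chi[rows])]
  })
  restype <- vapply(residues, function(rn)
    s$atoms$resid[which(s$atoms$resno == rn)[1L]], character(1))
  for (i in seq_along(residues)) {
    if (is.null(rotamers[[restype[i]]]))
      stop("no rotamers for residue type ", restype[i])
    if (ncol(rotamers[[restype[i]]]) < length(chi_rows[[i]]))
      stop("rotamer library has fewer chi angles than residue ",
           residues[i], " requires")
  }
  e0 <- energy_fn(s)
  assignments <- rep(NA_integer_, length(residues))
  passes <- 0L
  repeat {
    passes <- passes + 1L
    changed <- FALSE
    for (i in seq_along(residues)) {
      cand <- rotamers[[restype[i]]]
      best_e <- energy_fn(s); best_r <- assignments[i]; best_s <- s
      for (rr in seq_len(nrow(cand))) {
        s_try <- s
        for (ci in seq_along(chi_rows[[i]]))
          s_try <- set_torsion(s_try, chi_rows[[i]][ci],
                               cand[rr, ci] * pi / 180)
        e_try <- energy_fn(s_try)
        if (e_try < best_e - 1e-12) {
          best_e <- e_try; best_r <- rr; best_s <- s_try
        }
      }
      if (!identical(best_r, assignments[i])) {
        assignments[i] <- best_r; s <- best_s; changed <- TRUE
      }
    }
    if (!changed || passes >= max_passes) break
  }
  list(structure = s, assignments = assignments, passes = passes,
       converged = !changed, energy_initial = e0, energy_final = energy_fn(s))
}
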