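# Deterministic, seeded generators for toy systems with known ground truth:
# a rigid receptor with attraction pockets plus an anchored flexible lid, MD
# style trajectories with planted hydrogen-bond occupancies and per-residue
# fluctuation amplitudes, conformer sets with planted cluster structure and
# harmonic systems with closed-form normal modes. All generators are pure
# functions of their arguments; seeds are mandatory, never global state.

.element_mass <- function(element) {
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
         P = 30.974)
  out <- m[toupper(element)]
  out[is.na(out)] <- 12.011
  unname(out)
}

# serial bead chain (one pseudo-Calpha per residue): fixed 3.8 A bonds,
# fixed bond angles, rotatable torsions between consecutive quadruples
.make_bead_lid <- function(lid_length, bond_length = 3.8,
                           bond_angle = 110 * pi / 180, barrier = 1.0) {
  stopifnot(lid_length >= 2)
  xyz <- matrix(0, lid_length, 3)
  xyz[, 1] <- (seq_len(lid_length) - 1L) * bond_length
  if (lid_length >= 3L) {
    # fold into the fixed bond angle, zig-zag in the xy plane
    for (i in 3:lid_length) {
      prev <- xyz[i - 1L, ] - xyz[i - 2L, ]
      ang <- pi - bond_angle
      rot <- if (i %% 2L == 0L) ang else -ang
      R <- matrix(c(cos(rot), -sin(rot), 0, sin(rot), cos(rot), 0, 0, 0, 1),
                  3, 3, byrow = TRUE)
      xyz[i, ] <- xyz[i - 1L, ] + as.vector(R %*% prev) /
        sqrt(sum(prev^2)) * bond_length
    }
  }
  n <- lid_length
  atoms <- data.frame(name = "CA", element = "C", resid = "ALA",
                      resno = seq_len(n), chain = "L",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      charge = 0, hclass = "nonpolar",
                      stringsAsFactors = FALSE)
  bonds <- data.frame(i = seq_len(n - 1L), j = 2:n, k = NA_real_,
                      r0 = bond_length)
  torsions <- NULL
  if (n >= 4L)
    torsions <- data.frame(i = 1:(n - 3L), j = 2:(n - 2L), k = 3:(n - 1L),
                           l = 4:n, barrier = barrier, period = 3, phase = 0,
                           rotatable = TRUE)
  lidstruct(atoms, bonds = bonds, torsions = torsions,
            metadata = list(source = "toy lid"))
}

#' Generate a toy receptor-lid complex with a known energy minimum
#'
#' Builds a flexible bead-chain lid anchored at one terminal pseudo-Calpha
#' and a rigid receptor whose binding cleft consists of `n_pockets` smooth
#' attraction wells (deep Lennard-Jones sites placed at the soft-core
#' optimum distance below consecutive lid beads in a chosen native
#' conformation). The returned `known_minimum` pose realizes that native
#' conformation, so its energy under default docking parameters lies below
#' the energies of random or coarse-grid poses.
#'
#' @param n_pockets number of attraction pockets (default 3, mirroring a
#'   three-pocket hydrophobic cleft)
#' @param lid_length number of lid residues (beads), >= 2
#' @param anchor_seq_id residue number of the anchored bead (default 1)
#' @param pocket_depths well depths, kcal/mol, all negative (recycled to
#'   `n_pockets`)
#' @param seed integer RNG seed (mandatory)
#' @return list with `receptor`, `lid` (both `lidstruct`; the lid is stored
#'   in its native conformation) and `known_minimum` (a [pose_state()])
#' @export
make_toy_complex <- function(n_pockets = 3L, lid_length = 6L,
                             anchor_seq_id = 1L, pocket_depths = -5,
                             seed = 1L) {
  stopifnot(lid_length >= 2L, n_pockets >= 1L,
            n_pockets <= lid_length - 1L, all(pocket_depths < 0))
  pocket_depths <- rep_len(pocket_depths, n_pockets)
  set.seed(seed)
  lid <- .make_bead_lid(lid_length)
  # stiff single-well torsions (period 1, minimum at the native angle) make
  # the planted pose the unique funnel bottom: folded conformations pay more
  # in torsion strain than they can gain from the pockets
  if (!is.null(lid$torsions)) {
    native <- vapply(seq_len(nrow(lid$torsions)), function(r)
      measure_dihedral(lid, unlist(lid$torsions[r, c("i", "j", "k", "l")])),
      numeric(1))
    lid$torsions$period <- 1
    lid$torsions$barrier <- 15
    lid$torsions$phase <- atan2(sin(native + pi), cos(native + pi))
  }
  anchor_idx <- which(lid$atoms$resno == anchor_seq_id)[1L]
  if (is.na(anchor_idx)) stop("anchor residue not found in lid")
  # narrow pockets sit under alternating beads of the native conformation
  # (centre spacing ~6 A >> the well range) offset to the soft-core LJ
  # optimum r* = (2 - alpha)^(1/6) * sigma_ij, so no bead can engage two
  # pockets at once and the planted pose is the single-touch optimum
  params <- default_energy_params()
  sig_bead <- 1.2   # compact beads: wells too narrow for two beads to share
  sig_pocket <- 1.4
  sig_ij <- (sig_bead + sig_pocket) / 2
  rstar <- (2 - params$softcore$alpha)^(1 / 6) * sig_ij
  bead_idx <- rev(seq(lid_length, by = -2L, length.out = n_pockets))
  if (min(bead_idx) <= 1L)
    stop("lid too short for ", n_pockets, " pockets: need lid_length >= ",
         2L * n_pockets)
  xyz_lid <- coords(lid)
  pocket_xyz <- xyz_lid[bead_idx, , drop = FALSE]
  pocket_xyz[, 3] <- pocket_xyz[, 3] - rstar
  # pocket well depth: combined eps = sqrt(eps_pocket * eps_bead) = |depth|
  eps_bead <- params$vdw$eps[params$vdw$class == "nonpolar"]
  lid$atoms$sigma <- sig_bead
  # mild opposite charges on the pocketed beads and the pockets give the
  # landscape a long-range funnel toward the native orientation; the narrow
  # LJ wells dominate only at contact
  lid$atoms$charge[bead_idx] <- 0.25
  rec_atoms <- data.frame(name = "PKT", element = "C", resid = "PKT",
                          resno = seq_len(n_pockets), chain = "R",
                          x = pocket_xyz[, 1], y = pocket_xyz[, 2],
                          z = pocket_xyz[, 3], charge = -0.25,
                          hclass = "nonpolar", stringsAsFactors = FALSE)
  rec_atoms$eps <- pocket_depths^2 / eps_bead
  rec_atoms$sigma <- sig_pocket
  receptor <- lidstruct(rec_atoms,
                        metadata = list(source = "toy receptor",
                                        pockets = seq_len(n_pockets),
                                        pocket_xyz = pocket_xyz))
  native_torsions <- if (!is.null(lid$torsions))
    vapply(seq_len(nrow(lid$torsions)), function(r)
      measure_dihedral(lid, unlist(lid$torsions[r, c("i", "j", "k", "l")])),
      numeric(1))
  else numeric(0)
  known_minimum <- pose_state(
    translation = xyz_lid[anchor_idx, ],
    quaternion = c(1, 0, 0, 0),
    torsions = native_torsions,
    anchor_idx = anchor_idx)
  list(receptor = receptor, lid = lid, known_minimum = known_minimum)
}

#' Trajectory container
#'
#' Ordered conformations of one structure with strictly increasing time
#' stamps in picoseconds.
#' @param base a `lidstruct` defining the fixed atom set
#' @param xyz list of n x 3 coordinate matrices, one per frame
#' @param times numeric vector of frame times (ps), strictly increasing
#' @return object of class `lidtraj`
#' @export
lidtraj <- function(base, xyz, times) {
  stopifnot(length(xyz) == length(times), length(times) >= 1L,
            all(diff(times) > 0) || length(times) == 1L)
  for (f in xyz) stopifnot(nrow(f) == natoms(base), ncol(f) == 3L)
  structure(list(base = base, xyz = xyz, times = times), class = "lidtraj")
}

#' @export
print.lidtraj <- function(x, ...) {
  cat("lidtraj:", length(x$xyz), "frames x", natoms(x$base), "atoms,",
      "t =", x$times[1], "...", x$times[length(x$times)], "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `lidtraj`
#' @return integer frame count
#' @export
nframes <- function(traj) length(traj$xyz)

#' Extract one trajectory frame as a structure
#' @param traj a `lidtraj`
#' @param i frame index
#' @return a `lidstruct`
#' @export
traj_frame <- function(traj, i) set_coords(traj$base, traj$xyz[[i]])

#' Generate a trajectory with planted interactions and fluctuations
#'
#' Produces frames of `base` in which (a) each planted donor-acceptor pair
#' satisfies the default hydrogen-bond criterion (3.50 A, 120 degrees) in
#' exactly `round(occupancy * n_frames)` frames — the satisfying frames are
#' a seeded random subset, the geometry is set explicitly, so recovery is
#' exact, not Bernoulli — and (b) every other residue fluctuates about the
#' base coordinates with a planted per-residue root-mean-square amplitude
#' (displacements are centred per frame and rescaled per residue so the
#' realized pre-fit RMSF equals the requested amplitude exactly).
#'
#' @param base a classified `lidstruct`; planted donors need either a bonded
#'   hydrogen or a bonded heavy-atom antecedent for the angle criterion
#' @param n_frames number of frames (>= 1)
#' @param frame_interval time between frames, ps (default 2)
#' @param planted_pairs data.frame with columns `donor`, `acceptor` (atom
#'   indices into `base`) and `occupancy` in [0, 1]; NULL for none
#' @param fluctuation_amplitudes numeric vector, one RMS amplitude (A) per
#'   residue of `base` (0 = static); NULL for an all-static trajectory
#' @param seed integer RNG seed
#' @return a `lidtraj`
#' @export
make_synthetic_trajectory <- function(base, n_frames, frame_interval = 2,
                                      planted_pairs = NULL,
                                      fluctuation_amplitudes = NULL,
                                      seed = 1L) {
  stopifnot(n_frames >= 1L)
  set.seed(seed)
  a <- base$atoms
  res_key <- paste(a$chain, a$resno)
  res_levels <- unique(res_key)
  if (!is.null(fluctuation_amplitudes) &&
      length(fluctuation_amplitudes) != length(res_levels))
    stop("need one fluctuation amplitude per residue (",
         length(res_levels), ")")
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("donor", "acceptor", "occupancy") %in%
                    names(planted_pairs)))
    if (any(planted_pairs$occupancy < 0 | planted_pairs$occupancy > 1))
      stop("occupancy fractions must lie in [0, 1]")
  }
  x0 <- coords(base)
  planted_atoms <- integer(0)
  plant <- NULL
  if (!is.null(planted_pairs) && nrow(planted_pairs) > 0L) {
    plant <- lapply(seq_len(nrow(planted_pairs)), function(p) {
      d <- planted_pairs$donor[p]; acc <- planted_pairs$acceptor[p]
      # direction for the acceptor: along donor-H if a bonded H exists,
      # else away from the donor's bonded heavy antecedent
      dir <- NULL; hyd <- NA_integer_
      if (!is.null(base$bonds) && nrow(base$bonds) > 0L) {
        nb <- c(base$bonds$j[base$bonds$i == d],
                base$bonds$i[base$bonds$j == d])
        hs <- nb[a$element[nb] == "H"]
        if (length(hs) > 0L) {
          hyd <- hs[1L]
          dir <- x0[hyd, ] - x0[d, ]
        } else if (length(nb) > 0L) {
          dir <- x0[d, ] - x0[nb[1L], ]
        }
      }
      if (is.null(dir)) dir <- c(1, 0, 0)
      dir <- dir / sqrt(sum(dir^2))
      n_on <- round(planted_pairs$occupancy[p] * n_frames)
      if (n_on > 0 && (sum(a$element == "H") == 0) && is.na(hyd) &&
          is.null(base$bonds))
        stop("cannot plant hydrogen bond: donor ", d,
             " has no hydrogen and no bonded antecedent")
      on_frames <- if (n_on > 0) sort(sample.int(n_frames, n_on)) else
        integer(0)
      list(donor = d, acceptor = acc, dir = dir,
           on = x0[d, ] + dir * 2.9, off = x0[d, ] + dir * 6.0,
           on_frames = on_frames)
    })
    planted_atoms <- unique(c(planted_pairs$donor, planted_pairs$acceptor))
  }
  # residues whose atoms are planted stay static so geometry is exact
  frozen_res <- unique(res_key[planted_atoms])
  xyz <- vector("list", n_frames)
  if (is.null(fluctuation_amplitudes) || n_frames == 1L) {
    for (f in seq_len(n_frames)) xyz[[f]] <- x0
  } else {
    disp <- array(rnorm(n_frames * natoms(base) * 3L),
                  dim = c(n_frames, natoms(base), 3L))
    for (ri in seq_along(res_levels)) {
      rows <- which(res_key == res_levels[ri])
      amp <- fluctuation_amplitudes[ri]
      if (res_levels[ri] %in% frozen_res) amp <- 0
      if (amp == 0) { disp[, rows, ] <- 0; next }
      d <- disp[, rows, , drop = FALSE]
      # centre over frames, then rescale so RMS displacement is exactly amp
      for (at in seq_along(rows)) for (cc in 1:3)
        d[, at, cc] <- d[, at, cc] - mean(d[, at, cc])
      rms <- sqrt(mean(d^2) * 3)
      disp[, rows, ] <- if (rms > 0) d * (amp / rms) else 0
    }
    for (f in seq_len(n_frames)) {
      df <- disp[f, , , drop = TRUE]
      if (is.null(dim(df))) df <- matrix(df, ncol = 3L)
      xyz[[f]] <- x0 + df
    }
  }
  if (!is.null(plant)) {
    for (p in plant) for (f in seq_len(n_frames)) {
      xyz[[f]][p$acceptor, ] <- if (f %in% p$on_frames) p$on else p$off
    }
  }
  lidtraj(base, xyz, times = (seq_len(n_frames) - 1L) * frame_interval)
}

#' Generate conformer sets with planted cluster structure
#'
#' Clusters are rigid displacements of `base` separated by
#' `between_separation` along x; members jitter isotropically with RMS
#' `within_spread`. With the default similarity parameters this guarantees
#' within-cluster Tanimoto similarity above and between-cluster similarity
#' below the 0.85 clustering threshold; incompatible spread/separation
#' combinations raise an error rather than silently producing ambiguous
#' ground truth.
#'
#' @param base a classified `lidstruct`
#' @param k_clusters number of clusters
#' @param members_per_cluster integer vector of cluster sizes (recycled)
#' @param within_spread RMS jitter within a cluster (A)
#' @param between_separation centre-to-centre cluster separation (A)
#' @param seed integer RNG seed
#' @param params similarity parameters (see [similarity_params()]) used for
#'   the compatibility check
#' @return list with `conformations` (list of `lidstruct`) and `labels`
#'   (integer ground-truth cluster per conformation)
#' @export
make_planted_conformers <- function(base, k_clusters = 3L,
                                    members_per_cluster = 5L,
                                    within_spread = 0.15,
                                    between_separation = 20,
                                    seed = 1L,
                                    params = similarity_params()) {
  stopifnot(k_clusters >= 1L, between_separation > within_spread)
  if (between_separation < 2 * params$cutoff + 10 * within_spread ||
      within_spread > params$cutoff / 5)
    stop("spread/separation incompatible with the similarity threshold: ",
         "need between_separation >= 2*cutoff + 10*within_spread and ",
         "within_spread <= cutoff/5")
  sizes <- rep_len(members_per_cluster, k_clusters)
  set.seed(seed)
  x0 <- coords(base)
  confs <- list(); labels <- integer(0)
  for (cl in seq_len(k_clusters)) {
    offset <- c((cl - 1L) * between_separation, 0, 0)
    for (m in seq_len(sizes[cl])) {
      jit <- matrix(rnorm(length(x0), sd = within_spread / sqrt(3)),
                    ncol = 3L)
      confs[[length(confs) + 1L]] <-
        set_coords(base, sweep(x0 + jit, 2L, offset, `+`))
      labels <- c(labels, cl)
    }
  }
  list(conformations = confs, labels = labels)
}

#' Generate harmonic systems with closed-form normal modes
#'
#' Builds one diatomic per force constant (atoms 1.5 A apart along x,
#' diatomics spaced 50 A apart so they are uncoupled), with harmonic bond
#' energy k (r - r0)^2. The analytic angular frequency of each diatomic,
#' sqrt(2 k / mu) converted to s^-1, is stored in
#' `metadata$frequencies_s1`, giving a closed-form oracle for the numerical
#' Hessian and the vibrational entropy.
#'
#' @param force_constants positive bond constants, kcal/mol/A^2 (one
#'   diatomic each)
#' @param masses atomic masses, amu; length 2 * length(force_constants)
#'   (recycled)
#' @param bond_length equilibrium length r0 (A)
#' @return a `lidstruct` with harmonic topology, per-atom `mass` column and
#'   analytic frequencies in the metadata
#' @export
make_harmonic_system <- function(force_constants, masses = 12.011,
                                 bond_length = 1.5) {
  if (any(force_constants <= 0)) stop("force constants must be positive")
  if (any(masses <= 0)) stop("masses must be positive")
  nd <- length(force_constants)
  masses <- rep_len(masses, 2L * nd)
  atoms <- data.frame(name = "X", element = "C", resid = "HRM",
                      resno = rep(seq_len(nd), each = 2L), chain = "H",
                      x = rep((seq_len(nd) - 1L) * 50, each = 2L) +
                        rep(c(0, bond_length), nd),
                      y = 0, z = 0, charge = 0, hclass = NA_character_,
                      stringsAsFactors = FALSE)
  atoms$mass <- masses
  bonds <- data.frame(i = seq(1L, 2L * nd, by = 2L),
                      j = seq(2L, 2L * nd, by = 2L),
                      k = force_constants, r0 = bond_length)
  mu <- masses[seq(1L, 2L * nd, by = 2L)] * masses[seq(2L, 2L * nd, by = 2L)] /
    (masses[seq(1L, 2L * nd, by = 2L)] + masses[seq(2L, 2L * nd, by = 2L)])
  # 1 kcal/mol/A^2/amu = 4.184e26 s^-2; V = k (r-r0)^2 has curvature 2k
  freq <- sqrt(2 * force_constants / mu * 4.184e26)
  lidstruct(atoms, bonds = bonds,
            metadata = list(source = "harmonic system", nonbonded = FALSE,
                            frequencies_s1 = freq))
}
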