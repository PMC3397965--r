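# Shared toy builders. All toys are tiny, deterministic structures with
# explicit atom classes so tests control every parameter that enters the
# energy and similarity models.

xyz_rmsd <- function(a, b) {
  A <- if (inherits(a, "lidstruct")) coords(a) else a
  B <- if (inherits(b, "lidstruct")) coords(b) else b
  sqrt(mean(rowSums((A - B)^2)))
}

toy_atom <- function(x = 0, y = 0, z = 0, element = "C", name = "CA",
                     resid = "ALA", resno = 1L, chain = "A", charge = 0,
                     hclass = "nonpolar") {
  lidstruct(data.frame(name = name, element = element, resid = resid,
                       resno = resno, chain = chain, x = x, y = y, z = z,
                       charge = charge, hclass = hclass,
                       stringsAsFactors = FALSE))
}

# n single-atom residues at the given coordinates (n x 3 matrix)
toy_beads <- function(xyz, chain = "A", hclass = "nonpolar", charge = 0,
                      resid = "ALA", element = "C", name = "CA") {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  lidstruct(data.frame(name = rep_len(name, n),
                       element = rep_len(element, n),
                       resid = rep_len(resid, n),
                       resno = seq_len(n), chain = rep_len(chain, n),
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       charge = rep_len(charge, n),
                       hclass = rep_len(hclass, n),
                       stringsAsFactors = FALSE))
}

# Donor O (with bonded H at 1.0 A) plus acceptor O, placed so that the
# donor-acceptor distance is `dist` and the donor-H-acceptor angle (at the
# hydrogen) is `angle_deg`. Solves the planar triangle exactly.
toy_hbond_system <- function(dist = 2.9, angle_deg = 180) {
  phi <- angle_deg * pi / 180
  # acceptor at H + r_a * (direction of H->D rotated by phi in the plane)
  ra <- cos(phi) + sqrt(pmax(0, cos(phi)^2 - 1 + dist^2))
  ax <- 1 - ra * cos(phi)
  ay <- ra * sin(phi)
  atoms <- data.frame(
    name = c("OD", "HD", "OA"), element = c("O", "H", "O"),
    resid = "HOH", resno = c(1L, 1L, 2L), chain = "A",
    x = c(0, 1, ax), y = c(0, 0, ay), z = 0,
    charge = 0, hclass = c("donor", "nonpolar", "acceptor"),
    stringsAsFactors = FALSE)
  lidstruct(atoms, bonds = data.frame(i = 1L, j = 2L, k = NA_real_, r0 = 1))
}

hbond_satisfied_at <- function(dist, angle_deg = 180,
                               criteria = hbond_criteria()) {
  s <- toy_hbond_system(dist, angle_deg)
  traj <- lidtraj(s, list(coords(s)), times = 0)
  occ <- hbond_occupancy(traj, criteria,
                         pairs = data.frame(donor = 1L, acceptor = 3L))
  occ$occupancy == 1
}

# Two disconnected 4-atom arms P-Q-R-S, one chi torsion each (rotation of
# the tip S about the Q-R axis); the tips clash for facing rotamers, so the
# two residues are sterically coupled.
toy_rotamer_system <- function(gap = 4.0) {
  mk <- function(x0, rn) data.frame(
    name = c("P", "Q", "R", "S"), element = "C", resid = "TOY",
    resno = rn, chain = "A",
    x = x0 + c(0, 1.5, 1.5, 2.9), y = c(0, 0, 1.5, 1.5), z = 0,
    charge = 0, hclass = "nonpolar", stringsAsFactors = FALSE)
  atoms <- rbind(mk(0, 1L), mk(gap, 2L))
  bonds <- data.frame(i = c(1L, 2L, 3L, 5L, 6L, 7L),
                      j = c(2L, 3L, 4L, 6L, 7L, 8L),
                      k = NA_real_, r0 = NA_real_)
  torsions <- data.frame(i = c(1L, 5L), j = c(2L, 6L), k = c(3L, 7L),
                         l = c(4L, 8L), barrier = 0, period = 1, phase = 0,
                         rotatable = TRUE, resno = c(1L, 2L), chi = 1L)
  lidstruct(atoms, bonds = bonds, torsions = torsions)
}

# a mixed-class 3-atom rigid fragment used by similarity tests
toy_fragment <- function(shift = 0) {
  lidstruct(data.frame(
    name = c("N", "O", "C"), element = c("N", "O", "C"),
    resid = "ALA", resno = 1L, chain = "A",
    x = c(0, 1.4, 2.8) + shift, y = c(0, 1.0, 0), z = 0,
    charge = 0, hclass = c("donor", "acceptor", "nonpolar"),
    stringsAsFactors = FALSE))
}

# brute-force intermolecular oracle: explicit double loop over atom pairs
brute_intermolecular <- function(lid, receptor,
                                 params = default_energy_params()) {
  al <- lid$atoms; ar <- receptor$atoms
  XL <- coords(lid); XR <- coords(receptor)
  alpha <- if (params$softcore$enabled) params$softcore$alpha else 0
  w <- params$solvation$weights
  vdw <- 0; coul <- 0; solv <- 0
  for (i in seq_len(nrow(XL))) for (j in seq_len(nrow(XR))) {
    r <- sqrt(sum((XL[i, ] - XR[j, ])^2))
    if (r > params$cutoff) next
    pe <- softcore_pair(r, sqrt(al$eps[i] * ar$eps[j]),
                        (al$sigma[i] + ar$sigma[j]) / 2,
                        al$charge[i], ar$charge[j], alpha, params$dielectric)
    vdw <- vdw + pe$vdw
    coul <- coul + pe$coulomb
    solv <- solv + w[[al$hclass[i]]] * w[[ar$hclass[j]]] *
      exp(-r^2 / (2 * params$solvation$sigma^2))
  }
  list(vdw_inter = vdw, electrostatic = coul, solvation = solv)
}

# brute-force residue contact oracle on a single structure
brute_contacts <- function(s, cutoff = 4.2) {
  a <- s$atoms
  xyz <- coords(s)
  key <- paste0(a$chain, ":", a$resno)
  rlev <- unique(key[a$heavy])
  out <- NULL
  for (p in seq_along(rlev)) for (q in seq_along(rlev)) {
    if (q <= p) next
    ip <- which(key == rlev[p] & a$heavy)
    iq <- which(key == rlev[q] & a$heavy)
    dmin <- Inf
    for (i in ip) for (j in iq)
      dmin <- min(dmin, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
    out <- rbind(out, data.frame(res_i = rlev[p], res_j = rlev[q],
                                 min_dist = dmin,
                                 contact = dmin < cutoff))
  }
  out
}

# brute-force per-atom descriptor oracle
brute_descriptor <- function(i, conf_a, conf_b,
                             params = similarity_params()) {
  XA <- coords(conf_a); XB <- coords(conf_b)
  ca <- conf_a$atoms$hclass; cb <- conf_b$atoms$hclass
  acc <- 0
  for (j in seq_len(nrow(XB))) {
    d <- sqrt(sum((XA[i, ] - XB[j, ])^2))
    g <- if (d <= params$cutoff) exp(-d^2 / (2 * params$sigma^2)) else 0
    acc <- acc + g * params$compat[ca[i], cb[j]]
  }
  acc
}
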