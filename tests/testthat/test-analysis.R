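# trajectory analyses: hydrogen bonds, salt bridges, RMSD/RMSF, contacts,
# surface-area changes, side-chain movement and interaction mimicry

test_that("hydrogen-bond criteria default to 3.50 A and 120 degrees", {
  crit <- hbond_criteria()
  expect_identical(crit$max_distance, 3.50)
  expect_identical(crit$min_angle, 120.00)
  expect_error(hbond_criteria(max_distance = -1))
  expect_error(hbond_criteria(min_angle = 200))
})

test_that("the distance rule is inclusive at the cutoff", {
  expect_true(hbond_satisfied_at(3.50, 180))
  expect_false(hbond_satisfied_at(3.50 + 1e-6, 180))
  expect_true(hbond_satisfied_at(2.9, 180))
})

test_that("the angle rule switches at the cutoff", {
  # exact 120 is not reachable after the acos round-trip; bracket tightly
  expect_true(hbond_satisfied_at(2.9, 120.001))
  expect_false(hbond_satisfied_at(2.9, 119.999))
  expect_true(hbond_satisfied_at(2.9, 175))
})

test_that("heavy-atom structures fall back to the antecedent angle", {
  # donor C-N arm with the acceptor placed for a known N-centred angle
  mk <- function(theta_deg) {
    th <- theta_deg * pi / 180
    atoms <- data.frame(
      name = c("C", "N", "O"), element = c("C", "N", "O"),
      resid = "TOY", resno = c(1L, 1L, 2L), chain = "A",
      x = c(-1.5, 0, 3 * cos(pi - th)), y = c(0, 0, 3 * sin(pi - th)), z = 0,
      charge = 0, hclass = c("nonpolar", "donor", "acceptor"),
      stringsAsFactors = FALSE)
    s <- lidstruct(atoms, bonds = data.frame(i = 1L, j = 2L, k = NA_real_,
                                             r0 = 1.5))
    traj <- lidtraj(s, list(coords(s)), times = 0)
    hbond_occupancy(traj, pairs = data.frame(donor = 2L, acceptor = 3L))
  }
  expect_identical(mk(170)$occupancy, 1)   # nearly linear C-N...O
  expect_identical(mk(90)$occupancy, 0)    # bent below 120 degrees
})

test_that("occupancy is the exact satisfied-frame fraction", {
  s <- toy_hbond_system(6.0, 180)
  pairs <- data.frame(donor = 1L, acceptor = 3L, occupancy = 0.4)
  traj <- make_synthetic_trajectory(s, n_frames = 10, planted_pairs = pairs,
                                    seed = 3)
  occ <- hbond_occupancy(traj, pairs = pairs[, 1:2])
  expect_identical(occ$n_satisfied, 4L)
  expect_identical(occ$occupancy, 0.4)
})

test_that("salt bridges reject same-sign pairs and track geometry", {
  s <- toy_hbond_system(2.9, 180)
  s$atoms$charge <- c(1, 0, -1)
  traj <- lidtraj(s, list(coords(s)), times = 0)
  pairs <- data.frame(donor = 1L, acceptor = 3L)
  out <- salt_bridge_series(traj, pairs)
  expect_identical(dim(out), c(1L, 1L))
  expect_true(out[1, 1])
  s2 <- s; s2$atoms$charge <- c(1, 0, 1)
  expect_error(salt_bridge_series(lidtraj(s2, list(coords(s2)), times = 0),
                                  pairs), "same-sign")
  empty <- salt_bridge_series(traj, pairs[0, ])
  expect_identical(dim(empty), c(1L, 0L))
})

test_that("rmsd series is zero for rigid transforms and matches an oracle", {
  set.seed(9)
  base <- toy_beads(matrix(runif(18, 0, 10), ncol = 3))
  th <- 0.6
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  moved <- sweep(coords(base) %*% t(R), 2, c(5, -2, 1), `+`)
  jittered <- coords(base) + matrix(rnorm(18, sd = 0.5), ncol = 3)
  traj <- lidtraj(base, list(coords(base), moved, jittered),
                  times = c(0, 2, 4))
  out <- rmsd_series(traj, base)
  expect_identical(out$time, c(0, 2, 4))
  expect_equal(out$rmsd[1:2], c(0, 0), tolerance = 1e-9)
  oracle <- kabsch(jittered, coords(base))$rmsd
  expect_equal(out$rmsd[3], oracle, tolerance = 1e-12)
})

test_that("static trajectories have zero RMSF", {
  base <- toy_beads(cbind(0:4 * 4, 0, 0))
  traj <- make_synthetic_trajectory(base, n_frames = 5, seed = 1)
  prof <- rmsf_profile(traj)
  expect_equal(prof$rmsf, rep(0, 5), tolerance = 1e-12)
  expect_error(rmsf_profile(make_synthetic_trajectory(base, 1, seed = 1)),
               "two frames")
})

test_that("contact maps equal the brute-force all-pairs scan", {
  set.seed(14)
  xyz <- rbind(c(0, 0, 0), c(3.0, 0, 0), c(6.5, 0, 0), c(20, 0, 0),
               c(3.0, 3.0, 0))
  s <- toy_beads(xyz)   # 5 single-atom residues
  cm <- contact_map(s)
  oracle <- brute_contacts(s)
  key <- function(d) paste(d$res_i, d$res_j)
  cm <- cm[order(key(cm)), ]; oracle <- oracle[order(key(oracle)), ]
  expect_identical(key(cm), key(oracle))
  expect_equal(cm$min_dist, oracle$min_dist, tolerance = 1e-12)
  expect_identical(cm$contact, oracle$contact)
})

test_that("the contact rule is strictly below 4.2 A", {
  at_cut <- toy_beads(rbind(c(0, 0, 0), c(4.2, 0, 0)))
  cm <- contact_map(at_cut)
  expect_false(cm$contact)
  inside <- toy_beads(rbind(c(0, 0, 0), c(4.2 - 1e-6, 0, 0)))
  expect_true(contact_map(inside)$contact)
})

test_that("contact frequency averages over ensemble members", {
  base <- toy_beads(rbind(c(0, 0, 0), c(3, 0, 0)))
  frames <- list(coords(base),
                 rbind(c(0, 0, 0), c(10, 0, 0)),
                 coords(base),
                 coords(base))
  traj <- lidtraj(base, frames, times = 0:3)
  cm <- contact_map(traj)
  expect_identical(cm$frequency, 0.75)
  expect_true(cm$contact)
})

test_that("split restricts contact maps to cross-partner pairs", {
  s <- toy_beads(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)),
                 chain = c("R", "R", "L"))
  full <- contact_map(s)
  crossed <- contact_map(s, split = c(1L, 1L, 2L))
  expect_identical(nrow(full), 3L)
  expect_identical(nrow(crossed), 2L)
  expect_true(all(grepl("^L", crossed$res_j) | grepl("^L", crossed$res_i)))
})

test_that("delta %ASA reports burial upon binding", {
  iso <- toy_beads(rbind(c(0, 0, 0)), resid = "ALA")
  bound <- toy_beads(rbind(c(0, 0, 0), c(3.4, 0, 0)), chain = c("A", "B"),
                     resid = "ALA")
  p <- gbsa_params()
  d <- delta_asa(bound, iso, residues = "A:1", params = p)
  expect_identical(nrow(d), 1L)
  expect_lt(d$delta_pct, 0)   # the neighbour buries part of the residue
  expect_equal(d$pct_reference,
               100 * sum(sasa_atoms(iso, p$probe_radius, p$sasa_points)) /
                 129,   # ALA reference area from the shipped table
               tolerance = 1e-6)
  expect_error(delta_asa(bound, iso, residues = "Z:9"), "shared")
})

test_that("side-chain movement measures displaced tips, not backbones", {
  mk <- function(tip_y) {
    atoms <- data.frame(
      name = c("N", "CA", "C", "CB", "N", "CA", "C"),
      element = c("N", "C", "C", "C", "N", "C", "C"),
      resid = c(rep("TOY", 4), rep("GLY", 3)),
      resno = c(1L, 1L, 1L, 1L, 2L, 2L, 2L), chain = "A",
      x = c(0, 1.5, 3.0, 1.5, 4.5, 6.0, 7.5),
      y = c(0, 0, 0, tip_y, 0, 0, 0), z = 0,
      charge = 0, hclass = "nonpolar", stringsAsFactors = FALSE)
    lidstruct(atoms)
  }
  ref <- mk(1.5); moved <- mk(4.5)
  out <- sidechain_movement(moved, ref, threshold = 2)
  per <- out$per_residue
  expect_equal(per$sidechain_rmsd[per$resno == 1], 3, tolerance = 1e-9)
  expect_true(is.na(per$sidechain_rmsd[per$resno == 2]))  # glycine: no tip
  expect_identical(out$movers, "A:1")
})

test_that("mimicry maps pair receptor residues with both partners", {
  rec <- data.frame(name = "OD", element = "O", resid = "TOY", resno = 1L,
                    chain = "R", x = 0, y = 0, z = 0, charge = 0,
                    hclass = "acceptor", stringsAsFactors = FALSE)
  pep <- function(chain, x) data.frame(
    name = c("N", "HN"), element = c("N", "H"), resid = "TOY",
    resno = 1L, chain = chain, x = c(x, x - 1), y = 0, z = 0, charge = 0,
    hclass = c("donor", "nonpolar"), stringsAsFactors = FALSE)
  mk <- function(chain) lidstruct(rbind(rec, pep(chain, 2.9)),
                                  bonds = data.frame(i = 2L, j = 3L,
                                                     k = NA_real_, r0 = 1))
  mm <- mimicry_map(mk("L"), mk("P"), receptor_chain = "R")
  expect_identical(mm$receptor_res, "R:1")
  expect_identical(mm$ref_hbond, "P:1")
  expect_identical(mm$lid_hbond, "L:1")
  expect_identical(mm$ref_contact, "P:1")
  expect_identical(mm$lid_contact, "L:1")
})
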