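# SASA, generalized Born, molecular-mechanics terms, minimization,
# normal-mode entropy, knowledge-based score and MM-GB/SA decomposition

test_that("gbsa defaults pin the documented constants", {
  p <- gbsa_params()
  expect_identical(p$eps_interior, 2)
  expect_identical(p$eps_exterior, 80)
  expect_identical(p$vdw_cutoff, 8)
  expect_identical(p$ele_cutoff, 20)
  expect_identical(p$surface_tension, 0.0072)
  expect_error(gbsa_params(eps_interior = 0.5))
})

test_that("an isolated sphere has SASA 4 pi (r + probe)^2 exactly", {
  for (el in c("C", "O", "N", "S")) {
    s <- toy_atom(element = el)
    radius <- c(C = 1.70, O = 1.52, N = 1.55, S = 1.80)[[el]]
    expect_equal(sasa_atoms(s, probe = 1.4), 4 * pi * (radius + 1.4)^2,
                 tolerance = 1e-12)
  }
})

test_that("far-apart atoms are additive and engulfed atoms are buried", {
  two <- toy_beads(rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_equal(sum(sasa_atoms(two)), 2 * 4 * pi * (1.7 + 1.4)^2,
               tolerance = 1e-12)
  # a tiny sphere centred inside a much larger one is fully occluded
  eng <- toy_beads(rbind(c(0, 0, 0), c(0.1, 0, 0)))
  a <- sasa_atoms(eng, radii = c(1.0, 8.0))
  expect_identical(a[1], 0)
})

test_that("nonpolar solvation is exactly surface tension times SASA", {
  s <- toy_beads(rbind(c(0, 0, 0), c(3.1, 0.5, 0), c(1.2, 2.9, 1)))
  p <- gbsa_params()
  res <- sasa_nonpolar(s, p)
  expect_identical(res$dG_nonpolar, p$surface_tension * res$sasa)
  expect_equal(res$sasa, sum(sasa_atoms(s, p$probe_radius, p$sasa_points)),
               tolerance = 1e-12)
})

test_that("a single ion reproduces the Born equation", {
  for (el in c("O", "N")) for (q in c(1, -0.5)) {
    ion <- toy_atom(element = el, charge = q)
    rho <- c(O = 1.52, N = 1.55)[[el]]
    p <- gbsa_params()
    born <- -0.5 * 332.0637 * (1 / p$eps_interior - 1 / p$eps_exterior) *
      q^2 / rho
    expect_equal(gb_polar_energy(ion, p), born, tolerance = 1e-9)
  }
  expect_identical(gb_polar_energy(toy_atom(charge = 0)), 0)
})

test_that("two distant ions approach the sum of their Born energies", {
  s <- toy_beads(rbind(c(0, 0, 0), c(400, 0, 0)), element = "O",
                 charge = c(1, -1))
  p <- gbsa_params()
  pref <- -0.5 * 332.0637 * (1 / p$eps_interior - 1 / p$eps_exterior)
  self <- 2 * pref * 1 / 1.52
  cross <- 2 * pref * (1 * -1) / 400   # f -> r at large separation
  expect_equal(gb_polar_energy(s, p), self + cross, tolerance = 1e-6)
})

test_that("mm terms match a brute-force loop with explicit cutoff logic", {
  # three single-atom residues at 0, 6 and 19 A: pair (1,2) inside both
  # cutoffs, pairs (2,3) and (1,3) inside the electrostatic cutoff only
  s <- toy_beads(cbind(c(0, 6, 19), 0, 0), charge = c(0.4, -0.3, 0.2))
  s <- assign_vdw_params(s)
  mm <- mm_energy(s)
  a <- s$atoms
  lj <- function(i, j) {
    r <- abs(a$x[i] - a$x[j])
    sig <- (a$sigma[i] + a$sigma[j]) / 2
    eps <- sqrt(a$eps[i] * a$eps[j])
    4 * eps * ((sig / r)^12 - (sig / r)^6)
  }
  cou <- function(i, j) 332.0637 * a$charge[i] * a$charge[j] /
    abs(a$x[i] - a$x[j])
  expect_equal(mm$E_vdw, lj(1, 2), tolerance = 1e-9)
  expect_equal(mm$E_ele, cou(1, 2) + cou(2, 3) + cou(1, 3),
               tolerance = 1e-9)
  expect_identical(mm$E_int, 0)
})

test_that("minimization reaches the gradient cutoff and never goes uphill", {
  s <- make_harmonic_system(250)
  xyz <- coords(s); xyz[2, ] <- xyz[2, ] + c(0.4, 0.2, -0.3)
  s <- set_coords(s, xyz)
  fit <- minimize_structure(s)
  expect_true(fit$converged)
  expect_lte(fit$max_gradient, 0.1)
  expect_lte(fit$energy_final, fit$energy_initial)
  r <- sqrt(sum((coords(fit$structure)[2, ] - coords(fit$structure)[1, ])^2))
  expect_equal(r, 1.5, tolerance = 1e-4)
  # the reported gradient is honest: recompute from scratch
  g <- system_gradient(fit$structure, nonbonded = FALSE)
  expect_equal(max(abs(g)), fit$max_gradient, tolerance = 1e-6)
})

test_that("minimization contracts: zero-step paths and fixed atoms", {
  s <- make_harmonic_system(250)   # already at its minimum
  fit0 <- minimize_structure(s)
  expect_true(fit0$converged)
  expect_identical(fit0$steps, 0L)
  xyz <- coords(s); xyz[2, 1] <- xyz[2, 1] + 0.5
  sp <- set_coords(s, xyz)
  none <- minimize_structure(sp, max_steps = 0L)
  expect_false(none$converged)
  expect_identical(coords(none$structure), coords(sp))
  fx <- minimize_structure(sp, fixed = 1L)
  expect_identical(coords(fx$structure)[1, ], coords(sp)[1, ])
  expect_true(fx$converged)
})

test_that("numerical normal modes reproduce the analytic frequencies", {
  k <- c(180, 420)
  s <- make_harmonic_system(k, masses = c(12.011, 12.011, 1.008, 15.999))
  nm <- normal_mode_entropy(s, t = 300)
  expect_identical(nm$n_removed, 10L)     # 12 coordinates, 2 vibrations
  expect_identical(nm$n_imaginary, 0L)
  expect_equal(sort(nm$frequencies_s1), sort(s$metadata$frequencies_s1),
               tolerance = 1e-4)
})

test_that("entropy terms match the classical closed forms", {
  kB <- 0.0019872041
  hbar <- 1.054571817e-34; kBJ <- 1.380649e-23
  t <- 300
  s <- make_harmonic_system(300)
  nm <- normal_mode_entropy(s, t = t)
  omega <- s$metadata$frequencies_s1
  ts_vib <- t * kB * (1 + log(kBJ * t / (hbar * omega)))
  expect_equal(nm$TS_vib, ts_vib, tolerance = 1e-4)
  # Sackur-Tetrode translation
  M <- 2 * 12.011 * 1.66053906660e-27
  V <- kBJ * t / 101325
  qt <- (2 * pi * M * kBJ * t / (2 * pi * hbar)^2)^1.5 * V
  expect_equal(nm$TS_trans, t * kB * (log(qt) + 2.5), tolerance = 1e-9)
  # linear rigid rotor
  mu <- 12.011 / 2 * 1.66053906660e-27
  I <- mu * (1.5e-10)^2
  qr <- 8 * pi^2 * I * kBJ * t / (2 * pi * hbar)^2
  expect_equal(nm$TS_rot, t * kB * (log(qr) + 1), tolerance = 1e-6)
  expect_equal(nm$TS_total, nm$TS_trans + nm$TS_rot + nm$TS_vib,
               tolerance = 1e-12)
})

test_that("entropy refuses structures away from a minimum", {
  s <- make_harmonic_system(300)
  xyz <- coords(s); xyz[2, 1] <- xyz[2, 1] + 0.5
  expect_error(normal_mode_entropy(set_coords(s, xyz)), "not at a minimum")
})

test_that("the knowledge-based score is an exact weighted sum", {
  tc <- make_toy_complex(seed = 4)
  ks <- kb_score(tc$receptor, tc$lid)
  comp_sum <- ks$dG_hydrophobic + ks$dG_hydrogen_bond + ks$dG_vdW +
    ks$dG_electrostatic + ks$dG_desolvation + ks$dG_entropy
  expect_equal(ks$dG_total, comp_sum, tolerance = 1e-9)
  w <- kb_weights()
  expect_equal(ks$dG_entropy,
               w$trans_rot + w$rotor * sum(tc$lid$torsions$rotatable),
               tolerance = 1e-12)
  expect_error(kb_score(tc$receptor, tc$lid, weights = list()), "weights")
})

test_that("gbsa breakdown identities hold to 1e-9", {
  set.seed(31)
  for (i in 1:25) {
    v <- rnorm(6, sd = 10)
    b <- gbsa_breakdown(v[1], v[2], v[3], v[4], v[5], v[6])
    expect_lt(abs(b$dE_MM_gas - (b$dE_ele + b$dE_vdw + b$dE_int)), 1e-9)
    expect_lt(abs(b$dG_gb_total - (b$dG_gb_nb + b$dG_gb_pol)), 1e-9)
    expect_lt(abs(b$dG_total - (b$dE_MM_gas + b$dG_gb_total + b$TdS_total)),
              1e-9)
  }
})

test_that("atom selections pick chains and residue ranges", {
  s <- toy_beads(cbind(1:6, 0, 0), chain = c("R", "R", "R", "L", "L", "L"))
  expect_identical(select_atoms(s, chain = "L"), 4:6)
  expect_identical(select_atoms(s, chain = "R", resno = 2:3), 2:3)
  expect_identical(select_atoms(s), 1:6)
})

test_that("mmgbsa respects the single-trajectory protocol identities", {
  # complex: two single-atom "molecules" on separate chains, no cross bonds
  base <- toy_beads(rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0)),
                    chain = c("R", "R", "L"),
                    charge = c(0.2, -0.2, 0.3))
  traj <- make_synthetic_trajectory(base, n_frames = 3,
                                    fluctuation_amplitudes = c(0.2, 0.2, 0.2),
                                    seed = 6)
  out <- mmgbsa_binding(traj, receptor_sel = list(chain = "R"),
                        ligand_sel = list(chain = "L"))
  expect_identical(attr(out, "n_frames"), 3L)
  expect_lt(abs(out$dE_MM_gas - (out$dE_ele + out$dE_vdw + out$dE_int)),
            1e-9)
  expect_lt(abs(out$dG_total -
                  (out$dE_MM_gas + out$dG_gb_total + out$TdS_total)), 1e-9)
  # no bonded terms cross the interface, so the strain difference is zero
  expect_equal(out$dE_int, 0, tolerance = 1e-12)
  expect_error(mmgbsa_binding(traj, list(chain = "X"), list(chain = "L")),
               "selection")
})
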