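# pose algebra, Monte Carlo kernels, exact detailed-balance checks, the
# replica-exchange sampler and rotamer optimization

test_that("the identity pose reproduces the reference geometry", {
  tc <- make_toy_complex(seed = 1)
  p <- tc$known_minimum
  s <- realize_pose(p, tc$lid)
  expect_equal(coords(s), coords(tc$lid), tolerance = 1e-9)
  expect_error(realize_pose(pose_state(p$translation, torsions = numeric(0),
                                       anchor_idx = 1L), tc$lid),
               "rotatable")
})

test_that("the anchor atom never moves: displacement is exactly zero", {
  tc <- make_toy_complex(seed = 1)
  anchor <- tc$known_minimum$anchor_idx
  target <- tc$known_minimum$translation
  set.seed(8)
  for (i in 1:20) {
    p <- pose_state(target, rnorm(4), runif(3, -pi, pi), anchor)
    got <- unname(coords(realize_pose(p, tc$lid))[anchor, ])
    expect_identical(max(abs(got - target)), 0)
  }
})

test_that("set_torsion hits the target angle and preserves bond lengths", {
  tc <- make_toy_complex(seed = 1)
  lid <- tc$lid
  row <- which(lid$torsions$rotatable)[1]
  b <- lid$bonds
  len0 <- sqrt(rowSums((coords(lid)[b$i, ] - coords(lid)[b$j, ])^2))
  for (target in c(-2.5, -0.7, 0.4, 1.9, pi)) {
    s2 <- set_torsion(lid, row, target)
    got <- measure_dihedral(s2, unlist(lid$torsions[row,
                                                    c("i", "j", "k", "l")]))
    expect_equal(sin(got), sin(target), tolerance = 1e-8)
    expect_equal(cos(got), cos(target), tolerance = 1e-8)
    len <- sqrt(rowSums((coords(s2)[b$i, ] - coords(s2)[b$j, ])^2))
    expect_equal(len, len0, tolerance = 1e-9)
  }
})

test_that("temperature ladders are spaced as requested", {
  arit <- make_temperature_ladder(300, 5300, 1000)
  expect_length(arit$levels, 1000L)
  expect_equal(range(arit$levels), c(300, 5300))
  expect_equal(diff(arit$levels), rep(5000 / 999, 999), tolerance = 1e-9)
  geo <- make_temperature_ladder(300, 4800, 5, spacing = "geometric")
  expect_equal(geo$levels[-1] / geo$levels[-5], rep(2, 4), tolerance = 1e-9)
  expect_error(make_temperature_ladder(500, 300, 4), "exceed")
  expect_error(make_temperature_ladder(300, 500, 1), "t_min == t_max")
  expect_identical(make_temperature_ladder(300, 300, 1)$levels, 300)
  expect_error(make_temperature_ladder(-1, 300, 2), "positive")
})

test_that("search box matches a brute-force coordinate scan", {
  set.seed(3)
  xyz <- matrix(runif(60, -12, 17), ncol = 3)
  box <- define_search_box(xyz, cushion = 10)
  expect_equal(box$lo, apply(xyz, 2, min) - 10)
  expect_equal(box$hi, apply(xyz, 2, max) + 10)
  vol <- prod(box$hi - box$lo)
  vol_brute <- prod(apply(xyz, 2, max) - apply(xyz, 2, min) + 20)
  expect_equal(vol, vol_brute, tolerance = 1e-12)
  expect_error(define_search_box(xyz[0, , drop = FALSE]), "empty")
})

test_that("proposals are symmetric: torsion increments balance in sign", {
  tc <- make_toy_complex(seed = 1)
  lid <- prepare_topology(tc$lid)
  p0 <- tc$known_minimum
  set.seed(10)
  n <- 4000
  deltas <- numeric(0)
  for (i in seq_len(n)) {
    pr <- propose_move(p0, lid, box = NULL)
    d <- pr$torsions - p0$torsions
    d <- d[d != 0]
    if (length(d)) deltas <- c(deltas, atan2(sin(d), cos(d)))
  }
  npos <- sum(deltas > 0)
  m <- length(deltas)
  expect_gt(m, 1000)
  # binomial 3-sigma band around one half
  expect_lt(abs(npos - m / 2), 3 * sqrt(m / 4))
})

test_that("metropolis acceptance follows min(1, exp(-dE/kT))", {
  expect_true(metropolis_accept(-5, 300))
  expect_true(metropolis_accept(0, 300))
  expect_error(metropolis_accept(1, 0), "positive")
  kB <- 0.0019872041
  set.seed(6)
  n <- 20000
  acc <- sum(replicate(n, metropolis_accept(kB * 300 * log(2), 300)))
  expect_lt(abs(acc - n / 2), 3 * sqrt(n / 4))
})

test_that("swap acceptance follows min(1, exp(dbeta * dE))", {
  expect_true(swap_attempt(-3, -3, 300, 600))     # equal energies
  kB <- 0.0019872041
  # choose energies so that dbeta * dE = -ln 2
  dbeta <- 1 / (kB * 300) - 1 / (kB * 600)
  de <- -log(2) / dbeta
  set.seed(13)
  n <- 20000
  acc <- sum(replicate(n, swap_attempt(de, 0, 300, 600)))
  expect_lt(abs(acc - n / 2), 3 * sqrt(n / 4))
})

test_that("exact Metropolis kernel leaves the Boltzmann distribution fixed", {
  e <- c(0, 0.4, 1.1, 2.3)
  for (t in c(300, 1200)) {
    K <- metropolis_kernel_matrix(e, t)
    expect_equal(rowSums(K), rep(1, 4), tolerance = 1e-12)
    p <- boltzmann_weights(e, t)
    expect_lt(max(abs(p %*% K - p)), 1e-12)
  }
})

test_that("exact two-replica kernel is stationary at the product Boltzmann", {
  e <- c(0, 0.5, 1.3)
  t1 <- 300; t2 <- 900
  K <- remc_kernel_matrix(e, t1, t2)
  expect_equal(rowSums(K), rep(1, 9), tolerance = 1e-12)
  pi1 <- boltzmann_weights(e, t1)
  pi2 <- boltzmann_weights(e, t2)
  # state (a, b) has index (a-1)*n + b: row-major flattening of the product
  pjoint <- as.vector(t(outer(pi1, pi2)))
  expect_lt(max(abs(pjoint %*% K - pjoint)), 1e-10)
})

test_that("the sampler is reproducible and validates its inputs", {
  tc <- make_toy_complex(seed = 1)
  run <- function() run_remc_docking(
    tc$receptor, tc$lid, ladder = make_temperature_ladder(300, 5300, 4),
    cycles = 3, moves_per_cycle = 15, swaps_per_cycle = 10, seed = 21)
  a <- run(); b <- run()
  expect_identical(a$cold_energies, b$cold_energies)
  expect_identical(a$best_energy, b$best_energy)
  expect_identical(coords(realize_pose(a$best_pose, tc$lid)),
                   coords(realize_pose(b$best_pose, tc$lid)))
  expect_error(run_remc_docking(tc$receptor, tc$lid, cycles = 0), "cycles")
})

test_that("cached energies equal fresh re-evaluation and anchors hold", {
  tc <- make_toy_complex(seed = 1)
  fit <- run_remc_docking(
    tc$receptor, tc$lid, ladder = make_temperature_ladder(300, 5300, 4),
    cycles = 4, moves_per_cycle = 20, swaps_per_cycle = 10, seed = 2)
  lid <- prepare_topology(assign_vdw_params(tc$lid))
  rec <- assign_vdw_params(tc$receptor)
  fresh <- vapply(fit$cold_poses, function(p)
    total_docking_energy(realize_pose(p, lid), rec)$total, numeric(1))
  expect_equal(fit$cold_energies, fresh, tolerance = 1e-9)
  anchor <- tc$known_minimum$anchor_idx
  target <- tc$known_minimum$translation
  disp <- vapply(fit$cold_poses, function(p)
    max(abs(unname(coords(realize_pose(p, lid))[anchor, ]) - target)),
    numeric(1))
  expect_identical(max(disp), 0)
})

test_that("hotter replicas accept at least as often as the coldest", {
  tc <- make_toy_complex(seed = 1)
  fit <- run_remc_docking(
    tc$receptor, tc$lid, ladder = make_temperature_ladder(300, 5300, 4),
    cycles = 4, moves_per_cycle = 40, swaps_per_cycle = 10, seed = 5)
  n <- length(fit$acceptance)
  expect_gte(fit$acceptance[n], fit$acceptance[1])
})

test_that("rotamer optimization handles the trivial contracts", {
  s <- toy_rotamer_system()
  lib <- list(TOY = matrix(c(-60, 60, 180), ncol = 1,
                           dimnames = list(NULL, "chi1")))
  none <- self_consistent_rotamer_optimization(s, integer(0), lib)
  expect_identical(coords(none$structure), coords(s))
  expect_identical(none$passes, 0L)
  one <- self_consistent_rotamer_optimization(s, 1L, lib)
  expect_lte(one$energy_final, one$energy_initial)
  expect_true(one$converged)
  expect_error(self_consistent_rotamer_optimization(s, 1L, list()),
               "no rotamers")
})

test_that("coupled residues reach the exhaustive-enumeration optimum", {
  s <- toy_rotamer_system()
  chis <- c(-60, 60, 180)
  lib <- list(TOY = matrix(chis, ncol = 1, dimnames = list(NULL, "chi1")))
  fit <- self_consistent_rotamer_optimization(s, c(1L, 2L), lib)
  # brute force over the 9-combination product space
  best <- Inf
  for (c1 in chis) for (c2 in chis) {
    st <- set_torsion(s, 1L, c1 * pi / 180)
    st <- set_torsion(st, 2L, c2 * pi / 180)
    best <- min(best, system_energy(st))
  }
  expect_equal(fit$energy_final, best, tolerance = 1e-9)
})

test_that("the shipped rotamer library loads with chi columns", {
  lib <- load_rotamer_library()
  expect_true(length(lib) > 0)
  expect_true("TOY" %in% names(lib))
  expect_true(all(vapply(lib, is.matrix, logical(1))))
})
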