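# Binding free-energy machinery: structure minimization, a six-term
# knowledge-based score, and MM-GB/SA decomposition (molecular-mechanics
# terms with residue-based cutoffs, HCT-style generalized Born polar
# solvation, surface-area nonpolar solvation and normal-mode entropy) under
# the single-trajectory protocol.

# Bondi-style intrinsic radii by element (A)
.element_radius <- function(element) {
  r <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  out <- r[toupper(element)]
  out[is.na(out)] <- 1.70
  unname(out)
}

.atom_masses <- function(s) {
  if (!is.null(s$atoms$mass)) s$atoms$mass else .element_mass(s$atoms$element)
}

#' MM-GB/SA parameters
#'
#' Interior/exterior dielectrics (2 and 80), residue-based nonbonded
#' cutoffs (8 A van der Waals, 20 A electrostatic), the surface tension
#' coefficient 0.0072 kcal/mol/A^2, the solvent probe radius and the
#' temperature for entropy terms.
#'
#' @param eps_interior,eps_exterior dielectric constants (>= 1)
#' @param vdw_cutoff,ele_cutoff residue-based cutoffs (A): a residue pair
#'   contributes iff its minimal inter-residue atom distance is within the
#'   cutoff
#' @param surface_tension kcal/mol/A^2
#' @param probe_radius solvent probe (A)
#' @param temperature K
#' @param sasa_points quadrature points per atom sphere
#' @return list of class `gbsa_params`
#' @export
gbsa_params <- function(eps_interior = 2, eps_exterior = 80, vdw_cutoff = 8,
                        ele_cutoff = 20, surface_tension = 0.0072,
                        probe_radius = 1.4, temperature = 300,
                        sasa_points = 480) {
  stopifnot(eps_interior >= 1, eps_exterior >= 1, vdw_cutoff > 0,
            ele_cutoff > 0)
  structure(as.list(environment()), class = "gbsa_params")
}

# ---- SASA ------------------------------------------------------------------

# deterministic golden-spiral quadrature points on the unit sphere
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a deterministic golden-spiral quadrature on each
#' atom sphere of radius r_atom + probe; a point is accessible when it lies
#' outside every neighbouring sphere.
#'
#' @param s a `lidstruct`
#' @param probe probe radius (A)
#' @param n_points quadrature points per atom
#' @param radii per-atom radii (default: element-based)
#' @return numeric vector of per-atom SASA (A^2)
#' @export
sasa_atoms <- function(s, probe = 1.4, n_points = 480, radii = NULL) {
  xyz <- coords(s)
  n <- nrow(xyz)
  if (is.null(radii)) radii <- .element_radius(s$atoms$element)
  pts <- .sphere_points(n_points)
  re <- radii + probe
  out <- numeric(n)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * tcrossprod(xyz)
  for (i in seq_len(n)) {
    nbr <- which(d2[i, ] < (re[i] + re)^2 & seq_len(n) != i)
    p <- sweep(pts * re[i], 2L, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nbr) {
      dj2 <- rowSums(sweep(p, 2L, xyz[j, ])^2)
      acc <- acc & dj2 >= re[j]^2
      if (!any(acc)) break
    }
    out[i] <- 4 * pi * re[i]^2 * mean(acc)
  }
  out
}

#' Nonpolar solvation from solvent-accessible surface area
#'
#' dG_nonpolar = surface_tension x SASA, exactly.
#'
#' @param s a `lidstruct`
#' @param params a [gbsa_params()] list
#' @return list with `sasa` (A^2) and `dG_nonpolar` (kcal/mol)
#' @export
sasa_nonpolar <- function(s, params = gbsa_params()) {
  a <- sum(sasa_atoms(s, params$probe_radius, params$sasa_points))
  list(sasa = a, dG_nonpolar = params$surface_tension * a)
}

# ---- generalized Born ------------------------------------------------------

# HCT pairwise-descreening effective Born radii; rho are intrinsic radii,
# neighbours descreen with scaled radii S * rho_j
.born_radii <- function(xyz, rho, scale = 0.8) {
  n <- nrow(xyz)
  inv <- 1 / rho
  if (n >= 2L) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    sj <- scale * rho[j]
    if (rho[i] >= r + sj) next
    L <- max(abs(r - sj), rho[i]); U <- r + sj
    term <- (1 / L - 1 / U) + (r / 4) * (1 / U^2 - 1 / L^2) +
      (1 / (2 * r)) * log(L / U) + (sj^2 / (4 * r)) * (1 / L^2 - 1 / U^2)
    if (rho[i] < sj - r) term <- term + 2 * (1 / rho[i] - 1 / L)
    inv[i] <- inv[i] - 0.5 * term
  }
  1 / pmax(inv, 1e-6)
}

#' Generalized-Born polar solvation energy
#'
#' Pairwise generalized-Born sum with HCT-style effective radii:
#' \deqn{\Delta G_{pol} = -\tfrac{1}{2}\, 332.0637
#'   \left(\frac{1}{\epsilon_{in}} - \frac{1}{\epsilon_{out}}\right)
#'   \sum_{ij} \frac{q_i q_j}{f_{ij}}}
#' with \eqn{f_{ij} = \sqrt{r_{ij}^2 + R_i R_j e^{-r_{ij}^2 / 4 R_i R_j}}}.
#' A single ion reduces exactly to the Born equation with its intrinsic
#' radius.
#'
#' @param s a `lidstruct` with partial charges
#' @param params a [gbsa_params()] list
#' @param radii optional intrinsic radii (default element-based)
#' @return polar solvation energy (kcal/mol)
#' @export
gb_polar_energy <- function(s, params = gbsa_params(), radii = NULL) {
  q <- s$atoms$charge
  if (all(q == 0)) return(0)
  xyz <- coords(s)
  if (is.null(radii)) radii <- .element_radius(s$atoms$element)
  if (any(!is.finite(radii) | radii <= 0)) stop("missing or invalid radius")
  R <- .born_radii(xyz, radii)
  n <- nrow(xyz)
  pref <- -0.5 * .COULOMB * (1 / params$eps_interior - 1 / params$eps_exterior)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * tcrossprod(xyz)
  d2 <- pmax(d2, 0)
  RR <- outer(R, R)
  f <- sqrt(d2 + RR * exp(-d2 / (4 * RR)))
  pref * sum(outer(q, q) / f)
}

# ---- molecular-mechanics terms with residue-based cutoffs ------------------

#' Molecular-mechanics energy terms of a structure
#'
#' Gas-phase terms of the MM-GB/SA decomposition: electrostatic and van der
#' Waals interactions between residues (a residue pair contributes iff the
#' minimal inter-residue atom distance is within the 20 A / 8 A residue
#' based cutoff respectively; standard unsoftened 12-6 and Coulomb forms at
#' unit dielectric), plus the internal strain energy E_int (bond + angle +
#' torsion terms).
#'
#' @param s a `lidstruct`
#' @param params a [gbsa_params()] list
#' @param eparams energy parameters supplying the van der Waals classes
#' @return list with `E_ele`, `E_vdw`, `E_int` (kcal/mol)
#' @export
mm_energy <- function(s, params = gbsa_params(),
                      eparams = default_energy_params()) {
  s <- assign_vdw_params(s, eparams)
  a <- s$atoms
  xyz <- coords(s)
  res <- paste(a$chain, a$resno)
  rlev <- unique(res)
  nr <- length(rlev)
  e_int <- system_energy(s, eparams, nonbonded = FALSE)
  e_vdw <- 0; e_ele <- 0
  if (nr >= 2L) {
    rows <- lapply(rlev, function(r) which(res == r))
    for (p in seq_len(nr - 1L)) for (q in (p + 1L):nr) {
      ip <- rows[[p]]; iq <- rows[[q]]
      d2 <- outer(rowSums(xyz[ip, , drop = FALSE]^2),
                  rowSums(xyz[iq, , drop = FALSE]^2), `+`) -
        2 * tcrossprod(xyz[ip, , drop = FALSE], xyz[iq, , drop = FALSE])
      dmin <- sqrt(max(0, min(d2)))
      if (dmin > params$ele_cutoff) next
      r <- sqrt(pmax(d2, 0))
      if (dmin <= params$vdw_cutoff) {
        sig <- outer(a$sigma[ip], a$sigma[iq], function(x, y) (x + y) / 2)
        eps <- sqrt(outer(a$eps[ip], a$eps[iq]))
        sr6 <- (sig / r)^6
        e_vdw <- e_vdw + sum(4 * eps * (sr6^2 - sr6))
      }
      e_ele <- e_ele + sum(.COULOMB * outer(a$charge[ip], a$charge[iq]) / r)
    }
  }
  list(E_ele = e_ele, E_vdw = e_vdw, E_int = e_int)
}

# ---- minimization ----------------------------------------------------------

#' Minimize a structure under its own energy model
#'
#' Gradient-based minimization (L-BFGS-B over the free Cartesian
#' coordinates) of [system_energy()] until the maximum component of the
#' energy gradient falls below `gradient_cutoff`. Fixed atoms are held in
#' place. If the cutoff cannot be reached within `max_steps` objective
#' iterations, the best structure found so far is returned with
#' `converged = FALSE`.
#'
#' @param s a `lidstruct`
#' @param params energy parameters
#' @param gradient_cutoff termination criterion, kcal/mol/A (default 0.1)
#' @param max_steps iteration budget
#' @param fixed integer atom indices held fixed
#' @param nonbonded include intramolecular nonbonded terms
#' @return list with `structure`, `converged`, `steps`, `max_gradient`,
#'   `energy_initial`, `energy_final`
#' @export
minimize_structure <- function(s, params = default_energy_params(),
                               gradient_cutoff = 0.1, max_steps = 500L,
                               fixed = NULL, nonbonded = TRUE) {
  n <- natoms(s)
  free <- setdiff(seq_len(n), fixed)
  fidx <- sort(unlist(lapply(free, function(a) (a - 1L) * 3L + 1:3)))
  x_full <- as.vector(t(coords(s)))
  build <- function(xf) {
    x <- x_full; x[fidx] <- xf
    set_coords(s, matrix(x, ncol = 3L, byrow = TRUE))
  }
  fn <- function(xf) system_energy(build(xf), params, nonbonded)
  gr <- function(xf) system_gradient(build(xf), params,
                                     nonbonded = nonbonded)[fidx]
  e0 <- fn(x_full[fidx])
  g0 <- gr(x_full[fidx])
  if (max(abs(g0)) <= gradient_cutoff)
    return(list(structure = s, converged = TRUE, steps = 0L,
                max_gradient = max(abs(g0)), energy_initial = e0,
                energy_final = e0))
  if (max_steps <= 0L)
    return(list(structure = s, converged = FALSE, steps = 0L,
                max_gradient = max(abs(g0)), energy_initial = e0,
                energy_final = e0))
  opt <- optim(x_full[fidx], fn, gr, method = "L-BFGS-B",
               control = list(maxit = max_steps, factr = 10,
                              pgtol = gradient_cutoff / 100))
  out <- build(opt$par)
  g <- system_gradient(out, params, nonbonded = nonbonded)[fidx]
  ef <- opt$value
  if (ef > e0) { out <- s; ef <- e0; g <- g0 }  # never report uphill
  list(structure = out, converged = max(abs(g)) <= gradient_cutoff,
       steps = opt$counts[["function"]], max_gradient = max(abs(g)),
       energy_initial = e0, energy_final = ef)
}

# ---- normal-mode entropy ---------------------------------------------------

# 1 kcal/mol/A^2/amu in s^-2
.FREQ_CONV <- 4.184e26
.HBAR <- 1.054571817e-34   # J s
.KB_J <- 1.380649e-23      # J/K

#' Numerical Hessian of the system energy
#' @param s a `lidstruct`
#' @param params energy parameters
#' @param h finite-difference step (A)
#' @param nonbonded passed to [system_energy()]
#' @return symmetric 3n x 3n matrix (kcal/mol/A^2)
#' @export
system_hessian <- function(s, params = default_energy_params(), h = 1e-4,
                           nonbonded = TRUE) {
  x0 <- as.vector(t(coords(s)))
  m <- length(x0)
  gx <- function(x) system_gradient(set_coords(s, matrix(x, ncol = 3L,
                                                         byrow = TRUE)),
                                    params, nonbonded = nonbonded)
  H <- matrix(0, m, m)
  for (k in seq_len(m)) {
    xp <- x0; xp[k] <- xp[k] + h
    xm <- x0; xm[k] <- xm[k] - h
    H[, k] <- (gx(xp) - gx(xm)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Normal-mode entropy of a minimized structure
#'
#' Diagonalizes the mass-weighted Hessian; near-zero rigid-body modes (six,
#' or five for linear molecules) are removed and each vibrational mode
#' contributes the classical harmonic-oscillator entropy
#' S = kB (1 + ln(kB T / (hbar omega))). Translational entropy follows
#' Sackur-Tetrode at 1 atm and rotational entropy the classical rigid-rotor
#' formula (symmetry number 1). All terms are returned as T*S in kcal/mol.
#'
#' @param s a minimized `lidstruct` (max gradient component must be within
#'   `gradient_cutoff`, else a precondition error)
#' @param t temperature (K)
#' @param params energy parameters
#' @param gradient_cutoff minimization criterion used for the check
#' @param nonbonded passed through to the energy model (harmonic test
#'   systems disable it via their metadata)
#' @return list with `TS_trans`, `TS_rot`, `TS_vib`, `TS_total` (kcal/mol),
#'   `frequencies_s1`, `n_removed`, `n_imaginary`
#' @export
normal_mode_entropy <- function(s, t = 300, params = default_energy_params(),
                                gradient_cutoff = 0.1, nonbonded = NULL) {
  if (is.null(nonbonded)) nonbonded <- isTRUE(s$metadata$nonbonded %||% TRUE)
  g <- system_gradient(s, params, nonbonded = nonbonded)
  if (max(abs(g)) > gradient_cutoff)
    stop("structure is not at a minimum (max gradient ",
         format(max(abs(g)), digits = 3), " kcal/mol/A); minimize first")
  H <- system_hessian(s, params, nonbonded = nonbonded)
  mass <- .atom_masses(s)
  mw <- rep(1 / sqrt(mass), each = 3L)
  Hm <- H * outer(mw, mw)
  ev <- eigen(Hm, symmetric = TRUE, only.values = TRUE)$values
  tol <- max(abs(ev)) * 1e-8 + 1e-12
  zero <- abs(ev) <= tol
  neg <- ev < -tol
  if (any(neg))
    warning(sum(neg), " imaginary frequencies beyond the rigid-body modes")
  vib <- ev[!zero & !neg]
  omega <- sqrt(vib * .FREQ_CONV)
  s_vib_permode <- .kB * (1 + log(.KB_J * t / (.HBAR * omega)))
  TS_vib <- t * sum(s_vib_permode)
  # translation: Sackur-Tetrode at P = 1 atm
  M <- sum(mass) * 1.66053906660e-27
  V <- .KB_J * t / 101325
  q_t <- (2 * pi * M * .KB_J * t / (2 * pi * .HBAR)^2)^1.5 * V
  TS_trans <- t * .kB * (log(q_t) + 2.5)
  # rotation: principal moments (amu A^2 -> kg m^2)
  xyz <- coords(s)
  com <- colSums(xyz * mass) / sum(mass)
  X <- sweep(xyz, 2L, com)
  Imat <- matrix(0, 3, 3)
  for (i in seq_len(nrow(X))) {
    r2 <- sum(X[i, ]^2)
    Imat <- Imat + mass[i] * (diag(3) * r2 - tcrossprod(X[i, ]))
  }
  Iprin <- sort(eigen(Imat, symmetric = TRUE, only.values = TRUE)$values) *
    1.66053906660e-27 * 1e-20
  h2 <- (2 * pi * .HBAR)^2
  if (Iprin[1] < 1e-3 * Iprin[3] || nrow(X) == 2L) {
    q_r <- 8 * pi^2 * Iprin[3] * .KB_J * t / h2
    TS_rot <- t * .kB * (log(q_r) + 1)
  } else {
    q_r <- sqrt(pi * prod(Iprin)) * (8 * pi^2 * .KB_J * t / h2)^1.5
    TS_rot <- t * .kB * (log(q_r) + 1.5)
  }
  list(TS_trans = TS_trans, TS_rot = TS_rot, TS_vib = TS_vib,
       TS_total = TS_trans + TS_rot + TS_vib, frequencies_s1 = omega,
       n_removed = sum(zero), n_imaginary = sum(neg))
}

# ---- knowledge-based score -------------------------------------------------

#' Default weights of the knowledge-based score
#'
#' The six-term score is a linear combination of hydrophobic (buried
#' nonpolar surface), interface hydrogen-bond, van der Waals,
#' electrostatic, polar-desolvation and rigid-body/rotor entropy terms.
#' These package defaults are documented, editable coefficients; they are
#' not a reproduction of any externally fitted weight set.
#'
#' @return named list of weights
#' @export
kb_weights <- function() {
  list(hydrophobic = -0.025,  # kcal/mol per buried nonpolar A^2
       hydrogen_bond = -0.5,  # kcal/mol per interface hydrogen bond
       vdw = 0.1,             # scaling of the intermolecular LJ energy
       electrostatic = 0.1,   # scaling of the intermolecular Coulomb energy
       desolvation = 0.02,    # kcal/mol per buried polar A^2
       trans_rot = 2.0,       # rigid-body entropy penalty, kcal/mol
       rotor = 0.3)           # kcal/mol per frozen rotatable torsion
}

#' Knowledge-based binding score
#'
#' Six-component decomposition of a receptor-ligand pose: hydrophobic
#' burial, interface hydrogen bonds, intermolecular van der Waals and
#' electrostatic energies, polar desolvation and the entropy penalty for
#' the loss of translational/rotational freedom plus frozen rotors. The
#' total is the exact weighted sum; sums hold to 1e-9 on every evaluation.
#'
#' @param receptor,ligand classified `lidstruct` parts of the complex pose
#' @param weights weight list (see [kb_weights()])
#' @param params energy parameters
#' @param gparams [gbsa_params()] for the surface-area terms
#' @return list of class `kb_breakdown` with `dG_hydrophobic`,
#'   `dG_hydrogen_bond`, `dG_vdW`, `dG_electrostatic`, `dG_desolvation`,
#'   `dG_entropy`, `dG_total` (kcal/mol)
#' @export
kb_score <- function(receptor, ligand, weights = kb_weights(),
                     params = default_energy_params(),
                     gparams = gbsa_params()) {
  if (is.null(weights) ||
      !all(c("hydrophobic", "hydrogen_bond", "vdw", "electrostatic",
             "desolvation", "trans_rot", "rotor") %in% names(weights)))
    stop("missing knowledge-based score weights")
  receptor <- assign_vdw_params(receptor, params)
  ligand <- assign_vdw_params(ligand, params)
  complx <- .merge_structures(receptor, ligand)
  sr <- sasa_atoms(receptor, gparams$probe_radius, gparams$sasa_points)
  sl <- sasa_atoms(ligand, gparams$probe_radius, gparams$sasa_points)
  sc <- sasa_atoms(complx, gparams$probe_radius, gparams$sasa_points)
  buried <- c(sr, sl) - sc
  np <- complx$atoms$hclass == "nonpolar"
  buried_np <- sum(buried[np]); buried_pol <- sum(buried[!np])
  nhb <- nrow(.hbond_pairs_single(complx,
                                  split = c(rep(1L, natoms(receptor)),
                                            rep(2L, natoms(ligand)))))
  hard <- default_energy_params(dielectric = params$dielectric, alpha = 0,
                                softcore_enabled = FALSE,
                                cutoff = params$cutoff)
  inter <- intermolecular_energy(ligand, receptor, hard)
  n_rotors <- sum(ligand$torsions$rotatable %||% 0)
  comp <- c(dG_hydrophobic = weights$hydrophobic * buried_np,
            dG_hydrogen_bond = weights$hydrogen_bond * nhb,
            dG_vdW = weights$vdw * inter$vdw_inter,
            dG_electrostatic = weights$electrostatic * inter$electrostatic,
            dG_desolvation = weights$desolvation * buried_pol,
            dG_entropy = weights$trans_rot + weights$rotor * n_rotors)
  structure(as.list(c(comp, dG_total = sum(comp))), class = "kb_breakdown")
}

#' @export
print.kb_breakdown <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-18s %10.4f kcal/mol\n", nm, x[[nm]]))
  invisible(x)
}

.merge_structures <- function(a, b) {
  at <- rbind(a$atoms[, intersect(names(a$atoms), names(b$atoms))],
              b$atoms[, intersect(names(a$atoms), names(b$atoms))])
  shift <- natoms(a)
  sh <- function(tab, cols) {
    if (is.null(tab)) return(NULL)
    for (cc in cols) tab[[cc]] <- tab[[cc]] + shift
    tab
  }
  comb <- function(x, y) if (is.null(x)) y else if (is.null(y)) x else {
    common <- intersect(names(x), names(y))
    rbind(x[, common, drop = FALSE], y[, common, drop = FALSE])
  }
  lidstruct(at, bonds = comb(a$bonds, sh(b$bonds, c("i", "j"))),
            angles = comb(a$angles, sh(b$angles, c("i", "j", "k"))),
            torsions = comb(a$torsions, sh(b$torsions,
                                           c("i", "j", "k", "l"))),
            metadata = a$metadata)
}

# ---- MM-GB/SA decomposition ------------------------------------------------

#' MM-GB/SA breakdown container
#'
#' Component identities hold exactly: `dE_MM_gas = dE_ele + dE_vdw +
#' dE_int`, `dG_gb_total = dG_gb_nb + dG_gb_pol` and `dG_total = dE_MM_gas
#' + dG_gb_total + TdS_total`. `TdS_total` is reported as a positive
#' penalty added to the binding free energy.
#'
#' @param dE_ele,dE_vdw,dE_int,dG_gb_nb,dG_gb_pol,TdS_total component
#'   energies (kcal/mol)
#' @return list of class `gbsa_breakdown`
#' @export
gbsa_breakdown <- function(dE_ele = 0, dE_vdw = 0, dE_int = 0, dG_gb_nb = 0,
                           dG_gb_pol = 0, TdS_total = 0) {
  out <- list(dE_ele = dE_ele, dE_vdw = dE_vdw, dE_int = dE_int,
              dE_MM_gas = dE_ele + dE_vdw + dE_int,
              dG_gb_nb = dG_gb_nb, dG_gb_pol = dG_gb_pol,
              dG_gb_total = dG_gb_nb + dG_gb_pol,
              TdS_total = TdS_total)
  out$dG_total <- out$dE_MM_gas + out$dG_gb_total + out$TdS_total
  structure(out, class = "gbsa_breakdown")
}

#' @export
print.gbsa_breakdown <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-12s %10.4f kcal/mol\n", nm, x[[nm]]))
  invisible(x)
}

#' Select atom indices by chain and/or residue range
#' @param s a `lidstruct`
#' @param chain optional chain id
#' @param resno optional integer vector of residue numbers
#' @return integer atom indices
#' @export
select_atoms <- function(s, chain = NULL, resno = NULL) {
  keep <- rep(TRUE, natoms(s))
  if (!is.null(chain)) keep <- keep & s$atoms$chain %in% chain
  if (!is.null(resno)) keep <- keep & s$atoms$resno %in% resno
  which(keep)
}

.subset_atoms <- function(s, idx) {
  remap <- rep(NA_integer_, natoms(s))
  remap[idx] <- seq_along(idx)
  restrict <- function(tab, cols) {
    if (is.null(tab) || nrow(tab) == 0L) return(NULL)
    keep <- apply(tab[, cols, drop = FALSE], 1L,
                  function(r) all(!is.na(remap[unlist(r)])))
    out <- tab[keep, , drop = FALSE]
    if (nrow(out) == 0L) return(NULL)
    for (cc in cols) out[[cc]] <- remap[out[[cc]]]
    out
  }
  lidstruct(s$atoms[idx, , drop = FALSE],
            bonds = restrict(s$bonds, c("i", "j")),
            angles = restrict(s$angles, c("i", "j", "k")),
            torsions = restrict(s$torsions, c("i", "j", "k", "l")),
            metadata = s$metadata)
}

#' MM-GB/SA binding free energy over a trajectory (single-trajectory
#' protocol)
#'
#' Every frame of the complex trajectory is split into receptor and ligand
#' by the given selections; each part is (optionally) re-minimized, and the
#' binding differences Delta X = X(complex) - X(receptor) - X(ligand) of
#' the molecular-mechanics, generalized-Born and surface-area terms are
#' averaged over frames. With `entropy_stride > 0` the solute entropy
#' difference is estimated by normal-mode analysis on every
#' `entropy_stride`-th frame (each part minimized to the gradient cutoff
#' first) and reported as a positive `TdS_total` penalty.
#'
#' @param traj a `lidtraj` of the complex
#' @param receptor_sel,ligand_sel selection lists passed to
#'   [select_atoms()], e.g. `list(chain = "R")`
#' @param params a [gbsa_params()] list
#' @param eparams energy parameters
#' @param minimize_parts re-minimize the separated parts each frame
#' @param min_steps minimization budget per part (default 100000, shared
#'   with the pre-entropy minimization)
#' @param entropy_stride 0 disables the entropy term; k computes it on
#'   frames 1, 1+k, ...
#' @return a [gbsa_breakdown()] with attribute `n_frames`
#' @export
mmgbsa_binding <- function(traj, receptor_sel, ligand_sel,
                           params = gbsa_params(),
                           eparams = default_energy_params(),
                           minimize_parts = FALSE, min_steps = 100000L,
                           entropy_stride = 0L) {
  n <- nframes(traj)
  ir <- do.call(select_atoms, c(list(traj$base), receptor_sel))
  il <- do.call(select_atoms, c(list(traj$base), ligand_sel))
  if (length(ir) == 0L || length(il) == 0L)
    stop("trajectory frames are missing the receptor or ligand selection")
  terms <- function(st) {
    mm <- mm_energy(st, params, eparams)
    c(E_ele = mm$E_ele, E_vdw = mm$E_vdw, E_int = mm$E_int,
      G_pol = gb_polar_energy(st, params),
      G_np = sasa_nonpolar(st, params)$dG_nonpolar)
  }
  deltas <- matrix(0, n, 5L,
                   dimnames = list(NULL, c("E_ele", "E_vdw", "E_int",
                                           "G_pol", "G_np")))
  for (f in seq_len(n)) {
    st <- traj_frame(traj, f)
    parts <- list(complex = st, receptor = .subset_atoms(st, ir),
                  ligand = .subset_atoms(st, il))
    if (minimize_parts)
      parts[c("receptor", "ligand")] <- lapply(
        parts[c("receptor", "ligand")],
        function(p) minimize_structure(p, eparams,
                                       max_steps = min_steps)$structure)
    tv <- lapply(parts, terms)
    deltas[f, ] <- tv$complex - tv$receptor - tv$ligand
  }
  avg <- colMeans(deltas)
  TdS <- 0
  if (entropy_stride > 0L) {
    idx <- seq(1L, n, by = entropy_stride)
    dts <- vapply(idx, function(f) {
      st <- traj_frame(traj, f)
      parts <- list(st, .subset_atoms(st, ir), .subset_atoms(st, il))
      ts <- vapply(parts, function(p) {
        pm <- minimize_structure(p, eparams, max_steps = min_steps)
        normal_mode_entropy(pm$structure, params$temperature,
                            eparams)$TS_total
      }, numeric(1))
      ts[1L] - ts[2L] - ts[3L]
    }, numeric(1))
    TdS <- -mean(dts)
  }
  out <- gbsa_breakdown(dE_ele = avg[["E_ele"]], dE_vdw = avg[["E_vdw"]],
                        dE_int = avg[["E_int"]], dG_gb_nb = avg[["G_np"]],
                        dG_gb_pol = avg[["G_pol"]], TdS_total = TdS)
  attr(out, "n_frames") <- n
  out
}
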