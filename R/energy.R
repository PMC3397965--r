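# Composite docking energy model: DREIDING-style intramolecular terms
# (cosine torsions + excluded-pair nonbonded) for the flexible lid,
# AMBER-style intermolecular Lennard-Jones and Coulomb terms with a
# pairwise Gaussian-envelope desolvation model, and a Beutler-style
# soft-core modification of the dispersion-repulsion and electrostatic
# potentials that keeps them finite at zero separation.

#' Default energy parameters
#'
#' Per-class Lennard-Jones well depths and diameters, the dielectric model,
#' the soft-core softness, desolvation weights and nonbonded exclusion
#' scalings. All energies are in kcal/mol, distances in Angstrom.
#'
#' The docking electrostatics default to a distance-dependent dielectric
#' eps(r) = 4r, the common screening choice for docking. The soft-core
#' softness `alpha` defaults to 0.5; `alpha = 0` recovers the unmodified
#' 12-6 and Coulomb forms exactly.
#'
#' @param dielectric list: `model` one of `"distance"` (eps(r) = k*r) or
#'   `"constant"` (eps = k); `k` the scaling constant (must give eps >= 1
#'   at contact ranges)
#' @param alpha soft-core softness (dimensionless, >= 0)
#' @param softcore_enabled logical; disable to use the raw potentials
#' @param cutoff nonbonded cutoff distance (A)
#' @return a list of class `energy_params`
#' @export
default_energy_params <- function(dielectric = list(model = "distance", k = 4),
                                  alpha = 0.5, softcore_enabled = TRUE,
                                  cutoff = 12) {
  stopifnot(alpha >= 0, cutoff > 0)
  structure(list(
    vdw = data.frame(
      class = c("donor", "acceptor", "both", "nonpolar"),
      eps = c(0.10, 0.20, 0.20, 0.15),
      sigma = c(3.0, 3.0, 3.0, 3.5),
      stringsAsFactors = FALSE),
    dielectric = dielectric,
    softcore = list(alpha = alpha, enabled = softcore_enabled),
    # Gaussian-envelope desolvation: pairwise w_i * w_j * exp(-r^2/(2 s^2));
    # polar classes pay a burial penalty, nonpolar burial is favourable
    solvation = list(weights = c(donor = 0.60, acceptor = 0.60, both = 0.60,
                                 nonpolar = -0.15),
                     sigma = 3.5),
    scale14 = list(vdw = 0.5, elec = 1 / 1.2),
    cutoff = cutoff
  ), class = "energy_params")
}

#' Fill per-atom Lennard-Jones parameters from the class table
#' @param s a classified `lidstruct`
#' @param params an `energy_params` list
#' @return the structure with `eps` and `sigma` columns populated
#' @export
assign_vdw_params <- function(s, params = default_energy_params()) {
  if (!is.null(s$atoms$eps) && !is.null(s$atoms$sigma) &&
      !anyNA(s$atoms$eps) && !anyNA(s$atoms$sigma))
    return(s)
  if (any(is.na(s$atoms$hclass))) s <- assign_atom_classes(s)
  m <- match(s$atoms$hclass, params$vdw$class)
  # fill only missing entries so generator-planted parameters survive
  na_e <- is.na(s$atoms$eps); na_s <- is.na(s$atoms$sigma)
  s$atoms$eps[na_e] <- params$vdw$eps[m][na_e]
  s$atoms$sigma[na_s] <- params$vdw$sigma[m][na_s]
  s
}

#' Energy breakdown container
#'
#' Component terms of the docking energy, all kcal/mol; `total` is always
#' the exact sum of the components.
#' @param torsional,vdw_intra,vdw_inter,electrostatic,solvation component
#'   energies (kcal/mol)
#' @return list of class `energy_breakdown`
#' @export
energy_breakdown <- function(torsional = 0, vdw_intra = 0, vdw_inter = 0,
                             electrostatic = 0, solvation = 0) {
  comp <- c(torsional = torsional, vdw_intra = vdw_intra,
            vdw_inter = vdw_inter, electrostatic = electrostatic,
            solvation = solvation)
  structure(as.list(c(comp, total = sum(comp))), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-14s %12.4f kcal/mol\n", nm, x[[nm]]))
  invisible(x)
}

#' Add two energy breakdowns component-wise
#' @param a,b `energy_breakdown` objects
#' @return their component-wise sum
#' @export
add_breakdowns <- function(a, b) {
  energy_breakdown(torsional = a$torsional + b$torsional,
                   vdw_intra = a$vdw_intra + b$vdw_intra,
                   vdw_inter = a$vdw_inter + b$vdw_inter,
                   electrostatic = a$electrostatic + b$electrostatic,
                   solvation = a$solvation + b$solvation)
}

#' Soft-core nonbonded pair energy
#'
#' Beutler-style soft-core forms with a single softness parameter `alpha`:
#' \deqn{V_{LJ} = 4\epsilon\left[\frac{\sigma^{12}}{(\alpha\sigma^6+r^6)^2}
#'   - \frac{\sigma^6}{\alpha\sigma^6+r^6}\right]}
#' and Coulomb over the softened distance
#' \eqn{r_{sc} = \sqrt{r^2 + \alpha\sigma^2}}: with a constant dielectric
#' \eqn{k}, \eqn{V_C = 332.0637\, q_i q_j / (k\, r_{sc})}; with the
#' distance-dependent model \eqn{\epsilon(r) = k r},
#' \eqn{V_C = 332.0637\, q_i q_j / (k\, r_{sc}^2)}. Both terms are finite
#' at r = 0 whenever `alpha > 0`, and reduce exactly to the unmodified
#' 12-6 and Coulomb potentials at `alpha = 0`.
#'
#' @param r separation (A, >= 0); vectorized
#' @param eps,sigma combined Lennard-Jones parameters (kcal/mol, A)
#' @param qi,qj partial charges (e)
#' @param alpha soft-core softness
#' @param dielectric dielectric model list (see [default_energy_params()])
#' @return list with numeric vectors `vdw` and `coulomb` (kcal/mol)
#' @export
softcore_pair <- function(r, eps, sigma, qi = 0, qj = 0, alpha = 0.5,
                          dielectric = list(model = "distance", k = 4)) {
  if (any(r < 0)) stop("negative separation")
  den <- alpha * sigma^6 + r^6
  vdw <- 4 * eps * (sigma^12 / den^2 - sigma^6 / den)
  rsc2 <- r^2 + alpha * sigma^2
  coul <- if (dielectric$model == "distance") {
    .COULOMB * qi * qj / (dielectric$k * rsc2)
  } else {
    .COULOMB * qi * qj / (dielectric$k * sqrt(rsc2))
  }
  list(vdw = vdw, coulomb = coul)
}

# topological bond distance (1=bonded, 2=angle, 3=dihedral, Inf otherwise),
# capped at 4; dense matrix, fine for the peptide-sized systems used here
.bond_separation <- function(n, bonds) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  if (!is.null(bonds) && nrow(bonds) > 0L) {
    adj <- vector("list", n)
    for (b in seq_len(nrow(bonds))) {
      i <- bonds$i[b]; j <- bonds$j[b]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
    for (src in seq_len(n)) {   # BFS truncated at depth 3
      frontier <- src
      for (depth in 1:3) {
        nxt <- unique(unlist(adj[frontier]))
        nxt <- nxt[D[src, nxt] > depth]
        if (length(nxt) == 0L) break
        D[src, nxt] <- depth
        frontier <- nxt
      }
    }
  }
  D
}

# dihedral angle (radians) for atom quadruple rows of xyz
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Measure a dihedral angle in a structure
#' @param s a `lidstruct`
#' @param idx integer vector of 4 atom indices
#' @return angle in radians, in (-pi, pi]
#' @export
measure_dihedral <- function(s, idx) {
  xyz <- coords(s)
  .dihedral(xyz[idx[1], ], xyz[idx[2], ], xyz[idx[3], ], xyz[idx[4], ])
}

# torsional energy: E = 0.5 * V * (1 + cos(n*phi - delta)); the minimum of
# each term is 0 and the barrier height is V
.torsion_energy <- function(s) {
  tt <- s$torsions
  if (is.null(tt) || nrow(tt) == 0L) return(0)
  xyz <- coords(s)
  e <- 0
  for (r in seq_len(nrow(tt))) {
    phi <- .dihedral(xyz[tt$i[r], ], xyz[tt$j[r], ], xyz[tt$k[r], ],
                     xyz[tt$l[r], ])
    e <- e + 0.5 * tt$barrier[r] * (1 + cos(tt$period[r] * phi - tt$phase[r]))
  }
  e
}

#' Intramolecular energy of the flexible lid
#'
#' Torsional cosine terms plus nonbonded interactions between atom pairs
#' separated by more than three bonds; 1-2 and 1-3 pairs are excluded and
#' 1-4 pairs scaled by the configured factors.
#'
#' @param lid a classified `lidstruct` with topology
#' @param params an `energy_params` list
#' @return an `energy_breakdown` (torsional, vdw_intra and the
#'   intramolecular electrostatic contribution; intermolecular fields 0)
#' @export
intramolecular_energy <- function(lid, params = default_energy_params()) {
  lid <- assign_vdw_params(lid, params)
  a <- lid$atoms
  n <- nrow(a)
  etor <- .torsion_energy(lid)
  evdw <- 0; eel <- 0
  pt <- lid$metadata$pair_table %||% .pair_table(lid)
  if (nrow(pt) > 0L) {
    xyz <- coords(lid)
    alpha <- if (params$softcore$enabled) params$softcore$alpha else 0
    r <- sqrt(rowSums((xyz[pt$i, , drop = FALSE] -
                         xyz[pt$j, , drop = FALSE])^2))
    keep <- r <= params$cutoff
    if (any(keep)) {
      i <- pt$i[keep]; j <- pt$j[keep]; r <- r[keep]
      pe <- softcore_pair(r, sqrt(a$eps[i] * a$eps[j]),
                          (a$sigma[i] + a$sigma[j]) / 2,
                          a$charge[i], a$charge[j], alpha, params$dielectric)
      sv <- ifelse(pt$sep[keep] == 3L, params$scale14$vdw, 1)
      se <- ifelse(pt$sep[keep] == 3L, params$scale14$elec, 1)
      evdw <- sum(sv * pe$vdw)
      eel <- sum(se * pe$coulomb)
    }
  }
  energy_breakdown(torsional = etor, vdw_intra = evdw, electrostatic = eel)
}

# eligible intramolecular pairs (bond separation >= 3) with their separation
.pair_table <- function(s) {
  n <- natoms(s)
  if (n < 2L)
    return(data.frame(i = integer(0), j = integer(0), sep = integer(0)))
  sep <- .bond_separation(n, s$bonds)
  ij <- which(upper.tri(sep) & sep >= 3, arr.ind = TRUE)
  data.frame(i = ij[, 1L], j = ij[, 2L],
             sep = ifelse(is.finite(sep[ij]), sep[ij], 4L))
}

#' Precompute topology caches used by the pose-sampling hot path
#'
#' Stores the eligible nonbonded pair table and, per rotatable torsion, the
#' set of atoms moved by that torsion in the structure metadata. Purely an
#' optimization; all functions compute these on the fly when absent.
#'
#' @param s a `lidstruct`
#' @return the structure with `metadata$pair_table` and
#'   `metadata$moving_sides` populated
#' @export
prepare_topology <- function(s) {
  s$metadata$pair_table <- .pair_table(s)
  rot <- which(s$torsions$rotatable %||% logical(0))
  s$metadata$rot_rows <- rot
  s$metadata$moving_sides <- lapply(rot, function(r)
    .moving_side(natoms(s), s$bonds, s$torsions$j[r], s$torsions$k[r],
                 s$torsions$k[r]))
  s
}

#' Intermolecular lid-receptor energy
#'
#' All lid-receptor atom pairs within the cutoff contribute soft-core
#' Lennard-Jones and Coulomb terms (under the configured dielectric model)
#' plus the pairwise Gaussian-envelope desolvation term.
#'
#' @param lid realized lid conformation (`lidstruct`)
#' @param receptor classified receptor (`lidstruct`)
#' @param params an `energy_params` list
#' @return an `energy_breakdown` (vdw_inter, electrostatic, solvation)
#' @export
intermolecular_energy <- function(lid, receptor,
                                  params = default_energy_params()) {
  lid <- assign_vdw_params(lid, params)
  receptor <- assign_vdw_params(receptor, params)
  al <- lid$atoms; ar <- receptor$atoms
  if (any(is.na(al$hclass)) || any(is.na(ar$hclass)))
    stop("unclassified atoms; run assign_atom_classes() first")
  XL <- coords(lid); XR <- coords(receptor)
  d2 <- outer(rowSums(XL^2), rowSums(XR^2), `+`) - 2 * tcrossprod(XL, XR)
  r <- sqrt(pmax(d2, 0))
  within <- r <= params$cutoff
  alpha <- if (params$softcore$enabled) params$softcore$alpha else 0
  epsm <- sqrt(outer(al$eps, ar$eps))
  sigm <- outer(al$sigma, ar$sigma, function(a, b) (a + b) / 2)
  qq <- outer(al$charge, ar$charge)
  den <- alpha * sigm^6 + r^6
  vdw <- 4 * epsm * (sigm^12 / den^2 - sigm^6 / den)
  rsc2 <- r^2 + alpha * sigm^2
  coul <- if (params$dielectric$model == "distance")
    .COULOMB * qq / (params$dielectric$k * rsc2)
  else .COULOMB * qq / (params$dielectric$k * sqrt(rsc2))
  w <- params$solvation$weights
  ww <- outer(w[al$hclass], w[ar$hclass])
  solv <- ww * exp(-r^2 / (2 * params$solvation$sigma^2))
  energy_breakdown(vdw_inter = sum(vdw[within]),
                   electrostatic = sum(coul[within]),
                   solvation = sum(solv[within]))
}

#' Total docking energy of a lid conformation against the rigid receptor
#'
#' Sum of the intramolecular lid terms and the intermolecular
#' lid-receptor terms; a pure, deterministic function of the coordinates.
#'
#' @inheritParams intermolecular_energy
#' @return an `energy_breakdown` whose `total` drives the Metropolis
#'   criterion
#' @export
total_docking_energy <- function(lid, receptor,
                                 params = default_energy_params()) {
  add_breakdowns(intramolecular_energy(lid, params),
                 intermolecular_energy(lid, receptor, params))
}

# ---- generic system energy (bond/angle/torsion strain + intra nonbonded),
# used by the minimizer, the normal-mode machinery and E_int --------------

#' Potential energy of a single structure from its own topology
#'
#' Harmonic bond and angle terms, cosine torsions and excluded-pair
#' intramolecular nonbonded terms. This is the objective minimized by
#' [minimize_structure()] and the source of the internal (strain) energy
#' in MM-GB/SA decompositions.
#'
#' @param s a `lidstruct` with topology
#' @param params an `energy_params` list
#' @param nonbonded include intramolecular nonbonded terms (default TRUE;
#'   harmonic test systems typically set FALSE)
#' @return energy in kcal/mol
#' @export
system_energy <- function(s, params = default_energy_params(),
                          nonbonded = TRUE) {
  xyz <- coords(s)
  e <- 0
  b <- s$bonds
  if (!is.null(b) && nrow(b) > 0L && !is.null(b$k)) {
    dr <- sqrt(rowSums((xyz[b$i, , drop = FALSE] -
                          xyz[b$j, , drop = FALSE])^2))
    e <- e + sum(b$k * (dr - b$r0)^2, na.rm = TRUE)
  }
  an <- s$angles
  if (!is.null(an) && nrow(an) > 0L && !is.null(an$ktheta)) {
    for (r in seq_len(nrow(an))) {
      v1 <- xyz[an$i[r], ] - xyz[an$j[r], ]
      v2 <- xyz[an$k[r], ] - xyz[an$j[r], ]
      th <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                (sqrt(sum(v1^2)) * sqrt(sum(v2^2))))))
      e <- e + an$ktheta[r] * (th - an$theta0[r])^2
    }
  }
  e <- e + .torsion_energy(s)
  if (nonbonded && isTRUE(s$metadata$nonbonded %||% TRUE) &&
      !is.null(s$atoms$hclass) && !all(is.na(s$atoms$hclass))) {
    nb <- intramolecular_energy(s, params)
    e <- e + nb$vdw_intra + nb$electrostatic
  }
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerical gradient of [system_energy()] by central differences
#' @param s a `lidstruct`
#' @param params an `energy_params` list
#' @param h finite-difference step (A)
#' @param nonbonded passed through to [system_energy()]
#' @return numeric vector of length 3*natoms (kcal/mol/A)
#' @export
system_gradient <- function(s, params = default_energy_params(), h = 1e-5,
                            nonbonded = TRUE) {
  x0 <- as.vector(t(coords(s)))
  f <- function(x) system_energy(set_coords(s, matrix(x, ncol = 3,
                                                      byrow = TRUE)),
                                 params, nonbonded)
  g <- numeric(length(x0))
  for (k in seq_along(x0)) {
    xp <- x0; xp[k] <- xp[k] + h
    xm <- x0; xm[k] <- xm[k] - h
    g[k] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
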