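# Trajectory and ensemble analyses: RMSD/RMSF, hydrogen-bond and
# salt-bridge occupancy, residue contact maps, accessible-surface-area
# changes upon binding, side-chain movements and interaction-mimicry
# pairing between a docked lid and a reference peptide complex.

#' Hydrogen-bond criteria
#'
#' A donor-acceptor pair satisfies the criterion in a frame iff the
#' donor-acceptor distance is <= `max_distance` AND the donor-H-acceptor
#' angle is >= `min_angle` (for heavy-atom-only structures, the
#' antecedent-donor-acceptor angle with the same cutoff is used instead).
#'
#' @param max_distance donor-acceptor distance cutoff (A, default 3.50)
#' @param min_angle angle cutoff (degrees, default 120.00)
#' @return list of class `hbond_criteria`
#' @export
hbond_criteria <- function(max_distance = 3.50, min_angle = 120.00) {
  stopifnot(max_distance > 0, min_angle > 0, min_angle <= 180)
  structure(list(max_distance = max_distance, min_angle = min_angle),
            class = "hbond_criteria")
}

.angle_deg <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  acos(pmin(1, pmax(-1, sum(v1 * v2) /
                      (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
}

# for each donor heavy atom: its bonded hydrogens, and a bonded heavy
# antecedent for the heavy-atom fallback
.donor_probes <- function(s) {
  a <- s$atoms
  out <- vector("list", natoms(s))
  bnd <- s$bonds
  for (d in which(a$hclass %in% c("donor", "both") & a$heavy)) {
    nb <- integer(0)
    if (!is.null(bnd) && nrow(bnd) > 0L)
      nb <- c(bnd$j[bnd$i == d], bnd$i[bnd$j == d])
    hs <- nb[a$element[nb] == "H"]
    ante <- nb[a$heavy[nb]]
    out[[d]] <- list(h = hs, antecedent = if (length(ante)) ante[1L] else NA)
  }
  out
}

# does pair (donor d, acceptor acc) satisfy the criteria at coordinates xyz
.hbond_satisfied <- function(xyz, d, acc, probes, crit) {
  dist <- sqrt(sum((xyz[d, ] - xyz[acc, ])^2))
  if (dist > crit$max_distance) return(FALSE)
  p <- probes[[d]]
  if (!is.null(p) && length(p$h) > 0L) {
    for (h in p$h)
      if (.angle_deg(xyz[d, ], xyz[h, ], xyz[acc, ]) >= crit$min_angle)
        return(TRUE)
    return(FALSE)
  }
  if (!is.null(p) && !is.na(p$antecedent))
    return(.angle_deg(xyz[p$antecedent, ], xyz[d, ], xyz[acc, ]) >=
             crit$min_angle)
  TRUE  # no hydrogen and no antecedent: distance-only criterion
}

# hydrogen bonds present in a single structure across a two-group split
.hbond_pairs_single <- function(s, split, crit = hbond_criteria()) {
  if (any(is.na(s$atoms$hclass))) s <- assign_atom_classes(s)
  a <- s$atoms
  xyz <- coords(s)
  probes <- .donor_probes(s)
  don <- which(a$hclass %in% c("donor", "both") & a$heavy)
  acc <- which(a$hclass %in% c("acceptor", "both") & a$heavy)
  hits <- NULL
  for (d in don) for (x in acc) {
    if (d == x || split[d] == split[x]) next
    if (.hbond_satisfied(xyz, d, x, probes, crit))
      hits <- rbind(hits, data.frame(donor = d, acceptor = x))
  }
  if (is.null(hits)) data.frame(donor = integer(0), acceptor = integer(0))
  else hits
}

#' Per-frame RMSD time series
#'
#' Best-fit RMSD of the selected atoms of every frame against the
#' reference, after superposition on the fit selection.
#'
#' @param traj a `lidtraj`
#' @param reference a `lidstruct` (e.g. frame 1 or a crystal structure)
#' @param select atom-name filter for the RMSD (NULL = all atoms)
#' @param fit_select atom-name filter for the superposition (default: same
#'   as `select`)
#' @return data.frame with `time` (ps) and `rmsd` (A)
#' @export
rmsd_series <- function(traj, reference, select = NULL,
                        fit_select = select) {
  pick <- function(s, sel) if (is.null(sel)) seq_len(natoms(s))
  else which(s$atoms$name %in% sel)
  isel <- pick(traj$base, select)
  ifit <- pick(traj$base, fit_select)
  rsel <- pick(reference, select)
  rfit <- pick(reference, fit_select)
  if (length(isel) == 0L || length(rsel) == 0L)
    stop("empty atom selection")
  if (length(isel) != length(rsel) || length(ifit) != length(rfit))
    stop("selection sizes differ between trajectory and reference")
  Yf <- coords(reference)[rfit, , drop = FALSE]
  Ys <- coords(reference)[rsel, , drop = FALSE]
  r <- vapply(traj$xyz, function(X) {
    fit <- kabsch(X[ifit, , drop = FALSE], Yf)
    Xs <- sweep(X[isel, , drop = FALSE] %*% t(fit$R), 2L, fit$t, `+`)
    sqrt(mean(rowSums((Xs - Ys)^2)))
  }, numeric(1))
  data.frame(time = traj$times, rmsd = r)
}

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation about the mean structure after per-frame
#' superposition (two-pass: fit to frame 1, average, refit to the mean).
#' Per-residue values aggregate the selected atoms as
#' sqrt(mean of squared deviations).
#'
#' @param traj a `lidtraj` with at least two frames
#' @param select atom-name filter (NULL = all atoms)
#' @param fit superpose frames before measuring (default TRUE)
#' @return data.frame with `chain`, `resno` and `rmsf` (A)
#' @export
rmsf_profile <- function(traj, select = NULL, fit = TRUE) {
  if (nframes(traj) < 2L) stop("RMSF needs at least two frames")
  idx <- if (is.null(select)) seq_len(natoms(traj$base))
  else which(traj$base$atoms$name %in% select)
  if (length(idx) == 0L) stop("empty atom selection")
  frames <- lapply(traj$xyz, function(X) X[idx, , drop = FALSE])
  if (fit) {
    ref <- frames[[1L]]
    for (pass in 1:2) {
      frames <- lapply(frames, function(X) {
        f <- kabsch(X, ref)
        sweep(X %*% t(f$R), 2L, f$t, `+`)
      })
      ref <- Reduce(`+`, frames) / length(frames)
    }
  }
  mean_xyz <- Reduce(`+`, frames) / length(frames)
  dev2 <- Reduce(`+`, lapply(frames, function(X)
    rowSums((X - mean_xyz)^2))) / length(frames)
  a <- traj$base$atoms[idx, ]
  key <- paste(a$chain, a$resno)
  agg <- tapply(dev2, key, mean)
  ord <- unique(key)
  data.frame(chain = a$chain[match(ord, key)],
             resno = a$resno[match(ord, key)],
             rmsf = sqrt(as.numeric(agg[ord])))
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' For every candidate (or requested) donor-acceptor pair, the fraction of
#' frames in which the geometric criterion holds. The occupancy is the
#' exact ratio n_satisfied / n_frames over all analyzed frames.
#'
#' @param traj a `lidtraj` with classified atoms
#' @param criteria a [hbond_criteria()] list
#' @param pairs optional data.frame with columns `donor`, `acceptor` (atom
#'   indices) restricting the analysis; default: all donor x acceptor
#'   heavy-atom pairs that satisfy the criterion in at least one frame
#' @return data.frame with `donor`, `acceptor`, `n_satisfied`, `occupancy`
#' @export
hbond_occupancy <- function(traj, criteria = hbond_criteria(),
                            pairs = NULL) {
  if (nframes(traj) < 1L) stop("empty trajectory")
  base <- traj$base
  if (any(is.na(base$atoms$hclass))) base <- assign_atom_classes(base)
  a <- base$atoms
  probes <- .donor_probes(base)
  if (is.null(pairs)) {
    don <- which(a$hclass %in% c("donor", "both") & a$heavy)
    acc <- which(a$hclass %in% c("acceptor", "both") & a$heavy)
    pairs <- expand.grid(donor = don, acceptor = acc)
    pairs <- pairs[pairs$donor != pairs$acceptor, , drop = FALSE]
  }
  n <- nframes(traj)
  cnt <- integer(nrow(pairs))
  for (f in seq_len(n)) {
    xyz <- traj$xyz[[f]]
    for (p in seq_len(nrow(pairs)))
      if (.hbond_satisfied(xyz, pairs$donor[p], pairs$acceptor[p], probes,
                           criteria))
        cnt[p] <- cnt[p] + 1L
  }
  out <- data.frame(donor = pairs$donor, acceptor = pairs$acceptor,
                    n_satisfied = cnt, occupancy = cnt / n)
  out[out$n_satisfied > 0L | !is.null(pairs), , drop = FALSE]
}

#' Salt-bridge time series
#'
#' Per-frame satisfaction of hydrogen-bond-like geometry between
#' oppositely charged side-chain group atoms (e.g. phosphate oxygens vs
#' lysine amine). Pairs whose atoms carry same-sign charges are rejected.
#'
#' @param traj a `lidtraj`
#' @param pairs data.frame with columns `donor`, `acceptor` (atom indices
#'   of the charged-group atoms)
#' @param criteria a [hbond_criteria()] list
#' @return logical matrix, frames x pairs
#' @export
salt_bridge_series <- function(traj, pairs, criteria = hbond_criteria()) {
  if (nrow(pairs) == 0L)
    return(matrix(logical(0), nrow = nframes(traj), ncol = 0L))
  base <- traj$base
  if (any(is.na(base$atoms$hclass))) base <- assign_atom_classes(base)
  q <- base$atoms$charge
  for (p in seq_len(nrow(pairs))) {
    qd <- q[pairs$donor[p]]; qa <- q[pairs$acceptor[p]]
    if (qd != 0 && qa != 0 && sign(qd) == sign(qa))
      stop("salt-bridge pair ", p, " has same-sign charges")
  }
  probes <- .donor_probes(base)
  out <- matrix(FALSE, nframes(traj), nrow(pairs))
  for (f in seq_len(nframes(traj))) {
    xyz <- traj$xyz[[f]]
    for (p in seq_len(nrow(pairs)))
      out[f, p] <- .hbond_satisfied(xyz, pairs$donor[p], pairs$acceptor[p],
                                    probes, criteria)
  }
  out
}

#' Residue-residue contact map over an ensemble
#'
#' Two residues are in contact in one conformation when the minimum
#' distance over all their heavy-atom pairs is strictly below the cutoff
#' (default 4.2 A). The frequency is the fraction of ensemble members in
#' contact.
#'
#' @param ensemble a `lidstruct`, a list of them, or a `lidtraj`
#' @param split optional integer vector (one entry per atom, values 1/2)
#'   restricting the map to cross-partner residue pairs (e.g. receptor vs
#'   lid); NULL maps all residue pairs
#' @param cutoff contact cutoff (A, strict `<`)
#' @return data.frame with `res_i`, `res_j` (chain:resno labels),
#'   `min_dist` (ensemble minimum, A), `contact` (any member), `frequency`
#' @export
contact_map <- function(ensemble, split = NULL, cutoff = 4.2) {
  members <- if (inherits(ensemble, "lidtraj"))
    lapply(seq_len(nframes(ensemble)), function(f) traj_frame(ensemble, f))
  else if (inherits(ensemble, "lidstruct")) list(ensemble)
  else ensemble
  base <- members[[1L]]
  a <- base$atoms
  heavy <- which(a$heavy)
  if (length(heavy) == 0L) stop("no heavy atoms")
  key <- paste0(a$chain, ":", a$resno)
  rlev <- unique(key[heavy])
  rows <- lapply(rlev, function(r) intersect(which(key == r), heavy))
  rsplit <- if (is.null(split)) NULL else
    vapply(rows, function(ii) split[ii[1L]], numeric(1))
  nr <- length(rlev)
  out <- NULL
  for (p in seq_len(nr - 1L)) for (q in (p + 1L):nr) {
    if (!is.null(rsplit) && rsplit[p] == rsplit[q]) next
    dmins <- vapply(members, function(m) {
      X <- coords(m)
      .min_dist(X[rows[[p]], , drop = FALSE], X[rows[[q]], , drop = FALSE])
    }, numeric(1))
    hits <- dmins < cutoff
    out <- rbind(out, data.frame(res_i = rlev[p], res_j = rlev[q],
                                 min_dist = min(dmins),
                                 contact = any(hits),
                                 frequency = mean(hits)))
  }
  if (is.null(out))
    out <- data.frame(res_i = character(0), res_j = character(0),
                      min_dist = numeric(0), contact = logical(0),
                      frequency = numeric(0))
  out
}

#' Per-residue change in percentage accessible surface area
#'
#' %ASA of each residue is its SASA normalized by the residue type's
#' maximum exposure in an extended Gly-X-Gly reference (shipped table),
#' times 100. The change is %ASA(bound) - %ASA(reference): positive values
#' mean the residue became more exposed, negative more buried.
#'
#' @param bound,reference `lidstruct` objects sharing the same receptor
#'   residue set (e.g. receptor with docked lid vs the reference complex)
#' @param residues optional chain:resno labels restricting the output
#' @param params a [gbsa_params()] list
#' @return data.frame with `chain`, `resno`, `resid`, `pct_bound`,
#'   `pct_reference`, `delta_pct`
#' @export
delta_asa <- function(bound, reference, residues = NULL,
                      params = gbsa_params()) {
  per_res <- function(s) {
    at <- sasa_atoms(s, params$probe_radius, params$sasa_points)
    key <- paste0(s$atoms$chain, ":", s$atoms$resno)
    tapply(at, key, sum)
  }
  maxtab <- .max_asa_table()
  pct <- function(s, asa_res) {
    key <- names(asa_res)
    first <- match(key, paste0(s$atoms$chain, ":", s$atoms$resno))
    rid <- s$atoms$resid[first]
    mx <- maxtab$max_asa[match(rid, maxtab$resid)]
    mx[is.na(mx)] <- mean(maxtab$max_asa)
    setNames(100 * as.numeric(asa_res) / mx, key)
  }
  pb <- pct(bound, per_res(bound))
  pr <- pct(reference, per_res(reference))
  common <- intersect(names(pb), names(pr))
  if (!is.null(residues)) common <- intersect(common, residues)
  if (length(common) == 0L) stop("no shared residues between structures")
  first <- match(common, paste0(bound$atoms$chain, ":", bound$atoms$resno))
  data.frame(chain = bound$atoms$chain[first],
             resno = bound$atoms$resno[first],
             resid = bound$atoms$resid[first],
             pct_bound = as.numeric(pb[common]),
             pct_reference = as.numeric(pr[common]),
             delta_pct = as.numeric(pb[common] - pr[common]))
}

.max_asa_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      f <- system.file("extdata", "max_asa.csv", package = "liddock")
      if (!nzchar(f)) f <- file.path("inst", "extdata", "max_asa.csv")
      cache <<- read.csv(f, stringsAsFactors = FALSE, comment.char = "#")
    }
    cache
  }
})

#' Side-chain movement between two structures
#'
#' Backbone-superposes `pose` onto `reference` (names N, CA, C), then
#' reports the per-residue RMSD over side-chain heavy atoms and the
#' residues moving more than the threshold.
#'
#' @param pose,reference `lidstruct` objects with shared residues
#' @param threshold mover cutoff (A, default 2.0)
#' @return list with `per_residue` (data.frame: chain, resno, resid,
#'   sidechain_rmsd, n_atoms) and `movers` (chain:resno labels above the
#'   threshold); residues without shared side-chain atoms are reported
#'   with NA, not dropped
#' @export
sidechain_movement <- function(pose, reference, threshold = 2.0) {
  bb <- c("N", "CA", "C")
  sup <- superpose(pose, reference, select = bb)
  pose <- sup$fitted
  skip <- c(bb, "O", "OXT")
  keyp <- paste0(pose$atoms$chain, ":", pose$atoms$resno)
  keyr <- paste0(reference$atoms$chain, ":", reference$atoms$resno)
  rlev <- intersect(unique(keyp), unique(keyr))
  rows <- lapply(rlev, function(r) {
    ip <- which(keyp == r & !(pose$atoms$name %in% skip) & pose$atoms$heavy)
    ir <- which(keyr == r & !(reference$atoms$name %in% skip) &
                  reference$atoms$heavy)
    mp <- match(reference$atoms$name[ir], pose$atoms$name[ip])
    list(ip = ip[mp[!is.na(mp)]], ir = ir[!is.na(mp)])
  })
  Xp <- coords(pose); Xr <- coords(reference)
  rms <- vapply(rows, function(rr) {
    if (length(rr$ip) == 0L) return(NA_real_)
    sqrt(mean(rowSums((Xp[rr$ip, , drop = FALSE] -
                         Xr[rr$ir, , drop = FALSE])^2)))
  }, numeric(1))
  first <- match(rlev, keyp)
  per <- data.frame(chain = pose$atoms$chain[first],
                    resno = pose$atoms$resno[first],
                    resid = pose$atoms$resid[first],
                    sidechain_rmsd = rms,
                    n_atoms = vapply(rows, function(rr) length(rr$ip),
                                     integer(1)))
  list(per_residue = per,
       movers = rlev[!is.na(rms) & rms > threshold])
}

#' Interaction-mimicry table between a docked lid and a reference peptide
#'
#' For every receptor residue, lists the reference-peptide residues and the
#' lid residues it interacts with, separately for hydrogen bonds and for
#' hydrophobic (heavy-atom distance) contacts — the pairing showing whether
#' the lid mimics the reference peptide's interaction pattern.
#'
#' @param lid_complex `lidstruct` containing the receptor plus the docked
#'   lid
#' @param reference_complex `lidstruct` containing the same receptor plus
#'   the reference peptide
#' @param receptor_chain chain id of the receptor in both structures
#' @param criteria a [hbond_criteria()] list
#' @param contact_cutoff heavy-atom contact cutoff (A)
#' @return data.frame with one row per receptor residue that interacts in
#'   either complex: `receptor_res`, `ref_hbond`, `ref_contact`,
#'   `lid_hbond`, `lid_contact` (comma-separated partner residue labels)
#' @export
mimicry_map <- function(lid_complex, reference_complex, receptor_chain = "R",
                        criteria = hbond_criteria(), contact_cutoff = 4.2) {
  partners <- function(cmplx) {
    if (any(is.na(cmplx$atoms$hclass))) cmplx <- assign_atom_classes(cmplx)
    split <- ifelse(cmplx$atoms$chain == receptor_chain, 1L, 2L)
    key <- paste0(cmplx$atoms$chain, ":", cmplx$atoms$resno)
    hb <- .hbond_pairs_single(cmplx, split, criteria)
    hb_map <- list()
    for (r in seq_len(nrow(hb))) {
      d <- hb$donor[r]; a <- hb$acceptor[r]
      rec <- if (split[d] == 1L) key[d] else key[a]
      pep <- if (split[d] == 1L) key[a] else key[d]
      hb_map[[rec]] <- union(hb_map[[rec]], pep)
    }
    cm <- contact_map(cmplx, split = split, cutoff = contact_cutoff)
    ct_map <- list()
    for (r in which(cm$contact)) {
      ri <- cm$res_i[r]; rj <- cm$res_j[r]
      rec <- if (startsWith(ri, paste0(receptor_chain, ":"))) ri else rj
      pep <- if (identical(rec, ri)) rj else ri
      ct_map[[rec]] <- union(ct_map[[rec]], pep)
    }
    list(hb = hb_map, ct = ct_map)
  }
  ref <- partners(reference_complex)
  lid <- partners(lid_complex)
  recs <- sort(unique(c(names(ref$hb), names(ref$ct), names(lid$hb),
                        names(lid$ct))))
  collapse <- function(m, r) if (is.null(m[[r]])) "" else
    paste(sort(m[[r]]), collapse = ",")
  data.frame(receptor_res = recs,
             ref_hbond = vapply(recs, function(r) collapse(ref$hb, r), ""),
             ref_contact = vapply(recs, function(r) collapse(ref$ct, r), ""),
             lid_hbond = vapply(recs, function(r) collapse(lid$hb, r), ""),
             lid_contact = vapply(recs, function(r) collapse(lid$ct, r), ""),
             row.names = NULL)
}
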