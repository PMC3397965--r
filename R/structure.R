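#' @importFrom stats optim rnorm runif setNames
#' @importFrom graphics matplot lines
#' @importFrom utils read.csv
NULL

# Boltzmann / gas constant in kcal/mol/K and the electrostatic conversion
# constant in kcal*Angstrom/(mol*e^2).
.kB <- 0.0019872041
.COULOMB <- 332.0637

#' Construct a molecular structure object
#'
#' A `lidstruct` holds an atom table (names, elements, residue identity,
#' coordinates in Angstrom, partial charges, van der Waals parameters and
#' hydrogen-bond class) together with optional covalent topology: harmonic
#' bonds, harmonic angles and cosine torsions (with a rotatable flag).
#' It is the substrate for every energy, sampling and analysis function in
#' the package.
#'
#' @param atoms data.frame with columns `name`, `element`, `resid`, `resno`,
#'   `chain`, `x`, `y`, `z`; optional `charge`, `hclass`, `eps`, `sigma`.
#'   Missing optional columns are filled with defaults (charge 0, class NA,
#'   eps/sigma NA until parameters are assigned).
#' @param bonds data.frame with integer columns `i`, `j` (atom indices) and
#'   optional harmonic constants `k` (kcal/mol/A^2) and `r0` (A).
#' @param angles data.frame with `i`, `j`, `k` and optional `ktheta`
#'   (kcal/mol/rad^2), `theta0` (radians).
#' @param torsions data.frame with `i`, `j`, `k`, `l` and optional `barrier`
#'   (kcal/mol), `period`, `phase` (radians), logical `rotatable`.
#' @param metadata named list of free-form annotations (source label,
#'   pocket indices, analytic frequencies, ...).
#' @return An object of class `lidstruct`.
#' @export
lidstruct <- function(atoms, bonds = NULL, angles = NULL, torsions = NULL,
                      metadata = list()) {
  stopifnot(is.data.frame(atoms))
  need <- c("name", "element", "resid", "resno", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0L)
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$hclass)) atoms$hclass <- NA_character_
  if (is.null(atoms$eps)) atoms$eps <- NA_real_
  if (is.null(atoms$sigma)) atoms$sigma <- NA_real_
  atoms$heavy <- toupper(atoms$element) != "H"
  chk_idx <- function(tab, cols) {
    if (is.null(tab) || nrow(tab) == 0L) return(invisible())
    for (cc in cols)
      if (any(tab[[cc]] < 1L | tab[[cc]] > nrow(atoms)))
        stop("topology references atoms outside the atom table")
  }
  chk_idx(bonds, c("i", "j"))
  chk_idx(angles, c("i", "j", "k"))
  chk_idx(torsions, c("i", "j", "k", "l"))
  if (!is.null(torsions) && nrow(torsions) > 0L) {
    if (is.null(torsions$rotatable)) torsions$rotatable <- FALSE
    if (is.null(torsions$barrier)) torsions$barrier <- 0
    if (is.null(torsions$period)) torsions$period <- 3
    if (is.null(torsions$phase)) torsions$phase <- 0
  }
  structure(list(atoms = atoms, bonds = bonds, angles = angles,
                 torsions = torsions, metadata = metadata),
            class = "lidstruct")
}

#' @export
print.lidstruct <- function(x, ...) {
  a <- x$atoms
  cat("lidstruct:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno))), "residues,",
      length(unique(a$chain)), "chain(s)\n")
  if (!is.null(x$bonds)) cat("  bonds:", nrow(x$bonds), "\n")
  if (!is.null(x$torsions))
    cat("  torsions:", nrow(x$torsions),
        sprintf("(%d rotatable)", sum(x$torsions$rotatable)), "\n")
  if (!all(is.na(a$hclass))) {
    cat("  atom classes:\n")
    print(table(a$hclass))
  }
  invisible(x)
}

#' Number of atoms
#' @param s a `lidstruct`
#' @return integer atom count
#' @export
natoms <- function(s) nrow(s$atoms)

#' Atom coordinates as an n x 3 matrix (Angstrom)
#' @param s a `lidstruct`
#' @return numeric matrix with columns x, y, z
#' @export
coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

#' Replace atom coordinates
#' @param s a `lidstruct`
#' @param xyz n x 3 numeric matrix
#' @return the structure with updated coordinates
#' @export
set_coords <- function(s, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == natoms(s), ncol(xyz) == 3L, all(is.finite(xyz)))
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), keeping blank or 'A' alternate
#' locations and preserving author residue numbering. Multi-model files
#' yield the requested model (first by default); use [read_ensemble()] to
#' load every model.
#'
#' @param path PDB file path
#' @param model 1-based model index for multi-model files
#' @return a `lidstruct`
#' @export
read_pdb <- function(path, model = 1L) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("PDB format error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L)
    stop("PDB format error: no ATOM/HETATM records in ", path)
  keep <- is.na(pdb$atom$alt) | pdb$atom$alt %in% c("", "A")
  at <- pdb$atom[keep, , drop = FALSE]
  nm <- nrow(pdb$xyz)
  if (model < 1L || model > nm)
    stop("model index ", model, " out of range (file has ", nm, " models)")
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)[keep, , drop = FALSE]
  bad <- which(!is.finite(xyz[, 1]) | !is.finite(xyz[, 2]) | !is.finite(xyz[, 3]))
  if (length(bad) > 0L)
    stop("PDB format error: malformed coordinate field at atom record ",
         bad[1L], " (serial ", at$eleno[bad[1L]], ")")
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- .guess_element(at$elety)
  elem <- ifelse(is.na(elem) | elem == "", .guess_element(at$elety), elem)
  atoms <- data.frame(name = at$elety, element = toupper(trimws(elem)),
                      resid = at$resid, resno = at$resno,
                      chain = ifelse(is.na(at$chain) | at$chain == "", "A",
                                     at$chain),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  lidstruct(atoms, metadata = list(source = path, n_models = nm))
}

.guess_element <- function(name) {
  n <- gsub("[0-9' ]", "", name)
  first <- toupper(substr(n, 1L, 1L))
  # two-letter biological elements seen in PDB atom names
  ifelse(first %in% c("C", "N", "O", "S", "P", "H", "F"), first,
         toupper(substr(n, 1L, 2L)))
}

#' Read a multi-model PDB file as a conformational ensemble
#' @param path PDB file path
#' @return list of `lidstruct`, one per MODEL
#' @export
read_ensemble <- function(path) {
  s1 <- read_pdb(path, model = 1L)
  nm <- s1$metadata$n_models
  if (nm == 1L) return(list(s1))
  lapply(seq_len(nm), function(m) read_pdb(path, model = m))
}

#' Write a structure (or ensemble) to a PDB file
#'
#' Coordinates are written with the standard 3-decimal PDB precision. A
#' list of structures over the same atom set is written as a multi-model
#' file (MODEL/ENDMDL records).
#'
#' @param s a `lidstruct` or a list of them sharing one atom table
#' @param path output file path
#' @return invisibly, the path
#' @export
write_pdb <- function(s, path) {
  models <- if (inherits(s, "lidstruct")) list(s) else s
  a <- models[[1L]]$atoms
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (m in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    am <- models[[m]]$atoms
    for (i in seq_len(nrow(am))) {
      nm <- am$name[i]
      # PDB column rules: 4-char names start in col 13 only for 2-letter
      # elements; standard names are left-padded by one space
      nmf <- if (nchar(nm) >= 4L) substr(nm, 1L, 4L) else sprintf(" %-3s", nm)
      writeLines(sprintf(
        "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        i %% 100000L, nmf, substr(am$resid[i], 1L, 3L),
        substr(am$chain[i], 1L, 1L), am$resno[i] %% 10000L,
        am$x[i], am$y[i], am$z[i], 1, 0, substr(am$element[i], 1L, 2L)), con)
    }
    writeLines(if (multi) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- atom classification ---------------------------------------------------

.atom_class_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      f <- system.file("extdata", "atom_classes.csv", package = "liddock")
      if (!nzchar(f)) f <- file.path("inst", "extdata", "atom_classes.csv")
      cache <<- read.csv(f, stringsAsFactors = FALSE, comment.char = "#")
    }
    cache
  }
})

#' Assign hydrogen-bond classes to every atom
#'
#' Each atom receives exactly one of the four classes `donor`, `acceptor`,
#' `both` (donates and accepts) or `nonpolar`, from a shipped dictionary
#' keyed on (residue name, atom name) with element-based fallbacks.
#' Standard amino acids plus phosphoserine (SEP), the S17D aspartate and
#' the acetyl cap (ACE) are covered. Classification is deterministic and
#' idempotent.
#'
#' @param s a `lidstruct`
#' @param on_unknown `"warn"` (default) assigns unknown atoms `nonpolar`
#'   with a warning; `"error"` aborts listing the offenders.
#' @return the structure with `hclass` filled for every atom
#' @export
assign_atom_classes <- function(s, on_unknown = c("warn", "error")) {
  on_unknown <- match.arg(on_unknown)
  tab <- .atom_class_table()
  a <- s$atoms
  key_exact <- paste(a$resid, a$name)
  tab_exact <- tab[tab$resid != "*", ]
  tab_any <- tab[tab$resid == "*", ]
  m1 <- match(key_exact, paste(tab_exact$resid, tab_exact$name))
  cls <- tab_exact$class[m1]
  m2 <- match(a$name, tab_any$name)
  cls[is.na(cls)] <- tab_any$class[m2[is.na(cls)]]
  # element fallback: N donates, O accepts, everything else nonpolar
  fb <- ifelse(a$element == "N", "donor",
               ifelse(a$element == "O", "acceptor", "nonpolar"))
  unknown <- is.na(cls) & !(a$element %in% c("H", "C", "N", "O", "S", "P"))
  if (any(unknown)) {
    off <- unique(paste(a$resid[unknown], a$name[unknown]))
    msg <- paste("unclassified atoms defaulted to nonpolar:",
                 paste(off, collapse = ", "))
    if (on_unknown == "error") stop(msg) else warning(msg)
  }
  cls[is.na(cls)] <- fb[is.na(cls)]
  s$atoms$hclass <- cls
  s
}

#' Extract a residue range as a new structure
#'
#' @param s a `lidstruct`
#' @param chain chain identifier
#' @param first,last inclusive author residue numbers (`first <= last`)
#' @return a `lidstruct` containing exactly the requested residues, with
#'   topology restricted to bonds/angles/torsions internal to the segment
#' @export
extract_segment <- function(s, chain, first, last) {
  if (first > last) stop("segment range has first > last")
  sel <- which(s$atoms$chain == chain & s$atoms$resno >= first &
                 s$atoms$resno <= last)
  have <- sort(unique(s$atoms$resno[sel]))
  want <- first:last
  if (!all(want %in% have))
    stop("residues missing from segment ", chain, ":", first, "-", last, ": ",
         paste(setdiff(want, have), collapse = ", "))
  remap <- rep(NA_integer_, natoms(s))
  remap[sel] <- seq_along(sel)
  restrict <- function(tab, cols) {
    if (is.null(tab) || nrow(tab) == 0L) return(NULL)
    idx <- tab[, cols, drop = FALSE]
    keep <- apply(idx, 1L, function(r) all(!is.na(remap[unlist(r)])))
    out <- tab[keep, , drop = FALSE]
    if (nrow(out) == 0L) return(NULL)
    for (cc in cols) out[[cc]] <- remap[out[[cc]]]
    out
  }
  lidstruct(s$atoms[sel, , drop = FALSE],
            bonds = restrict(s$bonds, c("i", "j")),
            angles = restrict(s$angles, c("i", "j", "k")),
            torsions = restrict(s$torsions, c("i", "j", "k", "l")),
            metadata = s$metadata)
}

# ---- superposition ---------------------------------------------------------

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' selected mobile atoms onto the corresponding reference atoms, pairing
#' atoms by order within the selection.
#'
#' @param mobile,reference `lidstruct` objects
#' @param select optional character vector of atom names defining the fit
#'   selection (e.g. `c("CA")`); `NULL` uses all atoms. Selections must
#'   yield equal-length atom lists.
#' @return list with `R` (3x3 rotation), `t` (translation, applied as
#'   `x %*% t(R) + t`), `rmsd` (Angstrom over the selection) and
#'   `fitted` (the whole mobile structure after the transform)
#' @export
superpose <- function(mobile, reference, select = NULL) {
  pick <- function(s) {
    if (is.null(select)) seq_len(natoms(s))
    else which(s$atoms$name %in% select)
  }
  im <- pick(mobile); ir <- pick(reference)
  if (length(im) == 0L || length(ir) == 0L)
    stop("empty atom selection for superposition")
  if (length(im) != length(ir))
    stop("mismatched selections: ", length(im), " vs ", length(ir), " atoms")
  X <- coords(mobile)[im, , drop = FALSE]
  Y <- coords(reference)[ir, , drop = FALSE]
  fit <- kabsch(X, Y)
  all_new <- sweep(coords(mobile) %*% t(fit$R), 2L, fit$t, `+`)
  list(R = fit$R, t = fit$t, rmsd = fit$rmsd,
       fitted = set_coords(mobile, all_new))
}

#' Kabsch alignment of two paired point sets
#' @param X,Y n x 3 matrices of paired coordinates (X is rotated onto Y)
#' @return list with rotation `R`, translation `t`, and the residual `rmsd`
#' @export
kabsch <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), ncol(X) == 3L, ncol(Y) == 3L)
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2L, cx); Y0 <- sweep(Y, 2L, cy)
  sv <- svd(crossprod(X0, Y0))
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cy - as.vector(R %*% cx)
  Xf <- sweep(X %*% t(R), 2L, t, `+`)
  list(R = R, t = t, rmsd = sqrt(mean(rowSums((Xf - Y)^2))))
}

# minimum distance between two coordinate sets
.min_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  sqrt(max(0, min(d2)))
}
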