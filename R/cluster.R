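# Conformational similarity: atom-class compatibility weighted by Gaussian
# spatial proximity gives per-atom descriptors; conformations are compared
# with the continuous Tanimoto coefficient and grouped by a two-pass leader
# algorithm at a similarity threshold (default 0.85).

#' Atom-class compatibility matrix
#'
#' Symmetric 4 x 4 table over {donor, acceptor, both, nonpolar} in [0, 1]:
#' identical classes are fully compatible (1.0), donor vs acceptor are
#' incompatible (0.0); a dual donor/acceptor atom matches either polar role
#' (1.0), and nonpolar atoms are incompatible with all polar classes.
#' Entries are editable.
#'
#' @return named 4 x 4 numeric matrix
#' @export
compatibility_matrix <- function() {
  cls <- c("donor", "acceptor", "both", "nonpolar")
  m <- diag(4)
  dimnames(m) <- list(cls, cls)
  m["both", "donor"] <- m["donor", "both"] <- 1
  m["both", "acceptor"] <- m["acceptor", "both"] <- 1
  m
}

#' Similarity-metric parameters
#'
#' The Gaussian proximity is g(d) = exp(-d^2 / (2 sigma^2)) for d <= cutoff
#' and 0 beyond, with sigma fixed so that g(cutoff) equals
#' `proximity_threshold`.
#'
#' @param cutoff proximity cutoff distance (A, default 2.5)
#' @param proximity_threshold value of g at the cutoff, in (0, 1)
#'   (default 0.1)
#' @param compat compatibility matrix (see [compatibility_matrix()])
#' @param convention Tanimoto operand pairing: `"self_cross"` (default)
#'   compares the self-descriptor D(A|A) against the cross descriptor
#'   D(A|B), averaged over both directions; `"cross_cross"` compares
#'   D(A|B) against D(B|A)
#' @return list of class `similarity_params`
#' @export
similarity_params <- function(cutoff = 2.5, proximity_threshold = 0.1,
                              compat = compatibility_matrix(),
                              convention = c("self_cross", "cross_cross")) {
  stopifnot(cutoff > 0, proximity_threshold > 0, proximity_threshold < 1)
  structure(list(cutoff = cutoff,
                 proximity_threshold = proximity_threshold,
                 sigma = sqrt(cutoff^2 / (-2 * log(proximity_threshold))),
                 compat = compat,
                 convention = match.arg(convention)),
            class = "similarity_params")
}

#' Gaussian spatial proximity
#' @param d distances (A); vectorized
#' @param params a `similarity_params` list
#' @return g(d) in [0, 1]; exactly 0 beyond the cutoff
#' @export
proximity <- function(d, params = similarity_params()) {
  ifelse(d <= params$cutoff, exp(-d^2 / (2 * params$sigma^2)), 0)
}

# descriptor vector of every atom of A evaluated against molecule B:
# D_i(A|B) = sum_j g(d_ij) * c(class_i, class_j)
.descriptor_vector <- function(conf_a, conf_b, params) {
  ca <- conf_a$atoms$hclass; cb <- conf_b$atoms$hclass
  if (any(is.na(ca)) || any(is.na(cb)))
    stop("unclassified atoms; run assign_atom_classes() first")
  XA <- coords(conf_a); XB <- coords(conf_b)
  d2 <- outer(rowSums(XA^2), rowSums(XB^2), `+`) - 2 * tcrossprod(XA, XB)
  g <- proximity(sqrt(pmax(d2, 0)), params)
  cmp <- params$compat[ca, cb, drop = FALSE]
  unname(rowSums(g * cmp))
}

#' Per-atom similarity descriptor
#'
#' The descriptor of atom `i` of conformation A against conformation B is
#' the sum over all atoms j of B of the Gaussian proximity of the pair
#' times the class compatibility. Conformations must share a coordinate
#' frame (same receptor frame or pre-aligned).
#'
#' @param i atom index in `conf_a`
#' @param conf_a,conf_b classified `lidstruct` conformations
#' @param params a `similarity_params` list
#' @return nonnegative descriptor value
#' @export
atom_descriptor <- function(i, conf_a, conf_b,
                            params = similarity_params()) {
  .descriptor_vector(conf_a, conf_b, params)[i]
}

.tanimoto <- function(x, y) {
  xy <- sum(x * y); den <- sum(x^2) + sum(y^2) - xy
  if (den == 0) return(if (isTRUE(all.equal(x, y))) 1 else 0)
  xy / den
}

#' Tanimoto similarity between two conformations
#'
#' Continuous Tanimoto coefficient over descriptor vectors; symmetric,
#' bounded to [0, 1], and exactly 1 for identical conformations. The
#' default operand convention compares each conformation's self-descriptor
#' D(A|A) with the cross descriptor D(A|B) and averages the two directions;
#' set `convention = "cross_cross"` in the parameters for D(A|B) vs D(B|A).
#'
#' @param conf_a,conf_b classified conformations of the same atom set
#' @param params a `similarity_params` list
#' @return similarity in [0, 1]
#' @export
tanimoto_similarity <- function(conf_a, conf_b,
                                params = similarity_params()) {
  if (natoms(conf_a) != natoms(conf_b))
    stop("conformations have different atom sets; pair them explicitly")
  if (params$convention == "self_cross") {
    saa <- .descriptor_vector(conf_a, conf_a, params)
    sab <- .descriptor_vector(conf_a, conf_b, params)
    sbb <- .descriptor_vector(conf_b, conf_b, params)
    sba <- .descriptor_vector(conf_b, conf_a, params)
    (.tanimoto(saa, sab) + .tanimoto(sbb, sba)) / 2
  } else {
    .tanimoto(.descriptor_vector(conf_a, conf_b, params),
              .descriptor_vector(conf_b, conf_a, params))
  }
}

#' Pairwise similarity matrix of a conformer set
#' @param conformations list of classified `lidstruct`
#' @param params a `similarity_params` list
#' @return symmetric matrix with unit diagonal
#' @export
similarity_matrix <- function(conformations, params = similarity_params()) {
  n <- length(conformations)
  S <- diag(n)
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    S[i, j] <- S[j, i] <- tanimoto_similarity(conformations[[i]],
                                              conformations[[j]], params)
  S
}

# one leader-clustering pass over conformations in the given order;
# `order_idx` are original conformation indices
.leader_pass <- function(S, order_idx, threshold) {
  clusters <- list()
  for (p in order_idx) {
    best_cl <- 0L; best_sim <- -Inf
    for (ci in seq_along(clusters)) {
      sim <- max(S[p, clusters[[ci]]])
      if (sim > best_sim + 1e-15) { best_sim <- sim; best_cl <- ci }
    }
    if (best_cl > 0L && best_sim > threshold) {
      clusters[[best_cl]] <- c(clusters[[best_cl]], p)
    } else {
      clusters[[length(clusters) + 1L]] <- p
    }
  }
  clusters
}

#' Two-pass leader clustering of conformations
#'
#' First pass: each conformation, in input order, joins the cluster holding
#' its most similar existing member if that similarity exceeds the
#' threshold, otherwise it founds a new cluster (and is that cluster's
#' center). The conformations are then reordered from the largest cluster
#' to the smallest and the identical procedure is applied once more.
#' Equally similar clusters are broken toward the earlier-founded cluster.
#'
#' @param conformations list of classified `lidstruct` (>= 1)
#' @param threshold similarity threshold for joining a cluster
#'   (default 0.85)
#' @param params a `similarity_params` list
#' @return object of class `cluster_set`: clusters ordered by size
#'   (descending), each with `members` (original indices, first member =
#'   center) and `center`; plus `labels`, the per-conformation cluster id,
#'   and the `threshold` used
#' @export
cluster_conformations <- function(conformations, threshold = 0.85,
                                  params = similarity_params()) {
  n <- length(conformations)
  if (n == 0L) stop("no conformations to cluster")
  S <- similarity_matrix(conformations, params)
  pass1 <- .leader_pass(S, seq_len(n), threshold)
  sizes <- vapply(pass1, length, integer(1))
  reorder <- unlist(pass1[order(-sizes)])
  pass2 <- .leader_pass(S, reorder, threshold)
  sizes2 <- vapply(pass2, length, integer(1))
  pass2 <- pass2[order(-sizes2)]
  labels <- integer(n)
  for (ci in seq_along(pass2)) labels[pass2[[ci]]] <- ci
  structure(list(
    clusters = lapply(pass2, function(m)
      list(members = m, center = m[1L], size = length(m))),
    labels = labels, threshold = threshold, n = n),
    class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$clusters), "clusters over", x$n,
      "conformations (threshold", x$threshold, ")\n")
  for (ci in seq_along(x$clusters))
    cat(sprintf("  cluster %d: %d members, center %d\n", ci,
                x$clusters[[ci]]$size, x$clusters[[ci]]$center))
  invisible(x)
}
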