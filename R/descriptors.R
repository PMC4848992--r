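# The five physicochemical descriptors of the FXR model: b_rotN, RPC-,
# opr_leadlike, SlogP_VSA2 and ASA.

#' Count rotatable single bonds (b_rotN)
#'
#' A bond counts as rotatable when it is a single, non-aromatic, acyclic
#' bond whose two end atoms are both non-terminal heavy atoms (heavy degree
#' >= 2). Amide C-N bonds are counted: the descriptor is a plain flexibility
#' count, which reproduces the relative orderings observed along the
#' homologous chain-extended members of the series.
#'
#' @param mol a `molgraph` (see [parse_structure()]).
#' @return integer count.
#' @export
count_rotatable_bonds <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0L) return(0L)
  ring <- .ring_bonds(mol)
  heavy <- mol$atoms$element != "H"
  deg <- .heavy_degree(mol)
  single <- b$order == 1          # mol2 'am' bonds were mapped to order 1
  ok <- single & !ring &
    heavy[b$from] & heavy[b$to] &
    deg[b$from] >= 2L & deg[b$to] >= 2L
  sum(ok)
}

#' Relative negative partial charge (RPC-)
#'
#' The charge of the most negative atom divided by the sum of all negative
#' charges: `q_min / sum(q[q < 0])`. Lies in `[0, 1]`; 0 when the molecule
#' carries no negative partial charge.
#'
#' @param x a `conformer` or `molgraph` with assigned partial charges.
#' @return a value in `[0, 1]`.
#' @export
relative_negative_partial_charge <- function(x) {
  q <- x$atoms$charge
  neg <- q[q < 0]
  if (!length(neg)) return(0)
  min(neg) / sum(neg)
}

# reduced Wildman-Crippen-style atomic logP contribution scheme ------------
# Atoms are assigned to coarse classes by element, aromaticity and bonded
# environment; each class carries a published-scale logP increment. The
# scheme is intentionally compact (it covers the chemistry of this series:
# C, H, N, O, S and halogens) and is documented in the methods vignette.

.crippen_class <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  n <- nrow(a)
  adj <- .adjacency(mol)
  nb_el <- lapply(adj, function(v) a$element[v])
  has_double_to <- function(i, el) {
    k <- which((b$from == i | b$to == i) & b$order == 2)
    any(a$element[ifelse(b$from[k] == i, b$to[k], b$from[k])] %in% el)
  }
  cls <- character(n)
  for (i in seq_len(n)) {
    el <- a$element[i]; ar <- a$aromatic[i]; nb <- nb_el[[i]]
    cls[i] <- switch(el,
      H = if (any(nb %in% c("O", "N", "S"))) "H.polar" else "H.c",
      C = if (ar) {
            het <- any(nb %in% c("N", "O", "S", "F", "Cl", "Br", "I"))
            arnb <- sum(a$aromatic[adj[[i]]])
            if (any(nb == "H")) "C.ar.h"
            else if (het) "C.ar.het"
            else if (arnb >= 3) "C.ar.ar"   # biaryl link
            else "C.ar.c"
          } else if (has_double_to(i, c("O", "N", "S"))) "C.carbonyl"
          else if (any(nb == "N") && sum(b$order[b$from == i | b$to == i] == 3)) "C.nitrile"
          else if (has_double_to(i, "C")) "C.sp2"
          else if (any(nb %in% c("N", "O", "S", "F", "Cl", "Br", "I"))) "C.sp3.het"
          else "C.sp3",
      N = if (ar) "N.ar"
          else if (any(vapply(adj[[i]], function(j) {
                   any(b$order[(b$from == j | b$to == j)] == 2) &&
                     a$element[j] == "C" && has_double_to(j, "O")
                 }, TRUE))) "N.amide"
          else if (sum(b$order[b$from == i | b$to == i] == 3)) "N.nitrile"
          else "N.amine",
      O = if (ar) "O.ar"
          else if (has_double_to(i, c("C", "N", "S")) ||
                   any((b$from == i | b$to == i) & b$order == 2)) "O.carbonyl"
          else if (any(nb == "H")) "O.hydroxyl"
          else "O.ether",
      S = "S.thio",
      F = "F", Cl = "Cl", Br = "Br", I = "I",
      "other")
  }
  cls
}

.CRIPPEN_LOGP <- c(
  H.c = 0.1230, H.polar = -0.2677,
  C.sp3 = 0.1441, C.sp3.het = -0.2035, C.sp2 = 0.1551,
  C.carbonyl = -0.2783, C.nitrile = -0.0967,
  C.ar.h = 0.1581, C.ar.c = 0.1360, C.ar.ar = 0.2713, C.ar.het = 0.1893,
  N.amine = -1.0190, N.amide = -0.4458, N.ar = -0.3396, N.nitrile = -0.5188,
  O.hydroxyl = -0.2893, O.ether = -0.0684, O.carbonyl = -0.1526,
  O.ar = 0.1552,
  S.thio = 0.6482,
  F = 0.4202, Cl = 0.6895, Br = 0.8456, I = 0.8857,
  other = 0.0
)

#' Per-atom logP contributions
#'
#' Atomic contributions to the octanol/water partition coefficient using
#' the package's reduced Wildman-Crippen-style class scheme.
#'
#' @param mol a `molgraph`.
#' @return numeric vector, one contribution per atom (hydrogens included).
#' @export
crippen_contribs <- function(mol) {
  unname(.CRIPPEN_LOGP[.crippen_class(mol)])
}

#' Molecular logP (sum of atomic contributions)
#' @param mol a `molgraph`.
#' @return estimated logP.
#' @export
crippen_logp <- function(mol) sum(crippen_contribs(mol))

#' Approximate per-atom van der Waals surface areas
#'
#' Topology-only VSA: each atom starts from its full Bondi sphere area and
#' loses the spherical caps occluded by bonded neighbours placed at
#' idealized bond lengths (sum of covalent radii, clamped into the
#' geometrically valid range).
#'
#' @param mol a `molgraph`.
#' @return numeric vector of areas (Angstrom^2), one per atom.
#' @export
atom_vsa <- function(mol) {
  a <- mol$atoms
  R <- vdw_radius(a$element)
  area <- 4 * pi * R^2
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$from[k]; j <- mol$bonds$to[k]
    ri <- R[i]; rj <- R[j]
    d <- .COVALENT[[a$element[i]]] + .COVALENT[[a$element[j]]]
    d <- min(max(d, abs(ri - rj) + 1e-6), ri + rj)
    hi <- ri - (d^2 + ri^2 - rj^2) / (2 * d)
    hj <- rj - (d^2 + rj^2 - ri^2) / (2 * d)
    if (hi > 0) area[i] <- area[i] - 2 * pi * ri * hi
    if (hj > 0) area[j] <- area[j] - 2 * pi * rj * hj
  }
  pmax(area, 0)
}

#' SlogP_VSA2: surface area of mildly hydrophilic atoms
#'
#' Sum of the approximate accessible van der Waals surface areas
#' ([atom_vsa()]) of atoms whose atomic logP contribution falls in the bin
#' `(-0.2, 0]`.
#'
#' @param mol a `molgraph`.
#' @return area in Angstrom^2 (>= 0).
#' @export
slogp_vsa2 <- function(mol) {
  L <- crippen_contribs(mol)
  v <- atom_vsa(mol)
  sum(v[L > -0.2 & L <= 0])
}

#' Violations of the Oprea lead-like criteria
#'
#' Criteria set (each violated criterion counts one): molecular weight
#' <= 450; logP in `[-3.5, 4.5]`; rings <= 4; rotatable bonds <= 10;
#' H-bond donors (O-H/N-H/S-H) <= 5; H-bond acceptors (N + O count) <= 8.
#'
#' @param mol a `molgraph`.
#' @return integer number of violated criteria.
#' @export
oprea_violations <- function(mol) {
  a <- mol$atoms
  mw <- sum(.elem_mass(a$element))
  logp <- crippen_logp(mol)
  rings <- .ring_count(mol)
  rot <- count_rotatable_bonds(mol)
  adj <- .adjacency(mol)
  donors <- sum(vapply(which(a$element %in% c("N", "O", "S")), function(i)
    any(a$element[adj[[i]]] == "H"), TRUE))
  acceptors <- sum(a$element %in% c("N", "O"))
  sum(mw > 450, logp < -3.5 || logp > 4.5, rings > 4, rot > 10,
      donors > 5, acceptors > 8)
}

#' Oprea lead-likeness indicator (opr_leadlike)
#'
#' 1 if the molecule violates fewer than two of the lead-like criteria
#' (see [oprea_violations()]), otherwise 0.
#'
#' @param mol a `molgraph`.
#' @return 0 or 1.
#' @export
oprea_leadlike <- function(mol) {
  as.integer(oprea_violations(mol) < 2L)
}

# deterministic quasi-uniform sphere points (spherical Fibonacci lattice)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numeric accessible surface area with a water-sized probe: each atom's
#' sphere of radius `r_vdw + probe` is sampled with a fixed deterministic
#' point set and points buried inside any neighbour's expanded sphere are
#' discarded.
#'
#' @param conf a `conformer`.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere points per atom (default 960).
#' @return area in Angstrom^2.
#' @export
accessible_surface_area <- function(conf, probe = 1.4, n_points = 960L) {
  a <- conf$atoms
  n <- nrow(a)
  if (n == 0L) return(0)
  X <- coords(conf)
  R <- a$radius + probe
  sp <- .sphere_points(n_points)
  total <- 0
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(X, 2, X[i, ])^2)
    nbr <- which(d2 < (R[i] + R)^2 & seq_len(n) != i)
    pts <- sweep(sp * R[i], 2, X[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nbr) {
      dj <- sweep(pts, 2, X[j, ])
      acc <- acc & (rowSums(dj^2) >= R[j]^2)
      if (!any(acc)) break
    }
    total <- total + 4 * pi * R[i]^2 * sum(acc) / n_points
  }
  total
}

#' Compute the five-descriptor matrix for an activity table
#'
#' One deterministic 3D conformer is generated per compound
#' ([generate_conformer()]); the graph descriptors (b_rotN, opr_leadlike,
#' SlogP_VSA2) and charge descriptor (RPC-) come from the annotated graph,
#' ASA from the 3D geometry.
#'
#' @param table an `activity_table` (or data frame with `id` and
#'   `structure` columns).
#' @param seed integer seed forwarded to conformer generation.
#' @param charge_model partial charge model (see [parse_structure()]).
#' @return a data frame with row names = compound ids and columns `b_rotN`,
#'   `RPC_neg`, `opr_leadlike`, `SlogP_VSA2`, `ASA`.
#' @export
compute_descriptor_matrix <- function(table, seed = 1L,
                                      charge_model = "gasteiger") {
  n <- nrow(table)
  out <- data.frame(b_rotN = integer(n), RPC_neg = numeric(n),
                    opr_leadlike = integer(n), SlogP_VSA2 = numeric(n),
                    ASA = numeric(n), row.names = table$id)
  mols <- tryCatch(
    parse_structures(table$structure, gen3d = TRUE, seed = seed,
                     charge_model = charge_model),
    error = function(e) stop("descriptor computation failed: ",
                             conditionMessage(e)))
  for (k in seq_len(n)) {
    mol <- mols[[k]]
    conf <- as_conformer(mol)
    out$b_rotN[k] <- count_rotatable_bonds(mol)
    out$RPC_neg[k] <- relative_negative_partial_charge(mol)
    out$opr_leadlike[k] <- oprea_leadlike(mol)
    out$SlogP_VSA2[k] <- slogp_vsa2(mol)
    out$ASA[k] <- accessible_surface_area(conf)
  }
  out
}

#' Write / read a descriptor matrix as CSV
#' @param desc descriptor matrix (data frame with compound-id row names).
#' @param path file path.
#' @return invisibly `path`, or the matrix for the reader.
#' @export
write_descriptor_matrix <- function(desc, path) {
  utils::write.csv(cbind(id = rownames(desc), desc), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_matrix
#' @export
read_descriptor_matrix <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(id = "character"))
  rownames(d) <- d$id
  d$id <- NULL
  d
}
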