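# Molecule handling: SMILES/SDF input via an RDKit helper, molecular
# graphs, 3D conformers, rigid alignment and maximum common substructure
# mapping.

.python_path <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("python not found on the PATH; ",
                       "it is required for structure handling")
  p
}

.molbuild_script <- function() {
  system.file("python", "molbuild.py", package = "anthraqsar",
              mustWork = TRUE)
}

# molecule cache so repeated descriptor/field calls do not re-run the helper
.mol_cache <- new.env(parent = emptyenv())

.mol_key <- function(structure, gen3d, seed, k, charge_model) {
  paste(charge_model, gen3d, if (gen3d) seed else 0, if (gen3d) k else 0,
        structure, sep = "|")
}

# run the structure helper on a batch of jobs; returns the raw result list
.molbuild <- function(jobs) {
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)))
  jsonlite::write_json(jobs, fin, auto_unbox = TRUE, digits = NA)
  status <- system2(.python_path(),
                    c(shQuote(.molbuild_script()), shQuote(fin),
                      shQuote(fout)))
  if (status != 0 || !file.exists(fout))
    stop("structure helper failed (exit status ", status, ")")
  jsonlite::read_json(fout)
}

.result_to_molgraph <- function(res, smiles) {
  if (!isTRUE(res$ok))
    stop("structure could not be processed: '", smiles, "' (",
         res$error, ")")
  am <- do.call(rbind, lapply(res$atoms, function(a)
    data.frame(element = a[[1]], x = a[[2]], y = a[[3]], z = a[[4]],
               charge = a[[5]], aromatic = as.logical(a[[6]]),
               stringsAsFactors = FALSE)))
  bm <- if (length(res$bonds))
    do.call(rbind, lapply(res$bonds, function(b)
      data.frame(from = as.integer(b[[1]]), to = as.integer(b[[2]]),
                 order = b[[3]], aromatic = as.logical(b[[4]]))))
  else data.frame(from = integer(0), to = integer(0), order = numeric(0),
                  aromatic = logical(0))
  structure(list(atoms = am, bonds = bm, smiles = smiles),
            class = "molgraph")
}

#' Parse structures into annotated molecular graphs
#'
#' Converts SMILES strings to molecular graphs through the packaged RDKit
#' helper: elements, aromaticity, bonds with orders, Gasteiger-type partial
#' charges and, optionally, one 3D conformer per molecule (the lowest-MMFF-
#' energy geometry among `k` seeded distance-geometry embeddings;
#' deterministic for fixed `(structure, seed, k)`).
#'
#' `parse_structure()` handles a single string; `parse_structures()` runs a
#' whole batch through one helper process, which is much faster for tables
#' of compounds. Results are cached for the session.
#'
#' @param structure a SMILES string describing one connected molecule.
#' @param structures character vector of SMILES strings.
#' @param gen3d logical; build 3D coordinates.
#' @param seed integer seed for the distance-geometry embeddings.
#' @param k number of embeddings to minimize (default 10).
#' @param charge_model `"gasteiger"` (default) or `"mmff94"`.
#' @return an object of class `molgraph`: a list with `atoms` (data frame
#'   with columns `element`, `x`, `y`, `z`, `charge`, `aromatic`), `bonds`
#'   (data frame with `from`, `to`, `order` — 1.5 for aromatic bonds — and
#'   `aromatic`) and `smiles`. The batch version returns a list of these.
#' @export
parse_structure <- function(structure, gen3d = FALSE, seed = 1L, k = 10L,
                            charge_model = "gasteiger") {
  parse_structures(structure, gen3d = gen3d, seed = seed, k = k,
                   charge_model = charge_model)[[1L]]
}

#' @rdname parse_structure
#' @export
parse_structures <- function(structures, gen3d = FALSE, seed = 1L, k = 10L,
                             charge_model = "gasteiger") {
  stopifnot(is.character(structures), all(nzchar(structures)))
  keys <- unname(vapply(structures, .mol_key, "", gen3d, seed, k,
                        charge_model))
  todo <- which(!vapply(keys, function(kk)
    !is.null(.mol_cache[[kk]]), TRUE))
  if (length(todo)) {
    jobs <- lapply(unname(todo), function(i) list(
      id = as.character(i), smiles = structures[i], gen3d = gen3d,
      seed = seed, k = k, charge_model = charge_model))
    res <- .molbuild(jobs)
    for (j in seq_along(todo)) {
      i <- todo[j]
      .mol_cache[[keys[i]]] <- .result_to_molgraph(res[[j]], structures[i])
    }
  }
  lapply(keys, function(kk) .mol_cache[[kk]])
}

.n_components <- function(n, bonds) {
  if (n == 0L) return(0L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(bonds))) {
    ri <- find(bonds$from[k]); rj <- find(bonds$to[k])
    if (ri != rj) parent[ri] <- rj
  }
  length(unique(vapply(seq_len(n), find, 1L)))
}

# adjacency list over all atoms
.adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$from[k]; j <- mol$bonds$to[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# logical vector over bonds: TRUE if the bond lies on a cycle (not a bridge)
.ring_bonds <- function(mol) {
  n <- nrow(mol$atoms); m <- nrow(mol$bonds)
  if (m == 0L) return(logical(0))
  adj <- vector("list", n)
  for (k in seq_len(m)) {
    i <- mol$bonds$from[k]; j <- mol$bonds$to[k]
    adj[[i]] <- rbind(adj[[i]], c(j, k)); adj[[j]] <- rbind(adj[[j]], c(i, k))
  }
  disc <- low <- integer(n); timer <- 0L
  is_bridge <- logical(m)
  # iterative DFS (avoid recursion limits)
  for (start in seq_len(n)) {
    if (disc[start] != 0L) next
    stack <- list(c(start, 0L, 1L))  # node, incoming bond id, next-neighbor ptr
    timer <- timer + 1L; disc[start] <- low[start] <- timer
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      v <- fr[1]; inb <- fr[2]; ptr <- fr[3]
      nb <- adj[[v]]
      if (is.null(nb) || ptr > nrow(nb)) {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          pf <- stack[[length(stack)]]
          u <- pf[1]
          low[u] <- min(low[u], low[v])
          if (low[v] > disc[u]) is_bridge[inb] <- TRUE
        }
        next
      }
      stack[[length(stack)]][3] <- ptr + 1L
      w <- nb[ptr, 1]; bid <- nb[ptr, 2]
      if (bid == inb) next
      if (disc[w] == 0L) {
        timer <- timer + 1L; disc[w] <- low[w] <- timer
        stack[[length(stack) + 1L]] <- c(w, bid, 1L)
      } else {
        low[v] <- min(low[v], disc[w])
      }
    }
  }
  !is_bridge
}

# number of smallest rings (cyclomatic number; molecules here are connected)
.ring_count <- function(mol) {
  nrow(mol$bonds) - nrow(mol$atoms) + .n_components(nrow(mol$atoms), mol$bonds)
}

.heavy_degree <- function(mol) {
  n <- nrow(mol$atoms)
  deg <- integer(n)
  heavy <- mol$atoms$element != "H"
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$from[k]; j <- mol$bonds$to[k]
    if (heavy[j]) deg[i] <- deg[i] + 1L
    if (heavy[i]) deg[j] <- deg[j] + 1L
  }
  deg
}

# conformers ----------------------------------------------------------------

#' Construct a conformer from raw atom data
#'
#' A conformer is a 3D point-atom representation: element, Cartesian
#' coordinates (Angstrom), partial charge (elementary charges) and van der
#' Waals radius. Used both for real molecules and for the synthetic
#' point-atom "molecules" of [simulate_field_dataset()].
#'
#' @param element character vector of element symbols.
#' @param xyz numeric matrix (n x 3) of coordinates in Angstrom.
#' @param charge numeric vector of partial charges (default 0).
#' @param radius optional numeric vector of vdW radii; defaults to the Bondi
#'   radius of each element.
#' @return an object of class `conformer` wrapping the atom table.
#' @export
conformer <- function(element, xyz, charge = 0, radius = NULL) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  stopifnot(length(element) == n, all(is.finite(xyz)))
  if (is.null(radius)) radius <- vdw_radius(element)
  stopifnot(all(radius > 0))
  atoms <- data.frame(element = element, x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], charge = rep_len(charge, n),
                      radius = rep_len(radius, n), stringsAsFactors = FALSE)
  structure(list(atoms = atoms), class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat("conformer:", nrow(x$atoms), "atoms, net charge",
      round(sum(x$atoms$charge), 3), "\n")
  invisible(x)
}

coords <- function(conf) as.matrix(conf$atoms[, c("x", "y", "z")])

#' Convert a molecular graph with 3D coordinates to a conformer
#' @param mol a `molgraph` with 3D coordinates.
#' @return a `conformer`.
#' @export
as_conformer <- function(mol) {
  conformer(mol$atoms$element,
            as.matrix(mol$atoms[, c("x", "y", "z")]),
            charge = mol$atoms$charge)
}

#' Generate a 3D conformer for a structure
#'
#' Embeds `k` distance-geometry conformers with a seeded ETKDG protocol,
#' refines each with the MMFF94 force field, keeps the lowest-energy
#' geometry and assigns partial charges. Deterministic: calling this twice
#' with the same `(structure, seed)` yields identical coordinates.
#'
#' @param structure a SMILES string.
#' @param seed integer RNG seed for the embeddings.
#' @param k number of embeddings (default 10).
#' @param charge_model partial charge model (see [parse_structure()]).
#' @return a `conformer`.
#' @export
generate_conformer <- function(structure, seed = 1L, k = 10L,
                               charge_model = "gasteiger") {
  mol <- parse_structure(structure, gen3d = TRUE, seed = seed, k = k,
                         charge_model = charge_model)
  as_conformer(mol)
}

#' Read conformers from an SDF file
#'
#' Thin wrapper over ChemmineR's SDF reader; charges are assigned with Open
#' Babel from the connection table.
#'
#' @param path an SDF file with 3D coordinates.
#' @return a list of `conformer` objects, named by SDF molecule id.
#' @export
read_sdf_conformers <- function(path) {
  stopifnot(file.exists(path))
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("reading SDF requires the ChemmineR package")
  sdfs <- ChemmineR::read.SDFset(path)
  out <- lapply(seq_along(sdfs), function(i) {
    ab <- ChemmineR::atomblock(sdfs[[i]])
    el <- gsub("_.*$", "", rownames(ab))
    conformer(el, ab[, 1:3, drop = FALSE])
  })
  names(out) <- ChemmineR::sdfid(sdfs)
  out
}

#' Write conformers to an SDF (V2000) file
#'
#' @param conformers a `conformer` or list of conformers.
#' @param path output file path.
#' @param ids molecule names; defaults to list names or an index.
#' @return invisibly, `path`.
#' @export
write_sdf_conformers <- function(conformers, path, ids = NULL) {
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  if (is.null(ids)) ids <- names(conformers)
  if (is.null(ids)) ids <- as.character(seq_along(conformers))
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_along(conformers)) {
    a <- conformers[[k]]$atoms
    writeLines(c(ids[k], "  anthraqsar", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), 0L), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       a$x, a$y, a$z, a$element), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

# alignment -----------------------------------------------------------------

#' Rigidly align a conformer onto a template (Kabsch superposition)
#'
#' Finds the least-squares rotation and translation mapping the `mapping`
#' atoms of `conf` onto the corresponding atoms of `template`, applies it to
#' all atoms of `conf`, and reports the minimal RMSD over the mapped atoms.
#'
#' @param conf,template `conformer` objects.
#' @param mapping two-column integer matrix of (conf atom index, template
#'   atom index) pairs; at least 3 non-collinear pairs.
#' @return a list with `conformer` (the transformed copy) and `rmsd`
#'   (Angstrom).
#' @export
align_to_template <- function(conf, template, mapping) {
  mapping <- matrix(as.integer(mapping), ncol = 2)
  if (nrow(mapping) < 3L)
    stop("alignment needs at least 3 mapped atom pairs")
  P <- coords(conf)[mapping[, 1], , drop = FALSE]      # moving
  Q <- coords(template)[mapping[, 2], , drop = FALSE]  # fixed
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  if (qr(P0)$rank < 2L) stop("mapped atoms are collinear; alignment is underdetermined")
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  X <- coords(conf)
  Xn <- sweep(sweep(X, 2, cp) %*% t(R), 2, cq, `+`)
  out <- conf
  out$atoms$x <- Xn[, 1]; out$atoms$y <- Xn[, 2]; out$atoms$z <- Xn[, 3]
  Pn <- Xn[mapping[, 1], , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((Pn - Q)^2)))
  list(conformer = out, rmsd = rmsd)
}

# maximum common substructure -----------------------------------------------

#' Map the common scaffold between a molecule and a template
#'
#' Finds a maximum common connected substructure over the heavy atoms of the
#' two molecular graphs by anchored backtracking search (atoms must match by
#' element; bonds between already-mapped atoms must agree in both
#' molecules). Deterministic: candidate pairs are explored in canonical
#' (lowest index) order, so ties always resolve the same way. A node budget
#' bounds the search; when it is exhausted the best mapping found so far is
#' returned.
#'
#' @param mol,template `molgraph` objects (see [parse_structure()]).
#' @param budget maximum number of search-tree extensions.
#' @return integer matrix with columns `mol` and `template` (atom indices of
#'   the mapped scaffold).
#' @export
common_scaffold_mapping <- function(mol, template, budget = 20000L) {
  hm <- which(mol$atoms$element != "H")
  ht <- which(template$atoms$element != "H")
  adj_m <- .adjacency(mol); adj_t <- .adjacency(template)
  # heavy-atom neighbours only
  nm <- lapply(adj_m, function(v) sort(v[mol$atoms$element[v] != "H"]))
  nt <- lapply(adj_t, function(v) sort(v[template$atoms$element[v] != "H"]))
  el_m <- mol$atoms$element; el_t <- template$atoms$element
  ar_m <- mol$atoms$aromatic; ar_t <- template$atoms$aromatic
  best <- matrix(integer(0), ncol = 2)
  nodes <- 0L
  # map_m[i] = matched template atom for mol atom i (0 = unmatched,
  # -1 = excluded on this branch)
  map_m <- integer(length(el_m)); map_t <- integer(length(el_t))
  compatible <- function(i, j) {
    el_m[i] == el_t[j] && ar_m[i] == ar_t[j]
  }
  consistent <- function(i, j) {
    # every mapped neighbour of i must map to a neighbour of j and vice versa
    for (x in nm[[i]]) {
      if (map_m[x] > 0L && !(map_m[x] %in% nt[[j]])) return(FALSE)
    }
    for (y in nt[[j]]) {
      if (map_t[y] > 0L && !(map_t[y] %in% nm[[i]])) return(FALSE)
    }
    TRUE
  }
  max_possible <- min(length(hm), length(ht))
  # frontiers (candidate atoms adjacent to the mapped core) are carried
  # down the recursion and updated incrementally
  extend <- function(size, frontier_m, frontier_t) {
    if (size > nrow(best)) {
      pairs <- which(map_m > 0L)
      best <<- cbind(mol = pairs, template = map_m[pairs])
    }
    if (nodes > budget || nrow(best) >= max_possible) return()
    frontier_m <- frontier_m[map_m[frontier_m] == 0L]
    if (!length(frontier_m)) return()
    i <- frontier_m[1L]
    cand_j <- frontier_t[map_t[frontier_t] == 0L]
    for (j in cand_j) {
      if (!compatible(i, j) || !consistent(i, j)) next
      nodes <<- nodes + 1L
      map_m[i] <<- j; map_t[j] <<- i
      extend(size + 1L,
             unique(c(frontier_m[-1L], nm[[i]])),
             unique(c(frontier_t, nt[[j]])))
      map_m[i] <<- 0L; map_t[j] <<- 0L
      if (nodes > budget || nrow(best) >= max_possible) return()
    }
    # also consider leaving atom i unmatched on this branch
    nodes <<- nodes + 1L
    map_m[i] <<- -1L
    extend(size, frontier_m[-1L], frontier_t)
    map_m[i] <<- 0L
  }
  # anchor on the rarest element first for a small branching factor
  anchor_order <- hm[order(table(el_m)[el_m[hm]], hm)]
  for (i0 in anchor_order) {
    for (j0 in ht) {
      if (!compatible(i0, j0)) next
      map_m[] <- 0L; map_t[] <- 0L
      map_m[i0] <- j0; map_t[j0] <- i0
      extend(1L, nm[[i0]], nt[[j0]])
      if (nrow(best) >= max_possible || nodes > budget) break
    }
    if (nrow(best) >= max_possible || nodes > budget) break
  }
  map_m[] <- 0L; map_t[] <- 0L
  if (nrow(best) < 3L)
    stop("common substructure smaller than 3 atoms; cannot derive a mapping")
  best[order(best[, 1]), , drop = FALSE]
}
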