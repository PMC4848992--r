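# CoMFA-style 3D-QSAR: lattice over aligned conformers, steric
# (Lennard-Jones) and electrostatic (Coulomb) probe fields, column
# filtering, NIPALS PLS, field contributions and contour grids.

#' Build a lattice enclosing a set of aligned conformers
#'
#' The minimal axis-aligned grid with the given spacing whose box extends
#' at least `margin` Angstrom beyond every atom on all six faces.
#'
#' @param conformers a `conformer` or list of conformers.
#' @param spacing grid spacing in Angstrom (default 2.0).
#' @param margin minimal clearance beyond the molecules (default 4.0).
#' @return an object of class `lattice`: list with `origin` (length-3),
#'   `spacing`, `dims` (nx, ny, nz).
#' @export
build_lattice <- function(conformers, spacing = 2.0, margin = 4.0) {
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  if (!length(conformers)) stop("need at least one conformer")
  stopifnot(spacing > 0, margin >= 0)
  XYZ <- do.call(rbind, lapply(conformers, coords))
  lo <- apply(XYZ, 2, min) - margin
  hi <- apply(XYZ, 2, max) + margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  structure(list(origin = lo, spacing = spacing, dims = dims),
            class = "lattice")
}

#' @export
print.lattice <- function(x, ...) {
  cat(sprintf("lattice %d x %d x %d, spacing %.2f A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Cartesian coordinates of all lattice points
#'
#' Points are ordered x-fastest (index `ix + nx*(iy + ny*iz)`, 0-based).
#'
#' @param lattice a `lattice`.
#' @return numeric matrix (n_points x 3).
#' @export
lattice_points <- function(lattice) {
  g <- expand.grid(ix = seq_len(lattice$dims[1]) - 1L,
                   iy = seq_len(lattice$dims[2]) - 1L,
                   iz = seq_len(lattice$dims[3]) - 1L)
  sweep(as.matrix(g) * lattice$spacing, 2, lattice$origin, `+`)
}

.lj_lookup <- function(elements) {
  idx <- match(elements, .LJ_PARAMS$element)
  if (anyNA(idx)) {
    idx[is.na(idx)] <- match("C", .LJ_PARAMS$element)
  }
  .LJ_PARAMS[idx, ]
}

#' Steric (Lennard-Jones) probe field
#'
#' Interaction energy of an sp3-carbon probe with the molecule at every
#' lattice point: `E = sum_i eps_i [ (rmin_i/r)^12 - 2 (rmin_i/r)^6 ]`
#' with Lorentz-Berthelot-style combination (`rmin_i = r_atom + r_probe`,
#' `eps_i = sqrt(eps_atom * eps_probe)`). Values are truncated at
#' `+cutoff`; a grid point coinciding with a nucleus scores `+cutoff`.
#' Atoms with a custom `radius` (synthetic point atoms) use that radius as
#' their Lennard-Jones `r_min`.
#'
#' @param conf a `conformer`.
#' @param lattice a `lattice`.
#' @param probe_radius probe vdW radius in Angstrom (default 1.52).
#' @param probe_epsilon probe well depth in kcal/mol (default 0.107).
#' @param cutoff truncation energy in kcal/mol (default 30).
#' @return numeric vector, one energy (kcal/mol) per lattice point.
#' @export
steric_field <- function(conf, lattice, probe_radius = 1.52,
                         probe_epsilon = 0.107, cutoff = 30) {
  a <- conf$atoms
  if (!nrow(a)) stop("empty conformer")
  P <- lattice_points(lattice)
  lj <- .lj_lookup(a$element)
  rmin <- a$radius + probe_radius          # per-atom combined r_min
  eps <- sqrt(lj$epsilon * probe_epsilon)
  E <- numeric(nrow(P))
  X <- coords(conf)
  for (i in seq_len(nrow(a))) {
    d <- sqrt(rowSums(sweep(P, 2, X[i, ])^2))
    zero <- d < 1e-8
    d[zero] <- 1e-8
    s6 <- (rmin[i] / d)^6
    E <- E + eps[i] * (s6^2 - 2 * s6)
    E[zero] <- cutoff
  }
  pmin(E, cutoff)
}

#' Electrostatic (Coulomb) probe field
#'
#' Energy of a unit positive probe: `E = sum_i 332.0636 q_i q_probe /
#' (eps(r) r)` with the distance-dependent dielectric `eps(r) = r`, i.e. a
#' `1/r^2` falloff. Values are truncated to `[-cutoff, +cutoff]`. Points
#' buried inside any atom's van der Waals sphere are flagged in the
#' `"buried"` attribute; [field_block()] replaces them by the across-
#' molecule mean of the unburied values of the same column (two-pass
#' convention).
#'
#' @param conf a `conformer` with assigned charges.
#' @param lattice a `lattice`.
#' @param probe_charge probe charge in elementary units (default +1).
#' @param cutoff truncation energy in kcal/mol (default 30).
#' @return numeric vector per lattice point with attribute `buried`
#'   (logical).
#' @export
electrostatic_field <- function(conf, lattice, probe_charge = 1,
                                cutoff = 30) {
  a <- conf$atoms
  if (!nrow(a)) stop("empty conformer")
  P <- lattice_points(lattice)
  E <- numeric(nrow(P))
  buried <- logical(nrow(P))
  X <- coords(conf)
  for (i in seq_len(nrow(a))) {
    d2 <- rowSums(sweep(P, 2, X[i, ])^2)
    buried <- buried | d2 < a$radius[i]^2
    E <- E + 332.0636 * a$charge[i] * probe_charge / pmax(d2, 1e-12)
  }
  E <- pmin(pmax(E, -cutoff), cutoff)
  attr(E, "buried") <- buried
  E
}

#' Assemble the molecule-by-column field matrix
#'
#' Evaluates the steric and electrostatic fields of every conformer on a
#' common lattice and stacks them into the n_molecules x (2 n_points)
#' matrix (steric block first). Buried electrostatic entries are replaced
#' column-wise by the mean of the unburied values (or 0 when a column is
#' buried for every molecule).
#'
#' @param conformers list of aligned `conformer`s.
#' @param lattice a `lattice`; built from the conformers when NULL.
#' @param cutoff truncation energy (kcal/mol).
#' @param ... forwarded to [steric_field()].
#' @return a numeric matrix of class `field_block` with attributes
#'   `lattice`, `field` (`"steric"`/`"electrostatic"` per column), `point`
#'   (lattice point index per column), `retained` (all columns initially).
#' @export
field_block <- function(conformers, lattice = NULL, cutoff = 30, ...) {
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  n <- length(conformers)
  if (n < 1L) stop("need at least one conformer")
  if (is.null(lattice)) lattice <- build_lattice(conformers)
  np <- prod(lattice$dims)
  S <- matrix(0, n, np); El <- matrix(0, n, np); B <- matrix(FALSE, n, np)
  for (k in seq_len(n)) {
    S[k, ] <- steric_field(conformers[[k]], lattice, cutoff = cutoff, ...)
    e <- electrostatic_field(conformers[[k]], lattice, cutoff = cutoff)
    El[k, ] <- e
    B[k, ] <- attr(e, "buried")
  }
  # two-pass replacement of buried electrostatic values
  for (j in which(colSums(B) > 0L)) {
    out <- !B[, j]
    El[B[, j], j] <- if (any(out)) mean(El[out, j]) else 0
  }
  M <- cbind(S, El)
  colnames(M) <- c(paste0("S", seq_len(np)), paste0("E", seq_len(np)))
  structure(M, class = c("field_block", "matrix"),
            lattice = lattice,
            field = rep(c("steric", "electrostatic"), each = np),
            point = rep(seq_len(np), 2L),
            retained = seq_len(2L * np))
}

#' Drop low-variation field columns (minimum-sigma filtering)
#'
#' Retains only columns whose standard deviation across molecules is at
#' least `sigma_min` kcal/mol; the CoMFA "minimum sigma" column filter.
#'
#' @param block a `field_block`.
#' @param sigma_min threshold in kcal/mol (default 6.0).
#' @return the `field_block` with its `retained` attribute restricted
#'   (column order preserved; the matrix itself is unchanged).
#' @export
column_filter <- function(block, sigma_min = 6.0) {
  if (nrow(block) < 2L) stop("need at least two molecules to filter columns")
  sds <- apply(unclass(block), 2, stats::sd)
  keep <- which(sds >= sigma_min)
  if (!length(keep))
    stop("all columns filtered out; lower sigma_min (largest column sd is ",
         signif(max(sds), 3), ")")
  attr(block, "retained") <- keep
  block
}

# NIPALS PLS core on already centered/scaled data, single response
.nipals_pls <- function(Xc, yc, ncomp) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, ncomp); Pl <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    tt <- drop(Xc %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) { ncomp <- a - 1L; break }
    pl <- drop(crossprod(Xc, tt)) / tt2
    qa <- sum(yc * tt) / tt2
    Xc <- Xc - tcrossprod(tt, pl)
    yc <- yc - qa * tt
    W[, a] <- w; Pl[, a] <- pl; Tm[, a] <- tt; q[a] <- qa
  }
  if (ncomp == 0L) stop("no PLS component could be extracted")
  W <- W[, seq_len(ncomp), drop = FALSE]
  Pl <- Pl[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  beta <- drop(W %*% solve(crossprod(Pl, W), q))
  list(beta = beta, ncomp = ncomp, scores = Tm[, seq_len(ncomp), drop = FALSE])
}

# centering/scaling info for a field block restricted to retained columns
.block_prep <- function(block, block_scale) {
  keep <- attr(block, "retained")
  X <- unclass(block)[, keep, drop = FALSE]
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  w <- rep(1, ncol(Xc))
  if (block_scale) {
    fld <- attr(block, "field")[keep]
    for (f in unique(fld)) {
      v <- Xc[, fld == f, drop = FALSE]
      s <- sqrt(mean(v^2))
      if (s > 1e-12) w[fld == f] <- 1 / s
    }
  }
  list(keep = keep, mu = mu, w = w)
}

#' Fit a PLS model to a field block (NIPALS)
#'
#' Mean-centers the retained columns, optionally applies CoMFA-style block
#' scaling (each field block weighted by the inverse of its overall
#' standard deviation so neither field dominates), extracts `n_components`
#' NIPALS components, and back-transforms the coefficients to the original
#' energy units. Field contributions are the summed |coefficient x column
#' sd| mass per block, normalized to 1.
#'
#' @param block a (possibly filtered) `field_block`.
#' @param y numeric activities, one per molecule.
#' @param n_components number of latent components.
#' @param block_scale logical; apply block scaling (default TRUE).
#' @return an object of class `pls_field_model`: coefficients (named by
#'   retained column), intercept, fitted values, `r2`, `contributions`
#'   (steric, electrostatic fractions), `n_components`.
#' @export
fit_pls <- function(block, y, n_components, block_scale = TRUE) {
  stopifnot(nrow(block) == length(y))
  if (stats::sd(y) == 0) stop("zero-variance response")
  prep <- .block_prep(block, block_scale)
  X <- unclass(block)[, prep$keep, drop = FALSE]
  n <- nrow(X)
  if (n_components > min(n - 1L, ncol(X)))
    stop("n_components exceeds min(n - 1, retained columns)")
  Xs <- sweep(sweep(X, 2, prep$mu), 2, prep$w, `*`)
  ym <- mean(y)
  fit <- .nipals_pls(Xs, y - ym, n_components)
  beta <- fit$beta * prep$w               # back to original units
  intercept <- ym - sum(beta * prep$mu)
  fitted <- drop(X %*% beta) + intercept
  sse <- sum((y - fitted)^2); sst <- sum((y - ym)^2)
  sds <- apply(X, 2, stats::sd)
  fld <- attr(block, "field")[prep$keep]
  mass <- abs(beta) * sds
  contr <- c(steric = sum(mass[fld == "steric"]),
             electrostatic = sum(mass[fld == "electrostatic"]))
  contr <- if (sum(contr) > 0) contr / sum(contr) else c(steric = 0.5,
                                                         electrostatic = 0.5)
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    intercept = intercept,
    n_components = fit$ncomp,
    fitted = fitted,
    r2 = 1 - sse / sst,
    rmse = sqrt(sse / n),
    contributions = contr,
    retained = prep$keep,
    block_scale = block_scale
  ), class = "pls_field_model")
}

#' @export
print.pls_field_model <- function(x, ...) {
  cat(sprintf("PLS field model: %d components, %d retained columns\n",
              x$n_components, length(x$coefficients)))
  cat(sprintf("R2 = %.3f  RMSE = %.3f  contributions: steric %.1f%% / electrostatic %.1f%%\n",
              x$r2, x$rmse, 100 * x$contributions[["steric"]],
              100 * x$contributions[["electrostatic"]]))
  invisible(x)
}

#' Predict activities for new field rows
#' @param object a `pls_field_model`.
#' @param newblock a `field_block` evaluated on the same lattice (the
#'   model's retained columns are extracted by index).
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.pls_field_model <- function(object, newblock, ...) {
  X <- unclass(newblock)[, object$retained, drop = FALSE]
  drop(X %*% object$coefficients) + object$intercept
}

#' Choose the number of PLS components by leave-one-out Q2
#'
#' Evaluates LOO Q2 for 1..`max_components` components (column filtering is
#' applied once, up front, not inside each fold) and returns the argmax;
#' ties resolve to the smallest component count.
#'
#' @param block a (filtered) `field_block`.
#' @param y numeric activities.
#' @param max_components largest count to try (default 10).
#' @param block_scale logical, see [fit_pls()].
#' @return a list with `n_components`, `q2` (at the optimum) and `q2_all`.
#' @export
select_components <- function(block, y, max_components = 10L,
                              block_scale = TRUE) {
  stopifnot(max_components >= 1L)
  n <- nrow(block)
  keep <- attr(block, "retained")
  amax <- min(max_components, n - 2L, length(keep))
  sst <- sum((y - mean(y))^2)
  q2s <- rep(NA_real_, amax)
  for (a in seq_len(amax)) {
    press <- 0
    ok <- TRUE
    for (i in seq_len(n)) {
      sub <- unclass(block)[-i, , drop = FALSE]
      attr(sub, "field") <- attr(block, "field")
      attr(sub, "retained") <- keep
      m <- tryCatch(fit_pls(sub, y[-i], a, block_scale = block_scale),
                    error = function(e) NULL)
      if (is.null(m)) { ok <- FALSE; break }
      pred <- drop(unclass(block)[i, keep] %*% m$coefficients) + m$intercept
      press <- press + (y[i] - pred)^2
    }
    if (ok) q2s[a] <- 1 - press / sst
  }
  if (all(is.na(q2s))) stop("no component count could be evaluated")
  best <- which.max(q2s)   # first maximum = smallest count on ties
  list(n_components = best, q2 = q2s[best], q2_all = q2s)
}

#' STDEV*COEFF contour grid of a fitted field model
#'
#' Per lattice point and field, the PLS coefficient times the column's
#' across-molecule standard deviation (filtered-out columns are 0). The
#' favored / disfavored iso-levels are the stated percentiles of the
#' positive and negative value distributions of each field.
#'
#' @param model a `pls_field_model`.
#' @param block the `field_block` the model was fitted on.
#' @param favored_level percentile (percent) of positive values for the
#'   favored contour (default 80).
#' @param disfavored_level percentile of negative values for the
#'   disfavored contour (default 20).
#' @return an object of class `contour_grid`: list with `lattice`,
#'   `steric`, `electrostatic` (numeric vectors per point) and `levels`
#'   (named thresholds per field).
#' @export
contour_grid <- function(model, block, favored_level = 80,
                         disfavored_level = 20) {
  stopifnot(0 < disfavored_level, disfavored_level < favored_level,
            favored_level < 100)
  lattice <- attr(block, "lattice")
  np <- prod(lattice$dims)
  vals <- numeric(2L * np)
  sds <- apply(unclass(block)[, model$retained, drop = FALSE], 2, stats::sd)
  vals[model$retained] <- model$coefficients * sds
  fld <- attr(block, "field")
  out <- list(lattice = lattice,
              steric = vals[fld == "steric"],
              electrostatic = vals[fld == "electrostatic"])
  lev <- function(v) {
    pos <- v[v > 0]; neg <- v[v < 0]
    c(favored = if (length(pos)) unname(stats::quantile(pos, favored_level / 100))
                else NA_real_,
      disfavored = if (length(neg)) unname(stats::quantile(neg, disfavored_level / 100))
                   else NA_real_)
  }
  out$levels <- list(steric = lev(out$steric),
                     electrostatic = lev(out$electrostatic))
  class(out) <- "contour_grid"
  out
}

#' Export a contour grid as OpenDX volumetric text files
#'
#' Writes `<prefix>_steric.dx` and `<prefix>_electrostatic.dx` on the
#' model's lattice (regular grid, x-fastest ordering re-mapped to the
#' OpenDX z-fastest convention).
#'
#' @param grid a `contour_grid`.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_contour_dx <- function(grid, prefix) {
  l <- grid$lattice
  nx <- l$dims[1]; ny <- l$dims[2]; nz <- l$dims[3]
  paths <- character(2)
  for (k in 1:2) {
    field <- c("steric", "electrostatic")[k]
    v <- grid[[field]]
    # our ordering is x-fastest; OpenDX expects z-fastest
    arr <- array(v, dim = c(nx, ny, nz))
    vz <- as.vector(aperm(arr, c(3, 2, 1)))
    path <- paste0(prefix, "_", field, ".dx")
    con <- file(path, "w")
    writeLines(c(
      sprintf("object 1 class gridpositions counts %d %d %d", nx, ny, nz),
      sprintf("origin %.4f %.4f %.4f", l$origin[1], l$origin[2], l$origin[3]),
      sprintf("delta %.4f 0 0", l$spacing),
      sprintf("delta 0 %.4f 0", l$spacing),
      sprintf("delta 0 0 %.4f", l$spacing),
      sprintf("object 2 class gridconnections counts %d %d %d", nx, ny, nz),
      sprintf("object 3 class array type double rank 0 items %d data follows",
              length(vz))), con)
    writeLines(apply(matrix(c(vz, rep(NA, (3 - length(vz) %% 3) %% 3)),
                            nrow = 3), 2,
                     function(r) paste(format(r[!is.na(r)], digits = 6),
                                       collapse = " ")), con)
    writeLines('attribute "dep" string "positions"', con)
    close(con)
    paths[k] <- path
  }
  invisible(paths)
}
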