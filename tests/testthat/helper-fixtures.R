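# Shared fixtures, computed lazily once per test run (parse results are
# additionally cached inside the package for the session).

.fixture_env <- new.env(parent = emptyenv())

fixture_table <- function() {
  if (is.null(.fixture_env$table)) .fixture_env$table <- aad_compounds()
  .fixture_env$table
}

# small toy conformers ------------------------------------------------------

# four non-coplanar points with distinct elements, handy for alignment tests
toy_conformer <- function() {
  conformer(c("C", "N", "O", "S"),
            rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.2, 0), c(0.3, 0.4, 1.1)),
            charge = c(0.1, -0.2, -0.3, 0.4))
}

rigid_motion <- function(conf, angles = c(0.3, -0.7, 1.1),
                         shift = c(1, -2, 3)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  X <- as.matrix(conf$atoms[, c("x", "y", "z")]) %*% t(R)
  X <- sweep(X, 2, shift, `+`)
  out <- conf
  out$atoms$x <- X[, 1]; out$atoms$y <- X[, 2]; out$atoms$z <- X[, 3]
  out
}

# brute-force rigid superposition oracle: dense rotation grid (Euler angles)
# plus centroid matching; adequate to ~1e-3 A on tiny point sets when the
# optimum is refined with a fine local grid
brute_force_rmsd <- function(P, Q, coarse = 24L) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  rot <- function(a, b, g) {
    ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
    cg <- cos(g); sg <- sin(g)
    rbind(c(cb * cg, sa * sb * cg - ca * sg, ca * sb * cg + sa * sg),
          c(cb * sg, sa * sb * sg + ca * cg, ca * sb * sg - sa * cg),
          c(-sb, sa * cb, ca * cb))
  }
  eval_rmsd <- function(a, b, g) {
    D <- P0 %*% t(rot(a, b, g)) - Q0
    sqrt(mean(rowSums(D^2)))
  }
  best <- c(0, 0, 0); bv <- Inf
  gr <- seq(0, 2 * pi, length.out = coarse + 1L)[-(coarse + 1L)]
  gb <- seq(-pi / 2, pi / 2, length.out = coarse)
  for (a in gr) for (b in gb) for (g in gr) {
    v <- eval_rmsd(a, b, g)
    if (v < bv) { bv <- v; best <- c(a, b, g) }
  }
  # local refinement
  step <- diff(gr[1:2])
  for (iter in 1:40) {
    improved <- FALSE
    for (d in seq_len(3)) for (s in c(-step, step)) {
      cand <- best; cand[d] <- cand[d] + s
      v <- eval_rmsd(cand[1], cand[2], cand[3])
      if (v < bv) { bv <- v; best <- cand; improved <- TRUE }
    }
    if (!improved) step <- step / 2
    if (step < 1e-6) break
  }
  bv
}
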