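# Independent oracles and small builders shared across tests. These
# deliberately avoid the package's own computational paths.

# LOOCV accuracy of a brute-force 1-nearest-neighbour classifier on
# standardized features: the model-free yardstick for planted-signal
# recoverability.
nn_loocv_accuracy <- function(tab) {
  X <- scale(as.matrix(tab[setdiff(names(tab), c("site_id", "label"))]))
  y <- tab$label
  n <- nrow(X)
  correct <- 0
  for (i in seq_len(n)) {
    d <- colSums((t(X[-i, , drop = FALSE]) - X[i, ])^2)
    correct <- correct + (y[-i][which.min(d)] == y[i])
  }
  correct / n
}

# Dense latitude-longitude quadrature of solvent-accessible area, an
# integration scheme unrelated to the golden-spiral point test used by the
# implementation. xyz: n x 3 centers; rad: expanded radii (vdw + probe).
sasa_quadrature_oracle <- function(xyz, rad, n_theta = 180, n_phi = 360) {
  n <- nrow(xyz)
  theta <- (seq_len(n_theta) - 0.5) * pi / n_theta
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  grid <- expand.grid(theta = theta, phi = phi)
  dirs <- cbind(sin(grid$theta) * cos(grid$phi),
                sin(grid$theta) * sin(grid$phi),
                cos(grid$theta))
  w <- sin(grid$theta)  # quadrature weight per point
  wsum <- sum(w)
  vapply(seq_len(n), function(i) {
    p <- dirs * rad[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    exposed <- rep(TRUE, nrow(p))
    for (j in seq_len(n)) {
      if (j == i) next
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & (dj >= rad[j]^2)
    }
    4 * pi * rad[i]^2 * sum(w[exposed]) / wsum
  }, numeric(1))
}

# Write a bare atom table (CA-style pseudo-atoms by default) as a PDB and
# read it back as a structure.
structure_from_atoms <- function(df) {
  defaults <- data.frame(type = "ATOM", chain = "A", resno = seq_len(nrow(df)),
                         insert = "", resid = "ALA", elety = "CA",
                         elesy = "C", o = 1, b = 0)
  for (col in names(defaults))
    if (is.null(df[[col]])) df[[col]] <- defaults[[col]]
  f <- tempfile(fileext = ".pdb")
  write_pdb_atoms(df, f)
  read_structure(f)
}

# Apply a rigid-body rotation + translation to a structure and return the
# transformed structure (re-read from disk, so file precision applies).
transform_structure <- function(s, angle = 0.7, axis = c(1, 2, 3),
                                shift = c(5, -3, 11)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  at <- rbind(cbind(s$atoms, type = "ATOM"),
              if (nrow(s$het)) cbind(s$het, type = "HETATM"))
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at$x <- xyz[, 1] + shift[1]
  at$y <- xyz[, 2] + shift[2]
  at$z <- xyz[, 3] + shift[3]
  f <- tempfile(fileext = ".pdb")
  write_pdb_atoms(at, f)
  read_structure(f)
}

default_params <- function() {
  list(learning_rate = 0.1, min_samples_split = 4, n_estimators = 100)
}

# one replicate of the noisy-curve Khalf recovery experiment
fit_hill_curve_khalf <- function(seed) {
  hc <- make_hill_curve(fixture_spec(seed = seed), vmax = 2, khalf = 1,
                        h = 2, n_points = 20, noise_sd = 0.05 * 2)
  fit_hill(hc$x, hc$y)$khalf
}
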