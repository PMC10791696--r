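# Deterministic synthetic fixtures: ideal-geometry toy structures, planted
# labeled site tables, and noisy Hill curves. Pure functions of (spec, seed)
# so every other module is testable without external data.

# --- ideal backbone construction (NeRF internal-coordinate placement) ------

# Place atom D given A-B-C, bond length |CD|, angle B-C-D (deg) and
# dihedral A-B-C-D (deg).
.place_atom <- function(a, b, c, length, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(dih),
          length * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Canonical backbone geometry (Engh-Huber averages).
.BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.5, omega = 180)

#' Build an ideal poly-alanine backbone from phi/psi angles
#'
#' Constructs N, CA, C, O coordinates for `length(phi)` residues using
#' canonical bond lengths and angles, with the given backbone dihedrals and
#' omega fixed at 180 degrees. The classic alpha-helix is phi = -57,
#' psi = -47.
#'
#' @param phi,psi numeric vectors (degrees), one value per residue.
#' @return data.frame: resno, elety, x, y, z.
#' @export
build_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(n >= 1, length(psi) == n)
  # Seed atoms for residue 1.
  N1 <- c(0, 0, 0)
  CA1 <- c(.BB$n_ca, 0, 0)
  ang <- .BB$ang_n_ca_c * pi / 180
  C1 <- CA1 + .BB$ca_c * c(-cos(ang), sin(ang), 0)
  coords <- list()
  coords[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in seq_len(n)) {
    if (i > 1) {
      prev <- coords[[i - 1]]
      Ni <- .place_atom(prev$N, prev$CA, prev$C, .BB$c_n, .BB$ang_ca_c_n,
                        psi[i - 1])
      CAi <- .place_atom(prev$CA, prev$C, Ni, .BB$n_ca, .BB$ang_c_n_ca,
                         .BB$omega)
      Ci <- .place_atom(prev$C, Ni, CAi, .BB$ca_c, .BB$ang_n_ca_c, phi[i])
      coords[[i]] <- list(N = Ni, CA = CAi, C = Ci)
    }
  }
  # Carbonyl oxygens: anti to the next residue's N (dihedral psi - 180).
  rows <- list()
  for (i in seq_len(n)) {
    r <- coords[[i]]
    O <- .place_atom(r$N, r$CA, r$C, .BB$c_o, .BB$ang_ca_c_o,
                     psi[i] - 180)
    rows[[i]] <- data.frame(
      resno = i,
      elety = c("N", "CA", "C", "O"),
      x = c(r$N[1], r$CA[1], r$C[1], O[1]),
      y = c(r$N[2], r$CA[2], r$C[2], O[2]),
      z = c(r$N[3], r$CA[3], r$C[3], O[3]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fixture specification
#'
#' @param seed integer RNG seed; identical specs give byte-identical output.
#' @param helices integer vector of helix lengths (residues).
#' @param loops integer vector of loop lengths between consecutive helices;
#'   must have `length(helices) - 1` entries, all >= 1.
#' @param burial_shell if TRUE, surround the mid-point of the first loop
#'   with a shell of occluding pseudo-atoms (for burial/SASA tests).
#' @param active_site_offset 3-vector (Angstrom) placing a ligand
#'   pseudo-atom relative to the first residue's CA, or NULL for none.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 0, helices = c(12, 12), loops = 5,
                         burial_shell = FALSE, active_site_offset = NULL) {
  if (length(helices) >= 2) {
    if (length(loops) != length(helices) - 1)
      stop("spec error: need ", length(helices) - 1, " loop length(s)")
    if (any(loops < 1))
      stop("spec error: zero-length loop between helices is infeasible")
  }
  structure(list(seed = as.integer(seed), helices = as.integer(helices),
                 loops = as.integer(loops), burial_shell = burial_shell,
                 active_site_offset = active_site_offset),
            class = "fixture_spec")
}

#' Build a toy helix-loop-helix structure and write it as PDB
#'
#' Constructs an ideal-geometry poly-alanine chain alternating helical
#' (phi = -57, psi = -47) and extended loop (phi = -120, psi = 120)
#' segments, optionally with an occluder shell (chain X) for burial tests
#' and a ligand pseudo-atom (HETATM, resid LIG) marking a designated
#' active site.
#'
#' @param spec a [fixture_spec()].
#' @param path output PDB path; default a tempfile.
#' @return invisibly, a list with `path` and the `insrtr_structure`
#'   re-read from it.
#' @export
make_toy_structure <- function(spec, path = tempfile(fileext = ".pdb")) {
  stopifnot(inherits(spec, "fixture_spec"))
  seg_len <- integer(0)
  seg_ss <- character(0)
  for (i in seq_along(spec$helices)) {
    seg_len <- c(seg_len, spec$helices[i])
    seg_ss <- c(seg_ss, "H")
    if (i < length(spec$helices)) {
      seg_len <- c(seg_len, spec$loops[i])
      seg_ss <- c(seg_ss, "C")
    }
  }
  ss <- rep(seg_ss, seg_len)
  phi <- ifelse(ss == "H", -57, -120)
  psi <- ifelse(ss == "H", -47, 120)
  bb <- build_backbone(phi, psi)

  atoms <- data.frame(
    type = "ATOM", chain = "A", resno = bb$resno, insert = "",
    resid = "ALA", elety = bb$elety, elesy = substr(bb$elety, 1, 1),
    x = bb$x, y = bb$y, z = bb$z, o = 1, b = 10,
    stringsAsFactors = FALSE)

  if (spec$burial_shell) {
    # Shell of carbon pseudo-atoms around the first loop's mid residue CA.
    loop_mid <- spec$helices[1] + ceiling(spec$loops[1] / 2)
    ca <- bb[bb$resno == loop_mid & bb$elety == "CA", c("x", "y", "z")]
    pts <- .sphere_points(200) * 5.5  # 5.5 A shell radius
    shell <- data.frame(
      type = "ATOM", chain = "X", resno = seq_len(nrow(pts)), insert = "",
      resid = "OCC", elety = "C1", elesy = "C",
      x = pts[, 1] + ca$x, y = pts[, 2] + ca$y, z = pts[, 3] + ca$z,
      o = 1, b = 0, stringsAsFactors = FALSE)
    atoms <- rbind(atoms, shell)
  }
  if (!is.null(spec$active_site_offset)) {
    ca1 <- bb[bb$resno == 1 & bb$elety == "CA", c("x", "y", "z")]
    off <- spec$active_site_offset
    atoms <- rbind(atoms, data.frame(
      type = "HETATM", chain = "L", resno = 1, insert = "", resid = "LIG",
      elety = "O1", elesy = "O", x = ca1$x + off[1], y = ca1$y + off[2],
      z = ca1$z + off[3], o = 1, b = 0, stringsAsFactors = FALSE))
  }
  write_pdb_atoms(atoms, path)
  invisible(list(path = path, structure = read_structure(path)))
}

# Deterministic golden-section spiral points on the unit sphere.
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Write an atom table as fixed-column PDB text
#'
#' Minimal writer for the fixture generators (and tests): emits
#' ATOM/HETATM records with 3-decimal coordinates and an END record.
#'
#' @param atoms data.frame with columns x, y, z plus optionally type,
#'   chain, resno, insert, resid, elety, elesy, o, b (sensible defaults are
#'   filled in; `element` is accepted as an alias for `elesy`).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pdb_atoms <- function(atoms, path) {
  n <- nrow(atoms)
  if (is.null(atoms$elesy) && !is.null(atoms$element))
    atoms$elesy <- atoms$element
  defaults <- list(type = "ATOM", chain = "A", resno = seq_len(n),
                   insert = "", resid = "ALA", elety = "CA", elesy = "C",
                   o = 1, b = 0)
  for (col in names(defaults))
    if (is.null(atoms[[col]])) atoms[[col]] <- defaults[[col]]
  fmt <- "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  name4 <- ifelse(nchar(atoms$elety) >= 4, atoms$elety,
                  paste0(" ", atoms$elety))
  lines <- sprintf(fmt, atoms$type, seq_len(nrow(atoms)), name4, "",
                   atoms$resid, atoms$chain, atoms$resno,
                   ifelse(atoms$insert == "", " ", atoms$insert),
                   atoms$x, atoms$y, atoms$z, atoms$o, atoms$b,
                   atoms$elesy)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# --- planted labeled site tables ------------------------------------------

# Default planted model: two informative features (the loop SASA and the
# active-site distance analogues) on standardized scales. Labels are
# deterministic by default (sign of the linear predictor), the regime in
# which a planted signal is fully recoverable at n ~ 47; `label_noise =
# "bernoulli"` draws labels from logistic probabilities instead.
.SITE_FEATURES <- c("loop_sasa", "dist_active_site_nm", "loop_length",
                    "anchor_gap_nm", "bfactor_mean_loop")

#' Generate a planted labeled insertion-site table
#'
#' Draws descriptor vectors from fixed distributions (log-normal loop SASA,
#' uniform active-site distances 0.5-5 nm, integer loop lengths 3-15) and
#' assigns binary permissive labels from a planted linear model on
#' standardized features. Mirrors the scale of the training data the
#' site classifier is designed for (47 labeled sites, two dominant
#' features).
#'
#' @param spec a [fixture_spec()] (only `seed` is used).
#' @param n number of rows (>= 4); default 47.
#' @param weights named numeric vector of planted coefficients on
#'   standardized features; defaults put weight +4 on `loop_sasa` and -4 on
#'   `dist_active_site_nm`.
#' @param intercept planted intercept.
#' @param label_noise "deterministic" (label = indicator of positive linear
#'   predictor) or "bernoulli" (label ~ Bernoulli(logistic(predictor))).
#' @param margin minimum |linear predictor| a row must reach (deterministic
#'   labels only); rows inside the margin are redrawn, so the planted
#'   classes are separated. The default was fixed by requiring that a
#'   brute-force 1-nearest-neighbour classifier recovers the planted
#'   labels with LOOCV accuracy above 0.9; it is the generator's
#'   signal-strength dial, not a tunable of the classifier under test.
#' @return data.frame with site_id, the feature columns and a 0/1 `label`,
#'   of class `labeled_site_table`.
#' @export
make_labeled_sites <- function(spec, n = 47,
                               weights = c(loop_sasa = 4,
                                           dist_active_site_nm = -4),
                               intercept = 0,
                               label_noise = c("deterministic", "bernoulli"),
                               margin = 2) {
  stopifnot(inherits(spec, "fixture_spec"))
  label_noise <- match.arg(label_noise)
  if (n < 4) stop("need n >= 4")
  if (!all(names(weights) %in% .SITE_FEATURES))
    stop("unknown planted feature(s): ",
         paste(setdiff(names(weights), .SITE_FEATURES), collapse = ", "))
  set.seed(spec$seed)
  # theoretical feature moments, so standardization does not depend on the
  # drawn sample and per-row margin rejection stays a pure sampler
  mu <- c(loop_sasa = 300 * exp(0.125), dist_active_site_nm = 2.75,
          loop_length = 9, anchor_gap_nm = 0.95, bfactor_mean_loop = 40)
  sg <- c(loop_sasa = 300 * exp(0.125) * sqrt(exp(0.25) - 1),
          dist_active_site_nm = 4.5 / sqrt(12),
          loop_length = sqrt((13^2 - 1) / 12),
          anchor_gap_nm = 1.1 / sqrt(12), bfactor_mean_loop = 10)
  draw <- function(m) data.frame(
    loop_sasa = rlnorm2(m, meanlog = log(300), sdlog = 0.5),
    dist_active_site_nm = runif(m, 0.5, 5),
    loop_length = sample(3:15, m, replace = TRUE),
    anchor_gap_nm = runif(m, 0.4, 1.5),
    bfactor_mean_loop = rnorm(m, 40, 10))
  linpred <- function(tab) {
    z <- sweep(sweep(as.matrix(tab[.SITE_FEATURES]), 2, mu), 2, sg, "/")
    intercept + as.numeric(z[, names(weights), drop = FALSE] %*% weights)
  }
  for (try in seq_len(1000)) {
    tab <- draw(n)
    eta <- linpred(tab)
    if (label_noise == "deterministic" && margin > 0) {
      # per-row rejection: redraw rows whose planted predictor sits inside
      # the margin band
      for (redraw in seq_len(1000)) {
        bad <- abs(eta) < margin
        if (!any(bad)) break
        tab[bad, ] <- draw(sum(bad))
        eta <- linpred(tab)
      }
      if (any(abs(eta) < margin)) next
    }
    lab <- if (label_noise == "deterministic") as.integer(eta > 0)
           else rbinom(n, 1, plogis(eta))
    if (length(unique(lab)) == 2) {
      tab <- cbind(site_id = sprintf("s%03d", seq_len(n)), tab,
                   stringsAsFactors = FALSE)
      tab$label <- lab
      class(tab) <- c("labeled_site_table", class(tab))
      return(tab)
    }
  }
  stop("spec error: planted model produced a single class (or no row set ",
       "clearing the margin) after 1000 draws")
}

# log-normal helper kept explicit so the generator reads as its distribution
rlnorm2 <- function(n, meanlog, sdlog) exp(rnorm(n, meanlog, sdlog))

# --- noisy Hill curves -----------------------------------------------------

#' Generate a (noisy) Hill dose-response series
#'
#' Evaluates Y = Vmax * X^h / (Khalf^h + X^h) on a log-spaced grid and adds
#' Gaussian noise.
#'
#' @param spec a [fixture_spec()] (only `seed` is used).
#' @param vmax,khalf,h Hill parameters (khalf > 0, h > 0).
#' @param n_points grid size; log-spaced over `xlim`.
#' @param xlim concentration range, default `khalf * c(0.01, 100)`.
#' @param noise_sd Gaussian noise standard deviation (same units as Y).
#' @return data.frame with x and y.
#' @export
make_hill_curve <- function(spec, vmax = 1, khalf = 1, h = 1,
                            n_points = 20, xlim = NULL, noise_sd = 0) {
  stopifnot(inherits(spec, "fixture_spec"), khalf > 0, h > 0, n_points >= 2)
  if (is.null(xlim)) xlim <- khalf * c(0.01, 100)
  set.seed(spec$seed)
  x <- exp(seq(log(xlim[1]), log(xlim[2]), length.out = n_points))
  y <- vmax * x^h / (khalf^h + x^h)
  if (noise_sd > 0) y <- y + rnorm(n_points, 0, noise_sd)
  data.frame(x = x, y = y)
}
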