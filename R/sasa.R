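# Shrake-Rupley solvent-accessible surface area with a deterministic
# golden-section spiral point set, so values are bit-stable across runs.

# Theoretical maximum accessible areas per residue type (A^2), Tien et al.
# 2013, used to normalize to relative SASA.
.MAX_SASA <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174
)

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the van der Waals surface by testing a
#' deterministic set of points on each atom's expanded sphere
#' (radius = vdW + probe) against all neighbouring expanded spheres. The
#' per-atom SASA is the exposed point fraction times the expanded sphere
#' area; per-residue values are sums over the residue's atoms.
#'
#' @param s an `insrtr_structure`.
#' @param probe_radius probe radius in Angstrom (water = 1.4).
#' @param n_points points per atom sphere (>= 100); the point set is a
#'   golden-section spiral, identical across runs.
#' @param include_het include heteroatom (ligand) records as occluders and
#'   targets.
#' @return list with `atom` (numeric per atom row of `s$atoms`), `residue`
#'   (named by res_key), and `total`, all in Angstrom^2.
#' @export
shrake_rupley_sasa <- function(s, probe_radius = 1.4, n_points = 960,
                               include_het = FALSE) {
  stopifnot(probe_radius > 0, n_points >= 100)
  a <- s$atoms
  if (include_het && nrow(s$het) > 0) a <- rbind(a, s$het)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- a$vdw + probe_radius
  n <- nrow(xyz)
  pts <- .sphere_points(n_points)
  area <- numeric(n)
  # neighbour prune via pairwise distances in blocks
  for (i in seq_len(n)) {
    d2 <- rowSums((xyz - matrix(xyz[i, ], n, 3, byrow = TRUE))^2)
    nb <- which(d2 < (rad[i] + rad)^2 & seq_len(n) != i)
    p <- pts * rad[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & (dj >= rad[j]^2)
    }
    area[i] <- 4 * pi * rad[i]^2 * mean(exposed)
  }
  res <- tapply(area[seq_len(nrow(s$atoms))],
                factor(s$atoms$res_key, levels = unique(s$atoms$res_key)),
                sum)
  list(atom = area[seq_len(nrow(s$atoms))],
       residue = setNames(as.numeric(res), names(res)),
       total = sum(area[seq_len(nrow(s$atoms))]),
       probe_radius = probe_radius, n_points = n_points)
}

#' Relative per-residue SASA
#'
#' Residue SASA divided by the residue type's theoretical maximum
#' accessible area. Residue types outside the standard twenty get NA.
#'
#' @param s an `insrtr_structure`.
#' @param sasa result of [shrake_rupley_sasa()].
#' @return named numeric vector (res_key), values typically in [0, 1].
#' @export
relative_sasa <- function(s, sasa) {
  rt <- residue_table(s)
  mx <- .MAX_SASA[rt$resid]
  setNames(as.numeric(sasa$residue[rt$res_key] / mx), rt$res_key)
}
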