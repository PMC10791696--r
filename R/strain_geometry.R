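# Mechanical model of the switch: when the regulatory peptide binds, the
# inserted peptide folds into an alpha-helix whose end-to-end span (~4 nm
# for a 27-residue coiled-coil peptide) must be accommodated by the loop.
# The mismatch between that span and the native anchor gap, minus the slack
# contributed by flexible linkers, decides whether CC formation strains the
# host fold.

#' End-to-end span of an ideal alpha-helix
#'
#' Axial distance between the first and last residue of an n-residue
#' helix at the canonical rise per residue.
#'
#' @param n number of residues (>= 1).
#' @param rise helical rise per residue in Angstrom (canonical 1.5).
#' @return span in nm: (n - 1) * rise / 10.
#' @export
helix_end_to_end <- function(n, rise = 1.5) {
  if (any(n < 1)) stop("domain error: helix length must be >= 1 residue")
  (n - 1) * rise / 10
}

#' Measure the CA-CA span of an explicitly built ideal helix
#'
#' Builds an n-residue poly-alanine helix from canonical backbone dihedrals
#' (phi = -57, psi = -47) and returns the CA(1)-CA(n) distance. Serves as a
#' geometric cross-check of [helix_end_to_end()].
#'
#' @param n number of residues (>= 2).
#' @return CA(1)-CA(n) distance in nm.
#' @export
ideal_helix_span <- function(n) {
  stopifnot(n >= 2)
  bb <- build_backbone(rep(-57, n), rep(-47, n))
  ca <- as.matrix(bb[bb$elety == "CA", c("x", "y", "z")])
  sqrt(sum((ca[n, ] - ca[1, ])^2)) / 10
}

#' Insert geometry parameters
#'
#' @param insert_length inserted CC peptide length in residues (default 27,
#'   the length whose helical span matches the ~4 nm coiled coil).
#' @param linker_length flexible linker residues per side (default 5).
#' @param helix_rise helical rise, Angstrom per residue.
#' @param linker_extension maximum extension of a flexible linker residue,
#'   nm per residue (extended-chain 0.35).
#' @return a list of class `insert_geometry`.
#' @export
insert_geometry <- function(insert_length = 27, linker_length = 5,
                            helix_rise = 1.5, linker_extension = 0.35) {
  stopifnot(insert_length >= 1, linker_length >= 0, helix_rise > 0)
  structure(list(insert_length = insert_length,
                 linker_length = linker_length,
                 helix_rise = helix_rise,
                 linker_extension = linker_extension),
            class = "insert_geometry")
}

#' Strain report for insertion sites
#'
#' For each site, Delta = helical span of the insert minus the native
#' anchor gap (nm): the extension the folded insert tries to impose on the
#' loop. Linkers add slack (2 sides x linker_length x max extension);
#' when slack >= Delta the insert is mechanically decoupled from the host
#' (long linkers are known to weaken inhibition), otherwise coupled.
#'
#' @param sites an `insertion_sites` data.frame (needs `anchor_gap_nm`), or
#'   a numeric vector of anchor gaps in nm.
#' @param geom an [insert_geometry()].
#' @return data.frame: anchor_gap_nm, helix_span_nm, delta_nm, slack_nm,
#'   strain_class ("coupled"/"decoupled").
#' @export
site_strain <- function(sites, geom = insert_geometry()) {
  gaps <- if (is.numeric(sites)) sites else sites$anchor_gap_nm
  span <- helix_end_to_end(geom$insert_length, geom$helix_rise)
  delta <- span - gaps
  slack <- 2 * geom$linker_length * geom$linker_extension
  out <- data.frame(
    anchor_gap_nm = gaps,
    helix_span_nm = span,
    delta_nm = delta,
    slack_nm = slack,
    strain_class = ifelse(slack >= delta, "decoupled", "coupled"),
    stringsAsFactors = FALSE)
  if (!is.numeric(sites)) out <- cbind(sites, out[-1])
  out
}
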