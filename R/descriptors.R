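# Per-site descriptor vectors for the insertion-site classifier. The two
# features that dominate prediction in practice -- the solvent-accessible
# surface of the loop and the distance to the active site -- are always
# present; the schema is pluggable so users can extend it.

#' Default descriptor schema
#'
#' @return data.frame with columns name, unit, aggregation; the mandatory
#'   entries `loop_sasa` and `dist_active_site_nm` are always included.
#' @export
default_descriptor_schema <- function() {
  data.frame(
    name = c("loop_sasa", "loop_sasa_mean", "site_rel_sasa",
             "dist_active_site_nm", "anchor_gap_nm", "loop_length",
             "pos_in_loop", "contact_density", "bfactor_mean_loop",
             "ss_context"),
    unit = c("A^2", "A^2", "fraction", "nm", "nm", "residues", "fraction",
             "count", "A^2", "indicator"),
    aggregation = c("loop", "loop", "site", "site", "site", "loop", "site",
                    "site", "loop", "site"),
    stringsAsFactors = FALSE)
}

#' Compute the descriptor vector for one candidate site
#'
#' @param s an `insrtr_structure`.
#' @param site one row of an `insertion_sites` table.
#' @param active_site residue selectors of the functional site.
#' @param sasa result of [shrake_rupley_sasa()] (computed if NULL).
#' @param ss labels from [assign_secondary_structure()] (computed if NULL).
#' @param schema descriptor schema data.frame; entries outside the default
#'   set raise a configuration error.
#' @return named numeric vector over `schema$name` with attribute
#'   `missing_mask` (logical; TRUE where a value could not be computed and
#'   was set NA).
#' @export
compute_site_descriptors <- function(s, site, active_site, sasa = NULL,
                                     ss = NULL,
                                     schema = default_descriptor_schema()) {
  known <- default_descriptor_schema()$name
  bad <- setdiff(schema$name, known)
  if (length(bad))
    stop("configuration error: unknown schema entr",
         if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "))
  if (is.null(sasa)) sasa <- shrake_rupley_sasa(s)
  if (is.null(ss)) ss <- assign_secondary_structure(s)
  rt <- residue_table(s)
  as_keys <- .resolve_selector(s, active_site)
  as_xyz <- .ca_coords(s, as_keys)

  loop_keys <- .loop_keys(s, site$loop_id)
  res_sasa <- sasa$residue
  rel <- relative_sasa(s, sasa)

  vals <- setNames(rep(NA_real_, length(known)), known)
  vals["loop_sasa"] <- sum(res_sasa[loop_keys])
  vals["loop_sasa_mean"] <- mean(res_sasa[loop_keys])
  vals["site_rel_sasa"] <- rel[site$after_key]
  p <- tryCatch(.ca_coords(s, c(site$after_key, site$next_key)),
                error = function(e) NULL)
  if (!is.null(p)) {
    dmat <- sqrt(pmax(outer(rowSums(p^2), rowSums(as_xyz^2), "+") -
                        2 * p %*% t(as_xyz), 0)) / 10
    vals["dist_active_site_nm"] <- min(dmat)
    ca_all <- as.matrix(rt[rt$has_ca, c("ca_x", "ca_y", "ca_z")])
    d_all <- sqrt(rowSums((t(t(ca_all) - p[1, ]))^2)) / 10
    vals["contact_density"] <- sum(d_all <= 1.0) - 1
  }
  vals["anchor_gap_nm"] <- site$anchor_gap_nm
  vals["loop_length"] <- site$loop_length
  pos <- match(site$after_key, loop_keys)
  vals["pos_in_loop"] <- if (length(loop_keys) == 1) 0.5 else
    (pos - 0.5) / length(loop_keys)
  b <- s$atoms$b[s$atoms$res_key %in% loop_keys]
  vals["bfactor_mean_loop"] <- mean(b)
  # flanking secondary-structure context: 1 if either loop anchor is helix
  i0 <- match(loop_keys[1], rt$res_key)
  i1 <- match(loop_keys[length(loop_keys)], rt$res_key)
  flank <- c(if (i0 > 1 && rt$chain[i0 - 1] == rt$chain[i0]) ss[i0 - 1],
             if (i1 < nrow(rt) && rt$chain[i1 + 1] == rt$chain[i1]) ss[i1 + 1])
  vals["ss_context"] <- as.numeric(any(flank == "H"))

  out <- vals[schema$name]
  attr(out, "missing_mask") <- is.na(out)
  out
}

#' Descriptor table for a list of candidate sites
#'
#' @inheritParams compute_site_descriptors
#' @param sites an `insertion_sites` data.frame.
#' @return data.frame: site_id (chain:after_resno), one column per schema
#'   entry.
#' @export
compute_descriptor_table <- function(s, sites, active_site, sasa = NULL,
                                     ss = NULL,
                                     schema = default_descriptor_schema()) {
  if (is.null(sasa)) sasa <- shrake_rupley_sasa(s)
  if (is.null(ss)) ss <- assign_secondary_structure(s)
  rows <- lapply(seq_len(nrow(sites)), function(i)
    compute_site_descriptors(s, sites[i, ], active_site, sasa, ss, schema))
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(site_id = paste(sites$chain, sites$after_resno, sep = ":"),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
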