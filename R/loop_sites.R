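# Secondary-structure assignment (simplified Kabsch-Sander: helix, bridge,
# coil), loop enumeration, candidate insertion sites, and the heuristic
# admissibility rules (a)-(e) for coiled-coil switch insertion.

# Backbone coordinates per residue as a list of matrices keyed by res_key.
.backbone_coords <- function(s) {
  a <- s$atoms
  bb <- a[a$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  keys <- unique(s$atoms$res_key)
  out <- lapply(keys, function(k) {
    sub <- bb[bb$res_key == k, , drop = FALSE]
    m <- matrix(NA_real_, 4, 3, dimnames = list(c("N", "CA", "C", "O"),
                                                c("x", "y", "z")))
    idx <- match(c("N", "CA", "C", "O"), sub$elety)
    ok <- !is.na(idx)
    m[ok, ] <- as.matrix(sub[idx[ok], c("x", "y", "z")])
    m
  })
  names(out) <- keys
  out
}

# Kabsch-Sander electrostatic hydrogen-bond energy between donor residue i
# (backbone NH) and acceptor residue j (backbone C=O), kcal/mol. The amide
# hydrogen is placed 1.0 A from N along the C=O bond direction of the
# preceding residue. Returns +Inf when atoms are missing or placement is
# impossible (chain start, proline donors have no NH and are excluded by
# the caller).
.hbond_energy <- function(bb, i, j, prev_of_i) {
  di <- bb[[i]]; aj <- bb[[j]]
  if (anyNA(di["N", ]) || anyNA(aj["C", ]) || anyNA(aj["O", ])) return(Inf)
  if (is.na(prev_of_i)) return(Inf)
  pv <- bb[[prev_of_i]]
  if (anyNA(pv["C", ]) || anyNA(pv["O", ])) return(Inf)
  co <- pv["C", ] - pv["O", ]
  co <- co / sqrt(sum(co^2))
  H <- di["N", ] + co
  N <- di["N", ]; C <- aj["C", ]; O <- aj["O", ]
  r_on <- sqrt(sum((O - N)^2))
  r_ch <- sqrt(sum((C - H)^2))
  r_oh <- sqrt(sum((O - H)^2))
  r_cn <- sqrt(sum((C - N)^2))
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5) return(-Inf)  # clash guard
  0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

#' Assign secondary structure (helix / strand / coil)
#'
#' Hydrogen-bond based assignment in the Kabsch-Sander style, simplified to
#' three states. A backbone H-bond is declared between donor NH(i) and
#' acceptor CO(j) when the electrostatic energy
#' E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol falls
#' below -0.5, with the amide hydrogen placed geometrically from the
#' preceding peptide unit. A residue is labeled H when it participates in
#' an (i, i+4) helical bond (as donor or acceptor), E when it sits in an
#' isolated or laddered bridge, otherwise C. Residues with incomplete
#' backbones are labeled C.
#'
#' @param s an `insrtr_structure`.
#' @param energy_cutoff H-bond energy threshold (kcal/mol), default -0.5.
#' @return named character vector of labels in {H, E, C}, one per residue,
#'   named by residue key; attribute `table` holds a per-residue data.frame.
#' @export
assign_secondary_structure <- function(s, energy_cutoff = -0.5) {
  rt <- residue_table(s)
  n <- nrow(rt)
  bb <- .backbone_coords(s)
  keys <- rt$res_key

  complete <- vapply(bb, function(m) !anyNA(m), logical(1))
  # chain-adjacency: previous residue in same chain (for H placement and
  # peptide-bond continuity); author numbering runs within chains.
  prev_idx <- c(NA_integer_, seq_len(n - 1))
  prev_idx[c(TRUE, rt$chain[-1] != rt$chain[-n])] <- NA_integer_

  # Donor i cannot be proline (no amide H) and needs a preceding residue.
  can_donate <- rt$resid != "PRO" & !is.na(prev_idx)

  # Candidate acceptor pairs: prune by N-O distance < 5.2 A.
  hb <- matrix(FALSE, n, n)  # hb[i, j]: NH(i) ... CO(j)
  Ncoord <- t(vapply(bb, function(m) m["N", ], numeric(3)))
  Ocoord <- t(vapply(bb, function(m) m["O", ], numeric(3)))
  for (i in seq_len(n)) {
    if (!can_donate[i] || anyNA(Ncoord[i, ])) next
    d2 <- rowSums((Ocoord - matrix(Ncoord[i, ], n, 3, byrow = TRUE))^2)
    cand <- which(d2 < 5.2^2 & seq_len(n) != i)
    for (j in cand) {
      if (abs(i - j) < 2 && rt$chain[i] == rt$chain[j]) next
      e <- .hbond_energy(bb, keys[i], keys[j], keys[prev_idx[i]])
      if (is.finite(e) && e < energy_cutoff) hb[i, j] <- TRUE
      if (identical(e, -Inf)) hb[i, j] <- TRUE
    }
  }

  lab <- rep("C", n)
  # 4-turn at j: CO(j) ... NH(j+4) within one chain.
  turn <- vapply(seq_len(n), function(j) {
    k <- j + 4
    k <= n && rt$chain[j] == rt$chain[k] && hb[k, j]
  }, logical(1))
  # Helix: two consecutive 4-turns at j and j+1 mark residues j+1..j+4
  # (Kabsch-Sander minimal helix). An isolated turn is not a helix, which
  # keeps helix-flanking loop residues out even though their junction
  # H-bonds exist.
  for (j in seq_len(n - 1)) {
    if (turn[j] && turn[j + 1] && all(rt$chain[j:(j + 5)] == rt$chain[j]))
      lab[(j + 1):(j + 4)] <- "H"
  }
  # Boundary convention: a chain-terminal residue that participates in the
  # adjacent helix's hydrogen-bond network belongs to the helix.
  for (ch in unique(rt$chain)) {
    idx <- which(rt$chain == ch)
    i0 <- idx[1]; i1 <- idx[length(idx)]
    if (turn[i0] && i0 + 1 <= n && lab[i0 + 1] == "H") lab[i0] <- "H"
    if (i1 - 4 >= 1 && turn[i1 - 4] && lab[i1 - 1] == "H") lab[i1] <- "H"
  }
  # Bridges (strand): Kabsch-Sander parallel/antiparallel definitions on
  # residues not already helical.
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) < 3 && rt$chain[i] == rt$chain[j]) next
      if (i - 1 < 1 || i + 1 > n || j - 1 < 1 || j + 1 > n) next
      par <- (hb[j, i - 1] && hb[i + 1, j]) || (hb[i, j - 1] && hb[j + 1, i])
      anti <- (hb[i, j] && hb[j, i]) || (hb[j + 1, i - 1] && hb[i + 1, j - 1])
      if (par || anti) {
        if (lab[i] != "H") lab[i] <- "E"
        if (lab[j] != "H") lab[j] <- "E"
      }
    }
  }
  lab[!complete] <- "C"
  names(lab) <- keys
  attr(lab, "table") <- data.frame(rt[c("chain", "resno", "insert", "resid",
                                        "res_key")],
                                   ss = lab, stringsAsFactors = FALSE)
  lab
}

#' Enumerate loop segments
#'
#' Contiguous runs of coil-labeled residues per chain, with flanking anchor
#' residues. Loops touching a chain terminus are flagged terminal.
#'
#' @param s an `insrtr_structure`.
#' @param ss labels from [assign_secondary_structure()].
#' @return data.frame: chain, start_key, end_key, start_resno, end_resno,
#'   length, terminal, loop_id.
#' @export
find_loops <- function(s, ss) {
  rt <- residue_table(s)
  stopifnot(length(ss) == nrow(rt))
  loops <- list()
  for (ch in unique(rt$chain)) {
    idx <- which(rt$chain == ch)
    lab <- ss[idx]
    r <- rle(lab == "C")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i0 <- idx[starts[k]]; i1 <- idx[ends[k]]
      loops[[length(loops) + 1]] <- data.frame(
        chain = ch,
        start_key = rt$res_key[i0], end_key = rt$res_key[i1],
        start_resno = rt$resno[i0], end_resno = rt$resno[i1],
        length = ends[k] - starts[k] + 1,
        terminal = starts[k] == 1 || ends[k] == length(idx),
        stringsAsFactors = FALSE)
    }
  }
  if (length(loops) == 0)
    return(data.frame(chain = character(), start_key = character(),
                      end_key = character(), start_resno = integer(),
                      end_resno = integer(), length = integer(),
                      terminal = logical(), loop_id = character()))
  out <- do.call(rbind, loops)
  out$loop_id <- sprintf("%s_%d_%d", out$chain, out$start_resno,
                         out$end_resno)
  rownames(out) <- NULL
  out
}

#' Enumerate candidate insertion sites
#'
#' One candidate per inter-residue peptide bond whose two flanking residues
#' lie in the same internal loop segment ("after residue i", author
#' numbering). Terminal loops are excluded by default. The anchor gap is
#' the CA-CA distance (nm) across the insertion point.
#'
#' @param s an `insrtr_structure`.
#' @param ss labels from [assign_secondary_structure()].
#' @param include_terminal include loops touching chain termini.
#' @return data.frame of class `insertion_sites`: chain, after_resno,
#'   after_key, next_key, loop_id, loop_start, loop_end, loop_length,
#'   anchor_gap_nm.
#' @export
enumerate_candidate_sites <- function(s, ss, include_terminal = FALSE) {
  rt <- residue_table(s)
  loops <- find_loops(s, ss)
  if (!include_terminal) loops <- loops[!loops$terminal, , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(loops))) {
    lp <- loops[k, ]
    i0 <- which(rt$res_key == lp$start_key)
    i1 <- which(rt$res_key == lp$end_key)
    if (i1 <= i0) next
    for (i in i0:(i1 - 1)) {
      gap <- tryCatch(ca_distance(s, rt$res_key[i], rt$res_key[i + 1]),
                      error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        chain = lp$chain, after_resno = rt$resno[i],
        after_key = rt$res_key[i], next_key = rt$res_key[i + 1],
        loop_id = lp$loop_id, loop_start = lp$start_resno,
        loop_end = lp$end_resno, loop_length = lp$length,
        anchor_gap_nm = gap, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(), after_resno = integer(),
               after_key = character(), next_key = character(),
               loop_id = character(), loop_start = integer(),
               loop_end = integer(), loop_length = integer(),
               anchor_gap_nm = numeric())
  rownames(out) <- NULL
  class(out) <- c("insertion_sites", class(out))
  out
}

# residues of a loop_id as res_keys
.loop_keys <- function(s, loop_id) {
  rt <- residue_table(s)
  parts <- strsplit(loop_id, "_", fixed = TRUE)[[1]]
  ch <- paste(head(parts, -2), collapse = "_")
  r0 <- as.integer(parts[length(parts) - 1])
  r1 <- as.integer(parts[length(parts)])
  idx <- which(rt$chain == ch)
  i0 <- idx[match(r0, rt$resno[idx])]
  i1 <- idx[match(r1, rt$resno[idx])]
  rt$res_key[i0:i1]
}

#' Apply the heuristic admissibility rules to candidate sites
#'
#' Implements the design rules for permissive insertion: (a) the site lies
#' in a solvent-exposed loop (relative SASA of the site residue at or above
#' a threshold), (b) no direct involvement in the functional site (neither
#' flanking residue belongs to, or lies within a contact distance of, the
#' active-site set), (c) the target loop is variable in length/sequence
#' across orthologues when an alignment is supplied (otherwise marked
#' not-evaluated and never a veto), (d) separation from the functional site
#' of 1-4 nm, and (e) proximity/structural connection reported descriptively
#' as the raw distance and a contact count, not as a veto.
#'
#' @param sites from [enumerate_candidate_sites()].
#' @param s the `insrtr_structure`.
#' @param active_site vector of residue selectors for the functional site.
#' @param sasa result of [shrake_rupley_sasa()] on `s` (computed if NULL).
#' @param msa optional aligned-FASTA path or alignment matrix (rows =
#'   sequences, first row the target) for rule (c).
#' @param exposure_threshold relative-SASA cutoff for rule (a).
#' @param contact_dist_nm contact distance for rule (b), nm.
#' @param dist_range_nm admissible active-site distance window, nm.
#' @param variability_threshold minimum fraction of variable loop columns
#'   for rule (c).
#' @return `sites` with columns rule_a, rule_b, rule_d (logical), rule_c
#'   (logical or NA = not-evaluated), dist_active_site_nm, contact_count,
#'   and admissible (conjunction of a, b, d and, when evaluated, c).
#' @export
apply_heuristic_rules <- function(sites, s, active_site, sasa = NULL,
                                  msa = NULL, exposure_threshold = 0.25,
                                  contact_dist_nm = 0.5,
                                  dist_range_nm = c(1, 4),
                                  variability_threshold = 0.5) {
  if (length(active_site) == 0) stop("active_site must be non-empty")
  as_keys <- tryCatch(.resolve_selector(s, active_site), error = function(e)
    stop("active-site identifier error: ", conditionMessage(e)))
  if (is.null(sasa)) sasa <- shrake_rupley_sasa(s)
  rel <- relative_sasa(s, sasa)
  rt <- residue_table(s)
  as_xyz <- .ca_coords(s, as_keys)

  n <- nrow(sites)
  rule_a <- rule_b <- rule_d <- logical(n)
  rule_c <- rep(NA, n)
  dist_as <- contact_count <- numeric(n)
  loop_var <- if (!is.null(msa)) .loop_variability(s, msa) else NULL

  for (i in seq_len(n)) {
    k1 <- sites$after_key[i]; k2 <- sites$next_key[i]
    rule_a[i] <- isTRUE(rel[k1] >= exposure_threshold)
    # (d)/(e): min CA distance of the two flanking residues to the set
    p <- .ca_coords(s, c(k1, k2))
    dmat <- sqrt(pmax(outer(rowSums(p^2), rowSums(as_xyz^2), "+") -
                        2 * p %*% t(as_xyz), 0)) / 10
    dist_as[i] <- min(dmat)
    rule_d[i] <- dist_as[i] >= dist_range_nm[1] & dist_as[i] <= dist_range_nm[2]
    in_as <- c(k1, k2) %in% as_keys
    rule_b[i] <- !any(in_as) && dist_as[i] > contact_dist_nm
    # (e): contact count of structure CAs within 1.0 nm of the site CA
    ca_all <- rt[rt$has_ca, c("ca_x", "ca_y", "ca_z")]
    d_all <- sqrt(rowSums((t(t(as.matrix(ca_all)) - p[1, ]))^2)) / 10
    contact_count[i] <- sum(d_all <= 1.0) - 1
    if (!is.null(loop_var))
      rule_c[i] <- isTRUE(loop_var[sites$loop_id[i]] >= variability_threshold)
  }
  sites$rule_a <- rule_a
  sites$rule_b <- rule_b
  sites$rule_c <- rule_c
  sites$rule_d <- rule_d
  sites$dist_active_site_nm <- dist_as
  sites$contact_count <- contact_count
  sites$admissible <- rule_a & rule_b & rule_d &
    (is.na(rule_c) | rule_c)
  sites
}

# Rule (c): fraction of MSA columns mapped to each loop whose occupancy is
# variable (some but not all orthologues have a residue there). The first
# sequence of the alignment is taken as the target chain.
.loop_variability <- function(s, msa) {
  aln <- if (is.character(msa) && length(msa) == 1 && file.exists(msa)) {
    bio3d::read.fasta(msa)$ali
  } else if (is.matrix(msa)) msa else
    stop("msa must be an aligned FASTA path or a character matrix")
  target <- aln[1, ]
  cols <- which(!(target %in% c("-", ".")))
  rt <- residue_table(s)
  ch <- rt$chain[1]
  chain_keys <- rt$res_key[rt$chain == ch]
  if (length(cols) < length(chain_keys))
    warning("alignment shorter than target chain; trailing residues unmapped")
  map <- setNames(rep(NA_integer_, length(chain_keys)), chain_keys)
  m <- min(length(cols), length(chain_keys))
  map[seq_len(m)] <- cols[seq_len(m)]
  gapfrac <- colMeans(matrix(aln %in% c("-", "."), nrow(aln)))
  sslab <- assign_secondary_structure(s)
  loops <- find_loops(s, sslab)
  out <- setNames(numeric(nrow(loops)), loops$loop_id)
  for (k in seq_len(nrow(loops))) {
    keys <- .loop_keys(s, loops$loop_id[k])
    colz <- map[keys]
    colz <- colz[!is.na(colz)]
    out[k] <- if (length(colz) == 0) 0 else
      mean(gapfrac[colz] > 0 & gapfrac[colz] < 1)
  }
  out
}

#' Write a candidate-site table as TSV
#'
#' @param sites a sites data.frame (any stage of the pipeline).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
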