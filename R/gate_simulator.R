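# Equilibrium model of coiled-coil switch constructs. A construct carries
# one in-loop inserted peptide (the switch element) and optionally tethered
# peptides (inhibitors/blockers) at effective intramolecular concentrations;
# soluble partners (the regulatory peptide, or peptides released by
# protease cleavage) bind from the bath. The small state space of one
# construct is enumerated exactly: each microstate is a matching of
# construct elements to each other or to soluble species, weighted by
# Ceff/Kd (intramolecular) or [free]/Kd (bath). Activity is the
# probability that the insert is not in a CC dimer.

.pair_key <- function(a, b) paste(sort(c(a, b)), collapse = ":")

#' Default coiled-coil affinity table
#'
#' Dissociation constants (molar) for the peptide pairs used by the
#' shipped designs. The N/P series respects the experimental affinity rank
#' N7:N8 > P7A:N8 > P7:N8 > P7N:N8 (strongest to weakest); B1/B2 are
#' high-affinity blocker pairs used by the inverted gates.
#'
#' @return named numeric vector; names are alphabetically sorted pair keys
#'   ("A:B").
#' @export
default_kd_table <- function() {
  c("N7:N8" = 5e-9, "N8:P7A" = 5e-8, "N8:P7" = 2e-7, "N8:P7N" = 1e-6,
    "B1:P7N" = 1e-10, "B2:P7" = 1e-10, "N7:P7N" = 5e-9)
}

#' Validate the affinity rank order of a Kd table
#'
#' Checks Kd(N7:N8) < Kd(P7A:N8) < Kd(P7:N8) < Kd(P7N:N8).
#'
#' @param kd named Kd vector as in [default_kd_table()].
#' @return TRUE invisibly, or an error describing the violation.
#' @export
validate_affinity_rank <- function(kd = default_kd_table()) {
  series <- c("N7:N8", "N8:P7A", "N8:P7", "N8:P7N")
  v <- kd[series]
  if (anyNA(v)) stop("Kd table missing pairs: ",
                     paste(series[is.na(v)], collapse = ", "))
  if (any(diff(v) <= 0))
    stop("affinity rank violated: require Kd(N7:N8) < Kd(P7A:N8) < ",
         "Kd(P7:N8) < Kd(P7N:N8)")
  invisible(TRUE)
}

#' Declare a tethered element of a construct
#'
#' @param peptide peptide identifier (must appear in the Kd table with its
#'   binding partners).
#' @param ceff effective intramolecular concentration (molar) the tether
#'   presents, default 100 uM.
#' @param cleavage character vector of protease site ids on the tether
#'   (empty = uncleavable).
#' @param severed_by "any": the element is lost when any of its sites is
#'   cut (sites in series on one tether); "all": lost only when all are cut
#'   (element held at both ends).
#' @param terminus which terminus carries the fusion (annotation only).
#' @return list describing the element.
#' @export
tethered <- function(peptide, ceff = 1e-4, cleavage = character(),
                     severed_by = c("any", "all"), terminus = "C") {
  stopifnot(ceff > 0)
  list(peptide = peptide, ceff = ceff, cleavage = cleavage,
       severed_by = match.arg(severed_by), terminus = terminus)
}

#' Declare a protease-released soluble element
#'
#' A peptide that is inert until its trigger site(s) are cleaved and then
#' acts in trans at a stated release concentration.
#'
#' @param peptide peptide identifier.
#' @param conc concentration once released (molar), default 1 uM.
#' @param trigger protease site id(s) controlling release.
#' @param trigger_mode "any" or "all" of the trigger sites.
#' @return list describing the element.
#' @export
released <- function(peptide, conc = 1e-6, trigger,
                     trigger_mode = c("any", "all")) {
  stopifnot(conc > 0, length(trigger) >= 1)
  list(peptide = peptide, conc = conc, trigger = trigger,
       trigger_mode = match.arg(trigger_mode))
}

#' Declare a switch construct
#'
#' @param insert peptide id of the in-loop inserted CC peptide.
#' @param tethered_elements list of [tethered()] elements.
#' @param released_elements list of [released()] elements.
#' @param regulator peptide id the soluble regulator uses (its
#'   concentration is given per call), or NULL.
#' @param kd Kd table ([default_kd_table()]).
#' @param inputs optional named character vector mapping the two Boolean
#'   inputs to protease site ids, e.g. `c(A = "prot1", B = "prot2")`.
#' @return object of class `construct_design`.
#' @export
construct_design <- function(insert, tethered_elements = list(),
                             released_elements = list(),
                             regulator = NULL, kd = default_kd_table(),
                             inputs = NULL) {
  for (t in tethered_elements)
    if (anyDuplicated(t$cleavage))
      stop("design error: duplicated cleavage site id within one tether")
  structure(list(insert = insert, tethered = tethered_elements,
                 released = released_elements, regulator = regulator,
                 kd = kd, inputs = inputs),
            class = "construct_design")
}

.all_site_ids <- function(design) {
  unique(c(unlist(lapply(design$tethered, `[[`, "cleavage")),
           unlist(lapply(design$released, `[[`, "trigger"))))
}

.kd_of <- function(design, a, b) {
  unname(design$kd[.pair_key(a, b)])
}

# Construct nodes and bath species present for a given cleavage state.
.state_space <- function(design, regulator_conc, cleaved) {
  unknown <- setdiff(cleaved, c(.all_site_ids(design),
                                unname(design$inputs)))
  if (length(unknown))
    stop("design error: unknown cleavage site id(s): ",
         paste(unknown, collapse = ", "))
  attached <- Filter(function(t) {
    if (length(t$cleavage) == 0) return(TRUE)
    hit <- t$cleavage %in% cleaved
    if (t$severed_by == "any") !any(hit) else !all(hit)
  }, design$tethered)
  bath <- list()
  if (!is.null(design$regulator) && regulator_conc > 0)
    bath[[length(bath) + 1]] <- list(peptide = design$regulator,
                                     conc = regulator_conc, name = "REG")
  for (r in design$released) {
    hit <- r$trigger %in% cleaved
    on <- if (r$trigger_mode == "any") any(hit) else all(hit)
    if (on) bath[[length(bath) + 1]] <- list(peptide = r$peptide,
                                             conc = r$conc,
                                             name = paste0("REL:", r$peptide))
  }
  list(attached = attached, bath = bath)
}

# Exact enumeration of matchings of construct nodes (insert + attached
# tethered elements) among themselves (weight Ceff/Kd) and to bath species
# (weight conc/Kd). Returns the partition function restricted by an
# indicator on the insert's state.
.enumerate <- function(design, nodes, bath, bath_conc = NULL) {
  n <- length(nodes)
  if (is.null(bath_conc)) bath_conc <- vapply(bath, `[[`, numeric(1), "conc")
  # recursive sum over matchings; state[i]: 0 free, j>0 paired with node j,
  # -k bound to bath k
  states <- list()
  recurse <- function(assigned, weight) {
    i <- which(is.na(assigned))[1]
    if (is.na(i)) {
      states[[length(states) + 1]] <<- list(state = assigned, w = weight)
      return(invisible())
    }
    # free
    a <- assigned; a[i] <- 0
    recurse(a, weight)
    # pair with a later unassigned node
    for (j in seq_len(n)) {
      if (j <= i || !is.na(assigned[j])) next
      kd <- .kd_of(design, nodes[[i]]$peptide, nodes[[j]]$peptide)
      if (is.na(kd)) next
      ceff <- if (!is.null(nodes[[j]]$ceff)) nodes[[j]]$ceff else
        nodes[[i]]$ceff
      a <- assigned; a[i] <- j; a[j] <- i
      recurse(a, weight * ceff / kd)
    }
    # bind a bath species
    for (k in seq_along(bath)) {
      kd <- .kd_of(design, nodes[[i]]$peptide, bath[[k]]$peptide)
      if (is.na(kd) || bath_conc[k] <= 0) next
      a <- assigned; a[i] <- -k
      recurse(a, weight * bath_conc[k] / kd)
    }
  }
  recurse(rep(NA_real_, n), 1)
  states
}

#' Equilibrium occupancy and activity of a switch construct
#'
#' Computes the exact single-construct partition over binding microstates
#' at fixed bath concentrations (regulator treated as in excess; see
#' [solve_mass_balance()] for the depletion-aware solver). Cleavage is
#' binary and complete: severed tethered elements contribute nothing
#' intramolecularly, and released elements join the bath.
#'
#' @param design a [construct_design()].
#' @param regulator_conc free regulator concentration (molar, >= 0).
#' @param cleaved character vector of cleaved protease site ids.
#' @return list of class `equilibrium_state`: `occupancy` (named
#'   probabilities of the insert's states), `activity` (probability the
#'   insert is in no CC dimer).
#' @export
equilibrium_activity <- function(design, regulator_conc = 0,
                                 cleaved = character()) {
  stopifnot(regulator_conc >= 0)
  sp <- .state_space(design, regulator_conc, cleaved)
  nodes <- c(list(list(peptide = design$insert, ceff = NULL)), sp$attached)
  states <- .enumerate(design, nodes, sp$bath)
  w <- vapply(states, `[[`, numeric(1), "w")
  ins <- vapply(states, function(st) st$state[1], numeric(1))
  total <- sum(w)
  lab <- vapply(seq_along(states), function(i) {
    s <- ins[i]
    if (s == 0) "free"
    else if (s > 0) paste0("bound:", nodes[[s]]$peptide)
    else paste0("bound:", sp$bath[[-s]]$name)
  }, character(1))
  occ <- tapply(w, lab, sum) / total
  structure(list(occupancy = setNames(as.numeric(occ), names(occ)),
                 activity = sum(w[ins == 0]) / total),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("activity %.4f | occupancy: %s\n", x$activity,
              paste(sprintf("%s=%.4f", names(x$occupancy), x$occupancy),
                    collapse = " ")))
  invisible(x)
}

#' Brute-force mass-balance equilibrium over total concentrations
#'
#' General oracle for [equilibrium_activity()]: instead of treating bath
#' species as in excess, solves the self-consistent free concentrations by
#' damped fixed-point iteration of the mass balances
#' total_s = free_s + [construct] * E[bound s per construct](free).
#'
#' @param design a [construct_design()].
#' @param construct_tot total construct concentration (molar).
#' @param regulator_tot total regulator concentration (molar).
#' @param cleaved cleaved site ids.
#' @param tol convergence tolerance on free concentrations (relative).
#' @param max_iter iteration cap.
#' @return as [equilibrium_activity()], plus `free` (bath free
#'   concentrations) and `iterations`.
#' @export
solve_mass_balance <- function(design, construct_tot, regulator_tot = 0,
                               cleaved = character(), tol = 1e-12,
                               max_iter = 10000) {
  sp <- .state_space(design, regulator_tot, cleaved)
  nodes <- c(list(list(peptide = design$insert, ceff = NULL)), sp$attached)
  tots <- vapply(sp$bath, `[[`, numeric(1), "conc")
  free <- tots
  nb <- length(sp$bath)
  it <- 0
  if (nb > 0) {
    repeat {
      it <- it + 1
      states <- .enumerate(design, nodes, sp$bath, bath_conc = free)
      w <- vapply(states, `[[`, numeric(1), "w")
      total <- sum(w)
      bound <- vapply(seq_len(nb), function(k) {
        nbk <- vapply(states, function(st) sum(st$state == -k), numeric(1))
        sum(w * nbk) / total
      }, numeric(1))
      new_free <- tots / (1 + construct_tot * bound / pmax(free, 1e-300))
      if (all(abs(new_free - free) <= tol * pmax(free, 1e-300)) ||
          it >= max_iter) { free <- new_free; break }
      free <- 0.5 * free + 0.5 * new_free
    }
  }
  states <- .enumerate(design, nodes, sp$bath, bath_conc = free)
  w <- vapply(states, `[[`, numeric(1), "w")
  ins <- vapply(states, function(st) st$state[1], numeric(1))
  structure(list(activity = sum(w[ins == 0]) / sum(w),
                 free = free, iterations = it),
            class = "equilibrium_state")
}

#' Boolean truth table of a two-protease design
#'
#' Evaluates the construct's activity for the four input combinations
#' (neither, B only, A only, both proteases active) and thresholds it.
#'
#' @param design a [construct_design()] referencing at most two protease
#'   site ids; `design$inputs` may name them A and B explicitly.
#' @param threshold activity threshold in (0, 1), default 0.5.
#' @param regulator_conc regulator concentration during readout.
#' @return data.frame: A, B (0/1 protease inputs), activity, output (0/1).
#' @export
truth_table <- function(design, threshold = 0.5, regulator_conc = 0) {
  stopifnot(threshold > 0, threshold < 1)
  ids <- .all_site_ids(design)
  if (length(ids) > 2)
    stop("unsupported arity: design references ", length(ids),
         " protease sites (max 2)")
  inputs <- design$inputs
  if (is.null(inputs)) {
    inputs <- c(A = if (length(ids) >= 1) ids[1] else NA,
                B = if (length(ids) >= 2) ids[2] else NA)
  }
  rows <- expand.grid(B = 0:1, A = 0:1)[, c("A", "B")]
  act <- vapply(seq_len(4), function(i) {
    cl <- c(if (rows$A[i] == 1 && !is.na(inputs["A"])) inputs["A"],
            if (rows$B[i] == 1 && !is.na(inputs["B"])) inputs["B"])
    equilibrium_activity(design, regulator_conc, cleaved = cl)$activity
  }, numeric(1))
  data.frame(A = rows$A, B = rows$B, activity = act,
             output = as.integer(act > threshold))
}

#' Library of two-input Boolean logic gates
#'
#' Parameterized switch designs realizing the nontrivial two-input Boolean
#' functions under the equilibrium model. Inverting gates use
#' protease-released high-affinity peptides acting in trans; AND-type
#' removal uses elements tethered at both ends (severed only when both
#' sites are cut). Every shipped design passes its truth table at default
#' parameters.
#'
#' @param kd Kd table.
#' @param ceff effective intramolecular concentration for tethered
#'   elements (molar).
#' @param release_conc concentration of protease-released trans peptides
#'   (molar).
#' @return named list of `construct_design` objects with a
#'   `truth` attribute on each (expected outputs for inputs 00, 01, 10, 11).
#' @export
gate_library <- function(kd = default_kd_table(), ceff = 1e-4,
                         release_conc = 1e-6) {
  ins <- "N8"
  inp <- c(A = "protA", B = "protB")
  g <- function(truth, tethered_elements = list(),
                released_elements = list()) {
    d <- construct_design(ins, tethered_elements, released_elements,
                          kd = kd, inputs = inp)
    attr(d, "truth") <- truth
    d
  }
  list(
    AND = g(c(0, 0, 0, 1), list(
      tethered("P7N", ceff, cleavage = "protA"),
      tethered("P7", ceff, cleavage = "protB", terminus = "N"))),
    OR = g(c(0, 1, 1, 1), list(
      tethered("P7N", ceff, cleavage = c("protA", "protB"),
               severed_by = "any"))),
    NOT_A = g(c(1, 1, 0, 0), released_elements = list(
      released("N7", release_conc, trigger = "protA"))),
    NOT_B = g(c(1, 0, 1, 0), released_elements = list(
      released("N7", release_conc, trigger = "protB"))),
    A_AND_NOT_B = g(c(0, 0, 1, 0), list(
      tethered("P7N", ceff, cleavage = "protA")),
      list(released("N7", release_conc, trigger = "protB"))),
    B_AND_NOT_A = g(c(0, 1, 0, 0), list(
      tethered("P7N", ceff, cleavage = "protB")),
      list(released("N7", release_conc, trigger = "protA"))),
    NAND = g(c(1, 1, 1, 0), list(
      tethered("P7N", ceff),
      tethered("B1", ceff, cleavage = c("protA", "protB"),
               severed_by = "all"))),
    NOR = g(c(1, 0, 0, 0), released_elements = list(
      released("N7", release_conc, trigger = c("protA", "protB"),
               trigger_mode = "any"))),
    XOR = g(c(0, 1, 1, 0), list(
      tethered("P7N", ceff, cleavage = c("protA", "protB"),
               severed_by = "any"),
      tethered("P7", ceff),
      tethered("B2", ceff, cleavage = c("protA", "protB"),
               severed_by = "all"))),
    XNOR = g(c(1, 0, 0, 1), list(
      tethered("P7N", ceff),
      tethered("B1", ceff, cleavage = c("protA", "protB"),
               severed_by = "any")),
      list(released("B1", release_conc, trigger = c("protA", "protB"),
                    trigger_mode = "all"))),
    A_IMPLY_B = g(c(1, 1, 0, 1), list(
      tethered("P7N", ceff),
      tethered("B1", ceff, cleavage = "protA")),
      list(released("B1", release_conc, trigger = "protB"))),
    B_IMPLY_A = g(c(1, 0, 1, 1), list(
      tethered("P7N", ceff),
      tethered("B1", ceff, cleavage = "protB")),
      list(released("B1", release_conc, trigger = "protA"))))
}

#' OFF-switch design: regulator binding inactivates
#'
#' The plain switch of the mechanism's first demonstration: an inserted
#' peptide alone; the soluble regulatory peptide forces the CC helix and
#' strains the loop.
#'
#' @param insert insert peptide id.
#' @param regulator regulator peptide id.
#' @param kd Kd table.
#' @return a `construct_design`.
#' @export
off_switch_design <- function(insert = "N8", regulator = "N7",
                              kd = default_kd_table()) {
  construct_design(insert, regulator = regulator, kd = kd)
}

#' ON-switch design: autoinhibited, activated by cleavage or competition
#'
#' A weak inhibitory peptide tethered to the terminus occupies the insert
#' intramolecularly (autoinhibition despite low affinity, thanks to the
#' effective concentration); protease cleavage of the tether, or a soluble
#' competitor binding the inhibitor, releases activity.
#'
#' @param insert insert peptide id.
#' @param inhibitor tethered inhibitory peptide id.
#' @param regulator soluble competitor peptide id binding the inhibitor
#'   (default: the insert peptide itself supplied in trans, which pairs
#'   with the inhibitor but not with the in-loop insert).
#' @param ceff effective intramolecular concentration (molar).
#' @param cleavage protease site id on the tether.
#' @param kd Kd table.
#' @return a `construct_design`.
#' @export
on_switch_design <- function(insert = "N8", inhibitor = "P7N",
                             regulator = "N8", ceff = 1e-4,
                             cleavage = "protA", kd = default_kd_table()) {
  construct_design(insert,
                   tethered_elements = list(
                     tethered(inhibitor, ceff, cleavage = cleavage)),
                   regulator = regulator, kd = kd)
}

#' Dose-response of a design over a regulator concentration grid
#'
#' @param design a `construct_design`.
#' @param regulator_grid ascending molar concentrations.
#' @param cleaved cleaved site ids held fixed across the curve.
#' @return data.frame: regulator_conc, activity.
#' @export
dose_response <- function(design, regulator_grid, cleaved = character()) {
  if (is.unsorted(regulator_grid))
    stop("regulator_grid must be sorted ascending")
  act <- vapply(regulator_grid, function(r)
    equilibrium_activity(design, r, cleaved)$activity, numeric(1))
  data.frame(regulator_conc = regulator_grid, activity = act)
}

#' Fit the Hill equation to a dose-response series
#'
#' Least-squares fit of Y = Vmax * X^h / (Khalf^h + X^h) with the
#' deterministic initialization Vmax0 = max(y), Khalf0 = x at half-max,
#' h0 = 1.
#'
#' @param x concentrations (or times), >= 0, length >= 4.
#' @param y responses.
#' @return list of class `hill_fit`: vmax, khalf, h, residual_norm,
#'   converged, and the underlying nls object (`fit`).
#' @export
fit_hill <- function(x, y) {
  if (length(x) < 4) stop("need at least 4 points")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0))
    stop("data error: x must be finite and >= 0, y finite")
  vmax0 <- max(y)
  khalf0 <- x[which.min(abs(y - vmax0 / 2))]
  if (khalf0 <= 0) khalf0 <- median(x[x > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ Vmax * x^h / (Khalf^h + x^h),
                      start = list(Vmax = vmax0, Khalf = khalf0, h = 1),
                      lower = c(-Inf, 1e-12, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 500,
                                                           ftol = 1e-14,
                                                           ptol = 1e-14)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(structure(list(vmax = NA_real_, khalf = NA_real_, h = NA_real_,
                          residual_norm = NA_real_, converged = FALSE,
                          diagnostics = conditionMessage(fit), fit = NULL),
                     class = "hill_fit"))
  cf <- stats::coef(fit)
  structure(list(vmax = unname(cf["Vmax"]), khalf = unname(cf["Khalf"]),
                 h = unname(cf["h"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = fit$convInfo$isConv, fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("hill_fit: Vmax %.4g | Khalf %.4g | h %.4g | resid %.3g%s\n",
              x$vmax, x$khalf, x$h, x$residual_norm,
              if (!isTRUE(x$converged)) " [not converged]" else ""))
  invisible(x)
}
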