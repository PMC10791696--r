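test_that("single-construct partition matches closed-form hand weights", {
  # nothing to bind: fully active
  d0 <- construct_design("N8")
  expect_equal(equilibrium_activity(d0)$activity, 1)
  # one tethered inhibitor at Ceff = Kd: weights 1:1
  d1 <- construct_design("N8", list(tethered("P7N", ceff = 1e-6)))
  st <- equilibrium_activity(d1)
  expect_equal(st$activity, 0.5)
  expect_equal(sum(st$occupancy), 1)
  # autoinhibition despite weak affinity: Ceff/Kd = 99 gives 1% activity
  d99 <- on_switch_design(ceff = 99e-6)
  expect_equal(equilibrium_activity(d99)$activity, 0.01)
  expect_equal(equilibrium_activity(d99, cleaved = "protA")$activity, 1)
})

test_that("competitive release by the regulator is monotone and saturating", {
  d <- on_switch_design(ceff = 99e-6)
  grid <- 10^seq(-9, -2, by = 0.5)
  dr <- dose_response(d, grid)
  expect_true(all(diff(dr$activity) >= 0))
  expect_gt(dr$activity[length(grid)], 0.99)
  expect_equal(dose_response(d, 0)$activity,
               equilibrium_activity(d, 0)$activity)
})

test_that("OFF-switch inhibition deepens with affinity and dose", {
  grid <- 10^seq(-9, -4, by = 0.5)
  kd_strong <- c(default_kd_table(), "N8:R1" = 1e-8)
  kd_weak <- c(default_kd_table(), "N8:R1" = 1e-6)
  d_strong <- construct_design("N8", regulator = "R1", kd = kd_strong)
  d_weak <- construct_design("N8", regulator = "R1", kd = kd_weak)
  a_strong <- dose_response(d_strong, grid)$activity
  a_weak <- dose_response(d_weak, grid)$activity
  expect_true(all(diff(a_strong) <= 0))
  expect_true(all(a_strong <= a_weak))       # 10 nM binder inhibits more
  expect_lt(a_strong[length(grid)], 0.01)     # saturating dose switches off
  # the four-peptide affinity series inhibits in rank order at fixed dose
  acts <- vapply(c("N7:N8", "N8:P7A", "N8:P7", "N8:P7N"), function(pair) {
    reg <- setdiff(strsplit(pair, ":")[[1]], "N8")
    d <- construct_design("N8", regulator = reg)
    equilibrium_activity(d, regulator_conc = 1e-6)$activity
  }, numeric(1))
  expect_true(all(diff(acts) > 0))
  validate_affinity_rank()
  bad <- default_kd_table(); bad["N7:N8"] <- 1
  expect_error(validate_affinity_rank(bad), "affinity rank")
})

test_that("closed-form equilibria agree with the mass-balance solver", {
  # dilute-construct regime: depletion is negligible and both routes must
  # agree to 1e-8
  set.seed(42)
  for (rep in 1:5) {
    kd <- default_kd_table() * exp(runif(7, -1, 1))
    d <- on_switch_design(ceff = exp(runif(1, log(1e-6), log(1e-4))),
                          kd = kd)
    R <- 10^runif(1, -8, -5)
    cf <- equilibrium_activity(d, R)$activity
    bf <- solve_mass_balance(d, construct_tot = 1e-15, regulator_tot = R)
    expect_lt(abs(cf - bf$activity), 1e-8)
  }
  # outside that regime the solver shows real depletion
  d <- off_switch_design()
  deep <- solve_mass_balance(d, construct_tot = 1e-6, regulator_tot = 1e-6)
  shallow <- equilibrium_activity(d, 1e-6)
  expect_gt(deep$activity, shallow$activity)
})

test_that("every shipped gate reproduces its Boolean truth table", {
  lib <- gate_library()
  expect_gte(length(lib), 10)
  for (nm in names(lib)) {
    tt <- truth_table(lib[[nm]])
    expect_equal(tt$output, attr(lib[[nm]], "truth"),
                 info = paste("gate", nm))
    expect_true(all(tt$activity >= 0 & tt$activity <= 1))
  }
  # Boolean identities through the model
  and_out <- truth_table(lib$AND)$output
  nand_out <- truth_table(lib$NAND)$output
  expect_equal(and_out, c(0, 0, 0, 1))
  expect_equal(nand_out, 1 - and_out)
  expect_equal(truth_table(lib$XOR)$output, c(0, 1, 1, 0))
})

test_that("gate truth tables survive two-fold parameter perturbation", {
  for (f in c(0.5, 2)) {
    lib <- gate_library(kd = default_kd_table() * f, ceff = 1e-4 / f,
                        release_conc = 1e-6 * f)
    for (nm in names(lib))
      expect_equal(truth_table(lib[[nm]])$output, attr(lib[[nm]], "truth"),
                   info = paste("gate", nm, "perturbation", f))
  }
})

test_that("activity is monotone in autoinhibition strength", {
  ceffs <- c(1e-7, 1e-6, 1e-5, 1e-4)
  acts <- vapply(ceffs, function(cf)
    equilibrium_activity(construct_design(
      "N8", list(tethered("P7N", ceff = cf))))$activity, numeric(1))
  expect_true(all(diff(acts) < 0))
})

test_that("design validation rejects malformed constructs", {
  d <- on_switch_design()
  expect_error(equilibrium_activity(d, cleaved = "no_such_site"),
               "unknown cleavage site")
  three <- construct_design("N8", list(
    tethered("P7N", cleavage = c("p1", "p2")),
    tethered("P7", cleavage = "p3")), inputs = NULL)
  expect_error(truth_table(three), "arity")
  expect_error(construct_design("N8", list(
    tethered("P7N", cleavage = c("p1", "p1")))), "duplicated")
  # a design with no inhibitors and no cleavage sites is constitutively TRUE
  expect_equal(truth_table(construct_design(
    "N8", inputs = c(A = "pA", B = "pB")))$output, c(1, 1, 1, 1))
})
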