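test_that("ideal helix is fully helical and an extended chain is all coil", {
  helix <- make_toy_structure(fixture_spec(helices = 12,
                                           loops = integer(0)))$structure
  expect_true(all(assign_secondary_structure(helix) == "H"))

  bb <- build_backbone(rep(-120, 10), rep(120, 10))
  ext <- structure_from_atoms(data.frame(resno = bb$resno, elety = bb$elety,
                                         x = bb$x, y = bb$y, z = bb$z,
                                         resid = "ALA"))
  expect_true(all(assign_secondary_structure(ext) == "C"))
})

test_that("an engineered turn between helices is labeled coil exactly", {
  s <- make_toy_structure(fixture_spec(helices = c(12, 12), loops = 5))$structure
  ss <- assign_secondary_structure(s)
  expect_equal(as.character(ss), rep(c("H", "C", "H"), c(12, 5, 12)))
  # independent H-bond check: no helical O(i)..N(i+4) contact lies wholly
  # inside the turn
  a <- s$atoms
  get <- function(resno, elety) unlist(a[a$resno == resno & a$elety == elety,
                                         c("x", "y", "z")])
  for (i in 13:13 + 0:4) {
    j <- i + 4
    if (j > 17) next
    expect_gt(sqrt(sum((get(i, "O") - get(j, "N"))^2)), 3.5)
  }
})

test_that("secondary structure is invariant under rigid-body motion", {
  s <- make_toy_structure(fixture_spec(helices = c(12, 12), loops = 5))$structure
  s_rot <- transform_structure(s)
  expect_equal(as.character(assign_secondary_structure(s_rot)),
               as.character(assign_secondary_structure(s)))
})

test_that("candidate counts follow the loop combinatorics", {
  helix <- make_toy_structure(fixture_spec(helices = 12,
                                           loops = integer(0)))$structure
  ss_h <- assign_secondary_structure(helix)
  expect_equal(nrow(enumerate_candidate_sites(helix, ss_h)), 0)

  one_loop <- make_toy_structure(fixture_spec(helices = c(12, 12),
                                              loops = 5))$structure
  ss1 <- assign_secondary_structure(one_loop)
  sites1 <- enumerate_candidate_sites(one_loop, ss1)
  expect_equal(nrow(sites1), 4)  # 5-residue loop -> 4 internal bonds
  expect_equal(sites1$after_resno, 13:16)
  expect_true(all(sites1$anchor_gap_nm > 0))

  two_loops <- make_toy_structure(fixture_spec(helices = c(10, 8, 10),
                                               loops = c(3, 6)))$structure
  ss2 <- assign_secondary_structure(two_loops)
  sites2 <- enumerate_candidate_sites(two_loops, ss2)
  expect_equal(nrow(sites2), (3 - 1) + (6 - 1))
  # candidate count identity: sum over internal loops of (length - 1)
  loops <- find_loops(two_loops, ss2)
  internal <- loops[!loops$terminal, ]
  expect_equal(nrow(sites2), sum(internal$length - 1))
})

test_that("terminal loops are excluded by default but available on request", {
  bb <- build_backbone(c(rep(-120, 4), rep(-57, 12)),
                       c(rep(120, 4), rep(-47, 12)))
  s <- structure_from_atoms(data.frame(resno = bb$resno, elety = bb$elety,
                                       x = bb$x, y = bb$y, z = bb$z,
                                       resid = "ALA"))
  ss <- assign_secondary_structure(s)
  expect_equal(nrow(enumerate_candidate_sites(s, ss)), 0)
  expect_gt(nrow(enumerate_candidate_sites(s, ss, include_terminal = TRUE)), 0)
})

test_that("admissibility rules follow the stated distance and exposure logic", {
  s <- make_toy_structure(fixture_spec(helices = c(12, 12), loops = 5))$structure
  ss <- assign_secondary_structure(s)
  sites <- enumerate_candidate_sites(s, ss)
  sasa <- shrake_rupley_sasa(s)

  # functional-site involvement: a site flanked by an active-site residue
  # fails rule (b)
  res14 <- apply_heuristic_rules(sites, s, active_site = 14, sasa)
  expect_false(res14$rule_b[res14$after_resno == 14])
  expect_false(res14$rule_d[res14$after_resno == 14])  # 0 nm < 1 nm

  # rule (d) band computed from independent coordinate arithmetic
  rt <- residue_table(s)
  res1 <- apply_heuristic_rules(sites, s, active_site = 1, sasa)
  for (k in seq_len(nrow(res1))) {
    p <- as.matrix(rt[rt$resno %in% c(res1$after_resno[k],
                                      res1$after_resno[k] + 1),
                      c("ca_x", "ca_y", "ca_z")])
    q <- unlist(rt[rt$resno == 1, c("ca_x", "ca_y", "ca_z")])
    d_hand <- sqrt(min(rowSums((p - matrix(q, nrow(p), 3, TRUE))^2))) / 10
    expect_equal(res1$dist_active_site_nm[k], d_hand, tolerance = 1e-9)
    expect_equal(res1$rule_d[k], d_hand >= 1 && d_hand <= 4)
  }

  # rule (c) is not-evaluated (NA) without an alignment and never vetoes
  expect_true(all(is.na(res1$rule_c)))
  expect_equal(res1$admissible, res1$rule_a & res1$rule_b & res1$rule_d)

  # missing active-site residues are reported by identifier
  expect_error(apply_heuristic_rules(sites, s, active_site = 999, sasa),
               "identifier")
})

test_that("rule evaluation is idempotent and order-independent", {
  s <- make_toy_structure(fixture_spec(helices = c(10, 8, 10),
                                       loops = c(3, 6)))$structure
  ss <- assign_secondary_structure(s)
  sites <- enumerate_candidate_sites(s, ss)
  sasa <- shrake_rupley_sasa(s)
  once <- apply_heuristic_rules(sites, s, 1, sasa)
  twice <- apply_heuristic_rules(once[names(sites)], s, 1, sasa)
  expect_equal(once$rule_d, twice$rule_d)
  perm <- sample(nrow(sites))
  shuffled <- apply_heuristic_rules(sites[perm, ], s, 1, sasa)
  expect_equal(shuffled$rule_d[order(perm)], once$rule_d)
})

test_that("a buried loop fails the exposure rule", {
  s <- make_toy_structure(fixture_spec(helices = c(12, 12), loops = 5,
                                       burial_shell = TRUE))$structure
  ss <- assign_secondary_structure(s)
  sites <- enumerate_candidate_sites(s, ss)
  sasa <- shrake_rupley_sasa(s)
  rel <- relative_sasa(s, sasa)
  buried_key <- "A:15:"  # mid-loop residue inside the occluder shell
  expect_lt(rel[buried_key], 0.25)
  res <- apply_heuristic_rules(sites, s, "A:1", sasa)
  expect_false(res$rule_a[res$after_key == buried_key])
})

test_that("orthologue loop variability gates rule (c) when an MSA is given", {
  s <- make_toy_structure(fixture_spec(helices = c(12, 12), loops = 5))$structure
  n <- nrow(residue_table(s))
  target <- rep("a", n)
  # orthologues with indels confined to loop columns 13..17
  varied <- target; varied[13:17] <- "-"
  conserved <- target
  msa_var <- rbind(target, varied, conserved)
  msa_cons <- rbind(target, conserved, conserved)
  ss <- assign_secondary_structure(s)
  sites <- enumerate_candidate_sites(s, ss)
  sasa <- shrake_rupley_sasa(s)
  with_var <- apply_heuristic_rules(sites, s, 1, sasa, msa = msa_var)
  without_var <- apply_heuristic_rules(sites, s, 1, sasa, msa = msa_cons)
  expect_true(all(with_var$rule_c))
  expect_false(any(without_var$rule_c))
})
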