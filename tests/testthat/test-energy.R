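vina <- scoring_params("vina")
vinardo <- scoring_params("vinardo")

test_that("elementary terms reproduce their closed forms", {
  expect_equal(surface_distance(3.8, 1.9, 1.9), 0)
  expect_equal(surface_distance(6.8, 1.9, 1.9), 3)
  expect_equal(surface_distance(3.0, 2.0, 1.6), -0.6)

  expect_equal(gauss_term(0, 0, 0.8), 1)
  expect_equal(gauss_term(0.8, 0, 0.8), exp(-1), tolerance = 1e-12)
  expect_equal(gauss_term(0, 3, 2), exp(-2.25), tolerance = 1e-12)

  expect_equal(repulsion_term(-0.5), 0.25)
  expect_equal(repulsion_term(0), 0)
  expect_equal(repulsion_term(1), 0)

  expect_equal(hydrophobic_term(1.0, 0.5, 1.5), 0.5)   # Vina midpoint
  expect_equal(hydrophobic_term(1.25, 0, 2.5), 0.5)    # Vinardo midpoint
  expect_equal(hydrophobic_term(2.5, 0, 2.5), 0)
  expect_equal(hydrophobic_term(-1, 0, 2.5), 1)

  expect_equal(hbond_term(-0.6, -0.6), 1)
  expect_equal(hbond_term(-0.3, -0.6), 0.5)
  expect_equal(hbond_term(0.2, -0.6), 0)
})

test_that("m-n Lennard-Jones term has its well at r_min", {
  expect_equal(lj_mn_term(2.5, 4, 8, 1.3, 2.5), -1.3)
  expect_lt(abs(lj_mn_term(1e4, 4, 8, 1.3, 2.5)), 1e-12)
  # closed-form value at r = r_min * 2^(1/4) for the 4-8 form
  expect_equal(lj_mn_term(2 ^ 0.25, 4, 8, 1, 1), -0.75, tolerance = 1e-12)
  expect_error(lj_mn_term(1, 8, 4, 1, 1), "m < n")
})

test_that("piecewise terms are continuous at every joint", {
  eps <- 1e-9
  joints <- list(
    list(f = function(d) repulsion_term(d), at = 0),
    list(f = function(d) hydrophobic_term(d, 0.5, 1.5), at = c(0.5, 1.5)),
    list(f = function(d) hydrophobic_term(d, 0, 2.5), at = c(0, 2.5)),
    list(f = function(d) hbond_term(d, -0.7), at = c(-0.7, 0)),
    list(f = function(d) hbond_term(d, -0.6), at = c(-0.6, 0))
  )
  for (j in joints) {
    for (a in j$at) {
      expect_lt(abs(j$f(a - eps) - j$f(a + eps)), 1e-6)
    }
  }
})

test_that("pair energies match hand-evaluated worked examples", {
  # Vina, aromatic C vs plain N at contact (steric only)
  e1 <- pair_energy(atom_rec("CA", "hydrophobic"),
                    atom_rec("N", "polar_nonhb"), 3.7, vina)
  expect_equal(e1, -0.035579 - 0.005156 * exp(-2.25), tolerance = 1e-9)
  expect_equal(e1, -0.036122, tolerance = 1e-4)

  # Vinardo, two hydrophobic aromatic carbons at contact
  e2 <- pair_energy(atom_rec("CA", "hydrophobic"),
                    atom_rec("CA", "hydrophobic"), 3.8, vinardo)
  expect_equal(e2, -0.080, tolerance = 1e-12)

  # Vinardo, donor N vs acceptor O at d = -0.6 (full overlap + H-bond)
  e3 <- pair_energy(atom_rec("N", "donor"), atom_rec("O", "acceptor"),
                    1.7 + 1.6 - 0.6, vinardo)
  expect_equal(e3, 0.8 * 0.36 - 0.045 * exp(-0.5625) - 0.600,
               tolerance = 1e-9)
  expect_equal(e3, -0.33764, tolerance = 1e-5)
})

test_that("pair energy is symmetric and gated by interaction classes", {
  a <- atom_rec("CA", "hydrophobic")
  b <- atom_rec("O", "donor_acceptor")
  m <- atom_rec("Met", "metal")
  for (r in c(3.1, 3.6, 4.2, 6.0)) {
    expect_equal(pair_energy(a, b, r, vina), pair_energy(b, a, r, vina))
    expect_equal(pair_energy(m, b, r, vinardo),
                 pair_energy(b, m, r, vinardo))
  }
  # hydrophobic term only fires for hydrophobic-hydrophobic
  ref <- pair_energy(atom_rec("C", "polar_nonhb"),
                     atom_rec("C", "polar_nonhb"), 4.5, vinardo,
                     breakdown = TRUE)
  expect_equal(unname(ref$per_term_raw[c("hydrophobic", "hbond")]), c(0, 0))
  # metal counts as donor against an acceptor
  mb <- pair_energy(m, atom_rec("O", "acceptor"), 2.6, vinardo,
                    breakdown = TRUE)
  expect_gt(mb$per_term_raw[["hbond"]], 0)
})

test_that("steric profiles: single Vinardo minimum, two Vina minima", {
  # every heavy-type pairing under Vinardo: one minimum, at contact
  for (c1 in c("C", "CA", "N", "O")) {
    for (c2 in c("C", "CA", "N", "O")) {
      mins <- find_steric_minima(vinardo, c1, c2)
      expect_length(mins, 1L)
      expect_equal(mins, vinardo$radii[[c1]] + vinardo$radii[[c2]],
                   tolerance = 1e-6)
    }
  }
  mins_vina <- find_steric_minima(vina, "CA", "CA")
  expect_length(mins_vina, 2L)
  expect_equal(mins_vina[2], 6.8, tolerance = 0.05)
})

test_that("intermolecular energy equals brute force, with and without index", {
  vinardo_local <- vinardo
  for (seed in 1:25) {
    cx <- random_complex(seed)
    with_index <- intermolecular_energy(cx$ligand, cx$receptor,
                                        vinardo_local, use_index = TRUE)
    without <- intermolecular_energy(cx$ligand, cx$receptor, vinardo_local,
                                     use_index = FALSE)
    expect_lt(abs(with_index$total - without$total), 1e-9)
    expect_equal(with_index$n_pairs_evaluated, without$n_pairs_evaluated)
    expect_lt(abs(with_index$total -
                    brute_force_inter(cx$ligand, cx$receptor, vinardo_local)),
              1e-9)
    # total is the sum of the weighted terms
    expect_lt(abs(with_index$total - sum(with_index$per_term_weighted)),
              1e-12)
  }
})

test_that("single pair and beyond-cutoff cases behave exactly", {
  rec <- one_atom_receptor(0, 0, 0, "A")
  lig <- parse_pdbqt(one_atom_ligand(3.8, 0, 0, "A"), role = "ligand")
  bd <- intermolecular_energy(lig, rec, vinardo)
  expect_equal(bd$total,
               pair_energy(lig$atoms[1, ], rec$atoms[1, ], 3.8, vinardo))
  # surface distance 9 A: beyond the 8 A cutoff, exactly zero
  far <- parse_pdbqt(one_atom_ligand(3.8 + 9, 0, 0, "A"), role = "ligand")
  expect_identical(intermolecular_energy(far, rec, vinardo)$total, 0)
  expect_identical(intermolecular_energy(far, rec, vinardo)$n_pairs_evaluated,
                   0L)
})

test_that("intramolecular energy counts only torsion-separated pairs", {
  rigid <- make_toy_ligand(0)
  expect_identical(intramolecular_energy(rigid, vinardo), 0)

  # 5-atom chain, 2 torsions: only the (1,5) pair is >= 4 bonds apart
  chain <- make_toy_ligand(2)
  expect_equal(nrow(chain$intra_pairs), 1L)
  expect_equal(unname(chain$intra_pairs[1, ]), c(1L, 5L))
  r15 <- sqrt(sum((chain$xyz[1, ] - chain$xyz[5, ])^2))
  expect_equal(intramolecular_energy(chain, vinardo),
               pair_energy(chain$atoms[1, ], chain$atoms[5, ], r15, vinardo))

  # longer chain: brute-force enumeration with an independent BFS
  long <- make_toy_ligand(4)
  expected <- 0
  for (i in which(long$atoms$is_heavy)) {
    dist <- bfs_bond_dist(nrow(long$atoms), long$bonds, i)
    for (j in which(long$atoms$is_heavy)) {
      if (j <= i) next
      if (long$fragments[i] == long$fragments[j]) next
      if (!is.na(dist[j]) && dist[j] < 4L) next
      r <- sqrt(sum((long$xyz[i, ] - long$xyz[j, ])^2))
      d <- r - 2 * vinardo$radii[["C"]]
      if (d < vinardo$cutoff) {
        expected <- expected +
          pair_energy(long$atoms[i, ], long$atoms[j, ], r, vinardo)
      }
    }
  }
  expect_equal(intramolecular_energy(long, vinardo), expected,
               tolerance = 1e-12)
})

test_that("torsion scaling divides by 1 + c * n_rot", {
  expect_equal(predicted_affinity(-8, 0, vinardo), -8)
  ps0 <- set_param(vinardo, "torsion_coeff", 0)
  expect_equal(predicted_affinity(-8, 7, ps0), -8)
  expect_equal(predicted_affinity(-8, 4, vinardo), -8 / 1.23384,
               tolerance = 1e-5)
  expect_error(predicted_affinity(-8, -1, vinardo), "non-negative")
})

test_that("term contributions average to percentages that sum to 100", {
  bd <- pair_energy(atom_rec("CA", "hydrophobic"),
                    atom_rec("CA", "hydrophobic"), 3.8, vinardo,
                    breakdown = TRUE)
  pct <- term_contributions(list(bd))
  expect_equal(unname(pct[["gauss1"]]), 56.25, tolerance = 1e-9)
  expect_equal(unname(pct[["hydrophobic"]]), 43.75, tolerance = 1e-9)
  expect_equal(sum(pct), 100, tolerance = 1e-9)

  # with the steric weights off, a donor-acceptor pair is 100% hbond
  ps_hb <- set_param(set_param(vinardo, "weight_gauss1", 0),
                     "weight_repulsion", 0)
  hb <- pair_energy(atom_rec("N", "donor"), atom_rec("O", "acceptor"),
                    1.7 + 1.6 - 0.3, ps_hb, breakdown = TRUE)
  expect_equal(unname(term_contributions(list(hb))[["hbond"]]), 100)

  mixed <- term_contributions(list(bd, hb))
  expect_equal(sum(mixed), 100, tolerance = 1e-9)
  expect_error(term_contributions(list()), "empty")
})
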