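test_that("the Coulomb kernel reproduces closed forms", {
  tr <- two_point_traj(3.320636)
  ie <- interaction_energy(tr, 1, 1L, 2L, charges = c(1, -1))
  expect_equal(ie$e_total, -100, tolerance = 1e-3)
  # doubling the separation halves the unscreened energy
  tr2 <- two_point_traj(2 * 3.320636)
  ie2 <- interaction_energy(tr2, 1, 1L, 2L, charges = c(1, -1))
  expect_equal(ie2$e_total, ie$e_total / 2, tolerance = 1e-9)
  # dielectric scales linearly
  ie4 <- interaction_energy(tr, 1, 1L, 2L, charges = c(1, -1), eps = 4)
  expect_equal(ie4$e_total, ie$e_total / 4, tolerance = 1e-9)
})

test_that("Debye screening shrinks every pair energy in magnitude", {
  lam <- debye_length(0.150)
  expect_equal(lam, 3.04 / sqrt(0.15), tolerance = 1e-9)
  fx <- build_fixture("ADP_PI_A")
  lig <- which(fx$traj$atoms$resname == "PO4")
  rec <- setdiff(which(!fx$traj$atoms$is_solvent), lig)
  q <- assign_charges(fx$traj)
  plain <- interaction_energy(fx$traj, 1, lig, rec, q)
  screened <- interaction_energy(fx$traj, 1, lig, rec, q, lambda_D = lam)
  nz <- plain$e_coulomb != 0
  expect_true(all(abs(screened$e_coulomb[nz]) < abs(plain$e_coulomb[nz])))
  expect_true(all(sign(screened$e_coulomb[nz]) == sign(plain$e_coulomb[nz])))
})

test_that("terms vanish with all-zero charges and swap symmetrically", {
  fx <- build_fixture("ADP_PI_A")
  lig <- which(fx$traj$atoms$resname == "PO4")
  rec <- which(fx$traj$atoms$resname %in% c("MG", "ADP"))
  zero <- interaction_energy(fx$traj, 1, lig, rec,
                             charges = rep(0, n_atoms(fx$traj)))
  expect_true(all(zero$e_total == 0))
  q <- assign_charges(fx$traj)
  ab <- interaction_energy(fx$traj, 1, lig, rec, q)
  ba <- interaction_energy(fx$traj, 1, rec, lig, q)
  expect_equal(sum(ab$e_coulomb), sum(ba$e_coulomb), tolerance = 1e-9)
})

test_that("error contracts: overlap, clash, unassigned charge", {
  fx <- build_fixture("ADP_PI_A")
  lig <- which(fx$traj$atoms$resname == "PO4")
  rec <- setdiff(which(!fx$traj$atoms$is_solvent), lig)
  q <- assign_charges(fx$traj)
  expect_error(interaction_energy(fx$traj, 1, lig, c(rec, lig[1]), q),
               "overlap")
  qq <- q
  qq[which(fx$traj$atoms$resname == "MG")] <- NA_real_
  expect_error(interaction_energy(fx$traj, 1, lig, rec, qq),
               "charge model error")
  clash <- fx$traj
  co <- frame_coords(clash, 1)
  co[lig[1], ] <- co[rec[1], ] + 0.01
  clash <- set_frame_coords(clash, 1, co)
  expect_error(interaction_energy(clash, 1, lig, rec, q), "clash")
})

test_that("per-entity terms are additive to the global total", {
  fx <- build_fixture("ADP_PI_A", n_frames = 8, noise_sigma = 0.15,
                      seed = 19)
  lig <- which(fx$traj$atoms$resname == "PO4")
  rec <- setdiff(which(!fx$traj$atoms$is_solvent), lig)
  q <- assign_charges(fx$traj)
  for (f in c(1, 5)) {
    tab <- interaction_energy(fx$traj, f, lig, rec, q, lj = TRUE)
    expect_equal(sum(tab$e_total), sum(tab$e_coulomb) + sum(tab$e_lj),
                 tolerance = 1e-6)
  }
  et <- decompose_trajectory(fx$traj, lig, rec, q)
  expect_equal(sum(et$per_entity$e_total), et$global_total,
               tolerance = 1e-6)
})

test_that("trajectory decomposition means equal external re-averaging", {
  fx <- build_fixture("ADP_PI_A", n_frames = 6, noise_sigma = 0.2,
                      seed = 29)
  lig <- which(fx$traj$atoms$resname == "PO4")
  rec <- setdiff(which(!fx$traj$atoms$is_solvent), lig)
  q <- assign_charges(fx$traj)
  et <- decompose_trajectory(fx$traj, lig, rec, q)
  manual <- sapply(1:6, function(f) {
    tab <- interaction_energy(fx$traj, f, lig, rec, q)
    tab$e_total[match(et$per_entity$entity, tab$entity)]
  })
  expect_equal(et$per_entity$e_total, rowMeans(manual), tolerance = 1e-9)
  expect_equal(et$per_entity$se_total,
               apply(manual, 1, stats::sd) / sqrt(6), tolerance = 1e-9)
  # constant trajectory: zero standard errors
  const <- build_fixture("ADP_PI_A", n_frames = 4)
  lig2 <- which(const$traj$atoms$resname == "PO4")
  rec2 <- setdiff(which(!const$traj$atoms$is_solvent), lig2)
  ec <- decompose_trajectory(const$traj, lig2, rec2,
                             assign_charges(const$traj))
  expect_true(all(ec$per_entity$se_total == 0))
  expect_equal(ec$global_se, 0)
})

test_that("Mg2+ and K251 stabilize the leaving phosphate most in state A", {
  fx <- build_fixture("ADP_PI_A", n_frames = 10, noise_sigma = 0.1,
                      seed = 41)
  lig <- which(fx$traj$atoms$resname == "PO4")
  rec <- setdiff(which(!fx$traj$atoms$is_solvent), lig)
  et <- decompose_trajectory(fx$traj, lig, rec, assign_charges(fx$traj))
  expect_setequal(et$per_entity$entity[1:2], c("MG", "A:LYS251"))
  # ADP is the dominant destabilizing entity
  expect_equal(et$per_entity$entity[which.max(et$per_entity$e_total)],
               "ADP")
})

test_that("phosphate binding is weaker in state B than in state A", {
  total <- function(st) {
    fx <- build_fixture(st, n_frames = 10, noise_sigma = 0.1, seed = 43)
    lig <- which(fx$traj$atoms$resname == "PO4")
    rec <- setdiff(which(!fx$traj$atoms$is_solvent), lig)
    decompose_trajectory(fx$traj, lig, rec,
                         assign_charges(fx$traj))$global_total
  }
  ta <- total("ADP_PI_A")
  tb <- total("ADP_PI_B")
  expect_lt(ta, tb)
})
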