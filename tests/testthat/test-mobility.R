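test_that("RMSF of planted isotropic noise converges to sigma*sqrt(3)", {
  mob <- build_mobility_fixture(sigma = 0.2, n_residues = 60,
                                n_frames = 1500, seed = 2)
  pr <- compute_rmsf(mob$traj)
  interior <- pr$resid %in% 5:56
  expect_true(all(abs(pr$rmsf[interior] - 0.2 * sqrt(3)) /
                    (0.2 * sqrt(3)) < 0.05))
  expect_true(all(pr$rmsf >= 0))
})

test_that("rigid-motion copies of a frame have (near) zero RMSF", {
  mob <- build_mobility_fixture(sigma = 0, n_residues = 30, n_frames = 40,
                                seed = 3, global_motion = TRUE)
  pr <- compute_rmsf(mob$traj)
  expect_true(all(pr$rmsf <= 1e-6))
})

test_that("global rigid motion does not change RMSF (alignment contract)", {
  plain <- build_mobility_fixture(sigma = 0.2, n_residues = 40,
                                  n_frames = 400, seed = 4)
  moved <- build_mobility_fixture(sigma = 0.2, n_residues = 40,
                                  n_frames = 400, seed = 4,
                                  global_motion = TRUE)
  r1 <- compute_rmsf(plain$traj)
  r2 <- compute_rmsf(moved$traj)
  expect_true(all(abs(r1$rmsf - r2$rmsf) / r1$rmsf < 0.01))
})

test_that("a residue with doubled sigma shows ~2x RMSF and ratio ~2", {
  sig <- rep(0.2, 50)
  sig[25] <- 0.4
  hot <- build_mobility_fixture(sigma = sig, n_frames = 1200, seed = 5)
  base <- build_mobility_fixture(sigma = 0.2, n_residues = 50,
                                 n_frames = 1200, seed = 6)
  ph <- compute_rmsf(hot$traj)
  pb <- compute_rmsf(base$traj)
  scaffold_med <- stats::median(ph$rmsf[-25])
  expect_equal(ph$rmsf[25] / scaffold_med, 2, tolerance = 0.1)
  rr <- rmsf_ratio(ph, pb)
  expect_equal(rr$ratio[rr$resid == 25], 2, tolerance = 0.1)
  expect_equal(stats::median(rr$ratio[rr$resid != 25]), 1, tolerance = 0.1)
})

test_that("rmsf_ratio handles identical profiles and the denominator floor", {
  mob <- build_mobility_fixture(sigma = 0.15, n_residues = 20,
                                n_frames = 200, seed = 7)
  pr <- compute_rmsf(mob$traj)
  rr <- rmsf_ratio(pr, pr)
  expect_true(all(rr$ratio == 1))
  frozen <- pr
  frozen$rmsf[3] <- 0
  rf <- rmsf_ratio(pr, frozen)
  expect_true(rf$flagged[rf$resid == 3])
  expect_true(is.na(rf$ratio[rf$resid == 3]))
  other <- pr
  other$chain <- "Z"
  expect_error(rmsf_ratio(pr, other), "no residues")
})

test_that("planted 3-10 torsions are assigned 3-10; alpha and beta are not", {
  fd <- build_fixture("ADP_LIKE")
  lc <- loop_conformation(fd$traj, "A")
  hel <- lc$per_frame[lc$per_frame$resid %in% 349:353, ]
  expect_true(all(hel$is_310))
  expect_equal(lc$helix_fraction, 1.0)
  fa <- build_fixture("ADP_PI_A")
  la <- loop_conformation(fa$traj, "A")
  expect_false(any(la$per_frame$is_310))
  expect_equal(la$helix_fraction, 0)
  # canonical alpha (-57, -47): psi deviates 21 > 15 -> rejected
  is310 <- function(phi, psi, tol_phi = 20, tol_psi = 15)
    abs(phi + 49) <= tol_phi && abs(psi + 26) <= tol_psi
  expect_false(is310(-57, -47))
  expect_false(is310(-120, 120))
  expect_true(is310(-49, -26))
})

test_that("helix_fraction is monotone in the torsion tolerances", {
  fx <- build_fixture("ADP_LIKE", n_frames = 30, noise_sigma = 0.3,
                      seed = 8)
  fr <- vapply(c(5, 10, 15, 25), function(tp)
    loop_conformation(fx$traj, "A", tol_psi = tp)$helix_fraction,
    numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("ramachandran table matches the definitional dihedrals", {
  fx <- build_fixture("ADP_PI_B")
  tab <- ramachandran_table(fx$traj, 1, "A", c(348, 360))
  expect_equal(nrow(tab), 13L)
  co <- frame_coords(fx$traj, 1)
  for (r in c(350, 355, 359)) {
    idx <- function(resid, nm) atom_index(fx$traj, "A", resid, nm)
    expect_equal(tab$phi[tab$resid == r],
                 dihedral(co, idx(r - 1, "C"), idx(r, "N"), idx(r, "CA"),
                          idx(r, "C")))
    expect_equal(tab$psi[tab$resid == r],
                 dihedral(co, idx(r, "N"), idx(r, "CA"), idx(r, "C"),
                          idx(r + 1, "N")))
  }
  # chain-terminal residue: psi undefined, row omitted with a notice
  expect_message(out <- ramachandran_table(fx$traj, 1, "A", c(348, 361)),
                 "omitting")
  expect_false(361 %in% out$resid)
})

test_that("loop phi/psi recover the planted torsions exactly at zero noise", {
  for (st in c("ADP_PI_A", "ADP_LIKE")) {
    fx <- build_fixture(st)
    tab <- ramachandran_table(fx$traj, 1, "A", c(348, 360))
    want_phi <- ifelse(st == "ADP_LIKE" & tab$resid %in% 349:353, -49, -75)
    want_psi <- ifelse(st == "ADP_LIKE" & tab$resid %in% 349:353, -26, -50)
    expect_equal(tab$phi, want_phi, tolerance = 1e-6)
    expect_equal(tab$psi, want_psi, tolerance = 1e-6)
  }
})

test_that("RMSF is invariant under one global rigid motion of all frames", {
  mob <- build_mobility_fixture(sigma = 0.2, n_residues = 25,
                                n_frames = 150, seed = 9)
  ref <- compute_rmsf(mob$traj)
  set.seed(10)
  rot <- random_rotation()
  shift <- runif(3, -30, 30)
  moved <- mob$traj
  for (f in seq_len(n_frames(moved)))
    moved <- set_frame_coords(moved, f,
                              rigid_move(frame_coords(moved, f), rot, shift))
  expect_equal(compute_rmsf(moved)$rmsf, ref$rmsf, tolerance = 1e-6)
})
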