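test_that("distances match the componentwise oracle and basic identities", {
  co <- rbind(c(0, 0, 0), c(3, 4, 0))
  expect_equal(atom_distance(co, 1, 2), 5)
  expect_equal(atom_distance(co, 1, 1), 0)
  set.seed(1)
  pts <- matrix(rnorm(60, sd = 5), ncol = 3)
  for (k in 1:20) {
    ij <- sample(nrow(pts), 2)
    expect_equal(atom_distance(pts, ij[1], ij[2]),
                 sqrt(sum((pts[ij[1], ] - pts[ij[2], ])^2)))
    expect_equal(atom_distance(pts, ij[1], ij[2]),
                 atom_distance(pts, ij[2], ij[1]))
  }
  expect_error(atom_distance(pts, 0, 1), "bounds")
})

test_that("dihedrals use the IUPAC convention, its symmetries and range", {
  cis <- rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0))
  expect_equal(dihedral(cis, 1, 2, 3, 4), 0)
  anti <- rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, -1, 0))
  expect_equal(abs(dihedral(anti, 1, 2, 3, 4)), 180)
  set.seed(2)
  for (k in 1:25) {
    p <- matrix(rnorm(12, sd = 3), ncol = 3)
    ang <- tryCatch(dihedral(p, 1, 2, 3, 4), error = function(e) NA)
    if (is.na(ang)) next
    expect_equal(ang, torsion_oracle(p[1, ], p[2, ], p[3, ], p[4, ]))
    # reading the chain backwards leaves the torsion unchanged;
    # a mirror reflection negates it (true antisymmetry of chirality)
    expect_equal(dihedral(p, 4, 3, 2, 1), ang)
    mir <- p
    mir[, 3] <- -mir[, 3]
    refl <- dihedral(mir, 1, 2, 3, 4)
    if (abs(ang) < 179.999) expect_equal(refl, -ang) else
      expect_equal(abs(refl), abs(ang))
    expect_gt(ang, -180)
    expect_lte(ang, 180)
  }
  coll <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(dihedral(coll, 1, 2, 3, 4), "collinear")
})

test_that("dihedrals are invariant under global rigid motion", {
  set.seed(3)
  p <- matrix(rnorm(12, sd = 3), ncol = 3)
  ref <- dihedral(p, 1, 2, 3, 4)
  for (k in 1:5) {
    expect_equal(dihedral(rigid_move(p), 1, 2, 3, 4), ref,
                 tolerance = 1e-9)
  }
})

test_that("chi1 recovers the planted rotamers and rigid invariance holds", {
  fa <- build_fixture("ADP_PI_A")
  expect_equal(chi1(fa$traj, 1, "B", 360), -60, tolerance = 1e-6)
  fb <- build_fixture("ADP_PI_B")
  expect_equal(abs(chi1(fb$traj, 1, "B", 360)), 180, tolerance = 1e-6)
  rot <- fa$traj
  rot <- set_frame_coords(rot, 1, rigid_move(frame_coords(rot, 1)))
  expect_equal(chi1(rot, 1, "B", 360), -60, tolerance = 1e-6)
  # missing gamma atom is named in the error
  broken <- fa$traj
  broken$atoms$name[broken$atoms$chain == "B" & broken$atoms$resid == 360 &
                      broken$atoms$name == "CG"] <- "XX"
  expect_error(chi1(broken, 1, "B", 360), "missing atom CG")
  expect_error(chi1(fa$traj, 1, "A", 351), "no chi1")
})

test_that("hydrogen-bond detection matches the exhaustive oracle", {
  co <- rbind(c(0, 0, 0), c(2.8, 0, 0), c(4.2, 4, 0))
  hb <- detect_hbonds(co, donors = 1L, acceptors = c(2L, 3L))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$d_DA, 2.8)
  none <- detect_hbonds(rbind(c(0, 0, 0), c(4.2, 0, 0)), 1L, 2L)
  expect_equal(nrow(none), 0L)
  # explicit hydrogen: angle criterion decides
  co_h <- rbind(c(0, 0, 0), c(0.95, 0, 0), c(2.9, 0, 0))
  el <- c("N", "H", "O")
  good <- detect_hbonds(co_h, 1L, 3L, elements = el)
  expect_equal(nrow(good), 1L)
  expect_gt(good$angle, 170)
  co_bad <- rbind(c(0, 0, 0), c(0, 0.95, 0), c(2.9, 0, 0))
  expect_equal(nrow(detect_hbonds(co_bad, 1L, 3L, elements = el)), 0L)
  set.seed(4)
  cloud <- matrix(runif(3 * 120, 0, 12), ncol = 3)
  donors <- sample(120, 25)
  acceptors <- sample(120, 25)
  got <- detect_hbonds(cloud, donors, acceptors, d_max = 3.5)
  want <- hbond_oracle(cloud, donors, acceptors, 3.5)
  expect_equal(nrow(got), nrow(want))
  key <- function(x) sort(paste(x$donor, x$acceptor))
  expect_equal(key(got), key(want))
})

test_that("Kabsch superposition is optimal and matches the quaternion oracle", {
  set.seed(6)
  ref <- matrix(rnorm(45, sd = 4), ncol = 3)
  self <- kabsch_superpose(ref, ref)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)
  moved <- rigid_move(ref)
  expect_lt(kabsch_superpose(ref, moved)$rmsd, 1e-6)
  for (k in 1:10) {
    noisy <- rigid_move(ref + matrix(rnorm(45, sd = 0.4), ncol = 3))
    fit <- kabsch_superpose(ref, noisy)
    expect_equal(fit$rmsd, quaternion_rmsd(ref, noisy), tolerance = 1e-6)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    # no tested rigid transform does better
    for (j in 1:5) {
      alt <- rigid_move(noisy)
      expect_gte(sqrt(mean(rowSums((alt - ref)^2))), fit$rmsd - 1e-9)
    }
  }
  line <- cbind(1:5, 0, 0) + 0
  expect_error(kabsch_superpose(line, line + 1), "degenerate")
  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "degenerate")
})

test_that("coordination shells and octahedricity match direct enumeration", {
  oct <- rbind(c(0, 0, 0),
               c(2.1, 0, 0), c(-2.1, 0, 0), c(0, 2.1, 0), c(0, -2.1, 0),
               c(0, 0, 2.1), c(0, 0, -2.1))
  sh <- coordination_shell(oct, 1L, 2:7, cutoff = 2.6)
  expect_equal(nrow(sh$ligands), 6L)
  expect_equal(sh$octahedricity, 0, tolerance = 1e-9)
  five <- coordination_shell(oct[1:6, ], 1L, 2:6, cutoff = 2.6)
  expect_equal(nrow(five$ligands), 5L)
  expect_true(is.na(five$octahedricity))
  set.seed(7)
  pert <- oct
  pert[2:7, ] <- pert[2:7, ] + matrix(rnorm(18, sd = 0.15), ncol = 3)
  shp <- coordination_shell(pert, 1L, 2:7, cutoff = 2.8)
  expect_equal(shp$octahedricity,
               octahedricity_oracle(pert, 1L, shp$ligands$atom),
               tolerance = 1e-9)
  expect_true(all(diff(shp$ligands$distance) >= 0))
})

test_that("scalar descriptors survive a global rigid motion of the frame", {
  fx <- build_fixture("ADP_PI_A")
  co <- frame_coords(fx$traj, 1)
  mg <- which(fx$traj$atoms$resname == "MG")
  cand <- which(fx$traj$atoms$element %in% c("O", "N"))
  ref <- coordination_shell(co, mg, cand, 2.6)
  set.seed(8)
  moved <- rigid_move(co)
  got <- coordination_shell(moved, mg, cand, 2.6)
  expect_setequal(got$ligands$atom, ref$ligands$atom)
  expect_equal(sort(got$ligands$distance), sort(ref$ligands$distance),
               tolerance = 1e-9)
  expect_equal(got$octahedricity, ref$octahedricity, tolerance = 1e-6)
})
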