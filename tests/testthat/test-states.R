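test_that("state fixtures featurize with the defining geometry", {
  t <- default_thresholds()
  fa <- build_fixture("ADP_PI_A")
  ft <- featurize_site(fa$traj, 1, fa$pocket)
  expect_lte(ft$d1, ft$d2)
  expect_lte(ft$d2, t$r_arg)            # bidentate arginine finger
  expect_lte(ft$d_K251_Pi, t$r_K)       # Walker-A lysine engaged
  expect_lte(ft$d_N348_Pi, t$hbond_d_max)
  expect_gt(ft$d_Mg_T252, t$r_mg_shell) # Mg dissociated from T252
  expect_lte(ft$d_Mg_D304, t$r_mg_shell)
  expect_equal(nrow(ft$mg_shell$ligands), 6L)
  expect_lt(ft$mg_shell$octahedricity, 10)

  fb <- build_fixture("ADP_PI_B")
  fb_ft <- featurize_site(fb$traj, 1, fb$pocket)
  expect_lte(fb_ft$d1, t$r_arg)
  expect_gt(fb_ft$d2, t$r_arg)          # monodentate
  expect_gt(fb_ft$d_K251_Pi, t$r_K)     # detached from K251
  expect_lt(fb_ft$d_R362_Pi, ft$d_R362_Pi)  # pulled toward R362

  fd <- build_fixture("ADP_LIKE")
  fd_ft <- featurize_site(fd$traj, 1, fd$pocket)
  expect_true(is.na(fd_ft$d1))          # Pi-dependent features absent
  expect_equal(fd_ft$n_pi, 0L)
})

test_that("classification follows the rule tree, with UNASSIGNED fallback", {
  states <- c(ATP_LIKE = "ATP_LIKE", REACTIVE_ATP = "ATP_LIKE",
              ADP_PI_A = "ADP_PI_A", ADP_PI_B = "ADP_PI_B",
              ADP_LIKE = "ADP_LIKE", APO_2PI_MIMIC = "APO_2PI_MIMIC")
  for (st in names(states)) {
    fx <- build_fixture(st)
    expect_equal(classify_state(featurize_site(fx$traj, 1, fx$pocket)),
                 unname(states[st]), label = st)
  }
  # conflicting evidence: bidentate arginine finger but trans chi1
  fa <- build_fixture("ADP_PI_A")
  ft <- featurize_site(fa$traj, 1, fa$pocket)
  ft$chi1_F360 <- 180
  expect_equal(classify_state(ft), "UNASSIGNED")
  ft2 <- featurize_site(fa$traj, 1, fa$pocket)
  ft2$d_K251_Pi <- 9   # bidentate but disengaged lysine
  expect_equal(classify_state(ft2), "UNASSIGNED")
  # purity: same features, same label
  expect_identical(classify_state(ft2), classify_state(ft2))
})

test_that("rotamer bins cover the canonical chi1 wells with wraparound", {
  expect_equal(rotamer_bin(-60), "gauche_minus")
  expect_equal(rotamer_bin(180), "trans")
  expect_equal(rotamer_bin(-170), "trans")
  expect_equal(rotamer_bin(60), "gauche_plus")
  expect_equal(rotamer_bin(0, w = 40), "outlier")
  expect_equal(rotamer_bin(120, w = 40), "outlier")
})

test_that("competence criteria respond to the planted perturbations", {
  fx <- build_fixture("REACTIVE_ATP")
  flags <- score_competence(fx$traj, 1, fx$pocket)
  expect_true(flags$crit_water_E305)
  expect_true(flags$crit_R359_polarizes)
  expect_true(flags$crit_N348_holds)
  expect_true(flags$reactive)

  # lytic water deleted -> criterion (i) and reactivity collapse
  keep <- which(!(fx$traj$atoms$chain == "S" & fx$traj$atoms$resid == 500))
  dry <- subset_atoms(fx$traj, keep)
  f2 <- score_competence(dry, 1, fx$pocket)
  expect_false(f2$crit_water_E305)
  expect_false(f2$reactive)
  expect_true(f2$crit_N348_holds)

  # sensor amide displaced beyond the cutoff (the N348Q congestion analogue)
  moved <- fx$traj
  amide <- which(moved$atoms$chain == "A" & moved$atoms$resid == 348 &
                   moved$atoms$name %in% c("ND2", "OD1"))
  co <- frame_coords(moved, 1)
  co[amide, ] <- co[amide, ] + matrix(c(-6, 6, -6), length(amide), 3,
                                      byrow = TRUE)
  moved <- set_frame_coords(moved, 1, co)
  f3 <- score_competence(moved, 1, fx$pocket)
  expect_false(f3$crit_N348_holds)
  expect_false(f3$reactive)

  # plain ATP pocket: geometry present but no positioned lytic water
  fx0 <- build_fixture("ATP_LIKE")
  expect_false(score_competence(fx0$traj, 1, fx0$pocket)$crit_water_E305)

  # ADP pocket has no triphosphate
  fa <- build_fixture("ADP_PI_A")
  expect_error(score_competence(fa$traj, 1, fa$pocket), "state mismatch")
})

test_that("competence flags are monotone in the geometric cutoffs", {
  fx <- build_fixture("REACTIVE_ATP", n_frames = 20, noise_sigma = 0.3,
                      seed = 31)
  t0 <- default_thresholds()
  t_wide <- t0
  t_wide$r_lytic <- t0$r_lytic + 1
  t_wide$r_polar <- t0$r_polar + 1
  t_wide$hbond_d_max <- t0$hbond_d_max + 1
  for (f in seq_len(20)) {
    a <- score_competence(fx$traj, f, fx$pocket, t0)
    b <- score_competence(fx$traj, f, fx$pocket, t_wide)
    expect_true(!a$crit_water_E305 || b$crit_water_E305)
    expect_true(!a$crit_R359_polarizes || b$crit_R359_polarizes)
    expect_true(!a$crit_N348_holds || b$crit_N348_holds)
  }
})

test_that("planted labels are recovered: exactly at zero noise, >=0.95 at 0.3 A", {
  sw0 <- build_fixture("ADP_PI_A", n_frames = 80, noise_sigma = 0,
                       switch = list(to_state = "ADP_PI_B", frame = 41))
  ts0 <- state_timeseries(sw0$traj, sw0$pocket)
  expect_equal(mean(ts0$records$label == sw0$truth$state), 1.0)
  sw <- build_fixture("ADP_PI_A", n_frames = 200, noise_sigma = 0.3,
                      switch = list(to_state = "ADP_PI_B", frame = 101),
                      seed = 23)
  ts <- state_timeseries(sw$traj, sw$pocket)
  expect_gte(mean(ts$records$label == sw$truth$state), 0.95)
})

test_that("transitions honour the persistence filter", {
  sw <- build_fixture("ADP_PI_A", n_frames = 100, noise_sigma = 0,
                      switch = list(to_state = "ADP_PI_B", frame = 60))
  for (p in c(1L, 5L, 10L, 25L)) {
    ts <- state_timeseries(sw$traj, sw$pocket, persistence = p)
    expect_equal(ts$transitions$frame, 60L, label = paste("persistence", p))
  }
  const <- build_fixture("ADP_PI_A", n_frames = 30)
  expect_equal(nrow(state_timeseries(const$traj, const$pocket)$transitions),
               0L)
  # a 4-frame flicker is suppressed at persistence 10
  flick <- build_fixture("ADP_PI_A", n_frames = 40)
  bpatch <- build_fixture("ADP_PI_B")
  for (f in 20:23)
    flick$traj <- set_frame_coords(flick$traj, f,
                                   frame_coords(bpatch$traj, 1))
  ts <- state_timeseries(flick$traj, flick$pocket, persistence = 10L)
  expect_equal(nrow(ts$transitions), 0L)
  ts1 <- state_timeseries(flick$traj, flick$pocket, persistence = 1L)
  expect_gte(nrow(ts1$transitions), 2L)
})

test_that("ion-position clustering recovers the two planted sites", {
  sw <- build_fixture("ADP_PI_A", n_frames = 300, noise_sigma = 0.3,
                      switch = list(to_state = "ADP_PI_B", frame = 121),
                      seed = 13)
  cl <- cluster_ion_positions(sw$traj, sw$pocket, "PI", radius = 2)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$occupancy[1], 0.6, tolerance = 0.02 / 0.6)
  expect_equal(cl$occupancy[2], 0.4, tolerance = 0.02 / 0.4)
  expect_gt(sqrt(sum((as.numeric(cl[1, 1:3]) -
                        as.numeric(cl[2, 1:3]))^2)), 3)
  stat <- build_fixture("ADP_PI_A", n_frames = 25, noise_sigma = 0.1,
                        seed = 2)
  cs <- cluster_ion_positions(stat$traj, stat$pocket, "PI", radius = 2)
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$occupancy, 1.0)
  mg <- cluster_ion_positions(stat$traj, stat$pocket, "MG", radius = 2)
  expect_equal(nrow(mg), 1L)
})

test_that("clustering is invariant to a global rigid motion of all frames", {
  sw <- build_fixture("ADP_PI_A", n_frames = 60, noise_sigma = 0.2,
                      switch = list(to_state = "ADP_PI_B", frame = 31),
                      seed = 17)
  ref <- cluster_ion_positions(sw$traj, sw$pocket, "PI", radius = 2)
  set.seed(99)
  rot <- random_rotation()
  shift <- runif(3, -20, 20)
  moved <- sw$traj
  for (f in seq_len(n_frames(moved)))
    moved <- set_frame_coords(moved, f,
                              rigid_move(frame_coords(moved, f), rot, shift))
  got <- cluster_ion_positions(moved, sw$pocket, "PI", radius = 2)
  expect_equal(got$occupancy, ref$occupancy)
  expect_equal(got$n_frames, ref$n_frames)
})
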