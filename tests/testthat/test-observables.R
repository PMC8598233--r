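make_traj <- function(pos, dt = 1e-3) {
  focisim:::new_trajectory(t = (seq_len(nrow(pos)) - 1) * dt, pos = pos,
                           dt = dt, record_every = 1L)
}

test_that("measurement model projects, subsamples, slabs, splits, adds noise", {
  set.seed(1)
  pos <- cbind(cumsum(rnorm(400, sd = 0.01)), cumsum(rnorm(400, sd = 0.01)),
               seq(-0.3, 0.3, length.out = 400))
  tr <- make_traj(pos, dt = 1e-3)
  # sigma = 0, no slab: exact projection at the subsampled frames
  obs <- apply_measurement_model(tr, sigma = 0, dt_obs = 2e-3, z_slab = Inf)
  expect_equal(obs$x_um, pos[seq(1, 400, 2), 1])
  expect_equal(length(unique(obs$track_id)), 1L)
  # frames are 0-based and contiguous within each track after slab filtering
  obs2 <- apply_measurement_model(tr, sigma = 0, dt_obs = 1e-3, z_slab = 0.15)
  expect_true(all(obs2$frame >= 0))
  spl <- split(obs2$frame, obs2$track_id)
  expect_true(all(vapply(spl, function(f) all(diff(f) == 1), logical(1))))
  # a z-excursion in the middle creates two tracks
  pos3 <- pos; pos3[180:220, 3] <- 0.5; pos3[-(180:220), 3] <- 0
  obs3 <- apply_measurement_model(make_traj(pos3), 0, 1e-3, 0.15)
  expect_equal(length(unique(obs3$track_id)), 2L)
  # static particle: apparent per-axis displacement variance is 2 sigma^2
  posS <- matrix(0, 2000, 3)
  obs4 <- apply_measurement_model(make_traj(posS), sigma = 0.03,
                                  dt_obs = 1e-3, z_slab = Inf, seed = 3)
  expect_equal(stats::var(diff(obs4$x_um)), 2 * 0.03^2, tolerance = 0.1)
  # slab retention on uniform-in-ball positions matches the geometric ratio
  set.seed(9)
  u <- matrix(rnorm(3 * 40000), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * runif(40000)^(1 / 3) * 0.3
  obs5 <- apply_measurement_model(make_traj(u), 0, 1e-3, 0.15)
  h <- 0.15 / 0.3
  expect_equal(nrow(obs5) / 40000, 1.5 * h - 0.5 * h^3, tolerance = 0.02)
  expect_error(apply_measurement_model(tr, dt_obs = 1.5e-3), "multiple")
})

test_that("displacement histogram matches free-diffusion theory when true", {
  tab <- synth_free_tracks_2d(30, 200, D = 0.5, dt = 1e-3, seed = 4)
  dh <- displacement_histogram(tab, lag = 1L)
  expect_equal(dh$D_fit, 0.5, tolerance = 0.05)
  expect_gt(dh$ks$p.value, 0.01)
  expect_error(displacement_histogram(tab[1:50, ]), "100")
})

test_that("radial diffusivity profile is flat for free diffusion and
           noise-corrected when sigma is supplied", {
  tab <- synth_free_tracks_2d(60, 200, D = 0.8, dt = 1e-3, seed = 5,
                              start_radius = 0.3)
  pr <- radial_diffusivity_profile(tab, center = c(0, 0), bin_width = 0.1)
  ok <- pr$n > 300
  expect_true(all(abs(pr$value[ok] - 0.8) < 3 * pr$se[ok] + 0.02))
  # corrupt with localization noise, then correct
  set.seed(6)
  tabn <- tab
  tabn$x_um <- tabn$x_um + rnorm(nrow(tab), sd = 0.03)
  tabn$y_um <- tabn$y_um + rnorm(nrow(tab), sd = 0.03)
  pr_raw <- radial_diffusivity_profile(tabn, c(0, 0), 0.2)
  pr_cor <- radial_diffusivity_profile(tabn, c(0, 0), 0.2, sigma = 0.03)
  okk <- pr_raw$n > 500
  expect_gt(mean(pr_raw$value[okk]), 0.8 + 0.0005 / 1e-3)  # inflated by 2sig^2/(2dt)...
  expect_equal(stats::weighted.mean(pr_cor$value[okk], pr_cor$n[okk]), 0.8,
               tolerance = 0.05)
})

test_that("radial density profile is flat in volume for uniform occupancy", {
  set.seed(7)
  u <- matrix(rnorm(3 * 30000), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * runif(30000)^(1 / 3) * 0.3
  tab <- as_track_table(make_traj(u))
  pr <- radial_density_profile(tab, c(0, 0, 0), bin_width = 0.05, r_max = 0.3)
  ok <- pr$n > 100
  v0 <- 1 / (4 / 3 * pi * 0.3^3)
  expect_true(all(abs(pr$value[ok] - v0) < 4 * pr$se[ok]))
})

test_that("mean radial displacement shows the d = 2 coordinate drift", {
  tab <- synth_free_tracks_2d(150, 150, D = 1, dt = 2.5e-4, seed = 8,
                              start_radius = 0.45)
  pr <- mean_radial_displacement(tab, c(0, 0), bin_width = 0.05, r_max = 0.45)
  sel <- which(pr$n > 1500 & pr$r >= 0.15)
  th <- 2.5e-4 * 1 / pr$r[sel]
  expect_true(all(abs(pr$value[sel] - th) <
                    pmax(3 * pr$se[sel], 0.1 * th)))
})

test_that("angle distribution: uniform for free motion, reversal-enriched in
           a droplet", {
  tab <- synth_free_tracks_2d(40, 300, D = 0.5, dt = 1e-3, seed = 9)
  a <- angle_distribution(tab)
  expect_gt(suppressWarnings(a$chisq$p.value), 0.01)
  expect_lt(abs(a$asymmetry - 1), 0.25)
  # confined droplet tracks: enrichment of ~180 degree reversals
  trL <- lpm_obs()
  obsL <- apply_measurement_model(trL, sigma = 0.03, dt_obs = 0.02,
                                  z_slab = 0.15, seed = 10)
  aL <- angle_distribution(obsL)
  expect_gt(aL$asymmetry, 1.3)
})

test_that("two-population mixture fit recovers diffusivities", {
  # single population flags degenerate and recovers D within 5%
  tab1 <- synth_free_tracks_2d(50, 200, D = 0.3, dt = 1e-3, seed = 12)
  f1 <- fit_two_population_displacements(tab1, sigma = 0)
  expect_true(f1$degenerate)
  expect_equal(f1$D_slow, 0.3, tolerance = 0.05)
  # synthetic two-population tracks: recovery within 15% at ~1e4 displacements
  tabA <- synth_free_tracks_2d(30, 120, D = 0.05, dt = 5e-3, seed = 13)
  tabB <- synth_free_tracks_2d(30, 120, D = 1.0, dt = 5e-3, seed = 14)
  tabB$track_id <- paste0("f", tabB$track_id)
  f2 <- fit_two_population_displacements(rbind(tabA, tabB), sigma = 0)
  expect_false(f2$degenerate)
  expect_equal(f2$D_slow, 0.05, tolerance = 0.15)
  expect_equal(f2$D_fast, 1.0, tolerance = 0.15)
  expect_equal(f2$weight_slow, 0.5, tolerance = 0.15)
  # droplet tracks with localization noise: noise-corrected recovery
  obsL <- apply_measurement_model(lpm_obs(), sigma = 0.03, dt_obs = 5e-3,
                                  z_slab = Inf, seed = 15)
  fL <- fit_two_population_displacements(obsL, sigma = 0.03)
  expect_equal(fL$D_slow, 0.05, tolerance = 0.3)
  expect_equal(fL$D_fast, 1.0, tolerance = 0.25)
})

test_that("focus centre and droplet parameters are recovered from tracks", {
  tab <- as_track_table(lpm_obs())
  est <- estimate_focus_center_and_params(tab, bin_width = 5e-3)
  expect_lt(sqrt(sum(est$center^2)), 0.02)
  expect_equal(est$r_f, 0.1, tolerance = 0.2)
  expect_equal(est$D0, 0.05, tolerance = 0.15)
  expect_lt(abs(est$A - 5), 0.5)
  # translation equivariance
  tab2 <- tab
  tab2$x_um <- tab2$x_um + 0.35
  est2 <- estimate_focus_center_and_params(tab2, bin_width = 5e-3)
  expect_equal(est2$center[1] - est$center[1], 0.35, tolerance = 1e-6)
  expect_equal(est2$A, est$A, tolerance = 1e-6)
  # uniform tracks: no focus
  set.seed(16)
  u <- matrix(rnorm(3 * 5000), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * runif(5000)^(1 / 3) * 0.3
  expect_error(estimate_focus_center_and_params(as_track_table(make_traj(u))),
               "no focus")
})

test_that("profile estimators are invariant under rotations about the centre", {
  tab <- as_track_table(pbm_main())
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- as.matrix(tab[, c("x_um", "y_um", "z_um")]) %*% R
  tabR <- tab
  tabR$x_um <- rot[, 1]; tabR$y_um <- rot[, 2]; tabR$z_um <- rot[, 3]
  p1 <- radial_density_profile(tab, c(0, 0, 0), 0.01, r_max = 0.19)
  p2 <- radial_density_profile(tabR, c(0, 0, 0), 0.01, r_max = 0.19)
  expect_equal(p1$value, p2$value, tolerance = 1e-12)
  d1 <- radial_diffusivity_profile(tab, c(0, 0, 0), 0.01, r_max = 0.19)
  d2 <- radial_diffusivity_profile(tabR, c(0, 0, 0), 0.01, r_max = 0.19)
  expect_equal(d1$value, d2$value, tolerance = 1e-12)
})

test_that("maximal positive difference separates droplet from binding sites", {
  # binding-site tracks: the statistic is consistent with zero
  mpdP <- maximal_positive_difference(as_track_table(pbm_main()),
                                      c(0, 0, 0), Db_assumed = 0.005,
                                      r_f = 0.1, bin_width = 5e-3)
  expect_lt(mpdP$mpd, 3 * mpdP$se)
  # droplet tracks: significantly positive, and larger at higher D0
  mpdL <- maximal_positive_difference(as_track_table(lpm_main(0.05)),
                                      c(0, 0, 0), Db_assumed = 0.005,
                                      r_f = 0.1, bin_width = 5e-3)
  expect_gt(mpdL$mpd, 3 * mpdL$se)
  mpdL2 <- maximal_positive_difference(as_track_table(lpm_main(0.2)),
                                       c(0, 0, 0), Db_assumed = 0.005,
                                       r_f = 0.1, bin_width = 5e-3)
  expect_gt(mpdL2$mpd, mpdL$mpd)
})

test_that("binding detectability degrades with fast exchange and with noise", {
  p <- pbm_params(geometry(0.1, 0.5), Dn = 1, Db = 0.005, rho = 2e3,
                  r_b = 0.01, kappa = 100, k_off = 100)
  m0 <- ks_detectability(p, dt_obs_grid = c(1e-3, 4e-3),
                         k_off_grid = c(50, 5000), sigma = 0,
                         n_disp = 1200L, seed = 21L, box_size = 0.15)
  slow_small <- m0[m0$k_off == 50 & m0$dt_obs == 1e-3, ]
  fast <- m0[m0$k_off == 5000 & m0$dt_obs == 4e-3, ]
  expect_true(slow_small$detectable)
  expect_gt(slow_small$statistic, fast$statistic)
  # localization noise shrinks the KS statistic in the detectable corner
  mN <- ks_detectability(p, dt_obs_grid = 1e-3, k_off_grid = 50,
                         sigma = 0.03, n_disp = 1200L, seed = 21L,
                         box_size = 0.15)
  expect_lt(mN$statistic, slow_small$statistic)
  # no sites: the null is true
  p0 <- pbm_params(geometry(0.1, 0.5), rho = 0, kappa = 1e-9)
  m00 <- ks_detectability(p0, dt_obs_grid = 1e-3, k_off_grid = 500,
                          sigma = 0, n_disp = 800L, seed = 22L,
                          box_size = 0.15)
  expect_gt(m00$p_value, 0.01)
})
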