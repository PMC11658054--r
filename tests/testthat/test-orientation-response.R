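# Specified-direction Rayleigh statistic, orientation sampling, difference
# maps, attraction test, pre/post mobility.

test_that("rayleigh rho hits its analytic anchor points", {
  set.seed(1)
  mu <- runif(100, 0, 2 * pi)
  expect_equal(rayleigh_rho(mu, mu), 1)
  expect_equal(rayleigh_rho(mu + pi, mu), -1)
  # orthogonal-quadrant cancellation
  th <- c(0, pi / 2, pi, 3 * pi / 2)
  expect_equal(rayleigh_rho(th, rep(0, 4)), 0, tolerance = 1e-12)
  # oracle identity: rho is the brute-force mean cosine
  th2 <- runif(57, 0, 2 * pi); mu2 <- runif(57, 0, 2 * pi)
  expect_equal(rayleigh_rho(th2, mu2), sum(cos(th2 - mu2)) / 57)
  expect_true(is.na(rayleigh_rho(numeric(0), numeric(0))))
})

orient_scene <- function(rx, ry, rhead = 1, mhead = 0, n = 21) {
  tgrid <- (seq_len(n) - 1) * 0.5
  mkb <- function(id, x, y, h) data.frame(bee_id = id, time_s = tgrid,
                                          x = x, y = y, heading_rad = h,
                                          side = 0)
  traj <- rbind(mkb("Q", 10, 10, 0), mkb("M", 0, 0, mhead),
                mkb("R", rx, ry, rhead))
  bees <- data.frame(bee_id = c("Q", "M", "R"),
                     role = c("queen", "worker", "worker"))
  qc <- data.frame(i = "Q", j = "M", t_start_s = 4, t_end_s = 6,
                   frac_frames_i_inspects = 0, frac_frames_j_inspects = 1)
  collect_orientation_samples(qc, traj, bees, window = 4)
}

test_that("orientation samples: radius cut, frame rotation and mu geometry", {
  # neighbour at 2.5 BL: excluded
  expect_equal(nrow(orient_scene(2.5, 0)), 0)
  # messenger heading pi/2, receiver due north -> +x in messenger frame
  s <- orient_scene(0, 1.5, mhead = pi / 2)
  post <- s[s$t_rel_s > 0, ]
  expect_gt(nrow(post), 0)
  expect_equal(unique(post$x_bl), 1.5, tolerance = 1e-9)
  expect_equal(unique(post$y_bl), 0, tolerance = 1e-9)
  # mu equals the hand-computed bearing to the nearest trapezium point
  s2 <- orient_scene(1.5, 0.8, mhead = 0)
  post2 <- s2[s2$t_rel_s > 0, ][1, ]
  quad <- build_body_polygon(0, 0, 0, "worker")
  dens <- do.call(rbind, lapply(1:4, function(k) {
    k2 <- if (k == 4) 1 else k + 1
    tt <- seq(0, 1, length.out = 2001)
    cbind(quad[k, 1] + tt * (quad[k2, 1] - quad[k, 1]),
          quad[k, 2] + tt * (quad[k2, 2] - quad[k, 2]))
  }))
  d2 <- (dens[, 1] - 1.5)^2 + (dens[, 2] - 0.8)^2
  np <- dens[which.min(d2), ]
  mu_hand <- atan2(np[2] - 0.8, np[1] - 1.5) %% (2 * pi)
  expect_equal(post2$mu, mu_hand, tolerance = 1e-3)
  # pre-window samples carry negative relative times
  expect_true(any(s2$t_rel_s < 0))
})

fake_samples <- function(n = 400, seed = 2) {
  set.seed(seed)
  base <- data.frame(
    colony = "C1", messenger = sample(c("M1", "M2"), n, TRUE),
    receiver = "R", x_bl = runif(n, -1, 1), y_bl = runif(n, -1, 1),
    theta = runif(n, 0, 2 * pi), mu = runif(n, 0, 2 * pi),
    messenger_load_pg = runif(n, 0, 100))
  rbind(cbind(base, t_rel_s = runif(n, 0, 60)),
        cbind(base, t_rel_s = runif(n, -60, 0)))
}

test_that("difference maps: identical strata cancel, swapped strata negate,
           sparse cells mask", {
  s <- fake_samples()
  # identical post and pre samples (same theta/mu/cells) -> zero map
  dm <- difference_map(s, "time", k = 1, cell = 1, min_count = 5)
  expect_true(all(abs(dm$drho) < 1e-12, na.rm = TRUE))
  expect_true(any(!is.na(dm$drho)))
  # masked exactly where either stratum count is below threshold
  dm2 <- difference_map(s, "time", k = 1, cell = 1, min_count = 1e6)
  expect_true(all(is.na(dm2$drho)))
  # antisymmetry under stratum swap: negate pre/post roles by flipping time
  s_swap <- s
  s_swap$t_rel_s <- -s_swap$t_rel_s
  set.seed(9)
  s3 <- s
  s3$theta[s3$t_rel_s > 0] <- (s3$theta[s3$t_rel_s > 0] + 0.7) %% (2 * pi)
  s3_swap <- s3
  s3_swap$t_rel_s <- -s3_swap$t_rel_s
  d3 <- difference_map(s3, "time", k = 1, cell = 1, min_count = 5)
  d3s <- difference_map(s3_swap, "time", k = 1, cell = 1, min_count = 5)
  expect_equal(d3$drho, -d3s$drho, tolerance = 1e-12)
})

test_that("angular transect: zero for identical strata; counts add up", {
  s <- fake_samples()
  tr <- angular_transect(s, "time", k = 1, n_bins = 8)
  expect_true(all(abs(tr$drho) < 1e-12, na.rm = TRUE))
  expect_equal(sum(tr$n), sum(s$t_rel_s > 0 & s$t_rel_s <= 60))
  # load variant on deciles
  s <- assign_load_deciles(s)
  expect_true(all(s$load_decile %in% 1:10))
  trl <- angular_transect(s, "load", decile = 10, n_bins = 8)
  expect_equal(nrow(trl), 8)
})

# mean-reverting track: mixes over ~25 s so 60-s-thinned samples are
# close to independent
rw_track <- function(id, n, seed, x0 = 20, y0 = 20, sd = 0.35,
                     phi = 0.98) {
  set.seed(seed)
  ar <- function() {
    v <- numeric(n)
    v[1] <- rnorm(1, 0, sd / sqrt(1 - phi^2))
    for (t in 2:n) v[t] <- phi * v[t - 1] + rnorm(1, 0, sd)
    v
  }
  data.frame(bee_id = id, time_s = (seq_len(n) - 1) * 0.5,
             x = pmin(pmax(x0 + ar(), 1), 63),
             y = pmin(pmax(y0 + ar(), 1), 43),
             heading_rad = 0, side = 0)
}

test_that("attraction test: glued worker highly significant, negative effect", {
  n <- 2000
  qt <- rw_track("Q", n, seed = 31)
  wt <- qt
  wt$bee_id <- "W"
  wt$x <- wt$x + 0.5 # glued at constant 0.5 BL offset
  bouts <- data.frame(state = "S", t_start_s = 0, t_end_s = n * 0.5,
                      duration_s = n * 0.5, mean_posterior = 1)
  r <- queen_attraction_test(wt, qt, bouts, thin_s = 10)
  expect_lt(r$p, 1e-4)
  expect_lt(r$effect_bl, 0)
  # time-shuffling the worker trajectory destroys the signal
  set.seed(5)
  wt2 <- wt
  wt2[, c("x", "y")] <- wt[sample(n), c("x", "y")]
  r2 <- queen_attraction_test(wt2, qt, bouts, thin_s = 10)
  expect_gt(r2$p, 0.01)
})

test_that("attraction test is calibrated under independence", {
  bouts <- data.frame(state = "S", t_start_s = 0, t_end_s = 900,
                      duration_s = 900, mean_posterior = 1)
  ps <- vapply(1:60, function(s) {
    qt <- rw_track("Q", 1800, seed = 1000 + s)
    wt <- rw_track("W", 1800, seed = 5000 + s, x0 = 25, y0 = 18)
    queen_attraction_test(wt, qt, bouts, thin_s = 30, seed = s)$p
  }, numeric(1))
  # roughly uniform p-values: false-positive rate near alpha
  expect_lte(sum(ps < 0.05), 9)
  expect_gt(mean(ps), 0.25)
})

test_that("mobility pre/post: planted excitation raises early post speed", {
  sim <- small_colony()
  ct <- small_contacts()
  qc <- ct[ct$i == "Q" | ct$j == "Q", ]
  mc <- mobility_prepost(qc, sim$traj, sim$bees, window = 300)
  # side-switch rates bounded by the frame rate
  expect_true(all(mc$switch_pre >= 0 & mc$switch_pre <= 2, na.rm = TRUE))
  # positive speed difference while the excitation boost lasts
  early <- mc$t_s <= 120
  expect_gt(mean(mc$speed_diff[early], na.rm = TRUE), 0)
  # stationary workers throughout give an identically zero difference
  n <- 30
  still <- rbind(
    data.frame(bee_id = "Q", time_s = (1:n) / 2, x = 5, y = 5,
               heading_rad = 0, side = 0),
    data.frame(bee_id = "W", time_s = (1:n) / 2, x = 8, y = 8,
               heading_rad = 0, side = 0))
  bees <- data.frame(bee_id = c("Q", "W"), role = c("queen", "worker"))
  qc0 <- data.frame(i = "Q", j = "W", t_start_s = 5, t_end_s = 7)
  m0 <- mobility_prepost(qc0, still, bees, window = 4)
  expect_true(all(m0$speed_diff == 0, na.rm = TRUE))
})
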