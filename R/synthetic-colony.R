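# Seeded synthetic colonies: a two-state queen, age-structured workers
# introduced in staggered cohorts on a double-sided comb with one broodnest
# patch per side, and ground truth for every latent quantity the downstream
# modules estimate.

#' Synthetic colony configuration
#'
#' Defaults mirror the study design: a 64 x 44 body-length (BL) double-sided
#' comb tracked at 2 frames/s for 24-h days, eight cohorts of 290 callows
#' introduced three days apart, a queen alternating between a stationary (S)
#' and a travelling (T) movement state (mean dwell 60 s / 44 s, long-run
#' stationary fraction ~0.58), and workers whose queen attraction peaks at
#' 3-4 days of age before the transition to foraging. Tests and examples use
#' far smaller colonies by overriding `cohort_schedule`, `day_length_s` and
#' `frame_rate`-derived sizes.
#'
#' @param cohort_schedule data.frame with `day` (introduction day) and `size`.
#' @param n_days number of days available for simulation.
#' @param frame_rate frames per second.
#' @param day_length_s seconds simulated per day.
#' @param comb_width,comb_height comb dimensions (BL).
#' @param queen_state_params list: `step_mean`, `step_sd` (BL/frame, named
#'   S/T), `zero_prob` (per-state probability of an exact zero step),
#'   `turn_kappa` (von Mises concentration of turning angles), `switch`
#'   (2 x 2 row-stochastic state-switch matrix, order S,T).
#' @param worker_age_profiles list of age-profile parameters: queen-attraction
#'   peak/width/strength, broodnest-fidelity decay, mobility rise, forager
#'   transition age.
#' @param broodnest_centres data.frame `x, y, side` (one patch per side).
#' @param broodnest_radius patch radius (BL); each worker keeps a private
#'   home site drawn within its patch.
#' @param queen_roam_radius soft confinement radius of the queen around her
#'   side's broodnest centre (BL).
#' @param entrance `c(x, y)` of the nest entrance corner (side 0).
#' @param excitation list: post-queen-contact `boost` (speed multiplier),
#'   `duration_s`, `radius_bl` (queen proximity that triggers it).
#' @param side_switch_prob per-frame switching probability within 1 BL of the
#'   comb boundary.
#' @param seed integer master seed.
#' @return a `colony_config` list.
#' @export
colony_config <- function(cohort_schedule = data.frame(day = seq(0, 21, by = 3),
                                                       size = 290),
                          n_days = 25,
                          frame_rate = 2,
                          day_length_s = 86400,
                          comb_width = 64, comb_height = 44,
                          queen_state_params = list(
                            step_mean = c(S = 0.02, T = 0.25),
                            step_sd = c(S = 0.02, T = 0.15),
                            zero_prob = c(S = 0.40, T = 0.02),
                            turn_kappa = c(S = 0.5, T = 8),
                            switch = matrix(c(1 - 1 / 120, 1 / 120,
                                              1 / 88, 1 - 1 / 88),
                                            2, 2, byrow = TRUE,
                                            dimnames = list(c("S", "T"),
                                                            c("S", "T")))
                          ),
                          worker_age_profiles = list(
                            attraction_max = 0.8,
                            attraction_peak_age = 3.5,
                            attraction_sd = 1.5,
                            fidelity_max = 1.0,
                            fidelity_decay_age = 6,
                            mobility_min = 0.04,
                            mobility_max = 0.15,
                            mobility_rise_age = 4,
                            forager_transition_age = 10
                          ),
                          broodnest_centres = data.frame(
                            x = c(24, 40), y = c(22, 22), side = c(0, 1)),
                          broodnest_radius = 8,
                          queen_roam_radius = 9,
                          entrance = c(64, 0),
                          excitation = list(boost = 2.0, duration_s = 240,
                                            radius_bl = 1.5),
                          side_switch_prob = 0.02,
                          seed = 1L) {
  stopifnot(frame_rate > 0, day_length_s > 0, comb_width > 0, comb_height > 0,
            all(cohort_schedule$size > 0), all(cohort_schedule$day >= 0),
            nrow(broodnest_centres) == 2)
  sw <- queen_state_params$switch
  if (any(sw < 0) || any(abs(rowSums(sw) - 1) > 1e-9)) {
    stop("state-switch matrix must be row-stochastic")
  }
  stopifnot(all(queen_state_params$step_mean > 0),
            all(queen_state_params$step_sd > 0),
            all(queen_state_params$turn_kappa >= 0))
  cfg <- list(cohort_schedule = cohort_schedule, n_days = n_days,
              frame_rate = frame_rate, day_length_s = day_length_s,
              comb_width = comb_width, comb_height = comb_height,
              queen_state_params = queen_state_params,
              worker_age_profiles = worker_age_profiles,
              broodnest_centres = broodnest_centres,
              broodnest_radius = broodnest_radius,
              queen_roam_radius = queen_roam_radius,
              entrance = entrance, excitation = excitation,
              side_switch_prob = side_switch_prob, seed = as.integer(seed))
  class(cfg) <- "colony_config"
  cfg
}

#' @export
print.colony_config <- function(x, ...) {
  cat("colony_config:", sum(x$cohort_schedule$size), "workers in",
      nrow(x$cohort_schedule), "cohorts;", x$day_length_s, "s/day at",
      x$frame_rate, "fps;", x$comb_width, "x", x$comb_height, "BL comb\n")
  invisible(x)
}

# gamma draws parameterised by mean and sd
rgamma_ms <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

age_attraction <- function(p, age) {
  p$attraction_max * exp(-((age - p$attraction_peak_age)^2) /
                           (2 * p$attraction_sd^2))
}

age_fidelity <- function(p, age) {
  p$fidelity_max * exp(-age / p$fidelity_decay_age)
}

age_mobility <- function(p, age) {
  p$mobility_min + (p$mobility_max - p$mobility_min) *
    (1 - exp(-age / p$mobility_rise_age))
}

day_seed <- function(config, day, stream = 0L) {
  derive_seeds(config$seed + 131L * stream, config$n_days + 1L)[day + 1L]
}

#' Simulate one daily queen trajectory
#'
#' Correlated random walk with a hidden two-state Markov chain: per state,
#' step lengths are zero-inflated gamma and turning angles von Mises. The
#' true state sequence is returned alongside the trajectory.
#'
#' @param config [colony_config()].
#' @param day day index (0-based, days since first cohort introduction).
#' @return list with `traj` (data.frame `bee_id, time_s, x, y, heading_rad,
#'   side`) and `states` (data.frame `time_s, queen_state`).
#' @export
simulate_queen_trajectory <- function(config, day) {
  qp <- config$queen_state_params
  sw <- qp$switch
  if (any(rowSums(sw) != 1) && any(abs(rowSums(sw) - 1) > 1e-9)) {
    stop("non-stochastic state-switch matrix")
  }
  set.seed(day_seed(config, day, 1L))
  n <- round(config$day_length_s * config$frame_rate)
  dt <- 1 / config$frame_rate
  states <- integer(n) # 1=S, 2=T
  states[1] <- 1L
  u <- stats::runif(n)
  for (t in 2:n) {
    states[t] <- if (u[t] < sw[states[t - 1], 1]) 1L else 2L
  }
  lab <- c("S", "T")[states]
  step <- numeric(n)
  turn <- numeric(n)
  for (s in 1:2) {
    idx <- which(states == s)
    z <- stats::runif(length(idx)) < qp$zero_prob[s]
    st <- rgamma_ms(length(idx), qp$step_mean[s], qp$step_sd[s])
    st[z] <- 0
    step[idx] <- st
    turn[idx] <- angle_diff(rvonmises(length(idx), 0, qp$turn_kappa[s]), 0)
  }
  dir <- cumsum(c(stats::runif(1, 0, 2 * pi), turn[-1])) %% (2 * pi)
  x <- numeric(n); y <- numeric(n)
  # queen starts in the side-0 broodnest patch
  bc <- config$broodnest_centres[config$broodnest_centres$side == 0, ]
  x[1] <- bc$x[1]; y[1] <- bc$y[1]
  m <- 1 # boundary margin, BL
  roam <- config$queen_roam_radius
  for (t in 2:n) {
    # soft confinement to the broodnest area: outside the roam radius the
    # direction blends toward the patch centre
    dxc <- bc$x[1] - x[t - 1]; dyc <- bc$y[1] - y[t - 1]
    if (dxc^2 + dyc^2 > roam^2) {
      home_ang <- atan2(dyc, dxc)
      blend <- atan2(0.25 * sin(home_ang) + 0.75 * sin(dir[t]),
                     0.25 * cos(home_ang) + 0.75 * cos(dir[t]))
      dir[t:n] <- dir[t:n] + (blend - dir[t])
    }
    nx <- x[t - 1] + step[t] * cos(dir[t])
    ny <- y[t - 1] + step[t] * sin(dir[t])
    if (nx < m || nx > config$comb_width - m) {
      dir[t:n] <- (pi - dir[t:n]) %% (2 * pi)
      nx <- min(max(nx, m), config$comb_width - m)
    }
    if (ny < m || ny > config$comb_height - m) {
      dir[t:n] <- (-dir[t:n]) %% (2 * pi)
      ny <- min(max(ny, m), config$comb_height - m)
    }
    x[t] <- nx; y[t] <- ny
  }
  heading <- dir
  if (n > 1) { # stationary frames keep the previous heading
    keep <- step < 1e-9
    keep[1] <- FALSE
    for (t in which(keep)) heading[t] <- heading[max(t - 1, 1)]
  }
  tsec <- (seq_len(n) - 1) * dt
  list(
    traj = data.frame(bee_id = "Q", time_s = tsec, x = x, y = y,
                      heading_rad = wrap_angle(heading), side = 0,
                      stringsAsFactors = FALSE),
    states = data.frame(time_s = tsec, queen_state = lab,
                        stringsAsFactors = FALSE)
  )
}

# workers present on a given day, with ages, home patches and private home
# sites (stable across days for a given worker)
worker_roster <- function(config, day) {
  cs <- config$cohort_schedule
  present <- cs$day <= day
  if (!any(present)) return(NULL)
  ids <- character(0); ecl <- numeric(0)
  for (k in seq_len(nrow(cs))) {
    ids <- c(ids, sprintf("W%02d_%03d", cs$day[k], seq_len(cs$size[k])))
    ecl <- c(ecl, rep(cs$day[k], cs$size[k]))
  }
  # deterministic home-patch assignment: alternate within cohort
  patch <- rep_len(c("A", "B"), length(ids))
  # private home sites within the patch, fixed for the colony lifetime
  set.seed(derive_seeds(config$seed + 977L, 1))
  r <- config$broodnest_radius * sqrt(stats::runif(length(ids)))
  th <- stats::runif(length(ids), 0, 2 * pi)
  out <- data.frame(bee_id = ids, eclosion_day = ecl, age = day - ecl,
                    patch = patch, home_dx = r * cos(th),
                    home_dy = r * sin(th), stringsAsFactors = FALSE)
  out <- out[out$eclosion_day <= day, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate the worker population for one day
#'
#' Each worker present on `day` receives a biased correlated random walk
#' whose drift mixes broodnest fidelity, queen attraction (same side only)
#' and, past the forager transition age, a pull toward the entrance corner;
#' age-dependent weights follow the configured profiles. Physical contact
#' with the queen triggers a transient mobility boost ("excitation").
#'
#' @param config [colony_config()].
#' @param day day index.
#' @param queen output of [simulate_queen_trajectory()] for the same day.
#' @return list with `traj` (all workers, long format), `roster`
#'   (per-worker `bee_id, eclosion_day, age, patch, community`).
#' @export
simulate_worker_population <- function(config, day, queen) {
  roster <- worker_roster(config, day)
  if (is.null(roster)) {
    warning("day precedes first cohort introduction: empty worker set")
    return(list(traj = empty_traj(), roster = data.frame()))
  }
  set.seed(day_seed(config, day, 2L))
  ap <- config$worker_age_profiles
  nb <- nrow(roster)
  n <- nrow(queen$traj)
  dt <- 1 / config$frame_rate
  W <- config$comb_width; Hh <- config$comb_height
  qx <- queen$traj$x; qy <- queen$traj$y; qside <- queen$traj$side

  w_att <- age_attraction(ap, roster$age)
  w_fid <- age_fidelity(ap, roster$age)
  mob <- age_mobility(ap, roster$age)
  is_for <- roster$age >= ap$forager_transition_age
  w_fid[is_for] <- 0 # foragers have left the broodnest
  bc <- config$broodnest_centres
  home <- ifelse(roster$patch == "A", 1, 2)
  hx <- pmin(pmax(bc$x[home] + roster$home_dx, 1), W - 1)
  hy <- pmin(pmax(bc$y[home] + roster$home_dy, 1), Hh - 1)
  hside <- bc$side[home]
  roster$community <- ifelse(is_for, "F", ifelse(roster$patch == "A",
                                                 "N_A", "N_B"))

  x <- matrix(0, n, nb); y <- matrix(0, n, nb)
  side <- matrix(0L, n, nb); headm <- matrix(0, n, nb)
  # foragers keep private rest sites spread between the entrance corner
  # and the broodnest margin: most wait near the entrance, a minority
  # (nectar receivers) station closer to the brood area
  pull <- stats::runif(nb, 0, 0.45)
  bx0 <- bc$x[1]; by0 <- bc$y[1]
  ex0 <- config$entrance[1] - 3; ey0 <- config$entrance[2] + 3
  rest_x <- pmin(pmax((1 - pull) * ex0 + pull * bx0 + roster$home_dx, 1),
                 W - 1)
  rest_y <- pmin(pmax((1 - pull) * ey0 + pull * by0 + roster$home_dy, 1),
                 Hh - 1)
  # start near home patch (foragers at their rest sites, side 0)
  x0 <- ifelse(is_for, rest_x, hx) + stats::rnorm(nb, 0, 2)
  y0 <- ifelse(is_for, rest_y, hy) + stats::rnorm(nb, 0, 2)
  x[1, ] <- pmin(pmax(x0, 1), W - 1)
  y[1, ] <- pmin(pmax(y0, 1), Hh - 1)
  side[1, ] <- ifelse(is_for, 0L, as.integer(hside))
  headm[1, ] <- stats::runif(nb, 0, 2 * pi)
  dirw <- headm[1, ]
  excite <- numeric(nb)     # remaining excitation, s
  attending <- logical(nb)  # currently in the retinue
  attend_left <- numeric(nb) # remaining stint, s
  refract <- numeric(nb)    # post-retinue refractory period, s
  excur <- numeric(nb)      # foragers: remaining broodnest excursion, s
  # queen-seeking motivation switches on sporadically; until then a worker
  # goes about its ordinary business near its home site
  motiv <- stats::runif(nb) < 0.2
  exc <- config$excitation
  kappa_dir <- 2 # heading persistence noise

  for (t in 2:n) {
    on_q_side <- side[t - 1, ] == qside[t]
    dxq <- qx[t] - x[t - 1, ]; dyq <- qy[t] - y[t - 1, ]
    dq <- sqrt(dxq^2 + dyq^2)
    # retinue attendance: join within touch range (unless refractory),
    # stay until the stint ends or the queen moves off, then depart
    # excited with a refractory period before rejoining
    join <- on_q_side & dq <= 0.95 & !attending & refract <= 0
    if (any(join)) {
      attending[join] <- TRUE
      attend_left[join] <- rgamma_ms(sum(join), 45, 30)
    }
    leave <- attending & (attend_left <= 0 | dq > 1.4 | !on_q_side)
    if (any(leave)) {
      attending[leave] <- FALSE
      refract[leave] <- 150
      excite[leave] <- exc$duration_s
      motiv[leave] <- FALSE
    }
    motiv <- motiv | stats::runif(nb) < dt / 600
    att_w <- ifelse(refract > 0 | !motiv, 0, w_att)
    # drift components
    gx <- w_fid * (hx - x[t - 1, ]) + ifelse(on_q_side, att_w, 0) *
      ifelse(dq > 1e-9, dxq / pmax(dq, 1e-9), 0) * 6
    gy <- w_fid * (hy - y[t - 1, ]) + ifelse(on_q_side, att_w, 0) *
      ifelse(dq > 1e-9, dyq / pmax(dq, 1e-9), 0) * 6
    # foragers make periodic excursions into the broodnest (unloading
    # visits); otherwise they hold near the entrance corner
    start_exc <- is_for & excur <= 0 & stats::runif(nb) < dt / 1800
    excur[start_exc] <- 150
    on_exc <- is_for & excur > 0
    fx <- ifelse(on_exc, bc$x[1], rest_x)
    fy <- ifelse(on_exc, bc$y[1], rest_y)
    gx <- gx + is_for * 0.6 * (fx - x[t - 1, ])
    gy <- gy + is_for * 0.6 * (fy - y[t - 1, ])
    excur <- pmax(excur - dt, 0)
    excited <- excite > 0
    if (any(excited)) {
      # excited messengers run fast and straight, ranging over the whole
      # broodnest patch: no home/queen drift, only a soft pull back toward
      # the patch once they stray beyond its radius
      pcx <- bc$x[home]; pcy <- bc$y[home]
      dxp <- pcx - x[t - 1, ]; dyp <- pcy - y[t - 1, ]
      dp <- sqrt(dxp^2 + dyp^2)
      outside <- dp > config$broodnest_radius
      gx[excited] <- ifelse(outside[excited], 2 * dxp[excited], 0)
      gy[excited] <- ifelse(outside[excited], 2 * dyp[excited], 0)
    }
    # post-retinue (refractory) workers steer away from the queen rather
    # than re-joining her
    avoid <- refract > 0 & on_q_side & dq < 4
    if (any(avoid)) {
      gx[avoid] <- gx[avoid] - 4 * dxq[avoid] / pmax(dq[avoid], 1e-9)
      gy[avoid] <- gy[avoid] - 4 * dyq[avoid] / pmax(dq[avoid], 1e-9)
    }
    drift_ang <- atan2(gy + 1e-12, gx + 1e-12)
    gmag <- sqrt(gx^2 + gy^2)
    kap <- ifelse(excited, 6, kappa_dir)
    # blend previous direction with drift direction, weight by drift size
    wdrift <- pmin(gmag / 4, 1)
    base <- atan2(wdrift * sin(drift_ang) + (1 - wdrift) * sin(dirw),
                  wdrift * cos(drift_ang) + (1 - wdrift) * cos(dirw))
    noise <- numeric(nb)
    for (k in unique(kap)) {
      idx <- which(kap == k)
      noise[idx] <- rvonmises(length(idx), 0, k)
    }
    dirw <- wrap_angle(base + angle_diff(noise, 0))
    # attending workers halt and face the queen; the excitation boost
    # applies once they leave the retinue
    spd <- rgamma_ms(nb, mob, mob * 0.6) * ifelse(excited, exc$boost, 1)
    spd[attending] <- 0
    nx <- x[t - 1, ] + spd * cos(dirw)
    ny <- y[t - 1, ] + spd * sin(dirw)
    # reflect the travel direction off the comb walls
    hit_x <- nx < 0.5 | nx > W - 0.5
    hit_y <- ny < 0.5 | ny > Hh - 0.5
    dirw[hit_x] <- wrap_angle(pi - dirw[hit_x])
    dirw[hit_y] <- wrap_angle(-dirw[hit_y])
    nx <- pmin(pmax(nx, 0.5), W - 0.5)
    ny <- pmin(pmax(ny, 0.5), Hh - 0.5)
    # side switches only within 1 BL of the comb boundary
    near_edge <- nx < 1 | nx > W - 1 | ny < 1 | ny > Hh - 1
    psw <- config$side_switch_prob * ifelse(is_for, 3, 1) *
      ifelse(excited, 2, 1)
    flip <- near_edge & stats::runif(nb) < psw
    side[t, ] <- ifelse(flip, 1L - side[t - 1, ], side[t - 1, ])
    x[t, ] <- nx; y[t, ] <- ny
    moved <- spd > 1e-9
    headm[t, ] <- ifelse(moved, dirw, headm[t - 1, ])
    headm[t, attending] <- wrap_angle(atan2(dyq, dxq))[attending]
    excite <- pmax(excite - dt, 0)
    attend_left <- pmax(attend_left - dt, 0)
    refract <- pmax(refract - dt, 0)
  }
  tsec <- (seq_len(n) - 1) * dt
  traj <- data.frame(
    bee_id = rep(roster$bee_id, each = n),
    time_s = rep(tsec, nb),
    x = as.vector(x), y = as.vector(y),
    heading_rad = wrap_angle(as.vector(headm)),
    side = as.vector(side),
    stringsAsFactors = FALSE
  )
  list(traj = traj, roster = roster)
}

empty_traj <- function() {
  data.frame(bee_id = character(), time_s = numeric(), x = numeric(),
             y = numeric(), heading_rad = numeric(), side = integer(),
             stringsAsFactors = FALSE)
}

#' Simulate a full colony-day
#'
#' @param config [colony_config()].
#' @param day day index.
#' @param colony_id label stored in the metadata table.
#' @return a `colony_day` list: `traj` (queen + workers), `bees` metadata
#'   (`bee_id, role, eclosion_day, colony_id`), `ground_truth` (list with
#'   `queen_state` and `workers` tables), `config`, `day`.
#' @export
simulate_colony_day <- function(config, day, colony_id = "C1") {
  q <- simulate_queen_trajectory(config, day)
  w <- simulate_worker_population(config, day, q)
  bees <- data.frame(
    bee_id = c("Q", w$roster$bee_id),
    role = c("queen", rep("worker", nrow(w$roster))),
    eclosion_day = c(NA_real_, w$roster$eclosion_day),
    colony_id = colony_id, stringsAsFactors = FALSE
  )
  gt_workers <- w$roster[, c("bee_id", "community", "age")]
  out <- list(traj = rbind(q$traj, w$traj), bees = bees,
              ground_truth = list(queen_state = q$states,
                                  workers = gt_workers),
              config = config, day = day, colony_id = colony_id)
  class(out) <- "colony_day"
  out
}

#' @export
print.colony_day <- function(x, ...) {
  cat("colony_day:", x$colony_id, "day", x$day, "-",
      nrow(x$bees) - 1, "workers,",
      length(unique(x$traj$time_s)), "frames\n")
  invisible(x)
}

#' Write a simulated dataset to plain-text tables
#'
#' Emits `trajectories.csv`, `bees.csv` and the synthetic-only ground-truth
#' sidecars `ground_truth_queen.csv` / `ground_truth_workers.csv`.
#'
#' @param sim a `colony_day` from [simulate_colony_day()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  ids_t <- unique(sim$traj$bee_id)
  if (!all(ids_t %in% sim$bees$bee_id)) {
    stop("trajectory ids missing from metadata")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$traj, file.path(dir, "trajectories.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$bees, file.path(dir, "bees.csv"), row.names = FALSE)
  utils::write.csv(sim$ground_truth$queen_state,
                   file.path(dir, "ground_truth_queen.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$ground_truth$workers,
                   file.path(dir, "ground_truth_workers.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @param with_ground_truth read the synthetic sidecars too?
#' @export
read_dataset <- function(dir, with_ground_truth = TRUE) {
  out <- list(
    traj = utils::read.csv(file.path(dir, "trajectories.csv"),
                           stringsAsFactors = FALSE),
    bees = utils::read.csv(file.path(dir, "bees.csv"),
                           stringsAsFactors = FALSE)
  )
  gq <- file.path(dir, "ground_truth_queen.csv")
  gw <- file.path(dir, "ground_truth_workers.csv")
  if (with_ground_truth && file.exists(gq)) {
    out$ground_truth <- list(
      queen_state = utils::read.csv(gq, stringsAsFactors = FALSE),
      workers = utils::read.csv(gw, stringsAsFactors = FALSE)
    )
  }
  out
}

#' Simulate per-bee-day messaging-syndrome metrics directly
#'
#' A lightweight generator for the developmental-trajectory stage: instead of
#' simulating full trajectories over weeks, it draws the six messaging
#' metrics from age profiles that change regime at a planted switch age
#' (default 4 days), with independent noise. Used to test quantile
#' transformation, pooled PCA and inflection recovery at scale.
#'
#' @param n_bees bees per cohort-day.
#' @param ages integer ages present (days).
#' @param n_days observation days (each age appears on each day).
#' @param switch_age planted regime-change age.
#' @param noise_sd metric noise standard deviation.
#' @param colony colony label.
#' @param seed integer seed.
#' @return data.frame of syndrome rows
#'   `colony, bee_id, day, age, m1..m6`.
#' @export
simulate_syndrome_rows <- function(n_bees = 20, ages = 0:14, n_days = 3,
                                   switch_age = 4, noise_sd = 0.15,
                                   colony = "C1", seed = 1L) {
  set.seed(seed)
  rows <- expand.grid(age = ages, day = seq_len(n_days), b = seq_len(n_bees))
  a <- rows$age
  rise <- pmin(a / switch_age, 1)           # growth phase, kinked at switch
  fall <- pmax(0, (a - switch_age)) / 10    # post-switch decline
  m <- cbind(
    m1 = rise - 1.2 * fall,                 # queen attraction effect
    m2 = 6 * (rise - fall),                 # queen contact count scale
    m3 = 1 - pmin(fall * 1.2, 1),           # nurse affiliation
    m4 = pmin(rise, 1 - fall),              # bridging
    m5 = 100 + 200 * (rise - fall),         # k_out
    m6 = -50 + 150 * rise - 180 * fall      # delta k
  )
  m <- m + matrix(stats::rnorm(length(m), 0,
                               noise_sd * rep(apply(abs(m), 2, max),
                                              each = nrow(m))),
                  nrow(m), ncol(m))
  data.frame(colony = colony,
             bee_id = sprintf("B%04d", seq_len(nrow(rows))),
             day = rows$day, age = a, m, stringsAsFactors = FALSE)
}
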