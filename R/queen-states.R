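# Two-state movement HMM for daily queen trajectories: step/turn
# decomposition, maximum-likelihood fitting (zero-inflated gamma steps,
# von Mises turns), Viterbi bout decoding, bout filtering and
# state-dependent encounter statistics.

#' Decompose a trajectory into movement steps and turning angles
#'
#' Step `i` is the displacement between frames `i-1` and `i` (BL/frame); the
#' turning angle is the signed change in direction between successive
#' displacement vectors, undefined (NA) when either adjacent step is zero or
#' at track/segment starts. Gaps larger than 1.5 frame intervals split the
#' track into segments.
#'
#' @param traj single-bee trajectory data.frame (`time_s, x, y`).
#' @return data.frame `time_s, step_length, turn_angle, segment`.
#' @export
trajectory_to_steps <- function(traj) {
  traj <- traj[order(traj$time_s), ]
  n <- nrow(traj)
  if (n < 3) {
    warning("fewer than 3 frames: no steps")
    return(data.frame(time_s = numeric(), step_length = numeric(),
                      turn_angle = numeric(), segment = integer()))
  }
  dt <- stats::median(diff(traj$time_s))
  gap <- c(FALSE, diff(traj$time_s) > 1.5 * dt)
  seg_frame <- cumsum(gap) + 1L
  dx <- diff(traj$x); dy <- diff(traj$y)
  step <- sqrt(dx^2 + dy^2)
  dirv <- atan2(dy, dx)
  seg <- seg_frame[-1]
  same_seg <- c(FALSE, diff(seg) == 0)
  turn <- c(NA_real_, angle_diff(dirv[-1], dirv[-length(dirv)]))
  moved <- step > 1e-9
  ok_turn <- same_seg & moved & c(FALSE, moved[-length(moved)])
  turn[!ok_turn] <- NA_real_
  cross_gap <- c(FALSE, diff(seg_frame) != 0)[-1]
  out <- data.frame(time_s = traj$time_s[-1], step_length = step,
                    turn_angle = turn, segment = seg)
  out <- out[!cross_gap, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dt") <- dt
  out
}

# precomputed emission features: evaluated once per track, reused across
# all likelihood evaluations
hmm_features <- function(steps) {
  zero <- steps$step_length < 1e-9
  x <- steps$step_length
  lx <- ifelse(zero, 0, log(pmax(x, 1e-300)))
  ok <- !is.na(steps$turn_angle)
  list(zero = zero, x = x, lx = lx, turn_ok = ok,
       cosT = ifelse(ok, cos(steps$turn_angle), 0),
       sinT = ifelse(ok, sin(steps$turn_angle), 0))
}

# emission log-density matrix for the 2 states given natural parameters
hmm_logdens <- function(steps, par, feat = NULL) {
  if (is.null(feat)) feat <- hmm_features(steps)
  n <- length(feat$x)
  ld <- matrix(0, n, 2)
  for (s in 1:2) {
    m <- par$step_mean[s]; sd <- par$step_sd[s]
    shape <- (m / sd)^2; rate <- shape / m
    dsl <- log1p(-par$zero_prob[s]) + shape * log(rate) - lgamma(shape) +
      (shape - 1) * feat$lx - rate * feat$x
    dsl[feat$zero] <- log(par$zero_prob[s])
    kap <- par$turn_kappa[s]; mu <- par$turn_mean[s]
    cvm <- -kap - log(2 * pi * besselI(kap, 0, expon.scaled = TRUE))
    dtn <- kap * (cos(mu) * feat$cosT + sin(mu) * feat$sinT) + cvm
    dtn[!feat$turn_ok] <- 0
    ld[, s] <- dsl + dtn
  }
  ld
}

par_to_vec <- function(p) {
  c(log(p$step_mean), log(p$step_sd),
    stats::qlogis(pmin(pmax(p$zero_prob, 1e-6), 1 - 1e-6)),
    p$turn_mean, log(p$turn_kappa),
    stats::qlogis(pmin(pmax(c(p$gamma[1, 2], p$gamma[2, 1]), 1e-6),
                       1 - 1e-6)))
}

vec_to_par <- function(v) {
  g12 <- stats::plogis(v[11]); g21 <- stats::plogis(v[12])
  list(step_mean = exp(v[1:2]), step_sd = exp(v[3:4]),
       zero_prob = stats::plogis(v[5:6]),
       turn_mean = angle_diff(v[7:8], 0),
       turn_kappa = pmin(exp(v[9:10]), 700),
       gamma = matrix(c(1 - g12, g12, g21, 1 - g21), 2, 2, byrow = TRUE))
}

stat_dist <- function(gamma) {
  d <- c(gamma[2, 1], gamma[1, 2])
  d / sum(d)
}

#' Fit a two-state movement HMM
#'
#' Direct numerical maximisation of the forward-algorithm likelihood for a
#' two-state HMM with zero-inflated gamma step lengths and von Mises turning
#' angles, from `n_restarts` jittered moment-based initialisations. States
#' are labelled so that S (stationary) has the smaller fitted mean step
#' length; log-likelihood ties are broken toward the lower S mean.
#'
#' @param steps output of [trajectory_to_steps()] (>= 200 steps).
#' @param n_restarts random restarts.
#' @param seed integer seed for the restart jitter.
#' @return an `hmm_fit`: per-state `step_mean`, `step_sd`, `zero_prob`,
#'   `turn_mean`, `turn_kappa`; transition matrix `gamma` (rows S,T);
#'   `loglik`; `states = c("S","T")`.
#' @export
fit_two_state_hmm <- function(steps, n_restarts = 10, seed = 1L) {
  stopifnot(nrow(steps) >= 200)
  set.seed(seed)
  nz <- steps$step_length[steps$step_length > 1e-9]
  med <- stats::median(nz)
  lo <- nz[nz <= med]; hi <- nz[nz > med]
  pz <- mean(steps$step_length < 1e-9)
  base <- list(step_mean = c(mean(lo), mean(hi)),
               step_sd = c(stats::sd(lo) + 1e-6, stats::sd(hi) + 1e-6),
               zero_prob = pmin(pmax(c(2 * pz, pz / 4), 1e-4), 0.95),
               turn_mean = c(0, 0),
               turn_kappa = c(0.7, 3),
               gamma = matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2))
  feat <- hmm_features(steps)
  nll <- function(v) {
    p <- vec_to_par(v)
    ld <- hmm_logdens(steps, p, feat)
    -hmm_forward_loglik(ld, log(p$gamma), log(stat_dist(p$gamma)))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    v0 <- par_to_vec(base)
    if (r > 1) v0 <- v0 + stats::rnorm(length(v0), 0, 0.4)
    fit <- try(stats::optim(v0, nll, method = "BFGS",
                            control = list(maxit = 200, reltol = 1e-8)),
               silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    p <- vec_to_par(fit$par)
    cand <- list(value = fit$value, par = p)
    if (is.null(best) || cand$value < best$value - 1e-9 ||
        (abs(cand$value - best$value) <= 1e-9 &&
         min(p$step_mean) < min(best$par$step_mean))) {
      best <- cand
    }
  }
  if (is.null(best)) stop("HMM fit failed in all restarts")
  p <- best$par
  ord <- order(p$step_mean) # S first
  fitobj <- list(step_mean = p$step_mean[ord], step_sd = p$step_sd[ord],
                 zero_prob = p$zero_prob[ord], turn_mean = p$turn_mean[ord],
                 turn_kappa = p$turn_kappa[ord],
                 gamma = p$gamma[ord, ord, drop = FALSE],
                 loglik = -best$value, states = c("S", "T"),
                 n_steps = nrow(steps), dt = attr(steps, "dt") %||% 0.5)
  names(fitobj$step_mean) <- names(fitobj$step_sd) <-
    names(fitobj$zero_prob) <- names(fitobj$turn_mean) <-
    names(fitobj$turn_kappa) <- c("S", "T")
  dimnames(fitobj$gamma) <- list(c("S", "T"), c("S", "T"))
  class(fitobj) <- "hmm_fit"
  fitobj
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("Two-state movement HMM (", x$n_steps, " steps), logLik ",
      sprintf("%.1f", x$loglik), "\n", sep = "")
  cat("  step mean (BL/frame): S =", signif(x$step_mean[1], 3),
      " T =", signif(x$step_mean[2], 3), "\n")
  cat("  turn kappa:           S =", signif(x$turn_kappa[1], 3),
      " T =", signif(x$turn_kappa[2], 3), "\n")
  invisible(x)
}

#' Decode stationary/travelling bouts
#'
#' Viterbi decoding segmented into maximal same-state runs; each bout's
#' confidence is the mean per-frame posterior probability of its decoded
#' state.
#'
#' @param fit an `hmm_fit`.
#' @param steps the steps the fit was computed on.
#' @return data.frame `state, t_start_s, t_end_s, duration_s,
#'   mean_posterior`; bouts tile the decoded track.
#' @export
decode_bouts <- function(fit, steps) {
  p <- fit
  ld <- hmm_logdens(steps, p)
  lg <- log(p$gamma); ldelta <- log(stat_dist(p$gamma))
  path <- hmm_viterbi(ld, lg, ldelta)
  post <- hmm_posterior(ld, lg, ldelta)
  dt <- attr(steps, "dt") %||% fit$dt
  run <- cumsum(c(TRUE, diff(path) != 0 | diff(steps$segment) != 0))
  out <- do.call(rbind, lapply(split(seq_along(path), run), function(idx) {
    s <- path[idx[1]]
    data.frame(state = c("S", "T")[s],
               t_start_s = steps$time_s[idx[1]] - dt,
               t_end_s = steps$time_s[idx[length(idx)]],
               duration_s = length(idx) * dt,
               mean_posterior = mean(post[idx, s]))
  }))
  rownames(out) <- NULL
  out
}

#' Filter decoded bouts
#'
#' Drops bouts shorter than `min_dur` seconds or with mean posterior below
#' `min_post`; longer bouts are retained but capped at an analysis horizon of
#' `max_dur` seconds (column `horizon_s`).
#'
#' @param bouts output of [decode_bouts()].
#' @param min_dur,min_post,max_dur filter parameters (s, probability, s).
#' @return filtered bouts with an extra `horizon_s` column.
#' @export
filter_bouts <- function(bouts, min_dur = 10, min_post = 0.75,
                         max_dur = 305) {
  keep <- bouts$duration_s >= min_dur & bouts$mean_posterior >= min_post
  out <- bouts[keep, , drop = FALSE]
  out$horizon_s <- pmin(out$duration_s, max_dur)
  rownames(out) <- NULL
  out
}

#' State-dependent queen encounter statistics
#'
#' Assigns each queen contact to the bout containing its start and summarises
#' encounter rate (contacts/min of state time) and mean contact duration per
#' state. With a `day` column on `bouts`, per-day values and a paired S vs T
#' comparison (mean difference +/- SE, Wilcoxon signed-rank p) are returned.
#'
#' @param bouts decoded (optionally filtered) bouts, optional `day` column.
#' @param contacts contacts involving the queen (`t_start_s, t_end_s`),
#'   optional `day` column.
#' @return list with `per_state` (data.frame `day, state, time_min,
#'   n_contacts, rate_per_min, mean_duration_s`) and `paired` (S vs T rate
#'   and duration comparisons across days, NULL for a single day).
#' @export
state_encounter_stats <- function(bouts, contacts) {
  if (!"day" %in% names(bouts)) bouts$day <- rep(0, nrow(bouts))
  if (!"day" %in% names(contacts)) contacts$day <- rep(0, nrow(contacts))
  rows <- list()
  for (d in unique(bouts$day)) {
    bd <- bouts[bouts$day == d, ]
    cd <- contacts[contacts$day == d, ]
    bi <- if (nrow(cd)) {
      findInterval(cd$t_start_s, bd$t_start_s)
    } else integer(0)
    inb <- bi >= 1 & bi <= nrow(bd) &
      cd$t_start_s < bd$t_end_s[pmax(bi, 1)]
    for (s in c("S", "T")) {
      tm <- sum(bd$duration_s[bd$state == s]) / 60
      sel <- inb & bd$state[pmax(bi, 1)] == s
      nc <- sum(sel)
      rows[[length(rows) + 1L]] <- data.frame(
        day = d, state = s, time_min = tm, n_contacts = nc,
        rate_per_min = if (tm > 0) nc / tm else NA_real_,
        mean_duration_s = if (nc > 0) {
          mean(cd$t_end_s[sel] - cd$t_start_s[sel])
        } else NA_real_)
    }
  }
  per_state <- do.call(rbind, rows)
  paired <- NULL
  days <- unique(per_state$day)
  if (length(days) >= 2) {
    wide <- function(col) {
      s <- per_state[per_state$state == "S", col]
      t <- per_state[per_state$state == "T", col]
      ok <- stats::complete.cases(s, t)
      d <- t[ok] - s[ok]
      list(mean_diff = mean(d), se = stats::sd(d) / sqrt(length(d)),
           p = if (length(d) >= 2 && any(d != 0)) {
             stats::wilcox.test(t[ok], s[ok], paired = TRUE)$p.value
           } else NA_real_)
    }
    paired <- list(rate = wide("rate_per_min"),
                   duration = wide("mean_duration_s"))
  }
  list(per_state = per_state, paired = paired)
}
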