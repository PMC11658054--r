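# Receiver orientation toward messengers (specified-direction Rayleigh
# statistic, difference maps, angular transects), worker attraction to the
# queen, and pre/post-retinue mobility comparisons.

#' Specified-direction Rayleigh statistic
#'
#' `rho = sum(cos(theta - mu)) / n`: 1 when every receiver faces exactly
#' along its specified direction, -1 when every receiver faces away, ~0 for
#' uniform or orthogonal orientations.
#'
#' @param theta observed body orientations (radians).
#' @param mu specified directions (radians), same length.
#' @return rho in `[-1, 1]`; NA for empty input.
#' @export
rayleigh_rho <- function(theta, mu) {
  stopifnot(length(theta) == length(mu))
  if (!length(theta)) return(NA_real_)
  mean(cos(theta - mu))
}

# nearest point on a quad boundary from points (px, py); quad: list(X, Y)
# 4 x 1. Returns list(nx, ny). Points inside get the quad centroid.
nearest_point_on_quad <- function(px, py, quad) {
  n <- length(px)
  best_d2 <- rep(Inf, n)
  nx <- numeric(n); ny <- numeric(n)
  for (k in 1:4) {
    k2 <- if (k == 4) 1L else k + 1L
    ax <- quad$X[k, 1]; ay <- quad$Y[k, 1]
    bx <- quad$X[k2, 1]; by <- quad$Y[k2, 1]
    ex <- bx - ax; ey <- by - ay
    tt <- pmin(pmax(((px - ax) * ex + (py - ay) * ey) /
                      (ex^2 + ey^2), 0), 1)
    qx <- ax + tt * ex; qy <- ay + tt * ey
    d2 <- (px - qx)^2 + (py - qy)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]; nx[upd] <- qx[upd]; ny[upd] <- qy[upd]
  }
  # inside test (convex, consistent vertex order): same sign of all edge
  # cross products
  sgn <- matrix(0, n, 4)
  for (k in 1:4) {
    k2 <- if (k == 4) 1L else k + 1L
    sgn[, k] <- (quad$X[k2, 1] - quad$X[k, 1]) * (py - quad$Y[k, 1]) -
      (quad$Y[k2, 1] - quad$Y[k, 1]) * (px - quad$X[k, 1])
  }
  inside <- apply(sgn >= 0, 1, all) | apply(sgn <= 0, 1, all)
  if (any(inside)) {
    nx[inside] <- mean(quad$X[, 1]); ny[inside] <- mean(quad$Y[, 1])
  }
  list(nx = nx, ny = ny)
}

# aligned per-bee matrices from a long trajectory table
traj_matrices <- function(traj, ids = NULL) {
  times <- sort(unique(traj$time_s))
  if (is.null(ids)) ids <- unique(traj$bee_id)
  tidx <- match(traj$time_s, times)
  bidx <- match(traj$bee_id, ids)
  keep <- !is.na(bidx)
  mk <- function(col) {
    m <- matrix(NA_real_, length(times), length(ids),
                dimnames = list(NULL, ids))
    m[cbind(tidx[keep], bidx[keep])] <- traj[[col]][keep]
    m
  }
  list(times = times, X = mk("x"), Y = mk("y"), H = mk("heading_rad"),
       S = mk("side"), ids = ids)
}

#' Collect receiver orientation samples around queen encounters
#'
#' For every queen-worker contact, the contacted worker is a messenger; at
#' each frame within `window` seconds before the contact start (pre,
#' negative `t_rel`) and after the contact end (post, positive `t_rel`),
#' every other worker within `radius` body-lengths on the same side is a
#' receiver. Receiver position and orientation are rotated into the
#' messenger frame (messenger at the origin heading +x); the specified
#' direction `mu` points from the receiver to the nearest point of the
#' messenger's trapezium.
#'
#' @param queen_contacts contact rows involving the queen.
#' @param traj trajectory table.
#' @param bees metadata.
#' @param window seconds either side of the contact.
#' @param radius receiver inclusion radius (BL).
#' @param dims [body_dims()].
#' @param messenger_loads optional `transmission_ensemble` used to attach
#'   each messenger's ensemble-mean load at the contact end (for load
#'   deciles).
#' @param colony colony label attached to the samples.
#' @return data.frame `colony, messenger, receiver, t_rel_s, x_bl, y_bl,
#'   theta, mu, messenger_load_pg`.
#' @export
collect_orientation_samples <- function(queen_contacts, traj, bees,
                                        window = 300, radius = 2,
                                        dims = body_dims(),
                                        messenger_loads = NULL,
                                        colony = "C1") {
  qid <- bees$bee_id[bees$role == "queen"]
  workers <- bees$bee_id[bees$role == "worker"]
  tm <- traj_matrices(traj)
  dt <- stats::median(diff(tm$times))
  wd <- dims$worker
  out <- vector("list", 2 * nrow(queen_contacts))
  oi <- 0L
  for (e in seq_len(nrow(queen_contacts))) {
    msgr <- if (queen_contacts$i[e] %in% qid) queen_contacts$j[e] else
      queen_contacts$i[e]
    if (!msgr %in% workers) next
    mload <- if (!is.null(messenger_loads)) {
      ti <- findInterval(queen_contacts$t_end_s[e], messenger_loads$times)
      if (ti >= 1) messenger_loads$mean_load[msgr, ti] else NA_real_
    } else NA_real_
    for (phase in c("pre", "post")) {
      if (phase == "post") {
        tsel <- tm$times > queen_contacts$t_end_s[e] &
          tm$times <= queen_contacts$t_end_s[e] + window
        tref <- queen_contacts$t_end_s[e]
      } else {
        tsel <- tm$times >= queen_contacts$t_start_s[e] - window &
          tm$times < queen_contacts$t_start_s[e]
        tref <- queen_contacts$t_start_s[e]
      }
      fr <- which(tsel)
      if (!length(fr)) next
      mi <- match(msgr, tm$ids)
      others <- setdiff(workers, msgr)
      oidx <- match(others, tm$ids)
      recs <- list()
      for (t in fr) {
        xm <- tm$X[t, mi]
        if (is.na(xm)) next
        ym <- tm$Y[t, mi]; hm <- tm$H[t, mi]; sm <- tm$S[t, mi]
        dx <- tm$X[t, oidx] - xm; dy <- tm$Y[t, oidx] - ym
        near <- which(!is.na(dx) & tm$S[t, oidx] == sm &
                        dx^2 + dy^2 <= radius^2)
        if (!length(near)) next
        quad <- quad_coords(xm, ym, hm, wd, "full")
        px <- tm$X[t, oidx[near]]; py <- tm$Y[t, oidx[near]]
        np <- nearest_point_on_quad(px, py, quad)
        mu_abs <- atan2(np$ny - py, np$nx - px)
        ca <- cos(-hm); sa <- sin(-hm)
        recs[[length(recs) + 1L]] <- data.frame(
          colony = colony, messenger = msgr,
          receiver = others[near],
          t_rel_s = tm$times[t] - tref,
          x_bl = ca * dx[near] - sa * dy[near],
          y_bl = sa * dx[near] + ca * dy[near],
          theta = wrap_angle(tm$H[t, oidx[near]] - hm),
          mu = wrap_angle(mu_abs - hm),
          messenger_load_pg = mload, stringsAsFactors = FALSE)
      }
      if (length(recs)) {
        oi <- oi + 1L
        out[[oi]] <- do.call(rbind, recs)
      }
    }
  }
  if (!oi) {
    return(data.frame(colony = character(), messenger = character(),
                      receiver = character(), t_rel_s = numeric(),
                      x_bl = numeric(), y_bl = numeric(), theta = numeric(),
                      mu = numeric(), messenger_load_pg = numeric()))
  }
  res <- do.call(rbind, out[seq_len(oi)])
  rownames(res) <- NULL
  res
}

#' Attach load deciles to orientation samples
#'
#' Deciles (1-10) of the messenger ensemble-mean loads across samples.
#'
#' @param samples output of [collect_orientation_samples()].
#' @return samples with a `load_decile` column.
#' @export
assign_load_deciles <- function(samples) {
  ld <- samples$messenger_load_pg
  qs <- stats::quantile(ld, probs = seq(0, 1, 0.1), na.rm = TRUE,
                        names = FALSE)
  qs[1] <- -Inf; qs[11] <- Inf
  samples$load_decile <- findInterval(ld, qs, rightmost.closed = TRUE)
  samples$load_decile[samples$load_decile > 10] <- 10L
  samples
}

sample_strata <- function(samples, variant, k = 1, decile = 10) {
  if (variant == "time") {
    strat <- samples$t_rel_s > (k - 1) * 60 & samples$t_rel_s <= k * 60
    ref <- samples$t_rel_s >= -k * 60 & samples$t_rel_s < -(k - 1) * 60
  } else {
    post <- samples$t_rel_s > 0
    strat <- post & samples$load_decile == decile
    ref <- post
  }
  list(stratum = strat, reference = ref)
}

#' Orientation-strength difference map around the messenger
#'
#' Bins receiver positions in the messenger frame and, per cell, subtracts
#' the reference-stratum mean Rayleigh orientation strength from the focal
#' stratum's. Variants: `"time"` (post minute `k` minus pre minute `k`) and
#' `"load"` (messenger load decile `decile` minus all post-retinue
#' samples). Cells with fewer than `min_count` samples in either stratum
#' are masked (NA).
#'
#' @param samples orientation samples (with `load_decile` for the load
#'   variant, see [assign_load_deciles()]).
#' @param variant `"time"` or `"load"`.
#' @param k post/pre minute for the time variant.
#' @param decile focal decile for the load variant.
#' @param cell cell side (BL).
#' @param extent half-width of the map (BL).
#' @param min_count per-cell minimum samples per stratum.
#' @return data.frame `x_bl, y_bl, drho, dvx, dvy, n_stratum, n_ref`.
#' @export
difference_map <- function(samples, variant = c("time", "load"), k = 1,
                           decile = 10, cell = 0.2, extent = 2,
                           min_count = 50) {
  variant <- match.arg(variant)
  st <- sample_strata(samples, variant, k, decile)
  breaks <- seq(-extent, extent, by = cell)
  nbin <- length(breaks) - 1
  cx <- cut(samples$x_bl, breaks, labels = FALSE)
  cy <- cut(samples$y_bl, breaks, labels = FALSE)
  cellid <- (cx - 1) * nbin + cy
  co <- cos(samples$theta - samples$mu)
  ux <- cos(samples$theta); uy <- sin(samples$theta)
  agg <- function(sel) {
    ok <- sel & !is.na(cellid)
    list(n = tapply(co[ok], cellid[ok], length),
         rho = tapply(co[ok], cellid[ok], mean),
         vx = tapply(ux[ok], cellid[ok], mean),
         vy = tapply(uy[ok], cellid[ok], mean))
  }
  a <- agg(st$stratum); b <- agg(st$reference)
  ids <- seq_len(nbin * nbin)
  get <- function(tab, id) {
    v <- tab[as.character(id)]
    ifelse(is.na(names(v)), NA_real_, as.numeric(v))
  }
  n1 <- get(a$n, ids); n2 <- get(b$n, ids)
  n1[is.na(n1)] <- 0; n2[is.na(n2)] <- 0
  drho <- get(a$rho, ids) - get(b$rho, ids)
  dvx <- get(a$vx, ids) - get(b$vx, ids)
  dvy <- get(a$vy, ids) - get(b$vy, ids)
  mask <- n1 < min_count | n2 < min_count
  drho[mask] <- NA_real_; dvx[mask] <- NA_real_; dvy[mask] <- NA_real_
  mid <- breaks[-length(breaks)] + cell / 2
  data.frame(x_bl = rep(mid, each = nbin), y_bl = rep(mid, nbin),
             drho = drho, dvx = dvx, dvy = dvy,
             n_stratum = n1, n_ref = n2)
}

#' Angular transect of orientation-strength differences
#'
#' Bins receiver positions by clockwise angle from the messenger heading and
#' reports the stratum-minus-reference Rayleigh difference per bin, with SE
#' across colonies (across messengers when only one colony is present).
#'
#' @inheritParams difference_map
#' @param n_bins angular bins.
#' @return data.frame `angle_deg, drho, se, n`.
#' @export
angular_transect <- function(samples, variant = c("time", "load"), k = 1,
                             decile = 10, n_bins = 24) {
  variant <- match.arg(variant)
  st <- sample_strata(samples, variant, k, decile)
  ang_cw <- wrap_angle(-atan2(samples$y_bl, samples$x_bl))
  bin <- findInterval(ang_cw, seq(0, 2 * pi, length.out = n_bins + 1),
                      rightmost.closed = TRUE)
  grp <- if (length(unique(samples$colony)) > 1) samples$colony else
    samples$messenger
  co <- cos(samples$theta - samples$mu)
  rows <- lapply(seq_len(n_bins), function(bb) {
    per_grp <- vapply(unique(grp), function(g) {
      s1 <- st$stratum & bin == bb & grp == g
      s2 <- st$reference & bin == bb & grp == g
      if (!any(s1) || !any(s2)) return(NA_real_)
      mean(co[s1]) - mean(co[s2])
    }, numeric(1))
    ok <- !is.na(per_grp)
    data.frame(angle_deg = (bb - 0.5) * 360 / n_bins,
               drho = if (any(ok)) mean(per_grp[ok]) else NA_real_,
               se = if (sum(ok) > 1) {
                 stats::sd(per_grp[ok]) / sqrt(sum(ok))
               } else NA_real_,
               n = sum(st$stratum & bin == bb))
  })
  do.call(rbind, rows)
}

#' Test a worker's spatial attraction to the (stationary) queen
#'
#' Compares observed simultaneous worker-queen distances with the expected
#' distribution formed from all (worker frame, queen frame) pairs,
#' restricted to frames where the queen is in the stationary state. The
#' default is a one-tailed Wilcoxon rank-sum test of the thinned observed
#' distances against the expected sample (alternative: observed shorter);
#' thinning reduces the temporal autocorrelation of the observed series.
#' `paired = TRUE` selects a quantile-matched signed-rank variant (sorted
#' observed distances against expected quantiles at the same plotting
#' positions); note that matched order statistics violate the signed-rank
#' exchangeability assumption, making that variant anticonservative - it is
#' provided for comparability, not inference.
#'
#' @param worker_traj,queen_traj single-bee trajectory tables.
#' @param bouts decoded bouts; only `state == "S"` intervals are used.
#' @param comb_dims `c(width, height)` (BL).
#' @param thin_s thinning interval for observed frames (s).
#' @param max_pairs expected-distribution subsample cap.
#' @param min_frames minimum simultaneous frames required.
#' @param paired use the quantile-matched signed-rank construction instead
#'   of the default rank-sum test (see Details).
#' @param seed integer seed for the expected-pair subsample.
#' @return list `p`, `effect_bl` (median observed - median expected;
#'   negative = attraction), `n_obs`; NULL components when data are
#'   insufficient.
#' @export
queen_attraction_test <- function(worker_traj, queen_traj, bouts,
                                  comb_dims = c(64, 44), thin_s = 60,
                                  max_pairs = 1e5, min_frames = 100,
                                  paired = FALSE, seed = 1L) {
  sb <- bouts[bouts$state == "S", , drop = FALSE]
  if (!nrow(sb)) return(list(p = NA_real_, effect_bl = NA_real_, n_obs = 0L))
  in_s <- function(t) {
    bi <- findInterval(t, sb$t_start_s)
    bi >= 1 & t <= sb$t_end_s[pmax(bi, 1)]
  }
  qt <- queen_traj[in_s(queen_traj$time_s), , drop = FALSE]
  wt <- worker_traj[worker_traj$time_s %in% qt$time_s, , drop = FALSE]
  qt2 <- qt[qt$time_s %in% wt$time_s, , drop = FALSE]
  if (nrow(wt) < min_frames) {
    return(list(p = NA_real_, effect_bl = NA_real_, n_obs = nrow(wt)))
  }
  dt <- stats::median(diff(sort(unique(worker_traj$time_s))))
  stride <- max(1L, round(thin_s / dt))
  keep <- seq(1, nrow(wt), by = stride)
  obs <- cross_side_distance(cbind(wt$x, wt$y)[keep, , drop = FALSE],
                             cbind(qt2$x, qt2$y)[keep, , drop = FALSE],
                             wt$side[keep], qt2$side[keep], comb_dims)
  set.seed(seed)
  np <- min(max_pairs, nrow(wt) * nrow(qt2))
  iw <- sample.int(nrow(wt), np, replace = TRUE)
  iq <- sample.int(nrow(qt2), np, replace = TRUE)
  expd <- cross_side_distance(cbind(wt$x, wt$y)[iw, , drop = FALSE],
                              cbind(qt2$x, qt2$y)[iq, , drop = FALSE],
                              wt$side[iw], qt2$side[iq], comb_dims)
  if (paired) {
    n <- length(obs)
    oq <- sort(obs)
    eq <- stats::quantile(expd, probs = (seq_len(n) - 0.5) / n,
                          names = FALSE, type = 8)
    p <- stats::wilcox.test(oq, eq, paired = TRUE,
                            alternative = "less", exact = FALSE)$p.value
  } else {
    p <- stats::wilcox.test(obs, expd, alternative = "less",
                            exact = FALSE)$p.value
  }
  list(p = p, effect_bl = stats::median(obs) - stats::median(expd),
       n_obs = length(obs))
}

#' Worker mobility before and after queen encounters
#'
#' Aligns per-frame speed, unsigned turning angle and side-switch
#' indicators on the contact start (pre window, negative times) and contact
#' end (post window, positive times) of each queen-worker encounter, and
#' forms the post-minus-pre difference at matched `|t|`. Windows that would
#' overlap a neighbouring queen contact of the same worker are truncated.
#'
#' @param queen_contacts contact rows involving the queen.
#' @param traj trajectory table.
#' @param bees metadata.
#' @param window seconds either side.
#' @return data.frame `t_s, speed_pre, speed_post, speed_diff, turn_pre,
#'   turn_post, turn_diff, switch_pre, switch_post, switch_diff, n_pre,
#'   n_post` (speeds BL/s, turns rad, switch rates 1/s).
#' @export
mobility_prepost <- function(queen_contacts, traj, bees, window = 300) {
  qid <- bees$bee_id[bees$role == "queen"]
  dtall <- stats::median(diff(sort(unique(traj$time_s))))
  nlag <- round(window / dtall)
  acc <- list(
    pre = list(speed = numeric(nlag), turn = numeric(nlag),
               sw = numeric(nlag), n = numeric(nlag),
               nturn = numeric(nlag)),
    post = list(speed = numeric(nlag), turn = numeric(nlag),
                sw = numeric(nlag), n = numeric(nlag),
                nturn = numeric(nlag)))
  qc_by_w <- split(queen_contacts,
                   ifelse(queen_contacts$i %in% qid, queen_contacts$j,
                          queen_contacts$i))
  for (w in names(qc_by_w)) {
    wt <- traj[traj$bee_id == w, , drop = FALSE]
    if (nrow(wt) < 3) next
    wt <- wt[order(wt$time_s), ]
    st <- trajectory_to_steps(wt)
    sw_full <- diff(wt$side) != 0
    sw <- sw_full[match(st$time_s, wt$time_s[-1])] # align by arrival frame
    cc <- qc_by_w[[w]]
    cc <- cc[order(cc$t_start_s), , drop = FALSE]
    for (e in seq_len(nrow(cc))) {
      pre_lo <- cc$t_start_s[e] - window
      if (e > 1) pre_lo <- max(pre_lo, cc$t_end_s[e - 1])
      post_hi <- cc$t_end_s[e] + window
      if (e < nrow(cc)) post_hi <- min(post_hi, cc$t_start_s[e + 1])
      # pre: lag index from contact start; post: lag from contact end
      pre_sel <- which(st$time_s >= pre_lo & st$time_s < cc$t_start_s[e])
      post_sel <- which(st$time_s > cc$t_end_s[e] & st$time_s <= post_hi)
      add <- function(phase, sel, lags) {
        ok <- lags >= 1 & lags <= nlag
        sel <- sel[ok]; lags <- lags[ok]
        if (!length(sel)) return()
        a <- acc[[phase]]
        a$speed[lags] <- a$speed[lags] + st$step_length[sel] / dtall
        tv <- abs(st$turn_angle[sel])
        tv0 <- ifelse(is.na(tv), 0, tv)
        a$turn[lags] <- a$turn[lags] + tv0
        a$nturn[lags] <- a$nturn[lags] + !is.na(tv)
        a$sw[lags] <- a$sw[lags] + sw[sel]
        a$n[lags] <- a$n[lags] + 1
        acc[[phase]] <<- a
      }
      add("pre", pre_sel,
          round((cc$t_start_s[e] - st$time_s[pre_sel]) / dtall))
      add("post", post_sel,
          round((st$time_s[post_sel] - cc$t_end_s[e]) / dtall))
    }
  }
  t_s <- seq_len(nlag) * dtall
  m <- function(phase, what, denom) {
    a <- acc[[phase]]
    ifelse(a[[denom]] > 0, a[[what]] / a[[denom]], NA_real_)
  }
  out <- data.frame(
    t_s = t_s,
    speed_pre = m("pre", "speed", "n"), speed_post = m("post", "speed", "n"),
    turn_pre = m("pre", "turn", "nturn"),
    turn_post = m("post", "turn", "nturn"),
    switch_pre = m("pre", "sw", "n") / dtall,
    switch_post = m("post", "sw", "n") / dtall,
    n_pre = acc$pre$n, n_post = acc$post$n)
  out$speed_diff <- out$speed_post - out$speed_pre
  out$turn_diff <- out$turn_post - out$turn_pre
  out$switch_diff <- out$switch_post - out$switch_pre
  out
}
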