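# Audience metrics over ensemble load series, and the in-silico
# experiments: within-bout, daily, queen removal, direct-only and
# forward versus time-reversed transmission.

#' Shortest distance between bees, allowing paths around the comb edge
#'
#' Same-side pairs use the Euclidean distance; opposite-side pairs use the
#' shortest straight-line path around the comb edges, computed by reflecting
#' the second position across each of the four edges and taking the minimum
#' Euclidean distance to a reflection.
#'
#' @param p_i,p_j positions: length-2 vectors or 2-column matrices (BL).
#' @param side_i,side_j comb sides (0/1).
#' @param comb_dims `c(width, height)` (BL).
#' @return distances (BL).
#' @export
cross_side_distance <- function(p_i, p_j, side_i, side_j,
                                comb_dims = c(64, 44)) {
  if (is.null(dim(p_i))) p_i <- matrix(p_i, ncol = 2)
  if (is.null(dim(p_j))) p_j <- matrix(p_j, ncol = 2)
  W <- comb_dims[1]; H <- comb_dims[2]
  same <- side_i == side_j
  d <- sqrt((p_i[, 1] - p_j[, 1])^2 + (p_i[, 2] - p_j[, 2])^2)
  if (any(!same)) {
    xi <- p_i[!same, 1]; yi <- p_i[!same, 2]
    xj <- p_j[!same, 1]; yj <- p_j[!same, 2]
    dd <- pmin(
      sqrt((xi + xj)^2 + (yi - yj)^2),            # around x = 0
      sqrt((2 * W - xi - xj)^2 + (yi - yj)^2),    # around x = W
      sqrt((xi - xj)^2 + (yi + yj)^2),            # around y = 0
      sqrt((xi - xj)^2 + (2 * H - yi - yj)^2)     # around y = H
    )
    d[!same] <- dd
  }
  d
}

# nearest-frame positions of given bees at given times -> list(x, y, side)
# matrices (bees x times)
traj_positions <- function(traj, ids, times) {
  ft <- sort(unique(traj$time_s))
  idx <- findInterval(times, ft, all.inside = TRUE)
  # snap to nearest frame
  lower <- ft[idx]
  upper <- ft[pmin(idx + 1, length(ft))]
  snap <- ifelse(times - lower <= upper - times, idx, pmin(idx + 1,
                                                           length(ft)))
  bidx <- match(traj$bee_id, ids)
  keep <- !is.na(bidx)
  tpos <- match(traj$time_s, ft)
  mk <- function(col) {
    m <- matrix(NA_real_, length(ids), length(ft),
                dimnames = list(ids, NULL))
    m[cbind(bidx[keep], tpos[keep])] <- traj[[col]][keep]
    m[, snap, drop = FALSE]
  }
  list(x = mk("x"), y = mk("y"), side = mk("side"))
}

#' Audience size, coverage and load curves from an ensemble
#'
#' At each grid time the informed set is the workers whose ensemble-mean
#' load exceeds `lambda_min`. A(t) is the informed proportion of the tagged
#' workers (of the `group` restriction when given), S(t) the mean pairwise
#' cross-side distance among informed workers (NA below 2 informed), L(t)
#' their mean load.
#'
#' @param ens a `transmission_ensemble`.
#' @param traj trajectory table covering the grid times (for S(t)); NULL
#'   skips S.
#' @param group optional character vector of bee ids to restrict to.
#' @param comb_dims `c(width, height)` (BL).
#' @return data.frame `t_s, A, S_bl, L_pg, n_informed`.
#' @export
audience_curves <- function(ens, traj = NULL, group = NULL,
                            comb_dims = c(64, 44)) {
  workers <- ens$bees$bee_id[ens$bees$role == "worker"]
  if (!is.null(group)) workers <- intersect(workers, group)
  n <- length(workers)
  L <- ens$mean_load[workers, , drop = FALSE]
  lam <- ens$params$lambda_min
  informed <- L > lam
  A <- colSums(informed) / max(n, 1)
  Lbar <- ifelse(colSums(informed) > 0,
                 colSums(L * informed) / pmax(colSums(informed), 1),
                 NA_real_)
  Sbar <- rep(NA_real_, length(ens$times))
  if (!is.null(traj) && n) {
    pos <- traj_positions(traj, workers, ens$times)
    for (ti in seq_along(ens$times)) {
      inf_ids <- which(informed[, ti])
      if (length(inf_ids) >= 2) {
        pr <- utils::combn(inf_ids, 2)
        Sbar[ti] <- mean(cross_side_distance(
          cbind(pos$x[pr[1, ], ti], pos$y[pr[1, ], ti]),
          cbind(pos$x[pr[2, ], ti], pos$y[pr[2, ], ti]),
          pos$side[pr[1, ], ti], pos$side[pr[2, ], ti], comb_dims))
      }
    }
  }
  data.frame(t_s = ens$times, A = A, S_bl = Sbar, L_pg = Lbar,
             n_informed = colSums(informed))
}

#' Grand mean and standard error across colonies
#'
#' Each colony contributes exactly one value per time point.
#'
#' @param curves list of per-colony curve data.frames sharing the time grid.
#' @param cols columns to aggregate.
#' @return data.frame with `t_s` and `mean_`/`se_` columns.
#' @export
aggregate_curves <- function(curves, cols = c("A", "S_bl", "L_pg")) {
  t_s <- curves[[1]]$t_s
  out <- data.frame(t_s = t_s)
  for (cl in cols) {
    m <- vapply(curves, function(cu) cu[[cl]], numeric(length(t_s)))
    m <- matrix(m, nrow = length(t_s))
    out[[paste0("mean_", cl)]] <- rowMeans(m, na.rm = TRUE)
    nn <- rowSums(!is.na(m))
    out[[paste0("se_", cl)]] <- apply(m, 1, stats::sd, na.rm = TRUE) /
      sqrt(pmax(nn, 1))
  }
  out
}

#' Within-bout transmission experiment
#'
#' For every filtered queen bout, zeroes all worker loads, runs the ensemble
#' on the contacts starting and ending inside the bout, and evaluates the
#' audience curves on the bout-relative clock up to 305 s (or the bout's
#' horizon). Bout curves are then averaged by state on the common relative
#' grid.
#'
#' @param bouts filtered bouts ([filter_bouts()]).
#' @param contacts day contact table.
#' @param bees metadata.
#' @param params [transmission_params()].
#' @param traj optional trajectories for S(t).
#' @param grid_step bout-relative grid spacing (s).
#' @param seed integer seed.
#' @return list: `per_bout` (list of curves with bout metadata),
#'   `by_state` (data.frame `state, t_s, A, S_bl, L_pg` of per-state means).
#' @export
within_bout_experiment <- function(bouts, contacts, bees, params,
                                   traj = NULL, grid_step = 5, seed = 1L) {
  per_bout <- list()
  for (b in seq_len(nrow(bouts))) {
    hz <- bouts$horizon_s[b] %||% min(bouts$duration_s[b], 305)
    sel <- contacts$t_start_s >= bouts$t_start_s[b] &
      contacts$t_end_s <= bouts$t_end_s[b]
    grid <- bouts$t_start_s[b] + seq(0, hz, by = grid_step)
    ens <- run_ensemble(contacts[sel, , drop = FALSE], bees, params,
                        seed = seed + b, grid_times = grid,
                        t0 = bouts$t_start_s[b])
    cu <- audience_curves(ens, traj)
    cu$t_s <- cu$t_s - bouts$t_start_s[b]
    attr(cu, "state") <- bouts$state[b]
    per_bout[[b]] <- cu
  }
  rel_grid <- seq(0, 305, by = grid_step)
  by_state <- do.call(rbind, lapply(c("S", "T"), function(s) {
    cus <- per_bout[vapply(per_bout, attr, "", "state") == s]
    if (!length(cus)) return(NULL)
    agg <- vapply(rel_grid, function(tt) {
      vals <- vapply(cus, function(cu) {
        j <- match(tt, cu$t_s)
        if (is.na(j)) c(NA_real_, NA_real_, NA_real_)
        else c(cu$A[j], cu$S_bl[j], cu$L_pg[j])
      }, numeric(3))
      rowMeans(matrix(vals, nrow = 3), na.rm = TRUE)
    }, numeric(3))
    data.frame(state = s, t_s = rel_grid, A = agg[1, ], S_bl = agg[2, ],
               L_pg = agg[3, ])
  }))
  list(per_bout = per_bout, by_state = by_state)
}

#' Daily transmission experiment
#'
#' Zero initial loads; ensemble over the contacts that start and finish
#' inside the day window; audience curves overall and per task group.
#'
#' @param contacts day contact table.
#' @param bees metadata.
#' @param params [transmission_params()].
#' @param groups optional named list of bee-id vectors (e.g. nurse/forager).
#' @param day_window `c(start, end)` seconds; default 00:00:00-23:59:00.
#' @param grid_step grid spacing (s).
#' @param traj optional trajectories for S(t).
#' @param seed integer seed.
#' @return list: `ensemble`, `curves` (data.frame with a `group` column;
#'   `"all"` for the unrestricted curve).
#' @export
daily_experiment <- function(contacts, bees, params, groups = NULL,
                             day_window = c(0, 86340), grid_step = 60,
                             traj = NULL, seed = 1L) {
  sel <- contacts$t_start_s >= day_window[1] &
    contacts$t_end_s <= day_window[2]
  grid <- seq(day_window[1], day_window[2], by = grid_step)
  ens <- run_ensemble(contacts[sel, , drop = FALSE], bees, params,
                      seed = seed, grid_times = grid, t0 = day_window[1])
  curves <- cbind(group = "all", audience_curves(ens, traj))
  for (g in names(groups)) {
    if (!length(groups[[g]])) next
    curves <- rbind(curves, cbind(group = g,
                                  audience_curves(ens, traj,
                                                  group = groups[[g]])))
  }
  list(ensemble = ens, curves = curves)
}

# first time (minutes from removal) the count falls to <= half its value at
# removal, linear interpolation between grid samples
half_life_minutes <- function(times, counts, removal_time) {
  i0 <- max(which(times <= removal_time))
  c0 <- counts[i0]
  if (!is.finite(c0) || c0 <= 0) return(NA_real_)
  target <- c0 / 2
  after <- which(times >= removal_time)
  for (j in after) {
    if (counts[j] <= target) {
      if (j == after[1] || counts[j] == target) {
        t_half <- times[j]
      } else {
        t1 <- times[j - 1]; t2 <- times[j]
        c1 <- counts[j - 1]; c2 <- counts[j]
        t_half <- t1 + (c1 - target) / (c1 - c2) * (t2 - t1)
      }
      return((t_half - removal_time) / 60)
    }
  }
  NA_real_
}

#' In-silico queen removal experiment
#'
#' Deletes all queen-worker contacts starting at or after `removal_time`,
#' reruns the daily ensemble, and computes each group's informed-count
#' half-life (minutes from removal; linear interpolation between grid
#' samples).
#'
#' @inheritParams daily_experiment
#' @param removal_time removal time (s from midnight; default 12:00).
#' @return list: `curves` (as in [daily_experiment()]), `half_life`
#'   (data.frame `group, t_half_min, n_informed_at_removal`).
#' @export
queen_removal_experiment <- function(contacts, bees, params, groups = NULL,
                                     removal_time = 43200,
                                     day_window = c(0, 86340),
                                     grid_step = 60, traj = NULL,
                                     seed = 1L) {
  qid <- bees$bee_id[bees$role == "queen"]
  drop <- (contacts$i %in% qid | contacts$j %in% qid) &
    contacts$t_start_s >= removal_time
  res <- daily_experiment(contacts[!drop, , drop = FALSE], bees, params,
                          groups, day_window, grid_step, traj, seed)
  hl <- do.call(rbind, lapply(unique(res$curves$group), function(g) {
    cu <- res$curves[res$curves$group == g, ]
    i0 <- max(which(cu$t_s <= removal_time))
    data.frame(group = g,
               t_half_min = half_life_minutes(cu$t_s, cu$n_informed,
                                              removal_time),
               n_informed_at_removal = cu$n_informed[i0])
  }))
  list(curves = res$curves, half_life = hl, ensemble = res$ensemble)
}

#' Direct-transmission-only experiment
#'
#' Removes all worker-to-worker contacts so that only queen-to-worker
#' transmission remains, then reruns the daily ensemble.
#'
#' @inheritParams daily_experiment
#' @return as [daily_experiment()].
#' @export
direct_only_experiment <- function(contacts, bees, params, groups = NULL,
                                   day_window = c(0, 86340), grid_step = 60,
                                   traj = NULL, seed = 1L) {
  qid <- bees$bee_id[bees$role == "queen"]
  keep <- contacts$i %in% qid | contacts$j %in% qid
  daily_experiment(contacts[keep, , drop = FALSE], bees, params, groups,
                   day_window, grid_step, traj, seed)
}

# time-reverse a contact block around [t_lo, t_hi]: t -> t_hi + t_lo - t
reverse_contacts <- function(contacts, t_lo, t_hi) {
  out <- contacts
  out$t_start_s <- t_hi + t_lo - contacts$t_end_s
  out$t_end_s <- t_hi + t_lo - contacts$t_start_s
  out[order(out$t_start_s), , drop = FALSE]
}

#' Forward versus time-reversed transmission around queen encounters
#'
#' For each queen-worker encounter, runs the ensemble on the worker-to-worker
#' contacts of the five-minute window after the encounter ("forward") and on
#' the time-reversed contacts of the window before it ("reverse"), seeding
#' the focal worker with the expected load it acquired from the queen
#' encounter in both runs. Returns the per-time relative audience difference
#' `(N_fwd - N_rev)/N_rev` averaged over encounters.
#'
#' @param contacts full day contact table.
#' @param bees metadata.
#' @param params [transmission_params()].
#' @param window window length (s).
#' @param grid_step grid spacing (s).
#' @param min_duration minimum duration (s) of the focal queen contact:
#'   only genuine retinue stints make a worker a messenger; sub-second
#'   brushes load it too lightly to relay.
#' @param max_encounters cap on queen encounters analysed (NULL = all).
#' @param seed integer seed.
#' @return list: `curve` (data.frame `t_s, mean_rel_diff, se_rel_diff, n`),
#'   `per_encounter` (matrix of relative differences).
#' @export
forward_reverse_experiment <- function(contacts, bees, params, window = 300,
                                       grid_step = 5, min_duration = 25,
                                       max_encounters = NULL, seed = 1L) {
  qid <- bees$bee_id[bees$role == "queen"]
  isq <- contacts$i %in% qid | contacts$j %in% qid
  qc <- contacts[isq, , drop = FALSE]
  ww <- contacts[!isq, , drop = FALSE]
  t_all_lo <- min(contacts$t_start_s); t_all_hi <- max(contacts$t_end_s)
  ok <- qc$t_start_s - window >= t_all_lo & qc$t_end_s + window <= t_all_hi &
    qc$t_end_s - qc$t_start_s >= min_duration
  qc <- qc[ok, , drop = FALSE]
  if (!is.null(max_encounters) && nrow(qc) > max_encounters) {
    set.seed(seed)
    qc <- qc[sort(sample.int(nrow(qc), max_encounters)), , drop = FALSE]
  }
  rel_grid <- seq(0, window, by = grid_step)
  rel <- matrix(NA_real_, nrow(qc), length(rel_grid))
  for (e in seq_len(nrow(qc))) {
    focal <- if (qc$i[e] %in% qid) qc$j[e] else qc$i[e]
    dur <- qc$t_end_s[e] - qc$t_start_s[e]
    p <- lick_probability(dur, params)
    ktau <- (p * params$k_lick + (1 - p) * params$k_ant) * dur
    seed_load <- (1 - params$ingestion_fraction) *
      params$lambda_queen * ktau
    init <- data.frame(bee_id = focal, lambda_qw_pg = seed_load,
                       lambda_ww_pg = 0)
    t0 <- qc$t_end_s[e]; t1 <- qc$t_start_s[e]
    fwd_c <- ww[ww$t_start_s > t0 & ww$t_end_s <= t0 + window, ,
                drop = FALSE]
    rev_c <- ww[ww$t_start_s >= t1 - window & ww$t_end_s < t1, ,
                drop = FALSE]
    rev_c <- reverse_contacts(rev_c, t1 - window, t1)
    if (!nrow(fwd_c) && !nrow(rev_c)) next
    nf <- informed_count_curve(fwd_c, bees, params, t0, t0 + rel_grid,
                               init, seed + 2 * e)
    # reversed block occupies [t1 - window, t1]; its relative clock starts
    # at t1 - window
    nr <- informed_count_curve(rev_c, bees, params, t1 - window,
                               t1 - window + rel_grid, init, seed + 2 * e + 1)
    rel[e, ] <- ifelse(nr > 0, (nf - nr) / nr, NA_real_)
  }
  curve <- data.frame(
    t_s = rel_grid,
    mean_rel_diff = colMeans(rel, na.rm = TRUE),
    se_rel_diff = apply(rel, 2, stats::sd, na.rm = TRUE) /
      sqrt(pmax(colSums(!is.na(rel)), 1)),
    n = colSums(!is.na(rel)))
  list(curve = curve, per_encounter = rel)
}

informed_count_curve <- function(contacts, bees, params, t0, grid, init,
                                 seed) {
  ens <- run_ensemble(contacts, bees, params, seed = seed,
                      grid_times = grid, t0 = t0, init_loads = init)
  workers <- bees$bee_id[bees$role == "worker"]
  colSums(ens$mean_load[workers, , drop = FALSE] > params$lambda_min)
}
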