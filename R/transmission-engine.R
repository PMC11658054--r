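# Stochastic queen-pheromone transmission over a time-ordered contact
# sequence. The queen is a constant, inexhaustible surface source; workers
# start as empty sinks. During a contact the inspecting bee (receiver)
# extracts pheromone from the inspected bee (donor) at a first-order rate
# that depends on the behavioural mode (licking > antennation); worker
# donors deplete (diminishing returns) while the queen is clamped; half of
# every transfer is ingested and lost to onward transmission; worker surface
# loads decay exponentially between events.

#' Transmission model parameters
#'
#' Default rates are a calibrated profile, not measurements. The regime
#' they encode: a ~30 s licking retinue contact loads a messenger with
#' ~2000 pg, roughly 250 times the worker sensitivity threshold
#' `lambda_min` = 9.03 pg, so that even a 2 s antennation of a fresh
#' messenger transfers enough to inform the receiver (audience growth then
#' tracks contact rates, and one further relay hop straddles the
#' threshold); at the same time secondary receivers sit only a few-fold
#' above the threshold, so that when the queen stops supplying the network
#' the informed population decays away on the tens-of-minutes scale set by
#' `decay_rate` (~20 min surface half-life) plus ingestion attrition.
#' Every value is overridable.
#'
#' @param lambda_queen constant queen surface load (pg).
#' @param lambda_min informed threshold (pg).
#' @param decay_rate exponential decay rate of worker surface loads (1/s).
#' @param k_lick,k_ant first-order extraction rate constants (1/s);
#'   `k_lick > k_ant`.
#' @param lick_prob_params `c(p_max, tau0, s)` of the logistic
#'   duration-to-lick-probability curve (probability, s, s).
#' @param ingestion_fraction fraction of each transfer the receiver ingests
#'   (lost to onward transmission); the rest lands on its cuticle.
#' @param n_sims ensemble size.
#' @param per_frame_redraw redraw the lick/antennate mode every frame rather
#'   than once per contact.
#' @param frame_dt frame interval (s), used only with `per_frame_redraw`.
#' @return a `transmission_params` list.
#' @export
transmission_params <- function(lambda_queen = 5000, lambda_min = 9.03,
                                decay_rate = 5.8e-4, k_lick = 0.03,
                                k_ant = 0.008,
                                lick_prob_params = c(p_max = 0.8, tau0 = 20,
                                                     s = 5),
                                ingestion_fraction = 0.5, n_sims = 100,
                                per_frame_redraw = FALSE, frame_dt = 0.5) {
  stopifnot(lambda_queen > 0, lambda_min > 0, lambda_min < lambda_queen,
            decay_rate >= 0, k_lick > 0, k_ant > 0, k_lick > k_ant,
            ingestion_fraction >= 0, ingestion_fraction <= 1, n_sims >= 1,
            lick_prob_params[1] >= 0, lick_prob_params[1] <= 1,
            lick_prob_params[3] > 0)
  out <- list(lambda_queen = lambda_queen, lambda_min = lambda_min,
              decay_rate = decay_rate, k_lick = k_lick, k_ant = k_ant,
              lick_prob_params = lick_prob_params,
              ingestion_fraction = ingestion_fraction,
              n_sims = as.integer(n_sims),
              per_frame_redraw = isTRUE(per_frame_redraw),
              frame_dt = frame_dt)
  class(out) <- "transmission_params"
  out
}

#' Probability that a contact is a licking contact
#'
#' Monotone logistic in contact duration:
#' `p(tau) = p_max / (1 + exp(-(tau - tau0)/s))`. Longer contacts are more
#' likely to involve licking, which extracts pheromone faster than
#' antennation.
#'
#' @param duration contact duration (s).
#' @param params [transmission_params()].
#' @return probabilities in `[0, p_max]`.
#' @export
lick_probability <- function(duration, params = transmission_params()) {
  p <- params$lick_prob_params
  p[[1]] / (1 + exp(-(duration - p[[2]]) / p[[3]]))
}

#' Amount removed from a donor and acquired by a receiver over one contact
#'
#' Donor loss follows first-order extraction `dq/dt = k * lambda_donor(t)`.
#' Worker donors deplete, giving `removed = lambda0 * (1 - exp(-k tau))`
#' (diminishing returns); the queen's load is clamped, giving
#' `removed = k * lambda_queen * tau`. The receiver's cuticle gains
#' `(1 - ingestion_fraction) * removed`.
#'
#' @param donor_load donor surface load at contact start (pg); ignored for
#'   the queen.
#' @param duration contact duration (s), positive.
#' @param mode `"lick"` or `"antennate"`.
#' @param params [transmission_params()].
#' @param donor_is_queen clamp the donor load?
#' @return named numeric `c(removed, acquired)` (pg).
#' @export
integrate_contact <- function(donor_load, duration, mode, params,
                              donor_is_queen = FALSE) {
  if (any(duration < 0)) stop("negative contact duration")
  k <- ifelse(mode == "lick", params$k_lick, params$k_ant)
  removed <- if (donor_is_queen) {
    k * params$lambda_queen * duration
  } else {
    donor_load * (1 - exp(-k * duration))
  }
  c(removed = removed,
    acquired = (1 - params$ingestion_fraction) * removed)
}

#' Run one stochastic transmission realisation
#'
#' Processes the time-ordered contacts one by one, applying each contact's
#' transfer when it completes (at `t_end_s`). Per contact the inspection
#' roles come from the majority per-frame flags (the inspector receives);
#' mutual inspection resolves toward the higher-load donor, exact load ties
#' give symmetric half-transfers; the behavioural mode is a single
#' Bernoulli draw from [lick_probability()]. Worker loads decay at
#' `decay_rate` between events; queen-derived and worker-derived fractions
#' are tracked separately (transfers from a worker donor credit the
#' worker-derived pool regardless of the donor's own mix).
#'
#' @param contacts contact table (`i, j, t_start_s, t_end_s,
#'   frac_frames_i_inspects, frac_frames_j_inspects`), time-sorted.
#' @param bees metadata (`bee_id, role`); exactly one queen.
#' @param params [transmission_params()].
#' @param seed integer seed.
#' @param t0 simulation start time (workers have zero load at `t0`).
#' @param init_loads optional data.frame `bee_id, lambda_qw_pg,
#'   lambda_ww_pg` of non-zero worker loads at `t0`.
#' @return a `transmission_run`: `events` data.frame (`t_s, donor, receiver,
#'   mode, removed_pg, acquired_pg`), `history` data.frame (`bee_id, t_s,
#'   lambda_qw_pg, lambda_ww_pg` post-event snapshots), `final` per-bee
#'   loads, plus `params`, `t0`.
#' @export
run_transmission <- function(contacts, bees, params = transmission_params(),
                             seed = 1L, t0 = NULL, init_loads = NULL) {
  ids <- bees$bee_id
  if (!all(c(contacts$i, contacts$j) %in% ids)) {
    stop("contact references unknown bee")
  }
  qid <- ids[bees$role == "queen"]
  stopifnot(length(qid) <= 1)
  # transfers complete at contact end; processing in end order keeps every
  # per-bee load history time-sorted even for overlapping contacts
  contacts <- contacts[order(contacts$t_end_s, contacts$t_start_s), ,
                       drop = FALSE]
  if (is.null(t0)) t0 <- if (nrow(contacts)) min(contacts$t_start_s) else 0
  set.seed(seed)
  nb <- length(ids)
  lqw <- numeric(nb); lww <- numeric(nb); tlast <- rep(t0, nb)
  if (!is.null(init_loads) && nrow(init_loads)) {
    m <- match(init_loads$bee_id, ids)
    stopifnot(!anyNA(m))
    lqw[m] <- init_loads$lambda_qw_pg
    lww[m] <- init_loads$lambda_ww_pg
  }
  iq <- if (length(qid)) match(qid, ids) else 0L
  ci <- match(contacts$i, ids); cj <- match(contacts$j, ids)
  nct <- nrow(contacts)
  # pre-draw modes for reproducibility independent of branchy code below
  durs <- contacts$t_end_s - contacts$t_start_s
  p_l <- lick_probability(durs, params)
  if (!params$per_frame_redraw) {
    lick <- stats::runif(nct) < p_l
    ktau <- ifelse(lick, params$k_lick, params$k_ant) * durs
  } else {
    lick <- logical(nct); ktau <- numeric(nct)
    for (c0 in seq_len(nct)) {
      nfr <- max(1L, round(durs[c0] / params$frame_dt))
      dl <- stats::runif(nfr) < p_l[c0]
      ktau[c0] <- mean(ifelse(dl, params$k_lick, params$k_ant)) * durs[c0]
      lick[c0] <- mean(dl) >= 0.5
    }
  }
  delta <- params$decay_rate
  cap <- max(2L * nct, 16L)
  ev_t <- numeric(cap); ev_d <- integer(cap); ev_r <- integer(cap)
  ev_m <- integer(cap); ev_rem <- numeric(cap); ev_acq <- numeric(cap)
  ne <- 0L
  hist_b <- integer(cap); hist_t <- numeric(cap)
  hist_q <- numeric(cap); hist_w <- numeric(cap)
  nh <- 0L
  push_hist <- function(b, t) {
    nh <<- nh + 1L
    if (nh > length(hist_b)) {
      hist_b <<- c(hist_b, integer(nh)); hist_t <<- c(hist_t, numeric(nh))
      hist_q <<- c(hist_q, numeric(nh)); hist_w <<- c(hist_w, numeric(nh))
    }
    hist_b[nh] <<- b; hist_t[nh] <<- t
    hist_q[nh] <<- lqw[b]; hist_w[nh] <<- lww[b]
  }
  if (!is.null(init_loads) && nrow(init_loads)) {
    for (b in match(init_loads$bee_id, ids)) push_hist(b, t0)
  }
  transfer <- function(d, r, t, kt, mode, scale, dl_pre = NULL,
                       fq_pre = NULL) {
    donor_is_queen <- d == iq
    dl <- dl_pre %||% (lqw[d] + lww[d])
    removed <- if (donor_is_queen) {
      params$lambda_queen * kt
    } else {
      dl * (1 - exp(-kt))
    }
    removed <- removed * scale
    acquired <- (1 - params$ingestion_fraction) * removed
    if (!donor_is_queen && dl > 0) {
      fq <- fq_pre %||% (lqw[d] / dl)
      lqw[d] <<- lqw[d] - removed * fq
      lww[d] <<- lww[d] - removed * (1 - fq)
    }
    if (r != iq) {
      if (donor_is_queen) lqw[r] <<- lqw[r] + acquired
      else lww[r] <<- lww[r] + acquired
    }
    if (removed > 0) {
      ne <<- ne + 1L
      if (ne > length(ev_t)) {
        ev_t <<- c(ev_t, numeric(ne)); ev_d <<- c(ev_d, integer(ne))
        ev_r <<- c(ev_r, integer(ne)); ev_m <<- c(ev_m, integer(ne))
        ev_rem <<- c(ev_rem, numeric(ne)); ev_acq <<- c(ev_acq, numeric(ne))
      }
      ev_t[ne] <<- t; ev_d[ne] <<- d; ev_r[ne] <<- r
      ev_m[ne] <<- if (mode == "lick") 1L else 2L
      ev_rem[ne] <<- removed; ev_acq[ne] <<- acquired
    }
  }
  for (c0 in seq_len(nct)) {
    a <- ci[c0]; b <- cj[c0]
    t <- contacts$t_end_s[c0]
    kt <- ktau[c0]
    # decay both participants up to t (queen exempt)
    for (u in c(a, b)) {
      if (u != iq && delta > 0 && t > tlast[u]) {
        f <- exp(-delta * (t - tlast[u]))
        lqw[u] <- lqw[u] * f; lww[u] <- lww[u] * f
      }
      tlast[u] <- t
    }
    ai <- contacts$frac_frames_i_inspects[c0] > 0.5
    bi <- contacts$frac_frames_j_inspects[c0] > 0.5
    mode <- if (lick[c0]) "lick" else "antennate"
    if (!ai && !bi) next
    if (ai && bi) {
      la <- if (a == iq) params$lambda_queen else lqw[a] + lww[a]
      lb <- if (b == iq) params$lambda_queen else lqw[b] + lww[b]
      if (la > lb) {
        if (b != iq) transfer(a, b, t, kt, mode, 1)
      } else if (lb > la) {
        if (a != iq) transfer(b, a, t, kt, mode, 1)
      } else {
        # exact tie: symmetric half-transfers computed from the
        # pre-contact state of both participants
        fa <- if (la > 0 && a != iq) lqw[a] / la else 0
        fb <- if (lb > 0 && b != iq) lqw[b] / lb else 0
        if (b != iq) transfer(a, b, t, kt, mode, 0.5, la, fa)
        if (a != iq) transfer(b, a, t, kt, mode, 0.5, lb, fb)
      }
    } else if (ai) { # a inspects b: b is donor
      if (a != iq) transfer(b, a, t, kt, mode, 1)
    } else {
      if (b != iq) transfer(a, b, t, kt, mode, 1)
    }
    if (a != iq) push_hist(a, t)
    if (b != iq) push_hist(b, t)
  }
  events <- data.frame(
    t_s = ev_t[seq_len(ne)], donor = ids[ev_d[seq_len(ne)]],
    receiver = ids[ev_r[seq_len(ne)]],
    mode = c("lick", "antennate")[ev_m[seq_len(ne)]],
    removed_pg = ev_rem[seq_len(ne)], acquired_pg = ev_acq[seq_len(ne)],
    stringsAsFactors = FALSE)
  history <- data.frame(
    bee_id = ids[hist_b[seq_len(nh)]], t_s = hist_t[seq_len(nh)],
    lambda_qw_pg = hist_q[seq_len(nh)], lambda_ww_pg = hist_w[seq_len(nh)],
    stringsAsFactors = FALSE)
  out <- list(events = events, history = history,
              final = data.frame(bee_id = ids, lambda_qw_pg = lqw,
                                 lambda_ww_pg = lww, t_last = tlast,
                                 stringsAsFactors = FALSE),
              params = params, t0 = t0, queen_id = if (iq) qid else NA)
  class(out) <- "transmission_run"
  out
}

#' Evaluate per-bee loads of one run on a time grid
#'
#' @param run a `transmission_run`.
#' @param times evaluation times (s).
#' @param ids bees to evaluate (default: all in the run).
#' @return list of matrices `lqw`, `lww` (bees x times, pg); rows named by
#'   bee id.
#' @export
loads_at <- function(run, times, ids = NULL) {
  if (is.null(ids)) ids <- run$final$bee_id
  delta <- run$params$decay_rate
  lqw <- matrix(0, length(ids), length(times), dimnames = list(ids, NULL))
  lww <- lqw
  h <- run$history
  sp <- split(seq_len(nrow(h)), h$bee_id)
  for (k in seq_along(ids)) {
    rows <- sp[[ids[k]]]
    if (is.null(rows)) next
    ht <- h$t_s[rows]
    idx <- findInterval(times, ht)
    pos <- which(idx >= 1)
    if (!length(pos)) next
    f <- exp(-delta * (times[pos] - ht[idx[pos]]))
    lqw[k, pos] <- h$lambda_qw_pg[rows][idx[pos]] * f
    lww[k, pos] <- h$lambda_ww_pg[rows][idx[pos]] * f
  }
  list(lqw = lqw, lww = lww)
}

#' Classify informed status from load components
#'
#' @param lqw,lww queen-derived and worker-derived loads (pg).
#' @param lambda_min informed threshold (pg).
#' @return character: `"direct"`, `"indirect"` or `"uninformed"`.
#' @export
informed_class <- function(lqw, lww, lambda_min = 9.03) {
  tot <- lqw + lww
  out <- rep("uninformed", length(tot))
  out[tot > lambda_min & lqw > lww] <- "direct"
  out[tot > lambda_min & lqw <= lww] <- "indirect"
  out
}

#' Run an ensemble of transmission realisations
#'
#' Repeats [run_transmission()] `params$n_sims` times with derived seeds and
#' returns ensemble-mean load series on a time grid together with the
#' per-pair mean transferred volumes `Q[i -> j] = sum(removed) / S` used by
#' relay networks.
#'
#' @param contacts,bees,params,seed,t0 as in [run_transmission()].
#' @param grid_times evaluation grid (s); default 60 s spacing across the
#'   contact span.
#' @return a `transmission_ensemble`: `times`, matrices `mean_lqw`,
#'   `mean_lww`, `mean_load`, data.frame `pair_flows`
#'   (`donor, receiver, Q_pg`), `n_sims`, `params`, `bees`.
#' @export
run_ensemble <- function(contacts, bees, params = transmission_params(),
                         seed = 1L, grid_times = NULL, t0 = NULL,
                         init_loads = NULL) {
  S <- params$n_sims
  if (is.null(t0)) t0 <- if (nrow(contacts)) min(contacts$t_start_s) else 0
  if (is.null(grid_times)) {
    tmax <- if (nrow(contacts)) max(contacts$t_end_s) else t0
    grid_times <- seq(t0, max(tmax, t0 + 1), by = 60)
  }
  ids <- bees$bee_id
  seeds <- derive_seeds(seed, S)
  sum_lqw <- matrix(0, length(ids), length(grid_times),
                    dimnames = list(ids, NULL))
  sum_lww <- sum_lqw
  fkeys <- character(0); fvals <- numeric(0)
  for (s in seq_len(S)) {
    run <- run_transmission(contacts, bees, params, seed = seeds[s], t0 = t0,
                            init_loads = init_loads)
    ll <- loads_at(run, grid_times, ids)
    sum_lqw <- sum_lqw + ll$lqw
    sum_lww <- sum_lww + ll$lww
    ev <- run$events
    if (nrow(ev)) {
      fkeys <- c(fkeys, paste(ev$donor, ev$receiver, sep = "\r"))
      fvals <- c(fvals, ev$removed_pg)
    }
  }
  pair_flows <- if (length(fkeys)) {
    agg <- tapply(fvals, fkeys, sum)
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    data.frame(donor = vapply(parts, `[`, "", 1),
               receiver = vapply(parts, `[`, "", 2),
               Q_pg = as.numeric(agg) / S,
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(donor = character(), receiver = character(),
               Q_pg = numeric(), stringsAsFactors = FALSE)
  }
  out <- list(times = grid_times, mean_lqw = sum_lqw / S,
              mean_lww = sum_lww / S,
              mean_load = (sum_lqw + sum_lww) / S,
              pair_flows = pair_flows, n_sims = S, params = params,
              bees = bees, t0 = t0)
  class(out) <- "transmission_ensemble"
  out
}

#' @export
print.transmission_ensemble <- function(x, ...) {
  cat("transmission_ensemble:", x$n_sims, "runs,", nrow(x$bees), "bees,",
      length(x$times), "grid points\n")
  invisible(x)
}
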