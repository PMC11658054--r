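# Shared fixtures. Heavy objects are built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# small mixed-age colony: cohorts aged 7, 4 and 1 days on the observation day
small_config <- function(seed = 42, day_length_s = 1800, size = 8,
                         forager_age = 6) {
  colony_config(
    cohort_schedule = data.frame(day = c(0, 3, 6), size = size),
    day_length_s = day_length_s,
    worker_age_profiles = utils::modifyList(
      colony_config()$worker_age_profiles,
      list(forager_transition_age = forager_age)),
    seed = seed)
}

small_colony <- function() {
  cached("small_colony", function() simulate_colony_day(small_config(), 7))
}

small_contacts <- function() {
  cached("small_contacts", function() {
    sim <- small_colony()
    detect_contacts(sim$traj, sim$bees)
  })
}

# denser colony with all three task groups well populated: 16 nurses per
# broodnest patch plus 16 foragers
medium_config <- function(seed = 101, day_length_s = 1200) {
  cfg <- colony_config(
    cohort_schedule = data.frame(day = c(0, 3, 6), size = 16),
    day_length_s = day_length_s,
    broodnest_radius = 6,
    worker_age_profiles = utils::modifyList(
      colony_config()$worker_age_profiles,
      list(forager_transition_age = 6)),
    seed = seed)
  cfg
}

medium_colony <- function() {
  cached("medium_colony", function() simulate_colony_day(medium_config(), 7))
}

medium_contacts <- function() {
  cached("medium_contacts", function() {
    sim <- medium_colony()
    detect_contacts(sim$traj, sim$bees)
  })
}

# three-hour colony-day used for the end-to-end audience experiments
accept_colony <- function() {
  cached("accept_colony", function() {
    simulate_colony_day(medium_config(seed = 202, day_length_s = 10800), 7)
  })
}

accept_contacts <- function() {
  cached("accept_contacts", function() {
    sim <- accept_colony()
    detect_contacts(sim$traj, sim$bees)
  })
}

# a single worker + queen metadata table
two_bees <- function(ids = c("A", "B"), roles = c("worker", "worker")) {
  data.frame(bee_id = ids, role = roles, stringsAsFactors = FALSE)
}

# hand-built trajectory table from per-bee pose matrices
pose_traj <- function(..., dt = 0.5) {
  bees <- list(...)
  out <- do.call(rbind, lapply(names(bees), function(id) {
    p <- bees[[id]]
    data.frame(bee_id = id, time_s = (seq_len(nrow(p)) - 1) * dt,
               x = p[, 1], y = p[, 2], heading_rad = p[, 3],
               side = if (ncol(p) >= 4) p[, 4] else 0,
               stringsAsFactors = FALSE)
  }))
  out
}

# independent convex-polygon intersection oracle: any vertex of one polygon
# inside the other, or any pair of edges crossing (classic two-phase test,
# no separating axes)
point_in_convex <- function(px, py, P) {
  n <- nrow(P)
  s <- 0
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1 else k + 1
    cr <- (P[k2, 1] - P[k, 1]) * (py - P[k, 2]) -
      (P[k2, 2] - P[k, 2]) * (px - P[k, 1])
    if (abs(cr) < 1e-12) next
    if (s == 0) s <- sign(cr) else if (sign(cr) != s) return(FALSE)
  }
  TRUE
}

segments_cross <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) {
    (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  }
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

polys_intersect_oracle <- function(P, Q) {
  for (k in seq_len(nrow(P))) {
    if (point_in_convex(P[k, 1], P[k, 2], Q)) return(TRUE)
  }
  for (k in seq_len(nrow(Q))) {
    if (point_in_convex(Q[k, 1], Q[k, 2], P)) return(TRUE)
  }
  for (k in seq_len(nrow(P))) {
    k2 <- if (k == nrow(P)) 1 else k + 1
    for (m in seq_len(nrow(Q))) {
      m2 <- if (m == nrow(Q)) 1 else m + 1
      if (segments_cross(P[k, ], P[k2, ], Q[m, ], Q[m2, ])) return(TRUE)
    }
  }
  FALSE
}

# quad matrix (4 x 2) for a pose, via the package's own constructor
pose_quad <- function(x, y, h, role = "worker", part = "full",
                      dims = body_dims()) {
  q <- queenrelay:::quad_coords(x, y, h, dims[[role]], part)
  cbind(q$X[, 1], q$Y[, 1])
}
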