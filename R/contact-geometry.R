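# Trapezoidal body models and detection of transmission-relevant contacts.
#
# A bee body is a trapezium centred on its tag, long axis along the heading,
# wider at the head (antennal reach) than at the tail. A frame counts as a
# contact frame for a pair when the head half of one bee's trapezium overlaps
# any part of the other's trapezium; side-by-side or tail-to-tail touching is
# thereby excluded.

#' Body trapezium dimensions per role
#'
#' All dimensions are in worker body-lengths (BL). The queen's trapezium is
#' scaled longer than a worker's; widths scale with length.
#'
#' @param worker_length,worker_head_width,worker_tail_width worker trapezium
#'   dimensions (BL).
#' @param queen_scale queen length relative to a worker.
#' @return list with `worker` and `queen` entries, each
#'   `(length, head_width, tail_width)`.
#' @export
body_dims <- function(worker_length = 1.0, worker_head_width = 0.55,
                      worker_tail_width = 0.35, queen_scale = 1.5) {
  stopifnot(worker_length > 0, worker_head_width >= worker_tail_width,
            worker_tail_width > 0, queen_scale >= 1)
  list(
    worker = c(length = worker_length, head_width = worker_head_width,
               tail_width = worker_tail_width),
    queen = c(length = worker_length * queen_scale,
              head_width = worker_head_width * queen_scale,
              tail_width = worker_tail_width * queen_scale)
  )
}

# Quad vertex coordinates for n poses. part = "full" is the whole trapezium,
# "head" its front half (split at the tag line, where the width interpolates
# linearly between tail and head widths). Returns list(X, Y): 4 x n matrices,
# vertices in order front-left, front-right, rear-right, rear-left.
quad_coords <- function(x, y, heading, dims_role, part = c("full", "head")) {
  part <- match.arg(part)
  L <- dims_role[["length"]]
  wh <- dims_role[["head_width"]]
  wt <- dims_role[["tail_width"]]
  ux <- cos(heading); uy <- sin(heading)
  vx <- -uy; vy <- ux
  if (part == "full") {
    s_front <- L / 2; s_rear <- -L / 2
    w_front <- wh; w_rear <- wt
  } else {
    s_front <- L / 2; s_rear <- 0
    w_front <- wh; w_rear <- (wh + wt) / 2
  }
  fx <- x + s_front * ux; fy <- y + s_front * uy
  rx <- x + s_rear * ux; ry <- y + s_rear * uy
  X <- rbind(fx + (w_front / 2) * vx, fx - (w_front / 2) * vx,
             rx - (w_rear / 2) * vx, rx + (w_rear / 2) * vx)
  Y <- rbind(fy + (w_front / 2) * vy, fy - (w_front / 2) * vy,
             ry - (w_rear / 2) * vy, ry + (w_rear / 2) * vy)
  list(X = X, Y = Y)
}

#' Build a single body trapezium
#'
#' @param x,y tag (centre) position, BL.
#' @param heading body heading, CCW radians from +x in `[0, 2*pi)`.
#' @param role `"worker"` or `"queen"`.
#' @param dims output of [body_dims()].
#' @return a `body_polygon`: 4 x 2 matrix of vertices (front-left,
#'   front-right, rear-right, rear-left) with attributes `head_edge`
#'   (rows 1:2) and `role`.
#' @examples
#' p <- build_body_polygon(0, 0, 0, "worker")
#' attr(p, "head_edge")
#' @export
build_body_polygon <- function(x, y, heading, role, dims = body_dims()) {
  stopifnot(is.finite(x), is.finite(y), is.finite(heading))
  if (!role %in% c("worker", "queen")) {
    stop("unknown role: ", role)
  }
  q <- quad_coords(x, y, heading, dims[[role]], "full")
  out <- cbind(x = q$X[, 1], y = q$Y[, 1])
  rownames(out) <- c("front_left", "front_right", "rear_right", "rear_left")
  attr(out, "head_edge") <- out[1:2, , drop = FALSE]
  attr(out, "role") <- role
  class(out) <- c("body_polygon", class(out))
  out
}

# Separating-axis intersection test between two quads, vectorised over n
# frames. A, B: lists with 4 x n matrices X, Y. Returns logical n-vector.
sat_intersect <- function(A, B) {
  n <- ncol(A$X)
  hit <- rep(TRUE, n)
  for (src in list(A, B)) {
    for (k in 1:4) {
      k2 <- if (k == 4) 1L else k + 1L
      ex <- src$X[k2, ] - src$X[k, ]
      ey <- src$Y[k2, ] - src$Y[k, ]
      ax <- -ey; ay <- ex
      pa1 <- ax * A$X[1, ] + ay * A$Y[1, ]
      pa2 <- ax * A$X[2, ] + ay * A$Y[2, ]
      pa3 <- ax * A$X[3, ] + ay * A$Y[3, ]
      pa4 <- ax * A$X[4, ] + ay * A$Y[4, ]
      pb1 <- ax * B$X[1, ] + ay * B$Y[1, ]
      pb2 <- ax * B$X[2, ] + ay * B$Y[2, ]
      pb3 <- ax * B$X[3, ] + ay * B$Y[3, ]
      pb4 <- ax * B$X[4, ] + ay * B$Y[4, ]
      minA <- pmin(pa1, pa2, pa3, pa4); maxA <- pmax(pa1, pa2, pa3, pa4)
      minB <- pmin(pb1, pb2, pb3, pb4); maxB <- pmax(pb1, pb2, pb3, pb4)
      hit <- hit & !(maxA < minB | maxB < minA)
      if (!any(hit)) return(hit)
    }
  }
  hit
}

# Per-frame inspection geometry for a pair, vectorised. i inspects j iff i's
# head half overlaps j's full trapezium AND j's centre lies within
# +/- facing_halfangle of i's heading.
inspection_flags <- function(xi, yi, hi, dims_i, xj, yj, hj, dims_j,
                             facing_halfangle = pi / 2) {
  Hi <- quad_coords(xi, yi, hi, dims_i, "head")
  Pj <- quad_coords(xj, yj, hj, dims_j, "full")
  bear <- atan2(yj - yi, xj - xi)
  abs(angle_diff(bear, hi)) <= facing_halfangle & sat_intersect(Hi, Pj)
}

#' Classify inspection roles for one frame of a bee pair
#'
#' During a contact the inspecting bee (the one licking/antennating) is the
#' pheromone receiver and the inspected bee the donor. `i` inspects `j` when
#' `i`'s head half overlaps `j`'s trapezium and `j` lies within the frontal
#' half-plane of `i` (default facing half-angle 90 degrees). Both flags may be
#' false (no transmission that frame).
#'
#' @param pose_i,pose_j lists with `x`, `y`, `heading`, `role`.
#' @param dims [body_dims()].
#' @param facing_halfangle radians; default `pi/2`.
#' @return list with logicals `i_inspects`, `j_inspects`.
#' @export
classify_inspection <- function(pose_i, pose_j, dims = body_dims(),
                                facing_halfangle = pi / 2) {
  list(
    i_inspects = inspection_flags(pose_i$x, pose_i$y, pose_i$heading,
                                  dims[[pose_i$role]], pose_j$x, pose_j$y,
                                  pose_j$heading, dims[[pose_j$role]],
                                  facing_halfangle),
    j_inspects = inspection_flags(pose_j$x, pose_j$y, pose_j$heading,
                                  dims[[pose_j$role]], pose_i$x, pose_i$y,
                                  pose_i$heading, dims[[pose_i$role]],
                                  facing_halfangle)
  )
}

#' Detect transmission-relevant contacts in a trajectory table
#'
#' A frame is a contact frame for a pair when both bees are on the same comb
#' side and the head half of either trapezium intersects the other's
#' trapezium. Consecutive contact frames merge into one contact; dropouts of
#' at most `gap_tol` frames are bridged; contacts never span a side switch.
#'
#' @param traj trajectory data.frame with columns
#'   `bee_id, time_s, x, y, heading_rad, side` on a shared regular time grid.
#' @param bees metadata data.frame with columns `bee_id, role`.
#' @param dims [body_dims()].
#' @param gap_tol number of missing frames tolerated inside a contact.
#' @param facing_halfangle facing cone half-angle (radians) for inspection
#'   classification.
#' @return data.frame of contacts: `i, j, t_start_s, t_end_s, side, n_frames,
#'   frac_frames_i_inspects, frac_frames_j_inspects`, sorted by `t_start_s`.
#'   `t_end_s - t_start_s` is the contact duration (multiples of the frame
#'   interval when no gap is bridged).
#' @export
detect_contacts <- function(traj, bees, dims = body_dims(), gap_tol = 1L,
                            facing_halfangle = pi / 2) {
  stopifnot(all(c("bee_id", "time_s", "x", "y", "heading_rad", "side")
                %in% names(traj)),
            all(c("bee_id", "role") %in% names(bees)))
  times <- sort(unique(traj$time_s))
  nt <- length(times)
  if (nt < 1) return(empty_contacts())
  dt <- if (nt > 1) stats::median(diff(times)) else 0.5
  if (is.unsorted(traj$time_s[order(traj$bee_id)]) &&
      is.unsorted(traj$time_s)) {
    traj <- traj[order(traj$bee_id, traj$time_s), ]
  }
  ids <- intersect(unique(traj$bee_id), bees$bee_id)
  roles <- stats::setNames(bees$role[match(ids, bees$bee_id)], ids)
  if (anyNA(roles) || !all(roles %in% c("worker", "queen"))) {
    stop("every bee needs a known role (worker/queen)")
  }
  # per-bee aligned series
  tidx <- match(traj$time_s, times)
  if (anyNA(tidx)) stop("trajectory times off the shared grid")
  mk <- function(col) {
    m <- matrix(NA_real_, nt, length(ids), dimnames = list(NULL, ids))
    m[cbind(tidx, match(traj$bee_id, ids))] <- traj[[col]]
    m
  }
  X <- mk("x"); Y <- mk("y"); H <- mk("heading_rad"); S <- mk("side")
  circum <- vapply(ids, function(b) {
    d <- dims[[roles[[b]]]]
    sqrt((d[["length"]] / 2)^2 + (d[["head_width"]] / 2)^2)
  }, numeric(1))

  res <- list()
  pairs <- utils::combn(seq_along(ids), 2)
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    ok <- !is.na(X[, a]) & !is.na(X[, b]) & S[, a] == S[, b]
    if (!any(ok)) next
    dx <- X[, a] - X[, b]; dy <- Y[, a] - Y[, b]
    reach <- (circum[a] + circum[b])^2
    cand <- which(ok & (dx * dx + dy * dy) <= reach)
    if (!length(cand)) next
    da <- dims[[roles[[a]]]]; db <- dims[[roles[[b]]]]
    ii <- inspection_flags(X[cand, a], Y[cand, a], H[cand, a], da,
                           X[cand, b], Y[cand, b], H[cand, b], db,
                           facing_halfangle)
    jj <- inspection_flags(X[cand, b], Y[cand, b], H[cand, b], db,
                           X[cand, a], Y[cand, a], H[cand, a], da,
                           facing_halfangle)
    # contact frame: head half of either bee overlaps the other's body
    Ha <- quad_coords(X[cand, a], Y[cand, a], H[cand, a], da, "head")
    Pb <- quad_coords(X[cand, b], Y[cand, b], H[cand, b], db, "full")
    Hb <- quad_coords(X[cand, b], Y[cand, b], H[cand, b], db, "head")
    Pa <- quad_coords(X[cand, a], Y[cand, a], H[cand, a], da, "full")
    hit <- sat_intersect(Ha, Pb) | sat_intersect(Hb, Pa)
    cf <- cand[hit]
    if (!length(cf)) next
    fi <- ii[hit]; fj <- jj[hit]
    sides_cf <- S[cf, a]
    # split runs: frame gap > gap_tol + 1 or side change
    brk <- c(TRUE, diff(cf) > (gap_tol + 1L) | diff(sides_cf) != 0)
    run <- cumsum(brk)
    for (r in unique(run)) {
      sel <- run == r
      fr <- cf[sel]
      res[[length(res) + 1L]] <- data.frame(
        i = ids[a], j = ids[b],
        t_start_s = times[fr[1]],
        t_end_s = times[fr[length(fr)]] + dt,
        side = sides_cf[sel][1],
        n_frames = sum(sel),
        frac_frames_i_inspects = mean(fi[sel]),
        frac_frames_j_inspects = mean(fj[sel]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(res)) return(empty_contacts())
  out <- do.call(rbind, res)
  out <- out[order(out$t_start_s, out$i, out$j), ]
  rownames(out) <- NULL
  out
}

empty_contacts <- function() {
  data.frame(i = character(), j = character(), t_start_s = numeric(),
             t_end_s = numeric(), side = numeric(), n_frames = integer(),
             frac_frames_i_inspects = numeric(),
             frac_frames_j_inspects = numeric(), stringsAsFactors = FALSE)
}

#' Write / read a contacts table
#' @param contacts contacts data.frame from [detect_contacts()].
#' @param path file path.
#' @return `read_contacts` returns the contacts data.frame.
#' @export
write_contacts <- function(contacts, path) {
  utils::write.csv(contacts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contacts
#' @export
read_contacts <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
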