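# The messaging syndrome: six per-bee-day metrics, within-day quantile
# transformation, pooled PCA, age-cohort mean trajectories and the
# developmental inflection point.

SYNDROME_METRICS <- c("m1", "m2", "m3", "m4", "m5", "m6")

#' Assemble messaging-syndrome rows
#'
#' One row per tagged worker per day with the six messaging metrics:
#' m1 queen-attraction effect (negated median distance difference, larger =
#' more attracted), m2 queen-contact count, m3 combined nurse affiliation
#' `N_A + N_B`, m4 bridging score H', m5 relay out-degree `k_out`,
#' m6 degree difference `delta_k`. Bees without an eclosion day are excluded
#' with a warning; missing metrics propagate as NA.
#'
#' @param bees metadata (`bee_id, role, eclosion_day, colony_id`).
#' @param day observation day index.
#' @param attraction data.frame `bee_id, effect_bl` from
#'   [queen_attraction_test()] results.
#' @param queen_contact_counts data.frame `bee_id, n`.
#' @param task data.frame from [classify_task_group()].
#' @param relay_nodes `nodes` table of a `relay_network`.
#' @return data.frame `colony, bee_id, day, age, m1..m6`.
#' @export
assemble_syndrome <- function(bees, day, attraction, queen_contact_counts,
                              task, relay_nodes) {
  w <- bees[bees$role == "worker", , drop = FALSE]
  no_ecl <- is.na(w$eclosion_day)
  if (any(no_ecl)) {
    warning(sum(no_ecl), " workers without eclosion day excluded")
    w <- w[!no_ecl, , drop = FALSE]
  }
  g <- function(tab, col, id = "bee_id") tab[[col]][match(w$bee_id,
                                                          tab[[id]])]
  data.frame(
    colony = w$colony_id, bee_id = w$bee_id, day = day,
    age = day - w$eclosion_day,
    m1 = -g(attraction, "effect_bl"),
    m2 = g(queen_contact_counts, "n"),
    m3 = g(task, "N_A") + g(task, "N_B"),
    m4 = g(task, "H_bridge"),
    m5 = g(relay_nodes, "k_out"),
    m6 = g(relay_nodes, "delta_k"),
    stringsAsFactors = FALSE)
}

#' Within-day quantile transformation
#'
#' Replaces each metric, independently per colony-day, by `rank/(n+1)` with
#' mean ranks for ties; missing values stay missing; a constant metric-day
#' maps to 0.5.
#'
#' @param rows syndrome rows (`colony, day, m1..m6`).
#' @return rows with metrics transformed to (0, 1).
#' @export
quantile_transform <- function(rows) {
  key <- paste(rows$colony, rows$day)
  for (m in SYNDROME_METRICS) {
    for (k in unique(key)) {
      sel <- key == k & !is.na(rows[[m]])
      n <- sum(sel)
      if (!n) next
      v <- rows[[m]][sel]
      rows[[m]][sel] <- if (max(v) == min(v)) {
        rep(0.5, n)
      } else {
        rank(v, ties.method = "average") / (n + 1)
      }
    }
  }
  rows
}

#' Pooled PCA and per-colony developmental trajectories
#'
#' Centred PCA on the pooled quantile-transformed metrics (complete cases);
#' the sign convention makes the PC1 loading of m5 (out-degree) positive.
#' Scores are averaged per colony, age and day (cohort-day means), then per
#' age.
#'
#' @param rows quantile-transformed syndrome rows.
#' @return list: `loadings` (6 x 2), `explained` (variance fractions),
#'   `scores` (per-row PC1/PC2 with colony/age/day),
#'   `age_path` (per colony and age: mean PC1, PC2).
#' @export
pca_development <- function(rows) {
  M <- as.matrix(rows[, SYNDROME_METRICS])
  cc <- stats::complete.cases(M)
  if (sum(cc) < 10) stop("too few complete syndrome rows")
  pr <- stats::prcomp(M[cc, , drop = FALSE], center = TRUE, scale. = FALSE)
  if (qr(M[cc, , drop = FALSE])$rank < 2) stop("rank-deficient metrics")
  sgn <- if (pr$rotation["m5", 1] < 0) -1 else 1
  pc <- pr$x[, 1:2] %*% diag(c(sgn, 1))
  scores <- data.frame(colony = rows$colony[cc], age = rows$age[cc],
                       day = rows$day[cc], pc1 = pc[, 1], pc2 = pc[, 2],
                       stringsAsFactors = FALSE)
  cohort_day <- stats::aggregate(cbind(pc1, pc2) ~ colony + age + day,
                                 scores, mean)
  age_path <- stats::aggregate(cbind(pc1, pc2) ~ colony + age,
                               cohort_day, mean)
  age_path <- age_path[order(age_path$colony, age_path$age), ]
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  list(loadings = pr$rotation[, 1:2] %*% diag(c(sgn, 1)),
       explained = ev[1:2], scores = scores, age_path = age_path)
}

#' Smooth an age path and locate its inflection point
#'
#' Savitzky-Golay smoothing of PC1(age) and PC2(age) followed by the
#' discrete-curvature maximum of the smoothed 2-D path (interior ages
#' only). A near-straight path yields a weak inflection (see
#' `attr(, "max_curvature")`).
#'
#' @param age_path data.frame `age, pc1, pc2` for one colony (contiguous
#'   ages).
#' @param window Savitzky-Golay window (odd).
#' @param order polynomial order.
#' @param weak_threshold curvature below which the inflection is flagged
#'   weak.
#' @return list: `smoothed` (age, pc1, pc2), `inflection_age`,
#'   `max_curvature`, `weak` flag; `inflection_age` NA when the path is too
#'   short.
#' @export
smooth_and_inflect <- function(age_path, window = 7, order = 3,
                               weak_threshold = 1e-3) {
  age_path <- age_path[order(age_path$age), , drop = FALSE]
  n <- nrow(age_path)
  if (n < 7) {
    return(list(smoothed = age_path, inflection_age = NA_real_,
                max_curvature = NA_real_, weak = TRUE))
  }
  w <- min(window, if (n %% 2 == 1) n else n - 1)
  if (w %% 2 == 0) w <- w - 1
  p <- min(order, w - 1)
  sx <- signal::sgolayfilt(age_path$pc1, p = p, n = w)
  sy <- signal::sgolayfilt(age_path$pc2, p = p, n = w)
  a <- age_path$age
  # central-difference curvature of the smoothed path
  d1x <- (sx[-(1:2)] - sx[1:(n - 2)]) / (a[-(1:2)] - a[1:(n - 2)])
  d1y <- (sy[-(1:2)] - sy[1:(n - 2)]) / (a[-(1:2)] - a[1:(n - 2)])
  h <- diff(a)
  d2x <- diff(diff(sx) / h) / h[-1] * 1 # uniform-grid second difference
  d2y <- diff(diff(sy) / h) / h[-1]
  kappa <- abs(d1x * d2y - d1y * d2x) /
    pmax((d1x^2 + d1y^2)^1.5, 1e-12)
  interior <- 2:(n - 1)
  imax <- which.max(kappa)
  list(smoothed = data.frame(age = a, pc1 = sx, pc2 = sy),
       inflection_age = a[interior[imax]],
       max_curvature = kappa[imax],
       weak = kappa[imax] < weak_threshold)
}

#' Per-colony developmental trajectories with inflection points
#'
#' @param rows quantile-transformed syndrome rows.
#' @param window,order smoothing parameters.
#' @return list: `pca` (from [pca_development()]), `per_colony` (named list
#'   of [smooth_and_inflect()] results), `inflections` data.frame
#'   (`colony, inflection_age`).
#' @export
development_trajectory <- function(rows, window = 7, order = 3) {
  pca <- pca_development(rows)
  cols <- unique(pca$age_path$colony)
  per <- lapply(cols, function(cl) {
    smooth_and_inflect(pca$age_path[pca$age_path$colony == cl,
                                    c("age", "pc1", "pc2")],
                       window, order)
  })
  names(per) <- cols
  list(pca = pca,
       per_colony = per,
       inflections = data.frame(
         colony = cols,
         inflection_age = vapply(per, `[[`, 0, "inflection_age")))
}
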