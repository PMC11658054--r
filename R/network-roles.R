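# Daily contact networks, soft (overlapping) community structure,
# task-group classification, bridging scores, pheromone relay networks and
# the age-cohort donation hierarchy.

#' Build the daily contact network
#'
#' Undirected graph weighted by the number of contacts between each pair.
#'
#' @param contacts contact table for one day.
#' @param ids optional node set (includes contact-free bees as isolates).
#' @return an igraph graph with edge attribute `weight`.
#' @export
build_contact_network <- function(contacts, ids = NULL) {
  if (is.null(ids)) ids <- sort(unique(c(contacts$i, contacts$j)))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(contacts)) {
    key <- paste(pmin(contacts$i, contacts$j),
                 pmax(contacts$i, contacts$j), sep = "\r")
    cnt <- table(key)
    parts <- strsplit(names(cnt), "\r", fixed = TRUE)
    el <- cbind(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2))
    g <- igraph::add_edges(g, t(el))
    igraph::E(g)$weight <- as.integer(cnt)
  }
  g
}

#' Soft community detection by symmetric non-negative factorisation
#'
#' Factorises the (normalised) weighted adjacency A ~ H H' with H >= 0 via
#' multiplicative updates, from `n_restarts` random initialisations keeping
#' the best Frobenius objective. Rows of H are renormalised to sum to one,
#' giving each bee a continuous affiliation score per community.
#'
#' @param g igraph graph from [build_contact_network()].
#' @param k number of communities.
#' @param n_restarts random restarts.
#' @param seed integer seed.
#' @param max_iter,tol update iterations / relative objective tolerance.
#' @return matrix (nodes x k) of affiliation scores, rows summing to 1
#'   (NA rows for isolated nodes); attribute `objective`.
#' @export
soft_communities <- function(g, k = 3, n_restarts = 10, seed = 1L,
                             max_iter = 500, tol = 1e-9) {
  n <- igraph::vcount(g)
  if (k > n) stop("k exceeds the number of nodes")
  comp <- igraph::components(g)
  if (max(comp$csize) < 0.9 * n) {
    warning("giant component below 90% of nodes")
  }
  A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  # symmetric degree normalisation keeps dense hubs from dominating the
  # factorisation
  dg <- rowSums(A)
  dinv <- ifelse(dg > 0, 1 / sqrt(dg), 0)
  A <- A * outer(dinv, dinv)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    H <- matrix(stats::runif(n * k, 0.1, 1), n, k) *
      sqrt(mean(A) / k + 1e-9)
    for (it in seq_len(max_iter)) {
      AH <- A %*% H
      HHtH <- H %*% crossprod(H)
      Hn <- H * (AH / pmax(HHtH, 1e-12))^0.5
      delta <- max(abs(Hn - H))
      H <- Hn
      if (delta < tol) break
    }
    obj <- sum((A - H %*% t(H))^2)
    if (is.null(best) || obj < best$obj) best <- list(H = H, obj = obj)
  }
  H <- best$H
  rs <- rowSums(H)
  scores <- H / ifelse(rs > 1e-12, rs, NA)
  rownames(scores) <- igraph::V(g)$name
  attr(scores, "objective") <- best$obj
  scores
}

#' Label soft communities as N_A, N_B and F
#'
#' The forager community F is the one whose members (by strongest
#' affiliation) have the highest mean age, ties broken by entrance-corner
#' occupancy; of the remaining two nurse communities, N_A is the one holding
#' more occupants of broodnest patch A.
#'
#' @param scores unlabelled score matrix from [soft_communities()].
#' @param ages data.frame `bee_id, age` (days).
#' @param occupancy data.frame `bee_id, patch` ("A"/"B": closest broodnest
#'   patch).
#' @param entrance_occ optional named numeric: per-bee entrance-corner
#'   occupancy used only to break exact age ties.
#' @return scores with columns reordered and named `N_A, N_B, F`.
#' @export
label_communities <- function(scores, ages, occupancy,
                              entrance_occ = NULL) {
  stopifnot(ncol(scores) == 3)
  member <- apply(scores, 1, which.max)
  ids <- rownames(scores)
  age <- ages$age[match(ids, ages$bee_id)]
  mean_age <- vapply(1:3, function(c0) {
    mean(age[member == c0], na.rm = TRUE)
  }, numeric(1))
  top <- which(mean_age == max(mean_age, na.rm = TRUE))
  if (length(top) > 1) {
    if (is.null(entrance_occ)) {
      stop("forager labelling ambiguous: identical mean ages, ",
           "supply entrance_occ")
    }
    eo <- vapply(top, function(c0) {
      mean(entrance_occ[ids[member == c0]], na.rm = TRUE)
    }, numeric(1))
    top <- top[which.max(eo)]
  }
  f <- top
  nurse <- setdiff(1:3, f)
  patch <- occupancy$patch[match(ids, occupancy$bee_id)]
  nA <- vapply(nurse, function(c0) sum(patch[member == c0] == "A",
                                       na.rm = TRUE), numeric(1))
  if (nA[1] == nA[2]) {
    # fall back on mean affiliation of patch-A bees
    affA <- vapply(nurse, function(c0) {
      mean(scores[patch == "A", c0], na.rm = TRUE)
    }, numeric(1))
    if (isTRUE(all.equal(affA[1], affA[2]))) {
      stop("nurse labelling ambiguous: patches equally represented")
    }
    nurse <- nurse[order(-affA)]
  } else {
    nurse <- nurse[order(-nA)]
  }
  out <- scores[, c(nurse, f), drop = FALSE]
  colnames(out) <- c("N_A", "N_B", "F")
  out
}

#' Nurse bridging score
#'
#' Normalised entropy of the two nurse affiliations after renormalising
#' them to sum to one: 1 when `N_A == N_B > 0` (the bee straddles both
#' broodnest communities), 0 when only one nurse affiliation is non-zero.
#'
#' @param n_a,n_b nurse community scores (>= 0).
#' @return H' in `[0, 1]`; NA when both scores are zero.
#' @export
bridging_score <- function(n_a, n_b) {
  if (any(c(n_a, n_b) < 0, na.rm = TRUE)) stop("negative scores")
  tot <- n_a + n_b
  p <- ifelse(tot > 0, n_a / tot, NA_real_)
  h <- function(x) ifelse(x <= 0 | x >= 1, 0, -x * log(x))
  out <- (h(p) + h(1 - p)) / log(2)
  out[is.na(p)] <- NA_real_
  out
}

#' Classify task groups from labelled scores
#'
#' @param scores labelled score matrix (columns `N_A, N_B, F`).
#' @return data.frame `bee_id, N_A, N_B, F, H_bridge, group` with group in
#'   nurse/forager/neither (thresholds at 2/3).
#' @export
classify_task_group <- function(scores) {
  na_ <- scores[, "N_A"]; nb_ <- scores[, "N_B"]; f <- scores[, "F"]
  grp <- ifelse(na_ + nb_ > 2 / 3, "nurse",
                ifelse(f > 2 / 3, "forager", "neither"))
  data.frame(bee_id = rownames(scores), N_A = na_, N_B = nb_, F = f,
             H_bridge = bridging_score(na_, nb_), group = grp,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the daily relay network from ensemble pair flows
#'
#' Directed edges weighted by the simulation-averaged pheromone flow
#' `Q[i -> j]` (pg/day); node out-degree counts receivers with positive
#' flow, in-degree donors, and `delta_k = k_out - k_in`.
#'
#' @param ens a `transmission_ensemble` (or its `pair_flows` data.frame).
#' @param ids optional node set to include.
#' @return a `relay_network`: list with `edges` (`i, j, Q_pg`) and `nodes`
#'   (`bee_id, k_out, k_in, delta_k, out_flow_pg, in_flow_pg`).
#' @export
build_relay_network <- function(ens, ids = NULL) {
  pf <- if (is.data.frame(ens)) ens else ens$pair_flows
  pf <- pf[pf$Q_pg > 0, , drop = FALSE]
  if (is.null(ids)) {
    ids <- if (!is.data.frame(ens)) ens$bees$bee_id else
      sort(unique(c(pf$donor, pf$receiver)))
  }
  k_out <- tapply(pf$receiver, factor(pf$donor, ids),
                  function(x) length(unique(x)))
  k_in <- tapply(pf$donor, factor(pf$receiver, ids),
                 function(x) length(unique(x)))
  of <- tapply(pf$Q_pg, factor(pf$donor, ids), sum)
  inf_ <- tapply(pf$Q_pg, factor(pf$receiver, ids), sum)
  z <- function(v) ifelse(is.na(v), 0, v)
  nodes <- data.frame(bee_id = ids, k_out = z(as.numeric(k_out)),
                      k_in = z(as.numeric(k_in)),
                      out_flow_pg = z(as.numeric(of)),
                      in_flow_pg = z(as.numeric(inf_)),
                      stringsAsFactors = FALSE)
  nodes$delta_k <- nodes$k_out - nodes$k_in
  out <- list(edges = data.frame(i = pf$donor, j = pf$receiver,
                                 Q_pg = pf$Q_pg, stringsAsFactors = FALSE),
              nodes = nodes)
  class(out) <- "relay_network"
  out
}

#' @export
print.relay_network <- function(x, ...) {
  cat("relay_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "directed edges, total flow", signif(sum(x$edges$Q_pg), 4), "pg\n")
  invisible(x)
}

#' Coarse-grain a relay network into age cohorts
#'
#' Sums flows between age cohorts and keeps, per ordered pair, the net flow
#' in its positive direction. Callows (age <= 2) pool into a "0-2" node by
#' default; the queen is excluded.
#'
#' @param relay a `relay_network`.
#' @param ages data.frame `bee_id, age` (workers only).
#' @param pool_callows pool ages 0-2?
#' @return a `cohort_flow_network`: `gross` matrix (cohort x cohort),
#'   `edges` data.frame (`a, b, net_pg` with net > 0).
#' @export
coarse_grain_by_age <- function(relay, ages, pool_callows = TRUE) {
  lab <- function(a) {
    if (pool_callows && a <= 2) "0-2" else as.character(a)
  }
  coh <- vapply(ages$age, lab, "")
  names(coh) <- ages$bee_id
  e <- relay$edges
  e <- e[e$i %in% names(coh) & e$j %in% names(coh), , drop = FALSE]
  ca <- coh[e$i]; cb <- coh[e$j]
  lv <- unique(coh[order(ages$age)])
  gross <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  if (nrow(e)) {
    agg <- tapply(e$Q_pg, list(factor(ca, lv), factor(cb, lv)), sum)
    agg[is.na(agg)] <- 0
    gross <- agg
  }
  net <- gross - t(gross)
  idx <- which(net > 0, arr.ind = TRUE)
  edges <- data.frame(a = lv[idx[, 1]], b = lv[idx[, 2]],
                      net_pg = net[idx], stringsAsFactors = FALSE)
  out <- list(gross = gross, edges = edges, cohorts = lv)
  class(out) <- "cohort_flow_network"
  out
}

#' Rank age cohorts by David's dominance score
#'
#' Dyadic donation proportions `P[a,b] = gross(a->b) / (gross(a->b) +
#' gross(b->a))` feed the standard David's score `DS = w + w2 - l - l2`;
#' cohorts are ranked by descending score, ties broken by total out-flow.
#'
#' @param cnet a `cohort_flow_network`.
#' @return data.frame `cohort, david_score, rank`.
#' @export
dominance_ranks <- function(cnet) {
  g <- cnet$gross
  nc <- nrow(g)
  if (nc < 2) stop("need at least 2 cohorts")
  tot <- g + t(g)
  P <- ifelse(tot > 0, g / tot, NA)
  w <- rowSums(P, na.rm = TRUE)
  l <- colSums(P, na.rm = TRUE)
  P0 <- ifelse(is.na(P), 0, P)
  w2 <- as.numeric(P0 %*% w)
  l2 <- as.numeric(t(P0) %*% l)
  ds <- w + w2 - l - l2
  out_flow <- rowSums(g)
  ord <- order(-ds, -out_flow)
  out <- data.frame(cohort = rownames(g), david_score = ds,
                    out_flow_pg = out_flow, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$rank <- match(seq_len(nc), ord)
  out[order(out$rank), ]
}
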