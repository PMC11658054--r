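# Contact networks, soft communities, bridging, relay networks, cohort
# flows and the donation hierarchy.

test_that("contact networks count encounters per pair", {
  ct <- data.frame(i = c("A", "A", "A", "B"), j = c("B", "B", "C", "C"),
                   t_start_s = 1:4, t_end_s = 2:5)
  g <- build_contact_network(ct)
  expect_equal(igraph::ecount(g), 3)
  w <- igraph::E(g)$weight
  names(w) <- apply(igraph::as_edgelist(g), 1, paste, collapse = "-")
  expect_equal(unname(w[["A-B"]]), 2)
  expect_equal(sum(w), nrow(ct)) # conservation of total contact count
  g0 <- build_contact_network(ct[0, ], ids = c("A", "B"))
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(igraph::vcount(g0), 2)
})

planted_graph <- function(sizes = c(8, 8, 8), w_in = 5, bridge = NULL) {
  ids <- paste0("N", seq_len(sum(sizes)))
  grp <- rep(seq_along(sizes), sizes)
  el <- list()
  for (g in seq_along(sizes)) {
    mem <- which(grp == g)
    pr <- utils::combn(mem, 2)
    el[[g]] <- data.frame(i = ids[pr[1, ]], j = ids[pr[2, ]],
                          t_start_s = 0, t_end_s = 1)
  }
  ct <- do.call(rbind, el)
  ct <- ct[rep(seq_len(nrow(ct)), w_in), ]
  if (!is.null(bridge)) ct <- rbind(ct, bridge)
  list(ct = ct, ids = ids, grp = grp)
}

test_that("soft communities recover planted disjoint cliques", {
  pg <- planted_graph()
  g <- build_contact_network(pg$ct)
  # disjoint planted cliques: the giant-component precondition warns
  expect_warning(sc <- soft_communities(g, k = 3, n_restarts = 6, seed = 1),
                 "giant component")
  expect_equal(unname(rowSums(sc)), rep(1, nrow(sc)), tolerance = 1e-9)
  # each node >= 0.95 in its own community, up to label permutation
  own <- vapply(seq_len(nrow(sc)), function(r) max(sc[r, ]), numeric(1))
  expect_true(all(own >= 0.95))
  lab <- apply(sc, 1, which.max)
  grp_at <- pg$grp[match(rownames(sc), pg$ids)]
  expect_equal(length(unique(paste(lab, grp_at))), 3)
  expect_error(soft_communities(g, k = 100), "exceeds")
})

test_that("a node wired equally to two cliques splits its affiliation", {
  bridge <- data.frame(i = "X", j = c(paste0("N", 1:4), paste0("N", 9:12)),
                       t_start_s = 0, t_end_s = 1)
  bridge <- bridge[rep(1:8, 5), ]
  pg <- planted_graph(bridge = bridge)
  g <- build_contact_network(pg$ct)
  sc <- suppressWarnings(soft_communities(g, k = 3, n_restarts = 6,
                                          seed = 2))
  xs <- sort(sc["X", ], decreasing = TRUE)
  expect_gt(xs[2], 0.3) # two communities share the bulk
  expect_lt(xs[1] - xs[2], 0.25)
  expect_lt(xs[3], 0.15)
})

test_that("community labelling follows age and broodnest occupancy", {
  pg <- planted_graph()
  g <- build_contact_network(pg$ct)
  sc <- suppressWarnings(soft_communities(g, k = 3, n_restarts = 6,
                                          seed = 1))
  ids <- rownames(sc)
  grp <- pg$grp[match(ids, pg$ids)]
  # community 3 is old (foragers); cliques 1/2 young, on patches A/B
  ages <- data.frame(bee_id = ids, age = ifelse(grp == 3, 15, 3))
  occ <- data.frame(bee_id = ids,
                    patch = c("A", "B", "A")[grp])
  lab <- label_communities(sc, ages, occ)
  expect_setequal(colnames(lab), c("N_A", "N_B", "F"))
  tg <- classify_task_group(lab)
  expect_true(all(tg$group[grp == 3] == "forager"))
  expect_true(all(tg$group[grp != 3] == "nurse"))
  # patch-A clique members sit in N_A
  expect_true(all(lab[grp == 1, "N_A"] > lab[grp == 1, "N_B"]))
  # swapping the patch labels swaps N_A and N_B only
  occ2 <- occ
  occ2$patch <- c("B", "A", "A")[grp]
  lab2 <- label_communities(sc, ages, occ2)
  expect_equal(unname(lab2[, "N_A"]), unname(lab[, "N_B"]))
  expect_equal(unname(lab2[, "F"]), unname(lab[, "F"]))
})

test_that("bridging score is the renormalised binary entropy", {
  expect_equal(bridging_score(1 / 3, 1 / 3), 1)
  expect_equal(bridging_score(1, 0), 0)
  # direct evaluation at p = 0.9
  p <- 0.9
  expect_equal(bridging_score(0.9, 0.1),
               -(p * log(p) + (1 - p) * log(1 - p)) / log(2))
  expect_equal(round(bridging_score(0.9, 0.1), 4), 0.469)
  expect_true(is.na(bridging_score(0, 0)))
  expect_error(bridging_score(-0.1, 0.5), "negative")
  # vectorised and symmetric
  expect_equal(bridging_score(c(0.2, 0.4), c(0.4, 0.2)),
               bridging_score(c(0.4, 0.2), c(0.2, 0.4)))
})

test_that("relay networks follow the ensemble flow formula", {
  pf <- data.frame(donor = c("Q", "A", "A"), receiver = c("A", "B", "C"),
                   Q_pg = c(10, 2, 0))
  rn <- build_relay_network(pf, ids = c("Q", "A", "B", "C"))
  # zero-flow pairs create no edge
  expect_equal(nrow(rn$edges), 2)
  nd <- rn$nodes
  expect_equal(nd$k_out[nd$bee_id == "A"], 1)
  expect_equal(nd$k_in[nd$bee_id == "A"], 1)
  expect_equal(nd$delta_k[nd$bee_id == "A"], 0)
  expect_equal(nd$delta_k[nd$bee_id == "B"], -1)
  expect_equal(nd$k_out[nd$bee_id == "B"], 0)
  # flow totals reconcile with engine event sums (ensemble-level identity)
  sim <- small_colony()
  ct <- small_contacts()[1:300, ]
  p <- transmission_params(n_sims = 4)
  ens <- run_ensemble(ct, sim$bees, p, seed = 6,
                      grid_times = c(0, 100))
  seeds <- queenrelay:::derive_seeds(6, 4)
  tot <- sum(vapply(seeds, function(s) {
    sum(run_transmission(ct, sim$bees, p, seed = s,
                         t0 = min(ct$t_start_s))$events$removed_pg)
  }, numeric(1)))
  expect_equal(sum(ens$pair_flows$Q_pg), tot / 4, tolerance = 1e-9)
})

test_that("age coarse-graining nets out opposing flows", {
  edges <- data.frame(i = c("a1", "a2", "b1", "b1", "c1"),
                      j = c("b1", "b2", "a1", "c1", "a1"),
                      Q_pg = c(5, 3, 2, 4, 1))
  relay <- list(edges = edges)
  ages <- data.frame(bee_id = c("a1", "a2", "b1", "b2", "c1"),
                     age = c(1, 2, 5, 5, 9))
  cn <- coarse_grain_by_age(relay, ages)
  # callows pooled: cohorts 0-2, 5, 9
  expect_setequal(cn$cohorts, c("0-2", "5", "9"))
  # hand sums: gross(0-2 -> 5) = 8, gross(5 -> 0-2) = 2 -> net 6
  e <- cn$edges
  expect_equal(e$net_pg[e$a == "0-2" & e$b == "5"], 6)
  expect_equal(e$net_pg[e$a == "5" & e$b == "9"], 4)
  expect_equal(e$net_pg[e$a == "9" & e$b == "0-2"], 1)
  # antisymmetry: no reciprocal edges survive
  expect_equal(anyDuplicated(t(apply(e[, 1:2], 1, sort))), 0)
  # equal opposing flows cancel to no edge
  edges2 <- data.frame(i = c("a1", "b1"), j = c("b1", "a1"),
                       Q_pg = c(3, 3))
  cn2 <- coarse_grain_by_age(list(edges = edges2), ages)
  expect_equal(nrow(cn2$edges), 0)
})

test_that("David's scores rank a transitive donation chain correctly", {
  # perfect linear chain a -> b -> c
  gross <- matrix(c(0, 5, 0,
                    0, 0, 5,
                    0, 0, 0), 3, 3, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  r <- dominance_ranks(list(gross = gross, cohorts = c("a", "b", "c")))
  expect_equal(r$cohort[order(r$rank)], c("a", "b", "c"))
  # hand-computed David's scores: P(a>b) = P(b>c) = 1
  # w = (1, 1, 0); w2 = (1, 0, 0); l = (0, 1, 1); l2 = (0, 0, 1)
  expect_equal(r$david_score[r$cohort == "a"], 2)
  expect_equal(r$david_score[r$cohort == "b"], 0)
  expect_equal(r$david_score[r$cohort == "c"], -2)
  # symmetric flows: all scores equal
  gs <- matrix(2, 3, 3, dimnames = dimnames(gross))
  diag(gs) <- 0
  rs <- dominance_ranks(list(gross = gs, cohorts = c("a", "b", "c")))
  expect_true(all(abs(rs$david_score) < 1e-12))
  expect_error(dominance_ranks(list(gross = gross[1, 1, drop = FALSE])),
               "at least 2")
})

test_that("planted colony communities match ground truth end to end", {
  sim <- medium_colony()
  ct <- medium_contacts()
  ww <- ct[ct$i != "Q" & ct$j != "Q", ]
  g <- build_contact_network(ww)
  sc <- suppressWarnings(soft_communities(g, k = 3, n_restarts = 8,
                                          seed = 4))
  gt <- sim$ground_truth$workers
  ids <- rownames(sc)[!is.na(rowSums(sc))]
  # occupancy from mean position: nearest broodnest patch
  occ <- do.call(rbind, lapply(ids, function(b) {
    tb <- sim$traj[sim$traj$bee_id == b, ]
    data.frame(bee_id = b,
               patch = ifelse(mean(tb$side) < 0.5, "A", "B"))
  }))
  ages <- data.frame(bee_id = gt$bee_id, age = gt$age)
  # entrance-corner occupancy for tie-breaking
  ent <- vapply(ids, function(b) {
    tb <- sim$traj[sim$traj$bee_id == b, ]
    mean(tb$side == 0 & sqrt((tb$x - 64)^2 + tb$y^2) < 15)
  }, numeric(1))
  lab <- label_communities(sc[ids, ], ages, occ, entrance_occ = ent)
  tg <- classify_task_group(lab)
  m <- merge(tg, gt, by = "bee_id")
  # most ground-truth foragers classified forager; nurses nurse
  f_ok <- mean(m$group[m$community == "F"] == "forager")
  n_ok <- mean(m$group[m$community != "F"] == "nurse")
  expect_gt(f_ok, 0.7)
  expect_gt(n_ok, 0.7)
})
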