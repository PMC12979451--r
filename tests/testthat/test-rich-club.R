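test_that("rich-club coefficient handles canonical small graphs", {
  k5 <- complete_graph(5)
  for (k in 0:4) expect_equal(rich_club_coefficient(k5, k), 1)
  # path of 5 at k = 2: the 3 interior nodes survive with 2 edges among them
  expect_equal(rich_club_coefficient(path_graph(5), 2), 2 / 3)
  # star at k = 2: only the centre survives -> undefined
  expect_true(is.na(rich_club_coefficient(star_graph(5), 2)))
})

test_that("survivor-rule variants differ as documented", {
  p5 <- path_graph(5)
  # ge keeps degree >= 2 (3 interior nodes); gt keeps degree > 2 (none)
  expect_equal(rich_club_coefficient(p5, 2, rule = "ge"), 2 / 3)
  expect_true(is.na(rich_club_coefficient(p5, 2, rule = "gt")))
})

test_that("curve spans min to max degree and starts at global density", {
  k6 <- complete_graph(6)
  curve <- rich_club_curve(k6)
  expect_equal(curve$k, 5L)
  expect_equal(curve$phi, 1)

  g <- rand_graph(30, 0.3, seed = 7)
  curve <- rich_club_curve(g)
  deg <- node_degree(g)
  expect_equal(curve$k[1], min(deg[deg > 0]))
  expect_equal(curve$k[nrow(curve)], max(deg))
  n <- nrow(g); e <- sum(g) / 2
  expect_equal(curve$phi[1], 2 * e / (n * (n - 1)))
  expect_error(rich_club_curve(matrix(0, 4, 4)), "no edges")
})

test_that("curve agrees with the brute-force oracle on random graphs", {
  for (seed in 1:25) {
    n <- sample(5:30, 1)
    g <- rand_graph(n, runif(1, 0.1, 0.7), seed = seed * 13)
    if (sum(g) == 0) next
    for (rule in c("ge", "gt")) {
      curve <- rich_club_curve(g, rule = rule)
      oracle <- vapply(curve$k, function(k) phi_oracle(g, k, rule), numeric(1))
      expect_equal(curve$phi, oracle, info = sprintf("seed %d rule %s", seed, rule))
    }
  }
})

test_that("rewiring conserves the degree sequence and stays simple", {
  g <- rand_graph(40, 0.2, seed = 2)
  for (seed in 1:20) {
    r <- rewire_degree_preserving(g, 10, seed = seed)
    expect_equal(node_degree(r), node_degree(g))
    expect_equal(sum(r), sum(g))
    expect_equal(r, t(r))
    expect_true(all(diag(r) == 0))
    expect_true(all(r %in% c(0, 1)))
  }
  # deterministic given seed
  expect_identical(rewire_degree_preserving(g, 10, seed = 99),
                   rewire_degree_preserving(g, 10, seed = 99))
  # complete graph admits no successful swap
  expect_equal(rewire_degree_preserving(complete_graph(6), 10, seed = 1),
               complete_graph(6))
  # rewiring actually moves edges on sparse graphs
  jacc <- vapply(1:30, function(s) {
    r <- rewire_degree_preserving(g, 10, seed = s)
    both <- sum(g * r) / 2
    both / (sum(g) - both)
  }, numeric(1))
  expect_gte(sum(jacc < 1), 29)
})

test_that("tiny networks are returned unchanged with a warning", {
  one_edge <- matrix(0, 3, 3); one_edge[1, 2] <- one_edge[2, 1] <- 1
  dimnames(one_edge) <- list(letters[1:3], letters[1:3])
  expect_warning(out <- rewire_degree_preserving(one_edge, 10, seed = 1), "fewer than 2")
  expect_equal(out, one_edge)
})

test_that("a network normalized against unswapped copies of itself gives ratio 1", {
  g <- rand_graph(25, 0.3, seed = 4)
  prof <- normalized_rich_club(g, n_random = 5, n_swap_per_edge = 0, seed = 1)
  defined <- !is.na(prof$phi_norm)
  expect_true(any(defined))
  expect_equal(prof$phi_norm[defined], rep(1, sum(defined)))
})

test_that("random graphs have normalized coefficient near 1", {
  g <- rand_graph(40, 0.3, seed = 9)
  prof <- normalized_rich_club(g, n_random = 100, seed = 3)
  mid <- prof$k <= stats::quantile(prof$k, 0.6)
  dev <- abs(prof$phi_norm[mid & !is.na(prof$phi_norm)] - 1)
  expect_lt(mean(dev), 0.1)
})

test_that("planted rich-club topologies show ratio above 1 at high k", {
  for (seed in c(2, 5, 8)) {
    top <- simulate_richclub_topology(90, 0.12, 0.15, 0.5, seed = seed)
    prof <- normalized_rich_club(top, n_random = 60, seed = seed + 100)
    top_k <- prof$k >= stats::quantile(prof$k, 0.75)
    vals <- prof$phi_norm[top_k & !is.na(prof$phi_norm)]
    expect_gt(mean(vals), 1.05)
  }
})

test_that("hub identification takes the top-degree fraction deterministically", {
  top <- simulate_richclub_topology(90, 0.12, 0.15, 0.5, seed = 1)
  hubs <- suppressMessages(identify_rich_club_nodes(top, 0.12))
  expect_length(hubs, 11)
  deg <- node_degree(top)
  expect_true(min(deg[hubs]) >= max(deg[setdiff(names(deg), hubs)]) - 0)

  s <- star_graph(6)
  expect_equal(identify_rich_club_nodes(s, 0.2), "A")

  # regular graph: pure tie, resolved by label order
  ring <- matrix(0, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; ring[i, j] <- ring[j, i] <- 1 }
  dimnames(ring) <- list(LETTERS[1:6], LETTERS[1:6])
  expect_message(h <- identify_rich_club_nodes(ring, 0.34), "tie")
  expect_equal(h, c("A", "B"))
})

test_that("hub identification is invariant to node permutation up to the tie-break", {
  top <- simulate_richclub_topology(60, 0.15, 0.2, 0.5, seed = 6)
  perm <- withr::with_seed(1, sample(nrow(top)))
  shuffled <- top[perm, perm]
  h1 <- suppressMessages(identify_rich_club_nodes(top, 0.15))
  h2 <- suppressMessages(identify_rich_club_nodes(shuffled, 0.15))
  deg <- node_degree(top)
  cut <- sort(deg, decreasing = TRUE)[length(h1)]
  # above the cut degree membership must agree exactly
  expect_setequal(h1[deg[h1] > cut], h2[deg[h2] > cut])
})

test_that("edge classification is exhaustive and exclusive", {
  tri <- complete_graph(3) * c(0, 4, 5, 4, 0, 6, 5, 6, 0)
  edges <- classify_edges(tri, hubs = "A")
  expect_equal(sort(as.character(edges$class)), c("feeder", "feeder", "local"))

  g <- rand_weighted(12, 0.4, 9, seed = 3)
  all_local <- classify_edges(g, hubs = character(0))
  expect_true(all(all_local$class == "local"))
  all_rich <- classify_edges(g, hubs = rownames(g))
  expect_true(all(all_rich$class == "rich"))
  expect_equal(nrow(all_rich), sum(g > 0) / 2)
  expect_error(classify_edges(g, hubs = "nope"), "unknown hub")
})

test_that("class metrics decompose whole-network strength exactly", {
  tri <- complete_graph(3) * c(0, 4, 5, 4, 0, 6, 5, 6, 0)
  cm <- class_metrics(tri, hubs = "A")
  expect_equal(cm$strength_rich, 0)
  expect_equal(cm$strength_feeder, 9)
  expect_equal(cm$strength_local, 6)
  expect_equal(cm$density_feeder, 0.6)
  expect_equal(cm$density_local, 0.4)

  for (seed in 1:10) {
    g <- rand_weighted(20, 0.3, 50, seed)
    hubs <- rownames(g)[1:4]
    cm <- class_metrics(g, hubs)
    expect_equal(cm$strength_rich + cm$strength_feeder + cm$strength_local,
                 sum(g) / 2)
    if (cm$strength_total > 0) {
      expect_equal(cm$density_rich + cm$density_feeder + cm$density_local, 1)
    }
    # scale invariance of densities
    cm3 <- class_metrics(g * 3, hubs)
    expect_equal(cm3$strength_total, 3 * cm$strength_total)
    expect_equal(cm3$density_feeder, cm$density_feeder)
  }

  empty <- matrix(0, 4, 4)
  cm0 <- class_metrics(empty, hubs = character(0))
  expect_true(is.na(cm0$density_rich))
  expect_equal(cm0$strength_total, 0)
})
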