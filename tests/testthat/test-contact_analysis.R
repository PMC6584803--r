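test_that("minimum residue distance matches the closed form and is symmetric", {
  A <- matrix(c(0, 0, 0), ncol = 3)
  B <- rbind(c(0, 0, 1.5), c(0, 0, 4))
  expect_equal(min_residue_distance(A, B), 1.5)
  set.seed(11)
  for (i in 1:10) {
    X <- random_residue(10, c(0, 0, 0))
    Y <- random_residue(10, c(4, 1, -2))
    expect_equal(min_residue_distance(X, Y), min_residue_distance(Y, X))
  }
  expect_error(min_residue_distance(A, matrix(numeric(0), ncol = 3)), "empty")
})

test_that("cell-list distances equal the exhaustive brute-force oracle", {
  set.seed(21)
  for (i in 1:50) {
    n1 <- sample(3:25, 1); n2 <- sample(3:25, 1)
    X <- random_residue(n1, stats::runif(3, -20, 20), spread = stats::runif(1, 0.5, 6))
    Y <- random_residue(n2, stats::runif(3, -20, 20), spread = stats::runif(1, 0.5, 6))
    expect_equal(min_residue_distance(X, Y, method = "cell"), brute_min_dist(X, Y))
    expect_equal(min_residue_distance(X, Y, method = "exhaustive"), brute_min_dist(X, Y))
  }
})

test_that("contact uses a strict inequality at the threshold", {
  atoms <- data.frame(name = c("C1", "C1"), element = "C",
                      chain = c("A", "B"), resno = 1L, icode = "", resid = "GLY")
  topo <- cx_topology(atoms)
  topo <- assign_entities(topo, list(entities = c(A = "P1", B = "AB1-HC"),
                                     regions = NULL))
  pairs <- data.frame(entity_a = "P1", resno_a = 1L, entity_b = "AB1-HC", resno_b = 1L)
  mk_traj <- function(d, n = 100) {
    row <- c(0, 0, 0, 0, 0, d)
    cx_trajectory(matrix(row, n, 6, byrow = TRUE), seq_len(n) * 0.01)
  }
  # exactly at the 2 A threshold: never a contact
  s_at <- pair_contact_series(mk_traj(2.0), topo, pairs, threshold = 2.0)
  expect_false(any(s_at$indicator))
  # comfortably below: always a contact
  s_in <- pair_contact_series(mk_traj(1.8), topo, pairs, threshold = 2.0)
  expect_true(all(s_in$indicator))
  expect_equal(interaction_probability(s_in)$pair_probability$probability, 100)
  expect_equal(interaction_probability(s_at)$pair_probability$probability, 0)
})

test_that("probabilities are monotone in the threshold", {
  cx <- toy_hexamer()
  sch <- contact_schedule(cx, fractions = c(0.3, 0.6, 0.9, 0.1, 0.5, 0.7, 0.2, 0.8))
  tr <- simulate_contact_trajectory(cx, sch, n_frames = 150, seed = 5)
  counts <- sapply(c(3.5, 2.0, 1.5), function(th)
    sum(pair_contact_series(tr, cx$topology, sch, threshold = th)$indicator))
  expect_true(all(diff(counts) <= 0))
})

test_that("interaction probability equals an independent frame recount", {
  cx <- toy_hexamer()
  sch <- contact_schedule(cx, fractions = c(0, 0.25, 0.5, 0.75, 1, 0.1, 0.9, 0.33))
  tr <- simulate_contact_trajectory(cx, sch, n_frames = 120, seed = 9)
  cs <- pair_contact_series(tr, cx$topology, sch)
  got <- interaction_probability(cs)$pair_probability$probability
  expect_equal(got, recount_probability(tr, cx$topology, sch, 2.0))
  # and matches the generator's own indicator truth exactly
  expect_equal(got, 100 * rowMeans(attr(tr, "indicator_truth")))
})

test_that("a Bernoulli-scheduled pair is estimated within three binomial standard errors", {
  cx <- toy_small()
  pairs1 <- cx$designated_pairs[1, c("entity_a", "resno_a", "entity_b", "resno_b")]
  sch <- contact_schedule(cx, fractions = 0.82, pairs = pairs1)
  tr <- simulate_contact_trajectory(cx, sch, n_frames = 5000, seed = 1)
  est <- interaction_probability(pair_contact_series(tr, cx$topology, sch))
  se3 <- 300 * sqrt(0.82 * 0.18 / 5000)
  expect_lt(abs(est$pair_probability$probability - 82), se3)
})

test_that("scheduled contact fractions are recovered within 3 SE in at least 99% of seeded replicates", {
  cx <- toy_small()
  pairs1 <- cx$designated_pairs[1, c("entity_a", "resno_a", "entity_b", "resno_b")]
  seeds <- 1:100
  for (p in c(0.05, 0.5, 0.82, 0.98)) {
    sch <- contact_schedule(cx, fractions = p, pairs = pairs1)
    ok <- vapply(seeds, function(s) {
      tr <- simulate_contact_trajectory(cx, sch, n_frames = 5000, seed = s)
      est <- interaction_probability(pair_contact_series(tr, cx$topology, sch))
      abs(est$pair_probability$probability / 100 - p) <= 3 * sqrt(p * (1 - p) / 5000)
    }, logical(1))
    expect_gte(mean(ok), 0.99)
  }
})

test_that("residue-level aggregation is the frame-wise union of pair indicators", {
  pairs <- data.frame(entity_a = c("P1", "P1"), resno_a = c(54L, 54L),
                      entity_b = c("AB1-HC", "AB1-HC"), resno_b = c(30L, 31L))
  ind <- matrix(FALSE, 2, 10)
  ind[1, 1:3] <- TRUE   # 30% of frames
  ind[2, 4:5] <- TRUE   # a disjoint 20%
  cs <- series_from_indicator(pairs, ind)
  agg <- aggregate_residue_level(cs, "P1")
  expect_equal(agg$probability[agg$resno == 54], 50)  # union of disjoint sets
  # a residue with a single pair equals its pair value
  agg_b <- aggregate_residue_level(cs, "AB1-HC")
  expect_equal(sort(agg_b$probability), c(20, 30))
  # union dominates every member pair, randomized
  set.seed(33)
  for (i in 1:20) {
    ind_r <- matrix(stats::runif(30) < 0.4, 3, 10)
    pr <- data.frame(entity_a = "P2", resno_a = 55L,
                     entity_b = "AB1-HC", resno_b = c(28L, 29L, 30L))
    cs_r <- series_from_indicator(pr, ind_r)
    u <- aggregate_residue_level(cs_r, "P2")$probability
    expect_true(all(u >= 100 * rowMeans(ind_r)))
  }
  expect_error(aggregate_residue_level(cs, "P9"), "absent")
})

test_that("residue-level values in the contact table dominate their pair values", {
  cx <- toy_hexamer()
  sch <- contact_schedule(cx, fractions = c(0.3, 0.6, 0.9, 0.1, 0.5, 0.7, 0.2, 0.8))
  tr <- simulate_contact_trajectory(cx, sch, n_frames = 100, seed = 13)
  tab <- interaction_probability(pair_contact_series(tr, cx$topology, sch))
  for (i in seq_len(nrow(tab$pair_probability))) {
    pp <- tab$pair_probability[i, ]
    rp <- tab$residue_probability
    rv <- rp$probability[rp$entity == pp$entity_a & rp$resno == pp$resno_a & rp$partner == "any"]
    expect_gte(rv, pp$probability)
  }
})

test_that("grid candidate-pair enumeration matches the exhaustive search", {
  cx <- toy_hexamer()
  prots <- paste0("P", 1:6)
  abs1 <- c("AB1-HC", "AB1-LC")
  got <- candidate_pairs(cx$topology, cx$coords, prots, abs1, cutoff = 7)
  # exhaustive oracle over all residue pairs
  rt <- residue_table(cx$topology)
  rt$entity <- cx$topology$entity_map[rt$chain]
  ra <- rt[rt$entity %in% prots, ]
  rb <- rt[rt$entity %in% abs1, ]
  want <- 0L
  for (i in seq_len(nrow(ra))) {
    ia <- connexitope:::residue_atom_idx(cx$topology, ra$entity[i], ra$resno[i])
    for (j in seq_len(nrow(rb))) {
      ib <- connexitope:::residue_atom_idx(cx$topology, rb$entity[j], rb$resno[j])
      if (brute_min_dist(cx$coords[ia, , drop = FALSE],
                         cx$coords[ib, , drop = FALSE]) < 7) want <- want + 1L
    }
  }
  expect_equal(nrow(got), want)
})
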