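test_that("the toy complex realizes its contact map under brute-force geometry", {
  cx <- toy_hexamer()
  prots <- paste0("P", 1:6)
  for (ab in c("AB1", "AB2")) {
    chains <- paste0(ab, c("-HC", "-LC"))
    cp <- candidate_pairs(cx$topology, cx$coords, prots, chains, cutoff = 2)
    expect_setequal(unique(cp$entity_a), cx$contact_truth[[ab]])
  }
  # custom map and small ring
  cx3 <- build_toy_complex(n_protomers = 3, contact_map = list(AB1 = c("P1", "P3")))
  cp <- candidate_pairs(cx3$topology, cx3$coords, paste0("P", 1:3),
                        c("AB1-HC", "AB1-LC"), cutoff = 2)
  expect_setequal(unique(cp$entity_a), c("P1", "P3"))
})

test_that("generator edge cases: no antibodies, bad maps, invalid schedules", {
  cx0 <- build_toy_complex(n_antibodies = 0)
  expect_equal(length(unique(cx0$topology$atoms$chain)), 6L)
  expect_null(cx0$designated_pairs)
  expect_error(build_toy_complex(contact_map = list(AB1 = "P9")), "absent protomer")
  cx <- toy_hexamer()
  expect_error(contact_schedule(cx, fractions = 1.2), "\\[0, 1\\]")
  dup <- cx$designated_pairs[c(1, 1), c("entity_a", "resno_a", "entity_b", "resno_b")]
  expect_error(contact_schedule(cx, fractions = 0.5, pairs = dup), "only one")
  sch <- contact_schedule(cx, fractions = 0.5)
  expect_error(simulate_contact_trajectory(cx, sch, n_frames = 0), "n_frames")
})

test_that("trajectory generation is bit-exact under the same seed", {
  cx <- toy_small()
  sch <- contact_schedule(cx, fractions = c(0.3))
  t1 <- simulate_contact_trajectory(cx, sch, n_frames = 50, seed = 99)
  t2 <- simulate_contact_trajectory(cx, sch, n_frames = 50, seed = 99)
  expect_identical(t1$xyz, t2$xyz)
  t3 <- simulate_contact_trajectory(cx, sch, n_frames = 50, seed = 100)
  expect_false(identical(t3$xyz, t2$xyz))
  # degenerate fractions are exact
  for (p in c(0, 1)) {
    schp <- contact_schedule(cx, fractions = p)
    trp <- simulate_contact_trajectory(cx, schp, n_frames = 30, seed = 1)
    est <- interaction_probability(pair_contact_series(trp, cx$topology, schp))
    expect_equal(est$pair_probability$probability, rep(100 * p, nrow(schp)))
  }
})

test_that("the Markov temporal model is unbiased with inflated variance versus Bernoulli", {
  cx <- toy_small()
  pairs1 <- cx$designated_pairs[1, c("entity_a", "resno_a", "entity_b", "resno_b")]
  p <- 0.5; nf <- 2000
  est <- function(model, seed) {
    sch <- contact_schedule(cx, fractions = p, pairs = pairs1,
                            model = model, dwell = 50)
    tr <- simulate_contact_trajectory(cx, sch, n_frames = nf, seed = seed)
    mean(attr(tr, "indicator_truth")[1, ])
  }
  seeds <- 1:40
  bern <- vapply(seeds, function(s) est("bernoulli", s), numeric(1))
  mark <- vapply(seeds, function(s) est("two_state_markov", s), numeric(1))
  # unbiasedness: both sample means near p (tolerance ~4 SD of the mean)
  expect_lt(abs(mean(bern) - p), 4 * sqrt(p * (1 - p) / nf / length(seeds)))
  expect_lt(abs(mean(mark) - p), 4 * sd(mark) / sqrt(length(seeds)))
  # bursty contacts carry far fewer effective samples per frame
  expect_gt(var(mark), 3 * var(bern))
})

test_that("labelled pose sets honour their requested composition", {
  expect_error(generate_pose_set(n = 5, n_correct = 6), "n_correct")
  all_ok <- generate_pose_set(n = 6, n_correct = 6, seed = 1)
  expect_true(all(vapply(all_ok, `[[`, TRUE, "oriented_correct")))
  none <- generate_pose_set(n = 6, n_correct = 0, seed = 1)
  expect_false(any(vapply(none, `[[`, TRUE, "oriented_correct")))
  # labels agree with the geometric filter on every pose
  mix <- generate_pose_set(n = 10, n_correct = 3, seed = 12)
  v <- filter_poses(mix)
  expect_identical(v$retained, vapply(mix, `[[`, TRUE, "oriented_correct"))
})

test_that("bundled reference tables match their transcription", {
  motifs <- cx_motif_table()
  expect_equal(nrow(motifs), 20L)
  expect_equal(motifs$ec1_54_58[motifs$protein == "hCx26"], "NTLQP")
  expect_equal(motifs$ec2_175_176[motifs$protein == "hCx26"], "PN")
  ch <- cx_channel_contact_table()
  expect_equal(nrow(ch), 31L)
  expect_equal(ch$probability_pct[ch$protomer == "P2" & ch$resno == 56], 100)
  expect_equal(ch$probability_pct[ch$protomer == "P1" & ch$resno == 54], 82)
  ab <- cx_antibody_contact_table()
  expect_equal(nrow(ab), 27L)
  expect_equal(ab$probability_pct[ab$chain == "LC" & ab$resno == 182], 98)
  cond <- cx_conductance_table()
  expect_equal(nrow(cond), 10L)
  expect_equal(cond$residual_pct[cond$isoform == "hCx26"], 16.8)
  expect_equal(cond$residual_pct[cond$isoform == "hCx45"], 98)
})

test_that("current-trace generation is seed-deterministic and parameterized correctly", {
  a <- simulate_current_traces(10, 0.3, seed = 5)
  b <- simulate_current_traces(10, 0.3, seed = 5)
  expect_identical(a$pre$current, b$pre$current)
  expect_identical(a$post$current, b$post$current)
  expect_error(simulate_current_traces(-1, 0.5), "non-negative")
  # residual 1.0 with no noise: statistically identical traces
  same <- simulate_current_traces(10, 1, noise_sd = 0, seed = 1)
  expect_equal(same$pre$current, same$post$current)
})

test_that("run configs validate and manifests embed a config hash", {
  cfg <- read_run_config()
  expect_equal(cfg$contact_threshold, 2.0)
  expect_equal(cfg$epitope_cutoff, 55)
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(epitope_cutoff = 150), f)
  expect_error(read_run_config(f), "epitope_cutoff")
  yaml::write_yaml(list(contact_threshold = 3.5), f)
  cfg2 <- read_run_config(f)
  expect_equal(cfg2$contact_threshold, 3.5)
  mf <- tempfile(fileext = ".yaml")
  m1 <- write_run_manifest(cfg, mf)
  m2 <- write_run_manifest(cfg2, tempfile(fileext = ".yaml"))
  expect_true(nzchar(m1$config_hash))
  expect_false(identical(m1$config_hash, m2$config_hash))
  expect_true(file.exists(mf))
})
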