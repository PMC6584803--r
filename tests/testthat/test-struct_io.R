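test_that("a minimal single-chain PDB parses into one residue of three atoms", {
  p <- write_tiny_pdb(tempfile(fileext = ".pdb"))
  st <- read_structure(p)
  expect_equal(st$topology$natoms, 3L)
  expect_equal(nrow(residue_table(st$topology)), 1L)
  expect_equal(residue_table(st$topology)$n_atoms, 3L)
  expect_equal(st$coords[2, 1], 1.458)
})

test_that("insertion codes at the same sequence number give distinct residues", {
  p <- write_icode_pdb(tempfile(fileext = ".pdb"))
  st <- read_structure(p)
  rt <- residue_table(st$topology)
  expect_equal(nrow(rt), 3L)
  expect_setequal(rt$icode, c("", "A", "B"))
  expect_true(all(rt$resno == 10L))
})

test_that("missing files and malformed records raise informative errors", {
  expect_error(read_structure(tempfile()), "no such file")
  bad <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1       0.000   0.000   0.000",
               "ATOM      2  CA"), bad)
  expect_error(read_structure(bad), "line 2")
  bad2 <- tempfile(fileext = ".pdb")
  writeLines("ATOM      1  CA  ALA A   1       0.000   x.000   0.000  1.00", bad2)
  expect_error(read_structure(bad2), "line 1")
})

test_that("the synthetic hexamer round-trips through PDB with keys and coordinates intact", {
  cx <- toy_hexamer()
  expect_equal(length(unique(cx$topology$atoms$chain)), 10L)  # 6 protomers + 4 antibody chains
  f <- tempfile(fileext = ".pdb")
  write_structure(cx$topology, cx$coords, f)
  rd <- read_structure(f)
  expect_identical(rd$topology$atoms$key, cx$topology$atoms$key)
  expect_equal(rd$coords, cx$coords, tolerance = 1e-3)
})

test_that("multi-model PDB trajectories read back with stride-derived times", {
  cx <- toy_small()
  sch <- contact_schedule(cx, fractions = 0.5)
  tr <- simulate_contact_trajectory(cx, sch, n_frames = 5, seed = 1, stride = 2)
  f <- tempfile(fileext = ".pdb")
  write_structure(cx$topology, tr, f)
  tr2 <- read_trajectory(f, cx$topology, stride = 2)
  expect_equal(tr2$n_frames, 5L)
  expect_equal(tr2$times, c(0, 2, 4, 6, 8))
  expect_equal(tr2$xyz, tr$xyz, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("time windows keep the closed interval, error when empty, and are idempotent", {
  cx <- toy_small()
  sch <- contact_schedule(cx, fractions = 1)
  tr <- simulate_contact_trajectory(cx, sch, n_frames = 15, seed = 1, stride = 10)
  expect_equal(tr$times, seq(0, 140, by = 10))
  # last 10 ns of a 150 ns run
  w <- window_trajectory(tr, c(140, 150))
  expect_true(all(w$times >= 140))
  expect_equal(w$n_frames, 1L)
  # no window keeps everything
  f <- tempfile(fileext = ".pdb")
  write_structure(cx$topology, tr, f)
  expect_equal(read_trajectory(f, cx$topology, stride = 10)$n_frames, 15L)
  # window outside the sampled range
  expect_error(window_trajectory(tr, c(500, 600)), "retains no frames")
  # idempotence
  w2 <- window_trajectory(window_trajectory(tr, c(50, 100)), c(50, 100))
  expect_identical(w2, window_trajectory(tr, c(50, 100)))
})

test_that("XYZ frame series parse, and atom-count mismatches are structural errors", {
  xyzf <- tempfile(fileext = ".xyz")
  writeLines(c("2", "frame 1", "C 0 0 0", "C 0 0 1.5",
               "2", "frame 2", "C 0 0 0", "C 0 0 2.5"), xyzf)
  st <- read_structure(xyzf, format = "xyz")
  expect_equal(st$topology$natoms, 2L)
  tr <- read_trajectory(xyzf, st$topology, stride = 0.5, format = "xyz")
  expect_equal(tr$n_frames, 2L)
  expect_equal(frame_coords(tr, 2)[2, 3], 2.5)
  bad <- tempfile(fileext = ".xyz")
  writeLines(c("3", "frame", "C 0 0 0", "C 1 1 1", "C 2 2 2"), bad)
  expect_error(read_trajectory(bad, st$topology, stride = 0.5, format = "xyz"),
               "atom-count mismatch")
  expect_error(read_trajectory(xyzf, st$topology, format = "xyz"), "stride")
})

test_that("entity assignment validates coverage, duplicates and region existence", {
  cx <- toy_hexamer()
  topo_bare <- cx_topology(cx$topology$atoms[, c("name", "element", "chain",
                                                 "resno", "icode", "resid")])
  full <- list(entities = cx$topology$entity_map, regions = cx$topology$region_map)
  topo <- assign_entities(topo_bare, full)
  expect_identical(sort(unique(unname(topo$entity_map))),
                   sort(c(paste0("P", 1:6), "AB1-HC", "AB1-LC", "AB2-HC", "AB2-LC")))
  expect_equal(nrow(region_residues(topo, "P1", "EC1")), 5L)  # EC1 = residues 54-58
  expect_equal(region_residues(topo, "P3", "EC1")$resno, 54:58)
  # unmapped chain
  part <- full
  part$entities <- part$entities[-1]
  expect_error(assign_entities(topo_bare, part), "without entity label")
  # duplicate protomer label
  dup <- full
  dup$entities[names(dup$entities)[2]] <- "P1"
  expect_error(assign_entities(topo_bare, dup), "duplicate protomer")
  # region referencing an absent residue
  badrg <- full
  badrg$regions$P1$EC1 <- c(54:58, 99)
  expect_error(assign_entities(topo_bare, badrg), "absent from topology")
})

test_that("entity/region YAML configs load with ranges expanded", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("entities:", "  A: P1", "  B: AB1-HC",
               "regions:",
               "  P1:", "    EC1:", "      range: [54, 58]",
               "  AB1-HC:", "    CDR1: [28, 29, 30]"), f)
  cfg <- read_entity_config(f)
  expect_equal(unname(cfg$entities["A"]), "P1")
  expect_equal(cfg$regions$P1$EC1, 54:58)
  expect_equal(cfg$regions$`AB1-HC`$CDR1, c(28L, 29L, 30L))
})
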