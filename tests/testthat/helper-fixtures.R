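# shared fixtures and independent oracles (plain loops, no package internals)

toy_hexamer <- function() build_toy_complex()
toy_small <- function() build_toy_complex(n_protomers = 3, n_antibodies = 1)

# brute-force O(na*nb) minimum distance, written independently of the package
brute_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- sqrt(sum((A[i, ] - B[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# independent frame-by-frame recount of pair contact probabilities (percent)
recount_probability <- function(traj, topo, pairs, threshold) {
  out <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ia <- connexitope:::residue_atom_idx(topo, pairs$entity_a[k], pairs$resno_a[k])
    ib <- connexitope:::residue_atom_idx(topo, pairs$entity_b[k], pairs$resno_b[k])
    hits <- 0L
    for (f in seq_len(traj$n_frames)) {
      co <- frame_coords(traj, f)
      if (brute_min_dist(co[ia, , drop = FALSE], co[ib, , drop = FALSE]) < threshold) {
        hits <- hits + 1L
      }
    }
    out[k] <- 100 * hits / traj$n_frames
  }
  out
}

# random blob of atoms around a centre
random_residue <- function(n = 10, centre = c(0, 0, 0), spread = 2) {
  matrix(stats::rnorm(3 * n, rep(centre, each = n), spread), ncol = 3)
}

# hand-written minimal PDB fixtures
write_tiny_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  path
}

write_icode_pdb <- function(path) {
  lines <- c(
    "ATOM      1  CA  ALA A  10       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A  10A      3.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  SER A  10B      6.000   0.000   0.000  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  path
}

# contact series built directly from an indicator matrix (for aggregation tests)
series_from_indicator <- function(pairs, indicator, threshold = 2) {
  structure(list(pairs = pairs, indicator = indicator, threshold = threshold,
                 times = seq_len(ncol(indicator)) * 0.01,
                 n_frames = ncol(indicator), atom_mode = "all"),
            class = "cx_contact_series")
}

family_fasta_path <- function() {
  p <- file.path(tempdir(), "cx_family_synthetic.fasta")
  if (!file.exists(p)) write_family_fasta(p)
  p
}

# residue-probability table in the layout extract_footprint() consumes,
# built from the bundled channel-side reference values
reference_residue_table <- function(partner = "AB1") {
  tab <- cx_channel_contact_table()
  data.frame(entity = tab$protomer, resno = tab$resno, partner = partner,
             probability = tab$probability_pct, stringsAsFactors = FALSE)
}
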