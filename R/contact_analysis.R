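#' @title Residue-contact analysis
#' @description Per-frame inter-residue minimum distances and the
#'   interaction-probability statistic: the fraction of simulation time in
#'   which a residue pair's distance is below a fixed threshold (2 Angstrom by
#'   default), expressed as a percentage, at pair and residue level.
#' @name contact_analysis
NULL

# squared distances between two coordinate sets (na x 3, nb x 3)
dist2_cross <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

min_dist_exhaustive <- function(A, B) sqrt(min(dist2_cross(A, B)))

# exact grid (cell-list) nearest-distance between two point sets: bin B into
# cubic cells of side `cell`, then for each point of A expand cell shells
# until no closer point can exist.
min_dist_cell <- function(A, B, cell = 3.0) {
  lo <- pmin(apply(A, 2, min), apply(B, 2, min))
  keyB <- floor(sweep(B, 2, lo) / cell)
  hash <- new.env(hash = TRUE, parent = emptyenv())
  kstr <- paste(keyB[, 1], keyB[, 2], keyB[, 3])
  for (i in seq_len(nrow(B))) {
    k <- kstr[i]
    hash[[k]] <- c(hash[[k]], i)
  }
  best <- Inf
  for (i in seq_len(nrow(A))) {
    a <- A[i, ]
    ka <- floor((a - lo) / cell)
    r <- 0L
    repeat {
      # points in the shell of cells at Chebyshev radius r
      idx <- integer(0)
      for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
        if (max(abs(c(dx, dy, dz))) != r) next
        k <- paste(ka[1] + dx, ka[2] + dy, ka[3] + dz)
        v <- hash[[k]]
        if (!is.null(v)) idx <- c(idx, v)
      }
      if (length(idx)) {
        d <- sqrt(colSums((t(B[idx, , drop = FALSE]) - a)^2))
        best <- min(best, d)
      }
      # any point in an unscanned shell (Chebyshev radius > r) is > r*cell away
      if (is.finite(best) && best <= r * cell) break
      if (r * cell > max_extent(A, B)) break  # all cells exhausted
      r <- r + 1L
    }
  }
  best
}

max_extent <- function(A, B) {
  rng <- apply(rbind(A, B), 2, range)
  sqrt(sum((rng[2, ] - rng[1, ])^2)) + 1
}

#' Minimum inter-residue distance
#'
#' The minimum over all atom pairs of the Euclidean distance between two
#' residues' atoms, in Angstrom. Symmetric in its arguments. `method = "cell"`
#' uses an exact grid (cell-list) search that returns the same value as the
#' exhaustive all-pairs scan.
#'
#' @param A,B numeric matrices of atom coordinates (n x 3, Angstrom).
#' @param method `"exhaustive"` (default) or `"cell"`.
#' @param cell grid cell side for the cell-list search, Angstrom.
#' @return minimum distance, Angstrom.
#' @export
min_residue_distance <- function(A, B, method = c("exhaustive", "cell"), cell = 3.0) {
  method <- match.arg(method)
  A <- as.matrix(A); B <- as.matrix(B)
  if (!nrow(A) || !nrow(B)) stop("empty atom selection")
  if (method == "exhaustive") min_dist_exhaustive(A, B) else min_dist_cell(A, B, cell)
}

#' Enumerate candidate inter-entity residue pairs
#'
#' All residue pairs between two entity groups whose minimum distance, in the
#' given frame, is below `cutoff`. Uses a grid prefilter (atoms binned into
#' cells of side `cutoff`, only neighbouring cells compared), so the cost
#' scales with the number of spatially close atoms rather than all pairs;
#' results equal the exhaustive enumeration.
#'
#' @param topology a `cx_topology` with entity maps.
#' @param coords natoms x 3 matrix for one frame.
#' @param entities_a,entities_b character vectors of entity labels for the two
#'   sides (e.g. protomers vs antibody chains).
#' @param cutoff distance cutoff, Angstrom.
#' @param atom_mode atom selection: `"all"`, `"heavy"` or `"calpha"`.
#' @return data.frame with columns `entity_a`, `resno_a`, `icode_a`,
#'   `entity_b`, `resno_b`, `icode_b`.
#' @export
candidate_pairs <- function(topology, coords, entities_a, entities_b,
                            cutoff = 12.0, atom_mode = "all") {
  a <- topology$atoms
  ent <- topology$entity_map[a$chain]
  sel_mode <- switch(atom_mode,
    all = rep(TRUE, nrow(a)),
    heavy = toupper(a$element) != "H",
    calpha = a$name == "CA",
    stop("unknown atom_mode"))
  ia <- which(ent %in% entities_a & sel_mode)
  ib <- which(ent %in% entities_b & sel_mode)
  if (!length(ia) || !length(ib)) stop("empty atom selection for candidate enumeration")
  lo <- apply(coords[c(ia, ib), , drop = FALSE], 2, min)
  key <- function(idx) {
    k <- floor(sweep(coords[idx, , drop = FALSE], 2, lo) / cutoff)
    paste(k[, 1], k[, 2], k[, 3])
  }
  hash <- new.env(hash = TRUE, parent = emptyenv())
  kb <- key(ib)
  for (j in seq_along(ib)) hash[[kb[j]]] <- c(hash[[kb[j]]], ib[j])
  ka <- floor(sweep(coords[ia, , drop = FALSE], 2, lo) / cutoff)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  rows <- list()
  for (q in seq_along(ia)) {
    i <- ia[q]
    neigh <- integer(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      v <- hash[[paste(ka[q, 1] + dx, ka[q, 2] + dy, ka[q, 3] + dz)]]
      if (!is.null(v)) neigh <- c(neigh, v)
    }
    if (!length(neigh)) next
    d <- sqrt(colSums((t(coords[neigh, , drop = FALSE]) - coords[i, ])^2))
    close <- neigh[d < cutoff]
    for (j in close) {
      pk <- paste(a$key[i], a$key[j], sep = "~")
      if (is.null(seen[[pk]])) {
        seen[[pk]] <- TRUE
        rows[[length(rows) + 1L]] <- data.frame(
          entity_a = unname(ent[i]), resno_a = a$resno[i], icode_a = a$icode[i],
          entity_b = unname(ent[j]), resno_b = a$resno[j], icode_b = a$icode[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(entity_a = character(), resno_a = integer(), icode_a = character(),
                      entity_b = character(), resno_b = integer(), icode_b = character(),
                      stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$entity_a, out$resno_a, out$entity_b, out$resno_b), ]
  rownames(out) <- NULL
  out
}

#' Per-frame contact indicator series for residue pairs
#'
#' A pair is in contact in a frame iff its minimum inter-residue distance is
#' strictly below `threshold` ("less than"; a distance exactly equal to the
#' threshold is non-contact).
#'
#' @param traj a `cx_trajectory`.
#' @param topology matching `cx_topology` with entity maps.
#' @param pairs data.frame with columns `entity_a`, `resno_a`, `entity_b`,
#'   `resno_b` (optional `icode_a`/`icode_b`).
#' @param threshold contact threshold, Angstrom (default 2).
#' @param atom_mode `"all"` (default; hydrogens participate when present),
#'   `"heavy"` or `"calpha"`.
#' @return object of class `cx_contact_series`: the pair table, a logical
#'   `indicator` matrix (pairs x frames), the threshold and frame times.
#' @export
pair_contact_series <- function(traj, topology, pairs, threshold = 2.0,
                                atom_mode = c("all", "heavy", "calpha")) {
  atom_mode <- match.arg(atom_mode)
  if (threshold <= 0) stop("threshold must be positive")
  if (traj$n_frames < 1L) stop("trajectory has no frames")
  if (!nrow(pairs)) stop("no residue pairs supplied")
  if (is.null(pairs$icode_a)) pairs$icode_a <- ""
  if (is.null(pairs$icode_b)) pairs$icode_b <- ""
  idx_a <- lapply(seq_len(nrow(pairs)), function(k)
    residue_atom_idx(topology, pairs$entity_a[k], pairs$resno_a[k], pairs$icode_a[k], atom_mode))
  idx_b <- lapply(seq_len(nrow(pairs)), function(k)
    residue_atom_idx(topology, pairs$entity_b[k], pairs$resno_b[k], pairs$icode_b[k], atom_mode))
  xyz_cols <- function(i) c(3L * (i - 1L) + 1L, 3L * (i - 1L) + 2L, 3L * i)
  ind <- matrix(FALSE, nrow(pairs), traj$n_frames)
  # vectorized over frames: per atom pair, squared distance as row operation
  for (k in seq_len(nrow(pairs))) {
    d2min <- rep(Inf, traj$n_frames)
    for (i in idx_a[[k]]) {
      Xa <- traj$xyz[, xyz_cols(i), drop = FALSE]
      for (j in idx_b[[k]]) {
        dd <- Xa - traj$xyz[, xyz_cols(j), drop = FALSE]
        d2 <- dd[, 1]^2 + dd[, 2]^2 + dd[, 3]^2
        d2min <- pmin(d2min, d2)
      }
    }
    ind[k, ] <- d2min < threshold^2
  }
  structure(list(pairs = pairs, indicator = ind, threshold = threshold,
                 times = traj$times, n_frames = traj$n_frames,
                 atom_mode = atom_mode),
            class = "cx_contact_series")
}

#' @export
print.cx_contact_series <- function(x, ...) {
  cat("cx_contact_series:", nrow(x$pairs), "pairs x", x$n_frames,
      "frames, threshold", x$threshold, "A\n")
  invisible(x)
}

#' Interaction probabilities from a contact series
#'
#' The interaction probability of a residue pair is the percentage of frames
#' in which the pair is in contact. The residue-level probability of a residue
#' against a partner entity group is the percentage of frames in which *any*
#' of its pairs with that group is in contact (frame-wise union), so a
#' residue's value is never below any of its pair values. Residue-level values
#' are reported per partner antibody group (`AB1`, `AB2`, ...) and against all
#' partners combined (`any`).
#'
#' @param series a `cx_contact_series`.
#' @return object of class `cx_contact_table` with `pair_probability` and
#'   `residue_probability` data.frames (probabilities in percent), the
#'   threshold and the time window.
#' @export
interaction_probability <- function(series) {
  if (series$n_frames < 1L) stop("zero frames")
  pr <- series$pairs
  pr$probability <- 100 * rowMeans(series$indicator)
  res_rows <- list()
  add_side <- function(ent_col, res_col, partner_col) {
    ents <- series$pairs[[ent_col]]
    resn <- series$pairs[[res_col]]
    partners <- entity_group(series$pairs[[partner_col]])
    keys <- paste(ents, resn)
    for (k in unique(keys)) {
      rows_k <- which(keys == k)
      ent <- ents[rows_k[1]]; rn <- resn[rows_k[1]]
      pgrp <- partners[rows_k]
      for (p in unique(c(pgrp, "any"))) {
        rr <- if (p == "any") rows_k else rows_k[pgrp == p]
        if (!length(rr)) next
        hit <- if (length(rr) == 1L) series$indicator[rr, ] else
          colSums(series$indicator[rr, , drop = FALSE]) > 0
        res_rows[[length(res_rows) + 1L]] <<- data.frame(
          entity = ent, resno = rn, partner = p,
          probability = 100 * mean(hit), stringsAsFactors = FALSE)
      }
    }
  }
  add_side("entity_a", "resno_a", "entity_b")
  add_side("entity_b", "resno_b", "entity_a")
  res <- do.call(rbind, res_rows)
  rownames(res) <- NULL
  structure(list(pair_probability = pr, residue_probability = res,
                 threshold = series$threshold,
                 window = range(series$times), n_frames = series$n_frames),
            class = "cx_contact_table")
}

#' @export
print.cx_contact_table <- function(x, ...) {
  cat("cx_contact_table:", nrow(x$pair_probability), "pairs,",
      nrow(x$residue_probability), "residue rows, threshold",
      x$threshold, "A, window", x$window[1], "-", x$window[2], "ns\n")
  invisible(x)
}

#' Residue-level interaction probabilities for one entity side
#'
#' Frame-wise union over all partner residues of the opposite side, then the
#' fraction of frames, in percent.
#'
#' @param series a `cx_contact_series`.
#' @param entity entity label (or antibody group label such as `"AB1"`).
#' @return data.frame with `entity`, `resno`, `probability` (percent), one row
#'   per residue of the requested entity, union over all partners.
#' @export
aggregate_residue_level <- function(series, entity) {
  on_a <- series$pairs$entity_a == entity | entity_group(series$pairs$entity_a) == entity
  on_b <- series$pairs$entity_b == entity | entity_group(series$pairs$entity_b) == entity
  if (!any(on_a) && !any(on_b)) stop("entity '", entity, "' absent from contact series")
  keys <- character(0); rows <- list()
  labs <- ifelse(on_a, paste(series$pairs$entity_a, series$pairs$resno_a),
                 ifelse(on_b, paste(series$pairs$entity_b, series$pairs$resno_b), NA))
  for (k in unique(stats::na.omit(labs))) {
    rr <- which(!is.na(labs) & labs == k)
    hit <- if (length(rr) == 1L) series$indicator[rr, ] else
      colSums(series$indicator[rr, , drop = FALSE]) > 0
    parts <- strsplit(k, " ")[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      entity = parts[1], resno = as.integer(parts[2]),
      probability = 100 * mean(hit), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$entity, out$resno), ]
  rownames(out) <- NULL
  out
}

#' Render a contact table in reporting layout
#'
#' One row per residue: entity, region, residue name+number, probability
#' rounded to integer percent (values are kept at full precision internally).
#'
#' @param table a `cx_contact_table`.
#' @param topology the `cx_topology` (for residue names and regions).
#' @param partner which partner attribution to render (default `"any"`).
#' @return data.frame with `entity`, `region`, `residue`, `probability_pct`.
#' @export
format_contact_table <- function(table, topology, partner = "any") {
  res <- table$residue_probability
  res <- res[res$partner == partner, , drop = FALSE]
  rt <- residue_table(topology)
  region_of <- function(entity, resno) {
    rg <- topology$region_map[[entity]]
    for (nm in names(rg)) if (resno %in% rg[[nm]]) return(nm)
    ""
  }
  res$region <- mapply(region_of, res$entity, res$resno)
  ch <- vapply(res$entity, function(e) entity_chains(topology, e)[1], "")
  nm <- mapply(function(c, r) rt$resid[rt$chain == c & rt$resno == r][1], ch, res$resno)
  out <- data.frame(
    entity = res$entity, region = res$region,
    residue = paste0(nm, res$resno),
    probability_pct = round(res$probability),
    stringsAsFactors = FALSE)
  out[order(out$entity, out$region, as.integer(sub("^[A-Za-z]+", "", out$residue))), ]
}
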