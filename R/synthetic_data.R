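#' @title Synthetic data generators
#' @description Seed-deterministic generators for every input the pipeline
#'   consumes: toy antibody-hemichannel complexes with known ground-truth
#'   contacts, trajectories with scheduled per-pair contact fractions,
#'   labelled docking-pose sets, and pre/post-antibody patch-clamp current
#'   traces. Toy residues are minimal (3 pseudo-atoms) so brute-force oracles
#'   stay fast; controllability, not physical realism, is the design goal.
#' @name synthetic_data
NULL

# toy geometry constants (Angstrom)
.toy <- list(
  ring_radius = 20, ec1_top_z = 30, ec2_top_z = 28, ec2_radius = 23,
  body_z = 10, atom_dz = 1.5, ec1_spread = 0.15, # rad between EC1 residues
  contact_gap = 1.2,        # base min distance of a designated contact pair
  cdr_shelf_z = 36, const_z = 52)

.ab_regions <- list(
  HC = list(CDR1 = 28:34, CDR2 = 50:58, CDR3 = 100:105, CONST = 120:131),
  LC = list(CDR1 = 24:34, CDR2 = 50:56, CONST = 108:119))

# designated contact residues, cycled over an antibody's target protomers:
# every HC CDR is used before falling back to LC loops
.contact_cycle <- data.frame(
  role = c("HC", "HC", "HC", "LC", "LC"),
  resno = c(30L, 54L, 102L, 28L, 52L),
  stringsAsFactors = FALSE)

# a stack of `n` pseudo-atoms rising in +z from `base`
atom_stack <- function(base, n = 3, dz = .toy$atom_dz, down = FALSE) {
  sgn <- if (down) -1 else 1
  cbind(rep(base[1], n), rep(base[2], n), base[3] + sgn * dz * (seq_len(n) - 1))
}

#' Build a toy antibody-hemichannel complex
#'
#' A hexameric (by default) channel of `n_protomers` protomer chains placed
#' with cyclic symmetry about the z axis, each carrying EC1 (residues 54-58)
#' and EC2 (residues 172-179) loop residues at the extracellular top plus a
#' short body stub, bound by `n_antibodies` antibody entities (heavy + light
#' chain each, with CDR1/2/3 and constant regions labelled). Antibodies are
#' positioned so that the ground-truth contact analysis of the generated
#' coordinates recovers exactly the protomer sets in `contact_map`: each
#' target protomer receives one designated CDR/loop residue placed 1.2 A
#' above its EC1 apex, and all other antibody atoms stay >= 6 A from the
#' channel.
#'
#' @param n_protomers number of channel protomers (default 6).
#' @param n_antibodies number of bound antibody entities (0, 1 or 2).
#' @param contact_map named list, antibody label -> character vector of target
#'   protomer labels; default is the 6:2 arrangement `AB1: P1-P4`,
#'   `AB2: P4, P5, P6, P1`.
#' @return list of class `cx_complex` with `topology` (entity and region maps
#'   attached), `coords` (natoms x 3), `contact_truth` (the map) and
#'   `designated_pairs` (data.frame of the constructed contact pairs).
#' @export
build_toy_complex <- function(n_protomers = 6, n_antibodies = 2,
                              contact_map = NULL) {
  if (n_protomers < 3) stop("need at least 3 protomers")
  prot_labels <- paste0("P", seq_len(n_protomers))
  if (is.null(contact_map)) {
    contact_map <- list()
    if (n_antibodies >= 1) contact_map$AB1 <- prot_labels[seq_len(min(4, n_protomers))]
    if (n_antibodies >= 2) {
      wrap <- ((4:7 - 1) %% n_protomers) + 1  # P4,P5,P6,P1 on a hexamer
      contact_map$AB2 <- prot_labels[unique(wrap)]
    }
  }
  n_antibodies <- length(contact_map)  # a supplied map is authoritative
  for (ab in names(contact_map)) {
    bad <- setdiff(contact_map[[ab]], prot_labels)
    if (length(bad)) stop("contact_map references absent protomer(s): ",
                          paste(bad, collapse = ", "))
    if (length(contact_map[[ab]]) > nrow(.contact_cycle)) {
      stop("at most ", nrow(.contact_cycle), " target protomers per antibody")
    }
  }
  theta <- (seq_len(n_protomers) - 1) * 2 * pi / n_protomers
  chains_p <- LETTERS[seq_len(n_protomers)]

  rows <- list(); coords <- list()
  add_res <- function(chain, resno, resid, base, n = 3, down = FALSE) {
    xyz <- atom_stack(base, n = n, down = down)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = paste0("C", seq_len(n)), element = "C",
      chain = chain, resno = resno, icode = "", resid = resid,
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- xyz
  }
  ec1_base <- function(k, resno) {
    # EC1 residues fan out around the protomer angle; apex atom on top
    off <- (resno - 56) * .toy$ec1_spread
    c(.toy$ring_radius * cos(theta[k] + off),
      .toy$ring_radius * sin(theta[k] + off), .toy$ec1_top_z)
  }
  res3 <- c("ASN", "THR", "LEU", "GLN", "PRO")  # N-T-L-Q-P epitope names
  for (k in seq_len(n_protomers)) {
    ch <- chains_p[k]
    for (r in 54:58) add_res(ch, r, res3[r - 53], ec1_base(k, r), down = TRUE)
    for (j in seq_along(172:179)) {
      r <- (172:179)[j]
      off <- (j - 4.5) * 0.1
      add_res(ch, r, "GLY",
              c(.toy$ec2_radius * cos(theta[k] + off),
                .toy$ec2_radius * sin(theta[k] + off), .toy$ec2_top_z),
              down = TRUE)
    }
    for (r in 20:22) {
      add_res(ch, r, "ALA",
              c(.toy$ring_radius * cos(theta[k]),
                .toy$ring_radius * sin(theta[k]),
                .toy$body_z - (r - 20) * 2), down = TRUE)
    }
  }

  ab_chain_ids <- list(AB1 = c(HC = "G", LC = "H"), AB2 = c(HC = "I", LC = "J"))
  designated <- list()
  for (ab in names(contact_map)) {
    targets <- contact_map[[ab]]
    tidx <- match(targets, prot_labels)
    # circular mean angle of the target protomers
    mx <- mean(cos(theta[tidx])); my <- mean(sin(theta[tidx]))
    thm <- atan2(my, mx)
    chains_ab <- ab_chain_ids[[ab]]
    placed <- list()  # role -> resnos already placed as contacts
    for (j in seq_along(targets)) {
      cyc <- .contact_cycle[((j - 1) %% nrow(.contact_cycle)) + 1, ]
      k <- tidx[j]
      # contact residue for the j-th target sits above EC1 residue 54+j
      a_res <- 54L + ((j - 1L) %% 5L)
      apex <- ec1_base(k, a_res)
      base <- c(apex[1], apex[2], .toy$ec1_top_z + .toy$contact_gap)
      add_res(chains_ab[[cyc$role]], cyc$resno, "GLY", base)
      placed[[cyc$role]] <- c(placed[[cyc$role]], cyc$resno)
      designated[[length(designated) + 1L]] <- data.frame(
        antibody = ab, protomer = targets[j],
        entity_a = targets[j], resno_a = a_res,
        entity_b = paste0(ab, "-", cyc$role), resno_b = cyc$resno,
        stringsAsFactors = FALSE)
    }
    # remaining CDR/constant residues on shelves well above the channel
    for (role in c("HC", "LC")) {
      regions <- .ab_regions[[role]]
      ch <- chains_ab[[role]]
      for (rg in names(regions)) {
        z <- if (rg == "CONST") .toy$const_z else .toy$cdr_shelf_z
        resnos <- setdiff(regions[[rg]], placed[[role]])
        for (j in seq_along(resnos)) {
          off <- (j - (length(resnos) + 1) / 2) * 0.08 +
            (match(rg, names(regions)) - 2) * 0.35 +
            (if (role == "LC") 0.12 else 0)
          add_res(ch, resnos[j], "GLY",
                  c(.toy$ring_radius * cos(thm + off),
                    .toy$ring_radius * sin(thm + off),
                    z + (if (rg == "CONST") (j %% 3) * 1.5 else 0)))
        }
      }
    }
  }

  atoms <- do.call(rbind, rows)
  xyz <- do.call(rbind, coords)
  topo <- cx_topology(atoms)
  entities <- stats::setNames(prot_labels, chains_p)
  regions <- stats::setNames(
    rep(list(list(EC1 = 54:58, EC2 = 172:179)), n_protomers), prot_labels)
  for (ab in names(contact_map)) {
    for (role in c("HC", "LC")) {
      lab <- paste0(ab, "-", role)
      entities[ab_chain_ids[[ab]][[role]]] <- lab
      regions[[lab]] <- .ab_regions[[role]]
    }
  }
  topo <- assign_entities(topo, list(entities = entities, regions = regions))
  structure(list(topology = topo, coords = xyz,
                 contact_truth = contact_map,
                 designated_pairs = if (length(designated)) do.call(rbind, designated)
                                    else NULL),
            class = "cx_complex")
}

#' @export
print.cx_complex <- function(x, ...) {
  cat("cx_complex:", length(x$contact_truth), "antibody(ies) on",
      sum(grepl("^P[0-9]+$", unique(x$topology$entity_map))), "protomers\n")
  invisible(x)
}

#' Build a contact schedule
#'
#' A contact schedule assigns each designated residue pair of a toy complex a
#' target contact fraction and a temporal model, and is the ground truth that
#' [simulate_contact_trajectory()] realizes.
#'
#' @param complex a `cx_complex`.
#' @param fractions numeric vector of target contact fractions in `[0, 1]`,
#'   recycled over the complex's designated pairs (or a subset via `pairs`).
#' @param pairs optional data.frame (`entity_a`, `resno_a`, `entity_b`,
#'   `resno_b`) overriding the designated pairs.
#' @param model `"bernoulli"` (i.i.d. per frame) or `"two_state_markov"`
#'   (bursty contacts with geometric dwell times).
#' @param dwell mean dwell time in the contact state, frames (Markov model).
#' @return data.frame schedule with a `fraction` column, class `cx_schedule`.
#' @export
contact_schedule <- function(complex, fractions, pairs = NULL,
                             model = c("bernoulli", "two_state_markov"),
                             dwell = 50) {
  model <- match.arg(model)
  if (is.null(pairs)) pairs <- complex$designated_pairs[, c("entity_a", "resno_a",
                                                            "entity_b", "resno_b")]
  if (is.null(pairs) || !nrow(pairs)) stop("complex has no designated pairs and none supplied")
  if (any(fractions < 0 | fractions > 1)) stop("contact fractions must lie in [0, 1]")
  sch <- pairs
  sch$fraction <- rep_len(fractions, nrow(sch))
  mob <- paste(sch$entity_b, sch$resno_b)
  if (anyDuplicated(mob)) stop("each mobile (antibody-side) residue may appear in only one scheduled pair")
  attr(sch, "model") <- model
  attr(sch, "dwell") <- dwell
  class(sch) <- c("cx_schedule", class(sch))
  sch
}

# one indicator series for a target fraction under the schedule's model
draw_indicator <- function(p, n, model, dwell) {
  if (p <= 0) return(rep(FALSE, n))
  if (p >= 1) return(rep(TRUE, n))
  if (model == "bernoulli") return(stats::rbinom(n, 1L, p) == 1L)
  # two-state Markov with stationary fraction p and mean contact dwell `dwell`
  q10 <- 1 / dwell                      # contact -> apart
  q01 <- p * q10 / (1 - p)              # apart -> contact
  if (q01 > 1) stop("dwell too short for requested fraction")
  s <- logical(n)
  s[1] <- stats::runif(1) < p           # start at stationarity
  for (i in 2:n) {
    s[i] <- if (s[i - 1]) stats::runif(1) >= q10 else stats::runif(1) < q01
  }
  s
}

#' Simulate a trajectory with scheduled contacts
#'
#' For every frame, each scheduled pair's mobile (second) residue is rigidly
#' translated so that its lowest atom sits exactly `contact_dist` (in-contact
#' draw) or `apart_dist` (out-of-contact draw) above the highest atom of the
#' partner channel residue; unscheduled atoms keep their base coordinates.
#' Realized contact fractions converge to the scheduled targets, and the same
#' seed reproduces the frames bit-exactly.
#'
#' @param complex a `cx_complex`.
#' @param schedule a [contact_schedule()].
#' @param n_frames number of frames (>= 1).
#' @param seed integer RNG seed.
#' @param stride frame spacing, ns (default 0.01).
#' @param contact_dist in-contact minimum distance, A (default 1.5, below the
#'   2 A threshold).
#' @param apart_dist out-of-contact minimum distance, A (default 6).
#' @return a [cx_trajectory] with attributes `indicator_truth` (logical
#'   pairs x frames matrix) and `schedule`.
#' @export
simulate_contact_trajectory <- function(complex, schedule, n_frames,
                                        seed = 1L, stride = 0.01,
                                        contact_dist = 1.5, apart_dist = 6.0) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (contact_dist <= 0 || apart_dist <= contact_dist) stop("need 0 < contact_dist < apart_dist")
  model <- attr(schedule, "model") %||% "bernoulli"
  dwell <- attr(schedule, "dwell") %||% 50
  topo <- complex$topology
  ind <- with_seed(seed, {
    t(vapply(seq_len(nrow(schedule)),
             function(k) draw_indicator(schedule$fraction[k], n_frames, model, dwell),
             logical(n_frames)))
  })
  if (n_frames == 1L) ind <- matrix(ind, nrow = nrow(schedule))
  base <- complex$coords
  idx_a <- lapply(seq_len(nrow(schedule)), function(k)
    residue_atom_idx(topo, schedule$entity_a[k], schedule$resno_a[k]))
  idx_b <- lapply(seq_len(nrow(schedule)), function(k)
    residue_atom_idx(topo, schedule$entity_b[k], schedule$resno_b[k]))
  # channel-side residues never move, so the per-pair rigid shift of the
  # mobile residue can be applied column-wise across all frames at once
  xyz <- matrix(as_xyz_row(base), n_frames, 3L * topo$natoms, byrow = TRUE)
  for (k in seq_len(nrow(schedule))) {
    A <- base[idx_a[[k]], , drop = FALSE]
    B <- base[idx_b[[k]], , drop = FALSE]
    a_top <- A[which.max(A[, 3]), ]
    b_bot <- B[which.min(B[, 3]), ]
    dvec <- ifelse(ind[k, ], contact_dist, apart_dist)
    shift0 <- a_top - b_bot
    for (j in idx_b[[k]]) {
      cz <- 3L * j
      xyz[, cz - 2L] <- B[match(j, idx_b[[k]]), 1] + shift0[1]
      xyz[, cz - 1L] <- B[match(j, idx_b[[k]]), 2] + shift0[2]
      xyz[, cz] <- B[match(j, idx_b[[k]]), 3] + shift0[3] + dvec
    }
  }
  traj <- cx_trajectory(xyz, (seq_len(n_frames) - 1L) * stride)
  attr(traj, "indicator_truth") <- ind
  attr(traj, "schedule") <- schedule
  traj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a labelled docking-pose set
#'
#' `n` single-frame poses of one antibody against the fixed channel; exactly
#' `n_correct` of them keep the built (CDRs-facing-EC1) orientation, the rest
#' are flipped 180 degrees about a horizontal axis through the antibody's own
#' centroid (CDRs pointing away from the channel) with a small seeded lateral
#' jitter. Orientation labels are retained for truth checks.
#'
#' @param n number of poses (default 50).
#' @param n_correct number of correctly oriented poses, `0 <= n_correct <= n`.
#' @param seed integer RNG seed.
#' @return list of `cx_pose` objects (`pose_id`, `topology`, `coords`,
#'   `oriented_correct`).
#' @export
generate_pose_set <- function(n = 50, n_correct = 1, seed = 1L) {
  if (n < 1 || n_correct < 0 || n_correct > n) stop("need 0 <= n_correct <= n, n >= 1")
  cx <- build_toy_complex(n_antibodies = 1)
  topo <- cx$topology
  ab_atoms <- which(topo$entity_map[topo$atoms$chain] %in% c("AB1-HC", "AB1-LC"))
  with_seed(seed, {
    correct_idx <- sort(sample.int(n, n_correct))
    lapply(seq_len(n), function(i) {
      co <- cx$coords
      ok <- i %in% correct_idx
      if (!ok) {
        cen <- centroid(co[ab_atoms, , drop = FALSE])
        B <- co[ab_atoms, , drop = FALSE]
        # 180-degree rotation about the x axis through the antibody centroid
        B <- sweep(B, 2, cen)
        B <- cbind(B[, 1], -B[, 2], -B[, 3])
        B <- sweep(B, 2, cen, "+")
        B[, 1:2] <- B[, 1:2] + matrix(stats::runif(2, -1, 1), nrow(B), 2, byrow = TRUE)
        co[ab_atoms, ] <- B
      }
      structure(list(pose_id = sprintf("pose%03d", i), topology = topo,
                     coords = co, score = NULL, oriented_correct = ok),
                class = "cx_pose")
    })
  })
}

#' Simulate pre/post-antibody current traces
#'
#' Ohmic whole-cell currents under a voltage protocol holding the cell at
#' 0 mV with a depolarization step to +40 mV: `I = g (V - V_rev) + leak +
#' noise`, with the post-antibody conductance equal to
#' `residual_fraction x g_control`. Units: nS, mV, pA, s.
#'
#' @param g_control control (pre-antibody) hemichannel conductance, nS.
#' @param residual_fraction post/pre conductance ratio, >= 0.
#' @param g_leak antibody-insensitive leak conductance, nS (default 0).
#' @param noise_sd additive current noise s.d., pA (default 5).
#' @param seed integer RNG seed.
#' @param protocol list with `dt` (s), `t_end` (s), `step_start`, `step_end`
#'   (s) and `step_mv`; default 1 s at 1 kHz with a +40 mV step over
#'   0.1-0.9 s.
#' @param v_rev reversal potential, mV (default 0).
#' @return list with `pre` and `post` [cx_recording] objects and the protocol.
#' @export
simulate_current_traces <- function(g_control, residual_fraction,
                                    g_leak = 0, noise_sd = 5, seed = 1L,
                                    protocol = NULL, v_rev = 0) {
  if (g_control < 0 || residual_fraction < 0 || g_leak < 0) {
    stop("conductances and residual fraction must be non-negative")
  }
  if (is.null(protocol)) {
    protocol <- list(dt = 0.001, t_end = 1.0, step_start = 0.1,
                     step_end = 0.9, step_mv = 40)
  }
  tt <- seq(0, protocol$t_end, by = protocol$dt)
  vv <- ifelse(tt >= protocol$step_start & tt <= protocol$step_end,
               protocol$step_mv, 0)
  mk <- function(g, label, sub_seed) {
    ii <- with_seed(sub_seed, {
      (g + g_leak) * (vv - v_rev) + stats::rnorm(length(tt), 0, noise_sd)
    })
    cx_recording(tt, vv, ii, condition = label)
  }
  list(pre = mk(g_control, "control", seed),
       post = mk(g_control * residual_fraction, "antibody", seed + 1L),
       protocol = protocol)
}
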