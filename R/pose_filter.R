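#' @title Docking-pose orientation filter
#' @description Selects docking poses in which the three heavy-chain
#'   complementarity-determining regions (CDRs) face the channel's EC1 loops.
#'   "Facing" is a reproducible surrogate for a visual criterion: a CDR faces
#'   EC1 iff (i) at least one CDR x EC1 residue pair is closer than a contact
#'   cutoff (8 A by default) and (ii) the CDR centroid lies nearer the EC1
#'   centroid than the whole antibody's centroid does.
#' @name pose_filter
NULL

# resolve a region (entity label + region name) to atom indices
region_atom_idx <- function(topology, entity, region) {
  rr <- region_residues(topology, entity, region)
  unlist(lapply(seq_len(nrow(rr)), function(i)
    residue_atom_idx(topology, topology$entity_map[rr$chain[i]], rr$resno[i], rr$icode[i])))
}

# all EC1 atoms of the channel (union over protomers)
channel_ec1_idx <- function(topology) {
  prots <- unique(topology$entity_map[grepl("^P[0-9]+$", topology$entity_map)])
  unlist(lapply(prots, function(p) region_atom_idx(topology, p, "EC1")))
}

#' Does a CDR face the EC1 loops?
#'
#' @param pose a `cx_pose` (list with `topology` and `coords`).
#' @param cdr_idx atom indices of the CDR residues.
#' @param ec1_idx atom indices of the EC1 residues.
#' @param ab_idx atom indices of the whole antibody entity the CDR belongs to.
#' @param contact_cutoff proximity cutoff, A (default 8).
#' @return logical.
#' @export
cdr_faces_ec1 <- function(pose, cdr_idx, ec1_idx, ab_idx, contact_cutoff = 8.0) {
  if (!length(cdr_idx) || !length(ec1_idx)) stop("empty region")
  if (contact_cutoff <= 0) return(FALSE)
  co <- pose$coords
  d <- min_residue_distance(co[cdr_idx, , drop = FALSE], co[ec1_idx, , drop = FALSE])
  if (d >= contact_cutoff) return(FALSE)
  ec1_cen <- centroid(co[ec1_idx, , drop = FALSE])
  cdr_cen <- centroid(co[cdr_idx, , drop = FALSE])
  ab_cen <- centroid(co[ab_idx, , drop = FALSE])
  sqrt(sum((cdr_cen - ec1_cen)^2)) < sqrt(sum((ab_cen - ec1_cen)^2))
}

#' Filter docking poses by CDR orientation
#'
#' A pose is retained iff [cdr_faces_ec1()] holds for CDR1, CDR2 and CDR3 of
#' the heavy chain (all three, when `require_all_cdrs`; any one otherwise).
#' Filtering is independent per pose, hence invariant to pose order.
#'
#' @param poses list of `cx_pose` objects.
#' @param hc_entity heavy-chain entity label carrying the CDR regions
#'   (default `"AB1-HC"`).
#' @param require_all_cdrs require all three CDRs to face EC1 (default TRUE).
#' @param contact_cutoff proximity cutoff, A (default 8).
#' @return data.frame of class `cx_pose_verdicts` with one row per pose
#'   (`pose_id`, `cdr1`, `cdr2`, `cdr3`, `retained`); the retained poses are
#'   in `attr(, "selected")`. If no pose passes, `attr(, "selected")` is an
#'   empty list and `attr(, "none_passed")` is TRUE.
#' @export
filter_poses <- function(poses, hc_entity = "AB1-HC", require_all_cdrs = TRUE,
                         contact_cutoff = 8.0) {
  if (!length(poses)) stop("at least one pose required")
  topo <- poses[[1]]$topology
  for (cdr in c("CDR1", "CDR2", "CDR3")) {
    if (is.null(topo$region_map[[hc_entity]][[cdr]])) {
      stop("region config missing ", cdr, " for entity ", hc_entity)
    }
  }
  cdr_idx <- lapply(c(CDR1 = "CDR1", CDR2 = "CDR2", CDR3 = "CDR3"),
                    function(r) region_atom_idx(topo, hc_entity, r))
  ec1_idx <- channel_ec1_idx(topo)
  ab_grp <- entity_group(hc_entity)
  ab_idx <- which(entity_group(topo$entity_map[topo$atoms$chain]) == ab_grp)
  rows <- lapply(poses, function(p) {
    v <- vapply(cdr_idx, function(ci)
      cdr_faces_ec1(p, ci, ec1_idx, ab_idx, contact_cutoff), logical(1))
    data.frame(pose_id = p$pose_id, cdr1 = v[["CDR1"]], cdr2 = v[["CDR2"]],
               cdr3 = v[["CDR3"]],
               retained = if (require_all_cdrs) all(v) else any(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "selected") <- poses[out$retained]
  attr(out, "none_passed") <- !any(out$retained)
  class(out) <- c("cx_pose_verdicts", "data.frame")
  out
}
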