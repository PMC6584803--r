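#' @title Epitope footprints and binding stoichiometry
#' @description Turns residue-level interaction probabilities into epitope
#'   footprints (the antigen residues whose probability exceeds a cutoff,
#'   >55% by default), per-protomer binding maps, and a stoichiometry summary
#'   for a hexameric channel bound by multiple antibodies.
#' @name epitope_mapping
NULL

#' Extract epitope footprints
#'
#' For each antibody group, the set of channel residues whose residue-level
#' interaction probability against that antibody satisfies the cutoff
#' comparison (strictly greater by default), grouped by protomer and loop
#' region. A residue contacted by both antibodies appears in both footprints.
#'
#' @param table a `cx_contact_table` whose residue rows carry per-antibody
#'   partner attribution, or a plain data.frame with columns `entity`,
#'   `resno`, `partner`, `probability`.
#' @param topology the `cx_topology` (for regions and residue names).
#' @param cutoff probability cutoff in percent (default 55).
#' @param comparison `"strict_greater"` (default, `> cutoff`) or
#'   `"greater_equal"`.
#' @return named list of `cx_footprint` objects, one per antibody group, each
#'   a data.frame (`protomer`, `region`, `resno`, `resid`, `probability`)
#'   with attributes `antibody` and `cutoff`.
#' @export
extract_footprint <- function(table, topology, cutoff = 55,
                              comparison = c("strict_greater", "greater_equal")) {
  comparison <- match.arg(comparison)
  if (cutoff < 0 || cutoff > 100) stop("cutoff outside [0, 100]")
  res <- if (inherits(table, "cx_contact_table")) table$residue_probability else table
  need <- c("entity", "resno", "partner", "probability")
  if (!all(need %in% names(res))) stop("residue table lacks columns: ",
                                       paste(setdiff(need, names(res)), collapse = ", "))
  # channel residues only, attributed to a specific antibody group
  res <- res[grepl("^P[0-9]+$", res$entity) & grepl("^AB", res$partner), , drop = FALSE]
  if (!nrow(res)) stop("no residue-level probabilities attributed to antibody entities")
  ab_labels <- sort(unique(res$partner))
  keep <- if (comparison == "strict_greater") res$probability > cutoff else res$probability >= cutoff
  res <- res[keep, , drop = FALSE]
  rt <- residue_table(topology)
  region_of <- function(entity, resno) {
    rg <- topology$region_map[[entity]]
    for (nm in names(rg)) if (resno %in% rg[[nm]]) return(nm)
    ""
  }
  out <- list()
  for (ab in ab_labels) {
    fp <- res[res$partner == ab, , drop = FALSE]
    ch <- vapply(fp$entity, function(e) entity_chains(topology, e)[1], "")
    fp_df <- data.frame(
      protomer = fp$entity,
      region = as.character(mapply(region_of, fp$entity, fp$resno)),
      resno = fp$resno,
      resid = as.character(mapply(function(c, r) rt$resid[rt$chain == c & rt$resno == r][1],
                                  ch, fp$resno)),
      probability = fp$probability,
      stringsAsFactors = FALSE)
    fp_df <- fp_df[order(fp_df$protomer, fp_df$resno), ]
    rownames(fp_df) <- NULL
    attr(fp_df, "antibody") <- ab
    attr(fp_df, "cutoff") <- cutoff
    class(fp_df) <- c("cx_footprint", "data.frame")
    out[[ab]] <- fp_df
  }
  out
}

#' Protomers contacted by a footprint
#' @param footprint a `cx_footprint`.
#' @return character vector of distinct protomer labels.
#' @export
footprint_protomers <- function(footprint) sort(unique(footprint$protomer))

# rotate protomer labels by k positions on an n-ring: P1 -> P(1+k)
rotate_protomers <- function(labels, k, n) {
  idx <- as.integer(sub("^P", "", labels))
  paste0("P", ((idx - 1 + k) %% n) + 1)
}

#' Binding stoichiometry summary
#'
#' Counts antibodies with non-empty footprints and the distinct protomers each
#' contacts, identifies protomers shared by two or more footprints, and tests
#' whether two footprints are arranged symmetrically about the channel pore
#' axis — operationalized as the two protomer sets being images of each other
#' under rotation by half the ring (3 positions on a hexamer, i.e. diametric
#' symmetry). Symmetry is only defined for exactly two non-empty footprints on
#' an even-sized ring; otherwise it is `FALSE`.
#'
#' @param footprints list of `cx_footprint` objects (from
#'   [extract_footprint()]).
#' @param topology the `cx_topology` (supplies the ring size).
#' @return list of class `cx_stoichiometry`: `n_antibodies`,
#'   `protomers_per_antibody` (named integer), `footprint_protomers` (named
#'   list), `shared_protomers`, `symmetric`, and `ratio` (e.g. `"6:2"`).
#' @export
stoichiometry_summary <- function(footprints, topology) {
  if (!length(footprints)) stop("at least one footprint required")
  prot_all <- sort(unique(topology$entity_map[grepl("^P[0-9]+$", topology$entity_map)]))
  n_ring <- length(prot_all)
  sets <- lapply(footprints, footprint_protomers)
  for (s in sets) {
    bad <- setdiff(s, prot_all)
    if (length(bad)) stop("footprint references unknown protomer(s): ",
                          paste(bad, collapse = ", "))
  }
  sets <- sets[vapply(sets, length, 1L) > 0]
  counts <- vapply(sets, length, 1L)
  tab <- table(unlist(sets))
  shared <- sort(names(tab)[tab >= 2])
  symmetric <- FALSE
  if (length(sets) == 2L && n_ring %% 2L == 0L) {
    half <- n_ring %/% 2L
    symmetric <- setequal(rotate_protomers(sets[[1]], half, n_ring), sets[[2]])
  }
  structure(list(
    n_antibodies = length(sets),
    protomers_per_antibody = counts,
    footprint_protomers = sets,
    shared_protomers = shared,
    symmetric = symmetric,
    ratio = paste0(n_ring, ":", length(sets))),
    class = "cx_stoichiometry")
}

#' @export
print.cx_stoichiometry <- function(x, ...) {
  cat("Binding stoichiometry", x$ratio, "\n")
  for (ab in names(x$footprint_protomers)) {
    cat(" ", ab, "->", paste(x$footprint_protomers[[ab]], collapse = ", "), "\n")
  }
  cat("  shared protomers:",
      if (length(x$shared_protomers)) paste(x$shared_protomers, collapse = ", ") else "none",
      "\n  symmetric about the pore axis:", x$symmetric, "\n")
  invisible(x)
}

#' Write footprints and stoichiometry as a plain-text report
#'
#' @param footprints list of `cx_footprint`.
#' @param summary a `cx_stoichiometry`.
#' @param path output file; a tab-separated footprint table is written next to
#'   it with suffix `.tsv`.
#' @return `path`, invisibly.
#' @export
write_footprint_report <- function(footprints, summary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("Epitope footprint report",
               paste0("cutoff: >", attr(footprints[[1]], "cutoff"), "%"), ""), con)
  for (ab in names(footprints)) {
    fp <- footprints[[ab]]
    writeLines(paste0("[", ab, "] ", nrow(fp), " residues on protomers ",
                      paste(footprint_protomers(fp), collapse = ", ")), con)
    writeLines(sprintf("  %s %s%d (%s) %.1f%%", fp$protomer, fp$resid, fp$resno,
                       fp$region, fp$probability), con)
  }
  writeLines(c("", paste("stoichiometry:", summary$ratio),
               paste("shared protomers:", paste(summary$shared_protomers, collapse = ", ")),
               paste("symmetric:", summary$symmetric)), con)
  tsv <- sub("\\.[^.]*$", ".tsv", path)
  all_fp <- do.call(rbind, lapply(names(footprints), function(ab) {
    cbind(antibody = ab, as.data.frame(footprints[[ab]]))
  }))
  utils::write.table(all_fp, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
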