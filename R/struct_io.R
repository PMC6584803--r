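#' @title Structure and trajectory input/output
#' @description Readers and writers for multi-chain structures (PDB, plain XYZ
#'   frame series) and the topology container that binds chains and residues to
#'   semantic entities: hemichannel protomers `P1..P6`, antibody chains
#'   (`AB1-HC`, `AB1-LC`, ...), and named regions (EC1, EC2, CDR1-3, constant
#'   regions).
#' @name struct_io
NULL

# residue identity = (chain, author resno, insertion code); never renumbered
res_key <- function(chain, resno, icode = "") {
  icode[is.na(icode) | icode == " "] <- ""
  paste(chain, resno, icode, sep = "|")
}

#' Construct a topology
#'
#' A topology is the static description of a structure: an ordered atom table
#' plus, optionally, the chain-to-entity and entity-to-region maps attached by
#' [assign_entities()]. Residue identity uses author numbering from the
#' coordinate file (1-based) and is never silently renumbered.
#'
#' @param atoms data.frame with columns `name` (atom label), `element`,
#'   `chain`, `resno` (integer), `icode` (insertion code, `""` if none),
#'   `resid` (3-letter residue code), in file order.
#' @param entity_map named character vector, chain id -> entity label, or NULL.
#' @param region_map nested list, entity label -> region name -> integer vector
#'   of residue numbers, or NULL.
#' @return object of class `cx_topology`.
#' @export
cx_topology <- function(atoms, entity_map = NULL, region_map = NULL) {
  need <- c("name", "element", "chain", "resno", "icode", "resid")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("topology needs at least one atom")
  if (any(!nzchar(atoms$element))) stop("empty element symbol in atom table")
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$resno <- as.integer(atoms$resno)
  atoms$key <- res_key(atoms$chain, atoms$resno, atoms$icode)
  structure(
    list(atoms = atoms, natoms = nrow(atoms),
         entity_map = entity_map, region_map = region_map),
    class = "cx_topology")
}

#' @export
print.cx_topology <- function(x, ...) {
  cat("cx_topology:", x$natoms, "atoms,",
      length(unique(x$atoms$key)), "residues,",
      length(unique(x$atoms$chain)), "chains\n")
  if (!is.null(x$entity_map)) {
    cat("entities:", paste(unique(x$entity_map), collapse = " "), "\n")
  }
  invisible(x)
}

#' Residue table of a topology
#'
#' One row per residue, in first-appearance order.
#' @param topology a `cx_topology`.
#' @return data.frame with `chain`, `resno`, `icode`, `resid`, `key`,
#'   `n_atoms`, and `entity` when an entity map is attached.
#' @export
residue_table <- function(topology) {
  a <- topology$atoms
  first <- !duplicated(a$key)
  out <- a[first, c("chain", "resno", "icode", "resid", "key")]
  out$n_atoms <- as.vector(table(a$key)[out$key])
  if (!is.null(topology$entity_map)) out$entity <- unname(topology$entity_map[out$chain])
  rownames(out) <- NULL
  out
}

#' Construct a trajectory
#'
#' @param xyz numeric matrix, one row per frame, `3 * natoms` columns in
#'   x,y,z interleaved order (the bio3d `xyz` convention); coordinates in
#'   Angstrom.
#' @param times numeric vector of per-frame times in ns, strictly increasing.
#' @return object of class `cx_trajectory`.
#' @export
cx_trajectory <- function(xyz, times) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (nrow(xyz) != length(times)) stop("one time per frame required")
  if (length(times) > 1 && any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  if (ncol(xyz) %% 3L != 0L) stop("xyz width must be a multiple of 3")
  structure(list(xyz = xyz, times = as.numeric(times),
                 n_frames = nrow(xyz), natoms = ncol(xyz) %/% 3L),
            class = "cx_trajectory")
}

#' @export
print.cx_trajectory <- function(x, ...) {
  cat("cx_trajectory:", x$n_frames, "frames,", x$natoms, "atoms, t =",
      min(x$times), "-", max(x$times), "ns\n")
  invisible(x)
}

#' Coordinates of one frame
#' @param traj a `cx_trajectory`.
#' @param i frame index.
#' @return natoms x 3 matrix (Angstrom).
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

# flat xyz row from an natoms x 3 matrix
as_xyz_row <- function(coords) as.vector(t(coords))

# quick well-formedness scan so parse failures report a line number
check_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  atom_idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in atom_idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("malformed ATOM/HETATM record at line ", i, " of ", path,
           ": fewer than 54 columns")
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz))) {
      stop("malformed coordinates at line ", i, " of ", path)
    }
  }
  invisible(length(atom_idx))
}

#' Read a structure file
#'
#' Reads a standard PDB file (ATOM/HETATM records; MODEL/ENDMDL allowed, the
#' first model supplies the returned coordinates) or a plain XYZ file (first
#' frame). PDB parsing is delegated to [bio3d::read.pdb()] after a
#' line-level well-formedness scan, so malformed records are reported with
#' their line number. Insertion codes are preserved and distinguish residues
#' sharing a sequence number; hydrogens are retained when present.
#'
#' @param path file path.
#' @param format `"pdb"` or `"xyz"`.
#' @return list with `topology` (a [cx_topology]) and `coords`
#'   (natoms x 3 matrix, Angstrom) for the first model/frame.
#' @export
read_structure <- function(path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (format == "pdb") {
    check_pdb_lines(path)
    pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    a <- pdb$atom
    element <- a$elesy
    if (is.null(element) || all(is.na(element)) || all(!nzchar(trimws(element)))) {
      element <- substr(trimws(a$elety), 1, 1)  # fall back to first letter of atom name
    }
    element <- trimws(element)
    element[!nzchar(element)] <- substr(trimws(a$elety[!nzchar(element)]), 1, 1)
    icode <- a$insert
    icode[is.na(icode)] <- ""
    atoms <- data.frame(
      name = trimws(a$elety), element = element,
      chain = a$chain, resno = as.integer(a$resno),
      icode = icode, resid = trimws(a$resid),
      stringsAsFactors = FALSE)
    coords <- cbind(a$x, a$y, a$z)
    if (any(!is.finite(coords))) stop("non-finite coordinates in ", path)
    list(topology = cx_topology(atoms), coords = coords)
  } else {
    fr <- read_xyz_frames(path, n_max = 1L)
    atoms <- data.frame(
      name = fr$elements[[1]], element = fr$elements[[1]],
      chain = "A", resno = 1L, icode = "", resid = "UNK",
      stringsAsFactors = FALSE)
    list(topology = cx_topology(atoms), coords = fr$coords[[1]])
  }
}

# parse a plain XYZ frame series: n / comment / n atom lines, repeated
read_xyz_frames <- function(path, n_max = Inf) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  elements <- list(); coords <- list()
  while (i <= length(lines) && length(coords) < n_max) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("malformed XYZ atom count at line ", i, " of ", path)
    if (i + 1L + n > length(lines)) stop("truncated XYZ frame starting at line ", i, " of ", path)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, 1L) < 4L)
    if (length(bad)) stop("malformed XYZ atom record at line ", i + 1L + bad[1], " of ", path)
    el <- vapply(parts, `[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(is.na(xyz))) stop("non-numeric XYZ coordinates in frame starting at line ", i, " of ", path)
    elements[[length(elements) + 1L]] <- el
    coords[[length(coords) + 1L]] <- xyz
    i <- i + 2L + n
  }
  list(elements = elements, coords = coords)
}

#' Read a trajectory (frame series)
#'
#' Multi-model PDB is the canonical trajectory dialect; plain XYZ frame series
#' are also accepted. Neither carries time metadata, so frame times default to
#' `model index x stride` ns; `stride` is therefore a required input. An
#' optional time `window` (closed interval, ns) retains only frames whose time
#' falls inside it — e.g. the last 10 ns of a 150 ns run is
#' `window = c(140, 150)`.
#'
#' @param paths one or more file paths, concatenated in order.
#' @param topology the `cx_topology` the frames must conform to.
#' @param stride time between consecutive frames, ns.
#' @param window optional length-2 numeric, closed time interval in ns.
#' @param format `"pdb"` (multi-model) or `"xyz"`.
#' @param t0 time of the first frame, ns (default 0).
#' @return a [cx_trajectory].
#' @export
read_trajectory <- function(paths, topology, stride, window = NULL,
                            format = c("pdb", "xyz"), t0 = 0) {
  format <- match.arg(format)
  if (missing(stride) || !is.finite(stride) || stride <= 0) {
    stop("a positive frame stride (ns) is required: the frame formats carry no time metadata")
  }
  frames <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("cannot read '", p, "': no such file")
    if (format == "pdb") {
      check_pdb_lines(p)
      pdb <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
      xyz <- pdb$xyz
      if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
      if (ncol(xyz) != 3L * topology$natoms) {
        stop("atom-count mismatch: trajectory has ", ncol(xyz) %/% 3L,
             " atoms, topology has ", topology$natoms)
      }
      for (k in seq_len(nrow(xyz))) frames[[length(frames) + 1L]] <- xyz[k, ]
    } else {
      fr <- read_xyz_frames(p)
      for (k in seq_along(fr$coords)) {
        if (nrow(fr$coords[[k]]) != topology$natoms) {
          stop("atom-count mismatch in XYZ frame ", k, " of ", p,
               ": ", nrow(fr$coords[[k]]), " vs topology ", topology$natoms)
        }
        frames[[length(frames) + 1L]] <- as_xyz_row(fr$coords[[k]])
      }
    }
  }
  if (!length(frames)) stop("no frames read")
  xyz <- do.call(rbind, frames)
  times <- t0 + (seq_len(nrow(xyz)) - 1L) * stride
  traj <- cx_trajectory(xyz, times)
  if (!is.null(window)) traj <- window_trajectory(traj, window) else traj
}

#' Restrict a trajectory to a closed time window
#'
#' Idempotent: applying the same window twice yields the same trajectory.
#' @param traj a `cx_trajectory`.
#' @param window length-2 numeric, closed interval in ns.
#' @return a `cx_trajectory` with only the frames whose time lies in `window`.
#' @export
window_trajectory <- function(traj, window) {
  if (length(window) != 2L || window[2] < window[1]) stop("window must be a valid closed interval")
  keep <- traj$times >= window[1] & traj$times <= window[2]
  if (!any(keep)) stop("window [", window[1], ", ", window[2], "] ns retains no frames")
  cx_trajectory(traj$xyz[keep, , drop = FALSE], traj$times[keep])
}

#' Write a structure or trajectory as (multi-model) PDB
#'
#' @param topology a `cx_topology`.
#' @param coords natoms x 3 matrix, or a `cx_trajectory` (written as one MODEL
#'   per frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(topology, coords, path) {
  a <- topology$atoms
  if (inherits(coords, "cx_trajectory")) {
    xyz <- coords$xyz
  } else {
    xyz <- matrix(as_xyz_row(coords), nrow = 1)
  }
  if (ncol(xyz) != 3L * topology$natoms) stop("coordinate/topology atom-count mismatch")
  insert <- a$icode
  insert[insert == ""] <- NA
  bio3d::write.pdb(
    file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
    resno = a$resno, resid = a$resid, chain = a$chain,
    insert = insert, eleno = seq_len(nrow(a)), elety = a$name,
    elesy = a$element)
  invisible(path)
}

#' Read an entity/region configuration file
#'
#' YAML with two top-level keys: `entities` (chain id -> entity label) and
#' `regions` (entity label -> region name -> residue numbers, either an
#' explicit vector or a `[start, end]` range given as a 2-element list under
#' key `range`).
#'
#' @param path config file path.
#' @return list with `entities` (named character) and `regions` (nested list
#'   of integer vectors).
#' @export
read_entity_config <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$entities)) stop("config lacks an 'entities' block")
  entities <- unlist(cfg$entities)
  regions <- lapply(cfg$regions, function(ent) {
    lapply(ent, function(r) {
      if (is.list(r) && !is.null(r$range)) {
        seq.int(r$range[[1]], r$range[[2]])
      } else as.integer(unlist(r))
    })
  })
  list(entities = entities, regions = regions)
}

#' Attach entity and region maps to a topology
#'
#' Binds every chain to exactly one entity label (protomers `P1..P6`, antibody
#' chains such as `AB1-HC`) and resolves named residue regions (EC1, EC2,
#' CDR1-3, constant regions) per entity. Protomer labels must be distinct;
#' protomers carry the cyclic order implied by their index.
#'
#' @param topology a `cx_topology`.
#' @param mapping a list as returned by [read_entity_config()], i.e.
#'   `list(entities = <named character>, regions = <nested list>)`.
#' @return the topology with `entity_map` and `region_map` populated.
#' @export
assign_entities <- function(topology, mapping) {
  entities <- mapping$entities
  chains <- unique(topology$atoms$chain)
  unmapped <- setdiff(chains, names(entities))
  if (length(unmapped)) {
    stop("configuration error: chain(s) without entity label: ",
         paste(unmapped, collapse = ", "))
  }
  prot <- entities[grepl("^P[0-9]+$", entities)]
  if (anyDuplicated(prot)) {
    stop("configuration error: duplicate protomer label: ",
         paste(unique(prot[duplicated(prot)]), collapse = ", "))
  }
  regions <- mapping$regions
  # every region residue must exist in the topology
  rt <- residue_table(topology)
  for (ent in names(regions)) {
    ch <- names(entities)[entities == ent]
    if (!length(ch)) stop("region map references unknown entity '", ent, "'")
    present <- rt$resno[rt$chain %in% ch]
    for (rg in names(regions[[ent]])) {
      missing_res <- setdiff(regions[[ent]][[rg]], present)
      if (length(missing_res)) {
        stop("region ", ent, "/", rg, " references residue(s) absent from topology: ",
             paste(missing_res, collapse = ", "))
      }
    }
  }
  topology$entity_map <- entities[chains]
  names(topology$entity_map) <- chains
  topology$region_map <- regions
  topology
}

#' Look up the residues of a named region
#'
#' @param topology a `cx_topology` with maps attached.
#' @param entity entity label.
#' @param region region name (e.g. `"EC1"`).
#' @return data.frame of residues (subset of [residue_table()]).
#' @export
region_residues <- function(topology, entity, region) {
  if (is.null(topology$region_map)) stop("topology has no region map; call assign_entities() first")
  rg <- topology$region_map[[entity]][[region]]
  if (is.null(rg)) stop("no region '", region, "' for entity '", entity, "'")
  rt <- residue_table(topology)
  ch <- names(topology$entity_map)[topology$entity_map == entity]
  out <- rt[rt$chain %in% ch & rt$resno %in% rg, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# chains belonging to an entity label
entity_chains <- function(topology, entity) {
  if (is.null(topology$entity_map)) stop("topology has no entity map")
  ch <- names(topology$entity_map)[topology$entity_map == entity]
  if (!length(ch)) stop("unknown entity '", entity, "'")
  ch
}

# antibody group label: AB1-HC -> AB1; protomers map to themselves
entity_group <- function(entity) sub("-(HC|LC)$", "", entity)

# atom row indices for one residue of an entity, under an atom mode
residue_atom_idx <- function(topology, entity, resno, icode = "",
                             atom_mode = c("all", "heavy", "calpha")) {
  atom_mode <- match.arg(atom_mode)
  ch <- entity_chains(topology, entity)
  a <- topology$atoms
  idx <- which(a$chain %in% ch & a$resno == resno & a$icode == icode)
  if (!length(idx)) stop("lookup error: no residue ", resno, icode, " in entity ", entity)
  if (atom_mode == "heavy") idx <- idx[toupper(a$element[idx]) != "H"]
  if (atom_mode == "calpha") idx <- idx[a$name[idx] == "CA"]
  if (!length(idx)) stop("empty atom selection for residue ", resno, " of ", entity,
                         " under atom_mode='", atom_mode, "'")
  idx
}
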