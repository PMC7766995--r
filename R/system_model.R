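## Static molecular description: atom table, bonds, named selections.

#' Construct a molecular system
#'
#' A `molecular_system` holds the static description of the simulated system:
#' one row per atom (or coarse-grained bead) with mass, charge and a role
#' label, a symmetric bond list, and named atom selections used by all
#' analysis stages.
#'
#' @param atoms data.frame with at least columns `atom_id` (1..n), `name`,
#'   `element`, `mass` (g/mol), `charge` (e), `role` (one of `core`,
#'   `backbone`, `side_segment`, `terminal_group`, `counterion`,
#'   `water_oxygen`, `other`), `residue_kind`, `segment_id`.
#' @param bonds two-column integer matrix of bonded atom id pairs (each bond
#'   listed once; symmetry is implied).
#' @param selections named list of integer atom-id vectors.
#' @param counts optional list with integers `Nend` (number of terminal
#'   charged amine groups) and `Nins` (number of inserted spacer residues).
#' @return object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, bonds, selections = list(), counts = list()) {
  stopifnot(is.data.frame(atoms))
  req <- c("atom_id", "name", "element", "mass", "charge", "role",
           "residue_kind", "segment_id")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(atoms$atom_id == seq_len(nrow(atoms))))
    stop("atom_id must be 1..n in order")
  if (any(atoms$mass <= 0)) stop("all atom masses must be > 0")
  roles <- c("core", "backbone", "side_segment", "terminal_group",
             "counterion", "water_oxygen", "other")
  if (!all(atoms$role %in% roles))
    stop("unknown role label(s): ", paste(setdiff(atoms$role, roles), collapse = ", "))
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) && (max(bonds) > nrow(atoms) || min(bonds) < 1))
    stop("bond references unknown atom id")
  for (nm in names(selections)) {
    ids <- selections[[nm]]
    if (length(ids) && (any(ids < 1) || any(ids > nrow(atoms))))
      stop("selection '", nm, "' references unknown atom id")
  }
  dend <- atoms$role %in% c("core", "backbone", "side_segment", "terminal_group")
  sys <- structure(list(
    atoms = atoms,
    bonds = bonds,
    selections = selections,
    bare_charge = as.integer(round(sum(atoms$charge[dend]))),
    counts = counts
  ), class = "molecular_system")
  sys
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("molecular_system:", nrow(x$atoms), "atoms,", nrow(x$bonds), "bonds\n")
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$atoms$role)),
                                table(x$atoms$role)), collapse = " "), "\n")
  cat("  bare charge:", x$bare_charge, "e;",
      "selections:", paste(names(x$selections), collapse = ", "), "\n")
  invisible(x)
}

## internal mutable accumulator for topology building
new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list(); env$bonds <- list(); env$n <- 0L
  env
}

add_atom <- function(b, name, element, mass, charge, role, residue_kind,
                     segment_id, is_ch2 = FALSE, ch2_class = NA_character_,
                     segment_end = FALSE, bond_to = integer()) {
  b$n <- b$n + 1L
  id <- b$n
  b$rows[[id]] <- data.frame(
    atom_id = id, name = name, element = element, mass = mass, charge = charge,
    role = role, residue_kind = residue_kind, segment_id = segment_id,
    is_ch2 = is_ch2, ch2_class = ch2_class, segment_end = segment_end,
    stringsAsFactors = FALSE)
  for (j in bond_to) b$bonds[[length(b$bonds) + 1L]] <- c(j, id)
  id
}

#' Build a coarse-grained toy dendrimer topology
#'
#' Builds the branch tree of a lysine-based peptide dendrimer with dipeptide
#' spacers, one bead per heavy-atom group: an alanine-lysine core, binary
#' branching lysines, two spacer residues between branching points (each with
#' a charged side chain, guanidinium for `2Arg` or ammonium for `2Lys`), and
#' doubly protonated terminal lysines. Chloride counterions are added to
#' neutralize the bare charge. Formal charges (+1 per protonated amine /
#' guanidinium, -1 per counterion) are used throughout.
#'
#' For generation 2 the builder reproduces the molecular counts of the real
#' dendrimer: 16 terminal NH3+ groups, 28 inserted spacer residues and a bare
#' charge of +44 e.
#'
#' @param generation non-negative integer; number of internal branching
#'   levels between the core and the terminal lysines.
#' @param spacer_kind `"2Arg"` or `"2Lys"` (dipeptide spacer chemistry).
#' @return a [molecular_system] with named selections `dendrimer`, `ions`,
#'   `terminal_N`, `terminal_C`, `core_branch_point`, `charged_side_groups`,
#'   `terminal_charged_groups`, `backbone`, `ch2_side`, `ch2_inner`,
#'   `ch2_terminal` and counts `Nend`, `Nins`.
#' @export
#' @examples
#' sys <- build_toy_dendrimer(2, "2Arg")
#' sys$counts$Nend   # 16
#' sys$bare_charge   # 44
build_toy_dendrimer <- function(generation, spacer_kind = c("2Arg", "2Lys")) {
  if (!is.numeric(generation) || length(generation) != 1 || generation < 0 ||
      generation != round(generation))
    stop("generation must be a non-negative integer")
  spacer_kind <- tryCatch(match.arg(spacer_kind),
                          error = function(e) stop("unsupported spacer_kind", call. = FALSE))
  b <- new_builder()
  seg_counter <- new.env(parent = emptyenv()); seg_counter$i <- 0L
  next_seg <- function() { seg_counter$i <- seg_counter$i + 1L; seg_counter$i }

  ## ---- core: Ala bead + Lys bead (first branching point)
  seg <- next_seg()
  ala <- add_atom(b, "ALA", "C", 71.0, 0, "core", "core-Ala", seg)
  core <- add_atom(b, "LYS", "C", 57.0, 0, "core", "core-Lys", seg, bond_to = ala)

  ## ---- one spacer residue (backbone bead + charged side chain); returns BB id
  add_spacer_residue <- function(attach) {
    seg <- next_seg()
    kind <- if (spacer_kind == "2Arg") "side-Arg" else "side-Lys"
    bb <- add_atom(b, "BB", "C", 56.0, 0, "backbone", kind, seg, bond_to = attach)
    if (spacer_kind == "2Arg") {
      cb <- add_atom(b, "CB", "C", 14.0, 0, "side_segment", kind, seg, TRUE, NA, bond_to = bb)
      cg <- add_atom(b, "CG", "C", 14.0, 0, "side_segment", kind, seg, TRUE, NA, bond_to = cb)
      cd <- add_atom(b, "CD", "C", 14.0, 0, "side_segment", kind, seg, TRUE, "side", bond_to = cg)
      ne <- add_atom(b, "NE", "N", 15.0, 0, "side_segment", kind, seg, bond_to = cd)
      cz <- add_atom(b, "CZ", "C", 12.0, 0, "side_segment", kind, seg, bond_to = ne)
      add_atom(b, "NH", "N", 16.0, +1, "side_segment", kind, seg,
               segment_end = TRUE, bond_to = cz)
    } else {
      cb <- add_atom(b, "CB", "C", 14.0, 0, "side_segment", kind, seg, TRUE, NA, bond_to = bb)
      cg <- add_atom(b, "CG", "C", 14.0, 0, "side_segment", kind, seg, TRUE, NA, bond_to = cb)
      cd <- add_atom(b, "CD", "C", 14.0, 0, "side_segment", kind, seg, TRUE, NA, bond_to = cg)
      ce <- add_atom(b, "CE", "C", 14.0, 0, "side_segment", kind, seg, TRUE, "side", bond_to = cd)
      add_atom(b, "NZ", "N", 17.0, +1, "side_segment", kind, seg,
               segment_end = TRUE, bond_to = ce)
    }
    bb
  }

  ## ---- spacer = two residues in series; returns BB id of the second residue
  add_spacer <- function(attach) add_spacer_residue(add_spacer_residue(attach))

  ## ---- branching lysine: BB + side chain ending in the branch amine NZ;
  ##      returns the two attachment points (BB, NZ) for the children
  add_branch_lys <- function(attach) {
    seg <- next_seg()
    bb <- add_atom(b, "BB", "C", 56.0, 0, "backbone", "inner-Lys", seg, bond_to = attach)
    cb <- add_atom(b, "CB", "C", 14.0, 0, "backbone", "inner-Lys", seg, TRUE, NA, bond_to = bb)
    cg <- add_atom(b, "CG", "C", 14.0, 0, "backbone", "inner-Lys", seg, TRUE, NA, bond_to = cb)
    cd <- add_atom(b, "CD", "C", 14.0, 0, "backbone", "inner-Lys", seg, TRUE, NA, bond_to = cg)
    ce <- add_atom(b, "CE", "C", 14.0, 0, "backbone", "inner-Lys", seg, TRUE, "inner", bond_to = cd)
    nz <- add_atom(b, "NZ", "N", 15.0, 0, "backbone", "inner-Lys", seg, bond_to = ce)
    c(bb, nz)
  }

  ## ---- terminal lysine: both amines protonated (+1 each)
  add_terminal_lys <- function(attach) {
    seg <- next_seg()
    bb <- add_atom(b, "BB", "C", 56.0, 0, "backbone", "terminal-Lys", seg, bond_to = attach)
    add_atom(b, "NA", "N", 17.0, +1, "terminal_group", "terminal-Lys", seg, bond_to = bb)
    cb <- add_atom(b, "CB", "C", 14.0, 0, "backbone", "terminal-Lys", seg, TRUE, NA, bond_to = bb)
    cg <- add_atom(b, "CG", "C", 14.0, 0, "backbone", "terminal-Lys", seg, TRUE, NA, bond_to = cb)
    cd <- add_atom(b, "CD", "C", 14.0, 0, "backbone", "terminal-Lys", seg, TRUE, NA, bond_to = cg)
    ce <- add_atom(b, "CE", "C", 14.0, 0, "backbone", "terminal-Lys", seg, TRUE, "terminal", bond_to = cd)
    add_atom(b, "NZ", "N", 17.0, +1, "terminal_group", "terminal-Lys", seg, bond_to = ce)
  }

  ## ---- recursive growth: each branch = spacer, then either a branching
  ##      lysine with two children (internal level) or a terminal lysine
  grow <- function(attach, level) {
    end_bb <- add_spacer(attach)
    if (level <= generation) {
      at <- add_branch_lys(end_bb)
      grow(at[1], level + 1L)
      grow(at[2], level + 1L)
    } else {
      add_terminal_lys(end_bb)
    }
  }
  grow(core, 1L)
  grow(core, 1L)

  atoms <- do.call(rbind, b$rows)
  n_dend <- nrow(atoms)
  q_bare <- as.integer(round(sum(atoms$charge)))

  ## counterions (no bonds)
  for (i in seq_len(q_bare))
    add_atom(b, "CL", "Cl", 35.45, -1, "counterion", "ion", next_seg())
  atoms <- do.call(rbind, b$rows)
  bonds <- do.call(rbind, b$bonds)

  term_N <- atoms$atom_id[atoms$role == "terminal_group"]
  ## C atom bonded to each terminal amine N (order matched to term_N)
  nbrs <- split(c(bonds[, 2], bonds[, 1]), c(bonds[, 1], bonds[, 2]))
  term_C <- vapply(term_N, function(i) {
    cand <- nbrs[[as.character(i)]]
    cand[atoms$element[cand] == "C"][1]
  }, integer(1))

  side_end <- atoms$atom_id[atoms$segment_end & atoms$role == "side_segment"]
  selections <- list(
    dendrimer = atoms$atom_id[atoms$role != "counterion"],
    ions = atoms$atom_id[atoms$role == "counterion"],
    terminal_N = term_N,
    terminal_C = term_C,
    core_branch_point = core,
    charged_side_groups = side_end,
    terminal_charged_groups = term_N,
    backbone = atoms$atom_id[atoms$role %in% c("core", "backbone")],
    ch2_side = atoms$atom_id[atoms$is_ch2 & atoms$role == "side_segment"],
    ch2_inner = atoms$atom_id[!is.na(atoms$ch2_class) & atoms$ch2_class == "inner"],
    ch2_terminal = atoms$atom_id[!is.na(atoms$ch2_class) & atoms$ch2_class == "terminal"]
  )
  ## Nins = number of inserted spacer residues (two per spacer)
  counts <- list(Nend = length(term_N),
                 Nins = sum(atoms$name == "BB" &
                              atoms$residue_kind %in% c("side-Arg", "side-Lys")))
  sys <- molecular_system(atoms, bonds, selections, counts)
  sys
}

#' Resolve a named atom selection
#'
#' @param system a [molecular_system].
#' @param name selection name registered in `system$selections`.
#' @return integer vector of atom ids (stable order).
#' @export
resolve_selection <- function(system, name) {
  stopifnot(inherits(system, "molecular_system"))
  if (!nrow(system$atoms))
    stop("selection error: system contains no atoms", call. = FALSE)
  if (!name %in% names(system$selections))
    stop("selection error: unknown selection '", name, "'", call. = FALSE)
  as.integer(system$selections[[name]])
}

## bond graph as igraph object (undirected); cached on first use
bond_graph <- function(system) {
  g <- attr(system, ".graph")
  if (!is.null(g)) return(g)
  igraph::graph_from_edgelist(system$bonds, directed = FALSE) +
    igraph::vertices(setdiff(seq_len(nrow(system$atoms)), as.vector(system$bonds)))
}

#' Topological distance of side-segment CH2 groups
#'
#' For every CH2 group in a charged side segment, counts the number of
#' chemical bonds along the bond graph from the CH2 carbon to the terminal
#' nitrogen of its own side segment. This bond count (the topological
#' distance) is the explanatory variable for the orientational mobility of
#' CH2 groups in the spacers: for an arginine side chain the attainable
#' values are 3, 4 and 5; for a lysine side chain 1, 2, 3 and 4.
#'
#' @param system a [molecular_system] whose atom table carries `is_ch2` and
#'   `segment_end` flags (as produced by [build_toy_dendrimer]).
#' @return data.frame with columns `group_id` (CH2 atom id), `segment_id`,
#'   `residue_kind` and `n_bonds_to_segment_end`.
#' @export
label_topological_distance <- function(system) {
  stopifnot(inherits(system, "molecular_system"))
  at <- system$atoms
  if (is.null(at$is_ch2) || is.null(at$segment_end))
    stop("system lacks CH2 / segment-end annotation")
  ch2 <- at$atom_id[at$is_ch2 & at$role == "side_segment"]
  if (!length(ch2))
    return(data.frame(group_id = integer(), segment_id = integer(),
                      residue_kind = character(),
                      n_bonds_to_segment_end = integer()))
  g <- bond_graph(system)
  res <- lapply(ch2, function(i) {
    seg <- at$segment_id[i]
    endN <- at$atom_id[at$segment_id == seg & at$segment_end]
    if (length(endN) != 1)
      stop("topology error: side segment ", seg, " has no unique end nitrogen")
    d <- igraph::distances(g, v = i, to = endN)[1, 1]
    if (!is.finite(d))
      stop("topology error: side segment ", seg, " is disconnected")
    data.frame(group_id = i, segment_id = seg,
               residue_kind = at$residue_kind[i],
               n_bonds_to_segment_end = as.integer(d))
  })
  out <- do.call(rbind, res)
  if (any(out$n_bonds_to_segment_end < 1))
    stop("topology error: CH2 coincides with segment end")
  out
}

#' Read a selection / charge configuration file
#'
#' Reads a YAML file declaring named selections as role / residue / element /
#' name filters on the atom table, and optional per-atom charge or mass
#' overrides. This decouples analysis selections from force-field specific
#' atom naming.
#'
#' Layout:
#' ```yaml
#' atoms:
#'   - filter: {residue_kind: side-Arg, name: NH}
#'     charge: 1.0
#' selections:
#'   my_sel: {role: terminal_group, element: N}
#' ```
#'
#' @param path YAML file path.
#' @param system a [molecular_system] to which filters are applied.
#' @return the system with overrides applied and selections added.
#' @export
read_selection_config <- function(path, system) {
  cfg <- yaml::read_yaml(path)
  at <- system$atoms
  apply_filter <- function(flt) {
    keep <- rep(TRUE, nrow(at))
    for (key in names(flt)) {
      if (!key %in% names(at)) stop("unknown filter field '", key, "'")
      keep <- keep & at[[key]] %in% flt[[key]]
    }
    at$atom_id[keep]
  }
  for (ov in cfg$atoms %||% list()) {
    ids <- apply_filter(ov$filter %||% list())
    if (!is.null(ov$charge)) at$charge[ids] <- ov$charge
    if (!is.null(ov$mass)) at$mass[ids] <- ov$mass
  }
  sels <- lapply(cfg$selections %||% list(), apply_filter)
  system$atoms <- at
  system$selections[names(sels)] <- sels
  system$bare_charge <- as.integer(round(sum(
    at$charge[at$role %in% c("core", "backbone", "side_segment", "terminal_group")])))
  system
}
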