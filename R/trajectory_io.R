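## Trajectory container and format readers/writers.
## Internal units are fixed: positions nm, times ps (readers convert on load).

#' Construct a trajectory object
#'
#' @param times numeric vector of frame times (ps), strictly increasing.
#' @param coords numeric array `[n_frames, n_atoms, 3]` of positions (nm).
#' @param box optional `n_frames x 3` matrix of orthorhombic box lengths (nm).
#' @return object of class `md_trajectory`.
#' @export
md_trajectory <- function(times, coords, box = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3,
            length(times) == dim(coords)[1])
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  uniform <- is_uniform_times(times)
  if (!uniform)
    warning("non-uniform frame spacing: autocorrelation analyses will refuse this trajectory")
  if (!is.null(box)) {
    box <- matrix(box, ncol = 3)
    if (nrow(box) == 1) box <- box[rep(1, length(times)), , drop = FALSE]
    stopifnot(nrow(box) == length(times))
  }
  structure(list(times = as.numeric(times), coords = coords, box = box,
                 uniform = uniform),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("md_trajectory:", d[1], "frames x", d[2], "atoms;",
      if (d[1] > 1) sprintf("dt = %g ps;", x$times[2] - x$times[1]) else "",
      if (is.null(x$box)) "no box\n" else "periodic box\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]
n_atoms <- function(traj) dim(traj$coords)[2]
frame_coords <- function(traj, i) matrix(traj$coords[i, , ], ncol = 3)

timestep <- function(traj) {
  if (!isTRUE(traj$uniform))
    stop("trajectory frame spacing is non-uniform; ACF analyses require uniform spacing")
  if (n_frames(traj) < 2) stop("need at least 2 frames")
  traj$times[2] - traj$times[1]
}

guess_mass <- function(element) {
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
         P = 30.974, Cl = 35.45, Na = 22.99)
  out <- unname(m[element])
  out[is.na(out)] <- 12.0
  out
}

## ---------------------------------------------------------------- GRO ----

#' Read a (possibly multi-frame) GRO file
#'
#' Positions are native nm; the frame time is taken from a `t=` token on the
#' title line (0, 1, 2, ... if absent).
#'
#' @param path GRO file.
#' @return list with `traj` ([md_trajectory]) and `atoms` (data.frame of
#'   residue/atom names from the first frame).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  i <- 1L; frames <- list(); times <- c(); boxes <- list(); atoms <- NULL
  k <- 0L
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    title <- lines[i]
    nat <- as.integer(trimws(lines[i + 1L]))
    if (is.na(nat)) stop("format error: bad atom count in GRO at line ", i + 1L)
    if (i + 1L + nat + 1L > length(lines))
      stop("format error: truncated GRO frame")
    body <- lines[(i + 2L):(i + 1L + nat)]
    ## coordinates: first three whitespace tokens after the fixed atom
    ## fields (tolerates wider-than-standard precision)
    xyz <- t(vapply(strsplit(trimws(substr(body, 21, 200)), "\\s+"),
                    function(s) as.numeric(s[1:3]), numeric(3)))
    x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
    if (any(is.na(c(x, y, z)))) stop("format error: bad coordinates in GRO")
    if (is.null(atoms)) {
      atoms <- data.frame(
        resid = as.integer(substr(body, 1, 5)),
        resname = trimws(substr(body, 6, 10)),
        name = trimws(substr(body, 11, 15)),
        stringsAsFactors = FALSE)
    } else if (nat != nrow(atoms)) {
      stop("format error: atom count changed between GRO frames")
    }
    k <- k + 1L
    frames[[k]] <- cbind(x, y, z)
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    times[k] <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else k - 1
    boxes[[k]] <- as.numeric(strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1]])[1:3]
    i <- i + nat + 3L
  }
  coords <- array(0, dim = c(k, nrow(atoms), 3))
  for (j in seq_len(k)) coords[j, , ] <- frames[[j]]
  box <- do.call(rbind, boxes)
  if (all(!is.finite(box)) || all(box == 0, na.rm = TRUE)) box <- NULL
  list(traj = md_trajectory(times, coords, box), atoms = atoms)
}

#' Write a trajectory as a multi-frame GRO file
#'
#' @param traj an [md_trajectory].
#' @param system a [molecular_system] supplying atom and residue names.
#' @param path output file.
#' @param digits coordinate decimals (3 = standard GRO; more for lossless
#'   round-trips of synthetic data).
#' @export
write_gro <- function(traj, system, path, digits = 3) {
  at <- system$atoms
  con <- file(path, "w"); on.exit(close(con))
  nf <- n_frames(traj)
  cfmt <- sprintf("%%%d.%df", digits + 5, digits)
  fmt <- paste0("%5d%-5s%5s%5d", cfmt, cfmt, cfmt)
  for (f in seq_len(nf)) {
    x <- frame_coords(traj, f)
    writeLines(sprintf("dendritraj frame t= %.6f", traj$times[f]), con)
    writeLines(sprintf("%5d", nrow(at)), con)
    writeLines(sprintf(fmt,
                       at$segment_id %% 100000L,
                       substr(at$residue_kind, 1, 5), substr(at$name, 1, 5),
                       at$atom_id %% 100000L, x[, 1], x[, 2], x[, 3]), con)
    bx <- if (is.null(traj$box)) c(0, 0, 0) else traj$box[f, ]
    writeLines(sprintf("%10.5f%10.5f%10.5f", bx[1], bx[2], bx[3]), con)
  }
  invisible(path)
}

## ------------------------------------------------------------- readers ----

#' Read structure + trajectory files
#'
#' Supported structures: PDB (via bio3d, Angstrom converted to nm) and GRO
#' (native nm). Supported trajectories: multi-frame GRO and DCD (via bio3d,
#' Angstrom converted to nm, frame times from `dt`). Positions are always
#' returned in nm and times in ps.
#'
#' @param structure_path PDB or GRO file.
#' @param trajectory_path optional multi-frame GRO or DCD file; if omitted
#'   the structure's single frame is the trajectory.
#' @param system optional [molecular_system]; if omitted a minimal one is
#'   derived from the structure file (guessed element masses, zero charges).
#' @param dt frame spacing in ps for formats that do not store times (DCD).
#' @return list with `traj` ([md_trajectory]) and `system`
#'   ([molecular_system]).
#' @export
read_trajectory <- function(structure_path, trajectory_path = NULL,
                            system = NULL, dt = 1) {
  ext <- tolower(tools::file_ext(structure_path))
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(structure_path)
    xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE) / 10
    atoms <- data.frame(name = pdb$atom$elety, resname = pdb$atom$resid,
                        stringsAsFactors = FALSE)
  } else if (ext == "gro") {
    g <- read_gro(structure_path)
    xyz <- frame_coords(g$traj, 1)
    atoms <- data.frame(name = g$atoms$name, resname = g$atoms$resname,
                        stringsAsFactors = FALSE)
  } else stop("format error: unsupported structure format '", ext, "'")

  if (is.null(system)) {
    el <- toupper(substr(gsub("[^A-Za-z].*", "", atoms$name), 1, 1))
    el[el == ""] <- "C"
    system <- molecular_system(
      data.frame(atom_id = seq_len(nrow(atoms)), name = atoms$name,
                 element = el, mass = guess_mass(el), charge = 0,
                 role = "other", residue_kind = atoms$resname,
                 segment_id = seq_len(nrow(atoms)), stringsAsFactors = FALSE),
      bonds = matrix(integer(), ncol = 2))
  }
  n_sys <- nrow(system$atoms)
  if (n_sys != nrow(xyz))
    stop("format error: structure has ", nrow(xyz),
         " atoms but system defines ", n_sys)

  if (is.null(trajectory_path)) {
    traj <- md_trajectory(0, array(xyz, dim = c(1, nrow(xyz), 3)))
    return(list(traj = traj, system = system))
  }
  text <- tolower(tools::file_ext(trajectory_path))
  if (text == "gro") {
    traj <- read_gro(trajectory_path)$traj
  } else if (text == "dcd") {
    m <- bio3d::read.dcd(trajectory_path, verbose = FALSE) / 10
    nf <- nrow(m)
    coords <- array(0, dim = c(nf, ncol(m) / 3, 3))
    for (f in seq_len(nf)) coords[f, , ] <- matrix(m[f, ], ncol = 3, byrow = TRUE)
    traj <- md_trajectory(seq(0, by = dt, length.out = nf), coords)
  } else stop("format error: unsupported trajectory format '", text, "'")
  if (n_atoms(traj) != n_sys)
    stop("format error: trajectory has ", n_atoms(traj),
         " atoms but structure/system defines ", n_sys)
  list(traj = traj, system = system)
}

## --------------------------------------------------- unwrap / centring ----

#' Make the dendrimer whole and centre it
#'
#' Resolves periodic imaging by walking the bond graph of the dendrimer
#' (each atom is moved to its minimum image relative to an already-placed
#' bonded neighbour), translates every frame so the mass-weighted dendrimer
#' centre of mass sits at the origin, and wraps unbonded particles
#' (counterions) to their minimum image relative to that centre. All radial
#' quantities downstream are measured from this origin.
#'
#' @param traj an [md_trajectory].
#' @param system a [molecular_system].
#' @param mode `"center"` (translate only, no box needed) or
#'   `"unwrap_center"` (periodic unwrap + centre; requires a box).
#' @return a new [md_trajectory], box removed (coordinates are whole).
#' @export
unwrap_or_center <- function(traj, system, mode = c("center", "unwrap_center")) {
  mode <- match.arg(mode)
  dend <- resolve_selection(system, "dendrimer")
  mass <- system$atoms$mass[dend]
  coords <- traj$coords
  nf <- n_frames(traj)

  if (mode == "unwrap_center") {
    if (is.null(traj$box))
      stop("configuration error: periodic unwrap requested but trajectory has no box")
    g <- bond_graph(system)
    comp <- igraph::components(g)
    ## BFS visit order with parents, over bonded components
    ord <- integer(0); par <- integer(0)
    for (root in dend[!duplicated(comp$membership[dend])]) {
      bf <- igraph::bfs(g, root = root, unreachable = FALSE, father = TRUE)
      o <- suppressWarnings(as.integer(bf$order))
      fa <- suppressWarnings(as.integer(bf$father))
      o <- o[!is.na(o)]
      ord <- c(ord, o)
      par <- c(par, fa[o])
    }
    for (f in seq_len(nf)) {
      x <- frame_coords(traj, f); bx <- traj$box[f, ]
      for (k in seq_along(ord)) {
        i <- ord[k]; p <- par[k]
        if (is.na(p) || p < 1) next
        d <- x[i, ] - x[p, ]
        x[i, ] <- x[p, ] + (d - bx * round(d / bx))
      }
      coords[f, , ] <- x
    }
  }
  for (f in seq_len(nf)) {
    x <- matrix(coords[f, , ], ncol = 3)
    com <- centre_of_mass(x[dend, , drop = FALSE], mass)
    x <- sweep(x, 2, com)
    if (mode == "unwrap_center") {
      bx <- traj$box[f, ]
      free <- setdiff(seq_len(nrow(x)), dend)
      if (length(free))
        x[free, ] <- x[free, ] - sweep(round(sweep(x[free, , drop = FALSE], 2, bx, "/")), 2, bx, "*")
    }
    coords[f, , ] <- x
  }
  md_trajectory(traj$times, coords, box = NULL)
}

## ------------------------------------------------------- result tables ----

#' Write an analysis result table as CSV with a provenance header
#'
#' @param df data.frame of results.
#' @param path output CSV path.
#' @param units named character vector mapping column names to units.
#' @param provenance named list (temperature, selections, parameters...).
#' @export
write_result_table <- function(df, path, units = NULL, provenance = list()) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(provenance))
    writeLines(sprintf("# %s: %s", nm,
                       paste(format(provenance[[nm]]), collapse = " ")), con)
  if (!is.null(units))
    writeLines(paste0("# units: ",
                      paste(sprintf("%s [%s]", names(units), units),
                            collapse = ", ")), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}
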