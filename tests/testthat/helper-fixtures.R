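## Fixture builders and independent oracles shared by the test files.
## Oracles are deliberately written in the most literal style possible and
## never share code with the implementation they check.

## minimal system of free point particles
make_point_system <- function(n, mass = 1, charge = 0, role = "backbone",
                              element = "C") {
  atoms <- data.frame(
    atom_id = seq_len(n), name = paste0("X", seq_len(n)),
    element = rep(element, length.out = n),
    mass = rep(mass, length.out = n),
    charge = rep(charge, length.out = n),
    role = rep(role, length.out = n),
    residue_kind = "pt", segment_id = seq_len(n), stringsAsFactors = FALSE)
  dend <- atoms$atom_id[atoms$role != "counterion"]
  molecular_system(atoms, matrix(integer(), ncol = 2),
                   selections = list(dendrimer = dend,
                                     ions = setdiff(seq_len(n), dend),
                                     all = seq_len(n)))
}

## static trajectory replicating one coordinate frame
make_static_traj <- function(x, n_frames = 1, dt = 1) {
  x <- as.matrix(x)
  coords <- array(0, dim = c(n_frames, nrow(x), 3))
  for (f in seq_len(n_frames)) coords[f, , ] <- x
  md_trajectory((seq_len(n_frames) - 1) * dt, coords)
}

## trajectory from a list of frames
make_traj <- function(frames, dt = 1) {
  coords <- array(0, dim = c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  md_trajectory((seq_along(frames) - 1) * dt, coords)
}

## uniformly random rotation matrix (QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## ---- oracle: breadth-first search distances on an edge list ------------
bfs_oracle <- function(edges, from, to) {
  adj <- list()
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[as.character(i)]] <- c(adj[[as.character(i)]], j)
    adj[[as.character(j)]] <- c(adj[[as.character(j)]], i)
  }
  dist <- c(); dist[as.character(from)] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == to) return(unname(dist[as.character(v)]))
    for (w in adj[[as.character(v)]]) {
      if (is.null(dist[as.character(w)]) || is.na(dist[as.character(w)])) {
        dist[as.character(w)] <- dist[as.character(v)] + 1
        queue <- c(queue, w)
      }
    }
  }
  Inf
}

## ---- oracle: literal per-triple hydrogen-bond criteria -----------------
hbond_oracle <- function(x, d_id, h_id, a_id, d_cut, angle_cut) {
  ok <- logical(length(d_id))
  for (k in seq_along(d_id)) {
    D <- x[d_id[k], ]; H <- x[h_id[k], ]; A <- x[a_id[k], ]
    dda <- sqrt(sum((A - D)^2))
    v1 <- H - D; v2 <- A - D
    ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    theta <- acos(max(-1, min(1, ct))) * 180 / pi
    ok[k] <- (dda < d_cut) && (theta < angle_cut)
  }
  ok
}

## small system with explicit donors (N-H) and acceptors (O) for HB tests:
## n_don donor N atoms each with one H, n_acc acceptor O atoms
make_hbond_system <- function(n_don, n_acc, roles_don = "side_segment",
                              roles_acc = "water_oxygen") {
  n <- 2 * n_don + n_acc
  acc_names <- if (n_acc) paste0("O", seq_len(n_acc)) else character(0)
  atoms <- data.frame(
    atom_id = seq_len(n),
    name = c(rbind(paste0("N", seq_len(n_don)), paste0("H", seq_len(n_don))),
             acc_names),
    element = c(rep(c("N", "H"), n_don), rep("O", n_acc)),
    mass = c(rep(c(14, 1), n_don), rep(16, n_acc)),
    charge = 0,
    role = c(rep(roles_don, each = 2, length.out = 2 * n_don),
             rep(roles_acc, length.out = n_acc)),
    residue_kind = "hb", segment_id = seq_len(n), stringsAsFactors = FALSE)
  bonds <- cbind(seq(1, 2 * n_don, by = 2), seq(2, 2 * n_don, by = 2))
  molecular_system(atoms, bonds,
                   selections = list(dendrimer = seq_len(2 * n_don),
                                     ions = integer(), all = seq_len(n)))
}
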