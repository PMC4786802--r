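# toy-structure builders shared across the suite

toy_atoms <- function(n, chain = "A", resid = seq_len(n), name = "CA",
                      element = "C", resname = "GLY") {
  data.frame(serial = seq_len(n), name = name, element = element,
             resname = resname, resid = resid, chain = chain,
             occupancy = 1, bfactor = 0)
}

toy_structure <- function(xyz, ...) {
  xyz <- as.matrix(xyz)
  structure3d(toy_atoms(nrow(xyz), ...), xyz)
}

# random proper rotation (QR with det fix), seeded by caller
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_transform <- function(xyz, R = random_rotation(),
                            t = rnorm(3, sd = 5)) {
  sweep(xyz %*% R, 2, t, "+")
}

euler_rotation <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# two-chain toy: one residue per chain, one atom each, at distance d
pair_structure <- function(d) {
  atoms <- rbind(toy_atoms(1, chain = "A"),
                 toy_atoms(1, chain = "B"))
  atoms$serial <- 1:2
  structure3d(atoms, rbind(c(0, 0, 0), c(d, 0, 0)))
}

# trajectory in which chain A/B single-atom pair is in contact (2.5 A)
# exactly in the frames of `contact_frames`, else far (8 A)
pair_trajectory <- function(n_frames, contact_frames, dt = 10) {
  topo <- pair_structure(2.5)
  frames <- lapply(seq_len(n_frames), function(f)
    rbind(c(0, 0, 0),
          c(if (f %in% contact_frames) 2.5 else 8, 0, 0)))
  trajectory(topo, frames, dt = dt)
}

expect_close <- function(x, y, tol = 1e-8) expect_lt(max(abs(x - y)), tol)
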