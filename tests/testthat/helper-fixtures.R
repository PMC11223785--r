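# Shared fixtures and independent oracles, built in code at test time.

# hand-written 3-residue PDB content with Calpha atoms on the x axis
minimal_pdb_lines <- function() {
  c("ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  SER A   3       7.600   0.000   0.000  1.00  0.00           C",
    "TER",
    "END")
}

# the same three residues in mmCIF dialect
minimal_mmcif_lines <- function() {
  c("data_test",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_asym_id",
    "ATOM 1 C CA . ALA A 1 0.000 0.000 0.000 1 A",
    "ATOM 2 C CA . GLY A 2 3.800 0.000 0.000 2 A",
    "ATOM 3 C CA . SER A 3 7.600 0.000 0.000 3 A",
    "#")
}

# rotation about z by `deg` degrees
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0,
           sin(a),  cos(a), 0,
           0,       0,      1), 3, 3, byrow = TRUE)
}

# rotation from Euler angles (z-y-x), used by the brute-force RMSD oracle
euler_rot <- function(ang) {
  a <- ang[1]; b <- ang[2]; c <- ang[3]
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), -sin(c), 0, sin(c), cos(c)), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# independent least-RMSD oracle: derivative-free optimization over Euler
# angles (translation handled by centering), multi-start
brute_force_rmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  obj <- function(ang) {
    sqrt(mean(rowSums((Bc %*% t(euler_rot(ang)) - Ac)^2)))
  }
  starts <- as.matrix(expand.grid(c(0, pi / 2, pi, -pi / 2),
                                  c(0, pi / 2, -pi / 2),
                                  c(0, pi)))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    r <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, r$value)
  }
  best
}

# independent corner-anchored bilinear interpolation oracle (plain loops)
bilinear_oracle <- function(D, m) {
  n <- nrow(D)
  out <- matrix(0, m, m)
  interp1 <- function(v, pos) {
    lo <- min(floor(pos), n - 1)
    fr <- pos - lo
    v[lo] * (1 - fr) + v[lo + 1] * fr
  }
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      pi_ <- 1 + (i - 1) * (n - 1) / (m - 1)
      pj <- 1 + (j - 1) * (n - 1) / (m - 1)
      rows <- vapply(seq_len(n), function(r) interp1(D[r, ], pj), numeric(1))
      out[i, j] <- interp1(rows, pi_)
    }
  }
  out
}

# small well-separated 2-blob embedding tibble for classifier/cluster tests
two_blob_embeddings <- function(n_per = 25, d = 4, sep = 10, seed = 42) {
  withr::with_seed(seed, {
    X <- rbind(matrix(stats::rnorm(n_per * d, 0), n_per, d),
               matrix(stats::rnorm(n_per * d, sep), n_per, d))
    colnames(X) <- sprintf("e%02d", seq_len(d))
    dplyr::bind_cols(
      tibble::tibble(id = sprintf("Q0%03d0", seq_len(2 * n_per))),
      tibble::as_tibble(X))
  })
}

# a small mixed bag of random chains for property sweeps
random_chain <- function(n, seed) {
  kind <- seed %% 3
  if (kind == 0) make_helix(n, id = sprintf("H%04d", seed))
  else if (kind == 1) make_strand(n, id = sprintf("S%04d", seed))
  else make_coil(n, seed = seed, id = sprintf("C%04d", seed))
}
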