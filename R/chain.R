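#' Construct a protein chain from a Calpha trace
#'
#' A `protein_chain` is the minimal tertiary-structure representation used
#' throughout the package: an identifier (canonically a UniProt-style
#' accession), a one-letter amino-acid sequence, and the ordered alpha-carbon
#' coordinates in Angstrom. Side chains, heteroatoms and B-factors are out of
#' scope; every downstream stage (embedding, indexing, alignment) consumes
#' only the Calpha trace.
#'
#' @param id Character scalar identifier.
#' @param sequence One-letter amino-acid string; its length must equal the
#'   number of coordinate rows.
#' @param ca_coords Numeric n x 3 matrix of Calpha coordinates (Angstrom),
#'   ordered by residue number. `n >= 3` is required: shorter traces carry no
#'   usable tertiary-structure signal and are rejected from embedding and
#'   alignment alike.
#' @return An object of class `protein_chain`.
#' @examples
#' ch <- protein_chain("Q0TEST0", "AAA",
#'                     matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE))
#' chain_length(ch)
#' @export
protein_chain <- function(id, sequence, ca_coords) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  ca_coords <- as.matrix(ca_coords)
  storage.mode(ca_coords) <- "double"
  if (ncol(ca_coords) != 3L) {
    rlang::abort("`ca_coords` must be an n x 3 matrix of Calpha coordinates.")
  }
  n <- nrow(ca_coords)
  if (nchar(sequence) != n) {
    rlang::abort(sprintf(
      "sequence length (%d) must equal the number of coordinate rows (%d)",
      nchar(sequence), n))
  }
  if (n < 3L) {
    rlang::abort("a protein chain needs at least 3 Calpha atoms")
  }
  if (!all(is.finite(ca_coords))) {
    rlang::abort("all Calpha coordinates must be finite")
  }
  dimnames(ca_coords) <- list(NULL, c("x", "y", "z"))
  structure(list(id = id, sequence = sequence, ca_coords = ca_coords),
            class = "protein_chain")
}

#' @export
print.protein_chain <- function(x, ...) {
  cat(sprintf("<protein_chain> %s: %d residues\n", x$id, nrow(x$ca_coords)))
  cat("  sequence:", substr(x$sequence, 1L, 40L),
      if (nchar(x$sequence) > 40L) "..." else "", "\n")
  invisible(x)
}

#' Number of residues in a chain
#' @param chain A [protein_chain()].
#' @return Integer residue count.
#' @export
chain_length <- function(chain) {
  stopifnot(inherits(chain, "protein_chain"))
  nrow(chain$ca_coords)
}

#' Construct a rigid-body transform
#'
#' A proper rotation (orthonormal, determinant +1) plus a translation,
#' applied as `x' = R x + t` for column vectors. Used mainly to generate
#' rigidly moved copies of chains when testing the rotation invariance of
#' embeddings and the superposition engine.
#'
#' @param rotation 3 x 3 proper orthonormal matrix.
#' @param translation Numeric length-3 vector (Angstrom).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  storage.mode(rotation) <- "double"
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    rlang::abort("`rotation` must be orthonormal (R'R = I within 1e-9)")
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    rlang::abort("`rotation` must be proper (det = +1); reflections are not rigid motions")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Draw a uniformly random rigid transform
#'
#' Rotation sampled uniformly over SO(3) (QR of a Gaussian matrix with sign
#' correction), translation components uniform on `[-t_max, t_max]`.
#'
#' @param seed Integer seed; same seed gives the same transform.
#' @param t_max Maximum absolute translation per axis (Angstrom).
#' @return A [rigid_transform()].
#' @export
random_rigid_transform <- function(seed, t_max = 50) {
  withr::with_seed(as.integer(seed), {
    m <- matrix(stats::rnorm(9), 3L, 3L)
    qr_ <- qr(m)
    q <- qr.Q(qr_)
    d <- sign(diag(qr.R(qr_)))
    d[d == 0] <- 1
    q <- q %*% diag(d)
    if (det(q) < 0) q[, 1L] <- -q[, 1L]
    rigid_transform(q, stats::runif(3, -t_max, t_max))
  })
}

#' Apply a rigid transform to a chain
#'
#' Coordinates become `R x + t`; identifier and sequence are preserved.
#' Rigid motion is an isometry, so all pairwise Calpha distances (and hence
#' the chain's embedding) are unchanged.
#'
#' @param chain A [protein_chain()].
#' @param transform A [rigid_transform()].
#' @return The transformed [protein_chain()].
#' @export
apply_rigid_transform <- function(chain, transform) {
  stopifnot(inherits(chain, "protein_chain"))
  if (!inherits(transform, "rigid_transform")) {
    rlang::abort("`transform` must be a rigid_transform")
  }
  xyz <- chain$ca_coords %*% t(transform$rotation)
  xyz <- sweep(xyz, 2L, transform$translation, "+")
  protein_chain(chain$id, chain$sequence, xyz)
}

# ---- synthetic generators ---------------------------------------------------

#' Ideal alpha-helical Calpha trace
#'
#' Places residue i at `(r cos(i theta), r sin(i theta), i * rise)` with
#' radius 2.3 A, twist 100 degrees and rise 1.5 A per residue — the textbook
#' alpha-helix Calpha geometry (3.6 residues/turn, 5.4 A pitch). Sequence is
#' poly-alanine.
#'
#' @param n Residue count, `n >= 3`.
#' @param id Identifier for the generated chain.
#' @return A [protein_chain()].
#' @examples
#' h <- make_helix(10)
#' # consecutive Calpha-Calpha distance of an ideal helix:
#' sqrt((2 * 2.3 * sin(pi * 100 / 360))^2 + 1.5^2)
#' @export
make_helix <- function(n, id = "HELIX") {
  n <- check_count(n, min = 3L, what = "n")
  i <- seq_len(n) - 1
  theta <- 100 * pi / 180
  xyz <- cbind(2.3 * cos(i * theta), 2.3 * sin(i * theta), i * 1.5)
  protein_chain(id, strrep("A", n), xyz)
}

#' Extended (beta-strand-like) Calpha trace
#'
#' Deterministic zigzag: 3.5 A rise per residue along z with an alternating
#' +/- 0.9 A lateral offset in x, approximating the pleat of an extended
#' strand. Sequence is poly-valine.
#'
#' @inheritParams make_helix
#' @return A [protein_chain()].
#' @export
make_strand <- function(n, id = "STRAND") {
  n <- check_count(n, min = 3L, what = "n")
  i <- seq_len(n) - 1
  xyz <- cbind(0.9 * (-1)^i, 0, i * 3.5)
  protein_chain(id, strrep("V", n), xyz)
}

#' Self-avoiding random-coil Calpha trace
#'
#' A seeded self-avoiding random walk with fixed 3.8 A steps (the canonical
#' trans Calpha-Calpha distance), emulating the unstructured regions that are
#' known to bias whole-structure similarity search. A proposed step is
#' rejected when it lands within `min_sep` of any previous residue; after
#' `max_tries` rejected proposals the least-clashing proposal is accepted so
#' the walk always terminates. The generator is a pure function of
#' `(n, seed)`.
#'
#' @inheritParams make_helix
#' @param seed Integer seed.
#' @param min_sep Minimum allowed distance to any non-adjacent residue
#'   (Angstrom); default 3.0, slightly below the step length.
#' @param max_tries Proposal budget per step.
#' @return A [protein_chain()].
#' @export
make_coil <- function(n, seed, id = "COIL", min_sep = 3.0, max_tries = 100L) {
  n <- check_count(n, min = 3L, what = "n")
  step <- 3.8
  withr::with_seed(as.integer(seed), {
    xyz <- matrix(0, n, 3L)
    for (i in 2:n) {
      best <- NULL
      best_gap <- -Inf
      for (k in seq_len(max_tries)) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        cand <- xyz[i - 1L, ] + step * u
        prev <- xyz[seq_len(i - 1L), , drop = FALSE]
        gap <- min(sqrt(rowSums(sweep(prev, 2L, cand)^2))[seq_len(max(1L, i - 2L))])
        if (gap >= min_sep) {
          best <- cand
          break
        }
        if (gap > best_gap) {
          best_gap <- gap
          best <- cand
        }
      }
      xyz[i, ] <- best
    }
    protein_chain(id, strrep("G", n), xyz)
  })
}

#' Add coordinate noise to a chain
#'
#' Independent zero-mean Gaussian noise with standard deviation `sigma`
#' (Angstrom) added to every coordinate component; seeded and deterministic.
#' Used to generate structural families around a seed fold.
#'
#' @param chain A [protein_chain()].
#' @param sigma Noise standard deviation per component (Angstrom), `>= 0`.
#' @param seed Integer seed.
#' @return A perturbed [protein_chain()].
#' @export
perturb_coordinates <- function(chain, sigma, seed) {
  stopifnot(inherits(chain, "protein_chain"))
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    rlang::abort("`sigma` must be a single non-negative number")
  }
  n <- chain_length(chain)
  withr::with_seed(as.integer(seed), {
    noise <- matrix(stats::rnorm(3L * n, sd = sigma), n, 3L)
    protein_chain(chain$id, chain$sequence, chain$ca_coords + noise)
  })
}

#' Generate a labelled synthetic structure database
#'
#' Desk-scale stand-in for a large predicted-structure collection: each
#' family starts from one seed fold (helix, strand or coil, chosen at
#' random) that is given a coarse family-specific deformation
#' (`family_sigma`, default 2 Angstrom) so that two families of the same
#' secondary-structure class are still distinct folds; its members are then
#' copies with fine coordinate noise (`sigma`) placed at random rigid
#' positions. Because members share a fold up to sub-Angstrom noise while
#' families differ by several Angstrom RMSD, the set carries ground-truth
#' neighbourhood labels for recall benchmarking.
#'
#' Identifiers are generated in UniProt accession shape (`Q0xxx0`) so they
#' pass the searcher's accession detector unchanged.
#'
#' @param n_families Number of families, `>= 1`.
#' @param members_per_family Members per family, `>= 1` (the first member is
#'   the unperturbed seed fold).
#' @param length_range Integer 2-vector: inclusive residue-count range from
#'   which each family's length is drawn.
#' @param sigma Intra-family coordinate noise (Angstrom).
#' @param family_sigma Coarse fold deformation applied once per family seed
#'   chain (Angstrom); keep well above `sigma`.
#' @param seed Integer master seed; the whole database is a pure function of
#'   the arguments.
#' @return A list with elements `chains` (list of [protein_chain()]) and
#'   `labels` (tibble with columns `id`, `family`).
#' @examples
#' db <- generate_benchmark_db(3, 4, c(30, 60), sigma = 0.5, seed = 1)
#' length(db$chains)
#' db$labels
#' @export
generate_benchmark_db <- function(n_families, members_per_family,
                                  length_range = c(50L, 200L),
                                  sigma = 0.5, family_sigma = 2.0,
                                  seed = 1L) {
  n_families <- check_count(n_families, 1L, "n_families")
  members_per_family <- check_count(members_per_family, 1L, "members_per_family")
  length_range <- as.integer(round(length_range))
  if (length(length_range) != 2L || any(length_range < 3L) ||
      length_range[2L] < length_range[1L]) {
    rlang::abort("`length_range` must be an increasing pair of counts >= 3")
  }
  if (sigma < 0) rlang::abort("`sigma` must be non-negative")
  seed <- as.integer(seed)

  alphabet <- c(0:9, LETTERS)
  base36 <- function(k, width = 3L) {
    out <- character(width)
    for (j in rev(seq_len(width))) {
      out[j] <- alphabet[k %% 36L + 1L]
      k <- k %/% 36L
    }
    paste(out, collapse = "")
  }

  kinds <- c("helix", "strand", "coil")
  chains <- vector("list", n_families * members_per_family)
  ids <- character(length(chains))
  fams <- integer(length(chains))
  idx <- 0L
  withr::with_seed(seed, {
    fam_len <- sample(seq(length_range[1L], length_range[2L]),
                      n_families, replace = TRUE)
    fam_kind <- sample(kinds, n_families, replace = TRUE)
    fam_seed <- sample.int(2^20, n_families)
  })
  for (f in seq_len(n_families)) {
    seed_chain <- switch(
      fam_kind[f],
      helix = make_helix(fam_len[f]),
      strand = make_strand(fam_len[f]),
      coil = make_coil(fam_len[f], seed = fam_seed[f])
    )
    # family-specific coarse deformation: same-class families stay distinct
    seed_chain <- perturb_coordinates(seed_chain, family_sigma,
                                      seed = fam_seed[f] + 13L)
    for (m in seq_len(members_per_family)) {
      idx <- idx + 1L
      id <- paste0("Q0", base36(idx - 1L), "0")
      if (m == 1L) {
        ch <- seed_chain
      } else {
        sub_seed <- (fam_seed[f] + 7919L * m) %% .Machine$integer.max
        ch <- perturb_coordinates(seed_chain, sigma, seed = sub_seed)
        ch <- apply_rigid_transform(ch, random_rigid_transform(sub_seed + 1L))
      }
      ch$id <- id
      chains[[idx]] <- ch
      ids[idx] <- id
      fams[idx] <- f
    }
  }
  list(chains = chains,
       labels = tibble::tibble(id = ids, family = fams))
}

# internal: validate an integer count argument
check_count <- function(x, min, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    rlang::abort(sprintf("`%s` must be a single integer >= %d", what, min))
  }
  as.integer(x)
}
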