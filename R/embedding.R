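#' Pairwise Calpha distance matrix
#'
#' The n x n matrix of Euclidean distances between Calpha atoms: the
#' sequence-free summary of a chain's tertiary structure. It is exactly
#' invariant under rotation, translation and mirror reflection, which is
#' what makes the downstream embedding comparable across arbitrarily posed
#' structures (and, intrinsically, blind to chirality).
#'
#' @param chain A [protein_chain()] with at least 3 residues.
#' @return An n x n symmetric numeric matrix with zero diagonal (Angstrom).
#' @export
distance_matrix <- function(chain) {
  stopifnot(inherits(chain, "protein_chain"))
  d <- as.matrix(stats::dist(chain$ca_coords, method = "euclidean"))
  dimnames(d) <- NULL
  # exact symmetry; dist() already guarantees it, the diagonal is 0
  d
}

#' Embedding configuration
#'
#' Controls the compression of a distance matrix into a fixed-length vector.
#' The matrix is bilinearly resampled onto an `m x m` grid and the strict
#' upper triangle is flattened, giving dimension `m(m-1)/2` — 28 at the
#' default `m = 8`, i.e. roughly a hundred bytes per structure at single
#' precision, compact enough to hold hundreds of millions of embeddings in
#' memory.
#'
#' @param grid_size Resample grid side `m >= 2` (default 8).
#' @param include_diagonal Keep the resampled diagonal entries? Default
#'   `FALSE`: the resampled diagonal is near zero and carries no signal.
#' @param scale Divisor applied to the flattened values (default 1, i.e. raw
#'   Angstrom). Absolute distances are kept on purpose: global size is part
#'   of whole-structure similarity.
#' @return An object of class `embedding_config`.
#' @export
embedding_config <- function(grid_size = 8L, include_diagonal = FALSE,
                             scale = 1.0) {
  grid_size <- check_count(grid_size, 2L, "grid_size")
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  structure(list(grid_size = grid_size,
                 include_diagonal = isTRUE(include_diagonal),
                 scale = as.numeric(scale)),
            class = "embedding_config")
}

#' Dimension of embeddings under a configuration
#' @param config An [embedding_config()].
#' @return Integer embedding dimension.
#' @export
embedding_dim <- function(config = embedding_config()) {
  m <- config$grid_size
  as.integer(m * (m - 1L) / 2L + if (config$include_diagonal) m else 0L)
}

#' Bilinearly resample a square matrix onto an m x m grid
#'
#' Corner-anchored bilinear interpolation: output grid point `i` maps to the
#' continuous input index `1 + (i-1)(n-1)/(m-1)`, so the four corner samples
#' coincide exactly with the corner entries of the input. Symmetry of the
#' input is preserved (the sample grid is itself symmetric). `m > n`
#' (up-sampling) is permitted but flagged with a message, since it adds no
#' information.
#'
#' @param D An n x n numeric matrix, `n >= 2`.
#' @param m Output grid side, `>= 2`.
#' @return An m x m numeric matrix.
#' @export
resize_matrix <- function(D, m) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L || ncol(D) != n) {
    rlang::abort("`D` must be a square matrix with side >= 2")
  }
  m <- check_count(m, 2L, "m")
  if (m > n) {
    rlang::inform(sprintf("up-sampling a %d x %d matrix to %d x %d", n, n, m, m))
  }
  if (m == n) return(D)
  # continuous source index for each target grid point
  pos <- 1 + (seq_len(m) - 1) * (n - 1) / (m - 1)
  lo <- pmin(floor(pos), n - 1L)
  fr <- pos - lo
  # separable bilinear: interpolate rows then columns
  W <- matrix(0, m, n)                     # m x n row-interpolation weights
  W[cbind(seq_len(m), lo)] <- 1 - fr
  W[cbind(seq_len(m), lo + 1L)] <- W[cbind(seq_len(m), lo + 1L)] + fr
  W %*% D %*% t(W)
}

#' Embed a chain as a fixed-length vector
#'
#' The chain's Calpha distance matrix is resampled to `m x m`
#' ([resize_matrix()]) and its strict upper triangle is flattened row-major
#' (optionally with the diagonal) and divided by `scale`. The result
#' inherits the distance matrix's invariance under rigid motion and mirror
#' reflection, is deterministic, and scales linearly with a uniform scaling
#' of the coordinates.
#'
#' @param chain A [protein_chain()].
#' @param config An [embedding_config()].
#' @return A numeric vector of length [embedding_dim()] with attribute
#'   `source_id`; class `embedding`.
#' @export
embed_chain <- function(chain, config = embedding_config()) {
  stopifnot(inherits(chain, "protein_chain"))
  if (!inherits(config, "embedding_config")) {
    rlang::abort("`config` must be an embedding_config")
  }
  R <- resize_matrix(distance_matrix(chain), config$grid_size)
  m <- config$grid_size
  keep <- if (config$include_diagonal) {
    upper.tri(R, diag = TRUE)
  } else {
    upper.tri(R, diag = FALSE)
  }
  # row-major order of the upper triangle
  v <- t(R)[t(keep)] / config$scale
  structure(as.numeric(v), source_id = chain$id, class = "embedding")
}

#' Embed a list of chains into a tibble
#'
#' Order-preserving batch version of [embed_chain()]: one row per chain,
#' columns `id` then `e01 ... e<d>`. Invalid entries (anything that is not a
#' `protein_chain`) are skipped with a warning; the valid ones are still
#' embedded.
#'
#' @param chains List of [protein_chain()] objects.
#' @param config An [embedding_config()].
#' @return A tibble with one `id` column and [embedding_dim()] numeric
#'   columns.
#' @export
embed_batch <- function(chains, config = embedding_config()) {
  d <- embedding_dim(config)
  cols <- sprintf("e%02d", seq_len(d))
  ok <- vapply(chains, inherits, logical(1), what = "protein_chain")
  if (any(!ok)) {
    rlang::warn(sprintf("%d invalid chain(s) skipped in embed_batch", sum(!ok)))
  }
  chains <- chains[ok]
  if (!length(chains)) {
    out <- tibble::as_tibble(stats::setNames(
      c(list(character(0)), rep(list(numeric(0)), d)), c("id", cols)))
    return(out)
  }
  vecs <- purrr::map(chains, embed_chain, config = config)
  mat <- do.call(rbind, purrr::map(vecs, as.numeric))
  colnames(mat) <- cols
  dplyr::bind_cols(
    tibble::tibble(id = vapply(chains, function(ch) ch$id, character(1))),
    tibble::as_tibble(mat))
}

# internal: numeric matrix + ids from an embedding tibble
embedding_matrix <- function(embeddings) {
  stopifnot(is.data.frame(embeddings), "id" %in% names(embeddings))
  m <- as.matrix(embeddings[setdiff(names(embeddings), "id")])
  rownames(m) <- embeddings$id
  m
}

#' Save or load an embedding collection
#'
#' The collection is written as a single versioned binary container holding
#' the id vector and the dense embedding matrix (uncompressed, so file size
#' is linear in the number of embeddings). [write_embeddings_csv()] offers a
#' plain-text export for debugging.
#'
#' @param embeddings Embedding tibble from [embed_batch()].
#' @param path File path.
#' @return `save_embeddings()`: invisibly `path`; `load_embeddings()`: the
#'   embedding tibble.
#' @export
save_embeddings <- function(embeddings, path) {
  stopifnot(is.data.frame(embeddings), "id" %in% names(embeddings))
  container_save(list(embeddings = embeddings), "foldmatch-embeddings", path)
}

#' @rdname save_embeddings
#' @export
load_embeddings <- function(path) {
  container_load(path, "foldmatch-embeddings")$embeddings
}

#' @rdname save_embeddings
#' @export
write_embeddings_csv <- function(embeddings, path) {
  readr::write_csv(embeddings, path)
  invisible(path)
}

# ---- versioned binary container --------------------------------------------

CONTAINER_VERSION <- 1L

container_save <- function(payload, tag, path) {
  obj <- list(format = tag, version = CONTAINER_VERSION, payload = payload)
  ok <- tryCatch({
    saveRDS(obj, path, compress = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) rlang::abort(sprintf("cannot write container to %s", path))
  invisible(path)
}

container_load <- function(path, tag) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  obj <- tryCatch(readRDS(path), error = function(e) {
    rlang::abort(sprintf("unreadable container %s: %s", path,
                         conditionMessage(e)))
  })
  if (!is.list(obj) || !identical(obj$format, tag)) {
    rlang::abort(sprintf("%s is not a %s container", path, tag))
  }
  if (!identical(obj$version, CONTAINER_VERSION)) {
    rlang::abort(sprintf(
      "container version mismatch in %s: found %s, this build reads %d",
      path, format(obj$version), CONTAINER_VERSION))
  }
  obj$payload
}
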