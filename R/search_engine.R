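#' Search configuration
#'
#' The staged-retrieval constants of the query workflow: after the index
#' probe, candidates are ranked by Euclidean embedding distance and cut at
#' `candidate_cap` (1000); the `first_page` nearest (50) get full structural
#' scores immediately, and the page can be expanded by one of the
#' `expansion_steps` (50, 100, 200 or 300 more).
#'
#' @param candidate_cap Maximum candidates kept after ranking (default 1000).
#' @param first_page Hits scored structurally on the first pass (default 50).
#' @param expansion_steps Allowed expansion increments (default
#'   `c(50, 100, 200, 300)`).
#' @param n_probe Clusters probed per query (default 10).
#' @return An object of class `search_config`.
#' @export
search_config <- function(candidate_cap = 1000L, first_page = 50L,
                          expansion_steps = c(50L, 100L, 200L, 300L),
                          n_probe = 10L) {
  candidate_cap <- check_count(candidate_cap, 1L, "candidate_cap")
  first_page <- check_count(first_page, 1L, "first_page")
  if (first_page > candidate_cap) {
    rlang::abort("`first_page` cannot exceed `candidate_cap`")
  }
  expansion_steps <- vapply(expansion_steps, check_count, integer(1),
                            min = 1L, what = "expansion_steps")
  structure(list(candidate_cap = candidate_cap, first_page = first_page,
                 expansion_steps = as.integer(expansion_steps),
                 n_probe = check_count(n_probe, 1L, "n_probe")),
            class = "search_config")
}

# ---- identifier mapping -----------------------------------------------------

# the official UniProt accession pattern (6- and 10-character forms)
UNIPROT_RE <- paste0(
  "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$")
PDB_RE <- "^[0-9][A-Z0-9]{3}$"

#' Load offline identifier-mapping tables
#'
#' Reads two-column tab-separated files mapping PDB ids and gene symbols to
#' UniProt accessions (the internal key of the search engine). Keys are
#' case-normalized to upper case. Either table may be omitted.
#'
#' @param pdb_path Path to a TSV with columns `pdb`, `uniprot` (no header
#'   required; first column PDB id, second accession).
#' @param gene_path Path to a TSV with columns gene symbol, accession.
#' @return An object of class `id_mapping_table`.
#' @export
read_id_mapping <- function(pdb_path = NULL, gene_path = NULL) {
  read_two_col <- function(path) {
    if (is.null(path)) return(tibble::tibble(key = character(), value = character()))
    tb <- readr::read_tsv(path, col_names = c("key", "value"),
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    tb$key <- toupper(tb$key)
    tb$value <- toupper(tb$value)
    tb
  }
  structure(list(pdb_to_uniprot = read_two_col(pdb_path),
                 gene_to_uniprot = read_two_col(gene_path)),
            class = "id_mapping_table")
}

#' Build a mapping table from data frames (for offline/synthetic use)
#' @param pdb_to_uniprot,gene_to_uniprot Two-column data frames
#'   (`key`, `value`).
#' @return An `id_mapping_table`.
#' @export
id_mapping_table <- function(pdb_to_uniprot = NULL, gene_to_uniprot = NULL) {
  norm <- function(tb) {
    if (is.null(tb)) return(tibble::tibble(key = character(), value = character()))
    tb <- tibble::as_tibble(tb)
    names(tb)[1:2] <- c("key", "value")
    tb$key <- toupper(tb$key)
    tb$value <- toupper(tb$value)
    tb
  }
  structure(list(pdb_to_uniprot = norm(pdb_to_uniprot),
                 gene_to_uniprot = norm(gene_to_uniprot)),
            class = "id_mapping_table")
}

#' Resolve a query token to a UniProt accession
#'
#' Classification follows the order in which the three accepted input forms
#' are tried: a token matching the official UniProt accession pattern is
#' returned as-is; a 4-character PDB-shaped token is looked up in the PDB
#' table; anything else is treated as a gene symbol. One-to-many mappings
#' resolve to the lexicographically smallest accession, with the
#' alternatives noted in a message.
#'
#' @param token Non-empty query string (case-insensitive).
#' @param table An [id_mapping_table()].
#' @return The canonical accession (upper case).
#' @export
resolve_identifier <- function(token, table = id_mapping_table()) {
  stopifnot(is.character(token), length(token) == 1L)
  token <- toupper(trimws(token))
  if (!nzchar(token)) rlang::abort("empty query token")
  if (!inherits(table, "id_mapping_table")) {
    rlang::abort("`table` must be an id_mapping_table")
  }
  if (grepl(UNIPROT_RE, token)) return(token)
  lookup <- function(tb, key) sort(unique(tb$value[tb$key == key]))
  tried <- "UniProt accession"
  if (grepl(PDB_RE, token)) {
    tried <- c(tried, "PDB id")
    hits <- lookup(table$pdb_to_uniprot, token)
    if (length(hits)) {
      if (length(hits) > 1L) {
        rlang::inform(sprintf("PDB id %s maps to %d accessions; using %s (others: %s)",
                              token, length(hits), hits[1L],
                              paste(hits[-1L], collapse = ", ")))
      }
      return(hits[1L])
    }
  }
  tried <- c(tried, "gene symbol")
  hits <- lookup(table$gene_to_uniprot, token)
  if (length(hits)) {
    if (length(hits) > 1L) {
      rlang::inform(sprintf("gene symbol %s maps to %d accessions; using %s (others: %s)",
                            token, length(hits), hits[1L],
                            paste(hits[-1L], collapse = ", ")))
    }
    return(hits[1L])
  }
  rlang::abort(sprintf("no mapping found for '%s' (tried: %s)",
                       token, paste(tried, collapse = ", ")))
}

# ---- chain store ------------------------------------------------------------

#' Build a chain store
#'
#' Holds the indexed chains by id, optional per-accession organism metadata,
#' and the engine's session cache (computed rankings and alignment metrics
#' are stored so that repeating a query does not recompute them; the
#' `alignments_computed` counter makes the caching observable).
#'
#' @param chains List of [protein_chain()] objects with unique ids.
#' @param metadata Optional data frame with columns `id`, `organism`.
#' @return An object of class `chain_store` (environment-backed; the cache
#'   mutates in place).
#' @export
chain_store <- function(chains, metadata = NULL) {
  ids <- vapply(chains, function(ch) ch$id, character(1))
  if (anyDuplicated(ids)) rlang::abort("chain ids must be unique")
  names(chains) <- ids
  if (!is.null(metadata)) {
    metadata <- tibble::as_tibble(metadata)
    stopifnot(all(c("id", "organism") %in% names(metadata)))
  }
  env <- new.env(parent = emptyenv())
  env$chains <- chains
  env$metadata <- metadata
  env$cache <- new.env(parent = emptyenv())
  env$counters <- new.env(parent = emptyenv())
  env$counters$alignments_computed <- 0L
  class(env) <- "chain_store"
  env
}

#' @export
print.chain_store <- function(x, ...) {
  cat(sprintf("<chain_store> %d chains, %d cached entries\n",
              length(x$chains), length(ls(x$cache))))
  invisible(x)
}

#' Read a two-column organism metadata table (accession TAB organism)
#' @param path TSV path.
#' @return Tibble with columns `id`, `organism`.
#' @export
read_metadata_table <- function(path) {
  tb <- readr::read_tsv(path, col_names = c("id", "organism"),
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  tb$id <- toupper(tb$id)
  tb
}

# internal counters
bump_counter <- function(store, name) {
  store$counters[[name]] <- (store$counters[[name]] %||% 0L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of structural alignments computed by a store so far
#' @param store A [chain_store()].
#' @return Integer counter (cache hits do not increment it).
#' @export
alignment_counter <- function(store) {
  store$counters$alignments_computed %||% 0L
}

# ---- ranking ----------------------------------------------------------------

#' Rank candidates by Euclidean embedding distance
#'
#' Hits are sorted by ascending distance to the query embedding (ties by
#' ascending id) and truncated at the candidate cap.
#'
#' @param query Embedding vector.
#' @param candidates Tibble with `id` plus embedding columns (as from
#'   [gather_candidates()]).
#' @param cap Maximum number of hits kept (default 1000).
#' @return Tibble `id`, `embedding_distance`, sorted.
#' @export
rank_candidates <- function(query, candidates, cap = 1000L) {
  cap <- check_count(cap, 1L, "cap")
  q <- as.numeric(query)
  X <- embedding_matrix(candidates)
  if (ncol(X) != length(q)) {
    rlang::abort(sprintf("query dimension %d does not match candidate dimension %d",
                         length(q), ncol(X)))
  }
  d <- unname(sqrt(pmax(rowSums(sweep(X, 2L, q)^2), 0)))
  out <- tibble::tibble(id = candidates$id, embedding_distance = d)
  out <- dplyr::arrange(out, .data$embedding_distance, .data$id)
  utils::head(out, cap)
}

# ---- search sessions --------------------------------------------------------

# internal: cache key for one scored pair under one scorer configuration
scorer_digest <- function(params) {
  paste(format(c(params$gap_penalty, params$max_iterations,
                 params$convergence_tol), digits = 17), collapse = "|")
}

# internal: compute (or fetch) alignment metrics for rows `rows` of a ranked
# hit tibble; returns the tibble with metric columns filled for those rows
score_hits <- function(hits, rows, query_chain, store) {
  for (r in rows) {
    target_id <- hits$id[r]
    params <- tm_params(l_norm = chain_length(query_chain))
    key <- paste(query_chain$id, target_id, scorer_digest(params), sep = "\r")
    cached <- store$cache[[key]]
    if (is.null(cached)) {
      target <- store$chains[[target_id]]
      if (is.null(target)) {
        rlang::abort(sprintf("hit %s is not present in the chain store", target_id))
      }
      res <- align_chains(query_chain, target, params)
      bump_counter(store, "alignments_computed")
      cached <- list(tm_score = res$tm_score, rmsd = res$rmsd,
                     aligned_residues = res$aligned_count,
                     sequence_identity = res$seq_identity)
      store$cache[[key]] <- cached
    }
    hits$tm_score[r] <- cached$tm_score
    hits$rmsd[r] <- cached$rmsd
    hits$aligned_residues[r] <- cached$aligned_residues
    hits$sequence_identity[r] <- cached$sequence_identity
  }
  hits
}

#' Run the full similarity-search workflow for one query
#'
#' Orchestrates the staged pipeline: resolve the token to an accession, embed
#' the query chain, route the embedding to the `n_probe` most promising
#' clusters, collect their contents, rank them by Euclidean embedding
#' distance under the candidate cap, score the first page of hits with the
#' structural aligner (TM-score, RMSD, aligned residues, sequence identity),
#' and attach organism metadata where available. Rankings and per-pair
#' metrics are cached in the store, so repeating a query is served without
#' recomputation.
#'
#' @param query_token UniProt accession, PDB id, or gene symbol.
#' @param index A [build_index()] result over the store's chains.
#' @param store A [chain_store()].
#' @param table An [id_mapping_table()] for non-accession tokens.
#' @param config A [search_config()].
#' @param embedding_cfg The [embedding_config()] the index was built with.
#' @return A `search_session`: tibble of ranked hits (`hits`), the query id,
#'   and the number of structurally scored hits (`scored_count`, the scored
#'   hits being a prefix of the ranking).
#' @export
search <- function(query_token, index, store, table = id_mapping_table(),
                   config = search_config(),
                   embedding_cfg = embedding_config()) {
  stopifnot(inherits(index, "learned_index"), inherits(store, "chain_store"),
            inherits(config, "search_config"))
  query_id <- resolve_identifier(query_token, table)
  query_chain <- store$chains[[query_id]]
  if (is.null(query_chain)) {
    rlang::abort(sprintf(
      "accession %s resolved but its structure is not in the chain store", query_id))
  }
  rank_key <- paste("rank", query_id, config$n_probe, config$candidate_cap,
                    sep = "\r")
  hits <- store$cache[[rank_key]]
  if (is.null(hits)) {
    q <- embed_chain(query_chain, embedding_cfg)
    clusters <- probe(index, q, n_probe = min(config$n_probe,
                                              index$config$n_clusters))
    candidates <- gather_candidates(index, clusters)
    hits <- rank_candidates(q, candidates, cap = config$candidate_cap)
    hits$tm_score <- NA_real_
    hits$rmsd <- NA_real_
    hits$aligned_residues <- NA_integer_
    hits$sequence_identity <- NA_real_
    hits$organism <- NA_character_
    if (!is.null(store$metadata)) {
      idx <- match(hits$id, store$metadata$id)
      hits$organism <- store$metadata$organism[idx]
    }
    store$cache[[rank_key]] <- hits
  }
  scored <- min(config$first_page, nrow(hits))
  hits <- score_hits(hits, seq_len(scored), query_chain, store)
  store$cache[[rank_key]] <- hits
  structure(list(query_id = query_id, hits = hits, scored_count = scored,
                 config = config, store = store),
            class = "search_session")
}

#' @export
print.search_session <- function(x, ...) {
  cat(sprintf("<search_session> query %s: %d candidates, %d scored\n",
              x$query_id, nrow(x$hits), x$scored_count))
  print(utils::head(dplyr::filter(x$hits, !is.na(.data$tm_score)), 10L))
  invisible(x)
}

#' Expand a search session by scoring more ranked hits
#'
#' Structural metrics are computed for the next `increment` hits down the
#' ranking (clamped at the candidate count); previously scored hits are
#' untouched. Only the configured increments are accepted.
#'
#' @param session A [search()] result.
#' @param increment One of the session's configured expansion steps
#'   (by default 50, 100, 200 or 300).
#' @return The expanded `search_session`.
#' @export
expand_session <- function(session, increment) {
  stopifnot(inherits(session, "search_session"))
  increment <- check_count(increment, 1L, "increment")
  allowed <- session$config$expansion_steps
  if (!increment %in% allowed) {
    rlang::abort(sprintf("increment %d not allowed; choose one of: %s",
                         increment, paste(allowed, collapse = ", ")))
  }
  new_scored <- min(session$scored_count + increment, nrow(session$hits))
  if (new_scored > session$scored_count) {
    query_chain <- session$store$chains[[session$query_id]]
    session$hits <- score_hits(session$hits,
                               (session$scored_count + 1L):new_scored,
                               query_chain, session$store)
    session$scored_count <- new_scored
  }
  session
}

#' Export the scored hits of a session as CSV
#'
#' Fixed schema, one row per scored hit in rank order:
#' `query_id,result_id,embedding_distance,tm_score,rmsd,aligned_residues,sequence_identity,organism`.
#' Unscored hits are excluded; missing organisms export as empty fields.
#'
#' @param session A [search()] result with at least one scored hit.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
export_csv <- function(session, path) {
  stopifnot(inherits(session, "search_session"))
  if (session$scored_count < 1L) {
    rlang::abort("session has no scored hits to export")
  }
  rows <- utils::head(session$hits, session$scored_count)
  out <- tibble::tibble(
    query_id = session$query_id,
    result_id = rows$id,
    embedding_distance = rows$embedding_distance,
    tm_score = rows$tm_score,
    rmsd = rows$rmsd,
    aligned_residues = rows$aligned_residues,
    sequence_identity = rows$sequence_identity,
    organism = rows$organism)
  ok <- tryCatch({
    readr::write_csv(out, path, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) rlang::abort(sprintf("cannot write CSV to %s", path))
  invisible(path)
}

#' Group scored hits by organism
#'
#' Scored hits are partitioned by organism label (missing labels fall into
#' `"unknown"`); within each group the rank order is preserved, and groups
#' are ordered by their best (smallest) member distance.
#'
#' @param session A [search()] result.
#' @return Named list of hit tibbles.
#' @export
group_by_organism <- function(session) {
  stopifnot(inherits(session, "search_session"))
  rows <- utils::head(session$hits, session$scored_count)
  org <- ifelse(is.na(rows$organism) | !nzchar(rows$organism),
                "unknown", rows$organism)
  groups <- split(rows, org)
  best <- vapply(groups, function(g) min(g$embedding_distance), numeric(1))
  groups[order(best)]
}
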