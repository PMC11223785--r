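#' Brute-force exact nearest neighbours in embedding space
#'
#' The oracle the approximate engine is benchmarked against: exhaustive
#' Euclidean ranking of every indexed embedding (ties by ascending id).
#'
#' @param query Embedding vector.
#' @param embeddings Embedding tibble (full collection).
#' @param k Number of neighbours to return.
#' @return Tibble `id`, `embedding_distance`, the exact `k` nearest.
#' @export
brute_force_neighbors <- function(query, embeddings, k = 10L) {
  rank_candidates(query, embeddings, cap = k)
}

#' Recall of the learned index against brute force
#'
#' For a seeded sample of query embeddings drawn from the collection,
#' measures recall@k: the fraction of each query's true k nearest
#' neighbours (by exhaustive search) that appear among the candidates
#' retrieved through the learned index at a given probe width. Averaged
#' over queries, per `n_probe` value.
#'
#' Because probing more clusters only ever grows the candidate set (the
#' probe list is a prefix of the classifier's cluster ranking), recall is
#' non-decreasing in `n_probe`; `n_probe = K` scans everything and reaches
#' recall 1 exactly.
#'
#' @param index A [build_index()] result.
#' @param embeddings The full embedding tibble the index was built on.
#' @param n_probe_values Integer vector of probe widths to sweep.
#' @param k_values Recall depths to report (default `c(1, 10, 50)`).
#' @param n_queries Number of query points sampled from the collection.
#' @param seed Seed for the query sample.
#' @return Tibble with columns `n_probe`, `k`, `recall`, `n_queries`;
#'   class `recall_report`.
#' @export
recall_benchmark <- function(index, embeddings,
                             n_probe_values = c(1L, 2L, 5L, 10L, 20L,
                                                index$config$n_clusters),
                             k_values = c(1L, 10L, 50L),
                             n_queries = 50L, seed = 1L) {
  stopifnot(inherits(index, "learned_index"))
  X <- embedding_matrix(embeddings)
  n <- nrow(X)
  n_probe_values <- sort(unique(pmin(as.integer(n_probe_values),
                                     index$config$n_clusters)))
  k_values <- sort(unique(as.integer(k_values)))
  qi <- withr::with_seed(as.integer(seed), sample.int(n, min(n_queries, n)))
  max_k <- max(k_values)

  truth <- purrr::map(qi, function(i) {
    brute_force_neighbors(X[i, ], embeddings, k = max_k)$id
  })
  probes <- purrr::map(qi, function(i) {
    probe(index, X[i, ], n_probe = index$config$n_clusters)
  })
  member_cluster <- index$labels
  names(member_cluster) <- embeddings$id

  rows <- list()
  for (np in n_probe_values) {
    for (k in k_values) {
      rec <- purrr::map2_dbl(truth, probes, function(tr, pr) {
        probed <- pr[seq_len(np)]
        tr_k <- tr[seq_len(min(k, length(tr)))]
        mean(member_cluster[tr_k] %in% probed)
      })
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n_probe = np, k = k, recall = mean(rec), n_queries = length(qi))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("recall_report", class(out))
  out
}
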