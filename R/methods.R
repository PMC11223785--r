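#' Tidy an alignment result
#'
#' One row per aligned residue pair: indices into the query and target
#' chains and the post-superposition Calpha distance.
#'
#' @param x An `alignment_result` from [align_chains()].
#' @param ... Unused.
#' @return A tibble with columns `query_pos`, `target_pos`, `distance`.
#' @method tidy alignment_result
#' @export
tidy.alignment_result <- function(x, ...) {
  tibble::tibble(
    query_pos = x$pairs[, 1L],
    target_pos = x$pairs[, 2L],
    distance = x$pair_distances)
}

#' Summarise an alignment result in one row
#' @param x An `alignment_result`.
#' @param ... Unused.
#' @return One-row tibble: `query_id`, `target_id`, `tm_score`, `rmsd`,
#'   `aligned_count`, `seq_identity`.
#' @method glance alignment_result
#' @export
glance.alignment_result <- function(x, ...) {
  tibble::tibble(query_id = x$query_id, target_id = x$target_id,
                 tm_score = x$tm_score, rmsd = x$rmsd,
                 aligned_count = x$aligned_count,
                 seq_identity = x$seq_identity)
}

#' Tidy a learned index: one row per cluster
#' @param x A `learned_index`.
#' @param ... Unused.
#' @return Tibble `cluster`, `size`.
#' @method tidy learned_index
#' @export
tidy.learned_index <- function(x, ...) {
  tibble::tibble(cluster = seq_len(x$config$n_clusters),
                 size = vapply(x$buckets, function(b) length(b$ids), integer(1)))
}

#' One-row summary of a learned index
#' @param x A `learned_index`.
#' @param ... Unused.
#' @return Tibble `n`, `dim`, `n_clusters`, `n_probe`,
#'   `classifier_train_accuracy`.
#' @method glance learned_index
#' @export
glance.learned_index <- function(x, ...) {
  tibble::tibble(n = x$n, dim = x$dim,
                 n_clusters = x$config$n_clusters,
                 n_probe = x$config$n_probe,
                 classifier_train_accuracy = x$classifier$train_accuracy)
}

#' Tidy a search session: the ranked (scored) hit table
#' @param x A `search_session`.
#' @param ... Unused.
#' @return Tibble of scored hits with rank column.
#' @method tidy search_session
#' @export
tidy.search_session <- function(x, ...) {
  out <- utils::head(x$hits, x$scored_count)
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
}

#' One-row summary of a search session
#' @param x A `search_session`.
#' @param ... Unused.
#' @return Tibble `query_id`, `candidates`, `scored_count`, `best_tm_score`.
#' @method glance search_session
#' @export
glance.search_session <- function(x, ...) {
  scored <- utils::head(x$hits, x$scored_count)
  tibble::tibble(query_id = x$query_id, candidates = nrow(x$hits),
                 scored_count = x$scored_count,
                 best_tm_score = suppressWarnings(max(scored$tm_score,
                                                      na.rm = TRUE)))
}

#' Plot a recall sweep
#'
#' Recall against probe width, one line per recall depth k, on a log-scaled
#' probe axis.
#'
#' @param object A `recall_report` from [recall_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recall_report
#' @export
autoplot.recall_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n_probe, y = .data$recall,
                               colour = factor(.data$k))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10(breaks = unique(object$n_probe)) +
    ggplot2::labs(x = "clusters probed", y = "recall vs brute force",
                  colour = "k") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a search session's score landscape
#'
#' Embedding distance against TM-score for the scored hits: close embedding
#' neighbours should score high, so the cloud falling from top-left to
#' bottom-right is the expected signature of a healthy index.
#'
#' @param object A `search_session`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot search_session
#' @export
autoplot.search_session <- function(object, ...) {
  df <- tidy.search_session(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$embedding_distance,
                                   y = .data$tm_score)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "embedding distance", y = "TM-score (query-normalized)",
                  title = sprintf("query %s", object$query_id)) +
    ggplot2::theme_minimal()
}
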