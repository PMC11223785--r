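#' Learned-index configuration
#'
#' @param n_clusters Number of k-means partitions `K` (default 64, a
#'   desk-scale value; at production scale this is a free capacity knob).
#' @param n_probe How many top-scoring clusters a query retrieves
#'   (default 10); trades recall against candidate-set size.
#' @param classifier_hidden Integer vector of hidden-layer widths for the
#'   routing network (default one layer of 128).
#' @param epochs Training epochs (default 50).
#' @param learning_rate Adam step size (default 0.005).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Integer seed governing clustering initialization, network
#'   initialization and batch shuffling.
#' @return An object of class `index_config`.
#' @export
index_config <- function(n_clusters = 64L, n_probe = 10L,
                         classifier_hidden = 128L, epochs = 50L,
                         learning_rate = 0.005, batch_size = 32L,
                         seed = 1L) {
  n_clusters <- check_count(n_clusters, 1L, "n_clusters")
  n_probe <- check_count(n_probe, 1L, "n_probe")
  if (n_probe > n_clusters) {
    rlang::abort("`n_probe` cannot exceed `n_clusters`")
  }
  classifier_hidden <- vapply(classifier_hidden, check_count, integer(1),
                              min = 1L, what = "classifier_hidden")
  structure(list(n_clusters = n_clusters, n_probe = n_probe,
                 classifier_hidden = as.integer(classifier_hidden),
                 epochs = check_count(epochs, 1L, "epochs"),
                 learning_rate = as.numeric(learning_rate),
                 batch_size = check_count(batch_size, 1L, "batch_size"),
                 seed = as.integer(seed)),
            class = "index_config")
}

# ---- k-means ----------------------------------------------------------------

# internal: k-means++ seeding, deterministic under the active RNG state
kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(0, K, ncol(X))
  first <- sample.int(n, 1L)
  centers[1L, ] <- X[first, ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  if (K > 1L) {
    for (k in 2:K) {
      p <- d2 / sum(d2)
      if (!all(is.finite(p)) || sum(d2) == 0) {
        pick <- sample.int(n, 1L)
      } else {
        pick <- sample.int(n, 1L, prob = p)
      }
      centers[k, ] <- X[pick, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[k, ])^2))
    }
  }
  centers
}

# internal: squared distances from every row of X to every centroid
dist2_to_centers <- function(X, centers) {
  outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * X %*% t(centers)
}

#' Cluster embeddings with k-means (k-means++ seeding)
#'
#' Lloyd iterations from a k-means++ start, fully deterministic given
#' `seed`. A cluster that empties during an iteration is re-seeded with the
#' point currently farthest from its assigned centroid, so the partition
#' always has exactly `K` non-degenerate cells. Every embedding ends up
#' assigned to its nearest final centroid.
#'
#' @param embeddings Embedding tibble from [embed_batch()] (or any data
#'   frame with an `id` column plus numeric columns).
#' @param K Number of clusters, `1 <= K <= n`.
#' @param seed Integer seed.
#' @param max_iter Lloyd iteration cap.
#' @return List with `centroids` (K x d matrix) and `labels` (integer
#'   vector in `1..K`, one per row of `embeddings`).
#' @export
fit_clusters <- function(embeddings, K, seed = 1L, max_iter = 100L) {
  X <- embedding_matrix(embeddings)
  n <- nrow(X)
  K <- check_count(K, 1L, "K")
  if (K > n) {
    rlang::abort(sprintf("K (%d) cannot exceed the number of embeddings (%d)", K, n))
  }
  withr::with_seed(as.integer(seed), {
    centers <- kmeanspp_init(X, K)
    labels <- integer(n)
    for (it in seq_len(max_iter)) {
      d2 <- dist2_to_centers(X, centers)
      new_labels <- max.col(-d2, ties.method = "first")
      # refill empties with the worst-assigned point (deterministic)
      empty <- setdiff(seq_len(K), unique(new_labels))
      for (k in empty) {
        worst <- which.max(d2[cbind(seq_len(n), new_labels)])
        centers[k, ] <- X[worst, ]
        new_labels[worst] <- k
        d2[, k] <- rowSums(sweep(X, 2L, centers[k, ])^2)
      }
      if (identical(new_labels, labels)) break
      labels <- new_labels
      for (k in seq_len(K)) {
        centers[k, ] <- colMeans(X[labels == k, , drop = FALSE])
      }
    }
    # final assignment: nearest centroid, guaranteed
    d2 <- dist2_to_centers(X, centers)
    labels <- max.col(-d2, ties.method = "first")
    list(centroids = centers, labels = labels)
  })
}

# ---- feed-forward softmax classifier ---------------------------------------

# internal: initialise MLP weights (He-style), deterministic under RNG state
mlp_init <- function(d_in, hidden, K) {
  sizes <- c(d_in, hidden, K)
  layers <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * sizes[l + 1L], sd = sqrt(2 / fan_in)),
                 fan_in, sizes[l + 1L]),
      b = rep(0, sizes[l + 1L]))
  }
  layers
}

# internal: forward pass; returns softmax probabilities and hidden activations
mlp_forward <- function(layers, X) {
  acts <- list(X)
  A <- X
  nl <- length(layers)
  for (l in seq_len(nl)) {
    Z <- sweep(A %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    if (l < nl) {
      A <- pmax(Z, 0)       # rectifier
      acts[[l + 1L]] <- A
    } else {
      Z <- Z - apply(Z, 1L, max)
      E <- exp(Z)
      P <- E / rowSums(E)
      return(list(probs = P, acts = acts))
    }
  }
}

#' Train the cluster-routing classifier
#'
#' A fully connected network (input dimension d, rectifier hidden layers,
#' K-way softmax output) trained with cross-entropy loss and Adam on the
#' cluster labels produced by [fit_clusters()]. Inputs are standardized with
#' the training mean/sd (stored in the model). Training is deterministic
#' given `config$seed`.
#'
#' @param embeddings Embedding tibble (same rows that were clustered).
#' @param labels Integer cluster labels in `1..K` from [fit_clusters()].
#' @param config An [index_config()].
#' @return An object of class `cluster_classifier` with a `predict()`
#'   method returning a row-stochastic K-column probability matrix.
#' @export
train_classifier <- function(embeddings, labels, config = index_config()) {
  X <- embedding_matrix(embeddings)
  n <- nrow(X)
  K <- config$n_clusters
  labels <- as.integer(labels)
  if (length(labels) != n) {
    rlang::abort("`labels` must have one entry per embedding")
  }
  if (any(labels < 1L) || any(labels > K)) {
    rlang::abort(sprintf("labels must lie in 1..%d", K))
  }
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), labels)] <- 1

  withr::with_seed(config$seed, {
    layers <- mlp_init(ncol(X), config$classifier_hidden, K)
    nl <- length(layers)
    mom <- purrr::map(layers, function(l) {
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    })
    lr <- config$learning_rate
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (idx in batches) {
        step <- step + 1L
        Xb <- Xs[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        fw <- mlp_forward(layers, Xb)
        delta <- (fw$probs - Yb) / length(idx)
        for (l in rev(seq_len(nl))) {
          gW <- crossprod(fw$acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- (delta %*% t(layers[[l]]$W)) * (fw$acts[[l]] > 0)
          }
          m <- mom[[l]]
          m$mW <- beta1 * m$mW + (1 - beta1) * gW
          m$vW <- beta2 * m$vW + (1 - beta2) * gW^2
          m$mb <- beta1 * m$mb + (1 - beta1) * gb
          m$vb <- beta2 * m$vb + (1 - beta2) * gb^2
          mom[[l]] <- m
          corr1 <- 1 - beta1^step
          corr2 <- 1 - beta2^step
          layers[[l]]$W <- layers[[l]]$W -
            lr * (m$mW / corr1) / (sqrt(m$vW / corr2) + eps)
          layers[[l]]$b <- layers[[l]]$b -
            lr * (m$mb / corr1) / (sqrt(m$vb / corr2) + eps)
        }
      }
    }
    fit <- mlp_forward(layers, Xs)$probs
    acc <- mean(max.col(fit, ties.method = "first") == labels)
    structure(list(layers = layers, mu = mu, sd = sdv, K = K,
                   train_accuracy = acc, config = config),
              class = "cluster_classifier")
  })
}

#' @export
print.cluster_classifier <- function(x, ...) {
  cat(sprintf("<cluster_classifier> d=%d -> [%s] -> K=%d, train acc %.3f\n",
              length(x$mu), paste(x$config$classifier_hidden, collapse = ","),
              x$K, x$train_accuracy))
  invisible(x)
}

#' Predict cluster-relevance probabilities
#'
#' @param object A `cluster_classifier`.
#' @param newdata Embedding tibble, numeric matrix, or a single embedding
#'   vector.
#' @param ... Unused.
#' @return Row-stochastic matrix (rows sum to 1) of K cluster scores.
#' @export
predict.cluster_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "embedding")) newdata <- matrix(as.numeric(newdata), 1L)
  if (is.data.frame(newdata)) newdata <- embedding_matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(as.numeric(newdata), 1L)
  if (ncol(newdata) != length(object$mu)) {
    rlang::abort(sprintf("embedding dimension %d does not match classifier input %d",
                         ncol(newdata), length(object$mu)))
  }
  Xs <- sweep(sweep(newdata, 2L, object$mu), 2L, object$sd, "/")
  mlp_forward(object$layers, Xs)$probs
}

# ---- index build / probe ----------------------------------------------------

#' Build the learned index
#'
#' Composition of [fit_clusters()] and [train_classifier()] plus bucket
#' filling: every embedding is stored in the bucket of its nearest centroid,
#' and the classifier learns to route a query embedding to the buckets most
#' likely to contain its neighbours. Deterministic given `config$seed`.
#'
#' @param embeddings Embedding tibble from [embed_batch()].
#' @param config An [index_config()].
#' @return An object of class `learned_index`.
#' @export
build_index <- function(embeddings, config = index_config()) {
  stopifnot(inherits(config, "index_config"))
  fit <- fit_clusters(embeddings, config$n_clusters, seed = config$seed)
  classifier <- train_classifier(embeddings, fit$labels, config)
  X <- embedding_matrix(embeddings)
  buckets <- purrr::map(seq_len(config$n_clusters), function(k) {
    rows <- which(fit$labels == k)
    list(ids = embeddings$id[rows],
         embeddings = X[rows, , drop = FALSE])
  })
  structure(list(centroids = fit$centroids,
                 labels = fit$labels,
                 buckets = buckets,
                 classifier = classifier,
                 config = config,
                 n = nrow(X),
                 dim = ncol(X)),
            class = "learned_index")
}

#' @export
print.learned_index <- function(x, ...) {
  cat(sprintf("<learned_index> %d embeddings (d=%d) in %d clusters, n_probe=%d\n",
              x$n, x$dim, x$config$n_clusters, x$config$n_probe))
  invisible(x)
}

#' Route a query to its most promising clusters
#'
#' The classifier scores all K clusters for the query embedding; the
#' `n_probe` highest-scoring cluster ids are returned in descending score
#' order (ties broken by ascending cluster id, for reproducibility).
#'
#' @param index A [build_index()] result.
#' @param query An embedding vector ([embed_chain()]) or numeric vector of
#'   matching dimension.
#' @param n_probe Number of clusters to return; defaults to the index
#'   configuration (10).
#' @return Integer vector of `n_probe` cluster ids.
#' @export
probe <- function(index, query, n_probe = NULL) {
  stopifnot(inherits(index, "learned_index"))
  if (is.null(n_probe)) n_probe <- index$config$n_probe
  n_probe <- check_count(n_probe, 1L, "n_probe")
  K <- index$config$n_clusters
  if (n_probe > K) rlang::abort("`n_probe` cannot exceed the cluster count")
  q <- as.numeric(query)
  if (length(q) != index$dim) {
    rlang::abort(sprintf("query dimension %d does not match index dimension %d",
                         length(q), index$dim))
  }
  scores <- as.numeric(predict(index$classifier, q))
  ord <- order(-scores, seq_len(K))
  ord[seq_len(n_probe)]
}

#' Collect the candidate contents of a set of clusters
#'
#' @param index A [build_index()] result.
#' @param cluster_ids Integer cluster ids (as from [probe()]).
#' @return Tibble with `id` plus the embedding columns; one row per indexed
#'   item in the named buckets, no duplicates.
#' @export
gather_candidates <- function(index, cluster_ids) {
  stopifnot(inherits(index, "learned_index"))
  cluster_ids <- as.integer(cluster_ids)
  K <- index$config$n_clusters
  if (!length(cluster_ids)) {
    d <- index$dim
    return(tibble::as_tibble(stats::setNames(
      c(list(character(0)), rep(list(numeric(0)), d)),
      c("id", sprintf("e%02d", seq_len(d))))))
  }
  if (any(cluster_ids < 1L) || any(cluster_ids > K) || anyDuplicated(cluster_ids)) {
    rlang::abort(sprintf("cluster ids must be distinct and in 1..%d", K))
  }
  ids <- unlist(purrr::map(index$buckets[cluster_ids], "ids"), use.names = FALSE)
  mats <- purrr::map(index$buckets[cluster_ids], "embeddings")
  X <- do.call(rbind, mats)
  colnames(X) <- sprintf("e%02d", seq_len(index$dim))
  dplyr::bind_cols(tibble::tibble(id = ids), tibble::as_tibble(X))
}

#' Persist or restore a learned index
#'
#' Single versioned binary container holding centroids, bucket membership,
#' classifier weights and the configuration. A container whose format tag or
#' version does not match raises a load error; a reloaded index reproduces
#' [probe()] results bit-identically.
#'
#' @param index A [build_index()] result.
#' @param path File path.
#' @return `save_index()`: invisibly `path`; `load_index()`: the
#'   `learned_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "learned_index"))
  container_save(unclass(index), "foldmatch-index", path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  payload <- container_load(path, "foldmatch-index")
  structure(payload, class = "learned_index")
}
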