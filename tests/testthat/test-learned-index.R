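test_that("k-means: K=1 gives the coordinate-wise mean; blobs split exactly", {
  tb <- two_blob_embeddings()
  fit1 <- fit_clusters(tb, K = 1, seed = 1)
  X <- as.matrix(tb[, -1])
  expect_equal(as.numeric(fit1$centroids), colMeans(X), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(fit1$labels, rep(1L, nrow(tb)))
  # two well-separated blobs, K = 2: partition recovers the blobs and every
  # point sits with its nearest centroid (brute-force check)
  fit2 <- fit_clusters(tb, K = 2, seed = 1)
  truth <- rep(1:2, each = 25)
  expect_true(all(table(fit2$labels, truth) %in% c(0L, 25L)))
  d2 <- as.matrix(dist(rbind(fit2$centroids, X)))[-(1:2), 1:2]
  expect_equal(fit2$labels, apply(d2, 1, which.min), ignore_attr = TRUE)
  # agreement with the reference k-means objective on well-behaved data
  wss <- function(labels, X) {
    sum(vapply(unique(labels), function(k) {
      xk <- X[labels == k, , drop = FALSE]
      sum(sweep(xk, 2, colMeans(xk))^2)
    }, numeric(1)))
  }
  km <- withr::with_seed(1, stats::kmeans(X, centers = 2, nstart = 10))
  expect_equal(wss(fit2$labels, X), km$tot.withinss, tolerance = 1e-6)
})

test_that("k-means is deterministic and validates K", {
  tb <- two_blob_embeddings()
  expect_identical(fit_clusters(tb, 5, seed = 9)$labels,
                   fit_clusters(tb, 5, seed = 9)$labels)
  expect_error(fit_clusters(tb, 51, seed = 1), "cannot exceed")
  # K equal to n is degenerate but legal: every point its own centroid
  fitn <- fit_clusters(tb[1:8, ], 8, seed = 2)
  expect_equal(sort(fitn$labels), 1:8)
})

test_that("classifier reaches perfect held-in accuracy on separable blobs", {
  tb <- two_blob_embeddings()
  fit <- fit_clusters(tb, 2, seed = 1)
  cfg <- index_config(n_clusters = 2, n_probe = 1, seed = 4)
  clf <- train_classifier(tb, fit$labels, cfg)
  expect_gte(clf$train_accuracy, 1.0)
  P <- predict(clf, tb)
  expect_equal(dim(P), c(50L, 2L))
  expect_true(all(P >= 0))
  expect_equal(unname(rowSums(P)), rep(1, 50), tolerance = 1e-6)
  # determinism: same config + seed -> identical predictions
  clf2 <- train_classifier(tb, fit$labels, cfg)
  expect_identical(predict(clf2, tb), P)
  # label validation
  expect_error(train_classifier(tb, fit$labels + 5L, cfg), "labels must lie")
})

test_that("built index satisfies its structural invariants", {
  db <- generate_benchmark_db(6, 12, c(30, 60), seed = 21)
  emb <- embed_batch(db$chains)
  cfg <- index_config(n_clusters = 10, n_probe = 3, seed = 5)
  idx <- build_index(emb, cfg)
  sizes <- tidy(idx)$size
  # conservation: every id in exactly one bucket
  expect_equal(sum(sizes), 72)
  all_ids <- unlist(purrr::map(idx$buckets, "ids"))
  expect_equal(sort(all_ids), sort(emb$id))
  expect_false(anyDuplicated(all_ids) > 0)
  # bucket membership is nearest-centroid by construction
  X <- as.matrix(emb[, -1])
  d2 <- outer(rowSums(X^2), rowSums(idx$centroids^2), "+") -
    2 * X %*% t(idx$centroids)
  expect_equal(idx$labels, max.col(-d2, ties.method = "first"))
  # rebuild with the same seed is identical
  idx2 <- build_index(emb, cfg)
  expect_identical(purrr::map(idx$buckets, "ids"), purrr::map(idx2$buckets, "ids"))
  expect_identical(idx$centroids, idx2$centroids)
  g <- glance(idx)
  expect_equal(g$n, 72L)
  expect_equal(g$n_clusters, 10L)
})

test_that("probe returns the top clusters, deterministically tie-broken", {
  tb <- two_blob_embeddings()
  idx <- build_index(tb, index_config(n_clusters = 4, n_probe = 2, seed = 6))
  q <- as.numeric(tb[1, -1])
  # n_probe = K is a permutation of all cluster ids
  expect_setequal(probe(idx, q, n_probe = 4), 1:4)
  expect_length(probe(idx, q, n_probe = 2), 2)
  # a training point's own cluster ranks first on separable data
  own <- idx$labels[1]
  expect_equal(probe(idx, q, n_probe = 1), own)
  expect_error(probe(idx, q, n_probe = 5), "cannot exceed")
  expect_error(probe(idx, c(1, 2), ), "dimension")
  # ties (identical scores) break by ascending cluster id: a uniform-score
  # classifier stub must return 1..n_probe
  idx_stub <- idx
  idx_stub$classifier$layers <- purrr::map(idx_stub$classifier$layers,
                                           function(l) {
                                             l$W <- l$W * 0
                                             l$b <- l$b * 0
                                             l
                                           })
  expect_equal(probe(idx_stub, q, n_probe = 3), 1:3)
})

test_that("gather_candidates concatenates buckets without duplication", {
  db <- generate_benchmark_db(5, 10, c(30, 50), seed = 3)
  emb <- embed_batch(db$chains)
  idx <- build_index(emb, index_config(n_clusters = 8, n_probe = 3, seed = 2))
  sizes <- tidy(idx)$size
  all50 <- gather_candidates(idx, 1:8)
  expect_equal(sort(all50$id), sort(emb$id))
  empty <- gather_candidates(idx, integer(0))
  expect_equal(nrow(empty), 0)
  some <- gather_candidates(idx, c(2, 5))
  expect_equal(nrow(some), sizes[2] + sizes[5])
  expect_false(anyDuplicated(some$id) > 0)
  expect_error(gather_candidates(idx, 9), "cluster ids")
  expect_error(gather_candidates(idx, c(1, 1)), "distinct")
})

test_that("probing a fixed share of uniform clusters yields that share of data", {
  # near-uniform synthetic embeddings: probing 10 of 64 equal-ish clusters
  # returns roughly 10/64 of the collection
  withr::with_seed(10, {
    X <- matrix(runif(1280 * 6), 1280, 6)
    colnames(X) <- sprintf("e%02d", 1:6)
    tb <- dplyr::bind_cols(tibble::tibble(id = sprintf("U%04d", 1:1280)),
                           tibble::as_tibble(X))
  })
  idx <- build_index(tb, index_config(n_clusters = 64, n_probe = 10,
                                      epochs = 20, seed = 8))
  got <- nrow(gather_candidates(idx, probe(idx, as.numeric(tb[5, -1]))))
  frac <- got / 1280
  expect_gt(frac, 10 / 64 / 3)
  expect_lt(frac, 3 * 10 / 64)
})

test_that("index container round-trips probes and rejects bad headers", {
  db <- generate_benchmark_db(4, 10, c(30, 50), seed = 17)
  emb <- embed_batch(db$chains)
  idx <- build_index(emb, index_config(n_clusters = 6, n_probe = 2, seed = 2))
  f <- withr::local_tempfile(fileext = ".bin")
  save_index(idx, f)
  idx2 <- load_index(f)
  X <- as.matrix(emb[, -1])
  for (i in seq(1, 40, by = 2)) {   # 20 fixed queries
    expect_identical(probe(idx2, X[i, ], n_probe = 6),
                     probe(idx, X[i, ], n_probe = 6))
  }
  # version bump in the header -> explicit load error
  obj <- readRDS(f)
  obj$version <- 999L
  saveRDS(obj, f)
  expect_error(load_index(f), "version mismatch")
  # foreign tag
  saveRDS(list(format = "other", version = 1L), f)
  expect_error(load_index(f), "not a")
})

test_that("index file size grows linearly with the indexed count", {
  sizes <- vapply(c(100L, 200L, 300L), function(n) {
    withr::with_seed(n, {
      X <- matrix(runif(n * 8), n, 8)
      colnames(X) <- sprintf("e%02d", 1:8)
      tb <- dplyr::bind_cols(tibble::tibble(id = sprintf("U%04d", 1:n)),
                             tibble::as_tibble(X))
    })
    idx <- build_index(tb, index_config(n_clusters = 4, n_probe = 2,
                                        epochs = 5, seed = 1))
    f <- withr::local_tempfile(fileext = ".bin")
    save_index(idx, f)
    file.size(f)
  }, numeric(1))
  expect_true(all(diff(sizes) > 0))
  # increments agree within 25% (fixed overhead aside, growth is linear)
  expect_lt(abs(diff(diff(sizes))), 0.25 * diff(sizes)[1])
})
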