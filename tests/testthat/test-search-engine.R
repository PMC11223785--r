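# shared small corpus for the search tests: 5 families x 10 members
local({
  db <<- generate_benchmark_db(5, 10, c(30, 60), sigma = 0.5, seed = 2)
  emb <<- embed_batch(db$chains)
  idx <<- build_index(emb, index_config(n_clusters = 8, n_probe = 3, seed = 3))
})

test_that("identifier resolution tries accession, PDB id, then gene symbol", {
  tbl <- id_mapping_table(
    pdb_to_uniprot = data.frame(key = c("1ABC", "2XYZ", "2XYZ"),
                                value = c("Q00001", "P33333", "P11111")),
    gene_to_uniprot = data.frame(key = c("HBA1", "MYG"),
                                 value = c("P69905", "P02144")))
  # accession-shaped tokens pass through, case-normalized
  expect_equal(resolve_identifier("P69905", tbl), "P69905")
  expect_equal(resolve_identifier("p69905", tbl), "P69905")
  expect_equal(resolve_identifier("A0A2G9QLR9", tbl), "A0A2G9QLR9")
  # PDB ids look up
  expect_equal(resolve_identifier("1abc", tbl), "Q00001")
  # one-to-many resolves to the lexicographically smallest, with a note
  expect_message(hit <- resolve_identifier("2XYZ", tbl), "others: P33333")
  expect_equal(hit, "P11111")
  # gene symbols look up
  expect_equal(resolve_identifier("hba1", tbl), "P69905")
  # misses name the attempted categories
  expect_error(resolve_identifier("NOPE123", tbl), "gene symbol")
  expect_error(resolve_identifier("9ZZZ", tbl), "PDB id")
  expect_error(resolve_identifier("", tbl), "empty")
})

test_that("mapping and metadata tables load from delimited text", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1abc\tq00001", "hba1\tp69905"), f)
  tbl <- read_id_mapping(pdb_path = f, gene_path = f)
  expect_equal(resolve_identifier("1ABC", tbl), "Q00001")
  expect_equal(resolve_identifier("HBA1", tbl), "P69905")
  m <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q00001\tHomo sapiens", "p69905\tMus musculus"), m)
  meta <- read_metadata_table(m)
  expect_equal(meta$id, c("Q00001", "P69905"))
  expect_equal(meta$organism[1], "Homo sapiens")
})

test_that("rank_candidates sorts by distance with id tie-break and cap", {
  cand <- tibble::tibble(id = c("a", "b", "c"),
                         e01 = c(1, 0, 3), e02 = c(0, 2, 0))
  hits <- rank_candidates(c(0, 0), cand, cap = 10)
  expect_equal(hits$id, c("a", "b", "c"))
  expect_equal(hits$embedding_distance, c(1, 2, 3))
  # ties break by id
  tie <- tibble::tibble(id = c("z", "y"), e01 = c(1, 1), e02 = c(0, 0))
  expect_equal(rank_candidates(c(0, 0), tie, cap = 10)$id, c("y", "z"))
  # cap truncates: 5000 uniform candidates, default cap -> exactly 1000
  withr::with_seed(1, {
    big <- tibble::tibble(id = sprintf("U%05d", 1:5000),
                          e01 = runif(5000), e02 = runif(5000))
  })
  expect_equal(nrow(rank_candidates(c(0.5, 0.5), big)), 1000)
  # query equal to one candidate -> that candidate first at distance 0
  expect_equal(rank_candidates(c(3, 0), cand, 10)$id[1], "c")
  expect_equal(rank_candidates(c(3, 0), cand, 10)$embedding_distance[1], 0)
  expect_error(rank_candidates(c(1, 2, 3), cand, 5), "dimension")
})

test_that("search retrieves the query itself at rank 1 with full scores", {
  store <- chain_store(db$chains)
  cfg <- search_config(candidate_cap = 100, first_page = 5, n_probe = 8)
  qid <- db$chains[[13]]$id
  s <- search(qid, idx, store, config = cfg)
  expect_s3_class(s, "search_session")
  expect_equal(s$hits$id[1], qid)
  expect_equal(s$hits$embedding_distance[1], 0)
  expect_equal(s$hits$tm_score[1], 1.0, tolerance = 1e-9)
  expect_equal(s$scored_count, 5)
  expect_true(all(diff(s$hits$embedding_distance) >= 0))
  # unknown accession and absent structure produce distinct errors
  expect_error(search("Q9ZZZ9", idx, store, config = cfg), "not in the chain store")
  expect_error(search("totally-unknown", idx, store, config = cfg), "no mapping")
})

test_that("repeated searches are served from the session cache", {
  store <- chain_store(db$chains)
  cfg <- search_config(candidate_cap = 100, first_page = 5, n_probe = 8)
  qid <- db$chains[[7]]$id
  s1 <- search(qid, idx, store, config = cfg)
  n1 <- alignment_counter(store)
  expect_equal(n1, 5L)
  s2 <- search(qid, idx, store, config = cfg)
  expect_identical(alignment_counter(store), n1)  # zero new alignments
  expect_equal(s2$hits, s1$hits)                  # cached == fresh
})

test_that("expansion scores further ranked hits in allowed increments", {
  store <- chain_store(db$chains)
  cfg <- search_config(candidate_cap = 100, first_page = 5, n_probe = 8,
                       expansion_steps = c(5L, 10L, 50L, 100L))
  s <- search(db$chains[[1]]$id, idx, store, config = cfg)
  s10 <- expand_session(s, 10)
  expect_equal(s10$scored_count, 15)
  # previously scored rows untouched
  expect_equal(utils::head(s10$hits, 5), utils::head(s$hits, 5))
  # clamped at candidate count, no error
  s_all <- expand_session(expand_session(s10, 100), 100)
  expect_equal(s_all$scored_count, nrow(s_all$hits))
  expect_error(expand_session(s, 37), "not allowed")
  # expansion order does not change the scored set: 5 then 10 == 10 then 5
  store_a <- chain_store(db$chains)
  store_b <- chain_store(db$chains)
  sa <- expand_session(expand_session(
    search(db$chains[[1]]$id, idx, store_a, config = cfg), 5), 10)
  sb <- expand_session(expand_session(
    search(db$chains[[1]]$id, idx, store_b, config = cfg), 10), 5)
  expect_equal(sa$scored_count, sb$scored_count)
  expect_equal(sa$hits, sb$hits)
})

test_that("CSV export has the fixed schema, rank order and empty missing fields", {
  meta <- tibble::tibble(id = db$labels$id[1:25],
                         organism = rep(c("Homo sapiens", "Mus musculus",
                                          "Zea mays", "Equus caballus",
                                          "Danio rerio"), 5))
  store <- chain_store(db$chains, metadata = meta)
  cfg <- search_config(candidate_cap = 100, first_page = 10, n_probe = 8)
  s <- search(db$chains[[2]]$id, idx, store, config = cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  export_csv(s, f)
  lines <- readLines(f)
  expect_equal(lines[1], paste0("query_id,result_id,embedding_distance,",
                                "tm_score,rmsd,aligned_residues,",
                                "sequence_identity,organism"))
  expect_length(lines, 11)  # header + 10 scored rows
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(back$result_id, utils::head(s$hits$id, 10))
  expect_equal(round(back$tm_score, 4),
               round(utils::head(s$hits$tm_score, 10), 4))
  # every exported id exists among the candidates, no duplicates
  expect_true(all(back$result_id %in% s$hits$id))
  expect_false(anyDuplicated(back$result_id) > 0)
  # hits without metadata export an empty organism field, not a crash
  raw <- strsplit(lines[-1], ",")
  norg <- sum(vapply(raw, length, integer(1)) == 7)  # trailing empty field
  expect_equal(norg, sum(is.na(utils::head(s$hits$organism, 10))))
  expect_error(export_csv(s, file.path(tempdir(), "no", "dir", "x.csv")),
               "cannot write")
})

test_that("organism grouping preserves rank order within groups", {
  meta <- tibble::tibble(id = db$labels$id,
                         organism = rep_len(c("A", "A", "B", NA), 50))
  store <- chain_store(db$chains, metadata = meta)
  cfg <- search_config(candidate_cap = 50, first_page = 10, n_probe = 8)
  s <- search(db$chains[[4]]$id, idx, store, config = cfg)
  groups <- group_by_organism(s)
  expect_true(all(names(groups) %in% c("A", "B", "unknown")))
  # within-group distances ascending; groups ordered by best member
  for (g in groups) expect_true(all(diff(g$embedding_distance) >= 0))
  best <- vapply(groups, function(g) g$embedding_distance[1], numeric(1))
  expect_true(all(diff(best) >= 0))
  # flattening and re-sorting reproduces the original scored ranking
  flat <- dplyr::arrange(dplyr::bind_rows(groups), embedding_distance, id)
  expect_equal(flat$id, utils::head(s$hits$id, 10))
  # all-missing metadata gives the single "unknown" group
  store2 <- chain_store(db$chains)
  s2 <- search(db$chains[[4]]$id, idx, store2, config = cfg)
  expect_named(group_by_organism(s2), "unknown")
})

test_that("probing all clusters reproduces brute-force ranking end to end", {
  store <- chain_store(db$chains)
  cfg <- search_config(candidate_cap = 50, first_page = 3, n_probe = 8)
  for (qi in c(3, 27, 44)) {
    qid <- db$chains[[qi]]$id
    s <- search(qid, idx, store, config = cfg)
    oracle <- rank_candidates(embed_chain(db$chains[[qi]]), emb, cap = 50)
    expect_identical(s$hits$id, oracle$id)
    expect_equal(s$hits$embedding_distance, oracle$embedding_distance)
  }
})

test_that("session accessors tidy/glance/autoplot work", {
  store <- chain_store(db$chains)
  cfg <- search_config(candidate_cap = 20, first_page = 5, n_probe = 8)
  s <- search(db$chains[[11]]$id, idx, store, config = cfg)
  td <- tidy(s)
  expect_equal(nrow(td), 5)
  expect_equal(td$rank, 1:5)
  g <- glance(s)
  expect_equal(g$scored_count, 5L)
  expect_equal(g$best_tm_score, 1, tolerance = 1e-9)
  p <- ggplot2::autoplot(s)
  expect_s3_class(p, "ggplot")
})
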