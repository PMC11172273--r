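small_collection <- function(seed = 5) {
  v <- mdf_vocabulary()
  ssm <- fixture_ssm(v, seed = seed)
  cfg <- synth_config(n_docs = 60, n_queries = 5, seed = seed)
  list(vocab = v, ssm = ssm, coll = generate_collection(cfg, v, ssm))
}

test_that("bm25 scoring matches hand arithmetic and saturates in tf", {
  corpus <- tibble::tibble(id = "d1", text = "cancer")
  idx <- bm25_index(corpus)
  expect_equal(bm25_score(c("cancer"), c("cancer"), idx), log(4 / 3),
               tolerance = 1e-12)
  expect_equal(bm25_score(c("mri"), c("cancer"), idx), 0)

  corpus2 <- tibble::tibble(id = c("d1", "d2"),
                            text = c("cancer cancer cancer lung lung lung",
                                     "lung lung lung lung lung lung"))
  idx2 <- bm25_index(corpus2)
  s1 <- bm25_score("cancer", rep("cancer", 1), idx2)
  s2 <- bm25_score("cancer", rep("cancer", 2), idx2)
  s3 <- bm25_score("cancer", rep("cancer", 5), idx2)
  expect_true(s1 < s2 && s2 < s3)  # non-decreasing in tf
})

test_that("bm25 search ranks by score with deterministic ties", {
  corpus <- tibble::tibble(id = c("db", "da", "dc"),
                           text = c("cancer lung", "cancer lung", "bone"))
  idx <- bm25_index(corpus)
  q <- tibble::tibble(id = "q1", text = "cancer")
  run <- bm25_search(q, idx, k = 10)
  expect_equal(run$doc_id, c("da", "db"))  # equal scores: id ascending
  expect_equal(run$rank, c(1L, 2L))
  expect_equal(nrow(bm25_search(q, idx, k = 1)), 1)
  # K beyond corpus returns all scored documents
  expect_equal(nrow(bm25_search(q, idx, k = 100)), 2)
})

test_that("cosine matching handles identity, orthogonality and zero norms", {
  expect_equal(rsv_cosine(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rsv_cosine(c(1, 0), c(0, 1)), 0)
  expect_equal(rsv_cosine(c(1, 1, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 0)),
               1 / sqrt(2), tolerance = 1e-12)
  expect_equal(rsv_cosine(rep(0, 6), c(1, 0, 0, 0, 0, 0)), 0)
})

test_that("dmm score is bounded, zero for MDF-free queries, and deterministic", {
  sc <- small_collection()
  ca <- annotate_corpus(sc$coll$corpus, sc$vocab)
  st <- corpus_statistics(ca$ann)
  qa <- mdf_annotate(sc$coll$queries$text[1], sc$vocab)
  da <- ca$ann[[1]]

  self <- dmm_score(qa, qa, sc$ssm, st, doc_rank = 1L)
  expect_gte(self, 0); expect_lte(self, 1)

  empty_q <- mdf_annotate("no features here", sc$vocab)
  expect_equal(dmm_score(empty_q, da, sc$ssm, st, 1L), 0)

  s1 <- dmm_score(qa, da, sc$ssm, st, 3L)
  s2 <- dmm_score(qa, da, sc$ssm, st, 3L)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("fusion matches a brute-force oracle on random score tables", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    ids <- sprintf("d%02d", sample(50, n))
    base <- tibble::tibble(query_id = "q", doc_id = sort(ids),
                           rank = seq_len(n),
                           score = sort(round(runif(n, 0, 5), 3),
                                        decreasing = TRUE),
                           tag = "BM25")
    dmm <- stats::setNames(round(runif(n), 3), base$doc_id)
    alpha <- sample(c(0, 0.3, 0.5, 1), 1)
    got <- semrank_fuse(base, dmm, alpha = alpha)

    # ten-line oracle
    bn <- if (max(base$score) > 0) base$score / max(base$score) else rep(0, n)
    dn <- if (max(dmm) > 0) dmm[base$doc_id] / max(dmm) else rep(0, n)
    fused <- alpha * bn + (1 - alpha) * dn
    ord <- order(-fused, -base$score, base$doc_id)
    expect_equal(got$doc_id, base$doc_id[ord])
    expect_equal(got$score, unname(fused[ord]), tolerance = 1e-12)
    expect_true(all(got$score >= 0 & got$score <= 1))
  }
})

test_that("fusion limits reproduce each component's ordering", {
  base <- tibble::tibble(query_id = "q", doc_id = c("a", "b", "c"),
                         rank = 1:3, score = c(3, 2, 1), tag = "BM25")
  dmm <- c(a = 0.1, b = 0.9, c = 0.5)
  expect_equal(semrank_fuse(base, dmm, alpha = 1)$doc_id, c("a", "b", "c"))
  expect_equal(semrank_fuse(base, dmm, alpha = 0)$doc_id, c("b", "c", "a"))
  # normalized components 1.0 and 0.5 fuse to 0.65 at alpha = 0.3
  f <- semrank_fuse(base, c(a = 0.5, b = 1, c = 0.2), alpha = 0.3)
  expect_equal(f$score[f$doc_id == "a"], 0.3 * 1 + 0.7 * 0.5,
               tolerance = 1e-12)
  expect_warning(semrank_fuse(base, c(a = 1, zz = 1), alpha = 0.3), "absent")
})

test_that("reranking permutes the baseline candidate set deterministically", {
  sc <- small_collection()
  rr1 <- semrank_rerank(sc$coll$corpus, sc$coll$queries, sc$ssm, sc$vocab,
                        cfg = semrank_config(alpha = 0.3, depth = 50))
  rr2 <- semrank_rerank(sc$coll$corpus, sc$coll$queries, sc$ssm, sc$vocab,
                        cfg = semrank_config(alpha = 0.3, depth = 50))
  expect_identical(rr1$run, rr2$run)
  for (q in unique(rr1$baseline$query_id)) {
    expect_setequal(rr1$run$doc_id[rr1$run$query_id == q],
                    rr1$baseline$doc_id[rr1$baseline$query_id == q])
  }
  # alpha = 1 reproduces the baseline ordering
  rr_b <- semrank_fuse(rr1$baseline, rr1$dmm, alpha = 1)
  expect_equal(rr_b$doc_id, rr1$baseline$doc_id)
  expect_equal(rr_b$rank, rr1$baseline$rank)
})
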