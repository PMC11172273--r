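qrels_of <- function(...) {
  ids <- c(...)
  tibble::tibble(query_id = "q1", doc_id = ids, rel = 1L)
}

run_of <- function(ids, qid = "q1") {
  tibble::tibble(query_id = qid, doc_id = ids, rank = seq_along(ids),
                 score = rev(seq_along(ids)), tag = "t")
}

test_that("precision and average precision match hand-worked cases", {
  qr <- qrels_of("d1", "d3")
  ranked <- c("d1", "d2", "d3", "d4", "d5")
  expect_equal(precision_at_k(ranked, qr, "q1", 5), 0.4)
  expect_equal(precision_at_k(c("d2", "d4"), qr, "q1", 5), 0)
  expect_equal(precision_at_k(c("d1", "d3"), qrels_of("d1", "d3"), "q1", 2), 1)
  # short list still divides by k
  expect_equal(precision_at_k(c("d1"), qr, "q1", 5), 0.2)

  expect_equal(average_precision(ranked, qr, "q1"), (1 + 2 / 3) / 2,
               tolerance = 1e-12)
  expect_equal(average_precision(c("d1", "d3"), qr, "q1"), 1)
  expect_equal(average_precision(c("d2", "d4"), qr, "q1"), 0)
  expect_equal(average_precision(ranked, qrels_of("zz"), "q1"), 0)
})

test_that("MAP averages per-query AP over evaluable queries", {
  qr <- dplyr::bind_rows(qrels_of("d1", "d3"),
                         tibble::tibble(query_id = "q2", doc_id = "d9", rel = 1L))
  run <- dplyr::bind_rows(run_of(c("d1", "d3")),                  # AP 1
                          run_of(c("d8", "d9"), qid = "q2"))      # AP 0.5
  expect_equal(mean_average_precision(run, qr), 0.75)
  expect_equal(mean_average_precision(run[c(3, 4, 1, 2), ], qr), 0.75)
  single <- run_of(c("d1", "d2", "d3"))
  expect_equal(mean_average_precision(single, qrels_of("d1", "d3")),
               average_precision(c("d1", "d2", "d3"), qrels_of("d1", "d3"), "q1"))
  expect_error(suppressWarnings(
    mean_average_precision(run_of("d1"), qrels_of("zz")[0, ])),
    "no evaluable")
  # unjudged queries are skipped with a warning
  run3 <- dplyr::bind_rows(run, run_of("d1", qid = "q3"))
  expect_warning(m <- mean_average_precision(run3, qr), "skipping")
  expect_equal(m, 0.75)
})

test_that("metrics agree with the reference implementation on random instances", {
  set.seed(404)
  for (i in 1:100) {
    n_docs <- sample(5:30, 1)
    ids <- sprintf("d%03d", seq_len(n_docs))
    ranked <- sample(ids, sample(3:n_docs, 1))
    rel_ids <- sample(ids, sample(1:n_docs, 1))
    qr <- tibble::tibble(query_id = "q1", doc_id = rel_ids, rel = 1L)
    k <- sample(1:15, 1)
    expect_equal(precision_at_k(ranked, qr, "q1", k),
                 ref_precision_at_k(ranked, rel_ids, k), tolerance = 1e-9)
    expect_equal(average_precision(ranked, qr, "q1"),
                 ref_average_precision(ranked, rel_ids), tolerance = 1e-9)
  }
})

test_that("metrics are invariant to consistent doc id relabeling", {
  set.seed(9)
  ids <- sprintf("d%02d", 1:20)
  ranked <- sample(ids, 12)
  rel_ids <- sample(ids, 5)
  qr <- tibble::tibble(query_id = "q1", doc_id = rel_ids, rel = 1L)
  relabel <- stats::setNames(sprintf("x%02d", sample(99, 20)), ids)
  qr2 <- dplyr::mutate(qr, doc_id = unname(relabel[doc_id]))
  expect_equal(average_precision(unname(relabel[ranked]), qr2, "q1"),
               average_precision(ranked, qr, "q1"))
  expect_equal(precision_at_k(unname(relabel[ranked]), qr2, "q1", 5),
               precision_at_k(ranked, qr, "q1", 5))
})

test_that("run comparison pairs queries and applies the Wilcoxon test", {
  set.seed(15)
  qids <- sprintf("q%02d", 1:10)
  qr <- purrr::map_dfr(qids, function(q)
    tibble::tibble(query_id = q, doc_id = c("d1", "d2"), rel = 1L))
  good <- purrr::map_dfr(qids, function(q) run_of(c("d1", "d2", "d3"), qid = q))
  bad <- purrr::map_dfr(qids, function(q) run_of(c("d3", "d4", "d1", "d2"), qid = q))

  same <- compare_runs(good, good, qr)
  expect_equal(same$per_query$delta, rep(0, 10))
  expect_false(same$significant)
  expect_match(same$reason, "non-zero")

  cmp <- compare_runs(bad, good, qr)  # B strictly better on all 10 queries
  expect_true(all(cmp$per_query$delta > 0))
  expect_lt(cmp$p_value, 0.05)
  expect_true(cmp$significant)
  expect_gt(cmp$improvement_rate, 0)

  swap <- compare_runs(good, bad, qr)
  expect_equal(swap$per_query$delta, -cmp$per_query$delta)
  expect_equal(swap$p_value, cmp$p_value, tolerance = 1e-12)

  expect_s3_class(tidy(cmp), "tbl_df")
  expect_equal(nrow(glance(cmp)), 1)
})

test_that("run and qrels files round-trip through TREC formats", {
  run <- run_of(c("d1", "d2", "d3"))
  p <- withr::local_tempfile(fileext = ".txt")
  write_run(run, p)
  expect_equal(read_run(p), run, tolerance = 1e-10)
  qr <- qrels_of("d1", "d3")
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_qrels(qr, p2)
  expect_equal(read_qrels(p2), qr)
  ev <- evaluate_run(run, qr)
  expect_s3_class(glance(ev), "tbl_df")
  expect_equal(ev$map, average_precision(c("d1", "d2", "d3"), qr, "q1"))
})
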