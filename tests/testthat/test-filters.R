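# All hand-worked examples use the reference corpus: D1=[a,b], D2=[b,c],
# D3=[a,c,d] over vocabulary a..d (indices 1..4).

ctx_of <- function(Q, D, rank = NA_integer_) {
  ref <- ref_corpus()
  filter_context(new_annotation(Q, 4), new_annotation(D, 4), ref$stats, rank)
}

test_that("query filters reproduce the hand-worked reference values", {
  expect_equal(co_qf(ctx_of(1L, c(2L, 3L))), 0.5)         # (1+1)/4
  expect_equal(co_qf(ctx_of(4L, c(1L, 2L))), 0.25)        # (1+0)/4
  expect_equal(co_qf(ctx_of(1L, integer(0))), 0)

  expect_equal(l_qf(ctx_of(1L, c(1L, 2L))), 0.5)
  expect_equal(l_qf(ctx_of(c(1L, 3L, 4L), c(1L, 3L, 4L))), 1)
  expect_equal(l_qf(ctx_of(c(1L, 2L), c(1L, 3L, 4L))), 0) # b missing from D3

  expect_equal(r_qf(ctx_of(1L, 1L, rank = 1L)), 1)
  expect_equal(r_qf(ctx_of(1L, 1L, rank = 4L)), 0.25)
  expect_equal(r_qf(ctx_of(1L, 1L)), 0)                   # absent from baseline

  expect_equal(p_qf(ctx_of(c(1L, 4L), c(1L, 3L, 4L))), 0.5)  # one feature between
  expect_equal(p_qf(ctx_of(1L, c(1L, 2L))), 1)               # single occurrence
  expect_equal(p_qf(ctx_of(4L, c(1L, 2L))), 0)

  expect_equal(pmi_qf(ctx_of(1L, c(2L, 3L))), log(0.75), tolerance = 1e-12)
  expect_equal(pmi_qf(ctx_of(4L, c(1L, 2L))), log(1.5), tolerance = 1e-12)
  expect_equal(pmi_qf(ctx_of(4L, 2L)), 0)                 # b,d never co-occur

  expect_equal(fd_qf(ctx_of(1L, c(1L, 2L))), 1)
  expect_equal(fd_qf(ctx_of(c(1L, 2L, 4L), c(1L, 2L))), 0.5)
  expect_equal(fd_qf(ctx_of(c(2L, 3L, 4L), integer(0))), 0.25)
  # printed-formula variant counts the intersection instead
  expect_equal(fd_qf(ctx_of(1L, c(1L, 2L)), variant = "intersection"), 0.5)
})

test_that("document filters reproduce the hand-worked reference values", {
  expect_equal(co_df(ctx_of(c(1L, 2L), c(1L, 3L, 4L))), 1)
  expect_equal(co_df(ctx_of(4L, c(1L, 2L))), 0)
  expect_equal(co_df(ctx_of(c(1L, 3L, 4L), c(1L, 3L, 4L))), 3)

  expect_equal(l_df(ctx_of(c(1L, 4L), c(1L, 3L, 4L))), 2 / 3)
  expect_equal(l_df(ctx_of(1L, integer(0))), 0)
  expect_equal(l_df(ctx_of(c(1L, 2L, 3L), c(1L, 2L))), 1)

  expect_equal(r_df(ctx_of(c(1L, 3L), c(1L, 3L, 4L))), 2)   # order preserved
  expect_equal(r_df(ctx_of(c(3L, 1L), c(1L, 3L, 4L))), 1)   # order violated
  expect_equal(r_df(ctx_of(2L, c(1L, 3L, 4L))), 0)

  expect_equal(p_df(ctx_of(c(1L, 4L), c(1L, 3L, 4L))), 0.5)
  expect_equal(p_df(ctx_of(1L, c(1L, 2L))), 1)
  expect_equal(p_df(ctx_of(2L, c(1L, 3L, 4L))), 0)

  # D3 with document size 3: pairs (a,c), (a,d), (c,d)
  expect_equal(pmi_df(ctx_of(integer(0), c(1L, 3L, 4L))),
               mean(c(log(3 / 4), log(3 / 2), log(3 / 2))), tolerance = 1e-12)
  expect_equal(pmi_df(ctx_of(integer(0), 1L)), 0)           # no pairs
  expect_equal(pmi_df(ctx_of(integer(0), c(1L, 2L))), log(0.5), tolerance = 1e-12)

  expect_equal(fd_df(ctx_of(c(1L, 2L, 3L), c(1L, 2L))), 1)
  expect_equal(fd_df(ctx_of(1L, c(1L, 3L, 4L))), 1 / 3)
  expect_equal(fd_df(ctx_of(4L, c(1L, 2L))), 1 / 3)
})

test_that("the combined filter bank matches the tabulated reference row", {
  s <- compute_filter_scores(ctx_of(1L, c(1L, 2L), rank = 1L))
  expect_equal(s$co_qf, 0.75)   # (codf(a,a)+codf(b,a))/(df(a)+df(b)) = 3/4
  expect_equal(s$l_qf, 0.5)
  expect_equal(s$r_qf, 1)
  expect_equal(s$p_qf, 1)
  expect_equal(s$fd_qf, 1)
  expect_equal(s$co_df, 1)
  expect_equal(s$l_df, 0.5)
  expect_equal(s$r_df, 1)
  expect_equal(s$p_df, 1)
  expect_equal(s$fd_df, 0.5)

  empty <- compute_filter_scores(ctx_of(integer(0), integer(0)))
  expect_equal(as.numeric(empty),
               c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 1))

  # determinism
  expect_identical(compute_filter_scores(ctx_of(c(1L, 3L), c(1L, 3L, 4L), 2L)),
                   compute_filter_scores(ctx_of(c(1L, 3L), c(1L, 3L, 4L), 2L)))
})

test_that("all twelve filters agree with brute-force oracles on random contexts", {
  set.seed(101)
  for (i in 1:300) {
    rc <- random_context()
    ost <- oracle_stats(rc$docs, rc$n)
    ann <- lapply(rc$docs, new_annotation, n = rc$n)
    st <- corpus_statistics(ann)
    ctx <- filter_context(new_annotation(rc$Q, rc$n),
                          new_annotation(rc$D, rc$n), st, rc$rank)
    expect_identical(co_qf(ctx), oracle_co_qf(rc$Q, rc$D, ost))
    expect_identical(l_qf(ctx), oracle_l_qf(rc$Q, rc$D))
    expect_identical(r_qf(ctx), oracle_r_qf(rc$rank))
    expect_identical(p_qf(ctx), oracle_p_qf(rc$Q, rc$D))
    expect_equal(pmi_qf(ctx), oracle_pmi_qf(rc$Q, rc$D, ost), tolerance = 1e-12)
    expect_identical(fd_qf(ctx), oracle_fd_qf(rc$Q, rc$D))
    expect_identical(as.numeric(co_df(ctx)), as.numeric(oracle_co_df(rc$Q, rc$D)))
    expect_identical(l_df(ctx), oracle_l_df(rc$Q, rc$D))
    expect_identical(r_df(ctx), oracle_r_df(rc$Q, rc$D))
    expect_identical(p_df(ctx), oracle_p_df(rc$Q, rc$D))
    expect_equal(pmi_df(ctx), oracle_pmi_df(rc$D, ost), tolerance = 1e-12)
    expect_identical(fd_df(ctx), oracle_fd_df(rc$Q, rc$D))
  }
})

test_that("bounded filters stay in [0,1] and overlap monotonicity holds", {
  set.seed(202)
  for (i in 1:100) {
    rc <- random_context()
    ann <- lapply(rc$docs, new_annotation, n = rc$n)
    st <- corpus_statistics(ann)
    ctx <- filter_context(new_annotation(rc$Q, rc$n),
                          new_annotation(rc$D, rc$n), st, rc$rank)
    s <- compute_filter_scores(ctx)
    for (f in c("l_qf", "r_qf", "p_qf", "fd_qf", "l_df", "p_df", "fd_df")) {
      expect_gte(s[[f]], 0); expect_lte(s[[f]], 1)
    }
    expect_true(s$co_df >= 0 && s$co_df == round(s$co_df))

    # append a query value to D: co_df never decreases
    shared <- rc$Q[1]
    ctx2 <- filter_context(new_annotation(rc$Q, rc$n),
                           new_annotation(c(rc$D, shared), rc$n), st, rc$rank)
    expect_gte(co_df(ctx2), co_df(ctx))
    # append a non-query value: fd_df never increases
    out <- setdiff(seq_len(rc$n), rc$Q)
    if (length(out) > 0) {
      ctx3 <- filter_context(new_annotation(rc$Q, rc$n),
                             new_annotation(c(rc$D, out[1]), rc$n), st, rc$rank)
      expect_lte(fd_df(ctx3), fd_df(ctx))
    }
  }
})
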