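#' SemRank configuration
#'
#' @param alpha Balancing parameter of the late fusion, in \[0, 1\]: weight of
#'   the normalized baseline score (default 0.3, the operating point at which
#'   the fused model performs best across the alpha sweep).
#' @param depth Re-rank depth K: number of baseline candidates re-scored per
#'   query (default 1000).
#' @param k1,b BM25 term-frequency saturation and length-normalization
#'   parameters (defaults 1.2 and 0.75).
#' @param fdqf_variant See [compute_filter_scores()].
#' @param network A [network_config()].
#' @return An object of class `semrank_config`.
#' @export
semrank_config <- function(alpha = 0.3, depth = 1000, k1 = 1.2, b = 0.75,
                           fdqf_variant = "difference",
                           network = network_config()) {
  stopifnot(alpha >= 0, alpha <= 1, depth >= 1)
  structure(list(alpha = alpha, depth = as.integer(depth), k1 = k1, b = b,
                 fdqf_variant = fdqf_variant, network = network),
            class = "semrank_config")
}

# Lowercase, split on runs of non-alphanumeric characters.
tokenize <- function(text) {
  toks <- stringr::str_split(tolower(text), "[^[:alnum:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Build a BM25 index over a corpus
#'
#' @param corpus Tibble with columns `id` and `text`.
#' @return An object of class `bm25_index`: document lengths, average length,
#'   per-token document frequencies and a postings table.
#' @export
bm25_index <- function(corpus) {
  stopifnot(is.data.frame(corpus), all(c("id", "text") %in% names(corpus)))
  toks <- purrr::map(corpus$text, tokenize)
  doc_len <- lengths(toks)
  postings <- tibble::tibble(
    doc_id = rep(corpus$id, doc_len),
    token = unlist(toks)
  )
  postings <- dplyr::count(postings, .data$doc_id, .data$token, name = "tf")
  df <- dplyr::count(dplyr::distinct(postings, .data$token, .data$doc_id),
                     .data$token, name = "df")
  structure(list(N = nrow(corpus),
                 doc_ids = corpus$id,
                 doc_len = stats::setNames(doc_len, corpus$id),
                 avgdl = mean(doc_len),
                 df = stats::setNames(df$df, df$token),
                 postings = postings),
            class = "bm25_index")
}

#' @export
print.bm25_index <- function(x, ...) {
  cat("<bm25_index> ", x$N, " documents, ", length(x$df),
      " distinct tokens\n", sep = "")
  invisible(x)
}

# Non-negative idf variant; any constant idf shift is absorbed by the
# max-normalization of the fusion step.
bm25_idf <- function(df, N) log(1 + (N - df + 0.5) / (df + 0.5))

#' BM25 score of one document for one query
#'
#' Standard Okapi BM25 with non-negative idf
#' `ln(1 + (N - df + 0.5)/(df + 0.5))` and term-frequency saturation
#' `tf (k1 + 1) / (tf + k1 (1 - b + b dl/avgdl))`.
#'
#' @param query_tokens,doc_tokens Character token vectors (see the
#'   tokenization rule in [bm25_index()]: lowercase, split on
#'   non-alphanumeric runs).
#' @param index A [bm25_index()] (supplies N, document frequencies, avgdl).
#' @param k1,b BM25 parameters.
#' @return Numeric score (0 when no query token occurs in the document).
#' @export
bm25_score <- function(query_tokens, doc_tokens, index, k1 = 1.2, b = 0.75) {
  stopifnot(inherits(index, "bm25_index"))
  dl <- length(doc_tokens)
  score <- 0
  for (t in unique(query_tokens)) {
    tf <- sum(doc_tokens == t)
    if (tf == 0) next
    df <- index$df[t]
    if (is.na(df)) df <- 0
    idf <- bm25_idf(df, index$N)
    score <- score + idf * tf * (k1 + 1) / (tf + k1 * (1 - b + b * dl / index$avgdl))
  }
  unname(score)
}

#' First-pass BM25 retrieval
#'
#' Scores every document sharing at least one token with the query and
#' returns the top K as a TREC-style run tibble. Ties are broken by
#' lexicographically smaller document id so runs are reproducible.
#'
#' @param queries Tibble with columns `id` and `text`.
#' @param index A [bm25_index()].
#' @param k Number of results per query.
#' @param k1,b BM25 parameters.
#' @param tag Run tag.
#' @return Run tibble: `query_id`, `doc_id`, `rank`, `score`, `tag`.
#' @export
bm25_search <- function(queries, index, k = 1000, k1 = 1.2, b = 0.75,
                        tag = "BM25") {
  stopifnot(inherits(index, "bm25_index"),
            is.data.frame(queries), all(c("id", "text") %in% names(queries)))
  purrr::map_dfr(seq_len(nrow(queries)), function(qi) {
    qtok <- unique(tokenize(queries$text[qi]))
    post <- dplyr::filter(index$postings, .data$token %in% qtok)
    if (nrow(post) == 0) {
      return(tibble::tibble(query_id = character(0), doc_id = character(0),
                            rank = integer(0), score = numeric(0),
                            tag = character(0)))
    }
    post <- dplyr::mutate(
      post,
      idf = bm25_idf(index$df[.data$token], index$N),
      dl = index$doc_len[.data$doc_id],
      part = .data$idf * .data$tf * (k1 + 1) /
        (.data$tf + k1 * (1 - b + b * .data$dl / index$avgdl))
    )
    scores <- dplyr::summarise(dplyr::group_by(post, .data$doc_id),
                               score = sum(.data$part), .groups = "drop")
    scores <- dplyr::arrange(scores, dplyr::desc(.data$score), .data$doc_id)
    scores <- utils::head(scores, k)
    tibble::tibble(query_id = queries$id[qi], doc_id = scores$doc_id,
                   rank = seq_len(nrow(scores)), score = scores$score,
                   tag = tag)
  })
}

#' Cosine retrieval status value
#'
#' The matching function between the query and document representations:
#' cosine similarity, with the convention that a zero-norm representation
#' (an item with no MDF evidence) scores 0.
#'
#' @param q,d Numeric vectors of equal length.
#' @return Cosine similarity in \[-1, 1\] (in \[0, 1\] for the identity-FCL
#'   network, whose representations are non-negative).
#' @export
rsv_cosine <- function(q, d) {
  stopifnot(length(q) == length(d))
  nq <- sqrt(sum(q^2)); nd <- sqrt(sum(d^2))
  if (nq == 0 || nd == 0) return(0)
  sum(q * d) / (nq * nd)
}

# Shared forward pass given precomputed per-item pieces.
dmm_score_impl <- function(q_ann, d_ann, v_q, v_d, nqm_q, nqm_d, stats,
                           doc_rank, cfg) {
  ctx <- filter_context(q_ann, d_ann, stats, doc_rank)
  fs <- filter_scores_vec(ctx, cfg$fdqf_variant)
  rep_q <- represent(nqm_q, fs[query_filter_names()], v_q, cfg$network)
  rep_d <- represent(nqm_d, fs[doc_filter_names()], v_d, cfg$network)
  rsv_cosine(rep_q, rep_d)
}

# All twelve filters as a named numeric vector (fast path; tibble wrapper in
# compute_filter_scores).
filter_scores_vec <- function(ctx, fdqf_variant = "difference") {
  c(co_qf = co_qf(ctx), l_qf = l_qf(ctx), r_qf = r_qf(ctx),
    p_qf = p_qf(ctx), pmi_qf = pmi_qf(ctx),
    fd_qf = fd_qf(ctx, variant = fdqf_variant),
    co_df = co_df(ctx), l_df = l_df(ctx), r_df = r_df(ctx),
    p_df = p_df(ctx), pmi_df = pmi_df(ctx), fd_df = fd_df(ctx))
}

#' Deep matching model score of one (query, document) pair
#'
#' Builds both feature matrices, evaluates the twelve filters, runs the
#' forward pass for each side (query filters on the query's feature matrix,
#' document filters on the document's) and returns the cosine of the two
#' representations. Deterministic for fixed inputs.
#'
#' @param query_ann,doc_ann `mdf_annotation` objects over the vocabulary the
#'   `ssm` was built for.
#' @param ssm An `ssm` object.
#' @param stats A `corpus_stats` object.
#' @param doc_rank Baseline rank of the document (1-based) or `NA`.
#' @param cfg A [semrank_config()].
#' @return Numeric matching score.
#' @export
dmm_score <- function(query_ann, doc_ann, ssm, stats, doc_rank = NA_integer_,
                      cfg = semrank_config()) {
  stopifnot(inherits(ssm, "ssm"))
  v_q <- binary_from_ann(query_ann, ssm$n)
  v_d <- binary_from_ann(doc_ann, ssm$n)
  dmm_score_impl(query_ann, doc_ann, v_q, v_d,
                 build_feature_matrix(v_q, ssm),
                 build_feature_matrix(v_d, ssm),
                 stats, doc_rank, cfg)
}

binary_from_ann <- function(ann, n) {
  stopifnot(inherits(ann, "mdf_annotation"), ann$n == n)
  v <- integer(n)
  v[ann$distinct] <- 1L
  v
}

#' Late fusion of baseline and DMM scores
#'
#' For each query, both score components are normalized by their maximum over
#' the query's candidate list (a non-positive maximum normalizes to 0) and
#' combined as `alpha * baseline_norm + (1 - alpha) * dmm_norm`. Candidates
#' are re-sorted by the fused score; ties are broken by higher baseline
#' score, then by document id. Fusion re-ranks the baseline list: DMM scores
#' for documents absent from the baseline are ignored with a warning.
#'
#' @param baseline Run tibble (`query_id`, `doc_id`, `rank`, `score`, ...).
#' @param dmm_scores Tibble with columns `query_id`, `doc_id`, `dmm`; or, for
#'   a single-query baseline, a named numeric vector keyed by `doc_id`.
#' @param alpha Fusion weight of the baseline component.
#' @param tag Run tag for the output.
#' @return Run tibble with recomputed `rank` and fused `score`.
#' @export
semrank_fuse <- function(baseline, dmm_scores, alpha = 0.3, tag = "SemRank") {
  stopifnot(is.data.frame(baseline), nrow(baseline) > 0,
            alpha >= 0, alpha <= 1)
  if (!is.data.frame(dmm_scores)) {
    qids <- unique(baseline$query_id)
    stopifnot(length(qids) == 1)
    dmm_scores <- tibble::tibble(query_id = qids,
                                 doc_id = names(dmm_scores),
                                 dmm = as.numeric(dmm_scores))
  }
  extra <- dplyr::anti_join(dmm_scores, baseline,
                            by = c("query_id", "doc_id"))
  if (nrow(extra) > 0) {
    warning("ignoring ", nrow(extra),
            " DMM score(s) for documents absent from the baseline list",
            call. = FALSE)
  }
  fused <- dplyr::left_join(baseline, dmm_scores, by = c("query_id", "doc_id"))
  fused$dmm[is.na(fused$dmm)] <- 0
  fused <- dplyr::group_by(fused, .data$query_id)
  fused <- dplyr::mutate(
    fused,
    base_norm = norm_by_max(.data$score),
    dmm_norm = norm_by_max(.data$dmm),
    fused_score = alpha * .data$base_norm + (1 - alpha) * .data$dmm_norm
  )
  fused <- dplyr::arrange(fused, dplyr::desc(.data$fused_score),
                          dplyr::desc(.data$score), .data$doc_id,
                          .by_group = TRUE)
  fused <- dplyr::mutate(fused, rank = dplyr::row_number())
  fused <- dplyr::ungroup(fused)
  tibble::tibble(query_id = fused$query_id, doc_id = fused$doc_id,
                 rank = fused$rank, score = fused$fused_score, tag = tag)
}

norm_by_max <- function(x) {
  m <- max(x)
  if (m <= 0) return(rep(0, length(x)))
  x / m
}

#' End-to-end SemRank re-ranking
#'
#' Annotates corpus and queries, computes collection statistics, runs BM25
#' first-pass retrieval, scores every baseline candidate with the deep
#' matching model (the candidate's baseline rank feeding the rank filter),
#' and fuses the two scores. The output candidate set per query is exactly
#' the baseline's.
#'
#' @param corpus,queries Tibbles with columns `id` and `text`.
#' @param ssm An `ssm` object over `vocab`.
#' @param vocab An [mdf_vocabulary()] object.
#' @param cfg A [semrank_config()].
#' @return An object of class `semrank_run`: list with `run` (fused run
#'   tibble), `baseline` (BM25 run tibble), `dmm` (tibble `query_id`,
#'   `doc_id`, `dmm`) and `cfg`.
#' @export
semrank_rerank <- function(corpus, queries, ssm, vocab,
                           cfg = semrank_config()) {
  stopifnot(inherits(ssm, "ssm"), inherits(vocab, "mdf_vocabulary"),
            ssm$n == vocab_size(vocab))
  corpus_ann <- annotate_corpus(corpus, vocab)
  queries_ann <- annotate_corpus(queries, vocab)
  stats <- corpus_statistics(corpus_ann$ann)
  index <- bm25_index(corpus)
  baseline <- bm25_search(queries, index, k = cfg$depth, k1 = cfg$k1, b = cfg$b)
  empty_q <- setdiff(queries$id, unique(baseline$query_id))
  if (length(empty_q) > 0) {
    message("queries with empty baseline result list: ",
            paste(empty_q, collapse = ", "))
  }
  dmm <- dmm_score_candidates(baseline, corpus_ann, queries_ann, ssm, stats, cfg)
  run <- semrank_fuse(baseline, dmm, alpha = cfg$alpha)
  structure(list(run = run, baseline = baseline, dmm = dmm, cfg = cfg),
            class = "semrank_run")
}

#' @export
print.semrank_run <- function(x, ...) {
  cat("<semrank_run> ", length(unique(x$run$query_id)), " queries, ",
      nrow(x$run), " scored candidates (alpha = ", x$cfg$alpha, ")\n", sep = "")
  invisible(x)
}

# DMM scores for every (query, baseline candidate) pair, caching per-item
# binary vectors and feature matrices.
dmm_score_candidates <- function(baseline, corpus_ann, queries_ann, ssm,
                                 stats, cfg) {
  if (nrow(baseline) == 0) {
    return(tibble::tibble(query_id = character(0), doc_id = character(0),
                          dmm = numeric(0)))
  }
  doc_ann <- stats::setNames(corpus_ann$ann, corpus_ann$id)
  q_ann <- stats::setNames(queries_ann$ann, queries_ann$id)
  doc_cache <- new.env(parent = emptyenv())
  doc_item <- function(id) {
    it <- doc_cache[[id]]
    if (is.null(it)) {
      v <- binary_from_ann(doc_ann[[id]], ssm$n)
      it <- list(v = v, nqm = build_feature_matrix(v, ssm))
      doc_cache[[id]] <- it
    }
    it
  }
  purrr::map_dfr(split(baseline, baseline$query_id), function(cand) {
    qid <- cand$query_id[1]
    qa <- q_ann[[qid]]
    v_q <- binary_from_ann(qa, ssm$n)
    nqm_q <- build_feature_matrix(v_q, ssm)
    dmm <- purrr::map2_dbl(cand$doc_id, cand$rank, function(did, rk) {
      it <- doc_item(did)
      dmm_score_impl(qa, doc_ann[[did]], v_q, it$v, nqm_q, it$nqm,
                     stats, rk, cfg)
    })
    tibble::tibble(query_id = qid, doc_id = cand$doc_id, dmm = dmm)
  })
}

#' Sweep the fusion weight alpha
#'
#' Computes the baseline run and DMM scores once, fuses at each alpha on the
#' grid and evaluates MAP, P@5 and P@10 against the qrels. `alpha = 0` is the
#' DMM-only ranking, `alpha = 1` the pure baseline.
#'
#' @inheritParams semrank_rerank
#' @param qrels Qrels tibble (see [read_qrels()]).
#' @param alphas Numeric grid in \[0, 1\].
#' @return A tibble of class `semrank_sweep` with columns `alpha`, `map`,
#'   `p5`, `p10`.
#' @export
alpha_sweep <- function(corpus, queries, ssm, vocab, qrels,
                        alphas = seq(0, 1, by = 0.1),
                        cfg = semrank_config()) {
  rr <- semrank_rerank(corpus, queries, ssm, vocab, cfg)
  out <- purrr::map_dfr(alphas, function(a) {
    run <- semrank_fuse(rr$baseline, rr$dmm, alpha = a)
    ev <- evaluate_run(run, qrels)
    tibble::tibble(alpha = a, map = ev$map, p5 = ev$p5, p10 = ev$p10)
  })
  class(out) <- c("semrank_sweep", class(out))
  out
}

#' Plot an alpha sweep
#'
#' @param object A `semrank_sweep` tibble from [alpha_sweep()].
#' @param ... Unused.
#' @return A ggplot: metric value against alpha, one line per metric.
#' @export
autoplot.semrank_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("map", "p5", "p10"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$alpha, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(alpha), y = "metric value",
                  colour = NULL,
                  title = "Fusion weight sweep",
                  subtitle = "alpha = 0: DMM only; alpha = 1: BM25 only") +
    ggplot2::theme_minimal()
}
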