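#' TREC-format run and qrels input/output
#'
#' Runs are whitespace-separated `qid Q0 docid rank score tag` lines; qrels
#' are `qid 0 docid rel` lines. Relevance is treated as binary: a document is
#' relevant iff its grade is positive.
#'
#' @param path File path.
#' @return `read_run`: a run tibble (`query_id`, `doc_id`, `rank`, `score`,
#'   `tag`); `read_qrels`: a qrels tibble (`query_id`, `doc_id`, `rel`).
#' @name trec_io
NULL

#' @rdname trec_io
#' @export
read_run <- function(path) {
  df <- utils::read.table(path, col.names = c("query_id", "q0", "doc_id",
                                              "rank", "score", "tag"),
                          colClasses = c("character", "character", "character",
                                         "integer", "numeric", "character"))
  tibble::as_tibble(df[, c("query_id", "doc_id", "rank", "score", "tag")])
}

#' @rdname trec_io
#' @param run A run tibble.
#' @export
write_run <- function(run, path) {
  lines <- sprintf("%s Q0 %s %d %.12g %s", run$query_id, run$doc_id,
                   as.integer(run$rank), run$score, run$tag)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname trec_io
#' @export
read_qrels <- function(path) {
  df <- utils::read.table(path, col.names = c("query_id", "iter", "doc_id",
                                              "rel"),
                          colClasses = c("character", "character", "character",
                                         "integer"))
  tibble::as_tibble(df[, c("query_id", "doc_id", "rel")])
}

#' @rdname trec_io
#' @param qrels A qrels tibble.
#' @export
write_qrels <- function(qrels, path) {
  writeLines(sprintf("%s 0 %s %d", qrels$query_id, qrels$doc_id,
                     as.integer(qrels$rel)), path)
  invisible(path)
}

relevant_set <- function(qrels, query_id) {
  qrels$doc_id[qrels$query_id == query_id & qrels$rel > 0]
}

#' Precision at cutoff k
#'
#' Fraction of the top k retrieved documents that are relevant; the divisor
#' is k even when fewer than k documents were retrieved (trec_eval
#' convention).
#'
#' @param ranked Character vector of document ids in rank order.
#' @param qrels Qrels tibble.
#' @param query_id Query identifier.
#' @param k Cutoff (>= 1).
#' @return Precision in \[0, 1\].
#' @export
precision_at_k <- function(ranked, qrels, query_id, k) {
  stopifnot(k >= 1)
  rel <- relevant_set(qrels, query_id)
  sum(utils::head(ranked, k) %in% rel) / k
}

#' Average precision of one ranked list
#'
#' Mean of precision-at-rank over the ranks holding relevant documents,
#' divided by R, the total number of relevant documents in the qrels for the
#' query (so unretrieved relevant documents count against the score).
#' Returns 0 when R = 0; such queries are skipped by
#' [mean_average_precision()].
#'
#' @inheritParams precision_at_k
#' @return Average precision in \[0, 1\].
#' @export
average_precision <- function(ranked, qrels, query_id) {
  rel <- relevant_set(qrels, query_id)
  R <- length(rel)
  if (R == 0) return(0)
  hits <- ranked %in% rel
  if (!any(hits)) return(0)
  prec_at_hit <- cumsum(hits)[hits] / which(hits)
  sum(prec_at_hit) / R
}

#' Mean average precision of a run
#'
#' Unweighted mean of per-query average precision over queries with at least
#' one relevant document in the qrels; queries with none are skipped with a
#' warning (trec_eval convention).
#'
#' @param run Run tibble.
#' @param qrels Qrels tibble.
#' @return MAP in \[0, 1\].
#' @export
mean_average_precision <- function(run, qrels) {
  per <- per_query_metrics(run, qrels)
  if (nrow(per) == 0) {
    stop("no evaluable query: no run query has relevant documents in the qrels",
         call. = FALSE)
  }
  mean(per$ap)
}

# Per-query AP/P@5/P@10 over evaluable queries (R > 0), warning on skips.
per_query_metrics <- function(run, qrels) {
  qids <- unique(run$query_id)
  evaluable <- qids[purrr::map_int(qids, function(q)
    length(relevant_set(qrels, q))) > 0]
  skipped <- setdiff(qids, evaluable)
  if (length(skipped) > 0) {
    warning("skipping ", length(skipped),
            " quer(y/ies) with no relevant documents in the qrels",
            call. = FALSE)
  }
  purrr::map_dfr(evaluable, function(q) {
    ranked <- run$doc_id[run$query_id == q][order(run$rank[run$query_id == q])]
    tibble::tibble(query_id = q,
                   ap = average_precision(ranked, qrels, q),
                   p5 = precision_at_k(ranked, qrels, q, 5),
                   p10 = precision_at_k(ranked, qrels, q, 10))
  })
}

#' Evaluate a run against qrels
#'
#' @param run Run tibble.
#' @param qrels Qrels tibble.
#' @return An object of class `run_eval`: list with `per_query` (tibble
#'   `query_id`, `ap`, `p5`, `p10`) and scalar `map`, `p5`, `p10` means.
#' @export
evaluate_run <- function(run, qrels) {
  per <- per_query_metrics(run, qrels)
  if (nrow(per) == 0) {
    stop("no evaluable query: no run query has relevant documents in the qrels",
         call. = FALSE)
  }
  structure(list(per_query = per, map = mean(per$ap), p5 = mean(per$p5),
                 p10 = mean(per$p10)),
            class = "run_eval")
}

#' @export
print.run_eval <- function(x, ...) {
  cat(sprintf("<run_eval> %d queries | MAP %.4f | P@5 %.4f | P@10 %.4f\n",
              nrow(x$per_query), x$map, x$p5, x$p10))
  invisible(x)
}

#' @export
tidy.run_eval <- function(x, ...) x$per_query

#' @export
glance.run_eval <- function(x, ...) {
  tibble::tibble(n_queries = nrow(x$per_query), map = x$map, p5 = x$p5,
                 p10 = x$p10)
}

#' Paired per-query comparison of two runs
#'
#' Computes the chosen per-query metric for both runs over their common
#' evaluable queries, the per-query deltas (B - A), the mean relative
#' improvement of B over A, and a two-sided Wilcoxon signed-rank test on the
#' paired values (zero deltas dropped, per the test's convention). The
#' difference is flagged significant when p < 0.05. With fewer than two
#' non-zero deltas the p-value is undefined and the comparison is reported
#' as not significant with a reason.
#'
#' @param run_a,run_b Run tibbles over the same query set.
#' @param qrels Qrels tibble.
#' @param metric `"ap"` (per-query average precision, default), `"p5"` or
#'   `"p10"`.
#' @return An object of class `run_comparison`: list with `per_query`
#'   (tibble `query_id`, `metric_a`, `metric_b`, `delta`), `p_value`,
#'   `significant`, `improvement_rate` (mean of (B - A)/A over queries with
#'   A > 0) and `reason` (when the test is undefined).
#' @export
compare_runs <- function(run_a, run_b, qrels, metric = c("ap", "p5", "p10")) {
  metric <- match.arg(metric)
  pa <- per_query_metrics(run_a, qrels)
  pb <- per_query_metrics(run_b, qrels)
  common <- intersect(pa$query_id, pb$query_id)
  stopifnot(length(common) > 0)
  pa <- pa[match(common, pa$query_id), ]
  pb <- pb[match(common, pb$query_id), ]
  per <- tibble::tibble(query_id = common,
                        metric_a = pa[[metric]],
                        metric_b = pb[[metric]],
                        delta = pb[[metric]] - pa[[metric]])
  nonzero <- per$delta[per$delta != 0]
  if (length(nonzero) < 2) {
    p <- NA_real_; sig <- FALSE
    reason <- "fewer than 2 non-zero per-query differences"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(per$metric_b, per$metric_a, paired = TRUE)$p.value)
    sig <- is.finite(p) && p < 0.05
    reason <- NA_character_
  }
  pos <- per$metric_a > 0
  impr <- if (any(pos)) mean((per$metric_b[pos] - per$metric_a[pos]) /
                               per$metric_a[pos]) else NA_real_
  structure(list(per_query = per, p_value = p, significant = sig,
                 improvement_rate = impr, metric = metric, reason = reason),
            class = "run_comparison")
}

#' @export
print.run_comparison <- function(x, ...) {
  cat(sprintf(
    "<run_comparison> metric %s | mean delta %+.4f | improvement %+.1f%% | p = %s%s\n",
    x$metric, mean(x$per_query$delta),
    100 * (x$improvement_rate %||% NA_real_),
    format(x$p_value, digits = 3),
    if (isTRUE(x$significant)) " (significant)" else ""))
  invisible(x)
}

#' @export
tidy.run_comparison <- function(x, ...) x$per_query

#' @export
glance.run_comparison <- function(x, ...) {
  tibble::tibble(metric = x$metric, mean_delta = mean(x$per_query$delta),
                 improvement_rate = x$improvement_rate, p_value = x$p_value,
                 significant = x$significant)
}

#' Turn model results into tidy tibbles
#'
#' Broom-style generics for the package's result objects: `tidy()` returns
#' the per-query table, `glance()` a one-row summary.
#'
#' @param x A `run_eval` or `run_comparison` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
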