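#' Filter evaluation context
#'
#' Bundles everything the twelve retrieval filters read: the query and
#' document annotations, the collection statistics, and the document's rank
#' in the first-pass (baseline) result list.
#'
#' @param query,doc `mdf_annotation` objects over the same vocabulary.
#' @param stats A `corpus_stats` object (same vocabulary).
#' @param doc_rank 1-based baseline rank of the document for this query, or
#'   `NA` when the document is absent from the baseline list.
#' @return An object of class `filter_context`.
#' @export
filter_context <- function(query, doc, stats, doc_rank = NA_integer_) {
  stopifnot(inherits(query, "mdf_annotation"), inherits(doc, "mdf_annotation"),
            inherits(stats, "corpus_stats"))
  if (!is.na(doc_rank) && doc_rank < 1) {
    stop("doc_rank must be >= 1 when present", call. = FALSE)
  }
  structure(list(Q = query, D = doc, stats = stats,
                 doc_rank = doc_rank),
            class = "filter_context")
}

#' The twelve retrieval filters
#'
#' Six query-side and six document-side scalar filters measure complementary
#' relevance evidence between a query annotation Q and a document annotation
#' D (set notation below uses the distinct index sets; position-based filters
#' use the ordered occurrence lists):
#'
#' * `co_qf` — confidence: collection co-occurrence of query values with
#'   document values, `sum_{j in Q} sum_{i in D} fr(i,j) / sum_{i in D} fr(i)`.
#' * `l_qf` — length: `|Q n D| / |D|` when the document contains *all* query
#'   values, else 0 (specific-and-exhaustive documents score high).
#' * `r_qf` — rank: inverse baseline rank `1/docrank`; 0 when the document
#'   was not retrieved by the baseline.
#' * `p_qf` — proximity: `1 / (1 + sum of gaps)` where the gaps count the
#'   features lying strictly between consecutive query-value occurrences in
#'   the document; 0 when no query value occurs.
#' * `pmi_qf` — mean [pmi()] over (document value, query value) pairs with
#'   non-zero co-occurrence, with N the collection size.
#' * `fd_qf` — feature difference: `1 / (1 + |Q \\ D|)`.
#' * `co_df` — number of shared values `|Q n D|`.
#' * `l_df` — `|Q n D| / |D|` (no containment condition).
#' * `r_df` — within-document frequency of query values times the
#'   organization factor gamma (1 if the query's value order is preserved in
#'   the document, 0.5 if not); 0 if no query value occurs.
#' * `p_df` — `1 / |D n Q|`; 0 when no value is shared.
#' * `pmi_df` — mean [pmi()] over distinct document-value pairs, with N the
#'   document size (occurrence count).
#' * `fd_df` — `1 / (1 + |D \\ Q|)`.
#'
#' All filters are total functions: every 0-denominator or no-evidence case
#' returns 0 (the document carries no relevance evidence of that kind).
#'
#' @param ctx A [filter_context()].
#' @return A single numeric score.
#' @name filters
NULL

#' @rdname filters
#' @export
co_qf <- function(ctx) {
  q <- ctx$Q$distinct; d <- ctx$D$distinct
  if (length(q) == 0 || length(d) == 0) return(0)
  denom <- sum(ctx$stats$df[d])
  if (denom == 0) return(0)
  sum(ctx$stats$codf[d, q, drop = FALSE]) / denom
}

#' @rdname filters
#' @export
l_qf <- function(ctx) {
  q <- ctx$Q$distinct; d <- ctx$D$distinct
  if (length(q) == 0 || length(d) == 0) return(0)
  if (!all(q %in% d)) return(0)
  length(intersect(q, d)) / length(d)
}

#' @rdname filters
#' @export
r_qf <- function(ctx) {
  if (is.na(ctx$doc_rank)) return(0)
  1 / ctx$doc_rank
}

#' @rdname filters
#' @export
p_qf <- function(ctx) {
  pos <- which(ctx$D$occurrences %in% ctx$Q$distinct)
  if (length(pos) == 0) return(0)
  gaps <- diff(pos) - 1  # features strictly between consecutive occurrences
  1 / (1 + sum(gaps))
}

#' @rdname filters
#' @export
pmi_qf <- function(ctx) {
  mean_pmi_over_pairs(ctx$D$distinct, ctx$Q$distinct, ctx$stats,
                      N_override = NULL)
}

#' @rdname filters
#' @export
fd_qf <- function(ctx, variant = c("difference", "intersection")) {
  variant <- match.arg(variant)
  q <- ctx$Q$distinct; d <- ctx$D$distinct
  k <- if (variant == "difference") length(setdiff(q, d)) else length(intersect(q, d))
  1 / (1 + k)
}

#' @rdname filters
#' @export
co_df <- function(ctx) {
  length(intersect(ctx$Q$distinct, ctx$D$distinct))
}

#' @rdname filters
#' @export
l_df <- function(ctx) {
  d <- ctx$D$distinct
  if (length(d) == 0) return(0)
  length(intersect(ctx$Q$distinct, d)) / length(d)
}

#' @rdname filters
#' @export
r_df <- function(ctx) {
  counts <- tabulate(ctx$D$occurrences, nbins = ctx$D$n)[ctx$Q$distinct]
  freq <- sum(counts)
  if (freq == 0) return(0)
  freq * organization_factor(ctx$Q, ctx$D)
}

# gamma of the rank document filter: 1 if the first-occurrence order of the
# query's values (restricted to those present in the document) appears as a
# subsequence of the document's occurrence list, else 0.5.
organization_factor <- function(Q, D) {
  q_order <- unique(Q$occurrences)
  q_order <- q_order[q_order %in% D$distinct]
  if (length(q_order) <= 1) return(1)
  pos <- 1L
  for (x in D$occurrences) {
    if (x == q_order[pos]) {
      pos <- pos + 1L
      if (pos > length(q_order)) return(1)
    }
  }
  0.5
}

#' @rdname filters
#' @export
p_df <- function(ctx) {
  k <- length(intersect(ctx$D$distinct, ctx$Q$distinct))
  if (k == 0) return(0)
  1 / k
}

#' @rdname filters
#' @export
pmi_df <- function(ctx) {
  d <- ctx$D$distinct
  if (length(d) < 2) return(0)
  pairs <- utils::combn(d, 2)
  vals <- numeric(0)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    if (ctx$stats$df[i] > 0 && ctx$stats$df[j] > 0 && ctx$stats$codf[i, j] > 0) {
      vals <- c(vals, pmi(i, j, ctx$stats,
                          N_override = length(ctx$D$occurrences)))
    }
  }
  if (length(vals) == 0) return(0)
  mean(vals)
}

#' @rdname filters
#' @export
fd_df <- function(ctx) {
  1 / (1 + length(setdiff(ctx$D$distinct, ctx$Q$distinct)))
}

# Mean PMI over pairs (i in left, j in right) with positive frequencies and
# co-occurrence; 0 when no valid pair.
mean_pmi_over_pairs <- function(left, right, stats, N_override) {
  if (length(left) == 0 || length(right) == 0) return(0)
  vals <- numeric(0)
  for (j in right) {
    for (i in left) {
      if (stats$df[i] > 0 && stats$df[j] > 0 && stats$codf[i, j] > 0) {
        vals <- c(vals, pmi(i, j, stats, N_override = N_override))
      }
    }
  }
  if (length(vals) == 0) return(0)
  mean(vals)
}

#' Evaluate all twelve filters
#'
#' @param ctx A [filter_context()].
#' @param fdqf_variant `"difference"` (default: counts query values missing
#'   from the document) or `"intersection"` (counts shared values) for the
#'   query-side feature-difference filter.
#' @return A one-row tibble with columns `co_qf`, `l_qf`, `r_qf`, `p_qf`,
#'   `pmi_qf`, `fd_qf`, `co_df`, `l_df`, `r_df`, `p_df`, `pmi_df`, `fd_df`.
#' @export
compute_filter_scores <- function(ctx, fdqf_variant = "difference") {
  stopifnot(inherits(ctx, "filter_context"))
  tibble::tibble(
    co_qf = co_qf(ctx), l_qf = l_qf(ctx), r_qf = r_qf(ctx),
    p_qf = p_qf(ctx), pmi_qf = pmi_qf(ctx),
    fd_qf = fd_qf(ctx, variant = fdqf_variant),
    co_df = co_df(ctx), l_df = l_df(ctx), r_df = r_df(ctx),
    p_df = p_df(ctx), pmi_df = pmi_df(ctx), fd_df = fd_df(ctx)
  )
}

query_filter_names <- function() c("co_qf", "l_qf", "r_qf", "p_qf", "pmi_qf", "fd_qf")
doc_filter_names <- function() c("co_df", "l_df", "r_df", "p_df", "pmi_df", "fd_df")
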