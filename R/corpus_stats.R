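#' Collection-level MDF frequency statistics
#'
#' Computes, from a list of document annotations, the document frequency of
#' every feature value (number of documents containing it) and the document
#' co-occurrence count of every value pair (number of documents containing
#' both). Counting is presence-based: duplicate occurrences within one
#' document count once. These statistics feed the confidence and pointwise
#' mutual information filters.
#'
#' @param annotations List of `mdf_annotation` objects (one per document), or
#'   a tibble with an `ann` list-column as returned by [annotate_corpus()].
#' @return An object of class `corpus_stats`: list with `N` (number of
#'   documents), `df` (integer vector of length n, document frequencies) and
#'   `codf` (n x n symmetric integer matrix of pair co-occurrence counts;
#'   `codf[i, i] == df[i]`).
#' @examples
#' v <- mdf_vocabulary()
#' docs <- annotate_corpus(
#'   tibble::tibble(id = c("d1", "d2"),
#'                  text = c("MRI of the brain", "CT and MRI")), v)
#' st <- corpus_statistics(docs$ann)
#' st$N
#' @export
corpus_statistics <- function(annotations) {
  if (is.data.frame(annotations)) annotations <- annotations$ann
  stopifnot(all(purrr::map_lgl(annotations, inherits, "mdf_annotation")))
  if (length(annotations) == 0) {
    return(structure(list(N = 0L, df = integer(0),
                          codf = matrix(0L, 0, 0)),
                     class = "corpus_stats"))
  }
  n <- annotations[[1]]$n
  stopifnot(all(purrr::map_int(annotations, "n") == n))
  # docs x n presence matrix; crossprod gives pairwise document co-occurrence
  pres <- matrix(0L, length(annotations), n)
  for (d in seq_along(annotations)) {
    pres[d, annotations[[d]]$distinct] <- 1L
  }
  codf <- crossprod(pres)
  structure(list(N = length(annotations),
                 df = as.integer(diag(codf)),
                 codf = codf),
            class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat("<corpus_stats> N = ", x$N, ", vocabulary n = ", length(x$df), "\n",
      sep = "")
  invisible(x)
}

#' Merge corpus statistics computed on corpus partitions
#'
#' Document-level counts are additive, so statistics over a partitioned
#' corpus equal the sum of per-partition statistics.
#'
#' @param ... `corpus_stats` objects over the same vocabulary.
#' @return A combined `corpus_stats` object.
#' @export
merge_corpus_statistics <- function(...) {
  parts <- purrr::discard(list(...), function(p) p$N == 0)
  if (length(parts) == 0) return(corpus_statistics(list()))
  n <- length(parts[[1]]$df)
  stopifnot(all(purrr::map_int(parts, function(p) length(p$df)) == n))
  structure(list(N = sum(purrr::map_int(parts, "N")),
                 df = as.integer(Reduce(`+`, purrr::map(parts, "df"))),
                 codf = Reduce(`+`, purrr::map(parts, "codf"))),
            class = "corpus_stats")
}

#' Pointwise mutual information of a feature-value pair
#'
#' PMI(i, j) = ln( N * fr(i, j) / (fr(i) * fr(j)) ), where fr(.) are
#' document frequencies and fr(i, j) the document co-occurrence count.
#' Positive values mean the pair co-occurs more often than independence
#' predicts, i.e. the values have close meaning in this collection. Natural
#' logarithm; the document-filter variant substitutes the document size for N
#' via `N_override`.
#'
#' @param i,j Vocabulary indices (1-based).
#' @param stats A `corpus_stats` object.
#' @param N_override Optional replacement for `stats$N`.
#' @return PMI value (finite real).
#' @export
pmi <- function(i, j, stats, N_override = NULL) {
  stopifnot(inherits(stats, "corpus_stats"))
  n_eff <- N_override %||% stats$N
  dfi <- stats$df[i]; dfj <- stats$df[j]; co <- stats$codf[i, j]
  if (dfi == 0 || dfj == 0 || co == 0) {
    stop("PMI undefined for pair (", i, ", ", j,
         "): zero frequency or co-occurrence", call. = FALSE)
  }
  log(n_eff * co / (dfi * dfj))
}
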