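#' Synthetic collection configuration
#'
#' Parameters of the seeded generator that emulates the structure the
#' re-ranker assumes: image captions carrying a handful of MDF value strings
#' mixed with non-MDF lexical filler, queries of one to a few MDF values, and
#' ground-truth relevance driven by semantic MDF overlap with label noise.
#' Defaults are the package's standard study conditions (500 documents, 20
#' queries, relevance threshold 0.6, 5% label noise).
#'
#' @param n_docs,n_queries Collection sizes.
#' @param mdf_per_doc,mdf_per_query Inclusive integer ranges `c(lo, hi)` for
#'   the number of MDF value mentions per item.
#' @param filler_vocab_size Size of the synthetic non-MDF lexicon.
#' @param filler_per_doc,filler_per_query Inclusive ranges for filler token
#'   counts per item.
#' @param zipf_exponent Exponent of the Zipf law used for both the MDF
#'   vocabulary and the filler lexicon.
#' @param topic_cross_rate Probability that an MDF mention is drawn from the
#'   global vocabulary distribution instead of the item's focus category.
#'   Documents and queries are topically coherent (a radiology caption
#'   mentions radiology features): each item draws a focus category and
#'   samples MDFs within it with probability `1 - topic_cross_rate`. This
#'   gives the collection the co-occurrence structure of real captions, in
#'   which values of one category co-occur far more often than chance.
#' @param tau Relevance threshold on the semantic overlap score, in \[0, 1\].
#' @param epsilon Label-noise probability in \[0, 0.5\]: each pair's binary
#'   relevance is flipped independently with this probability.
#' @param seed Integer seed; generation is a pure function of (config, seed).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_docs = 500, n_queries = 20,
                         mdf_per_doc = c(2, 5), mdf_per_query = c(1, 3),
                         filler_vocab_size = 200,
                         filler_per_doc = c(5, 15), filler_per_query = c(0, 2),
                         zipf_exponent = 1.1, topic_cross_rate = 0.2,
                         tau = 0.6, epsilon = 0.05, seed = 1) {
  stopifnot(n_docs >= 1, n_queries >= 1,
            length(mdf_per_doc) == 2, mdf_per_doc[1] <= mdf_per_doc[2],
            length(mdf_per_query) == 2, mdf_per_query[1] <= mdf_per_query[2],
            length(filler_per_doc) == 2, filler_per_doc[1] <= filler_per_doc[2],
            length(filler_per_query) == 2,
            filler_per_query[1] <= filler_per_query[2],
            epsilon >= 0, epsilon <= 0.5,
            topic_cross_rate >= 0, topic_cross_rate <= 1)
  if (tau < 0 || tau > 1) {
    stop("relevance threshold tau must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_docs = n_docs, n_queries = n_queries,
                 mdf_per_doc = mdf_per_doc, mdf_per_query = mdf_per_query,
                 filler_vocab_size = filler_vocab_size,
                 filler_per_doc = filler_per_doc,
                 filler_per_query = filler_per_query,
                 zipf_exponent = zipf_exponent,
                 topic_cross_rate = topic_cross_rate,
                 tau = tau, epsilon = epsilon, seed = as.integer(seed)),
            class = "synth_config")
}

zipf_weights <- function(n, s) (1 / seq_len(n)^s)

rand_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(range[1]:range[2], n, replace = TRUE)
}

#' Semantic MDF overlap score
#'
#' The generator's relevance model (also usable as a diagnostic): the mean,
#' over the query's distinct MDF values, of the best semantic similarity to
#' any of the document's distinct MDF values,
#' `S(q, d) = (1/|Q|) sum_{j in Q} max_{i in D} SSM[i, j]`; 0 when either
#' side has no MDF. Best-match rather than full bipartite matching: cheap,
#' monotone in the document's MDF set, and aligned with how the filters
#' reward shared or similar values.
#'
#' @param q_ann,d_ann `mdf_annotation` objects.
#' @param ssm An `ssm` object.
#' @return Overlap score in \[0, 1\].
#' @export
overlap_score <- function(q_ann, d_ann, ssm) {
  q <- q_ann$distinct; d <- d_ann$distinct
  if (length(q) == 0 || length(d) == 0) return(0)
  mean(apply(ssm$values[d, q, drop = FALSE], 2, max))
}

#' Generate a synthetic retrieval collection
#'
#' Draws documents (MDF value strings interleaved with Zipf-distributed
#' filler tokens), queries (a few MDF values plus optional filler), and
#' binary qrels from the semantic-overlap relevance model thresholded at
#' `tau` and flipped with probability `epsilon`. Byte-identical output for
#' the same (config, seed).
#'
#' @param cfg A [synth_config()].
#' @param vocab An [mdf_vocabulary()] object.
#' @param ssm An `ssm` object over `vocab`.
#' @return List with tibbles `corpus` (`id`, `text`), `queries` (`id`,
#'   `text`) and `qrels` (`query_id`, `doc_id`, `rel`; relevant pairs only).
#' @export
generate_collection <- function(cfg, vocab, ssm) {
  stopifnot(inherits(cfg, "synth_config"), inherits(vocab, "mdf_vocabulary"),
            inherits(ssm, "ssm"), ssm$n == vocab_size(vocab))
  n <- vocab_size(vocab)
  withr::local_seed(cfg$seed)
  # Zipf ranks are spread over the vocabulary by a seeded permutation so that
  # frequent values occur in every category; rank-in-index-order would put
  # nearly all mass in the first category and make most pairs relevant.
  w_mdf <- zipf_weights(n, cfg$zipf_exponent)[sample.int(n)]
  filler_lex <- sprintf("filler%03d", seq_len(cfg$filler_vocab_size))
  w_fill <- zipf_weights(cfg$filler_vocab_size, cfg$zipf_exponent)
  cat_of <- vocab$values$category
  cat_weight <- tapply(w_mdf, cat_of, sum)[vocab$categories]

  make_item <- function(n_mdf, n_fill) {
    # Topical item: MDF mentions come from a focus category, with occasional
    # cross-topic mentions from the global distribution.
    focus <- sample(vocab$categories, 1, prob = cat_weight)
    in_focus <- which(cat_of == focus)
    mdf_idx <- purrr::map_int(seq_len(n_mdf), function(i) {
      if (stats::runif(1) < cfg$topic_cross_rate) {
        sample.int(n, 1, prob = w_mdf)
      } else {
        in_focus[sample.int(length(in_focus), 1, prob = w_mdf[in_focus])]
      }
    })
    fill <- if (n_fill > 0) {
      sample(filler_lex, n_fill, replace = TRUE, prob = w_fill)
    } else character(0)
    words <- c(vocab$values$value[mdf_idx], fill)
    words <- words[sample.int(length(words))]
    list(text = paste(words, collapse = " "), mdf = mdf_idx)
  }

  docs <- purrr::map2(rand_int(cfg$n_docs, cfg$mdf_per_doc),
                      rand_int(cfg$n_docs, cfg$filler_per_doc), make_item)
  qrys <- purrr::map2(rand_int(cfg$n_queries, cfg$mdf_per_query),
                      rand_int(cfg$n_queries, cfg$filler_per_query), make_item)
  corpus <- tibble::tibble(id = sprintf("d%04d", seq_len(cfg$n_docs)),
                           text = purrr::map_chr(docs, "text"))
  queries <- tibble::tibble(id = sprintf("q%02d", seq_len(cfg$n_queries)),
                            text = purrr::map_chr(qrys, "text"))

  doc_sets <- purrr::map(docs, function(d) sort(unique(d$mdf)))
  q_sets <- purrr::map(qrys, function(q) sort(unique(q$mdf)))
  qrels <- purrr::map_dfr(seq_len(cfg$n_queries), function(qi) {
    qs <- q_sets[[qi]]
    s <- purrr::map_dbl(doc_sets, function(ds) {
      if (length(qs) == 0 || length(ds) == 0) return(0)
      mean(apply(ssm$values[ds, qs, drop = FALSE], 2, max))
    })
    rel <- as.integer(s >= cfg$tau)
    if (cfg$epsilon > 0) {
      flip <- stats::runif(length(rel)) < cfg$epsilon
      rel[flip] <- 1L - rel[flip]
    }
    tibble::tibble(query_id = queries$id[qi], doc_id = corpus$id[rel == 1L],
                   rel = 1L)
  })
  list(corpus = corpus, queries = queries, qrels = qrels)
}

#' Write a synthetic collection to disk
#'
#' Writes `corpus.jsonl` and `queries.jsonl` (one `{"id": ..., "text": ...}`
#' object per line) and `qrels.txt` in TREC qrels format.
#'
#' @param collection List as returned by [generate_collection()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(collection, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_jsonl <- function(df, path) {
    lines <- purrr::map_chr(seq_len(nrow(df)), function(i) {
      jsonlite::toJSON(list(id = df$id[i], text = df$text[i]),
                       auto_unbox = TRUE)
    })
    writeLines(lines, path)
  }
  write_jsonl(collection$corpus, file.path(dir, "corpus.jsonl"))
  write_jsonl(collection$queries, file.path(dir, "queries.jsonl"))
  write_qrels(collection$qrels, file.path(dir, "qrels.txt"))
  invisible(dir)
}

#' Read a JSONL corpus or query file
#'
#' @param path File with one `{"id": ..., "text": ...}` object per line.
#' @return Tibble with columns `id` and `text`.
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path)
  purrr::map_dfr(lines, function(l) {
    obj <- jsonlite::fromJSON(l)
    tibble::tibble(id = obj$id, text = obj$text)
  })
}
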