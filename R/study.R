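#' Replicated synthetic improvement study
#'
#' Runs the full pipeline on seeded replicates of the default synthetic
#' collection and evaluates the BM25 baseline, the DMM-only ranking
#' (fusion weight 0) and the fused SemRank ranking at the given alpha
#' against the generated qrels. This is the package's standard end-to-end
#' benchmark: each replicate draws a fresh collection and fixture similarity
#' matrix from its own seed.
#'
#' @param n_reps Number of replicates.
#' @param base_seed Integer; replicate r uses seed `base_seed + r - 1` for
#'   both the collection and the fixture similarity matrix.
#' @param cfg A [synth_config()] (its `seed` field is overridden per
#'   replicate).
#' @param alpha Fusion weight for the SemRank run.
#' @param vocab An [mdf_vocabulary()] object.
#' @return Tibble with one row per replicate: `rep`, `seed`, `n_relevant`,
#'   `bm25_map`, `dmm_map`, `semrank_map`, `bm25_p5`, `semrank_p5`,
#'   `bm25_p10`, `semrank_p10`.
#' @export
improvement_study <- function(n_reps = 20, base_seed = 1,
                              cfg = synth_config(), alpha = 0.3,
                              vocab = mdf_vocabulary()) {
  purrr::map_dfr(seq_len(n_reps), function(r) {
    seed <- base_seed + r - 1
    cfg_r <- cfg
    cfg_r$seed <- as.integer(seed)
    ssm <- fixture_ssm(vocab, seed = seed)
    coll <- generate_collection(cfg_r, vocab, ssm)
    rr <- semrank_rerank(coll$corpus, coll$queries, ssm, vocab,
                         cfg = semrank_config(alpha = alpha))
    ev <- function(run) suppressWarnings(evaluate_run(run, coll$qrels))
    e_bm <- ev(rr$baseline)
    e_dmm <- ev(semrank_fuse(rr$baseline, rr$dmm, alpha = 0))
    e_sem <- ev(rr$run)
    tibble::tibble(rep = r, seed = seed, n_relevant = nrow(coll$qrels),
                   bm25_map = e_bm$map, dmm_map = e_dmm$map,
                   semrank_map = e_sem$map,
                   bm25_p5 = e_bm$p5, semrank_p5 = e_sem$p5,
                   bm25_p10 = e_bm$p10, semrank_p10 = e_sem$p10)
  })
}
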