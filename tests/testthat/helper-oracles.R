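# Independent brute-force oracles: straight loops over sets and positions,
# sharing no code with the package internals. Annotations are plain integer
# vectors of 1-based vocabulary indices here; `docs` is a list of such
# vectors (one per document).

oracle_stats <- function(docs, n) {
  df <- integer(n)
  codf <- matrix(0L, n, n)
  for (d in docs) {
    present <- unique(d)
    for (i in present) df[i] <- df[i] + 1L
    for (i in present) for (j in present) codf[i, j] <- codf[i, j] + 1L
  }
  list(N = length(docs), df = df, codf = codf)
}

oracle_pmi <- function(i, j, ost, N) log(N * ost$codf[i, j] / (ost$df[i] * ost$df[j]))

oracle_co_qf <- function(Q, D, ost) {
  q <- unique(Q); d <- unique(D)
  if (length(q) == 0 || length(d) == 0) return(0)
  num <- 0
  for (j in q) for (i in d) num <- num + ost$codf[i, j]
  den <- 0
  for (i in d) den <- den + ost$df[i]
  if (den == 0) 0 else num / den
}

oracle_l_qf <- function(Q, D) {
  q <- unique(Q); d <- unique(D)
  if (length(q) == 0 || length(d) == 0) return(0)
  for (j in q) if (!(j %in% d)) return(0)
  sum(d %in% q) / length(d)
}

oracle_r_qf <- function(rank) if (is.na(rank)) 0 else 1 / rank

oracle_p_qf <- function(Q, D) {
  qset <- unique(Q)
  pos <- integer(0)
  for (k in seq_along(D)) if (D[k] %in% qset) pos <- c(pos, k)
  if (length(pos) == 0) return(0)
  total <- 0
  if (length(pos) > 1) {
    for (k in 2:length(pos)) total <- total + (pos[k] - pos[k - 1] - 1)
  }
  1 / (1 + total)
}

oracle_pmi_qf <- function(Q, D, ost) {
  vals <- c()
  for (j in unique(Q)) for (i in unique(D)) {
    if (ost$df[i] > 0 && ost$df[j] > 0 && ost$codf[i, j] > 0) {
      vals <- c(vals, oracle_pmi(i, j, ost, ost$N))
    }
  }
  if (length(vals) == 0) 0 else mean(vals)
}

oracle_fd_qf <- function(Q, D) {
  missing <- 0
  for (j in unique(Q)) if (!(j %in% D)) missing <- missing + 1
  1 / (1 + missing)
}

oracle_co_df <- function(Q, D) sum(unique(Q) %in% unique(D))

oracle_l_df <- function(Q, D) {
  d <- unique(D)
  if (length(d) == 0) return(0)
  sum(d %in% unique(Q)) / length(d)
}

oracle_r_df <- function(Q, D) {
  freq <- 0
  for (j in unique(Q)) freq <- freq + sum(D == j)
  if (freq == 0) return(0)
  first_order <- unique(Q)
  first_order <- first_order[first_order %in% D]
  gamma <- 1
  if (length(first_order) > 1) {
    p <- 1
    for (x in D) {
      if (p <= length(first_order) && x == first_order[p]) p <- p + 1
    }
    if (p <= length(first_order)) gamma <- 0.5
  }
  freq * gamma
}

oracle_p_df <- function(Q, D) {
  k <- sum(unique(D) %in% unique(Q))
  if (k == 0) 0 else 1 / k
}

oracle_pmi_df <- function(D, ost) {
  d <- unique(D)
  vals <- c()
  if (length(d) >= 2) {
    for (a in seq_along(d)) for (b in seq_along(d)) {
      if (a < b) {
        i <- d[a]; j <- d[b]
        if (ost$df[i] > 0 && ost$df[j] > 0 && ost$codf[i, j] > 0) {
          vals <- c(vals, oracle_pmi(i, j, ost, length(D)))
        }
      }
    }
  }
  if (length(vals) == 0) 0 else mean(vals)
}

oracle_fd_df <- function(Q, D) {
  extra <- 0
  for (i in unique(D)) if (!(i %in% Q)) extra <- extra + 1
  1 / (1 + extra)
}

# Reference IR metric implementations: rank-by-rank loops.
ref_precision_at_k <- function(ranked, rel_ids, k) {
  hits <- 0
  for (r in seq_len(min(k, length(ranked)))) {
    if (ranked[r] %in% rel_ids) hits <- hits + 1
  }
  hits / k
}

ref_average_precision <- function(ranked, rel_ids) {
  R <- length(rel_ids)
  if (R == 0) return(0)
  total <- 0; hits <- 0
  for (r in seq_along(ranked)) {
    if (ranked[r] %in% rel_ids) {
      hits <- hits + 1
      total <- total + hits / r
    }
  }
  total / R
}

# The hand-counted reference corpus used across the filter tests:
# three documents over a four-value vocabulary a=1, b=2, c=3, d=4.
ref_corpus <- function() {
  docs <- list(c(1L, 2L), c(2L, 3L), c(1L, 3L, 4L))
  ann <- lapply(docs, semrank::new_annotation, n = 4)
  list(docs = docs, ann = ann,
       stats = semrank::corpus_statistics(ann))
}

# Random tiny filter context for the oracle suite.
random_context <- function(n_vocab = 8) {
  n_docs <- sample(2:5, 1)
  docs <- lapply(seq_len(n_docs), function(i) {
    sample.int(n_vocab, sample(1:6, 1), replace = TRUE)
  })
  Q <- sample.int(n_vocab, sample(1:4, 1), replace = TRUE)
  D <- docs[[sample.int(n_docs, 1)]]
  rank <- if (runif(1) < 0.2) NA_integer_ else sample.int(20, 1)
  list(docs = docs, Q = Q, D = D, rank = rank, n = n_vocab)
}

# Tiny concrete vocabulary written to a temp YAML, for annotation tests.
tiny_vocab_yaml <- function() {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  writeLines(c(
    "categories:",
    "  Modality:",
    "    Magnetic Resonance Imaging: [MRI]",
    "    Computerized Tomography: [CT]",
    "    Electron Microscopy: []",
    "    Transmission Microscopy: []",
    "  Condition:",
    "    Cancer: [carcinoma]",
    "    Fracture: []"
  ), path)
  path
}
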