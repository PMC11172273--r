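#' Semantic similarity matrices over the MDF vocabulary
#'
#' An `ssm` object is the n x n symmetric matrix of pairwise semantic
#' similarities between feature values, with entries in \[0, 1\] and unit
#' diagonal. In production use the raw similarities come from an external
#' ontology-based computation (information-content measures such as Resnik
#' over a medical metathesaurus are unbounded above), so loading normalizes
#' them; for testing a seeded random fixture with within-category structure is
#' provided.
#'
#' @name ssm
NULL

new_ssm <- function(values, provenance) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  structure(list(n = nrow(values), values = values, provenance = provenance),
            class = "ssm")
}

#' @export
print.ssm <- function(x, ...) {
  cat("<ssm> ", x$n, " x ", x$n, " (", x$provenance, ")\n", sep = "")
  invisible(x)
}

#' Load a semantic similarity matrix from TSV
#'
#' Reads a tab-separated matrix whose first row and first column hold
#' canonical vocabulary value names, reindexes it to vocabulary order,
#' symmetrizes by averaging (path-based ontology tools can emit asymmetric
#' estimates), and -- when `normalize` is `TRUE` -- min-max rescales the
#' off-diagonal entries to \[0, 1\] and forces the diagonal to 1, making
#' downstream cosine scores stable across similarity measures with different
#' ranges.
#'
#' @param path TSV file; cell (i, j) is a raw non-negative similarity.
#' @param vocab An [mdf_vocabulary()] object; every canonical value must be
#'   present in the file.
#' @param normalize Min-max normalize off-diagonal entries and force the
#'   diagonal to 1 (default `TRUE`).
#' @return An `ssm` object with `provenance = "external"`.
#' @export
load_ssm <- function(path, vocab, normalize = TRUE) {
  stopifnot(inherits(vocab, "mdf_vocabulary"))
  raw <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(raw)
  missing <- setdiff(vocab$values$value, intersect(rownames(m), colnames(m)))
  if (length(missing) > 0) {
    stop("similarity matrix is missing vocabulary value(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- m[vocab$values$value, vocab$values$value]
  if (any(m < 0)) stop("negative entries in similarity matrix", call. = FALSE)
  m <- (m + t(m)) / 2
  if (normalize) m <- normalize_ssm_values(m)
  dimnames(m) <- list(vocab$values$value, vocab$values$value)
  new_ssm(m, "external")
}

# Min-max rescale off-diagonal entries to [0,1]. Degenerate constant
# off-diagonal: positive constants map to 1, an all-zero off-diagonal stays 0.
# Diagonal forced to 1.
normalize_ssm_values <- function(m) {
  off <- m[row(m) != col(m)]
  if (length(off) > 0) {
    lo <- min(off); hi <- max(off)
    if (hi > lo) {
      m <- (m - lo) / (hi - lo)
    } else if (hi > 0) {
      m[] <- 1
    }
  }
  m[m < 0] <- 0
  m[m > 1] <- 1
  diag(m) <- 1
  m
}

#' Write a semantic similarity matrix to TSV
#'
#' Inverse of [load_ssm()]'s file format: first row and column are canonical
#' value names.
#'
#' @param ssm An `ssm` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ssm <- function(ssm, path) {
  stopifnot(inherits(ssm, "ssm"))
  fmt <- matrix(sprintf("%.17g", ssm$values), ssm$n, ssm$n,
                dimnames = dimnames(ssm$values))  # round-trips doubles exactly
  utils::write.table(as.data.frame(fmt), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Seeded fixture semantic similarity matrix
#'
#' Generates a deterministic stand-in for an ontology-derived similarity
#' matrix: symmetric Uniform(0, 0.5) background entries, plus
#' `within_category_boost` added to pairs of values in the same MDF category
#' before clipping to \[0, 1\] (modelling ontology locality: values under one
#' modality family are closer than values across families), with unit
#' diagonal.
#'
#' @param vocab An [mdf_vocabulary()] object.
#' @param seed Integer seed; the matrix is a pure function of (vocab, seed,
#'   boost).
#' @param within_category_boost Amount added to same-category pairs, in
#'   \[0, 1\] (default 0.5).
#' @return An `ssm` object with `provenance = "fixture"`.
#' @export
fixture_ssm <- function(vocab, seed, within_category_boost = 0.5) {
  stopifnot(inherits(vocab, "mdf_vocabulary"),
            within_category_boost >= 0, within_category_boost <= 1)
  n <- vocab_size(vocab)
  withr::local_seed(as.integer(seed))
  m <- matrix(stats::runif(n * n, 0, 0.5), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  same_cat <- outer(vocab$values$category, vocab$values$category, "==")
  m <- m + within_category_boost * same_cat
  m[m > 1] <- 1
  diag(m) <- 1
  dimnames(m) <- list(vocab$values$value, vocab$values$value)
  new_ssm(m, "fixture")
}

#' Per-item feature matrix (NQM)
#'
#' Builds the matrix fed to the convolutional filters: the binary presence
#' vector V is broadcast row-wise into M (M\[i, j\] = V\[i\]), then masked
#' elementwise against the semantic similarity matrix, NQM\[i, j\] =
#' M\[i, j\] * SSM\[i, j\]. Row i therefore carries value i's similarity
#' profile when the item contains value i, and is zero otherwise.
#'
#' @param v Binary 0/1 vector of length `ssm$n` (see [to_binary_vector()]).
#' @param ssm An `ssm` object.
#' @return n x n numeric matrix.
#' @export
build_feature_matrix <- function(v, ssm) {
  stopifnot(inherits(ssm, "ssm"))
  if (length(v) != ssm$n) {
    stop("binary vector length ", length(v), " != ssm dimension ", ssm$n,
         call. = FALSE)
  }
  as.numeric(v) * ssm$values  # column-major recycling multiplies row i by v[i]
}
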