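#' Medical-Dependent Feature (MDF) vocabulary
#'
#' Loads the catalogue of Medical-Dependent Features: an ordered set of
#' categories (imaging modality families, dimensionality, colour, test and
#' condition specifics), each holding an ordered list of canonical feature
#' values, optionally with synonym surface forms. Queries and image captions
#' are represented over this closed vocabulary; every downstream matrix and
#' filter is indexed by its dense value index.
#'
#' The packaged default vocabulary has 9 categories and 87 values covering
#' radiology, microscopy, visible-light photography, printed signals and
#' waves, generic biomedical illustrations, dimensionality and
#' visual/test/condition specifics.
#'
#' @param source `"default"` for the packaged vocabulary, or the path to a
#'   YAML file of the form `categories: {<category>: {<canonical>: [synonyms]}}`.
#' @return An object of class `mdf_vocabulary`: a list with elements
#'   `categories` (character), `values` (tibble with columns `index`,
#'   `category`, `value`), `synonyms` (named list, canonical value ->
#'   character vector of surface forms), and `index` (named integer, canonical
#'   value -> dense 1-based index).
#' @examples
#' vocab <- mdf_vocabulary()
#' length(vocab$categories)  # 9
#' nrow(vocab$values)        # 87
#' @export
mdf_vocabulary <- function(source = "default") {
  path <- if (identical(source, "default")) {
    system.file("extdata", "mdf_vocabulary.yaml", package = "semrank", mustWork = TRUE)
  } else {
    source
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$categories) || length(raw$categories) == 0) {
    stop("vocabulary source has no `categories` block", call. = FALSE)
  }
  cats <- names(raw$categories)
  rows <- purrr::imap(raw$categories, function(vals, cat) {
    if (length(vals) == 0) {
      stop("empty category in vocabulary: ", cat, call. = FALSE)
    }
    tibble::tibble(category = cat, value = names(vals))
  })
  values <- dplyr::bind_rows(rows[cats])
  dup <- values$value[duplicated(values$value)]
  if (length(dup) > 0) {
    stop("duplicate canonical value(s) in vocabulary: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  values <- dplyr::mutate(values, index = dplyr::row_number(), .before = 1)
  synonyms <- purrr::flatten(purrr::map(raw$categories, function(vals) {
    purrr::map(vals, function(s) as.character(unlist(s)))
  }))
  synonyms <- synonyms[values$value]
  all_surface <- tolower(c(values$value, unlist(synonyms, use.names = FALSE)))
  dup_surface <- unique(all_surface[duplicated(all_surface)])
  if (length(dup_surface) > 0) {
    stop("surface form(s) mapping to more than one canonical value: ",
         paste(dup_surface, collapse = ", "), call. = FALSE)
  }
  idx <- stats::setNames(values$index, values$value)
  out <- structure(
    list(categories = cats, values = values, synonyms = synonyms, index = idx),
    class = "mdf_vocabulary"
  )
  out$surface <- surface_table(out)
  out
}

#' @export
print.mdf_vocabulary <- function(x, ...) {
  cat("<mdf_vocabulary> ", nrow(x$values), " values in ",
      length(x$categories), " categories\n", sep = "")
  invisible(x)
}

#' Number of feature values in a vocabulary
#' @param vocab An [mdf_vocabulary()] object.
#' @return Integer count of (category, value) pairs.
#' @export
vocab_size <- function(vocab) {
  stopifnot(inherits(vocab, "mdf_vocabulary"))
  nrow(vocab$values)
}

#' Write a vocabulary back to YAML
#'
#' Produces the same `categories:` mapping layout [mdf_vocabulary()] reads, so
#' that export followed by import reproduces the vocabulary exactly.
#'
#' @param vocab An [mdf_vocabulary()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "mdf_vocabulary"))
  by_cat <- split(vocab$values$value, vocab$values$category)[vocab$categories]
  out <- list(categories = purrr::map(by_cat, function(vals) {
    stats::setNames(purrr::map(vals, function(v) as.list(vocab$synonyms[[v]])), vals)
  }))
  yaml::write_yaml(out, path)
  invisible(path)
}

# Build the surface-form match table: one row per surface form (canonical
# values and synonyms), with a whitespace/hyphen-tolerant regex and the
# longest-match-first priority (token count desc, char length desc, then
# vocabulary order).
surface_table <- function(vocab) {
  rows <- purrr::map2_dfr(vocab$values$value, vocab$values$index, function(v, k) {
    tibble::tibble(surface = c(v, vocab$synonyms[[v]]), index = k)
  })
  toks <- stringr::str_split(tolower(rows$surface), "[\\s-]+")
  rows$n_tok <- lengths(toks)
  rows$n_chr <- nchar(rows$surface)
  esc <- purrr::map_chr(toks, function(t) {
    paste0(purrr::map_chr(t, function(x) {
      stringr::str_replace_all(x, "([\\\\.^$|()\\[\\]{}*+?])", "\\\\\\1")
    }), collapse = "[\\s-]+")
  })
  rows$pattern <- paste0("(?<![[:alnum:]])", esc, "(?![[:alnum:]])")
  rows[order(-rows$n_tok, -rows$n_chr, rows$index), ]
}

#' Annotate free text with MDF occurrences
#'
#' Scans text for vocabulary surface forms (canonical values and synonyms),
#' case-insensitively, on token boundaries, longest match first; shorter
#' matches nested inside or overlapping an accepted longer match are
#' suppressed. Duplicate occurrences are retained in text order because the
#' proximity and organization filters need positions.
#'
#' This lexicon matcher is the package's concept annotator: a deterministic
#' dictionary pass over the closed MDF terminology.
#'
#' @param text A single character string (may be empty).
#' @param vocab An [mdf_vocabulary()] object.
#' @return An object of class `mdf_annotation`: list with `occurrences`
#'   (integer vector of 1-based vocabulary indices in text order), `distinct`
#'   (sorted unique indices), `n` (vocabulary size).
#' @examples
#' v <- mdf_vocabulary()
#' mdf_annotate("MRI of the chest, suspected cancer", v)$occurrences
#' @export
mdf_annotate <- function(text, vocab) {
  stopifnot(inherits(vocab, "mdf_vocabulary"), is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(new_annotation(integer(0), vocab_size(vocab)))
  }
  tab <- vocab$surface %||% surface_table(vocab)
  low <- tolower(text)
  taken <- rep(FALSE, nchar(low))
  hits <- list()
  for (r in seq_len(nrow(tab))) {
    loc <- stringr::str_locate_all(low, stringr::regex(tab$pattern[r]))[[1]]
    if (nrow(loc) == 0) next
    for (m in seq_len(nrow(loc))) {
      span <- loc[m, 1]:loc[m, 2]
      if (any(taken[span])) next
      taken[span] <- TRUE
      hits[[length(hits) + 1]] <- c(start = unname(loc[m, 1]),
                                    index = tab$index[r])
    }
  }
  if (length(hits) == 0) {
    return(new_annotation(integer(0), vocab_size(vocab)))
  }
  hits <- do.call(rbind, hits)
  occ <- as.integer(hits[order(hits[, "start"]), "index"])
  new_annotation(occ, vocab_size(vocab))
}

#' Construct an MDF annotation from raw indices
#'
#' Low-level constructor used by the annotator, the synthetic-data generator
#' and tests; validates that indices fall inside the vocabulary.
#'
#' @param occurrences Integer vector of 1-based vocabulary indices, text order,
#'   duplicates allowed.
#' @param n Vocabulary size.
#' @return An `mdf_annotation` object.
#' @export
new_annotation <- function(occurrences, n) {
  occurrences <- as.integer(occurrences)
  if (length(occurrences) > 0 && (min(occurrences) < 1 || max(occurrences) > n)) {
    stop("annotation index outside vocabulary [1, ", n, "]", call. = FALSE)
  }
  structure(
    list(occurrences = occurrences,
         distinct = sort(unique(occurrences)),
         n = as.integer(n)),
    class = "mdf_annotation"
  )
}

#' @export
print.mdf_annotation <- function(x, ...) {
  cat("<mdf_annotation> ", length(x$occurrences), " occurrence(s), ",
      length(x$distinct), " distinct (vocab n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Binary MDF presence vector
#'
#' Maps an annotation to the 0/1 vector V of length n with V\[k\] = 1 iff
#' feature value k occurs in the annotated text. This is the vector that is
#' broadcast into the feature matrix M and masked against the semantic
#' similarity matrix.
#'
#' @param ann An `mdf_annotation`.
#' @param vocab An [mdf_vocabulary()] object (defines n).
#' @return Integer 0/1 vector of length `vocab_size(vocab)`.
#' @export
to_binary_vector <- function(ann, vocab) {
  stopifnot(inherits(ann, "mdf_annotation"), inherits(vocab, "mdf_vocabulary"))
  n <- vocab_size(vocab)
  if (length(ann$distinct) > 0 && max(ann$distinct) > n) {
    stop("annotation refers to index ", max(ann$distinct),
         " beyond vocabulary size ", n, call. = FALSE)
  }
  v <- integer(n)
  v[ann$distinct] <- 1L
  v
}

#' Annotate a corpus tibble
#'
#' Convenience wrapper mapping [mdf_annotate()] over a tibble of documents or
#' queries, adding a list-column of annotations.
#'
#' @param x A tibble with columns `id` and `text`.
#' @param vocab An [mdf_vocabulary()] object.
#' @return `x` with an added list-column `ann` of `mdf_annotation` objects.
#' @export
annotate_corpus <- function(x, vocab) {
  stopifnot(is.data.frame(x), all(c("id", "text") %in% names(x)))
  dplyr::mutate(tibble::as_tibble(x),
                ann = purrr::map(.data$text, mdf_annotate, vocab = vocab))
}
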