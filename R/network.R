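#' Forward-pass configuration
#'
#' The matching network has no trained parameters: no loss, labels or
#' optimizer are part of the method, so the fully connected layer defaults to
#' the identity map and the network acts as a deterministic feature
#' aggregator. A seeded random weight matrix is available for ablation.
#'
#' @param fcl_weights 6 x 6 weight matrix of the fully connected layer
#'   (default identity).
#' @param fcl_bias Length-6 bias (default zero).
#' @param vectorization_mode How a scalar filter score is lifted to a
#'   length-n filter vector before convolution: `"active_mask"` (score on the
#'   item's active vocabulary positions, 0 elsewhere; default) or
#'   `"constant"` (score broadcast to all positions).
#' @param seed When given and `fcl_weights` is `NULL`, draws a seeded random
#'   Uniform(0, 1) 6 x 6 weight matrix.
#' @return An object of class `network_config`.
#' @export
network_config <- function(fcl_weights = NULL, fcl_bias = rep(0, 6),
                           vectorization_mode = c("active_mask", "constant"),
                           seed = NULL) {
  vectorization_mode <- match.arg(vectorization_mode)
  if (is.null(fcl_weights)) {
    if (is.null(seed)) {
      fcl_weights <- diag(6)
    } else {
      withr::local_seed(as.integer(seed))
      fcl_weights <- matrix(stats::runif(36), 6, 6)
    }
  }
  stopifnot(is.matrix(fcl_weights), all(dim(fcl_weights) == c(6, 6)),
            all(is.finite(fcl_weights)), length(fcl_bias) == 6)
  structure(list(fcl_weights = fcl_weights, fcl_bias = as.numeric(fcl_bias),
                 vectorization_mode = vectorization_mode),
            class = "network_config")
}

#' Lift a scalar filter score to a filter vector
#'
#' The twelve retrieval filters are scalar formulas, while the convolutional
#' layer consumes length-n filter vectors; this bridges the two. In
#' `active_mask` mode the score is placed on the item's active vocabulary
#' positions (F\[k\] = score * V\[k\]), in `constant` mode it is broadcast to
#' every position. The two coincide when V is all-ones.
#'
#' @param score Scalar filter score.
#' @param active Binary 0/1 vector of length n (the item's presence vector).
#' @param mode `"active_mask"` or `"constant"`.
#' @return Numeric vector of length `length(active)`.
#' @export
vectorize_filter <- function(score, active, mode = c("active_mask", "constant")) {
  mode <- match.arg(mode)
  if (mode == "active_mask") score * as.numeric(active)
  else rep(score, length(active))
}

#' Convolve a feature matrix with a filter vector
#'
#' Each component of the feature map is the dot product of one feature-matrix
#' row with the filter: C\[i\] = sum_k NQM\[i, k\] * F\[k\]. One value per
#' vocabulary row, so the map has length n.
#'
#' @param nqm n x n feature matrix (see [build_feature_matrix()]).
#' @param f Filter vector of length n.
#' @return Numeric feature map of length n.
#' @export
convolve_filter <- function(nqm, f) {
  if (!is.matrix(nqm) || ncol(nqm) != length(f)) {
    stop("dimension mismatch: feature matrix is ", nrow(nqm), " x ",
         ncol(nqm), ", filter has length ", length(f), call. = FALSE)
  }
  as.numeric(nqm %*% f)
}

#' Rectified linear activation
#' @param x Numeric vector.
#' @return `pmax(x, 0)`.
#' @export
relu <- function(x) pmax(x, 0)

#' Max-pooling of a feature map
#' @param x Non-empty numeric vector.
#' @return The maximum element.
#' @export
max_pool <- function(x) {
  if (length(x) == 0) stop("cannot max-pool an empty feature map", call. = FALSE)
  max(x)
}

#' Fully connected layer
#' @param p Length-6 pooled vector.
#' @param cfg A [network_config()].
#' @return Length-6 numeric representation vector.
#' @export
fully_connected <- function(p, cfg) {
  stopifnot(inherits(cfg, "network_config"), length(p) == 6)
  as.numeric(cfg$fcl_weights %*% p + cfg$fcl_bias)
}

#' Build the fixed-length representation of one side
#'
#' Runs the full forward pass for a query or a document: each of the side's
#' six filter scores is lifted to a filter vector, convolved against the
#' item's feature matrix, passed through ReLU and max-pooled to one scalar;
#' the six pooled scalars are then mapped through the fully connected layer.
#'
#' @param nqm The item's feature matrix ([build_feature_matrix()]).
#' @param side_scores Named or unnamed numeric vector of the side's 6 filter
#'   scores (query filters for a query, document filters for a document).
#' @param active The item's binary presence vector.
#' @param cfg A [network_config()].
#' @return Length-6 numeric representation.
#' @export
represent <- function(nqm, side_scores, active, cfg = network_config()) {
  stopifnot(length(side_scores) == 6)
  pooled <- purrr::map_dbl(as.numeric(side_scores), function(s) {
    f <- vectorize_filter(s, active, mode = cfg$vectorization_mode)
    max_pool(relu(convolve_filter(nqm, f)))
  })
  fully_connected(pooled, cfg)
}
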