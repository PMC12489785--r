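#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# All unordered node pairs of a label vector, as a two-column character matrix
# in canonical order (i < j by position).
all_pairs <- function(labels) {
  n <- length(labels)
  if (n < 2) return(matrix(character(), ncol = 2))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(labels[idx[, 1]], labels[idx[, 2]])
}

# Euclidean distance matrix between rows of two coordinate matrices (n x 3).
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

coord_matrix <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("x", "y", "z") %in% names(x)))
    x <- cbind(x$x, x$y, x$z)
  }
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, ncol = 3)
  stopifnot(is.matrix(x), ncol(x) == 3)
  x
}
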