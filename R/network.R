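#' Binary connectivity network over electrode contact nodes
#'
#' A `binary_network` is a symmetric, zero-diagonal boolean adjacency matrix
#' whose rows/columns are labelled electrode contacts. It is the common
#' container for both structural (streamline-density) and effective
#' (CCEP-derived) networks, so that similarity and topology functions apply
#' to either modality.
#'
#' @param adjacency Square logical or 0/1 numeric matrix with identical row
#'   and column names (contact labels). Must be symmetric; the diagonal is
#'   forced to `FALSE`.
#' @param labels Optional character vector of node labels, used when
#'   `adjacency` carries no dimnames.
#' @return An object of class `binary_network`: a logical adjacency matrix
#'   with attributes preserved.
#' @examples
#' adj <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
#' adj["a", "b"] <- adj["b", "a"] <- 1
#' net <- binary_network(adj)
#' network_density(net)
#' @export
binary_network <- function(adjacency, labels = NULL) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    stop("`adjacency` must be a square matrix.", call. = FALSE)
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(adjacency)) {
      stop("`labels` length does not match adjacency dimension.", call. = FALSE)
    }
    dimnames(adjacency) <- list(labels, labels)
  }
  if (is.null(rownames(adjacency))) {
    lab <- sprintf("n%02d", seq_len(nrow(adjacency)))
    dimnames(adjacency) <- list(lab, lab)
  }
  if (!identical(rownames(adjacency), colnames(adjacency))) {
    stop("Row and column labels must be identical.", call. = FALSE)
  }
  if (anyDuplicated(rownames(adjacency))) {
    stop("Node labels must be unique.", call. = FALSE)
  }
  a <- adjacency
  if (is.numeric(a)) {
    if (any(!a %in% c(0, 1))) {
      stop("Adjacency entries must be 0/1 or logical.", call. = FALSE)
    }
    storage.mode(a) <- "logical"
  }
  if (!is.logical(a)) stop("Adjacency must be logical or 0/1 numeric.", call. = FALSE)
  if (anyNA(a)) stop("Adjacency must not contain NA.", call. = FALSE)
  if (!isTRUE(all(a == t(a)))) stop("Adjacency must be symmetric.", call. = FALSE)
  diag(a) <- FALSE
  class(a) <- c("binary_network", class(a))
  a
}

#' Build a binary network from an edge list
#'
#' @param edges Data frame with columns `from` and `to` (contact labels).
#' @param labels Character vector of all node labels (fixes node order; may
#'   include isolated nodes).
#' @return A [binary_network()].
#' @export
network_from_edges <- function(edges, labels) {
  stopifnot(is.character(labels), length(labels) >= 2)
  a <- matrix(FALSE, length(labels), length(labels), dimnames = list(labels, labels))
  if (nrow(edges) > 0) {
    bad <- !(edges$from %in% labels) | !(edges$to %in% labels)
    if (any(bad)) stop("Edge endpoints not among node labels.", call. = FALSE)
    for (k in seq_len(nrow(edges))) {
      i <- edges$from[k]; j <- edges$to[k]
      if (i != j) {
        a[i, j] <- TRUE
        a[j, i] <- TRUE
      }
    }
  }
  binary_network(a)
}

#' @export
print.binary_network <- function(x, ...) {
  n <- nrow(x)
  e <- sum(x) / 2
  cat(sprintf("<binary_network> %d nodes, %d undirected edges, density %.3f\n",
              n, e, if (n >= 2) sum(x) / (n * (n - 1)) else NA_real_))
  invisible(x)
}

#' Tidy a binary network into an undirected edge list
#'
#' @param x A [binary_network()].
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, one row per undirected edge
#'   (`from` precedes `to` in node order).
#' @export
tidy.binary_network <- function(x, ...) {
  idx <- which(upper.tri(x) & x, arr.ind = TRUE)
  tibble::tibble(
    from = rownames(x)[idx[, 1]],
    to = colnames(x)[idx[, 2]]
  )
}

#' @export
as.matrix.binary_network <- function(x, ...) {
  a <- unclass(x)
  storage.mode(a) <- "integer"
  a
}

network_labels <- function(net) rownames(net)

assert_same_nodes <- function(a, b) {
  if (!identical(rownames(a), rownames(b))) {
    stop("Networks must share an identical node set and ordering.", call. = FALSE)
  }
  invisible(TRUE)
}

#' Adjacency heat-map of one or two binary networks
#'
#' With a single network, tiles mark present connections. With two networks
#' (structural and effective), tiles distinguish intersection and
#' modality-unique connections, mirroring the usual side-by-side adjacency
#' comparison of the two modalities.
#'
#' @param object A [binary_network()].
#' @param other Optional second [binary_network()] on the same nodes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binary_network <- function(object, other = NULL, ...) {
  lab <- rownames(object)
  df <- tidyr::expand_grid(from = lab, to = lab)
  a <- unclass(object)
  if (is.null(other)) {
    df$status <- ifelse(a[cbind(df$from, df$to)], "connected", "absent")
    palette <- c(connected = "#2166ac", absent = "grey95")
  } else {
    assert_same_nodes(object, other)
    b <- unclass(other)
    s <- a[cbind(df$from, df$to)]
    e <- b[cbind(df$from, df$to)]
    df$status <- dplyr::case_when(
      s & e ~ "both",
      s ~ "structural only",
      e ~ "effective only",
      TRUE ~ "absent"
    )
    palette <- c(`both` = "#e08214", `structural only` = "#2166ac",
                 `effective only` = "#1b7837", absent = "grey95")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from, fill = .data$status)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = palette, name = NULL) +
    ggplot2::scale_y_discrete(limits = rev(lab)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}
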