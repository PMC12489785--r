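# Independent brute-force oracles used to cross-check the implementation.

# Betweenness by exhaustive enumeration of simple paths: for each unordered
# pair (s, t), list all simple paths recursively, keep the shortest, and
# credit every interior node with its share of shortest paths.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        out[[length(out) + 1]] <<- path
        return(invisible())
      }
      for (nb in which(adj[last, ] == 1)) {
        if (!(nb %in% path)) walk(c(path, nb))
      }
    }
    walk(s)
    out
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      ps <- paths_between(s, t)
      if (length(ps) == 0) next
      lens <- lengths(ps)
      shortest <- ps[lens == min(lens)]
      for (p in shortest) {
        interior <- p[-c(1, length(p))]
        bc[interior] <- bc[interior] + 1 / length(shortest)
      }
    }
  }
  bc
}

# Random symmetric zero-diagonal 0/1 adjacency with labels.
random_adjacency <- function(n, p_edge = 0.4) {
  a <- matrix(0L, n, n)
  up <- upper.tri(a)
  a[up] <- as.integer(stats::runif(sum(up)) < p_edge)
  a <- a + t(a)
  dimnames(a) <- list(sprintf("v%d", 1:n), sprintf("v%d", 1:n))
  a
}

# Shorthand: binary network on given labels from "a-b" edge strings.
net_from_strings <- function(labels, edges) {
  df <- if (length(edges) == 0) {
    tibble::tibble(from = character(), to = character())
  } else {
    parts <- strsplit(edges, "-", fixed = TRUE)
    tibble::tibble(from = vapply(parts, `[`, "", 1),
                   to = vapply(parts, `[`, "", 2))
  }
  network_from_edges(df, labels)
}

# Pure-noise ERP set: n_erps independent noise channels through the real
# epoching/averaging machinery (single pre-averaged epoch; the 10-epoch
# averaging identity is covered by its own tests). Two extra channels act as
# the stimulated pair. Window spans -2 s to +0.15 s around the stimulus.
make_noise_erps <- function(n_erps, fs = 2048, sd = 1, modality = "ECoG",
                            seed = 1) {
  channels <- c("stimA", "stimB", sprintf("c%04d", seq_len(n_erps)))
  rel <- seq(round(-2 * fs), round(0.15 * fs) - 1)
  n_samp <- length(rel)
  arr <- withr::with_seed(seed, {
    array(stats::rnorm(n_samp * length(channels), sd = sd),
          dim = c(n_samp, length(channels), 1),
          dimnames = list(NULL, channels, NULL))
  })
  epochs <- structure(list(
    trials = tibble::tibble(pair_id = 1L, site = "stimA-stimB",
                            anode = "stimA", cathode = "stimB", n_epochs = 1L),
    data = list(arr),
    times = rel / fs, fs = fs, channels = channels,
    modality = modality, n_dropped = 0L
  ), class = "spes_epochs")
  average_erp(epochs)
}
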