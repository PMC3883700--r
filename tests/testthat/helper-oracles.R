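# Independent oracles used across the suite.  Each is a deliberately naive
# implementation: exhaustive enumeration or a literal transcription of the
# defining formula, kept separate from the package's own code paths.

# --- brute-force normalized betweenness by explicit shortest-path
#     enumeration (all simple paths; only graphs with <= 8 nodes) ----------
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  stopifnot(n <= 8)
  score <- numeric(n)
  # all simple paths between s and t via depth-first enumeration
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        paths[[length(paths) + 1]] <<- path
        return()
      }
      for (nb in which(adj[last, ] == 1)) {
        if (!(nb %in% path)) walk(c(path, nb))
      }
    }
    walk(s)
    paths
  }
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1))
    shortest <- paths[lens == min(lens)]
    for (p in shortest) {
      inner <- setdiff(p, c(s, t))
      score[inner] <- score[inner] + 1 / length(shortest)
    }
  }
  score / ((n - 1) * (n - 2) / 2)
}

# random connected undirected simple graph with n nodes (adjacency matrix)
random_connected_graph <- function(n, p = 0.4) {
  repeat {
    adj <- matrix(0L, n, n)
    upper <- which(upper.tri(adj))
    on <- upper[stats::runif(length(upper)) < p]
    adj[on] <- 1L
    adj <- adj + t(adj)
    # connectivity via reachability
    reach <- (diag(n) + adj)
    for (i in seq_len(n)) reach <- sign(reach %*% (diag(n) + adj))
    if (all(reach[1, ] > 0) && sum(adj) > 0) return(adj)
  }
}

adj_to_igraph <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- paste0("n", seq_len(nrow(adj)))
  g
}

# --- brute-force Benjamini-Hochberg step-up:
#     adj_i = min_{j: p_j >= p_i-rank} m * p_(j) / j, literally -------------
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- exhaustive hypergeometric tail sums (classical and EASE) -------------
# P(X >= j) with set_size successes among background, list_size draws
brute_hyper_tail <- function(j, list_size, set_size, background) {
  lo <- max(0, list_size - (background - set_size))
  hi <- min(list_size, set_size)
  ks <- lo:hi
  terms <- choose(set_size, ks) * choose(background - set_size,
                                         list_size - ks) /
    choose(background, list_size)
  sum(terms[ks >= j])
}

brute_ease <- function(overlap, list_size, set_size, background) {
  if (overlap <= 1) return(1)
  min(1, brute_hyper_tail(overlap - 1, list_size, set_size, background))
}

# --- step-by-step transcription of the omnibus normality statistic --------
# kept textbook-literal (log form, explicit cube root) rather than sharing
# code with the package
transcribe_k2 <- function(x) {
  n <- length(x)
  m2 <- sum((x - mean(x))^2) / n
  m3 <- sum((x - mean(x))^3) / n
  m4 <- sum((x - mean(x))^4) / n
  sqrt_b1 <- m3 / m2^(3 / 2)
  b2 <- m4 / m2^2
  # skewness transform
  Y <- sqrt_b1 * sqrt(((n + 1) * (n + 3)) / (6 * (n - 2)))
  beta2_b1 <- (3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3)) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2_b1 - 1))
  W <- sqrt(W2)
  delta <- 1 / sqrt(log(W))
  alpha <- sqrt(2 / (W2 - 1))
  Zb1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis transform
  meanb2 <- 3 * (n - 1) / (n + 1)
  varb2 <- (24 * n * (n - 2) * (n - 3)) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - meanb2) / sqrt(varb2)
  sqrt_beta1_b2 <- (6 * (n^2 - 5 * n + 2)) / ((n + 7) * (n + 9)) *
    sqrt((6 * (n + 3) * (n + 5)) / (n * (n - 2) * (n - 3)))
  A <- 6 + (8 / sqrt_beta1_b2) *
    (2 / sqrt_beta1_b2 + sqrt(1 + 4 / sqrt_beta1_b2^2))
  inner <- (1 - 2 / A) / (1 + xx * sqrt(2 / (A - 4)))
  Zb2 <- ((1 - 2 / (9 * A)) - sign(inner) * abs(inner)^(1 / 3)) /
    sqrt(2 / (9 * A))
  Zb1^2 + Zb2^2
}

# --- fixtures -------------------------------------------------------------

# published stage-count table for the eight retained AD processes
ad_process_counts <- function() {
  data.frame(
    process = c("regulation of transcription", "histone acetylation",
                "RNA processing and transport", "protein transport",
                "glycolysis", "cellular respiration", "endocytosis",
                "regulation of protein ubiquitination"),
    direction = c("up", "up", "up", "down", "down", "down", "down", "down"),
    early = c(40L, 7L, 11L, 32L, 9L, 14L, 16L, 19L),
    medium = c(54L, 9L, 16L, 19L, 3L, 12L, 7L, 16L),
    late = c(48L, 10L, 11L, 24L, 3L, 13L, 9L, 10L),
    stringsAsFactors = FALSE
  )
}

# tiny three-gene expression file on disk, returns the path
write_tiny_expression <- function(dir = tempdir()) {
  path <- file.path(dir, "tiny_expr.tsv")
  writeLines(c(
    "gene_id\tS1\tS2\tS3\tS4",
    "G1\t1.5\t2.5\t3.5\t4.5",
    "G2\t2\t4\t8\t16",
    "G3\t0.1\t0.2\t\t0.4"
  ), path)
  path
}
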