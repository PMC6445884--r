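# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (no cumsum tricks, no igraph) so agreement is informative.

# best window of exactly L: explicit loop over every start, leftmost max
oracle_best_window <- function(profile, L) {
  n <- length(profile)
  if (n < L) return(NULL)
  best_start <- NA_integer_
  best_score <- -Inf
  for (s in 1:(n - L + 1)) {
    sc <- 0
    for (j in s:(s + L - 1)) sc <- sc + profile[j]
    if (sc > best_score + 1e-12) {
      best_score <- sc
      best_start <- s
    }
  }
  list(start = best_start, score = best_score)
}

# best 21-mer by explicit enumeration; windows with unknown residues skipped
oracle_best_21mer <- function(sequence, weights) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  best_start <- NA_integer_
  best_raw <- -Inf
  for (s in 1:(n - 20)) {
    raw <- 0
    ok <- TRUE
    for (k in 1:21) {
      aa <- chars[s + k - 1]
      if (!aa %in% colnames(weights)) {
        ok <- FALSE
        break
      }
      raw <- raw + weights[k, aa]
    }
    if (ok && raw > best_raw + 1e-12) {
      best_raw <- raw
      best_start <- s
    }
  }
  list(start = best_start, raw = best_raw)
}

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration:
# sum of probabilities of all tables (same margins) no more likely than the
# observed one, with the relative tolerance R uses
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  lo <- max(0, k - m2)
  hi <- min(k, m1)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m1, x) + lchoose(m2, k - x) - lchoose(m1 + m2, k))
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# adjacency list from an edge data frame over `nodes`
oracle_adjacency <- function(edges, nodes) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]
    b <- edges[i, 2]
    if (a == b) next
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

# single-source BFS distances over an adjacency list
oracle_bfs <- function(adj, from) {
  dist <- setNames(rep(Inf, length(adj)), names(adj))
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# connected components of the subgraph induced by `keep`, via union-find
oracle_lcc <- function(edges, keep) {
  keep <- unique(keep)
  parent <- setNames(keep, keep)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]
    b <- edges[i, 2]
    if (a %in% keep && b %in% keep) {
      ra <- find(a)
      rb <- find(b)
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(keep, find, character(1))
  max(table(roots))
}

# intra-set edge count by direct filtering
oracle_intra_edges <- function(edges, keep) {
  n <- 0L
  seen <- character()
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]
    b <- edges[i, 2]
    if (a == b || !(a %in% keep) || !(b %in% keep)) next
    key <- paste(sort(c(a, b)), collapse = "|")
    if (!key %in% seen) {
      seen <- c(seen, key)
      n <- n + 1L
    }
  }
  n
}

# mean shortest distance oracle: BFS per set member over the FULL graph
oracle_msd <- function(edges, nodes, set) {
  adj <- oracle_adjacency(edges, nodes)
  set <- intersect(set, nodes)
  nearest <- vapply(set, function(v) {
    d <- oracle_bfs(adj, v)
    min(d[setdiff(set, v)])
  }, numeric(1))
  ok <- is.finite(nearest)
  if (!any(ok)) NA_real_ else mean(nearest[ok])
}

# mean silhouette by explicit double loops (Euclidean)
oracle_mean_silhouette <- function(x, labels) {
  n <- nrow(x)
  euclid <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  s <- numeric(n)
  for (i in 1:n) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(vapply(own, function(j) euclid(i, j), numeric(1)))
    b <- Inf
    for (k in setdiff(unique(labels), labels[i])) {
      members <- which(labels == k)
      b <- min(b, mean(vapply(members, function(j) euclid(i, j), numeric(1))))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# small random simple graph as an edge data frame
random_edges <- function(n_nodes, p, seed) {
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  set.seed(seed)
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  list(nodes = nodes,
       edges = data.frame(id_a = pairs[keep, 1], id_b = pairs[keep, 2],
                          stringsAsFactors = FALSE))
}

# annotation table from a membership list: term -> protein ids
make_annotation_table <- function(membership, namespace = "BP",
                                  evidence = "EXP") {
  rows <- do.call(rbind, lapply(names(membership), function(tm) {
    if (length(membership[[tm]]) == 0) return(NULL)
    data.frame(protein_id = membership[[tm]], term_id = tm,
               namespace = namespace, evidence = evidence,
               stringsAsFactors = FALSE)
  }))
  read_annotations(rows)
}
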