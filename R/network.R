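#' Read an undirected binary interactome from an edge list
#'
#' @param x TSV path (columns `id_a`, `id_b`, no header required) or a
#'   two-column data frame. Self-loops and duplicate edges are removed so the
#'   result is a simple undirected graph.
#' @param nodes Optional full node set (to keep isolated genes).
#' @return An `igraph` graph.
#' @export
read_interactome <- function(x, nodes = NULL) {
  df <- if (is.character(x)) {
    first <- readLines(x, n = 1)
    has_header <- grepl("^id_a\t", first)
    read.delim(x, sep = "\t", header = has_header, stringsAsFactors = FALSE,
               col.names = c("id_a", "id_b"))
  } else {
    setNames(as.data.frame(x)[, 1:2], c("id_a", "id_b"))
  }
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = if (is.null(nodes)) NULL else unique(nodes))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Collapse protein identifiers to unique gene identifiers
#'
#' Proteins (e.g. isoforms) mapping to the same gene collapse to one id;
#' proteins without a mapping are dropped with a message and reported.
#'
#' @param protein_ids Character vector of protein ids.
#' @param mapping Named character vector (protein -> gene) or two-column data
#'   frame (`protein_id`, `gene_id`).
#' @return Character vector of distinct gene ids, with attribute `n_unmapped`.
#' @export
collapse_to_genes <- function(protein_ids, mapping) {
  if (is.data.frame(mapping)) {
    mapping <- setNames(as.character(mapping$gene_id),
                        as.character(mapping$protein_id))
  }
  genes <- mapping[protein_ids]
  n_unmapped <- sum(is.na(genes))
  if (n_unmapped > 0) {
    message(sprintf("collapse_to_genes: %d proteins without gene mapping dropped",
                    n_unmapped))
  }
  out <- unique(unname(genes[!is.na(genes)]))
  attr(out, "n_unmapped") <- n_unmapped
  out
}

# set members actually present in the graph; error when empty
set_in_graph <- function(graph, gene_set) {
  present <- intersect(unique(gene_set), igraph::V(graph)$name)
  if (length(present) == 0) {
    stop_validation("no gene of the set is present in the graph")
  }
  present
}

#' Degrees of set members in the interactome
#'
#' @param graph An `igraph` interactome.
#' @param gene_set Gene ids; members absent from the graph are excluded and
#'   counted.
#' @return List with `degrees` (named vector), `mean_degree`, `n_absent`.
#' @export
set_degree_stats <- function(graph, gene_set) {
  present <- set_in_graph(graph, gene_set)
  deg <- igraph::degree(graph, v = present)
  list(degrees = deg, mean_degree = mean(deg),
       n_absent = length(unique(gene_set)) - length(present))
}

#' Number of interactions between set members
#'
#' @inheritParams set_degree_stats
#' @return Integer count of edges with both endpoints in the set.
#' @export
intra_set_edges <- function(graph, gene_set) {
  present <- intersect(unique(gene_set), igraph::V(graph)$name)
  if (length(present) < 2) return(0L)
  igraph::ecount(igraph::induced_subgraph(graph, present))
}

#' Largest connected component of the set-induced subgraph
#'
#' @inheritParams set_degree_stats
#' @return Size (node count) of the largest connected component of the
#'   subgraph induced by the set members present in the graph.
#' @export
lcc_size <- function(graph, gene_set) {
  present <- set_in_graph(graph, gene_set)
  sub <- igraph::induced_subgraph(graph, present)
  max(igraph::components(sub)$csize)
}

#' Mean shortest distance of a set (network separation)
#'
#' For each set member, the shortest-path distance *in the full graph* to its
#' nearest other set member; the mean is taken over members with at least one
#' reachable partner. Members with no reachable set partner are excluded and
#' counted; if all are excluded the result is `NA`.
#'
#' @inheritParams set_degree_stats
#' @return List with `msd` (numeric or `NA`), `n_excluded`, `per_member`
#'   (named vector of nearest-member distances).
#' @export
mean_shortest_distance <- function(graph, gene_set) {
  present <- set_in_graph(graph, gene_set)
  if (length(present) < 2) {
    stop_validation("need at least two set members in the graph")
  }
  d <- igraph::distances(graph, v = present, to = present)
  diag(d) <- Inf
  nearest <- apply(d, 1, min)
  ok <- is.finite(nearest)
  list(msd = if (any(ok)) mean(nearest[ok]) else NA_real_,
       n_excluded = sum(!ok),
       per_member = nearest)
}

#' Empirical network null for a set statistic
#'
#' Draws `n_samples` uniform random node sets of `set_size` (without
#' replacement within a draw, no degree matching) and evaluates the statistic
#' on each; Z-score and empirical p as in [resampled_null()]. Draws where the
#' statistic is undefined (e.g. mean shortest distance on a fully isolated
#' draw) are excluded from the null with a reported count.
#'
#' @param graph An `igraph` interactome.
#' @param set_size Size of each random node set.
#' @param statistic Function `(graph, gene_set) -> number`, e.g. [lcc_size()].
#' @param observed Observed value; when `NULL`, no comparison fields are
#'   meaningful and only the null is of interest.
#' @param n_samples Number of random sets (default 1000).
#' @param seed Integer seed.
#' @return A `resampling_result`.
#' @export
network_null <- function(graph, set_size, statistic, observed,
                         n_samples = 1000L, seed = 1L) {
  nodes <- igraph::V(graph)$name
  if (set_size > length(nodes)) {
    stop_validation("set_size exceeds the number of graph nodes")
  }
  resampled_null(observed, nodes, set_size,
                 statistic = function(v) {
                   out <- statistic(graph, v)
                   if (is.list(out)) out <- out$msd
                   as.numeric(out)
                 },
                 n_samples = n_samples, seed = seed, drop_na = TRUE)
}

#' Full interactome characterization of a gene set
#'
#' Computes the four set statistics of the network analysis — mean degree,
#' intra-set edge count, largest-connected-component size and mean shortest
#' distance — each with its empirical null over `n_samples` random same-size
#' node sets, plus a Wilcoxon rank-sum p-value comparing the set's member
#' degrees with pooled random-member degrees.
#'
#' @inheritParams network_null
#' @param gene_set Gene ids of the set.
#' @return List of class `network_set_stats`: observed values, one
#'   `resampling_result` per statistic, `wilcox_p_degree`, `n_in_graph`.
#' @export
#' @examples
#' g <- generate_interactome(200, 0.02, module = paste0("g", 1:20),
#'                           p_module = 0.3, seed = 1)
#' st <- network_set_stats(g$graph, paste0("g", 1:20), n_samples = 50, seed = 1)
#' st$lcc$z
network_set_stats <- function(graph, gene_set, n_samples = 1000L, seed = 1L) {
  present <- set_in_graph(graph, gene_set)
  deg <- set_degree_stats(graph, present)
  obs_msd <- mean_shortest_distance(graph, present)
  stats_list <- list(
    degree = list(obs = deg$mean_degree,
                  fun = function(g, v) mean(igraph::degree(g, v = v))),
    intra_edges = list(obs = intra_set_edges(graph, present),
                       fun = function(g, v) intra_set_edges(g, v)),
    lcc = list(obs = lcc_size(graph, present),
               fun = function(g, v) lcc_size(g, v)),
    msd = list(obs = obs_msd$msd,
               fun = function(g, v) mean_shortest_distance(g, v)$msd))
  res <- lapply(seq_along(stats_list), function(i) {
    st <- stats_list[[i]]
    network_null(graph, length(present), st$fun, st$obs,
                 n_samples = n_samples,
                 seed = derive_seed(seed, names(stats_list)[i]))
  })
  names(res) <- names(stats_list)
  # rank-sum: set-member degrees vs degrees of random members
  null_members <- with_seed(derive_seed(seed, "wilcox"), {
    unlist(lapply(seq_len(min(n_samples, 200L)), function(i) {
      igraph::degree(graph, v = sample(igraph::V(graph)$name, length(present)))
    }))
  })
  wil <- stats::wilcox.test(deg$degrees, null_members, exact = FALSE)
  structure(
    c(res,
      list(mean_degree = deg$mean_degree, intra = stats_list$intra_edges$obs,
           lcc_size = stats_list$lcc$obs, msd_value = obs_msd$msd,
           msd_excluded = obs_msd$n_excluded,
           wilcox_p_degree = wil$p.value,
           n_in_graph = length(present),
           n_absent = length(unique(gene_set)) - length(present))),
    class = "network_set_stats")
}

#' @export
print.network_set_stats <- function(x, ...) {
  fmt <- function(name, r) {
    sprintf("  %-12s observed %8.3f | null %8.3f +/- %.3f | Z %7.2f | emp. p %.4g",
            name, r$observed, r$null_mean, r$null_sd,
            ifelse(is.na(r$z), NaN, r$z), r$empirical_p)
  }
  cat(sprintf("network set statistics (%d genes in graph, %d absent):\n",
              x$n_in_graph, x$n_absent))
  for (nm in c("degree", "intra_edges", "lcc", "msd")) {
    cat(fmt(nm, x[[nm]]), "\n")
  }
  cat(sprintf("  degree rank-sum p = %.4g\n", x$wilcox_p_degree))
  invisible(x)
}
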