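#' Convert a textual expression-rank table to ordinal 0-3 coding
#'
#' Tissue atlases report per-gene expression as ranks "none" / "low" /
#' "medium" / "high"; these map to 0 / 1 / 2 / 3 (case-insensitive;
#' "not detected" is accepted as a synonym of "none"). Numeric input in
#' `{0,1,2,3}` passes through unchanged. Unknown labels become `NA` with a
#' warning — missingness is explicit, never coerced to 0.
#'
#' @param raw Data frame (or TSV path) with a `gene_id` column followed by one
#'   column per tissue, textual or numeric.
#' @return Numeric matrix (genes x tissues, rownames = gene ids) with values
#'   in `{0,1,2,3}` or `NA`.
#' @export
#' @examples
#' code_expression(data.frame(gene_id = "g1", liver = "high", lung = "none"))
code_expression <- function(raw) {
  df <- if (is.character(raw)) read_tsv(raw) else as.data.frame(raw)
  if (!"gene_id" %in% names(df)) {
    stop_validation("expression table needs a `gene_id` column")
  }
  genes <- as.character(df$gene_id)
  vals <- df[, setdiff(names(df), "gene_id"), drop = FALSE]
  rank_map <- c(none = 0, "not detected" = 0, low = 1, medium = 2, high = 3)
  coded <- vapply(vals, function(col) {
    if (is.numeric(col)) {
      bad <- !is.na(col) & !(col %in% 0:3)
      if (any(bad)) {
        warning(sprintf("%d numeric values outside {0,1,2,3} set to NA", sum(bad)))
        col[bad] <- NA_real_
      }
      as.numeric(col)
    } else {
      key <- tolower(trimws(as.character(col)))
      out <- unname(rank_map[key])
      unknown <- is.na(out) & !is.na(col) & nzchar(key)
      if (any(unknown)) {
        warning(sprintf("%d unknown expression labels set to NA", sum(unknown)))
      }
      out
    }
  }, numeric(nrow(df)))
  coded <- matrix(coded, nrow = nrow(df),
                  dimnames = list(genes, setdiff(names(df), "gene_id")))
  coded
}

#' Mean expression profile of a gene set per tissue
#'
#' Averages the coded expression of the set genes within each tissue; missing
#' cells are excluded from both numerator and denominator. When a
#' cell-type-to-tissue map is given, cell-type columns are first averaged into
#' tissues, then genes are averaged — matching the order cell type -> tissue
#' -> gene set.
#'
#' @param set_genes Character vector of gene ids.
#' @param table Coded expression matrix from [code_expression()].
#' @param celltype_map `NULL`, or named character vector mapping column name
#'   (cell type) to tissue label.
#' @return Named numeric vector, one mean (in `[0, 3]`) per tissue.
#' @export
set_tissue_profile <- function(set_genes, table, celltype_map = NULL) {
  if (!is.null(celltype_map)) {
    tissues <- unique(unname(celltype_map[colnames(table)]))
    tissues <- tissues[!is.na(tissues)]
    table <- vapply(tissues, function(ts) {
      cols <- colnames(table)[celltype_map[colnames(table)] %in% ts]
      rowMeans(table[, cols, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(table)))
    table[is.nan(table)] <- NA_real_
    colnames(table) <- tissues
  }
  rows <- intersect(set_genes, rownames(table))
  if (length(rows) == 0) {
    stop_validation("no overlap between the gene set and the expression table")
  }
  colMeans(table[rows, , drop = FALSE], na.rm = TRUE)
}

#' Deviation vectors of set genes against a proteome background
#'
#' For each set gene g and tissue t, `V_g[t] = E_g,t - mean_t` where `mean_t`
#' is the per-tissue mean over all background genes with non-missing values —
#' i.e. each gene is represented by how far its expression deviates from the
#' proteome-level tissue average.
#'
#' @param set_genes Gene ids to build vectors for (must be rows of
#'   `set_table`).
#' @param set_table,background_table Coded expression matrices with identical
#'   tissue columns.
#' @return Numeric matrix (set genes x tissues) of deviations; `NA` where the
#'   gene's own value is missing. Background means are kept in attribute
#'   `background_mean`.
#' @export
deviation_vectors <- function(set_genes, set_table,
                              background_table = set_table) {
  if (!identical(colnames(set_table), colnames(background_table))) {
    stop_validation("tissue columns of set and background tables differ")
  }
  rows <- intersect(set_genes, rownames(set_table))
  if (length(rows) == 0) stop_validation("no set gene present in the table")
  bg_mean <- colMeans(background_table, na.rm = TRUE)
  v <- sweep(set_table[rows, , drop = FALSE], 2, bg_mean, "-")
  attr(v, "background_mean") <- bg_mean
  v
}

# mean silhouette width for a labelled point set under Euclidean distance
mean_silhouette <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  ks <- sort(unique(labels))
  if (length(ks) < 2) return(NA_real_)
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1
    if (n_own == 0) return(0)                     # singleton convention
    a <- sum(d[i, own]) / n_own
    b <- min(vapply(ks[ks != labels[i]],
                    function(k) mean(d[i, labels == k]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Cluster gene deviation vectors with silhouette-selected k
#'
#' Runs k-means (Euclidean distance, k-means++-style multiple random restarts
#' keeping the best within-cluster sum of squares) for each k in
#' `k_min..k_max` and selects the k maximizing the mean silhouette width;
#' ties go to the smaller k. Genes with more than 50% missing tissues are
#' excluded (listed in the result); remaining missing entries are imputed
#' with 0, i.e. "at the background mean" on the deviation scale.
#'
#' @param vectors Numeric matrix from [deviation_vectors()] (genes x tissues).
#' @param k_min,k_max Range of cluster numbers to test (defaults 3 and 10).
#' @param n_restarts Random restarts per k (default 25).
#' @param seed Integer seed; fixes the restart stream.
#' @return List of class `cluster_result`: `chosen_k`, `labels` (named
#'   integer vector), `silhouette_by_k` (named numeric), `excluded_genes`,
#'   `seed`.
#' @export
#' @examples
#' expr <- generate_expression(paste0("g", 1:60), paste0("t", 1:10),
#'                             k_true = 3, effect = 2, seed = 1)
#' v <- deviation_vectors(rownames(expr$table), expr$table)
#' cluster_genes(v, k_min = 2, k_max = 5, seed = 1)$chosen_k
cluster_genes <- function(vectors, k_min = 3L, k_max = 10L, n_restarts = 25L,
                          seed = 1L) {
  x <- as.matrix(vectors)
  frac_missing <- rowMeans(is.na(x))
  excluded <- rownames(x)[frac_missing > 0.5]
  x <- x[frac_missing <= 0.5, , drop = FALSE]
  x[is.na(x)] <- 0
  n <- nrow(x)
  if (n < k_max + 1) {
    k_max_new <- max(k_min, n - 1L)
    warning(sprintf("only %d genes: truncating k range to %d..%d",
                    n, k_min, k_max_new))
    k_max <- k_max_new
  }
  if (n < k_min + 1) stop_validation("too few genes to cluster")
  ks <- seq.int(k_min, k_max)
  fits <- with_seed(seed, lapply(ks, function(k) {
    suppressWarnings(kmeans(x, centers = k, nstart = n_restarts,
                            iter.max = 100))
  }))
  sil <- vapply(fits, function(f) mean_silhouette(x, f$cluster), numeric(1))
  names(sil) <- ks
  chosen <- ks[which.max(sil)]              # which.max: first (smallest) k on ties
  structure(
    list(chosen_k = chosen,
         labels = fits[[match(chosen, ks)]]$cluster,
         silhouette_by_k = sil,
         excluded_genes = excluded,
         seed = as.integer(seed)),
    class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("k-means over k = %s..%s: chosen k = %d (mean silhouette %.3f)\n",
              names(x$silhouette_by_k)[1],
              names(x$silhouette_by_k)[length(x$silhouette_by_k)],
              x$chosen_k, max(x$silhouette_by_k)))
  invisible(x)
}
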