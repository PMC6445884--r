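#' Load a protein-to-term annotation table
#'
#' Expects tab-separated columns `protein_id`, `term_id`, `namespace`,
#' `evidence`. Duplicate (protein, term) pairs are collapsed.
#'
#' @param x Path to a TSV file or a data frame with those columns.
#' @return Data frame of class `annotation_table`.
#' @export
read_annotations <- function(x) {
  df <- if (is.character(x)) read_tsv(x) else as.data.frame(x)
  need <- c("protein_id", "term_id", "namespace", "evidence")
  if (!all(need %in% names(df))) {
    stop_validation("annotation table needs columns: %s",
                    paste(need, collapse = ", "))
  }
  df <- df[!duplicated(df[, c("protein_id", "term_id")]), need, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Filter annotations by evidence code and map to a slim vocabulary
#'
#' Rows whose evidence code is in `excluded_evidence` are removed (the
#' electronic-annotation code IEA by default). If a slim map is given, term
#' ids are replaced by their slim target — resolved transitively for
#' multi-level maps, with cycle detection — and duplicate (protein, slim term)
#' rows collapsed.
#'
#' @param table An annotation table ([read_annotations()]).
#' @param excluded_evidence Character vector of evidence codes to drop
#'   (default `"IEA"`).
#' @param slim_map `NULL`, or a named character vector / two-column data frame
#'   (`term_id`, `slim_id`) mapping terms to slim terms. Terms absent from the
#'   map are kept unchanged.
#' @return Filtered `annotation_table`.
#' @export
filter_annotations <- function(table, excluded_evidence = "IEA",
                               slim_map = NULL) {
  df <- read_annotations(table)
  if (length(excluded_evidence)) {
    df <- df[!(df$evidence %in% excluded_evidence), , drop = FALSE]
    if (nrow(df) == 0) warning("all annotation rows removed by evidence filter")
  }
  if (!is.null(slim_map)) {
    if (is.data.frame(slim_map)) {
      slim_map <- setNames(as.character(slim_map[[2]]),
                           as.character(slim_map[[1]]))
    }
    resolve <- function(term) {
      seen <- character()
      while (term %in% names(slim_map)) {
        if (term %in% seen) stop_validation("slim map contains a cycle at '%s'", term)
        seen <- c(seen, term)
        nxt <- slim_map[[term]]
        if (identical(nxt, term)) break
        term <- nxt
      }
      term
    }
    uniq <- unique(df$term_id)
    resolved <- vapply(uniq, resolve, character(1))
    df$term_id <- unname(resolved[match(df$term_id, uniq)])
    df <- df[!duplicated(df[, c("protein_id", "term_id")]), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Term enrichment of a protein set against a background
#'
#' For every term of the requested namespace, builds the 2x2 protein table
#' (in set with term / in set without / out of set with / out of set without)
#' over the background universe, applies a two-sided Fisher's exact test, and
#' Bonferroni-corrects over the number of terms tested within the namespace.
#' The direction (`enriched`/`depleted`) follows the sample odds ratio
#' relative to 1, and the per-annotation log-ratio enrichment score
#' ([log_enrichment_score()]) is attached.
#'
#' @param set_ids Character vector of set protein ids (subset of background).
#' @param background_ids Character vector: the background universe.
#' @param table An annotation table.
#' @param namespace Namespace to test (e.g. `"BP"`, `"pfam"`); `NULL` tests
#'   all rows as one family.
#' @param freq_mode Denominator for the enrichment score `E`:
#'   `"annotation"` (term occurrences over total annotation rows, default) or
#'   `"protein"` (proteins carrying the term over proteins annotated).
#' @return Data frame sorted by adjusted p: `term_id`, `set_count`,
#'   `set_total`, `background_count`, `background_total`, `odds_ratio`,
#'   `fisher_p`, `adjusted_p`, `direction`, `score_E`.
#' @export
term_enrichment <- function(set_ids, background_ids, table, namespace = NULL,
                            freq_mode = c("annotation", "protein")) {
  freq_mode <- match.arg(freq_mode)
  df <- read_annotations(table)
  set_ids <- unique(set_ids)
  background_ids <- unique(background_ids)
  if (length(set_ids) == 0) stop_validation("empty protein set")
  if (!all(set_ids %in% background_ids)) {
    stop_validation("set_ids must be a subset of background_ids")
  }
  if (!is.null(namespace)) {
    df <- df[df$namespace %in% namespace, , drop = FALSE]
    if (nrow(df) == 0) stop_validation("namespace '%s' not present", namespace)
  }
  df <- df[df$protein_id %in% background_ids, , drop = FALSE]
  terms <- sort(unique(df$term_id))
  m <- length(terms)
  n_set <- length(set_ids)
  n_bg <- length(background_ids)
  in_set <- df$protein_id %in% set_ids
  set_rows <- df[in_set, , drop = FALSE]
  # per-annotation totals for E
  tot_ann_set <- nrow(set_rows)
  tot_ann_bg <- nrow(df)
  rows <- lapply(terms, function(tm) {
    k_set <- length(unique(set_rows$protein_id[set_rows$term_id == tm]))
    k_bg <- length(unique(df$protein_id[df$term_id == tm]))
    tab <- matrix(c(k_set, n_set - k_set,
                    k_bg - k_set, n_bg - n_set - (k_bg - k_set)), nrow = 2)
    ft <- fisher.test(tab)
    or <- unname(ft$estimate)
    degenerate <- (k_bg == n_bg) || (k_bg == 0)
    e <- if (freq_mode == "annotation") {
      a_set <- sum(set_rows$term_id == tm)
      a_bg <- sum(df$term_id == tm)
      if (a_set == 0 || tot_ann_set == 0) NA_real_
      else log(a_set / tot_ann_set) - log(a_bg / tot_ann_bg)
    } else {
      if (k_set == 0) NA_real_
      else log(k_set / n_set) - log(k_bg / n_bg)
    }
    data.frame(term_id = tm, set_count = k_set, set_total = n_set,
               background_count = k_bg, background_total = n_bg,
               odds_ratio = if (degenerate) NA_real_ else or,
               fisher_p = if (degenerate) 1 else ft$p.value,
               direction = if (!degenerate && or > 1) "enriched" else "depleted",
               score_E = e, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- pmin(1, m * out$fisher_p)
  out <- out[order(out$adjusted_p, out$fisher_p, out$term_id), , drop = FALSE]
  out <- out[, c("term_id", "set_count", "set_total", "background_count",
                 "background_total", "odds_ratio", "fisher_p", "adjusted_p",
                 "direction", "score_E")]
  rownames(out) <- NULL
  attr(out, "family_size") <- m
  out
}

#' Log-ratio enrichment score of one term
#'
#' `E = log(f_set) - log(f_background)` where `f` is the term's annotation
#' frequency: occurrences of the term among the set's annotation rows over the
#' set's total annotation rows (and likewise for the background). Natural
#' logarithm. A term absent from the set yields `NA` (reported, excluded from
#' plots); a term absent from the background is an error.
#'
#' @param term Term id.
#' @param set_ids,background_ids Protein id vectors (set must be a subset).
#' @param table An annotation table.
#' @param freq_mode `"annotation"` (default) or `"protein"`; see
#'   [term_enrichment()].
#' @return Single numeric score (or `NA`).
#' @export
log_enrichment_score <- function(term, set_ids, background_ids, table,
                                 freq_mode = c("annotation", "protein")) {
  freq_mode <- match.arg(freq_mode)
  df <- read_annotations(table)
  bg_rows <- df[df$protein_id %in% background_ids, , drop = FALSE]
  set_rows <- df[df$protein_id %in% set_ids, , drop = FALSE]
  if (!term %in% bg_rows$term_id) {
    stop_validation("term '%s' not annotated in the background", term)
  }
  if (freq_mode == "annotation") {
    a_set <- sum(set_rows$term_id == term)
    if (a_set == 0 || nrow(set_rows) == 0) return(NA_real_)
    log(a_set / nrow(set_rows)) -
      log(sum(bg_rows$term_id == term) / nrow(bg_rows))
  } else {
    k_set <- length(unique(set_rows$protein_id[set_rows$term_id == term]))
    if (k_set == 0) return(NA_real_)
    log(k_set / length(unique(set_ids))) -
      log(length(unique(bg_rows$protein_id[bg_rows$term_id == term])) /
            length(unique(background_ids)))
  }
}
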