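#' Segmentation scheme for terminal localization
#'
#' The N- and C-terminal segments each take a fixed fraction (default 25%) of
#' the residues; the remainder is internal.
#'
#' @param n_fraction Fraction of residues in the N-terminal segment.
#' @param c_fraction Fraction of residues in the C-terminal segment.
#' @return Object of class `segment_scheme`.
#' @export
segment_scheme <- function(n_fraction = 0.25, c_fraction = 0.25) {
  check_proportion(n_fraction, "n_fraction")
  check_proportion(c_fraction, "c_fraction")
  if (n_fraction + c_fraction >= 1) {
    stop_validation("n_fraction + c_fraction must be < 1")
  }
  structure(list(n_fraction = n_fraction, c_fraction = c_fraction),
            class = "segment_scheme")
}

#' Segment boundaries of a protein under the 25/50/25 scheme
#'
#' Sizes the C segment first, then the N segment, with banker's rounding
#' (round-half-even) on the segment sizes; the internal segment is the exact
#' remainder, so the three intervals always partition `1..protein_length`.
#'
#' @param protein_length Protein length in residues (>= 4).
#' @param scheme A [segment_scheme()].
#' @return List of three integer vectors `n`, `internal`, `c`, each
#'   `c(start, end)` 1-based inclusive; empty segments are `NULL`.
#' @export
#' @examples
#' segment_boundaries(100)
segment_boundaries <- function(protein_length, scheme = segment_scheme()) {
  if (!is.numeric(protein_length) || length(protein_length) != 1 ||
      protein_length < 4) {
    stop_validation("`protein_length` must be a single length >= 4")
  }
  L <- as.integer(protein_length)
  c_size <- as.integer(round(L * scheme$c_fraction))
  n_size <- as.integer(round(L * scheme$n_fraction))
  if (n_size + c_size > L) n_size <- L - c_size
  list(
    n = if (n_size > 0) c(1L, n_size) else NULL,
    internal = if (L - c_size - n_size > 0) c(n_size + 1L, L - c_size) else NULL,
    c = if (c_size > 0) c(L - c_size + 1L, L) else NULL)
}

# residues of [a1, a2] falling inside segment `seg` (c(start,end) or NULL)
overlap_len <- function(a1, a2, seg) {
  if (is.null(seg)) return(0L)
  max(0L, min(a2, seg[2]) - max(a1, seg[1]) + 1L)
}

#' Classify one PrLD as N-terminal, internal or C-terminal
#'
#' Counts the PrLD residues falling in each of the three segments of
#' [segment_boundaries()] and assigns the segment holding the plurality of
#' residues; ties are assigned to `internal` (conservative with respect to
#' terminal-enrichment claims).
#'
#' @param domain_start,domain_end PrLD interval, 1-based inclusive.
#' @param protein_length Protein length in residues.
#' @param scheme A [segment_scheme()].
#' @param rule Assignment rule: `"plurality"` (default), `"midpoint"` (segment
#'   containing the domain midpoint) or `"any_overlap"` (terminal if the
#'   domain touches a terminal segment; C wins over N on double overlap).
#' @return List with `n_count`, `internal_count`, `c_count` and `category`
#'   (one of `"N"`, `"internal"`, `"C"`).
#' @export
#' @examples
#' classify_prld(1, 20, 100)$category
classify_prld <- function(domain_start, domain_end, protein_length,
                          scheme = segment_scheme(),
                          rule = c("plurality", "midpoint", "any_overlap")) {
  rule <- match.arg(rule)
  if (domain_start < 1 || domain_end > protein_length ||
      domain_start > domain_end) {
    stop_validation("domain interval [%d, %d] outside protein of length %d",
                    domain_start, domain_end, protein_length)
  }
  segs <- segment_boundaries(protein_length, scheme)
  counts <- c(N = overlap_len(domain_start, domain_end, segs$n),
              internal = overlap_len(domain_start, domain_end, segs$internal),
              C = overlap_len(domain_start, domain_end, segs$c))
  category <- switch(
    rule,
    plurality = {
      mx <- max(counts)
      winners <- names(counts)[counts == mx]
      if (length(winners) > 1) "internal" else winners
    },
    midpoint = {
      mid <- floor((domain_start + domain_end) / 2)
      in_seg <- function(seg) !is.null(seg) && mid >= seg[1] && mid <= seg[2]
      if (in_seg(segs$n)) "N" else if (in_seg(segs$c)) "C" else "internal"
    },
    any_overlap = {
      if (counts["C"] > 0) "C" else if (counts["N"] > 0) "N" else "internal"
    })
  list(n_count = counts[["N"]], internal_count = counts[["internal"]],
       c_count = counts[["C"]], category = category)
}

#' Localize every PrLD call and summarize the terminal imbalance
#'
#' @param calls A `prld_calls` data frame (only rows with `positive == TRUE`
#'   are used unless `positives_only = FALSE`).
#' @param scheme A [segment_scheme()].
#' @param rule Assignment rule, see [classify_prld()].
#' @param positives_only Use final positives only (default `TRUE`).
#' @return List of class `localization_result`: per-call data frame
#'   (`protein_id`, counts, `category`), aggregate `tallies` (N/internal/C),
#'   `terminal_fraction`, and the [terminal_bias_test()] output (`z`,
#'   `p_value`, `c_to_n_ratio`).
#' @export
localize_calls <- function(calls, scheme = segment_scheme(),
                           rule = "plurality", positives_only = TRUE) {
  df <- as.data.frame(calls)
  if (positives_only && "positive" %in% names(df)) {
    df <- df[df$positive, , drop = FALSE]
  }
  if (nrow(df) == 0) stop_validation("no calls to localize")
  per <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    cl <- classify_prld(df$domain_start[i], df$domain_end[i],
                        df$protein_length[i], scheme, rule)
    data.frame(protein_id = df$protein_id[i], n_count = cl$n_count,
               internal_count = cl$internal_count, c_count = cl$c_count,
               category = cl$category, stringsAsFactors = FALSE)
  }))
  tallies <- c(N = sum(per$category == "N"),
               internal = sum(per$category == "internal"),
               C = sum(per$category == "C"))
  bias <- if (tallies["N"] + tallies["C"] >= 1) {
    terminal_bias_test(tallies[["N"]], tallies[["C"]])
  } else {
    list(z = NA_real_, p_value = NA_real_, c_to_n_ratio = NA_real_)
  }
  structure(list(per_call = per, tallies = tallies,
                 terminal_fraction = unname((tallies["N"] + tallies["C"]) / nrow(per)),
                 z = bias$z, p_value = bias$p_value,
                 c_to_n_ratio = bias$c_to_n_ratio),
            class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf(
    "PrLD localization: N %d | internal %d | C %d (terminal fraction %.1f%%)\nC/N ratio %.2f, Z = %.2f, two-sided p = %.3g\n",
    x$tallies["N"], x$tallies["internal"], x$tallies["C"],
    100 * x$terminal_fraction, x$c_to_n_ratio, x$z, x$p_value))
  invisible(x)
}

#' One-sample Z-test for the C-versus-N terminal imbalance
#'
#' Tests whether C-terminal PrLDs are more frequent than N-terminal ones among
#' terminally located domains: `z = (n_C - n/2) / sqrt(n/4)` with
#' `n = n_N + n_C`, two-sided normal p-value.
#'
#' @param n_count_N Number of N-terminal calls.
#' @param n_count_C Number of C-terminal calls.
#' @return List with `z`, `p_value`, `c_to_n_ratio` (`Inf` when `n_count_N`
#'   is 0).
#' @export
#' @examples
#' terminal_bias_test(73, 122)
terminal_bias_test <- function(n_count_N, n_count_C) {
  if (n_count_N < 0 || n_count_C < 0 || n_count_N + n_count_C < 1) {
    stop_validation("need at least one terminal call")
  }
  n <- n_count_N + n_count_C
  z <- (n_count_C - n / 2) / sqrt(n / 4)
  list(z = z, p_value = 2 * pnorm(-abs(z)),
       c_to_n_ratio = if (n_count_N == 0) Inf else n_count_C / n_count_N)
}

#' Relative-position histogram of PrLD starts and ends
#'
#' Maps each call's domain start and end to `floor((pos - 1) / L * n_bins)`
#' (clamped to the last bin), yielding the start- and end-position histograms
#' over protein-length-normalized bins.
#'
#' @param calls A `prld_calls` data frame (must carry `protein_length`).
#' @param n_bins Number of bins (default 20, i.e. 5% of the length each).
#' @param positives_only Use final positives only (default `TRUE`).
#' @return List with integer vectors `start_bins` and `end_bins`, both of
#'   length `n_bins` (bin 1 = first `100/n_bins`% of the sequence).
#' @export
position_histogram <- function(calls, n_bins = 20L, positives_only = TRUE) {
  if (!is.numeric(n_bins) || n_bins < 1) {
    stop_validation("`n_bins` must be >= 1")
  }
  n_bins <- as.integer(n_bins)
  df <- as.data.frame(calls)
  if (positives_only && "positive" %in% names(df)) {
    df <- df[df$positive, , drop = FALSE]
  }
  bin_of <- function(pos, L) {
    pmin(n_bins - 1L, as.integer(floor((pos - 1) / L * n_bins)))
  }
  tally <- function(bins) {
    tabulate(bins + 1L, nbins = n_bins)
  }
  list(start_bins = tally(bin_of(df$domain_start, df$protein_length)),
       end_bins = tally(bin_of(df$domain_end, df$protein_length)))
}
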