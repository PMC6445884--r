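#' Composition model for the compositional PrLD scan
#'
#' Bundles the prion-domain and background amino-acid frequency tables with
#' the core window length used by the stage-one scan. Frequencies are floored
#' at 1e-6 (pseudocount) and renormalized so every log-likelihood ratio is
#' finite.
#'
#' @param prion_freqs Named frequency vector over the 20 standard residues
#'   describing prion-domain composition. Default [prion_frequencies()].
#' @param background_freqs Background frequency vector, typically the proteome
#'   average. Default [background_frequencies()]; use
#'   [estimate_background_frequencies()] to estimate from the input proteome.
#' @param core_length Length of the core scoring window in residues
#'   (default 60).
#' @return Object of class `composition_model`.
#' @export
#' @examples
#' m <- composition_model()
#' m$core_length
composition_model <- function(prion_freqs = prion_frequencies(),
                              background_freqs = background_frequencies(),
                              core_length = 60L) {
  norm_freqs <- function(f, name) {
    if (is.null(names(f)) || !all(AMINO_ACIDS %in% names(f))) {
      stop_validation("`%s` must be named over the 20 standard residues", name)
    }
    f <- f[AMINO_ACIDS]
    if (any(!is.finite(f)) || any(f < 0)) {
      stop_validation("`%s` must be finite and non-negative", name)
    }
    f <- pmax(f, 1e-6)
    f <- f / sum(f)
    if (abs(sum(f) - 1) > 1e-9) stop_validation("`%s` does not normalize", name)
    f
  }
  if (!is.numeric(core_length) || length(core_length) != 1 || core_length < 1) {
    stop_validation("`core_length` must be a positive integer")
  }
  structure(
    list(prion_freqs = norm_freqs(prion_freqs, "prion_freqs"),
         background_freqs = norm_freqs(background_freqs, "background_freqs"),
         core_length = as.integer(core_length)),
    class = "composition_model")
}

#' @export
print.composition_model <- function(x, ...) {
  qn <- sum(x$prion_freqs[c("Q", "N")])
  cat(sprintf(
    "composition_model: core window %d residues; prion-table Q+N mass %.2f\n",
    x$core_length, qn))
  invisible(x)
}

# Normalize the many accepted proteome representations (named character
# vector, AAStringSet, synthetic_proteome, FASTA path) to a named character
# vector of upper-case sequences.
as_sequences <- function(x) {
  if (inherits(x, "synthetic_proteome")) {
    return(setNames(x$records$sequence, x$records$protein_id))
  }
  if (inherits(x, "AAStringSet") || inherits(x, "XStringSet")) {
    seqs <- as.character(x)
    names(seqs) <- sub("\\|.*$", "", sub("\\s.*$", "", names(x)))
    return(toupper(seqs))
  }
  if (is.character(x) && length(x) == 1 && !grepl("[\n>]", x) &&
      file.exists(x)) {
    return(as_sequences(Biostrings::readAAStringSet(x)))
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- sprintf("seq%04d", seq_along(x))
    return(toupper(x))
  }
  stop_validation("unsupported proteome representation of class %s",
                  paste(class(x), collapse = "/"))
}

#' Estimate background amino-acid frequencies from a proteome
#'
#' Tallies the 20 standard residues over all sequences; non-standard letters
#' (B, J, O, U, X, Z, ...) are skipped and their count reported as a message.
#' Frequencies are floored at 1e-6 and renormalized.
#'
#' @param proteome Proteome in any representation accepted by the detection
#'   functions (named character vector, `AAStringSet`, `synthetic_proteome`,
#'   or FASTA path).
#' @return Named frequency vector over the 20 standard residues, sum 1.
#' @export
estimate_background_frequencies <- function(proteome) {
  seqs <- as_sequences(proteome)
  if (length(seqs) == 0 || sum(nchar(seqs)) == 0) {
    stop_validation("empty proteome: no residues to tally")
  }
  letters <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  keep <- letters %in% AMINO_ACIDS
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(sprintf("estimate_background_frequencies: skipped %d non-standard residues",
                    n_skipped))
  }
  if (!any(keep)) stop_validation("proteome contains no standard residues")
  counts <- table(factor(letters[keep], levels = AMINO_ACIDS))
  f <- as.numeric(counts) / sum(counts)
  names(f) <- AMINO_ACIDS
  f <- pmax(f, 1e-6)
  f / sum(f)
}

#' Per-residue compositional log-likelihood-ratio profile
#'
#' Scores every residue `r` of a sequence as
#' `log(prion_freqs[r] / background_freqs[r])` (natural log). Non-standard
#' residues score 0, so they neither create nor destroy candidate windows.
#'
#' @param sequence Single amino-acid string.
#' @param model A [composition_model()].
#' @return Numeric vector, one score per residue.
#' @export
llr_profile <- function(sequence, model = composition_model()) {
  stopifnot(inherits(model, "composition_model"))
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) < 1) {
    stop_validation("`sequence` must be a single non-empty string")
  }
  llr <- log(model$prion_freqs / model$background_freqs)
  chars <- strsplit(toupper(sequence), "")[[1]]
  out <- llr[chars]
  out[is.na(out)] <- 0
  unname(out)
}

#' Locate the candidate prion-like domain on an LLR profile
#'
#' Stage one of the caller. The core score is the maximum sum over all
#' contiguous windows of exactly `core_length` residues (leftmost window on
#' ties). If the sequence is shorter than the core window, or the best window
#' sum is not positive, the protein is a no-call (`NULL`). The reported
#' domain is the best core window greedily extended left and right one
#' residue at a time while the running sum of the extension stays positive.
#'
#' @param profile Numeric score vector from [llr_profile()].
#' @param model A [composition_model()] (supplies `core_length`).
#' @return `NULL` (no-call) or a list with `domain_start`, `domain_end`
#'   (1-based inclusive), `core_start`, `core_end`, `core_score`.
#' @export
find_prion_domain <- function(profile, model = composition_model()) {
  stopifnot(inherits(model, "composition_model"))
  n <- length(profile)
  L <- model$core_length
  if (n < L) return(NULL)
  # window sums of length L via cumulative sums
  cs <- c(0, cumsum(profile))
  win <- cs[(L + 1):(n + 1)] - cs[1:(n - L + 1)]
  best <- which.max(win)             # leftmost maximum
  core_score <- win[best]
  if (core_score <= 0) return(NULL)
  core_start <- best
  core_end <- best + L - 1
  # greedy extension: grow while the cumulative extension gain stays positive
  start <- core_start
  acc <- 0
  j <- core_start - 1
  while (j >= 1) {
    acc <- acc + profile[j]
    if (acc <= 0) break
    start <- j
    j <- j - 1
  }
  end <- core_end
  acc <- 0
  j <- core_end + 1
  while (j <= n) {
    acc <- acc + profile[j]
    if (acc <= 0) break
    end <- j
    j <- j + 1
  }
  list(domain_start = start, domain_end = end,
       core_start = core_start, core_end = core_end,
       core_score = core_score)
}

#' Score the best soft amyloid core of a domain
#'
#' Stage two of the caller. Every 21-residue window of the domain is scored
#' by the position-weight sum of an [amyloid_matrix()], linearly rescaled to
#' 0-100 via the matrix's theoretical extreme sums and clamped. Windows
#' containing non-standard residues are excluded. Ties break to the leftmost
#' window.
#'
#' @param domain_sequence Amino-acid string of the candidate domain.
#' @param matrix An [amyloid_matrix()].
#' @return List with `start`, `end` (1-based inclusive, relative to the
#'   domain), `score` (0-100) and `raw`; or, when no scorable window exists,
#'   a list with `score = NA` and a `reason` string.
#' @export
amyloid_core_score <- function(domain_sequence, matrix = amyloid_matrix()) {
  stopifnot(inherits(matrix, "amyloid_matrix"))
  chars <- strsplit(toupper(domain_sequence), "")[[1]]
  n <- length(chars)
  if (n < 21) {
    return(list(start = NA_integer_, end = NA_integer_, score = NA_real_,
                raw = NA_real_, reason = "domain shorter than 21 residues"))
  }
  col <- match(chars, AMINO_ACIDS)          # NA for non-standard residues
  n_win <- n - 20L
  per_pos <- matrix(NA_real_, nrow = 21, ncol = n_win)
  for (k in seq_len(21)) {
    idx <- col[k:(k + n_win - 1)]
    per_pos[k, ] <- ifelse(is.na(idx), NA_real_, matrix$weights[k, ][idx])
  }
  raw <- colSums(per_pos)                   # NA where a window has odd residues
  if (all(is.na(raw))) {
    return(list(start = NA_integer_, end = NA_integer_, score = NA_real_,
                raw = NA_real_, reason = "no window free of non-standard residues"))
  }
  best <- which.max(raw)                    # leftmost max, NAs never win
  scaled <- (raw[best] - matrix$score_min) /
    (matrix$score_max - matrix$score_min) * 100
  list(start = best, end = best + 20L,
       score = min(100, max(0, scaled)), raw = raw[best])
}

#' Two-stage prion-like protein caller
#'
#' Runs the compositional scan ([find_prion_domain()]) on every sequence and,
#' for stage-one candidates, scores the best soft amyloid core of the called
#' domain ([amyloid_core_score()]). A protein is a final positive when it
#' passes both stages, i.e. has a positive-scoring compositional core window
#' and an amyloid-core score at or above `matrix$cutoff`.
#'
#' @param proteome Proteome (named character vector, `AAStringSet`,
#'   `synthetic_proteome`, or FASTA path).
#' @param model A [composition_model()].
#' @param matrix An [amyloid_matrix()]; its `cutoff` decides stage two.
#' @return Data frame of class `prld_calls`, one row per stage-one candidate,
#'   sorted by protein id: `protein_id`, `protein_length`, `domain_start`,
#'   `domain_end`, `core_score`, `amyloid_start`, `amyloid_end` (absolute
#'   coordinates), `amyloid_score`, `passes_composition`, `passes_amyloid`,
#'   `positive`. The number of proteins scanned is kept in attribute
#'   `n_scanned`.
#' @export
#' @examples
#' prot <- generate_proteome(n_proteins = 30, prion_fraction = 0.2, seed = 1)
#' calls <- call_prionlike(prot)
#' table(calls$positive)
call_prionlike <- function(proteome, model = composition_model(),
                           matrix = amyloid_matrix()) {
  seqs <- as_sequences(proteome)
  if (anyDuplicated(names(seqs))) {
    stop_validation("duplicate protein ids in proteome")
  }
  rows <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    dom <- find_prion_domain(llr_profile(s, model), model)
    if (is.null(dom)) return(NULL)
    dseq <- substr(s, dom$domain_start, dom$domain_end)
    am <- amyloid_core_score(dseq, matrix)
    has_score <- !is.na(am$score)
    data.frame(
      protein_id = id,
      protein_length = nchar(s),
      domain_start = dom$domain_start,
      domain_end = dom$domain_end,
      core_score = dom$core_score,
      amyloid_start = if (has_score) dom$domain_start + am$start - 1L else NA_integer_,
      amyloid_end = if (has_score) dom$domain_start + am$end - 1L else NA_integer_,
      amyloid_score = am$score,
      passes_composition = TRUE,
      passes_amyloid = has_score && am$score >= matrix$cutoff,
      stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    NULL
  }
  if (is.null(out)) {
    out <- data.frame(protein_id = character(), protein_length = integer(),
                      domain_start = integer(), domain_end = integer(),
                      core_score = numeric(), amyloid_start = integer(),
                      amyloid_end = integer(), amyloid_score = numeric(),
                      passes_composition = logical(),
                      passes_amyloid = logical(), stringsAsFactors = FALSE)
  }
  out$positive <- out$passes_composition & out$passes_amyloid
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_scanned") <- length(seqs)
  attr(out, "cutoff") <- matrix$cutoff
  class(out) <- c("prld_calls", "data.frame")
  out
}

#' Write PrLD calls to a tab-separated file
#'
#' @param calls A `prld_calls` data frame from [call_prionlike()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_calls <- function(calls, path) {
  write_tsv(as.data.frame(calls), path)
}

#' Read PrLD calls written by [write_calls()]
#'
#' @param path Input TSV path.
#' @return A `prld_calls` data frame.
#' @export
read_calls <- function(path) {
  out <- read_tsv(path)
  class(out) <- c("prld_calls", "data.frame")
  out
}
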