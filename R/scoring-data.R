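#' Average amino-acid composition of a large reference proteome
#'
#' A fixed background frequency table over the 20 standard amino acids,
#' matching the long-run average composition of the curated protein
#' knowledgebase (values in widespread use for compositional scoring). Shipped
#' as code so that all scoring is reproducible without downloads; for real
#' analyses the background can instead be estimated from the input proteome
#' with [estimate_background_frequencies()].
#'
#' @return Named numeric vector over the 20 standard residues, summing to 1.
#' @export
#' @examples
#' sum(background_frequencies())
background_frequencies <- function() {
  f <- c(A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0545, C = 0.0137,
         Q = 0.0393, E = 0.0675, G = 0.0707, H = 0.0227, I = 0.0596,
         L = 0.0966, K = 0.0584, M = 0.0242, F = 0.0386, P = 0.0470,
         S = 0.0656, T = 0.0534, W = 0.0108, Y = 0.0292, V = 0.0687)
  f <- f[AMINO_ACIDS]
  f / sum(f)
}

#' Prion-domain amino-acid composition
#'
#' Frequency table describing the strong Q/N bias of experimentally supported
#' yeast prion domains, the composition class that compositional PrLD scanners
#' are trained on. Glutamine plus asparagine carry 0.43 of the mass; charged
#' and hydrophobic residues are strongly depleted.
#'
#' @return Named numeric vector over the 20 standard residues, summing to 1.
#' @export
prion_frequencies <- function() {
  f <- c(Q = 0.240, N = 0.190, S = 0.090, G = 0.070, Y = 0.050, P = 0.050,
         A = 0.050, T = 0.040, L = 0.030, D = 0.030, E = 0.025, K = 0.025,
         R = 0.020, F = 0.020, V = 0.020, M = 0.015, H = 0.015, I = 0.015,
         C = 0.0025, W = 0.0025)
  f <- f[AMINO_ACIDS]
  f / sum(f)
}

#' Amyloid-propensity position weight matrix (synthetic stand-in)
#'
#' A 21-position x 20-residue weight matrix used to score candidate soft
#' amyloid cores inside PrLDs. Each cell is the product of a per-residue
#' amyloid propensity (beta-aggregation scale: high for I/V/F/L/Y/W, moderate
#' for polar residues, near zero for P/D/E/K/R) and a deterministic positional
#' modulation peaking at the window centre. The matrix is a documented
#' SYNTHETIC stand-in constructed in code — it reproduces the behaviour of
#' published amyloid-core matrices (random proteome windows score near 50/100,
#' genuine cores well above 60/100) without redistributing third-party data.
#' `score_min`/`score_max` are the theoretical extreme 21-mer sums and pin
#' the 0-100 rescaling.
#'
#' @param cutoff Acceptance cutoff on the 0-100 scale (default 60).
#' @return An object of class `amyloid_matrix`: list with `weights` (21 x 20
#'   matrix, rows positions, columns residues), `score_min`, `score_max`,
#'   `cutoff`.
#' @export
#' @examples
#' m <- amyloid_matrix()
#' dim(m$weights)
amyloid_matrix <- function(cutoff = 60) {
  propensity <- c(A = 0.55, C = 0.70, D = 0.05, E = 0.08, F = 0.92,
                  G = 0.25, H = 0.30, I = 0.95, K = 0.10, L = 0.85,
                  M = 0.65, N = 0.40, P = 0.02, Q = 0.38, R = 0.10,
                  S = 0.45, T = 0.50, V = 0.90, W = 0.75, Y = 0.80)
  propensity <- propensity[AMINO_ACIDS]
  pos_factor <- 0.8 + 0.4 * (1 - abs(seq_len(21) - 11) / 10)
  w <- outer(pos_factor, propensity)
  dimnames(w) <- list(position = seq_len(21), residue = AMINO_ACIDS)
  structure(
    list(weights = w,
         score_min = sum(apply(w, 1, min)),
         score_max = sum(apply(w, 1, max)),
         cutoff = cutoff),
    class = "amyloid_matrix")
}

#' @export
print.amyloid_matrix <- function(x, ...) {
  cat(sprintf(
    "amyloid_matrix: 21 x 20 position weights (synthetic stand-in)\n raw range [%.3f, %.3f], cutoff %.2f/100\n",
    x$score_min, x$score_max, x$cutoff))
  invisible(x)
}

# Residue composition used to draw planted soft amyloid cores: a mix of
# high-propensity residues inside a polar Q/N context, so planted 21-mers
# score clearly above the cutoff while the surrounding segment keeps its
# prion-like compositional bias.
core_frequencies <- function() {
  f <- c(N = 0.15, Q = 0.15, Y = 0.12, F = 0.10, I = 0.10, V = 0.10,
         S = 0.08, A = 0.06, T = 0.05, L = 0.05, M = 0.04)
  out <- setNames(numeric(20), AMINO_ACIDS)
  out[names(f)] <- f
  out / sum(out)
}
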