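#' @keywords internal
#' @noRd
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so generators never disturb user randomness.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage seed derivation from one master seed. Keeps the
# result a valid 32-bit integer for any master seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(simulate = 11L, detect = 23L, localize = 37L, enrich = 53L,
               express = 71L, disease = 89L, network = 107L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else {
    sum(utf8ToInt(stage)) %% 997L
  }
  as.integer((abs(as.numeric(seed)) * 7919 + off) %% 2147483587)
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop_validation("`%s` must be a single proportion in [0, 1], got %s",
                    name, deparse(substitute(x)))
  }
  invisible(x)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE,
             ...)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
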