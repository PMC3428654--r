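# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Round half away from zero at a fixed number of decimals
#'
#' Presentation rounding used for all printed percentages and ratios;
#' internal computations stay in full double precision.  `round()` in base R
#' rounds half to even, which does not reproduce conventionally formatted
#' tables (e.g. 0.125 -> 0.13, not 0.12).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(2.3125, 2)  # 2.31
#' round_half_up(0.125, 2)   # 0.13
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Single-sequence input convenience: wrap a bare character string as a
# one-record transcript_set.
as_transcript_input <- function(x) {
  if (inherits(x, "transcript_set")) return(x)
  if (is.character(x) && length(x) == 1L && !grepl("^>", x) && !file.exists(x)) {
    return(transcript_set(id = "seq1", seq = toupper(x)))
  }
  stop("expected a transcript_set or a single nucleotide string")
}
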