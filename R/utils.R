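#' @keywords internal
#' @importFrom rlang .data abort warn %||%
"_PACKAGE"

# Deterministic fan-out of one master seed into per-stage child seeds.
# Kept below 2^31 - 1 so the result is always a valid integer seed.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((abs(seed) + 10007 * stage) %% .Machine$integer.max)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Shared column checks ------------------------------------------------------

check_cols <- function(data, cols, what = "column") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s%s not found in data: %s",
                  what, if (length(missing) > 1) "s" else "",
                  paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

check_binary_outcome <- function(y, outcome) {
  vals <- unique(y[!is.na(y)])
  if (!all(vals %in% c(0, 1))) {
    abort(sprintf("outcome column '%s' must be binary 0/1", outcome))
  }
  invisible(TRUE)
}
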