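#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a plain character DNA string
#' @noRd
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Round half away from zero (printed tables round 3110.285 -> 3110.29)
#' @noRd
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Strip thousands separators from printed numbers ("3,214,418" -> 3214418)
#' @noRd
parse_printed_number <- function(x) {
  as.numeric(gsub(",", "", trimws(as.character(x)), fixed = TRUE))
}

#' Derive a stage-specific RNG seed from the pipeline seed.
#' Kept below 2^31 so it is a valid R integer.
#' @noRd
derive_seed <- function(seed, stage_index) {
  as.integer((as.double(seed) * 1009 + 97 * stage_index) %% 2147483647L)
}

#' Stable assertion helper with sprintf-style messages
#' @noRd
gs_assert <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
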