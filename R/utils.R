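#' @importFrom rlang .data %||%
#' @importFrom tibble tibble as_tibble
NULL

# round half away from zero; reproduces 17.64 -> 18, 43.84 -> 44, 89.2 -> 89
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# derive a reproducible child seed from a base seed and a stream index,
# kept inside 32-bit integer range
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1103L + as.numeric(stream) * 12347) %% 2147483647
}

`%notin%` <- function(x, table) !(x %in% table)
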