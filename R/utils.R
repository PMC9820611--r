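#' @keywords internal
"_PACKAGE"

# Round half away from zero to `digits` decimals.  base::round() rounds
# half to even, which would turn e.g. 62.85 into 62.8; reported percentages
# follow the conventional half-up rule instead.
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hiergrn <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_hiergrn(sprintf("`%s` must be TRUE or FALSE", name))
  }
  x
}
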