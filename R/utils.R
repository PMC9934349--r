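`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round a proportion to the nearest printed percent
#'
#' Reporting helper used when reproducing published whole-percent
#' summaries: `percent(0.8666) == 87`.
#'
#' @param x Numeric proportion(s) in \[0, 1\].
#' @return Integer percent(s).
#' @export
percent <- function(x) round(100 * x)
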