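#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data %||%
#' @importFrom stats quantile sd var cor density setNames rnorm runif rpois
#'   rlnorm rbinom rmultinom median mad approx pt pf ptukey t.test aov TukeyHSD
#' @importFrom utils head tail modifyList
NULL

# run `expr` under a private RNG stream derived from `seed`; the global RNG
# state is untouched, so generators are pure functions of (spec, seed)
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

assert_scalar_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      (if (open_left) x <= 0 else x < 0) ||
      (if (open_right) x >= 1 else x > 1)) {
    abort(sprintf("`%s` must be a single value in %s0, 1%s",
                  name, if (open_left) "(" else "[", if (open_right) ")" else "]"))
  }
  invisible(x)
}

# trapezoid integral of y over x
trapz_ <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

#' Significance stars
#'
#' Maps p-values to the conventional asterisk bins: `ns` for P >= 0.05,
#' `*` < 0.05, `**` < 0.01, `***` < 0.001, `****` < 0.0001.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return character vector of the same length.
#' @export
#' @examples
#' signif_stars(c(0.2, 0.03, 0.0005))
signif_stars <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  dplyr::case_when(
    is.na(p)    ~ NA_character_,
    p < 1e-4    ~ "****",
    p < 1e-3    ~ "***",
    p < 1e-2    ~ "**",
    p < 0.05    ~ "*",
    TRUE        ~ "ns"
  )
}
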