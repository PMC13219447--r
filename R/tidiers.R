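#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname idaa_pipeline
#' @param x an `idaa_result`.
#' @param ... unused.
#' @export
tidy.idaa_result <- function(x, ...) x$peaks

#' @rdname idaa_pipeline
#' @export
glance.idaa_result <- function(x, ...) x$outcome

#' @rdname anova_tukey
#' @param x an `anova_tukey` object.
#' @param ... unused.
#' @export
tidy.anova_tukey <- function(x, ...) x$pairwise

#' @rdname anova_tukey
#' @export
glance.anova_tukey <- function(x, ...) x$omnibus

#' @export
print.idaa_result <- function(x, ...) {
  cat("IDAA editing-outcome quantification\n")
  cat(sprintf("  %d peak(s), %d retained\n", nrow(x$peaks),
              sum(x$peaks$class != "EXCLUDED")))
  print(x$outcome)
  invisible(x)
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat("One-way ANOVA with Tukey HSD\n")
  print(x$omnibus)
  print(x$pairwise)
  invisible(x)
}
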