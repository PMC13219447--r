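#' Assign cell-cycle phases from EdU and DAPI measurements
#'
#' S-phase nuclei are recognised by nuclear EdU signal: a two-class Otsu
#' split of the log-transformed per-nucleus EdU means. EdU-negative
#' nuclei are split on integrated DAPI at the midpoint between the 2N and
#' 4N population modes (kernel-density peaks): G1 below, G2/M above.
#' Border-touching nuclei are left unassigned.
#'
#' @param nuclei per-nucleus tibble with columns `edu_mean`,
#'   `dapi_integrated` and (optionally) `touches_border`.
#' @param edu_threshold optional explicit EdU positivity threshold
#'   (a.u., raw scale); overrides the Otsu split.
#' @param dapi_2n optional explicit 2N anchor (integrated DAPI); the
#'   G1/G2M split is then `1.5 * dapi_2n`. Required when the EdU-negative
#'   DAPI distribution is unimodal.
#' @param min_n minimum number of analysed nuclei for automatic
#'   thresholding; below this, explicit thresholds must be supplied.
#' @return `nuclei` with a `phase` column (`"G1"`, `"S"`, `"G2M"`, or NA
#'   for border nuclei). The thresholds used are attached as attribute
#'   `"thresholds"`.
#' @export
assign_cell_cycle <- function(nuclei, edu_threshold = NULL, dapi_2n = NULL,
                              min_n = 30) {
  stopifnot(is.data.frame(nuclei),
            all(c("edu_mean", "dapi_integrated") %in% names(nuclei)))
  border <- if ("touches_border" %in% names(nuclei)) nuclei$touches_border else
    rep(FALSE, nrow(nuclei))
  usable <- !border & is.finite(nuclei$edu_mean) & is.finite(nuclei$dapi_integrated)
  if (sum(usable) < min_n && (is.null(edu_threshold) || is.null(dapi_2n))) {
    abort(sprintf("only %d analysable nuclei (< %d); supply `edu_threshold` and `dapi_2n`",
                  sum(usable), min_n))
  }
  eps <- 1e-6
  if (is.null(edu_threshold)) {
    log_thr <- otsu_threshold(log(nuclei$edu_mean[usable] + eps))
    edu_threshold <- exp(log_thr)
  }
  is_s <- usable & nuclei$edu_mean > edu_threshold

  neg_dapi <- nuclei$dapi_integrated[usable & !is_s]
  if (is.null(dapi_2n)) {
    dapi_split <- dapi_modes_split_(neg_dapi)
  } else {
    dapi_split <- 1.5 * dapi_2n
  }
  phase <- rep(NA_character_, nrow(nuclei))
  phase[is_s] <- "S"
  phase[usable & !is_s] <- ifelse(nuclei$dapi_integrated[usable & !is_s] <= dapi_split,
                                  "G1", "G2M")
  out <- dplyr::mutate(nuclei, phase = phase)
  attr(out, "thresholds") <- list(edu = edu_threshold, dapi_split = dapi_split)
  out
}

# midpoint between the two dominant kernel-density modes of the
# EdU-negative integrated-DAPI distribution; errors when unimodal
dapi_modes_split_ <- function(x) {
  if (length(x) < 10) abort("too few EdU-negative nuclei to locate DAPI modes")
  d <- density(x, n = 512)
  y <- d$y
  is_peak <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                 y[2:(length(y) - 1)] >= y[3:length(y)], FALSE)
  peaks <- which(is_peak & y > 0.05 * max(y))
  unimodal_msg <- paste("EdU-negative DAPI distribution looks unimodal;",
                        "supply an explicit 2N anchor via `dapi_2n`")
  if (length(peaks) < 2) abort(unimodal_msg)
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  # genuine 2N/4N modes are separated by a real valley
  valley <- min(y[top2[1]:top2[2]])
  if (valley > 0.8 * min(y[top2])) abort(unimodal_msg)
  mean(d$x[top2])
}

#' Flag damaged cells against a control distribution
#'
#' A cell is damaged when its nuclear marker intensity strictly exceeds
#' the 95th percentile (linear-interpolation quantile) of the
#' vehicle-control population.
#'
#' @param nuclei tibble of treated per-nucleus records.
#' @param control tibble of control per-nucleus records.
#' @param column intensity column to compare, default `"marker_mean"`.
#' @param probs control percentile, default 0.95.
#' @return `nuclei` with a logical `damaged` column; the cutoff is
#'   attached as attribute `"threshold"`.
#' @export
classify_damaged <- function(nuclei, control, column = "marker_mean",
                             probs = 0.95) {
  stopifnot(is.data.frame(nuclei), is.data.frame(control),
            column %in% names(nuclei), column %in% names(control))
  vals <- control[[column]]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) abort("empty control population")
  if (length(vals) < 100) {
    warn(sprintf("control population has only %d nuclei; the percentile cutoff will be noisy",
                 length(vals)))
  }
  thr <- quantile(vals, probs, type = 7, names = FALSE)
  out <- dplyr::mutate(nuclei, damaged = .data[[column]] > thr)
  attr(out, "threshold") <- thr
  out
}
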