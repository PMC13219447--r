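#' Subtract the non-signal background of a channel
#'
#' Non-signal pixels are defined by a global two-class Otsu threshold on
#' the channel; their mean intensity is subtracted from the whole image
#' and negatives are clipped to zero. If the threshold degenerates (the
#' image is effectively single-class), the global minimum is subtracted
#' instead, with a warning.
#'
#' @param img numeric matrix of intensities.
#' @return matrix of the same shape, background-corrected.
#' @export
subtract_background <- function(img) {
  stopifnot(is.matrix(img), length(img) > 0)
  if (diff(range(img)) == 0) return(img * 0)
  thr <- otsu_threshold(img)
  bg <- img[img <= thr]
  if (length(bg) == 0 || length(bg) == length(img)) {
    warn("degenerate background split; subtracting the global minimum")
    return(pmax(img - min(img), 0))
  }
  pmax(img - mean(bg), 0)
}

#' Segment nuclei from a DAPI channel
#'
#' Foreground by the minimum-cross-entropy global threshold, hole
#' filling, a distance-transform watershed to split touching nuclei, and
#' removal of sub-minimum objects. Objects touching the image border are
#' flagged; downstream statistics exclude them.
#'
#' @param dapi background-corrected DAPI matrix (see
#'   [subtract_background()]).
#' @param min_area minimum object area in px.
#' @param watershed_tolerance minimum depth between distance-map maxima
#'   for a split (px).
#' @return list with `labels` (integer label matrix, 0 = background) and
#'   `nuclei`: tibble with `label`, `area`, `row`, `col` (centroid),
#'   `equiv_radius`, `touches_border`.
#' @export
segment_nuclei <- function(dapi, min_area = 40, watershed_tolerance = 2) {
  stopifnot(is.matrix(dapi))
  empty <- list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
                nuclei = tibble::tibble(label = integer(), area = numeric(),
                                        row = numeric(), col = numeric(),
                                        equiv_radius = numeric(),
                                        touches_border = logical()))
  if (diff(range(dapi)) == 0) return(empty)
  thr <- li_threshold(dapi)
  mask <- dapi > thr
  if (!any(mask)) return(empty)
  mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5
  dist <- EBImage::distmap(EBImage::Image(mask * 1))
  lab <- EBImage::watershed(dist, tolerance = watershed_tolerance, ext = 1)
  lab <- matrix(as.integer(lab), nrow = nrow(dapi))

  feats <- nucleus_features_(lab)
  feats <- dplyr::filter(feats, .data$area >= min_area)
  if (nrow(feats) == 0) return(empty)
  lab[!(lab %in% feats$label)] <- 0L
  # renumber 1..n
  feats <- dplyr::arrange(feats, .data$label)
  remap <- setNames(seq_len(nrow(feats)), feats$label)
  lab[lab > 0] <- as.integer(remap[as.character(lab[lab > 0])])
  feats$label <- as.integer(remap[as.character(feats$label)])
  list(labels = lab, nuclei = feats)
}

# centroid/area/border features for every nonzero label
nucleus_features_ <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0) {
    return(tibble::tibble(label = integer(), area = numeric(), row = numeric(),
                          col = numeric(), equiv_radius = numeric(),
                          touches_border = logical()))
  }
  nr <- nrow(lab)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  lv <- lab[idx]
  border_labels <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, ncol(lab)]))
  tibble::tibble(
    label = as.integer(names(tapply(rows, lv, length))),
    area = as.numeric(tapply(rows, lv, length)),
    row = as.numeric(tapply(rows, lv, mean)),
    col = as.numeric(tapply(cols, lv, mean))
  ) |>
    dplyr::mutate(equiv_radius = sqrt(.data$area / pi),
                  touches_border = .data$label %in% border_labels)
}

#' Per-nucleus intensity measurements
#'
#' Mean and integrated (summed) intensity of a channel within each
#' nucleus mask.
#'
#' @param nuclei per-nucleus tibble (from [segment_nuclei()]).
#' @param labels integer label matrix.
#' @param channel background-corrected intensity matrix.
#' @param prefix column-name prefix, e.g. `"marker"` gives `marker_mean`
#'   and `marker_integrated`.
#' @return `nuclei` with two added columns.
#' @export
nuclear_intensities <- function(nuclei, labels, channel, prefix = "marker") {
  stopifnot(is.matrix(labels), is.matrix(channel),
            all(dim(labels) == dim(channel)))
  idx <- which(labels > 0)
  lv <- labels[idx]
  means <- tapply(channel[idx], lv, mean)
  sums <- tapply(channel[idx], lv, sum)
  pos <- match(nuclei$label, as.integer(names(means)))
  nuclei[[paste0(prefix, "_mean")]] <- as.numeric(means)[pos]
  nuclei[[paste0(prefix, "_integrated")]] <- as.numeric(sums)[pos]
  nuclei
}
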