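#' Count marker foci per nucleus
#'
#' Speckle enhancement by a white top-hat with a disk structuring element
#' of roughly the expected focus radius, then — per nucleus — a
#' three-class Otsu threshold on the enhanced in-nucleus pixels with only
#' the top intensity class kept as foreground (the middle class is
#' background haze). Foreground connected components (8-connectivity) of
#' at least `min_focus_area` pixels are counted as foci.
#'
#' @param nuclei per-nucleus tibble from [segment_nuclei()].
#' @param labels integer label matrix.
#' @param marker background-corrected marker channel matrix.
#' @param radius structuring-element (expected focus) radius in px.
#' @param min_focus_area minimum focus area in px.
#' @return `nuclei` with an integer `foci_count` column. Nuclei smaller
#'   than the structuring element get 0 with a warning.
#' @export
detect_foci <- function(nuclei, labels, marker, radius = 5, min_focus_area = 2) {
  stopifnot(is.matrix(labels), is.matrix(marker), all(dim(labels) == dim(marker)))
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  enhanced <- as.matrix(EBImage::whiteTopHat(EBImage::Image(marker), brush))
  brush_area <- sum(brush)
  counts <- integer(nrow(nuclei))
  too_small <- FALSE
  for (i in seq_len(nrow(nuclei))) {
    lb <- nuclei$label[i]
    sel <- labels == lb
    npx <- sum(sel)
    if (npx < brush_area) {
      too_small <- TRUE
      counts[i] <- 0L
      next
    }
    vals <- enhanced[sel]
    if (diff(range(vals)) == 0) { counts[i] <- 0L; next }
    thr <- otsu3_thresholds(vals)
    fg <- sel & enhanced > thr[["high"]]
    if (!any(fg)) { counts[i] <- 0L; next }
    comp <- label_components(fg, connectivity = 8)
    sizes <- tabulate(comp[comp > 0])
    counts[i] <- sum(sizes >= min_focus_area)
  }
  if (too_small) warn("some nuclei are smaller than the structuring element; their foci_count is 0")
  dplyr::mutate(nuclei, foci_count = counts)
}

#' Per-nucleus Pearson colocalization
#'
#' Sample Pearson correlation of two channels over each nucleus mask.
#' Nuclei where either channel is constant within the mask get `NA` with
#' `r_defined = FALSE`.
#'
#' @param nuclei per-nucleus tibble from [segment_nuclei()].
#' @param labels integer label matrix.
#' @param channel_a,channel_b background-corrected intensity matrices.
#' @return `nuclei` with `pearson_r` and `r_defined` columns.
#' @export
pearson_colocalization <- function(nuclei, labels, channel_a, channel_b) {
  stopifnot(is.matrix(channel_a), is.matrix(channel_b),
            all(dim(labels) == dim(channel_a)), all(dim(labels) == dim(channel_b)))
  r <- rep(NA_real_, nrow(nuclei))
  for (i in seq_len(nrow(nuclei))) {
    sel <- labels == nuclei$label[i]
    a <- channel_a[sel]; b <- channel_b[sel]
    if (length(a) >= 2 && sd(a) > 0 && sd(b) > 0) r[i] <- cor(a, b)
  }
  dplyr::mutate(nuclei, pearson_r = r, r_defined = !is.na(r))
}

#' Detect micronuclei and the fraction of affected nuclei
#'
#' Small DAPI objects — area between `min_frac` and `max_frac` of the
#' median nucleus area — whose centroid lies within
#' `assign_factor * equivalent radius` of a nucleus centroid are counted
#' as that nucleus's micronuclei (nearest nucleus wins; ties go to the
#' lower label). Satellites beyond every nucleus's assignment radius are
#' left unassigned.
#'
#' @param dapi background-corrected DAPI matrix.
#' @param seg segmentation result from [segment_nuclei()].
#' @param min_frac,max_frac satellite area bounds as fractions of the
#'   median nucleus area.
#' @param assign_factor assignment radius in units of the parent
#'   nucleus's equivalent radius.
#' @return list with `nuclei` (the per-nucleus tibble plus an integer
#'   `micronuclei` column), `fraction` (share of analysed, non-border
#'   nuclei with at least one micronucleus) and `satellites` (tibble of
#'   detected satellite objects with their assigned parent, NA if
#'   unassigned).
#' @export
detect_micronuclei <- function(dapi, seg, min_frac = 0.01, max_frac = 0.15,
                               assign_factor = 1.5) {
  nuclei <- seg$nuclei
  if (nrow(nuclei) == 0) {
    return(list(nuclei = dplyr::mutate(nuclei, micronuclei = integer(0)),
                fraction = NA_real_,
                satellites = tibble::tibble(row = numeric(), col = numeric(),
                                            area = numeric(), parent = integer())))
  }
  thr <- li_threshold(dapi)
  mask <- dapi > thr
  mask[seg$labels > 0] <- FALSE # satellites are objects outside nuclei
  comp <- label_components(mask, connectivity = 4)
  med_area <- median(nuclei$area)
  sat <- nucleus_features_(comp)
  sat <- dplyr::filter(sat, .data$area >= min_frac * med_area,
                       .data$area <= max_frac * med_area)
  parent <- rep(NA_integer_, nrow(sat))
  if (nrow(sat) > 0) {
    for (i in seq_len(nrow(sat))) {
      d <- sqrt((nuclei$row - sat$row[i])^2 + (nuclei$col - sat$col[i])^2)
      ok <- d <= assign_factor * nuclei$equiv_radius
      if (any(ok)) {
        cand <- which(ok)
        parent[i] <- nuclei$label[cand[order(d[cand], nuclei$label[cand])][1]]
      }
    }
  }
  counts <- table(factor(parent, levels = nuclei$label))
  out <- dplyr::mutate(nuclei, micronuclei = as.integer(counts))
  analysed <- !out$touches_border
  list(nuclei = out,
       fraction = if (any(analysed)) mean(out$micronuclei[analysed] >= 1) else NA_real_,
       satellites = dplyr::mutate(dplyr::select(sat, "row", "col", "area"),
                                  parent = parent))
}
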