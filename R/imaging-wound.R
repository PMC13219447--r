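#' Quantify wound closure over a scratch-assay time series
#'
#' Each frame is rescaled to 8-bit, band-pass filtered (difference of
#' Gaussians), and converted to a local-entropy texture map in which the
#' cell monolayer is bright (textured) and the cell-free wound is dark.
#' The wound/monolayer threshold is frozen from the 0-h frame — the mean
#' of the maximum-entropy (Kapur) and Otsu thresholds of the 0-h texture
#' map — to avoid threshold drift at later timepoints. The wound at each
#' time is the union of low-texture components overlapping the previous
#' wound, intersected with the previous wound mask (the monotonic rule:
#' the wound can only shrink). Closure is reported as a percentage of the
#' 0-h wound area.
#'
#' The local-entropy window erodes the apparent wound by roughly half its
#' width (wound pixels near the border see monolayer texture); the wound
#' mask is therefore dilated by `boundary_dilation` px to restore the
#' boundary before areas are measured.
#'
#' @param frames list of numeric matrices, one per timepoint, same shape.
#' @param times acquisition times in hours; must include 0.
#' @param dog_sigmas band-pass Gaussian sigmas `c(small, large)` in px.
#' @param entropy_window odd window size (px) of the local-entropy map.
#' @param entropy_levels quantization levels of the local-entropy map.
#' @param boundary_dilation wound-boundary restoration radius in px.
#' @return tibble of class `wound_series` with columns `t`, `wound_area`
#'   (px) and `closure` (%, non-decreasing, in `[0, 100]`). Frames whose
#'   wound border is undefinable (degenerate texture map) are dropped
#'   with a warning. The frozen threshold is attached as attribute
#'   `"threshold"`.
#' @export
wound_closure_series <- function(frames, times, dog_sigmas = c(1, 3),
                                 entropy_window = 5, entropy_levels = 16,
                                 boundary_dilation = 2) {
  stopifnot(is.list(frames), length(frames) == length(times), 0 %in% times)
  dims <- vapply(frames, dim, numeric(2))
  if (any(dims != dims[, 1])) abort("all frames must share the same shape")
  ord <- order(times)
  frames <- frames[ord]; times <- times[ord]

  # 8-bit rescale and entropy quantization are frozen from the 0-h frame
  # so the frozen threshold sees a drift-free texture scale
  rng0 <- range(frames[[1]])
  dog_range <- NULL
  texture_map <- function(img) {
    if (diff(range(img)) == 0 || rng0[1] == rng0[2]) return(NULL) # undefinable
    x8 <- pmin(pmax(round(255 * (img - rng0[1]) / (rng0[2] - rng0[1])), 0), 255)
    dog <- as.matrix(EBImage::gblur(EBImage::Image(x8), dog_sigmas[1])) -
      as.matrix(EBImage::gblur(EBImage::Image(x8), dog_sigmas[2]))
    if (is.null(dog_range)) dog_range <<- range(dog)
    local_entropy(dog, window = entropy_window, levels = entropy_levels,
                  range = dog_range)
  }

  dilate_ <- function(mask) {
    if (boundary_dilation < 1 || !any(mask)) return(mask)
    brush <- EBImage::makeBrush(2 * boundary_dilation + 1, "disc")
    as.matrix(EBImage::dilate(EBImage::Image(mask * 1), brush)) > 0.5
  }

  tex0 <- texture_map(frames[[1]])
  if (is.null(tex0)) abort("0-h frame has no detectable texture; no wound can be defined")
  thr <- mean(c(kapur_threshold(tex0), otsu_threshold(tex0)))
  comp0 <- label_components(tex0 <= thr, connectivity = 4)
  if (max(comp0) == 0) abort("no wound detectable in the 0-h frame")
  sizes0 <- tabulate(comp0[comp0 > 0])
  core_prev <- comp0 == which.max(sizes0) # un-dilated wound core
  core0_size <- sum(core_prev)
  area0 <- sum(dilate_(core_prev))

  keep_t <- numeric(0); keep_area <- numeric(0)
  dropped <- character(0)
  for (i in seq_along(frames)) {
    if (i == 1) {
      keep_t <- c(keep_t, times[i]); keep_area <- c(keep_area, area0)
      next
    }
    tex <- texture_map(frames[[i]])
    if (is.null(tex)) {
      dropped <- c(dropped, sprintf("t = %g h", times[i]))
      next
    }
    comp <- label_components(tex <= thr, connectivity = 4)
    core <- matrix(FALSE, nrow(tex), ncol(tex))
    if (max(comp) > 0) {
      overlapping <- setdiff(unique(comp[core_prev & comp > 0]), 0L)
      # speckle-sized false patches are not a wound
      big <- which(tabulate(comp[comp > 0]) >= 0.01 * core0_size)
      overlapping <- intersect(overlapping, big)
      if (length(overlapping) > 0) {
        core <- matrix(comp %in% overlapping, nrow(tex)) & core_prev
      }
    }
    keep_t <- c(keep_t, times[i]); keep_area <- c(keep_area, sum(dilate_(core)))
    core_prev <- core
  }
  if (length(dropped) > 0) {
    warn(paste("dropped frames with undefinable wound borders:",
               paste(dropped, collapse = ", ")))
  }
  out <- tibble::tibble(t = keep_t, wound_area = keep_area,
                        closure = 100 * (1 - keep_area / area0))
  class(out) <- c("wound_series", class(out))
  attr(out, "threshold") <- thr
  out
}
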