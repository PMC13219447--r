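#' Simulate a scratch-wound image series
#'
#' Produces one frame per timepoint: a speckled high-texture cell
#' monolayer with a centred vertical cell-free band whose area equals
#' `(1 - closure_fn(t))` times the initial band area. The band shrinks
#' symmetrically from both wound edges, emulating cell migration into the
#' scratch. Truth records the exact per-frame band area in pixels.
#'
#' @param times acquisition times in hours; must include 0.
#' @param closure_fn function `t -> closed fraction` in `[0, 1]`,
#'   non-decreasing with `closure_fn(0) = 0`.
#' @param shape frame size `c(rows, cols)`.
#' @param band_frac initial wound width as a fraction of the frame width.
#' @param cell_levels intensity levels `c(low, high)` of the monolayer
#'   speckle texture (a.u.); their contrast is what the local-entropy
#'   texture map keys on.
#' @param background_level,noise_sd background intensity and i.i.d. noise.
#' @param seed integer seed.
#' @return object of class `wound_sim`: list with `frames` (list of
#'   matrices, one per time), `times`, `truth` (tibble `t`,
#'   `wound_area`, `closure`), `params`.
#' @export
#' @examples
#' sim <- simulate_wound_series(closure_fn = function(t) pmin(t / 24, 1), seed = 1)
#' sim$truth
simulate_wound_series <- function(times = seq(0, 24, by = 4),
                                  closure_fn = function(t) pmin(t / 24, 1),
                                  shape = c(256, 256), band_frac = 0.4,
                                  cell_levels = c(40, 160),
                                  background_level = 20, noise_sd = 3,
                                  seed = NULL) {
  stopifnot(0 %in% times, length(shape) == 2)
  cl <- vapply(times, closure_fn, numeric(1))
  if (any(cl < 0 | cl > 1)) abort("`closure_fn` must map into [0, 1]")
  if (abs(cl[which(times == 0)[1]]) > 1e-12) abort("`closure_fn(0)` must be 0")
  if (any(diff(cl[order(times)]) < -1e-12)) abort("`closure_fn` must be non-decreasing")

  with_seed_(seed, {
    nr <- shape[1]; nc <- shape[2]
    width0 <- round(band_frac * nc)
    if (width0 < 4) abort("initial wound band too narrow; increase `band_frac` or `shape`")
    mid <- nc / 2
    # one static speckle texture; cells that migrate in reveal the texture
    speckle <- matrix(sample(cell_levels, nr * nc, replace = TRUE), nr, nc)
    frames <- vector("list", length(times))
    area <- numeric(length(times))
    for (i in seq_along(times)) {
      w <- round((1 - cl[i]) * width0)
      lo <- floor(mid - w / 2) + 1L
      hi <- lo + w - 1L
      wound_cols <- if (w > 0) seq(lo, hi) else integer(0)
      frame <- speckle
      frame[, wound_cols] <- 0
      frame <- frame + background_level + rnorm(nr * nc, 0, noise_sd)
      frames[[i]] <- pmax(frame, 0)
      area[i] <- nr * length(wound_cols)
    }
    structure(list(
      frames = frames, times = times,
      truth = tibble::tibble(t = times, wound_area = area,
                             closure = 100 * (1 - area / area[which(times == 0)[1]])),
      params = list(shape = shape, band_frac = band_frac, seed = seed)
    ), class = "wound_sim")
  })
}
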