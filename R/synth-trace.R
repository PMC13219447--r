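#' Affine-plus-convexity migration model
#'
#' Maps fragment size (bp) to electrophoretic migration (scan units) as
#' `migration = intercept + slope * size + convexity * size^2`. The mild
#' convexity term emulates the nonlinearity of capillary electrophoresis
#' that makes piecewise (Local Southern) size calling necessary.
#'
#' @param slope scans per bp.
#' @param intercept scan offset.
#' @param convexity quadratic term; keep small and non-negative.
#' @return a function `size -> migration`, strictly increasing for
#'   positive sizes.
#' @export
migration_model <- function(slope = 5, intercept = 40, convexity = 0.002) {
  stopifnot(slope > 0, convexity >= 0)
  function(size) intercept + slope * size + convexity * size^2
}

#' Simulate an IDAA fragment-analysis chromatogram
#'
#' Generates a sample trace as a sum of Gaussian peaks — one per editing
#' outcome, with integrated area exactly proportional to its area fraction —
#' plus i.i.d. Gaussian noise, together with a size-standard ladder trace
#' and a ground-truth table. Emulates the amplicon pool of an edited cell
#' population carrying wild-type, donor-templated (+8 bp) and indel products.
#'
#' @param wt_size wild-type amplicon size in bp.
#' @param mix data frame with columns `offset` (bp relative to wild type)
#'   and `fraction` (area fractions, must sum to 1).
#' @param peak_sigma peak standard deviation in bp.
#' @param height_scale apex height (RFU) of a fraction-1 peak.
#' @param noise_sd i.i.d. noise standard deviation in RFU.
#' @param ladder size-standard fragment sizes in bp, strictly increasing.
#' @param migration function mapping size (bp) to migration (scan units);
#'   must be strictly monotone over the ladder range.
#' @param ladder_height apex height of ladder peaks in RFU.
#' @param seed integer seed; identical inputs give bit-identical output.
#' @return an object of class `trace_sim`: a list with `trace` and
#'   `ladder_trace` (tibbles with columns `migration`, `rfu`), `ladder`
#'   (sizes), `truth` (per-peak true size, offset, fraction and a
#'   `resolvable` flag marking peaks closer than `2 * peak_sigma` to a
#'   neighbour), and `params`.
#' @export
#' @examples
#' sim <- simulate_trace(mix = data.frame(offset = c(0, 8), fraction = c(0.7, 0.3)),
#'                       seed = 1)
#' head(sim$trace)
simulate_trace <- function(wt_size = 300,
                           mix = data.frame(offset = 0, fraction = 1),
                           peak_sigma = 0.7,
                           height_scale = 2000,
                           noise_sd = 0,
                           ladder = c(50, 75, 100, 139, 150, 160, 200, 250,
                                      300, 340, 350, 400, 450, 490, 500),
                           migration = migration_model(),
                           ladder_height = 800,
                           seed = NULL) {
  mix <- tibble::as_tibble(mix)
  stopifnot(all(c("offset", "fraction") %in% names(mix)),
            nrow(mix) >= 1, all(mix$fraction > 0))
  if (abs(sum(mix$fraction) - 1) > 1e-8) abort("`mix$fraction` must sum to 1")
  if (any(diff(ladder) <= 0)) abort("`ladder` sizes must be strictly increasing")
  mig_l <- migration(ladder)
  if (any(diff(mig_l) <= 0)) abort("`migration` must be strictly monotone over the ladder")

  sizes <- wt_size + mix$offset
  if (any(sizes <= min(ladder)) || any(sizes >= max(ladder))) {
    warn("some peak sizes fall outside the ladder range; size calls will be extrapolated")
  }
  grid <- seq(floor(migration(min(ladder)) - 60), ceiling(migration(max(ladder)) + 60))

  # slope of the migration map at the wild-type size sets the reference
  # sigma in scan units; per-peak amplitudes are chosen so that each
  # integrated area is exactly proportional to its fraction
  slope_at <- function(s) {
    eps <- 1e-4
    (migration(s + eps) - migration(s - eps)) / (2 * eps)
  }
  sigma_ref <- peak_sigma * slope_at(wt_size)
  gauss_sum <- function(centers, areas, sigmas) {
    sig <- rep(0, length(grid))
    for (k in seq_along(centers)) {
      sig <- sig + areas[k] / (sigmas[k] * sqrt(2 * pi)) *
        exp(-(grid - centers[k])^2 / (2 * sigmas[k]^2))
    }
    sig
  }
  total_area <- height_scale * sigma_ref * sqrt(2 * pi)
  centers <- migration(sizes)
  sigmas <- peak_sigma * vapply(sizes, slope_at, numeric(1))
  signal <- gauss_sum(centers, mix$fraction * total_area, sigmas)
  ladder_signal <- gauss_sum(mig_l, ladder_height * sigma_ref * sqrt(2 * pi) *
                               rep(1, length(mig_l)), peak_sigma * vapply(ladder, slope_at, numeric(1)))
  if (noise_sd > 0) {
    signal <- with_seed_(seed, signal + rnorm(length(grid), 0, noise_sd))
    ladder_signal <- with_seed_(if (is.null(seed)) NULL else seed + 1L,
                                ladder_signal + rnorm(length(grid), 0, noise_sd))
  }

  ord <- order(sizes)
  gap_ok <- rep(TRUE, nrow(mix))
  if (nrow(mix) > 1) {
    gaps <- diff(sizes[ord])
    close_pair <- gaps < 2 * peak_sigma
    flag <- rep(FALSE, nrow(mix))
    flag[ord[which(close_pair)]] <- TRUE
    flag[ord[which(close_pair) + 1L]] <- TRUE
    gap_ok <- !flag
  }
  structure(list(
    trace = tibble::tibble(migration = grid, rfu = pmax(signal, 0)),
    ladder_trace = tibble::tibble(migration = grid, rfu = pmax(ladder_signal, 0)),
    ladder = ladder,
    migration = migration,
    truth = tibble::tibble(size = sizes, offset = mix$offset,
                           fraction = mix$fraction, resolvable = gap_ok),
    params = list(wt_size = wt_size, peak_sigma = peak_sigma,
                  height_scale = height_scale, noise_sd = noise_sd, seed = seed)
  ), class = "trace_sim")
}

#' Simulate a competitive-growth co-culture
#'
#' Day-10 knockout fraction under a relative-fitness odds model: the KO/WT
#' odds at the end of co-culture equal the starting odds scaled by
#' `fitness` (the net relative growth of KO over the interval). `days` is
#' carried as metadata describing the interval length.
#'
#' @param ko_d0 starting KO fraction, in (0, 1).
#' @param fitness relative fitness of KO vs WT over the interval (> 0);
#'   1 means neutral.
#' @param days length of the co-culture interval (metadata).
#' @return tibble with `ko_d0`, `ko_d10`, `fitness`, `days`.
#' @export
#' @examples
#' simulate_competition(0.5, fitness = 0.5) # ko_d10 = 1/3
simulate_competition <- function(ko_d0, fitness = 1, days = 10) {
  assert_scalar_prob(ko_d0, "ko_d0", open_left = TRUE, open_right = TRUE)
  if (!is.numeric(fitness) || fitness <= 0) abort("`fitness` must be > 0")
  odds <- ko_d0 / (1 - ko_d0) * fitness
  tibble::tibble(ko_d0 = ko_d0, ko_d10 = odds / (1 + odds),
                 fitness = fitness, days = days)
}
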