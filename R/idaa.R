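#' Detect peaks in a fragment-analysis chromatogram
#'
#' Local maxima above an RFU floor after rolling-baseline subtraction.
#' No smoothing is applied to the signal. The apex position is refined to
#' sub-sample resolution by a cubic fit over a short window around the
#' discrete maximum; peak area is the trapezoid integral over the peak's
#' support (bounded by the flanking signal minima).
#'
#' @param trace data frame with columns `migration` (strictly increasing)
#'   and `rfu`.
#' @param height_threshold minimum apex height in RFU; the comparison is
#'   inclusive (`height >= threshold` is retained).
#' @param min_half_width minimum width at half height, in samples.
#' @param baseline_window rolling-baseline window length in samples
#'   (rolling minimum followed by a rolling mean of the same length).
#' @param apex_window,apex_degree window length (odd) and polynomial degree
#'   of the sub-sample apex localization fit.
#' @return tibble with one row per detected peak: `apex_migration`,
#'   `height` (RFU, baseline-corrected observed apex), `area`, `left`,
#'   `right` (support bounds, scan units).
#' @export
detect_peaks <- function(trace, height_threshold = 100, min_half_width = 1,
                         baseline_window = 35, apex_window = 7, apex_degree = 3) {
  stopifnot(is.data.frame(trace), all(c("migration", "rfu") %in% names(trace)))
  if (nrow(trace) == 0) abort("empty trace")
  m <- trace$migration
  y <- trace$rfu
  if (any(!is.finite(m)) || any(!is.finite(y))) abort("trace contains non-finite values")
  if (any(diff(m) <= 0)) abort("`migration` must be strictly increasing")
  if (height_threshold <= 0) abort("`height_threshold` must be > 0")

  empty <- tibble::tibble(apex_migration = numeric(), height = numeric(),
                          area = numeric(), left = numeric(), right = numeric())
  if (length(y) < 3) return(empty)

  base_min <- zoo::rollapply(y, baseline_window, min, partial = TRUE, align = "center")
  baseline <- zoo::rollapply(base_min, baseline_window, mean, partial = TRUE, align = "center")
  s <- pmax(y - baseline, 0)

  n <- length(s)
  is_max <- c(FALSE, s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n], FALSE)
  # an apex must also be the maximum of its surrounding peak window
  w0 <- (apex_window - 1) %/% 2
  win_max <- zoo::rollapply(s, apex_window, max, partial = TRUE, align = "center")
  # inclusive floor, robust to baseline round-off
  thr_eff <- height_threshold * (1 - sqrt(.Machine$double.eps))
  apices <- which(is_max & s >= thr_eff & s >= win_max)
  # plateau guard: keep only the first of any apices closer than the window
  if (length(apices) > 1) {
    apices <- apices[c(TRUE, diff(apices) > w0)]
  }
  if (length(apices) == 0) return(empty)

  # support bounds: the valley towards an adjacent detected peak, or where
  # the signal has decayed to ~1% of the apex height
  bounds <- function(k) {
    i <- apices[k]
    floor_val <- max(1e-9, 0.01 * s[i])
    l <- i
    while (l > 1 && s[l - 1] > floor_val) l <- l - 1
    if (k > 1) {
      prev <- apices[k - 1]
      valley <- prev + which.min(s[prev:i]) - 1L
      l <- max(l, valley)
    }
    r <- i
    while (r < n && s[r + 1] > floor_val) r <- r + 1
    if (k < length(apices)) {
      nxt <- apices[k + 1]
      valley <- i + which.min(s[i:nxt]) - 1L
      r <- min(r, valley)
    }
    c(l, r)
  }
  rows <- lapply(seq_along(apices), function(k) {
    i <- apices[k]
    b <- bounds(k)
    l <- b[1]; r <- b[2]
    if (r - l + 1 < 3) return(NULL)
    # width at half height within the support, in samples
    half <- s[i] / 2
    above <- which(s[l:r] >= half)
    if (length(above) < 1 || (max(above) - min(above)) < min_half_width) return(NULL)
    # sub-sample apex via local polynomial fit
    wi <- max(l, i - w0):min(r, i + w0)
    apex <- m[i]
    if (length(wi) > apex_degree) {
      xc <- m[wi] - m[i] # centered abscissa keeps the fit well-conditioned
      fit <- stats::lm(s[wi] ~ stats::poly(xc, degree = apex_degree, raw = TRUE))
      cf <- stats::coef(fit)
      if (all(is.finite(cf))) {
        # analytic stationary points of the fitted polynomial
        dcf <- cf[-1] * seq_len(apex_degree)
        roots <- polyroot(dcf)
        roots <- Re(roots[abs(Im(roots)) < 1e-8])
        roots <- roots[roots >= xc[1] & roots <= xc[length(xc)]]
        if (length(roots) > 0) {
          val <- vapply(roots, function(r) sum(cf * r^(0:apex_degree)), numeric(1))
          apex <- m[i] + roots[which.max(val)]
        }
      }
    }
    tibble::tibble(apex_migration = apex, height = s[i],
                   area = trapz_(m[l:r], s[l:r]), left = m[l], right = m[r])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty else dplyr::arrange(out, .data$apex_migration)
}

# exact hyperbolic fit size = c/(migration - m0) + L0 through three
# (migration, size) points; falls back to a line when the points are
# collinear (affine migration)
fit_southern3_ <- function(mm, ss) {
  stopifnot(length(mm) == 3, length(ss) == 3)
  R <- (ss[1] - ss[3]) / (ss[2] - ss[3])
  K <- R * (mm[3] - mm[2]) / (mm[3] - mm[1])
  if (!is.finite(K) || abs(K - 1) < 1e-10) {
    cf <- stats::coef(stats::lm(ss ~ mm))
    return(function(m) cf[[1]] + cf[[2]] * m)
  }
  m0 <- (K * mm[1] - mm[2]) / (K - 1)
  cc <- (ss[1] - ss[3]) / (1 / (mm[1] - m0) - 1 / (mm[3] - m0))
  L0 <- ss[1] - cc / (mm[1] - m0)
  function(m) cc / (m - m0) + L0
}

#' Local Southern size calling
#'
#' Assigns a fragment size in bp to each detected peak from a size
#' standard, using the Local Southern method: the reciprocal model
#' `size = c / (migration - m0) + L0` is fitted exactly through the two
#' bracketing standards below plus one above, and through one below plus
#' two above, and the two fitted sizes are averaged. Peaks too close to
#' the ends of the standard for both fits fall back to a single fit
#' through the three nearest standards and are flagged.
#'
#' @param peaks tibble from [detect_peaks()].
#' @param standard data frame with columns `size` (bp) and `migration`
#'   (scan units), both strictly increasing, at least 4 entries.
#' @return `peaks` with columns `size` (bp) and `size_fallback` (logical;
#'   `TRUE` when the single-fit fallback or extrapolation was used).
#' @export
call_sizes_local_southern <- function(peaks, standard) {
  stopifnot(is.data.frame(standard), all(c("size", "migration") %in% names(standard)))
  standard <- dplyr::arrange(tibble::as_tibble(standard), .data$migration)
  if (nrow(standard) < 4) abort("size standard needs at least 4 entries")
  if (any(diff(standard$size) <= 0) || any(diff(standard$migration) <= 0)) {
    abort("size standard must be strictly increasing in both size and migration")
  }
  if (nrow(peaks) == 0) {
    return(dplyr::mutate(peaks, size = numeric(0), size_fallback = logical(0)))
  }
  ms <- standard$migration
  ss <- standard$size
  call_one <- function(m) {
    n_below <- sum(ms <= m)
    n_above <- length(ms) - sum(ms < m) # standards at exactly m count on both sides
    if (n_below >= 2 && n_above >= 1 && length(ms) - n_below >= 1) {
      ib <- which(ms <= m)
      ia <- which(ms > m)
      fitA <- fit_southern3_(c(ms[ib[length(ib) - 1]], ms[ib[length(ib)]], ms[ia[1]]),
                             c(ss[ib[length(ib) - 1]], ss[ib[length(ib)]], ss[ia[1]]))
      sizeA <- fitA(m)
      if (length(ia) >= 2) {
        fitB <- fit_southern3_(c(ms[ib[length(ib)]], ms[ia[1]], ms[ia[2]]),
                               c(ss[ib[length(ib)]], ss[ia[1]], ss[ia[2]]))
        return(list(size = mean(c(sizeA, fitB(m))), fallback = FALSE))
      }
      return(list(size = sizeA, fallback = TRUE))
    }
    # near the ends (or outside the standard): three nearest standards
    nearest <- order(abs(ms - m))[1:3]
    nearest <- sort(nearest)
    fit <- fit_southern3_(ms[nearest], ss[nearest])
    list(size = fit(m), fallback = TRUE)
  }
  res <- lapply(peaks$apex_migration, call_one)
  dplyr::mutate(peaks,
                size = vapply(res, `[[`, numeric(1), "size"),
                size_fallback = vapply(res, `[[`, logical(1), "fallback"))
}

#' Classify sized peaks into editing outcomes
#'
#' Applies the retention window and outcome rules: peaks more than
#' `window_halfwidth` bp from the wild-type size are `EXCLUDED` (the
#' comparison allows the sizing tolerance, so a boundary peak is not
#' flipped by sub-0.5-bp sizing error); within `size_tolerance` of the
#' wild-type size they are `WT`; within `size_tolerance` of
#' `wt + hdr_offset` they are `HDR` (the donor-templated precise
#' insertion); every other retained length shift is `NHEJ`.
#'
#' @param peaks tibble with a `size` column (bp), e.g. from
#'   [call_sizes_local_southern()].
#' @param wt_size wild-type amplicon size in bp; if `NULL`, inferred as
#'   the size of the largest-area peak (requires an `area` column).
#' @param window_halfwidth retention window half-width in bp (inclusive).
#' @param hdr_offset expected HDR insertion size in bp.
#' @param size_tolerance sizing tolerance in bp for the WT and HDR calls.
#' @return `peaks` with columns `offset` (bp) and `class` (factor with
#'   levels WT, HDR, NHEJ, EXCLUDED).
#' @export
filter_and_classify <- function(peaks, wt_size = NULL, window_halfwidth = 25,
                                hdr_offset = 8, size_tolerance = 0.5) {
  stopifnot(is.data.frame(peaks), "size" %in% names(peaks))
  if (is.null(wt_size)) {
    if (!"area" %in% names(peaks) || nrow(peaks) == 0) {
      abort("no `wt_size` supplied and no peaks to infer it from")
    }
    wt_size <- peaks$size[which.max(peaks$area)]
  }
  dplyr::mutate(peaks,
    offset = .data$size - wt_size,
    class = factor(dplyr::case_when(
      # the window edge honours the same sizing tolerance as the class
      # calls: fractional sizing must not flip a boundary peak
      abs(.data$offset) > window_halfwidth + size_tolerance ~ "EXCLUDED",
      abs(.data$offset) <= size_tolerance               ~ "WT",
      abs(.data$offset - hdr_offset) <= size_tolerance  ~ "HDR",
      TRUE                                              ~ "NHEJ"
    ), levels = c("WT", "HDR", "NHEJ", "EXCLUDED"))
  )
}

#' Quantify editing outcomes from classified peak areas
#'
#' Area fractions of the retained (non-excluded) peaks per outcome class;
#' total editing is the non-wild-type fraction and the HDR/NHEJ ratio is
#' reported when NHEJ area is present.
#'
#' @param peaks tibble from [filter_and_classify()], with `area` and
#'   `class` columns.
#' @return one-row tibble: `frac_wt`, `frac_hdr`, `frac_nhej`,
#'   `total_editing`, `hdr_nhej_ratio` (NA when undefined),
#'   `ratio_defined`.
#' @export
quantify_outcomes <- function(peaks) {
  stopifnot(is.data.frame(peaks), all(c("area", "class") %in% names(peaks)))
  kept <- dplyr::filter(peaks, .data$class != "EXCLUDED")
  if (nrow(kept) == 0) abort("all peaks are excluded; nothing to quantify")
  tot <- sum(kept$area)
  a <- function(cl) sum(kept$area[kept$class == cl]) / tot
  frac_wt <- a("WT"); frac_hdr <- a("HDR"); frac_nhej <- a("NHEJ")
  tibble::tibble(
    frac_wt = frac_wt, frac_hdr = frac_hdr, frac_nhej = frac_nhej,
    total_editing = 1 - frac_wt,
    hdr_nhej_ratio = if (frac_nhej > 0) frac_hdr / frac_nhej else NA_real_,
    ratio_defined = frac_nhej > 0
  )
}

#' Run the full IDAA quantification pipeline
#'
#' Detects ladder and sample peaks, builds the size standard, sizes the
#' sample peaks by Local Southern, classifies them against the wild-type
#' size and quantifies outcome fractions from peak areas.
#'
#' @param trace sample chromatogram (data frame `migration`, `rfu`) or a
#'   `trace_sim` object from [simulate_trace()] (then `ladder_trace` and
#'   `ladder_sizes` are taken from it).
#' @param ladder_trace ladder chromatogram (data frame `migration`, `rfu`).
#' @param ladder_sizes numeric vector of ladder fragment sizes in bp.
#' @param wt_size wild-type size in bp, or `NULL` to infer from the
#'   largest-area peak.
#' @inheritParams detect_peaks
#' @inheritParams filter_and_classify
#' @param ladder_threshold RFU floor for ladder peak detection.
#' @return object of class `idaa_result`: list with `peaks` (sized,
#'   classified tibble), `outcome` (one-row tibble), `standard`, and
#'   `config`. Use [generics::tidy()] / [generics::glance()].
#' @export
#' @examples
#' sim <- simulate_trace(mix = data.frame(offset = c(0, 8, -4),
#'                                        fraction = c(0.5, 0.3, 0.2)), seed = 1)
#' res <- idaa_pipeline(sim)
#' glance(res)
idaa_pipeline <- function(trace, ladder_trace = NULL, ladder_sizes = NULL,
                          wt_size = NULL, height_threshold = 100,
                          min_half_width = 1, baseline_window = 35,
                          window_halfwidth = 25, hdr_offset = 8,
                          size_tolerance = 0.5, ladder_threshold = 100) {
  if (inherits(trace, "trace_sim")) {
    ladder_trace <- trace$ladder_trace
    ladder_sizes <- trace$ladder
    trace <- trace$trace
  }
  if (is.null(ladder_trace) || is.null(ladder_sizes)) {
    abort("`ladder_trace` and `ladder_sizes` are required")
  }
  lad <- detect_peaks(ladder_trace, height_threshold = ladder_threshold,
                      baseline_window = baseline_window)
  if (nrow(lad) < length(ladder_sizes)) {
    abort(sprintf("found %d ladder peaks for %d ladder sizes",
                  nrow(lad), length(ladder_sizes)))
  }
  if (nrow(lad) > length(ladder_sizes)) { # keep the tallest, in order
    lad <- dplyr::arrange(dplyr::slice_max(lad, .data$height,
                                           n = length(ladder_sizes)),
                          .data$apex_migration)
  }
  standard <- tibble::tibble(size = sort(ladder_sizes),
                             migration = lad$apex_migration)
  peaks <- detect_peaks(trace, height_threshold = height_threshold,
                        min_half_width = min_half_width,
                        baseline_window = baseline_window)
  if (nrow(peaks) == 0) abort("no peaks detected in the sample trace")
  peaks <- call_sizes_local_southern(peaks, standard)
  peaks <- filter_and_classify(peaks, wt_size = wt_size,
                               window_halfwidth = window_halfwidth,
                               hdr_offset = hdr_offset,
                               size_tolerance = size_tolerance)
  structure(list(
    peaks = peaks,
    outcome = quantify_outcomes(peaks),
    standard = standard,
    config = list(height_threshold = height_threshold,
                  min_half_width = min_half_width,
                  baseline_window = baseline_window,
                  window_halfwidth = window_halfwidth,
                  hdr_offset = hdr_offset, size_tolerance = size_tolerance)
  ), class = "idaa_result")
}
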