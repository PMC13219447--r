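# Multi-channel field generator: non-overlapping elliptical nuclei whose
# DAPI content encodes cell-cycle phase, an EdU channel positive only in
# S phase, a marker channel with planted Gaussian foci, and optional
# micronuclear DAPI satellites.

#' Simulate a multi-channel fluorescence field
#'
#' Renders `n_nuclei` non-overlapping near-circular nuclei into DAPI, EdU
#' and marker channels. DAPI encodes DNA content (2N in G1, uniformly
#' between 2N and 4N in S, 4N in G2/M, as integrated intensity); the EdU
#' channel is positive only in S-phase nuclei; the marker channel carries
#' the requested number of Gaussian foci per nucleus; micronuclei are
#' small DAPI satellites placed just outside their parent's boundary.
#'
#' @param shape field size in pixels, `c(rows, cols)`.
#' @param n_nuclei number of nuclei to place. Placement is rejection
#'   sampling; an infeasible packing is an error, never a silent
#'   truncation.
#' @param phase_fractions named or ordered fractions `(G1, S, G2M)`,
#'   summing to 1.
#' @param phase_mode `"quota"` assigns exact per-phase counts (largest
#'   remainders); `"multinomial"` samples each nucleus independently.
#' @param dapi_2n_mean,dapi_4n_mean mean integrated DAPI content of 2N and
#'   4N nuclei (a.u.); the 4N default is twice the 2N value.
#' @param dapi_cv coefficient of variation of DNA content within a phase.
#' @param radius_range nucleus equivalent-radius range in px.
#' @param foci_per_nucleus foci per nucleus: a single count, a vector of
#'   length `n_nuclei`, or a named list of per-phase Poisson means
#'   `list(G1 =, S =, G2M =)`.
#' @param focus_amplitude,focus_sigma focus peak amplitude (a.u.) and
#'   Gaussian sigma (px).
#' @param focus_min_sep minimum distance between planted foci centres, px.
#' @param micronucleus_prob per-nucleus probability of carrying one
#'   micronucleus (a DAPI disk of 2--8% parent area next to the boundary).
#' @param edu_level EdU per-pixel intensity of S-phase nuclei (a.u.).
#' @param background_level,noise_sd additive background and i.i.d.
#'   Gaussian noise (a.u.) applied to every channel.
#' @param centers optional `n_nuclei x 2` matrix of (row, col) centres to
#'   use instead of random placement (e.g. to plant border nuclei).
#' @param seed integer seed.
#' @return object of class `field_sim`: list with `channels` (named list
#'   of matrices `dapi`, `edu`, `marker`), `truth` (per-nucleus tibble:
#'   `id`, `row`, `col`, `radius`, `phase`, `dapi_total`, `n_foci`,
#'   `n_micronuclei`, `touches_border`) and `params`.
#' @export
simulate_image_field <- function(shape = c(256, 256), n_nuclei = 30,
                                 phase_fractions = c(G1 = 0.6, S = 0.25, G2M = 0.15),
                                 phase_mode = c("quota", "multinomial"),
                                 dapi_2n_mean = 2e4,
                                 dapi_4n_mean = 2 * dapi_2n_mean,
                                 dapi_cv = 0.04,
                                 radius_range = c(9, 13),
                                 foci_per_nucleus = 0,
                                 focus_amplitude = 200, focus_sigma = 1.5,
                                 focus_min_sep = 4 * focus_sigma,
                                 micronucleus_prob = 0,
                                 edu_level = 40,
                                 background_level = 20, noise_sd = 2,
                                 centers = NULL, seed = NULL) {
  phase_mode <- match.arg(phase_mode)
  stopifnot(length(shape) == 2, all(shape >= 32))
  pf <- as.numeric(phase_fractions)
  if (length(pf) != 3 || any(pf < 0) || abs(sum(pf) - 1) > 1e-8) {
    abort("`phase_fractions` must be three non-negative values summing to 1")
  }
  with_seed_(seed, {
    nr <- shape[1]; nc <- shape[2]
    radii <- runif(n_nuclei, radius_range[1], radius_range[2])
    # a micronucleus can extend to ~1.6x its parent radius, so reserve room
    reach <- if (micronucleus_prob > 0) 1.7 else 1.0

    if (is.null(centers) && n_nuclei > 0) {
      centers <- matrix(NA_real_, n_nuclei, 2)
      for (k in seq_len(n_nuclei)) {
        placed <- FALSE
        bm <- reach * radii[k] + 4 # border margin
        for (try in seq_len(4000)) {
          p <- c(runif(1, bm, nr - bm), runif(1, bm, nc - bm))
          if (k == 1 || all(sqrt(rowSums((centers[seq_len(k - 1), , drop = FALSE] -
                                            matrix(p, k - 1, 2, byrow = TRUE))^2)) >
                              reach * (radii[k] + radii[seq_len(k - 1)]) + 6)) {
            centers[k, ] <- p; placed <- TRUE; break
          }
        }
        if (!placed) abort("cannot place nuclei without overlap; reduce `n_nuclei` or enlarge `shape`")
      }
    } else if (n_nuclei > 0) {
      centers <- as.matrix(centers)
      stopifnot(nrow(centers) == n_nuclei, ncol(centers) == 2)
    }

    phases <- character(0)
    if (n_nuclei > 0) {
      if (phase_mode == "quota") {
        counts <- floor(pf * n_nuclei)
        rem <- n_nuclei - sum(counts)
        if (rem > 0) {
          extra <- order(pf * n_nuclei - counts, decreasing = TRUE)[seq_len(rem)]
          counts[extra] <- counts[extra] + 1L
        }
        phases <- sample(rep(c("G1", "S", "G2M"), counts))
      } else {
        phases <- sample(c("G1", "S", "G2M"), n_nuclei, replace = TRUE, prob = pf)
      }
    }

    dapi_total <- vapply(phases, function(ph) {
      switch(ph,
             G1 = dapi_2n_mean * exp(rnorm(1, 0, dapi_cv)),
             S = runif(1, dapi_2n_mean * 1.15, dapi_4n_mean * 0.85),
             G2M = dapi_4n_mean * exp(rnorm(1, 0, dapi_cv)))
    }, numeric(1))

    n_foci <- if (is.list(foci_per_nucleus)) {
      vapply(seq_len(n_nuclei),
             function(k) as.numeric(rpois(1, foci_per_nucleus[[phases[k]]])), numeric(1))
    } else if (length(foci_per_nucleus) == 1) {
      rep(foci_per_nucleus, n_nuclei)
    } else {
      stopifnot(length(foci_per_nucleus) == n_nuclei)
      foci_per_nucleus
    }

    dapi <- matrix(0, nr, nc); edu <- matrix(0, nr, nc); marker <- matrix(0, nr, nc)
    rowg <- matrix(seq_len(nr), nr, nc)
    colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    has_mn <- if (n_nuclei > 0) runif(n_nuclei) < micronucleus_prob else logical(0)
    touches_border <- logical(n_nuclei)

    for (k in seq_len(n_nuclei)) {
      r <- radii[k]
      ax1 <- r * runif(1, 0.9, 1.1); ax2 <- r^2 / ax1 # area-preserving ellipse
      th <- runif(1, 0, pi)
      dr <- rowg - centers[k, 1]; dc <- colg - centers[k, 2]
      u <- dr * cos(th) + dc * sin(th); v <- -dr * sin(th) + dc * cos(th)
      inside <- (u / ax1)^2 + (v / ax2)^2 <= 1
      area <- sum(inside)
      if (area == 0) abort("nucleus rendered with zero area; check `centers`")
      touches_border[k] <- any(inside[1, ]) || any(inside[nr, ]) ||
        any(inside[, 1]) || any(inside[, nc])
      dapi[inside] <- dapi[inside] + dapi_total[k] / area
      if (phases[k] == "S") edu[inside] <- edu[inside] + edu_level
      if (n_foci[k] > 0) {
        pts <- matrix(NA_real_, 0, 2)
        for (f in seq_len(n_foci[k])) {
          ok <- FALSE
          for (try in seq_len(2000)) {
            ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * 0.65 * r
            p <- centers[k, ] + rad * c(cos(ang), sin(ang))
            if (nrow(pts) == 0 ||
                all(sqrt(rowSums((pts - matrix(p, nrow(pts), 2, byrow = TRUE))^2)) >= focus_min_sep)) {
              pts <- rbind(pts, p); ok <- TRUE; break
            }
          }
          if (!ok) break
        }
        if (nrow(pts) < n_foci[k]) {
          # deterministic fallback: equally spaced on a ring (random phase)
          kk <- n_foci[k]
          ring_r <- 0.65 * r
          chord <- if (kk > 1) 2 * ring_r * sin(pi / kk) else Inf
          if (chord < focus_min_sep) {
            abort("cannot place foci with the requested separation; reduce counts or separation")
          }
          phi <- runif(1, 0, 2 * pi) + 2 * pi * seq_len(kk) / kk
          pts <- cbind(centers[k, 1] + ring_r * cos(phi),
                       centers[k, 2] + ring_r * sin(phi))
        }
        for (f in seq_len(nrow(pts))) {
          marker <- marker + focus_amplitude *
            exp(-((rowg - pts[f, 1])^2 + (colg - pts[f, 2])^2) / (2 * focus_sigma^2))
        }
      }
      if (has_mn[k]) {
        frac <- runif(1, 0.02, 0.08)
        mr <- max(1.2, sqrt(frac * area / pi))
        ang <- runif(1, 0, 2 * pi)
        mc <- centers[k, ] + (r + mr + 2) * c(cos(ang), sin(ang))
        mn_in <- (rowg - mc[1])^2 + (colg - mc[2])^2 <= mr^2
        dapi[mn_in] <- dapi[mn_in] + dapi_total[k] / area # parent-like per-pixel level
      }
    }

    dapi <- dapi + background_level + rnorm(nr * nc, 0, noise_sd)
    edu <- edu + background_level + rnorm(nr * nc, 0, noise_sd)
    marker <- marker + background_level + rnorm(nr * nc, 0, noise_sd)

    truth <- tibble::tibble(
      id = seq_len(n_nuclei),
      row = if (n_nuclei > 0) centers[, 1] else numeric(0),
      col = if (n_nuclei > 0) centers[, 2] else numeric(0),
      radius = radii[seq_len(n_nuclei)],
      phase = phases,
      dapi_total = dapi_total,
      n_foci = as.integer(n_foci),
      n_micronuclei = as.integer(has_mn),
      touches_border = touches_border
    )
    structure(list(
      channels = list(dapi = pmax(dapi, 0), edu = pmax(edu, 0), marker = pmax(marker, 0)),
      truth = truth,
      params = list(shape = shape, phase_fractions = pf, seed = seed,
                    focus_sigma = focus_sigma, background_level = background_level)
    ), class = "field_sim")
  })
}

#' Simulate per-nucleus feature records
#'
#' Generates the per-nucleus feature table that image extraction would
#' produce — integrated DAPI, mean EdU and marker intensities — directly
#' from the population model, without rendering pixels. Useful for
#' population-scale validation of cell-cycle gating and damage
#' classification.
#'
#' @inheritParams simulate_image_field
#' @param n number of nuclei.
#' @param edu_noise_sd spread of the (log-scale) EdU-negative floor.
#' @param marker_meanlog,marker_sdlog log-normal parameters of the nuclear
#'   marker mean intensity.
#' @return tibble with columns `label`, `area`, `dapi_integrated`,
#'   `edu_mean`, `marker_mean`, `touches_border`, and the true `phase`.
#' @export
simulate_nucleus_records <- function(n = 2000,
                                     phase_fractions = c(G1 = 0.6, S = 0.25, G2M = 0.15),
                                     phase_mode = c("quota", "multinomial"),
                                     dapi_2n_mean = 2e4,
                                     dapi_4n_mean = 2 * dapi_2n_mean,
                                     dapi_cv = 0.04,
                                     edu_level = 40, edu_noise_sd = 0.4,
                                     marker_meanlog = log(50), marker_sdlog = 0.3,
                                     seed = NULL) {
  phase_mode <- match.arg(phase_mode)
  pf <- as.numeric(phase_fractions)
  stopifnot(length(pf) == 3, all(pf >= 0), abs(sum(pf) - 1) < 1e-8, n >= 1)
  with_seed_(seed, {
    phases <- if (phase_mode == "quota") {
      counts <- floor(pf * n)
      rem <- n - sum(counts)
      if (rem > 0) {
        extra <- order(pf * n - counts, decreasing = TRUE)[seq_len(rem)]
        counts[extra] <- counts[extra] + 1L
      }
      sample(rep(c("G1", "S", "G2M"), counts))
    } else {
      sample(c("G1", "S", "G2M"), n, replace = TRUE, prob = pf)
    }
    dapi <- vapply(phases, function(ph) {
      switch(ph,
             G1 = dapi_2n_mean * exp(rnorm(1, 0, dapi_cv)),
             S = runif(1, dapi_2n_mean * 1.15, dapi_4n_mean * 0.85),
             G2M = dapi_4n_mean * exp(rnorm(1, 0, dapi_cv)))
    }, numeric(1))
    edu <- ifelse(phases == "S",
                  edu_level * exp(rnorm(n, 0, 0.15)),
                  exp(rnorm(n, 0, edu_noise_sd))) # dim autofluorescence floor
    tibble::tibble(
      label = seq_len(n),
      area = round(runif(n, 250, 500)),
      dapi_integrated = dapi,
      edu_mean = edu,
      marker_mean = rlnorm(n, marker_meanlog, marker_sdlog),
      touches_border = FALSE,
      phase = phases
    )
  })
}
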