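#' Gate configuration
#'
#' Reproducible replacements for manual polygon gates: the intact-cell
#' gate keeps the highest-density `intact_quantile` of events in
#' (log FSC-A, log SSC-A); the singlet gate keeps events within
#' `singlet_mad` MADs of a robust linear fit of FSC-H on FSC-A; the live
#' gate excludes 7-AAD-bright events; reporter positivity thresholds
#' default to the 100 a.u. convention and are normally derived from
#' control tables via [threshold_from_control()].
#'
#' @param intact_quantile fraction of highest-density events kept by the
#'   intact gate.
#' @param intact_min_fsc absolute FSC-A floor of the intact gate (a.u.);
#'   sub-cellular debris scatter falls below it regardless of density.
#' @param singlet_mad residual band half-width of the singlet gate, in
#'   MADs.
#' @param live_threshold 7-AAD-A value above which events are dead.
#' @param transfection_threshold,mclover_threshold,irfp670_threshold
#'   reporter positivity thresholds (a.u.).
#' @return a `gate_config` list.
#' @export
gate_config <- function(intact_quantile = 0.90, singlet_mad = 3,
                        intact_min_fsc = 20000,
                        live_threshold = 1000,
                        transfection_threshold = 100,
                        mclover_threshold = 100,
                        irfp670_threshold = 100) {
  stopifnot(intact_quantile > 0, intact_quantile <= 1, singlet_mad > 0,
            intact_min_fsc > 0,
            live_threshold > 0, transfection_threshold > 0,
            mclover_threshold > 0, irfp670_threshold > 0)
  structure(list(intact_quantile = intact_quantile, singlet_mad = singlet_mad,
                 intact_min_fsc = intact_min_fsc,
                 live_threshold = live_threshold,
                 transfection_threshold = transfection_threshold,
                 mclover_threshold = mclover_threshold,
                 irfp670_threshold = irfp670_threshold),
            class = "gate_config")
}

#' Positivity threshold from a negative-control table
#'
#' The conventional control-derived threshold: the maximum of the
#' channel in the negative control.
#'
#' @param control event data frame.
#' @param channel channel name.
#' @return scalar threshold.
#' @export
threshold_from_control <- function(control, channel) {
  stopifnot(is.data.frame(control), channel %in% names(control))
  max(control[[channel]])
}

#' Run a sequential gating chain
#'
#' Labels every event with pass/fail per gate: intact (FSC-A vs SSC-A
#' density gate), singlet (FSC-A vs FSC-H residual band) and — for the
#' sorting assay — live (7-AAD). Gates are nested: `in_analysis` is the
#' conjunction, so populations only shrink along the chain.
#'
#' @param events event data frame; required channels: `FSC_A`, `FSC_H`,
#'   `SSC_A`, plus `AAD7_A` for `assay = "idaa"`.
#' @param cfg a [gate_config()].
#' @param assay `"mclover"` (HDR readout; no viability dye) or `"idaa"`
#'   (sort; includes the 7-AAD live gate).
#' @return `events` with logical columns `gate_intact`, `gate_singlet`,
#'   (`gate_live`,) `in_analysis`. Warns if the final population is
#'   empty.
#' @export
gate_chain <- function(events, cfg = gate_config(), assay = c("mclover", "idaa")) {
  assay <- match.arg(assay)
  stopifnot(is.data.frame(events), nrow(events) >= 1)
  need <- c("FSC_A", "FSC_H", "SSC_A", if (assay == "idaa") "AAD7_A")
  missing <- setdiff(need, names(events))
  if (length(missing) > 0) {
    abort(paste("missing required channel(s):", paste(missing, collapse = ", ")))
  }

  # intact: an absolute cell-scale scatter floor plus a robust elliptical
  # density gate around the main (log FSC-A, log SSC-A) mode: events are
  # ranked by a median/MAD-standardized squared distance and the top
  # intact_quantile kept (deterministic)
  lx <- log10(pmax(events$FSC_A, 1)); ly <- log10(pmax(events$SSC_A, 1))
  std2 <- function(v) { # constant dimensions contribute nothing
    s <- mad(v)
    if (s == 0) rep(0, length(v)) else ((v - median(v)) / s)^2
  }
  d2 <- std2(lx) + std2(ly)
  gate_intact <- d2 <= quantile(d2, cfg$intact_quantile, names = FALSE) &
    events$FSC_A >= cfg$intact_min_fsc

  # singlet: robust fit of FSC_H on FSC_A among intact events
  if (sum(gate_intact) >= 3) {
    fit <- MASS::rlm(FSC_H ~ FSC_A, data = events[gate_intact, , drop = FALSE],
                     maxit = 50)
    resid_all <- events$FSC_H - stats::predict(fit, events)
    band <- cfg$singlet_mad * mad(resid_all[gate_intact])
    gate_singlet <- abs(resid_all) <= band
  } else {
    gate_singlet <- rep(FALSE, nrow(events))
  }

  out <- dplyr::mutate(events, gate_intact = gate_intact,
                       gate_singlet = gate_singlet)
  if (assay == "idaa") {
    out <- dplyr::mutate(out, gate_live = .data$AAD7_A <= cfg$live_threshold,
                         in_analysis = gate_intact & gate_singlet & .data$gate_live)
  } else {
    out <- dplyr::mutate(out, in_analysis = gate_intact & gate_singlet)
  }
  if (!any(out$in_analysis)) warn("empty analysis population after gating")
  out
}

#' Transfection efficiency
#'
#' Percentage of the analysis population whose reporter channel exceeds
#' the positivity threshold (derived from a negative control by default).
#'
#' @param gated output of [gate_chain()].
#' @param channel reporter channel, default `"GFP_A"`.
#' @param threshold explicit threshold (a.u.); if `NULL`, derived from
#'   `negative_control` via [threshold_from_control()].
#' @param negative_control negative-control event table.
#' @return one-row tibble: `n_analysis`, `n_positive`, `efficiency` (%).
#' @export
transfection_efficiency <- function(gated, channel = "GFP_A", threshold = NULL,
                                    negative_control = NULL) {
  stopifnot(is.data.frame(gated), "in_analysis" %in% names(gated),
            channel %in% names(gated))
  if (is.null(threshold)) {
    if (is.null(negative_control)) abort("supply `threshold` or `negative_control`")
    threshold <- threshold_from_control(negative_control, channel)
  }
  pop <- gated[gated$in_analysis, , drop = FALSE]
  if (nrow(pop) == 0) abort("empty analysis population")
  tibble::tibble(n_analysis = nrow(pop),
                 n_positive = sum(pop[[channel]] > threshold),
                 efficiency = 100 * sum(pop[[channel]] > threshold) / nrow(pop))
}

#' HDR efficiency readout
#'
#' The proportion of mClover-positive cells among the iRFP670-positive
#' (transfected) analysis population.
#'
#' @param gated output of [gate_chain()].
#' @param cfg a [gate_config()] carrying the reporter thresholds.
#' @return one-row tibble: `n_transfected`, `n_hdr`, `hdr_percent`
#'   (NA with `defined = FALSE` when no transfected events).
#' @export
hdr_percent <- function(gated, cfg = gate_config()) {
  stopifnot(is.data.frame(gated), "in_analysis" %in% names(gated),
            all(c("mClover_A", "iRFP670_A") %in% names(gated)))
  pop <- gated[gated$in_analysis, , drop = FALSE]
  transfected <- pop$iRFP670_A > cfg$irfp670_threshold
  n_tf <- sum(transfected)
  n_hdr <- sum(transfected & pop$mClover_A > cfg$mclover_threshold)
  if (n_tf == 0) {
    warn("no transfected events; HDR percentage is undefined")
    return(tibble::tibble(n_transfected = 0L, n_hdr = 0L,
                          hdr_percent = NA_real_, defined = FALSE))
  }
  tibble::tibble(n_transfected = n_tf, n_hdr = n_hdr,
                 hdr_percent = 100 * n_hdr / n_tf, defined = TRUE)
}
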