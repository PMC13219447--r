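#' Simulate a flow-cytometry event table with ground truth
#'
#' Draws events from log-normal populations for each gate label. The
#' hierarchy mirrors the analysis chain: a `debris` fraction (low
#' scatter), a `doublet` fraction among non-debris (low FSC-H/FSC-A
#' ratio), a `dead` fraction among intact singlets (bright 7-AAD), a
#' `transfected` fraction among clean live events, and an `hdr` fraction
#' among transfected events (mClover-positive). Channels not meaningful
#' for a label (e.g. reporter channels of untransfected cells) are drawn
#' from a dim negative population.
#'
#' @param n_events number of events (>= 1).
#' @param fractions named fractions:
#'   `c(debris =, doublet =, dead =, transfected =, hdr =)`, each the
#'   conditional fraction described above, all in `[0, 1]`.
#' @param assay `"mclover"` (iRFP670 transfection marker, mClover HDR
#'   reporter) or `"idaa"` (GFP transfection marker, 7-AAD viability).
#' @param mode `"multinomial"` samples labels independently;
#'   `"quota"` assigns exact largest-remainder counts at every split.
#' @param negative_control if `TRUE`, no event is transfected and all
#'   reporter values are drawn from the dim negative population (for
#'   threshold derivation).
#' @param pop overrides for population parameters; see Details.
#' @param seed integer seed.
#'
#' @details Population parameters (log-normal `meanlog`/`sdlog`, a.u.)
#' default to well-separated populations: intact scatter around 5e4,
#' debris around 6e3; singlet FSC-H/FSC-A ratio 0.75 with 3% spread,
#' doublets 0.45; live 7-AAD around 60, dead around 8e3; reporter
#' negatives around 15 (below the 100 a.u. positivity threshold),
#' positives around 5e3.
#'
#' @return object of class `flow_sim`: list with `events` (tibble of
#'   channels `FSC_A`, `FSC_H`, `SSC_A`, `AAD7_A`, `GFP_A`, `mClover_A`,
#'   `iRFP670_A`), `truth` (tibble of logical `is_debris`, `is_doublet`,
#'   `is_dead`, `is_transfected`, `is_hdr`) and `params`.
#' @export
#' @examples
#' sim <- simulate_flow_events(5000, seed = 1)
#' dplyr::count(sim$truth, is_transfected, is_hdr)
simulate_flow_events <- function(n_events = 20000,
                                 fractions = c(debris = 0.10, doublet = 0.05,
                                               dead = 0.05, transfected = 0.40,
                                               hdr = 0.05),
                                 assay = c("mclover", "idaa"),
                                 mode = c("multinomial", "quota"),
                                 negative_control = FALSE,
                                 pop = list(), seed = NULL) {
  assay <- match.arg(assay)
  mode <- match.arg(mode)
  if (n_events < 1) abort("`n_events` must be >= 1")
  fr <- fractions
  stopifnot(all(c("debris", "doublet", "dead", "transfected", "hdr") %in% names(fr)))
  for (nm in names(fr)) assert_scalar_prob(fr[[nm]], nm)

  p <- utils::modifyList(list(
    fsc_intact = c(log(5e4), 0.15), ssc_intact = c(log(3e4), 0.20),
    fsc_debris = c(log(6e3), 0.40), ssc_debris = c(log(4e3), 0.45),
    hratio_singlet = c(0.75, 0.03), hratio_doublet = c(0.45, 0.05),
    aad_live = c(log(60), 0.5), aad_dead = c(log(8e3), 0.30),
    rep_neg = c(log(15), 0.6), rep_pos = c(log(5e3), 0.5)
  ), pop)

  draw_split <- function(n, frac) { # TRUE with probability/quota frac
    if (mode == "quota") {
      k <- round(frac * n)
      sample(c(rep(TRUE, k), rep(FALSE, n - k)))
    } else {
      runif(n) < frac
    }
  }

  with_seed_(seed, {
    n <- n_events
    is_debris <- draw_split(n, fr[["debris"]])
    is_doublet <- !is_debris & draw_split(n, fr[["doublet"]]) # conditional on non-debris
    clean <- !is_debris & !is_doublet
    is_dead <- clean & draw_split(n, fr[["dead"]])
    eligible <- clean & !is_dead
    tf_frac <- if (negative_control) 0 else fr[["transfected"]]
    is_transfected <- eligible & draw_split(n, tf_frac)
    is_hdr <- is_transfected & draw_split(n, fr[["hdr"]])

    ln <- function(par, k) rlnorm(k, par[1], par[2])
    # reporter values of true negatives stay strictly below the 100 a.u.
    # positivity threshold (inverse-CDF truncated log-normal), so labels
    # and control-derived thresholds are consistent
    ln_neg <- function(par, k) {
      cap <- stats::plnorm(100, par[1], par[2])
      stats::qlnorm(runif(k, 0, cap * (1 - 1e-12)), par[1], par[2])
    }
    FSC_A <- ifelse(is_debris, ln(p$fsc_debris, n), ln(p$fsc_intact, n))
    SSC_A <- ifelse(is_debris, ln(p$ssc_debris, n), ln(p$ssc_intact, n))
    ratio <- ifelse(is_doublet,
                    rnorm(n, p$hratio_doublet[1], p$hratio_doublet[2]),
                    rnorm(n, p$hratio_singlet[1], p$hratio_singlet[2]))
    FSC_H <- pmax(FSC_A * ratio, 1)
    AAD7_A <- ifelse(is_dead, ln(p$aad_dead, n), ln(p$aad_live, n))
    pos <- function(flag) ifelse(flag, ln(p$rep_pos, n), ln_neg(p$rep_neg, n))
    GFP_A <- if (assay == "idaa") pos(is_transfected) else ln_neg(p$rep_neg, n)
    iRFP670_A <- if (assay == "mclover") pos(is_transfected) else ln_neg(p$rep_neg, n)
    mClover_A <- pos(is_hdr)

    structure(list(
      events = tibble::tibble(FSC_A = FSC_A, FSC_H = FSC_H, SSC_A = SSC_A,
                              AAD7_A = AAD7_A, GFP_A = GFP_A,
                              mClover_A = mClover_A, iRFP670_A = iRFP670_A),
      truth = tibble::tibble(is_debris = is_debris, is_doublet = is_doublet,
                             is_dead = is_dead, is_transfected = is_transfected,
                             is_hdr = is_hdr),
      params = list(fractions = fr, assay = assay, mode = mode,
                    negative_control = negative_control, seed = seed)
    ), class = "flow_sim")
  })
}
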