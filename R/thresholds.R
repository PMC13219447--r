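# Global histogram thresholds used across the imaging pipeline.
#
# All operate on a fixed-width histogram of the raw intensities; thresholds
# are returned on the intensity scale (upper edge of the selected bin), so
# `x > threshold` selects the upper class.

hist_counts_ <- function(x, levels = 256L, range = NULL) {
  x <- x[is.finite(x)]
  if (length(x) == 0) abort("no finite values to threshold")
  rng <- range %||% range(x)
  if (rng[1] == rng[2]) rng[2] <- rng[1] + 1 # degenerate: single bin occupied
  edges <- seq(rng[1], rng[2], length.out = levels + 1L)
  idx <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), levels)
  counts <- tabulate(idx, nbins = levels)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  list(counts = counts, mids = mids, edges = edges)
}

#' Two-class Otsu threshold
#'
#' Classic between-class-variance-maximizing global threshold on a
#' fixed-width histogram.
#'
#' @param x numeric vector, matrix or image of intensities.
#' @param levels number of histogram bins.
#' @return scalar threshold on the intensity scale; pixels `> threshold`
#'   belong to the upper (signal) class.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  h <- hist_counts_(as.numeric(x), levels)
  p <- h$counts / sum(h$counts)
  w <- cumsum(p)
  mu <- cumsum(p * h$mids)
  mu_t <- mu[length(mu)]
  denom <- w * (1 - w)
  sigma_b <- ifelse(denom > 0, (mu_t * w - mu)^2 / denom, 0)
  k <- which.max(head(sigma_b, -1)) # last bin cannot be a cut
  h$edges[k + 1L]
}

#' Three-class Otsu thresholds
#'
#' Exhaustive search over all ordered threshold pairs minimizing the
#' weighted within-class variance of the three classes. Used for focus
#' detection where only the top intensity class is foreground and the
#' middle class is assigned to background.
#'
#' @inheritParams otsu_threshold
#' @return named numeric `c(low = , high = )` on the intensity scale;
#'   focus pixels are those `> high`.
#' @export
otsu3_thresholds <- function(x, levels = 256L) {
  h <- hist_counts_(as.numeric(x), levels)
  n <- length(h$counts)
  cs0 <- cumsum(h$counts)
  cs1 <- cumsum(h$counts * h$mids)
  cs2 <- cumsum(h$counts * h$mids^2)
  # class sums between cut indices i < j (class: bins (a, b])
  ssw_class <- function(a, b) { # vectors of same length (recycled)
    w <- cs0[b] - ifelse(a > 0, cs0[pmax(a, 1)], 0)
    s <- cs1[b] - ifelse(a > 0, cs1[pmax(a, 1)], 0)
    q <- cs2[b] - ifelse(a > 0, cs2[pmax(a, 1)], 0)
    out <- q - ifelse(w > 0, s^2 / pmax(w, 1), 0)
    ifelse(w > 0, out, 0)
  }
  i <- rep(seq_len(n - 2L), times = n - 2L)            # first cut
  j <- rep(2:(n - 1L), each = n - 2L)                  # second cut
  keep <- i < j
  i <- i[keep]; j <- j[keep]
  ssw <- ssw_class(rep(0L, length(i)), i) + ssw_class(i, j) + ssw_class(j, rep(n, length(i)))
  best <- which.min(ssw)
  c(low = h$edges[i[best] + 1L], high = h$edges[j[best] + 1L])
}

#' Minimum cross-entropy (Li) threshold
#'
#' Global threshold minimizing the cross-entropy between the image and its
#' two-level reconstruction; the default foreground/background split for
#' nucleus segmentation.
#'
#' @inheritParams otsu_threshold
#' @return scalar threshold on the intensity scale.
#' @export
li_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  shift <- min(x[is.finite(x)])
  h <- hist_counts_(x - shift, levels) # work on non-negative support
  mids <- h$mids + 1e-9
  cs0 <- cumsum(h$counts)
  cs1 <- cumsum(h$counts * mids)
  n <- length(h$counts)
  tot0 <- cs0[n]; tot1 <- cs1[n]
  k <- seq_len(n - 1L)
  w1 <- cs0[k]; s1 <- cs1[k]
  w2 <- tot0 - w1; s2 <- tot1 - s1
  m1 <- ifelse(w1 > 0, s1 / w1, NA_real_)
  m2 <- ifelse(w2 > 0, s2 / w2, NA_real_)
  # Li's criterion: minimize -sum_x x log mu_class(x)  (up to constants)
  eta <- -(s1 * log(ifelse(m1 > 0, m1, NA_real_)) +
             s2 * log(ifelse(m2 > 0, m2, NA_real_)))
  if (all(!is.finite(eta))) return(shift + h$edges[2])
  best <- which.min(eta)
  shift + h$edges[best + 1L]
}

#' Maximum-entropy (Kapur) threshold
#'
#' Global threshold maximizing the sum of the Shannon entropies of the two
#' class histograms; used to freeze the wound/monolayer split from the
#' 0-h local-entropy texture map.
#'
#' @inheritParams otsu_threshold
#' @return scalar threshold on the intensity scale.
#' @export
kapur_threshold <- function(x, levels = 256L) {
  h <- hist_counts_(as.numeric(x), levels)
  p <- h$counts / sum(h$counts)
  P <- cumsum(p)
  plogp <- ifelse(p > 0, p * log(p), 0)
  S <- cumsum(plogp)
  n <- length(p)
  k <- seq_len(n - 1L)
  w1 <- P[k]; w2 <- 1 - w1
  H1 <- ifelse(w1 > 0, log(w1) - S[k] / w1, -Inf)
  H2 <- ifelse(w2 > 0, log(w2) - (S[n] - S[k]) / w2, -Inf)
  tot <- H1 + H2
  tot[!is.finite(tot)] <- -Inf
  best <- which.max(tot)
  h$edges[best + 1L]
}

# Connected-component labeling. EBImage::bwlabel gives 4-connectivity;
# 8-connectivity is obtained by merging label pairs that touch diagonally.
label_components <- function(mask, connectivity = c(8, 4)) {
  connectivity <- match.arg(as.character(connectivity[1]), c("8", "4"))
  lab <- EBImage::bwlabel(mask != 0)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  if (connectivity == "4" || max(lab) == 0L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])), # down-right diag
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))  # up-right diag
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  nlab <- max(lab)
  parent <- seq_len(nlab)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[out > 0] <- relab[out[out > 0]]
  out
}

# Local Shannon entropy (bits) of the quantized image in a square window.
# `range` fixes the quantization interval (e.g. frozen from a reference
# frame of a time series); defaults to the image's own range.
local_entropy <- function(img, window = 9L, levels = 16L, range = NULL) {
  stopifnot(window %% 2 == 1)
  rng <- range %||% base::range(img)
  if (rng[1] == rng[2]) return(matrix(0, nrow(img), ncol(img)))
  q <- pmin(pmax(findInterval(img, seq(rng[1], rng[2], length.out = levels + 1L),
                              rightmost.closed = TRUE), 1L), levels)
  q <- matrix(q, nrow(img))
  box <- matrix(1, window, window)
  tot <- window^2
  ent <- matrix(0, nrow(img), ncol(img))
  for (lev in seq_len(levels)) {
    ind <- matrix(as.numeric(q == lev), nrow(img))
    cnt <- EBImage::filter2(ind, box, boundary = "replicate")
    cnt <- pmin(pmax(cnt, 0), tot) # FFT round-off
    p <- cnt / tot
    ent <- ent - ifelse(p > 0, p * log2(p), 0)
  }
  ent
}
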