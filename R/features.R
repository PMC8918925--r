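#' Canonical feature names
#'
#' The fourteen beat-to-beat features, in the package's canonical order:
#' mean, standard deviation and RMSSD of the RR and relative-RR series,
#' deceleration capacity (DC) and deceleration reserve (DR) of the RR
#' series, and Shannon, sample and spectral entropy of both series.
#' Acceleration capacity (`ac`) is carried as an auxiliary column (it is
#' needed to form DR) but is not one of the fourteen.
#'
#' @return Character vector of the 14 feature names.
#' @export
hrv_feature_names <- function() {
  c("mean_rr", "mean_relrr", "sd_rr", "sd_relrr",
    "rmssd_rr", "rmssd_relrr", "dc", "dr",
    "shanen_rr", "shanen_relrr", "sampen_rr", "sampen_relrr",
    "specen_rr", "specen_relrr")
}

#' Feature-extraction configuration
#'
#' @param relrr_mode Relative-RR convention, `"ratio"` or `"symmetric"`
#'   (see [to_relative()]).
#' @param shannon_bins Number of equal-width histogram bins for Shannon
#'   entropy (default 16).
#' @param sampen_m Sample-entropy template length (default 2).
#' @param sampen_r_factor Sample-entropy tolerance as a multiple of the
#'   segment's own standard deviation (default 0.2).
#' @param prsa_L PRSA anchor half-window in beats (default 2, the minimum
#'   needed to form the capacity quadruple).
#' @param prsa_anchor_limit Anchors with a beat-to-beat change larger than
#'   this fraction are treated as artifacts and excluded (default 0.20).
#' @param specen_method `"periodogram"` (default) or `"welch"`.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(relrr_mode = "ratio", shannon_bins = 16,
                           sampen_m = 2, sampen_r_factor = 0.2,
                           prsa_L = 2, prsa_anchor_limit = 0.20,
                           specen_method = c("periodogram", "welch")) {
  structure(list(relrr_mode = relrr_mode, shannon_bins = shannon_bins,
                 sampen_m = sampen_m, sampen_r_factor = sampen_r_factor,
                 prsa_L = prsa_L, prsa_anchor_limit = prsa_anchor_limit,
                 specen_method = match.arg(specen_method)),
            class = "feature_config")
}

#' Time-domain statistics of a series
#'
#' @param x Numeric vector (RR in ms or relative RR in percent).
#' @return Named list `mean`, `sd` (denominator n-1) and `rmssd` (root
#'   mean square of successive differences); all `NA` if fewer than
#'   2 values.
#' @export
time_domain <- function(x) {
  if (length(x) < 2)
    return(list(mean = NA_real_, sd = NA_real_, rmssd = NA_real_))
  list(mean = mean(x), sd = stats::sd(x),
       rmssd = sqrt(mean(diff(x)^2)))
}

#' Phase-rectified signal averaging capacity
#'
#' Anchor-based averaging separating decelerating from accelerating
#' heart-rate excursions.  Deceleration anchors are beats longer than
#' their predecessor (`rr[i] > rr[i-1]`), acceleration anchors shorter.
#' Anchors whose beat-to-beat change exceeds `anchor_limit` (as a
#' fraction) are excluded as artifacts, as are anchors too close to the
#' series edge to supply the `-L .. L-1` beat window.  The capacity is
#' the PRSA quadruple `(X(0) + X(1) - X(-1) - X(-2)) / 4`, where `X(k)`
#' is the mean of `rr[i + k]` over anchors `i`.
#'
#' @param rr Numeric vector of RR intervals (ms).
#' @param direction `"decel"` or `"accel"`.
#' @param L Anchor window half-width in beats.
#' @param anchor_limit Maximum fractional beat-to-beat change at an anchor.
#' @return Capacity in ms (positive for deceleration, typically negative
#'   for acceleration), or `NA` if there is no valid anchor.
#' @export
prsa_capacity <- function(rr, direction = c("decel", "accel"),
                          L = 2, anchor_limit = 0.20) {
  direction <- match.arg(direction)
  n <- length(rr)
  if (n < 2 * L + 2) return(NA_real_)
  i <- 2:n
  anchor <- if (direction == "decel") rr[i] > rr[i - 1] else rr[i] < rr[i - 1]
  anchor <- anchor & abs(rr[i] / rr[i - 1] - 1) <= anchor_limit
  idx <- i[anchor]
  idx <- idx[idx - L >= 1 & idx + L - 1 <= n]
  if (length(idx) == 0) return(NA_real_)
  X <- function(k) mean(rr[idx + k])
  (X(0) + X(1) - X(-1) - X(-2)) / 4
}

#' Deceleration reserve
#'
#' The sum of deceleration and acceleration capacity.  AC is negative by
#' construction, so DR measures the asymmetry between slow decelerating
#' and fast accelerating heart-rate trends: a time-symmetric series has
#' DR = 0.
#'
#' @inheritParams prsa_capacity
#' @return DR in ms, `NA` if either capacity is undefined.
#' @export
deceleration_reserve <- function(rr, L = 2, anchor_limit = 0.20) {
  dc <- prsa_capacity(rr, "decel", L, anchor_limit)
  ac <- prsa_capacity(rr, "accel", L, anchor_limit)
  if (is.na(dc) || is.na(ac)) return(NA_real_)
  dc + ac
}

#' Shannon entropy of a series
#'
#' Histogram entropy with `n_bins` equal-width bins spanning the series'
#' own min-max range (hence scale-free), in bits.  A constant series has
#' entropy 0 by convention.
#'
#' @param x Numeric vector.
#' @param n_bins Number of bins (default 16).
#' @return Entropy in bits, `NA` if fewer than 2 values.
#' @export
shannon_entropy <- function(x, n_bins = 16) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(0)
  bin <- pmin(floor((x - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  p <- tabulate(bin, n_bins) / n
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Sample entropy of a series
#'
#' Negative log conditional probability that runs similar for `m` points
#' remain similar for `m + 1`, with Chebyshev tolerance
#' `r = r_factor * sd(x)` and self-matches excluded.
#'
#' @param x Numeric vector.
#' @param m Template length (default 2).
#' @param r_factor Tolerance as a multiple of `sd(x)`; ignored when `r`
#'   is given directly.
#' @param r Absolute tolerance (optional override).
#' @return Sample entropy in nats; `NA` when the series is too short or
#'   no template pair matches at either length.
#' @export
sample_entropy <- function(x, m = 2, r_factor = 0.2, r = NULL) {
  if (length(x) < m + 2) return(NA_real_)
  if (is.null(r)) r <- r_factor * stats::sd(x)
  sampen_cpp(as.numeric(x), as.integer(m), as.numeric(r))
}

#' Spectral entropy of a series
#'
#' Shannon entropy of the normalised periodogram of the mean-subtracted
#' series, treated as evenly spaced over beat index, normalised by
#' `log2 K` to \[0, 1\]: 0 for a single spectral line, 1 for a flat
#' (white) spectrum.  The `K = floor(n/2)` positive-frequency bins
#' (including Nyquist for even `n`) are used.
#'
#' @param x Numeric vector, length at least 8.
#' @param method `"periodogram"` (default) or `"welch"` (averaged
#'   modified periodograms over 50%-overlapping Hann-windowed halves).
#' @return Spectral entropy in \[0, 1\]; `NA` if too short or if the
#'   series is constant (zero power).
#' @export
spectral_entropy <- function(x, method = c("periodogram", "welch")) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 8) return(NA_real_)
  x <- x - mean(x)
  if (all(x == 0)) return(NA_real_)
  if (method == "periodogram") {
    P <- Mod(stats::fft(x))^2
    K <- n %/% 2
    p <- P[2:(K + 1)]
  } else {
    half <- n %/% 2
    step <- half %/% 2
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(half) / (half + 1))
    starts <- seq(1, n - half + 1, by = max(step, 1))
    P <- 0
    for (s in starts) P <- P + Mod(stats::fft((x[s:(s + half - 1)]) * w))^2
    K <- half %/% 2
    p <- P[2:(K + 1)]
  }
  tot <- sum(p)
  if (tot <= 0) return(NA_real_)
  p <- p / tot
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(K)
}

#' Extract the full feature vector of one segment
#'
#' Applies the time-domain statistics and the Shannon, sample and
#' spectral entropies to both the RR series and its relative-RR
#' transform, and the PRSA capacities (DC, AC) and deceleration reserve
#' to the RR series alone.  Undefined features (e.g. no valid PRSA
#' anchors) come back as `NA` and are preserved downstream.
#'
#' @param segment An `rr_segment`, `rr_series`, or bare numeric RR vector
#'   (ms).
#' @param config A [feature_config()].
#' @return Named numeric vector: the 14 features of
#'   [hrv_feature_names()] plus `ac`.
#' @export
extract_features <- function(segment, config = feature_config()) {
  rr <- if (inherits(segment, "rr_series")) segment$rr else rr_of(segment)
  relrr <- to_relative(rr, mode = config$relrr_mode)
  td_rr <- time_domain(rr)
  td_rel <- time_domain(relrr)
  dc <- prsa_capacity(rr, "decel", config$prsa_L, config$prsa_anchor_limit)
  ac <- prsa_capacity(rr, "accel", config$prsa_L, config$prsa_anchor_limit)
  c(mean_rr = td_rr$mean, mean_relrr = td_rel$mean,
    sd_rr = td_rr$sd, sd_relrr = td_rel$sd,
    rmssd_rr = td_rr$rmssd, rmssd_relrr = td_rel$rmssd,
    dc = dc,
    dr = if (is.na(dc) || is.na(ac)) NA_real_ else dc + ac,
    shanen_rr = shannon_entropy(rr, config$shannon_bins),
    shanen_relrr = shannon_entropy(relrr, config$shannon_bins),
    sampen_rr = sample_entropy(rr, config$sampen_m, config$sampen_r_factor),
    sampen_relrr = sample_entropy(relrr, config$sampen_m,
                                  config$sampen_r_factor),
    specen_rr = spectral_entropy(rr, config$specen_method),
    specen_relrr = spectral_entropy(relrr, config$specen_method),
    ac = ac)
}

#' Build the per-segment feature table for a cohort
#'
#' Segments every series, optionally restricts to a circadian window,
#' and extracts all features.  This is the modelling dataset: one row per
#' segment with full patient/label lineage for grouped splitting.
#'
#' @param cohort A list of `rr_series` (e.g. from [read_rr_table()] or
#'   [simulate_cohort()]).
#' @param duration_s Segment length in seconds (default 300).
#' @param min_beats Minimum beats per segment (default 100).
#' @param window Circadian window: `"full"`, `"day"` or `"night"`.
#' @param config A [feature_config()].
#' @return A data.frame with columns `patient_id`, `segment_idx`,
#'   `circadian_tag`, `start_clock`, `label`, the 14 features and `ac`.
#' @export
feature_table <- function(cohort, duration_s = 300, min_beats = 100,
                          window = "full", config = feature_config()) {
  rows <- lapply(cohort, function(series) {
    segs <- circadian_filter(
      segment_series(series, duration_s, min_beats), window)
    if (length(segs) == 0) return(NULL)
    feats <- t(vapply(segs, extract_features,
                      numeric(15), config = config))
    data.frame(patient_id = series$patient_id,
               segment_idx = vapply(segs, `[[`, numeric(1), "segment_idx"),
               circadian_tag = vapply(segs, `[[`, character(1),
                                      "circadian_tag"),
               start_clock = vapply(segs, `[[`, numeric(1), "start_clock"),
               label = series$label,
               feats,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
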