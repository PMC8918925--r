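# Naive reference implementations, kept deliberately independent of the
# package's code paths: explicit loops and direct-summation formulas.

oracle_relrr <- function(rr) {
  out <- numeric(length(rr) - 1)
  for (i in seq_len(length(rr) - 1)) out[i] <- 100 * rr[i + 1] / rr[i]
  out
}

oracle_time_domain <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  ss <- 0
  for (v in x) ss <- ss + (v - mu)^2
  sq <- 0
  for (i in 2:n) sq <- sq + (x[i] - x[i - 1])^2
  list(mean = mu, sd = sqrt(ss / (n - 1)), rmssd = sqrt(sq / (n - 1)))
}

oracle_prsa <- function(rr, direction, L = 2, anchor_limit = 0.20) {
  n <- length(rr)
  anchors <- integer(0)
  for (i in 2:n) {
    is_anchor <- if (direction == "decel") rr[i] > rr[i - 1]
    else rr[i] < rr[i - 1]
    if (!is_anchor) next
    if (abs(rr[i] / rr[i - 1] - 1) > anchor_limit) next
    if (i - L < 1 || i + L - 1 > n) next
    anchors <- c(anchors, i)
  }
  if (length(anchors) == 0) return(NA_real_)
  X <- function(k) {
    s <- 0
    for (i in anchors) s <- s + rr[i + k]
    s / length(anchors)
  }
  (X(0) + X(1) - X(-1) - X(-2)) / 4
}

oracle_shannon <- function(x, n_bins = 16) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(0)
  counts <- integer(n_bins)
  for (v in x) {
    b <- min(floor((v - lo) / (hi - lo) * n_bins) + 1, n_bins)
    counts[b] <- counts[b] + 1
  }
  h <- 0
  for (k in seq_len(n_bins)) {
    p <- counts[k] / length(x)
    if (p > 0) h <- h - p * log2(p)
  }
  h
}

# vectorised but structurally different template matching: full pairwise
# Chebyshev distance matrices from shifted copies
oracle_sampen <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  nt <- n - m
  if (nt < 2) return(NA_real_)
  cheb <- function(len) {
    D <- matrix(0, nt, nt)
    for (k in 0:(len - 1)) {
      xk <- x[(1:nt) + k]
      D <- pmax(D, abs(outer(xk, xk, "-")))
    }
    D
  }
  Dm <- cheb(m)
  Dm1 <- cheb(m + 1)
  B <- (sum(Dm <= r) - nt) / 2
  A <- (sum(Dm1 <= r) - nt) / 2
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# periodogram through stats::spec.pgram rather than a raw fft call
oracle_specen <- function(x) {
  n <- length(x)
  if (n < 8) return(NA_real_)
  if (sd(x) == 0) return(NA_real_)
  sp <- stats::spec.pgram(x - mean(x), taper = 0, detrend = FALSE,
                          fast = FALSE, plot = FALSE)
  p <- sp$spec
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(length(sp$spec))
}

oracle_features <- function(rr, cfg = feature_config()) {
  relrr <- oracle_relrr(rr)
  td <- oracle_time_domain(rr)
  tdr <- oracle_time_domain(relrr)
  dc <- oracle_prsa(rr, "decel", cfg$prsa_L, cfg$prsa_anchor_limit)
  ac <- oracle_prsa(rr, "accel", cfg$prsa_L, cfg$prsa_anchor_limit)
  c(mean_rr = td$mean, mean_relrr = tdr$mean,
    sd_rr = td$sd, sd_relrr = tdr$sd,
    rmssd_rr = td$rmssd, rmssd_relrr = tdr$rmssd,
    dc = dc, dr = if (is.na(dc) || is.na(ac)) NA_real_ else dc + ac,
    shanen_rr = oracle_shannon(rr, cfg$shannon_bins),
    shanen_relrr = oracle_shannon(relrr, cfg$shannon_bins),
    sampen_rr = oracle_sampen(rr, cfg$sampen_m, cfg$sampen_r_factor * sd(rr)),
    sampen_relrr = oracle_sampen(relrr, cfg$sampen_m,
                                 cfg$sampen_r_factor * sd(relrr)),
    specen_rr = oracle_specen(rr),
    specen_relrr = oracle_specen(relrr),
    ac = ac)
}

oracle_confusion <- function(pred, truth, positive = "AF-HF") {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == positive && truth[i] == positive) tp <- tp + 1
    else if (pred[i] == positive) fp <- fp + 1
    else if (truth[i] == positive) fn <- fn + 1
    else tn <- tn + 1
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       acc = 100 * (tp + tn) / length(pred),
       sens = 100 * tp / (tp + fn), spec = 100 * tn / (tn + fp),
       ppv = 100 * tp / (tp + fp))
}

# exact one-sided rank-sum p-value by full enumeration of group assignments
oracle_ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  w_obs <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  w_all <- apply(combs, 2, function(idx)
    sum(rk[idx]) - nx * (nx + 1) / 2)
  mean(w_all <= w_obs)
}

# exhaustive-coalition Shapley with interventional expectations, using
# rpart's own predict as the value function
oracle_shapley <- function(tree, x_row, background, features) {
  nf <- length(features)
  vfun <- function(S) {
    hyb <- background
    for (f in features[S]) hyb[[f]] <- x_row[[f]]
    mean(predict(tree, newdata = hyb, type = "prob")[, "AF-HF"])
  }
  phi <- setNames(numeric(nf), features)
  subsets <- lapply(0:(2^nf - 1), function(mask)
    which(bitwAnd(mask, 2^(seq_len(nf) - 1)) > 0))
  for (j in seq_len(nf)) {
    for (S in subsets) {
      if (j %in% S) next
      s <- length(S)
      w <- factorial(s) * factorial(nf - s - 1) / factorial(nf)
      phi[j] <- phi[j] + w * (vfun(c(S, j)) - vfun(S))
    }
  }
  phi
}

# --- synthetic feature datasets for selection / evaluation tests ----------

# one informative feature among noise, iid segments grouped by patient
make_feature_dataset <- function(n_per_class = 20, segs = 20, d = 2,
                                 informative = "specen_rr", seed = 1,
                                 duplicate_of = NULL, dup_r = 0.99,
                                 null = FALSE) {
  set.seed(seed)
  pats <- c(sprintf("HF%02d", seq_len(n_per_class)),
            sprintf("CT%02d", seq_len(n_per_class)))
  labs <- rep(c("AF-HF", "control"), each = n_per_class)
  n <- 2 * n_per_class * segs
  df <- data.frame(patient_id = rep(pats, each = segs),
                   label = rep(labs, each = segs),
                   segment_idx = rep(seq_len(segs), 2 * n_per_class),
                   circadian_tag = "day",
                   stringsAsFactors = FALSE)
  for (f in hrv_feature_names()) df[[f]] <- rnorm(n)
  if (!null)
    df[[informative]] <- df[[informative]] + d * (df$label == "AF-HF")
  if (!is.null(duplicate_of)) {
    # overwrite the first pure-noise feature with a noisy copy
    others <- setdiff(hrv_feature_names(), c(informative, duplicate_of))
    df[[others[1]]] <- df[[duplicate_of]] +
      rnorm(n, 0, sqrt(stats::var(df[[duplicate_of]]) * (1 / dup_r^2 - 1)))
    attr(df, "duplicate_col") <- others[1]
  }
  df
}
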