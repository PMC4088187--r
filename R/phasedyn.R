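#' Relative phase with respect to the reference-channel mean
#'
#' Per trial and sample, subtracts the circular mean of the phases on the
#' four reference channels (FC3, FC4, CP3, CP4 by default; symmetric about
#' the midline, surrounding C3/Cz/C4) from each analysis channel's phase:
#' `Phi_i(t) = wrap(theta_i(t) - theta_R(t))`. The circular mean (atan2 of
#' summed sines and cosines) is used because arithmetic averaging of
#' wrapped angles is ill-defined at the wrap point.
#'
#' @param phases a `phase_set`.
#' @param channels channels for which relative phase is computed.
#' @param refs reference channel labels.
#' @return a `relative_phase_set`: trials x channels x samples array `phi`
#'   wrapped to `(-pi, pi]`.
#' @export
relative_phase <- function(phases, channels = analysis_channels(),
                           refs = reference_channels()) {
  stopifnot(inherits(phases, "phase_set"))
  idx <- match(channels, phases$channel_labels)
  ridx <- match(refs, phases$channel_labels)
  if (anyNA(idx) || anyNA(ridx))
    stopf("missing analysis or reference channel")
  ph <- phases$phases
  n_tr <- dim(ph)[1]; n_s <- dim(ph)[3]
  phi <- array(0, c(n_tr, length(channels), n_s))
  for (tr in seq_len(n_tr)) {
    p <- matrix(ph[tr, , ], nrow = dim(ph)[2])
    theta_r <- atan2(colSums(sin(p[ridx, , drop = FALSE])),
                     colSums(cos(p[ridx, , drop = FALSE])))
    phi[tr, , ] <- wrap_angle(sweep(p[idx, , drop = FALSE], 2, theta_r, "-"))
  }
  structure(list(phi = phi, channel_labels = channels, refs = refs,
                 sampling_rate = phases$sampling_rate,
                 time_axis = phases$time_axis, band = phases$band,
                 conditions = phases$conditions,
                 participant = phases$participant),
            class = "relative_phase_set")
}

#' Instantaneous Instability Index
#'
#' For each sample, `d_i(t) = mean_h (1 - cos(Phi_i(t) - Phi_h(t)))` over
#' the N channels and `I(t) = sum_i d_i(t)^2`. `I` is zero when all
#' channels share one relative phase and grows with cross-channel phase
#' dispersion; its fluctuations index transitions between transiently
#' stable phase patterns.
#'
#' @param rel a `relative_phase_set` (or a channels x samples matrix of
#'   relative phases for one trial).
#' @return for a matrix input, a list with `I` (samples) and `d`
#'   (channels x samples); for a `relative_phase_set`, a list of such
#'   per-trial results.
#' @export
instability_index <- function(rel) {
  one <- function(phi) {
    n <- nrow(phi)
    if (n < 2) stopf("instability index needs >= 2 channels")
    C <- cos(phi); S <- sin(phi)
    sc <- colSums(C); ss <- colSums(S)
    d <- 1 - (C * rep(sc, each = n) + S * rep(ss, each = n)) / n
    list(I = colSums(d^2), d = d)
  }
  if (is.matrix(rel)) return(one(rel))
  stopifnot(inherits(rel, "relative_phase_set"))
  lapply(seq_len(dim(rel$phi)[1]),
         function(tr) one(matrix(rel$phi[tr, , ], nrow = dim(rel$phi)[2])))
}

#' Segment an instability series into GPS episodes
#'
#' Global phase synchronization (GPS) episodes are maximal runs of samples
#' where the instability index lies strictly below a percentile threshold
#' (default: the 50th percentile, linear interpolation). The threshold may
#' be supplied so that it can be pooled over all trials of one participant
#' and condition.
#'
#' @param I numeric instability series.
#' @param percentile percentile of `I` used as threshold (ignored if
#'   `threshold` given).
#' @param threshold explicit threshold (e.g. from the pooled series).
#' @return data.frame with 1-based `start` and exclusive `end` sample
#'   indices of each episode (possibly zero rows, e.g. for a constant
#'   series, where no sample is strictly below the median).
#' @export
gps_segment <- function(I, percentile = 50, threshold = NULL) {
  if (length(I) == 0) stopf("empty instability series")
  if (is.null(threshold))
    threshold <- as.numeric(quantile(I, percentile / 100, type = 7))
  below <- I < threshold
  if (!any(below))
    return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep] + 1L)
}

#' Circular-mean phase patterns of GPS episodes
#'
#' For each episode, the per-channel circular mean of the relative phase
#' over the episode samples:
#' `Xi_i = atan2(sum_t sin Phi_i(t), sum_t cos Phi_i(t))`. Episodes whose
#' resultant length is numerically zero on some channel (antipodal phases)
#' get 0 on that channel and are flagged.
#'
#' @param phi channels x samples matrix of relative phases (one trial).
#' @param episodes data.frame from [gps_segment()].
#' @return episodes x channels matrix of wrapped mean phases, with logical
#'   attribute `low_resultant` (one flag per episode).
#' @export
gps_patterns <- function(phi, episodes) {
  stopifnot(is.matrix(phi))
  if (nrow(episodes) == 0)
    return(structure(matrix(0, 0, nrow(phi)), low_resultant = logical(0)))
  if (any(episodes$start < 1 | episodes$end > ncol(phi) + 1 |
          episodes$end <= episodes$start))
    stopf("episode outside series")
  out <- matrix(0, nrow(episodes), nrow(phi))
  low <- logical(nrow(episodes))
  for (g in seq_len(nrow(episodes))) {
    idx <- episodes$start[g]:(episodes$end[g] - 1)
    s <- rowSums(sin(phi[, idx, drop = FALSE]))
    c <- rowSums(cos(phi[, idx, drop = FALSE]))
    r <- sqrt(s^2 + c^2) / length(idx)
    xi <- wrap_angle(atan2(s, c))
    xi[r < 1e-8] <- 0
    low[g] <- any(r < 1e-8)
    out[g, ] <- xi
  }
  structure(out, low_resultant = low)
}

# (cos, sin) embedding of phase patterns for Euclidean clustering.
embed_patterns <- function(patterns) {
  cbind(cos(patterns), sin(patterns))
}

# k-means++ seeding over rows of x.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - rep(centers[1, ], each = n))^2)
  for (j in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1, ] <- x[sample(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums((x - rep(centers[j + 1, ], each = n))^2))
  }
  centers
}

#' Cluster pooled GPS patterns into K labelled microstates
#'
#' Embeds every pattern as its per-channel `(cos, sin)` pair and runs
#' K-means (k-means++ seeding, >= `nstart` restarts, best total
#' within-cluster sum of squares kept). Patterns from all participants and
#' both groups must be pooled into one call so that cluster labels are
#' shared across participants - a prerequisite for cross-participant HMM
#' classification.
#'
#' @param patterns episodes x channels matrix of pooled phase patterns.
#' @param K number of clusters (default 6).
#' @param seed RNG seed.
#' @param nstart number of k-means++ restarts.
#' @return list with `labels` (1..K per pattern), `centers` (embedded
#'   space), `tot_withinss`, and `K`.
#' @export
cluster_patterns <- function(patterns, K = 6, seed = 1, nstart = 10) {
  if (nrow(patterns) < K)
    stopf("need at least K = %d patterns (got %d)", K, nrow(patterns))
  x <- embed_patterns(patterns)
  if (nrow(unique(x)) < K) {
    # degenerate pooled set: fewer distinct patterns than clusters
    u <- unique(x)
    labels <- match(data.frame(t(x)), data.frame(t(u)))
    return(list(labels = labels, centers = u, tot_withinss = 0, K = K,
                degenerate = TRUE))
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      cen <- kmeanspp_centers(x, K)
      km <- suppressWarnings(kmeans(x, centers = cen, iter.max = 100))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    list(labels = as.integer(best$cluster), centers = best$centers,
         tot_withinss = best$tot.withinss, K = K, degenerate = FALSE)
  })
}

#' Assign phase patterns to existing clusters
#'
#' Nearest-centroid assignment in the embedded `(cos, sin)` space.
#'
#' @param model result of [cluster_patterns()].
#' @param patterns episodes x channels matrix.
#' @return integer labels in `1..K`.
#' @export
assign_patterns <- function(model, patterns) {
  x <- embed_patterns(patterns)
  d <- outer(rowSums(x^2), rowSums(model$centers^2), "+") -
    2 * x %*% t(model$centers)
  max.col(-d, ties.method = "first")
}
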