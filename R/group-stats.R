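#' Pointwise t-tests across subjects
#'
#' Two-tailed t-test at every point (e.g. every TRF lag, or every
#' (channel, lag) pair) between two subject sets: paired (on differences,
#' df = n - 1) or unpaired (Welch by default, pooled-variance optional).
#'
#' @param a,b numeric matrices, subjects x points. For `paired = TRUE`
#'   the rows must be the same subjects in the same order.
#' @param paired paired-samples test (default TRUE).
#' @param var_equal for unpaired tests, assume equal variances (pooled
#'   df) instead of Welch.
#' @return List with vectors `t`, `df`, `p` (two-tailed), one entry per
#'   point (column).
#' @export
pointwise_ttest <- function(a, b, paired = TRUE, var_equal = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("point grids must match")
  if (paired) {
    if (nrow(a) != nrow(b)) stop("paired test requires equal subject counts")
    if (nrow(a) < 3) stop("insufficient subjects: need n >= 3")
    d <- a - b
    n <- nrow(d)
    num <- colMeans(d)
    den <- apply(d, 2, sd) / sqrt(n)
    t <- num / den
    t[num == 0 & den == 0] <- 0   # identical inputs: no difference
    df <- rep(n - 1, ncol(d))
  } else {
    n1 <- nrow(a); n2 <- nrow(b)
    if (n1 < 3 || n2 < 3) stop("insufficient subjects: need n >= 3 per group")
    v1 <- apply(a, 2, stats::var); v2 <- apply(b, 2, stats::var)
    if (var_equal) {
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      t <- (colMeans(a) - colMeans(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- rep(n1 + n2 - 2, ncol(a))
    } else {
      se2 <- v1 / n1 + v2 / n2
      t <- (colMeans(a) - colMeans(b)) / sqrt(se2)
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment controlling the expected proportion of false
#' positives among significant discoveries.
#'
#' @param p_values raw p-values in \[0, 1\].
#' @param alpha FDR level for the rejection mask (default 0.05).
#' @return List with `p_adjusted` and logical `reject`.
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, reject = !is.na(adj) & adj <= alpha)
}

#' Mean TRF amplitude over a lag window
#'
#' Arithmetic mean of the TRF samples whose lag falls inside
#' `[start_ms, end_ms]`, boundary samples included. The 300-500 ms default
#' targets the N400 range.
#'
#' @param trf a `trf_cv` fit, or a numeric array whose SECOND dimension is
#'   the lag axis (feature x lag x channel).
#' @param start_ms,end_ms window edges in ms.
#' @param lag_ms lag axis (required when `trf` is a bare array).
#' @return Matrix feature x channel of window means.
#' @export
window_mean <- function(trf, start_ms = 300, end_ms = 500, lag_ms = NULL) {
  if (inherits(trf, "trf_cv")) {
    lag_ms <- trf$lag_ms
    arr <- trf$coef
  } else arr <- trf
  sel <- which(lag_ms >= start_ms & lag_ms <= end_ms)
  if (!length(sel)) stop("empty lag window")
  out <- apply(arr[, sel, , drop = FALSE], c(1, 3), mean)
  rownames(out) <- dimnames(arr)[[1]]
  out
}

# label connected components of a channels x lags logical mask;
# contiguity = adjacent lags on the same channel OR adjacent channels
# (per ch_adj) at the same lag. Returns integer label matrix (0 = none).
label_clusters <- function(mask, ch_adj) {
  mask[is.na(mask)] <- FALSE   # NaN t-values (zero-variance points) are not significant
  nc <- nrow(mask); nl <- ncol(mask)
  id <- matrix(0L, nc, nl)
  id[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(id)
  big <- sum(mask) + 1L
  repeat {
    m <- matrix(big, nc, nl)
    m[mask] <- id[mask]
    best <- m
    if (nl > 1) {
      best[, -1] <- pmin(best[, -1, drop = FALSE], m[, -nl, drop = FALSE])
      best[, -nl] <- pmin(best[, -nl, drop = FALSE], m[, -1, drop = FALSE])
    }
    for (c in seq_len(nc)) {
      nb <- which(ch_adj[c, ])
      if (length(nb)) {
        best[c, ] <- pmin(best[c, ],
                          if (length(nb) == 1) m[nb, ] else
                            do.call(pmin, asplit(m[nb, , drop = FALSE], 1)))
      }
    }
    best[!mask] <- 0L
    if (identical(best, id)) break
    id <- best
  }
  # relabel 1..K
  u <- sort(unique(id[id > 0]))
  id[id > 0] <- match(id[id > 0], u)
  id
}

cluster_sums <- function(t_map, labels) {
  if (!any(labels > 0)) return(numeric(0))
  as.numeric(tapply(t_map[labels > 0], labels[labels > 0], sum))
}

max_cluster_stat <- function(t_map, tcrit, ch_adj) {
  s_pos <- cluster_sums(t_map, label_clusters(t_map > tcrit, ch_adj))
  s_neg <- cluster_sums(t_map, label_clusters(t_map < -tcrit, ch_adj))
  max(c(abs(s_pos), abs(s_neg), 0))
}

# vectorized t statistics over flattened point grids (subjects x points)
t_vec_onesample <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  v <- (colSums(d * d) - n * m^2) / (n - 1)
  m / sqrt(v / n)
}

t_vec_welch <- function(x, g1) {
  n1 <- sum(g1); n2 <- nrow(x) - n1
  xa <- x[g1, , drop = FALSE]; xb <- x[!g1, , drop = FALSE]
  m1 <- colMeans(xa); m2 <- colMeans(xb)
  v1 <- (colSums(xa * xa) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(xb * xb) - n2 * m2^2) / (n2 - 1)
  (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
}

#' Spatio-temporal cluster-based permutation test
#'
#' Nonparametric family-wise-error control over a channels x lags grid.
#' Points whose uncorrected two-tailed p falls below `cluster_alpha` are
#' grouped into spatio-temporally contiguous clusters (adjacent lags on a
#' channel, or spatially adjacent channels at a lag); each cluster's
#' statistic is the sum of its t-values ("maxsum"), positive and negative
#' clusters formed separately. The null distribution is the maximum
#' absolute cluster statistic over random relabelings: subject-wise sign
#' flips (paired) or group-label shuffles (unpaired). Cluster p-values use
#' the add-one Monte-Carlo estimate `(1 + #null >= |observed|) /
#' (1 + n_perm)`. If the number of distinct relabelings does not exceed
#' `n_perm`, the test enumerates them exhaustively instead.
#'
#' @param a,b numeric arrays, subjects x channels x lags.
#' @param adjacency logical channels x channels spatial adjacency matrix
#'   (see [channel_adjacency()], [adjacency_from_coords()]).
#' @param n_perm number of permutations (>= 100).
#' @param cluster_alpha uncorrected threshold for cluster formation.
#' @param paired paired design (sign-flip null) or unpaired (label
#'   shuffle).
#' @param seed integer seed.
#' @return An object of class `cluster_test`: `clusters` (list of data
#'   frames with `channel`, `lag` indices), `statistic`, `p_value`,
#'   `sign`, plus the observed `t_map`, `n_perm` and `null_max`.
#' @export
cluster_permutation <- function(a, b, adjacency, n_perm = 1000,
                                cluster_alpha = 0.05, paired = FALSE,
                                seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  dima <- dim(a); dimb <- dim(b)
  if (!identical(dima[2:3], dimb[2:3])) stop("channel/lag grids must match")
  nc <- dima[2]
  if (nrow(adjacency) != nc) stop("adjacency must cover all channels")
  set.seed(seed)
  nl <- dima[3]
  if (paired) {
    if (dima[1] != dimb[1]) stop("paired design requires equal subject counts")
    n <- dima[1]
    d <- matrix(a - b, n, nc * nl)   # columns: channel fastest, then lag
    df <- n - 1
    t_obs <- matrix(t_vec_onesample(d), nc, nl)
  } else {
    x <- rbind(matrix(a, dima[1], nc * nl), matrix(b, dimb[1], nc * nl))
    g1 <- c(rep(TRUE, dima[1]), rep(FALSE, dimb[1]))
    df <- dima[1] + dimb[1] - 2   # threshold df; Welch t used pointwise
    t_obs <- matrix(t_vec_welch(x, g1), nc, nl)
  }
  tcrit <- qt(1 - cluster_alpha / 2, df)
  lab_pos <- label_clusters(t_obs > tcrit, adjacency)
  lab_neg <- label_clusters(t_obs < -tcrit, adjacency)
  obs <- c(cluster_sums(t_obs, lab_pos), cluster_sums(t_obs, lab_neg))
  signs <- c(rep(1L, max(lab_pos)), rep(-1L, max(lab_neg)))
  members <- c(
    lapply(seq_len(max(lab_pos)), function(k) {
      ij <- which(lab_pos == k, arr.ind = TRUE)
      data.frame(channel = ij[, 1], lag = ij[, 2])
    }),
    lapply(seq_len(max(lab_neg)), function(k) {
      ij <- which(lab_neg == k, arr.ind = TRUE)
      data.frame(channel = ij[, 1], lag = ij[, 2])
    }))
  # permutation null of the maximum |cluster sum|
  if (paired) {
    exhaustive <- 2^n <= n_perm
    flips <- if (exhaustive) {
      m <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
      n_perm <- nrow(m); m
    } else matrix(sample(c(1, -1), n_perm * n, replace = TRUE), n_perm)
    null_max <- vapply(seq_len(n_perm), function(i) {
      tm <- matrix(t_vec_onesample(d * flips[i, ]), nc, nl)
      max_cluster_stat(tm, tcrit, adjacency)
    }, numeric(1))
  } else {
    ntot <- length(g1); n1 <- sum(g1)
    exhaustive <- choose(ntot, n1) <= n_perm
    picks <- if (exhaustive) {
      cmb <- utils::combn(ntot, n1)
      n_perm <- ncol(cmb)
      lapply(seq_len(n_perm), function(i) cmb[, i])
    } else lapply(seq_len(n_perm), function(i) sample.int(ntot, n1))
    null_max <- vapply(picks, function(sel) {
      gp <- logical(ntot); gp[sel] <- TRUE
      tm <- matrix(t_vec_welch(x, gp), nc, nl)
      max_cluster_stat(tm, tcrit, adjacency)
    }, numeric(1))
  }
  p <- vapply(obs, function(s) (1 + sum(null_max >= abs(s))) / (1 + n_perm),
              numeric(1))
  structure(list(clusters = members, statistic = obs, p_value = p,
                 sign = signs, t_map = t_obs, tcrit = tcrit,
                 n_perm = n_perm, null_max = null_max),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d cluster(s), %d permutations\n",
              length(x$clusters), x$n_perm))
  for (i in seq_along(x$clusters)) {
    cat(sprintf("  cluster %d (%s): %d points, maxsum = %.2f, p = %.4f\n",
                i, if (x$sign[i] > 0) "+" else "-",
                nrow(x$clusters[[i]]), x$statistic[i], x$p_value[i]))
  }
  invisible(x)
}

#' Chain adjacency for synthetic channel layouts
#'
#' Channels i and i+1 are neighbors. Suitable for simulated recordings
#' without real electrode geometry.
#' @param n_channels number of channels.
#' @return Logical adjacency matrix (no self-adjacency).
#' @export
channel_adjacency <- function(n_channels) {
  adj <- matrix(FALSE, n_channels, n_channels)
  if (n_channels > 1) {
    idx <- seq_len(n_channels - 1)
    adj[cbind(idx, idx + 1)] <- TRUE
    adj[cbind(idx + 1, idx)] <- TRUE
  }
  adj
}

#' Spatial adjacency from 2-D electrode coordinates
#'
#' Two channels are neighbors when their distance is at most `scale`
#' times the median nearest-neighbor distance of the layout.
#'
#' @param xy numeric matrix, channels x 2.
#' @param scale neighborhood radius multiplier (default 1.5).
#' @return Logical adjacency matrix.
#' @export
adjacency_from_coords <- function(xy, scale = 1.5) {
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  thr <- scale * stats::median(apply(d, 1, min))
  adj <- d <= thr
  diag(adj) <- FALSE
  adj
}

#' Correlation screen with Bonferroni-corrected significance
#'
#' Pearson correlation with a two-tailed p-value, reported against a
#' Bonferroni-adjusted level `alpha / m_tests` for exploratory screens
#' over several subject-level metrics.
#'
#' @param x,y paired finite observations, n >= 4.
#' @param m_tests number of tests in the screening family.
#' @param alpha family-wise level (default 0.05).
#' @return List with `r`, `p`, `alpha_adjusted`, `significant`, `n`.
#' @export
corr_screen <- function(x, y, m_tests = 1, alpha = 0.05) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) stop("need at least 4 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("degenerate input: zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       alpha_adjusted = alpha / m_tests,
       significant = ct$p.value < alpha / m_tests, n = length(x))
}

#' One-sample t statistic from summary statistics
#'
#' `t = (m - mu0) / (s / sqrt(n))` with `n - 1` degrees of freedom;
#' recomputes a test against a chance level from printed mean/SD
#' summaries (e.g. comprehension accuracy vs. 50% chance).
#'
#' @param m sample mean.
#' @param s sample standard deviation (> 0).
#' @param n sample size (>= 2).
#' @param mu0 null-hypothesis mean.
#' @return List with `t`, `df`, `p` (two-tailed).
#' @export
one_sample_t <- function(m, s, n, mu0) {
  if (n < 2) stop("need n >= 2")
  if (s <= 0) stop("degenerate input: sd must be > 0")
  t <- (m - mu0) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}
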