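# Inferential battery: pointwise paired t tests with Benjamini-Hochberg
# FDR, directional paired t tests, default-prior (JZS) Bayes factors, exact
# binomial tests, ratio-versus-unity tests, and the paired spatiotemporal
# cluster permutation test.

#' Paired t test with explicit direction
#'
#' t on the within-pair differences x - y; the p value follows the stated
#' alternative: "upper" (mean difference > 0), "lower" (< 0) or
#' "two_tailed".
#'
#' @param x,y paired samples, length >= 3.
#' @param direction "two_tailed", "upper" or "lower".
#' @return a `stat_test_result`: list(statistic, dof, direction, p_raw,
#'   p_fdr = NA, bf01 = NA).
#' @export
paired_t <- function(x, y, direction = c("two_tailed", "upper", "lower")) {
  direction <- match.arg(direction)
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) stop("zero-variance differences: t statistic undefined")
  n <- length(d)
  t <- mean(d) / (s / sqrt(n))
  df <- n - 1
  p <- switch(direction,
              two_tailed = 2 * stats::pt(-abs(t), df),
              upper = stats::pt(t, df, lower.tail = FALSE),
              lower = stats::pt(t, df))
  structure(list(statistic = t, dof = df, direction = direction,
                 p_raw = p, p_fdr = NA_real_, bf01 = NA_real_),
            class = "stat_test_result")
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment (monotone in rank, adjusted >= raw).
#'
#' @param p_values numeric vector of raw p values in [0, 1].
#' @return adjusted p values, same order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Pointwise paired t tests with FDR correction over a lag window
#'
#' Two-tailed paired t at every lag in the window; Benjamini-Hochberg
#' adjustment across all lags in the window at level `alpha`.
#'
#' @param cond_a,cond_b subjects x lags matrices, paired by row.
#' @param lags_ms lag axis for the columns.
#' @param window_ms lag window to test (both edges included).
#' @param alpha FDR level for the significance flags.
#' @return data.frame(lag_ms, t, dof, p_raw, p_fdr, significant).
#' @export
pointwise_paired_t_fdr <- function(cond_a, cond_b, lags_ms,
                                   window_ms = range(lags_ms),
                                   alpha = 0.05) {
  stopifnot(all(dim(cond_a) == dim(cond_b)),
            ncol(cond_a) == length(lags_ms))
  if (nrow(cond_a) < 3) stop("need at least 3 subjects")
  sel <- lags_ms >= window_ms[1] - 1e-9 & lags_ms <= window_ms[2] + 1e-9
  if (!any(sel)) stop("window outside available lags")
  d <- cond_a[, sel, drop = FALSE] - cond_b[, sel, drop = FALSE]
  n <- nrow(d)
  m <- colMeans(d)
  s <- sqrt(pmax((colSums(d^2) - n * m^2) / (n - 1), 0))
  t <- ifelse(s > 0, m / (s / sqrt(n)),
              ifelse(m == 0, 0, sign(m) * Inf))  # identical lags: t = 0
  p <- 2 * stats::pt(-abs(t), n - 1)
  p_fdr <- bh_fdr(p)
  data.frame(lag_ms = lags_ms[sel], t = t, dof = n - 1, p_raw = p,
             p_fdr = p_fdr, significant = p_fdr < alpha)
}

#' JZS (default-prior) Bayes factor for a paired t test
#'
#' BF01 = m0 / m1, where m0 is the central-t density of the observed t at
#' n - 1 degrees of freedom and m1 marginalizes the noncentral-t density
#' over a Cauchy(0, `cauchy_scale`) prior on the standardized effect size
#' (noncentrality delta * sqrt(n)). For one-sided directions the Cauchy is
#' truncated to the corresponding half-line and renormalized (doubled).
#' BF01 > 1 favors the null.
#'
#' @param t observed t statistic.
#' @param n number of pairs (>= 2); dof = n - 1.
#' @param direction "two_tailed", "upper" (delta > 0) or "lower".
#' @param cauchy_scale prior scale (default 0.707, the conventional
#'   sqrt(2)/2).
#' @param rel_tol relative integration tolerance.
#' @return BF01 (numeric scalar).
#' @export
jzs_bf01 <- function(t, n, direction = c("two_tailed", "upper", "lower"),
                     cauchy_scale = 0.707, rel_tol = 1e-6) {
  direction <- match.arg(direction)
  stopifnot(n >= 2, is.finite(t))
  df <- n - 1
  m0 <- stats::dt(t, df)
  f <- function(delta) {
    # far-tail noncentral-t evaluations warn about precision where the
    # density is numerically zero; they do not affect the integral
    suppressWarnings(stats::dt(t, df, ncp = delta * sqrt(n))) *
      stats::dcauchy(delta, 0, cauchy_scale)
  }
  m1 <- tryCatch(switch(direction,
    two_tailed = stats::integrate(f, -Inf, Inf, rel.tol = rel_tol,
                                  abs.tol = 0)$value,
    upper = 2 * stats::integrate(f, 0, Inf, rel.tol = rel_tol,
                                 abs.tol = 0)$value,
    lower = 2 * stats::integrate(f, -Inf, 0, rel.tol = rel_tol,
                                 abs.tol = 0)$value),
    error = function(e) stop("Bayes factor integration failed: ",
                             conditionMessage(e)))
  m0 / m1
}

#' Exact two-sided binomial test
#'
#' Sums the probabilities of all outcomes no more likely than the observed
#' count under Binomial(n, p0).
#'
#' @param k observed successes (0 <= k <= n).
#' @param n number of trials.
#' @param p0 null success probability.
#' @return two-sided p value.
#' @export
binomial_two_sided <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, k <= n)
  stats::binom.test(k, n, p = p0, alternative = "two.sided")$p.value
}

#' One-tailed test of ratios against unity
#'
#' Tests whether paired response-size ratios exceed one: one-tailed upper t
#' of (ratios - 1), or of log(ratios) against 0 when `use_log`.
#'
#' @param ratios positive ratios, length >= 3.
#' @param use_log test log ratios against zero instead.
#' @return a `stat_test_result` (direction "upper").
#' @export
ratio_gt_one_t <- function(ratios, use_log = FALSE) {
  stopifnot(length(ratios) >= 3)
  if (any(ratios <= 0)) stop("ratios must be positive")
  x <- if (use_log) log(ratios) else ratios - 1
  s <- stats::sd(x)
  if (s == 0 && mean(x) == 0) {
    # all ratios exactly 1: t = 0 by convention is still undefined (0/0)
    stop("zero-variance ratios: t statistic undefined")
  }
  if (s == 0) stop("zero-variance ratios: t statistic undefined")
  n <- length(x)
  t <- mean(x) / (s / sqrt(n))
  structure(list(statistic = t, dof = n - 1, direction = "upper",
                 p_raw = stats::pt(t, n - 1, lower.tail = FALSE),
                 p_fdr = NA_real_, bf01 = NA_real_),
            class = "stat_test_result")
}

# Connected components over supra-threshold (channel, time) cells:
# neighbors are the same channel at adjacent times and adjacent channels at
# the same time; components are sign-consistent. Union-find over the
# (usually sparse) supra-threshold cells.
cluster_cells <- function(tmap, threshold, adjacency) {
  C <- nrow(tmap); nt <- ncol(tmap)
  supra <- abs(tmap) > threshold
  cells <- which(supra)           # linear indices, column-major (channel fast)
  if (length(cells) == 0) return(list())
  id <- match(seq_len(C * nt), cells)  # cell -> compact index or NA
  parent <- seq_along(cells)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  sgn <- sign(tmap)
  ch <- ((cells - 1L) %% C) + 1L
  tt <- ((cells - 1L) %/% C) + 1L
  for (m in seq_along(cells)) {
    c0 <- ch[m]; t0 <- tt[m]; s0 <- sgn[c0, t0]
    if (t0 > 1L) {
      j <- id[cells[m] - C]
      if (!is.na(j) && sgn[c0, t0 - 1L] == s0) union(m, j)
    }
    nb <- which(adjacency[c0, ])
    for (c1 in nb) {
      if (c1 == c0) next
      j <- id[(t0 - 1L) * C + c1]
      if (!is.na(j) && sgn[c1, t0] == s0) union(m, j)
    }
  }
  roots <- vapply(seq_along(cells), find, integer(1))
  split(cells, roots)
}

#' Paired spatiotemporal cluster permutation test
#'
#' Paired comparison of two subjects x channels x times arrays. The
#' cluster-forming threshold is the two-tailed t critical value at
#' `cluster_alpha` with n - 1 dof; supra-threshold cells form
#' sign-consistent clusters connected through channel adjacency and
#' temporal contiguity; the cluster statistic is the sum of t values. The
#' null distribution of the maximum absolute cluster mass comes from random
#' sign flips of the subject difference maps (exhaustive over all 2^n flips
#' when n <= 12, random sampling otherwise); each cluster's p value is the
#' proportion of permutations whose maximum mass is at least as large.
#'
#' @param cond_a,cond_b arrays subjects x channels x times.
#' @param adjacency symmetric logical channels x channels matrix (a channel
#'   is implicitly adjacent to itself).
#' @param n_perm number of permutations when sampling.
#' @param seed integer seed for the sampled null.
#' @param cluster_alpha threshold (and significance) level.
#' @return a `cluster_test_result`: list of clusters (cells, mass,
#'   p_cluster), the t map, the threshold, and a channels x times
#'   `significant_mask` covering clusters with p < `cluster_alpha`.
#' @export
spatiotemporal_cluster_test <- function(cond_a, cond_b, adjacency,
                                        n_perm = 10000, seed = 1,
                                        cluster_alpha = 0.05) {
  stopifnot(all(dim(cond_a) == dim(cond_b)))
  d <- dim(cond_a)
  n <- d[1]; C <- d[2]; nt <- d[3]
  if (n < 5) stop("need at least 5 subjects for a meaningful sign-flip null")
  adjacency <- as.matrix(adjacency)
  stopifnot(nrow(adjacency) == C, ncol(adjacency) == C,
            isTRUE(all.equal(adjacency, t(adjacency))))
  diff <- cond_a - cond_b
  dm <- matrix(diff, nrow = n)            # subjects x (C*T), channel fast
  ss <- colSums(dm^2)
  tmap_from_signs <- function(s) {
    m <- as.vector(s %*% dm) / n
    v <- (ss - n * m^2) / (n - 1)
    matrix(m / sqrt(v / n), C, nt)
  }
  threshold <- stats::qt(1 - cluster_alpha / 2, n - 1)
  max_mass <- function(tm) {
    cl <- cluster_cells(tm, threshold, adjacency)
    if (length(cl) == 0) 0 else max(abs(vapply(cl, function(cells) {
      sum(tm[cells])
    }, numeric(1))))
  }
  tobs <- tmap_from_signs(rep(1, n))
  obs_clusters <- cluster_cells(tobs, threshold, adjacency)
  obs_mass <- vapply(obs_clusters, function(cells) sum(tobs[cells]),
                     numeric(1))
  exhaustive <- n <= 12
  null_max <- if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    apply(signs, 1, function(s) max_mass(tmap_from_signs(s)))
  } else {
    with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        s <- sample(c(-1, 1), n, replace = TRUE)
        max_mass(tmap_from_signs(s))
      }, numeric(1))
    })
  }
  p_cluster <- vapply(obs_mass, function(m) {
    if (exhaustive) mean(null_max >= abs(m))
    else (1 + sum(null_max >= abs(m))) / (1 + length(null_max))
  }, numeric(1))
  mask <- matrix(FALSE, C, nt)
  clusters <- vector("list", length(obs_clusters))
  for (i in seq_along(obs_clusters)) {
    cells <- obs_clusters[[i]]
    clusters[[i]] <- list(
      channels = ((cells - 1L) %% C) + 1L,
      times = ((cells - 1L) %/% C) + 1L,
      mass = obs_mass[i], p_cluster = p_cluster[i])
    if (p_cluster[i] < cluster_alpha) mask[cells] <- TRUE
  }
  structure(list(clusters = clusters, t_map = tobs, threshold = threshold,
                 significant_mask = mask, n_perm = length(null_max),
                 exhaustive = exhaustive),
            class = "cluster_test_result")
}

#' Run the four-peak inferential family
#'
#' The peak-comparison battery: directional t test per comparison, BH-FDR
#' across the family, and JZS Bayes factor per comparison.
#'
#' @param comparisons named list of list(x, y, direction) entries.
#' @param cauchy_scale JZS prior scale.
#' @return data.frame(name, direction, t, dof, p_raw, p_fdr, bf01).
#' @export
peak_test_battery <- function(comparisons, cauchy_scale = 0.707) {
  res <- lapply(comparisons, function(cmp) {
    r <- paired_t(cmp$x, cmp$y, cmp$direction)
    r$bf01 <- jzs_bf01(r$statistic, r$dof + 1, cmp$direction,
                       cauchy_scale = cauchy_scale)
    r
  })
  p_fdr <- bh_fdr(vapply(res, `[[`, numeric(1), "p_raw"))
  data.frame(name = names(comparisons),
             direction = vapply(res, `[[`, character(1), "direction"),
             t = vapply(res, `[[`, numeric(1), "statistic"),
             dof = vapply(res, `[[`, numeric(1), "dof"),
             p_raw = vapply(res, `[[`, numeric(1), "p_raw"),
             p_fdr = p_fdr,
             bf01 = vapply(res, `[[`, numeric(1), "bf01"),
             row.names = NULL)
}

#' Channel adjacency helpers
#'
#' Chain (1-D montage) and grid (rows x cols) channel adjacency matrices
#' for the spatiotemporal cluster test; no montage geometry is needed for
#' synthetic fixtures.
#'
#' @param n number of channels in the chain.
#' @return symmetric logical adjacency matrix.
#' @export
chain_adjacency <- function(n) {
  abs(outer(seq_len(n), seq_len(n), "-")) <= 1
}

#' @rdname chain_adjacency
#' @param nrow,ncol grid dimensions (channels = nrow * ncol, row-major).
#' @export
grid_adjacency <- function(nrow, ncol) {
  r <- rep(seq_len(nrow), times = ncol)
  c <- rep(seq_len(ncol), each = nrow)
  (abs(outer(r, r, "-")) + abs(outer(c, c, "-"))) <= 1
}
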