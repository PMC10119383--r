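# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, window = 5L) {
  half <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Growth-curve metrics: maximum OD and time to exponential phase
#'
#' Computes the two batch observables from a blank-corrected OD600 time
#' series. The curve is smoothed on the log scale (`log(OD + eps)`, centered
#' moving window); the maximum OD is the maximum of the smoothed curve within
#' the first `t_max` hours, and the time to reach exponential phase is the
#' earliest time at which the smoothed per-capita rate `d log(OD)/dt` first
#' reaches 50% of its maximum (linear interpolation between samples). The
#' per-capita rate is scale-free, so the timing metric is invariant to uniform
#' OD scaling. Flat curves (range below `noise_floor`) are flagged as
#' no-growth and return `NA` metrics.
#'
#' @param time sampling times (h), strictly increasing.
#' @param od blank-corrected OD600 values.
#' @param t_max analysis horizon in hours (default 36).
#' @param window smoothing window in samples (default 5).
#' @param eps additive OD offset before taking logs (default 1e-3).
#' @param noise_floor minimum OD range for a curve to count as growth.
#' @return list with `max_od`, `t_exp` (h), `no_growth` (logical).
#' @export
growth_metrics <- function(time, od, t_max = 36, window = 5L, eps = 1e-3,
                           noise_floor = 0.02) {
  if (length(time) < 10) stop("growth_metrics: need at least 10 time points")
  if (is.unsorted(time, strictly = TRUE))
    stop("growth_metrics: time must be strictly increasing")
  if (any(!is.finite(od))) stop("growth_metrics: OD values must be finite")
  if (max(od) - min(od) < noise_floor)
    return(list(max_od = NA_real_, t_exp = NA_real_, no_growth = TRUE))
  slod <- moving_average(log(od + eps), window)
  keep <- time <= t_max
  max_od <- max(exp(slod[keep]) - eps)
  n <- length(time)
  rate <- rep(NA_real_, n)
  rate[2:(n - 1)] <- (slod[3:n] - slod[1:(n - 2)]) / (time[3:n] - time[1:(n - 2)])
  rate[1] <- rate[2]; rate[n] <- rate[n - 1]
  r <- rate[keep]; tt <- time[keep]
  thr <- 0.5 * max(r)
  i <- which(r >= thr)[1]
  t_exp <- if (i <= 1) tt[1] else {
    # linear interpolation of the crossing between samples i-1 and i
    tt[i - 1] + (thr - r[i - 1]) / (r[i] - r[i - 1]) * (tt[i] - tt[i - 1])
  }
  list(max_od = max_od, t_exp = t_exp, no_growth = FALSE)
}

#' Lag reduction from enzyme supplementation
#'
#' For each strain, the reduction in time to reach exponential phase caused by
#' supplementing the medium with external enzyme:
#' `mean(t_exp plain) - mean(t_exp supplemented)`, with a 95% t-interval over
#' replicate pairs. Replicates are paired by replicate id when counts match,
#' otherwise by rank order (with a warning).
#'
#' @param plain,supplemented long-format OD data frames with columns `strain`,
#'   `replicate`, `time`, `od` for the two conditions.
#' @param ... passed to [growth_metrics()].
#' @return data frame per strain: `reduction` (h), `ci_lo`, `ci_hi`,
#'   `n_pairs`.
#' @export
lag_reduction <- function(plain, supplemented, ...) {
  per_strain_te <- function(df) {
    lapply(split(df, df$strain), function(ds)
      vapply(split(ds, ds$replicate), function(dr)
        growth_metrics(dr$time, dr$od, ...)$t_exp, numeric(1)))
  }
  te_p <- per_strain_te(plain)
  te_s <- per_strain_te(supplemented)
  strains <- intersect(names(te_p), names(te_s))
  out <- lapply(strains, function(s) {
    a <- te_p[[s]]; b <- te_s[[s]]
    if (length(a) != length(b)) {
      warning(sprintf(
        "lag_reduction: unmatched replicate counts for strain %s; pairing by rank order", s))
      k <- min(length(a), length(b))
      a <- sort(a)[seq_len(k)]; b <- sort(b)[seq_len(k)]
    } else if (!identical(names(a), names(b))) {
      a <- sort(a); b <- sort(b)
    }
    d <- a - b
    # a degenerate (constant) set of pairwise differences has no t-interval
    ci <- if (length(d) < 2 || stats::sd(d) == 0) c(mean(d), mean(d)) else
      tryCatch(as.numeric(stats::t.test(d)$conf.int),
               error = function(e) c(mean(d), mean(d)))
    data.frame(strain = s, reduction = mean(d), ci_lo = ci[1], ci_hi = ci[2],
               n_pairs = length(d))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# All permutations of 1..n as an n! x n matrix (recursive construction).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Exact or asymptotic Spearman rank correlation
#'
#' Spearman's r with a two-sided p-value: exact by full permutation
#' enumeration for `n <= 9` (feasible at n! <= 362880), the t-approximation
#' above. Mid-ranks handle ties.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r`, `p`, `method`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, method = "undefined (zero variance)"))
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)
  if (n <= 9) {
    pm <- all_perms(n)
    # statistic: sum of rx[i] * ry[perm[i]] is linear in the permuted ranks
    stat <- as.numeric(matrix(ry[pm], nrow(pm)) %*% rx)
    obs <- sum(rx * ry)
    center <- mean(stat)
    p <- mean(abs(stat - center) >= abs(obs - center) - 1e-12)
    method <- "exact"
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    method <- "t-approximation"
  }
  list(r = r, p = p, method = method)
}

#' Secretion-growth correlation across strains
#'
#' Ordinary least squares of maximum OD on halo diameter (the plate-assay
#' secretion readout) across strains, plus the Spearman rank correlation.
#'
#' @param assay data frame with columns `strain`, `max_od`, `halo`.
#' @return list with `slope`, `intercept`, `R2`, `spearman_r`, `spearman_p`,
#'   `n`, and the fitted `lm` object as `fit`.
#' @export
correlate_secretion <- function(assay) {
  stopifnot(all(c("strain", "max_od", "halo") %in% names(assay)))
  if (nrow(assay) < 4) stop("correlate_secretion: need at least 4 strains")
  if (stats::sd(assay$halo) == 0 || stats::sd(assay$max_od) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, R2 = NA_real_,
                spearman_r = NA_real_, spearman_p = NA_real_,
                n = nrow(assay), fit = NULL,
                note = "correlation undefined: zero variance"))
  fit <- stats::lm(max_od ~ halo, data = assay)
  sp <- spearman_cor(assay$halo, assay$max_od)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       R2 = summary(fit)$r.squared,
       spearman_r = sp$r, spearman_p = sp$p, n = nrow(assay), fit = fit)
}
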