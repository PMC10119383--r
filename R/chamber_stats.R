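#' Remove cells with negative growth rates
#'
#' Tracked-cell tables derived from segmentation contain artefactual records
#' (mis-linked tracks, deformed non-growing cells) that show up as negative
#' growth rates; these are excluded before analysis. The visual curation used
#' on real data is replaced by this purely automatic filter.
#'
#' @param tracks a track table: data frame with at least columns `strain`,
#'   `chamber`, `cell`, `founder`, `birth` (h), `rate` (1/h), and optionally
#'   `depart` (h, `NA` when the cell never leaves).
#' @return list with `tracks` (filtered table) and `report` (data frame with
#'   per-strain `n_total`, `n_excluded`, `frac_excluded`).
#' @export
filter_tracks <- function(tracks) {
  check_track_table(tracks)
  if (!nrow(tracks)) stop("filter_tracks: track table is empty")
  bad <- tracks$rate < 0
  rep <- do.call(rbind, lapply(split(bad, tracks$strain), function(b)
    data.frame(n_total = length(b), n_excluded = sum(b),
               frac_excluded = mean(b))))
  rep <- cbind(data.frame(strain = rownames(rep)), rep)
  rownames(rep) <- NULL
  out <- tracks[!bad, , drop = FALSE]
  if (!nrow(out)) stop("filter_tracks: all rows excluded (every growth rate negative)")
  list(tracks = out, report = rep)
}

check_track_table <- function(tracks) {
  need <- c("strain", "chamber", "cell", "founder", "birth", "rate")
  miss <- setdiff(need, names(tracks))
  if (length(miss))
    stop("track table is missing columns: ", paste(miss, collapse = ", "))
  invisible(tracks)
}

#' Bin cells into birth-time intervals and count chamber occupancy
#'
#' Cells are binned into fixed-width intervals (default 2 h over a 28 h
#' experiment) by birth time, using the half-open convention `[t, t + width)`
#' (births at exactly `duration` fall in the last interval). Each bin records
#' the median growth rate of the cells *born* in it and the number of cells
#' *present* during it: born before the interval's end and resident for a
#' positive overlap with the interval (a cell that departs at its birth time
#' is never counted as present).
#'
#' @param tracks a (filtered) track table; see [filter_tracks()].
#' @param width bin width in hours (default 2).
#' @param duration experiment duration in hours (default 28).
#' @return data frame with one row per (chamber, bin): `chamber`, `t0`, `t1`,
#'   `n_born`, `median_rate` (`NA` for empty bins), `n_present`.
#' @export
bin_by_birth <- function(tracks, width = 2, duration = 28) {
  check_track_table(tracks)
  if (!("depart" %in% names(tracks))) tracks$depart <- NA_real_
  bad <- which(tracks$birth < 0 | tracks$birth > duration)
  if (length(bad))
    stop("bin_by_birth: birth times outside [0, duration] in rows: ",
         paste(utils::head(bad, 20L), collapse = ", "))
  breaks <- seq(0, duration, by = width)
  out <- lapply(split(tracks, tracks$chamber), function(tc) {
    k <- pmin(findInterval(tc$birth, breaks), length(breaks) - 1L)
    res <- lapply(seq_len(length(breaks) - 1L), function(b) {
      t0 <- breaks[b]; t1 <- breaks[b + 1L]
      born <- k == b
      present <- tc$birth < t1 &
        (is.na(tc$depart) | (tc$depart > t0 & tc$depart > tc$birth))
      data.frame(chamber = tc$chamber[1], t0 = t0, t1 = t1,
                 n_born = sum(born),
                 median_rate = if (any(born)) stats::median(tc$rate[born]) else NA_real_,
                 n_present = sum(present))
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Density-response curve: growth rate as a function of chamber occupancy
#'
#' The unimodal (rise-then-decline) relationship between growth rate and cell
#' number is modelled with a Haldane-type substrate-inhibition form in cell
#' number, `mu(N) = a N / (K_N + N + N^2 / K_I)`. The curve rises with N
#' (intercellular synergy: more neighbours means more shared breakdown
#' products), peaks at `N* = sqrt(K_N K_I)`, and declines as competition and
#' boundary losses take over. `K_I = Inf` recovers a pure Monod form in N.
#'
#' @param N cell numbers.
#' @param a,K_N,K_I curve parameters (`a` in 1/h; `K_N`, `K_I` in cells).
#' @return Growth rates (1/h).
#' @export
density_response <- function(N, a, K_N, K_I) {
  quad <- if (is.infinite(K_I)) 0 else N^2 / K_I
  a * N / (K_N + N + quad)
}

#' Smallest cell number reaching half the peak growth rate
#'
#' For the fitted [density_response()] curve, finds the smallest `N` at which
#' `mu(N)` equals half of the fitted curve's maximum, by root finding on the
#' rising limb. With `K_I = Inf` (pure Monod) this is `K_N` exactly.
#'
#' @inheritParams density_response
#' @return `N_half` (cells).
#' @export
n_half_from_fit <- function(a, K_N, K_I) {
  if (is.infinite(K_I)) return(K_N)
  n_star <- sqrt(K_N * K_I)
  peak <- density_response(n_star, a, K_N, K_I)
  f <- function(N) density_response(N, a, K_N, K_I) - peak / 2
  stats::uniroot(f, lower = 1e-12, upper = n_star, tol = 1e-10)$root
}

fit_one_density <- function(N, mu) {
  ok <- is.finite(N) & is.finite(mu) & N > 0
  N <- N[ok]; mu <- mu[ok]
  if (length(N) < 5) return(NULL)
  df <- data.frame(N = N, mu = mu)
  a0 <- max(mu) * 2
  K_N0 <- max(1, stats::median(N[mu <= max(mu) / 2], na.rm = TRUE), na.rm = TRUE)
  starts <- expand.grid(a = a0 * c(0.5, 1, 2, 5),
                        K_N = unique(pmax(1, c(K_N0 * c(0.3, 1, 3),
                                               stats::quantile(N, c(0.25, 0.5))))),
                        K_I = max(N) * c(0.5, 2, 10, 100))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::nls(mu ~ a * N / (K_N + N + N^2 / K_I), data = df,
                 start = as.list(starts[s, ]), algorithm = "port",
                 lower = c(a = 1e-8, K_N = 1e-6, K_I = 1e-6),
                 control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(NULL)
  cf <- stats::coef(best$fit)
  ss_tot <- sum((mu - mean(mu))^2)
  r2 <- if (ss_tot > 0) 1 - best$rss / ss_tot else NA_real_
  data.frame(a = cf[["a"]], K_N = cf[["K_N"]], K_I = cf[["K_I"]], R2 = r2,
             N_half = n_half_from_fit(cf[["a"]], cf[["K_N"]], cf[["K_I"]]),
             converged = TRUE)
}

#' Fit the density-response curve per chamber
#'
#' Least-squares fit of [density_response()] to (cells present, median growth
#' rate) pairs for each chamber (multi-start port-algorithm `nls`), and the
#' derived half-max cell number `N_half` per chamber. Chambers with fewer than
#' 5 non-empty bins or a non-converging fit are flagged (`converged = FALSE`)
#' and should be excluded from downstream comparisons.
#'
#' @param bins output of [bin_by_birth()] (columns `chamber`, `median_rate`,
#'   `n_present`).
#' @return data frame with one row per chamber: `chamber`, `a`, `K_N`, `K_I`,
#'   `R2`, `N_half`, `converged`.
#' @export
fit_density_response <- function(bins) {
  stopifnot(all(c("chamber", "median_rate", "n_present") %in% names(bins)))
  out <- lapply(split(bins, bins$chamber), function(bc) {
    fit <- fit_one_density(bc$n_present, bc$median_rate)
    if (is.null(fit))
      fit <- data.frame(a = NA_real_, K_N = NA_real_, K_I = NA_real_,
                        R2 = NA_real_, N_half = NA_real_, converged = FALSE)
    cbind(data.frame(chamber = bc$chamber[1]), fit)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fit logistic growth to chamber cell-count time series
#'
#' Least-squares fit of `N(t) = K_max / (1 + ((K_max - N0)/N0) exp(-k t))`
#' per chamber via the self-starting logistic. Constant (no-growth) series and
#' non-converging fits are flagged rather than fitted.
#'
#' @param counts data frame with columns `chamber`, `time` (h), `count`.
#' @return data frame per chamber: `K_max`, `k` (1/h), `N0`, `R2`, `converged`.
#' @export
fit_logistic_counts <- function(counts) {
  stopifnot(all(c("chamber", "time", "count") %in% names(counts)))
  out <- lapply(split(counts, counts$chamber), function(cc) {
    bad <- data.frame(chamber = cc$chamber[1], K_max = NA_real_, k = NA_real_,
                      N0 = NA_real_, R2 = NA_real_, converged = FALSE)
    if (nrow(cc) < 6 || stats::sd(cc$count) == 0) return(bad)
    fit <- tryCatch(
      stats::nls(count ~ SSlogis(time, Asym, xmid, scal), data = cc,
                 control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
      error = function(e) NULL)
    if (is.null(fit)) return(bad)
    cf <- stats::coef(fit)
    if (cf[["Asym"]] <= 0 || cf[["scal"]] <= 0) return(bad)
    rss <- sum(stats::resid(fit)^2)
    ss_tot <- sum((cc$count - mean(cc$count))^2)
    data.frame(chamber = cc$chamber[1],
               K_max = cf[["Asym"]], k = 1 / cf[["scal"]],
               N0 = cf[["Asym"]] / (1 + exp(cf[["xmid"]] / cf[["scal"]])),
               R2 = 1 - rss / ss_tot, converged = TRUE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Peak founder-lineage size per chamber
#'
#' The aggregation proxy: for each chamber, the maximum over founder lineages
#' of the peak number of that founder's descendants simultaneously resident in
#' the chamber. Computed by an event sweep over birth and departure times;
#' departures at a given instant are processed before births, so a cell that
#' departs at its birth time never contributes.
#'
#' @param tracks a track table with `founder` ids; see [filter_tracks()].
#' @return data frame with columns `chamber`, `max_aggregate`.
#' @export
aggregate_metric <- function(tracks) {
  check_track_table(tracks)
  if (any(is.na(tracks$founder)))
    stop("aggregate_metric: missing founder/lineage ids")
  if (!("depart" %in% names(tracks))) tracks$depart <- NA_real_
  peak_lineage <- function(birth, depart) {
    ev_t <- c(birth, depart[!is.na(depart)])
    # departures first at equal times: order by time, then by event sign
    ev_d <- c(rep(1, length(birth)), rep(-1, sum(!is.na(depart))))
    o <- order(ev_t, ev_d) # -1 (departure) sorts before +1 at equal time
    max(cumsum(ev_d[o]))
  }
  out <- lapply(split(tracks, tracks$chamber), function(tc) {
    peaks <- vapply(split(tc, tc$founder),
                    function(tf) peak_lineage(tf$birth, tf$depart), numeric(1))
    data.frame(chamber = tc$chamber[1], max_aggregate = max(peaks))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Exact Mann-Whitney comparison with Hodges-Lehmann difference
#'
#' Two-sample comparison of per-chamber statistics. The U statistic counts
#' pairs with `x > y` (ties count 1/2). For `n + m <= 16` the two-sided
#' p-value is exact, computed by full enumeration of all `choose(n+m, n)`
#' group labelings of the pooled observed values (with ties this is the exact
#' permutation test; without ties it coincides with the classical exact
#' Mann-Whitney distribution); above that, the normal approximation with tie
#' correction and continuity correction is used. The effect size is the
#' Hodges-Lehmann difference: the median of all pairwise differences `y - x`.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @return list with `U`, `p`, `hl` (Hodges-Lehmann difference `y - x`),
#'   `method` (`"exact"` or `"normal"`), `n`, `m`.
#' @export
compare_groups <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2)
    stop("compare_groups: both groups need at least 2 values")
  if (any(!is.finite(c(x, y))))
    stop("compare_groups: values must be finite")
  n <- length(x); m <- length(y)
  u_stat <- function(xx, yy) {
    d <- outer(xx, yy, "-")
    sum(d > 0) + 0.5 * sum(d == 0)
  }
  U <- u_stat(x, y)
  pooled <- c(x, y)
  if (n + m <= 16) {
    idx <- utils::combn(n + m, n)
    Us <- apply(idx, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
    p <- min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
    method <- "exact"
  } else {
    mu_U <- n * m / 2
    tie_tab <- table(pooled)
    N <- n + m
    sigma2 <- n * m / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- (abs(U - mu_U) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    method <- "normal"
  }
  hl <- stats::median(outer(y, x, "-"))
  list(U = U, p = p, hl = hl, method = method, n = n, m = m)
}
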