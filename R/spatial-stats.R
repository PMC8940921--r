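## Quantification layer: specific growth rates, geometric summaries,
## distance fold-changes, Welch t-tests (from the Welch formulas), balanced
## two-way ANOVA from sums of squares, and a permutation trend test.

#' Specific growth rate from log cell densities
#'
#' mu = (ln N(t2) - ln N(t1)) / (t2 - t1), computed per replicate and then
#' summarised. Densities are expected as a replicate-by-time layout: either a
#' numeric vector (one replicate) or a matrix/data.frame with one row per
#' replicate, with \code{times} giving the column times.
#'
#' @param densities Numeric vector or matrix of cell densities (> 0 at the
#'   window ends), replicates in rows.
#' @param times Times (days) of the columns.
#' @param t1,t2 Window ends (must be grid times, t2 > t1).
#' @return list(mu, sd, window, replicates): mean and sd across replicates,
#'   the window, and the per-replicate rates.
#' @examples
#' specificGrowthRate(c(1e5, 2e5), times = c(0, 1), t1 = 0, t2 = 1)$mu
#' # log(2)
#' @export
specificGrowthRate <- function(densities, times, t1 = min(times),
                               t2 = max(times)) {
  m <- if (is.null(dim(densities))) matrix(densities, nrow = 1) else
    as.matrix(densities)
  if (ncol(m) != length(times)) {
    stop("densities must have one column per time point")
  }
  if (t2 <= t1) stop("t2 must be greater than t1")
  i1 <- which(abs(times - t1) < 1e-9)
  i2 <- which(abs(times - t2) < 1e-9)
  if (!length(i1) || !length(i2)) stop("t1 and t2 must be grid times")
  n1 <- m[, i1[1]]; n2 <- m[, i2[1]]
  if (any(n1 <= 0) || any(n2 <= 0)) {
    stop("densities must be positive at the window ends")
  }
  mu <- (log(n2) - log(n1)) / (t2 - t1)
  list(mu = mean(mu), sd = if (length(mu) > 1) stats::sd(mu) else NA_real_,
       window = c(t1, t2), replicates = as.numeric(mu))
}

#' Geometric mean and geometric standard deviation
#'
#' geo_mean = exp(mean(log v)), geo_sd = exp(sd(log v)); the multiplicative
#' error summary used for spread of replicate abundances.
#'
#' @param values Positive numeric vector.
#' @return list(geo_mean, geo_sd); geo_sd is NA for a single value.
#' @examples
#' geometricStats(c(1, 100))$geo_mean  # 10
#' @export
geometricStats <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("all values must be positive and finite")
  }
  lv <- log(values)
  list(geo_mean = exp(mean(lv)),
       geo_sd = if (length(lv) > 1) exp(stats::sd(lv)) else NA_real_)
}

#' Distance fold-change of a taxon's abundance
#'
#' Ratio of geometric-mean density in the innermost distance group to the
#' outermost, at one timepoint. Densities below the detection floor are
#' clamped to the floor before the geometric means, so "negligible" outer
#' growth yields a large finite fold rather than infinity. The reported
#' statistic is the Spearman correlation of log density with distance; a
#' permutation p-value is attached when a seed is given.
#'
#' @param table An \linkS4class{AbundanceTable}.
#' @param taxon Taxon name.
#' @param t Timepoint (defaults to the last in the table).
#' @param floor Detection floor, cells ml^-1 (default 1e3).
#' @param n_perm,seed Permutation settings for the trend p-value; with
#'   \code{seed = NULL} the p-value is NA (deterministic mode).
#' @return list(taxon, fold, statistic, p_value, n_per_location).
#' @export
foldChangeByDistance <- function(table, taxon, t = NULL, floor = 1e3,
                                 n_perm = 999, seed = NULL) {
  d <- abundanceData(table)
  d <- d[d$taxon == taxon, , drop = FALSE]
  if (!nrow(d)) stop("taxon not present in table: ", taxon)
  if (is.null(t)) t <- max(d$timepoint)
  d <- d[abs(d$timepoint - t) < 1e-9, , drop = FALSE]
  dists <- sort(unique(d$distance_mm))
  if (length(dists) < 2) stop("need >= 2 distance groups")
  dens <- pmax(d$density, floor)
  inner <- dens[d$distance_mm == dists[1]]
  outer <- dens[d$distance_mm == dists[length(dists)]]
  fold <- geometricStats(inner)$geo_mean / geometricStats(outer)$geo_mean
  at_floor <- all(outer <= floor)
  stat <- if (stats::sd(log(dens)) == 0 || stats::sd(d$distance_mm) == 0) 0
    else stats::cor(log(dens), d$distance_mm, method = "spearman")
  p <- if (!is.null(seed)) {
    permutationTrendTest(log(dens), d$distance_mm, n_perm = n_perm,
                         seed = seed)$p
  } else NA_real_
  out <- list(taxon = taxon, fold = fold, statistic = stat, p_value = p,
              n_per_location = as.integer(table(d$distance_mm)))
  if (at_floor) attr(out$fold, "at_detection_floor") <- TRUE
  out
}

#' Welch two-sample t-test (unequal variances), two-tailed
#'
#' Implemented from the Welch statistic and the Welch-Satterthwaite degrees
#' of freedom. Two zero-variance samples with equal means give p = 1.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return list(t, df, p_two_tailed).
#' @examples
#' welchTTest(rnorm(9), rnorm(9))$p_two_tailed
#' @export
welchTTest <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("both samples need n >= 2")
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p_two_tailed = 1))
    return(list(t = Inf * sign(mean(a) - mean(b)), df = NA_real_,
                p_two_tailed = 0))
  }
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = tstat, df = df, p_two_tailed = 2 * stats::pt(-abs(tstat), df))
}

#' Balanced two-way ANOVA with interaction, from sums of squares
#'
#' Decomposes SS_total = SS_A + SS_B + SS_AB + SS_error on a balanced
#' factorial design (equal replicates in every cell; empty or unequal cells
#' are an error directing the user to the permutation trend test). F
#' statistics are mean-square ratios against the within-cell error; p-values
#' come from the F distribution.
#'
#' @param response Numeric response vector.
#' @param factor_a,factor_b Factors (coerced), each with >= 2 levels.
#' @return data.frame with one row per term (A, B, A:B, error): df, ss, f, p.
#' @export
twoWayAnovaInteraction <- function(response, factor_a, factor_b) {
  a <- as.factor(factor_a); b <- as.factor(factor_b)
  if (nlevels(a) < 2 || nlevels(b) < 2) {
    stop("both factors need >= 2 levels")
  }
  counts <- table(a, b)
  if (any(counts == 0)) {
    stop("empty factor cells: use permutationTrendTest for unbalanced designs")
  }
  if (length(unique(as.vector(counts))) != 1) {
    stop("unequal cell sizes: this decomposition requires a balanced design")
  }
  r <- counts[1, 1]
  if (r < 2) stop("need >= 2 replicates per cell")
  I <- nlevels(a); J <- nlevels(b)
  grand <- mean(response)
  mean_a <- tapply(response, a, mean)
  mean_b <- tapply(response, b, mean)
  mean_ab <- tapply(response, list(a, b), mean)
  ss_a <- J * r * sum((mean_a - grand)^2)
  ss_b <- I * r * sum((mean_b - grand)^2)
  ss_ab <- r * sum((mean_ab - outer(mean_a, rep(1, J)) -
                    outer(rep(1, I), mean_b) + grand)^2)
  cellmean_per_obs <- mean_ab[cbind(as.integer(a), as.integer(b))]
  ss_err <- sum((response - cellmean_per_obs)^2)
  df_a <- I - 1; df_b <- J - 1; df_ab <- df_a * df_b
  df_err <- I * J * (r - 1)
  ms_err <- ss_err / df_err
  fvals <- c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab) / ms_err
  pvals <- stats::pf(fvals, c(df_a, df_b, df_ab), df_err, lower.tail = FALSE)
  if (ss_err == 0) {
    fvals <- ifelse(c(ss_a, ss_b, ss_ab) == 0, 0, Inf)
    pvals <- ifelse(is.finite(fvals), 1, 0)
    warning("zero within-cell error sum of squares: F undefined, flagged")
  }
  data.frame(
    term = c("A", "B", "A:B", "error"),
    df = c(df_a, df_b, df_ab, df_err),
    ss = c(ss_a, ss_b, ss_ab, ss_err),
    f = c(fvals, NA),
    p = c(pvals, NA),
    stringsAsFactors = FALSE
  )
}

#' Permutation trend test of abundance versus distance
#'
#' Statistic: Spearman correlation of abundance with distance. The p-value is
#' the permutation probability (with the +1 correction) of an absolute
#' correlation at least as large under random relabelling of abundances.
#' Distribution-free alternative to t-tests for small unbalanced spatial
#' designs.
#'
#' @param abundance Numeric vector (n >= 4).
#' @param distance Numeric vector of matching length.
#' @param n_perm Number of permutations (>= 999).
#' @param seed Integer seed (required).
#' @return list(statistic, p).
#' @export
permutationTrendTest <- function(abundance, distance, n_perm = 999, seed) {
  n <- length(abundance)
  if (n < 4) stop("need n >= 4")
  if (length(distance) != n) stop("length mismatch")
  if (n_perm < 999) stop("n_perm must be >= 999")
  if (stats::sd(abundance) == 0) return(list(statistic = 0, p = 1))
  ra <- rank(abundance); rd <- rank(distance)
  ra_c <- ra - mean(ra); rd_c <- rd - mean(rd)
  denom <- sqrt(sum(ra_c^2) * sum(rd_c^2))
  obs <- sum(ra_c * rd_c) / denom
  perm_stats <- .withSeed(seed, {
    perm <- matrix(0, n, n_perm)
    for (k in seq_len(n_perm)) perm[, k] <- ra_c[sample.int(n)]
    as.numeric(crossprod(perm, rd_c)) / denom
  })
  p <- (1 + sum(abs(perm_stats) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(statistic = obs, p = p)
}

#' Benjamini-Hochberg adjusted p-values for a result table
#'
#' Convenience wrapper adding an FDR column to per-genus test results.
#'
#' @param p Numeric vector of p-values.
#' @return Numeric vector of BH-adjusted p-values.
#' @export
adjustFDR <- function(p) stats::p.adjust(p, method = "BH")
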