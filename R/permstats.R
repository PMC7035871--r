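# Locality-blocked permutation regression. Most sampling localities yield
# several faecal specimens per sampling interval, so a naive OLS over all
# specimens is pseudo-replicated: heavily collected localities dominate the
# fit. Each permutation iteration instead draws exactly ONE specimen per
# locality x interval unit, fits %C4 ~ grassiness by OLS, and the
# distribution of fits over iterations gives permuted means and 95%
# confidence limits for r2, intercept and slope that are unbiased with
# respect to repeated collections. Monte Carlo significance is
#   p_hat = 1 - (# iterations with model p < 0.05) / iterations.

#' Simple linear regression of %C4 on grassiness
#'
#' Closed-form OLS (normal equations) with the two-sided slope t-test;
#' kept closed-form because it sits inside the permutation loop.
#'
#' @param g predictor (grassiness index values).
#' @param y response (%C4).
#' @return list: \code{r2}, \code{a} (intercept), \code{b} (slope),
#'   \code{p} (two-sided slope p-value), \code{n}.
#' @export
ols_fit <- function(g, y) {
  n <- length(g)
  stop_if(n != length(y), "predictor and response lengths differ")
  stop_if(n < 3, "need at least 3 points")
  sxx <- sum((g - mean(g))^2)
  stop_if(sxx == 0, "constant predictor: grassiness does not vary")
  b <- sum((g - mean(g)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(g)
  res <- y - a - b * g
  rss <- sum(res^2)
  syy <- sum((y - mean(y))^2)
  r2 <- if (syy > 0) 1 - rss / syy else 0
  se <- sqrt(rss / (n - 2) / sxx)
  # exact fit: no residual variance, slope either certain or absent
  p <- if (se == 0) (if (b != 0) 0 else 1) else
    2 * stats::pt(-abs(b / se), n - 2)
  list(r2 = r2, a = a, b = b, p = p, n = n)
}

#' Permutation regression over locality x interval units
#'
#' @param records analysis table: columns \code{locality_id},
#'   \code{interval}, \code{season}, \code{pct_c4} and the grassiness column
#'   named by \code{grass_col}.
#' @param grass_col name of the grassiness column to regress on.
#' @param season subset: "both", "dry" or "wet".
#' @param iterations number of permutation iterations (default 1000).
#' @param seed RNG seed; results are bit-reproducible given it. Draw order:
#'   units are taken in sorted (locality, interval) order within each
#'   iteration, iterations run in sequence off one seeded stream.
#' @param scheme resampling scheme. \code{"one_per_unit"} (default): each
#'   iteration draws one specimen uniformly at random from every locality x
#'   interval unit. \code{"shuffle"} (sensitivity alternative): each
#'   iteration shuffles %C4 labels within each unit and fits on all
#'   specimens.
#' @param cl confidence-limit mode for the permuted mean: \code{"sem"}
#'   (default) mean +- 1.96 sd/sqrt(iterations);
#'   \code{"percentile"} the 2.5/97.5 percentiles of the iteration
#'   distribution.
#' @param alpha significance level used inside the Monte Carlo p-hat
#'   (default 0.05).
#' @return a \code{perm_summary}: permuted mean and CL for r2, intercept
#'   and slope, \code{p_hat}, \code{n} (distinct locality x interval units),
#'   plus the per-iteration draws matrix (columns r2, a, b, p) for
#'   downstream season comparisons.
#' @export
permutation_regression <- function(records, grass_col = "grassiness",
                                   season = c("both", "dry", "wet"),
                                   iterations = 1000, seed = 1,
                                   scheme = c("one_per_unit", "shuffle"),
                                   cl = c("sem", "percentile"),
                                   alpha = 0.05) {
  season <- match.arg(season); scheme <- match.arg(scheme)
  cl <- match.arg(cl)
  need <- c("locality_id", "interval", "season", "pct_c4", grass_col)
  stop_if(!all(need %in% names(records)), "records missing columns: ",
          paste(setdiff(need, names(records)), collapse = ", "))
  stop_if(iterations < 1, "iteration count must be >= 1")
  if (season != "both")
    records <- records[records$season == season, , drop = FALSE]
  units <- interaction(records$locality_id, records$interval, drop = TRUE)
  idx_by_unit <- split(seq_len(nrow(records)), units)
  idx_by_unit <- idx_by_unit[order(names(idx_by_unit))]
  n_units <- length(idx_by_unit)
  stop_if(n_units < 3, "fewer than 3 locality x interval units in subset")
  g_all <- records[[grass_col]]
  y_all <- records$pct_c4
  sizes <- lengths(idx_by_unit)
  draws <- matrix(NA_real_, iterations, 4,
                  dimnames = list(NULL, c("r2", "a", "b", "p")))
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      if (scheme == "one_per_unit") {
        pick <- vapply(seq_len(n_units), function(u) {
          ix <- idx_by_unit[[u]]
          if (sizes[u] == 1L) ix else ix[sample.int(sizes[u], 1L)]
        }, integer(1))
        fit <- ols_fit(g_all[pick], y_all[pick])
      } else {
        y_perm <- y_all
        for (u in seq_len(n_units)) {
          ix <- idx_by_unit[[u]]
          if (sizes[u] > 1L) y_perm[ix] <- y_all[ix[sample.int(sizes[u])]]
        }
        fit <- ols_fit(g_all, y_perm)
      }
      draws[it, ] <- c(fit$r2, fit$a, fit$b, fit$p)
    }
  })
  summ <- function(v) {
    m <- mean(v)
    if (cl == "sem") {
      half <- 1.96 * stats::sd(v) / sqrt(iterations)
      c(mean = m, lo = m - half, hi = m + half)
    } else {
      q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
      c(mean = m, lo = q[1], hi = q[2])
    }
  }
  structure(list(
    season = season, n = n_units, iterations = iterations, seed = seed,
    scheme = scheme, cl = cl, alpha = alpha, grass_col = grass_col,
    r2 = summ(draws[, "r2"]), a = summ(draws[, "a"]),
    b = summ(draws[, "b"]),
    p_hat = 1 - sum(draws[, "p"] < alpha) / iterations,
    draws = draws), class = "perm_summary")
}

#' @export
print.perm_summary <- function(x, ...) {
  fmt <- function(s) sprintf("%.4f (%.4f-%.4f)", s["mean"], s["lo"], s["hi"])
  cat(sprintf(
    "<perm_summary> season=%s  n=%d units  %d iterations (seed %s)\n",
    x$season, x$n, x$iterations, format(x$seed)))
  cat("  r2        ", fmt(x$r2), "\n  intercept ", fmt(x$a),
      "\n  slope     ", fmt(x$b), "\n  p-hat     ",
      format(x$p_hat, digits = 4), "\n")
  invisible(x)
}

#' One-tailed dry-vs-wet season comparison
#'
#' Pairs the dry- and wet-subset iterations by index and evaluates the
#' empirical distribution of per-iteration differences d_i = dry_i - wet_i.
#' The two-sided Monte Carlo p is twice the smaller tail fraction (with the
#' add-one convention, so complete separation gives p below the 1/iterations
#' Monte Carlo floor rather than zero), capped at 1, and is then halved for
#' the one-tailed test of the null hypothesis dry <= wet.
#'
#' @param dry,wet \code{perm_summary} objects (or iteration draw matrices)
#'   with equal iteration counts.
#' @param parameter "b" (slope) or "r2".
#' @return data frame: \code{parameter}, \code{p} (one-tailed),
#'   \code{null} ("dry <= wet").
#' @export
compare_seasons <- function(dry, wet, parameter = c("b", "r2")) {
  parameter <- match.arg(parameter)
  get_draws <- function(x) if (inherits(x, "perm_summary")) x$draws else x
  dd <- get_draws(dry); wd <- get_draws(wet)
  stop_if(nrow(dd) != nrow(wd),
          "dry and wet iteration counts differ; draws must be paired")
  d <- dd[, parameter] - wd[, parameter]
  m <- nrow(dd)
  lo <- (sum(d <= 0) + 1) / (m + 1)
  hi <- (sum(d >= 0) + 1) / (m + 1)
  p_two <- min(1, 2 * min(lo, hi))
  data.frame(parameter = parameter, p = p_two / 2, null = "dry <= wet",
             stringsAsFactors = FALSE)
}

#' Full permutation-regression report across buffer radii and seasons
#'
#' Runs \code{\link{permutation_regression}} for every radius x season cell
#' (seasons: both combined, dry only, wet only) and the one-tailed dry-vs-wet
#' comparisons of r2 and slope at each radius.
#'
#' @param records analysis table with columns \code{locality_id},
#'   \code{interval}, \code{season}, \code{pct_c4} and one grassiness column
#'   per radius named \code{grassiness_<r>km} (e.g. \code{grassiness_4km}).
#' @param radii_km buffer radii in km (default 2, 4, 8, 12).
#' @param iterations,seed,scheme,cl,alpha passed to
#'   \code{\link{permutation_regression}}. Each radius x season cell uses
#'   seed \code{seed + k} where k = 0, 1, 2, ... in row order (radius-major,
#'   both/dry/wet within radius), so the report is reproducible
#'   bit-for-bit.
#' @return a \code{perm_report}: \code{$summaries} (one row per radius x
#'   season: n, permuted means and 95% CLs for r2, intercept, slope, and
#'   p-hat) and \code{$comparisons} (one row per radius x parameter with the
#'   one-tailed dry-vs-wet p).
#' @export
permutation_report <- function(records, radii_km = c(2, 4, 8, 12),
                               iterations = 1000, seed = 1,
                               scheme = "one_per_unit", cl = "sem",
                               alpha = 0.05) {
  cols <- grassiness_column(radii_km * 1000)
  missing <- setdiff(cols, names(records))
  stop_if(length(missing) > 0, "records missing grassiness columns: ",
          paste(missing, collapse = ", "))
  summaries <- list(); comparisons <- list(); k <- 0
  for (i in seq_along(radii_km)) {
    fits <- list()
    for (ssn in c("both", "dry", "wet")) {
      fit <- permutation_regression(records, grass_col = cols[i],
                                    season = ssn, iterations = iterations,
                                    seed = seed + k, scheme = scheme,
                                    cl = cl, alpha = alpha)
      k <- k + 1
      fits[[ssn]] <- fit
      summaries[[length(summaries) + 1]] <- data.frame(
        radius_km = radii_km[i], season = ssn, n = fit$n,
        r2_mean = fit$r2["mean"], r2_lo = fit$r2["lo"], r2_hi = fit$r2["hi"],
        intercept_mean = fit$a["mean"], intercept_lo = fit$a["lo"],
        intercept_hi = fit$a["hi"],
        slope_mean = fit$b["mean"], slope_lo = fit$b["lo"],
        slope_hi = fit$b["hi"], p_hat = fit$p_hat,
        row.names = NULL, stringsAsFactors = FALSE)
    }
    for (par in c("r2", "b")) {
      cs <- compare_seasons(fits$dry, fits$wet, par)
      comparisons[[length(comparisons) + 1]] <- data.frame(
        radius_km = radii_km[i], parameter = par, p_one_tailed = cs$p,
        null = cs$null, stringsAsFactors = FALSE)
    }
  }
  structure(list(summaries = do.call(rbind, summaries),
                 comparisons = do.call(rbind, comparisons),
                 iterations = iterations, seed = seed, scheme = scheme,
                 cl = cl, alpha = alpha),
            class = "perm_report")
}

#' @export
print.perm_report <- function(x, ...) {
  cat(sprintf("<perm_report> %d iterations, seed %s, scheme %s\n",
              x$iterations, format(x$seed), x$scheme))
  print(x$summaries, digits = 4, row.names = FALSE)
  cat("\nSeason comparisons (one-tailed, null dry <= wet):\n")
  print(x$comparisons, digits = 4, row.names = FALSE)
  invisible(x)
}

# column naming convention for per-radius grassiness in merged tables
grassiness_column <- function(radius_m) sprintf("grassiness_%gkm",
                                                radius_m / 1000)
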