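# Synthetic-data generator. Emulates the statistical structure the analysis
# assumes: a spatially autocorrelated categorical landscape along the
# woody-cover gradient (plus water and bare ground), clustered sampling
# localities revisited over monthly intervals, and faecal %C4 linearly
# related to local grassiness with a season-dependent slope (strong in the
# dry season, weak in the wet) plus Gaussian noise. No attempt is made to
# model radiometry or phenology; the generator emits the categorical
# classification directly.

#' Landscape generator specification
#'
#' @param width,height grid size in cells.
#' @param cellsize cell edge in metres.
#' @param autocorr_len autocorrelation length in metres (0 = independent
#'   cells). Patch size grows with this length.
#' @param mixture named non-negative proportions over class abbreviations
#'   (any subset of the scheme), summing to 1. The default is the observed
#'   class composition of a southern-savanna study landscape: continuous
#'   grassland dominant (~41%), discontinuous grassland (~33%), open
#'   deciduous woodland (~22%), closed deciduous woodland (~4%), traces of
#'   bare ground and water.
#' @param seed integer RNG seed.
#' @return a \code{landscape_spec}.
#' @export
landscape_spec <- function(width = 250, height = 250, cellsize = 100,
                           autocorr_len = 2000,
                           mixture = c(CDW = 0.0410, ODW = 0.2156,
                                       DG = 0.3258, CG = 0.4069,
                                       W = 0.0013, BA = 0.0094),
                           seed = 1) {
  stop_if(width < 1 || height < 1, "grid must be at least 1x1")
  stop_if(cellsize <= 0, "cellsize must be positive")
  stop_if(autocorr_len < 0, "autocorrelation length must be >= 0")
  stop_if(is.null(names(mixture)) || any(names(mixture) == ""),
          "mixture must be named by class abbreviation")
  stop_if(any(mixture < 0), "mixture proportions must be non-negative")
  stop_if(sum(mixture) <= 0, "degenerate mixture: all proportions zero")
  mixture <- mixture / sum(mixture)
  structure(list(width = as.integer(width), height = as.integer(height),
                 cellsize = cellsize, autocorr_len = autocorr_len,
                 mixture = mixture, seed = seed),
            class = "landscape_spec")
}

# Gaussian random field on a torus: white noise smoothed by FFT with a
# Gaussian kernel of sd = autocorr_len (in cell units).
gaussian_field <- function(nr, nc, range_cells) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (range_cells <= 0) return(z)
  ki <- c(0:floor(nr / 2), -(ceiling(nr / 2 - 1):1))
  kj <- c(0:floor(nc / 2), -(ceiling(nc / 2 - 1):1))
  # separable kernel: exp(-(i^2+j^2)/2s^2) = exp(-i^2/..) * exp(-j^2/..)
  kern <- exp(-ki^2 / (2 * range_cells^2)) %o%
    exp(-kj^2 / (2 * range_cells^2))
  kern <- kern / sum(kern)
  Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) / (nr * nc)
}

#' Generate an autocorrelated categorical landscape
#'
#' A smoothed Gaussian random field is thresholded at the mixture's
#' cumulative quantiles (by rank), so empirical class proportions match the
#' requested mixture to within one cell, while spatial autocorrelation gives
#' contiguous patches. Threshold bins are ordered water, CDW, ODW, DG, CG,
#' bare (then any other classes), so water abuts the closed-woodland end of
#' the gradient, loosely mimicking riparian woodland.
#'
#' @param spec a \code{\link{landscape_spec}}.
#' @param scheme a \code{\link{class_scheme}} mapping abbreviations to
#'   codes.
#' @return an \code{\link{lc_raster}}; deterministic given
#'   \code{spec$seed}.
#' @export
generate_landscape <- function(spec, scheme = savanna_scheme()) {
  stop_if(!inherits(spec, "landscape_spec"), "spec must be a landscape_spec")
  mix <- spec$mixture[spec$mixture > 0]
  ord <- c(intersect(c("W", "CDW", "ODW", "DG", "CG", "BA"), names(mix)),
           setdiff(names(mix), c("W", "CDW", "ODW", "DG", "CG", "BA")))
  mix <- mix[ord]
  codes <- scheme_code(scheme, names(mix))
  nr <- spec$height; nc <- spec$width
  field <- with_seed(spec$seed,
                     gaussian_field(nr, nc, spec$autocorr_len / spec$cellsize))
  n <- nr * nc
  # rank-threshold: class k occupies the rank interval of its proportion
  brk <- round(cumsum(mix) * n)
  brk[length(brk)] <- n
  rk <- rank(as.vector(field), ties.method = "first")
  cls <- codes[findInterval(rk, c(0, brk), left.open = TRUE)]
  lc_raster(matrix(cls, nr, nc), cellsize = spec$cellsize,
            crs_name = "synthetic metric grid")
}

#' Diet model specification
#'
#' The generating relationship: a specimen collected at locality l in
#' interval t has true %C4 intake
#' \code{a_season + b_season * G(l) + N(0, sd)}, clamped to [0, 100], where
#' G(l) is the grassiness index of the locality's buffer at the reference
#' radius. Faecal delta13C is back-computed through the inverse mixing
#' model, so \code{\link{pct_c4}} recovers the generating %C4 exactly (up to
#' clamping). Defaults reproduce the fitted dry/wet contrast of the study
#' system: a strong dry-season slope (0.10 %C4 per grassiness unit) and a
#' weak wet-season slope (0.04), residual sd 10 %C4, 100 localities sampled
#' over 6 monthly intervals with 1-8 specimens per locality per interval.
#'
#' @param a_dry,b_dry dry-season intercept and slope (%C4, %C4 per
#'   grassiness unit).
#' @param a_wet,b_wet wet-season intercept and slope.
#' @param sd residual standard deviation (%C4), >= 0.
#' @param n_localities number of sampling localities.
#' @param specimens integer range \code{c(min, max)}; specimens per locality
#'   per interval are drawn uniformly from it.
#' @param intervals character vector of sampling months, "YYYY-MM".
#' @param reference_radius radius (m) of the buffer whose grassiness drives
#'   the generating relationship (default 4 km, the daily-range scale).
#' @param params \code{\link{mixing_params}} used to back-compute delta13C.
#' @param seed integer RNG seed.
#' @return a \code{diet_model_spec}.
#' @export
diet_model_spec <- function(a_dry = -2.3, b_dry = 0.10,
                            a_wet = 36.8, b_wet = 0.04, sd = 10,
                            n_localities = 100, specimens = c(1, 8),
                            intervals = c("2003-01", "2003-03", "2003-05",
                                          "2003-07", "2003-09", "2003-11"),
                            reference_radius = 4000,
                            params = mixing_params(), seed = 1) {
  stop_if(sd < 0, "residual sd must be >= 0")
  stop_if(!all(is.finite(c(a_dry, b_dry, a_wet, b_wet))),
          "diet model coefficients must be finite")
  stop_if(n_localities < 1, "need at least one locality")
  stop_if(length(specimens) != 2 || specimens[1] < 1 ||
            specimens[2] < specimens[1], "specimens must be c(min, max)")
  stop_if(reference_radius <= 0, "reference radius must be positive")
  structure(list(a_dry = a_dry, b_dry = b_dry, a_wet = a_wet, b_wet = b_wet,
                 sd = sd, n_localities = as.integer(n_localities),
                 specimens = as.integer(specimens), intervals = intervals,
                 reference_radius = reference_radius, params = params,
                 seed = seed),
            class = "diet_model_spec")
}

#' Season from sampling month
#'
#' Southern-hemisphere savanna convention: May-October dry, November-April
#' wet.
#'
#' @param interval "YYYY-MM" strings (or anything whose 6th-7th characters
#'   are the month).
#' @return character vector "dry"/"wet".
#' @export
season_of <- function(interval) {
  m <- as.integer(substr(interval, 6, 7))
  stop_if(anyNA(m) || any(m < 1 | m > 12), "intervals must be YYYY-MM")
  ifelse(m >= 5 & m <= 10, "dry", "wet")
}

#' Generate a synthetic faecal-sample table
#'
#' Places localities uniformly at random on non-water valid cells, computes
#' each locality's grassiness at the reference radius, then draws specimens
#' per locality x interval from the diet model (see
#' \code{\link{diet_model_spec}}).
#'
#' @param raster landscape \code{\link{lc_raster}}.
#' @param scheme \code{\link{class_scheme}}.
#' @param diet a \code{\link{diet_model_spec}}.
#' @return data frame of samples: \code{sample_id}, \code{locality_id},
#'   \code{x}, \code{y}, \code{date}, \code{interval}, \code{season},
#'   \code{d13C}, \code{pct_c4_true}, \code{grassiness_ref} (generator-side
#'   grassiness at the reference radius, kept for diagnostics).
#'   Deterministic given \code{diet$seed}.
#' @export
generate_samples <- function(raster, scheme = savanna_scheme(),
                             diet = diet_model_spec()) {
  stop_if(!inherits(diet, "diet_model_spec"), "diet must be a diet_model_spec")
  water <- scheme_code(scheme, "W")
  ok <- which(!is.na(raster$values) & raster$values != water)
  stop_if(length(ok) < diet$n_localities,
          "locality count exceeds available (non-water) placement area")
  with_seed(diet$seed, {
    cells <- sample(ok, diet$n_localities)
    ctr <- pixel_centres(raster)
    lx <- ctr$x[cells]; ly <- ctr$y[cells]
    g_ref <- vapply(seq_along(cells), function(i) {
      prof <- extract_buffer_profile(raster, lx[i], ly[i],
                                     diet$reference_radius, scheme)
      grassiness_index(prof, scheme)
    }, numeric(1))
    seasons <- season_of(diet$intervals)
    rows <- list(); sid <- 0
    for (l in seq_len(diet$n_localities)) {
      for (t in seq_along(diet$intervals)) {
        k <- if (diet$specimens[1] == diet$specimens[2]) diet$specimens[1]
        else diet$specimens[1] +
          sample.int(diet$specimens[2] - diet$specimens[1] + 1, 1) - 1
        dry <- seasons[t] == "dry"
        mu <- (if (dry) diet$a_dry else diet$a_wet) +
          (if (dry) diet$b_dry else diet$b_wet) * g_ref[l]
        true <- pmin(100, pmax(0, mu + rnorm(k, 0, diet$sd)))
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("S%05d", sid + seq_len(k)),
          locality_id = sprintf("L%03d", l),
          x = lx[l], y = ly[l],
          date = paste0(diet$intervals[t], "-01"),
          interval = diet$intervals[t], season = seasons[t],
          d13C = d13c_from_pct_c4(true, diet$params),
          pct_c4_true = true,
          grassiness_ref = g_ref[l])
        sid <- sid + k
      }
    }
    do.call(rbind, rows)
  })
}

#' Synthetic dual-date reflectance stacks for a landscape
#'
#' A classifier-exercising fixture, not a radiometric model: each land-cover
#' class gets fixed per-band mean reflectances (drawn once from the seed)
#' and pixels scatter around their class means with Gaussian noise. Returns
#' senescent- and flushed-date six-band stacks whose class means differ
#' between dates.
#'
#' @param raster an \code{\link{lc_raster}}.
#' @param noise_sd pixel noise sd around the class mean.
#' @param seed integer RNG seed.
#' @return list with elements \code{senescent} and \code{flushed}
#'   (\code{\link{reflectance_stack}}s; landscape nodata cells are masked).
#' @export
simulate_reflectance_stack <- function(raster, noise_sd = 3, seed = 1) {
  codes <- sort(unique(raster$values[!is.na(raster$values)]))
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  with_seed(seed, {
    make_date <- function() {
      means <- matrix(runif(length(codes) * 6, 0, 100), length(codes), 6,
                      dimnames = list(codes, NULL))
      arr <- array(0, c(nr, nc, 6))
      ci <- match(raster$values, codes)
      for (k in 1:6)
        arr[, , k] <- matrix(means[ci, k], nr, nc) + rnorm(nr * nc, 0, noise_sd)
      reflectance_stack(arr, band_names = c("b1", "b2", "b3", "b4", "b5", "b7"),
                        mask = !is.na(raster$values),
                        cellsize = raster$cellsize, xmin = raster$xmin,
                        ymin = raster$ymin)
    }
    list(senescent = make_date(), flushed = make_date())
  })
}
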