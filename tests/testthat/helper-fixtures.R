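# Fixtures built in code: small rasters, stacks and a brute-force buffer
# oracle kept deliberately independent of the package's windowed extraction.

uniform_raster <- function(code = 4L, n = 20, cellsize = 30) {
  lc_raster(matrix(as.integer(code), n, n), cellsize = cellsize)
}

checkerboard_raster <- function(codes = c(1L, 4L), n = 140, cellsize = 30) {
  idx <- (outer(seq_len(n), seq_len(n), `+`)) %% 2L
  lc_raster(matrix(codes[idx + 1L], n, n), cellsize = cellsize)
}

# exhaustive pixel-centre membership count over the whole grid
brute_profile <- function(raster, x, y, radius) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  cs <- raster$cellsize
  counts <- integer(0); n_members <- 0L
  for (row in seq_len(nr)) {
    cy <- raster$ymin + (nr - row + 0.5) * cs
    for (col in seq_len(nc)) {
      cx <- raster$xmin + (col - 0.5) * cs
      if ((cx - x)^2 + (cy - y)^2 <= radius^2) {
        n_members <- n_members + 1L
        v <- raster$values[row, col]
        if (!is.na(v)) {
          key <- as.character(v)
          counts[key] <- (if (key %in% names(counts)) counts[key] else 0L) + 1L
        }
      }
    }
  }
  list(counts = counts, n_valid = sum(counts), n_members = n_members)
}

expect_profile_matches_oracle <- function(raster, x, y, radius) {
  prof <- extract_buffer_profile(raster, x, y, radius)
  oracle <- brute_profile(raster, x, y, radius)
  expect_equal(prof$n_valid, oracle$n_valid)
  for (code in names(oracle$counts)) {
    expect_equal(prof[[paste0("pct_", code)]],
                 100 * oracle$counts[[code]] / oracle$n_valid,
                 tolerance = 1e-12)
  }
}

# single wide profile row from named percentages (by class abbreviation)
profile_row <- function(..., scheme = savanna_scheme()) {
  pct <- c(...)
  out <- as.data.frame(as.list(stats::setNames(
    rep(0, nrow(scheme)), sprintf("pct_%d", scheme$code))))
  for (ab in names(pct))
    out[[sprintf("pct_%d", scheme$code[scheme$abbrev == ab])]] <- pct[[ab]]
  out$radius_m <- 2000; out$valid_fraction <- 1
  out$n_valid <- 100L
  out
}

# analysis records with a known number of specimens per locality x interval
make_records <- function(g_by_unit, y_fun, specimens = 1,
                         season = "dry", interval = "2003-06") {
  rows <- list()
  for (l in seq_along(g_by_unit)) {
    k <- if (length(specimens) > 1) specimens[l] else specimens
    rows[[l]] <- data.frame(
      locality_id = sprintf("L%02d", l), interval = interval,
      season = season, grassiness = g_by_unit[l],
      pct_c4 = y_fun(g_by_unit[l], k))
  }
  do.call(rbind, rows)
}
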