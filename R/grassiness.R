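# Grassiness index: a single a-priori summary of buffer composition along
# the woody-cover gradient. Each gradient class percentage is multiplied by
# an integer modifier (x1 closed deciduous woodland ... x4 continuous
# grassland) and summed, so a buffer of pure continuous grassland scores
# 400 and pure closed woodland scores 100; classes off the gradient (water,
# bare, built-up, agriculture, coniferous plantation) contribute 0.

#' Grassiness index of one buffer profile
#'
#' @param profile one-row wide profile from
#'   \code{\link{extract_buffer_profile}} (columns \code{pct_<code>}), or a
#'   named numeric vector of percentages named by class abbreviation.
#' @param scheme a \code{\link{class_scheme}} carrying the gradient
#'   modifiers.
#' @param renormalise if TRUE, percentages are first rescaled to sum to 100
#'   over the gradient classes alone, so water/bare area does not dilute the
#'   index. Default FALSE: percentages are taken relative to total valid
#'   buffer area.
#' @return the index value (0 to 400 when the buffer is all gradient
#'   classes).
#' @export
grassiness_index <- function(profile, scheme = savanna_scheme(),
                             renormalise = FALSE) {
  grad <- scheme[!is.na(scheme$modifier), ]
  stop_if(nrow(grad) == 0, "scheme carries no gradient modifiers")
  if (is.data.frame(profile)) {
    stop_if(nrow(profile) != 1, "profile must be a single row")
    if ("n_valid" %in% names(profile))
      stop_if(profile$n_valid == 0, "profile has zero valid buffer area")
    cols <- sprintf("pct_%d", grad$code)
    missing <- setdiff(cols, names(profile))
    pct <- stats::setNames(rep(0, nrow(grad)), grad$abbrev)
    have <- cols %in% names(profile)
    pct[have] <- as.numeric(profile[1, cols[have]])
  } else {
    pct <- stats::setNames(rep(0, nrow(grad)), grad$abbrev)
    have <- intersect(names(profile), grad$abbrev)
    pct[have] <- profile[have]
  }
  stop_if(anyNA(pct), "profile has NA percentages (zero valid buffer area?)")
  if (renormalise) {
    tot <- sum(pct)
    stop_if(tot <= 0, "no gradient-class area to renormalise over")
    pct <- 100 * pct / tot
  }
  sum(pct * grad$modifier[match(names(pct), grad$abbrev)])
}

#' Grassiness index for a long profile table
#'
#' @param profiles long table from \code{\link{extract_all}}
#'   (\code{sample_id}, \code{radius_m}, \code{class_code}, \code{pct}).
#' @inheritParams grassiness_index
#' @return data frame: \code{sample_id}, \code{radius_m},
#'   \code{grassiness}.
#' @export
grassiness_table <- function(profiles, scheme = savanna_scheme(),
                             renormalise = FALSE) {
  need <- c("sample_id", "radius_m", "class_code", "pct")
  stop_if(!all(need %in% names(profiles)), "profiles must be the long table ",
          "from extract_all()")
  grad <- scheme[!is.na(scheme$modifier), ]
  mod <- stats::setNames(rep(0, nrow(scheme)), scheme$code)
  mod[as.character(grad$code)] <- grad$modifier
  profiles$contrib <- profiles$pct * mod[as.character(profiles$class_code)]
  if (renormalise) {
    gsum <- stats::aggregate(
      pct ~ sample_id + radius_m,
      data = profiles[profiles$class_code %in% grad$code, ], FUN = sum)
    names(gsum)[3] <- "grad_total"
    profiles <- merge(profiles, gsum, by = c("sample_id", "radius_m"))
    profiles$contrib <- 100 * profiles$contrib / profiles$grad_total
  }
  out <- stats::aggregate(contrib ~ sample_id + radius_m, data = profiles,
                          FUN = sum)
  names(out)[3] <- "grassiness"
  out[order(out$sample_id, out$radius_m), , drop = FALSE]
}
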