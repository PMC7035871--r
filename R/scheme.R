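# Land-cover class scheme: the woody-cover gradient plus ancillary classes.

#' Define a land-cover class scheme
#'
#' A class scheme lists the integer codes, labels and abbreviations of a
#' categorical land-cover nomenclature, and, for the four classes that span
#' the woody-cover gradient, the woody-cover interval and the integer
#' grassiness modifier (1 for closed woodland up to 4 for continuous
#' grassland) used by \code{\link{grassiness_index}}.
#'
#' @param code integer class codes (unique).
#' @param label full class labels.
#' @param abbrev short class abbreviations (e.g. "CDW").
#' @param woody_lo,woody_hi lower/upper bound of the woody-cover interval in
#'   percent, \code{NA} for non-gradient classes.
#' @param modifier integer grassiness modifier, \code{NA} for non-gradient
#'   classes. Gradient classes must carry modifiers 1..4 with contiguous
#'   woody-cover intervals.
#' @return a \code{class_scheme} data frame.
#' @seealso \code{\link{savanna_scheme}} for the default nomenclature.
#' @export
class_scheme <- function(code, label, abbrev, woody_lo, woody_hi, modifier) {
  stop_if(anyDuplicated(code) > 0, "class codes must be unique")
  stop_if(anyDuplicated(abbrev) > 0, "class abbreviations must be unique")
  x <- data.frame(
    code = as.integer(code), label = as.character(label),
    abbrev = as.character(abbrev),
    woody_lo = as.numeric(woody_lo), woody_hi = as.numeric(woody_hi),
    modifier = as.integer(modifier),
    stringsAsFactors = FALSE
  )
  grad <- x[!is.na(x$modifier), ]
  stop_if(nrow(grad) > 0 && !setequal(grad$modifier, seq_len(nrow(grad))),
          "gradient modifiers must be 1..k with no gaps")
  class(x) <- c("class_scheme", "data.frame")
  x
}

#' Savanna woody-cover gradient nomenclature
#'
#' The default nine-class scheme: the forest-to-grassland gradient stratified
#' at 25% woody-cover intervals (closed deciduous woodland CDW 75-100%, open
#' deciduous woodland ODW 50-75%, discontinuous grassland DG 25-50%,
#' continuous grassland CG 0-25%, carrying grassiness modifiers 1,2,3,4),
#' plus anthropogenic classes (agriculture AG, built-up BU, closed coniferous
#' woodland CCW), bare ground BA, and water W, which carry no modifier and
#' contribute nothing to the grassiness index.
#'
#' @return a \code{\link{class_scheme}}.
#' @export
savanna_scheme <- function() {
  class_scheme(
    code     = 1:9,
    label    = c("Closed deciduous woodland", "Open deciduous woodland",
                 "Discontinuous grassland", "Continuous grassland",
                 "Agriculture", "Built-up", "Closed coniferous woodland",
                 "Bare ground", "Water"),
    abbrev   = c("CDW", "ODW", "DG", "CG", "AG", "BU", "CCW", "BA", "W"),
    woody_lo = c(75, 50, 25, 0, NA, NA, NA, NA, NA),
    woody_hi = c(100, 75, 50, 25, NA, NA, NA, NA, NA),
    modifier = c(1L, 2L, 3L, 4L, NA, NA, NA, NA, NA)
  )
}

scheme_code <- function(scheme, abbrev) {
  i <- match(abbrev, scheme$abbrev)
  stop_if(anyNA(i), "unknown class abbreviation: ",
          paste(abbrev[is.na(i)], collapse = ", "))
  scheme$code[i]
}
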