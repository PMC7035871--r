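# Supervised land-cover classification over the woody-cover nomenclature.
# A dual-date composite (senescent + flushed acquisition) separates woody
# from herbaceous vegetation phenologically: grasses senesce in the dry
# season while most woody plants stay photosynthetically active, so the two
# dates jointly discriminate classes that are spectrally similar on any
# single date.

#' Composite two single-date stacks into a dual-date stack
#'
#' Bands of the senescent-date stack come first, then the flushed-date
#' bands, in each stack's own band order. The composite validity mask is the
#' intersection of the two per-date masks (a pixel masked on either date,
#' e.g. by cloud, is masked in the composite).
#'
#' @param senescent,flushed \code{\link{reflectance_stack}}s on identical
#'   grids with the same number of bands.
#' @return a \code{reflectance_stack} with
#'   \code{n_bands(senescent) + n_bands(flushed)} bands named
#'   \code{sen_*}/\code{flu_*}.
#' @export
build_composite <- function(senescent, flushed) {
  stop_if(!inherits(senescent, "reflectance_stack") ||
            !inherits(flushed, "reflectance_stack"),
          "inputs must be reflectance_stacks")
  stop_if(!same_geometry(senescent, flushed),
          "senescent and flushed stacks differ in grid geometry")
  stop_if(dim(senescent$bands)[3] != dim(flushed$bands)[3],
          "band count differs between dates")
  d <- dim(senescent$bands)
  bands <- array(NA_real_, c(d[1], d[2], 2 * d[3]))
  bands[, , seq_len(d[3])] <- senescent$bands
  bands[, , d[3] + seq_len(d[3])] <- flushed$bands
  reflectance_stack(
    bands,
    band_names = c(paste0("sen_", senescent$band_names),
                   paste0("flu_", flushed$band_names)),
    mask = senescent$mask & flushed$mask,
    cellsize = senescent$cellsize, xmin = senescent$xmin,
    ymin = senescent$ymin, crs_units = senescent$crs_units,
    crs_name = senescent$crs_name)
}

#' Allocate reference points to training and validation roles
#'
#' Within each class, points are allocated on an alternating basis
#' (1st training, 2nd validation, 3rd training, ...), producing two
#' near-equal disjoint sets per class.
#'
#' @param points data frame with columns \code{x}, \code{y},
#'   \code{class_code}.
#' @return the same data frame with a \code{role} column
#'   ("training"/"validation").
#' @export
allocate_roles <- function(points) {
  stop_if(!all(c("x", "y", "class_code") %in% names(points)),
          "points need x, y, class_code columns")
  points$role <- NA_character_
  for (cl in unique(points$class_code)) {
    i <- which(points$class_code == cl)
    points$role[i] <- rep(c("training", "validation"),
                          length.out = length(i))
  }
  points
}

# features at point locations; errors identify offending points
stack_features_at <- function(stack, points) {
  r <- lc_raster(matrix(0L, dim(stack$bands)[1], dim(stack$bands)[2]),
                 stack$cellsize, stack$xmin, stack$ymin)
  idx <- cell_index(r, points$x, points$y)
  off <- which(is.na(idx$row))
  stop_if(length(off) > 0, "points off-grid at rows: ",
          paste(off, collapse = ", "))
  masked <- which(!stack$mask[cbind(idx$row, idx$col)])
  stop_if(length(masked) > 0, "points on masked pixels at rows: ",
          paste(masked, collapse = ", "))
  nb <- dim(stack$bands)[3]
  feats <- vapply(seq_len(nb),
                  function(k) stack$bands[, , k][cbind(idx$row, idx$col)],
                  numeric(nrow(points)))
  feats <- matrix(feats, nrow = nrow(points), ncol = nb)
  colnames(feats) <- stack$band_names
  feats
}

#' Train a random-forest land-cover classifier
#'
#' @param stack a composite \code{\link{reflectance_stack}}.
#' @param points training points (\code{x}, \code{y}, \code{class_code});
#'   if a \code{role} column is present only "training" rows are used. At
#'   least two classes must be present and all points must fall on valid
#'   pixels.
#' @param ntree number of trees (default 500).
#' @param seed RNG seed for the forest, recorded in the result.
#' @return an \code{lc_classifier} (random forest + metadata).
#' @export
train_classifier <- function(stack, points, ntree = 500, seed = 1) {
  if ("role" %in% names(points))
    points <- points[points$role == "training", , drop = FALSE]
  stop_if(nrow(points) == 0, "no training points")
  stop_if(length(unique(points$class_code)) < 2,
          "training data must contain at least two classes")
  feats <- stack_features_at(stack, points)
  y <- factor(points$class_code)
  fit <- with_seed(seed,
                   randomForest::randomForest(x = feats, y = y,
                                              ntree = ntree))
  structure(list(forest = fit, band_names = stack$band_names,
                 ntree = ntree, seed = seed,
                 classes = sort(unique(points$class_code))),
            class = "lc_classifier")
}

#' Classify a composite stack into a land-cover raster
#'
#' Masked pixels become nodata in the output.
#'
#' @param stack a \code{\link{reflectance_stack}} whose bands match the
#'   classifier's feature set.
#' @param classifier an \code{lc_classifier} from
#'   \code{\link{train_classifier}}.
#' @return an \code{\link{lc_raster}} of class codes.
#' @export
classify_raster <- function(stack, classifier) {
  stop_if(!inherits(classifier, "lc_classifier"),
          "classifier must come from train_classifier()")
  stop_if(dim(stack$bands)[3] != length(classifier$band_names),
          "stack band count (", dim(stack$bands)[3],
          ") does not match classifier features (",
          length(classifier$band_names), ")")
  d <- dim(stack$bands)
  valid <- which(stack$mask)
  feats <- vapply(seq_len(d[3]),
                  function(k) stack$bands[, , k][valid], numeric(length(valid)))
  feats <- matrix(feats, nrow = length(valid), ncol = d[3])
  colnames(feats) <- classifier$band_names
  pred <- stats::predict(classifier$forest, feats)
  out <- matrix(NA_integer_, d[1], d[2])
  out[valid] <- as.integer(as.character(pred))
  lc_raster(out, cellsize = stack$cellsize, xmin = stack$xmin,
            ymin = stack$ymin, crs_units = stack$crs_units,
            crs_name = stack$crs_name)
}

#' Confusion matrix of a classification against validation points
#'
#' Rows are the classified map, columns the reference (validation) class;
#' column sums therefore equal the number of validation points per reference
#' class.
#'
#' @param classified an \code{\link{lc_raster}}.
#' @param validation data frame (\code{x}, \code{y}, \code{class_code});
#'   a \code{role} column, if present, restricts to "validation" rows.
#' @param scheme optional \code{\link{class_scheme}} fixing class order;
#'   defaults to the sorted union of observed codes.
#' @return integer matrix of class \code{confusion_matrix}, dimnames =
#'   class codes.
#' @export
confusion_matrix <- function(classified, validation, scheme = NULL) {
  if ("role" %in% names(validation))
    validation <- validation[validation$role == "validation", , drop = FALSE]
  stop_if(nrow(validation) == 0, "empty validation set")
  idx <- cell_index(classified, validation$x, validation$y)
  off <- which(is.na(idx$row))
  stop_if(length(off) > 0, "validation points off-grid at rows: ",
          paste(off, collapse = ", "))
  pred <- classified$values[cbind(idx$row, idx$col)]
  stop_if(anyNA(pred), "validation points fall on nodata pixels")
  codes <- if (!is.null(scheme)) scheme$code else
    sort(unique(c(pred, validation$class_code)))
  cm <- table(factor(pred, levels = codes),
              factor(validation$class_code, levels = codes))
  cm <- unclass(as.matrix(cm))
  names(dimnames(cm)) <- c("classified", "reference")
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Accuracy summary of a confusion matrix
#'
#' Overall accuracy = 100 x trace / total. User's accuracy of class i
#' (commission) = 100 x cm[i,i] / row sum i; producer's accuracy
#' (omission) = 100 x cm[j,j] / column sum j. Classes with an empty row or
#' column are reported as \code{NA} (undefined), not zero.
#'
#' @param cm a square count matrix (classified x reference), e.g. from
#'   \code{\link{confusion_matrix}}.
#' @return list with \code{overall} (%), \code{users} and \code{producers}
#'   (named % vectors), and \code{n} (total count). Values are unrounded;
#'   use \code{\link{round_half_up}} for printing.
#' @export
accuracy_summary <- function(cm) {
  cm <- unclass(as.matrix(cm))
  stop_if(nrow(cm) != ncol(cm), "confusion matrix must be square")
  stop_if(any(cm < 0), "counts must be non-negative")
  total <- sum(cm)
  stop_if(total == 0, "empty confusion matrix")
  rs <- rowSums(cm); cs <- colSums(cm); dg <- diag(cm)
  users <- ifelse(rs > 0, 100 * dg / rs, NA_real_)
  producers <- ifelse(cs > 0, 100 * dg / cs, NA_real_)
  names(users) <- names(producers) <- rownames(cm)
  list(overall = 100 * sum(dg) / total, users = users,
       producers = producers, n = total)
}

#' Published validation confusion matrix for the savanna classification
#'
#' The printed 410-point confusion matrix distributed with the package as a
#' plain-text fixture (9 classes; 50 validation points per class except 30
#' each for agriculture and closed coniferous woodland). Useful for checking
#' the accuracy arithmetic against its published summary values (overall
#' accuracy 90.73%).
#'
#' @return a \code{confusion_matrix} (classified x reference, dimnames =
#'   class abbreviations).
#' @export
savanna_validation_matrix <- function() {
  path <- system.file("extdata", "savanna_confusion_matrix.csv",
                      package = "grazescape")
  stop_if(path == "", "bundled confusion matrix not found")
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  cm <- as.matrix(df)
  storage.mode(cm) <- "integer"
  names(dimnames(cm)) <- c("classified", "reference")
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}
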