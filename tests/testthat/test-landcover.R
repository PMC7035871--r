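# Dual-date compositing, classification and accuracy assessment.

make_stack <- function(fill, n = 12, mask = NULL, bands = 6) {
  arr <- array(fill, c(n, n, bands))
  reflectance_stack(arr, mask = mask, cellsize = 30)
}

test_that("composite stacks senescent bands first, then flushed", {
  sen <- make_stack(1); flu <- make_stack(2)
  comp <- build_composite(sen, flu)
  expect_equal(dim(comp$bands)[3], 12)
  expect_true(all(comp$bands[, , 7] == flu$bands[, , 1]))
  expect_true(all(comp$bands[, , 1] == 1))
  expect_equal(comp$band_names[7], "flu_b1")
})

test_that("composite mask is the intersection of per-date masks", {
  m1 <- matrix(TRUE, 12, 12); m1[3, 3] <- FALSE
  m2 <- matrix(TRUE, 12, 12); m2[5, 7] <- FALSE
  comp <- build_composite(make_stack(1, mask = m1), make_stack(2, mask = m2))
  expect_false(comp$mask[3, 3]); expect_false(comp$mask[5, 7])
  expect_equal(sum(!comp$mask), 2)
  allv <- build_composite(make_stack(1), make_stack(2))
  expect_true(all(allv$mask))
})

test_that("geometry and band mismatches are rejected", {
  expect_error(build_composite(make_stack(1, n = 12), make_stack(2, n = 10)),
               "geometry")
  expect_error(build_composite(make_stack(1), make_stack(2, bands = 5)),
               "band count")
})

test_that("alternating role allocation splits classes evenly and disjointly", {
  pts <- data.frame(x = runif(100, 0, 300), y = runif(100, 0, 300),
                    class_code = rep(1:2, each = 50))
  pts <- allocate_roles(pts)
  tab <- table(pts$class_code, pts$role)
  expect_true(all(tab == 25))
})

test_that("perfectly separable classes are learnt exactly", {
  # class decided by a threshold on one band: a known decision rule
  set.seed(101)
  n <- 40
  lc <- lc_raster(matrix(sample(c(1L, 4L), n * n, TRUE), n, n), cellsize = 30)
  arr <- array(rnorm(n * n * 12, 50, 3), c(n, n, 12))
  arr[, , 3] <- ifelse(lc$values == 1L, 20, 80) + rnorm(n * n, 0, 3)
  stack <- reflectance_stack(arr, cellsize = 30)
  ctr <- grazescape:::pixel_centres(lc)
  pts <- data.frame(x = ctr$x, y = ctr$y,
                    class_code = as.vector(lc$values))
  pts <- allocate_roles(pts[sample(nrow(pts), 400), ])
  clf <- train_classifier(stack, pts, ntree = 200, seed = 5)
  classified <- classify_raster(stack, clf)
  cm <- confusion_matrix(classified, pts)
  acc <- accuracy_summary(cm)
  expect_gte(acc$overall, 95)
})

test_that("classifier training is deterministic given the seed and rejects degenerate input", {
  stack <- make_stack(0, bands = 12)
  stack$bands[, , 1] <- matrix(runif(144), 12, 12)
  pts <- data.frame(x = runif(30, 0, 360), y = runif(30, 0, 360),
                    class_code = rep(1:2, 15))
  c1 <- train_classifier(stack, pts, ntree = 50, seed = 9)
  c2 <- train_classifier(stack, pts, ntree = 50, seed = 9)
  expect_identical(stats::predict(c1$forest, matrix(runif(12), 1, 12,
                     dimnames = list(NULL, stack$band_names))),
                   stats::predict(c2$forest, matrix(runif(12), 1, 12,
                     dimnames = list(NULL, stack$band_names))))
  pts1 <- pts; pts1$class_code <- 1
  expect_error(train_classifier(stack, pts1), "two classes")
  far <- pts; far$x[1] <- 1e6
  expect_error(train_classifier(stack, far), "off-grid")
})

test_that("constant stacks classify to a single class; masked pixels to nodata", {
  set.seed(4)
  stack <- make_stack(0, bands = 12)
  for (k in 1:12) stack$bands[, , k] <- runif(144, 0, 100)
  pts <- data.frame(x = runif(40, 0, 360), y = runif(40, 0, 360),
                    class_code = rep(c(2L, 3L), 20))
  # make class 2/3 separable on band 5
  idx <- grazescape:::cell_index(lc_raster(matrix(0L, 12, 12), 30), pts$x, pts$y)
  b5 <- stack$bands[, , 5]
  b5[cbind(idx$row, idx$col)] <- ifelse(pts$class_code == 2, 10, 90)
  stack$bands[, , 5] <- b5
  clf <- train_classifier(stack, pts, ntree = 100, seed = 2)
  const <- make_stack(0, bands = 12)
  const$bands[, , 5] <- 10
  out <- classify_raster(const, clf)
  expect_true(all(out$values == 2L))
  const$mask[1, 1] <- FALSE
  out2 <- classify_raster(const, clf)
  expect_true(is.na(out2$values[1, 1]))
  bad <- make_stack(0, bands = 5)
  expect_error(classify_raster(bad, clf), "does not match")
})

test_that("confusion matrix of a perfect classification is diagonal", {
  lc <- lc_raster(matrix(rep(1:4, each = 25), 10, 10), cellsize = 30)
  ctr <- grazescape:::pixel_centres(lc)
  val <- data.frame(x = ctr$x, y = ctr$y, class_code = as.vector(lc$values))
  cm <- confusion_matrix(lc, val)
  expect_true(all(cm[upper.tri(cm) | lower.tri(cm)] == 0))
  expect_equal(unname(colSums(cm)), as.vector(table(val$class_code)))
  expect_error(confusion_matrix(lc, val[0, ]), "empty")
})

test_that("accuracy summary handles identity, permutation and empty classes", {
  id <- diag(5); dimnames(id) <- list(1:5, 1:5)
  acc <- accuracy_summary(id)
  expect_equal(acc$overall, 100)
  expect_true(all(acc$users == 100) && all(acc$producers == 100))
  cm <- savanna_validation_matrix()
  perm <- sample(nrow(cm))
  expect_equal(accuracy_summary(cm[perm, perm])$overall,
               accuracy_summary(cm)$overall)
  z <- matrix(c(5, 0, 0, 0), 2, 2, dimnames = list(1:2, 1:2))
  accz <- accuracy_summary(z)
  expect_true(is.na(accz$users["2"]) && is.na(accz$producers["2"]))
  expect_error(accuracy_summary(matrix(0, 2, 2)), "empty")
})
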