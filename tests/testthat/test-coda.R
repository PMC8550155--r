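test_that("clr transform matches hand evaluation and is scale invariant", {
  # symmetric composition maps to zero
  x <- composition_series(matrix(1, 3, 4))
  expect_equal(clr_transform(x)$values, matrix(0, 3, 4),
               ignore_attr = TRUE)
  # (e, 1, 1) -> (2/3, -1/3, -1/3)
  y <- clr_transform(matrix(c(exp(1), 1, 1), 1, 3))
  expect_equal(drop(y$values), c(2 / 3, -1 / 3, -1 / 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  # per-time rescaling leaves log-ratios unchanged
  set.seed(1)
  m <- matrix(rexp(40) + 0.05, 10, 4)
  expect_equal(clr_transform(7.3 * m)$values, clr_transform(m)$values,
               tolerance = 1e-12)
  # rows sum to zero
  expect_lt(max(abs(rowSums(clr_transform(m)$values))), 1e-10)
})

test_that("nonpositive entries raise an error naming the offender", {
  m <- matrix(1, 4, 3)
  m[3, 2] <- 0
  expect_error(composition_series(m), "time index 3.*part 2")
  expect_error(closure(c(1, -1)), "positive")
})

test_that("replace_nonpositive repairs zeros loudly and preserves totals", {
  m <- matrix(c(1, 2, 0, 4, 5, 6), 2, 3)
  expect_message(r <- replace_nonpositive(m), "imputing 1 nonpositive")
  expect_true(all(r > 0))
  expect_equal(rowSums(r), rowSums(m))
  # strictly positive input passes through untouched
  expect_identical(replace_nonpositive(abs(m) + 1), abs(m) + 1)
})

test_that("pivot contrast matrix matches the closed form and is orthonormal", {
  expect_equal(make_pivot_contrast_matrix(2),
               matrix(sqrt(1 / 2) * c(1, -1), 2, 1), ignore_attr = TRUE)
  V3 <- make_pivot_contrast_matrix(3)
  expect_equal(V3,
               cbind(sqrt(2 / 3) * c(1, -1 / 2, -1 / 2),
                     sqrt(1 / 2) * c(0, 1, -1)),
               tolerance = 1e-12, ignore_attr = TRUE)
  for (p in 2:9) {
    V <- make_pivot_contrast_matrix(p)
    expect_lt(max(abs(crossprod(V) - diag(p - 1))), 1e-10)
    expect_lt(max(abs(colSums(V))), 1e-10)
  }
  expect_error(make_pivot_contrast_matrix(1), "integer >= 2")
})

test_that("ilr coordinates match the pivot formula", {
  # p = 2: sqrt(1/2) ln(e^2/1) = sqrt(2)
  y <- ilr_transform(matrix(c(exp(2), 1), 1, 2))
  expect_equal(drop(y$values), sqrt(2), tolerance = 1e-12)
  # neutral composition -> zero vector
  expect_equal(ilr_transform(matrix(1, 2, 5))$values, matrix(0, 2, 4),
               ignore_attr = TRUE)
  # first pivot coordinate = sqrt(p/(p-1)) clr_1, and the direct pivot
  # formula agrees with V' clr to 1e-10
  set.seed(2)
  p <- 5
  m <- matrix(rexp(20 * p) + 0.05, 20, p)
  ilr <- ilr_transform(m)$values
  clr <- clr_transform(m)$values
  expect_equal(ilr[, 1], sqrt(p / (p - 1)) * clr[, 1], tolerance = 1e-10)
  direct <- sapply(seq_len(p - 1), function(i) {
    gm <- exp(rowMeans(log(m[, (i + 1):p, drop = FALSE])))
    sqrt((p - i) / (p - i + 1)) * log(m[, i] / gm)
  })
  expect_equal(ilr, direct, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("clr = V ilr and ilr = V' clr (the basis link) hold exactly", {
  set.seed(3)
  for (p in c(3, 6)) {
    m <- matrix(rexp(15 * p) + 0.05, 15, p)
    V <- make_pivot_contrast_matrix(p)
    clr <- clr_transform(m)$values
    ilr <- ilr_transform(m)$values
    expect_lt(max(abs(clr - ilr %*% t(V))), 1e-10)
    expect_lt(max(abs(ilr - clr %*% V)), 1e-10)
  }
})

test_that("ilr round trips and hand inversion", {
  # zero coordinates -> uniform composition
  u <- ilr_inverse(matrix(0, 1, 3))
  expect_equal(drop(u$values), rep(1 / 4, 4), ignore_attr = TRUE)
  # p = 2 hand inversion of y = sqrt(2)
  inv <- ilr_inverse(matrix(sqrt(2), 1, 1))
  expect_equal(drop(inv$values),
               c(exp(2) / (exp(2) + 1), 1 / (exp(2) + 1)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # x -> ilr -> inverse = closure(x); ilr(inverse(y)) = y
  set.seed(4)
  m <- matrix(rexp(12 * 4) + 0.05, 12, 4)
  back <- ilr_inverse(ilr_transform(m))
  expect_equal(back$values, closure(m), tolerance = 1e-8,
               ignore_attr = TRUE)
  y <- matrix(rnorm(12 * 3), 12, 3)
  expect_equal(ilr_transform(ilr_inverse(y))$values, y, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("closure rescales, is idempotent, and transforms ignore it", {
  expect_equal(closure(c(2, 2)), c(0.5, 0.5))
  expect_equal(closure(c(1, 2, 7)), c(0.1, 0.2, 0.7))
  v <- c(0.3, 1.2, 4.5)
  expect_equal(closure(closure(v)), closure(v))
})

test_that("two orthonormal bases give ilr series related by V2' V1", {
  set.seed(5)
  p <- 4
  m <- matrix(rexp(30 * p) + 0.05, 30, p)
  V1 <- make_pivot_contrast_matrix(p)
  R <- rand_orth(p - 1)
  V2 <- V1 %*% R                       # still orthonormal, zero colsums
  y1 <- ilr_transform(m, basis = V1)$values
  y2 <- ilr_transform(m, basis = V2)$values
  expect_lt(max(abs(y2 - y1 %*% (t(V1) %*% V2))), 1e-10)
})

test_that("CSV round trip preserves values, gaps and the sidecar basis", {
  set.seed(6)
  m <- matrix(rexp(10 * 3) + 0.05, 10, 3)
  ts <- c(1:4, 7:12)                    # gap between 4 and 7
  x <- composition_series(m, ts, parts = c("a", "b", "c"))
  f <- tempfile(fileext = ".csv")
  write_series_csv(x, f)
  x2 <- read_composition_csv(f)
  expect_equal(x2$values, x$values, tolerance = 1e-12)
  expect_equal(x2$timestamps, x$timestamps)
  expect_equal(x2$parts, x$parts)
  y <- ilr_transform(x)
  fy <- tempfile(fileext = ".csv")
  write_series_csv(y, fy)
  side <- jsonlite::read_json(paste0(fy, ".json"), simplifyVector = TRUE)
  expect_equal(side$space, "ilr")
  expect_equal(as.matrix(side$basis), y$basis, tolerance = 1e-12,
               ignore_attr = TRUE)
  unlink(c(f, fy, paste0(fy, ".json")))
})

test_that("datetime timestamps map onto the declared grid", {
  tt <- as.POSIXct("2014-01-14 14:20:00", tz = "UTC") +
    60 * 10 * c(0, 1, 2, 5, 6)          # 10-min grid, 2 missing points
  df <- data.frame(time = format(tt, "%Y-%m-%d %H:%M:%S"),
                   a = 1:5, b = c(2, 2, 3, 1, 5))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  x <- read_composition_csv(f, grid = "10 min")
  expect_equal(x$timestamps, c(1, 2, 3, 6, 7))
  expect_error(read_composition_csv(f), "grid")
  unlink(f)
})
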