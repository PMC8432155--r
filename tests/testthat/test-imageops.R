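test_that("median filter matches direct computation on a small image", {
  set.seed(11)
  img <- matrix(sample(0:255, 15 * 12, TRUE), 15, 12)
  out <- median_filter_disc(img, 3)
  # direct recomputation with explicit reflection at a handful of pixels
  offs <- expand.grid(dr = -3:3, dc = -3:3)
  offs <- offs[offs$dr^2 + offs$dc^2 <= 9, ]
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  for (px in list(c(1, 1), c(8, 6), c(15, 12), c(2, 11))) {
    vals <- mapply(function(dr, dc) {
      img[reflect(px[1] + dr, 15), reflect(px[2] + dc, 12)]
    }, offs$dr, offs$dc)
    expect_equal(out[px[1], px[2]], median(vals))
  }
})

test_that("connected labeling, hole filling and distance transform behave", {
  m <- matrix(FALSE, 9, 9)
  m[2:4, 2:4] <- TRUE
  m[6:8, 6:8] <- TRUE
  m[3, 3] <- FALSE              # a hole
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_true(all(lab[2:4, 2:4][m[2:4, 2:4]] == 1))
  filled <- fill_holes(m)
  expect_true(filled[3, 3])
  expect_equal(sum(filled) - sum(m), 1)
  # diagonal touch: 8-connectivity joins, 4-connectivity separates
  d <- matrix(FALSE, 4, 4)
  d[1, 1] <- TRUE; d[2, 2] <- TRUE
  expect_equal(max(label_components(d, 8)), 1)
  expect_equal(max(label_components(d, 4)), 2)
  # EDT: single interior pixel of a 3x3 block is 1 away from background
  b <- matrix(FALSE, 7, 7)
  b[3:5, 3:5] <- TRUE
  dt <- distance_transform(b)
  expect_equal(dt[4, 4], 2)     # nearest FALSE pixel is 2 steps away
  expect_equal(dt[3, 3], 1)
  expect_true(all(dt[!b] == 0))
  # against brute force on a random mask
  set.seed(3)
  rb <- matrix(runif(100) > 0.4, 10, 10)
  rb[1, 1] <- FALSE
  dt2 <- distance_transform(rb)
  bgi <- which(!rb)
  bgr <- (bgi - 1) %% 10 + 1; bgc <- (bgi - 1) %/% 10 + 1
  for (i in which(rb)) {
    r <- (i - 1) %% 10 + 1; c <- (i - 1) %/% 10 + 1
    expect_equal(dt2[r, c], min(sqrt((bgr - r)^2 + (bgc - c)^2)))
  }
})

test_that("find_maxima handles the canonical cases", {
  flat <- matrix(500, 20, 20)
  expect_equal(nrow(find_maxima(flat, NULL, 150)), 0)
  # single Gaussian peak, amplitude 3000 on background 500
  g <- matrix(500, 21, 21)
  for (r in 1:21) for (c in 1:21)
    g[r, c] <- g[r, c] + 3000 * exp(-((r - 11)^2 + (c - 11)^2) / 8)
  calls <- find_maxima(g, NULL, 150)
  expect_equal(nrow(calls), 1)
  expect_equal(c(calls$row, calls$col), c(11, 11))
  # plateau: single representative at topmost-then-leftmost pixel
  p <- matrix(0, 8, 8)
  p[4:5, 3:5] <- 10
  calls <- find_maxima(p, NULL, 2)
  expect_equal(nrow(calls), 1)
  expect_equal(c(calls$row, calls$col), c(4, 3))
  # two peaks on a ridge; the connecting saddle sits at the lowest ridge
  # pixel between them (col 5: 400*exp(-25/50) ~ 242.6), so the lower
  # peak's prominence is 1000 - 242.6 ~ 757
  tw <- matrix(0, 10, 20)
  for (c in 1:20) tw[5, c] <- 400 * exp(-(c - 10)^2 / 50)
  tw[5, 4] <- 1000; tw[5, 16] <- 2000
  expect_equal(nrow(find_maxima(tw, NULL, 500)), 2)
  expect_equal(nrow(find_maxima(tw, NULL, 800)), 1)
  # mask restriction: only masked pixels are considered
  msk <- matrix(FALSE, 10, 20)
  msk[, 1:8] <- TRUE
  calls <- find_maxima(tw, msk, 150)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$col, 4)
})

test_that("find_maxima equals the flood oracle on random images", {
  set.seed(42)
  for (i in 1:40) {
    img <- matrix(sample(0:30, 100, TRUE), 10, 10)
    mask <- matrix(sample(c(TRUE, TRUE, TRUE, FALSE), 100, TRUE), 10, 10)
    for (tol in c(1, 5, 12)) {
      got <- find_maxima(img, mask, tol)
      want <- oracle_find_maxima(img, mask, tol)
      expect_equal(got$row, want$row, info = sprintf("i=%d tol=%d", i, tol))
      expect_equal(got$col, want$col, info = sprintf("i=%d tol=%d", i, tol))
      expect_equal(got$prominence, want$prominence,
                   info = sprintf("i=%d tol=%d", i, tol))
    }
  }
})

test_that("accepted maxima are monotone decreasing in tolerance", {
  set.seed(7)
  for (i in 1:20) {
    img <- matrix(sample(0:100, 144, TRUE), 12, 12)
    prev <- NULL
    for (tol in c(1, 5, 20, 60)) {
      calls <- find_maxima(img, NULL, tol)
      key <- paste(calls$row, calls$col)
      if (!is.null(prev)) expect_true(all(key %in% prev))
      prev <- key
    }
  }
})
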