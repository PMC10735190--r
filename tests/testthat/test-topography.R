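make_rec <- function(data, id = "S01", cond = "rest", fs = 100) {
  structure(list(subject_id = id, condition = cond, fs = fs,
                 channel_labels = montage_1020(), data = data),
            class = "eeg_recording")
}

test_that("pair normalization is scale-invariant and preserves power ratios", {
  set.seed(1)
  rest <- make_rec(matrix(rnorm(19 * 400), 19))
  task <- rest
  task$condition <- "task"
  task$data <- sqrt(2) * task$data   # task power exactly 2x rest

  n1 <- normalize_pair(rest, task)
  scaled <- rest; scaled$data <- 7 * scaled$data
  stask <- task; stask$data <- 7 * stask$data
  n2 <- normalize_pair(scaled, stask)
  expect_equal(n1$rest$data, n2$rest$data, tolerance = 1e-12)

  ratio <- rowMeans(n1$task$data^2) / rowMeans(n1$rest$data^2)
  expect_lt(max(abs(ratio - 2)), 1e-6)

  # identical rest/task: both end up unit variance per channel
  nid <- normalize_pair(rest, { r <- rest; r$condition <- "task"; r })
  v <- apply(cbind(nid$rest$data, nid$task$data), 1, stats::sd)
  expect_lt(max(abs(v - 1)), 1e-12)

  flat <- rest; flat$data[3, ] <- 5
  ftask <- task; ftask$data[3, ] <- 5
  expect_error(normalize_pair(flat, ftask), "degenerate channel")
})

test_that("channel power matches closed forms", {
  t <- (0:9999) / 100
  sine <- make_rec(matrix(rep(sin(2 * pi * 5 * t), 19), 19, byrow = TRUE))
  expect_lt(max(abs(channel_power(sine)$power - 0.5)), 1e-4)
  zeros <- make_rec(matrix(0, 19, 100))
  expect_equal(unname(channel_power(zeros)$power), rep(0, 19))
  set.seed(2)
  wn <- make_rec(matrix(rnorm(19 * 20000, sd = 3), 19))
  se <- sqrt(2 * 3^4 / 20000)   # SE of the mean of squares for N(0, 9)
  expect_lt(max(abs(channel_power(wn)$power - 9)), 3 * se * 1.5)
  # invariant under sample reordering
  perm <- wn; perm$data <- wn$data[, sample(ncol(wn$data))]
  expect_equal(channel_power(perm)$power, channel_power(wn)$power)
})

test_that("grand averages reduce correctly", {
  man <- data.frame(subject_id = c("A", "B"), X = c(5, 20),
                    group = c("BAD", "GOOD"), stringsAsFactors = FALSE)
  p1 <- structure(list(subject_id = "A", condition = "rest",
                       power = setNames(1:19, montage_1020())),
                  class = "channel_power")
  ga <- grand_average(list(p1), man)
  expect_equal(as.numeric(ga[1, montage_1020()]), 1:19)
  ga2 <- grand_average(list(p1, p1), man)   # two identical entries, same mean
  expect_equal(as.numeric(ga2[1, montage_1020()]), 1:19)
  bad <- p1; bad$subject_id <- "Z"
  expect_error(grand_average(list(bad), man), "missing from manifest")
})

test_that("topomap interpolation is exact, constant-preserving and localized", {
  tm <- render_topomap(rep(4.2, 19), grid_n = 24)
  expect_equal(range(tm$grid, na.rm = TRUE), c(4.2, 4.2))
  # mask: corners outside the head circle are NA
  expect_true(is.na(tm$grid[1, 1]))

  set.seed(3)
  v <- runif(19)
  tm2 <- render_topomap(v, grid_n = 24)
  pos <- electrode_positions()
  expect_lt(max(abs(topomap_at(tm2, pos$x, pos$y) - v)), 1e-6)

  hot <- rep(0, 19); hot[which(montage_1020() == "Cz")] <- 10
  tmh <- render_topomap(hot, grid_n = 65)   # odd grid: cell exactly at origin
  peak <- which(tmh$grid == max(tmh$grid, na.rm = TRUE), arr.ind = TRUE)
  expect_lt(abs(tmh$x[peak[2]]), 2 / 64 + 1e-9)
  expect_lt(abs(tmh$y[peak[1]]), 2 / 64 + 1e-9)

  expect_error(render_topomap(rep(1, 18)), "mismatch")
})

test_that("image similarity is reflexive, symmetric and matches a direct oracle", {
  set.seed(4)
  v <- runif(19)
  a <- render_topomap(v, grid_n = 24)
  b <- render_topomap(v + rnorm(19, sd = 0.2), grid_n = 24)
  expect_equal(image_similarity(a, a), 1)
  expect_equal(image_similarity(a, b), image_similarity(b, a))

  # closed-form oracle on unmasked 8x8 fields: constant vs constant plus a
  # fixed-contrast checkerboard, SSIM evaluated directly per window
  ga <- matrix(0.5, 8, 8)
  gb <- 0.5 + 0.25 * outer(1:8, 1:8, function(i, j) (-1)^(i + j))
  # min-max rescaling maps ga to all-zero (flat) and gb to {0,1}
  ra <- matrix(0, 8, 8); rb <- (gb - min(gb)) / diff(range(gb))
  C1 <- 1e-4; C2 <- 9e-4
  oracle <- mean(sapply(1:8, function(i) sapply(1:8, function(j) {
    ri <- max(1, i - 3):min(8, i + 3); rj <- max(1, j - 3):min(8, j + 3)
    wa <- ra[ri, rj]; wb <- rb[ri, rj]
    mua <- mean(wa); mub <- mean(wb)
    va <- mean((wa - mua)^2); vb <- mean((wb - mub)^2)
    cab <- mean((wa - mua) * (wb - mub))
    (2 * mua * mub + C1) * (2 * cab + C2) /
      ((mua^2 + mub^2 + C1) * (va + vb + C2))
  })))
  expect_equal(image_similarity(ga, gb), oracle, tolerance = 1e-12)

  mism <- render_topomap(v, grid_n = 16)
  expect_error(image_similarity(a, mism), "do not match")
})

test_that("similarity degrades monotonically with added noise", {
  set.seed(5)
  v <- runif(19)
  base <- render_topomap(v, grid_n = 24)
  sims <- vapply(c(0.05, 0.3, 1.5), function(sd_noise) {
    mean(vapply(1:5, function(s) {
      set.seed(100 * sd_noise + s)
      image_similarity(base, render_topomap(v + rnorm(19, sd = sd_noise),
                                            grid_n = 24))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sims) < 0))
})
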