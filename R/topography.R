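#' @title Channel power, scalp topography and image similarity
#' @name topography
#' @description
#' Per-channel mean signal power (microvolt squared), group-wise grand
#' averages, thin-plate-spline interpolation of the 19 electrode values
#' onto a unit head disc, and a structural-similarity index (SSIM) between
#' two such maps — higher means the rest and task power distributions look
#' more alike.
NULL

#' Normalize a subject's rest/task recording pair
#'
#' Each channel of both conditions is divided by that subject-channel's SD
#' computed over the concatenated rest + task samples. The shared scale
#' removes inter-subject amplitude differences while preserving the
#' rest/task power ratio within each channel (a per-condition
#' standardization would destroy exactly the contrast of interest).
#'
#' @param rest,task The two `eeg_recording`s of one subject.
#' @return List with normalized `rest` and `task` recordings.
#' @export
normalize_pair <- function(rest, task) {
  stopifnot(inherits(rest, "eeg_recording"), inherits(task, "eeg_recording"))
  if (!identical(rest$channel_labels, task$channel_labels))
    stop("rest and task recordings have different montages", call. = FALSE)
  for (ch in seq_len(nrow(rest$data))) {
    s <- stats::sd(c(rest$data[ch, ], task$data[ch, ]))
    if (s == 0) stop("degenerate channel (zero variance): ",
                     rest$channel_labels[ch], call. = FALSE)
    rest$data[ch, ] <- rest$data[ch, ] / s
    task$data[ch, ] <- task$data[ch, ] / s
  }
  list(rest = rest, task = task)
}

#' Per-channel mean signal power
#'
#' @param rec An `eeg_recording`.
#' @return Object of class `channel_power`: list with `subject_id`,
#'   `condition` and `power` (named vector, mean squared amplitude per
#'   channel).
#' @export
channel_power <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(rec$data) == 0L) stop("recording has no samples", call. = FALSE)
  structure(list(subject_id = rec$subject_id, condition = rec$condition,
                 power = rowMeans(rec$data^2)),
            class = "channel_power")
}

#' Group-wise grand-averaged channel power
#'
#' @param powers List of `channel_power` objects (all subjects, both
#'   conditions).
#' @param manifest Manifest mapping `subject_id` to `group`.
#' @return Data frame: one row per (group, condition) with the 19 mean
#'   power columns.
#' @export
grand_average <- function(powers, manifest) {
  groups <- manifest$group[match(vapply(powers, `[[`, "", "subject_id"),
                                 manifest$subject_id)]
  if (anyNA(groups)) stop("subject missing from manifest", call. = FALSE)
  conds <- vapply(powers, `[[`, "", "condition")
  key <- split(seq_along(powers), paste(groups, conds, sep = "."))
  if (any(vapply(key, length, 0L) == 0L)) stop("empty group", call. = FALSE)
  rows <- lapply(names(key), function(k) {
    mat <- do.call(rbind, lapply(powers[key[[k]]], `[[`, "power"))
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    cbind(data.frame(group = parts[1], condition = parts[2],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(colMeans(mat)), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Thin-plate spline kernel U(r) = r^2 log r, with U(0) = 0.
.tps_kernel <- function(r) ifelse(r > 0, r^2 * log(r), 0)

#' Interpolate electrode values onto a head-disc grid
#'
#' Exact thin-plate-spline interpolation (affine part plus `r^2 log r`
#' radial terms) of the 19 channel values over a `grid_n` x `grid_n` grid
#' spanning \[-1, 1\]^2; cells outside the unit head circle are `NA`.
#'
#' @param values Named (or montage-ordered) numeric vector of 19 channel
#'   values.
#' @param coords Electrode coordinates (data frame with `x`, `y`; default
#'   the bundled 10/20 projection).
#' @param grid_n Grid resolution per axis (default 64).
#' @return Object of class `topomap`: list with `grid` (matrix, rows = y
#'   from top), `x`, `y` axes, `coords`, `values`.
#' @export
render_topomap <- function(values, coords = electrode_positions(), grid_n = 64L) {
  if (length(values) != nrow(coords))
    stop("value/coordinate count mismatch: ", length(values), " values vs ",
         nrow(coords), " electrodes", call. = FALSE)
  p <- nrow(coords)
  xy <- as.matrix(coords[, c("x", "y")])
  d <- as.matrix(stats::dist(xy))
  K <- .tps_kernel(d)
  P <- cbind(1, xy)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(as.numeric(values), 0, 0, 0)
  wa <- solve(A, rhs)
  w <- wa[seq_len(p)]; a <- wa[p + 1:3]
  gx <- seq(-1, 1, length.out = grid_n)
  gy <- seq(1, -1, length.out = grid_n)
  grid <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n)) {
    for (j in seq_len(grid_n)) {
      if (gx[j]^2 + gy[i]^2 > 1) next
      r <- sqrt((gx[j] - xy[, 1])^2 + (gy[i] - xy[, 2])^2)
      grid[i, j] <- a[1] + a[2] * gx[j] + a[3] * gy[i] + sum(w * .tps_kernel(r))
    }
  }
  structure(list(grid = grid, x = gx, y = gy, coords = coords,
                 values = as.numeric(values)),
            class = "topomap")
}

#' Evaluate a topomap's interpolant at arbitrary points
#'
#' @param map A `topomap`.
#' @param x,y Coordinates on the unit disc.
#' @return Interpolated values (exact at the electrodes).
#' @export
topomap_at <- function(map, x, y) {
  xy <- as.matrix(map$coords[, c("x", "y")])
  p <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  A <- rbind(cbind(.tps_kernel(d), cbind(1, xy)),
             cbind(t(cbind(1, xy)), matrix(0, 3, 3)))
  wa <- solve(A, c(map$values, 0, 0, 0))
  w <- wa[seq_len(p)]; a <- wa[p + 1:3]
  vapply(seq_along(x), function(k) {
    r <- sqrt((x[k] - xy[, 1])^2 + (y[k] - xy[, 2])^2)
    a[1] + a[2] * x[k] + a[3] * y[k] + sum(w * .tps_kernel(r))
  }, numeric(1))
}

#' Structural-similarity image index between two topomaps
#'
#' Mean SSIM over the unmasked head disc, computed with a sliding uniform
#' `win` x `win` window (standard constants `C1 = (0.01)^2`,
#' `C2 = (0.03)^2`) after min-max rescaling each field to \[0, 1\]. Window
#' statistics use only unmasked cells; centers outside the disc are
#' skipped. Symmetric, and exactly 1 for identical maps.
#'
#' @param a,b `topomap` objects on identical grids/masks.
#' @param win Window side length (default 7).
#' @return Scalar similarity in \[-1, 1\].
#' @export
image_similarity <- function(a, b, win = 7L) {
  ga <- if (inherits(a, "topomap")) a$grid else as.matrix(a)
  gb <- if (inherits(b, "topomap")) b$grid else as.matrix(b)
  if (!all(dim(ga) == dim(gb)) || !identical(is.na(ga), is.na(gb)))
    stop("topomap grids/masks do not match", call. = FALSE)
  rescale <- function(g) {
    rng <- range(g, na.rm = TRUE)
    if (diff(rng) == 0) g - rng[1] else (g - rng[1]) / diff(rng)
  }
  ga <- rescale(ga); gb <- rescale(gb)
  C1 <- 0.01^2; C2 <- 0.03^2
  h <- (win - 1L) %/% 2L
  nr <- nrow(ga); nc <- ncol(ga)
  ssim_vals <- c()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (is.na(ga[i, j])) next
      ri <- max(1L, i - h):min(nr, i + h)
      rj <- max(1L, j - h):min(nc, j + h)
      wa <- ga[ri, rj]; wb <- gb[ri, rj]
      ok <- !is.na(wa)
      if (sum(ok) < 2L) next
      wa <- wa[ok]; wb <- wb[ok]
      mua <- mean(wa); mub <- mean(wb)
      va <- mean((wa - mua)^2); vb <- mean((wb - mub)^2)
      cab <- mean((wa - mua) * (wb - mub))
      ssim_vals <- c(ssim_vals,
                     ((2 * mua * mub + C1) * (2 * cab + C2)) /
                       ((mua^2 + mub^2 + C1) * (va + vb + C2)))
    }
  }
  mean(ssim_vals)
}

#' Plot a topomap
#'
#' @param x A `topomap`.
#' @param main Title.
#' @param ... Passed to [graphics::image()].
#' @export
plot.topomap <- function(x, main = "", ...) {
  graphics::image(x$x, rev(x$y), t(x$grid[nrow(x$grid):1, ]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  asp = 1, xlab = "", ylab = "", main = main, axes = FALSE, ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th))
  graphics::points(x$coords$x, x$coords$y, pch = 20, cex = 0.6)
  invisible(x)
}

#' Bar chart of rest-vs-task grand-averaged channel power
#'
#' @param ga One group's rows of the [grand_average()] output.
#' @param main Title.
#' @export
plot_channel_power <- function(ga, main = "") {
  chans <- montage_1020()
  m <- as.matrix(ga[, chans, drop = FALSE])
  rownames(m) <- ga$condition
  graphics::barplot(m, beside = TRUE, las = 2, main = main,
                    ylab = "mean power", legend.text = rownames(m))
  invisible(ga)
}
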