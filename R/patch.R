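# Landmark-based palm patch extraction: deltas, patch size, cropping and
# resizing to the network input side.

#' Landmark deltas
#'
#' Horizontal and vertical palm extents `delta_x = x1 - x2`,
#' `delta_y = y1 - y2`; both must come out positive under the landmark
#' convention (`x1 > x2`, `y1 > y2`).
#'
#' @param x1,x2,y1,y2 landmark pixel coordinates.
#' @return list with `delta_x`, `delta_y`.
#' @export
compute_deltas <- function(x1, x2, y1, y2) {
  dx <- x1 - x2
  dy <- y1 - y2
  if (dx <= 0 || dy <= 0)
    stop("landmark convention violated: need x1 > x2 and y1 > y2 ",
         "(deltas must be positive)")
  list(delta_x = dx, delta_y = dy)
}

#' Palm patch size
#'
#' The side of the square palm patch: the larger of the two landmark
#' deltas, rounded up to an integer so the palm is always covered.
#'
#' @param delta_x,delta_y positive landmark deltas.
#' @return integer patch side in pixels.
#' @export
compute_psize <- function(delta_x, delta_y) {
  if (delta_x <= 0 || delta_y <= 0) stop("deltas must be positive")
  as.integer(ceiling(max(delta_x, delta_y)))
}

#' Patch geometry for one record
#'
#' @param x1,x2,y1,y2 landmarks.
#' @param size patch side; defaults to the record's own patch size.
#' @return list with `delta_x`, `delta_y`, `p_size` and the half-open
#'   square `crop_box` `(row_min, col_min, row_max, col_max)` centered on
#'   the landmark bounding-box midpoint.
#' @export
patch_spec <- function(x1, x2, y1, y2, size = NULL) {
  d <- compute_deltas(x1, x2, y1, y2)
  p <- compute_psize(d$delta_x, d$delta_y)
  size <- as.integer(size %||% p)
  cr <- (y1 + y2) / 2
  cc <- (x1 + x2) / 2
  row_min <- as.integer(round(cr - size / 2 + 0.5))
  col_min <- as.integer(round(cc - size / 2 + 0.5))
  list(delta_x = d$delta_x, delta_y = d$delta_y, p_size = p,
       crop_box = c(row_min = row_min, col_min = col_min,
                    row_max = row_min + size, col_max = col_min + size))
}

#' Patch-size statistics over a dataset
#'
#' Per-record patch sizes, their histogram, and the dataset-level input
#' size chosen as the smallest integer at or above the requested coverage
#' quantile of the distribution (default: cover every record), optionally
#' capped by a hard limit.
#'
#' @param rs a [record_set()].
#' @param coverage quantile of records the chosen size must cover,
#'   in (0, 1]; default 1.
#' @param hard_limit optional cap on the chosen size in pixels.
#' @return list with `p_sizes`, `histogram` (`breaks`, `counts`),
#'   `chosen_global_size`, `coverage`.
#' @export
dataset_psize_stats <- function(rs, coverage = 1, hard_limit = NULL) {
  if (!length(rs$records)) stop("empty record set")
  if (coverage <= 0 || coverage > 1) stop("coverage must lie in (0, 1]")
  p <- vapply(rs$records, function(r) {
    d <- compute_deltas(r$x1, r$x2, r$y1, r$y2)
    as.numeric(compute_psize(d$delta_x, d$delta_y))
  }, 0)
  q <- stats::quantile(p, coverage, type = 1, names = FALSE)
  chosen <- as.integer(ceiling(q))
  if (!is.null(hard_limit)) chosen <- min(chosen, as.integer(hard_limit))
  h <- graphics::hist(p, plot = FALSE)
  list(p_sizes = p,
       histogram = list(breaks = h$breaks, counts = h$counts),
       chosen_global_size = chosen, coverage = coverage)
}

#' Extract the palm-centered square patch
#'
#' Crops a `size x size` window centered on the midpoint of the landmark
#' bounding box; regions falling outside the image are zero-padded (the
#' background carries no signal, so padding must not invent any).
#'
#' @param image `(H, W, 3)` array or `(H, W)` matrix (e.g. a mask).
#' @param landmarks list or named vector with `x1`, `x2`, `y1`, `y2`.
#' @param size patch side in pixels (>= 1).
#' @return patch of the same channel layout, with attribute `offset`
#'   `(row, col)` such that `patch coordinate = image coordinate - offset`.
#' @export
extract_patch <- function(image, landmarks, size) {
  size <- as.integer(size)
  if (size < 1L) stop("patch size must be at least 1 pixel")
  lm <- as.list(landmarks)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  if (lm$x1 < 1 || lm$x2 > W || lm$y1 < 1 || lm$y2 > H)
    stop("landmarks lie entirely outside the image")
  sp <- patch_spec(lm$x1, lm$x2, lm$y1, lm$y2, size = size)
  r0 <- sp$crop_box[["row_min"]]; c0 <- sp$crop_box[["col_min"]]
  rows <- r0:(r0 + size - 1L)
  cols <- c0:(c0 + size - 1L)
  rk <- which(rows >= 1L & rows <= H)
  ck <- which(cols >= 1L & cols <= W)
  if (length(d) == 3L) {
    patch <- array(0, c(size, size, d[3]))
    if (length(rk) && length(ck))
      patch[rk, ck, ] <- image[rows[rk], cols[ck], , drop = FALSE]
  } else {
    patch <- matrix(0, size, size)
    if (length(rk) && length(ck))
      patch[rk, ck] <- image[rows[rk], cols[ck], drop = FALSE]
  }
  attr(patch, "offset") <- c(row = r0 - 1L, col = c0 - 1L)
  patch
}

#' Bilinear image resize
#'
#' @param image `(H, W, C)` array or `(H, W)` matrix.
#' @param side target square side in pixels.
#' @return resized image of the same channel layout.
#' @export
resize_image <- function(image, side) {
  d <- dim(image)
  x <- if (length(d) == 2L) array(image, c(d, 1L, 1L))
       else array(image, c(d, 1L))
  y <- bilinear_fwd_cpp(x, as.integer(side), as.integer(side))
  if (length(d) == 2L) y[, , 1, 1] else y[, , , 1]
}

#' Assemble model inputs from records
#'
#' Crops every record's palm patch (one common `patch_size`, by default
#' the dataset's full-coverage size) and resizes it to the network input
#' side; ground-truth masks, when present and requested, are cropped and
#' resized the same way and re-thresholded at 0.5.
#'
#' @param rs a [record_set()].
#' @param input_side network input side in pixels.
#' @param patch_size common crop side; `NULL` uses
#'   [dataset_psize_stats()] at full coverage.
#' @param with_masks also return per-record binary masks.
#' @param base_dir directory for relative image paths.
#' @return list with `x` (`(side, side, 3, N)` array), `label_m`,
#'   `label_p`, `ids`, and optionally `mask_m`, `mask_p` (lists of
#'   matrices or `NULL`).
#' @export
prepare_inputs <- function(rs, input_side, patch_size = NULL,
                           with_masks = FALSE, base_dir = NULL) {
  n <- length(rs$records)
  if (!n) stop("empty record set")
  if (is.null(patch_size))
    patch_size <- dataset_psize_stats(rs)$chosen_global_size
  x <- array(0, c(input_side, input_side, 3, n))
  mm <- if (with_masks) vector("list", n)
  mp <- if (with_masks) vector("list", n)
  for (k in seq_len(n)) {
    r <- rs$records[[k]]
    lm <- r[c("x1", "x2", "y1", "y2")]
    patch <- extract_patch(record_image(r, base_dir), lm, patch_size)
    x[, , , k] <- resize_image(patch, input_side)
    if (with_masks) {
      for (side in c("m", "p")) {
        mk <- r[[paste0("mask_", side)]]
        res <- if (is.null(mk) || !any(mk)) NULL else {
          mpatch <- extract_patch(mk * 1, lm, patch_size)
          resize_image(mpatch, input_side) > 0.5
        }
        if (side == "m") mm[k] <- list(res) else mp[k] <- list(res)
      }
    }
  }
  out <- list(x = x,
              label_m = vapply(rs$records, function(r) r$label_m, 0L),
              label_p = vapply(rs$records, function(r) r$label_p, 0L),
              ids = vapply(rs$records, function(r) r$record_id, ""))
  if (with_masks) { out$mask_m <- mm; out$mask_p <- mp }
  out
}
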