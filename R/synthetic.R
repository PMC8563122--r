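# Seeded synthetic palm images. Each record is an elliptical "palm" on a
# dark background, with soft-edged circular intensity anomalies planted
# in the task-specific regions (knuckle band for task M, thenar area for
# task P), pixel noise, optional exclusion-flag contaminants, and exact
# ground-truth masks. The geometry mimics the clinical acquisition
# statistics with everything rescaled to the configured image side.

#' Synthetic-data generator configuration
#'
#' Defaults reproduce the desk-scale study conditions: 400 records,
#' anomaly contrast 0.5 against pixel noise of sd 0.1, class proportions
#' matching the clinical four-class composition, and landmark-delta
#' statistics (mean 423/439, sd 16.26/27.15 horizontally/vertically)
#' rescaled from the acquisition geometry by `image_side / 600` so the
#' palm fills most of the frame.
#'
#' @param n_records number of records.
#' @param image_side square image side in pixels.
#' @param class_proportions fractions of the four `(m, p)` label
#'   combinations, named `"00"`, `"01"`, `"10"`, `"11"`; must sum to 1.
#' @param delta_mean,delta_sd length-2 numeric (x, y): landmark-delta
#'   distribution in pixels at `image_side`; `NULL` uses the rescaled
#'   acquisition statistics.
#' @param lesion_contrast peak added intensity of a planted anomaly, in
#'   `[0, 1]` image units.
#' @param lesion_radius anomaly mask radius in pixels; `NULL` scales with
#'   the image side.
#' @param noise_sd additive Gaussian pixel-noise sd.
#' @param contaminant_rate fraction of records given a random exclusion
#'   flag.
#' @param seed global generator seed; per-record substreams derive from
#'   it by record index, so generation order never matters.
#' @export
generator_config <- function(n_records = 400L, image_side = 96L,
                             class_proportions = c("00" = 537, "01" = 530,
                                                   "10" = 522, "11" = 570) / 2159,
                             delta_mean = NULL, delta_sd = NULL,
                             lesion_contrast = 0.5,
                             lesion_radius = NULL,
                             noise_sd = 0.1,
                             contaminant_rate = 0,
                             seed = 1L) {
  scale <- image_side / 600
  cfg <- list(
    n_records = as.integer(n_records),
    image_side = as.integer(image_side),
    class_proportions = class_proportions,
    delta_mean = delta_mean %||% (c(423, 439) * scale),
    delta_sd = delta_sd %||% (c(16.26, 27.15) * scale),
    lesion_contrast = lesion_contrast,
    lesion_radius = lesion_radius %||% max(3L, round(0.07 * image_side)),
    noise_sd = noise_sd,
    contaminant_rate = contaminant_rate,
    seed = as.integer(seed))
  if (cfg$n_records < 1L) stop("n_records must be at least 1")
  if (abs(sum(cfg$class_proportions) - 1) > 1e-8)
    stop("class_proportions must sum to 1")
  if (!identical(names(cfg$class_proportions), c("00", "01", "10", "11")))
    stop('class_proportions must be named "00", "01", "10", "11"')
  if (cfg$lesion_contrast < 0 || cfg$lesion_contrast > 1)
    stop("lesion_contrast must lie in [0, 1]")
  if (cfg$contaminant_rate < 0 || cfg$contaminant_rate > 1)
    stop("contaminant_rate must lie in [0, 1]")
  structure(cfg, class = "generator_config")
}

# Largest-remainder apportionment of n among the class proportions.
class_counts <- function(n, proportions) {
  exact <- proportions * n
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(proportions))
}

# Soft-edged darkened disc (bruising-like) and the hard mask of pixels
# within the radius. The profile width (sigma = radius / 1.6) keeps the
# mean contrast over the disc above half the peak contrast.
plant_lesion <- function(img, rows, cols, cr, cc, radius, contrast) {
  d2 <- outer((rows - cr)^2, (cols - cc)^2, "+")
  bump <- contrast * exp(-d2 / (2 * (radius / 1.6)^2))
  for (ch in 1:3) img[, , ch] <- img[, , ch] - bump
  list(img = img, mask = d2 <= radius^2)
}

#' Generate one synthetic palm record
#'
#' Fully determined by `seed`: palm geometry, anomaly placement, and
#' noise are all drawn from a local RNG stream. Anomalies are planted in
#' the knuckle band (upper quarter of the palm) when `labels[1] = 1` and
#' in the lower-lateral thenar area when `labels[2] = 1`; their
#' ground-truth masks are attached (absent when the label is 0). Pixel
#' values are quantized to 8 bits so a written PNG reloads identically.
#'
#' @param cfg a [generator_config()].
#' @param labels length-2 binary vector `(m, p)`.
#' @param seed integer seed for this record.
#' @param record_id identifier for the record.
#' @return a [hand_record()] with in-memory image and masks.
#' @export
generate_record <- function(cfg, labels, seed, record_id = "synth-1") {
  stopifnot(length(labels) == 2L, all(labels %in% c(0, 1)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  side <- cfg$image_side
  dx <- max(8, stats::rnorm(1, cfg$delta_mean[1], cfg$delta_sd[1]))
  dy <- max(8, stats::rnorm(1, cfg$delta_mean[2], cfg$delta_sd[2]))
  dx <- min(dx, side - 4); dy <- min(dy, side - 4)
  a <- dx / 2; b <- dy / 2
  mid <- (side + 1) / 2
  cc <- mid + stats::runif(1, -0.03, 0.03) * side
  cr <- mid + stats::runif(1, -0.03, 0.03) * side
  cc <- min(max(cc, a + 1), side - a)
  cr <- min(max(cr, b + 1), side - b)

  rows <- seq_len(side); cols <- seq_len(side)
  e <- outer(((rows - cr) / b)^2, ((cols - cc) / a)^2, "+")
  palm <- pmin(1, pmax(0, (1.06 - e) / 0.12))   # soft ellipse edge

  bg <- 0.10 + stats::runif(1, 0, 0.06)
  skin <- c(0.74, 0.57, 0.47) * (1 + stats::runif(1, -0.05, 0.05))
  img <- array(0, c(side, side, 3))
  for (ch in 1:3) img[, , ch] <- bg * (1 - palm) + skin[ch] * palm

  radius <- cfg$lesion_radius
  # knuckle band: upper quarter of the palm (small row coordinates)
  cm_r <- (cr - b) + 0.13 * dy
  cm_c <- cc + stats::runif(1, -0.15, 0.15) * dx
  # thenar area: lower-lateral third, thumb side (large columns)
  cp_r <- (cr + b) - 0.20 * dy
  cp_c <- cc + (0.28 + stats::runif(1, -0.05, 0.05)) * a
  if (sqrt((cm_r - cp_r)^2 + (cm_c - cp_c)^2) <= 2 * radius)
    stop("lesion_radius too large: task regions would overlap")

  mask_m <- NULL; mask_p <- NULL
  if (labels[1] == 1) {
    pl <- plant_lesion(img, rows, cols, cm_r, cm_c, radius,
                       cfg$lesion_contrast)
    img <- pl$img; mask_m <- pl$mask
  }
  if (labels[2] == 1) {
    pl <- plant_lesion(img, rows, cols, cp_r, cp_c, radius,
                       cfg$lesion_contrast)
    img <- pl$img; mask_p <- pl$mask
  }

  img <- img + array(stats::rnorm(length(img), 0, cfg$noise_sd), dim(img))
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255

  hand_record(record_id,
              x1 = cc + a, x2 = cc - a, y1 = cr + b, y2 = cr - b,
              label_m = labels[1], label_p = labels[2],
              image = img, mask_m = mask_m, mask_p = mask_p)
}

#' Generate a synthetic dataset
#'
#' Class counts follow largest-remainder apportionment of the configured
#' proportions; a `contaminant_rate` fraction of records receives one
#' random exclusion flag each. Every record derives its own RNG
#' substream from the global seed and its index.
#'
#' @param cfg a [generator_config()].
#' @return a [record_set()] with provenance `"synthetic"`.
#' @export
generate_dataset <- function(cfg = generator_config()) {
  counts <- class_counts(cfg$n_records, cfg$class_proportions)
  combos <- list("00" = c(0, 0), "01" = c(0, 1),
                 "10" = c(1, 0), "11" = c(1, 1))
  labels <- do.call(rbind, lapply(names(counts), function(k)
    matrix(rep(combos[[k]], counts[k]), ncol = 2, byrow = TRUE)))

  recs <- lapply(seq_len(cfg$n_records), function(k) {
    generate_record(cfg, labels[k, ],
                    seed = (cfg$seed %% 100003L) * 10007L + 7919L * k,
                    record_id = sprintf("synth-%05d", k))
  })

  n_cont <- round(cfg$contaminant_rate * cfg$n_records)
  if (n_cont > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(cfg$seed + 777L)
    pick <- sample(cfg$n_records, n_cont)
    fl <- sample(KNOWN_FLAGS, n_cont, replace = TRUE)
    for (j in seq_along(pick)) recs[[pick[j]]]$flags <- fl[j]
  }
  record_set(recs, provenance = "synthetic")
}
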