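# Dataset records, manifest IO, exclusion rules and stratified splits.

KNOWN_FLAGS <- c("peeling", "scar", "not_unfolded")
MANIFEST_COLS <- c("record_id", "image_path", "x1", "x2", "y1", "y2",
                   "label_m", "label_p", "flags")

#' One annotated palm record
#'
#' Holds an image reference (in-memory array or file path), the four
#' palm landmarks, the two binary task labels, exclusion flags, and
#' (for synthetic records) ground-truth anomaly masks.
#'
#' Landmark convention: images are indexed (row, col) from the top-left;
#' `x1`/`x2` are column coordinates of the thumb-side / opposite palm
#' boundaries and `y1`/`y2` are row coordinates of the wrist-side /
#' finger-side palm boundaries, ordered so that `x1 > x2` and `y1 > y2`
#' (both landmark deltas positive).
#'
#' @param record_id unique identifier.
#' @param x1,x2,y1,y2 landmark pixel coordinates (`x1 > x2`, `y1 > y2`).
#' @param label_m,label_p binary labels: metacarpophalangeal-joint
#'   swelling (M) and palmar-thenar hypertrophy (P).
#' @param image optional `(H, W, 3)` array with values in `[0, 1]`.
#' @param image_path optional path to a PNG image.
#' @param flags character vector drawn from
#'   `c("peeling", "scar", "not_unfolded")`.
#' @param mask_m,mask_p optional binary matrices marking the planted
#'   anomaly pixels of each task (synthetic records).
#' @return a `hand_record` list.
#' @export
hand_record <- function(record_id, x1, x2, y1, y2, label_m, label_p,
                        image = NULL, image_path = NULL,
                        flags = character(0),
                        mask_m = NULL, mask_p = NULL) {
  x1 <- as.numeric(x1); x2 <- as.numeric(x2)
  y1 <- as.numeric(y1); y2 <- as.numeric(y2)
  if (anyNA(c(x1, x2, y1, y2)))
    stop("record ", record_id, ": landmarks must be numeric")
  if (!(x1 > x2) || !(y1 > y2))
    stop("record ", record_id,
         ": landmark convention violated (need x1 > x2 and y1 > y2)")
  for (lab in list(m = label_m, p = label_p))
    if (!lab %in% c(0, 1))
      stop("record ", record_id, ": labels must be exactly 0 or 1")
  bad <- setdiff(flags, KNOWN_FLAGS)
  if (length(bad))
    stop("record ", record_id, ": unknown flag(s): ",
         paste(bad, collapse = ", "))
  if (!is.null(image)) {
    d <- dim(image)
    if (length(d) != 3L || d[3] != 3L)
      stop("record ", record_id, ": image must be an (H, W, 3) array")
    for (mk in list(mask_m, mask_p))
      if (!is.null(mk) && !all(dim(mk) == d[1:2]))
        stop("record ", record_id, ": mask size must match the image")
  }
  structure(list(record_id = as.character(record_id),
                 x1 = x1, x2 = x2, y1 = y1, y2 = y2,
                 label_m = as.integer(label_m),
                 label_p = as.integer(label_p),
                 image = image, image_path = image_path,
                 flags = as.character(flags),
                 mask_m = mask_m, mask_p = mask_p),
            class = "hand_record")
}

#' An ordered collection of records
#' @param records list of [hand_record()]s; ids must be unique.
#' @param provenance `"synthetic"` or `"external"`.
#' @export
record_set <- function(records, provenance = "external") {
  ids <- vapply(records, function(r) r$record_id, "")
  if (anyDuplicated(ids))
    stop("duplicate record_id: ", ids[duplicated(ids)][1])
  structure(list(records = records, provenance = provenance),
            class = "record_set")
}

#' @export
length.record_set <- function(x) length(x$records)

#' @export
print.record_set <- function(x, ...) {
  lm <- vapply(x$records, function(r) r$label_m, 0L)
  lp <- vapply(x$records, function(r) r$label_p, 0L)
  cat(sprintf("<record_set> %d records (%s); task M positives: %d, task P positives: %d\n",
              length(x$records), x$provenance, sum(lm), sum(lp)))
  invisible(x)
}

record_labels <- function(rs) {
  data.frame(
    record_id = vapply(rs$records, function(r) r$record_id, ""),
    label_m = vapply(rs$records, function(r) r$label_m, 0L),
    label_p = vapply(rs$records, function(r) r$label_p, 0L))
}

#' Load an image for a record
#'
#' Returns the in-memory array if present, otherwise reads the file at
#' `image_path` (PNG natively; JPEG when the `jpeg` package is
#' installed). Grayscale files are expanded to three channels; an alpha
#' channel is dropped.
#'
#' @param record a [hand_record()].
#' @param base_dir directory that relative `image_path`s resolve against.
#' @return `(H, W, 3)` array in `[0, 1]`.
#' @export
record_image <- function(record, base_dir = NULL) {
  if (!is.null(record$image)) return(record$image)
  if (is.null(record$image_path))
    stop("record ", record$record_id, " has neither image nor image_path")
  path <- record$image_path
  if (!is.null(base_dir) && !file.exists(path))
    path <- file.path(base_dir, record$image_path)
  img <- if (grepl("\\.jpe?g$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("reading JPEG requires the 'jpeg' package")
    jpeg::readJPEG(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Read a dataset manifest
#'
#' Accepts the CSV layout (header `record_id, image_path, x1, x2, y1,
#' y2, label_m, label_p, flags`, with `flags` a semicolon-joined list and
#' optional `mask_m_path`/`mask_p_path` columns) or an equivalent JSON
#' array of objects. Landmarks must satisfy `x1 > x2`, `y1 > y2`; labels
#' must be 0/1; unknown flags are rejected.
#'
#' @param path manifest file (`.csv` or `.json`).
#' @param load_images read every image (and mask) into memory; otherwise
#'   records keep their paths and images are read on demand.
#' @return a [record_set()].
#' @export
load_manifest <- function(path, load_images = FALSE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(record_id = "character"))
  }
  missing <- setdiff(MANIFEST_COLS, names(df))
  if (length(missing))
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  base_dir <- dirname(path)
  recs <- lapply(seq_len(nrow(df)), function(k) {
    row <- df[k, ]
    flags <- if (is.na(row$flags) || !nzchar(row$flags)) character(0)
             else strsplit(row$flags, ";", fixed = TRUE)[[1]]
    rec <- hand_record(row$record_id, row$x1, row$x2, row$y1, row$y2,
                       row$label_m, row$label_p,
                       image_path = row$image_path, flags = flags)
    for (side in c("m", "p")) {
      col <- paste0("mask_", side, "_path")
      if (col %in% names(df) && !is.na(row[[col]]) && nzchar(row[[col]]))
        rec[[paste0("mask_", side, "_path")]] <- row[[col]]
    }
    if (load_images) {
      rec$image <- record_image(rec, base_dir)
      for (side in c("m", "p")) {
        mp <- rec[[paste0("mask_", side, "_path")]]
        if (!is.null(mp)) {
          p <- if (file.exists(mp)) mp else file.path(base_dir, mp)
          rec[[paste0("mask_", side)]] <- png::readPNG(p) > 0.5
        }
      }
    }
    rec
  })
  record_set(recs, provenance = "external")
}

#' Write a dataset manifest
#'
#' Inverse of [load_manifest()]: records must carry an `image_path`.
#' Writes CSV unless `path` ends in `.json`.
#'
#' @param rs a [record_set()].
#' @param path output file.
#' @export
write_manifest <- function(rs, path) {
  num <- function(x) sprintf("%.17g", x)   # exact double round-trip
  df <- do.call(rbind, lapply(rs$records, function(r) {
    if (is.null(r$image_path))
      stop("record ", r$record_id,
           " has no image_path; write images first (see write_dataset)")
    data.frame(record_id = r$record_id, image_path = r$image_path,
               x1 = num(r$x1), x2 = num(r$x2),
               y1 = num(r$y1), y2 = num(r$y2),
               label_m = r$label_m, label_p = r$label_p,
               flags = paste(r$flags, collapse = ";"),
               mask_m_path = r$mask_m_path %||% "",
               mask_p_path = r$mask_p_path %||% "",
               stringsAsFactors = FALSE)
  }))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows")
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Write a record set to disk
#'
#' Writes one PNG per image (and per ground-truth mask, if present)
#' under `dir` and a `manifest.csv` referencing them by relative path.
#'
#' @param rs a [record_set()] with in-memory images.
#' @param dir output directory (created if needed).
#' @return path of the written manifest.
#' @export
write_dataset <- function(rs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- lapply(rs$records, function(r) {
    img <- record_image(r)
    fn <- paste0(r$record_id, ".png")
    png::writePNG(img, file.path(dir, fn))
    r$image_path <- fn
    for (side in c("m", "p")) {
      mk <- r[[paste0("mask_", side)]]
      if (!is.null(mk) && any(mk)) {
        mfn <- sprintf("%s_mask_%s.png", r$record_id, side)
        png::writePNG(mk * 1, file.path(dir, mfn))
        r[[paste0("mask_", side, "_path")]] <- mfn
      }
    }
    r
  })
  out <- record_set(recs, provenance = rs$provenance)
  write_manifest(out, file.path(dir, "manifest.csv"))
}

#' Apply the study exclusion criteria
#'
#' Removes every record carrying any of the flags `peeling`, `scar`,
#' `not_unfolded` (severely peeling skin, palm scars, and palms not
#' naturally unfolded). A record with several flags is counted once per
#' criterion but removed once. Order of retained records is preserved;
#' the operation is idempotent.
#'
#' @param rs a [record_set()].
#' @return list with `records` (filtered [record_set()]) and `report`
#'   (per-criterion counts, `excluded`, `retained`).
#' @export
apply_exclusions <- function(rs) {
  flagged <- vapply(rs$records,
                    function(r) length(intersect(r$flags, KNOWN_FLAGS)) > 0,
                    TRUE)
  counts <- lapply(stats::setNames(KNOWN_FLAGS, KNOWN_FLAGS), function(fl)
    sum(vapply(rs$records, function(r) fl %in% r$flags, TRUE)))
  kept <- record_set(rs$records[!flagged], provenance = rs$provenance)
  list(records = kept,
       report = list(counts = counts,
                     excluded = sum(flagged),
                     retained = length(kept$records)))
}

#' Stratified train/validation split
#'
#' Stratifies on the four joint `(label_m, label_p)` combinations:
#' each stratum sends `floor(size * train_fraction)` records to
#' training, and the overall training size is topped up to
#' `floor(n * train_fraction)` by granting the strata with the largest
#' fractional remainders one extra record each, so every stratum's
#' training share stays within one record of the global fraction. A
#' size-one stratum always goes to training. Deterministic given
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param rs a [record_set()].
#' @param train_fraction fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return a `split_result` list with `train`, `val`, `seed`, `strata`.
#' @export
split_records <- function(rs, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  lab <- record_labels(rs)
  stratum <- paste0(lab$label_m, lab$label_p)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  keys <- c("00", "01", "10", "11")
  idx_by <- lapply(stats::setNames(keys, keys),
                   function(s) which(stratum == s))
  sizes <- vapply(idx_by, length, 0L)
  exact <- sizes * train_fraction
  n_tr <- as.integer(floor(exact))
  n_tr[sizes == 1L] <- 1L
  target <- floor(length(rs$records) * train_fraction + 1e-9)
  short <- target - sum(n_tr)
  if (short > 0) {
    for (s in order(exact - floor(exact), decreasing = TRUE)) {
      if (short == 0) break
      if (n_tr[s] < sizes[s]) { n_tr[s] <- n_tr[s] + 1L; short <- short - 1L }
    }
  }
  train_idx <- integer(0)
  strata <- list()
  for (j in seq_along(keys)) {
    s <- keys[j]
    if (!sizes[j]) { strata[[s]] <- c(train = 0L, val = 0L); next }
    pick <- if (sizes[j] == 1L) idx_by[[s]]
            else sample(idx_by[[s]], n_tr[j])
    train_idx <- c(train_idx, pick)
    strata[[s]] <- c(train = n_tr[j], val = sizes[j] - n_tr[j])
  }
  train_idx <- sort(train_idx)
  val_idx <- setdiff(seq_along(rs$records), train_idx)
  structure(list(
    train = record_set(rs$records[train_idx], provenance = rs$provenance),
    val = record_set(rs$records[val_idx], provenance = rs$provenance),
    seed = as.integer(seed), strata = strata),
    class = "split_result")
}
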