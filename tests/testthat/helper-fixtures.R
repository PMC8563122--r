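# Shared fixtures: tiny synthetic datasets, manifest builders, and small
# model configurations sized for fast tests.

# A record without pixels, for manifest/split logic.
bare_record <- function(id, m = 0L, p = 0L, flags = character(0),
                        dx = 40, dy = 42) {
  hand_record(id, x1 = 50 + dx / 2, x2 = 50 - dx / 2,
              y1 = 50 + dy / 2, y2 = 50 - dy / 2,
              label_m = m, label_p = p, image_path = paste0(id, ".png"),
              flags = flags)
}

bare_set <- function(n, labels_m = rep(0L, n), labels_p = rep(0L, n),
                     flags = vector("list", n)) {
  record_set(lapply(seq_len(n), function(k)
    bare_record(sprintf("r%04d", k), labels_m[k], labels_p[k],
                flags[[k]] %||% character(0))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small image-bearing synthetic sets.
tiny_generator <- function(n = 8, side = 48, seed = 5, ...) {
  generator_config(n_records = n, image_side = side, seed = seed, ...)
}

# Fast model: 32-px input so the pyramid sides are 8/4/2/1.
tiny_config <- function(...) {
  model_config(input_side = 32L, channels = c(4L, 8L, 8L, 8L), ...)
}

# Prepared inputs for a small labelled dataset.
tiny_inputs <- function(n = 16, side = 48, input_side = 32, seed = 5,
                        with_masks = FALSE) {
  rs <- generate_dataset(tiny_generator(n, side, seed))
  prepare_inputs(rs, input_side, with_masks = with_masks)
}

write_manifest_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

manifest_df <- function(n = 3) {
  data.frame(record_id = sprintf("r%d", seq_len(n)),
             image_path = sprintf("r%d.png", seq_len(n)),
             x1 = 70, x2 = 30, y1 = 72, y2 = 28,
             label_m = rep_len(c(0L, 1L), n),
             label_p = rep_len(c(1L, 0L), n),
             flags = "",
             stringsAsFactors = FALSE)
}
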