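test_that("a well-formed manifest parses into records", {
  path <- write_manifest_csv(manifest_df(3))
  rs <- load_manifest(path)
  expect_s3_class(rs, "record_set")
  expect_length(rs$records, 3)
  r <- rs$records[[1]]
  expect_identical(r$record_id, "r1")
  expect_equal(r$x1 - r$x2, 40)
  expect_equal(r$y1 - r$y2, 44)
  expect_identical(r$flags, character(0))
})

test_that("schema and domain violations are rejected with context", {
  df <- manifest_df(3)
  expect_error(load_manifest(write_manifest_csv(df[, -3])),
               "missing required column.*x1")
  df2 <- manifest_df(3); df2$label_m[2] <- 2L
  expect_error(load_manifest(write_manifest_csv(df2)), "r2.*0 or 1")
  df3 <- manifest_df(3); df3$flags[1] <- "peeling;sunburn"
  expect_error(load_manifest(write_manifest_csv(df3)), "unknown flag.*sunburn")
  df4 <- manifest_df(3); df4$x1[3] <- 10  # x1 < x2
  expect_error(load_manifest(write_manifest_csv(df4)), "landmark convention")
  expect_error(load_manifest(tempfile()), "not found")
})

test_that("write_dataset then load_manifest round-trips records", {
  rs <- generate_dataset(tiny_generator(n = 6, seed = 9))
  dir <- tempfile("ds")
  manifest <- write_dataset(rs, dir)
  back <- load_manifest(manifest, load_images = TRUE)
  expect_length(back$records, 6)
  for (k in seq_len(6)) {
    a <- rs$records[[k]]; b <- back$records[[k]]
    expect_identical(a$record_id, b$record_id)
    expect_equal(c(a$x1, a$x2, a$y1, a$y2), c(b$x1, b$x2, b$y1, b$y2))
    expect_identical(c(a$label_m, a$label_p), c(b$label_m, b$label_p))
    expect_identical(a$flags, b$flags)
    # generator quantizes to 8 bits, so PNG IO is lossless
    expect_equal(a$image, b$image, tolerance = 1e-12)
    expect_equal(is.null(a$mask_m), is.null(b$mask_m))
    if (!is.null(a$mask_m)) expect_equal(which(a$mask_m), which(b$mask_m))
  }
  # JSON mirror of the manifest round-trips too
  jpath <- file.path(dir, "manifest.json")
  write_manifest(back, jpath)
  again <- load_manifest(jpath)
  expect_equal(vapply(again$records, function(r) r$x1, 0),
               vapply(back$records, function(r) r$x1, 0))
})

test_that("exclusion rules drop flagged records and report counts", {
  flags <- vector("list", 10)
  flags[[2]] <- "scar"; flags[[5]] <- "scar"; flags[[9]] <- "scar"
  rs <- bare_set(10, flags = flags)
  res <- apply_exclusions(rs)
  expect_length(res$records$records, 7)
  expect_identical(res$report$counts$scar, 3L)
  expect_identical(res$report$excluded, 3L)
  expect_identical(res$report$retained, 7L)
  # retained order preserved
  expect_identical(vapply(res$records$records, function(r) r$record_id, ""),
                   sprintf("r%04d", c(1, 3, 4, 6, 7, 8, 10)))
})

test_that("a doubly flagged record counts once per criterion, removed once", {
  flags <- vector("list", 4)
  flags[[1]] <- c("peeling", "scar")
  rs <- bare_set(4, flags = flags)
  res <- apply_exclusions(rs)
  # brute-force oracle: removal set is the union over criteria
  removed <- unique(unlist(lapply(c("peeling", "scar", "not_unfolded"),
    function(f) which(vapply(rs$records, function(r) f %in% r$flags, TRUE)))))
  expect_identical(res$report$excluded, length(removed))
  expect_identical(res$report$counts$peeling, 1L)
  expect_identical(res$report$counts$scar, 1L)
  expect_length(res$records$records, 3)
})

test_that("exclusions are idempotent and identity without flags", {
  rs <- bare_set(5)
  res <- apply_exclusions(rs)
  expect_identical(res$records$records, rs$records)
  twice <- apply_exclusions(res$records)
  expect_identical(twice$records$records, res$records$records)
  expect_identical(apply_exclusions(record_set(list()))$report$retained, 0L)
})

test_that("the split reproduces the clinical train/validation sizes", {
  n <- 2414
  m <- rep_len(c(1L, 1L, 0L, 0L), n)
  p <- rep_len(c(1L, 0L, 1L, 0L), n)
  rs <- bare_set(n, m, p)
  sp <- split_records(rs, train_fraction = 1931 / 2414, seed = 3)
  expect_length(sp$train$records, 1931)
  expect_length(sp$val$records, 483)
})

test_that("the split is stratified, partitioning, and seed-deterministic", {
  set.seed(31)
  m <- rbinom(97, 1, 0.45); p <- rbinom(97, 1, 0.55)
  rs <- bare_set(97, m, p)
  for (frac in c(0.5, 0.8)) {
    sp <- split_records(rs, frac, seed = 7)
    ids <- function(x) vapply(x$records, function(r) r$record_id, "")
    expect_length(intersect(ids(sp$train), ids(sp$val)), 0)
    expect_setequal(c(ids(sp$train), ids(sp$val)), ids(rs))
    # train total hits floor(n * frac); each stratum stays within one
    # record of its proportional share
    expect_length(sp$train$records, floor(97 * frac))
    for (s in c("00", "01", "10", "11")) {
      size <- sum(paste0(m, p) == s)
      tr <- unname(sp$strata[[s]]["train"])
      expect_true(tr >= floor(size * frac) && tr <= ceiling(size * frac))
    }
  }
  a <- split_records(rs, 0.8, seed = 7)
  b <- split_records(rs, 0.8, seed = 7)
  expect_identical(vapply(a$train$records, function(r) r$record_id, ""),
                   vapply(b$train$records, function(r) r$record_id, ""))
  d <- split_records(rs, 0.8, seed = 8)
  expect_identical(length(d$train$records), length(a$train$records))
})

test_that("degenerate strata are handled", {
  rs <- bare_set(10)                       # all one stratum
  sp <- split_records(rs, 0.8, seed = 1)
  expect_length(sp$train$records, 8)
  expect_length(sp$val$records, 2)
  one <- bare_set(3, c(0L, 0L, 1L), c(0L, 0L, 1L))  # size-1 stratum "11"
  sp1 <- split_records(one, 0.5, seed = 1)
  expect_identical(unname(sp1$strata[["11"]]["train"]), 1L)
  expect_error(split_records(rs, 1.2), "between 0 and 1")
})

test_that("duplicate record ids are rejected", {
  expect_error(record_set(list(bare_record("a"), bare_record("a"))),
               "duplicate")
})
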