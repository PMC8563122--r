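test_that("the full variant carries four attention modules per branch", {
  m <- build_model(model_config(), seed = 1)
  nm <- names(m$params)
  for (b in c("m", "p")) {
    ams <- unique(sub("^[mp]\\.(am[0-9]+)\\..*$", "\\1",
                      grep(sprintf("^%s\\.am[0-9]", b), nm, value = TRUE)))
    expect_length(ams, 4)
  }
  # one interaction block per level, two 1x1 reductions each
  iims <- grep("^iim[0-9]\\.[mp]\\.w$", nm, value = TRUE)
  expect_length(iims, 8)
  # reduction maps 2C -> C
  expect_identical(dim(m$params[["iim3.m.w"]]), c(1L, 1L, 64L, 32L))
})

test_that("variants change the architecture as specified", {
  full <- build_model(model_config(), seed = 1)
  osn <- build_model(model_config(variant = "osn"), seed = 1)
  expect_length(grep("\\.am[0-9]", names(osn$params)), 0)
  expect_length(grep("^iim", names(osn$params)), 0)
  expect_lt(n_params(osn), n_params(full))

  am1 <- build_model(model_config(variant = "am_subset", am_levels = 1),
                     seed = 1)
  expect_lt(n_params(am1), n_params(full))

  single <- build_model(model_config(variant = "single_task_m"), seed = 1)
  expect_length(grep("^p\\.", names(single$params)), 0)
  expect_identical(single$arch$head_tasks, "m")

  expect_error(model_config(variant = "bogus"), "unknown variant")
  expect_error(model_config(lambda1 = -0.1), "non-negative")
  expect_error(model_config(variant = "am_subset", am_levels = integer(0)),
               "am_levels")
})

test_that("non-adjacent attention subsets get channel-matching convolutions", {
  m14 <- build_model(model_config(variant = "am_subset",
                                  am_levels = c(1, 4)), seed = 1)
  expect_true("m.am4.match.w" %in% names(m14$params))
  # 1x1 conv mapping level-1 channels to level-4 channels
  expect_identical(dim(m14$params[["m.am4.match.w"]]), c(1L, 1L, 8L, 64L))
  m12 <- build_model(model_config(variant = "am_subset",
                                  am_levels = c(1, 2)), seed = 1)
  expect_false("m.am2.match.w" %in% names(m12$params))
})

test_that("the shared pyramid halves its spatial size per level", {
  m <- build_model(model_config(), seed = 2)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  f <- forward_shared(m, x)
  expect_identical(vapply(f, function(a) dim(a)[1], 0L), c(16L, 8L, 4L, 2L))
  expect_identical(vapply(f, function(a) dim(a)[3], 0L),
                   c(8L, 16L, 32L, 64L))
  # batch composition does not change per-image features in eval mode
  f1 <- forward_shared(m, x[, , , 1, drop = FALSE])
  expect_equal(f1[[4]][, , , 1], f[[4]][, , , 1], tolerance = 1e-12)
  # zero input stays finite
  f0 <- forward_shared(m, array(0, c(64, 64, 3, 1)))
  expect_true(all(vapply(f0, function(a) all(is.finite(a)), TRUE)))
})

test_that("forward outputs normalized probabilities and permutes with the batch", {
  m <- build_model(tiny_config(), seed = 3)
  x <- array(runif(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  fw <- mtialm_forward(m, x)
  for (b in c("m", "p")) {
    expect_equal(colSums(fw$probs[[b]]), rep(1, 4), tolerance = 1e-6)
    expect_true(all(fw$probs[[b]] >= 0 & fw$probs[[b]] <= 1))
  }
  perm <- c(3, 1, 4, 2)
  fw2 <- mtialm_forward(m, x[, , , perm])
  expect_equal(fw2$probs$m, fw$probs$m[, perm], tolerance = 1e-10)
  expect_error(mtialm_forward(m, array(0, c(16, 16, 3, 1))), "input array")
})

test_that("attention masks are strictly inside (0, 1)", {
  m <- build_model(tiny_config(), seed = 4)
  x <- array(rnorm(32 * 32 * 3 * 3, 0.5, 0.5), c(32, 32, 3, 3))
  fw <- mtialm_forward(m, x, collect = TRUE)
  masks <- grep("^fprime", names(fw$nodes), value = TRUE)
  expect_length(masks, 8)
  for (nm in masks) {
    v <- fw$nodes[[nm]]$value
    expect_true(all(v > 0 & v < 1))
  }
  # standalone module: >1000 random draws through the mask path
  par <- am_params(4, 4, seed = 9)
  f <- array(rnorm(8 * 8 * 4 * 20, 0, 3), c(8, 8, 4, 20))
  st <- attention_stage(par, f, f_iim = array(0, dim(f)))
  expect_true(all(st$f_prime > 0 & st$f_prime < 1))
  expect_gt(length(st$f_prime), 1000)
})

test_that("the residual attention mask behaves at its limits", {
  par <- am_params(4, 4, seed = 5)
  f <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  # zero fused features annihilate the output
  st <- attention_stage(par, f, f_iim = array(0, dim(f)))
  expect_identical(unique(as.vector(st$f_m)), 0)
  # saturated-low mask leaves the fused features unchanged: f_m -> f_iim
  par$params[["am.t.b"]] <- rep(-50, 4)
  fiim <- array(rnorm(length(f)), dim(f))
  st2 <- attention_stage(par, f, f_iim = fiim)
  expect_lt(max(abs(st2$f_m - fiim)), 1e-12)
  # general case follows the residual identity (1 + f') * f_iim
  par$params[["am.t.b"]] <- rep(0.3, 4)
  st3 <- attention_stage(par, f, f_iim = fiim)
  expect_equal(st3$f_m, (1 + st3$f_prime) * fiim, tolerance = 1e-12)
  # cascaded input: previous output is pooled and concatenated
  prev <- array(rnorm(16 * 16 * 4 * 2), c(16, 16, 4, 2))
  par2 <- am_params(8, 4, seed = 6)
  st4 <- attention_stage(par2, f, f_iim = fiim, f_m_prev = prev)
  expect_identical(dim(st4$f_m), dim(f))
  expect_error(attention_stage(par, f, f_iim = prev), "shape")
})

test_that("interaction fusion weights the reference branch by lambda", {
  par <- iim_params(3, seed = 7)
  a <- array(runif(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  b <- array(runif(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  # lambda = 0 is equivalent to a zeroed reference branch
  expect_equal(iim_fuse(par, a, b, 0), iim_fuse(par, a, b * 0, 1),
               tolerance = 1e-12)
  expect_error(iim_fuse(par, a, b, -0.5), "non-negative")
  expect_error(iim_fuse(par, a, b[, , , 1, drop = FALSE], 0.2), "shape")
  # roles swap symmetrically given swapped parameters and weights
  parA <- iim_params(3, seed = 8); parB <- iim_params(3, seed = 9)
  out_m <- iim_fuse(parA, a, b, 0.2)
  out_p <- iim_fuse(parB, b, a, 0.4)
  expect_equal(iim_fuse(parB, b, a, 0.4), out_p)
  expect_equal(iim_fuse(parA, a, b, 0.2), out_m)
})

test_that("a 1x1 fusion kernel reduces to the hand-computed channel sum", {
  # single channel per branch, single pixel, batch norm at identity
  par <- iim_params(1, seed = 1)
  par$params[["iim.w"]] <- array(c(2, 3), c(1, 1, 2, 1))
  par$params[["iim.b"]] <- 0.25
  main <- array(0.5, c(1, 1, 1, 1))
  ref <- array(0.4, c(1, 1, 1, 1))
  got <- iim_fuse(par, main, ref, 0.5)
  # eval-mode batch norm with mean 0, var 1: y ~ x / sqrt(1 + eps)
  want <- (2 * 0.5 + 3 * 0.5 * 0.4 + 0.25) / sqrt(1 + 1e-5)
  expect_equal(as.vector(got), want, tolerance = 1e-8)
})

test_that("zeroed interaction reduces the full variant to no_iim exactly", {
  cfg0 <- tiny_config(lambda1 = 0, lambda2 = 0)
  full <- build_model(cfg0, seed = 11)
  ni <- build_model(tiny_config(variant = "no_iim"), seed = 11)
  # share every common parameter, and collapse the fusion kernels to
  # their main halves
  ch <- full$config$channels
  for (nm in names(ni$params)) {
    if (grepl("^[mp]\\.iim", nm)) next
    ni$params[[nm]] <- full$params[[nm]]
  }
  for (i in 1:4) for (b in c("m", "p")) {
    src <- sprintf("iim%d.%s", i, b)
    dst <- sprintf("%s.iim%d", b, i)
    ni$params[[paste0(dst, ".w")]] <-
      full$params[[paste0(src, ".w")]][, , seq_len(ch[i]), , drop = FALSE]
    ni$params[[paste0(dst, ".b")]] <- full$params[[paste0(src, ".b")]]
    ni$params[[paste0(dst, "bn.g")]] <- full$params[[paste0(src, "bn.g")]]
    ni$params[[paste0(dst, "bn.b")]] <- full$params[[paste0(src, "bn.b")]]
  }
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  a <- mtialm_forward(full, x)
  b <- mtialm_forward(ni, x)
  expect_lt(max(abs(a$scores$m - b$scores$m)), 1e-5)
  expect_lt(max(abs(a$scores$p - b$scores$p)), 1e-5)
  # sanity: shared pyramids agree between variants for equal weights
  expect_equal(forward_shared(full, x), forward_shared(ni, x),
               tolerance = 1e-12)
})

test_that("every parameter group receives gradient on a random batch", {
  m <- build_model(tiny_config(), seed = 12)
  x <- array(runif(32 * 32 * 3 * 6), c(32, 32, 3, 6))
  ym <- c(1, 0, 1, 0, 1, 0); yp <- c(0, 0, 1, 1, 0, 1)
  fw <- mtialm_forward(m, x, training = TRUE, collect = TRUE)
  tape <- fw$tape
  lh <- mtialm:::op_softmax_bce(tape, fw$score_nodes$p, yp)
  lk <- mtialm:::op_softmax_bce(tape, fw$score_nodes$m, ym)
  tot <- mtialm:::op_uncertainty_total(tape, lh, lk,
                                       mtialm:::tp_leaf(tape, 0),
                                       mtialm:::tp_leaf(tape, 0))
  mtialm:::tp_backward(tape, tot)
  g <- mtialm:::ctx_grads(fw$ctx)
  expect_setequal(names(g), names(m$params))
  nz <- vapply(g, function(a) !is.null(a) && any(a != 0) &&
                 all(is.finite(a)), TRUE)
  expect_true(all(nz))
})

test_that("checkpoints round-trip the model exactly", {
  m <- build_model(tiny_config(), seed = 13)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  # perturb batch-norm state so it is not at initialization
  invisible(mtialm_forward(m, x, training = TRUE))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path, extra = list(note = "t"))
  ck <- load_checkpoint(path)
  expect_identical(ck$extra$note, "t")
  expect_equal(mtialm_forward(ck$model, x)$probs$m,
               mtialm_forward(m, x)$probs$m, tolerance = 1e-15)
})
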