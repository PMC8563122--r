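#' Model configuration
#'
#' Describes the shared residual backbone, the per-task attention
#' branches, the information-interaction weighting, and the ablation
#' variant to build.
#'
#' @param preset `"small"` (64-pixel input, channels 8/16/32/64, one
#'   residual block per stage; intended for tests and desk-scale runs) or
#'   `"paper"` (460-pixel input, channels 64/128/256/512, two blocks per
#'   stage, the standard 18-layer residual configuration). Individual
#'   fields can still be overridden.
#' @param input_side input patch side in pixels.
#' @param channels integer vector of per-stage channel counts (4 stages).
#' @param blocks_per_stage residual blocks in each backbone stage.
#' @param lambda1 weight of the reference (task P) features fused into the
#'   task-M branch; default 0.2.
#' @param lambda2 weight of the reference (task M) features fused into the
#'   task-P branch; default 0.4.
#' @param variant one of `"full"`, `"osn"` (backbone + heads only),
#'   `"am_subset"` (attention modules only at `am_levels`), `"no_iim"`
#'   (each branch's own features replace the cross-branch fusion),
#'   `"single_task_m"`, `"single_task_p"`.
#' @param am_levels which backbone levels (subset of 1:4) carry attention
#'   modules; only consulted for `variant = "am_subset"`.
#' @return a `mtialm_config` list.
#' @export
model_config <- function(preset = "small", input_side = NULL,
                         channels = NULL, blocks_per_stage = NULL,
                         lambda1 = 0.2, lambda2 = 0.4,
                         variant = "full", am_levels = 1:4) {
  preset <- match.arg(preset, c("small", "paper"))
  base <- if (preset == "small") {
    list(input_side = 64L, channels = c(8L, 16L, 32L, 64L),
         blocks_per_stage = 1L)
  } else {
    list(input_side = 460L, channels = c(64L, 128L, 256L, 512L),
         blocks_per_stage = 2L)
  }
  cfg <- list(
    preset = preset,
    input_side = as.integer(input_side %||% base$input_side),
    channels = as.integer(channels %||% base$channels),
    blocks_per_stage = as.integer(blocks_per_stage %||% base$blocks_per_stage),
    lambda1 = lambda1, lambda2 = lambda2,
    variant = variant,
    am_levels = sort(unique(as.integer(am_levels))),
    num_classes = 2L
  )
  variants <- c("full", "osn", "am_subset", "no_iim",
                "single_task_m", "single_task_p")
  if (!variant %in% variants)
    stop("unknown variant: ", variant)
  if (lambda1 < 0 || lambda2 < 0)
    stop("reference-information weights must be non-negative")
  if (length(cfg$channels) != 4L)
    stop("exactly four backbone stages are expected")
  if (variant == "am_subset" &&
      (length(cfg$am_levels) == 0 || any(!cfg$am_levels %in% 1:4)))
    stop("am_levels must be a non-empty subset of 1:4")
  if (variant != "am_subset") cfg$am_levels <- 1:4
  structure(cfg, class = "mtialm_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Which task branches a variant carries, and how the per-level fusion
# input of the second attention stage is formed.
variant_branches <- function(cfg) {
  switch(cfg$variant,
    osn = character(0),
    single_task_m = "m",
    single_task_p = "p",
    c("m", "p"))
}

variant_iim <- function(cfg) {
  switch(cfg$variant,
    full = "cross", am_subset = "cross",
    no_iim = "self", single_task_m = "self", single_task_p = "self",
    osn = "none")
}

# Spatial side of each backbone level for a given input side:
# stem halves twice, then stages 2-4 halve once each.
level_sides <- function(input_side) {
  s0 <- (input_side + 2L - 3L) %/% 2L + 1L          # stem conv, stride 2
  if (s0 %% 2L) stop("input side must give an even post-stem size")
  s1 <- s0 %/% 2L                                    # stem pool
  sides <- integer(4)
  sides[1] <- s1
  for (i in 2:4) sides[i] <- (sides[i - 1] + 2L - 3L) %/% 2L + 1L
  sides
}

#' Build the multitask attention model
#'
#' Constructs the parameter container for the configured variant: shared
#' backbone, per-task cascaded attention branches, cross-task interaction
#' blocks, and the per-class 1x1 + global-average-pooling heads.
#' Convolutions are He-initialized; batch-norm starts at identity.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return an environment of class `mtialm_model` with elements `params`
#'   (named list of arrays), `bn` (running batch-norm statistics),
#'   `config`, and `arch`.
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  stopifnot(inherits(cfg, "mtialm_config"))
  model <- new.env(parent = emptyenv())
  model$params <- list()
  model$bn <- list()
  model$config <- cfg
  ch <- cfg$channels
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # stem: 3x3/2 conv + bn + relu + 2x2 average pool
  add_conv(model, "shared.stem.conv", 3, 3, 3, ch[1])
  add_bn(model, "shared.stem.bn", ch[1])

  # four residual stages; stage i>1 downsamples via its first block
  cin <- ch[1]
  for (i in 1:4) {
    for (b in seq_len(cfg$blocks_per_stage)) {
      stride <- if (i > 1 && b == 1) 2L else 1L
      pre <- sprintf("shared.s%d.b%d", i, b)
      add_conv(model, paste0(pre, ".conv1"), 3, 3, cin, ch[i])
      add_bn(model, paste0(pre, ".bn1"), ch[i])
      add_conv(model, paste0(pre, ".conv2"), 3, 3, ch[i], ch[i])
      add_bn(model, paste0(pre, ".bn2"), ch[i])
      if (stride != 1L || cin != ch[i]) {
        add_conv(model, paste0(pre, ".down"), 1, 1, cin, ch[i])
        add_bn(model, paste0(pre, ".downbn"), ch[i])
      }
      cin <- ch[i]
    }
  }

  branches <- variant_branches(cfg)
  iim_mode <- variant_iim(cfg)
  S <- cfg$am_levels
  sides <- level_sides(cfg$input_side)

  for (b in branches) {
    for (j in seq_along(S)) {
      i <- S[j]
      pre <- sprintf("%s.am%d", b, i)
      if (j == 1L) {
        gin <- ch[i]
      } else {
        prev <- S[j - 1]
        if (i - prev > 1L) {
          # non-adjacent cascade step: channels matched by 1x1 conv
          add_conv(model, paste0(pre, ".match"), 1, 1, ch[prev], ch[i])
          add_bn(model, paste0(pre, ".matchbn"), ch[i])
          gin <- 2L * ch[i]
        } else {
          gin <- ch[i] + ch[prev]
        }
      }
      add_conv(model, paste0(pre, ".g"), 3, 3, gin, ch[i])
      add_bn(model, paste0(pre, ".gbn"), ch[i])
      add_conv(model, paste0(pre, ".t"), 1, 1, ch[i], ch[i])
      add_bn(model, paste0(pre, ".tbn"), ch[i])
      if (iim_mode == "self") {
        add_conv(model, sprintf("%s.iim%d", b, i), 1, 1, ch[i], ch[i])
        add_bn(model, sprintf("%s.iim%dbn", b, i), ch[i])
      }
    }
  }
  if (iim_mode == "cross") {
    for (i in S) {
      for (b in c("m", "p")) {
        add_conv(model, sprintf("iim%d.%s", i, b), 1, 1, 2L * ch[i], ch[i])
        add_bn(model, sprintf("iim%d.%sbn", i, b), ch[i])
      }
    }
  }

  head_ch <- if (length(branches)) ch[S[length(S)]] else ch[4]
  head_tasks <- if (length(branches)) branches else c("m", "p")
  for (b in head_tasks)
    add_conv(model, paste0("head.", b), 1, 1, head_ch, cfg$num_classes)

  model$arch <- list(branches = branches, iim = iim_mode, levels = S,
                     sides = sides, head_tasks = head_tasks)
  class(model) <- c("mtialm_model", "environment")
  model
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Number of trainable parameters
#' @param model a built model.
#' @return integer count of scalar parameters.
#' @export
n_params <- function(model) sum(vapply(model$params, length, 1L))

#' @export
print.mtialm_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<mtialm_model> variant=%s preset=%s input=%dpx channels=%s\n",
    cfg$variant, cfg$preset, cfg$input_side,
    paste(cfg$channels, collapse = "/")))
  cat(sprintf("  attention levels: %s | lambda1=%.2f lambda2=%.2f | %s parameters\n",
              paste(x$arch$levels, collapse = ","),
              cfg$lambda1, cfg$lambda2,
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

# ---- forward passes (tape-based) ----

residual_block <- function(ctx, pre, x, stride, project) {
  h <- op_relu(ctx$tape, fwd_bn(ctx, paste0(pre, ".bn1"),
                                fwd_conv(ctx, paste0(pre, ".conv1"), x,
                                         stride = stride, pad = 1L)))
  h <- fwd_bn(ctx, paste0(pre, ".bn2"),
              fwd_conv(ctx, paste0(pre, ".conv2"), h, 1L, 1L))
  sc <- if (project) {
    fwd_bn(ctx, paste0(pre, ".downbn"),
           fwd_conv(ctx, paste0(pre, ".down"), x, stride = stride, pad = 0L))
  } else x
  op_relu(ctx$tape, op_add(ctx$tape, h, sc))
}

shared_pyramid <- function(model, ctx, x) {
  cfg <- model$config
  h <- op_relu(ctx$tape, fwd_bn(ctx, "shared.stem.bn",
                                fwd_conv(ctx, "shared.stem.conv", x, 2L, 1L)))
  h <- op_avgpool2(ctx$tape, h)
  ch <- cfg$channels
  f <- vector("list", 4)
  cin <- ch[1]
  for (i in 1:4) {
    for (b in seq_len(cfg$blocks_per_stage)) {
      stride <- if (i > 1 && b == 1) 2L else 1L
      project <- stride != 1L || cin != ch[i]
      h <- residual_block(ctx, sprintf("shared.s%d.b%d", i, b), h,
                          stride, project)
      cin <- ch[i]
    }
    f[[i]] <- h
  }
  f
}

# First attention stage: 3x3 conv + bn + relu (G), then 1x1 conv + bn +
# sigmoid (T) producing the bounded mask f'.
am_stage1 <- function(ctx, pre, f_in) {
  g <- op_relu(ctx$tape, fwd_bn(ctx, paste0(pre, ".gbn"),
                                fwd_conv(ctx, paste0(pre, ".g"), f_in, 1L, 1L)))
  fprime <- op_sigmoid(ctx$tape, fwd_bn(ctx, paste0(pre, ".tbn"),
                                        fwd_conv(ctx, paste0(pre, ".t"), g,
                                                 1L, 0L)))
  list(g = g, fprime = fprime)
}

# Second attention stage: residual-identity mask applied to the fused
# feature, f_m = (1 + f') * f_iim.
am_stage2 <- function(ctx, fprime, f_iim) {
  op_cmul(ctx$tape, op_add_const(ctx$tape, fprime, 1), f_iim)
}

# Cross-branch interaction at one level: concatenate the main branch's
# mask features with a lambda-weighted copy of the reference branch's,
# then reduce 2C -> C with a 1x1 conv + bn. Main half comes first.
iim_cross <- function(ctx, pre, main, ref, lambda) {
  z <- op_concat_ch(ctx$tape, main, op_scale(ctx$tape, ref, lambda))
  fwd_bn(ctx, paste0(pre, "bn"), fwd_conv(ctx, pre, z, 1L, 0L))
}

iim_self <- function(ctx, pre, main) {
  fwd_bn(ctx, paste0(pre, "bn"), fwd_conv(ctx, pre, main, 1L, 0L))
}

# Align the previous attention output to the current level: 2x2 average
# pooling when the sides differ by exactly a factor of two, bilinear
# interpolation otherwise; non-adjacent steps also pass a channel-matching
# 1x1 conv + bn.
align_prev <- function(ctx, pre_am, node, side_to, gap) {
  d <- dim(node$value)
  a <- if (d[1] == 2L * side_to && d[2] == 2L * side_to) {
    op_avgpool2(ctx$tape, node)
  } else {
    op_bilinear(ctx$tape, node, side_to, side_to)
  }
  if (gap > 1L)
    a <- fwd_bn(ctx, paste0(pre_am, ".matchbn"),
                fwd_conv(ctx, paste0(pre_am, ".match"), a, 1L, 0L))
  a
}

#' Forward pass
#'
#' Runs a batch of patches through the configured variant and returns
#' per-task class scores and softmax probabilities. With `collect = TRUE`
#' the tape and named intermediate nodes are returned as well (used by
#' training and by the class-activation maps).
#'
#' @param model a built model.
#' @param x `(side, side, 3, N)` numeric array of input patches.
#' @param training logical; batch-norm uses batch statistics and updates
#'   running averages when `TRUE`.
#' @param collect keep the tape and intermediate nodes.
#' @return list with `scores` and `probs` (each a per-task list of
#'   2 x N matrices), and when collected, `tape`, `ctx`, `nodes`.
#' @export
mtialm_forward <- function(model, x, training = FALSE, collect = FALSE) {
  cfg <- model$config
  d <- dim(x)
  if (length(d) != 4L || d[1] != cfg$input_side || d[2] != cfg$input_side ||
      d[3] != 3L)
    stop(sprintf("expected a (%d, %d, 3, N) input array", cfg$input_side,
                 cfg$input_side))
  tape <- tape_new()
  ctx <- fwd_ctx(model, tape, training)
  xin <- tp_leaf(tape, x)
  f <- shared_pyramid(model, ctx, xin)

  branches <- model$arch$branches
  S <- model$arch$levels
  nodes <- list(input = xin, pyramid = f)
  fm_last <- list()

  if (length(branches)) {
    fm_prev <- stats::setNames(vector("list", length(branches)), branches)
    for (j in seq_along(S)) {
      i <- S[j]
      st1 <- list()
      for (b in branches) {
        pre <- sprintf("%s.am%d", b, i)
        f_in <- if (j == 1L) f[[i]] else {
          gap <- i - S[j - 1]
          op_concat_ch(ctx$tape, f[[i]],
                       align_prev(ctx, pre, fm_prev[[b]],
                                  model$arch$sides[i], gap))
        }
        st1[[b]] <- am_stage1(ctx, pre, f_in)
        nodes[[sprintf("fprime.%s.%d", b, i)]] <- st1[[b]]$fprime
      }
      for (b in branches) {
        f_iim <- if (model$arch$iim == "cross") {
          other <- if (b == "m") "p" else "m"
          lambda <- if (b == "m") cfg$lambda1 else cfg$lambda2
          iim_cross(ctx, sprintf("iim%d.%s", i, b),
                    st1[[b]]$fprime, st1[[other]]$fprime, lambda)
        } else {
          iim_self(ctx, sprintf("%s.iim%d", b, i), st1[[b]]$fprime)
        }
        nodes[[sprintf("fiim.%s.%d", b, i)]] <- f_iim
        fm_prev[[b]] <- am_stage2(ctx, st1[[b]]$fprime, f_iim)
        nodes[[sprintf("fm.%s.%d", b, i)]] <- fm_prev[[b]]
      }
    }
    fm_last <- fm_prev
  } else {
    for (b in c("m", "p")) fm_last[[b]] <- f[[4]]
  }

  scores <- list(); probs <- list()
  for (b in model$arch$head_tasks) {
    sc <- op_gap(ctx$tape, fwd_conv(ctx, paste0("head.", b),
                                    fm_last[[b]], 1L, 0L))
    scores[[b]] <- sc
    probs[[b]] <- softmax_cols(sc$value)
    nodes[[paste0("scores.", b)]] <- sc
    nodes[[paste0("fm_last.", b)]] <- fm_last[[b]]
  }

  out <- list(scores = lapply(scores, function(nd) nd$value), probs = probs)
  if (collect) {
    out$tape <- tape
    out$ctx <- ctx
    out$nodes <- nodes
    out$score_nodes <- scores
  }
  out
}

# ---- standalone operation surfaces (plain arrays in, plain arrays out) ----

#' Attention-module parameters
#'
#' Initializes one attention module: the 3x3 feature convolution (with
#' batch norm and ReLU) and the 1x1 mask convolution (with batch norm and
#' sigmoid).
#'
#' @param c_in input channels (level channels, plus the cascaded channels
#'   when a previous attention output is concatenated).
#' @param c_out level channels.
#' @param seed initialization seed.
#' @export
am_params <- function(c_in, c_out, seed = 1L) {
  m <- new.env(parent = emptyenv()); m$params <- list(); m$bn <- list()
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  add_conv(m, "am.g", 3, 3, c_in, c_out); add_bn(m, "am.gbn", c_out)
  add_conv(m, "am.t", 1, 1, c_out, c_out); add_bn(m, "am.tbn", c_out)
  m
}

#' One attention module applied to plain arrays
#'
#' The first stage forms the bounded mask `f_prime` from the level
#' features (concatenated with the aligned previous attention output when
#' given); the second stage applies the residual-identity mask to the
#' fused features: `f_m = (1 + f_prime) * f_iim`.
#'
#' @param par parameters from [am_params()].
#' @param f_i `(H, W, C, N)` level features.
#' @param f_iim fused features from the interaction module (same shape as
#'   the module output).
#' @param f_m_prev optional previous attention output, already at a
#'   spatial size that pools or resizes to this level (it is aligned
#'   here by average pooling / bilinear interpolation).
#' @param training batch-norm mode.
#' @return list with `f_prime` and `f_m` arrays.
#' @export
attention_stage <- function(par, f_i, f_iim, f_m_prev = NULL,
                            training = FALSE) {
  tape <- tape_new()
  ctx <- fwd_ctx(par, tape, training)
  fi <- tp_leaf(tape, f_i)
  f_in <- if (is.null(f_m_prev)) fi else {
    prev <- tp_leaf(tape, f_m_prev)
    d <- dim(f_m_prev); dt <- dim(f_i)
    a <- if (d[1] == 2L * dt[1] && d[2] == 2L * dt[2])
      op_avgpool2(tape, prev) else op_bilinear(tape, prev, dt[1], dt[2])
    op_concat_ch(tape, fi, a)
  }
  st <- am_stage1(ctx, "am", f_in)
  if (!all(dim(f_iim) == dim(st$fprime$value)))
    stop("f_iim shape does not match the attention-module output")
  fm <- am_stage2(ctx, st$fprime, tp_leaf(tape, f_iim))
  list(f_prime = st$fprime$value, f_m = fm$value)
}

#' Interaction-module parameters (one direction)
#' @param c level channels; the 1x1 reduction maps 2c -> c.
#' @param seed initialization seed.
#' @export
iim_params <- function(c, seed = 1L) {
  m <- new.env(parent = emptyenv()); m$params <- list(); m$bn <- list()
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  add_conv(m, "iim", 1, 1, 2L * c, c); add_bn(m, "iimbn", c)
  m
}

#' Cross-branch information fusion applied to plain arrays
#'
#' Concatenates the main branch's mask features with a lambda-weighted
#' copy of the reference branch's (main half first) and reduces the
#' channel dimension back with a 1x1 convolution + batch norm.
#'
#' @param par parameters from [iim_params()].
#' @param f_prime_main,f_prime_ref `(H, W, C, N)` mask features of the
#'   main and reference branches.
#' @param lambda non-negative reference weight.
#' @param training batch-norm mode.
#' @return fused `(H, W, C, N)` array.
#' @export
iim_fuse <- function(par, f_prime_main, f_prime_ref, lambda,
                     training = FALSE) {
  if (lambda < 0) stop("reference-information weight must be non-negative")
  if (!all(dim(f_prime_main) == dim(f_prime_ref)))
    stop("branch features must share a shape at each level")
  tape <- tape_new()
  ctx <- fwd_ctx(par, tape, training)
  iim_cross(ctx, "iim", tp_leaf(tape, f_prime_main),
            tp_leaf(tape, f_prime_ref), lambda)$value
}

#' Shared-backbone features for a batch of patches
#'
#' @param model a built model.
#' @param x `(side, side, 3, N)` input array.
#' @param training batch-norm mode.
#' @return list of four `(H_i, W_i, C_i, N)` arrays, spatial size halving
#'   from level to level.
#' @export
forward_shared <- function(model, x, training = FALSE) {
  tape <- tape_new()
  ctx <- fwd_ctx(model, tape, training)
  lapply(shared_pyramid(model, ctx, tp_leaf(tape, x)),
         function(nd) nd$value)
}

# ---- checkpoints ----

#' Save / load a model checkpoint
#'
#' The checkpoint holds the named parameter arrays, batch-norm running
#' statistics, and the model configuration; `load_checkpoint` rebuilds an
#' identical model.
#'
#' @param model a built model.
#' @param path file path (`.rds`).
#' @param extra optional list stored alongside (e.g. uncertainty weights,
#'   training history).
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  bn <- lapply(model$bn, function(st) list(mean = st$mean, var = st$var))
  saveRDS(list(params = model$params, bn = bn,
               config = unclass(model$config), extra = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns a list with `model` and `extra`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- structure(ck$config, class = "mtialm_config")
  model <- build_model(cfg, seed = 1L)
  stopifnot(identical(sort(names(model$params)), sort(names(ck$params))))
  model$params <- ck$params
  for (nm in names(ck$bn)) {
    model$bn[[nm]]$mean <- ck$bn[[nm]]$mean
    model$bn[[nm]]$var <- ck$bn[[nm]]$var
  }
  list(model = model, extra = ck$extra)
}
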