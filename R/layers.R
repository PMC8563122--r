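# Parameter initialization and the forward-context plumbing shared by the
# full model and the standalone attention/interaction operations.

he_conv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

add_conv <- function(model, name, kh, kw, cin, cout) {
  model$params[[paste0(name, ".w")]] <- he_conv(kh, kw, cin, cout)
  model$params[[paste0(name, ".b")]] <- numeric(cout)
  invisible(model)
}

add_bn <- function(model, name, c) {
  model$params[[paste0(name, ".g")]] <- rep(1, c)
  model$params[[paste0(name, ".b")]] <- numeric(c)
  st <- new.env(parent = emptyenv())
  st$mean <- numeric(c)
  st$var <- rep(1, c)
  model$bn[[name]] <- st
  invisible(model)
}

# A forward context bundles the tape, the parameter store, lazily created
# leaf nodes (one per parameter actually touched), and the train/eval flag.
fwd_ctx <- function(model, tape, training) {
  ctx <- new.env(parent = emptyenv())
  ctx$tape <- tape
  ctx$params <- model$params
  ctx$bn <- model$bn
  ctx$leaves <- new.env(parent = emptyenv())
  ctx$training <- training
  ctx
}

ctx_leaf <- function(ctx, name) {
  nd <- ctx$leaves[[name]]
  if (is.null(nd)) {
    p <- ctx$params[[name]]
    if (is.null(p)) stop("unknown parameter: ", name)
    nd <- tp_leaf(ctx$tape, p)
    ctx$leaves[[name]] <- nd
  }
  nd
}

fwd_conv <- function(ctx, name, x, stride = 1L, pad = 1L) {
  op_conv(ctx$tape, x, ctx_leaf(ctx, paste0(name, ".w")),
          ctx_leaf(ctx, paste0(name, ".b")), stride, pad)
}

fwd_bn <- function(ctx, name, x) {
  op_bn(ctx$tape, x, ctx_leaf(ctx, paste0(name, ".g")),
        ctx_leaf(ctx, paste0(name, ".b")), ctx$bn[[name]], ctx$training)
}

# Collect gradients for every parameter leaf touched during the forward.
ctx_grads <- function(ctx) {
  out <- list()
  for (nm in ls(ctx$leaves)) out[[nm]] <- ctx$leaves[[nm]]$grad
  out
}

softmax_cols <- function(s) {
  e <- exp(sweep(s, 2, apply(s, 2, max)))
  sweep(e, 2, colSums(e), "/")
}
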