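# Training loop (Adam + stepped schedule + uncertainty-weighted total
# loss), evaluation, and the ablation harness.

adam_state_new <- function() new.env(parent = emptyenv())

adam_update <- function(st, name, param, grad, lr, cfg, t) {
  key_m <- paste0(name, ".m"); key_v <- paste0(name, ".v")
  m <- st[[key_m]]; v <- st[[key_v]]
  if (is.null(m)) { m <- param * 0; v <- param * 0 }
  if (cfg$weight_decay > 0) grad <- grad + cfg$weight_decay * param
  m <- cfg$beta1 * m + (1 - cfg$beta1) * grad
  v <- cfg$beta2 * v + (1 - cfg$beta2) * grad^2
  st[[key_m]] <- m; st[[key_v]] <- v
  mhat <- m / (1 - cfg$beta1^t)
  vhat <- v / (1 - cfg$beta2^t)
  param - lr * mhat / (sqrt(vhat) + cfg$eps)
}

model_tasks <- function(model) model$arch$head_tasks

#' Evaluate a model on prepared inputs
#'
#' Runs the model in eval mode and reports, per task, the confusion
#' counts, accuracy/sensitivity/specificity/F1, AUC, and the mean
#' cross-entropy loss; plus the uncertainty-weighted total loss when
#' both tasks are present.
#'
#' @param model a built model.
#' @param data list from [prepare_inputs()] (`x`, `label_m`, `label_p`).
#' @param uw an [uncertainty_weights()] used for the total loss.
#' @param batch_size evaluation batch size.
#' @return list with per-task entries (`m`, `p`) and `total_loss`.
#' @export
evaluate_model <- function(model, data, uw = uncertainty_weights(),
                           batch_size = 64L) {
  n <- dim(data$x)[4]
  tasks <- model_tasks(model)
  probs <- stats::setNames(vector("list", length(tasks)), tasks)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fw <- mtialm_forward(model, data$x[, , , idx, drop = FALSE])
    for (b in tasks) probs[[b]] <- cbind(probs[[b]], fw$probs[[b]])
  }
  out <- list()
  losses <- c(m = NA_real_, p = NA_real_)
  for (b in tasks) {
    y <- if (b == "m") data$label_m else data$label_p
    p1 <- probs[[b]][2, ]
    cc <- confusion_counts(p1, y)
    met <- compute_metrics(cc)
    met$auc <- if (length(unique(y)) == 2L) auc_score(p1, y) else NA_real_
    losses[b] <- task_loss(p1, y)
    out[[b]] <- c(list(counts = cc, loss = losses[b], prob = p1), met)
  }
  out$total_loss <- if (all(c("m", "p") %in% tasks)) {
    unname(total_loss(l_h = losses[["p"]], l_k = losses[["m"]], uw))
  } else unname(losses[tasks])
  out
}

#' Train the model
#'
#' Minibatch Adam on the uncertainty-weighted total of the two per-task
#' cross-entropies (single-task variants optimize their own loss alone),
#' with the stepped learning-rate schedule indexed by epoch. After every
#' epoch the model is scored on the validation set; the parameters with
#' the minimum validation total loss are restored at the end.
#'
#' @param model a built model (modified in place; also returned).
#' @param train_data,val_data lists from [prepare_inputs()].
#' @param config a [schedule_config()].
#' @param epochs number of epochs (defaults to `config$max_epochs`).
#' @param seed seed controlling batch order.
#' @param verbose print one line per epoch.
#' @return list with `model`, `history` (per-epoch data frame),
#'   `best_epoch`, `uw` (uncertainty weights at the best epoch), and
#'   `best_val` (validation report at the best epoch).
#' @export
train_model <- function(model, train_data, val_data,
                        config = schedule_config(),
                        epochs = config$max_epochs,
                        seed = 1L, verbose = FALSE) {
  n <- dim(train_data$x)[4]
  if (n < 1L || dim(val_data$x)[4] < 1L)
    stop("training and validation sets must be non-empty")
  tasks <- model_tasks(model)
  two_task <- all(c("m", "p") %in% tasks)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  st <- adam_state_new()
  eta <- c(eta_h = 0, eta_k = 0)
  t <- 0L
  best <- list(loss = Inf, epoch = NA_integer_)
  hist <- list()

  for (ep in seq_len(epochs)) {
    lr <- lr_at(ep, config)
    idx <- sample(n)
    ep_losses <- c(total = 0, m = 0, p = 0); nb <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      take <- idx[start:min(start + config$batch_size - 1, n)]
      xb <- train_data$x[, , , take, drop = FALSE]
      fw <- mtialm_forward(model, xb, training = TRUE, collect = TRUE)
      tape <- fw$tape
      loss_nodes <- list()
      for (b in tasks) {
        y <- if (b == "m") train_data$label_m[take]
             else train_data$label_p[take]
        loss_nodes[[b]] <- op_softmax_bce(tape, fw$score_nodes[[b]], y)
      }
      if (two_task) {
        eh <- tp_leaf(tape, eta[["eta_h"]])
        ek <- tp_leaf(tape, eta[["eta_k"]])
        tot <- op_uncertainty_total(tape, loss_nodes$p, loss_nodes$m,
                                    eh, ek)
      } else tot <- loss_nodes[[tasks]]
      if (!is.finite(tot$value))
        stop(sprintf("non-finite training loss at epoch %d (lr %.4g)",
                     ep, lr))
      tp_backward(tape, tot)
      t <- t + 1L
      grads <- ctx_grads(fw$ctx)
      for (nm in names(grads)) {
        if (is.null(grads[[nm]])) next
        model$params[[nm]] <- adam_update(st, nm, model$params[[nm]],
                                          grads[[nm]], lr, config, t)
      }
      if (two_task) {
        eta[["eta_h"]] <- adam_update(st, "eta_h", eta[["eta_h"]],
                                      eh$grad, lr, config, t)
        eta[["eta_k"]] <- adam_update(st, "eta_k", eta[["eta_k"]],
                                      ek$grad, lr, config, t)
      }
      ep_losses["total"] <- ep_losses["total"] + tot$value
      for (b in tasks)
        ep_losses[b] <- ep_losses[b] + loss_nodes[[b]]$value
      nb <- nb + 1L
    }
    ep_losses <- ep_losses / nb

    uw <- uncertainty_weights(eta[["eta_h"]], eta[["eta_k"]])
    ev <- evaluate_model(model, val_data, uw)
    val_total <- ev$total_loss
    hist[[ep]] <- data.frame(
      epoch = ep, lr = lr,
      train_total = ep_losses["total"],
      train_loss_m = if ("m" %in% tasks) ep_losses["m"] else NA_real_,
      train_loss_p = if ("p" %in% tasks) ep_losses["p"] else NA_real_,
      eta_h = eta[["eta_h"]], eta_k = eta[["eta_k"]],
      val_total = val_total,
      val_acc_m = if ("m" %in% tasks) ev$m$accuracy else NA_real_,
      val_acc_p = if ("p" %in% tasks) ev$p$accuracy else NA_real_,
      row.names = NULL)
    if (verbose)
      message(sprintf(
        "epoch %3d lr %.4g train %.4f val %.4f acc[%s]",
        ep, lr, ep_losses["total"], val_total,
        paste(sprintf("%s=%.3f", tasks, vapply(
          tasks, function(b) ev[[b]]$accuracy, 0)), collapse = " ")))
    if (val_total < best$loss) {
      best <- list(
        loss = val_total, epoch = ep,
        params = model$params,
        bn = lapply(model$bn, function(s) list(mean = s$mean,
                                               var = s$var)),
        uw = uw, ev = ev)
    }
  }

  model$params <- best$params
  for (nm in names(best$bn)) {
    model$bn[[nm]]$mean <- best$bn[[nm]]$mean
    model$bn[[nm]]$var <- best$bn[[nm]]$var
  }
  list(model = model, history = do.call(rbind, hist),
       best_epoch = best$epoch, uw = best$uw, best_val = best$ev)
}

#' The 15 attention-level combinations
#'
#' Every non-empty subset of the four backbone levels: 4 single-module,
#' 6 two-module, 4 three-module, and the full four-module configuration.
#'
#' @return list of integer vectors.
#' @export
am_subset_grid <- function() {
  out <- list()
  for (k in 1:4) {
    cm <- utils::combn(4, k)
    for (j in seq_len(ncol(cm))) out[[length(out) + 1]] <- cm[, j]
  }
  out
}

resolve_variant <- function(v, base_cfg) {
  if (inherits(v, "mtialm_config")) return(v)
  if (is.numeric(v))
    return(model_config(preset = base_cfg$preset,
                        input_side = base_cfg$input_side,
                        channels = base_cfg$channels,
                        blocks_per_stage = base_cfg$blocks_per_stage,
                        lambda1 = base_cfg$lambda1,
                        lambda2 = base_cfg$lambda2,
                        variant = "am_subset", am_levels = v))
  model_config(preset = base_cfg$preset,
               input_side = base_cfg$input_side,
               channels = base_cfg$channels,
               blocks_per_stage = base_cfg$blocks_per_stage,
               lambda1 = base_cfg$lambda1, lambda2 = base_cfg$lambda2,
               variant = v)
}

variant_label <- function(v) {
  if (inherits(v, "mtialm_config"))
    return(if (v$variant == "am_subset")
      paste0("am_", paste(v$am_levels, collapse = "")) else v$variant)
  if (is.numeric(v)) paste0("am_", paste(v, collapse = ""))
  else as.character(v)
}

#' Run an ablation sweep
#'
#' Trains each variant with each seed on the same data and tabulates the
#' validation metrics, one row per variant x seed x task, with the four
#' component-indicator columns marking which backbone levels carry
#' attention modules.
#'
#' @param variants list mixing variant names (`"full"`, `"osn"`,
#'   `"no_iim"`, `"single_task_m"`, `"single_task_p"`), integer vectors
#'   of attention levels, and full [model_config()]s. See
#'   [am_subset_grid()] for the 15 attention-level combinations.
#' @param train_data,val_data lists from [prepare_inputs()].
#' @param config a [schedule_config()].
#' @param seeds integer vector; each seeds both initialization and batch
#'   order of one run.
#' @param epochs training epochs per run.
#' @param base_cfg the [model_config()] whose preset/lambdas the named
#'   variants inherit.
#' @param verbose print per-epoch lines.
#' @return data frame of results.
#' @export
run_ablation <- function(variants, train_data, val_data,
                         config = schedule_config(), seeds = 1L,
                         epochs = 10L, base_cfg = model_config(),
                         verbose = FALSE) {
  stopifnot(length(variants) >= 1L, length(seeds) >= 1L)
  rows <- list()
  for (v in variants) {
    cfg <- resolve_variant(v, base_cfg)
    lab <- variant_label(v)
    comp <- as.integer(1:4 %in%
      (if (length(variant_branches(cfg))) cfg$am_levels else integer(0)))
    for (sd in seeds) {
      model <- build_model(cfg, seed = sd)
      fit <- train_model(model, train_data, val_data, config,
                         epochs = epochs, seed = sd, verbose = verbose)
      for (b in model_tasks(model)) {
        met <- fit$best_val[[b]]
        rows[[length(rows) + 1]] <- data.frame(
          variant = lab, seed = sd,
          c1 = comp[1], c2 = comp[2], c3 = comp[3], c4 = comp[4],
          task = toupper(b),
          accuracy = met$accuracy, sensitivity = met$sensitivity,
          specificity = met$specificity, f1 = met$f1, auc = met$auc,
          best_epoch = fit$best_epoch, row.names = NULL)
      }
    }
  }
  do.call(rbind, rows)
}
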