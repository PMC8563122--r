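# Gradient-weighted class activation maps per task branch, and a
# threshold-free localization score against ground-truth masks.

#' Gradient-weighted class activation map
#'
#' For the chosen task branch and class, backpropagates the class score
#' (post-GAP, pre-softmax) to the branch's deepest attention output with
#' usable spatial extent, weights each channel by the spatial mean of its
#' gradient, rectifies the weighted sum, upsamples it bilinearly to the
#' input size, and normalizes the maximum to 1 (a map that is
#' identically zero stays zero).
#'
#' The target layer is the deepest attention level of the branch whose
#' feature map is at least `min_side` pixels on a side (the backbone tap
#' for the shared-network-only variant). Attribution needs both
#' high-level semantics and spatial detail; at the clinical input size
#' of 460 pixels the deepest attention map (15 x 15) satisfies the
#' default, so the rule targets the input of the 1x1 class-map
#' convolution there, and only moves up the cascade when a small test
#' input degenerates the deepest maps to a few pixels.
#'
#' @param model a built (typically trained) model.
#' @param image `(side, side, 3)` input patch.
#' @param task `"m"` or `"p"`; must exist in the variant.
#' @param class_index 0 (negative) or 1 (positive).
#' @param level backbone level to target; `NULL` applies the `min_side`
#'   rule.
#' @param min_side minimum acceptable feature-map side, default 4.
#' @return a `cam_map` list with `heatmap` (input-sized matrix in
#'   `[0, 1]`), `task`, `class_index`, `level`.
#' @export
grad_cam <- function(model, image, task = c("m", "p"), class_index = 1L,
                     level = NULL, min_side = 4L) {
  task <- match.arg(task)
  if (!task %in% model$arch$head_tasks)
    stop("task '", task, "' is not present in this model variant")
  if (!class_index %in% c(0L, 1L)) stop("class_index must be 0 or 1")
  levels <- if (length(model$arch$branches)) model$arch$levels else 1:4
  if (is.null(level)) {
    ok <- levels[model$arch$sides[levels] >= min_side]
    level <- if (length(ok)) max(ok) else max(levels)
  }
  if (!level %in% levels)
    stop("level ", level, " carries no feature map in this variant")
  d <- dim(image)
  x <- array(image, c(d[1], d[2], 3, 1))
  fw <- mtialm_forward(model, x, training = FALSE, collect = TRUE)
  sel <- op_select(fw$tape, fw$score_nodes[[task]], class_index + 1L, 1L)
  tp_backward(fw$tape, sel)
  fm <- if (length(model$arch$branches)) {
    fw$nodes[[sprintf("fm.%s.%d", task, level)]]
  } else {
    fw$nodes$pyramid[[level]]
  }
  g <- fm$grad
  dd <- dim(fm$value)
  hw <- dd[1] * dd[2]
  alpha <- chan_sum(g) / hw
  v <- matrix(fm$value, hw, dd[3])
  cam <- matrix(pmax(v %*% alpha, 0), dd[1], dd[2])
  cam <- resize_image(cam, d[1])
  cam <- pmax(cam, 0)
  mx <- max(cam)
  if (mx > 0) cam <- cam / mx
  structure(list(heatmap = cam, task = task,
                 class_index = as.integer(class_index),
                 level = as.integer(level)),
            class = "cam_map")
}

#' Localization score of a heatmap against a mask
#'
#' Mean-contrast ratio: mean heatmap value inside the mask divided by
#' the sum of the means inside and outside. 0.5 means no localization;
#' 1 means all activation inside the mask. Threshold-free, so it suits
#' soft activation maps.
#'
#' @param cam a `cam_map` or a plain non-negative matrix.
#' @param gt_mask logical/0-1 matrix of the same size; must be non-empty.
#' @return score in `[0, 1]`.
#' @export
localization_score <- function(cam, gt_mask) {
  h <- if (inherits(cam, "cam_map")) cam$heatmap else cam
  if (!all(dim(h) == dim(gt_mask)))
    stop("heatmap and mask sizes differ")
  m <- gt_mask > 0
  if (!any(m)) stop("ground-truth mask is empty")
  mean_in <- mean(h[m])
  mean_out <- if (all(m)) 0 else mean(h[!m])
  if (mean_in + mean_out == 0) return(0.5)
  mean_in / (mean_in + mean_out)
}
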