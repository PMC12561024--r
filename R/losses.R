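#' Loss blending schedule
#'
#' Training warms up on weighted binary cross-entropy (WBCE) alone, then
#' blends in a soft centerline-Dice term: the first `warmup_epochs` epochs
#' use weights (1, 0); afterwards the centerline-Dice weight ramps from 0 up
#' to `final_cl_weight` at `total_epochs`, reaching a 50:50 blend at the last
#' epoch under the defaults.
#'
#' @param total_epochs total number of training epochs.
#' @param warmup_epochs epochs trained on WBCE only.
#' @param pos_weight multiplicative weight on the positive (bone) class in
#'   the WBCE term; counteracts the extreme foreground/background imbalance
#'   of a thin-curve target.
#' @param final_cl_weight centerline-Dice weight at the final epoch.
#' @param ramp `"linear"` or `"cosine"` ramp shape after warm-up.
#' @return an object of class `loss_schedule`.
#' @export
loss_schedule <- function(total_epochs, warmup_epochs = 10L, pos_weight = 20,
                          final_cl_weight = 0.5,
                          ramp = c("linear", "cosine")) {
  ramp <- match.arg(ramp)
  stopifnot(warmup_epochs >= 1, total_epochs > warmup_epochs,
            final_cl_weight >= 0, final_cl_weight <= 1, pos_weight > 0)
  structure(list(total_epochs = as.integer(total_epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 pos_weight = pos_weight,
                 final_cl_weight = final_cl_weight,
                 ramp = ramp),
            class = "loss_schedule")
}

#' Per-epoch blend weights of the compound loss
#'
#' @param epoch epoch number, 1-based.
#' @param schedule a [loss_schedule()].
#' @return named numeric vector `c(wbce = , cldice = )`, summing to 1.
#' @export
blend_weights <- function(epoch, schedule) {
  stopifnot(inherits(schedule, "loss_schedule"))
  if (epoch < 1 || epoch > schedule$total_epochs)
    stop("epoch out of schedule range")
  if (epoch <= schedule$warmup_epochs) {
    w_cl <- 0
  } else {
    t <- (epoch - schedule$warmup_epochs) /
      (schedule$total_epochs - schedule$warmup_epochs)
    w_cl <- switch(schedule$ramp,
                   linear = schedule$final_cl_weight * t,
                   cosine = schedule$final_cl_weight * (1 - cos(pi * t)) / 2)
  }
  c(wbce = 1 - w_cl, cldice = w_cl)
}

#' Weighted binary cross-entropy on logits
#'
#' Mean over all pixels (and frames) of the binary cross-entropy with the
#' positive-class term multiplied by `pos_weight`. Computed in a numerically
#' stable form directly from logits.
#'
#' @param logits numeric array of logits.
#' @param target binary array of the same shape.
#' @param pos_weight positive-class weight.
#' @return scalar loss.
#' @export
wbce_loss <- function(logits, target, pos_weight = 20) {
  if (!identical(length(logits), length(target)))
    stop("logits and target shapes differ")
  cpp_wbce(as_batch4(logits), as.numeric(target), pos_weight)$loss
}

#' Soft-skeleton parameters
#'
#' @param n_iterations number of soft-erosion iterations; must be at least
#'   half the maximal expected half-width of a predicted response.
#' @param epsilon smoothing constant keeping ratios finite on empty masks.
#' @export
soft_skeleton_params <- function(n_iterations = 10L, epsilon = 1e-6) {
  stopifnot(n_iterations >= 1, epsilon > 0)
  list(n_iterations = as.integer(n_iterations), epsilon = epsilon)
}

# soft-morphology primitives on tape nodes
soft_erode_nd <- function(x) {
  op_minimum(op_pool_same(x, 3L, 1L, "min"), op_pool_same(x, 1L, 3L, "min"))
}
soft_dilate_nd <- function(x) op_pool_same(x, 3L, 3L, "max")
soft_open_nd <- function(x) soft_dilate_nd(soft_erode_nd(x))

# iterative soft skeletonization (differentiable morphological thinning)
soft_skeleton_nd <- function(x, iters) {
  skel <- op_relu(op_sub(x, soft_open_nd(x)))
  img <- x
  for (j in seq_len(iters)) {
    img <- soft_erode_nd(img)
    delta <- op_relu(op_sub(img, soft_open_nd(img)))
    skel <- op_add(skel, op_relu(op_sub(delta, op_mul(skel, delta))))
  }
  skel
}

with_no_tape <- function(expr) {
  old <- .ag$on
  .ag$on <- FALSE
  on.exit(.ag$on <- old)
  expr
}

#' Soft (differentiable) skeleton of a probability map
#'
#' Iterated soft erosion (min-pooling) and soft opening, accumulating the
#' ridge residue; on a binary 1-px curve this returns the curve itself.
#'
#' @param probs array of probabilities in `[0,1]` (matrix or 4-d batch).
#' @param params a [soft_skeleton_params()].
#' @return array of the same shape.
#' @export
soft_skeleton <- function(probs, params = soft_skeleton_params()) {
  x <- as_batch4(probs)
  out <- with_no_tape(soft_skeleton_nd(ag_const(x), params$n_iterations)$v)
  if (is.matrix(probs)) out <- out[, , 1, 1] else out
}

# builds the per-batch mean soft-clDice loss node from a probability node
soft_cldice_node <- function(probs_nd, target, params) {
  eps <- params$epsilon
  tgt <- as_batch4(target)
  skel_t <- with_no_tape(soft_skeleton_nd(ag_const(tgt), params$n_iterations)$v)
  skel_p <- soft_skeleton_nd(probs_nd, params$n_iterations)
  sp_in_t <- op_sum_samples(op_mul(skel_p, ag_const(tgt)))
  sp_tot <- op_sum_samples(skel_p)
  st_in_p <- op_sum_samples(op_mul(ag_const(skel_t), probs_nd))
  st_tot <- ag_const(colSums(matrix(skel_t, ncol = dim(tgt)[4])))
  tprec <- op_div(op_sadd(sp_in_t, eps), op_sadd(sp_tot, eps))
  tsens <- op_div(op_sadd(st_in_p, eps), op_sadd(st_tot, eps))
  cl <- op_div(op_smul(op_mul(tprec, tsens), 2), op_add(tprec, tsens))
  op_mean(op_rsub(1, cl))
}

#' Soft centerline-Dice loss
#'
#' One minus the soft centerline Dice between a probability map and a binary
#' target, where hard morphological skeletons are replaced by the
#' differentiable soft skeleton. Per-frame scores are averaged over the
#' batch.
#'
#' @param probs probability array (matrix or (H,W,1,N) batch) in `[0,1]`.
#' @param target binary array of the same shape.
#' @param params a [soft_skeleton_params()].
#' @return scalar loss in `[0,1]`.
#' @export
soft_cldice_loss <- function(probs, target, params = soft_skeleton_params()) {
  x <- as_batch4(probs)
  with_no_tape(soft_cldice_node(ag_const(x), as_batch4(target), params)$v)
}

as_batch4 <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1, 1))
  else if (length(dim(x)) == 4) x
  else stop("expected a matrix or (H,W,C,N) array")
}

# blended training loss node: w1 * WBCE(logits) + w2 * softclDice(sigmoid)
compound_loss_node <- function(logits_nd, target, w, schedule, skel_params) {
  tgt <- as_batch4(target)
  loss <- op_smul(op_wbce(logits_nd, tgt, schedule$pos_weight), w[["wbce"]])
  if (w[["cldice"]] > 0) {
    cl <- soft_cldice_node(op_sigmoid(logits_nd), tgt, skel_params)
    loss <- op_add(loss, op_smul(cl, w[["cldice"]]))
  }
  loss
}
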