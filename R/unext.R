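#' Configuration for the tokenized-MLP segmentation network
#'
#' The network is a three-stage convolutional encoder (1 -> 16 -> 32 -> 128
#' channels, each stage conv + batch norm + ReLU + 2x2 max pool), followed by
#' two overlapping patch embeddings (stride-2 3x3 convs to 160 and 256
#' channels) each feeding a shifted-MLP token block, and a mirrored decoder
#' (bilinear 2x upsampling, convs 256 -> 160 -> 128 -> 32 -> 16 -> 16) with
#' encoder skip connections fused by element-wise addition. A final 1x1
#' convolution produces a single logit map at input resolution.
#'
#' @param in_channels number of input image channels.
#' @param conv_channels widths of the three encoder convolution stages.
#' @param embed_dims token widths of the two tokenized-MLP stages.
#' @param out_channels number of output logit channels.
#' @param input_size nominal (height, width); the network itself is fully
#'   convolutional and accepts any size divisible by 32.
#' @return an object of class `unext_config`.
#' @export
unext_config <- function(in_channels = 1L,
                         conv_channels = c(16L, 32L, 128L),
                         embed_dims = c(160L, 256L),
                         out_channels = 1L,
                         input_size = c(192L, 192L)) {
  stopifnot(length(conv_channels) == 3, length(embed_dims) == 2,
            all(conv_channels > 0), all(embed_dims > 0),
            in_channels > 0, out_channels > 0)
  structure(list(in_channels = as.integer(in_channels),
                 conv_channels = as.integer(conv_channels),
                 embed_dims = as.integer(embed_dims),
                 out_channels = as.integer(out_channels),
                 input_size = as.integer(input_size)),
            class = "unext_config")
}

# uniform Kaiming-style init, bound 1/sqrt(fan_in)
rinit <- function(dims, fan_in) {
  b <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -b, b), dim = dims)
}

new_conv <- function(kh, kw, cin, cout) {
  e <- new.env(parent = emptyenv())
  fan <- kh * kw * cin
  e$w <- ag_param(rinit(c(kh, kw, cin, cout), fan))
  e$b <- ag_param(rinit(cout, fan))
  e
}

new_bn <- function(c) {
  e <- new.env(parent = emptyenv())
  e$gamma <- ag_param(rep(1, c))
  e$beta <- ag_param(rep(0, c))
  e$rmean <- rep(0, c)
  e$rvar <- rep(1, c)
  e
}

new_lnorm <- function(c) {
  e <- new.env(parent = emptyenv())
  e$gamma <- ag_param(rep(1, c))
  e$beta <- ag_param(rep(0, c))
  e
}

new_dw <- function(c) {
  e <- new.env(parent = emptyenv())
  e$w <- ag_param(rinit(c(3, 3, c), 9))
  e$b <- ag_param(rinit(c, 9))
  e
}

# token block: LN -> shift(cols) -> fc1 -> DWConv -> GELU -> shift(rows)
# -> fc2 -> residual
new_token_block <- function(d) {
  e <- new.env(parent = emptyenv())
  e$norm <- new_lnorm(d)
  e$fc1 <- new_conv(1, 1, d, d)
  e$dw <- new_dw(d)
  e$fc2 <- new_conv(1, 1, d, d)
  g <- floor((seq_len(d) - 1) * 5 / d)  # five shift groups, offsets -2..2
  e$shifts <- as.integer(g - 2L)
  e
}

#' Build the bone-surface segmentation network
#'
#' Constructs the network with freshly initialised weights. Weight
#' initialisation draws from the current R RNG state, so seed beforehand for
#' reproducible models.
#'
#' @param cfg a [unext_config()].
#' @return an object of class `unext`; use [predict.unext()] for inference,
#'   [parameter_budget()] or `summary()` for the per-layer parameter table.
#' @export
unext <- function(cfg = unext_config()) {
  cc <- cfg$conv_channels; ed <- cfg$embed_dims
  m <- list(
    cfg = cfg,
    enc1 = new_conv(3, 3, cfg$in_channels, cc[1]), bn1 = new_bn(cc[1]),
    enc2 = new_conv(3, 3, cc[1], cc[2]), bn2 = new_bn(cc[2]),
    enc3 = new_conv(3, 3, cc[2], cc[3]), bn3 = new_bn(cc[3]),
    pe1 = new_conv(3, 3, cc[3], ed[1]), pe1_norm = new_lnorm(ed[1]),
    tok1 = new_token_block(ed[1]), tok1_out = new_lnorm(ed[1]),
    pe2 = new_conv(3, 3, ed[1], ed[2]), pe2_norm = new_lnorm(ed[2]),
    tok2 = new_token_block(ed[2]), tok2_out = new_lnorm(ed[2]),
    dec1 = new_conv(3, 3, ed[2], ed[1]), dbn1 = new_bn(ed[1]),
    dec2 = new_conv(3, 3, ed[1], cc[3]), dbn2 = new_bn(cc[3]),
    dec3 = new_conv(3, 3, cc[3], cc[2]), dbn3 = new_bn(cc[2]),
    dec4 = new_conv(3, 3, cc[2], cc[1]), dbn4 = new_bn(cc[1]),
    dec5 = new_conv(3, 3, cc[1], cc[1]),
    final = new_conv(1, 1, cc[1], cfg$out_channels)
  )
  class(m) <- "unext"
  m
}

token_block_fwd <- function(blk, x) {
  xn <- op_ln(x, blk$norm$gamma, blk$norm$beta)
  h <- op_shift(xn, 1L, blk$shifts)
  h <- op_conv(h, blk$fc1$w, blk$fc1$b, stride = 1L, pad = 0L)
  h <- op_gelu(op_dwconv3(h, blk$dw$w, blk$dw$b))
  h <- op_shift(h, 0L, blk$shifts)
  h <- op_conv(h, blk$fc2$w, blk$fc2$b, stride = 1L, pad = 0L)
  op_add(x, h)
}

# Forward pass. x: (H, W, C, N) array; returns the logit node.
unext_forward <- function(model, x, training = FALSE) {
  d <- dim(x)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("input height and width must be divisible by 32")
  if (d[3] != model$cfg$in_channels) stop("channel mismatch")
  xin <- ag_const(x)
  t1 <- op_relu(op_maxpool2(op_bn(op_conv(xin, model$enc1$w, model$enc1$b), model$bn1, training)))
  t2 <- op_relu(op_maxpool2(op_bn(op_conv(t1, model$enc2$w, model$enc2$b), model$bn2, training)))
  t3 <- op_relu(op_maxpool2(op_bn(op_conv(t2, model$enc3$w, model$enc3$b), model$bn3, training)))

  p1 <- op_conv(t3, model$pe1$w, model$pe1$b, stride = 2L, pad = 1L)
  p1 <- op_ln(p1, model$pe1_norm$gamma, model$pe1_norm$beta)
  t4 <- op_ln(token_block_fwd(model$tok1, p1),
              model$tok1_out$gamma, model$tok1_out$beta)

  p2 <- op_conv(t4, model$pe2$w, model$pe2$b, stride = 2L, pad = 1L)
  p2 <- op_ln(p2, model$pe2_norm$gamma, model$pe2_norm$beta)
  bt <- op_ln(token_block_fwd(model$tok2, p2),
              model$tok2_out$gamma, model$tok2_out$beta)

  u <- op_relu(op_up2(op_bn(op_conv(bt, model$dec1$w, model$dec1$b), model$dbn1, training)))
  u <- op_add(u, t4)
  u <- op_relu(op_up2(op_bn(op_conv(u, model$dec2$w, model$dec2$b), model$dbn2, training)))
  u <- op_add(u, t3)
  u <- op_relu(op_up2(op_bn(op_conv(u, model$dec3$w, model$dec3$b), model$dbn3, training)))
  u <- op_add(u, t2)
  u <- op_relu(op_up2(op_bn(op_conv(u, model$dec4$w, model$dec4$b), model$dbn4, training)))
  u <- op_add(u, t1)
  u <- op_relu(op_up2(op_conv(u, model$dec5$w, model$dec5$b)))
  op_conv(u, model$final$w, model$final$b, stride = 1L, pad = 0L)
}

# components holding trainable leaves, in a stable order
unext_components <- function(model) {
  nm <- c("enc1", "bn1", "enc2", "bn2", "enc3", "bn3",
          "pe1", "pe1_norm", "tok1", "tok1_out",
          "pe2", "pe2_norm", "tok2", "tok2_out",
          "dec1", "dbn1", "dec2", "dbn2", "dec3", "dbn3", "dec4", "dbn4",
          "dec5", "final")
  model[nm]
}

# flat named list of ag_param nodes
unext_params <- function(model) {
  out <- list()
  for (nm in names(unext_components(model))) {
    comp <- model[[nm]]
    if (!is.null(comp$w)) { out[[paste0(nm, ".w")]] <- comp$w }
    if (!is.null(comp$b)) { out[[paste0(nm, ".b")]] <- comp$b }
    if (!is.null(comp$gamma)) { out[[paste0(nm, ".gamma")]] <- comp$gamma }
    if (!is.null(comp$beta)) { out[[paste0(nm, ".beta")]] <- comp$beta }
    if (!is.null(comp$norm)) {
      out[[paste0(nm, ".norm.gamma")]] <- comp$norm$gamma
      out[[paste0(nm, ".norm.beta")]] <- comp$norm$beta
      out[[paste0(nm, ".fc1.w")]] <- comp$fc1$w
      out[[paste0(nm, ".fc1.b")]] <- comp$fc1$b
      out[[paste0(nm, ".dw.w")]] <- comp$dw$w
      out[[paste0(nm, ".dw.b")]] <- comp$dw$b
      out[[paste0(nm, ".fc2.w")]] <- comp$fc2$w
      out[[paste0(nm, ".fc2.b")]] <- comp$fc2$b
    }
  }
  out
}

#' Extract, save and restore network weights
#'
#' `unext_state()` returns all weights and batch-norm running statistics as a
#' plain list; `unext_load_state()` writes such a list back into a model of
#' the same configuration.
#'
#' @param model a fitted or fresh [unext()] model.
#' @return `unext_state()`: a named list of numeric arrays.
#' @export
unext_state <- function(model) {
  ps <- lapply(unext_params(model), function(p) p$v)
  run <- list()
  for (nm in c("bn1", "bn2", "bn3", "dbn1", "dbn2", "dbn3", "dbn4")) {
    run[[paste0(nm, ".rmean")]] <- model[[nm]]$rmean
    run[[paste0(nm, ".rvar")]] <- model[[nm]]$rvar
  }
  list(cfg = model$cfg, params = ps, running = run)
}

#' @rdname unext_state
#' @param state a list produced by `unext_state()`.
#' @export
unext_load_state <- function(model, state) {
  ps <- unext_params(model)
  stopifnot(identical(names(ps), names(state$params)))
  for (nm in names(ps)) ps[[nm]]$v <- state$params[[nm]]
  for (nm in c("bn1", "bn2", "bn3", "dbn1", "dbn2", "dbn3", "dbn4")) {
    model[[nm]]$rmean <- state$running[[paste0(nm, ".rmean")]]
    model[[nm]]$rvar <- state$running[[paste0(nm, ".rvar")]]
  }
  invisible(model)
}

#' Per-layer parameter budget
#'
#' Counts the parameters of the 18 named layers of the architecture
#' (convolutions, batch norms and the token-MLP fc layers). Normalisation
#' layers internal to the token blocks and the depthwise convolutions are
#' part of the network but are not part of this enumerated budget.
#'
#' @param model a [unext()] model.
#' @return a data frame with columns `layer`, `type`, `params`, and the
#'   grand total as attribute `total`.
#' @export
parameter_budget <- function(model) {
  np <- function(comp) length(comp$w$v) + length(comp$b$v)
  nbn <- function(comp) length(comp$gamma$v) + length(comp$beta$v)
  rows <- list(
    c("Encoder1_Conv2D", "Conv2d", np(model$enc1)),
    c("Encoder1_BatchNorm", "BatchNorm2d", nbn(model$bn1)),
    c("Encoder2_Conv2D", "Conv2d", np(model$enc2)),
    c("Encoder2_BatchNorm", "BatchNorm2d", nbn(model$bn2)),
    c("Encoder3_Conv2D", "Conv2d", np(model$enc3)),
    c("Encoder3_BatchNorm", "BatchNorm2d", nbn(model$bn3)),
    c("PatchEmbed3_Conv2D", "Conv2d", np(model$pe1)),
    c("PatchEmbed4_Conv2D", "Conv2d", np(model$pe2)),
    c("ShiftMLP1_fc1", "Linear", np(model$tok1$fc1)),
    c("ShiftMLP1_fc2", "Linear", np(model$tok1$fc2)),
    c("ShiftMLP2_fc1", "Linear", np(model$tok2$fc1)),
    c("ShiftMLP2_fc2", "Linear", np(model$tok2$fc2)),
    c("Decoder1_Conv2D", "Conv2d", np(model$dec1)),
    c("Decoder2_Conv2D", "Conv2d", np(model$dec2)),
    c("Decoder3_Conv2D", "Conv2d", np(model$dec3)),
    c("Decoder4_Conv2D", "Conv2d", np(model$dec4)),
    c("Decoder5_Conv2D", "Conv2d", np(model$dec5)),
    c("Final_1x1_Conv", "Conv2d (1x1)", np(model$final))
  )
  out <- data.frame(layer = vapply(rows, `[`, "", 1),
                    type = vapply(rows, `[`, "", 2),
                    params = as.integer(vapply(rows, `[`, "", 3)),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- sum(out$params)
  out
}

#' @export
print.unext <- function(x, ...) {
  b <- parameter_budget(x)
  cat("Tokenized-MLP bone segmentation network (UNeXt-style)\n")
  cat(sprintf("  encoder channels: %s | token widths: %s\n",
              paste(x$cfg$conv_channels, collapse = "-"),
              paste(x$cfg$embed_dims, collapse = "-")))
  cat(sprintf("  enumerated parameters: %s (in %d named layers)\n",
              format(attr(b, "total"), big.mark = ","), nrow(b)))
  invisible(x)
}

#' @export
summary.unext <- function(object, ...) {
  b <- parameter_budget(object)
  structure(b, class = c("summary.unext", "data.frame"))
}

#' @export
print.summary.unext <- function(x, ...) {
  cat("Layer                 Type            Number of Parameters\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("%-21s %-15s %s\n", x$layer[i], x$type[i],
                format(x$params[i], big.mark = ",")))
  cat(sprintf("%-21s %-15s Total: %s parameters\n", "", "",
              format(attr(x, "total"), big.mark = ",")))
  invisible(x)
}

#' @export
coef.unext <- function(object, ...) {
  lapply(unext_params(object), function(p) p$v)
}

#' Predict bone-surface probability maps
#'
#' Runs the network in evaluation mode (batch-norm running statistics) on one
#' or more frames.
#'
#' @param object a [unext()] model.
#' @param frames a single H x W matrix in `[0,1]`, a list of such matrices,
#'   or an (H, W, C, N) array.
#' @param type `"prob"` for sigmoid probability maps, `"logit"` for raw
#'   logits, `"mask"` for thresholded binary masks.
#' @param threshold binarisation threshold for `type = "mask"`.
#' @param ... unused.
#' @return a list of H x W matrices (one per frame).
#' @export
predict.unext <- function(object, frames, type = c("prob", "logit", "mask"),
                          threshold = 0.5, ...) {
  type <- match.arg(type)
  x <- frames_to_batch(frames)
  out <- unext_forward(object, x, training = FALSE)$v
  res <- lapply(seq_len(dim(out)[4]), function(n) out[, , 1, n])
  if (type != "logit") res <- lapply(res, function(m) cpp_sigmoid(m))
  if (type == "mask") res <- lapply(res, function(m) (m >= threshold) * 1L)
  res
}

# Coerce matrix / list of matrices / 4-d array into (H,W,C,N).
frames_to_batch <- function(frames) {
  if (is.list(frames)) {
    if (inherits(frames, "bmode_frame")) frames <- list(frames)
    mats <- lapply(frames, function(f) if (inherits(f, "bmode_frame")) f$pixels else f)
    d <- dim(mats[[1]])
    x <- array(0, dim = c(d[1], d[2], 1, length(mats)))
    for (i in seq_along(mats)) x[, , 1, i] <- mats[[i]]
    x
  } else if (is.matrix(frames)) {
    array(frames, dim = c(dim(frames), 1, 1))
  } else if (length(dim(frames)) == 4) {
    frames
  } else stop("unsupported frame input")
}
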