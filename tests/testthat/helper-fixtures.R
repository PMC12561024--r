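# Fixtures are generated in code; nothing is stored on disk.

# in-memory phantom pairs with group metadata
make_phantom_pairs <- function(n, size = 64L, empty_fraction = 0,
                               n_groups = 8L, seed = 1L,
                               spacing = 0.4) {
  pc <- phantom_config(height_px = size, width_px = size,
                       pixel_spacing_mm = spacing,
                       bone_depth_range_px = c(round(0.4 * size), size - 9L),
                       empty_fraction = empty_fraction)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    s <- render_sample(pc)
    list(frame = s$frame$pixels, label = s$label,
         meta = list(group_id = sprintf("g%02d", (i - 1) %% n_groups + 1),
                     anatomy = boneseg:::PHANTOM_ANATOMIES[(i - 1) %% 6 + 1]))
  })
}

# a small random binary mask mixing blobs and line segments
random_small_mask <- function(h = 24, w = 24, rng = NULL) {
  m <- matrix(0L, h, w)
  n_seg <- sample(1:3, 1)
  for (s in seq_len(n_seg)) {
    if (stats::runif(1) < 0.5) {  # horizontal-ish segment
      r <- sample(2:(h - 1), 1); c0 <- sample(1:(w - 6), 1)
      len <- sample(4:10, 1)
      cols <- c0:min(w, c0 + len)
      rows <- pmin(pmax(r + cumsum(sample(-1:1, length(cols), TRUE,
                                          prob = c(.2, .6, .2))), 1), h)
      m[cbind(rows, cols)] <- 1L
    } else {  # small blob
      r <- sample(3:(h - 2), 1); c <- sample(3:(w - 2), 1)
      m[max(1, r - 1):min(h, r + 1), max(1, c - 1):min(w, c + 1)] <- 1L
    }
  }
  m
}

# --- independent brute-force oracles (coordinate-set arithmetic in R) -----

as_key <- function(pts) paste(pts[, 1], pts[, 2])

oracle_cl_dice <- function(pred, label) {
  sp <- which(skeletonize(pred) == 1, arr.ind = TRUE)
  sl <- which(skeletonize(label) == 1, arr.ind = TRUE)
  vp <- which(pred == 1, arr.ind = TRUE)
  vl <- which(label == 1, arr.ind = TRUE)
  if (nrow(sp) == 0 && nrow(sl) == 0) return(1)
  if (nrow(sp) == 0 || nrow(sl) == 0) return(0)
  tprec <- sum(as_key(sp) %in% as_key(vl)) / nrow(sp)
  tsens <- sum(as_key(sl) %in% as_key(vp)) / nrow(sl)
  if (tprec + tsens == 0) 0 else 2 * tprec * tsens / (tprec + tsens)
}

oracle_msd <- function(pred, label, spacing = c(1, 1)) {
  sp <- which(skeletonize(pred) == 1, arr.ind = TRUE)
  sl <- which(skeletonize(label) == 1, arr.ind = TRUE)
  if (nrow(sp) == 0 || nrow(sl) == 0) return(NA_real_)
  mins <- numeric(nrow(sl))
  for (i in seq_len(nrow(sl))) {
    best <- Inf
    for (j in seq_len(nrow(sp))) {
      d <- sqrt(((sl[i, 1] - sp[j, 1]) * spacing[1])^2 +
                  ((sl[i, 2] - sp[j, 2]) * spacing[2])^2)
      if (d < best) best <- d
    }
    mins[i] <- best
  }
  mean(mins)
}

tiny_unext_cfg <- function(size = 32L) {
  unext_config(conv_channels = c(2L, 3L, 4L), embed_dims = c(5L, 6L),
               input_size = c(size, size))
}
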