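# Independent brute-force oracles used to validate the package's compiled
# and vectorised implementations. Deliberately naive.

# connected-component labelling by iterative minimum-label propagation
flood_fill_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  n <- prod(d)
  lab <- array(0L, d)
  lab[mask > 0] <- which(mask > 0)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  m <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[switch(as.character(connectivity),
                      "6" = m == 1, "18" = m <= 2, "26" = rep(TRUE, nrow(offs))), ]
  shift <- function(a, dx, dy, dz) {
    out <- array(0L, d)
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    out[xs, ys, zs] <- a[xs - dx, ys - dy, zs - dz]
    out
  }
  repeat {
    new <- lab
    for (i in seq_len(nrow(offs))) {
      sh <- shift(lab, offs$dx[i], offs$dy[i], offs$dz[i])
      upd <- mask > 0 & sh > 0 & (new == 0 | sh < new)
      new[upd] <- sh[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  # renumber components 1..k by first-voxel scan order
  ids <- sort(unique(lab[lab > 0]))
  out <- array(0L, d)
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

# directed+symmetric Hausdorff by the O(|X||Y|) pair loop
hausdorff_bruteforce <- function(a, b, spacing) {
  ca <- which(a > 0, arr.ind = TRUE)
  cb <- which(b > 0, arr.ind = TRUE)
  ca <- sweep(ca, 2, spacing, "*")
  cb <- sweep(cb, 2, spacing, "*")
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb)
  d2[d2 < 0] <- 0
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

# AUC by comparing every foreground/background score pair
auc_bruteforce <- function(scores, labels) {
  fg <- scores[labels > 0]
  bg <- scores[labels == 0]
  mean(outer(fg, bg, function(u, v) (u > v) + 0.5 * (u == v)))
}

# exact two-sided signed-rank p-value by enumerating all 2^n sign vectors
wilcoxon_enumerate <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  p_le <- mean(ws <= w + 1e-9)
  p_ge <- mean(ws >= w - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

random_mask_volume <- function(dims, p = 0.3) {
  label_volume(array(stats::rbinom(prod(dims), 1, p), dims))
}

# tiny phantom spec for fast structural tests
tiny_phantom_spec <- function(confounder_count = 2L) {
  phantom_spec(
    grid_size = 32,
    cochlea = list(turns = 2, base_radius = 6, tube_radius = 2, taper = 0.5,
                   rise = 3),
    canals = list(list(radius = 6, tube_radius = 1.2, span_deg = 220),
                  list(radius = 6, tube_radius = 1.2, span_deg = 220),
                  list(radius = 6, tube_radius = 1.2, span_deg = 220)),
    vestibule = c(4, 3, 3),
    confounders = list(count = confounder_count, radius_range = c(1.2, 2),
                       min_distance = 5),
    intensity = list(target = 1, bone = 0.3, background = 0.05,
                     texture_amp = 0.05, blur_sigma = 0.8, noise_sigma = 0.03))
}

dice_of <- function(pred, gt) {
  cc <- confusion(pred, gt)
  2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn)
}
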