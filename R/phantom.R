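#' Parametric specification of a synthetic inner-ear phantom
#'
#' The phantom emulates the geometry and intensity structure of a bright bony
#' labyrinth in micro-CT: a tapering spiral cochlear tube, three mutually
#' near-orthogonal semicircular-canal arcs and a vestibule ellipsoid, all
#' connected into a single 26-connected component, embedded in textured bone
#' together with disconnected "air cell" blobs at target-like intensity that
#' confound slice-wise segmentation. Rendering applies Gaussian blur (partial
#' volume effect) and additive Gaussian noise.
#'
#' Defaults give a 64-voxel cube at 0.15 mm isotropic spacing, a foreground
#' fraction of roughly 2 percent, and six confounder blobs.
#'
#' @param grid_size cube edge length in voxels.
#' @param spacing_mm voxel spacing in mm (scalar or length 3).
#' @param cochlea list: `turns`, `base_radius`, `tube_radius`, `taper` in
#'   (0,1) (tube and spiral radius shrink by this fraction over the turns),
#'   `rise` (axial climb of the spiral, voxels).
#' @param canals list of lists: `radius`, `tube_radius`, `span_deg`.
#'   Each canal is a partial torus anchored to the vestibule; the three
#'   default canals lie in near-orthogonal planes.
#' @param vestibule ellipsoid semi-axes in voxels, length 3.
#' @param confounders list: `count`, `radius_range` (length 2),
#'   `min_distance` from the labyrinth (voxels; must exceed the blur
#'   support so blobs never merge with the target).
#' @param intensity list: `target`, `bone`, `background`, `texture_amp`,
#'   `blur_sigma` (voxels), `noise_sigma`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 64L,
                         spacing_mm = 0.15,
                         cochlea = list(turns = 2.5, base_radius = 10,
                                        tube_radius = 3, taper = 0.5, rise = 6),
                         canals = list(
                           list(radius = 12, tube_radius = 1.8, span_deg = 240),
                           list(radius = 11, tube_radius = 1.8, span_deg = 240),
                           list(radius = 12, tube_radius = 1.8, span_deg = 240)),
                         vestibule = c(6, 5, 5),
                         confounders = list(count = 6L,
                                            radius_range = c(1.5, 3),
                                            min_distance = 6),
                         intensity = list(target = 1.0, bone = 0.3,
                                          background = 0.05,
                                          texture_amp = 0.08,
                                          blur_sigma = 0.8,
                                          noise_sigma = 0.05)) {
  spec <- list(grid_size = as.integer(grid_size),
               spacing_mm = rep(as.numeric(spacing_mm), length.out = 3),
               cochlea = cochlea, canals = canals,
               vestibule = as.numeric(vestibule),
               confounders = confounders, intensity = intensity)
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (s$grid_size < 16L) stop("phantom_spec: grid_size must be >= 16")
  if (any(s$spacing_mm <= 0)) stop("phantom_spec: spacing must be positive")
  co <- s$cochlea
  if (co$turns <= 0) stop("phantom_spec: cochlea turns must be > 0")
  if (co$taper <= 0 || co$taper >= 1)
    stop("phantom_spec: cochlea taper must be in (0, 1)")
  if (co$base_radius <= 0 || co$tube_radius <= 0)
    stop("phantom_spec: cochlea radii must be > 0")
  for (cn in s$canals)
    if (cn$radius <= 0 || cn$tube_radius <= 0)
      stop("phantom_spec: canal radii must be > 0")
  if (any(s$vestibule <= 0)) stop("phantom_spec: vestibule semi-axes must be > 0")
  cf <- s$confounders
  if (cf$count > 0) {
    if (cf$min_distance <= 3 * s$intensity$blur_sigma)
      stop("phantom_spec: confounder min_distance must exceed the blur support (3 sigma)")
    if (cf$radius_range[1] <= 0 || cf$radius_range[2] < cf$radius_range[1])
      stop("phantom_spec: invalid confounder radius_range")
  }
  invisible(s)
}

#' Preset: phantoms without confounders and with mild noise
#' @param ... overrides forwarded to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
phantom_spec_easy <- function(...) {
  phantom_spec(confounders = list(count = 0L, radius_range = c(1.5, 3),
                                  min_distance = 6),
               intensity = list(target = 1.0, bone = 0.3, background = 0.05,
                                texture_amp = 0.05, blur_sigma = 0.8,
                                noise_sigma = 0.02), ...)
}

#' Read / write a phantom specification as YAML
#' @param path file path.
#' @param spec a `phantom_spec`.
#' @return `read_phantom_spec` returns a `phantom_spec`; `write_phantom_spec`
#'   returns `path` invisibly.
#' @export
read_phantom_spec <- function(path) {
  s <- yaml::read_yaml(path)
  do.call(phantom_spec, s)
}

#' @rdname read_phantom_spec
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

# ---- rasterisation helpers --------------------------------------------------

stamp_ball <- function(mask, center, r) {
  n <- dim(mask)
  lo <- pmax(floor(center - r), 1)
  hi <- pmin(ceiling(center + r), n)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- (xs - center[1])^2
  dy2 <- (ys - center[2])^2
  dz2 <- (zs - center[3])^2
  sub <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
  mask[xs, ys, zs] <- mask[xs, ys, zs] | sub
  mask
}

stamp_tube <- function(mask, points, radii) {
  for (i in seq_len(nrow(points)))
    mask <- stamp_ball(mask, points[i, ], radii[i])
  mask
}

stamp_ellipsoid <- function(mask, center, semi) {
  n <- dim(mask)
  lo <- pmax(floor(center - semi), 1)
  hi <- pmin(ceiling(center + semi), n)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- ((xs - center[1]) / semi[1])^2
  dy2 <- ((ys - center[2]) / semi[2])^2
  dz2 <- ((zs - center[3]) / semi[3])^2
  sub <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
  mask[xs, ys, zs] <- mask[xs, ys, zs] | sub
  mask
}

# Fixed oblique tilt applied to the whole labyrinth. The cochlear spiral and
# canal planes of the real inner ear are oblique to all three cardinal
# anatomical planes, and segmentation difficulty is nearly
# orientation-independent; an axis-aligned spiral would hand one slicing
# orientation a privileged whole-structure view.
labyrinth_rotation <- function(ax_deg = 35, ay_deg = 25) {
  ax <- ax_deg * pi / 180; ay <- ay_deg * pi / 180
  rx <- matrix(c(1, 0, 0,
                 0, cos(ax), sin(ax),
                 0, -sin(ax), cos(ax)), 3, 3)
  ry <- matrix(c(cos(ay), 0, -sin(ay),
                 0, 1, 0,
                 sin(ay), 0, cos(ay)), 3, 3)
  ry %*% rx
}

rotate_about <- function(pts, center, R) {
  sweep(sweep(pts, 2, center, "-") %*% t(R), 2, center, "+")
}

# points along the tapering cochlear spiral (rows = xyz), obliquely tilted
cochlea_points <- function(co, vest, center, R, n_samples = 400L) {
  tt <- seq(0, 1, length.out = n_samples)
  theta <- 2 * pi * co$turns * tt
  r <- co$base_radius * (1 - co$taper * tt)
  sc <- center - c(co$base_radius - vest[1] + 2, 0, 0)
  pts <- cbind(sc[1] + r * cos(theta),
               sc[2] + r * sin(theta),
               sc[3] + co$rise * tt)
  rotate_about(pts, center, R)
}

canal_frames <- function(R) {
  lapply(list(list(e1 = c(0, 1, 0),  e2 = c(0, 0, 1)),
              list(e1 = c(0, 0, 1),  e2 = c(1, 0, 0)),
              list(e1 = c(-1, 0, 0), e2 = c(0, 1, 0))),
         function(fr) list(e1 = as.vector(R %*% fr$e1),
                           e2 = as.vector(R %*% fr$e2)))
}

canal_points <- function(cn, frame, vest, center, n_samples = 240L) {
  span <- cn$span_deg * pi / 180
  phi <- seq(pi - span / 2, pi + span / 2, length.out = n_samples)
  q <- center + (cn$radius - min(vest) + 2) * frame$e1
  t(q + cn$radius * (outer(frame$e1, cos(phi)) + outer(frame$e2, sin(phi))))
}

# separable Gaussian blur with edge-renormalised kernels (constants preserved)
gauss_blur3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  n <- dim(a)
  mk <- function(len) {
    r <- ceiling(3 * sigma)
    A <- matrix(0, len, len)
    for (i in seq_len(len)) {
      j <- max(1, i - r):min(len, i + r)
      w <- exp(-(j - i)^2 / (2 * sigma^2))
      A[i, j] <- w / sum(w)
    }
    A
  }
  out <- a
  for (ax in 1:3) {
    dm <- dim(out)
    m <- mk(dm[1]) %*% matrix(out, dm[1], dm[2] * dm[3])
    out <- aperm(array(m, dm), c(2, 3, 1))
  }
  out
}

rasterise_labyrinth <- function(spec) {
  n <- spec$grid_size
  center <- rep((n + 1) / 2, 3)
  mask <- array(FALSE, c(n, n, n))
  check_fit <- function(pts, r, what) {
    if (any(pts - r < 1) || any(pts + r > n))
      stop("phantom geometry does not fit the grid: ", what,
           " exceeds the ", n, "^3 volume")
  }
  R <- labyrinth_rotation()
  co <- spec$cochlea
  pts <- cochlea_points(co, spec$vestibule, center, R)
  radii <- co$tube_radius * (1 - co$taper * seq(0, 1, length.out = nrow(pts)))
  check_fit(pts, max(radii), "cochlea")
  mask <- stamp_tube(mask, pts, radii)
  frames <- canal_frames(R)
  for (i in seq_along(spec$canals)) {
    cn <- spec$canals[[i]]
    pts <- canal_points(cn, frames[[(i - 1) %% 3 + 1]], spec$vestibule, center)
    check_fit(pts, cn$tube_radius, paste0("canal ", i))
    mask <- stamp_tube(mask, pts, rep(cn$tube_radius, nrow(pts)))
  }
  check_fit(matrix(center, 1), max(spec$vestibule), "vestibule")
  mask <- stamp_ellipsoid(mask, center, spec$vestibule)
  mask
}

place_confounders <- function(spec, label_mask) {
  cf <- spec$confounders
  n <- spec$grid_size
  mask <- array(FALSE, c(n, n, n))
  if (cf$count < 1) return(mask)
  fg <- which(label_mask, arr.ind = TRUE)
  margin <- cf$radius_range[2] + 2
  placed_ctr <- matrix(0, 0, 3)
  placed_r <- numeric(0)
  for (b in seq_len(cf$count)) {
    placed <- FALSE
    for (attempt in 1:1000) {
      r <- runif(1, cf$radius_range[1], cf$radius_range[2])
      ctr <- runif(3, margin, n - margin + 1)
      d <- sqrt((fg[, 1] - ctr[1])^2 + (fg[, 2] - ctr[2])^2 + (fg[, 3] - ctr[3])^2)
      if (min(d) < cf$min_distance + r) next
      # blobs must stay separate from each other too (distinct air cells)
      if (nrow(placed_ctr) > 0) {
        dp <- sqrt(rowSums(sweep(placed_ctr, 2, ctr, "-")^2))
        if (any(dp < placed_r + r + 2)) next
      }
      mask <- stamp_ball(mask, ctr, r)
      placed_ctr <- rbind(placed_ctr, ctr)
      placed_r <- c(placed_r, r)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place confounder ", b,
           " after 1000 attempts; reduce count or min_distance")
  }
  mask
}

#' Generate one synthetic phantom image/label pair
#'
#' Fully determined by `(spec, seed)`. The label is the rasterised labyrinth
#' (exactly one 26-connected component); the image renders the label and the
#' confounder blobs at target intensity over textured bone, then applies
#' Gaussian blur and noise. Confounders never overlap or touch the label.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return An object of class `phantom_sample`: list with `image` ([volume()]),
#'   `label` ([label_volume()]), `spec`, `seed`.
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(seed, {
    n <- spec$grid_size
    lab <- rasterise_labyrinth(spec)
    conf <- place_confounders(spec, lab)
    it <- spec$intensity
    # textured bone block inside a large ellipsoid, dim background outside
    bone <- array(FALSE, c(n, n, n))
    bone <- stamp_ellipsoid(bone, rep((n + 1) / 2, 3), rep(0.47 * n, 3))
    img <- array(it$background, c(n, n, n))
    if (it$texture_amp > 0) {
      tex <- gauss_blur3(array(rnorm(n^3), c(n, n, n)), 1) -
        gauss_blur3(array(rnorm(n^3), c(n, n, n)), 2.5)
      tex <- tex / stats::sd(tex) * it$texture_amp
    } else tex <- array(0, c(n, n, n))
    img[bone] <- it$bone + tex[bone]
    img[lab] <- it$target
    img[conf] <- it$target
    img <- gauss_blur3(img, it$blur_sigma)
    if (it$noise_sigma > 0)
      img <- img + array(rnorm(n^3, 0, it$noise_sigma), c(n, n, n))
    sp <- spec$spacing_mm
    structure(list(image = volume(img, sp),
                   label = label_volume(array(as.double(lab), dim(lab)), sp),
                   confounder_mask = label_volume(array(as.double(conf), dim(conf)), sp),
                   spec = spec, seed = as.integer(seed)),
              class = "phantom_sample")
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %d^3, foreground %.2f%%, seed %d\n",
              x$spec$grid_size, 100 * mean(x$label$data), x$seed))
  invisible(x)
}

# multiply the geometric parameters of a spec by per-sample jitter factors
jitter_spec <- function(spec, amount = 0.1) {
  j <- function(v) v * runif(length(v), 1 - amount, 1 + amount)
  spec$cochlea$base_radius <- j(spec$cochlea$base_radius)
  spec$cochlea$tube_radius <- j(spec$cochlea$tube_radius)
  spec$cochlea$turns <- j(spec$cochlea$turns)
  spec$cochlea$rise <- j(spec$cochlea$rise)
  spec$canals <- lapply(spec$canals, function(cn) {
    cn$radius <- j(cn$radius); cn$tube_radius <- j(cn$tube_radius); cn
  })
  spec$vestibule <- j(spec$vestibule)
  spec
}

#' Generate a reproducible dataset of phantoms
#'
#' Per-sample seeds are derived deterministically from `seed`; unless
#' `jitter = FALSE`, each sample's geometric parameters are independently
#' jittered within +/- 10 percent so samples differ anatomically.
#'
#' @param spec a [phantom_spec()].
#' @param n number of samples.
#' @param seed master seed.
#' @param jitter logical; disable to make all labels identical.
#' @return List of `phantom_sample`s.
#' @export
generate_dataset <- function(spec, n, seed = 1L, jitter = TRUE) {
  stopifnot(n >= 1)
  seeds <- derive_seeds(seed, n)
  lapply(seq_len(n), function(i) {
    s <- if (jitter) with_seed(seeds[i] + 1L, jitter_spec(spec)) else spec
    generate_phantom(s, seeds[i])
  })
}
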