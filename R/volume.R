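#' 3D scalar volume with voxel spacing and anatomical axis labels
#'
#' The common currency of the whole pipeline: a 3D grid of intensities, the
#' physical voxel spacing in mm along each grid axis, and a mapping of the three
#' grid axes onto the anatomical slicing directions (`"sagittal"`, `"coronal"`,
#' `"axial"`). The axis labels determine which grid axis is sliced when a stage
#' of the cascade asks for, say, coronal slices.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric length-3, mm per voxel along each grid axis; all > 0.
#' @param axis_labels character length-3, a permutation of
#'   `c("sagittal", "coronal", "axial")`, giving the anatomical direction of
#'   each grid axis.
#' @return An object of class `volume` with fields `data`, `spacing`,
#'   `axis_labels`.
#' @export
volume <- function(data, spacing = c(1, 1, 1),
                   axis_labels = c("sagittal", "coronal", "axial")) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume: `data` must be a 3D array, got ", length(dim(data)), " dims")
  if (any(dim(data) < 1L)) stop("volume: all grid dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume: `spacing` must be 3 positive finite numbers (mm)")
  axis_labels <- as.character(axis_labels)
  if (length(axis_labels) != 3L || !setequal(axis_labels, ANATOMICAL_AXES))
    stop("volume: `axis_labels` must be a permutation of sagittal/coronal/axial")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, axis_labels = axis_labels),
            class = "volume")
}

#' Binary label volume aligned to an image volume
#'
#' @inheritParams volume
#' @param data 3D array containing only 0 and 1.
#' @return An object of class `c("label_volume", "volume")`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1),
                         axis_labels = c("sagittal", "coronal", "axial")) {
  v <- volume(data, spacing, axis_labels)
  if (!all(v$data %in% c(0, 1)))
    stop("label_volume: data must contain only 0 and 1")
  class(v) <- c("label_volume", "volume")
  v
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, axes %s\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(x$axis_labels, collapse = "/")))
  invisible(x)
}

is_binary <- function(a) all(a %in% c(0, 1))

# Reinterpret an image-valued volume as a label volume (values must be 0/1).
as_label_volume <- function(v) {
  label_volume(v$data, v$spacing, v$axis_labels)
}

axis_to_grid <- function(v, axis) {
  g <- match(axis, v$axis_labels)
  if (is.na(g))
    stop("unknown anatomical axis '", axis, "'; volume axes are ",
         paste(v$axis_labels, collapse = "/"))
  g
}

# ---- file formats -----------------------------------------------------------

nifti_ext <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
nrrd_ext  <- function(path) grepl("\\.nrrd$", path, ignore.case = TRUE)

# Orientation letter of the positive direction of a world axis, NIfTI RAS terms.
labels_from_orientation <- function(ort) {
  lut <- c(R = "sagittal", L = "sagittal", A = "coronal", P = "coronal",
           S = "axial", I = "axial")
  letters <- strsplit(ort, "")[[1]]
  labs <- unname(lut[letters])
  if (length(labs) != 3L || anyNA(labs) || anyDuplicated(labs)) return(NULL)
  labs
}

orientation_from_labels <- function(axis_labels) {
  lut <- c(sagittal = "R", coronal = "A", axial = "S")
  paste(lut[axis_labels], collapse = "")
}

#' Read a 3D volume from NIfTI or NRRD
#'
#' Voxel spacing is taken from the file header. The anatomical axis labels are
#' derived from the header orientation when present; otherwise `axis_labels`
#' must be supplied explicitly (they are never guessed).
#'
#' @param path path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @param axis_labels optional explicit axis labels overriding the header.
#' @return A [volume()].
#' @export
read_volume <- function(path, axis_labels = NULL) {
  if (!file.exists(path)) stop("cannot read volume: no such file '", path, "'")
  if (nifti_ext(path)) {
    img <- RNifti::readNifti(path)
    data <- as.array(img)
    attributes(data) <- list(dim = dim(data))  # drop niftiImage attributes
    if (length(dim(data)) != 3L)
      stop("format error: '", path, "' is not a 3D volume (",
           length(dim(data)), " dimensions)")
    spacing <- as.numeric(RNifti::pixdim(img))[1:3]
    if (any(!is.finite(spacing)) || any(spacing <= 0))
      stop("format error: '", path, "' has missing or zero voxel spacing")
    if (is.null(axis_labels)) {
      ort <- tryCatch(RNifti::orientation(img), error = function(e) NULL)
      if (!is.null(ort)) axis_labels <- labels_from_orientation(ort)
      if (is.null(axis_labels))
        stop("'", path, "' carries no usable orientation; pass `axis_labels`")
    }
    volume(data, spacing, axis_labels)
  } else if (nrrd_ext(path)) {
    nr <- read_nrrd_raw(path)
    if (is.null(axis_labels)) {
      axis_labels <- nr$axis_labels
      if (is.null(axis_labels))
        stop("'", path, "' carries no space directions; pass `axis_labels`")
    }
    volume(nr$data, nr$spacing, axis_labels)
  } else {
    stop("unsupported volume format: '", path, "' (expected .nii/.nii.gz/.nrrd)")
  }
}

#' Read a binary label mask (values are validated to be 0/1)
#' @inheritParams read_volume
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, axis_labels = NULL) {
  v <- read_volume(path, axis_labels)
  as_label_volume(v)
}

#' Write a volume to NIfTI or NRRD (format chosen from the file extension)
#'
#' Data are stored as 64-bit floats so that a write/read round trip reproduces
#' the grid bit-exactly; spacing and axis orientation go into the header.
#'
#' @param v a [volume()] or [label_volume()].
#' @param path output path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume"))
  if (nifti_ext(path)) {
    img <- RNifti::asNifti(v$data)
    RNifti::pixdim(img) <- v$spacing
    # Permuted diagonal xform in RAS world order encodes the axis labels.
    world <- match(v$axis_labels, ANATOMICAL_AXES)
    m <- matrix(0, 4, 4); m[4, 4] <- 1
    for (i in 1:3) m[world[i], i] <- v$spacing[i]
    RNifti::qform(img) <- structure(m, code = 2L)
    RNifti::sform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (nrrd_ext(path)) {
    write_nrrd_raw(v, path)
  } else {
    stop("unsupported volume format: '", path, "' (expected .nii/.nii.gz/.nrrd)")
  }
  invisible(path)
}

# Minimal NRRD0004 reader: attached raw-encoded data, 3D, little endian.
read_nrrd_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic))
    stop("format error: '", path, "' is not an NRRD file")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("format error: '", path, "' header not terminated")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  dim_n <- as.integer(fields[["dimension"]])
  if (is.na(dim_n) || dim_n != 3L)
    stop("format error: '", path, "' is not a 3D volume (dimension ", dim_n, ")")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  enc <- tolower(fields[["encoding"]] %||% "raw")
  if (enc != "raw") stop("unsupported NRRD encoding '", enc, "' in '", path, "'")
  type <- tolower(fields[["type"]])
  rd <- switch(type,
    "double" = list(what = "double", size = 8),
    "float"  = list(what = "double", size = 4),
    "int" = , "signed int" = , "int32" = list(what = "integer", size = 4),
    "short" = , "int16" = list(what = "integer", size = 2),
    "uchar" = , "unsigned char" = , "uint8" = list(what = "integer", size = 1,
                                                   signed = FALSE),
    stop("unsupported NRRD type '", type, "' in '", path, "'"))
  endian <- tolower(fields[["endian"]] %||% "little")
  n <- prod(sizes)
  data <- readBin(con, rd$what, n = n, size = rd$size, endian = endian,
                  signed = !identical(rd$signed, FALSE))
  if (length(data) < n) stop("I/O error: '", path, "' truncated data block")
  spacing <- NULL; axis_labels <- NULL
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    dirs <- lapply(vecs, function(s)
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]]))
    if (length(dirs) == 3L) {
      spacing <- vapply(dirs, function(d) sqrt(sum(d^2)), 0)
      world <- vapply(dirs, function(d) which.max(abs(d)), 0L)
      if (!anyDuplicated(world)) axis_labels <- ANATOMICAL_AXES[world]
    }
  }
  if (is.null(spacing) && !is.null(fields[["spacings"]]))
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  if (is.null(spacing) || length(spacing) != 3L ||
      any(!is.finite(spacing)) || any(spacing <= 0))
    stop("format error: '", path, "' has missing or zero voxel spacing")
  list(data = array(as.double(data), dim = sizes), spacing = spacing,
       axis_labels = axis_labels)
}

write_nrrd_raw <- function(v, path) {
  world <- match(v$axis_labels, ANATOMICAL_AXES)
  dirs <- vapply(1:3, function(i) {
    d <- c(0, 0, 0); d[world[i]] <- v$spacing[i]
    sprintf("(%.17g,%.17g,%.17g)", d[1], d[2], d[3])
  }, "")
  hdr <- c("NRRD0004",
           "# generated by cascadeseg",
           "type: double",
           "dimension: 3",
           "space: right-anterior-superior",
           paste("sizes:", paste(dim(v$data), collapse = " ")),
           paste("space directions:", paste(dirs, collapse = " ")),
           "kinds: domain domain domain",
           "endian: little",
           "encoding: raw",
           "space origin: (0,0,0)",
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.double(v$data), con, size = 8, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- resampling -------------------------------------------------------------

# Cell-centred sample positions of `size` output voxels on an n-voxel axis,
# clamped to the grid; preserves physical extent (spacing_out = spacing*n/size).
resample_positions <- function(n, size) {
  x <- (seq_len(size) - 0.5) * n / size - 0.5
  pmin(pmax(x, 0), n - 1)
}

interp_matrix <- function(n, size, order) {
  x <- resample_positions(n, size)
  if (order == 1L) {
    A <- matrix(0, size, n)
    lo <- pmin(floor(x), n - 2); lo[n == 1] <- 0
    t <- x - lo
    for (i in seq_len(size)) {
      A[i, lo[i] + 1] <- A[i, lo[i] + 1] + (1 - t[i])
      if (n > 1) A[i, lo[i] + 2] <- A[i, lo[i] + 2] + t[i]
    }
    A
  } else {  # natural cubic spline; interpolation is linear in the data
    A <- matrix(0, size, n)
    if (n < 4) return(interp_matrix(n, size, 1L))
    for (j in seq_len(n)) {
      e <- numeric(n); e[j] <- 1
      A[, j] <- stats::splinefun(0:(n - 1), e, method = "natural")(x)
    }
    A
  }
}

#' Resample a volume to an isotropic cube of a fixed size
#'
#' Physical extent is preserved: the output spacing along axis i is
#' `spacing[i] * dim[i] / size`. Interpolation order 0 is nearest neighbour,
#' 1 is trilinear, 3 (default) is a natural cubic spline applied separably.
#'
#' @param v a [volume()].
#' @param size output edge length in voxels (>= 2).
#' @param order interpolation order, one of 0, 1, 3.
#' @return A [volume()] of dimension `size^3`.
#' @export
resample_to_cube <- function(v, size, order = 3L) {
  stopifnot(inherits(v, "volume"))
  size <- as.integer(size)
  if (is.na(size) || size < 2L) stop("resample_to_cube: `size` must be >= 2")
  if (!order %in% c(0L, 1L, 3L))
    stop("resample_to_cube: interpolation order ", order,
         " is not supported (use 0, 1 or 3)")
  d <- dim(v$data)
  new_spacing <- v$spacing * d / size
  if (order == 0L) {
    idx <- lapply(1:3, function(i) {
      x <- resample_positions(d[i], size)
      pmin(pmax(floor(x + 0.5), 0), d[i] - 1) + 1L
    })
    out <- v$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    A <- lapply(1:3, function(i) interp_matrix(d[i], size, order))
    out <- v$data
    for (ax in 1:3) {
      dm <- dim(out)
      m <- A[[ax]] %*% matrix(out, dm[1], dm[2] * dm[3])
      out <- aperm(array(m, c(size, dm[2], dm[3])), c(2, 3, 1))
    }
  }
  volume(out, new_spacing, v$axis_labels)
}

#' Resample a label mask with nearest-neighbour interpolation
#'
#' Nearest neighbour keeps the mask strictly binary; spline interpolation
#' would introduce fractional label values.
#'
#' @param l a [label_volume()].
#' @inheritParams resample_to_cube
#' @return A [label_volume()] of dimension `size^3`.
#' @export
resample_label <- function(l, size) {
  stopifnot(inherits(l, "label_volume"))
  as_label_volume(resample_to_cube(l, size, order = 0L))
}

# ---- intensity normalisation ------------------------------------------------

#' Fit a zero-centre / unit-std intensity normalizer on training volumes
#'
#' Statistics are pooled over the voxels of the supplied (training) volumes
#' only; the API takes just the training list so test data can never leak in.
#' The population standard deviation (divisor n) is used.
#'
#' @param training_volumes list of [volume()]s.
#' @return An object of class `intensity_normalizer` with fields `mean`, `std`.
#' @export
fit_normalizer <- function(training_volumes) {
  if (inherits(training_volumes, "volume")) training_volumes <- list(training_volumes)
  if (length(training_volumes) < 1L) stop("fit_normalizer: need at least one volume")
  pooled <- unlist(lapply(training_volumes, function(v) as.vector(v$data)),
                   use.names = FALSE)
  m <- mean(pooled)
  s <- sqrt(mean((pooled - m)^2))
  if (!is.finite(s) || s <= 0)
    stop("fit_normalizer: degenerate (constant) training data, std = 0")
  structure(list(mean = m, std = s), class = "intensity_normalizer")
}

#' Apply an intensity normalizer voxelwise
#' @param n an `intensity_normalizer` from [fit_normalizer()].
#' @param v a [volume()].
#' @return A [volume()] with data `(v - mean) / std`; geometry unchanged.
#' @export
apply_normalizer <- function(n, v) {
  stopifnot(inherits(n, "intensity_normalizer"), inherits(v, "volume"))
  volume((v$data - n$mean) / n$std, v$spacing, v$axis_labels)
}

# ---- slice stacks -----------------------------------------------------------

#' Ordered stack of 2D slices along an anatomical axis
#'
#' @param slices numeric 4D array `(H, W, C, N)`: N slices of C channels.
#' @param axis the anatomical axis the stack was sliced along.
#' @return An object of class `slice_stack`.
#' @export
slice_stack <- function(slices, axis) {
  if (!is.array(slices) || length(dim(slices)) != 4L)
    stop("slice_stack: `slices` must be a 4D (H, W, C, N) array")
  axis <- match.arg(axis, ANATOMICAL_AXES)
  structure(list(slices = slices, axis = axis), class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("<slice_stack> %d %s slices of %dx%d, %d channel(s)\n",
              d[4], x$axis, d[1], d[2], d[3]))
  invisible(x)
}

#' Partition a volume into 2D slices along an anatomical axis
#'
#' Slice k is the k-th grid plane along the grid axis labelled `axis`; the two
#' in-plane grid axes keep their ascending order. Exact inverse of
#' [assemble_volume()].
#'
#' @param v a [volume()].
#' @param axis `"axial"`, `"coronal"` or `"sagittal"`.
#' @return A single-channel [slice_stack()].
#' @export
extract_slices <- function(v, axis) {
  stopifnot(inherits(v, "volume"))
  g <- axis_to_grid(v, axis)
  others <- setdiff(1:3, g)
  arr <- aperm(v$data, c(others, g))
  dim(arr) <- c(dim(arr)[1:2], 1L, dim(arr)[3])
  slice_stack(arr, axis)
}

#' Reassemble a slice stack into a volume on a template's geometry
#'
#' @param s a single-channel [slice_stack()].
#' @param template a [volume()] providing shape, spacing and axis labels.
#' @return A [volume()]; `assemble_volume(extract_slices(v, a), v)` is `v`
#'   bit-exactly for every axis `a`.
#' @export
assemble_volume <- function(s, template) {
  stopifnot(inherits(s, "slice_stack"), inherits(template, "volume"))
  g <- axis_to_grid(template, s$axis)
  others <- setdiff(1:3, g)
  d <- dim(s$slices)
  td <- dim(template$data)
  if (d[3] != 1L)
    stop("assembly error: slice stack has ", d[3], " channels, expected 1")
  if (d[4] != td[g] || !all(d[1:2] == td[others]))
    stop("assembly error: stack of ", d[4], " slices ", d[1], "x", d[2],
         " does not match template ", paste(td, collapse = "x"),
         " along ", s$axis)
  arr <- array(s$slices, c(d[1], d[2], d[4]))
  perm <- c(others, g)
  volume(aperm(arr, order(perm)), template$spacing, template$axis_labels)
}
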