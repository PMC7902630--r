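test_that("binarize uses a strict threshold and is idempotent", {
  p <- volume(array(0.5, c(3, 3, 3)))
  expect_identical(sum(binarize(p, 0.5)$data), 0)   # ties fall to background
  q <- volume(array(c(0.2, 0.7), c(2, 1, 1)))
  expect_identical(as.vector(binarize(q, 0.5)$data), c(0, 1))
  b <- binarize(q, 0.5)
  expect_identical(binarize(b, 0.3)$data, b$data)   # idempotent on binary input
  expect_error(binarize(volume(array(1.5, c(1, 1, 1)))), "\\[0, 1\\]")
})

test_that("largest_component keeps the biggest blob and respects connectivity", {
  m <- array(0, c(8, 8, 8))
  m[1:5, 1, 1] <- 1           # 5 voxels
  m[1:5, 5:6, 5] <- 1         # 10 voxels
  out <- largest_component(label_volume(m), 26)
  expect_identical(sum(out$data), 10)
  expect_true(all(out$data[1:5, 5:6, 5] == 1))
  # diagonal voxels: one component under 26, two under 6
  d <- array(0, c(3, 3, 3)); d[1, 1, 1] <- 1; d[2, 2, 1] <- 1
  expect_identical(sum(largest_component(label_volume(d), 26)$data), 2)
  expect_identical(sum(largest_component(label_volume(d), 6)$data), 1)
  # empty input passes through with a warning
  e <- label_volume(array(0, c(2, 2, 2)))
  expect_warning(out <- largest_component(e), "empty")
  expect_identical(sum(out$data), 0)
})

test_that("largest_component matches flood-fill: idempotent, subset, connected", {
  set.seed(77)
  for (case in 1:60) {
    m <- random_mask_volume(c(16, 16, 16), p = runif(1, 0.05, 0.4))
    conn <- sample(c(6L, 18L, 26L), 1)
    out <- suppressWarnings(largest_component(m, conn))
    oracle <- flood_fill_components(m$data, conn)
    if (max(oracle) > 0) {
      sizes <- tabulate(oracle[oracle > 0])
      expect_identical(as.integer(sum(out$data)), max(sizes))
      # subset of input
      expect_true(all(out$data <= m$data))
      # output is a single oracle component
      expect_lte(max(flood_fill_components(out$data, conn)), 1L)
      # idempotence
      expect_identical(suppressWarnings(largest_component(out, conn))$data,
                       out$data)
      # deterministic tie-break: earliest component in scan order among maxima
      winners <- which(sizes == max(sizes))
      got <- unique(oracle[out$data > 0])
      expect_identical(got, min(winners))
    }
  }
})

test_that("stack_stage_input lays out channels in stage order", {
  set.seed(12)
  img <- volume(array(rnorm(8^3), c(8, 8, 8)))
  m1 <- random_mask_volume(c(8, 8, 8))
  m2 <- random_mask_volume(c(8, 8, 8))
  # no priors reduces to plain slicing
  s0 <- stack_stage_input(img, list(), "axial")
  expect_identical(s0$slices, extract_slices(img, "axial")$slices)
  # one prior: channel 2 is the binary mask
  s1 <- stack_stage_input(img, list(m1), "coronal")
  expect_true(all(s1$slices[, , 2, ] %in% c(0, 1)))
  # two priors along axial: verify channel order voxel by voxel
  s2 <- stack_stage_input(img, list(m1, m2), "axial")
  expect_identical(dim(s2$slices), c(8L, 8L, 3L, 8L))
  ax <- which(img$axis_labels == "axial")
  for (k in c(1, 5)) {
    sl <- function(v) extract_slices(v, "axial")$slices[, , 1, k]
    expect_identical(s2$slices[, , 1, k], sl(img))
    expect_identical(s2$slices[, , 2, k], sl(m1))
    expect_identical(s2$slices[, , 3, k], sl(m2))
  }
  bad <- label_volume(array(0, c(4, 4, 4)))
  expect_error(stack_stage_input(img, list(bad), "axial"), "geometry")
})

test_that("ground-truth stubs make the cascade a fixed point", {
  ph <- generate_phantom(tiny_phantom_spec(2L), 4)
  gtprob <- volume(ph$label$data, ph$label$spacing)
  stubs <- lapply(1:3, function(s) stub_seg_model(gtprob, s))
  cm <- cascade_model(stubs, cascade_config(), normalizer = NULL)
  out <- run_cascade(cm, ph$image)
  expect_identical(out$data, ph$label$data)
  expect_lte(max(flood_fill_components(out$data, 26)), 1L)
})

test_that("a spurious blob from stage 1 is removed before stage 2", {
  ph <- generate_phantom(tiny_phantom_spec(0L), 4)
  noisy <- ph$label$data
  noisy[2:3, 2:3, 2] <- 1   # small disconnected blob
  stub1 <- stub_seg_model(volume(noisy, ph$label$spacing), 1)
  gtprob <- volume(ph$label$data, ph$label$spacing)
  cm <- cascade_model(list(stub1,
                           stub_seg_model(gtprob, 2),
                           stub_seg_model(gtprob, 3)),
                      cascade_config(), NULL)
  stages <- run_cascade(cm, ph$image, return_stages = TRUE)
  expect_identical(stages[[1]]$data, ph$label$data)
})

test_that("all-zero stages propagate empty masks with stage warnings", {
  ph <- generate_phantom(tiny_phantom_spec(0L), 4)
  zero <- volume(array(0, dim(ph$label$data)), ph$label$spacing)
  zs <- lapply(1:3, function(s) stub_seg_model(zero, s))
  cm <- cascade_model(zs, cascade_config(), NULL)
  warns <- character(0)
  out <- withCallingHandlers(run_cascade(cm, ph$image),
                             warning = function(w) {
                               warns <<- c(warns, conditionMessage(w))
                               invokeRestart("muffleWarning")
                             })
  expect_identical(sum(out$data), 0)
  expect_length(warns, 3)
  expect_match(warns[2], "stage 2")
})

test_that("axis order permutations keep the output contracts", {
  ph <- generate_phantom(tiny_phantom_spec(0L), 6)
  gtprob <- volume(ph$label$data, ph$label$spacing)
  for (ord in list(c("axial", "coronal", "sagittal"),
                   c("sagittal", "axial", "coronal"))) {
    cm <- cascade_model(lapply(1:3, function(s) stub_seg_model(gtprob, s)),
                        cascade_config(axis_order = ord), NULL)
    out <- run_cascade(cm, ph$image)
    expect_true(all(out$data %in% c(0, 1)))
    expect_lte(max(flood_fill_components(out$data, 26)), 1L)
  }
})

test_that("train_cascade runs one epoch, checkpoints stages, and is reproducible", {
  set.seed(2)
  sp <- tiny_phantom_spec(0L)
  sp$grid_size <- 16L
  sp$cochlea <- list(turns = 1.5, base_radius = 3.5, tube_radius = 1.2,
                     taper = 0.5, rise = 1)
  sp$canals <- list(list(radius = 3, tube_radius = 1, span_deg = 200))
  sp$vestibule <- c(2.5, 2, 2)
  ds <- generate_dataset(sp, 2, seed = 6)
  stage_cfg <- lapply(1:3, function(s)
    seg_model_config("unet", s, depth = 1, base_filters = 2,
                     input_size = c(16, 16)))
  ccfg <- cascade_config(stage_configs = stage_cfg)
  tcfg <- train_config(learning_rate = 1e-3, batch_size = 8, max_epochs = 1,
                       early_stop_patience = 1, seed = 4)
  dir <- tempfile()
  cm <- train_cascade(ds, ccfg, tcfg, checkpoint_dir = dir)
  expect_true(all(file.exists(file.path(dir, paste0("stage", 1:3, ".rds")))))
  expect_s3_class(run_cascade(cm, ds[[1]]$image), "label_volume")
  # deterministic re-run gives identical weights
  cm2 <- train_cascade(ds, ccfg, tcfg)
  for (s in 1:3)
    expect_identical(cm$stages[[s]]$params, cm2$stages[[s]]$params)
  unlink(dir, recursive = TRUE)
})
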