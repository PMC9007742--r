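# File formats, pipeline configuration and end-to-end orchestration.

test_that("oblique stacks round-trip through TIFF plus sidecar", {
  withr::with_seed(1, {
    dat <- array(sample(0:65535, 6 * 20 * 24, TRUE), c(6, 20, 24))
  })
  st <- oblique_stack(dat, acq_geometry(0.5, 0.146, view_id = 2,
                                        scan_origin_um = -3.5))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  back <- read_stack(path)
  expect_true(all(back$data == st$data))
  expect_equal(back$geometry$pixel_size_um, 0.146)
  expect_equal(back$geometry$view_id, 2L)
  expect_equal(back$geometry$scan_origin_um, -3.5)

  # malformed inputs are rejected with clear messages
  expect_error(read_stack(file.path(tempdir(), "absent.tif")), "no such file")
  bad <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, bad)
  meta <- jsonlite::read_json(paste0(bad, ".json"))
  meta$pixel_size_um <- NULL
  jsonlite::write_json(meta, paste0(bad, ".json"), auto_unbox = TRUE)
  expect_error(read_stack(bad), "pixel_size_um")
  expect_error(write_stack(oblique_stack(array(0.5, c(2, 2, 2)),
                                         acq_geometry(1, 1)),
                           withr::local_tempfile(fileext = ".tif")),
               "16-bit")
})

test_that("float volumes survive 16-bit export within one count", {
  withr::with_seed(2, {
    v <- ortho_volume(array(stats::runif(10 * 12 * 14, 0, 4000), c(10, 12, 14)),
                      c(0.5, 0.4, 0.3), origin_um = c(0, 0, -2))
  })
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, path)
  back <- read_volume(path)
  scale <- jsonlite::read_json(paste0(path, ".json"))$scale
  expect_lt(max(abs(back$data - v$data)), scale + 1e-9)
  expect_equal(back$voxel_size_um, v$voxel_size_um)
  expect_equal(back$origin_um, v$origin_um)
})

test_that("the chunked store round-trips losslessly and never expands much", {
  withr::with_seed(3, {
    arr <- array(stats::rpois(48^3, 400), c(48, 48, 48))
  })
  path <- file.path(withr::local_tempdir(), "store")
  write_chunked_store(arr, path, chunks = c(32, 32, 32), dtype = "u2",
                      attrs = list(voxel_size_um = c(1, 1, 1)))
  back <- read_chunked_store(path)
  expect_true(all(back$data == arr))
  expect_equal(unlist(back$attrs$voxel_size_um), c(1, 1, 1))
  raw_bytes <- prod(dim(arr)) * 2
  stored <- sum(file.size(list.files(path, all.files = TRUE,
                                     full.names = TRUE, no.. = TRUE)))
  expect_gte(raw_bytes / stored, 0.99)

  # float32 intermediates round-trip to float precision
  fpath <- file.path(withr::local_tempdir(), "fstore")
  fv <- arr + 0.25
  write_chunked_store(fv, fpath, dtype = "f4")
  expect_lt(max(abs(read_chunked_store(fpath)$data - fv)), 1e-3)
})

test_that("pipeline configs validate stage names and order", {
  ok <- pipeline_config(list(deskew = list(), register = list(),
                             fuse = list()))
  expect_s3_class(ok, "pipeline_config")
  expect_error(pipeline_config(list(deskew = list(), sharpen = list())),
               "unknown pipeline stage")
  expect_error(pipeline_config(list(fuse = list(), register = list())),
               "out of order")
  expect_error(pipeline_config(list(list())), "named list")
})

test_that("the pipeline processes a dual-view time series end to end", {
  drift <- rbind(c(0, 0, 0), c(1.5, -1, 0.5), c(3, -2, 1),
                 c(2, -0.8, 1.6), c(1, 0.4, 0.8))
  tps <- mk_drift_scene_frames(drift)
  out_dir <- withr::local_tempdir()
  cfg <- pipeline_config(
    list(deskew = list(),
         register = list(config = registration_config(max_iterations = 2,
                                                      min_chunk_voxels = 16)),
         fuse = list(),
         stabilize = list(n_neighbors = 3)),
    output_dir = out_dir, log_level = "quiet")
  res <- run_pipeline(cfg, tps)
  expect_length(res$volumes, 5)

  # drift removed: residual pairwise shifts below 0.1 voxel
  resid <- pairwise_shifts(res$volumes, n = 1)
  expect_lt(max(abs(as.matrix(resid[, c("dz", "dy", "dx")]))), 0.1)
  # recovered trajectory tracks the injected drift (z in deskew-grid
  # voxels of p * sin(theta) um); absolute accuracy of correlation on
  # resampled oblique data is a few tenths of a voxel
  expect_lt(max(abs(res$trajectory[, "dz"] - drift[, 1] / sin(pi / 4))), 0.75)

  # products and log on disk
  expect_true(file.exists(file.path(out_dir, "processed_t001.tif")))
  expect_true(file.exists(file.path(out_dir, "trajectory.json")))
  logj <- jsonlite::read_json(file.path(out_dir, "pipeline_log.json"))
  expect_named(logj$checksums)
})

test_that("identical pipeline runs reproduce outputs bit-exactly", {
  drift <- rbind(c(0, 0, 0), c(1.5, -1, 0.5))
  tps <- mk_drift_scene_frames(drift)
  stages <- list(deskew = list(),
                 register = list(config = registration_config(
                   max_iterations = 1, min_chunk_voxels = 16)),
                 fuse = list())
  outs <- c(withr::local_tempdir(), withr::local_tempdir())
  for (od in outs) {
    run_pipeline(pipeline_config(stages, output_dir = od,
                                 log_level = "quiet"), tps)
  }
  for (t in 1:2) {
    f <- sprintf("processed_t%03d.tif", t)
    expect_identical(unname(tools::md5sum(file.path(outs[1], f))),
                     unname(tools::md5sum(file.path(outs[2], f))))
  }
})

test_that("stage failures name the failing stage", {
  g1 <- acq_geometry(1, 1, view_id = 1)
  st <- oblique_stack(array(1, c(8, 8, 8)), g1)
  cfg <- pipeline_config(list(illumination_correct = list()),
                         log_level = "quiet")
  # illumination correction without a profile fails, naming the stage
  tp <- list(list(view1 = deskew(st)))
  expect_error(run_pipeline(cfg, tp), "illumination_correct")
})
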