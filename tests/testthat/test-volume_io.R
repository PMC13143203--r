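test_that("integer stacks round trip losslessly through TIFF", {
  set.seed(11)
  arr <- array(sample(0:255, 2 * 3 * 6 * 5, TRUE), dim = c(2, 3, 6, 5))
  stk <- volume_stack(arr, c("DAPI", "EdU"))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(stk, path, bits = 16L)
  back <- read_stack(path, c(DAPI = 1, EdU = 2))
  expect_identical(dim(back$data), dim(arr))
  expect_equal(back$data, arr, ignore_attr = TRUE)
  expect_identical(back$channel_names, c("DAPI", "EdU"))
})

test_that("channel_map permutes channels and nothing else", {
  set.seed(12)
  arr <- array(sample(0:99, 2 * 2 * 4 * 4, TRUE), dim = c(2, 2, 4, 4))
  stk <- volume_stack(arr, c("A", "B"))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(stk, path)
  fwd <- read_stack(path, c(A = 1, B = 2))
  rev <- read_stack(path, c(B = 2, A = 1))
  expect_equal(get_channel(fwd, "A"), get_channel(rev, "A"))
  expect_equal(get_channel(fwd, "B"), get_channel(rev, "B"))
  expect_identical(rev$channel_names, c("B", "A"))
})

test_that("single-plane TIFF loads as a z = 1 stack", {
  arr <- array(sample(0:9, 1 * 1 * 4 * 3, TRUE), dim = c(1, 1, 4, 3))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(volume_stack(arr, "DAPI"), path)
  back <- read_stack(path, c(DAPI = 1))
  expect_identical(dim(back$data), c(1L, 1L, 4L, 3L))
})

test_that("out-of-range channel indices and bad files are rejected", {
  arr <- array(0:15, dim = c(2, 1, 4, 2))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(volume_stack(arr, c("A", "B")), path)
  expect_error(read_stack(path, c(X = 3)), "out of range|not a multiple")
  expect_error(read_stack(tempfile(), c(A = 1)), "not found")
  txt <- withr::local_tempfile(fileext = ".tif")
  writeLines("not a tiff", txt)
  expect_error(read_stack(txt, c(A = 1)), "TIFF")
})

test_that("VolumeStack invariants are enforced", {
  arr <- array(1, dim = c(2, 2, 2, 2))
  expect_error(volume_stack(arr, c("A", "A")), "unique")
  expect_error(volume_stack(arr, "A"), "length")
  bad <- arr; bad[1] <- -1
  expect_error(volume_stack(bad, c("A", "B")), "finite")
  expect_error(volume_stack(array(1, c(2, 2, 2)), c("A", "B")), "4D")
})

test_that("masks round trip bit-exactly", {
  m <- array(FALSE, dim = c(4, 4, 4))
  path <- withr::local_tempfile(fileext = ".tif")
  write_mask(m, path)
  expect_identical(read_mask(path), m)
  set.seed(21)
  m2 <- array(runif(5 * 6 * 7) > 0.5, dim = c(5, 6, 7))
  write_mask(m2, path)
  expect_identical(read_mask(path), m2)
  expect_error(write_mask(array(1, c(2, 2, 2)), path), "logical")
})

test_that("quantification reports round trip at full precision", {
  rec <- data.frame(organoid_id = c("a", "b"),
                    edu_positive_voxels = c(100L, 3L),
                    dapi_positive_voxels = c(400L, 9L),
                    edu_dapi_ratio = c(0.25, 1 / 3),
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(rec, path)
  back <- read_report(path)
  expect_equal(nrow(back), 2L)
  expect_identical(back$organoid_id, rec$organoid_id)
  expect_identical(back$edu_dapi_ratio, rec$edu_dapi_ratio)
  expect_error(write_report(rec[0, ], path), "non-empty")
})

test_that("polygon ROIs validate and round trip as JSON", {
  roi <- polygon_roi(rbind(c(0, 0), c(4, 0), c(0, 3)), 1, "bud1")
  path <- withr::local_tempfile(fileext = ".json")
  write_roi(roi, path)
  back <- read_roi(path)
  expect_equal(back$vertices, roi$vertices)
  expect_equal(back$scale_px_per_um, 1)
  expect_identical(back$label, "bud1")
  # bow-tie self-intersection must be rejected
  expect_error(polygon_roi(rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2)), 1),
               "self-intersecting")
  expect_error(polygon_roi(rbind(c(0, 0), c(1, 1)), 1), "3 vertices")
  expect_error(polygon_roi(rbind(c(0, 0), c(4, 0), c(0, 3)), 0), "positive")
})

test_that("pipeline configs load from YAML and JSON with defaults applied", {
  ypath <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("channels:",
               "  DAPI:",
               "    role: nuclear",
               "  EdU:",
               "    role: proliferation",
               "    gaussian_sigma: 0.7",
               "seed: 99"), ypath)
  cfg <- read_pipeline_config(ypath)
  expect_equal(cfg$channels$DAPI$otsu_factor, 0.5)
  expect_equal(cfg$channels$EdU$otsu_factor, 0.2)
  expect_equal(cfg$channels$EdU$gaussian_sigma, 0.7)
  expect_equal(cfg$seed, 99)
  jpath <- withr::local_tempfile(fileext = ".json")
  writeLines('{"channels": {"DAPI": {"role": "nuclear"}}}', jpath)
  expect_equal(read_pipeline_config(jpath)$channels$DAPI$erosion_radius, 3L)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("channels: {}", bad)
  expect_error(read_pipeline_config(bad), "at least one")
})

test_that("OME-XML metadata drives channel layout and voxel size", {
  ome <- paste0(
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image><Pixels SizeZ="4" SizeC="2" DimensionOrder="XYCZT" ',
    'PhysicalSizeZ="2" PhysicalSizeY="0.5" PhysicalSizeX="0.5"/>',
    '</Image></OME>')
  layout <- tastequant:::parse_ome_layout(ome)
  expect_equal(layout$size_z, 4L)
  expect_equal(layout$size_c, 2L)
  expect_equal(layout$dimension_order, "XYCZT")
  expect_equal(layout$physical_z, 2)
  expect_null(tastequant:::parse_ome_layout("plain text"))
  expect_null(tastequant:::parse_ome_layout(NULL))
})

test_that("OME-TIFFs written by an independent tool load faithfully", {
  tmp <- withr::local_tempdir()
  ome_path <- file.path(tmp, "stack.ome.tif")
  script <- file.path(tmp, "make_ome.py")
  writeLines(c(
    "import numpy as np, tifffile, sys",
    "rng = np.random.default_rng(123)",
    "arr = rng.integers(0, 255, size=(3, 2, 8, 6)).astype('uint8')",
    "tifffile.imwrite(sys.argv[1], arr, ome=True,",
    "                 metadata={'axes': 'ZCYX'})",
    "np.savetxt(sys.argv[2], arr.reshape(-1), fmt='%d')"), script)
  ref_path <- file.path(tmp, "ref.txt")
  status <- system2("python", c(script, ome_path, ref_path),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  stk <- read_stack(ome_path, c(DAPI = 1, EdU = 2))
  expect_identical(dim(stk$data), c(2L, 3L, 8L, 6L))
  ref <- array(scan(ref_path, quiet = TRUE), dim = rev(c(3, 2, 8, 6)))
  ref <- aperm(ref, 4:1)  # back to (z, c, y, x)
  expect_equal(get_channel(stk, "DAPI"), ref[, 1, , ], ignore_attr = TRUE)
  expect_equal(get_channel(stk, "EdU"), ref[, 2, , ], ignore_attr = TRUE)
})
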