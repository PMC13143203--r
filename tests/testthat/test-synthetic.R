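test_that("the stack generator is a pure function of its seed", {
  a <- simulate_organoid_stack(shape = c(16, 32, 32), n_nuclei = 4,
                               nucleus_radius = 4, seed = 5)
  b <- simulate_organoid_stack(shape = c(16, 32, 32), n_nuclei = 4,
                               nucleus_radius = 4, seed = 5)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$centers, b$truth$centers)
  c <- simulate_organoid_stack(shape = c(16, 32, 32), n_nuclei = 4,
                               nucleus_radius = 4, seed = 6)
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("generated nuclei respect the packing invariants", {
  sim <- simulate_organoid_stack(shape = c(24, 48, 48), n_nuclei = 10,
                                 nucleus_radius = 4, edu_fraction = 0.5,
                                 seed = 7)
  ctr <- sim$truth$centers
  r <- sim$truth$radii
  expect_true(all(ctr >= r + 1 & ctr <= rep(sim$truth$shape, each = 10) - r))
  dmin <- min(stats::dist(ctr))
  expect_gte(dmin, 2 * r[1])
  expect_length(sim$truth$edu_labels, 10)
  expect_equal(sum(sim$truth$edu_labels), 5)  # exact-count labeling
  expect_error(simulate_organoid_stack(shape = c(12, 12, 12), n_nuclei = 50,
                                       nucleus_radius = 5, seed = 1,
                                       max_tries = 500),
               "packing|accommodate")
})

test_that("edu_fraction 0 leaves the EdU channel without signal", {
  sim <- simulate_organoid_stack(shape = c(20, 40, 40), n_nuclei = 6,
                                 nucleus_radius = 4, edu_fraction = 0,
                                 seed = 8)
  expect_false(any(sim$truth$edu_labels))
  edu <- get_channel(sim$stack, "EdU")
  expect_lt(max(edu), 0.2)  # background 0.02 + noise, far below signal 1
  # a truly signal-free (all-zero) channel flows through to an empty
  # mask and ratio 0; a noise-only channel does not (min-max
  # normalization stretches pure noise, a documented Otsu limitation)
  arr <- sim$stack$data
  arr[2, , , ] <- 0
  stk <- volume_stack(arr, c("DAPI", "EdU"))
  dapi_seg <- segment_channel(stk, "DAPI", channel_params("nuclear"))
  edu_seg <- segment_channel(stk, "EdU", channel_params("proliferation"))
  expect_equal(edu_dapi_ratio(edu_seg$mask, dapi_seg$mask), 0)
})

test_that("truth manifests round trip through JSON", {
  sim <- simulate_organoid_stack(shape = c(16, 32, 32), n_nuclei = 4,
                                 nucleus_radius = 4, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back$centers, sim$truth$centers)
  expect_identical(back$edu_labels, sim$truth$edu_labels)
  expect_equal(back$noise_sd, sim$truth$noise_sd)
  expect_identical(back$shape, sim$truth$shape)
})

test_that("lick sessions have the block structure and are seed-stable", {
  means <- c(water = 30, c30 = 35, c100 = 45, c300 = 55, c1000 = 60)
  s1 <- simulate_lick_session(means, seed = 10)
  s2 <- simulate_lick_session(means, seed = 10)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 8 * 5)
  for (b in 1:8)
    expect_setequal(s1$bottle[s1$block == b], names(means))
  zero <- simulate_lick_session(c(water = 0, c1 = 0), seed = 11)
  expect_true(all(zero$licks == 0))
  expect_error(simulate_lick_session(c(30, 60), seed = 1), "named")
})

test_that("lick-ratio recovery from the generative means", {
  # water mean 30, tastant mean 60 -> ratio near 2 pooled over two days
  ratios <- vapply(1:20, function(s) {
    d1 <- simulate_lick_session(c(water = 30, c1 = 60), day = 1,
                                seed = 1000 + s)
    d2 <- simulate_lick_session(c(water = 30, c1 = 60), day = 2,
                                seed = 2000 + s)
    lick_ratio(rbind(d1, d2), "c1")
  }, numeric(1))
  expect_true(all(abs(ratios - 2) <= 0.2 * 2))
  expect_lt(abs(mean(ratios) - 2), 0.2)
})

test_that("ct tables encode exact folds at zero noise", {
  tab <- simulate_ct_table(c(Plcb2 = -1), n_per_group = 3,
                           ct_noise_sd = 0, seed = 12)
  out <- ddct_fold_change(tab, "Plcb2")
  expect_equal(out$fold_change[out$group == "treated"], rep(0.5, 3))
  expect_equal(out$fold_change[out$group == "control"], rep(1, 3))
  tab0 <- simulate_ct_table(c(Plcb2 = 0), n_per_group = 3,
                            ct_noise_sd = 0, seed = 13)
  expect_equal(ddct_fold_change(tab0, "Plcb2")$fold_change, rep(1, 6))
})

test_that("noisy ct tables recover the fold within the Monte-Carlo band", {
  folds <- vapply(1:20, function(s) {
    tab <- simulate_ct_table(c(Gnat3 = 2), n_per_group = 6,
                             ct_noise_sd = 0.1, seed = 3000 + s)
    out <- ddct_fold_change(tab, "Gnat3")
    exp(mean(log(out$fold_change[out$group == "treated"])))
  }, numeric(1))
  # the across-seed estimate sits in the band; individual seeds may
  # stray ~2.5 sd under the noise model, so allow at most 2 of 20 out
  expect_gte(mean(folds), 3.5)
  expect_lte(mean(folds), 4.6)
  expect_gte(sum(folds >= 3.5 & folds <= 4.6), 18L)
})
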