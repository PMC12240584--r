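test_that("noiseless rendering and detection round-trip a static bead", {
  fl <- still_flow(width = 300, height = 300)
  stack <- render_bead_video(fl, n_beads = 1, D_bead = 1e-9, psf_sigma = 2,
                             pixel_size = 1, fps = 5, duration = 1,
                             seed = 3, region = c(0, 300, 0, 300),
                             noise = FALSE)
  sp <- detect_spots(stack, threshold = 1)
  truth_px <- stack$truth[[1]][1, ] / stack$pixel_size
  expect_equal(nrow(sp$spots[[1]]), 1)
  expect_lt(abs(sp$spots[[1]]$x[1] - truth_px[1]), 0.01)
  expect_lt(abs(sp$spots[[1]]$y[1] - truth_px[2]), 0.01)
})

test_that("bead count is preserved across frames (reflection keeps beads)", {
  fx <- small_flow()
  stack <- render_bead_video(fx$flow, n_beads = 12, psf_sigma = 2,
                             pixel_size = 10, fps = 5, duration = 1,
                             seed = 11)
  expect_true(all(vapply(stack$truth, nrow, integer(1)) == 12))
  for (tt in stack$truth) {
    expect_true(all(tt[, 1] >= 0 & tt[, 1] <= fx$config$width))
    expect_true(all(tt[, 2] >= 0 & tt[, 2] <= fx$config$height))
  }
})

test_that("empty frames yield empty spot sets", {
  stack <- structure(list(frames = list(matrix(0, 40, 40)), pixel_size = 1,
                          frame_interval = 0.1, bit_depth = 16),
                     class = "image_stack")
  sp <- detect_spots(stack, threshold = 5)
  expect_equal(nrow(sp$spots[[1]]), 0)
})

test_that("detection localizes to <0.1 px at SNR >= 10 and is translation
           equivariant", {
  img1 <- evapopore:::render_spots(20.3, 25.7, 60, 60, 1, 2, 400)
  set.seed(42)
  noisy <- matrix(rpois(length(img1), img1 + 4), 60, 60) # bg 4, peak ~400
  stack <- structure(list(frames = list(noisy), pixel_size = 1,
                          frame_interval = 0.1, bit_depth = 16),
                     class = "image_stack")
  sp <- detect_spots(stack)$spots[[1]]
  expect_equal(nrow(sp), 1)
  expect_lt(abs(sp$x - 20.3), 0.1)
  expect_lt(abs(sp$y - 25.7), 0.1)
  # integer-pixel shift moves the centroid by exactly that shift
  shifted <- matrix(0, 60, 60)
  shifted[6:60, 4:60] <- noisy[1:55, 1:57]
  st2 <- structure(list(frames = list(shifted), pixel_size = 1,
                        frame_interval = 0.1, bit_depth = 16),
                   class = "image_stack")
  sp2 <- detect_spots(st2)$spots[[1]]
  expect_equal(sp2$x, sp$x + 5, tolerance = 1e-8)
  expect_equal(sp2$y, sp$y + 3, tolerance = 1e-8)
})

test_that("spots below the minimum separation are reported as one", {
  img <- evapopore:::render_spots(c(30, 32), c(30, 31), 60, 60, 1, 1.5, 300)
  stack <- structure(list(frames = list(img), pixel_size = 1,
                          frame_interval = 0.1, bit_depth = 16),
                     class = "image_stack")
  sp <- detect_spots(stack, threshold = 10, min_separation = 5)$spots[[1]]
  expect_equal(nrow(sp), 1)
})

test_that("linking follows a moving spot and fragments ambiguous swaps", {
  # one spot advancing 5 px/frame within a 10 px radius: one full track
  frames <- lapply(0:4, function(k)
    evapopore:::render_spots(10 + 5 * k, 20, 60, 40, 1, 1.5, 300))
  stack <- structure(list(frames = frames, pixel_size = 1,
                          frame_interval = 0.1, bit_depth = 16),
                     class = "image_stack")
  tr <- link_tracks(detect_spots(stack, threshold = 10),
                    max_displacement = 10)
  lens <- vapply(tr$tracks, nrow, integer(1))
  expect_equal(max(lens), 5)
  # two spots swapping positions in one interval: identities are not
  # guessed, so no track spans the swap as a 10 px jump
  f1 <- evapopore:::render_spots(c(10, 40), c(20, 20), 60, 40, 1, 1.5, 300)
  f2 <- evapopore:::render_spots(c(40, 10), c(20, 20), 60, 40, 1, 1.5, 300)
  st2 <- structure(list(frames = list(f1, f2), pixel_size = 1,
                        frame_interval = 0.1, bit_depth = 16),
                   class = "image_stack")
  tr2 <- link_tracks(detect_spots(st2, threshold = 10),
                     max_displacement = 8)
  # no track makes the 30 px identity-crossing jump: the linker keeps each
  # track at its nearest position instead of guessing the exchange
  steps <- unlist(lapply(tr2$tracks, function(tk)
    if (nrow(tk) > 1) sqrt(diff(tk$x)^2 + diff(tk$y)^2) else numeric(0)))
  expect_true(all(steps <= 8))
  expect_equal(length(tr2$tracks), 2)
})

test_that("track speeds convert pixels and frames to um/s", {
  tracks <- structure(list(tracks = list(
    data.frame(frame = 1:3, x = c(0, 5, 10), y = c(0, 0, 0)),
    data.frame(frame = 1:3, x = c(7, 7, 7), y = c(2, 2, 2)),
    data.frame(frame = 2, x = 1, y = 1)),
    pixel_size = 1, frame_interval = 0.1), class = "track_set")
  sp <- track_velocities(tracks)
  expect_equal(as.numeric(sp), c(50, 50, 0, 0))
  expect_equal(attr(sp, "skipped"), 1L)
})

test_that("velocimetry round trip recovers bulk flow speeds within 10%", {
  # uniform drift field: ground-truth speed known everywhere
  g <- build_grid(chamber_config(width = 600, height = 600, nx = 32, ny = 32,
                                 refine = 1, inflow_rate = 0))
  v_true <- 40                                  # um/s downward drift
  fl <- flow_from_psi(g, v_true * matrix(g$xf, g$nx + 1, g$ny + 1))
  stack <- render_bead_video(fl, n_beads = 25, D_bead = 0.5, psf_sigma = 2,
                             photon_scale = 400, pixel_size = 2, fps = 10,
                             duration = 2, seed = 9,
                             region = c(0, 600, 0, 600))
  tr <- link_tracks(detect_spots(stack), max_displacement = 6)
  sp <- track_velocities(tr)
  expect_gt(length(sp), 50)
  expect_lt(abs(stats::median(sp) - v_true) / v_true, 0.1)
})

test_that("fluorescence quantification inverts the rendering", {
  fx <- small_flow()
  fld <- simulate_transport(fx$flow, solute_spec("mg", 705), duration = 150,
                            snapshot_times = c(0, 150))
  stack0 <- render_fluorescence(fld, photon_scale = 500, noise = FALSE)
  expect_equal(quantify_accumulation(stack0), max(fld$c), tolerance = 0.02)
  stack1 <- render_fluorescence(fld, photon_scale = 500, seed = 2)
  expect_equal(quantify_accumulation(stack1), max(fld$c), tolerance = 0.05)
  # uniform field: ratio 1
  fl0 <- still_flow()
  fu <- simulate_transport(fl0, solute_spec("x", 50), duration = 5,
                           dt = 0.5, snapshot_times = c(0, 5))
  expect_equal(quantify_accumulation(render_fluorescence(fu, noise = FALSE)),
               1, tolerance = 1e-9)
  expect_error(quantify_accumulation(
    render_fluorescence(fu, noise = FALSE), background = 1e9), "reference")
})
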