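## Synthetic microscopy (bead videos, fluorescence stacks) and the particle-
## tracking velocimetry pipeline validated against the generator's ground
## truth: Gaussian-PSF spots, Poisson photon noise + Gaussian read noise,
## bandpass detection with subpixel centroids, nearest-neighbor linking.

#' Render a synthetic bead video from a solved flow
#'
#' Beads are advected with the flow plus Brownian motion (same
#' Euler-Maruyama update and reflecting boundaries as
#' [simulate_trajectory()]) and rendered as Gaussian spots with Poisson
#' photon noise and additive Gaussian read noise.
#'
#' @param flow A `flow_field`.
#' @param n_beads Number of beads.
#' @param D_bead Bead diffusion coefficient, um^2/s. Default: Stokes-Einstein
#'   for a 0.5 um bead at 45 degC (~1.6 um^2/s).
#' @param psf_sigma PSF standard deviation, um.
#' @param photon_scale Expected photon count at a spot center.
#' @param read_noise Read-noise standard deviation, counts.
#' @param fps Frames per second.
#' @param pixel_size um per pixel.
#' @param duration Video length, s.
#' @param seed RNG seed.
#' @param region Imaged window `c(x0, x1, y0, y1)` in um. Default: the
#'   interface region (full width, uppermost 1/3 of the chamber).
#' @param noise If `FALSE`, render noiseless spots (ground-truth imaging).
#' @return An `image_stack`: list of frame matrices (`frames`), `pixel_size`,
#'   `frame_interval`, plus the ground-truth bead positions (`truth`, a list
#'   of per-frame matrices in um).
#' @export
render_bead_video <- function(flow, n_beads = 100, D_bead = NULL,
                              psf_sigma = 1.0, photon_scale = 200,
                              read_noise = 2, fps = 10, pixel_size = 3,
                              duration = 5, seed = 1, region = NULL,
                              noise = TRUE) {
  stopifnot(inherits(flow, "flow_field"))
  g <- flow$grid
  if (is.null(D_bead)) D_bead <- stokes_einstein_D(0.25, 45)
  if (is.null(region)) region <- c(0, g$width, g$height * 2 / 3, g$height)
  set.seed(seed)
  n_frames <- max(2L, as.integer(round(duration * fps)))
  frame_dt <- 1 / fps
  # start positions uniform over the imaged region
  xs <- runif(n_beads, region[1], region[2])
  ys <- runif(n_beads, region[3], region[4])
  h_min <- min(g$dx, g$dy)
  vmax <- max(sqrt(flow$u^2 + flow$v^2))
  dt <- min(if (D_bead > 0) h_min^2 / (4 * D_bead) else Inf,
            if (vmax > 0) 0.5 * h_min / vmax else frame_dt, frame_dt)
  sub <- max(1L, as.integer(ceiling(frame_dt / dt)))
  truth <- vector("list", n_frames)
  pos <- cbind(xs, ys)
  truth[[1]] <- pos
  for (fidx in 2:n_frames) {
    for (b in seq_len(n_beads)) {
      p <- walk_cpp(pos[b, 1], pos[b, 2], D_bead, frame_dt / sub, sub, sub,
                    g$xf, g$yf, flow$u, flow$v)
      pos[b, ] <- p[nrow(p), ]
    }
    truth[[fidx]] <- pos
  }
  npx <- ceiling((region[2] - region[1]) / pixel_size)
  npy <- ceiling((region[4] - region[3]) / pixel_size)
  frames <- lapply(truth, function(pp) {
    img <- render_spots(pp[, 1] - region[1], pp[, 2] - region[3],
                        npx, npy, pixel_size, psf_sigma, photon_scale)
    if (noise) {
      img <- matrix(rpois(length(img), img), nrow(img), ncol(img)) +
        matrix(rnorm(length(img), 0, read_noise), nrow(img), ncol(img))
      img[img < 0] <- 0
    }
    img
  })
  out <- list(frames = frames, pixel_size = pixel_size,
              frame_interval = frame_dt, bit_depth = 16,
              truth = truth, region = region, seed = seed)
  class(out) <- "image_stack"
  out
}

## Gaussian spots rendered on an npx x npy image (x = rows, y = cols),
## positions in um relative to the image origin.
render_spots <- function(x_um, y_um, npx, npy, pixel_size, psf_sigma,
                         photon_scale) {
  img <- matrix(0, npx, npy)
  s_px <- psf_sigma / pixel_size
  half <- max(3L, ceiling(4 * s_px))
  for (b in seq_along(x_um)) {
    cx <- x_um[b] / pixel_size + 0.5     # pixel-center convention
    cy <- y_um[b] / pixel_size + 0.5
    i0 <- max(1L, floor(cx) - half); i1 <- min(npx, floor(cx) + half)
    j0 <- max(1L, floor(cy) - half); j1 <- min(npy, floor(cy) + half)
    if (i0 > i1 || j0 > j1) next
    gx <- exp(-((i0:i1) - cx)^2 / (2 * s_px^2))
    gy <- exp(-((j0:j1) - cy)^2 / (2 * s_px^2))
    img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + photon_scale * outer(gx, gy)
  }
  img
}

#' Detect bead spots in an image stack
#'
#' Bandpass (Gaussian blur minus local background), intensity threshold,
#' local-maximum selection with a minimum separation, and intensity-weighted
#' subpixel centroid refinement.
#'
#' @param stack An `image_stack`.
#' @param threshold Absolute intensity threshold; default: 4 robust standard
#'   deviations above the frame median.
#' @param min_separation Minimum spot separation in pixels; closer maxima are
#'   merged into the brighter one (reported once, ambiguity is implicit).
#' @param window Centroid refinement half-width, px (use >= 4 PSF sigmas
#'   to avoid truncation bias).
#' @return A `spot_set`: per-frame data.frames with subpixel `x`, `y` in
#'   pixel units (multiply by the pixel size for physical coordinates) and
#'   `intensity`.
#' @export
detect_spots <- function(stack, threshold = NULL, min_separation = 3,
                         window = 8) {
  stopifnot(inherits(stack, "image_stack"))
  spots <- lapply(stack$frames, function(img) {
    if (max(img) >= 2^stack$bit_depth - 1) {
      warning("detect_spots: saturated frame")
    }
    bg <- stats::median(img)
    thr <- if (is.null(threshold)) {
      bg + 4 * stats::mad(img) + 1e-9
    } else threshold
    sm <- blur2d(img, sigma = 1)
    cand <- which(sm > thr, arr.ind = TRUE)
    if (nrow(cand) == 0L) {
      return(data.frame(x = numeric(0), y = numeric(0),
                        intensity = numeric(0)))
    }
    # local maxima in a (2r+1)^2 neighborhood
    keep <- vapply(seq_len(nrow(cand)), function(k) {
      i <- cand[k, 1]; j <- cand[k, 2]
      i0 <- max(1, i - 1); i1 <- min(nrow(sm), i + 1)
      j0 <- max(1, j - 1); j1 <- min(ncol(sm), j + 1)
      sm[i, j] >= max(sm[i0:i1, j0:j1])
    }, logical(1))
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0L) {
      return(data.frame(x = numeric(0), y = numeric(0),
                        intensity = numeric(0)))
    }
    # enforce min_separation, brightest first
    o <- order(sm[cand], decreasing = TRUE)
    cand <- cand[o, , drop = FALSE]
    sel <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      if (!any(sel)) { sel[k] <- TRUE; next }
      dd <- sqrt((cand[sel, 1] - cand[k, 1])^2 +
                 (cand[sel, 2] - cand[k, 2])^2)
      if (all(dd >= min_separation)) sel[k] <- TRUE
    }
    cand <- cand[sel, , drop = FALSE]
    # intensity-weighted centroid refinement on background-subtracted image
    res <- t(vapply(seq_len(nrow(cand)), function(k) {
      i <- cand[k, 1]; j <- cand[k, 2]
      i0 <- max(1, i - window); i1 <- min(nrow(img), i + window)
      j0 <- max(1, j - window); j1 <- min(ncol(img), j + window)
      w <- pmax(img[i0:i1, j0:j1] - bg, 0)
      tot <- sum(w)
      if (tot <= 0) return(c(i - 0.5, j - 0.5, 0))
      ci <- sum(w * ((i0:i1) - 0.5)) / tot      # row-weighted
      cj <- sum(t(w) * ((j0:j1) - 0.5)) / tot   # col-weighted
      c(ci, cj, tot)
    }, numeric(3)))
    data.frame(x = res[, 1], y = res[, 2], intensity = res[, 3])
  })
  structure(list(spots = spots, pixel_size = stack$pixel_size,
                 frame_interval = stack$frame_interval),
            class = "spot_set")
}

## separable Gaussian blur with reflected edges
blur2d <- function(img, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad <- function(m, n) m[c(pmax(1, (1 - n):0 + 1), seq_len(nrow(m)),
                            nrow(m) - seq_len(n) + 1), , drop = FALSE]
  conv_rows <- function(m) {
    n <- half
    mp <- pad(m, n)
    out <- matrix(0, nrow(m), ncol(m))
    for (t in seq_along(k)) {
      out <- out + k[t] * mp[(t - 1) + seq_len(nrow(m)), , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(img))))
}

#' Link detected spots into tracks
#'
#' Frame-to-frame nearest-neighbor assignment within `max_displacement`
#' pixels, greedy by increasing distance (ties by lowest spot index).
#' Unmatched spots end/start tracks; ambiguous crossings fragment rather
#' than guess.
#'
#' @param spotset A `spot_set` from [detect_spots()].
#' @param max_displacement Linking radius, px.
#' @return A `track_set`: list of data.frames (`frame`, `x`, `y`).
#' @export
link_tracks <- function(spotset, max_displacement = 10) {
  stopifnot(inherits(spotset, "spot_set"))
  spots <- spotset$spots
  if (length(spots) < 2L) stop("link_tracks: need at least 2 frames",
                               call. = FALSE)
  tracks <- list()
  active <- list()   # each: list(track_id, x, y)
  for (f in seq_along(spots)) {
    sp <- spots[[f]]
    n_new <- nrow(sp)
    assigned_new <- rep(FALSE, n_new)
    next_active <- list()
    if (length(active) > 0L && n_new > 0L) {
      # all candidate pairs within radius, sorted by distance then index
      pares <- expand.grid(a = seq_along(active), b = seq_len(n_new))
      d <- sqrt((vapply(active, `[[`, numeric(1), "x")[pares$a] - sp$x[pares$b])^2 +
                (vapply(active, `[[`, numeric(1), "y")[pares$a] - sp$y[pares$b])^2)
      ord <- order(d, pares$a, pares$b)
      used_a <- rep(FALSE, length(active))
      for (k in ord) {
        if (d[k] > max_displacement) break
        a <- pares$a[k]; b <- pares$b[k]
        if (used_a[a] || assigned_new[b]) next
        used_a[a] <- TRUE; assigned_new[b] <- TRUE
        id <- active[[a]]$track_id
        tracks[[id]] <- rbind(tracks[[id]],
                              data.frame(frame = f, x = sp$x[b], y = sp$y[b]))
        next_active[[length(next_active) + 1L]] <-
          list(track_id = id, x = sp$x[b], y = sp$y[b])
      }
    }
    # unmatched new spots start tracks
    for (b in which(!assigned_new)) {
      id <- length(tracks) + 1L
      tracks[[id]] <- data.frame(frame = f, x = sp$x[b], y = sp$y[b])
      next_active[[length(next_active) + 1L]] <-
        list(track_id = id, x = sp$x[b], y = sp$y[b])
    }
    active <- next_active
  }
  structure(list(tracks = tracks, pixel_size = spotset$pixel_size,
                 frame_interval = spotset$frame_interval),
            class = "track_set")
}

#' Per-step speeds of linked tracks
#'
#' @param trackset A `track_set`.
#' @param pixel_size um per pixel (default: from the track set).
#' @param frame_interval s per frame (default: from the track set).
#' @return Numeric vector of speeds, um/s, one per track step; the number of
#'   single-point tracks skipped is attached as attribute `"skipped"`.
#' @export
track_velocities <- function(trackset, pixel_size = NULL,
                             frame_interval = NULL) {
  stopifnot(inherits(trackset, "track_set"))
  if (length(trackset$tracks) == 0L) stop("track_velocities: no tracks",
                                          call. = FALSE)
  if (is.null(pixel_size)) pixel_size <- trackset$pixel_size
  if (is.null(frame_interval)) frame_interval <- trackset$frame_interval
  skipped <- 0L
  speeds <- unlist(lapply(trackset$tracks, function(tr) {
    if (nrow(tr) < 2L) { skipped <<- skipped + 1L; return(numeric(0)) }
    steps <- diff(tr$frame)
    sqrt(diff(tr$x)^2 + diff(tr$y)^2) * pixel_size /
      (steps * frame_interval)
  }))
  structure(speeds, skipped = skipped)
}

#' Render and quantify synthetic fluorescence of a concentration field
#'
#' `render_fluorescence()`: intensity proportional to concentration (times
#' the uniform chamber depth) with Poisson noise. `quantify_accumulation()`:
#' normalizes by the mean intensity of the initial frame and reports the
#' maximum ratio, the image-side counterpart of the fold-accumulation
#' readout.
#'
#' @param field A `concentration_field` (snapshots become frames).
#' @param photon_scale Expected counts at relative concentration 1.
#' @param seed RNG seed.
#' @param noise Poisson noise on/off.
#' @return An `image_stack` with one frame per snapshot.
#' @export
render_fluorescence <- function(field, photon_scale = 100, seed = 1,
                                noise = TRUE) {
  stopifnot(inherits(field, "concentration_field"))
  set.seed(seed)
  ns <- dim(field$c)[3]
  frames <- lapply(seq_len(ns), function(k) {
    img <- field$c[, , k] * photon_scale
    if (noise) img <- matrix(rpois(length(img), img), nrow(img), ncol(img))
    img
  })
  dtf <- if (ns > 1) diff(field$times[1:2]) else 1
  structure(list(frames = frames, pixel_size = field$grid$dx[1],
                 frame_interval = dtf, bit_depth = 16,
                 times = field$times),
            class = "image_stack")
}

#' @rdname render_fluorescence
#' @param stack An `image_stack` from [render_fluorescence()].
#' @param background Constant background counts subtracted before
#'   normalization.
#' @return `quantify_accumulation()`: the maximum intensity ratio relative to
#'   the initial frame mean.
#' @export
quantify_accumulation <- function(stack, background = 0) {
  stopifnot(inherits(stack, "image_stack"))
  ref <- mean(stack$frames[[1]]) - background
  if (ref <= 0) stop("quantify_accumulation: zero or negative reference
intensity after background subtraction", call. = FALSE)
  max(vapply(stack$frames, function(f) max(f - background), numeric(1))) / ref
}

#' Write an image stack as multi-page TIFF
#'
#' @param stack An `image_stack`.
#' @param file Output path.
#' @param scale Counts-to-[0,1] scaling for storage (default: stack max).
#' @export
write_image_stack <- function(stack, file, scale = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("write_image_stack needs the 'tiff' package", call. = FALSE)
  }
  if (is.null(scale)) scale <- max(unlist(lapply(stack$frames, max)), 1)
  imgs <- lapply(stack$frames, function(f) t(pmin(pmax(f / scale, 0), 1)))
  tiff::writeTIFF(imgs, file, bits.per.sample = 16L)
  invisible(file)
}
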