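# ---------------------------------------------------------------------------
# Synthetic data: parametric test images (constant / random / gaussian /
# sine / cosine) and ground-truth-labeled synthetic proliferation
# time-lapse videos.
#
# All randomness flows from one master seed: the generator derives one
# sub-seed per independent stream (frame noise, walks, textures, ...) from
# the master seed with a fixed splitting scheme, so every stream is
# reproducible in isolation and identical seeds give bit-identical stacks.
# ---------------------------------------------------------------------------

# Deterministic sub-seed derivation (kept below 2^31).
split_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 15485863) %% 2147483647
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a parametric test image
#'
#' Models: `constant` (all pixels `value`), `random` (i.i.d. uniform over
#' the full range), `gaussian` (i.i.d. normal(`mean`, `sd`) clamped to the
#' range), and `sine` / `cosine`
#' (`I(r, c) = round(amplitude * (1 + f(2 pi c / period)) / 2)` along the
#' column axis).  Identical seeds give identical images.
#'
#' @param model One of `"constant"`, `"random"`, `"gaussian"`, `"sine"`,
#'   `"cosine"`.
#' @param width,height Image size (>= 1).
#' @param depth Bit depth, 8 or 16.
#' @param value Constant intensity (model `constant`).
#' @param mean,sd Normal parameters (model `gaussian`); defaults mid-range
#'   and 1/8 of the range.
#' @param amplitude Peak intensity of the wave models; defaults to the top
#'   of the range.
#' @param period Wavelength in pixels of the wave models.
#' @param seed Integer seed for the stochastic models.
#' @return An `image_item` (`grey8` or `grey16`).
#' @export
generate_image <- function(model = c("constant", "random", "gaussian",
                                     "sine", "cosine"),
                           width = 64L, height = 64L, depth = 8L,
                           value = 0L, mean = NULL, sd = NULL,
                           amplitude = NULL, period = 16, seed = 1L) {
  model <- match.arg(model)
  if (width < 1L || height < 1L)
    stop_parameter("width and height must be >= 1")
  if (!depth %in% c(8L, 16L)) stop_parameter("depth must be 8 or 16")
  sm <- if (depth == 8L) "grey8" else "grey16"
  L <- sample_model_max(sm)
  px <- switch(model,
    constant = {
      if (value < 0 || value > L)
        stop_parameter(sprintf("value %s out of range [0, %d] for depth %d",
                               format(value), L, depth))
      matrix(value, height, width)
    },
    random = with_seed(seed,
      matrix(sample.int(L + 1L, height * width, replace = TRUE) - 1L,
             height, width)),
    gaussian = {
      mu <- mean %||% (L / 2)
      s <- sd %||% (L / 8)
      with_seed(seed, matrix(
        pmin(pmax(round_half_up(stats::rnorm(height * width, mu, s)), 0), L),
        height, width))
    },
    sine = ,
    cosine = {
      A <- amplitude %||% L
      if (A < 0 || A > L) stop_parameter("amplitude out of range")
      f <- if (model == "sine") sin else cos
      wave <- round_half_up(A * (1 + f(2 * pi * (seq_len(width) - 1L) / period)) / 2)
      matrix(rep(wave, each = height), height, width)
    })
  image_item(px, sm, name = sprintf("%s-%dx%d", model, height, width))
}

# --- time-lapse generator ---------------------------------------------------

# Raster a soft-edged disc onto matrix `canvas`: intensity `value` inside
# radius-1, ramping linearly to the existing canvas over the last pixel.
stamp_disc <- function(canvas, row, col, radius, value) {
  M <- nrow(canvas); N <- ncol(canvas)
  rr <- max(1L, floor(row - radius)):min(M, ceiling(row + radius))
  cc <- max(1L, floor(col - radius)):min(N, ceiling(col + radius))
  if (length(rr) == 0L || length(cc) == 0L) return(canvas)
  d <- sqrt(outer((rr - row)^2, (cc - col)^2, "+"))
  w <- pmin(pmax(radius - d, 0), 1)      # 1 inside, 1-px linear edge ramp
  canvas[rr, cc] <- canvas[rr, cc] * (1 - w) + value * w
  canvas
}

disc_mask <- function(M, N, row, col, radius) {
  d2 <- outer((seq_len(M) - row)^2, (seq_len(N) - col)^2, "+")
  d2 <= radius^2
}

#' Specify the ground truth of a synthetic time-lapse
#'
#' @param boundary_I_II Frame at which free-floating cells adhere (phase II
#'   starts); 0-based.
#' @param boundary_II_III Frame at which the field (except the spot) is
#'   confluent (phase III starts).
#' @param monolayer_frame Frame at which the unoccupied spot closes
#'   (phase IV starts).
#' @param artifact_frames 0-based indices of frames with the horizontal
#'   intensity-split recording artifact.
#' @param seed Master seed realized into the truth record.
#' @return A `timelapse_truth` list.
#' @export
timelapse_truth <- function(boundary_I_II, boundary_II_III, monolayer_frame,
                            artifact_frames = integer(0), seed = 1L) {
  structure(list(boundary_I_II = boundary_I_II,
                 boundary_II_III = boundary_II_III,
                 monolayer_frame = monolayer_frame,
                 artifact_frames = as.integer(artifact_frames),
                 seed = seed),
            class = "timelapse_truth")
}

#' Generate a synthetic cell-proliferation time-lapse with ground truth
#'
#' Emulates a phase-contrast recording of cultured cells on a uniform
#' background through four proliferation phases:
#'
#' * **Phase I** (frames `0 .. b1-1`): a handful of bright disc "cells"
#'   drift through the medium with large inter-frame displacements
#'   (seeded random walks).
#' * **Phase II** (`b1 .. b2-1`): the discs adhere and freeze; new cells
#'   appear adjacent to existing ones at an accelerating (logistic-style)
#'   rate while the settled population flickers in brightness (active
#'   migration/division), so inter-frame activity grows with the
#'   population.
#' * **Phase III** (`b2 .. m-1`): the field is confluent except for a
#'   designated unoccupied spot whose radius shrinks towards zero; the
#'   confluent monolayer is quiescent (contact inhibition), with only a
#'   faint intensity flicker.
#' * **Phase IV** (`m ..`): full coverage with the same faint flicker.
#'
#' Settled cells carry a fixed three-level per-pixel speckle texture so the
#' confluent field is heterogeneous at the pixel scale (as real monolayers
#' are under phase contrast), additive Gaussian noise is applied to every
#' frame, a few fixed sensor-defect pixels (saturated hot pixels and dark
#' dirt) anchor every frame's dynamic range as in real recordings, and
#' frames listed in `truth$artifact_frames` get
#' `artifact_delta` added to their top half (two regions separated by a
#' horizontal border, as in faulty recordings).
#'
#' @param n_frames Number of frames.
#' @param width,height Frame size in pixels.
#' @param truth A [timelapse_truth()]; its boundaries must be strictly
#'   ordered and below `n_frames`.
#' @param noise_sigma Additive Gaussian noise standard deviation
#'   (grey levels).
#' @param artifact_delta Intensity added to the top half of artifact frames.
#' @param seed Master seed; identical seeds give bit-identical stacks.
#' @param spot_seed Optional `(row, col)` center of the unoccupied spot,
#'   0-based; defaults to the frame center.
#' @param spot_radius Initial spot radius in pixels at the start of
#'   phase III (default 1/6 of the smaller frame side).
#' @return List with `frames` (list of grey8 `image_item`s), `truth` (the
#'   realized `timelapse_truth`, including `spot_seed`), and `spot_seed`.
#' @export
generate_timelapse <- function(n_frames = 120L, width = 128L, height = 96L,
                               truth = timelapse_truth(20L, 60L, 100L),
                               noise_sigma = 4, artifact_delta = 60,
                               seed = 1L, spot_seed = NULL,
                               spot_radius = min(width, height) / 6) {
  b1 <- truth$boundary_I_II; b2 <- truth$boundary_II_III
  m <- truth$monolayer_frame
  if (!(0 < b1 && b1 < b2 && b2 < m && m < n_frames))
    stop_parameter("truth boundaries must satisfy 0 < b1 < b2 < m < n_frames")
  M <- as.integer(height); N <- as.integer(width)
  if (2 * spot_radius >= min(M, N))
    stop_parameter("spot larger than the frame")
  if (is.null(spot_seed)) spot_seed <- c(floor(M / 2), floor(N / 2))
  sr <- spot_seed[1] + 1; sc <- spot_seed[2] + 1  # 1-based center

  bg <- 90                 # background (medium) intensity
  cell_value <- 200        # brightness of free-floating cells
  cell_radius <- 4
  n_float <- 12L           # free-floating cells in phase I
  step_sd <- 7             # random-walk step scale, px/frame
  jitter_active <- 20      # per-cell brightness flicker while proliferating
  jitter_quiet <- 2        # monolayer flicker after local confluence
  speckle_levels <- c(140, 200, 255)  # settled-cell per-pixel texture
  r_floor <- 3.5           # spot radius floor before the final closure

  truth$artifact_frames <- truth$artifact_frames[truth$artifact_frames < n_frames]
  truth$seed <- seed
  truth$spot_seed <- spot_seed

  # --- deterministic sub-streams -------------------------------------------
  walk <- with_seed(split_seed(seed, 1L), {
    pos <- cbind(stats::runif(n_float, cell_radius + 1, M - cell_radius),
                 stats::runif(n_float, cell_radius + 1, N - cell_radius))
    steps <- array(stats::rnorm(n_float * 2L * b1, 0, step_sd),
                   c(n_float, 2L, b1))
    list(pos = pos, steps = steps)
  })
  # full-field speckle texture for the settled monolayer (fixed per video)
  texture <- with_seed(split_seed(seed, 2L),
    matrix(sample(speckle_levels, M * N, replace = TRUE), M, N))
  # birth schedule: exponential growth of the settled population across
  # phase II, so births-per-frame (inter-frame activity) accelerates until
  # the field saturates at b2
  n_target_full <- ceiling(1.6 * M * N / (pi * cell_radius^2))
  growth <- (n_target_full / n_float)^(1 / (b2 - b1))
  pop_target <- pmin(round(n_float * growth^(seq_len(b2 - b1))), n_target_full)
  births <- diff(c(n_float, pop_target))
  birth_xy <- with_seed(split_seed(seed, 3L), {
    total <- sum(births)
    cbind(stats::runif(total, cell_radius + 1, M - cell_radius),
          stats::runif(total, cell_radius + 1, N - cell_radius),
          stats::runif(total))   # third column: parent-attachment jitter
  })

  spot_clear <- disc_mask(M, N, sr, sc, spot_radius)

  # fixed sensor defects (linear indices): dark dirt near the top-left,
  # saturated hot pixels near the bottom-right; they pin each frame's
  # intensity range so histogram normalization is stable across frames
  defect_dark <- c(3L + 2L * M, 3L + 5L * M, 6L + 2L * M)
  defect_hot <- c((M - 3L) + (N - 3L) * M, (M - 6L) + (N - 3L) * M,
                  (M - 3L) + (N - 6L) * M)

  # static layer: accumulates settled cells during phase II
  static_base <- matrix(bg, M, N)
  settled <- list()      # row, col of settled cells (for jitter patches)
  settled_masks <- list()
  young_masks <- list()  # newborn cells still spreading (half contrast)

  frames <- vector("list", n_frames)
  frame_noise_seed <- split_seed(seed, 4L)
  jitter_seed <- split_seed(seed, 5L)
  birth_ptr <- 0L

  # walker trajectories across phase I
  walk_pos <- array(0, c(n_float, 2L, b1 + 1L))
  walk_pos[, , 1L] <- walk$pos
  for (t in seq_len(b1)) {
    p <- walk_pos[, , t] + walk$steps[, , t]
    p[, 1] <- pmin(pmax(p[, 1], cell_radius + 1), M - cell_radius)
    p[, 2] <- pmin(pmax(p[, 2], cell_radius + 1), N - cell_radius)
    walk_pos[, , t + 1L] <- p
  }
  # progressive adhesion: cells settle one after another through phase I
  # (the last one right at the phase I/II boundary), so inter-frame motion
  # declines through phase I as it does in real recordings
  adhere_at <- pmin(b1, pmax(1L, round(b1 * seq(0.3, 1, length.out = n_float))))
  adhered <- rep(FALSE, n_float)

  bake_walker <- function(i) {
    rp <- walk_pos[i, 1, adhere_at[i] + 1L]
    cp <- walk_pos[i, 2, adhere_at[i] + 1L]
    mk <- which(disc_mask(M, N, rp, cp, cell_radius))
    static_base[mk] <<- texture[mk]
    settled[[length(settled) + 1L]] <<- c(rp, cp)
    settled_masks[[length(settled_masks) + 1L]] <<- mk
    adhered[i] <<- TRUE
  }

  for (j in seq_len(n_frames) - 1L) {          # 0-based frame index
    if (j < b1) {
      # phase I: settle walkers whose adhesion frame has arrived, render
      # the rest in flight at their current walk position
      for (i in which(!adhered & adhere_at <= j)) bake_walker(i)
      canvas <- static_base
      if (length(settled_masks) > 0L) {
        deltas <- with_seed(split_seed(jitter_seed, j),
                            stats::rnorm(length(settled_masks), 0,
                                         jitter_active))
        if (length(deltas) > 1L) deltas <- deltas - mean(deltas)
        for (i in seq_along(settled_masks))
          canvas[settled_masks[[i]]] <- canvas[settled_masks[[i]]] + deltas[i]
      }
      for (i in which(!adhered))
        canvas <- stamp_disc(canvas, walk_pos[i, 1, j + 1L],
                             walk_pos[i, 2, j + 1L], cell_radius, cell_value)
      canvas[spot_clear] <- bg
    } else if (j < b2) {
      # any walker not yet baked settles now (adhesion completes at b1)
      for (i in which(!adhered)) bake_walker(i)
      # cells born in the previous frame finish spreading: bake them in
      for (mk in young_masks) {
        static_base[mk] <- texture[mk]
        settled_masks[[length(settled_masks) + 1L]] <- mk
      }
      young_masks <- list()
      # births for this frame, placed adjacent to an existing settled cell;
      # a newborn spreads over two frames (half contrast, then full) so the
      # integer birth schedule does not imprint a sawtooth on the activity
      nb <- births[j - b1 + 1L]
      if (nb > 0L) for (q in seq_len(nb)) {
        birth_ptr <- birth_ptr + 1L
        parent <- settled[[1L + (birth_ptr %% length(settled))]]
        ang <- birth_xy[birth_ptr, 3] * 2 * pi
        rp <- parent[1] + 2.2 * cell_radius * sin(ang) +
          (birth_xy[birth_ptr, 1] - M / 2) * 0.15
        cp <- parent[2] + 2.2 * cell_radius * cos(ang) +
          (birth_xy[birth_ptr, 2] - N / 2) * 0.15
        rp <- pmin(pmax(rp, 1), M); cp <- pmin(pmax(cp, 1), N)
        mk <- which(disc_mask(M, N, rp, cp, cell_radius))
        settled[[length(settled) + 1L]] <- c(rp, cp)
        young_masks[[length(young_masks) + 1L]] <- mk
      }
      canvas <- static_base
      for (mk in young_masks)
        canvas[mk] <- (canvas[mk] + texture[mk]) / 2
      # active flicker: every settled cell shifts brightness this frame
      deltas <- with_seed(split_seed(jitter_seed, j),
                          stats::rnorm(length(settled_masks), 0, jitter_active))
      deltas <- deltas - mean(deltas)   # flicker redistributes contrast;
                                        # the field illumination is stable
      for (i in seq_along(settled_masks))
        canvas[settled_masks[[i]]] <- canvas[settled_masks[[i]]] + deltas[i]
      canvas[spot_clear] <- bg
    } else {
      # phases III / IV: confluent speckle field, quiescent flicker on a
      # coarse patch grid; spot open until the monolayer frame
      canvas <- texture
      flick <- with_seed(split_seed(jitter_seed, j), {
        gr <- matrix(stats::rnorm(ceiling(M / 8) * ceiling(N / 8), 0,
                                  jitter_quiet),
                     ceiling(M / 8), ceiling(N / 8))
        gr[(seq_len(M) - 1L) %/% 8L + 1L, (seq_len(N) - 1L) %/% 8L + 1L]
      })
      canvas <- canvas + flick
      if (j < m) {
        r_j <- max(r_floor, spot_radius * (m - j) / (m - b2))
        canvas[disc_mask(M, N, sr, sc, r_j)] <- bg
      }
    }

    if (noise_sigma > 0)
      canvas <- canvas + with_seed(split_seed(frame_noise_seed, j),
                                   matrix(stats::rnorm(M * N, 0, noise_sigma),
                                          M, N))
    if (j %in% truth$artifact_frames)
      canvas[seq_len(floor(M / 2)), ] <- canvas[seq_len(floor(M / 2)), ] +
        artifact_delta
    px <- matrix(pmin(pmax(round_half_up(canvas), 0), 255), M, N)
    px[defect_dark] <- 8L; px[defect_hot] <- 255L
    frames[[j + 1L]] <- image_item(px, "grey8",
                                   name = sprintf("frame_%04d", j))
  }
  list(frames = frames, truth = truth, spot_seed = spot_seed)
}
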