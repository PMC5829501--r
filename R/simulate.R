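# Synthetic embryo movies with known PCM kinetics.
#
# Every downstream module is validated against these renders: the generator
# writes down, per frame and per centrosome, the exact integrated mass it
# painted into the image, so segmentation and kinetics estimates can be
# compared against analytic truth.

#' Ground-truth disassembly kinetics for one centrosome
#'
#' Parameterises the analytic PCM mass trajectory used by the synthetic movie
#' generator. The trajectory is piecewise: a logistic accumulation phase up to
#' the disassembly onset, then exponential loss towards a residual plateau,
#'
#' \deqn{m(t) = m_{peak} (f_{res} + (1 - f_{res}) e^{-k_{decay}(t - t_{onset})})}
#'
#' for `t >= t_onset_s`. The rise is a logistic in `t` with rate `k_grow` and
#' midpoint `t_grow_mid_s`, rescaled so that the curve is continuous and equals
#' `m_peak` exactly at onset. With the default midpoint 200 s the curve is
#' still rising steeply when disassembly takes over at 275 s: onset marks the
#' point where removal outpaces growth (the anaphase peak), not a saturation
#' of growth.
#'
#' @param t_peak_s Time of maximal mass, seconds post-NEBD. PCM mass peaks
#'   roughly 275 s after nuclear envelope breakdown in the one-cell embryo.
#' @param m_peak Peak integrated mass, arbitrary intensity counts.
#' @param k_grow Logistic growth rate, 1/s.
#' @param t_grow_mid_s Midpoint of the logistic accumulation phase, seconds.
#' @param k_decay Exponential disassembly rate, 1/s. Must be >= 0.
#' @param f_residual Plateau mass as a fraction of `m_peak`, in `[0, 1)`.
#'   0 means complete disassembly.
#' @param t_onset_s Disassembly onset, seconds post-NEBD; defaults to
#'   `t_peak_s` (mass is maximal at onset).
#' @return An object of class `kinetic_truth`.
#' @seealso [mass_profile()], [condition_preset()]
#' @export
kinetic_truth <- function(t_peak_s = 275, m_peak = 1e5, k_grow = 0.015,
                          t_grow_mid_s = 200, k_decay = 0.018,
                          f_residual = 0, t_onset_s = t_peak_s) {
  if (f_residual < 0 || f_residual >= 1)
    stop("`f_residual` must lie in [0, 1)")
  if (k_decay < 0) stop("`k_decay` must be >= 0")
  if (t_onset_s < 0) stop("`t_onset_s` must be >= 0")
  if (m_peak < 0) stop("`m_peak` must be >= 0")
  if (k_grow < 0) stop("`k_grow` must be >= 0")
  structure(
    list(t_peak_s = t_peak_s, m_peak = m_peak, k_grow = k_grow,
         t_grow_mid_s = t_grow_mid_s, k_decay = k_decay,
         f_residual = f_residual, t_onset_s = t_onset_s),
    class = "kinetic_truth"
  )
}

#' @export
print.kinetic_truth <- function(x, ...) {
  cat("<kinetic_truth>\n")
  cat(sprintf("  peak %g counts at %g s post-NEBD; onset %g s\n",
              x$m_peak, x$t_peak_s, x$t_onset_s))
  cat(sprintf("  k_grow %g /s (midpoint %g s), k_decay %g /s, residual fraction %g\n",
              x$k_grow, x$t_grow_mid_s, x$k_decay, x$f_residual))
  invisible(x)
}

# Internal profile; tolerates t < 0 (pre-NEBD frames continue the logistic
# accumulation backwards in time).
.mass_profile <- function(truth, t) {
  scale <- stats::plogis(truth$k_grow * (truth$t_onset_s - truth$t_grow_mid_s))
  rise <- stats::plogis(truth$k_grow * (t - truth$t_grow_mid_s)) / scale
  decay <- truth$f_residual +
    (1 - truth$f_residual) * exp(-truth$k_decay * pmax(t - truth$t_onset_s, 0))
  truth$m_peak * ifelse(t < truth$t_onset_s, rise, decay)
}

#' Evaluate the analytic PCM mass trajectory
#'
#' @param truth A [kinetic_truth()] object.
#' @param t Time(s) in seconds post-NEBD; must be >= 0. Vectorised.
#' @return Mass in arbitrary intensity counts, same length as `t`. Continuous
#'   everywhere and equal to `m_peak` at `t_onset_s`.
#' @export
mass_profile <- function(truth, t) {
  stopifnot(inherits(truth, "kinetic_truth"))
  if (any(t < 0)) stop("`t` is seconds post-NEBD and must be >= 0")
  .mass_profile(truth, t)
}

#' Genetic-condition presets for the synthetic embryo
#'
#' Returns per-centrosome kinetics and centrosome motion for one of four
#' conditions modelled on the one-cell embryo: `wild_type`; depletion of the
#' PP2A(B55/SUR-6) phosphatase activity (`phosphatase_depleted`), which slows
#' disassembly by roughly half on both centrosomes and leaves a small
#' residual; depletion of cortical force generators (`force_depleted`), which
#' slows only the posterior centrosome by about a quarter; and the double
#' depletion (`double_depleted`), which slows both strongly, leaves ~25% of
#' peak mass behind, and collapses the spindle so that the two centrosomes can
#' no longer be resolved (`merge_centrosomes = TRUE`).
#'
#' All presets start with exactly two centrosomes and differ only in kinetic
#' and motion parameters. Individual fields may be overridden via arguments.
#'
#' @param name Preset name.
#' @param anterior,posterior Optional [kinetic_truth()] overrides.
#' @param motion_speed_um_per_s Optional override of the cortex-directed drift
#'   speed (micrometres per second).
#' @param merge_centrosomes Optional override of the merged flag.
#' @return A list of class `condition_preset` with fields `name`, `anterior`,
#'   `posterior`, `motion_speed_um_per_s`, `merge_centrosomes`.
#' @export
condition_preset <- function(name = c("wild_type", "phosphatase_depleted",
                                      "force_depleted", "double_depleted"),
                             anterior = NULL, posterior = NULL,
                             motion_speed_um_per_s = NULL,
                             merge_centrosomes = NULL) {
  name <- match.arg(name)
  k_ant_wt <- 0.018
  k_pos_wt <- 0.024
  base <- switch(name,
    wild_type = list(
      anterior = kinetic_truth(k_decay = k_ant_wt, f_residual = 0),
      posterior = kinetic_truth(k_decay = k_pos_wt, f_residual = 0),
      motion = 0.002, merge = FALSE),
    phosphatase_depleted = list(
      anterior = kinetic_truth(k_decay = 0.46 * k_ant_wt, f_residual = 0.10),
      posterior = kinetic_truth(k_decay = 0.35 * k_pos_wt, f_residual = 0.10),
      motion = 0.002, merge = FALSE),
    force_depleted = list(
      anterior = kinetic_truth(k_decay = k_ant_wt, f_residual = 0),
      posterior = kinetic_truth(k_decay = 0.73 * k_pos_wt, f_residual = 0),
      motion = 0.0005, merge = FALSE),
    double_depleted = list(
      anterior = kinetic_truth(k_decay = 0.41 * k_ant_wt, f_residual = 0.25),
      posterior = kinetic_truth(k_decay = 0.28 * k_pos_wt, f_residual = 0.25),
      motion = 0, merge = TRUE)
  )
  out <- structure(
    list(name = name,
         anterior = anterior %||% base$anterior,
         posterior = posterior %||% base$posterior,
         motion_speed_um_per_s = motion_speed_um_per_s %||% base$motion,
         merge_centrosomes = merge_centrosomes %||% base$merge),
    class = "condition_preset"
  )
  stopifnot(inherits(out$anterior, "kinetic_truth"),
            inherits(out$posterior, "kinetic_truth"))
  out
}

#' Camera noise model
#'
#' Standard CCD/EMCCD camera model: expected photon counts are drawn from a
#' Poisson distribution (scaled by `photon_scale` counts per photon), Gaussian
#' read noise is added, then a constant camera offset. With
#' `photon_scale = 0` and `read_noise_sd = 0` the render is deterministic.
#'
#' @param camera_offset Constant offset, counts.
#' @param read_noise_sd Gaussian read noise standard deviation, counts.
#' @param photon_scale Counts per expected photon; 0 disables photon noise.
#' @param background_level Cytoplasmic autofluorescence inside the embryo
#'   mask, counts (above offset).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(camera_offset = 100, read_noise_sd = 3,
                        photon_scale = 1, background_level = 200) {
  vals <- c(camera_offset, read_noise_sd, photon_scale, background_level)
  if (any(vals < 0)) stop("all noise model parameters must be >= 0")
  structure(
    list(camera_offset = camera_offset, read_noise_sd = read_noise_sd,
         photon_scale = photon_scale, background_level = background_level),
    class = "noise_model"
  )
}

#' @rdname noise_model
#' @export
zero_noise <- function(camera_offset = 100, background_level = 200) {
  noise_model(camera_offset = camera_offset, read_noise_sd = 0,
              photon_scale = 0, background_level = background_level)
}

# Add a 2D Gaussian spot of total mass `mass` centred at (cy, cx) (fractional
# pixel coordinates allowed). Pixel values are exact integrals of the Gaussian
# over the pixel (separable erf), so the painted-in mass is conserved up to
# truncation of the render window (+- 6 sigma, < 1e-7 of the mass).
.add_spot <- function(img, cy, cx, mass, sigma) {
  if (mass <= 0) return(img)
  w <- ceiling(6 * sigma)
  ys <- max(1L, floor(cy) - w):min(nrow(img), ceiling(cy) + w)
  xs <- max(1L, floor(cx) - w):min(ncol(img), ceiling(cx) + w)
  wy <- stats::pnorm(ys + 0.5, cy, sigma) - stats::pnorm(ys - 0.5, cy, sigma)
  wx <- stats::pnorm(xs + 0.5, cx, sigma) - stats::pnorm(xs - 0.5, cx, sigma)
  img[ys, xs] <- img[ys, xs] + mass * outer(wy, wx)
  img
}

.embryo_mask <- function(ny, nx) {
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  ry <- 0.42 * ny; rx <- 0.45 * nx
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
}

.apply_camera <- function(signal, noise) {
  out <- signal
  if (noise$photon_scale > 0) {
    lambda <- signal / noise$photon_scale
    out <- noise$photon_scale *
      matrix(stats::rpois(length(lambda), lambda), nrow(signal), ncol(signal))
  }
  if (noise$read_noise_sd > 0) {
    out <- out + matrix(stats::rnorm(length(out), 0, noise$read_noise_sd),
                        nrow(out), ncol(out))
  }
  out + noise$camera_offset
}

#' Render a ground-truthed synthetic embryo movie
#'
#' Renders two diffraction-blurred centrosome foci on a noisy cytoplasmic
#' background inside an ellipsoidal embryo. Each focus is an isotropic 2D
#' Gaussian whose total above-background count equals the analytic
#' [mass_profile()] of its [kinetic_truth()] at that frame's time, before
#' noise. Centrosomes drift linearly along the long (x) axis towards the
#' nearer cortex at the preset's `motion_speed_um_per_s` (for merged presets
#' they sit close together at mid-embryo and do not drift). Frame
#' `pre_nebd_frames + 1` is NEBD (t = 0).
#'
#' With `n_z > 1` each focus is additionally spread over z-slices with a
#' Gaussian axial profile and the cytoplasmic background is split evenly
#' across slices, so that a SUM projection recovers the 2D render; the default
#' is a single plane, since quantification operates on projections.
#'
#' @param preset A [condition_preset()].
#' @param noise A [noise_model()].
#' @param ny,nx Image height and width in pixels.
#' @param n_z Number of z-slices (1 = render directly on the projection plane).
#' @param frame_interval_s Seconds between frames.
#' @param n_frames Number of frames at/after NEBD; must be >= 1.
#' @param pre_nebd_frames Frames to prepend before NEBD (t < 0).
#' @param seed Integer RNG seed; identical inputs and seed give bit-identical
#'   output. The global RNG state is left untouched.
#' @param sigma_psf Gaussian spot width, pixels.
#' @param pixel_size_um,z_step_um Physical calibration (metadata).
#' @param border_margin_px Minimum allowed distance of any centrosome centre
#'   from the image border; geometries violating it (e.g. the background
#'   annulus would leave the frame) are rejected. Default 10 px, the outer
#'   annulus radius of the quantifier.
#' @return A list of class `pcm_simulation`: `stack` (a [movie_stack()]),
#'   `truth` (tibble with one row per frame and centrosome: `frame`, `time_s`,
#'   `centrosome`, `y`, `x`, `true_mass`, `stage`), plus the generating
#'   `preset`, `noise` and `sigma_psf`.
#' @export
render_movie <- function(preset, noise = noise_model(), ny = 100, nx = 180,
                         n_z = 1, frame_interval_s = 10, n_frames = 90,
                         pre_nebd_frames = 0, seed = 1, sigma_psf = 2,
                         pixel_size_um = 0.11, z_step_um = 0.5,
                         border_margin_px = 10) {
  stopifnot(inherits(preset, "condition_preset"), inherits(noise, "noise_model"))
  if (n_frames < 1) stop("`n_frames` must be >= 1")
  if (n_z < 1) stop("`n_z` must be >= 1")

  n_total <- pre_nebd_frames + n_frames
  t_s <- (seq_len(n_total) - 1 - pre_nebd_frames) * frame_interval_s
  v_px <- preset$motion_speed_um_per_s / pixel_size_um  # px per second

  y0 <- (ny + 1) / 2
  if (preset$merge_centrosomes) {
    x_ant0 <- nx / 2 - 3.5; x_pos0 <- nx / 2 + 3.5
  } else {
    x_ant0 <- 0.35 * nx; x_pos0 <- 0.65 * nx
  }
  tau <- pmax(t_s, 0)  # drift only after NEBD
  x_ant <- x_ant0 - v_px * tau
  x_pos <- x_pos0 + v_px * tau

  margin <- border_margin_px
  if (any(c(x_ant, x_pos) < 1 + margin) || any(c(x_ant, x_pos) > nx - margin) ||
      y0 < 1 + margin || y0 > ny - margin)
    stop("centrosome trajectory comes within `border_margin_px` of the image ",
         "border; enlarge the frame or reduce motion/duration")

  mask <- .embryo_mask(ny, nx)
  m_ant <- .mass_profile(preset$anterior, t_s)
  m_pos <- .mass_profile(preset$posterior, t_s)

  dims <- if (n_z == 1) c(ny, nx, n_total) else c(ny, nx, n_z, n_total)
  data <- array(0, dims)
  # axial weights: Gaussian over slices centred mid-stack
  if (n_z > 1) {
    zc <- (n_z + 1) / 2
    zw <- exp(-((seq_len(n_z) - zc)^2) / (2 * 1.5^2))
    zw <- zw / sum(zw)
  }

  withr::with_seed(seed, {
    for (i in seq_len(n_total)) {
      if (n_z == 1) {
        signal <- noise$background_level * mask
        signal <- .add_spot(signal, y0, x_ant[i], m_ant[i], sigma_psf)
        signal <- .add_spot(signal, y0, x_pos[i], m_pos[i], sigma_psf)
        data[, , i] <- .apply_camera(signal, noise)
      } else {
        for (k in seq_len(n_z)) {
          signal <- (noise$background_level / n_z) * mask
          signal <- .add_spot(signal, y0, x_ant[i], m_ant[i] * zw[k], sigma_psf)
          signal <- .add_spot(signal, y0, x_pos[i], m_pos[i] * zw[k], sigma_psf)
          data[, , k, i] <- .apply_camera(signal, noise)
        }
      }
    }
  })

  truth <- tibble::tibble(
    frame = rep(seq_len(n_total), 2),
    time_s = rep(t_s, 2),
    centrosome = rep(c("anterior", "posterior"), each = n_total),
    y = y0,
    x = c(x_ant, x_pos),
    true_mass = c(m_ant, m_pos),
    stage = ifelse(rep(t_s, 2) <
                     rep(c(preset$anterior$t_onset_s, preset$posterior$t_onset_s),
                         each = n_total),
                   "assembly", "disassembly")
  )

  stack <- movie_stack(data, frame_interval_s = frame_interval_s,
                       pixel_size_um = pixel_size_um,
                       nebd_frame = pre_nebd_frames + 1L,
                       z_step_um = if (n_z > 1) z_step_um else NULL)
  structure(list(stack = stack, truth = truth, preset = preset, noise = noise,
                 sigma_psf = sigma_psf, seed = seed),
            class = "pcm_simulation")
}

#' @export
print.pcm_simulation <- function(x, ...) {
  d <- dim(x$stack$data)
  cat(sprintf("<pcm_simulation> preset '%s', %d frame(s), %s px, seed %d\n",
              x$preset$name, d[length(d)],
              paste(d[-length(d)], collapse = "x"), x$seed))
  invisible(x)
}

#' Render two-channel fixed-embryo spot images with programmed ratios
#'
#' Substrate for ratiometric immunofluorescence: per cell-cycle stage, renders
#' pairs of registered single-spot images in which the channel-A spot mass is
#' exactly `ratio * channel-B mass` at an identical centre. Channel B plays
#' the role of the total-scaffold stain (used for segmentation); channel A the
#' modification-specific stain. Spot mass in channel B varies log-normally
#' between cells (`mass_cv`) to emulate PCM size differences; the programmed
#' ratio is exact per cell.
#'
#' @param stage_ratios Named positive numeric: true A/B ratio per stage. The
#'   names are the stage labels carried into the truth table.
#' @param n_per_stage Named/positive integer count of cells per stage (same
#'   order as `stage_ratios`).
#' @param base_mass_b Median channel-B spot mass, counts. Must be > 0.
#' @param mass_cv Log-normal coefficient of variation of channel-B mass.
#' @param noise A [noise_model()] applied independently to each channel.
#' @param size Image side, pixels.
#' @param center_jitter_px Uniform jitter of the spot centre around the image
#'   centre.
#' @param sigma_psf Gaussian spot width, pixels.
#' @param seed Integer RNG seed.
#' @return A list of class `two_channel_spots`: `spots` (list with elements
#'   `a`, `b`, `center`, `stage` per cell) and `truth` (tibble: `id`, `stage`,
#'   `ratio_true`, `mass_b_true`, `center_y`, `center_x`).
#' @export
render_two_channel_spots <- function(stage_ratios = c(interphase = 1,
                                                      prophase_metaphase = 2,
                                                      anaphase = 4,
                                                      telophase = 1.5),
                                     n_per_stage = c(interphase = 19L,
                                                     prophase_metaphase = 48L,
                                                     anaphase = 17L,
                                                     telophase = 33L),
                                     base_mass_b = 5e4, mass_cv = 0.2,
                                     noise = noise_model(), size = 64,
                                     center_jitter_px = 3, sigma_psf = 2,
                                     seed = 1) {
  if (any(stage_ratios <= 0)) stop("all `stage_ratios` must be > 0")
  if (any(n_per_stage <= 0)) stop("all `n_per_stage` must be >= 1")
  if (base_mass_b <= 0) stop("`base_mass_b` must be > 0 (zero-mass spots are not renderable)")
  if (length(n_per_stage) != length(stage_ratios))
    stop("`n_per_stage` and `stage_ratios` must have the same length")
  stages <- names(stage_ratios)
  if (is.null(stages)) stop("`stage_ratios` must be named by stage")

  mid <- (size + 1) / 2
  spots <- list()
  rows <- list()
  withr::with_seed(seed, {
    id <- 0L
    for (s in seq_along(stages)) {
      for (r in seq_len(n_per_stage[s])) {
        id <- id + 1L
        cy <- mid + stats::runif(1, -center_jitter_px, center_jitter_px)
        cx <- mid + stats::runif(1, -center_jitter_px, center_jitter_px)
        mass_b <- base_mass_b * exp(stats::rnorm(1, 0, mass_cv))
        mass_a <- stage_ratios[s] * mass_b
        bg <- matrix(noise$background_level, size, size)
        a <- .apply_camera(.add_spot(bg, cy, cx, mass_a, sigma_psf), noise)
        b <- .apply_camera(.add_spot(bg, cy, cx, mass_b, sigma_psf), noise)
        spots[[id]] <- list(a = a, b = b, center = c(y = cy, x = cx),
                            stage = stages[s])
        rows[[id]] <- tibble::tibble(id = id, stage = stages[s],
                                     ratio_true = unname(stage_ratios[s]),
                                     mass_b_true = mass_b,
                                     center_y = cy, center_x = cx)
      }
    }
  })
  structure(list(spots = spots, truth = do.call(rbind, rows)),
            class = "two_channel_spots")
}
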