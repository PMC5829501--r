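# From acquired/simulated stacks to the per-centrosome 2D time series the
# quantifier consumes: SUM projection over z, anterior/posterior split along
# the long axis, and cropping to frames at/after NEBD.

#' Construct a calibrated movie stack
#'
#' @param data Intensity array, either `[y, x, t]` (2D time-lapse) or
#'   `[y, x, z, t]` (z-stacks over time). Counts may be integer or real.
#' @param frame_interval_s Seconds between time points; must be > 0.
#' @param pixel_size_um Pixel size in micrometres; must be > 0.
#' @param nebd_frame 1-based index of the nuclear envelope breakdown frame
#'   (user annotation), in `[1, T]`; `NA` if not yet annotated.
#' @param z_step_um Z-step in micrometres for 4D data; `NULL` for 2D.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(data, frame_interval_s, pixel_size_um = 0.11,
                        nebd_frame = 1L, z_step_um = NULL) {
  nd <- length(dim(data))
  if (!nd %in% c(3, 4)) stop("`data` must be a [y, x, t] or [y, x, z, t] array")
  n_t <- dim(data)[nd]
  if (n_t < 1) stop("stack must contain at least one frame")
  if (!is.na(nebd_frame) && (nebd_frame < 1 || nebd_frame > n_t))
    stop("`nebd_frame` must be a frame index in [1, ", n_t, "]")
  if (frame_interval_s <= 0 || pixel_size_um <= 0 ||
      (!is.null(z_step_um) && z_step_um <= 0))
    stop("calibration values must be > 0")
  structure(
    list(data = data, frame_interval_s = frame_interval_s,
         pixel_size_um = pixel_size_um,
         nebd_frame = if (is.na(nebd_frame)) NA_integer_ else as.integer(nebd_frame),
         z_step_um = z_step_um),
    class = "movie_stack"
  )
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie_stack> %s, %g s/frame, %g um/px, NEBD frame %s\n",
              paste(d, collapse = "x"), x$frame_interval_s, x$pixel_size_um,
              ifelse(is.na(x$nebd_frame), "unannotated", x$nebd_frame)))
  invisible(x)
}

.new_projection <- function(data, frame_interval_s, pixel_size_um, nebd_frame,
                            provenance, origin = c(y = 1L, x = 1L)) {
  n_t <- dim(data)[3]
  times_s <- if (is.na(nebd_frame)) (seq_len(n_t) - 1) * frame_interval_s
             else (seq_len(n_t) - nebd_frame) * frame_interval_s
  structure(
    list(data = data, frame_interval_s = frame_interval_s,
         pixel_size_um = pixel_size_um, nebd_frame = nebd_frame,
         times_s = times_s, origin = origin, provenance = provenance),
    class = "pcm_projection"
  )
}

#' @export
print.pcm_projection <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pcm_projection> %dx%d px, %d frame(s), t = [%g, %g] s post-NEBD\n",
              d[1], d[2], d[3], min(x$times_s), max(x$times_s)))
  cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Collapse z-stacks into SUM projections
#'
#' Each time point's z-stack is collapsed by summing over z (in double
#' precision, so integer counts cannot overflow). A 3D (already projected or
#' single-plane) stack passes through unchanged apart from a provenance note.
#'
#' @param stack A [movie_stack()] or a `pcm_simulation` (its stack is used).
#' @return A projection object (class `pcm_projection`) with `[y, x, t]`
#'   data, inherited calibration, times in seconds post-NEBD, and provenance.
#' @export
sum_project <- function(stack) {
  if (inherits(stack, "pcm_simulation")) stack <- stack$stack
  stopifnot(inherits(stack, "movie_stack"))
  nd <- length(dim(stack$data))
  if (nd == 4) {
    # sum over z: make z the first dimension, then colSums collapses it
    proj <- colSums(aperm(stack$data, c(3, 1, 2, 4)))
    prov <- "sum_projection"
  } else {
    proj <- stack$data * 1  # force double
    prov <- "sum_projection(identity: input had no z axis)"
  }
  .new_projection(proj, stack$frame_interval_s, stack$pixel_size_um,
                  stack$nebd_frame, prov)
}

#' Split a projection into anterior and posterior halves
#'
#' Crops the movie into two along the given axis at a user-supplied boundary,
#' isolating the anterior and posterior centrosomes. The anterior crop keeps
#' indices `1..boundary`, the posterior crop `boundary+1..end`, so the two
#' crops partition every frame. Each crop records its `origin` so coordinates
#' map back to the full frame.
#'
#' @param proj A `pcm_projection`.
#' @param boundary Pixel index of the last anterior column (or row for
#'   `axis = "y"`); must be strictly inside the image. Defaults to the
#'   midline along the chosen axis.
#' @param axis `"x"` (default; split along the long axis into left/right) or
#'   `"y"`.
#' @return Named list with `anterior` and `posterior` projections.
#' @export
split_hemispheres <- function(proj, boundary = NULL, axis = c("x", "y")) {
  stopifnot(inherits(proj, "pcm_projection"))
  axis <- match.arg(axis)
  n <- if (axis == "x") dim(proj$data)[2] else dim(proj$data)[1]
  boundary <- boundary %||% floor(n / 2)
  if (boundary < 1 || boundary >= n)
    stop("`boundary` must be strictly inside the image (1 <= boundary < ", n, ")")
  crop <- function(idx, side) {
    data <- if (axis == "x") proj$data[, idx, , drop = FALSE]
            else proj$data[idx, , , drop = FALSE]
    origin <- proj$origin
    if (side == "posterior") {
      if (axis == "x") origin["x"] <- origin["x"] + boundary
      else origin["y"] <- origin["y"] + boundary
    }
    out <- .new_projection(data, proj$frame_interval_s, proj$pixel_size_um,
                           proj$nebd_frame,
                           c(proj$provenance,
                             sprintf("split_hemispheres(%s, axis=%s, boundary=%d)",
                                     side, axis, boundary)),
                           origin = origin)
    out$times_s <- proj$times_s
    out
  }
  list(anterior = crop(seq_len(boundary), "anterior"),
       posterior = crop((boundary + 1):n, "posterior"))
}

#' Keep only frames at/after NEBD
#'
#' Retains frames with time >= 0 (the NEBD frame itself is kept, so aligned
#' curves have a t = 0 sample) and re-expresses frame times as seconds
#' post-NEBD. Idempotent.
#'
#' @param proj A `pcm_projection` whose source stack carried an annotated
#'   `nebd_frame`.
#' @return The cropped projection.
#' @export
crop_post_nebd <- function(proj) {
  stopifnot(inherits(proj, "pcm_projection"))
  if (is.na(proj$nebd_frame))
    stop("no NEBD annotation: supply `nebd_frame` when constructing the ",
         "movie stack (the NEBD frame is identified manually)")
  keep <- which(proj$times_s >= 0)
  out <- proj
  out$data <- proj$data[, , keep, drop = FALSE]
  out$times_s <- proj$times_s[keep]
  out$nebd_frame <- 1L
  if (!"crop_post_nebd" %in% proj$provenance)
    out$provenance <- c(proj$provenance, "crop_post_nebd")
  out
}

# ---- disk I/O -------------------------------------------------------------

#' Write a movie to disk as multi-page TIFF plus sidecar JSON
#'
#' Pages are ordered time-major (for each time point, all z-slices). Counts
#' are rounded and clamped to the 16-bit range. The sidecar JSON carries the
#' calibration (`frame_interval_s`, `pixel_size_um`, `z_step_um`, `n_z`,
#' `nebd_frame`). For a `pcm_simulation` the ground-truth table is written as
#' `<name>_truth.csv` alongside.
#'
#' @param x A [movie_stack()], `pcm_projection`, or `pcm_simulation`.
#' @param dir Output directory (created if needed).
#' @param name Base file name (no extension).
#' @return Invisibly, the paths written.
#' @export
write_movie <- function(x, dir, name = "movie") {
  truth <- NULL
  if (inherits(x, "pcm_simulation")) { truth <- x$truth; x <- x$stack }
  if (inherits(x, "pcm_projection")) {
    x <- movie_stack(x$data, x$frame_interval_s, x$pixel_size_um,
                     nebd_frame = x$nebd_frame)
  }
  stopifnot(inherits(x, "movie_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nd <- length(dim(x$data))
  n_t <- dim(x$data)[nd]
  n_z <- if (nd == 4) dim(x$data)[3] else 1L
  pages <- vector("list", n_t * n_z)
  p <- 0L
  for (i in seq_len(n_t)) for (k in seq_len(n_z)) {
    p <- p + 1L
    pg <- if (nd == 4) x$data[, , k, i] else x$data[, , i]
    pages[[p]] <- pmin(pmax(round(pg), 0), 65535) / 65535
  }
  tif <- file.path(dir, paste0(name, ".tif"))
  meta <- file.path(dir, paste0(name, ".json"))
  tiff::writeTIFF(pages, tif, bits.per.sample = 16L)
  jsonlite::write_json(
    list(frame_interval_s = x$frame_interval_s,
         pixel_size_um = x$pixel_size_um,
         z_step_um = x$z_step_um,
         n_z = n_z, n_frames = n_t,
         nebd_frame = x$nebd_frame),
    meta, auto_unbox = TRUE, null = "null", digits = NA)
  paths <- c(tiff = tif, meta = meta)
  if (!is.null(truth)) {
    tr <- file.path(dir, paste0(name, "_truth.csv"))
    utils::write.csv(truth, tr, row.names = FALSE)
    paths <- c(paths, truth = tr)
  }
  invisible(paths)
}

#' Read a movie written by [write_movie()]
#'
#' @param tiff_path Multi-page TIFF, pages ordered time-major.
#' @param meta_path Sidecar JSON with calibration and NEBD annotation.
#' @return A [movie_stack()] with integer counts.
#' @export
read_movie <- function(tiff_path, meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiff_path, all = TRUE, as.is = TRUE)
  n_z <- meta$n_z %||% 1L
  n_t <- length(pages) / n_z
  if (n_t != round(n_t))
    stop("page count ", length(pages), " is not a multiple of n_z = ", n_z)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  data <- if (n_z == 1) array(0, c(ny, nx, n_t)) else array(0, c(ny, nx, n_z, n_t))
  p <- 0L
  for (i in seq_len(n_t)) for (k in seq_len(n_z)) {
    p <- p + 1L
    if (n_z == 1) data[, , i] <- pages[[p]] else data[, , k, i] <- pages[[p]]
  }
  movie_stack(data, frame_interval_s = meta$frame_interval_s,
              pixel_size_um = meta$pixel_size_um,
              nebd_frame = meta$nebd_frame %||% NA_integer_,
              z_step_um = if (n_z > 1) meta$z_step_um else NULL)
}
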