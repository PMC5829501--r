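# Ratiometric two-channel immunofluorescence: per-centrosome ratio of a
# modification-specific stain (channel A) to a total-scaffold stain
# (channel B), normalized to interphase, compared across cell-cycle stages.

#' Measure the two-channel signal ratio at one centrosome
#'
#' The ROI is segmented on channel B (the total-scaffold reference), so that
#' both channels are integrated over the identical pixel set — this controls
#' for changes in channel-A signal that merely reflect PCM growth. Each
#' channel gets its own threshold from its own annulus statistics at the same
#' centre; integrated signals are `sum(pixel - threshold)` over the shared
#' ROI and the ratio is `signal_a / signal_b`.
#'
#' @param image_a,image_b Registered numeric matrices of identical shape.
#' @param center Approximate centrosome centre `c(y, x)`; the seed is
#'   re-detected on channel B near it.
#' @param cfg A [quant_config()].
#' @param stage Optional cell-cycle stage label carried into the result.
#' @return A one-row tibble: `stage`, `seed_y`, `seed_x`, `area_roi`,
#'   `signal_a`, `signal_b`, `ratio`. An empty channel-B ROI or non-positive
#'   `signal_b` aborts with an error of class `pcm_ratio_rejected` naming the
#'   reason.
#' @export
measure_ratio <- function(image_a, image_b, center, cfg = quant_config(),
                          stage = NA_character_) {
  if (!identical(dim(image_a), dim(image_b)))
    stop("channels must be registered: image dimensions differ")
  seed <- detect_seed(image_b, cfg, prior = center)
  bg_b <- estimate_background(image_b, seed, cfg)
  thr_b <- compute_threshold(bg_b, cfg)
  roi <- segment_roi(image_b, thr_b, seed)
  if (roi$area == 0)
    stop(structure(class = c("pcm_ratio_rejected", "error", "condition"),
                   list(message = "empty reference-channel ROI: centrosome not resolvable in channel B",
                        call = sys.call())))
  bg_a <- estimate_background(image_a, seed, cfg)
  thr_a <- compute_threshold(bg_a, cfg)
  signal_b <- integrated_mass(image_b, roi, thr_b)
  signal_a <- sum(image_a[roi$indices] - thr_a)
  if (signal_b <= 0)
    stop(structure(class = c("pcm_ratio_rejected", "error", "condition"),
                   list(message = "non-positive channel-B signal: ratio undefined",
                        call = sys.call())))
  tibble::tibble(stage = stage, seed_y = unname(seed[1]), seed_x = unname(seed[2]),
                 area_roi = roi$area, signal_a = signal_a, signal_b = signal_b,
                 ratio = signal_a / signal_b)
}

#' Measure ratios for a set of two-channel spot images
#'
#' Convenience wrapper over [measure_ratio()] for a [render_two_channel_spots()]
#' result (or any list of `list(a, b, center, stage)` entries). Rejected
#' measurements are dropped and recorded.
#'
#' @param spots A `two_channel_spots` object or plain list of spot entries.
#' @param cfg A [quant_config()].
#' @return A tibble with one row per accepted measurement (columns of
#'   [measure_ratio()] plus `id`); attribute `rejected` is a tibble of
#'   `id` and `reason` for refused spots.
#' @export
measure_ratio_set <- function(spots, cfg = quant_config()) {
  entries <- if (inherits(spots, "two_channel_spots")) spots$spots else spots
  rows <- list(); rej <- list()
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    res <- tryCatch(
      measure_ratio(e$a, e$b, e$center, cfg, stage = e$stage %||% NA_character_),
      pcm_ratio_rejected = function(cnd) conditionMessage(cnd))
    if (is.character(res)) {
      rej[[length(rej) + 1]] <- tibble::tibble(id = i, reason = res)
    } else {
      res$id <- i
      rows[[length(rows) + 1]] <- res
    }
  }
  if (!length(rows)) stop("every measurement was rejected")
  out <- do.call(rbind, rows)
  attr(out, "rejected") <- if (length(rej)) do.call(rbind, rej)
                           else tibble::tibble(id = integer(0), reason = character(0))
  out
}

#' Normalize ratios to the interphase mean
#'
#' Adds `normalized_ratio = ratio / mean(interphase ratios)`, so the
#' interphase group mean of normalized ratios is exactly 1. Applying the
#' function twice is the same as applying it once (it always recomputes from
#' `ratio`).
#'
#' @param measurements Data frame with `ratio` and `stage` columns,
#'   containing at least one `"interphase"` row.
#' @return The measurements with a `normalized_ratio` column.
#' @export
normalize_to_interphase <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("ratio", "stage") %in% names(measurements)))
  inter <- measurements$ratio[measurements$stage == "interphase"]
  if (!length(inter))
    stop("no interphase measurements: nothing to normalize against")
  measurements$normalized_ratio <- measurements$ratio / mean(inter)
  measurements
}

#' Compare two stage groups with an unpaired t-test
#'
#' Welch's unequal-variance variant of the unpaired two-sided t-test. Two
#' degenerate zero-variance groups are handled by convention: p = 1 when they
#' are identical, p = 0 when they are constant but different; both flagged.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return List: `statistic`, `df`, `p_value`, `method`, `degenerate`.
#' @export
compare_stages <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 measurements")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    same <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(list(statistic = NA_real_, df = NA_real_,
                p_value = if (same) 1 else 0,
                method = "Welch two-sample t-test (degenerate)",
                degenerate = TRUE))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, method = "Welch two-sample t-test",
       degenerate = FALSE)
}

#' Per-stage summary of normalized ratios
#'
#' @param measurements Output of [normalize_to_interphase()] (normalization
#'   is applied if the column is missing).
#' @param conf_level Confidence level of the normal-approximation band.
#' @param reference Stage each group is tested against (default interphase).
#' @return Tibble: `stage`, `n`, `mean_normalized`, `ci_lo`, `ci_hi`,
#'   `p_vs_reference` (`NA` for the reference stage itself).
#' @export
stage_summary <- function(measurements, conf_level = 0.95,
                          reference = "interphase") {
  if (!"normalized_ratio" %in% names(measurements))
    measurements <- normalize_to_interphase(measurements)
  z <- stats::qnorm((1 + conf_level) / 2)
  stages <- unique(measurements$stage)
  ref_vals <- measurements$normalized_ratio[measurements$stage == reference]
  rows <- lapply(stages, function(s) {
    v <- measurements$normalized_ratio[measurements$stage == s]
    se <- stats::sd(v) / sqrt(length(v))
    p <- if (s == reference || length(v) < 2 || length(ref_vals) < 2) NA_real_
         else compare_stages(v, ref_vals)$p_value
    tibble::tibble(stage = s, n = length(v), mean_normalized = mean(v),
                   ci_lo = mean(v) - z * se, ci_hi = mean(v) + z * se,
                   p_vs_reference = p)
  })
  do.call(rbind, rows)
}
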