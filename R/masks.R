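#' Build onset and entrainment analysis masks from a frontal ITC map
#'
#' Masks select the time-frequency cells carrying the evoked response: cells
#' of the whole-sample mean frontal ITC map at or above `threshold`
#' (inclusive), inside a fixed time window, and valid (edge-free). Two masks
#' are produced: the onset-response mask (0-500 ms) and the entrainment mask
#' (750-2250 ms). The same shared pair is then applied to every subject and
#' ROI.
#'
#' @param frontal_itc_map an `itc_map`, normally the all-subject mean frontal
#'   map (see [average_maps()]).
#' @param threshold ITC threshold, applied as `>=`.
#' @param onset_window,entrain_window time windows in seconds, closed.
#' @param source free-text note recording which average built the map.
#' @return list with `onset` and `entrainment` `analysis_mask` objects
#'   (fields `kind`, `window_s`, `threshold`, `cells`, `freqs_hz`, `times_s`,
#'   `source`).
#' @export
build_masks <- function(frontal_itc_map, threshold = 0.13,
                        onset_window = c(0, 0.5),
                        entrain_window = c(0.75, 2.25),
                        source = "whole-sample mean frontal ITC") {
  stopifnot(inherits(frontal_itc_map, "itc_map"))
  t <- frontal_itc_map$times_s
  for (w in list(onset_window, entrain_window)) {
    if (w[1] < min(t) || w[2] > max(t)) {
      stopf("mask window [%g, %g] s outside the map extent [%g, %g] s",
            w[1], w[2], min(t), max(t))
    }
  }
  one_mask <- function(kind, window) {
    in_win <- matrix(rep(t >= window[1] & t <= window[2],
                         each = length(frontal_itc_map$freqs_hz)),
                     nrow = length(frontal_itc_map$freqs_hz))
    cells <- !is.na(frontal_itc_map$values) &
      frontal_itc_map$values >= threshold &
      in_win & frontal_itc_map$valid_mask
    structure(
      list(kind = kind, window_s = window, threshold = threshold,
           cells = cells, freqs_hz = frontal_itc_map$freqs_hz,
           times_s = t, source = source),
      class = "analysis_mask"
    )
  }
  list(onset = one_mask("onset", onset_window),
       entrainment = one_mask("entrainment", entrain_window))
}

#' @export
print.analysis_mask <- function(x, ...) {
  cat(sprintf("<analysis_mask> %s: ITC >= %g in [%g, %g] s, %d cells selected\n",
              x$kind, x$threshold, x$window_s[1], x$window_s[2], sum(x$cells)))
  invisible(x)
}

#' Frequency-band definitions for mask-based extraction
#'
#' Onset-response bands: theta 3-8 Hz, alpha 8-14 Hz, beta 14-17 Hz.
#' Entrainment bands: low gamma 30-55 Hz, high gamma 65-100 Hz. Band
#' membership is a closed interval (the printed onset bands share their
#' boundary frequencies).
#'
#' @return named list of `band_definition` objects (fields `name`,
#'   `range_hz`, `applicable_mask`).
#' @export
band_definitions <- function() {
  specs <- list(
    theta = list(c(3, 8), "onset"),
    alpha = list(c(8, 14), "onset"),
    beta = list(c(14, 17), "onset"),
    low_gamma = list(c(30, 55), "entrainment"),
    high_gamma = list(c(65, 100), "entrainment")
  )
  lapply(stats::setNames(names(specs), names(specs)), function(nm) {
    structure(list(name = nm, range_hz = specs[[nm]][[1]],
                   applicable_mask = specs[[nm]][[2]]),
              class = "band_definition")
  })
}

#' Within-mask band summary of a time-frequency map
#'
#' The arithmetic mean of map cells where the mask is true and the frequency
#' lies inside the band range. An empty mask-band intersection yields `NA`
#' with a warning (never a silent zero).
#'
#' @param map an `ersp_map` or `itc_map`.
#' @param mask an `analysis_mask` whose kind matches the band's
#'   `applicable_mask`.
#' @param band_def a `band_definition`.
#' @return list with `value`, `n_cells`, `band`, `measure`, `mask_kind`.
#' @export
band_summary <- function(map, mask, band_def) {
  stopifnot(inherits(map, "tf_map"), inherits(mask, "analysis_mask"),
            inherits(band_def, "band_definition"))
  if (band_def$applicable_mask != mask$kind) {
    stopf("band '%s' applies to the %s mask, got the %s mask",
          band_def$name, band_def$applicable_mask, mask$kind)
  }
  if (!identical(dim(map$values), dim(mask$cells))) {
    stopf("map and mask grids differ")
  }
  in_band <- map$freqs_hz >= band_def$range_hz[1] &
    map$freqs_hz <= band_def$range_hz[2]
  sel <- mask$cells & matrix(in_band, nrow = length(map$freqs_hz),
                             ncol = length(map$times_s)) & !is.na(map$values)
  n <- sum(sel)
  if (n == 0) {
    warning(sprintf("band '%s': no masked cells in %g-%g Hz; value undefined",
                    band_def$name, band_def$range_hz[1], band_def$range_hz[2]),
            call. = FALSE)
    return(list(value = NA_real_, n_cells = 0L, band = band_def$name,
                measure = map$measure, mask_kind = mask$kind))
  }
  list(value = mean(map$values[sel]), n_cells = n, band = band_def$name,
       measure = map$measure, mask_kind = mask$kind)
}

#' Average several ITC (or ERSP) maps cell-wise
#'
#' Used to build the whole-sample mean frontal ITC map that defines the
#' analysis masks. Maps must share grids.
#'
#' @param maps list of `tf_map` objects on identical grids.
#' @return a map of the same class holding the cell-wise mean.
#' @export
average_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  ref <- maps[[1]]
  for (m in maps[-1]) {
    if (!isTRUE(all.equal(m$freqs_hz, ref$freqs_hz)) ||
        !isTRUE(all.equal(m$times_s, ref$times_s))) {
      stopf("maps are on different grids")
    }
  }
  vals <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  out <- ref
  out$values <- vals
  out$n_trials <- sum(vapply(maps, `[[`, numeric(1), "n_trials"))
  out
}

#' Extract all within-mask band summaries across subjects and ROIs
#'
#' Applies [band_summary()] for every subject x ROI x band x measure
#' combination and returns a long-format table, one row each. Onset bands
#' use the onset mask, entrainment bands the entrainment mask; the same
#' shared mask pair (built from the whole-sample frontal ITC average) is
#' used throughout.
#'
#' @param subject_maps named list: per subject, a list with `group` and, per
#'   ROI name, a list holding `ersp` and `itc` maps.
#' @param masks the mask pair from [build_masks()].
#' @param band_defs list of band definitions; default [band_definitions()].
#' @param roi_list ROI names to extract; default the four standard ROIs.
#' @return data.frame with columns `subject_id`, `group`, `roi`, `band`,
#'   `measure`, `value`, `n_cells`.
#' @export
extract_all <- function(subject_maps, masks, band_defs = band_definitions(),
                        roi_list = names(roi_definitions())) {
  rows <- list()
  for (sid in names(subject_maps)) {
    subj <- subject_maps[[sid]]
    for (roi in roi_list) {
      if (is.null(subj[[roi]]) || is.null(subj[[roi]]$ersp) ||
          is.null(subj[[roi]]$itc)) {
        stopf("subject '%s' is missing maps for ROI '%s'", sid, roi)
      }
      for (bd in band_defs) {
        mask <- masks[[bd$applicable_mask]]
        for (meas in c("ersp", "itc")) {
          s <- band_summary(subj[[roi]][[meas]], mask, bd)
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = sid, group = subj$group %||% NA_character_,
            roi = roi, band = bd$name, measure = s$measure,
            value = s$value, n_cells = s$n_cells)
        }
      }
    }
  }
  do.call(rbind, rows)
}
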