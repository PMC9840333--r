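#' Construct a continuous multi-channel recording
#'
#' The basic container for continuous EEG/EMG data: a channels x samples
#' matrix in microvolts plus channel names, sampling rate, event markers and
#' a provenance trail of processing steps.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param channel_names character vector, one unique label per row of `data`.
#' @param rate sampling rate in Hz.
#' @param events data.frame with columns `time_s`, `label` (may be empty).
#' @param provenance character vector of applied processing steps.
#' @return an object of class `eeg_recording`.
#' @export
new_recording <- function(data, channel_names, rate,
                          events = data.frame(time_s = numeric(),
                                              label = character()),
                          provenance = character()) {
  data <- as.matrix(data)
  if (nrow(data) != length(channel_names)) {
    stopf("data has %d rows but %d channel names given",
          nrow(data), length(channel_names))
  }
  if (anyDuplicated(channel_names)) stopf("duplicate channel names")
  if (rate <= 0) stopf("rate must be positive")
  dur <- ncol(data) / rate
  if (nrow(events) && any(events$time_s < 0 | events$time_s > dur)) {
    stopf("event markers outside the recorded duration")
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, channel_names = as.character(channel_names),
         rate = rate, events = events, provenance = provenance),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate,
              nrow(x$events)))
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

duration_s <- function(recording) ncol(recording$data) / recording$rate

#' The four scalp regions of interest
#'
#' Named electrode groups averaged into virtual ROI channels: frontal (Fz),
#' central (Cz), parietal (Pz) and occipital (Oz), using 10-10 labels.
#'
#' @return named list of `roi_definition` objects (fields `name`, `electrodes`).
#' @export
roi_definitions <- function() {
  defs <- list(
    Fz = c("F3", "F1", "Fz", "F2", "F4"),
    Cz = c("C1", "Cz", "C2", "FC1", "FCz", "FC2"),
    Pz = c("P3", "P1", "Pz", "P2", "P4"),
    Oz = c("O1", "Oz", "O2", "PO3", "POz", "PO4")
  )
  lapply(stats::setNames(names(defs), names(defs)), function(nm) {
    structure(list(name = nm, electrodes = defs[[nm]]),
              class = "roi_definition")
  })
}

#' Default simulation montage
#'
#' The 22 distinct electrodes of the four ROIs plus 10 filler 10-10 sites
#' (32 total).
#'
#' @return character vector of channel labels.
#' @export
default_montage <- function() {
  roi <- unlist(lapply(roi_definitions(), `[[`, "electrodes"), use.names = FALSE)
  fillers <- c("Fp1", "Fp2", "AFz", "F7", "F8", "T7", "T8", "P7", "P8", "CPz")
  c(roi, fillers)
}

# per-channel weighting of the simulated cortical components:
# the evoked response is frontally dominant, fading toward occipital sites
montage_component_weights <- function(channel_names) {
  rois <- roi_definitions()
  w <- rep(0.4, length(channel_names))
  w[channel_names %in% rois$Fz$electrodes] <- 1.0
  w[channel_names %in% rois$Cz$electrodes] <- 0.7
  w[channel_names %in% rois$Pz$electrodes] <- 0.5
  w[channel_names %in% rois$Oz$electrodes] <- 0.3
  names(w) <- channel_names
  w
}

# blink topography: strongly frontal, weak elsewhere
montage_blink_weights <- function(channel_names) {
  frontal <- c("Fp1", "Fp2", "AFz", roi_definitions()$Fz$electrodes)
  w <- rep(0.15, length(channel_names))
  w[channel_names %in% frontal] <- 1.0
  names(w) <- channel_names
  w
}
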