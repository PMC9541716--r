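#' Multichannel extracellular recording container
#'
#' Bundles a channels-by-samples signal matrix with its sampling rate, an
#' optional event channel carrying the motor start/stop pulses of a stretch
#' protocol, and the electrode layout table.
#'
#' @param signals numeric matrix, channels x samples. Row names, if present,
#'   must match `layout$electrode`.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param layout data frame with columns `electrode`, `x_cm`, `y_cm`
#'   (electrode ids unique).
#' @param event_channel optional numeric vector, same length as
#'   `ncol(signals)`, holding the motor pulse trace.
#' @param meta free-form provenance list.
#' @return An object of class `"mea_recording"`.
#' @seealso [read_recording_csv()], [synthesize_electrograms()]
#' @export
mea_recording <- function(signals, sampling_rate, layout,
                          event_channel = NULL, meta = list()) {
  signals <- as.matrix(signals)
  if (!is.numeric(signals) || any(!is.finite(signals)))
    stop("'signals' must be a finite numeric matrix")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("'sampling_rate' must be a single positive number")
  layout <- validate_layout(layout)
  if (nrow(layout) != nrow(signals))
    stop("layout has ", nrow(layout), " electrodes but 'signals' has ",
         nrow(signals), " rows")
  if (is.null(rownames(signals)))
    rownames(signals) <- as.character(layout$electrode)
  if (!identical(rownames(signals), as.character(layout$electrode)))
    stop("row names of 'signals' do not match layout electrode ids")
  if (!is.null(event_channel)) {
    event_channel <- as.numeric(event_channel)
    if (length(event_channel) != ncol(signals))
      stop("'event_channel' must have one sample per signal column")
  }
  structure(
    list(signals = signals, sampling_rate = sampling_rate,
         event_channel = event_channel, layout = layout, meta = meta),
    class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signals), ncol(x$signals), x$sampling_rate,
              ncol(x$signals) / x$sampling_rate))
  cat(sprintf("  event channel: %s\n",
              if (is.null(x$event_channel)) "none" else "present"))
  invisible(x)
}

validate_layout <- function(layout) {
  layout <- as.data.frame(layout)
  need <- c("electrode", "x_cm", "y_cm")
  if (!all(need %in% names(layout)))
    stop("layout must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(layout$electrode))
    stop("layout electrode ids must be unique")
  if (any(!is.finite(layout$x_cm)) || any(!is.finite(layout$y_cm)))
    stop("layout coordinates must be finite")
  layout
}

#' Default 12-electrode array layout
#'
#' The recording electrodes of the stretchable array: a 2-mm-pitch square
#' grid (4 x 4 minus the four corners) centred inside the 8-mm culture disc.
#' Coordinates are in cm; all electrodes lie within the 0.4 cm disc radius.
#'
#' @return data frame with columns `electrode`, `x_cm`, `y_cm` (12 rows).
#' @examples
#' lay <- default_layout()
#' max(sqrt(lay$x_cm^2 + lay$y_cm^2)) # < 0.4 cm
#' @export
default_layout <- function() {
  g <- c(-0.3, -0.1, 0.1, 0.3)
  pos <- expand.grid(x_cm = g, y_cm = g)
  pos <- pos[!(abs(pos$x_cm) == 0.3 & abs(pos$y_cm) == 0.3), ]
  data.frame(electrode = paste0("E", seq_len(nrow(pos))),
             x_cm = pos$x_cm, y_cm = pos$y_cm,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read an electrode layout table
#'
#' @param path CSV file with columns `electrode,x_cm,y_cm`.
#' @return validated layout data frame.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  validate_layout(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a recording from a plain multi-column CSV
#'
#' Expects one time column (seconds) followed by one column per electrode,
#' plus optionally an `event` column with the motor pulse trace. Column
#' names after `time` must match the layout electrode ids.
#'
#' @param signal_file CSV of samples (`time`, one column per electrode,
#'   optional `event`).
#' @param layout layout data frame or path to a layout CSV.
#' @param sampling_rate sampling rate in Hz; inferred from the time column
#'   when `NULL`.
#' @return an [mea_recording()] object.
#' @export
read_recording_csv <- function(signal_file, layout, sampling_rate = NULL) {
  if (!file.exists(signal_file)) stop("signal file not found: ", signal_file)
  if (is.character(layout)) layout <- read_layout(layout)
  layout <- validate_layout(layout)
  d <- utils::read.csv(signal_file, stringsAsFactors = FALSE)
  if (!"time" %in% names(d)) stop("signal CSV must have a 'time' column")
  if (is.null(sampling_rate)) {
    dt <- diff(d$time)
    if (length(dt) < 1L || any(dt <= 0)) stop("cannot infer sampling rate")
    sampling_rate <- 1 / stats::median(dt)
  }
  ev <- if ("event" %in% names(d)) d$event else NULL
  ids <- as.character(layout$electrode)
  missing <- setdiff(ids, names(d))
  if (length(missing))
    stop("signal CSV lacks electrode columns: ", paste(missing, collapse = ", "))
  sig <- t(as.matrix(d[ids]))
  rownames(sig) <- ids
  mea_recording(sig, sampling_rate, layout, event_channel = ev,
                meta = list(source = signal_file))
}

#' Write a recording to a plain multi-column CSV
#'
#' Inverse of [read_recording_csv()]; mainly for exporting small synthetic
#' recordings.
#'
#' @param rec an [mea_recording()] object.
#' @param signal_file output CSV path.
#' @export
write_recording_csv <- function(rec, signal_file) {
  stopifnot(inherits(rec, "mea_recording"))
  n <- ncol(rec$signals)
  d <- data.frame(time = (seq_len(n) - 1) / rec$sampling_rate)
  d <- cbind(d, as.data.frame(t(rec$signals)))
  if (!is.null(rec$event_channel)) d$event <- rec$event_channel
  utils::write.csv(d, signal_file, row.names = FALSE)
  invisible(signal_file)
}
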