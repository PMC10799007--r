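#' Epoched ERP data container
#'
#' Holds a stack of fixed-length EEG epochs (microvolts) with their sampling
#' rate, time axis, lock event, channel names, and per-epoch condition
#' labels.
#'
#' @param data numeric array, epochs x channels x samples, in microvolts.
#' @param sfreq sampling rate in Hz (default 250).
#' @param tmin_ms time of the first sample in ms relative to the lock event.
#' @param channels character vector of channel names (length = dim 2).
#' @param labels data.frame with one row per epoch; recognised columns are
#'   `correctness` (`"correct"`/`"incorrect"`), `feedback`
#'   (`"positive"`/`"negative"`), and `target_side` (`"left"`/`"right"`).
#' @param lock lock event: `"response"`, `"feedback"`, or `"stimulus"`.
#' @return an `epoch_set` object.
#' @export
epoch_set <- function(data, sfreq = 250, tmin_ms,
                      channels, labels = NULL,
                      lock = c("stimulus", "response", "feedback")) {
  lock <- match.arg(lock)
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dim(data)[2] != length(channels)) {
    stop("channel names do not match the data's channel dimension",
         call. = FALSE)
  }
  if (is.null(labels)) labels <- data.frame(row.names = seq_len(dim(data)[1]))
  if (nrow(labels) != dim(data)[1]) {
    stop("labels must have one row per epoch", call. = FALSE)
  }
  dimnames(data)[[2]] <- channels
  structure(list(data = data, sfreq = sfreq, tmin_ms = tmin_ms,
                 channels = channels, labels = labels, lock = lock),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoch_set: %d epochs x %d channels x %d samples (%g Hz, %s-locked, %g..%g ms)\n",
              d[1], d[2], d[3], x$sfreq, x$lock, x$tmin_ms,
              max(epoch_times(x))))
  invisible(x)
}

#' Time axis of an epoch set, in ms
#' @param epochs an `epoch_set`.
#' @return numeric vector of sample times in ms.
#' @export
epoch_times <- function(epochs) {
  epochs$tmin_ms + (seq_len(dim(epochs$data)[3]) - 1L) * 1000 / epochs$sfreq
}

window_index <- function(epochs, window) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  tms <- epoch_times(epochs)
  if (window[1] < min(tms) - 1e-9 || window[2] > max(tms) + 1e-9) {
    stop(sprintf("window [%g, %g] ms lies outside the epoch span [%g, %g] ms",
                 window[1], window[2], min(tms), max(tms)), call. = FALSE)
  }
  idx <- which(tms >= window[1] - 1e-9 & tms <= window[2] + 1e-9)
  if (!length(idx)) stop("window contains no samples", call. = FALSE)
  idx
}

#' Baseline-correct every epoch
#'
#' Subtracts, per epoch and channel, the mean voltage over the baseline
#' window.
#'
#' @param epochs an `epoch_set`.
#' @param window ms pair inside the epoch span.
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window) {
  idx <- window_index(epochs, window)
  base <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(base)  # recycles over samples
  epochs
}

#' Reject epochs containing voltage artifacts
#'
#' Removes every epoch whose absolute voltage strictly exceeds the
#' threshold on any analyzed channel ("exceeding" is read as a strict
#' inequality: boundary values are retained).
#'
#' @param epochs an `epoch_set`.
#' @param threshold rejection threshold in microvolts (default 80).
#' @param channels channels to inspect (default: all).
#' @return list with the cleaned `epochs` and the `rejected_fraction`.
#' @export
reject_artifacts <- function(epochs, threshold = 80, channels = NULL) {
  stopifnot(threshold > 0)
  ch <- channels %||% epochs$channels
  chi <- match(ch, epochs$channels)
  if (anyNA(chi)) stop("unknown channel(s): ",
                       paste(ch[is.na(chi)], collapse = ", "), call. = FALSE)
  bad <- apply(epochs$data[, chi, , drop = FALSE], 1,
               function(e) any(abs(e) > threshold))
  frac <- mean(bad)
  if (all(bad)) {
    stop("all epochs exceed the artifact threshold; averages undefined",
         call. = FALSE)
  }
  epochs$data <- epochs$data[!bad, , , drop = FALSE]
  epochs$labels <- epochs$labels[!bad, , drop = FALSE]
  list(epochs = epochs, rejected_fraction = frac)
}

# Select epochs whose labels match all entries of a named character vector,
# e.g. c(correctness = "incorrect").
select_epochs <- function(epochs, label) {
  keep <- rep(TRUE, dim(epochs$data)[1])
  for (nm in names(label)) {
    if (is.null(epochs$labels[[nm]])) {
      stop("missing condition label column: ", nm, call. = FALSE)
    }
    keep <- keep & epochs$labels[[nm]] == label[[nm]]
  }
  keep
}

#' Average epochs of one condition into a waveform
#'
#' @param epochs an `epoch_set`.
#' @param label named character vector of label conditions, e.g.
#'   `c(correctness = "incorrect")`; empty selects all epochs.
#' @return matrix channels x samples (pointwise mean over epochs).
#' @export
condition_average <- function(epochs, label = character(0)) {
  keep <- select_epochs(epochs, label)
  if (!any(keep)) {
    stop("no epochs match condition ",
         paste(names(label), label, sep = "=", collapse = ", "),
         call. = FALSE)
  }
  avg <- apply(epochs$data[keep, , , drop = FALSE], c(2, 3), mean)
  rownames(avg) <- epochs$channels
  avg
}

#' Signed peak amplitude and latency inside a window
#'
#' Finds the extremum of the stated polarity (maximum for positive
#' components, minimum for negative ones) inside the measurement window;
#' ties are broken by the earliest latency.
#'
#' @param waveform numeric vector, one channel's waveform in microvolts.
#' @param times matching sample times in ms.
#' @param window ms pair inside the span of `times`.
#' @param polarity `"negative"` or `"positive"`.
#' @return list with `amplitude` (microvolts, signed) and `latency_ms`.
#' @export
peak_measure <- function(waveform, times, window,
                         polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  stopifnot(length(waveform) == length(times), length(window) == 2L)
  if (window[1] < min(times) - 1e-9 || window[2] > max(times) + 1e-9) {
    stop("measurement window lies outside the waveform span", call. = FALSE)
  }
  idx <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  seg <- waveform[idx]
  at <- if (polarity == "positive") which.max(seg) else which.min(seg)
  list(amplitude = seg[at], latency_ms = times[idx[at]])
}

#' ERP component extraction rule
#'
#' @param name component name.
#' @param channels channel(s) the component is measured at.
#' @param baseline baseline window, ms pair.
#' @param window measurement window, ms pair.
#' @param polarity `"negative"` or `"positive"`.
#' @param contrast `"incorrect-correct"`, `"negative-positive"`, `"none"`,
#'   or `"contra-ipsi"`.
#' @return a `component_spec` object.
#' @export
component_spec <- function(name, channels, baseline, window,
                           polarity = c("negative", "positive"),
                           contrast = c("none", "incorrect-correct",
                                        "negative-positive", "contra-ipsi")) {
  polarity <- match.arg(polarity)
  contrast <- match.arg(contrast)
  stopifnot(length(baseline) == 2L, length(window) == 2L)
  structure(list(name = name, channels = channels, baseline = baseline,
                 window = window, polarity = polarity, contrast = contrast),
            class = "component_spec")
}

#' Standard component extraction rules
#'
#' The four components analysed in the two-block associative-learning
#' paradigm:
#' * ERN — response-locked peak of the incorrect-minus-correct difference
#'   wave, 0-60 ms at FCz, negative polarity; baseline -800 to -700 ms
#'   pre-response.
#' * FRN — feedback-locked peak of the negative-minus-positive feedback
#'   difference wave, 252-352 ms at FCz, negative polarity; baseline -200
#'   to 0 ms.
#' * P300 — stimulus-locked positive peak of the correct-trial average,
#'   300-600 ms at Pz; baseline -200 to 0 ms.
#' * N2pc — stimulus-locked negative peak of the contralateral-minus-
#'   ipsilateral difference wave over PO7/PO8, 200-252 ms; baseline -100
#'   to 0 ms (the full pre-stimulus span of its epoch).
#'
#' @return named list of [component_spec()] objects.
#' @export
default_component_specs <- function() {
  list(
    ERN = component_spec("ERN", "FCz", c(-800, -700), c(0, 60),
                         "negative", "incorrect-correct"),
    FRN = component_spec("FRN", "FCz", c(-200, 0), c(252, 352),
                         "negative", "negative-positive"),
    P300 = component_spec("P300", "Pz", c(-200, 0), c(300, 600),
                          "positive", "none"),
    N2pc = component_spec("N2pc", c("PO7", "PO8"), c(-100, 0), c(200, 252),
                          "negative", "contra-ipsi"))
}

#' Extract one subject's component score from an epoch set
#'
#' Applies the full per-subject measurement pipeline: baseline correction,
#' artifact rejection at the threshold (strictly exceeding epochs removed),
#' condition averaging, and peak measurement. Difference components
#' (ERN, FRN) default to the peak of the difference wave; the alternative
#' reading — difference of the per-condition peaks — is available via
#' `peak_mode = "peak_difference"`.
#'
#' @param epochs an `epoch_set` for one subject.
#' @param spec a [component_spec()].
#' @param threshold artifact-rejection threshold in microvolts.
#' @param peak_mode `"difference_wave"` or `"peak_difference"` (difference
#'   components only).
#' @return list with `name`, `score` (microvolts), `latency_ms` (difference-
#'   wave and single-condition modes), and `rejected_fraction`.
#' @export
component_score <- function(epochs, spec, threshold = 80,
                            peak_mode = c("difference_wave", "peak_difference")) {
  stopifnot(inherits(spec, "component_spec"))
  peak_mode <- match.arg(peak_mode)
  miss <- setdiff(spec$channels, epochs$channels)
  if (length(miss)) {
    stop("epoch set lacks required channel(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  epochs <- baseline_correct(epochs, spec$baseline)
  rej <- reject_artifacts(epochs, threshold, spec$channels)
  epochs <- rej$epochs
  tms <- epoch_times(epochs)

  if (spec$contrast == "contra-ipsi") {
    n2 <- n2pc_score(epochs, window = spec$window, baseline = NULL,
                     threshold = NULL)
    return(list(name = spec$name, score = n2$score,
                latency_ms = n2$latency_ms,
                rejected_fraction = rej$rejected_fraction))
  }

  ch <- spec$channels[1]
  if (spec$contrast == "none") {
    lab <- if (!is.null(epochs$labels$correctness)) {
      c(correctness = "correct")
    } else {
      character(0)
    }
    wave <- condition_average(epochs, lab)[ch, ]
    pk <- peak_measure(wave, tms, spec$window, spec$polarity)
    return(list(name = spec$name, score = pk$amplitude,
                latency_ms = pk$latency_ms,
                rejected_fraction = rej$rejected_fraction))
  }

  labs <- if (spec$contrast == "incorrect-correct") {
    list(c(correctness = "incorrect"), c(correctness = "correct"))
  } else {
    list(c(feedback = "negative"), c(feedback = "positive"))
  }
  w1 <- condition_average(epochs, labs[[1]])[ch, ]
  w2 <- condition_average(epochs, labs[[2]])[ch, ]
  if (peak_mode == "difference_wave") {
    pk <- peak_measure(w1 - w2, tms, spec$window, spec$polarity)
    list(name = spec$name, score = pk$amplitude, latency_ms = pk$latency_ms,
         rejected_fraction = rej$rejected_fraction)
  } else {
    p1 <- peak_measure(w1, tms, spec$window, spec$polarity)
    p2 <- peak_measure(w2, tms, spec$window, spec$polarity)
    list(name = spec$name, score = p1$amplitude - p2$amplitude,
         latency_ms = NA_real_,
         rejected_fraction = rej$rejected_fraction)
  }
}

#' N2pc contralateral/ipsilateral waveforms and difference peak
#'
#' The ipsilateral waveform is the average of the left-sided electrode
#' (PO7) on left-target epochs and the right-sided electrode (PO8) on
#' right-target epochs; the contralateral waveform pairs each electrode
#' with the opposite target side. The score is the negative-polarity peak
#' of the contra-minus-ipsi difference in the measurement window.
#'
#' @param epochs an `epoch_set` with channels PO7 and PO8 and a
#'   `target_side` label column containing both sides.
#' @param window measurement window in ms (default 200-252).
#' @param baseline optional baseline window applied first (`NULL` to skip,
#'   e.g. when the caller has already corrected).
#' @param threshold optional artifact threshold applied first (`NULL` to
#'   skip).
#' @return list with `contra` and `ipsi` waveforms, the difference `score`
#'   in microvolts, and its `latency_ms`.
#' @export
n2pc_score <- function(epochs, window = c(200, 252), baseline = c(-100, 0),
                       threshold = 80) {
  miss <- setdiff(c("PO7", "PO8"), epochs$channels)
  if (length(miss)) {
    stop("N2pc requires channels PO7 and PO8", call. = FALSE)
  }
  if (is.null(epochs$labels$target_side)) {
    stop("N2pc requires a target_side label", call. = FALSE)
  }
  if (!is.null(baseline)) epochs <- baseline_correct(epochs, baseline)
  if (!is.null(threshold)) {
    epochs <- reject_artifacts(epochs, threshold, c("PO7", "PO8"))$epochs
  }
  sides <- unique(epochs$labels$target_side)
  if (!all(c("left", "right") %in% sides)) {
    stop("both target sides must be represented; contra/ipsi undefined",
         call. = FALSE)
  }
  left <- condition_average(epochs, c(target_side = "left"))
  right <- condition_average(epochs, c(target_side = "right"))
  ipsi <- (left["PO7", ] + right["PO8", ]) / 2
  contra <- (right["PO7", ] + left["PO8", ]) / 2
  tms <- epoch_times(epochs)
  pk <- peak_measure(contra - ipsi, tms, window, "negative")
  list(contra = contra, ipsi = ipsi, score = pk$amplitude,
       latency_ms = pk$latency_ms)
}
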