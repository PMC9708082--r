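#' Area-specific spike counting window
#'
#' Spikes are counted in a 200 ms window offset by the typical visually evoked
#' response latency of the area: 30--230 ms after stimulus onset for V1,
#' 50--250 ms for V4. The window is half-open, \code{[start, end)}, so
#' abutting windows never double-count a spike.
#'
#' @param area "V1" or "V4".
#' @return list with \code{area}, \code{startMs}, \code{endMs}.
#' @examples
#' areaWindow("V1")
#' @export
areaWindow <- function(area = c("V1", "V4")) {
  area <- match.arg(area)
  w <- switch(area, V1 = c(30, 230), V4 = c(50, 250))
  list(area = area, startMs = w[1], endMs = w[2])
}

#' Read trial-aligned spike events
#'
#' Expects a delimited file with columns \code{unit_id},
#' \code{presentation_id}, \code{time_ms} (spike times in ms relative to
#' stimulus onset).
#'
#' @param path CSV file path.
#' @return data.frame of spike events.
#' @export
readSpikeEvents <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "presentation_id", "time_ms")
  if (!all(need %in% names(df)))
    stop("spike file must have columns: ", paste(need, collapse = ", "))
  if (anyNA(df$time_ms) || any(!is.finite(df$time_ms)))
    stop("spike times must be finite")
  df$unit_id <- as.character(df$unit_id)
  df$presentation_id <- as.character(df$presentation_id)
  df[order(df$unit_id, df$presentation_id, df$time_ms), , drop = FALSE]
}

#' Read presentation metadata
#'
#' Expects columns \code{presentation_id}, \code{condition} (one of A, B,
#' AB), \code{stim_A}, \code{stim_B}, \code{correct}, \code{attended_in_rf},
#' \code{session_id}; a \code{condition_key} column is carried through when
#' present. Single-stimulus rows must name exactly one stimulus; AB rows must
#' name both.
#'
#' @param path CSV file path.
#' @return data.frame of presentation metadata.
#' @export
readPresentationMeta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("presentation_id", "condition", "stim_A", "stim_B", "correct",
            "attended_in_rf", "session_id")
  if (!all(need %in% names(df)))
    stop("metadata file must have columns: ", paste(need, collapse = ", "))
  if (!all(df$condition %in% c("A", "B", "AB")))
    stop("condition must be one of A, B, AB")
  hasA <- !is.na(df$stim_A) & nzchar(df$stim_A)
  hasB <- !is.na(df$stim_B) & nzchar(df$stim_B)
  bad <- (df$condition == "AB" & !(hasA & hasB)) |
    (df$condition == "A" & !(hasA & !hasB)) |
    (df$condition == "B" & !(!hasA & hasB))
  if (any(bad))
    stop("stimulus ids inconsistent with condition for presentations: ",
         paste(utils::head(df$presentation_id[bad]), collapse = ", "))
  df$presentation_id <- as.character(df$presentation_id)
  df$correct <- as.logical(df$correct)
  df$attended_in_rf <- as.logical(df$attended_in_rf)
  df
}

#' Read eye-position traces
#'
#' Expects columns \code{presentation_id}, \code{t_ms}, \code{x_deg},
#' \code{y_deg}. Returns one trace per presentation; the sample rate is
#' inferred from the median sample spacing unless given.
#'
#' @param path CSV file path.
#' @param sampleRate optional sampling rate in Hz, overriding inference.
#' @return named list of traces, each a list with \code{presentation_id},
#'   \code{sampleRate}, \code{x}, \code{y}.
#' @export
readEyeTraces <- function(path, sampleRate = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("presentation_id", "t_ms", "x_deg", "y_deg")
  if (!all(need %in% names(df)))
    stop("eye file must have columns: ", paste(need, collapse = ", "))
  df$presentation_id <- as.character(df$presentation_id)
  out <- lapply(split(df, df$presentation_id), function(d) {
    d <- d[order(d$t_ms), ]
    sr <- if (is.null(sampleRate)) 1000 / stats::median(diff(d$t_ms))
          else sampleRate
    eyeTrace(d$presentation_id[1], sr, d$x_deg, d$y_deg)
  })
  out[unique(df$presentation_id)]
}

#' Construct an eye trace
#'
#' @param presentationId identifier.
#' @param sampleRate sampling rate, Hz (> 0).
#' @param x,y horizontal and vertical eye position, degrees.
#' @return list with class "EyeTrace" fields.
#' @export
eyeTrace <- function(presentationId, sampleRate, x, y) {
  if (!is.numeric(sampleRate) || sampleRate <= 0)
    stop("sampleRate must be > 0")
  if (length(x) != length(y)) stop("x and y must have equal length")
  list(presentation_id = as.character(presentationId),
       sampleRate = sampleRate, x = as.numeric(x), y = as.numeric(y))
}

#' Count spikes in an area-specific window
#'
#' Counts each unit's spikes falling in the half-open interval
#' \code{[startMs, endMs)} of the given window, for every presentation in the
#' metadata (presentations without spikes get zero counts).
#'
#' @param spikes data.frame of spike events (see \code{\link{readSpikeEvents}}).
#' @param meta presentation metadata data.frame.
#' @param window a window from \code{\link{areaWindow}}.
#' @param units optional character vector fixing the unit roster (defaults to
#'   units present in \code{spikes}).
#' @return A \linkS4class{SpikeCountExperiment}, units x presentations.
#' @export
countSpikesInWindow <- function(spikes, meta, window, units = NULL) {
  if (is.null(window$startMs) || is.null(window$endMs) ||
      window$endMs - window$startMs != 200)
    stop("invalid counting window; use areaWindow()")
  if (is.null(units)) units <- sort(unique(as.character(spikes$unit_id)))
  pres <- as.character(meta$presentation_id)
  keep <- spikes$time_ms >= window$startMs & spikes$time_ms < window$endMs &
    spikes$presentation_id %in% pres & spikes$unit_id %in% units
  sp <- spikes[keep, , drop = FALSE]
  cts <- table(factor(sp$unit_id, levels = units),
               factor(sp$presentation_id, levels = pres))
  cts <- matrix(as.integer(cts), nrow = length(units),
                dimnames = list(units, pres))
  makeSpikeCountExperiment(cts, meta)
}

#' Assemble a SpikeCountExperiment from a count matrix and metadata
#'
#' @param counts integer matrix, units x presentations (dimnames required).
#' @param meta presentation metadata with one row per column of
#'   \code{counts}.
#' @return A \linkS4class{SpikeCountExperiment}.
#' @export
makeSpikeCountExperiment <- function(counts, meta) {
  meta <- meta[match(colnames(counts), as.character(meta$presentation_id)), ,
               drop = FALSE]
  if (anyNA(meta$presentation_id))
    stop("metadata missing for some presentations in the count matrix")
  rownames(meta) <- meta$presentation_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(meta))
  new("SpikeCountExperiment", se)
}

#' Read a pre-counted spike count table
#'
#' Bypasses event counting: expects a counts CSV (\code{unit_id},
#' \code{presentation_id}, \code{count}) plus the metadata file.
#'
#' @param countsPath,metaPath CSV file paths.
#' @return A \linkS4class{SpikeCountExperiment}.
#' @export
readCountTable <- function(countsPath, metaPath) {
  cdf <- utils::read.csv(countsPath, stringsAsFactors = FALSE)
  need <- c("unit_id", "presentation_id", "count")
  if (!all(need %in% names(cdf)))
    stop("counts file must have columns: ", paste(need, collapse = ", "))
  if (any(cdf$count < 0)) stop("counts must be non-negative")
  meta <- readPresentationMeta(metaPath)
  units <- sort(unique(as.character(cdf$unit_id)))
  pres <- as.character(meta$presentation_id)
  cts <- matrix(0L, length(units), length(pres),
                dimnames = list(units, pres))
  idx <- cbind(match(as.character(cdf$unit_id), units),
               match(as.character(cdf$presentation_id), pres))
  ok <- stats::complete.cases(idx)
  cts[idx[ok, , drop = FALSE]] <- as.integer(cdf$count[ok])
  makeSpikeCountExperiment(cts, meta)
}

## smoothed eye speed in deg/s (central differences, 5-sample moving average)
.eyeSpeed <- function(trace, smoothN = 5) {
  n <- length(trace$x)
  if (n < 3) stop("trace must have at least 3 samples")
  dt <- 1 / trace$sampleRate
  d <- function(p) {
    v <- numeric(n)
    v[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (2 * dt)
    v[1] <- v[2]          # continue the central estimate at the edges:
    v[n] <- v[n - 1]      # one-sided differences inflate edge noise
    v
  }
  sp <- sqrt(d(trace$x)^2 + d(trace$y)^2)
  if (smoothN > 1) {
    sm <- stats::filter(sp, rep(1 / smoothN, smoothN), sides = 2)
    sm <- as.numeric(sm)
    sm[is.na(sm)] <- sp[is.na(sm)]
    sp <- sm
  }
  sp
}

#' Detect microsaccades by a velocity threshold
#'
#' Flags samples whose smoothed eye speed exceeds the mean steady-fixation
#' speed by more than 6 standard deviations, and returns the contiguous
#' above-threshold intervals. When no baseline statistics are supplied they
#' are estimated from the trace itself in two passes: candidate events are
#' first flagged with robust whole-trace statistics (median and MAD, which a
#' large saccade cannot inflate), then the final mean and SD of the
#' steady-fixation speed are computed on the remaining samples.
#'
#' @param trace an eye trace (see \code{\link{eyeTrace}}).
#' @param baseline optional list with \code{mean} and \code{sd} of the
#'   steady-fixation speed (deg/s).
#' @param nSD threshold in baseline standard deviations (default 6).
#' @param smoothN moving-average width, samples (default 5).
#' @return data.frame with \code{onset_ms}, \code{offset_ms},
#'   \code{peak_speed}; zero rows when no event is detected.
#' @export
detectMicrosaccades <- function(trace, baseline = NULL, nSD = 6,
                                smoothN = 5) {
  if (trace$sampleRate <= 0) stop("sample rate must be positive")
  sp <- .eyeSpeed(trace, smoothN = smoothN)
  if (is.null(baseline)) {
    above <- sp > stats::median(sp) + nSD * stats::mad(sp)   # robust pass 1
    base <- sp[!above]
    baseline <- list(mean = mean(base), sd = stats::sd(base))
    if (!is.finite(baseline$sd)) baseline <- list(mean = mean(sp), sd = 0)
  }
  if (baseline$sd < 0) stop("baseline SD must be non-negative")
  thr <- baseline$mean + nSD * baseline$sd
  above <- sp > thr
  if (!any(above))
    return(data.frame(onset_ms = numeric(), offset_ms = numeric(),
                      peak_speed = numeric()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ev <- which(r$values)
  msPer <- 1000 / trace$sampleRate
  data.frame(
    onset_ms = (starts[ev] - 1) * msPer,
    offset_ms = (ends[ev] - 1) * msPer,
    peak_speed = vapply(ev, function(i) max(sp[starts[i]:ends[i]]), 0))
}

#' Apply presentation-level exclusions
#'
#' A presentation is kept iff the trial was performed correctly, attention
#' was directed away from the receptive fields, the eye stayed within the
#' fixation window (default half-width 0.5 degrees) throughout, and no
#' microsaccade was detected during the presentation. The exclusion log
#' records the first failing rule per excluded presentation. Presentations
#' without an eye trace keep their spike data; the eye-dependent rules are
#' skipped and flagged.
#'
#' @param meta presentation metadata data.frame.
#' @param traces optional named list of eye traces keyed by presentation id.
#' @param fixationHalfwidth fixation window half-width, degrees (default
#'   0.5).
#' @param ... passed to \code{\link{detectMicrosaccades}}.
#' @return list with \code{kept} (character ids), \code{exclusions}
#'   (data.frame presentation_id, reason) and \code{flags} (data.frame of
#'   non-fatal notes such as missing traces).
#' @export
filterPresentations <- function(meta, traces = NULL,
                                fixationHalfwidth = 0.5, ...) {
  ids <- as.character(meta$presentation_id)
  reason <- rep(NA_character_, length(ids))
  flags <- character(0); flagIds <- character(0)
  for (i in seq_along(ids)) {
    if (!isTRUE(meta$correct[i])) { reason[i] <- "incorrect"; next }
    if (isTRUE(meta$attended_in_rf[i])) { reason[i] <- "attended_in_rf"; next }
    tr <- if (!is.null(traces)) traces[[ids[i]]] else NULL
    if (is.null(tr)) {
      flags <- c(flags, "no_eye_trace"); flagIds <- c(flagIds, ids[i])
      next
    }
    if (any(abs(tr$x) > fixationHalfwidth | abs(tr$y) > fixationHalfwidth)) {
      reason[i] <- "fixation_break"; next
    }
    if (nrow(detectMicrosaccades(tr, ...)) > 0) {
      reason[i] <- "microsaccade"; next
    }
  }
  excl <- !is.na(reason)
  list(kept = ids[!excl],
       exclusions = data.frame(presentation_id = ids[excl],
                               reason = reason[excl]),
       flags = data.frame(presentation_id = flagIds, flag = flags))
}

#' Firing rate vs fixational scatter
#'
#' For each unit, the Pearson correlation between dual-stimulus spike counts
#' and the mean eye position projected onto the axis connecting the two
#' stimulus locations, with its p-value; a diagnostic that fixational scatter
#' does not drive the dual-stimulus analyses.
#'
#' @param sce a \linkS4class{SpikeCountExperiment}.
#' @param traces named list of eye traces keyed by presentation id.
#' @param stimulusAxis 2-vector along the line connecting the stimulus
#'   locations (normalized internally).
#' @param alpha significance level for the flag (default 0.05).
#' @return data.frame with unit_id, r, p, significant, flag, n.
#' @export
eyeRateCorrelation <- function(sce, traces, stimulusAxis = c(1, 0),
                               alpha = 0.05) {
  ax <- stimulusAxis / sqrt(sum(stimulusAxis^2))
  cd <- SummarizedExperiment::colData(sce)
  ab <- rownames(cd)[cd$condition == "AB"]
  ab <- ab[ab %in% names(traces)]
  if (length(ab) < 3)
    stop("need at least 3 dual-stimulus presentations with eye data")
  proj <- vapply(ab, function(id) {
    tr <- traces[[id]]
    mean(tr$x) * ax[1] + mean(tr$y) * ax[2]
  }, 0)
  cts <- spikeCounts(sce)[, ab, drop = FALSE]
  res <- lapply(rownames(cts), function(u) {
    y <- as.numeric(cts[u, ])
    if (stats::sd(y) == 0 || stats::sd(proj) == 0)
      return(data.frame(unit_id = u, r = NA_real_, p = NA_real_,
                        significant = NA, flag = "zero_variance",
                        n = length(y)))
    ct <- stats::cor.test(y, proj)
    data.frame(unit_id = u, r = unname(ct$estimate), p = ct$p.value,
               significant = ct$p.value < alpha, flag = "",
               n = length(y))
  })
  do.call(rbind, res)
}

#' Write a count table to CSV
#'
#' @param sce a \linkS4class{SpikeCountExperiment}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeCountTable <- function(sce, path) {
  cts <- spikeCounts(sce)
  df <- data.frame(unit_id = rep(rownames(cts), ncol(cts)),
                   presentation_id = rep(colnames(cts), each = nrow(cts)),
                   count = as.integer(cts))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
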