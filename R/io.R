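#' Read a behavioral event log
#'
#' Reads the tab-separated event-log format: optional metadata comment lines
#' (`# animal_id: ...`, `# group: ...`, `# day: ...`, `# protocol: ...`)
#' followed by a header `time_s  code  payload` and one row per event.
#' Times are quantized to the 10-ms acquisition grid and events are put in
#' canonical order (time, then fixed code priority), so the row order of
#' simultaneous events in the file does not matter.
#'
#' @param path path to a TSV event log.
#' @return a [Session-class].
#' @seealso [writeEventLog()]
#' @export
readEventLog <- function(path) {
  stopIfNot(file.exists(path), "event log not found: %s", path)
  lines <- readLines(path)
  meta <- list(animal_id = "unknown", group = "EYFP_CONTROL", day = 1L,
               protocol = "NONE")
  is_meta <- grepl("^#", lines)
  for (l in lines[is_meta]) {
    m <- regmatches(l, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", l))[[1]]
    if (length(m) == 3L && m[2] %in% names(meta))
      meta[[m[2]]] <- if (m[2] == "day") as.integer(m[3]) else trimws(m[3])
  }
  body <- lines[!is_meta]
  stopIfNot(length(body) >= 1L, "event log has no header: %s", path)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  stopIfNot(identical(header[1:2], c("time_s", "code")),
            "event log header must start with time_s, code")
  rows <- body[-1]
  rows <- rows[nzchar(rows)]
  n <- length(rows)
  time <- numeric(n); code <- character(n); payload <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(rows[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L)
      stop(sprintf("malformed row at line %d of %s",
                   which(!is_meta)[i + 1L], path), call. = FALSE)
    tv <- suppressWarnings(as.numeric(f[1]))
    if (is.na(tv))
      stop(sprintf("unparseable time at line %d of %s",
                   which(!is_meta)[i + 1L], path), call. = FALSE)
    if (!f[2] %in% EVENT_CODES)
      stop(sprintf("unknown event code '%s' at line %d of %s",
                   f[2], which(!is_meta)[i + 1L], path), call. = FALSE)
    time[i] <- tv; code[i] <- f[2]
    payload[i] <- if (length(f) >= 3L) f[3] else ""
  }
  if (n > 1L && any(diff(time) < -(TIME_RESOLUTION + 1e-9)))
    stop(sprintf("non-monotonic timestamps beyond 0.01-s tolerance in %s",
                 path), call. = FALSE)
  ev <- orderEvents(newEvents(time, code, payload))
  rownames(ev) <- NULL
  new("Session", animal_id = meta$animal_id, group = meta$group,
      day = as.integer(meta$day), protocol = meta$protocol, events = ev)
}

#' Write a behavioral event log
#'
#' Writes a [Session-class] to the TSV event-log format read by
#' [readEventLog()]. The round trip is bit-exact: metadata, quantized times
#' (printed with two decimals), codes and payloads are preserved verbatim.
#'
#' @param session a [Session-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEventLog <- function(session, path) {
  validObject(session)
  ev <- session@events
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# animal_id: %s", session@animal_id),
    sprintf("# group: %s", session@group),
    sprintf("# day: %d", session@day),
    sprintf("# protocol: %s", session@protocol),
    "time_s\tcode\tpayload"), con)
  if (nrow(ev))
    writeLines(sprintf("%.2f\t%s\t%s", ev$time, ev$code, ev$payload), con)
  invisible(path)
}

#' Read a spike-time table
#'
#' Reads a TSV with columns `unit_id`, `region`, `time_s` and returns one
#' [SpikeTrain-class] per unit, spike times sorted ascending. An optional
#' companion waveform table (`unit_id`, `sample_index`, `behavioral_uv`,
#' `light_evoked_uv`) attaches mean waveforms by unit id.
#'
#' @param path spike table path.
#' @param waveform_path optional waveform table path.
#' @return named list of [SpikeTrain-class] objects.
#' @export
readSpikeTable <- function(path, waveform_path = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopIfNot(all(c("unit_id", "region", "time_s") %in% names(tab)),
            "spike table needs columns unit_id, region, time_s")
  stopIfNot(!any(tab$time_s < 0), "negative spike time in %s", path)
  wf <- NULL
  if (!is.null(waveform_path)) {
    wf <- utils::read.delim(waveform_path, stringsAsFactors = FALSE)
    stopIfNot(all(c("unit_id", "sample_index", "behavioral_uv",
                    "light_evoked_uv") %in% names(wf)),
              "waveform table needs unit_id, sample_index, behavioral_uv, light_evoked_uv")
  }
  ids <- unique(tab$unit_id)
  out <- lapply(ids, function(id) {
    sub <- tab[tab$unit_id == id, , drop = FALSE]
    wb <- wl <- numeric(0)
    if (!is.null(wf) && any(wf$unit_id == id)) {
      ws <- wf[wf$unit_id == id, , drop = FALSE]
      ws <- ws[order(ws$sample_index), , drop = FALSE]
      wb <- ws$behavioral_uv; wl <- ws$light_evoked_uv
    }
    new("SpikeTrain", unit_id = as.character(id), region = sub$region[1],
        spike_times = sort(sub$time_s), waveform_behavioral = wb,
        waveform_light = wl, pid = NA)
  })
  names(out) <- as.character(ids)
  out
}

#' Write a spike-time table
#'
#' Inverse of [readSpikeTable()]; writes the spike TSV and, when any unit
#' carries waveforms and `waveform_path` is given, the companion waveform
#' TSV.
#'
#' @param units list of [SpikeTrain-class] objects.
#' @param path output spike table path.
#' @param waveform_path optional output waveform table path.
#' @return `path`, invisibly.
#' @export
writeSpikeTable <- function(units, path, waveform_path = NULL) {
  rows <- do.call(rbind, lapply(units, function(u)
    if (length(u@spike_times))
      data.frame(unit_id = u@unit_id, region = u@region,
                 time_s = u@spike_times, stringsAsFactors = FALSE)
    else NULL))
  if (is.null(rows))
    rows <- data.frame(unit_id = character(0), region = character(0),
                       time_s = numeric(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(waveform_path)) {
    wrows <- do.call(rbind, lapply(units, function(u)
      if (length(u@waveform_behavioral))
        data.frame(unit_id = u@unit_id,
                   sample_index = seq_along(u@waveform_behavioral),
                   behavioral_uv = u@waveform_behavioral,
                   light_evoked_uv = if (length(u@waveform_light))
                     u@waveform_light else NA_real_,
                   stringsAsFactors = FALSE)
      else NULL))
    if (!is.null(wrows))
      utils::write.table(wrows, waveform_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
  }
  invisible(path)
}
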