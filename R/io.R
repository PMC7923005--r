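# Event-table IO: FCS 3.1 (float32 list mode, little-endian; reads 3.0/3.1
# with DATATYPE F or I) and plain CSV. Flow rate, duration, dilution and
# sample annotations are not standard FCS keywords; they are written as
# custom $EVG* keywords and mirrored in the run manifest.

EVG_KEYWORDS <- c(flow_rate = "$EVGFLOWRATE", duration = "$EVGDURATION",
                  dilution_factor = "$EVGDILUTION",
                  trigger_channel = "$EVGTRIGCH",
                  trigger_threshold = "$EVGTRIGTHRESH")

fcs_pad_offset <- function(x) {
  s <- formatC(x, width = 8, flag = " ")
  if (nchar(s) > 8) stop("FCS segment offset exceeds header width",
                         call. = FALSE)
  s
}

#' Write an event table to disk
#'
#' FCS output is FCS 3.1, list mode, 32-bit float, little-endian, readable by
#' [read_events()] and standard FCS software. CSV output has one header row
#' (channel names plus `time`) and one row per event; metadata is carried by
#' the run manifest, not the CSV.
#'
#' @param events An [event_table()].
#' @param path Output file path.
#' @param format `"fcs"` or `"csv"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, format = c("auto", "fcs", "csv")) {
  stopifnot(inherits(events, "event_table"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  vals <- as.matrix(as.data.frame(events))
  if (nrow(vals) && any(!is.finite(vals))) {
    stop("event table contains non-finite intensities", call. = FALSE)
  }
  if (format == "csv") {
    utils::write.csv(as.data.frame(events), path, row.names = FALSE)
    return(invisible(path))
  }
  write_fcs(events, path)
}

write_fcs <- function(events, path) {
  df <- as.data.frame(events)
  pars <- c(channel_names(events), "TIME")
  mat <- cbind(as.matrix(df[channel_names(events)]), TIME = df$time)
  n <- nrow(mat)
  meta <- acq_meta(events)

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$TOT" = as.character(n), "$PAR" = as.character(length(pars)),
    "$TIMESTEP" = "1"
  )
  for (i in seq_along(pars)) {
    rng <- if (n) max(mat[, i]) else 1
    kw[sprintf("$P%dN", i)] <- pars[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- format(ceiling(max(rng, 1)), scientific = FALSE)
  }
  for (field in names(EVG_KEYWORDS)) {
    if (!is.null(meta[[field]])) {
      kw[EVG_KEYWORDS[[field]]] <- as.character(meta[[field]])
    }
  }
  sm <- meta$sample_meta
  if (!is.null(sm)) {
    for (field in names(sm)) {
      kw[paste0("$EVGSM", toupper(field))] <- as.character(sm[[field]])
    }
  }

  # DATA offsets depend on TEXT length; fix their width first.
  kw <- c(kw["$BEGINANALYSIS"], "$BEGINDATA" = "%010d",
          "$ENDDATA" = "%010d", kw[setdiff(names(kw), "$BEGINANALYSIS")])
  delim <- "/"
  build_text <- function(begin_data, end_data) {
    kv <- kw
    kv["$BEGINDATA"] <- sprintf("%010d", begin_data)
    kv["$ENDDATA"] <- sprintf("%010d", end_data)
    paste0(delim, paste(names(kv), kv, sep = delim, collapse = delim), delim)
  }
  text_start <- 58L
  text_len <- nchar(build_text(0L, 0L), type = "bytes")
  data_start <- text_start + text_len
  data_len <- n * length(pars) * 4L
  data_end <- if (data_len > 0) data_start + data_len - 1L else 0L
  text <- build_text(data_start, data_end)

  header <- paste0("FCS3.1    ",
                   fcs_pad_offset(text_start),
                   fcs_pad_offset(text_start + text_len - 1L),
                   fcs_pad_offset(if (data_len > 0) data_start else 0L),
                   fcs_pad_offset(data_end),
                   fcs_pad_offset(0L), fcs_pad_offset(0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (n > 0) {
    writeBin(as.vector(t(mat)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read an event table from disk
#'
#' Reads FCS 3.0/3.1 (list mode, DATATYPE F or I, uniform bit width) or the
#' package's CSV event format. For FCS the `TIME` parameter is converted to
#' seconds via `$TIMESTEP`; acquisition metadata is recovered from the
#' custom `$EVG*` keywords when present.
#'
#' @param path File path.
#' @param format `"fcs"`, `"csv"` or `"auto"` (extension).
#' @param channels Optional expected channel names; for CSV a missing expected
#'   column is an error naming it, an unknown extra channel is a warning and
#'   passed through.
#' @return An [event_table()].
#' @export
read_events <- function(path, format = c("auto", "fcs", "csv"),
                        channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    if (!"time" %in% names(df)) {
      stop("CSV event file is missing required column: time", call. = FALSE)
    }
    if (!is.null(channels)) {
      missing <- setdiff(channels, names(df))
      if (length(missing)) {
        stop("CSV event file is missing required column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      extra <- setdiff(names(df), c(channels, "time"))
      if (length(extra)) {
        warning("unknown channel(s) passed through: ",
                paste(extra, collapse = ", "), call. = FALSE)
      }
    }
    return(event_table(df[setdiff(names(df), "time")], df$time,
                       sort_by_time = FALSE))
  }
  read_fcs(path, channels)
}

read_fcs <- function(path, channels = NULL) {
  raw <- readBin(path, what = "raw", n = file.size(path))
  if (length(raw) < 58L) stop("not an FCS file (truncated header)",
                              call. = FALSE)
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version: ", version, call. = FALSE)
  }
  off <- function(i) {
    s <- trimws(rawToChar(raw[(11 + 8 * (i - 1)):(10 + 8 * i)]))
    if (s == "") 0 else as.numeric(s)
  }
  text_start <- off(1); text_end <- off(2)
  data_start <- off(3); data_end <- off(4)
  text <- rawToChar(raw[(text_start + 1):(text_end + 1)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substr(text, 2, nchar(text)), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        parts[seq(1, length(parts), 2)])
  need <- function(key) {
    if (is.na(kw[key])) {
      stop("FCS file is missing required keyword: ", key, call. = FALSE)
    }
    kw[[key]]
  }
  tot <- as.integer(need("$TOT"))
  par <- as.integer(need("$PAR"))
  dtype <- need("$DATATYPE")
  byteord <- need("$BYTEORD")
  endian <- if (byteord == "1,2,3,4") "little" else "big"
  pnames <- vapply(seq_len(par), function(i) need(sprintf("$P%dN", i)), "")
  bits <- vapply(seq_len(par),
                 function(i) as.integer(need(sprintf("$P%dB", i))), 1L)
  if (length(unique(bits)) != 1L) {
    stop("mixed $PnB bit widths are not supported", call. = FALSE)
  }
  if (data_start == 0 && !is.na(kw["$BEGINDATA"])) {
    data_start <- as.numeric(kw[["$BEGINDATA"]])
    data_end <- as.numeric(kw[["$ENDDATA"]])
  }
  nvals <- tot * par
  if (nvals > 0) {
    dat_raw <- raw[(data_start + 1):(data_end + 1)]
    vals <- switch(dtype,
      F = readBin(dat_raw, what = "numeric", n = nvals, size = 4L,
                  endian = endian),
      I = readBin(dat_raw, what = "integer", n = nvals, size = bits[1] / 8L,
                  signed = bits[1] <= 16L, endian = endian),
      stop("unsupported $DATATYPE: ", dtype, call. = FALSE))
    if (dtype == "I") vals[vals < 0] <- vals[vals < 0] + 2^bits[1]
    mat <- matrix(vals, nrow = tot, ncol = par, byrow = TRUE,
                  dimnames = list(NULL, pnames))
  } else {
    mat <- matrix(numeric(), nrow = 0, ncol = par,
                  dimnames = list(NULL, pnames))
  }
  timestep <- if (!is.na(kw["$TIMESTEP"])) as.numeric(kw[["$TIMESTEP"]]) else 1
  time_col <- which(toupper(pnames) == "TIME")
  if (length(time_col)) {
    time <- mat[, time_col[1]] * timestep
    mat <- mat[, -time_col[1], drop = FALSE]
  } else {
    warning("no TIME parameter; timestamps set to 0", call. = FALSE)
    time <- rep(0, tot)
  }
  if (!is.null(channels)) {
    missing <- setdiff(channels, colnames(mat))
    if (length(missing)) {
      stop("FCS file is missing required channel(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(colnames(mat), channels)
    if (length(extra)) {
      warning("unknown channel(s) passed through: ",
              paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  meta <- list()
  for (field in names(EVG_KEYWORDS)) {
    v <- kw[EVG_KEYWORDS[[field]]]
    if (!is.na(v)) {
      meta[[field]] <- if (field == "trigger_channel") v else as.numeric(v)
    }
  }
  sm_keys <- grep("^\\$EVGSM", names(kw), value = TRUE)
  if (length(sm_keys)) {
    meta$sample_meta <- stats::setNames(
      as.list(kw[sm_keys]), tolower(sub("^\\$EVGSM", "", sm_keys)))
  }
  event_table(as.data.frame(mat), time, meta = meta, sort_by_time = FALSE)
}

#' Read a spillover matrix from CSV
#'
#' Expects a square numeric matrix with a channel-name header row and the
#' same channel names as the first column.
#'
#' @param path CSV path.
#' @return A [spillover_matrix()].
#' @export
read_spillover_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  spillover_matrix(m)
}

#' Write a spillover matrix to CSV
#' @param spill A [spillover_matrix()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_spillover_csv <- function(spill, path) {
  df <- data.frame(channel = rownames(spill), unclass(spill),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
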