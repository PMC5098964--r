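#' Write a pressure record to plain-text files
#'
#' A record is stored as two files: `<path>.meta.json` (plate geometry, start
#' time, optional trial metadata, storage precision) and `<path>.frames.csv`,
#' a sparse table with header `t,row,col,p_kpa` holding one row per non-zero
#' cell. Indices in the file are 0-based (language-neutral); in-memory R
#' objects use 1-based indices. Footprints occupy a small fraction of the
#' plate, so the sparse layout is compact and diff-able.
#'
#' Values are rounded to `digits` decimals on write; a record whose values are
#' representable at that precision round-trips exactly, and write-read-write
#' is byte-idempotent.
#'
#' @param record A [pressure_record()].
#' @param path File stem (without extension); two files are written.
#' @param digits Decimal digits stored for pressures.
#' @return Invisibly, the two file paths.
#' @export
write_pressure_record <- function(record, path, digits = 6L) {
  stopifnot(inherits(record, "pressure_record"))
  meta_path <- paste0(path, ".meta.json")
  csv_path <- paste0(path, ".frames.csv")
  spec <- record$spec
  header <- list(
    format = "pedopress-record",
    version = 1L,
    plate = list(
      n_cols = spec$n_cols, n_rows = spec$n_rows,
      width_m = spec$width_m, length_m = spec$length_m,
      freq_hz = spec$freq_hz
    ),
    t0 = record$t0,
    n_frames = n_frames(record),
    precision_digits = as.integer(digits)
  )
  if (!is.null(record$meta)) header$meta <- unclass(record$meta)
  ok <- tryCatch(
    jsonlite::write_json(header, meta_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null"),
    error = function(e) stop("cannot write ", meta_path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  vals <- round(record$frames, digits)
  idx <- which(vals > 0, arr.ind = FALSE)
  d <- dim(vals)
  row1 <- ((idx - 1L) %% d[1]) + 1L
  col1 <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  t1 <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  dt <- data.table::data.table(
    t = t1 - 1L, row = row1 - 1L, col = col1 - 1L, p_kpa = vals[idx]
  )
  data.table::setorder(dt, t, row, col)
  data.table::fwrite(dt, csv_path)
  invisible(c(meta_path, csv_path))
}

#' Read a pressure record written by [write_pressure_record()]
#'
#' @param path File stem (without extension), as passed to
#'   [write_pressure_record()].
#' @return A [pressure_record()].
#' @export
read_pressure_record <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  csv_path <- paste0(path, ".frames.csv")
  for (p in c(meta_path, csv_path)) {
    if (!file.exists(p)) stop("missing record file: ", p, call. = FALSE)
  }
  header <- tryCatch(jsonlite::read_json(meta_path, simplifyVector = TRUE),
                     error = function(e) stop("malformed record header: ",
                                              conditionMessage(e), call. = FALSE))
  req <- c("format", "plate", "t0", "n_frames")
  if (!all(req %in% names(header)) || !identical(header$format, "pedopress-record")) {
    stop("malformed record header in ", meta_path, call. = FALSE)
  }
  pl <- header$plate
  spec <- plate_spec(pl$n_cols, pl$n_rows, pl$width_m, pl$length_m, pl$freq_hz)
  nfr <- as.integer(header$n_frames)
  dt <- data.table::fread(csv_path, colClasses = list(
    integer = c("t", "row", "col"), numeric = "p_kpa"
  ))
  if (!identical(names(dt), c("t", "row", "col", "p_kpa"))) {
    stop("malformed frames file: expected header t,row,col,p_kpa", call. = FALSE)
  }
  if (nrow(dt)) {
    bad_t <- dt$t < 0L | dt$t >= nfr
    if (any(bad_t)) {
      stop(sprintf("frame index out of range in frame %d", dt$t[which(bad_t)[1]]),
           call. = FALSE)
    }
    bad_rc <- dt$row < 0L | dt$row >= spec$n_rows | dt$col < 0L | dt$col >= spec$n_cols
    if (any(bad_rc)) {
      stop(sprintf("cell index out of grid in frame %d", dt$t[which(bad_rc)[1]]),
           call. = FALSE)
    }
    bad_p <- dt$p_kpa < 0
    if (any(bad_p)) {
      stop(sprintf("negative pressure in frame %d", dt$t[which(bad_p)[1]]),
           call. = FALSE)
    }
  }
  frames <- array(0, dim = c(spec$n_rows, spec$n_cols, nfr))
  if (nrow(dt)) frames[cbind(dt$row + 1L, dt$col + 1L, dt$t + 1L)] <- dt$p_kpa
  meta <- NULL
  if (!is.null(header$meta)) {
    m <- header$meta
    meta <- trial_meta(
      subject_id = m$subject_id %||% NA_character_,
      body_mass_kg = m$body_mass_kg %||% NA_real_,
      shoulder_height_m = m$shoulder_height_m %||% NA_real_,
      hip_height_m = m$hip_height_m %||% NA_real_,
      velocity_ms = m$velocity_ms %||% NA_real_,
      side_hint = m$side_hint %||% NA_character_
    )
  }
  pressure_record(frames, spec, t0 = header$t0, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Tolerant reader for delimited supplementary-style tables
#'
#' Reads a delimited text table with a header row. The delimiter (`,`, `;` or
#' tab) is auto-detected from the header, and numeric columns accept both
#' decimal point and decimal comma, so exports from different locales parse to
#' the same values. Columns named in `schema` are converted to the requested
#' type; all other columns are preserved as text.
#'
#' @param path File path.
#' @param schema Named character vector mapping required column names to types
#'   (`"numeric"`, `"integer"`, `"character"`), or `NULL` to keep everything
#'   as text.
#' @return A [tibble::tibble()] with one row per data line.
#' @export
read_table <- function(path, schema = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty table: ", path, call. = FALSE)
  delims <- c(",", ";", "\t")
  counts <- vapply(delims, function(d) lengths(regmatches(
    lines[1], gregexpr(d, lines[1], fixed = TRUE)
  )), integer(1))
  delim <- if (all(counts == 0L)) "," else delims[which.max(counts)]
  fields <- strsplit(lines, delim, fixed = TRUE)
  header <- trimws(fields[[1]])
  nfld <- length(header)
  body <- fields[-1]
  cols <- lapply(seq_len(nfld), function(j) {
    vapply(body, function(f) if (j <= length(f)) trimws(f[j]) else NA_character_,
           character(1))
  })
  names(cols) <- header
  if (!is.null(schema)) {
    missing <- setdiff(names(schema), header)
    if (length(missing)) {
      stop("missing required column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    for (nm in names(schema)) {
      cols[[nm]] <- switch(
        schema[[nm]],
        numeric = parse_locale_numeric(cols[[nm]]),
        integer = as.integer(parse_locale_numeric(cols[[nm]])),
        character = cols[[nm]],
        stop("unknown schema type: ", schema[[nm]], call. = FALSE)
      )
    }
  }
  tibble::as_tibble(cols)
}

# Accepts "1.5" and "1,5" alike; comma treated as decimal mark only when the
# value looks like a decimal-comma number (fields are already split).
parse_locale_numeric <- function(x) {
  dc <- grepl("^-?[0-9]+,[0-9]+([eE][+-]?[0-9]+)?$", x)
  x[dc] <- sub(",", ".", x[dc], fixed = TRUE)
  suppressWarnings(as.numeric(x))
}

#' Write / read COP trajectory tables
#'
#' Plain CSV with columns `step_id,frame,x_m,y_m,p_total_kpa`, one row per
#' trajectory point in recording order.
#'
#' @param trajs Named list of [cop_trajectory] objects (names become
#'   `step_id`), or a single trajectory.
#' @param path File path.
#' @export
write_cop_table <- function(trajs, path) {
  if (inherits(trajs, "cop_trajectory")) trajs <- list(step = trajs)
  rows <- lapply(names(trajs), function(id) {
    tr <- trajs[[id]]
    data.table::data.table(
      step_id = id,
      frame = if (is.null(tr$frame)) seq_len(tr$n_points) - 1L else tr$frame,
      x_m = tr$x, y_m = tr$y,
      p_total_kpa = if (is.null(tr$p_total)) NA_real_ else tr$p_total
    )
  })
  data.table::fwrite(data.table::rbindlist(rows), path)
  invisible(path)
}

#' @rdname write_cop_table
#' @return `read_cop_table()` returns a named list of [cop_trajectory] objects.
#' @export
read_cop_table <- function(path) {
  tb <- read_table(path, schema = c(
    step_id = "character", frame = "integer", x_m = "numeric",
    y_m = "numeric", p_total_kpa = "numeric"
  ))
  split_tb <- split(tb, tb$step_id)
  out <- lapply(split_tb, function(d) {
    new_cop_trajectory(
      frame = d$frame, frac = NULL, x = d$x_m, y = d$y_m, p_total = d$p_total_kpa
    )
  })
  out[unique(tb$step_id)]
}
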