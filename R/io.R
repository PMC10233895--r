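# TSV/JSON input and output. All tables are tab-separated with a header and
# optional '#'-prefixed metadata lines for provenance.

#' Write a table as TSV with provenance metadata
#'
#' @param df data.frame.
#' @param path output path.
#' @param meta character vector of metadata lines (written '#'-prefixed
#'   above the header, after a tool-version line).
#' @return invisibly, \code{path}.
#' @export
writeTSV <- function(df, path, meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  version <- tryCatch(as.character(utils::packageVersion("lpiscreen")),
                      error = function(e) "unknown")
  writeLines(paste0("# ", c(paste0("lpiscreen ", version), meta)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by this package
#'
#' @param path file path; '#' metadata lines are skipped.
#' @return data.frame.
#' @export
readTSV <- function(path) {
  read.delim(path, comment.char = "#", sep = "\t", stringsAsFactors = FALSE)
}

.requireColumns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("format error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
}

.numericOrDie <- function(df, cols, path) {
  for (col in cols) {
    v <- df[[col]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop("parse error in ", path, ": non-numeric ", col,
             " at data line ", bad[1])
      df[[col]] <- num
    }
  }
  df
}

#' Write growth curves as long-format TSV
#'
#' Columns: plate_id, row, col, time_h, value.
#'
#' @param x a \linkS4class{GrowthCurveSet}.
#' @param path output path.
#' @param meta extra metadata lines.
#' @return invisibly, \code{path}.
#' @export
writeCurves <- function(x, path, meta = character(0)) {
  info <- colonyInfo(x)
  times <- curveTimes(x)
  Y <- curveValues(x)
  df <- data.frame(
    plate_id = rep(info$plate_id, each = length(times)),
    row = rep(info$row, each = length(times)),
    col = rep(info$col, each = length(times)),
    time_h = rep(times, times = nrow(info)),
    value = as.vector(t(Y)),
    stringsAsFactors = FALSE
  )
  writeTSV(df, path, meta)
}

#' Read growth curves from long-format TSV
#'
#' Expects columns plate_id, row, col, time_h, value; curves are grouped by
#' (plate_id, row, col) and sorted by time. All colonies must share a common
#' time grid (scanner acquisitions are synchronous).
#'
#' @param path file path.
#' @return a \linkS4class{GrowthCurveSet}.
#' @export
readCurves <- function(path) {
  df <- readTSV(path)
  .requireColumns(df, c("plate_id", "row", "col", "time_h", "value"), path)
  df <- .numericOrDie(df, c("time_h", "value"), path)
  key <- paste(df$plate_id, df$row, df$col, df$time_h, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate record error in ", path,
         ": repeated (plate_id, row, col, time_h)")
  df <- df[order(df$plate_id, df$row, df$col, df$time_h), , drop = FALSE]
  colonyKey <- paste(df$plate_id, df$row, df$col, sep = "\r")
  firstIdx <- !duplicated(colonyKey)
  times <- sort(unique(df$time_h))
  counts <- table(colonyKey)
  if (any(counts != length(times)))
    stop("format error in ", path, ": colonies do not share a common time grid")
  info <- df[firstIdx, c("plate_id", "row", "col"), drop = FALSE]
  Y <- matrix(df$value, nrow = nrow(info), ncol = length(times), byrow = TRUE)
  GrowthCurveSet(Y, times, info)
}

#' Write plate layouts as TSV
#'
#' Columns: plate_id, row, col, strain_id, is_control, condition, replicate.
#'
#' @param layouts named list of \linkS4class{PlateLayout} objects.
#' @param path output path.
#' @param meta extra metadata lines.
#' @return invisibly, \code{path}.
#' @export
writeLayouts <- function(layouts, path, meta = character(0)) {
  writeTSV(do.call(rbind, lapply(layouts, as.data.frame)), path, meta)
}

#' Read plate layouts from TSV
#'
#' @param path file path (format of \code{\link{writeLayouts}}).
#' @return named list of \linkS4class{PlateLayout} objects.
#' @export
readLayouts <- function(path) {
  df <- readTSV(path)
  .requireColumns(df, c("plate_id", "row", "col", "strain_id", "is_control",
                        "condition", "replicate"), path)
  df$is_control <- as.logical(df$is_control)
  lapply(split(df, df$plate_id), function(pl) {
    rows <- max(pl$row) + 1L
    cols <- max(pl$col) + 1L
    strains <- matrix(NA_character_, rows, cols)
    ctrl <- matrix(FALSE, rows, cols)
    idx <- cbind(pl$row + 1L, pl$col + 1L)
    strains[idx] <- pl$strain_id
    ctrl[idx] <- pl$is_control
    new("PlateLayout", plateId = as.character(pl$plate_id[1]),
        strains = strains, isControl = ctrl,
        condition = as.character(pl$condition[1]),
        replicate = as.integer(pl$replicate[1]))
  })
}

#' Write simulation ground truth as JSON
#'
#' @param truth truth list of a \linkS4class{SimulatedScreen}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeTruth <- function(truth, path) {
  out <- list(
    seed = truth$seed,
    effects = as.data.frame(as.table(truth$effects),
                            stringsAsFactors = FALSE),
    bias = truth$bias,
    corrupted = truth$corrupted
  )
  names(out$effects) <- c("strain_id", "condition", "effect")
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read simulation ground truth from JSON
#'
#' @param path file path.
#' @return truth list (effects matrix, bias matrix, corrupted data.frame,
#'   seed).
#' @export
readTruth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  eff <- .effectMatrix(raw$effects, unique(raw$effects$condition))
  corrupted <- as.data.frame(raw$corrupted)
  if (!nrow(corrupted))
    corrupted <- data.frame(plate_id = character(0), row = integer(0),
                            col = integer(0))
  list(seed = raw$seed, effects = eff, bias = as.matrix(raw$bias),
       corrupted = corrupted)
}
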