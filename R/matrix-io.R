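# Measurement matrix container and file readers/writers.
#
# The unit of all downstream computation is a specimens x measurements
# matrix of continuous values (mm for linear measurements, degrees or
# dimensionless for angles/ratios) with explicit missingness, plus
# per-measurement class metadata and optional per-specimen cranial
# capacity (cm^3).

MISSING_MARKERS <- c("?", "", "NA", "-")

new_measurement_matrix <- function(values, classes = NULL, capacity = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry specimen row names and measurement column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))]
    stop("duplicate specimen ID: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))]
    stop("duplicate measurement ID: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.infinite(values))) stop("values must be finite or missing", call. = FALSE)
  if (is.null(classes)) {
    classes <- stats::setNames(rep("LINEAR", ncol(values)), colnames(values))
  }
  classes <- classes[colnames(values)]
  if (any(is.na(classes)) || !all(classes %in% MEASUREMENT_CLASSES)) {
    stop("every measurement needs a LINEAR/NONLINEAR class", call. = FALSE)
  }
  if (!is.null(capacity)) {
    capacity <- capacity[rownames(values)]
    if (any(!is.na(capacity) & capacity <= 0)) {
      stop("cranial capacity must be positive", call. = FALSE)
    }
  }
  structure(
    list(values = values, classes = classes, capacity = capacity),
    class = "measurement_matrix"
  )
}

#' Construct a measurement matrix
#'
#' @param values Numeric matrix with specimen row names and measurement
#'   column names; `NA` marks missing cells.
#' @param classes Named character vector (`"LINEAR"`/`"NONLINEAR"`) keyed by
#'   measurement ID; unspecified measurements default to `"LINEAR"`.
#' @param capacity Optional named numeric vector of cranial capacities
#'   (cm^3) keyed by specimen ID; must be positive where present.
#' @return A `"measurement_matrix"` object.
#' @export
measurement_matrix <- function(values, classes = NULL, capacity = NULL) {
  new_measurement_matrix(values, classes, capacity)
}

#' @export
print.measurement_matrix <- function(x, ...) {
  cat(sprintf("Measurement matrix: %d specimens x %d measurements, %.1f%% missing\n",
              nrow(x$values), ncol(x$values), 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Read a specimens x measurements matrix
#'
#' Supported dialects: `"CSV"`/`"TSV"` (first column `specimen_id`,
#' remaining columns measurement IDs, missing cells empty/`NA`/`?`/`-`) and
#' `"NEXUS_CONTINUOUS"` (a minimal CONTINUOUS CHARACTERS block:
#' DIMENSIONS/FORMAT/CHARLABELS/MATRIX only, `?` for missing). Measurement
#' classes may be supplied through a sidecar TSV (`measurement_id`, `class`)
#' or default to LINEAR.
#'
#' @param path Input file.
#' @param dialect One of `"CSV"`, `"TSV"`, `"NEXUS_CONTINUOUS"`.
#' @param class_sidecar Optional path to a class sidecar TSV.
#' @param capacity_column Optional name of a column holding cranial capacity
#'   (cm^3); it is removed from the measurement set.
#' @return A `"measurement_matrix"`.
#' @export
read_measurement_matrix <- function(path,
                                    dialect = c("CSV", "TSV", "NEXUS_CONTINUOUS"),
                                    class_sidecar = NULL,
                                    capacity_column = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "NEXUS_CONTINUOUS") {
    parsed <- read_nexus_continuous(path)
  } else {
    sep <- if (dialect == "CSV") "," else "\t"
    raw <- utils::read.table(path, sep = sep, header = TRUE,
                             colClasses = "character", check.names = FALSE,
                             na.strings = character(0), quote = "\"",
                             comment.char = "", strip.white = TRUE)
    if (names(raw)[1] != "specimen_id") {
      stop("format error: first column must be 'specimen_id'", call. = FALSE)
    }
    ids <- raw[[1]]
    if (anyDuplicated(ids)) {
      stop("format error: duplicate specimen ID: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
    }
    cells <- as.matrix(raw[, -1, drop = FALSE])
    parsed <- parse_numeric_cells(cells, ids, colnames(cells))
  }
  values <- parsed
  capacity <- NULL
  if (!is.null(capacity_column)) {
    if (!capacity_column %in% colnames(values)) {
      stop("capacity column not present: ", capacity_column, call. = FALSE)
    }
    capacity <- stats::setNames(values[, capacity_column], rownames(values))
    values <- values[, setdiff(colnames(values), capacity_column), drop = FALSE]
  }
  classes <- NULL
  if (!is.null(class_sidecar)) {
    sc <- utils::read.delim(class_sidecar, stringsAsFactors = FALSE)
    stopifnot(all(c("measurement_id", "class") %in% names(sc)))
    classes <- stats::setNames(rep("LINEAR", ncol(values)), colnames(values))
    hit <- intersect(sc$measurement_id, names(classes))
    classes[hit] <- sc$class[match(hit, sc$measurement_id)]
  }
  new_measurement_matrix(values, classes, capacity)
}

parse_numeric_cells <- function(cells, row_ids, col_ids) {
  out <- matrix(NA_real_, nrow = nrow(cells), ncol = ncol(cells),
                dimnames = list(row_ids, col_ids))
  for (j in seq_len(ncol(cells))) {
    col <- cells[, j]
    is_missing <- col %in% MISSING_MARKERS
    num <- suppressWarnings(as.numeric(col))
    bad <- !is_missing & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("parse error: non-numeric cell '%s' at row %s (specimen %s), column %s",
                   col[i], i, row_ids[i], col_ids[j]), call. = FALSE)
    }
    num[is_missing] <- NA_real_
    out[, j] <- num
  }
  out
}

# Minimal NEXUS reader: CONTINUOUS CHARACTERS block with DIMENSIONS, FORMAT,
# optional CHARLABELS, and MATRIX. Anything else inside the block is an
# unsupported-feature error.
read_nexus_continuous <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^#NEXUS", lines[1], ignore.case = TRUE)) {
    stop("format error: not a NEXUS file (missing #NEXUS header)", call. = FALSE)
  }
  txt <- paste(lines[-1], collapse = "\n")
  block <- regmatches(txt, regexpr("(?is)BEGIN\\s+CHARACTERS\\s*;.*?END\\s*;", txt, perl = TRUE))
  if (length(block) == 0) stop("format error: no CHARACTERS block", call. = FALSE)
  body <- sub("(?is)^BEGIN\\s+CHARACTERS\\s*;", "", block, perl = TRUE)
  body <- sub("(?is)END\\s*;$", "", body, perl = TRUE)
  # split into ;-terminated commands
  cmds <- strsplit(body, ";", fixed = TRUE)[[1]]
  cmds <- trimws(cmds)
  cmds <- cmds[nzchar(cmds)]
  ntax <- nchar_n <- NA_integer_
  charlabels <- NULL
  matrix_cmd <- NULL
  for (cmd in cmds) {
    key <- toupper(sub("\\s.*$", "", cmd))
    if (key == "DIMENSIONS") {
      ntax <- as.integer(sub(".*NTAX\\s*=\\s*(\\d+).*", "\\1", cmd, ignore.case = TRUE))
      nchar_n <- as.integer(sub(".*NCHAR\\s*=\\s*(\\d+).*", "\\1", cmd, ignore.case = TRUE))
    } else if (key == "FORMAT") {
      if (!grepl("DATATYPE\\s*=\\s*CONTINUOUS", cmd, ignore.case = TRUE)) {
        stop("unsupported NEXUS feature: only DATATYPE=CONTINUOUS is supported",
             call. = FALSE)
      }
    } else if (key == "CHARLABELS") {
      charlabels <- strsplit(trimws(sub("^\\S+\\s*", "", cmd)), "\\s+")[[1]]
    } else if (key == "MATRIX") {
      matrix_cmd <- sub("^\\S+", "", cmd)
    } else {
      stop("unsupported NEXUS feature: command '", key, "'", call. = FALSE)
    }
  }
  if (is.null(matrix_cmd)) stop("format error: no MATRIX command", call. = FALSE)
  rows <- strsplit(trimws(matrix_cmd), "\n")[[1]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows)]
  ids <- character(0)
  cells <- list()
  for (row in rows) {
    tokens <- strsplit(row, "\\s+")[[1]]
    ids <- c(ids, gsub("^'|'$", "", tokens[1]))
    cells[[length(cells) + 1L]] <- tokens[-1]
  }
  if (anyDuplicated(ids)) {
    stop("format error: duplicate specimen ID: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  ncols <- unique(lengths(cells))
  if (length(ncols) != 1) stop("format error: ragged MATRIX rows", call. = FALSE)
  if (!is.na(nchar_n) && ncols != nchar_n) {
    stop("format error: NCHAR does not match MATRIX width", call. = FALSE)
  }
  if (!is.na(ntax) && length(ids) != ntax) {
    stop("format error: NTAX does not match MATRIX rows", call. = FALSE)
  }
  col_ids <- charlabels %||% paste0("CHAR", seq_len(ncols))
  if (length(col_ids) != ncols) {
    stop("format error: CHARLABELS length does not match NCHAR", call. = FALSE)
  }
  cellmat <- do.call(rbind, cells)
  parse_numeric_cells(cellmat, ids, col_ids)
}

#' Write a measurement matrix
#'
#' CSV/TSV write `NA` for missing cells; NEXUS writes `?`. Round-trips
#' through [read_measurement_matrix()] reproduce values bit-for-bit
#' (values are serialized with full double precision).
#'
#' @param matrix A `"measurement_matrix"`.
#' @param path Output file.
#' @param dialect One of `"CSV"`, `"TSV"`, `"NEXUS_CONTINUOUS"`.
#' @return `path`, invisibly.
#' @export
write_measurement_matrix <- function(matrix, path,
                                     dialect = c("CSV", "TSV", "NEXUS_CONTINUOUS")) {
  dialect <- match.arg(dialect)
  values <- matrix$values
  fmt <- function(v) ifelse(is.na(v), NA, sprintf("%.17g", v))
  if (dialect %in% c("CSV", "TSV")) {
    sep <- if (dialect == "CSV") "," else "\t"
    df <- data.frame(specimen_id = rownames(values),
                     apply(values, 2, fmt),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                       na = "NA")
  } else {
    cells <- apply(values, c(1, 2), function(v) if (is.na(v)) "?" else sprintf("%.17g", v))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#NEXUS", con)
    writeLines("BEGIN CHARACTERS;", con)
    writeLines(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(values), ncol(values)), con)
    writeLines("  FORMAT DATATYPE=CONTINUOUS MISSING=?;", con)
    writeLines(paste0("  CHARLABELS ", paste(colnames(values), collapse = " "), ";"), con)
    writeLines("  MATRIX", con)
    for (i in seq_len(nrow(values))) {
      writeLines(paste0("    ", rownames(values)[i], " ",
                        paste(cells[i, ], collapse = " ")), con)
    }
    writeLines("  ;", con)
    writeLines("END;", con)
  }
  invisible(path)
}

#' Normalize linear measurements by cranial capacity
#'
#' Divides every LINEAR measurement by the cube root of the specimen's
#' cranial capacity, emulating the size-normalized variant of the source
#' dataset. Angles and ratios are inherently size-free and pass through
#' unchanged, as does the missingness pattern.
#'
#' @param matrix A `"measurement_matrix"` whose `capacity` is present for
#'   every specimen with at least one observed LINEAR measurement.
#' @return A normalized `"measurement_matrix"`.
#' @export
normalize_by_cranial_capacity <- function(matrix) {
  stopifnot(inherits(matrix, "measurement_matrix"))
  linear <- names(matrix$classes)[matrix$classes == "LINEAR"]
  values <- matrix$values
  has_linear <- rowSums(!is.na(values[, linear, drop = FALSE])) > 0
  cap <- matrix$capacity
  if (is.null(cap)) cap <- stats::setNames(rep(NA_real_, nrow(values)), rownames(values))
  need <- rownames(values)[has_linear & is.na(cap[rownames(values)])]
  if (length(need) > 0) {
    stop("cranial capacity missing for specimens with linear data: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  scale <- cap[rownames(values)]^(1 / 3)
  values[, linear] <- values[, linear, drop = FALSE] / scale
  new_measurement_matrix(values, matrix$classes, matrix$capacity)
}
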