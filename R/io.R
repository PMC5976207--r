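# Delimited-table IO mirroring the supplementary-table shapes: one record
# per row, mandatory header, comma or tab auto-detected.

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("empty file: ", path)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

read_delim_checked <- function(path, required, numeric_cols = character(0)) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "\"")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ", paste(miss, collapse = ", "))
  for (cl in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad))
      stop("non-numeric values in column '", cl, "' at data line(s): ",
           paste(bad + 1L, collapse = ", "))   # +1: header is line 1
    df[[cl]] <- v
  }
  df
}

#' Read a tetrad table
#'
#' Reads either of the two supported schemas and returns the matching
#' object:
#'
#' * grain schema — columns `grain1`..`grain4` holding phenotype strings
#'   (channel letters, `"-"` for a blank grain) plus optional `tetrad`,
#'   `genotype`, `temperature`; returns a `tetrad_data` data frame.
#' * count schema — columns `PD`, `T`, `NPD` (optional `OTHER`,
#'   `condition`, `interval`); returns a `class_counts` data frame that
#'   can be passed straight to [perkins()].
#'
#' A file mixing grain and count columns, or carrying extra `grainN`
#' columns, is rejected as a schema error; malformed grain strings are
#' rejected with their line numbers.
#'
#' @param path file path (comma- or tab-delimited, auto-detected).
#' @return A `tetrad_data` or `class_counts` data frame.
#' @seealso [write_tetrad_table()]
#' @export
read_tetrad_table <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "\"",
                          colClasses = "character")
  grain_cols <- grep("^grain[0-9]+$", names(df), value = TRUE)
  count_cols <- intersect(c("PD", "T", "NPD"), names(df))
  if (length(grain_cols) && length(count_cols))
    stop("schema error: file mixes grain columns and PD/T/NPD count columns")
  if (length(grain_cols)) {
    extra <- setdiff(grain_cols, paste0("grain", 1:4))
    if (length(extra))
      stop("schema error: unexpected grain column(s) ",
           paste(extra, collapse = ", "), " (a tetrad has 4 grains)")
    if (!all(paste0("grain", 1:4) %in% grain_cols))
      stop("schema error: grain schema needs columns grain1..grain4")
    gm <- as.matrix(df[, paste0("grain", 1:4)])
    bad <- which(!grepl("^([A-Za-z]+|-)$", gm))
    if (length(bad)) {
      rows <- sort(unique((bad - 1L) %% nrow(gm) + 1L))
      stop("malformed grain phenotype at data line(s): ",
           paste(rows + 1L, collapse = ", "))
    }
    tetrad_id <- if ("tetrad" %in% names(df)) df$tetrad else seq_len(nrow(df))
    ids <- suppressWarnings(as.integer(tetrad_id))
    if (!anyNA(ids)) tetrad_id <- ids
    out <- data.frame(
      tetrad = tetrad_id,
      genotype = if ("genotype" %in% names(df)) df$genotype else "unknown",
      temperature = if ("temperature" %in% names(df)) df$temperature else "unknown",
      grain1 = gm[, 1], grain2 = gm[, 2], grain3 = gm[, 3], grain4 = gm[, 4],
      stringsAsFactors = FALSE)
    class(out) <- c("tetrad_data", "data.frame")
    return(out)
  }
  if (length(count_cols) == 3L) {
    for (cl in c("PD", "T", "NPD", intersect("OTHER", names(df)))) {
      v <- suppressWarnings(as.numeric(df[[cl]]))
      bad <- which(is.na(v))
      if (length(bad))
        stop("non-numeric ", cl, " at data line(s): ", paste(bad + 1L, collapse = ", "))
      if (any(v < 0) || any(v != round(v)))
        stop("column ", cl, " must hold non-negative integer counts")
      df[[cl]] <- as.integer(v)
    }
    if (!"OTHER" %in% names(df)) df$OTHER <- 0L
    df$n <- df$PD + df$T + df$NPD
    if (!"interval" %in% names(df)) df$interval <- NA_character_
    class(df) <- c("class_counts", "data.frame")
    return(df)
  }
  stop("schema error: expected either grain1..grain4 or PD/T/NPD columns")
}

#' Write a tetrad dataset or count table
#'
#' Writes tab-delimited text re-readable by [read_tetrad_table()].
#'
#' @param x a `tetrad_data` or `class_counts` data frame.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_tetrad_table <- function(x, path, sep = "\t") {
  utils::write.table(as.data.frame(x), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a focus-count table
#'
#' Expects columns `genotype`, `temperature`, `antibody`, `count`
#' (optional `cell`); counts must be non-negative integers.
#'
#' @param path file path.
#' @return A data frame of focus records.
#' @export
read_foci_table <- function(path) {
  df <- read_delim_checked(path, c("genotype", "temperature", "antibody", "count"),
                           numeric_cols = "count")
  bad <- which(df$count < 0 | df$count != round(df$count))
  if (length(bad))
    stop("negative or non-integer counts at data line(s): ",
         paste(bad + 1L, collapse = ", "))
  df$count <- as.integer(df$count)
  if (!"cell" %in% names(df)) df$cell <- seq_len(nrow(df))
  df
}

#' @rdname read_foci_table
#' @param x data frame of focus records.
#' @param sep field separator (default tab).
#' @export
write_foci_table <- function(x, path, sep = "\t") {
  utils::write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a qPCR CT table
#'
#' Expects columns `sample`, `treatment`, `gene`, `ct` (optional technical
#' replicate column `rep`); CT values must be positive numbers.
#'
#' @param path file path.
#' @return A data frame of CT records.
#' @export
read_qpcr_table <- function(path) {
  df <- read_delim_checked(path, c("sample", "treatment", "gene", "ct"),
                           numeric_cols = "ct")
  bad <- which(!is.finite(df$ct) | df$ct <= 0)
  if (length(bad))
    stop("non-positive CT values at data line(s): ", paste(bad + 1L, collapse = ", "))
  if (!"rep" %in% names(df)) df$rep <- 1L
  df
}

#' @rdname read_qpcr_table
#' @param x data frame of CT records.
#' @param sep field separator (default tab).
#' @export
write_qpcr_table <- function(x, path, sep = "\t") {
  utils::write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
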