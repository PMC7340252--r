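# Minimal STAR (Relion dialect) reader/writer: a data block with a single
# loop_ of _rln-prefixed columns, whitespace-separated rows.

# parse the first loop of a STAR file into a data.frame (numeric columns
# where possible); returns a 0-row data.frame for an empty loop
parse_star_loop <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  loop_at <- which(lines == "loop_")
  if (length(loop_at) == 0) stop("STAR parse error: no loop_ block in ", path)
  i <- loop_at[1] + 1
  cols <- character(0)
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    cols <- c(cols, sub("\\s+#\\d+$", "", lines[i]))
    i <- i + 1
  }
  if (length(cols) == 0) stop("STAR parse error: loop_ without columns in ", path)
  rows <- list()
  while (i <= length(lines) && nzchar(lines[i]) &&
         !startsWith(lines[i], "data_") && !startsWith(lines[i], "#")) {
    fields <- strsplit(lines[i], "\\s+")[[1]]
    if (length(fields) != length(cols)) {
      stop("STAR parse error: row with ", length(fields),
           " fields for ", length(cols), " columns in ", path)
    }
    rows[[length(rows) + 1]] <- fields
    i <- i + 1
  }
  if (length(rows) == 0) {
    df <- as.data.frame(matrix(character(0), nrow = 0, ncol = length(cols)),
                        stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  }
  names(df) <- cols
  for (j in seq_along(df)) {
    num <- suppressWarnings(as.numeric(df[[j]]))
    if (nrow(df) == 0 || !any(is.na(num))) df[[j]] <- num
  }
  df
}

write_star_loop <- function(df, path, block = "data_") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(block, "", "loop_"), con)
  writeLines(sprintf("%s #%d", names(df), seq_along(df)), con)
  if (nrow(df) > 0) {
    fmt <- vapply(df, function(col) {
      if (is.numeric(col)) format(col, digits = 12, trim = TRUE,
                                  scientific = FALSE)
      else as.character(col)
    }, FUN.VALUE = character(nrow(df)))
    if (nrow(df) == 1) fmt <- matrix(fmt, nrow = 1)
    writeLines(apply(fmt, 1, paste, collapse = "  "), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Read particle coordinates from a STAR file
#'
#' Expects a loop with `_rlnCoordinateX` and `_rlnCoordinateY`; an optional
#' `_rlnAutopickFigureOfMerit` column is returned as `score`. Unknown
#' columns are ignored. Coordinates in this package are 0-based pixel
#' centers; set `one_based = TRUE` when reading files written by software
#' using 1-based conventions.
#'
#' @param path STAR file path
#' @param one_based subtract 1 from the stored coordinates on read
#' @return data.frame with columns `x`, `y` and, when present, `score`
#' @export
read_star_coords <- function(path, one_based = FALSE) {
  df <- parse_star_loop(path)
  need <- c("_rlnCoordinateX", "_rlnCoordinateY")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("STAR parse error: missing column(s) ",
         paste(missing, collapse = ", "), "; available: ",
         paste(names(df), collapse = ", "))
  }
  out <- data.frame(x = as.numeric(df[["_rlnCoordinateX"]]),
                    y = as.numeric(df[["_rlnCoordinateY"]]))
  if (one_based) {
    out$x <- out$x - 1
    out$y <- out$y - 1
  }
  if ("_rlnAutopickFigureOfMerit" %in% names(df)) {
    out$score <- as.numeric(df[["_rlnAutopickFigureOfMerit"]])
  }
  out
}

#' Write particle coordinates to a STAR file
#'
#' Writes `_rlnCoordinateX`/`_rlnCoordinateY` (plus
#' `_rlnAutopickFigureOfMerit` when a `score` column is present).
#'
#' @param coords data.frame with columns `x`, `y` and optionally `score`
#' @param path output path
#' @param one_based add 1 to the coordinates on write
#' @return `path`, invisibly
#' @export
write_star_coords <- function(coords, path, one_based = FALSE) {
  off <- if (one_based) 1 else 0
  df <- data.frame(`_rlnCoordinateX` = coords$x + off,
                   `_rlnCoordinateY` = coords$y + off,
                   check.names = FALSE)
  if (!is.null(coords$score)) {
    df[["_rlnAutopickFigureOfMerit"]] <- coords$score
  }
  write_star_loop(df, path, block = "data_")
}

#' Read per-class metadata from a class-averaging model STAR file
#'
#' Expects a loop holding `_rlnClassDistribution` (fraction of particles per
#' class, as stored) and `_rlnEstimatedResolution` (angstrom). Distributions
#' are returned on the stored fraction scale; [select_classes()] converts to
#' percent before applying the %/Res rule.
#'
#' @param path STAR file path
#' @return data.frame with columns `class_id`, `distribution`, `resolution`
#' @export
read_class_metadata <- function(path) {
  df <- parse_star_loop(path)
  need <- c("_rlnClassDistribution", "_rlnEstimatedResolution")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("STAR parse error: missing column(s) ",
         paste(missing, collapse = ", "), "; available: ",
         paste(names(df), collapse = ", "))
  }
  data.frame(class_id = seq_len(nrow(df)),
             distribution = as.numeric(df[["_rlnClassDistribution"]]),
             resolution = as.numeric(df[["_rlnEstimatedResolution"]]))
}
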