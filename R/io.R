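# Plain-text serialization for images and run artifacts. Well images are
# stored as ASCII NetPBM (P2) greyscale files, one per channel, with the
# quantization scale recorded in a header comment so the round trip is
# lossless to the stored precision and byte-identical for a fixed seed.

#' Write / read a matrix as an ASCII PGM (P2) image
#'
#' Intensities are scaled by `scale`, rounded to integers and clamped at 0;
#' `read_pgm()` undoes the scaling using the header comment.
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @param scale Quantization steps per intensity unit (default 10).
#' @return `write_pgm()`: the path, invisibly. `read_pgm()`: a numeric
#'   matrix.
#' @export
write_pgm <- function(m, path, scale = 10) {
  q <- pmax(round(m * scale), 0)
  maxval <- max(q, 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("# scale=%g", scale),
               sprintf("%d %d", ncol(m), nrow(m)),
               sprintf("%d", maxval)), con)
  writeLines(apply(q, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  assert_that(lines[1] == "P2", "read_pgm: %s is not an ASCII PGM", path)
  scale <- 1
  i <- 2
  while (startsWith(lines[i], "#")) {
    sm <- regmatches(lines[i], regexec("scale=([0-9.eE+-]+)", lines[i]))[[1]]
    if (length(sm) == 2) scale <- as.numeric(sm[2])
    i <- i + 1
  }
  dims <- as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]])
  body <- lines[(i + 2):length(lines)]
  vals <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
  matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE) / scale
}

#' Write a rendered well image (both channels + truth sidecar) to disk
#'
#' Produces `<stem>_nuclear.pgm`, `<stem>_marker.pgm` and
#' `<stem>_truth.json`.
#'
#' @param img Result of [render_well_image()].
#' @param stem Path stem (no extension).
#' @return Character vector of the written paths, invisibly.
#' @export
write_well_image <- function(img, stem) {
  p1 <- paste0(stem, "_nuclear.pgm")
  p2 <- paste0(stem, "_marker.pgm")
  p3 <- paste0(stem, "_truth.json")
  write_pgm(img$channels$nuclear, p1)
  write_pgm(img$channels$marker, p2)
  jsonlite::write_json(list(cells = img$cells, spots = img$spots,
                            params = img$params),
                       p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p1, p2, p3))
}

#' @rdname write_well_image
#' @param stem Path stem previously written by [write_well_image()].
#' @export
read_well_image <- function(stem) {
  truth <- jsonlite::read_json(paste0(stem, "_truth.json"),
                               simplifyVector = TRUE)
  list(channels = list(nuclear = read_pgm(paste0(stem, "_nuclear.pgm")),
                       marker = read_pgm(paste0(stem, "_marker.pgm"))),
       cells = as.data.frame(truth$cells),
       spots = as.data.frame(truth$spots),
       params = truth$params)
}

write_csv_out <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
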