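#' Write a hyperspectral scene to the package's text cube container
#'
#' A self-describing plain-text format: a header (scene id, quantity,
#' environment label, pixels per degree, dimensions, wavelength vector)
#' followed by one line per pixel (row-major over the image) of
#' per-wavelength values printed with 17 significant digits, so a write/read
#' round trip reproduces the cube bit for bit.
#'
#' @param scene a \linkS4class{HyperspectralScene}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeScene <- function(scene, path) {
  d <- dim(scene@cube)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# melanoscene cube v1",
               paste("scene_id", scene@sceneId),
               paste("quantity", scene@quantity),
               paste("environment", scene@environment),
               paste("pixels_per_degree", sprintf("%.17g", scene@pixelsPerDegree)),
               paste("dims", d[1], d[2], d[3]),
               paste("wavelengths",
                     paste(sprintf("%.17g", scene@wavelengths), collapse = " "))),
             con)
  flat <- matrix(aperm(scene@cube, c(3, 2, 1)), nrow = d[3])  # row-major pixels
  writeLines(apply(flat, 2, function(v)
    paste(sprintf("%.17g", v), collapse = " ")), con)
  invisible(path)
}

#' Read a hyperspectral scene from the text cube container
#'
#' Validates on read: the wavelength axis must be present and ascending, the
#' cube must be free of non-finite values (the error counts offending
#' pixels), and reflectance cubes must stay within [0, 1].
#'
#' @param path file written by \code{\link{writeScene}}.
#' @param environment optional override of the stored environment label.
#' @param pixelsPerDegree optional override of the stored angular sampling.
#' @return A \linkS4class{HyperspectralScene}.
#' @export
readScene <- function(path, environment = NULL, pixelsPerDegree = NULL) {
  if (!file.exists(path))
    stop("file_not_found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  header <- list()
  taken <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (parts[1] %in% c("scene_id", "quantity", "environment",
                        "pixels_per_degree", "dims", "wavelengths")) {
      header[[parts[1]]] <- parts[-1]
      taken <- taken + 1L
    } else break
  }
  if (is.null(header$wavelengths))
    stop("missing_wavelengths: container has no wavelength vector", call. = FALSE)
  if (is.null(header$dims))
    stop("missing_dims: container has no dims line", call. = FALSE)
  d <- as.integer(header$dims)
  wl <- as.numeric(header$wavelengths)
  if (any(diff(wl) <= 0))
    stop("non_ascending_wavelengths: wavelength axis must be strictly increasing",
         call. = FALSE)
  vals <- scan(text = lines[(taken + 1L):length(lines)], quiet = TRUE,
               na.strings = c("NA", "NaN", "nan"))
  if (length(vals) != prod(d))
    stop("truncated_cube: expected ", prod(d), " values, found ", length(vals),
         call. = FALSE)
  n_bad <- sum(!is.finite(vals))
  if (n_bad > 0)
    stop("non_finite_pixels: cube contains ", n_bad,
         " non-finite pixel value(s)", call. = FALSE)
  cube <- aperm(array(vals, dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  hyperspectralScene(cube, wl, quantity = header$quantity,
                     environment = if (is.null(environment))
                       header$environment else environment,
                     pixelsPerDegree = if (is.null(pixelsPerDegree))
                       as.numeric(header$pixels_per_degree) else pixelsPerDegree,
                     sceneId = header$scene_id)
}

#' Export patch records as tidy CSV
#'
#' @param records data.frame of patch records (with contrasts filled).
#' @param path output CSV path.
#' @param configHash optional hash embedded as a comment header so any number
#'   in a report can be traced to its configuration.
#' @return \code{path}, invisibly.
#' @export
writeRecordsCSV <- function(records, path, configHash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(configHash))
    writeLines(paste0("# config ", configHash), con)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}
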