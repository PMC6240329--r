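# Delimited-text readers/writers for localization tables and density
# matrices, and the machine-readable run report.
#
# All file coordinates are micrometers. Matrix files carry a 3-line header
# (pixel_size_um, n_rows, n_cols) followed by tab-separated rows.

#' Read a localization table
#'
#' Tab- (or otherwise-) delimited text with named columns \code{x_um},
#' \code{y_um} and optionally \code{z_um} and \code{channel}. A z column
#' yields a \linkS4class{Points3D}, otherwise a \linkS4class{Points2D}.
#' Non-numeric coordinates are rejected with the offending line numbers.
#'
#' @param path file path.
#' @param channel optional channel label: rows of the \code{channel} column
#'   are filtered to this value (required when the file mixes channels).
#' @param columnMap optional named character vector remapping file column
#'   names, e.g. \code{c(x_um = "x_nm_corrected")}.
#' @param sep field separator (default tab).
#' @return \linkS4class{Points2D} or \linkS4class{Points3D}.
#' @export
readLocalizations <- function(path, channel = NULL, columnMap = NULL,
                              sep = "\t") {
  if (!file.exists(path))
    .mpccStop(sprintf("file not found: %s", path), "mpccIOError")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  if (nrow(df) == 0)
    .mpccStop(sprintf("empty localization table: %s", path), "mpccIOError")
  for (std in names(columnMap)) {
    if (!columnMap[[std]] %in% names(df))
      .mpccStop(sprintf("mapped column '%s' absent from %s",
                        columnMap[[std]], path), "mpccIOError")
    names(df)[names(df) == columnMap[[std]]] <- std
  }
  for (col in c("x_um", "y_um"))
    if (!col %in% names(df))
      .mpccStop(sprintf("required column '%s' missing from %s", col, path),
                "mpccIOError")
  lab <- ""
  if ("channel" %in% names(df)) {
    if (!is.null(channel)) {
      df <- df[df$channel == channel, , drop = FALSE]
      if (nrow(df) == 0)
        .mpccStop(sprintf("no rows with channel '%s' in %s", channel, path),
                  "mpccIOError")
      lab <- channel
    } else {
      labs <- unique(df$channel)
      if (length(labs) > 1L)
        .mpccStop(sprintf(
          "file mixes channels (%s); pass 'channel' to select one",
          paste(labs, collapse = ", ")), "mpccIOError")
      lab <- labs
    }
  } else if (!is.null(channel)) lab <- channel
  has_z <- "z_um" %in% names(df)
  cols <- c("x_um", "y_um", if (has_z) "z_um")
  num <- lapply(cols, function(cl) suppressWarnings(as.numeric(df[[cl]])))
  bad <- Reduce(`|`, lapply(num, is.na))
  if (any(bad))
    .mpccStop(sprintf("non-numeric coordinates in %s at data line(s) %s",
                      path, paste(utils::head(which(bad), 10), collapse = ", ")),
              "mpccIOError")
  if (has_z) Points3D(num[[1]], num[[2]], num[[3]], channel = lab)
  else Points2D(num[[1]], num[[2]], channel = lab)
}

#' Write a localization table
#'
#' Tab-separated text with columns \code{x_um}, \code{y_um}
#' (\code{z_um} for 3D sets) and \code{channel}; the inverse of
#' \code{\link{readLocalizations}}.
#'
#' @param points \linkS4class{Points2D} or \linkS4class{Points3D}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLocalizations <- function(points, path) {
  df <- coords(points)
  names(df) <- paste0(names(df), "_um")
  df$channel <- channelLabel(points)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a density or reference matrix as TSV
#'
#' Three header lines (\code{#pixel_size_um}, \code{#n_rows},
#' \code{#n_cols}) followed by the matrix, one tab-separated row per line.
#' Integer counts round-trip exactly.
#'
#' @param image \linkS4class{DensityImage} or \linkS4class{ReferenceMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMatrix <- function(image, path) {
  g <- pixelGrid(image)
  m <- imageValues(image)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#pixel_size_um\t%.15g", pixelSize(g)),
               sprintf("#n_rows\t%d", g@nRows),
               sprintf("#n_cols\t%d", g@nCols)), con)
  utils::write.table(format(m, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a density matrix from TSV
#'
#' Inverse of \code{\link{writeMatrix}}. The grid is reconstructed centered
#' at the origin; when a \code{geom} is supplied the in-cell mask is
#' rebuilt from the geometry (the grid dimensions must then agree with
#' \code{\link{makeGrid}}), otherwise all pixels are masked.
#'
#' @param path file path.
#' @param geom optional \linkS4class{Spherocylinder} used to rebuild the
#'   mask.
#' @return a \linkS4class{DensityImage}.
#' @export
readMatrix <- function(path, geom = NULL) {
  if (!file.exists(path))
    .mpccStop(sprintf("file not found: %s", path), "mpccIOError")
  lines <- readLines(path)
  if (length(lines) < 4L)
    .mpccStop(sprintf("matrix file too short: %s", path), "mpccIOError")
  hdr <- function(i, key) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L || parts[1] != paste0("#", key))
      .mpccStop(sprintf("expected header '#%s' on line %d of %s",
                        key, i, path), "mpccIOError")
    as.numeric(parts[2])
  }
  p <- hdr(1, "pixel_size_um")
  nRows <- as.integer(hdr(2, "n_rows"))
  nCols <- as.integer(hdr(3, "n_cols"))
  body <- lines[-(1:3)]
  if (length(body) != nRows)
    .mpccStop(sprintf("header says %d rows but body has %d in %s",
                      nRows, length(body), path), "mpccIOError")
  vals <- lapply(body, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]]))
    if (length(v) != nCols || any(is.na(v)))
      .mpccStop(sprintf("malformed matrix row (expected %d numeric fields) in %s",
                        nCols, path), "mpccIOError")
    v
  })
  m <- do.call(rbind, vals)
  if (is.null(geom)) {
    grid <- new("PixelGrid", pixelSize = p, nRows = nRows, nCols = nCols,
                origin = c(-nCols * p / 2, -nRows * p / 2),
                mask = matrix(TRUE, nRows, nCols))
  } else {
    grid <- makeGrid(geom, p)
    if (!identical(gridDim(grid), c(nRows, nCols)))
      .mpccStop(sprintf(
        "matrix dimensions %dx%d do not match the grid of the given geometry (%dx%d)",
        nRows, nCols, grid@nRows, grid@nCols), "mpccIOError")
  }
  DensityImage(m, grid)
}

#' Machine-readable run report
#'
#' Collects the configuration, correlation results, null-model fit and
#' p-values (present only when a null was computed) plus any warnings into
#' a list, optionally written as JSON. The report records the seed and
#' software version so a run can be reproduced exactly.
#'
#' @param config named list of run settings (geometry, pixel size, sigmas,
#'   seed, ...).
#' @param correlations list of \linkS4class{CorrelationResult}s.
#' @param null optional \linkS4class{NullDistribution}.
#' @param observed optional observed MPCC to attach p-values for (defaults
#'   to the MPCC result in \code{correlations}, if any).
#' @param warnings character vector of warnings encountered.
#' @param path optional path; when given the report is written as JSON.
#' @return the report list, invisibly when written.
#' @export
runReport <- function(config, correlations = list(), null = NULL,
                      observed = NULL, warnings = character(), path = NULL) {
  corList <- lapply(correlations, function(cr) {
    list(method = corMethod(cr), value = corValue(cr), n_red = cr@nRed,
         n_green = cr@nGreen, pixel_size_um = cr@pixelSize,
         n_pixels_masked = cr@nPixelsMasked,
         mean_occupancy_red = cr@meanOccupancyRed,
         mean_occupancy_green = cr@meanOccupancyGreen)
  })
  # sparse images bias |MPCC| toward zero; flag occupancies below the
  # ~7 molecules/pixel reliability floor
  for (cr in corList)
    if (min(cr$mean_occupancy_red, cr$mean_occupancy_green) < 7)
      warnings <- c(warnings, sprintf(
        "%s computed at mean occupancy below 7 molecules/pixel; magnitude is biased toward zero",
        cr$method))
  report <- list(
    software = sprintf("mpcc %s", as.character(utils::packageVersion("mpcc"))),
    config = config, correlations = corList, warnings = warnings)
  if (!is.null(null)) {
    report$null <- list(n_trials = null@nTrials, fitted_mean = fittedMean(null),
                        fitted_sigma = fittedSigma(null),
                        settings = nullSettings(null))
    if (is.null(observed)) {
      meth <- vapply(correlations, corMethod, character(1))
      if (any(meth == "MPCC"))
        observed <- corValue(correlations[[which(meth == "MPCC")[1]]])
    }
    if (!is.null(observed)) {
      report$p_values <- list(
        observed = observed,
        gaussian = pValue(observed, fittedSigma(null)),
        gaussian_centered = pValue(observed, fittedSigma(null),
                                   mean = fittedMean(null)),
        empirical = empiricalPValue(observed, null))
    }
  }
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    return(invisible(report))
  }
  report
}
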