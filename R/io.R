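# Readers and writers for the on-disk formats: plain-text spectra,
# long-format map tables, text FLIM containers, JSON calibration curves
# and CSV/JSON analysis exports. Numbers are written with 9 significant
# digits, UTF-8, LF line endings.

fmt_num <- function(x) formatC(x, digits = 9, format = "g")

write_header <- function(con, meta) {
  for (nm in names(meta)) {
    v <- meta[[nm]]
    if (is.null(v) || length(v) == 0) next
    if (!is.atomic(v)) next
    writeLines(sprintf("# %s: %s", nm, paste(format(v, digits = 12), collapse = " ")),
               con)
  }
}

read_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) {
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(strsplit(val, "\\s+")[[1]]))
      meta[[trimws(m[2])]] <- if (!any(is.na(num))) num else val
    }
  }
  meta
}

#' Write a spectrum to a two-column text file
#'
#' '#'-prefixed header lines (key: value, including `laser_nm`) followed
#' by wavenumber/intensity columns.
#'
#' @param spectrum A `raman_spectrum`.
#' @param path Output file.
#' @param delimiter Column delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_spectrum_text <- function(spectrum, path, delimiter = "\t") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  meta <- c(list(laser_nm = spectrum$laser_nm),
            spectrum$metadata[vapply(spectrum$metadata, is.atomic, logical(1))])
  write_header(con, meta)
  writeLines(paste(fmt_num(spectrum$wavenumber), fmt_num(spectrum$intensity),
                   sep = delimiter), con)
  invisible(path)
}

#' Read a spectrum from a two-column text file
#'
#' @param path Input file: optional '#' header lines, then two numeric
#'   columns (wavenumber, intensity). Descending axes are normalized to
#'   ascending with intensities co-sorted.
#' @param laser_nm Laser line; taken from the header when omitted.
#' @return A `raman_spectrum`.
#' @export
read_spectrum_text <- function(path, laser_nm = NULL) {
  lines <- readLines(path, warn = FALSE)
  meta <- read_header(lines)
  data_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(data_idx) == 0) stop_data("no data rows in ", path)
  parts <- strsplit(trimws(lines[data_idx]), "[\t, ]+")
  bad <- which(vapply(parts, function(p) {
    length(p) < 2 || any(is.na(suppressWarnings(as.numeric(p[1:2]))))
  }, logical(1)))
  if (length(bad)) {
    stop_data("non-numeric spectrum row at line ", data_idx[bad[1]], " of ", path)
  }
  wn <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
  inten <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  o <- order(wn)
  laser <- laser_nm %||% meta$laser_nm
  if (is.null(laser)) stop_data("laser_nm missing from header and argument")
  raman_spectrum(wn[o], inten[o], laser, metadata = meta)
}

#' Write a spectral map as a long-format text table
#'
#' One row per (pixel, wavenumber) with columns x_um, y_um,
#' wavenumber_cm1, intensity; '#' header carries grid metadata.
#'
#' @param map A `spectral_map`.
#' @param path Output file.
#' @param delimiter `"\t"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_map_text <- function(map, path, delimiter = "\t") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write_header(con, list(plane = map$plane, laser_nm = map$laser_nm,
                         nx = map$nx, ny = map$ny,
                         pixel_size_um = map$pixel_size_um))
  writeLines(paste("x_um", "y_um", "wavenumber_cm1", "intensity",
                   sep = delimiter), con)
  nb <- length(map$wavenumber)
  x <- rep(map$x_um, each = nb)
  y <- rep(map$y_um, each = nb)
  wn <- rep(map$wavenumber, times = nrow(map$intensity))
  inten <- as.numeric(t(map$intensity))
  writeLines(paste(fmt_num(x), fmt_num(y), fmt_num(wn), fmt_num(inten),
                   sep = delimiter), con)
  invisible(path)
}

#' Read a long-format spectral map
#'
#' Infers the grid from the unique sorted pixel coordinates, checks the
#' pitch for uniformity (1e-6 relative) and that every pixel carries the
#' identical wavenumber set.
#'
#' @param path Input file.
#' @param delimiter Field delimiter; auto-detected from the header line
#'   when `NULL`.
#' @param laser_nm Laser override; default from the header.
#' @param plane Plane override; default from the header (or `"XY"`).
#' @return A `spectral_map`.
#' @export
read_map_text <- function(path, delimiter = NULL, laser_nm = NULL, plane = NULL) {
  lines <- readLines(path, warn = FALSE)
  meta <- read_header(lines)
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(body) < 2) stop_data("no data rows in ", path)
  delimiter <- delimiter %||% (if (grepl(",", body[1])) "," else "\t")
  header_cols <- strsplit(body[1], delimiter, fixed = TRUE)[[1]]
  df <- utils::read.table(text = body[-1], sep = delimiter,
                          col.names = header_cols, colClasses = "numeric")
  need <- c("x_um", "y_um", "wavenumber_cm1", "intensity")
  if (!all(need %in% names(df))) {
    stop_data("map file must have columns ", paste(need, collapse = ", "))
  }
  xs <- sort(unique(df$x_um)); ys <- sort(unique(df$y_um))
  check_pitch <- function(v, axis) {
    if (length(v) < 2) return(1)
    d <- diff(v)
    if (diff(range(d)) > 1e-6 * max(abs(d))) {
      stop_data("non-uniform ", axis, " pitch in ", path)
    }
    d[1]
  }
  px <- check_pitch(xs, "x"); py <- check_pitch(ys, "y")
  wn <- sort(unique(df$wavenumber_cm1))
  nb <- length(wn)
  key <- paste(df$x_um, df$y_um)
  counts <- table(key)
  if (any(counts != nb) || nrow(df) != length(xs) * length(ys) * nb) {
    bad <- names(counts)[counts != nb]
    stop_data("ragged map: pixels with incomplete wavenumber sets: ",
              paste(utils::head(bad, 5), collapse = "; "))
  }
  ix <- match(df$x_um, xs); iy <- match(df$y_um, ys)
  pix <- (iy - 1L) * length(xs) + ix
  ib <- match(df$wavenumber_cm1, wn)
  inten <- matrix(NA_real_, nrow = length(xs) * length(ys), ncol = nb)
  inten[cbind(pix, ib)] <- df$intensity
  spectral_map(wn, inten,
               x_um = xs[rep(seq_along(xs), times = length(ys))],
               y_um = ys[rep(seq_along(ys), each = length(xs))],
               nx = length(xs), ny = length(ys),
               pixel_size_um = c(px, py),
               plane = plane %||% (if (identical(meta$plane, "XZ")) "XZ" else "XY"),
               laser_nm = laser_nm %||% meta$laser_nm %||%
                 stop_data("laser_nm missing from header and argument"),
               metadata = meta)
}

#' Write a FLIM dataset to a text container
#'
#' '#' key-value header (nx, ny, bin_ps, g_factor, laser_power, ...)
#' followed by a long-format table x_px, y_px, t_ps, parallel,
#' perpendicular; zero-count rows are omitted.
#'
#' @param dataset A `flim_dataset`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_flim_text <- function(dataset, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write_header(con, list(nx = dataset$nx, ny = dataset$ny,
                         nt = length(dataset$time_ps),
                         bin_ps = dataset$bin_ps, g_factor = dataset$g_factor,
                         laser_power = dataset$laser_power,
                         excitation_nm = dataset$metadata$excitation_nm %||% 470,
                         emission_band = dataset$metadata$emission_band %||% "550/88"))
  writeLines("x_px\ty_px\tt_ps\tparallel\tperpendicular", con)
  npx <- nrow(dataset$parallel)
  ix <- rep((seq_len(npx) - 1L) %% dataset$nx + 1L, times = ncol(dataset$parallel))
  iy <- rep((seq_len(npx) - 1L) %/% dataset$nx + 1L, times = ncol(dataset$parallel))
  tt <- rep(dataset$time_ps, each = npx)
  p <- as.numeric(dataset$parallel)
  q <- as.numeric(dataset$perpendicular)
  keep <- p > 0 | q > 0
  writeLines(paste(ix[keep], iy[keep], fmt_num(tt[keep]), p[keep], q[keep],
                   sep = "\t"), con)
  invisible(path)
}

#' Read a FLIM text container
#'
#' @param path File written by [write_flim_text()].
#' @return A `flim_dataset`.
#' @export
read_flim_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- read_header(lines)
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  df <- utils::read.table(text = body[-1], sep = "\t",
                          col.names = strsplit(body[1], "\t")[[1]])
  nx <- as.integer(meta$nx); ny <- as.integer(meta$ny)
  nt <- as.integer(meta$nt); bin_ps <- meta$bin_ps
  time_ps <- (seq_len(nt) - 1) * bin_ps
  par_m <- matrix(0, nrow = nx * ny, ncol = nt)
  perp_m <- matrix(0, nrow = nx * ny, ncol = nt)
  pix <- (df$y_px - 1L) * nx + df$x_px
  ib <- round(df$t_ps / bin_ps) + 1L
  par_m[cbind(pix, ib)] <- df$parallel
  perp_m[cbind(pix, ib)] <- df$perpendicular
  flim_dataset(time_ps, par_m, perp_m, nx, ny,
               g_factor = meta$g_factor %||% 1,
               laser_power = meta$laser_power %||% 1, metadata = meta)
}

#' Serialize a calibration curve to JSON
#'
#' @param curve A `calibration_curve`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(curve, path) {
  jsonlite::write_json(unclass(curve), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a calibration curve from JSON
#'
#' @param path File written by [write_calibration_json()].
#' @return A `calibration_curve`.
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "calibration_curve")
}

#' Export pigment-map images and per-pixel values
#'
#' Writes, under `prefix`: one plain-text CSV matrix per image
#' (`<prefix>_<image>.csv`, rows = y, columns = x) and a long-format CSV
#' of all per-pixel values (`<prefix>_pixels.csv`).
#'
#' @param pigment_map A `pigment_map`.
#' @param prefix Output path prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_pigment_map <- function(pigment_map, prefix) {
  files <- character(0)
  for (nm in names(pigment_map$images)) {
    f <- paste0(prefix, "_", nm, ".csv")
    utils::write.table(t(pigment_map$images[[nm]]), f, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, f)
  }
  long <- data.frame(x_um = pigment_map$x_um, y_um = pigment_map$y_um,
                     mask = as.integer(pigment_map$mask))
  for (nm in names(pigment_map$images)) {
    long[[nm]] <- as.numeric(pigment_map$images[[nm]])
  }
  f <- paste0(prefix, "_pixels.csv")
  utils::write.csv(long, f, row.names = FALSE)
  invisible(c(files, f))
}
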