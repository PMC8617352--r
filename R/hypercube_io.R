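# Hypercube containers, ENVI band-sequential I/O, reflectance
# calibration, bean segmentation and per-bean spectrum extraction.

SPECTRUM_MODES <- c("raw", "reflectance", "absorbance", "snv", "derivative2")

#' Construct a spectrum
#' @param wavelengths Strictly increasing wavelength vector (nm).
#' @param values Per-band signal values.
#' @param mode One of raw, reflectance, absorbance, snv, derivative2.
#' @return A `bean_spectrum`.
#' @export
new_spectrum <- function(wavelengths, values, mode = "raw") {
  mode <- match.arg(mode, SPECTRUM_MODES)
  if (length(wavelengths) != length(values))
    stop("wavelengths and values lengths differ")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(values))) stop("spectrum values must be finite")
  structure(list(wavelengths = as.numeric(wavelengths),
                 values = as.numeric(values), mode = mode),
            class = "bean_spectrum")
}

#' @export
print.bean_spectrum <- function(x, ...) {
  cat(sprintf("<bean_spectrum> %d bands, %.0f-%.0f nm, mode=%s\n",
              length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), x$mode))
  invisible(x)
}

#' Construct a hypercube
#' @param data lines x samples x bands array.
#' @param wavelengths Strictly increasing nm vector, length = bands.
#' @param mode Signal mode of the cube (raw or reflectance).
#' @param meta Named list of acquisition tags.
#' @return A `hypercube`.
#' @export
new_hypercube <- function(data, wavelengths, mode = "raw", meta = list()) {
  if (length(dim(data)) != 3)
    stop("hypercube data must be a 3-D lines x samples x bands array")
  if (dim(data)[3] != length(wavelengths))
    stop("bands dimension (", dim(data)[3],
         ") does not match wavelength length (", length(wavelengths), ")")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (mode == "raw" && min(data) < 0)
    stop("raw intensities must be non-negative")
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 mode = mode, meta = meta),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d lines x %d samples x %d bands, mode=%s\n",
              d[1], d[2], d[3], x$mode))
  invisible(x)
}

#' Write a hypercube as an ENVI band-sequential raster
#'
#' Emits `<path>.hdr` (text header with the wavelength vector) and
#' `<path>.dat` (little-endian doubles, band-sequential), a lossless
#' round trip with [read_envi()].
#'
#' @param cube A `hypercube`.
#' @param path Output path without extension.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  hdr <- c("ENVI",
           "description = {beanspec hypercube}",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           "interleave = bsq",
           "byte order = 0",
           paste0("beanspec mode = ", cube$mode),
           "wavelength units = Nanometers",
           paste0("wavelength = {",
                  paste(sprintf("%.17g", cube$wavelengths),
                        collapse = ", "), "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  # BSQ: sample fastest, then line, then band
  writeBin(as.vector(aperm(cube$data, c(2, 1, 3))), con,
           size = 8, endian = "little")
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  fields <- list()
  lines <- strsplit(txt, "\n")[[1]]
  i <- 1
  while (i <= length(lines)) {
    line <- lines[i]
    if (grepl("=", line, fixed = TRUE)) {
      key <- trimws(sub("=.*", "", line))
      val <- trimws(sub("^[^=]*=", "", line))
      if (grepl("\\{", val) && !grepl("\\}", val)) {
        while (i < length(lines) && !grepl("\\}", val)) {
          i <- i + 1
          val <- paste(val, trimws(lines[i]))
        }
      }
      fields[[tolower(key)]] <- gsub("[{}]", "", val)
    }
    i <- i + 1
  }
  fields
}

#' Read an ENVI band-sequential raster
#'
#' Supports the subset of the ENVI format the package writes (BSQ
#' interleave, float32 or float64 payload) and validates header/payload
#' consistency.
#'
#' @param path Path without extension, or the `.hdr` path.
#' @return A `hypercube`.
#' @export
read_envi <- function(path) {
  path <- sub("\\.(hdr|dat)$", "", path)
  hdr_path <- paste0(path, ".hdr")
  dat_path <- paste0(path, ".dat")
  if (!file.exists(hdr_path)) stop("format error: header not found: ", hdr_path)
  if (!file.exists(dat_path)) stop("format error: payload not found: ", dat_path)
  f <- parse_envi_header(hdr_path)
  for (key in c("samples", "lines", "bands", "interleave", "data type"))
    if (is.null(f[[key]]))
      stop("format error: header field missing: ", key)
  if (is.null(f[["wavelength"]]))
    stop("format error: header field missing: wavelength")
  samples <- as.integer(f[["samples"]]); lines <- as.integer(f[["lines"]])
  bands <- as.integer(f[["bands"]])
  if (tolower(f[["interleave"]]) != "bsq")
    stop("format error: only bsq interleave is supported")
  dtype <- as.integer(f[["data type"]])
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("format error: unsupported data type ", dtype))
  wl <- as.numeric(strsplit(f[["wavelength"]], ",")[[1]])
  if (length(wl) != bands)
    stop("format error: wavelength list length (", length(wl),
         ") does not match bands (", bands, ")")
  expected <- as.numeric(samples) * lines * bands * size
  if (file.size(dat_path) != expected)
    stop("format error: payload is ", file.size(dat_path),
         " bytes, header implies ", expected)
  con <- file(dat_path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = samples * lines * bands, size = size,
               endian = "little")
  data <- aperm(array(v, c(samples, lines, bands)), c(2, 1, 3))
  mode <- if (!is.null(f[["beanspec mode"]])) f[["beanspec mode"]] else "raw"
  new_hypercube(data, wl, mode = mode, meta = f[setdiff(names(f),
    c("samples", "lines", "bands", "wavelength", "interleave"))])
}

#' Dark/white reflectance calibration
#'
#' Averages the dark-current and white-reference frame stacks over
#' their acquisitions and converts raw counts to reflectance per pixel
#' and band: `R = (raw - dark) / (white - dark)`, clipped to
#' `[clip_floor, clip_ceiling]` (the ceiling tolerates white-reference
#' overshoot; the floor protects the subsequent log(1/R) transform).
#'
#' @param raw A raw-mode `hypercube`.
#' @param dark,white frames x samples x bands arrays (or already
#'   averaged samples x bands matrices).
#' @param clip_floor,clip_ceiling Reflectance clip limits.
#' @return A reflectance-mode `hypercube`.
#' @export
calibrate_reflectance <- function(raw, dark, white, clip_floor = 1e-4,
                                  clip_ceiling = 1.5) {
  stopifnot(inherits(raw, "hypercube"))
  if (raw$mode != "raw") stop("calibration expects a raw-mode hypercube")
  avg <- function(a) if (length(dim(a)) == 3) apply(a, c(2, 3), mean) else a
  dk <- avg(dark); wt <- avg(white)
  d <- dim(raw$data)
  if (!all(dim(dk) == c(d[2], d[3])) || !all(dim(wt) == c(d[2], d[3])))
    stop("reference frame dimensions do not match the cube")
  bad <- which(apply(wt - dk, 2, min) <= 0)
  if (length(bad))
    stop("calibration error: white <= dark at band(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (", paste(round(raw$wavelengths[utils::head(bad, 5)]),
                     collapse = ", "), " nm)")
  out <- array(0, d)
  for (b in seq_len(d[3])) {
    dm <- matrix(dk[, b], d[1], d[2], byrow = TRUE)
    wm <- matrix(wt[, b], d[1], d[2], byrow = TRUE)
    out[, , b] <- pmin(pmax((raw$data[, , b] - dm) / (wm - dm), clip_floor),
                       clip_ceiling)
  }
  new_hypercube(out, raw$wavelengths, mode = "reflectance",
                meta = raw$meta)
}

# Otsu's threshold on a numeric matrix (256-bin histogram).
otsu_threshold <- function(img, n_bins = 256) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(floor((img - rng[1]) / diff(rng) * n_bins) + 1L,
                     n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / n_bins * diff(rng)
}

# 8-connectivity connected-component labelling (iterative BFS).
label_components <- function(fg) {
  nl <- nrow(fg); ns <- ncol(fg)
  labels <- matrix(0L, nl, ns)
  cur <- 0L
  offs <- expand.grid(dl = -1:1, ds = -1:1)
  offs <- offs[!(offs$dl == 0 & offs$ds == 0), ]
  for (start in which(fg)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      px <- queue[length(queue)]
      queue <- queue[-length(queue)]
      l0 <- (px - 1L) %% nl + 1L
      s0 <- (px - 1L) %/% nl + 1L
      for (j in seq_len(nrow(offs))) {
        l <- l0 + offs$dl[j]; s <- s0 + offs$ds[j]
        if (l >= 1 && l <= nl && s >= 1 && s <= ns &&
            fg[l, s] && labels[l, s] == 0L) {
          labels[l, s] <- cur
          queue <- c(queue, (s - 1L) * nl + l)
        }
      }
    }
  }
  labels
}

#' Segment beans in a reflectance cube
#'
#' Applies Otsu's threshold to the image at the band nearest
#' `threshold_nm` (1300 nm by default, where beans are much brighter
#' than the tray), labels foreground by 8-connected components, drops
#' components below `min_pixels`, and renumbers labels top-to-bottom
#' then left-to-right by centroid.
#'
#' @param cube A reflectance-mode `hypercube`.
#' @param min_pixels Minimum component size kept.
#' @param threshold_nm Wavelength of the thresholding band.
#' @return A `bean_mask`: integer lines x samples label matrix
#'   (0 = background) with a `pixel_counts` attribute. An empty scene
#'   yields an all-zero mask with a warning.
#' @export
segment_beans <- function(cube, min_pixels = 20, threshold_nm = 1300) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$mode != "reflectance")
    stop("segmentation expects a reflectance-mode hypercube")
  b <- which.min(abs(cube$wavelengths - threshold_nm))
  img <- cube$data[, , b]
  thr <- otsu_threshold(img)
  fg <- img > thr
  labels <- if (any(fg)) label_components(fg) else
    matrix(0L, nrow(img), ncol(img))
  counts <- tabulate(labels[labels > 0])
  keep <- which(counts >= min_pixels)
  if (length(keep) == 0) {
    warning("empty scene: no bean-sized components found")
    out <- matrix(0L, nrow(img), ncol(img))
    attr(out, "pixel_counts") <- integer(0)
    class(out) <- c("bean_mask", class(out))
    return(out)
  }
  # order kept components top-to-bottom then left-to-right
  cl <- vapply(keep, function(k) mean(row(labels)[labels == k]), numeric(1))
  cs <- vapply(keep, function(k) mean(col(labels)[labels == k]), numeric(1))
  keep <- keep[order(round(cl / 8), cs)]
  out <- matrix(0L, nrow(img), ncol(img))
  for (i in seq_along(keep)) out[labels == keep[i]] <- i
  attr(out, "pixel_counts") <- tabulate(out[out > 0])
  class(out) <- c("bean_mask", class(out))
  out
}

#' Mean spectrum of one labelled bean
#'
#' @param cube A `hypercube`.
#' @param mask Label matrix from [segment_beans()] (or ground truth).
#' @param label Bean label to extract.
#' @return A `bean_spectrum` (per-band arithmetic mean over the label's
#'   pixels); mode inherited from the cube.
#' @export
extract_mean_spectrum <- function(cube, mask, label) {
  stopifnot(inherits(cube, "hypercube"))
  idx <- which(mask == label)
  if (length(idx) == 0) stop("lookup error: label ", label, " not in mask")
  d <- dim(cube$data)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  vals <- colMeans(flat[idx, , drop = FALSE])
  mode <- if (cube$mode %in% SPECTRUM_MODES) cube$mode else "raw"
  new_spectrum(cube$wavelengths, vals, mode)
}

#' Average the two scanned sides of a bean
#' @param side_a,side_b `bean_spectrum` objects on the same wavelength
#'   grid and in the same mode.
#' @return Their element-wise mean spectrum.
#' @export
average_sides <- function(side_a, side_b) {
  stopifnot(inherits(side_a, "bean_spectrum"),
            inherits(side_b, "bean_spectrum"))
  if (length(side_a$wavelengths) != length(side_b$wavelengths) ||
      any(side_a$wavelengths != side_b$wavelengths))
    stop("alignment error: wavelength grids differ")
  if (side_a$mode != side_b$mode)
    stop("alignment error: spectrum modes differ")
  new_spectrum(side_a$wavelengths, (side_a$values + side_b$values) / 2,
               side_a$mode)
}

#' Trim noisy detector edges from a spectrum or spectra matrix
#' @param wavelengths Wavelength vector.
#' @param lower,upper Working range kept (default 950-2450 nm).
#' @return Logical keep-vector over bands.
#' @export
band_window <- function(wavelengths, lower = 950, upper = 2450) {
  wavelengths >= lower & wavelengths <= upper
}
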