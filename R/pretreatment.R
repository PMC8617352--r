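# Spectral pre-treatments: log(1/R) absorbance, standard normal
# variate, and Savitzky-Golay 2nd derivative.  Absorbance is the base
# representation: SNV and the derivative are applied to log(1/R).

#' Pre-treatment specification
#'
#' @param method One of `"log1R"` (absorbance only), `"snv"` (SNV on
#'   absorbance) or `"sg2"` (Savitzky-Golay 2nd derivative of
#'   absorbance).
#' @param sg_window Odd filter length in points (default 11, standard
#'   for ~6 nm sampling).
#' @param sg_polyorder Fitting polynomial order (default 2).
#' @return A `pretreatment_spec`.
#' @export
pretreat_spec <- function(method = c("log1R", "snv", "sg2"),
                          sg_window = 11, sg_polyorder = 2) {
  method <- match.arg(method)
  if (sg_window %% 2 != 1) stop("sg_window must be odd")
  if (sg_window < sg_polyorder + 2)
    stop("sg_window must be at least sg_polyorder + 2")
  structure(list(method = method, sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder)),
            class = "pretreatment_spec")
}

#' Reflectance to absorbance, log10(1/R)
#' @param s A reflectance-mode `bean_spectrum` with positive values.
#' @return An absorbance-mode spectrum.
#' @export
to_absorbance <- function(s) {
  stopifnot(inherits(s, "bean_spectrum"))
  if (s$mode != "reflectance")
    stop("to_absorbance expects a reflectance-mode spectrum")
  if (any(s$values <= 0))
    stop("domain error: non-positive reflectance values")
  new_spectrum(s$wavelengths, log10(1 / s$values), "absorbance")
}

#' Standard normal variate
#'
#' Centres and scales a spectrum by its own band mean and sample
#' standard deviation, removing additive baseline offsets and
#' multiplicative scatter exactly: `snv(a*x + b) = snv(x)` for `a > 0`.
#'
#' @param s A `bean_spectrum`.
#' @return An snv-mode spectrum (band mean 0, sample SD 1).
#' @export
snv <- function(s) {
  stopifnot(inherits(s, "bean_spectrum"))
  sdev <- stats::sd(s$values)
  if (!is.finite(sdev) || sdev == 0)
    stop("degenerate spectrum: zero variance, SNV undefined")
  new_spectrum(s$wavelengths, (s$values - mean(s$values)) / sdev, "snv")
}

#' Savitzky-Golay second derivative
#'
#' Least-squares polynomial convolution derivative with respect to
#' wavelength; the first and last half-windows are handled by the
#' filter's startup/end rows (polynomial fit within the edge window).
#' Requires an (approximately) uniform wavelength grid.
#'
#' @param s A `bean_spectrum`.
#' @param spec A [pretreat_spec()] supplying window and polynomial
#'   order (its `method` is ignored here).
#' @return A derivative2-mode spectrum, units per nm^2.
#' @export
sg_derivative2 <- function(s, spec = pretreat_spec("sg2")) {
  stopifnot(inherits(s, "bean_spectrum"))
  nb <- length(s$values)
  if (nb < spec$sg_window)
    stop("window error: ", nb, " bands < sg_window = ", spec$sg_window)
  dl <- diff(s$wavelengths)
  h <- mean(dl)
  if (max(abs(dl - h)) / h > 0.01)
    stop("spacing error: wavelength grid non-uniform beyond 1%")
  vals <- signal::sgolayfilt(s$values, p = spec$sg_polyorder,
                             n = spec$sg_window, m = 2, ts = h)
  new_spectrum(s$wavelengths, vals, "derivative2")
}

#' Apply a named pre-treatment to a reflectance spectrum
#' @param s A reflectance-mode `bean_spectrum`.
#' @param spec A [pretreat_spec()].
#' @return The pre-treated spectrum.
#' @export
pretreat <- function(s, spec) {
  stopifnot(inherits(spec, "pretreatment_spec"))
  a <- to_absorbance(s)
  switch(spec$method,
         log1R = a,
         snv = snv(a),
         sg2 = sg_derivative2(a, spec))
}

#' Pre-treat a matrix of reflectance spectra
#' @param R beans x bands matrix of reflectance values.
#' @param wavelengths Band wavelengths (nm).
#' @param spec A [pretreat_spec()].
#' @return beans x bands matrix of pre-treated values.
#' @export
pretreat_matrix <- function(R, wavelengths, spec) {
  out <- t(apply(R, 1, function(r)
    pretreat(new_spectrum(wavelengths, r, "reflectance"), spec)$values))
  dimnames(out) <- dimnames(R)
  out
}
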