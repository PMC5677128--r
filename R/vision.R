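#' Hyperspectral radiance cube
#'
#' @param data Numeric array H x W x B of non-negative radiance values
#'   (arbitrary but consistent units).
#' @param wavelengths Strictly increasing band-centre wavelengths (nm),
#'   length B >= 2. Default: 16 bands spanning 360-660 nm.
#' @return Object of class `hyperspectral_cube`.
#' @export
hyperspectral_cube <- function(data,
                               wavelengths = seq(360, 660, length.out = dim(data)[3])) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(wavelengths),
            dim(data)[3] >= 2, !is.unsorted(wavelengths, strictly = TRUE),
            all(data >= 0))
  structure(list(data = data, wavelengths = wavelengths),
            class = "hyperspectral_cube")
}

#' @export
print.hyperspectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("hyperspectral_cube: %d x %d pixels, %d bands (%g-%g nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Write / read a hyperspectral cube as a plain-text band stack
#'
#' The text format is self-describing: a header line `H W B`, a line of B
#' wavelengths, then B blocks of H lines x W whitespace-separated values.
#'
#' @param cube A [hyperspectral_cube()].
#' @param path File path.
#' @return `write_cube_txt()` returns `path` invisibly; `read_cube_txt()`
#'   returns a [hyperspectral_cube()].
#' @export
write_cube_txt <- function(cube, path) {
  d <- dim(cube$data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(d, collapse = " "), con)
  writeLines(paste(format(cube$wavelengths, digits = 15), collapse = " "), con)
  for (b in seq_len(d[3]))
    utils::write.table(cube$data[, , b], con, row.names = FALSE,
                       col.names = FALSE)
  invisible(path)
}

#' @rdname write_cube_txt
#' @export
read_cube_txt <- function(path) {
  lines <- readLines(path)
  d <- as.integer(strsplit(lines[1], " +")[[1]])
  wl <- as.numeric(strsplit(lines[2], " +")[[1]])
  vals <- scan(text = lines[-(1:2)], quiet = TRUE)
  arr <- array(0, d)
  per_band <- d[1] * d[2]
  for (b in seq_len(d[3])) {
    block <- vals[((b - 1) * per_band + 1):(b * per_band)]
    arr[, , b] <- matrix(block, nrow = d[1], byrow = TRUE)
  }
  hyperspectral_cube(arr, wl)
}

#' Receptor-noise-limited observer model
#'
#' Photoreceptor classes with Gaussian spectral sensitivities sampled at
#' the cube's wavelengths. Per-class noise is
#' `e_i = weber * sqrt(eta_ref / eta_i)` where `eta` are relative cone
#' abundances and the reference class is the most abundant one. The shipped
#' defaults (see [receptor_model_tetra()] / [receptor_model_tri()]) are
#' synthetic placeholder pigments, fully configurable.
#'
#' @param wavelengths Wavelength grid (nm) the sensitivities are sampled on.
#' @param peaks Peak wavelength of each receptor class (nm).
#' @param sigma Gaussian width of each pigment (nm; recycled).
#' @param eta Relative abundance of each class (> 0; recycled).
#' @param weber Weber fraction of the reference (most abundant) class.
#' @param names Class names.
#' @return Object of class `receptor_model` with fields `sensitivity`
#'   (bands x classes), `eta`, `e`, `weber`, `wavelengths`.
#' @export
receptor_model <- function(wavelengths, peaks, sigma = 40, eta = 1,
                           weber = 0.05, names = NULL) {
  n <- length(peaks)
  sigma <- rep_len(sigma, n)
  eta <- rep_len(eta, n)
  stopifnot(n >= 2, all(eta > 0), weber > 0)
  S <- vapply(seq_len(n), function(i)
    exp(-(wavelengths - peaks[i])^2 / (2 * sigma[i]^2)), numeric(length(wavelengths)))
  if (is.null(names)) names <- paste0("R", seq_len(n))
  colnames(S) <- names
  ref <- which.max(eta)
  structure(list(sensitivity = S, eta = eta, weber = weber,
                 e = weber * sqrt(eta[ref] / eta),
                 wavelengths = wavelengths, peaks = peaks, names = names),
            class = "receptor_model")
}

#' @rdname receptor_model
#' @details `receptor_model_tetra()` is a tetrachromatic (UV/S/M/L,
#'   peaks 370/445/508/565 nm, abundances 1:2:2:4) songbird-like observer;
#'   `receptor_model_tri()` is a trichromatic (S/M/L, 420/534/564 nm,
#'   abundances 1:2:4) human-like observer.
#' @export
receptor_model_tetra <- function(wavelengths = seq(360, 660, length.out = 16),
                                 weber = 0.05) {
  receptor_model(wavelengths, peaks = c(370, 445, 508, 565),
                 eta = c(1, 2, 2, 4), weber = weber,
                 names = c("UV", "S", "M", "L"))
}

#' @rdname receptor_model
#' @export
receptor_model_tri <- function(wavelengths = seq(360, 660, length.out = 16),
                               weber = 0.05) {
  receptor_model(wavelengths, peaks = c(420, 534, 564),
                 eta = c(1, 2, 4), weber = weber,
                 names = c("S", "M", "L"))
}

#' Luminance image
#'
#' Per-pixel sum of radiance across all bands.
#'
#' @param cube A [hyperspectral_cube()].
#' @return H x W numeric matrix.
#' @export
luminance_map <- function(cube) {
  rowSums(cube$data, dims = 2)
}

#' Percent luminance change of the butterfly against the background
#'
#' Per butterfly pixel, `100 * (L_pix - mean(L_bg)) / mean(L_bg)`;
#' the mean and standard deviation over the butterfly are reported.
#'
#' @param cube A [hyperspectral_cube()].
#' @param mask Logical H x W butterfly mask (complement = background);
#'   both regions must be non-empty.
#' @return List: `mean`, `sd`, per-pixel `values`.
#' @export
percent_luminance_change <- function(cube, mask) {
  stopifnot(is.logical(mask), any(mask), any(!mask))
  L <- luminance_map(cube)
  bg <- mean(L[!mask])
  if (bg == 0) stop("background luminance is zero")
  vals <- 100 * (L[mask] - bg) / bg
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}

#' Spatial-frequency granularity spectrum
#'
#' The masked region is mean-subtracted inside the mask and zero-filled
#' outside on the full image canvas, and its 2-D Fourier power is binned
#' into `n_bands` equal-width radial frequency bands spanning the
#' full-image scale (`1 / max(H, W)` cycles/pixel) up to the Nyquist
#' frequency (0.5); bins below the lowest edge fall into band 1 and
#' above-Nyquist corner bins into the top band. Because the bands are
#' anchored to the full masked image, spectra of complementary regions
#' (butterfly vs background) share band edges and are directly comparable.
#' Energies are normalized to sum to 1. A constant region is degenerate and
#' returns a uniform spectrum with `degenerate = TRUE`.
#'
#' @param image Numeric H x W matrix (e.g. a [luminance_map()]).
#' @param mask Logical H x W region mask (> 1 pixel).
#' @param n_bands Number of frequency bands (default 7).
#' @return Object of class `granularity_spectrum`: `energy` (sums to 1),
#'   `edges` (band edges, cycles/pixel), `degenerate`.
#' @export
granularity_spectrum <- function(image, mask, n_bands = 7) {
  stopifnot(dim(image)[1] == dim(mask)[1], dim(image)[2] == dim(mask)[2],
            sum(mask) > 1)
  h <- nrow(image); w <- ncol(image)
  f_min <- 1 / max(h, w)
  edges <- seq(f_min, 0.5, length.out = n_bands + 1)
  vals <- image
  vals[!mask] <- 0
  vals[mask] <- image[mask] - mean(image[mask])
  if (max(abs(vals)) < 1e-12)
    return(structure(list(energy = rep(1 / n_bands, n_bands), edges = edges,
                          degenerate = TRUE),
                     class = "granularity_spectrum"))
  P <- Mod(stats::fft(vals))^2
  fy <- (0:(h - 1)); fy <- ifelse(fy > h / 2, fy - h, fy) / h
  fx <- (0:(w - 1)); fx <- ifelse(fx > w / 2, fx - w, fx) / w
  fr <- sqrt(outer(fy^2, fx^2, "+"))
  keep <- fr > 0                       # drop DC
  band <- findInterval(fr[keep], edges, rightmost.closed = FALSE)
  band[band < 1] <- 1L
  band[band > n_bands] <- n_bands
  energy <- vapply(seq_len(n_bands), function(b) sum(P[keep][band == b]),
                   numeric(1))
  tot <- sum(energy)
  if (tot == 0)
    return(structure(list(energy = rep(1 / n_bands, n_bands), edges = edges,
                          degenerate = TRUE),
                     class = "granularity_spectrum"))
  structure(list(energy = energy / tot, edges = edges, degenerate = FALSE),
            class = "granularity_spectrum")
}

#' Kullback-Leibler divergence between two granularity spectra
#'
#' `sum(p * log(p / q))` after additive smoothing (`epsilon` added to every
#' band of both spectra, then renormalized). Non-negative; 0 iff the
#' smoothed spectra are equal. KL is not symmetric.
#'
#' @param p,q `granularity_spectrum` objects with identical band edges.
#' @param epsilon Additive smoothing constant (default 1e-9).
#' @return Non-negative scalar.
#' @export
kl_divergence <- function(p, q, epsilon = 1e-9) {
  if (!isTRUE(all.equal(p$edges, q$edges)))
    stop("band structures differ")
  ps <- p$energy + epsilon; ps <- ps / sum(ps)
  qs <- q$energy + epsilon; qs <- qs / sum(qs)
  max(0, sum(ps * log(ps / qs)))
}

#' Quantum catches of a radiance spectrum
#'
#' `Q_i = sum_b radiance(b) * S_i(b) * dlambda_b`, with band widths taken
#' from midpoints between band centres (edge bands use the adjacent width).
#'
#' @param spectrum Per-band radiance vector (length = number of bands).
#' @param receptors A [receptor_model()] on the same wavelength grid.
#' @return Named numeric vector of per-class catches.
#' @export
quantum_catches <- function(spectrum, receptors) {
  wl <- receptors$wavelengths
  stopifnot(length(spectrum) == length(wl))
  dl <- diff(wl)
  dlam <- c(dl[1], (dl[-1] + dl[-length(dl)]) / 2, dl[length(dl)])
  drop(crossprod(receptors$sensitivity, spectrum * dlam))
}

# receptor-noise-limited chromatic distance for contrast vectors;
# df: n_pixels x n_classes matrix of log-contrasts; e: per-class noise
.rnl_distance <- function(df, e) {
  n <- length(e)
  prod_e2 <- prod(e^2)
  den <- sum(prod_e2 / e^2)            # sum_i prod_{k != i} e_k^2
  num <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    w <- prod_e2 / (e[i]^2 * e[j]^2)   # (prod_{k != i,j} e_k)^2
    num <- num + w * (df[, i] - df[, j])^2
  }
  sqrt(num / den)
}

#' Just-noticeable-difference map under the receptor-noise-limited model
#'
#' The chromatic reference is the mean background radiance spectrum. Per
#' butterfly pixel, receptor contrasts are `df_i = log(Q_i(pixel) /
#' Q_i(reference))` and the chromatic distance is the general n-class
#' receptor-noise-limited (Vorobyev-Osorio) form
#' `JND^2 = sum_{i<j} (prod_{k != i,j} e_k)^2 (df_i - df_j)^2 /
#' sum_i (prod_{k != i} e_k)^2`, which reduces to the familiar
#' dichromatic, trichromatic and tetrachromatic formulas. The distance uses
#' contrast differences only, so it is exactly invariant under global
#' radiance scaling (a colour-opponent mechanism independent of achromatic
#' luminosity changes). Pixels with a non-positive quantum catch are
#' excluded and counted.
#'
#' @param cube A [hyperspectral_cube()].
#' @param mask Logical butterfly mask; the background (complement) must be
#'   non-empty with positive catches.
#' @param receptors A [receptor_model()].
#' @return Object of class `jnd_result`: `jnd` (values over valid butterfly
#'   pixels), `map` (H x W, `NA` outside the mask and at excluded pixels),
#'   `mean`, `sd`, `n_excluded`.
#' @export
jnd_map <- function(cube, mask, receptors) {
  stopifnot(any(mask), any(!mask))
  d <- dim(cube$data)
  flat <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  ref_spec <- colMeans(flat[!mask, , drop = FALSE])
  Qref <- quantum_catches(ref_spec, receptors)
  if (any(Qref <= 0)) stop("non-positive background quantum catch")
  dl <- diff(receptors$wavelengths)
  dlam <- c(dl[1], (dl[-1] + dl[-length(dl)]) / 2, dl[length(dl)])
  Q <- flat[mask, , drop = FALSE] %*% (receptors$sensitivity * dlam)
  valid <- rowSums(Q <= 0) == 0
  df <- log(sweep(Q[valid, , drop = FALSE], 2, Qref, "/"))
  jnd <- .rnl_distance(df, receptors$e)
  map <- matrix(NA_real_, d[1], d[2])
  idx <- which(mask)
  map[idx[valid]] <- jnd
  structure(list(jnd = jnd, map = map, mean = mean(jnd),
                 sd = if (length(jnd) > 1) stats::sd(jnd) else 0,
                 n_excluded = sum(!valid)),
            class = "jnd_result")
}

#' Summary statistics and log-density of a JND map
#'
#' @param result A `jnd_result` from [jnd_map()].
#' @param breaks Number of histogram bins, or a vector of bin edges, on the
#'   log10-JND axis (zero JNDs are excluded from the histogram and counted).
#' @return List: `mean`, `sd`, `n`, `n_zero`, and `density` data frame with
#'   `log10_mid`, `mass` (masses sum to 1 over positive values),
#'   `log_density`.
#' @export
jnd_summary <- function(result, breaks = 24) {
  stopifnot(length(result$jnd) >= 1)
  pos <- result$jnd[result$jnd > 0]
  dens <- NULL
  if (length(pos)) {
    lx <- log10(pos)
    h <- graphics::hist(lx, breaks = breaks, plot = FALSE)
    mass <- h$counts / sum(h$counts)
    dens <- data.frame(log10_mid = h$mids, mass = mass,
                       log_density = ifelse(mass > 0, log(h$density), -Inf))
  }
  list(mean = result$mean, sd = result$sd, n = length(result$jnd),
       n_zero = sum(result$jnd == 0), density = dens)
}
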