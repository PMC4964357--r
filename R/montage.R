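#' Build a spherical high-density EEG montage
#'
#' Generates an approximately equidistant sensor layout on a spherical scalp
#' surface: `n_scalp` electrodes on a spherical cap covering the head down to
#' just below the equator, an explicitly placed frontal-midline electrode
#' named `"Fz"` (at the conventional 10-20 position, ~46 degrees from the
#' vertex towards the nasion), and a left/right mastoid pair (`"M1"`, `"M2"`)
#' below the ears. Coordinates are metres in a head-centred frame:
#' +x right, +y nasion (anterior), +z vertex.
#'
#' @param n_scalp number of scalp electrodes (including Fz); default 128.
#' @param radius scalp sphere radius in metres (default 0.09, child-sized).
#' @return An object of class `eeg_montage`: list with `names` (character),
#'   `pos` (matrix n x 3, metres), `radius`, and indices `fz`, `mastoids`.
#' @examples
#' m <- spherical_montage(32)
#' m$names[m$fz]
#' @export
spherical_montage <- function(n_scalp = 128, radius = 0.09) {
  if (!is_count(n_scalp) || n_scalp < 4)
    stop_cfg("configuration error: n_scalp must be an integer >= 4")
  # Fz at polar angle 46 deg from vertex, on the anterior midline
  th_fz <- 46 * pi / 180
  fz <- radius * c(0, sin(th_fz), cos(th_fz))
  # Fibonacci lattice on a cap reaching 105 deg polar angle (below equator,
  # as high-density nets do), excluding whichever point lands nearest Fz.
  n_gen <- n_scalp - 1L
  k <- seq_len(n_gen + 1L) - 0.5
  cos_max <- cos(105 * pi / 180)
  z <- 1 - (1 - cos_max) * k / (n_gen + 1L)   # cos(theta) from 1 down
  th <- acos(z)
  ga <- pi * (3 - sqrt(5))
  az <- (k * ga) %% (2 * pi)
  pts <- radius * cbind(sin(th) * sin(az), sin(th) * cos(az), z)
  # drop the generated point closest to Fz to keep spacing even
  d2 <- colSums((t(pts) - fz)^2)
  pts <- pts[-which.min(d2), , drop = FALSE][seq_len(n_gen), , drop = FALSE]
  # mastoids: polar 110 deg, behind the ears (azimuth measured from nasion)
  th_m <- 110 * pi / 180
  az_m <- 100 * pi / 180
  m1 <- radius * c(-sin(th_m) * sin(az_m), sin(th_m) * cos(az_m), cos(th_m))
  m2 <- radius * c(+sin(th_m) * sin(az_m), sin(th_m) * cos(az_m), cos(th_m))
  pos <- rbind(fz, pts, M1 = m1, M2 = m2)
  nm <- c("Fz", sprintf("E%03d", seq_len(n_gen)), "M1", "M2")
  rownames(pos) <- nm
  out <- list(names = nm, pos = pos, radius = radius,
              fz = 1L, mastoids = c(n_scalp + 1L, n_scalp + 2L))
  class(out) <- "eeg_montage"
  out
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d scalp + 2 mastoid sensors, scalp radius %.3f m\n",
              length(x$names) - 2L, x$radius))
  invisible(x)
}

n_channels <- function(montage) length(montage$names)

channel_index <- function(montage, name) {
  i <- match(name, montage$names)
  if (is.na(i)) stop_cfg("channel '%s' not present in montage", name)
  i
}
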