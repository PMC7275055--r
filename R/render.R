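#' Render a trace set as a dual-channel image stack
#'
#' Produces a synthetic TIRF movie: each molecule is a 2-D Gaussian
#' point-spread spot, with the donor channel on the left half of the frame
#' and the acceptor channel on the right (related by a pure horizontal
#' translation of half the frame width). A configured fraction of the
#' donor emission (12% by default) leaks into the acceptor-channel spot,
#' reproducing the spectral bleed-through that the alpha factor of
#' [compute_fret()] corrects. Additive background and per-pixel Gaussian
#' noise complete the image model.
#'
#' Spot positions are drawn on a jittered grid inside the left half so
#' that no two spots approach within `min_separation` pixels; if the
#' molecule count exceeds what the grid can hold, an error is raised.
#'
#' @param sim A `fret_sim` from [simulate_traces()] (or a trace tibble).
#' @param ny,nx Image height and full (two-channel) width in pixels.
#' @param psf_sigma Gaussian PSF standard deviation (pixels).
#' @param leakage Fraction of donor intensity added to the acceptor spot.
#' @param background Constant background level per pixel.
#' @param read_noise Per-pixel Gaussian noise SD (0 for noise-free).
#' @param min_separation Minimum spot separation in pixels.
#' @param margin Border (pixels) kept free of spot centres.
#' @param seed RNG seed for positions and pixel noise.
#' @return List of class `fret_movie`: `movie` (array `ny` x `nx` x
#'   frames), `coords` (tibble with 0-based `x`, `y` donor-channel spot
#'   centres per molecule), and the render parameters.
#' @export
render_movie <- function(sim, ny = 64, nx = 128, psf_sigma = 1.1,
                         leakage = 0.12, background = 10, read_noise = 0,
                         min_separation = 6, margin = 10, seed = 1L) {
  traces <- if (inherits(sim, "fret_sim")) sim$traces else sim
  ids <- unique(traces$molecule_id)
  n_mol <- length(ids)
  half <- nx %/% 2
  set.seed(seed)

  # jittered grid placement inside the donor half-image
  gx <- seq(margin, half - 1 - margin, by = min_separation)
  gy <- seq(margin, ny - 1 - margin, by = min_separation)
  if (n_mol > length(gx) * length(gy)) {
    abort("too many molecules to place without overlap at this density")
  }
  grid <- expand.grid(x = gx, y = gy)
  pick <- sample(nrow(grid), n_mol)
  jit <- min_separation / 8   # keeps worst-case spacing above 3/4 of the grid
  coords <- tibble(
    molecule_id = ids,
    x = grid$x[pick] + runif(n_mol, -jit, jit),
    y = grid$y[pick] + runif(n_mol, -jit, jit)
  )

  frames <- sort(unique(traces$frame))
  movie <- array(background, dim = c(ny, nx, length(frames)))
  # unit-sum PSF stamp
  r <- ceiling(4 * psf_sigma)
  dx <- -r:r
  for (m in seq_len(n_mol)) {
    tr <- traces[traces$molecule_id == ids[m], ]
    tr <- tr[order(tr$frame), ]
    x0 <- coords$x[m]
    y0 <- coords$y[m]
    # pixel grid (0-based centres) around the spot in each channel
    px <- round(x0) + dx
    py <- round(y0) + dx
    kx <- dnorm(px, x0, psf_sigma)
    ky <- dnorm(py, y0, psf_sigma)
    stamp <- outer(ky, kx)
    stamp <- stamp / sum(stamp)
    okx <- px >= 0 & px < half
    oky <- py >= 0 & py < ny
    for (f in seq_along(frames)) {
      i_d <- tr$I_D[f]
      i_a <- tr$I_A[f]
      don <- stamp * i_d
      acc <- stamp * (i_a + leakage * i_d)
      movie[py[oky] + 1, px[okx] + 1, f] <-
        movie[py[oky] + 1, px[okx] + 1, f] + don[oky, okx]
      movie[py[oky] + 1, px[okx] + half + 1, f] <-
        movie[py[oky] + 1, px[okx] + half + 1, f] + acc[oky, okx]
    }
  }
  if (read_noise > 0) {
    movie <- movie + array(rnorm(length(movie), 0, read_noise), dim = dim(movie))
  }
  out <- list(movie = movie, coords = coords, ny = ny, nx = nx,
              psf_sigma = psf_sigma, leakage = leakage,
              background = background)
  class(out) <- "fret_movie"
  out
}

#' Write / read a movie as multi-page TIFF
#'
#' Stores the stack as 32-bit float TIFF pages scaled into `[0, 1]` by
#' `scale` (recorded by the caller; the reader multiplies it back).
#'
#' @param movie Numeric array (ny x nx x frames) or a `fret_movie`.
#' @param path Output file.
#' @param scale Intensity corresponding to 1.0 in the file; defaults to
#'   the stack maximum.
#' @return `write_movie_tiff()` returns `scale` invisibly;
#'   `read_movie_tiff()` returns the array.
#' @export
write_movie_tiff <- function(movie, path, scale = NULL) {
  if (inherits(movie, "fret_movie")) movie <- movie$movie
  if (is.null(scale)) scale <- max(movie)
  pages <- lapply(seq_len(dim(movie)[3]), function(f) {
    pmin(pmax(movie[, , f] / scale, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(scale)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- pages[[f]] * scale
  arr
}
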