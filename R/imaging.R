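#' @include AllClasses.R
NULL

# tolerance absorbed when clamping scaled values at +/-1 before arccos
.GADF_CLAMP_TOL <- 1e-9

#' Rescale a series onto [-1, 1]
#'
#' Affine min-max map: the minimum maps to -1 and the maximum to +1, the
#' first step of Gramian angular field encoding. A constant series maps to
#' all zeros (a well-defined choice: arccos(0) = pi/2 gives an all-zero
#' angular difference field).
#'
#' @param series numeric vector, non-empty and finite.
#' @return numeric vector in [-1, 1].
#' @examples
#' rescaleToUnit(c(0, 5, 10))
#' @export
rescaleToUnit <- function(series) {
  if (length(series) == 0L) stop("value error: empty series")
  if (any(!is.finite(series))) stop("value error: series must be finite")
  lo <- min(series)
  hi <- max(series)
  if (hi == lo) return(rep(0, length(series)))
  2 * (series - lo) / (hi - lo) - 1
}

#' Piecewise aggregate approximation
#'
#' Reduces a series of length L to \code{d} segment means. When \code{d}
#' does not divide L, boundary samples contribute fractional weight to the
#' adjacent segments so that every segment covers exactly width L/d (the
#' standard continuous-frame PAA generalization); most schedule dimensions
#' (e.g. 7020 out of 7200) need this.
#'
#' @param series numeric vector.
#' @param d target dimension, \code{1 <= d <= length(series)}.
#' @return numeric vector of length \code{d}; stays within the input range.
#' @examples
#' paa(c(1, 2, 3, 4), 2) # c(1.5, 3.5)
#' @export
paa <- function(series, d) {
  L <- length(series)
  if (d < 1 || d > L) stop("value error: d must satisfy 1 <= d <= length(series)")
  d <- as.integer(d)
  if (d == L) return(series)
  w <- L / d
  # prefix integral of the piecewise-constant series at the segment edges
  S <- c(0, cumsum(series))
  u <- pmin(pmax((0:d) * w, 0), L)
  i <- pmin(as.integer(floor(u)), L - 1L)
  frac <- u - i
  Fz <- S[i + 1L] + frac * series[i + 1L]
  Fz[length(Fz)] <- S[L + 1L] # right edge is exactly the total integral
  diff(Fz) / w
}

#' The PAA dimension schedule
#'
#' The multiscale schedule of target dimensions: starting at the full
#' signal length and decreasing by a fixed step down to the stop value,
#' inclusive. With the defaults (7200, step 180, stop 180) this yields the
#' 40 dimensions 7200, 7020, ..., 180.
#'
#' @param L signal length (every dimension must be <= L).
#' @param start,step,stop schedule parameters; \code{start - stop} must be
#'   divisible by \code{step}.
#' @return integer vector of dimensions, inclusive of both ends.
#' @examples
#' length(paaSchedule()) # 40
#' @export
paaSchedule <- function(L = 7200L, start = 7200L, step = 180L, stop = 180L) {
  start <- as.integer(start); step <- as.integer(step); stop <- as.integer(stop)
  if (stop < 1L || start < stop || step < 1L)
    stop("value error: need start >= stop >= 1 and step >= 1")
  if ((start - stop) %% step != 0L)
    stop("value error: (start - stop) must be divisible by step")
  if (start > L)
    stop("value error: start must not exceed the signal length")
  seq.int(start, stop, by = -step)
}

#' Gramian angular difference field
#'
#' Maps each scaled value onto a polar angle phi = arccos(x) and returns
#' the antisymmetric matrix of pairwise angular difference sines,
#' \deqn{GADF[i, j] = sin(phi_i - phi_j)
#'   = \sqrt{1 - x_i^2}\, x_j - x_i \sqrt{1 - x_j^2}.}
#' The diagonal is exactly zero and all entries lie in [-1, 1].
#'
#' @param series numeric vector with values in [-1, 1] (values within 1e-9
#'   of the boundary are clamped; anything further out is an error).
#' @return a d x d numeric matrix.
#' @examples
#' gadf(c(1, 0)) # matrix(c(0, 1, -1, 0), 2)
#' @export
gadf <- function(series) {
  if (any(abs(series) > 1 + .GADF_CLAMP_TOL))
    stop("domain error: scaled values must lie in [-1, 1]")
  x <- pmin(pmax(series, -1), 1)
  y <- sqrt(1 - x^2)
  m <- outer(y, x) - outer(x, y)
  pmin(pmax(m, -1), 1)
}

# bilinear interpolation matrix (align-corners): nOut x nIn, rows sum to 1
.interp_matrix <- function(nOut, nIn) {
  A <- matrix(0, nOut, nIn)
  if (nIn == 1L) {
    A[, 1] <- 1
    return(A)
  }
  s <- if (nOut == 1L) (nIn - 1) / 2 else (seq_len(nOut) - 1) * (nIn - 1) / (nOut - 1)
  i0 <- pmin(as.integer(floor(s)), nIn - 2L)
  t <- s - i0
  A[cbind(seq_len(nOut), i0 + 1L)] <- 1 - t
  A[cbind(seq_len(nOut), i0 + 2L)] <- A[cbind(seq_len(nOut), i0 + 2L)] + t
  A
}

#' Render a GADF matrix as an RGB image array
#'
#' Maps entries from [-1, 1] to [0, 1] via (v + 1) / 2, resizes to
#' \code{size x size} by bilinear interpolation (identity when the input is
#' already \code{size x size}), and replicates the single channel to RGB.
#' Channel replication rather than a colormap keeps the rendering
#' deterministic and invertible.
#'
#' @param m numeric matrix with entries in [-1, 1].
#' @param size output side length in pixels (default 224).
#' @return a \code{size x size x 3} array with values in [0, 1].
#' @export
renderImage <- function(m, size = 224L) {
  size <- as.integer(size)
  if (size < 1L) stop("value error: size must be >= 1")
  v <- (m + 1) / 2
  Ar <- .interp_matrix(size, nrow(v))
  Ac <- .interp_matrix(size, ncol(v))
  r <- Ar %*% v %*% t(Ac)
  r <- pmin(pmax(r, 0), 1)
  array(r, dim = c(size, size, 3L))
}

#' Convert one record into its GADF image stack
#'
#' For each dimension d in the schedule: rescale the trace to [-1, 1],
#' reduce it to d points by PAA, form the GADF and render it to a
#' \code{size x size} RGB image. With a gap-filled 7200-sample record and
#' the default schedule this yields the 40-image multiscale stack.
#'
#' @param record a gap-filled [FHRRecord-class] (no missing values in
#'   \code{fhrSamples}).
#' @param schedule integer vector of PAA dimensions; default
#'   \code{paaSchedule(length(fhrSamples(record)))}.
#' @param size image side length in pixels (default 224).
#' @return a [GADFStack-class].
#' @examples
#' rec <- fillMissing(generateRecord(0, synthPreset(0, 3), nSamples = 360))
#' st <- recordToStack(rec, schedule = c(360L, 180L), size = 32)
#' nImages(st)
#' @export
recordToStack <- function(record, schedule = NULL, size = 224L) {
  v <- record@samples
  if (any(!is.finite(v)))
    stop("record '", record@recordId,
         "' still has missing samples; run fillMissing() first")
  if (is.null(schedule)) schedule <- paaSchedule(length(v))
  if (any(schedule > length(v)))
    stop("length error: schedule dimensions exceed the record length")
  scaled <- rescaleToUnit(v)
  imgs <- lapply(schedule, function(d) renderImage(gadf(paa(scaled, d)), size))
  new("GADFStack", images = imgs, dims = as.integer(schedule),
      recordId = record@recordId)
}

#' Write a stack to disk
#'
#' \code{format = "ppm"} writes one 8-bit binary PPM raster per image
#' (\code{<recordId>_dim<d>.ppm}) for visual inspection; \code{"rds"}
#' writes a single lossless array container per record for training.
#'
#' @param stack a [GADFStack-class].
#' @param dir output directory.
#' @param format \code{"ppm"} or \code{"rds"}.
#' @return paths written, invisibly.
#' @export
writeStack <- function(stack, dir, format = c("rds", "ppm")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "rds") {
    p <- file.path(dir, paste0(stack@recordId, "_stack.rds"))
    saveRDS(list(recordId = stack@recordId, dims = stack@dims,
                 images = stack@images), p)
    return(invisible(p))
  }
  paths <- character(length(stack@images))
  for (k in seq_along(stack@images)) {
    p <- file.path(dir, sprintf("%s_dim%d.ppm", stack@recordId,
                                stack@dims[k]))
    .write_ppm(stack@images[[k]], p)
    paths[k] <- p
  }
  invisible(paths)
}

#' Read a stack written by \code{writeStack(format = "rds")}
#' @param path the \code{*_stack.rds} file.
#' @return a [GADFStack-class].
#' @export
readStack <- function(path) {
  x <- readRDS(path)
  new("GADFStack", images = x$images, dims = as.integer(x$dims),
      recordId = x$recordId)
}

# 8-bit binary PPM (P6); image is height x width x 3 in [0, 1]
.write_ppm <- function(img, path) {
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- as.integer(round(pmin(pmax(img, 0), 1) * 255))
  # interleave channels per pixel, row-major
  rgb <- array(px, dim(img))
  ord <- as.vector(aperm(rgb, c(3, 2, 1))) # channel fastest, then column
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
  writeBin(as.raw(ord), con)
  invisible(path)
}
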