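#' Rasterize a localization set to a local-density grid
#'
#' Bins molecule coordinates onto a square-pixel grid and converts counts to
#' local densities (molecules per nm^2), the discrete form of the local
#' density field entering the pair cross-correlation.  Mass is conserved:
#' `sum(values) * pixel_size_nm^2` equals the number of points.
#'
#' @param points data.frame with `x_nm`, `y_nm` (or a 2-column matrix).
#' @param pixel_size_nm pixel side, nm.
#' @param bounds `c(xmin, xmax, ymin, ymax)`; must cover all points.
#' @return a `density_grid`: list with `values` (matrix, rows = x bins),
#'   `pixel_size_nm`, `origin` and `n_points`.
#' @export
rasterize_density <- function(points, pixel_size_nm, bounds) {
  stopifnot(pixel_size_nm > 0, length(bounds) == 4)
  if (is.matrix(points)) points <- data.frame(x_nm = points[, 1],
                                              y_nm = points[, 2])
  nx <- max(1L, as.integer(ceiling((bounds[2] - bounds[1]) / pixel_size_nm)))
  ny <- max(1L, as.integer(ceiling((bounds[4] - bounds[3]) / pixel_size_nm)))
  n <- nrow(points)
  vals <- matrix(0, nx, ny)
  if (n > 0) {
    if (any(points$x_nm < bounds[1] | points$x_nm > bounds[2] |
            points$y_nm < bounds[3] | points$y_nm > bounds[4]))
      stop("points outside bounds")
    ix <- pmin(nx, 1L + as.integer((points$x_nm - bounds[1]) / pixel_size_nm))
    iy <- pmin(ny, 1L + as.integer((points$y_nm - bounds[3]) / pixel_size_nm))
    tab <- table(factor(ix, levels = seq_len(nx)),
                 factor(iy, levels = seq_len(ny)))
    vals <- matrix(as.numeric(tab), nx, ny) / pixel_size_nm^2
  }
  structure(list(values = vals, pixel_size_nm = pixel_size_nm,
                 origin = c(bounds[1], bounds[3]), n_points = n),
            class = "density_grid")
}

#' Pair cross-correlation of two density grids
#'
#' Computes the fluctuation cross-correlation between two local-density
#' images: at displacement r, c(r) is the mean over valid (non-wrapped)
#' overlapping pixels of the product of density fluctuations,
#' `(rho1 - <rho1>) * (rho2 - <rho2>)`, normalized by the product of the
#' full-grid mean densities.  Two independent species give c(r) ~ 0; values
#' above 0 at short range quantify colocalization.  The boundary is cropped
#' to the valid overlap (no periodic wrap-around), so per-displacement means
#' use only pixels where both shifted images exist.
#'
#' @param g1,g2 `density_grid`s of identical shape and pixel size.
#' @param max_shift_px maximum displacement in pixels in each axis.
#' @param method `"fft"` (zero-padded FFT, default) or `"direct"` (explicit
#'   double loop over pixels; the slow reference evaluation).
#' @return a `crosscorr_2d`: list with `c` ((2m+1) x (2m+1) matrix),
#'   `dx_px`, `dy_px` and `pixel_size_nm`.
#' @export
cross_correlation_2d <- function(g1, g2, max_shift_px,
                                 method = c("fft", "direct")) {
  method <- match.arg(method)
  stopifnot(inherits(g1, "density_grid"), inherits(g2, "density_grid"))
  if (!identical(dim(g1$values), dim(g2$values)))
    stop("grids must share shape")
  if (g1$pixel_size_nm != g2$pixel_size_nm)
    stop("grids must share pixel size")
  m1 <- mean(g1$values); m2 <- mean(g2$values)
  if (m1 <= 0 || m2 <= 0) stop("empty channel")
  d1 <- g1$values - m1
  d2 <- g2$values - m2
  nr <- nrow(d1); nc <- ncol(d1)
  m <- as.integer(max_shift_px)
  stopifnot(m >= 0, m < nr, m < nc)
  shifts <- (-m):m
  cc <- matrix(NA_real_, 2 * m + 1, 2 * m + 1)

  if (method == "direct") {
    for (a in seq_along(shifts)) {
      dx <- shifts[a]
      for (b in seq_along(shifts)) {
        dy <- shifts[b]
        s <- 0; n <- 0L
        for (i in seq_len(nr)) {
          ii <- i + dx
          if (ii < 1L || ii > nr) next
          for (j in seq_len(nc)) {
            jj <- j + dy
            if (jj < 1L || jj > nc) next
            s <- s + d1[i, j] * d2[ii, jj]
            n <- n + 1L
          }
        }
        cc[a, b] <- (s / n) / (m1 * m2)
      }
    }
  } else {
    # zero-padded FFT cross-correlation of the fluctuation fields, with the
    # valid-overlap pixel count recovered analytically for a full rectangle
    pr <- nr + m; pc <- nc + m
    p1 <- matrix(0, pr, pc); p2 <- matrix(0, pr, pc)
    p1[seq_len(nr), seq_len(nc)] <- d1
    p2[seq_len(nr), seq_len(nc)] <- d2
    corr <- Re(fft(Conj(fft(p1)) * fft(p2), inverse = TRUE)) / (pr * pc)
    for (a in seq_along(shifts)) {
      dx <- shifts[a]
      ia <- ((dx %% pr)) + 1L
      for (b in seq_along(shifts)) {
        dy <- shifts[b]
        jb <- ((dy %% pc)) + 1L
        n_overlap <- (nr - abs(dx)) * (nc - abs(dy))
        cc[a, b] <- (corr[ia, jb] / n_overlap) / (m1 * m2)
      }
    }
  }
  structure(list(c = cc, dx_px = shifts, dy_px = shifts,
                 pixel_size_nm = g1$pixel_size_nm),
            class = "crosscorr_2d")
}

#' Angular average of a 2D cross-correlation
#'
#' Averages c(dx, dy) over displacement angle within concentric annuli of
#' width `r_bin_nm`, yielding the correlation profile c(r) as a function of
#' radial distance.  Annuli that capture no displacement sample are kept with
#' `n = 0` and `c = NA` rather than zero-filled.
#'
#' @param c2d a `crosscorr_2d`.
#' @param r_bin_nm radial bin width, nm (default: one pixel).
#' @return a `radial_profile` data.frame: `r_nm` (bin centers, strictly
#'   increasing), `c`, `n`.
#' @export
radial_average <- function(c2d, r_bin_nm = c2d$pixel_size_nm) {
  stopifnot(inherits(c2d, "crosscorr_2d"), r_bin_nm > 0)
  px <- c2d$pixel_size_nm
  r <- outer(c2d$dx_px, c2d$dy_px, function(dx, dy) sqrt(dx^2 + dy^2) * px)
  bin <- floor(r / r_bin_nm)
  n_bins <- max(bin) + 1L
  idx <- factor(bin, levels = 0:(n_bins - 1L))
  n <- as.integer(table(idx))
  sums <- tapply(as.vector(c2d$c), idx, sum)
  prof <- data.frame(
    r_nm = (0:(n_bins - 1L) + 0.5) * r_bin_nm,
    c = ifelse(n > 0, as.numeric(sums) / n, NA_real_),
    n = n
  )
  class(prof) <- c("radial_profile", "data.frame")
  prof
}

#' Scalar association magnitude of a radial correlation profile
#'
#' Summarizes a radial profile as the mean of c(r) over populated bins with
#' center radius at most `r_max_nm` — the declared convention for the scalar
#' "association magnitude" of one ROI pair.
#'
#' @param profile a `radial_profile`.
#' @param r_max_nm upper radius of the summary window, nm.
#' @return single numeric magnitude.
#' @export
correlation_magnitude <- function(profile, r_max_nm = 200) {
  keep <- profile$r_nm <= r_max_nm & profile$n > 0
  if (!any(keep)) stop("no populated radial bins within r_max_nm")
  mean(profile$c[keep])
}

# full per-ROI-pair pipeline: rasterize both channels on a shared grid and
# reduce to the scalar magnitude
roi_pair_magnitude <- function(pts1, pts2, bounds, pixel_size_nm,
                               max_shift_px, r_max_nm) {
  g1 <- rasterize_density(pts1, pixel_size_nm, bounds)
  g2 <- rasterize_density(pts2, pixel_size_nm, bounds)
  prof <- radial_average(cross_correlation_2d(g1, g2, max_shift_px))
  correlation_magnitude(prof, r_max_nm)
}

#' Experimental per-ROI association magnitudes
#'
#' Runs the full colocalization pipeline (rasterization, pair
#' cross-correlation, angular averaging, scalar summary) on each ROI's two
#' channels.
#'
#' @param rois per-ROI channel pairs as produced by [gen_smlm_rois()].
#' @param pixel_size_nm raster pixel size, nm.
#' @param r_max_nm radius defining the scalar magnitude window.
#' @param max_shift_px maximum displacement in pixels (default: enough to
#'   cover `r_max_nm`).
#' @return data.frame `roi_id`, `group = "experimental"`, `magnitude`.
#' @export
smlm_experimental <- function(rois, pixel_size_nm = 20, r_max_nm = 200,
                              max_shift_px = ceiling(r_max_nm /
                                                       pixel_size_nm)) {
  mags <- vapply(rois, function(r) {
    bounds <- c(r$bounds[1], r$bounds[2], r$bounds[1], r$bounds[2])
    roi_pair_magnitude(r$channels$ch1, r$channels$ch2, bounds,
                       pixel_size_nm, max_shift_px, r_max_nm)
  }, numeric(1))
  data.frame(roi_id = vapply(rois, `[[`, character(1), "roi_id"),
             group = "experimental", magnitude = mags,
             stringsAsFactors = FALSE)
}

#' Randomized cross-ROI control magnitudes
#'
#' Pairs channel 1 of each ROI with channel 2 of a *different* ROI, the
#' standard randomization null for localization colocalization: cross-ROI
#' pairs describe what the correlation looks like for random distributions.
#' `scheme = "derangement"` samples a single seeded fixed-point-free
#' permutation (one control pair per ROI, balancing group sizes);
#' `scheme = "all"` enumerates every ordered cross pair.
#'
#' @param rois per-ROI channel pairs.
#' @param scheme `"derangement"` or `"all"`.
#' @param seed integer seed (derangement sampling).
#' @inheritParams smlm_experimental
#' @return data.frame `roi_id` ("<i>x<j>"), `group = "randomized"`,
#'   `magnitude`.
#' @export
randomized_control <- function(rois, scheme = c("derangement", "all"),
                               seed = 1, pixel_size_nm = 20, r_max_nm = 200,
                               max_shift_px = ceiling(r_max_nm /
                                                        pixel_size_nm)) {
  scheme <- match.arg(scheme)
  n <- length(rois)
  if (n < 2) stop("randomization impossible with a single ROI")
  pairs <- if (scheme == "all") {
    idx <- expand.grid(i = seq_len(n), j = seq_len(n))
    idx[idx$i != idx$j, , drop = FALSE]
  } else {
    set.seed(substream_seed(seed, "derangement"))
    repeat {
      p <- sample.int(n)
      if (all(p != seq_len(n))) break
    }
    data.frame(i = seq_len(n), j = p)
  }
  mags <- mapply(function(i, j) {
    # common bounding box covering both ROIs' coordinate frames
    b1 <- rois[[i]]$bounds; b2 <- rois[[j]]$bounds
    lo <- min(b1[1], b2[1]); hi <- max(b1[2], b2[2])
    roi_pair_magnitude(rois[[i]]$channels$ch1, rois[[j]]$channels$ch2,
                       c(lo, hi, lo, hi), pixel_size_nm, max_shift_px,
                       r_max_nm)
  }, pairs$i, pairs$j)
  data.frame(
    roi_id = sprintf("%sx%s", vapply(rois[pairs$i], `[[`, character(1),
                                     "roi_id"),
                     vapply(rois[pairs$j], `[[`, character(1), "roi_id")),
    group = "randomized", magnitude = mags, stringsAsFactors = FALSE)
}

#' Compare experimental and randomized association magnitudes
#'
#' Welch-form unpaired two-sample t-test (two-sided) between experimental and
#' randomized magnitudes, with per-group means and standard errors.
#'
#' @param exp,rnd numeric vectors of magnitudes (or data frames with a
#'   `magnitude` column).
#' @return list with `t`, `p`, `mean_exp`, `sem_exp`, `mean_rnd`, `sem_rnd`,
#'   `n_exp`, `n_rnd`.
#' @export
compare_exp_vs_random <- function(exp, rnd) {
  if (is.data.frame(exp)) exp <- exp$magnitude
  if (is.data.frame(rnd)) rnd <- rnd$magnitude
  stopifnot(length(exp) >= 2, length(rnd) >= 2)
  if (sd(exp) == 0 && sd(rnd) == 0) {
    # degenerate: no variance anywhere; equal means are maximally consistent
    t_stat <- 0
    p <- if (mean(exp) == mean(rnd)) 1 else 0
  } else {
    tt <- t.test(exp, rnd, var.equal = FALSE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  list(t = t_stat, p = p,
       mean_exp = mean(exp), sem_exp = sd(exp) / sqrt(length(exp)),
       mean_rnd = mean(rnd), sem_rnd = sd(rnd) / sqrt(length(rnd)),
       n_exp = length(exp), n_rnd = length(rnd))
}
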