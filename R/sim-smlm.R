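#' Simulate two-channel single-molecule localization ROIs
#'
#' Generates per-nucleus regions of interest (axis-aligned squares of side
#' `roi_size_nm`) containing two localization channels, emulating two imaged
#' species (e.g. a chromatin protein and metabolically labelled RNA).  Each
#' channel receives `n_clusters` Gaussian clusters of molecules plus a uniform
#' background.  A fraction `co_fraction` of the clusters share their centers
#' between the two channels (true colocalization); the rest are
#' channel-private.  With `co_fraction = 0` the channels are statistically
#' independent, so the pair cross-correlation is centered on zero.
#'
#' @param n_rois number of ROIs (nuclei) to simulate.
#' @param roi_size_nm side of the square ROI, nm.
#' @param n_bg_per_channel uniform background molecules per channel.
#' @param n_clusters clusters per channel.
#' @param cluster_sigma_nm Gaussian cluster spread (sd), nm.
#' @param co_fraction fraction of clusters with shared centers in `[0, 1]`.
#' @param points_per_cluster molecules drawn per cluster.
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `rois` (a list of per-ROI records: `roi_id`, `bounds`
#'   `c(0, roi_size_nm)`, and `channels`, two data frames of `x_nm`, `y_nm`)
#'   and `truth` (data.frame of `roi_id`, `co_fraction`, `n_shared_clusters`).
#' @export
gen_smlm_rois <- function(n_rois, roi_size_nm = 2000, n_bg_per_channel = 200,
                          n_clusters = 40, cluster_sigma_nm = 30,
                          co_fraction = 0.5, points_per_cluster = 25,
                          seed = 1) {
  if (roi_size_nm <= 0) stop("ROI size must be positive")
  if (n_rois < 1) stop("need at least one ROI")
  if (n_bg_per_channel < 0 || n_clusters < 0 || points_per_cluster < 0)
    stop("counts must be non-negative")
  if (co_fraction < 0 || co_fraction > 1) stop("co_fraction must be in [0, 1]")
  if (cluster_sigma_nm <= 0) stop("cluster_sigma_nm must be positive")

  set.seed(substream_seed(seed, "smlm"))
  n_shared <- round(co_fraction * n_clusters)

  sample_channel <- function(centers) {
    n_pts <- nrow(centers) * points_per_cluster
    pts <- if (n_pts > 0) {
      cx <- rep(centers$x, each = points_per_cluster)
      cy <- rep(centers$y, each = points_per_cluster)
      data.frame(x_nm = rnorm(n_pts, cx, cluster_sigma_nm),
                 y_nm = rnorm(n_pts, cy, cluster_sigma_nm))
    } else data.frame(x_nm = numeric(0), y_nm = numeric(0))
    bg <- data.frame(x_nm = runif(n_bg_per_channel, 0, roi_size_nm),
                     y_nm = runif(n_bg_per_channel, 0, roi_size_nm))
    out <- rbind(pts, bg)
    # clusters near the edge can spill out; reflect back inside the ROI
    out$x_nm <- pmin(pmax(out$x_nm, 0), roi_size_nm)
    out$y_nm <- pmin(pmax(out$y_nm, 0), roi_size_nm)
    out
  }

  rois <- vector("list", n_rois)
  for (i in seq_len(n_rois)) {
    shared <- data.frame(x = runif(n_shared, 0, roi_size_nm),
                         y = runif(n_shared, 0, roi_size_nm))
    priv1 <- data.frame(x = runif(n_clusters - n_shared, 0, roi_size_nm),
                        y = runif(n_clusters - n_shared, 0, roi_size_nm))
    priv2 <- data.frame(x = runif(n_clusters - n_shared, 0, roi_size_nm),
                        y = runif(n_clusters - n_shared, 0, roi_size_nm))
    rois[[i]] <- list(
      roi_id = sprintf("roi%03d", i),
      bounds = c(0, roi_size_nm),
      channels = list(ch1 = sample_channel(rbind(shared, priv1)),
                      ch2 = sample_channel(rbind(shared, priv2)))
    )
  }
  truth <- data.frame(
    roi_id = vapply(rois, `[[`, character(1), "roi_id"),
    co_fraction = co_fraction,
    n_shared_clusters = n_shared,
    stringsAsFactors = FALSE
  )
  list(rois = rois, truth = truth)
}

#' Flatten simulated ROIs to a localization table
#'
#' @param rois the `rois` element of [gen_smlm_rois()].
#' @return data.frame `roi_id`, `channel`, `x_nm`, `y_nm` (the on-disk CSV
#'   layout).
#' @export
smlm_locs_table <- function(rois) {
  do.call(rbind, lapply(rois, function(r) {
    do.call(rbind, lapply(names(r$channels), function(ch) {
      pts <- r$channels[[ch]]
      if (nrow(pts) == 0)
        return(data.frame(roi_id = character(0), channel = character(0),
                          x_nm = numeric(0), y_nm = numeric(0)))
      data.frame(roi_id = r$roi_id, channel = ch,
                 x_nm = pts$x_nm, y_nm = pts$y_nm, stringsAsFactors = FALSE)
    }))
  }))
}
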