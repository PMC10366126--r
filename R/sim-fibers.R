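#' Simulate stretched-DNA fiber measurements
#'
#' Emulates dual-pulse (CldU then IdU) fiber assays: each fiber carries one
#' measured CldU and one IdU segment whose expected length in micrometers is
#' `fork_speed_kb_min * pulse_min / kb_per_um`, with multiplicative Gaussian
#' noise of relative sd `noise`.  A subset of fibers additionally carries
#' `n_origins` initiation events whose spacings (in kb) are exponential with
#' mean `spacing_mean_kb`; origin positions are recorded in micrometers along
#' the fiber.
#'
#' @param n_tracks number of fibers with measurable fork segments.
#' @param fork_speed_kb_min true fork speed, kb/min.
#' @param pulse_min label pulse duration, min.
#' @param n_origins origins per origin-bearing fiber (>= 2 yields spacings).
#' @param n_origin_fibers number of origin-bearing fibers.
#' @param spacing_mean_kb mean inter-origin distance, kb.
#' @param noise relative measurement noise (0 = exact).
#' @param kb_per_um stretching conversion factor, kb per micrometer.
#' @param seed integer seed.
#' @return list with `fibers` (data.frame `fiber_id`, `cldu_um`, `idu_um`),
#'   `origins` (data.frame `fiber_id`, `position_um`, ordered along each
#'   fiber) and `truth` (list of the generating parameters).
#' @export
gen_fiber_measurements <- function(n_tracks = 150, fork_speed_kb_min = 1.0,
                                   pulse_min = 20, n_origins = 3,
                                   n_origin_fibers = 50,
                                   spacing_mean_kb = 100, noise = 0.1,
                                   kb_per_um = 2.59, seed = 1) {
  stopifnot(fork_speed_kb_min > 0, pulse_min > 0, spacing_mean_kb > 0,
            noise >= 0, kb_per_um > 0)
  set.seed(substream_seed(seed, "fibers"))
  mean_um <- fork_speed_kb_min * pulse_min / kb_per_um
  jitter <- function(n) if (noise > 0) pmax(1 + rnorm(n, 0, noise), 0.05)
  else rep(1, n)
  fibers <- data.frame(
    fiber_id = sprintf("f%04d", seq_len(n_tracks)),
    cldu_um = mean_um * jitter(n_tracks),
    idu_um = mean_um * jitter(n_tracks),
    stringsAsFactors = FALSE
  )
  origins <- NULL
  if (n_origin_fibers > 0 && n_origins > 0) {
    rows <- vector("list", n_origin_fibers)
    for (i in seq_len(n_origin_fibers)) {
      gaps_kb <- rexp(max(n_origins - 1, 0), rate = 1 / spacing_mean_kb)
      pos_um <- cumsum(c(0, gaps_kb)) / kb_per_um
      rows[[i]] <- data.frame(fiber_id = sprintf("of%04d", i),
                              position_um = pos_um, stringsAsFactors = FALSE)
    }
    origins <- do.call(rbind, rows)
  } else {
    origins <- data.frame(fiber_id = character(0), position_um = numeric(0))
  }
  list(fibers = fibers, origins = origins,
       truth = list(fork_speed_kb_min = fork_speed_kb_min,
                    pulse_min = pulse_min, spacing_mean_kb = spacing_mean_kb,
                    kb_per_um = kb_per_um))
}
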