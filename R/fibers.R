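#' Replication fork rate from an IdU track length
#'
#' Converts a measured IdU segment length (micrometers of stretched DNA) to
#' a fork rate in kb/min: `length * kb_per_um / pulse_min`, using the
#' standard stretching factor of 2.59 kb per micrometer and the duration of
#' the IdU pulse.
#'
#' @param idu_length_um measured IdU track length(s), micrometers (> 0).
#' @param pulse_min pulse duration, minutes (> 0).
#' @param kb_per_um stretching conversion factor.
#' @return fork rate(s), kb/min.
#' @export
fork_rate <- function(idu_length_um, pulse_min = 20, kb_per_um = 2.59) {
  if (any(idu_length_um <= 0)) stop("track lengths must be positive")
  if (pulse_min <= 0 || kb_per_um <= 0)
    stop("pulse and conversion factor must be positive")
  idu_length_um * kb_per_um / pulse_min
}

#' Inter-origin distances along fibers
#'
#' Distances between adjacent initiation events on each fiber, converted to
#' kb.  Fibers with fewer than two origins contribute no distance.  Origin
#' positions must already be ordered along each fiber.
#'
#' @param origins data.frame with `fiber_id` and `position_um` (ordered
#'   within fiber).
#' @param kb_per_um stretching conversion factor.
#' @return numeric vector of inter-origin distances, kb.
#' @export
inter_origin_distances <- function(origins, kb_per_um = 2.59) {
  out <- numeric(0)
  for (f in unique(origins$fiber_id)) {
    pos <- origins$position_um[origins$fiber_id == f]
    if (is.unsorted(pos)) stop("unordered origin positions on fiber ", f)
    if (length(pos) >= 2) out <- c(out, diff(pos) * kb_per_um)
  }
  out
}

#' Compare two fiber measurement groups
#'
#' Unpaired two-tailed Mann-Whitney U (Wilcoxon rank-sum) test between two
#' groups of fiber metrics (fork rates or inter-origin distances): exact for
#' combined n <= 20 without ties, normal approximation with tie correction
#' otherwise.  Medians are reported per group.
#'
#' @param group_a,group_b numeric vectors; at least one of length >= 2.
#' @return list with `u` (U statistic for group A), `p`, `median_a`,
#'   `median_b`, `n_a`, `n_b`.
#' @export
compare_fiber_groups <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) stop("empty group")
  if (length(group_a) < 2 && length(group_b) < 2)
    stop("at least one group needs n >= 2")
  exact <- (length(group_a) + length(group_b) <= 20) &&
    !anyDuplicated(c(group_a, group_b))
  wt <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = !exact))
  list(u = unname(wt$statistic), p = wt$p.value,
       median_a = median(group_a), median_b = median(group_b),
       n_a = length(group_a), n_b = length(group_b))
}
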