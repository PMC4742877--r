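# Tempo-changing pacing sequences for the temporal-prediction tapping task.
#
# Inter-onset intervals (IOIs) ride a sinusoid between 400 and 600 ms:
# IOI = 500 + 100 * sin(phi).  The phase phi is advanced by a variable
# amount each event so that successive IOI steps stay within 11..64 ms
# (a fixed advance would produce vanishing steps near the sinusoid's
# turning points).  Six arrangements differ only in the placement of switch
# points at which the direction of the phase advance flips, changing where
# accelerations become decelerations.

# switch times in seconds within the 40-s sequence, one set per arrangement
.pacing_switch_points <- list(
  c(8, 16, 24, 32),
  c(5, 15, 25, 35),
  c(10, 20, 30),
  c(6, 14, 26, 34),
  c(12, 24, 36),
  c(7, 18, 29)
)

#' Generate a tempo-changing pacing sequence
#'
#' @param arrangement_id Integer 1..6 selecting the switch-point layout.
#' @param seed Integer seed; the same `(arrangement_id, seed)` pair always
#'   yields the same sequence.
#' @param duration_s Target sequence duration in seconds (default 40).
#' @param phase_switch_points Optional numeric vector of switch times (s)
#'   overriding the arrangement's default; must lie inside the sequence
#'   duration.
#' @param ioi_center_ms,ioi_depth_ms Sinusoid center and half-range of the
#'   IOIs (defaults 500 and 100, i.e. IOIs in 400..600 ms).
#' @param step_range_ms Admissible range of successive IOI differences
#'   (default `c(11, 64)`).
#'
#' @return An object of class `pacing_sequence`: list with `onsets_ms`
#'   (first onset at 0), `iois_ms` (length `length(onsets_ms) - 1`),
#'   `arrangement_id`, `duration_s`, `seed`.
#' @export
#' @examples
#' p <- generate_pacing_sequence(1, seed = 42)
#' range(p$iois_ms)        # within 400..600
#' range(abs(diff(p$iois_ms)))  # within 11..64
generate_pacing_sequence <- function(arrangement_id, seed,
                                     duration_s = 40,
                                     phase_switch_points = NULL,
                                     ioi_center_ms = 500,
                                     ioi_depth_ms = 100,
                                     step_range_ms = c(11, 64)) {
  if (!arrangement_id %in% 1:6) stop("arrangement_id must be in 1..6")
  switches <- phase_switch_points
  if (is.null(switches)) switches <- .pacing_switch_points[[arrangement_id]]
  if (any(switches <= 0 | switches >= duration_s))
    stop("switch points must lie strictly inside the sequence duration")

  ioi_of <- function(phi) ioi_center_ms + ioi_depth_ms * sin(phi)
  smin <- step_range_ms[1]; smax <- step_range_ms[2]

  iois <- with_seed(seed + arrangement_id * 1000L, {
    phi <- stats::runif(1, 0, 2 * pi)
    dir <- sample(c(-1, 1), 1)
    out <- ioi_of(phi)
    t_ms <- 0
    switches_ms <- sort(switches) * 1000
    next_switch <- 1L
    while (t_ms < duration_s * 1000) {
      # flip the phase-advance direction at switch points
      if (next_switch <= length(switches_ms) && t_ms >= switches_ms[next_switch]) {
        dir <- -dir
        next_switch <- next_switch + 1L
      }
      cur <- out[length(out)]
      # nominal phase advance, jittered; extended when the step would be
      # too small (vaulting the sinusoid's turning point), shrunk by
      # bisection when too large
      dphi <- stats::runif(1, 0.40, 0.60)
      step <- function(d) abs(ioi_of(phi + dir * d) - cur)
      if (step(dphi) < smin) {
        while (step(dphi) < smin && dphi < 4 * pi) dphi <- dphi + 0.02
      } else if (step(dphi) > smax) {
        lo <- 0; hi <- dphi
        for (i in 1:60) {
          mid <- (lo + hi) / 2
          if (step(mid) > smax) hi <- mid else lo <- mid
          if (step(mid) >= smin && step(mid) <= smax) { dphi <- mid; break }
        }
      }
      phi <- phi + dir * dphi
      nxt <- ioi_of(phi)
      t_ms <- t_ms + nxt
      out <- c(out, nxt)
    }
    out
  })
  # iois[1] was only the sinusoid's starting point, not an interval
  iois <- iois[-1]
  structure(
    list(onsets_ms = cumsum(c(0, iois)), iois_ms = iois,
         arrangement_id = arrangement_id, duration_s = sum(iois) / 1000,
         seed = seed),
    class = "pacing_sequence"
  )
}

#' @export
print.pacing_sequence <- function(x, ...) {
  cat(sprintf(
    "<pacing_sequence: arrangement %d, %d onsets over %.1f s, IOI %.0f-%.0f ms>\n",
    x$arrangement_id, length(x$onsets_ms), x$duration_s,
    min(x$iois_ms), max(x$iois_ms)))
  invisible(x)
}

#' Write a pacing sequence as CSV
#'
#' Columns `onset_ms`, `ioi_ms` (the interval ending at each onset; NA for
#' the first).
#' @param pacing A `pacing_sequence`.
#' @param path Output file path.
#' @export
write_pacing_csv <- function(pacing, path) {
  stopifnot(inherits(pacing, "pacing_sequence"))
  utils::write.csv(
    data.frame(onset_ms = pacing$onsets_ms,
               ioi_ms = c(NA, pacing$iois_ms)),
    path, row.names = FALSE)
  invisible(path)
}
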