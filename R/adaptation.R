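#' Adapted per-click effective amplitudes
#'
#' Runs the deterministic sensory-adaptation dynamics over a merged left/right
#' click train and returns the effective amplitude each click delivers. The
#' adaptation state C starts unadapted at 1 and is shared across both
#' streams. Between clicks it relaxes towards 1 with time constant
#' \code{tau_phi}; closed form over a gap \eqn{\Delta t}:
#' \deqn{C(t + \Delta t) = 1 - (1 - C(t)) e^{-\Delta t / \tau_\phi}.}
#' A click at time \eqn{t_k} is delivered with amplitude \eqn{C(t_k^-)}, and
#' immediately afterwards \eqn{C \leftarrow \phi\, C(t_k^-)}, so the
#' multiplication affects only subsequent clicks. \code{phi} < 1 therefore
#' depresses (all amplitudes \eqn{\le} 1), \code{phi} > 1 facilitates.
#'
#' Exactly simultaneous left and right clicks are processed deterministically
#' left-then-right and flagged in the output so callers may treat them
#' specially (e.g. cancel them).
#'
#' @param left_clicks,right_clicks sorted numeric vectors of click times (s).
#' @param phi adaptation multiplier (>= 0).
#' @param tau_phi recovery time constant (s, > 0).
#' @return A data frame of class \code{adapted_clicks} with columns
#'   \code{time}, \code{side} (-1 left, +1 right), \code{amplitude} and
#'   \code{simultaneous}.
#' @export
adapt_clicks <- function(left_clicks, right_clicks, phi, tau_phi) {
  if (!is.numeric(phi) || phi < 0) stop("adapt_clicks: phi must be >= 0")
  if (!is.numeric(tau_phi) || tau_phi <= 0)
    stop("adapt_clicks: tau_phi must be > 0")
  if (is.unsorted(left_clicks) || is.unsorted(right_clicks))
    stop("adapt_clicks: click times must be sorted ascending")

  times <- c(left_clicks, right_clicks)
  side <- c(rep(-1L, length(left_clicks)), rep(1L, length(right_clicks)))
  if (length(times) == 0L) {
    return(structure(data.frame(time = numeric(0), side = integer(0),
                                amplitude = numeric(0),
                                simultaneous = logical(0)),
                     class = c("adapted_clicks", "data.frame")))
  }
  o <- order(times, side)      # ties: left (-1) before right (+1)
  times <- times[o]
  side <- side[o]

  n <- length(times)
  amp <- numeric(n)
  C <- 1
  t_prev <- 0
  for (k in seq_len(n)) {
    dt <- times[k] - t_prev
    C <- 1 - (1 - C) * exp(-dt / tau_phi)
    amp[k] <- C
    C <- phi * C
    t_prev <- times[k]
  }
  simult <- rep(FALSE, n)
  if (n > 1L) {
    same <- which(diff(times) == 0 & side[-n] != side[-1L])
    simult[same] <- TRUE
    simult[same + 1L] <- TRUE
  }
  structure(data.frame(time = times, side = side, amplitude = amp,
                       simultaneous = simult),
            class = c("adapted_clicks", "data.frame"))
}
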