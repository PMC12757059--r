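#' Double-exponential synaptic kernel
#'
#' \deqn{\eta(t) = \frac{e^{-t/\tau_d} - e^{-t/\tau_r}}{\tau_d - \tau_r},
#'   \quad t \ge 0,}
#' normalised to unit integral. The peak sits at
#' \eqn{t^* = \tau_r\tau_d \log(\tau_d/\tau_r)/(\tau_d - \tau_r)}.
#'
#' @param t times, ms (values < 0 give 0).
#' @param tau_r,tau_d rise and decay time constants, ms (`tau_d != tau_r`).
#' @return kernel values, 1/ms.
#' @export
synaptic_kernel <- function(t, tau_r, tau_d) {
  if (tau_d == tau_r) stop("degenerate kernel: tau_d must differ from tau_r")
  ifelse(t >= 0, (exp(-t / tau_d) - exp(-t / tau_r)) / (tau_d - tau_r), 0)
}

#' Filter a spike train with a synaptic kernel
#'
#' Causal convolution of a spike train with [synaptic_kernel()], evaluated
#' on a regular time grid by the exact closed form (sum of exponentials per
#' spike), matching the state-filter implementation in the network
#' integrator.
#'
#' @param spike_times spike times, ms.
#' @param tau_r,tau_d kernel time constants, ms.
#' @param dt grid step, ms.
#' @param T trace duration, ms.
#' @return numeric vector of length `round(T/dt)`, the current trace (1/ms
#'   units; multiply by a weight in mV for mV/ms).
#' @export
kernel_filter <- function(spike_times, tau_r, tau_d, dt, T) {
  if (tau_d == tau_r) stop("degenerate kernel: tau_d must differ from tau_r")
  grid <- (seq_len(round(T / dt)) - 1) * dt
  out <- numeric(length(grid))
  for (ts in spike_times) {
    lag <- grid - ts
    out <- out + synaptic_kernel(lag, tau_r, tau_d)
  }
  out
}
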