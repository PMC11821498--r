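#' Echo schedule of a multi-echo decay experiment
#'
#' Constructs the sampled echo times of a multi-echo (CPMG/GRASE-style)
#' acquisition: `n_echoes` echoes starting at `te_initial` with constant
#' spacing `te_spacing`, all in milliseconds. The specimen protocol this
#' package emulates used 24 echoes with a 13 ms initial echo time and 13 ms
#' spacing, so that is the default.
#'
#' @param n_echoes Number of echoes (integer, at least 2).
#' @param te_initial First echo time in ms (> 0).
#' @param te_spacing Echo spacing in ms (> 0).
#'
#' @return An object of class `echo_schedule`: a list with fields
#'   `n_echoes`, `te_initial`, `te_spacing`.
#' @seealso [echo_times()]
#' @export
#' @examples
#' sched <- echo_schedule()
#' echo_times(sched)
echo_schedule <- function(n_echoes = 24, te_initial = 13, te_spacing = 13) {
  if (length(n_echoes) != 1 || !is.finite(n_echoes) || n_echoes < 2 ||
      n_echoes != as.integer(n_echoes)) {
    stop("`n_echoes` must be a single integer >= 2", call. = FALSE)
  }
  if (length(te_initial) != 1 || !is.finite(te_initial) || te_initial <= 0) {
    stop("`te_initial` must be a single positive number (ms)", call. = FALSE)
  }
  if (length(te_spacing) != 1 || !is.finite(te_spacing) || te_spacing <= 0) {
    stop("`te_spacing` must be a single positive number (ms)", call. = FALSE)
  }
  structure(
    list(n_echoes = as.integer(n_echoes),
         te_initial = as.numeric(te_initial),
         te_spacing = as.numeric(te_spacing)),
    class = "echo_schedule"
  )
}

#' @export
print.echo_schedule <- function(x, ...) {
  te <- echo_times(x)
  cat(sprintf("<echo_schedule> %d echoes, TE = %g, %g, ..., %g ms\n",
              x$n_echoes, te[1], te[2], te[x$n_echoes]))
  invisible(x)
}

#' Echo times of a schedule
#'
#' @param schedule An [echo_schedule()].
#' @return Numeric vector of echo times in ms, strictly increasing, of length
#'   `schedule$n_echoes`.
#' @export
echo_times <- function(schedule) {
  stopifnot(inherits(schedule, "echo_schedule"))
  schedule$te_initial + schedule$te_spacing * (seq_len(schedule$n_echoes) - 1)
}

as_echo_times <- function(schedule) {
  if (inherits(schedule, "echo_schedule")) return(echo_times(schedule))
  te <- as.numeric(schedule)
  if (length(te) < 2 || any(!is.finite(te)) || any(diff(te) <= 0) || te[1] <= 0) {
    stop("echo times must be >= 2 strictly increasing positive values (ms)",
         call. = FALSE)
  }
  te
}

#' Single-compartment (mono-exponential) decay signal
#'
#' The signal of a single water pool with amplitude `s0` and transverse
#' relaxation time `t2`, sampled at the echo times of `schedule`:
#' \deqn{S(TE) = S_0 \exp(-TE / T_2).}
#'
#' @param s0 Signal amplitude at TE = 0 (arbitrary units, >= 0).
#' @param t2 Transverse relaxation time in ms (> 0).
#' @param schedule An [echo_schedule()] or a numeric vector of echo times (ms).
#' @return Numeric vector of signal values, one per echo.
#' @export
#' @examples
#' mono_signal(100, 80, echo_schedule())
mono_signal <- function(s0, t2, schedule) {
  stopifnot(length(s0) == 1, length(t2) == 1, is.finite(s0), is.finite(t2),
            s0 >= 0, t2 > 0)
  te <- as_echo_times(schedule)
  s0 * exp(-te / t2)
}

#' Two-compartment (bi-exponential) decay signal
#'
#' The signal of two non-exchanging water pools — a short-T2 (intra-cellular)
#' compartment holding fraction `f` of the signal and a long-T2
#' (extra-cellular) compartment holding the remainder:
#' \deqn{S(TE) = S_0 \left[ f \exp(-TE/T_{2S}) + (1 - f) \exp(-TE/T_{2L}) \right].}
#' The short component is identified with the intra-cellular pool, so
#' `t2s <= t2l` is required; `f` is the intra-cellular signal (volume)
#' fraction reported as the "volume ratio" outcome when multiplied by 100.
#'
#' @param s0 Total signal amplitude at TE = 0 (>= 0).
#' @param f Intra-cellular signal fraction in \[0, 1\].
#' @param t2s Short (intra-cellular) T2 in ms (> 0).
#' @param t2l Long (extra-cellular) T2 in ms (>= `t2s`).
#' @inheritParams mono_signal
#' @return Numeric vector of signal values, one per echo.
#' @export
#' @examples
#' bi_signal(100, 0.4, 65, 150, echo_schedule())
bi_signal <- function(s0, f, t2s, t2l, schedule) {
  stopifnot(length(s0) == 1, length(f) == 1, length(t2s) == 1, length(t2l) == 1,
            is.finite(s0), is.finite(f), is.finite(t2s), is.finite(t2l),
            s0 >= 0, f >= 0, f <= 1, t2s > 0)
  if (t2l < t2s) {
    stop("`t2l` must be >= `t2s` (the short component is intra-cellular)",
         call. = FALSE)
  }
  te <- as_echo_times(schedule)
  s0 * (f * exp(-te / t2s) + (1 - f) * exp(-te / t2l))
}
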