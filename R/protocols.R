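#' Stress protocols: piecewise-constant stressor level over time
#'
#' A stress protocol is the model's experimental input: the stressor level
#' `S(t)` (arbitrary stress units) as a right-continuous piecewise-constant
#' function of time in minutes.  Constructors are provided for the three
#' experiment classes used throughout: constant treatment, washout
#' (instantaneous drop of `S` to zero at the washout time, i.e. drug
#' removal), and autophagy modulation (a parameter change, see
#' [modulate_autophagy()]).
#'
#' @param start numeric vector of segment start times (min); strictly
#'   increasing, first element 0.
#' @param level numeric vector of stressor levels (>= 0), same length.
#' @param t_end end of the simulated horizon (min); must exceed the last
#'   start time.
#' @return an object of class `stress_protocol` with fields `start`,
#'   `level`, `t_end`.
#' @export
#' @examples
#' stress_protocol(c(0, 60), c(10, 0), t_end = 180)  # washout at 60 min
stress_protocol <- function(start, level, t_end) {
  if (length(start) != length(level) || length(start) < 1L) {
    stop("start and level must be equal-length, non-empty vectors")
  }
  if (start[1] != 0) stop("first segment must start at time 0")
  if (length(start) > 1L && any(diff(start) <= 0)) {
    stop("segment start times must be strictly increasing")
  }
  if (any(level < 0)) stop("stressor levels must be >= 0")
  if (t_end <= start[length(start)]) stop("t_end must exceed the last start time")
  structure(list(start = as.numeric(start), level = as.numeric(level),
                 t_end = as.numeric(t_end)),
            class = "stress_protocol")
}

#' @export
print.stress_protocol <- function(x, ...) {
  cat("<stress_protocol> horizon", x$t_end, "min\n")
  ends <- c(x$start[-1], x$t_end)
  for (i in seq_along(x$start)) {
    cat(sprintf("  [%g, %g) min : S = %g\n", x$start[i], ends[i], x$level[i]))
  }
  invisible(x)
}

#' Constant treatment at stressor level S0
#'
#' @param S0 stressor level (>= 0).
#' @param t_end treatment duration (min, > 0); default 240 min, the
#'   standard evaluation horizon.
#' @return a `stress_protocol`.
#' @export
constant_stress <- function(S0, t_end = 240) {
  if (S0 < 0) stop("S0 must be >= 0")
  stress_protocol(0, S0, t_end)
}

#' Washout protocol: stressor applied then removed
#'
#' `S = S0` on `[0, t_washout)`, then `S = 0` for a further `t_post`
#' minutes.  Evaluation of cell fates is conventionally done at the end of
#' the horizon, `t_washout + t_post`.
#'
#' @param S0 stressor level during treatment.
#' @param t_washout time of stressor removal (min, > 0).
#' @param t_post post-washout follow-up (min, > 0); default 120 min.
#' @return a `stress_protocol`.
#' @export
washout <- function(S0, t_washout, t_post = 120) {
  if (t_washout <= 0) stop("t_washout must be > 0")
  if (t_post <= 0) stop("t_post must be > 0")
  stress_protocol(c(0, t_washout), c(S0, 0), t_washout + t_post)
}

#' Evaluate the stressor level of a protocol at given times
#'
#' Right-continuous convention: at a segment boundary the new level
#' applies, so `protocol_level(washout(10, 60), 60)` is 0.
#'
#' @param protocol a `stress_protocol`.
#' @param t numeric vector of times (min).
#' @return numeric vector of stressor levels.
#' @export
protocol_level <- function(protocol, t) {
  stopifnot(inherits(protocol, "stress_protocol"))
  idx <- findInterval(t, protocol$start)
  idx[idx < 1L] <- 1L
  protocol$level[idx]
}

#' Serialize / deserialize protocols through the flat config dialect
#'
#' @param protocol a `stress_protocol`.
#' @param path file path (YAML).
#' @return `read_protocol()` returns a `stress_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stress_protocol"))
  yaml::write_yaml(list(start = protocol$start, level = protocol$level,
                        t_end = protocol$t_end), path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- c("start", "level", "t_end")
  if (!all(need %in% names(raw))) {
    stop("protocol file must define keys: ", paste(need, collapse = ", "))
  }
  stress_protocol(raw$start, raw$level, raw$t_end)
}
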