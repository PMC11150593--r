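#' Stimulus segments and protocols
#'
#' A stimulus protocol is an ordered sequence of segments describing the
#' inspired-CO2 target as a piecewise function of time. Four segment kinds
#' are supported: `baseline` (target 0), `box` (constant plateau at
#' `level`), `ramp` (linear from `start_level` to `level`) and `half_sine`
#' (the first half of a sinusoid, peaking at `level` mid-segment; a 60 s
#' segment corresponds to a 120 s full period).
#'
#' Concentrations are stored as dimensionless volume fractions throughout
#' the package; protocol files on disk use percent (the display unit of gas
#' analyzers). Time is continuous seconds from protocol start, and segment
#' boundaries are half-open `[start, end)` so the target is single-valued
#' at joins.
#'
#' @param kind One of `"baseline"`, `"box"`, `"ramp"`, `"half_sine"`.
#' @param duration Segment duration in seconds, strictly positive.
#' @param level CO2 volume fraction in `[0, 1]`: the box plateau, ramp end
#'   value, or half-sine peak. Forced to 0 for baselines.
#' @param start_level Ramp start fraction (default 0); ignored otherwise.
#' @return `stimulus_segment()` returns an object of class
#'   `"stimulus_segment"`; `stimulus_protocol()` an object of class
#'   `"stimulus_protocol"`.
#' @examples
#' seg <- stimulus_segment("box", 45, 0.05)
#' p <- stimulus_protocol(list(stimulus_segment("baseline", 60), seg))
#' protocol_duration(p)
#' @export
stimulus_segment <- function(kind, duration, level = 0, start_level = 0) {
  kind <- match.arg(kind, c("baseline", "box", "ramp", "half_sine"))
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0) {
    stop("segment duration must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level < 0 || level > 1) {
    stop("segment level must be a fraction in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(start_level) || length(start_level) != 1L ||
      !is.finite(start_level) || start_level < 0 || start_level > 1) {
    stop("segment start_level must be a fraction in [0, 1]", call. = FALSE)
  }
  if (kind == "baseline") level <- 0
  if (kind != "ramp") start_level <- 0
  structure(
    list(kind = kind, duration = as.numeric(duration),
         level = as.numeric(level), start_level = as.numeric(start_level)),
    class = "stimulus_segment"
  )
}

#' @param segments List of `stimulus_segment` objects, in order.
#' @param name Protocol name (free text).
#' @rdname stimulus_segment
#' @export
stimulus_protocol <- function(segments, name = "protocol") {
  if (length(segments) == 0L) stop("a protocol needs at least one segment",
                                   call. = FALSE)
  ok <- vapply(segments, inherits, logical(1), "stimulus_segment")
  if (!all(ok)) stop("all segments must be stimulus_segment objects",
                     call. = FALSE)
  structure(list(segments = segments, name = as.character(name)[1]),
            class = "stimulus_protocol")
}

#' @param protocol A `stimulus_protocol`.
#' @rdname stimulus_segment
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  sum(vapply(protocol$segments, function(s) s$duration, numeric(1)))
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> '%s': %d segments, %.0f s total\n",
              x$name, length(x$segments), protocol_duration(x)))
  for (i in seq_along(x$segments)) {
    s <- x$segments[[i]]
    cat(sprintf("  %2d. %-9s %5.1f s  level %.1f %%%s\n", i, s$kind,
                s$duration, 100 * s$level,
                if (s$kind == "ramp") sprintf(" (from %.1f %%)",
                                              100 * s$start_level) else ""))
  }
  invisible(x)
}

#' Default inspired-CO2 stimulus protocol
#'
#' The reference target function used throughout the package: an initial
#' 60 s baseline, three 45 s box stimuli at 1, 3 and 5 % CO2 separated by
#' 45 s baselines, a 60 s ramp from 0 to 5 %, a 45 s baseline, a 60 s
#' half-sinusoid peaking at 5 % (half of a 120 s period), and a final 60 s
#' baseline, for a total of 555 s (about 9 minutes).
#'
#' @return A `stimulus_protocol` of 11 segments totalling 555 s.
#' @examples
#' protocol_duration(default_protocol())
#' @export
default_protocol <- function() {
  stimulus_protocol(list(
    stimulus_segment("baseline", 60),
    stimulus_segment("box", 45, 0.01),
    stimulus_segment("baseline", 45),
    stimulus_segment("box", 45, 0.03),
    stimulus_segment("baseline", 45),
    stimulus_segment("box", 45, 0.05),
    stimulus_segment("baseline", 45),
    stimulus_segment("ramp", 60, 0.05, start_level = 0),
    stimulus_segment("baseline", 45),
    stimulus_segment("half_sine", 60, 0.05),
    stimulus_segment("baseline", 60)
  ), name = "default")
}

#' Evaluate the inspired-CO2 target function
#'
#' Piecewise evaluation of a stimulus protocol: baselines and boxes are
#' constant, ramps interpolate linearly from `start_level` to `level`, and
#' half-sine segments follow `level * sin(pi * tau / duration)` where `tau`
#' is time into the segment.
#'
#' @param protocol A `stimulus_protocol`.
#' @param t Time(s) in seconds from protocol start; each must satisfy
#'   `0 <= t < protocol_duration(protocol)`.
#' @return Numeric vector of CO2 volume fractions, same length as `t`.
#' @examples
#' target_fco2i(default_protocol(), c(0, 70, 360))
#' @export
target_fco2i <- function(protocol, t) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("t must be finite numeric", call. = FALSE)
  }
  durs <- vapply(protocol$segments, function(s) s$duration, numeric(1))
  starts <- cumsum(c(0, durs))
  total <- starts[length(starts)]
  if (any(t < 0 | t >= total)) {
    stop(sprintf("t outside protocol range [0, %g)", total), call. = FALSE)
  }
  idx <- findInterval(t, starts, rightmost.closed = FALSE)
  out <- numeric(length(t))
  for (i in unique(idx)) {
    s <- protocol$segments[[i]]
    sel <- idx == i
    tau <- t[sel] - starts[i]
    out[sel] <- switch(s$kind,
      baseline = 0,
      box = s$level,
      ramp = s$start_level + (s$level - s$start_level) * tau / s$duration,
      half_sine = s$level * sin(pi * tau / s$duration)
    )
  }
  out
}

#' Safety limits for inspired gas concentrations
#'
#' Hard limits imposed on the delivered inspired gas: a maximum inspired
#' CO2 fraction and a minimum inspired O2 fraction (defaults 5 % and 19 %).
#'
#' @param max_fco2i Maximal inspired CO2 fraction (default 0.05).
#' @param min_fo2i Minimal inspired O2 fraction (default 0.19).
#' @return An object of class `"safety_limits"`.
#' @export
safety_limits <- function(max_fco2i = 0.05, min_fo2i = 0.19) {
  if (!(max_fco2i > 0 && max_fco2i < 1)) stop("max_fco2i must be in (0, 1)",
                                              call. = FALSE)
  if (!(min_fo2i > 0 && min_fo2i < 1)) stop("min_fo2i must be in (0, 1)",
                                            call. = FALSE)
  structure(list(max_fco2i = max_fco2i, min_fo2i = min_fo2i),
            class = "safety_limits")
}

#' Clamp a requested inspired-CO2 target to the safety limits
#'
#' Reduces a requested inspired CO2 fraction so that (a) it does not exceed
#' `limits$max_fco2i` and (b) the inspired O2 that results from admixing
#' O2-free additional gas (see [resulting_fo2i()]) stays at or above
#' `limits$min_fo2i`. The conflict with the O2 floor is always resolved by
#' reducing the CO2 target, never by adding O2: the admixture system has no
#' O2 source. The operation is idempotent.
#'
#' @param fco2i_request Requested inspired CO2 fraction(s) in `[0, 1]`.
#' @param ambient [gas_fractions()] of the respiratory (carrier) gas.
#' @param limits A [safety_limits()] object.
#' @param additional_fco2 CO2 fraction of the additional gas (default 1,
#'   i.e. pure CO2).
#' @param quiet Suppress the warning emitted when clamping reduces the
#'   request.
#' @return Clamped fraction(s), same length as `fco2i_request`.
#' @examples
#' clamp_target(0.06, gas_fractions(0, 0.209))
#' @export
clamp_target <- function(fco2i_request, ambient = gas_fractions(),
                         limits = safety_limits(), additional_fco2 = 1,
                         quiet = FALSE) {
  stopifnot(inherits(ambient, "gas_fractions"),
            inherits(limits, "safety_limits"))
  if (any(fco2i_request < 0 | fco2i_request > 1)) {
    stop("fco2i_request must lie in [0, 1]", call. = FALSE)
  }
  if (ambient$fo2 < limits$min_fo2i) {
    stop(sprintf(
      "ambient O2 (%.1f %%) is already below the safety floor (%.1f %%)",
      100 * ambient$fo2, 100 * limits$min_fo2i), call. = FALSE)
  }
  x <- pmin(fco2i_request, limits$max_fco2i)
  # largest admixture ratio keeping inspired O2 >= floor, and the CO2
  # fraction that ratio can reach from the ambient gas
  r_max <- ambient$fo2 / limits$min_fo2i - 1
  x_max <- (r_max * additional_fco2 + ambient$fco2) / (1 + r_max)
  x <- pmin(x, x_max)
  x <- pmax(x, ambient$fco2)
  if (!quiet && any(x < fco2i_request - 1e-12)) {
    warning("requested inspired CO2 exceeded the safety limits and was clamped",
            call. = FALSE)
  }
  x
}

#' Read and write stimulus-protocol JSON files
#'
#' Protocols are serialized as JSON with concentrations in percent:
#' `{"version": 1, "name": ..., "segments": [{"kind": ..., "duration_s":
#' ..., "fco2_percent": ..., "start_fco2_percent": ...}]}`. Writing then
#' reading is the identity on valid protocols.
#'
#' @param path File path.
#' @param protocol A `stimulus_protocol`.
#' @return `read_protocol()` returns a `stimulus_protocol`;
#'   `write_protocol()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_protocol(default_protocol(), f)
#' p <- read_protocol(f)
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path,
                               call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$segments) || length(raw$segments) == 0L) {
    stop("protocol file has no segments", call. = FALSE)
  }
  segs <- vector("list", length(raw$segments))
  for (i in seq_along(raw$segments)) {
    s <- raw$segments[[i]]
    kinds <- c("baseline", "box", "ramp", "half_sine")
    if (is.null(s$kind) || !s$kind %in% kinds) {
      stop(sprintf("segment %d: unknown kind '%s'", i,
                   if (is.null(s$kind)) "<missing>" else s$kind),
           call. = FALSE)
    }
    if (is.null(s$duration_s) || !is.numeric(s$duration_s) ||
        s$duration_s <= 0) {
      stop(sprintf("segment %d: duration must be positive", i), call. = FALSE)
    }
    lev <- if (is.null(s$fco2_percent)) 0 else s$fco2_percent
    if (!is.numeric(lev) || lev < 0 || lev > 100) {
      stop(sprintf("segment %d: fco2_percent must lie in [0, 100]", i),
           call. = FALSE)
    }
    sl <- if (is.null(s$start_fco2_percent)) 0 else s$start_fco2_percent
    if (!is.numeric(sl) || sl < 0 || sl > 100) {
      stop(sprintf("segment %d: start_fco2_percent must lie in [0, 100]", i),
           call. = FALSE)
    }
    segs[[i]] <- stimulus_segment(s$kind, s$duration_s, lev / 100, sl / 100)
  }
  stimulus_protocol(segs, name = if (is.null(raw$name)) "protocol" else
    raw$name)
}

#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  segs <- lapply(protocol$segments, function(s) {
    out <- list(kind = s$kind, duration_s = s$duration,
                fco2_percent = 100 * s$level)
    if (s$kind == "ramp") out$start_fco2_percent <- 100 * s$start_level
    out
  })
  obj <- list(version = 1L, name = protocol$name, segments = segs)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}
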