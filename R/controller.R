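#' Gas-stream composition
#'
#' CO2 and O2 volume fractions of a gas stream (inspired, respiratory,
#' additional or alveolar); the balance is assumed inert (N2). The default
#' is dry room air with a negligible CO2 content modeled as zero.
#'
#' @param fco2,fo2 CO2 / O2 volume fractions in `[0, 1]`, summing to at
#'   most 1.
#' @return An object of class `"gas_fractions"`.
#' @export
gas_fractions <- function(fco2 = 0, fo2 = 0.209) {
  if (!is.numeric(fco2) || !is.numeric(fo2) || length(fco2) != 1L ||
      length(fo2) != 1L || fco2 < 0 || fco2 > 1 || fo2 < 0 || fo2 > 1) {
    stop("fco2 and fo2 must be single fractions in [0, 1]", call. = FALSE)
  }
  if (fco2 + fo2 > 1 + 1e-12) {
    stop("fco2 + fo2 must not exceed 1", call. = FALSE)
  }
  structure(list(fco2 = fco2, fo2 = fo2), class = "gas_fractions")
}

#' @export
print.gas_fractions <- function(x, ...) {
  cat(sprintf("<gas_fractions> CO2 %.3f %%, O2 %.3f %%\n",
              100 * x$fco2, 100 * x$fo2))
  invisible(x)
}

#' Admixture ratio from the inspired-CO2 mass balance
#'
#' The core of the flow-proportional admixture method: the ratio of
#' additional-gas to respiratory-gas mass flow that makes the mixed
#' inspired CO2 fraction hit the target. Solving the mixing mass balance
#' `FCO2i = (FCO2res * Mres + FCO2add * Madd) / (Mres + Madd)` for
#' `Madd / Mres` gives
#' `(target - FCO2res) / (FCO2add - target)`.
#'
#' @param target Target inspired CO2 fraction(s); must satisfy
#'   `respiratory$fco2 <= target < additional_fco2`.
#' @param respiratory [gas_fractions()] of the respiratory gas.
#' @param additional_fco2 CO2 fraction of the additional gas (default 1).
#' @return Dimensionless flow ratio(s) `Madd / Mres`.
#' @examples
#' additional_flow_ratio(0.05, gas_fractions(0, 0.209), 1) # 1/19
#' @export
additional_flow_ratio <- function(target, respiratory = gas_fractions(),
                                  additional_fco2 = 1) {
  stopifnot(inherits(respiratory, "gas_fractions"))
  if (any(target >= additional_fco2)) {
    stop("target is unreachable: it must be below the additional-gas CO2 fraction",
         call. = FALSE)
  }
  if (any(target < respiratory$fco2 - 1e-15)) {
    stop("target below respiratory CO2: admixture cannot remove CO2",
         call. = FALSE)
  }
  pmax(0, (target - respiratory$fco2) / (additional_fco2 - target))
}

#' Inspired O2 after CO2 admixture
#'
#' Admixing O2-free additional gas dilutes the inspired O2: with admixture
#' ratio `r = Madd/Mres`, the inspired O2 fraction is
#' `respiratory_fo2 / (1 + r)`.
#'
#' @param respiratory_fo2 O2 fraction of the respiratory gas.
#' @param ratio Admixture ratio(s) `Madd / Mres`, `>= 0`.
#' @return Inspired O2 fraction(s).
#' @examples
#' resulting_fo2i(0.20, 1 / 19) # exactly 0.19
#' @export
resulting_fo2i <- function(respiratory_fo2, ratio) {
  if (any(ratio < 0)) stop("ratio must be non-negative", call. = FALSE)
  respiratory_fo2 / (1 + ratio)
}

#' Mass-flow-controller setpoint from a flow-sensor sample
#'
#' The additional-CO2 setpoint is proportional to the measured respiratory
#' gas flow: `setpoint = ratio * flow`, capped at a configurable actuator
#' maximum and forced to zero for non-positive flow (expiration / no-flow).
#'
#' @param flow_lpm Measured respiratory gas flow, L/min.
#' @param ratio Admixture ratio `Madd / Mres`, `>= 0`.
#' @param cap_lpm Setpoint cap, L/min (default 5).
#' @return Added-CO2 flow setpoint(s), L/min.
#' @export
setpoint_from_flow <- function(flow_lpm, ratio, cap_lpm = 5) {
  if (any(ratio < 0)) stop("ratio must be non-negative", call. = FALSE)
  pmin(cap_lpm, ratio * pmax(0, flow_lpm))
}

#' Three-gas setpoints for the reservoir reference mixer
#'
#' The reservoir reference system blends O2, CO2 and N2 through three mass
#' flow controllers into a breathing reservoir. Setpoints are simply the
#' target fractions times the total fresh-gas flow, with N2 as balance.
#'
#' @param target [gas_fractions()] of the desired reservoir mixture.
#' @param total_flow_lpm Total fresh-gas flow, L/min (default 8).
#' @return An object of class `"reservoir_setpoints"` with fields
#'   `q_o2`, `q_co2`, `q_n2` (L/min) summing to `total_flow_lpm`.
#' @examples
#' reservoir_setpoints(gas_fractions(0.05, 0.21), 8)
#' @export
reservoir_setpoints <- function(target, total_flow_lpm = 8) {
  stopifnot(inherits(target, "gas_fractions"))
  if (total_flow_lpm <= 0) stop("total_flow_lpm must be positive",
                                call. = FALSE)
  if (target$fco2 + target$fo2 > 1 + 1e-12) {
    stop("infeasible mixture: fractions sum above 1", call. = FALSE)
  }
  q_co2 <- target$fco2 * total_flow_lpm
  q_o2 <- target$fo2 * total_flow_lpm
  structure(list(q_o2 = q_o2, q_co2 = q_co2,
                 q_n2 = total_flow_lpm - q_o2 - q_co2,
                 total_flow_lpm = total_flow_lpm),
            class = "reservoir_setpoints")
}

#' @export
print.reservoir_setpoints <- function(x, ...) {
  cat(sprintf("<reservoir_setpoints> O2 %.2f, CO2 %.2f, N2 %.2f L/min (total %.2f)\n",
              x$q_o2, x$q_co2, x$q_n2, x$total_flow_lpm))
  invisible(x)
}

#' Controller configuration
#'
#' Bundles the gas-delivery parameters used by [simulate_closed_loop()]:
#' which system is active (`"additional"` flow-proportional admixture or
#' the `"reservoir"` reference), the additional-gas CO2 fraction, the
#' flow-sensor gain (measured flow = gain x true flow; values below 1
#' reproduce the under-reading of laminar flow by a sensor calibrated on
#' more turbulent flow), the setpoint cap, the ambient/respiratory gas and
#' the reservoir parameters.
#'
#' @param system `"additional"` or `"reservoir"`.
#' @param additional_fco2 CO2 fraction of the additional gas (default 1).
#' @param sensor_gain Flow-sensor gain (default 1).
#' @param setpoint_cap_lpm Mass-flow-controller cap, L/min (default 5).
#' @param ambient [gas_fractions()] of the respiratory/room gas.
#' @param reservoir List with `total_flow_lpm` (default 8), `fo2` (target
#'   reservoir O2 fraction, default 0.21) and `volume_ml` (reservoir tube
#'   volume, default 700).
#' @return An object of class `"controller_config"`.
#' @export
controller_config <- function(system = c("additional", "reservoir"),
                              additional_fco2 = 1, sensor_gain = 1,
                              setpoint_cap_lpm = 5,
                              ambient = gas_fractions(),
                              reservoir = list(total_flow_lpm = 8,
                                               fo2 = 0.21,
                                               volume_ml = 700)) {
  system <- match.arg(system)
  stopifnot(inherits(ambient, "gas_fractions"),
            additional_fco2 > 0, additional_fco2 <= 1,
            sensor_gain > 0, setpoint_cap_lpm > 0)
  res <- utils::modifyList(list(total_flow_lpm = 8, fo2 = 0.21,
                                volume_ml = 700), reservoir)
  structure(list(system = system, additional_fco2 = additional_fco2,
                 sensor_gain = sensor_gain,
                 setpoint_cap_lpm = setpoint_cap_lpm,
                 ambient = ambient, reservoir = res),
            class = "controller_config")
}
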