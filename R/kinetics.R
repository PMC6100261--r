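#' Rate constants of the three reversible transesterification steps
#'
#' The stepwise conversion of triglyceride to glycerol with methanol,
#'
#' \preformatted{
#'   TG  + MeOH <-> DG + E1   (k1 forward, k2 reverse)
#'   DG  + MeOH <-> MG + E2   (k3 forward, k4 reverse)
#'   MG  + MeOH <-> GL + E3   (k5 forward, k6 reverse)
#' }
#'
#' where E1, E2, E3 are the fatty-acid methyl esters released at each step.
#' All rate coefficients are second order (concentration^-1 time^-1) and must
#' be strictly positive.
#'
#' @param k numeric vector of the six coefficients `k1..k6`, or six separate
#'   arguments.
#' @param ... the remaining coefficients when `k` is given as `k1`.
#' @return a named numeric vector of class `isd_rate_constants`.
#' @examples
#' rate_constants(c(0.049, 0.109, 0.211, 1.213, 2.407, 0.069))
#' @export
rate_constants <- function(k, ...) {
  k <- c(k, ...)
  if (length(k) != 6L || !is.numeric(k) || any(!is.finite(k)))
    stop("exactly six finite rate coefficients k1..k6 are required")
  if (any(k <= 0)) stop("all rate coefficients must be > 0")
  structure(setNames(as.numeric(k), paste0("k", 1:6)),
            class = "isd_rate_constants")
}

#' Default rate constants of the bundled kinetic model
#'
#' The generating truth for the parameter-recovery examples:
#' `k = (0.049, 0.109, 0.211, 1.213, 2.407, 0.069)`, the coefficients of the
#' three reversible transesterification steps at 50 degrees C.
#'
#' @return an [rate_constants()] object.
#' @export
default_rate_constants <- function() {
  rate_constants(c(0.049, 0.109, 0.211, 1.213, 2.407, 0.069))
}

#' Species state of the transesterification system
#'
#' Concentrations (mol/L) of the eight species in the fixed order
#' TG, DG, MG, GL, MeOH, E1, E2, E3.
#'
#' @param ... named concentrations; unnamed species default to 0.
#' @return named numeric vector of length 8.
#' @examples
#' species_state(TG = 1, MeOH = 0.023)
#' @export
species_state <- function(...) {
  given <- c(...)
  state <- setNames(numeric(8L), ISD_SPECIES)
  if (length(given)) {
    if (is.null(names(given)) || !all(names(given) %in% ISD_SPECIES))
      stop("species must be named among: ", paste(ISD_SPECIES, collapse = ", "))
    state[names(given)] <- given
  }
  if (any(state < 0)) stop("concentrations must be non-negative")
  state
}

#' Semi-batch reactor specification
#'
#' A perfectly mixed, constant-volume, isothermal vessel with equal inflow
#' and outflow characterised by the residence time.  The feed is a pure
#' methanol stream at the inlet concentration; the vessel initially holds
#' triglyceride at `c_tg0` plus methanol at `c_meoh0`.  Setting
#' `residence_time = Inf` gives a closed batch (no flow).
#'
#' @param residence_time residence time (s), `> 0`; `Inf` for closed batch.
#' @param c_tg0 initial triglyceride concentration (mol/L); default 1.
#' @param c_meoh0 methanol inlet/initial concentration (mol/L); default
#'   0.023.
#' @param t_end simulation horizon (s); default 3000.
#' @param dt sampling interval (s); default 30.
#' @param initial optional full initial [species_state()]; overrides the
#'   `c_tg0`/`c_meoh0` defaults.
#' @param feed optional full feed [species_state()]; default pure methanol at
#'   `c_meoh0`.
#' @return an object of class `isd_reactor_spec`.
#' @examples
#' reactor_spec(residence_time = 2000)
#' @export
reactor_spec <- function(residence_time, c_tg0 = 1, c_meoh0 = 0.023,
                         t_end = 3000, dt = 30,
                         initial = NULL, feed = NULL) {
  if (!is.numeric(residence_time) || length(residence_time) != 1L ||
      residence_time <= 0)
    stop("residence_time must be a single positive number (Inf allowed)")
  if (dt <= 0 || t_end < dt) stop("need t_end >= dt > 0")
  if (is.null(initial)) initial <- species_state(TG = c_tg0, MeOH = c_meoh0)
  if (is.null(feed)) feed <- species_state(MeOH = c_meoh0)
  stopifnot(length(initial) == 8L, length(feed) == 8L)
  structure(list(residence_time = residence_time,
                 initial = setNames(as.numeric(initial), ISD_SPECIES),
                 feed = setNames(as.numeric(feed), ISD_SPECIES),
                 t_end = t_end, dt = dt),
            class = "isd_reactor_spec")
}

#' @export
print.isd_reactor_spec <- function(x, ...) {
  cat(sprintf("<isd_reactor_spec> tau_res = %g s, t_end = %g s, dt = %g s\n",
              x$residence_time, x$t_end, x$dt))
  cat("  initial:", paste(sprintf("%s=%g", ISD_SPECIES, x$initial),
                          collapse = " "), "\n")
  cat("  feed:   ", paste(sprintf("%s=%g", ISD_SPECIES, x$feed),
                          collapse = " "), "\n")
  invisible(x)
}

#' Net reaction rates of the eight species
#'
#' Mass-action net rates of the three reversible steps:
#' `r1 = k1 C_TG C_MeOH - k2 C_DG C_E1`,
#' `r2 = k3 C_DG C_MeOH - k4 C_MG C_E2`,
#' `r3 = k5 C_MG C_MeOH - k6 C_GL C_E3`, combined through the stoichiometry
#' (each step consumes one methanol and releases one ester).
#'
#' @param state [species_state()] of non-negative concentrations.
#' @param k [rate_constants()].
#' @return named numeric vector of per-species net rates (mol L^-1 s^-1).
#' @examples
#' reaction_rates(species_state(TG = 1, MeOH = 0.023),
#'                default_rate_constants())
#' @export
reaction_rates <- function(state, k) {
  if (length(state) != 8L) stop("state must hold the 8 species")
  state <- setNames(as.numeric(state), ISD_SPECIES)
  if (any(state < 0)) stop("concentrations must be non-negative")
  r1 <- k[[1L]] * state[["TG"]] * state[["MeOH"]] -
        k[[2L]] * state[["DG"]] * state[["E1"]]
  r2 <- k[[3L]] * state[["DG"]] * state[["MeOH"]] -
        k[[4L]] * state[["MG"]] * state[["E2"]]
  r3 <- k[[5L]] * state[["MG"]] * state[["MeOH"]] -
        k[[6L]] * state[["GL"]] * state[["E3"]]
  setNames(c(-r1, r1 - r2, r2 - r3, r3, -r1 - r2 - r3, r1, r2, r3),
           ISD_SPECIES)
}

#' Simulate the semi-batch reactor on the sampling grid
#'
#' Integrates the flow balance
#' `dC_j/dt = R_j(C, k) + (C_j,feed - C_j) / tau_res`
#' from the initial state with a stiff-capable solver and returns the ideal
#' concentration series sampled exactly at `t = 0, dt, 2 dt, ..., t_end`.
#'
#' @param spec an [reactor_spec()].
#' @param k an [rate_constants()] vector.
#' @param rtol,atol relative and absolute solver tolerances.
#' @return an ideal [timeseries()] of the eight species.
#' @examples
#' ts <- simulate_reactor(reactor_spec(2000), default_rate_constants())
#' @export
simulate_reactor <- function(spec, k, rtol = 1e-8, atol = 1e-10) {
  if (!inherits(spec, "isd_reactor_spec")) stop("spec must be an isd_reactor_spec")
  k <- rate_constants(k)
  times <- seq(0, spec$t_end, by = spec$dt)
  inv_tau <- if (is.finite(spec$residence_time)) 1 / spec$residence_time else 0
  parms <- c(unclass(k), inv_tau = inv_tau, spec$feed)
  out <- deSolve::lsoda(y = spec$initial, times = times,
                        func = "derivs_semibatch", parms = parms,
                        dllname = "insilico", initfunc = "init_semibatch",
                        rtol = rtol, atol = atol)
  istate <- attr(out, "istate")[1L]
  if (is.null(istate) || istate < 0 || nrow(out) < length(times))
    stop("reactor integration failed (istate = ", istate,
         ", returned ", nrow(out), "/", length(times), " time points)")
  vals <- out[, ISD_SPECIES, drop = FALSE]
  if (min(vals) < -1e-8)
    stop("reactor integration produced negative concentrations (min = ",
         format(min(vals)), ")")
  vals[vals < 0] <- 0
  timeseries(times, vals, ISD_SPECIES, is_noisy = FALSE)
}
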