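## complex cable arguments for the ball-and-stick transfer functions:
## q^2 = 1 + i w tau_m, Y = q ds^2 / (d lambda), x = q l / lambda,
## with lambda the DC length constant sqrt(d Rm / (4 Ra)). tanh/sech forms
## keep the expressions finite for large |x| (tanh -> 1, sech -> 0).
.bas_args <- function(params, frequency) {
  tau_s <- params@rm * params@cm * 1e-6          # s
  q <- sqrt(complex(real = 1, imaginary = 2 * pi * frequency * tau_s))
  lambda <- .lambda_um(params@d, params@rm, params@ra)
  list(q = q, lambda = lambda,
       Y = q * params@ds^2 / (params@d * lambda),
       x = q * params@l / lambda)
}

.safe_tanh <- function(x) ifelse(Re(x) > 20, 1 + 0i, tanh(x))
.safe_sech <- function(x) ifelse(Re(x) > 20, 0 + 0i, 1 / cosh(x))

#' Somatic membrane-current transfer function of a ball-and-stick model
#'
#' Closed-form ratio between the net somatic membrane current (stimulus
#' included) and an intracellular current injected at the soma:
#' `T_Is = -sinh(ql/lambda) / (Y cosh(ql/lambda) + sinh(ql/lambda))`, with
#' `q^2 = 1 + i w tau_m` and `Y = q ds^2 / (d lambda)`. The leading minus
#' sign reflects the outward-positive membrane-current convention with an
#' inward-positive (depolarizing) stimulus: the soma acts as the sink
#' balancing the distributed return currents along the stick. `T_Is(-f)` is
#' the conjugate of `T_Is(f)` and `T_Is -> 0` as the stick length vanishes
#' (a point cell returns the injected current locally).
#'
#' @param params a [BASParameters-class].
#' @param frequency Hz (vectorized; may be negative for the conjugate).
#' @return complex dimensionless transfer factor.
#' @export
transferSomaticCurrent <- function(params, frequency) {
  if (params@l == 0) return(rep(0 + 0i, length(frequency)))
  neg <- frequency < 0
  a <- .bas_args(params, abs(frequency))
  th <- .safe_tanh(a$x)
  out <- -th / (a$Y + th)
  out[neg] <- Conj(out[neg])
  out
}

#' Current-dipole transfer function of a ball-and-stick model
#'
#' Closed-form ratio between the current-dipole moment (along the stick) and
#' an intracellular current injected at the soma:
#' `T_ps = (lambda / q) (cosh(ql/lambda) - 1) / (Y cosh(ql/lambda) +
#' sinh(ql/lambda))`, in um, so that `p = T_ps * I_in` is in nA um.
#'
#' @inheritParams transferSomaticCurrent
#' @return complex transfer factor, um.
#' @export
transferDipole <- function(params, frequency) {
  if (params@l == 0) return(rep(0 + 0i, length(frequency)))
  neg <- frequency < 0
  a <- .bas_args(params, abs(frequency))
  th <- .safe_tanh(a$x)
  se <- .safe_sech(a$x)
  out <- (a$lambda / a$q) * (1 - se) / (a$Y + th)
  out[neg] <- Conj(out[neg])
  out
}

#' Analytic susceptibility of a ball-and-stick soma to extracellular
#' stimulation
#'
#' Somatic membrane-potential response per nA of extracellular stimulation
#' current, obtained by composing the reciprocity relation with the
#' closed-form transfer functions: in the near field (`r` much smaller than
#' the frequency-dependent length constant) the extracellular potential from
#' a somatic injection is dominated by the somatic membrane current,
#' `|T_Is| / (4 pi sigma r)`; in the far field the current-dipole
#' approximation applies, `|T_ps| cos(theta) / (4 pi sigma r^2)`.
#'
#' @param params a [BASParameters-class].
#' @param frequency Hz.
#' @param r distance from the soma, um.
#' @param theta angle between the stick axis and the observation direction,
#'   radians (far field only).
#' @param sigma conductivity, S/m.
#' @param regime `"near"` or `"far"`.
#' @return susceptibility, mV per nA of stimulation current.
#' @export
analyticEsSusceptibility <- function(params, frequency, r, theta = 0,
                                     sigma = 0.3, regime = c("near", "far")) {
  regime <- match.arg(regime)
  if (any(r <= 0)) stop("r must be positive")
  if (regime == "near") {
    Mod(transferSomaticCurrent(params, frequency)) / (4 * pi * sigma * r)
  } else {
    Mod(transferDipole(params, frequency)) * abs(cos(theta)) /
      (4 * pi * sigma * r^2)
  }
}
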