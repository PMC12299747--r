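#' Air-blow sorting parameters
#'
#' Physical parameters of the pneumatic sorting stage: a timed air jet from
#' a tube of radius `r` at pump pressure `P` pushes a mushroom of mass `m`
#' sideways off a conveyor belt of width `W` moving at `Vx`, against belt
#' friction `mu`. All values are SI. `pi_const` defaults to 3.14 — the
#' rounded value used in the published worked arithmetic (50.24 mm2 tube
#' section, 40.19 N force, 41.01 kg break-even mass) — and can be set to
#' `"exact"` for full-precision pi.
#'
#' @param P Air pump pressure, Pa.
#' @param r Air-tube radius, m.
#' @param mu Belt friction coefficient in `(0, 1]`.
#' @param m Mushroom mass, kg (a typical specimen is about 0.030 kg).
#' @param g Gravitational acceleration, m/s2.
#' @param dt0 Blow duration, s.
#' @param Vy0 Initial cross-belt speed, m/s (0 on a steady belt).
#' @param Vx Belt speed, m/s.
#' @param W Belt width, m; the mushroom starts in the middle, so the
#'   crossing distance is `W / 2`.
#' @param pi_const Numeric value of pi to use, or `"exact"`.
#' @return An `air_blow_params` object (validated list).
#' @export
air_blow_params <- function(P = 0.80e6, r = 4e-3, mu = 0.10, m = 0.030,
                            g = 9.80, dt0 = 1e-3, Vy0 = 0, Vx = 0.10,
                            W = 0.20, pi_const = 3.14) {
  pi_const <- resolve_pi(pi_const)
  stopifnot(P > 0, r > 0, m > 0, g > 0, dt0 >= 0, Vy0 >= 0, Vx >= 0, W > 0,
            mu > 0, mu <= 1)
  structure(
    list(P = P, r = r, mu = mu, m = m, g = g, dt0 = dt0, Vy0 = Vy0,
         Vx = Vx, W = W, pi_const = pi_const),
    class = "air_blow_params"
  )
}

resolve_pi <- function(pi_const) {
  if (identical(pi_const, "exact")) return(pi)
  stopifnot(is.numeric(pi_const), pi_const > 0)
  pi_const
}

#' Blow force from pump pressure and tube geometry
#'
#' The jet's cross-section is `S = pi * r^2` and the force it applies is
#' `F = P * S` (pressure times area; Pa times m2 gives N).
#'
#' @param P Pressure, Pa.
#' @param r Tube radius, m.
#' @param pi_const Value of pi, or `"exact"`.
#' @return A list with `S_tube` (m2) and `F` (N).
#' @examples
#' f <- blow_force(P = 0.80e6, r = 4e-3)
#' f$S_tube * 1e6   # 50.24 mm2
#' f$F              # 40.192 N
#' @export
blow_force <- function(P, r, pi_const = 3.14) {
  stopifnot(P > 0, r > 0)
  S <- resolve_pi(pi_const) * r^2
  list(S_tube = S, F = P * S)
}

#' Break-even mass and blow-off feasibility
#'
#' The jet can displace the mushroom only if its force exceeds belt
#' friction `mu * m * g`. Equating the two gives the break-even mass
#' `m* = P * S / (mu * g)`: any specimen lighter than `m*` is blown off.
#' With the default parameters `m*` is about 41 kg — three orders of
#' magnitude above a real mushroom — so blow-off is always feasible.
#'
#' @inheritParams blow_force
#' @param mu Friction coefficient.
#' @param g Gravitational acceleration, m/s2.
#' @return Break-even mass, kg.
#' @export
break_even_mass <- function(P, r, mu, g, pi_const = 3.14) {
  stopifnot(mu > 0, g > 0)
  blow_force(P, r, pi_const)$F / (mu * g)
}

#' @param params An [air_blow_params()] object.
#' @rdname break_even_mass
#' @return `can_displace()` returns `TRUE` iff `F > mu * m * g` (strict:
#'   exact balance does not move the specimen).
#' @export
can_displace <- function(params) {
  stopifnot(inherits(params, "air_blow_params"))
  f <- blow_force(params$P, params$r, params$pi_const)
  f$F > params$mu * params$m * params$g
}

#' Cross-belt speed right after the blow
#'
#' Impulse-momentum balance over the short blow: `Vy1 = (F * dt0 + m *
#' Vy0) / m`. The blow is treated as instantaneous in position — the
#' mushroom does not move while being hit.
#'
#' @param F Blow force, N (from [blow_force()]).
#' @param dt0 Blow duration, s.
#' @param m Mass, kg.
#' @param Vy0 Initial cross-belt speed, m/s.
#' @return `Vy1`, m/s.
#' @export
post_blow_velocity <- function(F, dt0, m, Vy0 = 0) {
  stopifnot(m > 0)
  (F * dt0 + m * Vy0) / m
}

#' Kinematics of the cross-belt coast after the blow
#'
#' After the jet stops, only belt friction (deceleration `a = mu * g`) acts
#' while the mushroom coasts the half belt width `d = W / 2` to the edge.
#' Two sign conventions are provided. `"friction_decelerates"` (default,
#' physically correct) has friction oppose the crossing:
#' `Vy2 = sqrt(Vy1^2 - 2 a d)`, `dt1 = (Vy1 - Vy2) / a`; if `Vy1^2 < 2 a d`
#' the mushroom stalls on the belt (a stall warning is raised and the edge
#' is never reached). `"as_printed"` reproduces the published equations
#' verbatim, where the friction term enters with a plus sign:
#' `Vy2 = sqrt(2 a d + Vy1^2)`, `dt1 = (Vy2 - Vy1) / a`. In both modes the
#' belt carries the mushroom downstream during the crossing, giving the
#' horizontal displacement `X = dt1 * Vx` that positions the collection
#' box.
#'
#' @param params An [air_blow_params()] object (`mu`, `g`, `W`, `Vx` used).
#' @param Vy1 Cross-belt speed after the blow, m/s (see
#'   [post_blow_velocity()]).
#' @param mode `"friction_decelerates"` or `"as_printed"`.
#' @return A one-row tibble: `a` (m/s2), `Vy2` (m/s), `dt1` (s), `X` (m),
#'   `stalled` (logical).
#' @export
crossing_kinematics <- function(params, Vy1,
                                mode = c("friction_decelerates", "as_printed")) {
  stopifnot(inherits(params, "air_blow_params"), Vy1 > 0)
  mode <- match.arg(mode)
  a <- params$mu * params$g
  d <- params$W / 2
  stalled <- FALSE
  if (mode == "as_printed") {
    Vy2 <- sqrt(2 * a * d + Vy1^2)
    dt1 <- (Vy2 - Vy1) / a
  } else {
    disc <- Vy1^2 - 2 * a * d
    if (disc <= 0) {
      stalled <- TRUE
      warning(structure(
        class = c("mushgrade_stall", "warning", "condition"),
        list(message = sprintf(
          "stall: Vy1 = %.3f m/s cannot cross %.3f m against friction", Vy1, d),
          call = NULL)
      ))
    }
    Vy2 <- sqrt(max(disc, 0))
    dt1 <- (Vy1 - Vy2) / a
  }
  tibble::tibble(a = a, Vy2 = Vy2, dt1 = dt1, X = dt1 * params$Vx,
                 stalled = stalled)
}

#' Full blow-to-displacement trajectory
#'
#' Chains the whole model: tube section and force, feasibility check,
#' impulse, crossing kinematics, horizontal displacement.
#'
#' @inheritParams crossing_kinematics
#' @return An object of class `blow_trajectory` supporting
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' tr <- blow_trajectory(air_blow_params())
#' generics::tidy(tr)
#' @export
blow_trajectory <- function(params = air_blow_params(),
                            mode = c("friction_decelerates", "as_printed")) {
  stopifnot(inherits(params, "air_blow_params"))
  mode <- match.arg(mode)
  f <- blow_force(params$P, params$r, params$pi_const)
  Vy1 <- post_blow_velocity(f$F, params$dt0, params$m, params$Vy0)
  k <- crossing_kinematics(params, Vy1, mode)
  structure(
    list(params = params, mode = mode, S_tube = f$S_tube, F = f$F,
         displaceable = can_displace(params),
         Vy1 = Vy1, a = k$a, Vy2 = k$Vy2, dt1 = k$dt1, X = k$X,
         stalled = k$stalled),
    class = "blow_trajectory"
  )
}

#' @export
print.blow_trajectory <- function(x, ...) {
  cat(sprintf(
    paste0("<blow_trajectory> mode=%s\n  S=%.2f mm2  F=%.2f N  displaceable=%s\n",
           "  Vy1=%.4f m/s  Vy2=%.4f m/s  dt1=%.4f s  X=%.2f mm%s\n"),
    x$mode, x$S_tube * 1e6, x$F, x$displaceable, x$Vy1, x$Vy2, x$dt1,
    x$X * 1e3, if (x$stalled) "  [stalled]" else ""
  ))
  invisible(x)
}

#' Displacement envelope over a mass range
#'
#' Displacement depends on mass only through the impulse (`Vy1 = F dt0 / m
#' + Vy0`), and is monotone in `Vy1`, so evaluating the two mass extremes
#' brackets the displacement of every specimen in between; the interval is
#' returned sorted. (Heavier specimens eject slower, cross the belt more
#' slowly, and are carried farther downstream.) Used to size and place the
#' collection boxes.
#'
#' @inheritParams crossing_kinematics
#' @param m_min,m_max Mass extremes, kg, `0 < m_min <= m_max`.
#' @return A one-row tibble with `X_min`, `X_max` (m) and the masses at
#'   which each occurs.
#' @export
displacement_envelope <- function(params, m_min, m_max,
                                  mode = c("friction_decelerates", "as_printed")) {
  stopifnot(0 < m_min, m_min <= m_max)
  mode <- match.arg(mode)
  xs <- vapply(c(m_min, m_max), function(m) {
    p <- params; p$m <- m
    blow_trajectory(p, mode)$X
  }, 0)
  tibble::tibble(
    X_min = min(xs), X_max = max(xs),
    m_at_min = c(m_min, m_max)[which.min(xs)],
    m_at_max = c(m_min, m_max)[which.max(xs)]
  )
}
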