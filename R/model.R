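#' Construct the Ca2+-CaM-CAMTA binding model
#'
#' Bundles the anchored parameters, the derived 33-reaction table, the
#' stoichiometry matrix, and the simulation settings into one object used by
#' every downstream operation. Ca2+ is an externally clamped input: the model
#' never depletes it, matching the use of measured or constructed calcium
#' signatures as drivers.
#'
#' @param base A [base_parameters()] object; built from `...` if omitted.
#' @param control_ca Resting (control) Ca2+ concentration in uM. The system
#'   is settled to its equilibrium at this level before any signature is
#'   applied, and all fold changes are taken against that equilibrium.
#' @param rtol,atol Relative/absolute integrator tolerances.
#' @param ... Passed to [base_parameters()] when `base` is missing.
#' @return An object of class `cam_model`: a list with elements `base`,
#'   `control_ca`, `rtol`, `atol`, `species`, `reactions`, and internal
#'   index/stoichiometry fields.
#' @examples
#' m <- cam_model()
#' nrow(m$reactions)  # 33
#' @export
cam_model <- function(base = base_parameters(...), control_ca = 0.10,
                      rtol = 1e-5, atol = 1e-5, ...) {
  stopifnot(is.numeric(control_ca), length(control_ca) == 1, control_ca >= 0)
  reactions <- derive_reactions(base)
  sp <- cam_species()
  from_idx <- match(reactions$from, sp$name)
  to_idx <- match(reactions$to, sp$name)
  nr <- nrow(reactions)
  stoich <- matrix(0, nrow(sp), nr)
  for (j in seq_len(nr)) {
    stoich[from_idx[j], j] <- -1
    stoich[to_idx[j], j] <- 1
    if (reactions$type[j] == "bind") stoich[19L, j] <- -1
  }
  m <- list(base = base, control_ca = control_ca, rtol = rtol, atol = atol,
            species = sp, reactions = reactions,
            from_idx = from_idx, to_idx = to_idx,
            is_bind = reactions$type == "bind", stoich = stoich)
  class(m) <- "cam_model"
  m
}

#' @export
print.cam_model <- function(x, ...) {
  cat("Ca2+-CaM-CAMTA binding model: 19 species, 33 reactions\n")
  cat(sprintf("  totals: CaM %.4g uM, CAMTA %.4g uM; control Ca %.4g uM\n",
              x$base$cam_total, x$base$camta_total, x$control_ca))
  cat(sprintf("  cooperativity P = %.3g (Q = %.3g), CaM-CAMTA Kd = %.3g uM\n",
              x$base$p, x$base$q, x$base$kd_camta))
  invisible(x)
}

#' Mass-action time derivative of the binding network
#'
#' Pure mass-action fluxes under a clamped Ca2+ concentration. CaM and CAMTA
#' totals are conserved exactly by construction (columns of the
#' stoichiometry matrix sum to zero within each conserved group).
#'
#' @param state Named or unnamed numeric vector of 19 concentrations (uM) in
#'   canonical species order.
#' @param ca Clamped Ca2+ concentration (uM).
#' @param model A [cam_model()].
#' @return Numeric vector of 19 derivatives (uM s^-1), named by species.
#' @examples
#' m <- cam_model()
#' s <- initial_state(m)
#' d <- binding_rhs(s, ca = 1, m)
#' sum(d[1:18])  # 0: CaM conservation
#' @export
binding_rhs <- function(state, ca, model) {
  stopifnot(length(state) == 19, ca >= 0)
  lig <- ifelse(model$is_bind, state[19L], ca)
  flux <- model$reactions$kon * state[model$from_idx] * lig -
    model$reactions$koff * state[model$to_idx]
  d <- as.vector(model$stoich %*% flux)
  names(d) <- model$species$name
  d
}

# initial partition: all CaM apo and free, all CAMTA free
initial_state <- function(model) {
  s <- numeric(19)
  s[1L] <- model$base$cam_total
  s[19L] <- model$base$camta_total
  names(s) <- model$species$name
  s
}

# deSolve-style rhs closure with constant clamped ca (fast path)
rhs_const_ca <- function(model, ca) {
  kon <- model$reactions$kon; koff <- model$reactions$koff
  fi <- model$from_idx; ti <- model$to_idx
  isb <- model$is_bind; S <- model$stoich
  function(t, y, parms) {
    lig <- ifelse(isb, y[19L], ca)
    list(as.vector(S %*% (kon * y[fi] * lig - koff * y[ti])))
  }
}

# rhs closure with time-varying ca(t)
rhs_forced_ca <- function(model, cafun) {
  kon <- model$reactions$kon; koff <- model$reactions$koff
  fi <- model$from_idx; ti <- model$to_idx
  isb <- model$is_bind; S <- model$stoich
  function(t, y, parms) {
    lig <- ifelse(isb, y[19L], cafun(t))
    list(as.vector(S %*% (kon * y[fi] * lig - koff * y[ti])))
  }
}

#' Equilibrium of the clamped-Ca network by ODE relaxation
#'
#' Integrates the mass-action system at a fixed Ca2+ concentration from the
#' canonical initial partition (all CaM apo and free, all CAMTA free) over
#' successively longer horizons until the residual `max |d(state)/dt|`
#' drops below `residual_tol`. The binding lattice with clamped Ca2+ and
#' two conservation laws has a unique positive equilibrium, so the
#' relaxation endpoint does not depend on the start.
#'
#' @param model A [cam_model()].
#' @param ca Clamped Ca2+ concentration (uM); defaults to the control level.
#' @param residual_tol Convergence threshold on `max |rhs|` (uM s^-1).
#' @return Named state vector (19 concentrations, uM) with attributes
#'   `residual` and `ca`.
#' @seealso [equilibrium_oracle()] for the independent algebraic route.
#' @export
steady_state <- function(model, ca = model$control_ca,
                         residual_tol = 1e-10) {
  stopifnot(ca >= 0)
  y <- initial_state(model)
  f <- rhs_const_ca(model, ca)
  res <- max(abs(f(0, y, NULL)[[1]]))
  for (horizon in 10^(2:7)) {
    if (res < residual_tol) break
    out <- deSolve::lsoda(y, c(0, horizon), f, NULL,
                          rtol = 1e-10, atol = 1e-12)
    y <- pmax(as.numeric(out[nrow(out), -1]), 0)
    res <- max(abs(f(0, y, NULL)[[1]]))
  }
  if (res >= residual_tol)
    stop(sprintf("steady state did not converge: residual %.3e uM/s at ca = %g uM",
                 res, ca))
  names(y) <- model$species$name
  attr(y, "residual") <- res
  attr(y, "ca") <- ca
  y
}

#' Equilibrium by partition-function evaluation (algebraic oracle)
#'
#' Computes the same equilibrium as [steady_state()] without integrating any
#' ODE. Every species concentration is written as `[apo-CaM]` times a product
#' of `ca / Kd` (Ca2+ steps) and `[X] / Kd` (CAMTA steps) factors along a
#' path from apo-CaM; path independence is guaranteed by the Wegscheider
#' condition. The two conservation relations then reduce to one scalar
#' equation in free apo-CaM, solved by bracketed root finding
#' ([stats::uniroot()]), with free CAMTA eliminated in closed form.
#'
#' The weights are accumulated by breadth-first traversal of the reaction
#' table itself, so the oracle exercises the derived network rather than a
#' re-derivation of it.
#'
#' @inheritParams steady_state
#' @return Named state vector (19 concentrations, uM), attribute `ca`.
#' @export
equilibrium_oracle <- function(model, ca = model$control_ca) {
  stopifnot(ca >= 0)
  sp <- cam_species()$name
  rx <- model$reactions
  # weight of species s: conc(s) = apo * a[s] * x^(b[s]) with b = CAMTA count
  a <- setNames(rep(NA_real_, 19L), sp)
  b <- setNames(rep(NA_integer_, 19L), sp)
  a["M00"] <- 1; b["M00"] <- 0L
  queue <- "M00"
  while (length(queue)) {
    s <- queue[[1]]; queue <- queue[-1]
    fwd <- which(rx$from == s); bwd <- which(rx$to == s)
    for (j in fwd) {
      t <- rx$to[j]
      if (is.na(a[t])) {
        fac <- if (rx$type[j] == "bind") 1 / rx$kd[j] else ca / rx$kd[j]
        a[t] <- a[s] * fac
        b[t] <- b[s] + if (rx$type[j] == "bind") 1L else 0L
        queue <- c(queue, t)
      }
    }
    for (j in bwd) {
      t <- rx$from[j]
      if (is.na(a[t])) {
        fac <- if (rx$type[j] == "bind") rx$kd[j] else rx$kd[j] / ca
        if (rx$type[j] != "bind" && ca == 0) next  # unreachable at ca = 0
        a[t] <- a[s] * fac
        b[t] <- b[s] - if (rx$type[j] == "bind") 1L else 0L
        queue <- c(queue, t)
      }
    }
  }
  cam_i <- 1:18
  reach <- !is.na(a[cam_i])
  w_free <- sum(a[cam_i][reach & b[cam_i] == 0L])
  w_bound <- sum(a[cam_i][reach & b[cam_i] == 1L])
  camt <- model$base$cam_total; xt <- model$base$camta_total
  x_of <- function(m) xt / (1 + m * w_bound)
  g <- function(m) m * (w_free + x_of(m) * w_bound) - camt
  upper <- camt / w_free
  if (g(upper) < 0)  # numerically exact upper bracket can fall short
    upper <- upper * (1 + 1e-9)
  m <- stats::uniroot(g, c(0, upper), tol = .Machine$double.eps)$root
  x <- x_of(m)
  y <- numeric(19L)
  y[cam_i][reach] <- m * a[cam_i][reach] * x^b[cam_i][reach]
  y[19L] <- x
  names(y) <- sp
  attr(y, "ca") <- ca
  y
}

#' Simulate the binding network under a clamped calcium trace
#'
#' Integrates the 19-state mass-action system driven by a time-dependent
#' Ca2+ input. The default stiff-capable integrator is LSODA at relative and
#' absolute tolerance 1e-5. Trace values between samples are linearly
#' interpolated; beyond the trace ends the end values are held. Traces
#' produced by [piecewise_signature()] carry their switch times and constant
#' segment levels, and the integrator is then restarted at each switch with
#' the exact constant level, so square-wave discontinuities are handled
#' without interpolation smearing.
#'
#' @param trace A [ca_trace()] calcium trace (seconds, uM).
#' @param model A [cam_model()].
#' @param out_dt Output grid spacing in seconds.
#' @param t_end End of the simulated span (s); defaults to the trace end.
#' @param init Initial state; defaults to the control-Ca equilibrium.
#' @param rtol,atol Integrator tolerances; default from `model`.
#' @return A data frame of class `cam_trajectory`: `time_s` followed by the
#'   19 species columns (uM), attribute `ca_fun` (the interpolated input).
#' @export
simulate_binding <- function(trace, model, out_dt = 0.05,
                             t_end = max(trace$time_s), init = NULL,
                             rtol = model$rtol, atol = model$atol) {
  stopifnot(inherits(trace, "ca_trace"))
  if (is.null(init)) init <- steady_state(model)
  t0 <- trace$time_s[1]
  if (t_end <= t0) stop("t_end must exceed the trace start")
  cafun <- stats::approxfun(trace$time_s, trace$ca_um, rule = 2)
  seg <- attr(trace, "segments")
  y <- as.numeric(init)
  times_all <- numeric(0); states <- list()

  integrate_piece <- function(y, ta, tb, f) {
    times <- unique(c(seq(ta, tb, by = out_dt), tb))
    out <- deSolve::lsoda(y, times, f, NULL, rtol = rtol, atol = atol)
    if (attr(out, "istate")[1] < 0)
      stop(sprintf("integrator failed in [%g, %g] s: %s", ta, tb,
                   paste(attr(out, "istate"), collapse = " ")))
    out
  }

  if (!is.null(seg)) {
    # piecewise-constant input: restart at each switch, clamp exactly
    seg <- seg[seg$t1 > t0 & seg$t0 < t_end, , drop = FALSE]
    seg$t0 <- pmax(seg$t0, t0); seg$t1 <- pmin(seg$t1, t_end)
    if (max(seg$t1) < t_end)
      seg <- rbind(seg, data.frame(t0 = max(seg$t1), t1 = t_end,
                                   ca = seg$ca[nrow(seg)]))
    for (k in seq_len(nrow(seg))) {
      out <- integrate_piece(y, seg$t0[k], seg$t1[k],
                             rhs_const_ca(model, seg$ca[k]))
      y <- pmax(as.numeric(out[nrow(out), -1]), 0)
      keep <- if (k == 1) seq_len(nrow(out)) else -1L
      times_all <- c(times_all, out[keep, 1])
      states[[k]] <- out[keep, -1, drop = FALSE]
    }
  } else {
    out <- integrate_piece(y, t0, t_end, rhs_forced_ca(model, cafun))
    times_all <- out[, 1]
    states[[1]] <- out[, -1, drop = FALSE]
  }
  traj <- data.frame(time_s = times_all, do.call(rbind, states))
  names(traj) <- c("time_s", model$species$name)
  class(traj) <- c("cam_trajectory", "data.frame")
  attr(traj, "ca_fun") <- cafun
  attr(traj, "model") <- model
  traj
}

#' Verify conservation of CaM and CAMTA totals along a trajectory
#'
#' @param traj A `cam_trajectory` from [simulate_binding()].
#' @param model The model used to produce it (defaults to the one attached
#'   to the trajectory).
#' @param rel_tol Relative tolerance.
#' @return `TRUE` invisibly, or an error naming the worst time point.
#' @export
check_conservation <- function(traj, model = attr(traj, "model"),
                               rel_tol = 1e-6) {
  s <- as.matrix(traj[, model$species$name])
  cam <- rowSums(s[, 1:18, drop = FALSE])
  camta <- rowSums(s[, c(10:18, 19), drop = FALSE])
  err_cam <- max(abs(cam - model$base$cam_total)) / model$base$cam_total
  err_x <- max(abs(camta - model$base$camta_total)) / model$base$camta_total
  if (err_cam > rel_tol || err_x > rel_tol)
    stop(sprintf("conservation violated: CaM rel err %.2e, CAMTA rel err %.2e",
                 err_cam, err_x))
  invisible(TRUE)
}
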