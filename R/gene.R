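#' Gene expression parameters
#'
#' The expression stage is a single mRNA balance driven by the active
#' complex `M22X` (4Ca2+-CaM-CAMTA) through a Hill term, after a fixed
#' delay `tau_s` that stands for pre-initiation complex assembly. Two
#' regulation modes exist: activation (transcription increases with the
#' active complex) and repression (decreases).
#'
#' @param k1 Base transcription rate (uM s^-1).
#' @param k2 Maximal regulated transcription rate (uM s^-1).
#' @param k3 mRNA decay rate constant (s^-1).
#' @param k4 DNA-binding affinity of the active complex (uM).
#' @param n Hill coefficient (1, 2 or 3).
#' @param tau_s Delay between the calcium-driven complex and the
#'   transcriptional response (s).
#' @param mode `"activation"` or `"repression"`.
#' @return A list of class `gene_params`.
#' @export
gene_params <- function(k1 = 5.0e-6, k2 = 5.0e-2, k3 = 3.75e-4,
                        k4 = 1.1e-2, n = 2, tau_s = 600,
                        mode = c("activation", "repression")) {
  mode <- match.arg(mode)
  stopifnot(k1 > 0, k2 > 0, k3 > 0, k4 > 0, tau_s >= 0)
  if (!n %in% c(1, 2, 3)) stop("Hill coefficient n must be 1, 2 or 3")
  structure(list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, n = n,
                 tau_s = tau_s, mode = mode),
            class = "gene_params")
}

# instantaneous transcription rate as a function of the active complex
production_rate <- function(m22x, params) {
  h <- (m22x / params$k4)^params$n
  # 1 - 1/(1+h) rather than h/(1+h): well-defined in the saturation limit
  if (params$mode == "activation") params$k1 + params$k2 * (1 - 1 / (1 + h))
  else params$k1 + params$k2 / (1 + h)
}

#' mRNA balance right-hand side
#'
#' Activation: `d[mRNA]/dt = k1 + k2 (m/k4)^n / (1 + (m/k4)^n) - k3 [mRNA]`;
#' repression replaces the Hill term by `k2 / (1 + (m/k4)^n)`.
#'
#' @param mrna mRNA concentration (uM).
#' @param m22x Active complex concentration (uM).
#' @param params A [gene_params()].
#' @return d\[mRNA\]/dt in uM s^-1.
#' @export
mrna_rhs <- function(mrna, m22x, params) {
  stopifnot(mrna >= 0, m22x >= 0)
  production_rate(m22x, params) - params$k3 * mrna
}

#' Steady-state mRNA level and fold change
#'
#' Closed form: production rate divided by `k3`. The fold is taken against
#' the steady state at a reference (control) active-complex level.
#'
#' @inheritParams mrna_rhs
#' @param baseline_m22x Control active-complex level (uM) for the fold.
#' @return A list with `mrna_um` and `fold`.
#' @examples
#' gp <- gene_params()
#' mrna_steady_state(0, gp)$mrna_um          # k1 / k3
#' mrna_steady_state(1e6, gp, 0)$fold        # -> (k1 + k2) / k1
#' @export
mrna_steady_state <- function(m22x, params, baseline_m22x = 0) {
  ss <- production_rate(m22x, params) / params$k3
  ss0 <- production_rate(baseline_m22x, params) / params$k3
  list(mrna_um = ss, fold = ss / ss0)
}

#' Potential fold change over a grid of active-complex levels
#'
#' The potential fold is the steady-state expression fold that would be
#' reached if the active complex were held at a given level indefinitely.
#' It bounds what any transient excursion to that level can achieve.
#'
#' @param m22x_grid Positive, sorted grid of active-complex levels (uM).
#' @inheritParams mrna_steady_state
#' @return A data frame `m22x_um`, `fold`.
#' @export
potential_fold_curve <- function(m22x_grid, params, baseline_m22x = 0) {
  stopifnot(all(m22x_grid >= 0), !is.unsorted(m22x_grid))
  data.frame(m22x_um = m22x_grid,
             fold = vapply(m22x_grid, function(m)
               mrna_steady_state(m, params, baseline_m22x)$fold,
               numeric(1)))
}

#' Simulate delayed mRNA dynamics driven by an active-complex trajectory
#'
#' The mRNA balance is integrated with the delayed input `m22x(t - tau)`;
#' because expression does not feed back on the binding network, the delay
#' is implemented by time-shifting the input rather than by a
#' delay-differential solver. For `t - tau` before the trajectory start the
#' input is the control level, and the initial mRNA is the steady state at
#' that control level.
#'
#' @param m22x_traj Data frame with columns `time_s` and `m22x_um` (or a
#'   `cam_trajectory`, from which the active-complex column is taken).
#' @param params A [gene_params()].
#' @param control_m22x Control active-complex level (uM).
#' @param t_end End of the integration (s); defaults to the trajectory end.
#' @param out_dt Output grid spacing (s).
#' @param rtol,atol Integrator tolerances.
#' @return Data frame `time_s`, `mrna_um`, `fold` (fold against the control
#'   steady state).
#' @export
simulate_gene <- function(m22x_traj, params, control_m22x,
                          t_end = NULL, out_dt = 0.5,
                          rtol = 1e-7, atol = 1e-12) {
  if (inherits(m22x_traj, "cam_trajectory"))
    m22x_traj <- data.frame(time_s = m22x_traj$time_s,
                            m22x_um = m22x_traj[[active_species()]])
  stopifnot(all(c("time_s", "m22x_um") %in% names(m22x_traj)),
            control_m22x >= 0)
  t0 <- m22x_traj$time_s[1]
  if (is.null(t_end)) t_end <- max(m22x_traj$time_s)
  if (t_end > max(m22x_traj$time_s) + params$tau_s + 1e-9)
    stop("active-complex trajectory ends before the requested horizon")
  f_in <- stats::approxfun(m22x_traj$time_s, m22x_traj$m22x_um, rule = 2)
  delayed <- function(t) {
    td <- t - params$tau_s
    if (td < t0) control_m22x else f_in(td)
  }
  mrna0 <- mrna_steady_state(control_m22x, params)$mrna_um
  rhs <- function(t, y, p) list(production_rate(delayed(t), params) -
                                  params$k3 * y)
  times <- unique(c(seq(t0, t_end, by = out_dt), t_end))
  out <- deSolve::lsoda(c(mrna = mrna0), times, rhs, NULL,
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("mRNA integration failed: istate ", attr(out, "istate")[1])
  mrna <- pmax(out[, 2], 0)
  data.frame(time_s = out[, 1], mrna_um = mrna, fold = mrna / mrna0)
}
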