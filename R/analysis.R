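#' Fold-change amplification of a calcium signature
#'
#' Simulates the binding network under a signature and expresses both the
#' input Ca2+ and the active complex `M22X` as fold changes over their
#' control-steady-state values. The Ca2+-CaM-CAMTA ladder needs four Ca2+
#' ions to reach the active complex, so the complex fold is super-linear in
#' the calcium fold.
#'
#' @param trace A [ca_trace()].
#' @param model A [cam_model()].
#' @param out_dt Output grid spacing (s).
#' @param t_end Simulation horizon (s).
#' @return A list of class `fold_change_result` with `times`, `ca_fold`,
#'   `m22x_fold`, `controls` and `summary` (peak folds).
#' @export
amplification_analysis <- function(trace, model, out_dt = 0.05,
                                   t_end = max(trace$time_s)) {
  ctrl <- steady_state(model)
  ca0 <- model$control_ca
  m0 <- ctrl[[active_species()]]
  if (ca0 <= 0 || m0 <= 0)
    stop("control Ca or active-complex concentration is zero; folds undefined")
  traj <- simulate_binding(trace, model, out_dt = out_dt, t_end = t_end,
                           init = ctrl)
  cafun <- attr(traj, "ca_fun")
  res <- list(
    times = traj$time_s,
    ca_fold = cafun(traj$time_s) / ca0,
    m22x_fold = traj[[active_species()]] / m0,
    controls = list(ca_um = ca0, m22x_um = m0),
    summary = NULL)
  res$summary <- list(peak_ca_fold = max(res$ca_fold),
                      peak_m22x_fold = max(res$m22x_fold))
  class(res) <- "fold_change_result"
  res
}

#' Equilibrium amplification of the active complex
#'
#' For each requested calcium fold, the equilibrium active-complex
#' concentration at `fold * control_ca` is divided by its value at
#' `control_ca`. In the unsaturated regime a fold `f` in Ca2+ approaches an
#' `f^4` fold in the four-site-loaded complex; saturation of the CaM and
#' CAMTA pools bends it below that.
#'
#' @param folds Numeric vector of Ca2+ fold increases (>= 1).
#' @param model A [cam_model()].
#' @param control_ca Reference Ca2+ level (uM).
#' @return Data frame `ca_fold`, `m22x_fold`.
#' @export
steady_state_amplification <- function(folds, model,
                                       control_ca = model$control_ca) {
  stopifnot(all(folds >= 1), control_ca > 0)
  m0 <- steady_state(model, control_ca)[[active_species()]]
  m22 <- vapply(folds, function(f)
    steady_state(model, control_ca * f)[[active_species()]], numeric(1))
  data.frame(ca_fold = folds, m22x_fold = m22 / m0)
}

#' Decode a calcium signature into a gene-expression fold change
#'
#' The full pipeline: settle the binding network at the control calcium
#' level, simulate it under the signature, drive the delayed expression
#' stage with the resulting active-complex trajectory, and report all three
#' layers as fold changes over control. The summary reports folds at the
#' readout time (default one hour after the trace start) and whether the
#' gene counts as induced (>= 1.5-fold at readout).
#'
#' @param trace A [ca_trace()].
#' @param model A [cam_model()].
#' @param gene A [gene_params()].
#' @param readout_s Readout time (s) after the trace start.
#' @param out_dt Active-complex sampling interval (s) used to force the
#'   expression stage; must resolve the sub-second complex rise at spike
#'   edges.
#' @param gene_dt Output spacing of the expression stage (s).
#' @return A `fold_change_result` with `times`, `ca_fold`, `m22x_fold`,
#'   `mrna_fold`, `controls`, and `summary` (peaks, readout folds,
#'   induction flag).
#' @export
decode_signature <- function(trace, model, gene = gene_params(),
                             readout_s = 3600, out_dt = 0.05,
                             gene_dt = 0.5) {
  ctrl <- steady_state(model)
  ca0 <- model$control_ca
  m0 <- ctrl[[active_species()]]
  if (ca0 <= 0 || m0 <= 0)
    stop("control Ca or active-complex concentration is zero; folds undefined")
  t0 <- trace$time_s[1]
  horizon <- max(max(trace$time_s), t0 + readout_s)
  traj <- simulate_binding(trace, model, out_dt = out_dt, t_end = horizon,
                           init = ctrl)
  expr <- simulate_gene(traj, gene, control_m22x = m0, t_end = horizon,
                        out_dt = gene_dt)
  cafun <- attr(traj, "ca_fun")
  m22fun <- stats::approxfun(traj$time_s, traj[[active_species()]], rule = 2)
  t_read <- t0 + readout_s
  foldfun <- stats::approxfun(expr$time_s, expr$fold, rule = 2)
  res <- list(
    times = expr$time_s,
    ca_fold = cafun(expr$time_s) / ca0,
    m22x_fold = m22fun(expr$time_s) / m0,
    mrna_fold = expr$fold,
    controls = list(ca_um = ca0, m22x_um = m0,
                    mrna_um = mrna_steady_state(m0, gene)$mrna_um),
    summary = NULL)
  res$summary <- list(
    peak_ca_fold = max(res$ca_fold),
    peak_m22x_fold = max(res$m22x_fold),
    peak_mrna_fold = max(res$mrna_fold),
    readout_s = readout_s,
    mrna_fold_at_readout = foldfun(t_read),
    induced = foldfun(t_read) >= 1.5)
  class(res) <- "fold_change_result"
  res
}

#' @export
print.fold_change_result <- function(x, ...) {
  s <- x$summary
  cat("Fold-change result vs control steady state\n")
  cat(sprintf("  peak Ca fold    : %.4g\n", s$peak_ca_fold))
  cat(sprintf("  peak M22X fold  : %.4g\n", s$peak_m22x_fold))
  if (!is.null(s$peak_mrna_fold)) {
    cat(sprintf("  peak mRNA fold  : %.4g\n", s$peak_mrna_fold))
    cat(sprintf("  mRNA fold at %g s: %.4g (%s)\n", s$readout_s,
                s$mrna_fold_at_readout,
                if (isTRUE(s$induced)) "induced" else "not induced"))
  }
  invisible(x)
}

#' Potential-versus-actual expression history of a signature
#'
#' Pairs the actual expression fold along a signature with the potential
#' fold curve (steady-state fold as a function of the active-complex level).
#' The actual fold lags the potential: each excursion of the complex sets a
#' transient target the slow mRNA pool never reaches, and what has been
#' gained is retained into the next cycle, so expression accumulates the
#' signature's history.
#'
#' @inheritParams decode_signature
#' @param grid_n Number of points of the potential curve.
#' @return A list with `actual` (data frame `time_s`, `m22x_fold`,
#'   `mrna_fold`), `potential` (data frame `m22x_um`, `fold`), and
#'   `controls`.
#' @export
history_trace <- function(trace, model, gene = gene_params(),
                          readout_s = 3600, out_dt = 0.05, gene_dt = 0.5,
                          grid_n = 200) {
  dec <- decode_signature(trace, model, gene, readout_s = readout_s,
                          out_dt = out_dt, gene_dt = gene_dt)
  m0 <- dec$controls$m22x_um
  m_hi <- max(dec$m22x_fold) * m0
  grid <- m0 * exp(seq(0, log(max(m_hi / m0, 1 + 1e-9)),
                       length.out = grid_n))
  list(actual = data.frame(time_s = dec$times,
                           m22x_fold = dec$m22x_fold,
                           mrna_fold = dec$mrna_fold),
       potential = potential_fold_curve(grid, gene, baseline_m22x = m0),
       controls = dec$controls)
}

#' Calibrate the total CaM concentration against an expression anchor
#'
#' The total CaM concentration is not fixed by the anchored parameter set.
#' This operation finds the value for which a given signature produces a
#' target expression fold at the readout time, by bracketed root finding on
#' `log10(CaM_total)`. Monotonicity of the readout fold in the total is
#' verified at the bracket endpoints before solving; an unreachable target
#' is reported with the endpoint folds.
#'
#' @param target_fold Target mRNA fold at readout.
#' @param trace The anchor signature.
#' @param model Template [cam_model()]; every candidate total reuses its
#'   other parameters.
#' @param gene A [gene_params()].
#' @param bounds Search interval for the total (uM).
#' @param readout_s Readout time (s).
#' @param rel_tol Required relative accuracy of the achieved fold.
#' @param ... Passed to [decode_signature()].
#' @return The calibrated total (uM) with attributes `achieved_fold` and
#'   `iterations`.
#' @export
calibrate_cam_total <- function(target_fold, trace, model,
                                gene = gene_params(),
                                bounds = c(0.5, 500), readout_s = 3600,
                                rel_tol = 0.01, ...) {
  stopifnot(target_fold > 0, length(bounds) == 2, all(bounds > 0),
            bounds[1] < bounds[2])
  evals <- 0L
  fold_at <- function(camt) {
    evals <<- evals + 1L
    b <- model$base; b$cam_total <- camt
    m <- cam_model(base = b, control_ca = model$control_ca,
                   rtol = model$rtol, atol = model$atol)
    decode_signature(trace, m, gene, readout_s = readout_s,
                     ...)$summary$mrna_fold_at_readout
  }
  f_lo <- fold_at(bounds[1]); f_hi <- fold_at(bounds[2])
  if (f_lo >= f_hi)
    stop(sprintf("readout fold is not increasing over the bounds (%.4g at %g uM, %.4g at %g uM)",
                 f_lo, bounds[1], f_hi, bounds[2]))
  if (target_fold < f_lo || target_fold > f_hi)
    stop(sprintf("target fold %.4g outside achievable range [%.4g, %.4g] for CaM totals [%g, %g] uM",
                 target_fold, f_lo, f_hi, bounds[1], bounds[2]))
  root <- stats::uniroot(function(lc) fold_at(10^lc) - target_fold,
                         log10(bounds), tol = 1e-5)
  camt <- 10^root$root
  achieved <- fold_at(camt)
  if (abs(achieved - target_fold) / target_fold > rel_tol)
    stop(sprintf("calibration did not reach the target within %.2g%%: achieved %.6g vs %.6g",
                 100 * rel_tol, achieved, target_fold))
  structure(camt, achieved_fold = achieved, iterations = evals)
}

#' Expression fold as a function of the oscillation period
#'
#' Runs the decoding pipeline for square-wave signatures sharing average,
#' maximum, minimum, and duration but differing in period. Fewer, longer
#' spikes give the active complex time to equilibrate at the peak within
#' each cycle, so the readout fold increases with period at fixed duration.
#'
#' @param periods Periods to scan (s).
#' @param spec Named list of [piecewise_signature()] arguments except
#'   `period` (`a`, `ca_max`, `ca_min`, `duration`, optionally `onset`,
#'   `baseline`, `dt`).
#' @inheritParams decode_signature
#' @return Data frame `period_s`, `n_spikes`, `mrna_fold_at_readout`,
#'   `peak_m22x_fold`.
#' @export
period_scan <- function(periods, spec, model, gene = gene_params(),
                        readout_s = 3600, ...) {
  rows <- lapply(periods, function(T) {
    tr <- do.call(piecewise_signature, c(spec, list(period = T)))
    dec <- decode_signature(tr, model, gene, readout_s = readout_s, ...)
    data.frame(period_s = T, n_spikes = attr(tr, "n_spikes"),
               mrna_fold_at_readout = dec$summary$mrna_fold_at_readout,
               peak_m22x_fold = dec$summary$peak_m22x_fold)
  })
  do.call(rbind, rows)
}

#' Expression fold as a function of spike number at fixed period
#'
#' Varies the signature duration as `count * period` while keeping the
#' period fixed. More spikes deliver more integrated active complex, so the
#' readout fold increases with the count (activation mode).
#'
#' @param counts Spike counts to scan (>= 0; 0 means no signature).
#' @param spec Named list of [piecewise_signature()] arguments except
#'   `duration` (must include `period`).
#' @inheritParams decode_signature
#' @return Data frame `n_spikes`, `duration_s`, `mrna_fold_at_readout`.
#' @export
duration_scan <- function(counts, spec, model, gene = gene_params(),
                          readout_s = 3600, ...) {
  stopifnot(all(counts >= 0), !is.null(spec$period))
  rows <- lapply(counts, function(k) {
    dur <- k * spec$period
    fold <- if (k == 0) 1 else {
      tr <- do.call(piecewise_signature, c(spec, list(duration = dur)))
      decode_signature(tr, model, gene, readout_s = readout_s,
                       ...)$summary$mrna_fold_at_readout
    }
    data.frame(n_spikes = k, duration_s = dur, mrna_fold_at_readout = fold)
  })
  do.call(rbind, rows)
}
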