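#' Simulate tail-current G-V datasets from a known Boltzmann
#'
#' Generates per-condition tables of peak tail currents following
#' G/Gmax = 1 / (1 + exp((V - V0.5) / k)) with a condition-specific shift of
#' V0.5 (e.g. a hyperpolarizing shift under drug) plus Gaussian noise, the
#' form used for hyperpolarization-activated channels (conductance rises as
#' the membrane is hyperpolarized; k > 0).
#'
#' @param v_half control half-activation voltage (mV).
#' @param k inverse slope factor (mV, > 0).
#' @param shifts named numeric, condition -> V0.5 shift (mV); a `control`
#'   entry of 0 is added if absent.
#' @param noise_sd Gaussian noise SD on the normalized conductance scale.
#' @param voltages test voltages (mV); the default spans -20 to -140 mV in
#'   10-mV steps.
#' @param n_replicates replicates (cells) per condition.
#' @param amplitude maximal tail-current amplitude (arbitrary units).
#' @param seed RNG seed.
#' @return data.frame with columns `condition`, `replicate`, `voltage_mV`,
#'   `tail_current`, plus the true parameters in attributes
#'   `true_v_half`, `true_k`, `true_shifts`.
#' @export
generate_gv_dataset <- function(v_half = -90, k = 8,
                                shifts = c(control = 0),
                                noise_sd = 0.02,
                                voltages = seq(-20, -140, by = -10),
                                n_replicates = 5L, amplitude = 1,
                                seed = 1L) {
  if (k <= 0) stop("k must be positive")
  if (!length(voltages)) stop("voltages must be non-empty")
  if (!"control" %in% names(shifts)) shifts <- c(control = 0, shifts)
  set.seed(as.integer(seed))
  rows <- list()
  for (cond in names(shifts)) {
    for (rep_i in seq_len(n_replicates)) {
      g <- 1 / (1 + exp((voltages - (v_half + shifts[[cond]])) / k))
      cur <- amplitude * g + stats::rnorm(length(voltages), 0, noise_sd * amplitude)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, replicate = rep_i, voltage_mV = voltages,
        tail_current = cur)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "true_v_half") <- v_half
  attr(out, "true_k") <- k
  attr(out, "true_shifts") <- shifts
  out
}

#' Normalize peak tail currents to the maximum
#'
#' @param table data.frame with columns `voltage_mV` and `tail_current`
#'   (one replicate's recordings; >= 4 voltages).
#' @return object of class `gv_curve`: `voltages`, `g_norm`.
#' @export
normalize_tail_currents <- function(table) {
  stopifnot(all(c("voltage_mV", "tail_current") %in% names(table)))
  if (nrow(table) < 4L) stop("need at least 4 voltages spanning the transition")
  mx <- max(table$tail_current)
  if (mx == 0) stop("all tail currents are zero; cannot normalize")
  structure(list(voltages = table$voltage_mV, g_norm = table$tail_current / mx),
            class = "gv_curve")
}

#' Fit a two-parameter Boltzmann activation curve
#'
#' Least-squares fit of G/Gmax = 1 / (1 + exp((V - V0.5) / k)) with k
#' constrained positive. Initialization is deterministic: V0.5 from linear
#' interpolation of the voltage at which the curve crosses 0.5, and k from
#' the width of the 0.25-0.75 conductance span divided by 2.2 (for an exact
#' Boltzmann that width is 2 k ln 3).
#'
#' @param curve a `gv_curve` from [normalize_tail_currents()], or any list
#'   with `voltages` and `g_norm`.
#' @return object of class `boltzmann_fit`: `v_half`, `k`, their standard
#'   errors, `rss` and the `fitted` values.
#' @export
fit_boltzmann <- function(curve) {
  v <- curve$voltages; g <- curve$g_norm
  stopifnot(length(v) == length(g), length(v) >= 4L)
  if (any(g < -0.2 | g > 1.2))
    stop("normalized conductance outside the [-0.2, 1.2] tolerance band")
  o <- order(v)
  vs <- v[o]; gs <- g[o]
  interp_at <- function(level) {
    cross <- which(diff(sign(gs - level)) != 0)
    if (!length(cross)) return(vs[which.min(abs(gs - level))])
    i <- cross[1]
    vs[i] + (level - gs[i]) * (vs[i + 1] - vs[i]) / (gs[i + 1] - gs[i])
  }
  v0_init <- interp_at(0.5)
  k_init <- abs(interp_at(0.25) - interp_at(0.75)) / 2.2
  if (!is.finite(k_init) || k_init <= 0) k_init <- diff(range(vs)) / 10
  dat <- data.frame(v = v, g = g)
  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ 1 / (1 + exp((v - v0) / k)), data = dat,
                      start = list(v0 = v0_init, k = k_init),
                      lower = c(v0 = -Inf, k = 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf("Boltzmann fit failed to converge (start v0=%.2f, k=%.2f): %s",
                   v0_init, k_init, conditionMessage(e))))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(v0 = NA_real_, k = NA_real_))
  structure(list(v_half = unname(cf[["v0"]]), k = unname(cf[["k"]]),
                 se_v_half = unname(se[["v0"]]), se_k = unname(se[["k"]]),
                 rss = sum(stats::resid(fit)^2),
                 fitted = stats::fitted(fit), nls = fit),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> V0.5 = %.2f +/- %.2f mV, k = %.2f +/- %.2f mV (rss %.3g)\n",
              x$v_half, x$se_v_half, x$k, x$se_k, x$rss))
  invisible(x)
}

#' Drug-induced shift of half-activation voltage
#'
#' @param fit_drug,fit_control `boltzmann_fit` objects.
#' @return named numeric: `delta_v_half` (drug minus control, mV) and `se`
#'   (root sum of squares of the two standard errors).
#' @export
delta_v05 <- function(fit_drug, fit_control) {
  stopifnot(inherits(fit_drug, "boltzmann_fit"),
            inherits(fit_control, "boltzmann_fit"))
  c(delta_v_half = fit_drug$v_half - fit_control$v_half,
    se = sqrt(fit_drug$se_v_half^2 + fit_control$se_v_half^2))
}

#' Per-replicate Boltzmann fits of a G-V dataset
#'
#' Normalizes and fits each (condition, replicate) table separately and
#' summarizes V0.5 shifts relative to the mean control V0.5.
#'
#' @param gv data.frame as produced by [generate_gv_dataset()].
#' @param control_label control condition name.
#' @return list with `fits` (data.frame: condition, replicate, v_half, k)
#'   and `shifts` (data.frame: condition, mean shift, sd).
#' @export
fit_gv_dataset <- function(gv, control_label = "control") {
  pieces <- split(gv, list(gv$condition, gv$replicate), drop = TRUE)
  rows <- lapply(pieces, function(p) {
    f <- fit_boltzmann(normalize_tail_currents(p))
    data.frame(condition = p$condition[1], replicate = p$replicate[1],
               v_half = f$v_half, k = f$k)
  })
  fits <- do.call(rbind, rows)
  rownames(fits) <- NULL
  ctrl <- mean(fits$v_half[fits$condition == control_label])
  ag <- stats::aggregate(v_half ~ condition, fits,
                         function(x) c(mean = mean(x), sd = stats::sd(x)))
  shifts <- data.frame(condition = ag$condition,
                       delta_v_half = ag$v_half[, "mean"] - ctrl,
                       sd_v_half = ag$v_half[, "sd"])
  list(fits = fits, shifts = shifts)
}
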