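#' Settings for nonlinear least-squares fitting
#'
#' @param max_iterations iteration cap for the damped (Marquardt-style)
#'   least-squares minimizer.
#' @param step_tolerance,residual_tolerance relative convergence tolerances
#'   on the parameter step and on the sum of squares.
#' @param strategy `"staged"` fits DPA and Cry sigmoids first, then the
#'   biomass equation (with the fitted DPA curve inserted), then the PHB
#'   equation (fitted DPA and Cry inserted); `"joint"` refines all 15
#'   parameters in one least-squares problem initialized from the staged
#'   solution.
#' @param censoring_policy below-detection-limit points are recorded as 0;
#'   `"include"` keeps them in the fit as zeros (how non-detects enter the
#'   observed kinetics), `"exclude"` drops them.
#' @param clamp_predictions clamp model predictions of biomass/PHB at 0
#'   during fitting. Observed concentrations are non-negative while the raw
#'   two-term equations go negative late in culture; fitting the clamped
#'   model avoids penalizing the fit for negative predictions at
#'   late-culture zeros.
#' @return a list of class `fit_settings`.
#' @export
fit_settings <- function(max_iterations = 1000,
                         step_tolerance = 1e-8,
                         residual_tolerance = 1e-8,
                         strategy = c("staged", "joint"),
                         censoring_policy = c("include", "exclude"),
                         clamp_predictions = TRUE) {
  stopifnot(step_tolerance > 0, residual_tolerance > 0, max_iterations >= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 step_tolerance = step_tolerance,
                 residual_tolerance = residual_tolerance,
                 strategy = match.arg(strategy),
                 censoring_policy = match.arg(censoring_policy),
                 clamp_predictions = isTRUE(clamp_predictions)),
            class = "fit_settings")
}

.lm_control <- function(settings) {
  minpack.lm::nls.lm.control(maxiter = settings$max_iterations,
                             ftol = settings$residual_tolerance,
                             ptol = settings$step_tolerance,
                             maxfev = 100000)
}

# initial guess for one sigmoid: asymptote from the data maximum, critical
# time at the steepest finite-difference rise, rate from the Gompertz
# max-slope identity (max slope = mu * A / e)
gomp_init <- function(times, values) {
  a0 <- max(values)
  slopes <- diff(values) / diff(times)
  if (length(slopes) && max(slopes) > 0) {
    i <- which.max(slopes)
    tc0 <- (times[i] + times[i + 1]) / 2
    mu0 <- exp(1) * max(slopes) / a0
  } else {
    tc0 <- stats::median(times)
    mu0 <- 0.5
  }
  c(asymptote = a0, rate = min(max(mu0, 0.05), 10), critical_time = tc0)
}

#' Fit a single Gompertz curve by damped least squares
#'
#' Minimizes the sum of squared deviations between observations and
#' \eqn{A \exp(-\exp(-\mu(t - t_c)))} with a Levenberg--Marquardt
#' minimizer, bounds \eqn{A \ge 0}, \eqn{\mu > 0}, \eqn{t_c} free.
#'
#' @param times,values observed kinetics; at least 4 finite points, not all
#'   equal.
#' @param settings a [fit_settings()] object.
#' @return a list of class `gompertz_fit`: `params` ([gompertz_params()]),
#'   `sse`, `r_squared`, `n_iterations`, `converged`.
#' @examples
#' p <- gompertz_params(5.58, 0.78, 4.54)
#' t <- seq(0, 20, 2)
#' fit_gompertz(t, gompertz_value(t, p))$params
#' @export
fit_gompertz <- function(times, values, settings = fit_settings()) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  ok <- is.finite(times) & is.finite(values)
  times <- times[ok]; values <- values[ok]
  if (length(values) < 4L)
    stop("insufficient data: need at least 4 finite observations, got ",
         length(values))
  if (diff(range(values)) == 0)
    stop("degenerate data: all observations are equal (", values[1], ")")
  start <- gomp_init(times, values)
  fn <- function(par) values - par[1] * exp(-exp(-par[2] * (times - par[3])))
  res <- minpack.lm::nls.lm(par = start, lower = c(0, 1e-8, -Inf),
                            upper = rep(Inf, 3), fn = fn,
                            control = .lm_control(settings))
  par <- res$par
  pred <- par[1] * exp(-exp(-par[2] * (times - par[3])))
  structure(list(params = gompertz_params(par[[1]], par[[2]], par[[3]]),
                 sse = sum((values - pred)^2),
                 r_squared = tryCatch(r_squared(values, pred),
                                      error = function(e) NA_real_),
                 n_iterations = res$niter,
                 converged = res$info %in% 1:4,
                 info = res$info),
            class = "gompertz_fit")
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares taken
#' about the observed mean. Always <= 1; negative when the fit is worse than
#' the mean.
#'
#' @param observed,predicted numeric vectors of equal length >= 2; the
#'   observations must not be constant.
#' @return a single number <= 1.
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted),
            length(observed) == length(predicted))
  if (length(observed) < 2L) stop("need at least 2 observations")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("undefined variance: 'observed' is constant")
  1 - sum((observed - predicted)^2) / ss_tot
}

.compounds <- c("biomass", "phb", "dpa", "cry")
.kin_cols <- c("time_h", "biomass_g_per_l", "phb_g_per_l",
               "dpa_g_per_l", "cry_g_per_l")

# observed (t, y) for one compound honouring the censoring policy
.obs_for <- function(series, compound, policy) {
  col <- paste0(compound, "_g_per_l")
  y <- series[[col]]
  t <- series$time_h
  cens <- attr(series, "censored")
  if (policy == "exclude" && !is.null(cens)) {
    keep <- !cens[, compound]
    t <- t[keep]; y <- y[keep]
  }
  list(t = t, y = y)
}

#' Fit the full biodynamic model to observed kinetics
#'
#' Estimates the 15 model parameters from a four-compound kinetics series by
#' nonlinear minimum sum of squares (Levenberg--Marquardt). The staged
#' strategy exploits the model's one-way coupling: DPA and Cry are free
#' sigmoids (fitted first, independently), the biomass equation depends only
#' on DPA (fitted next, estimating the biomass triple plus Y_DPA/X with the
#' fitted DPA curve inserted), and the PHB equation depends on DPA and Cry
#' (fitted last, estimating the PHB triple plus Y_DPA/PHB and Y_Cry/PHB).
#' The joint strategy then treats all 15 parameters as one least-squares
#' problem over the pooled residuals of the four compounds, initialized at
#' the staged solution, so its total SSE can only improve on it.
#'
#' A compound whose observations are degenerate (e.g. identically zero) fails
#' its stage; the remaining stages still run, the failed compound keeps a
#' placeholder zero-asymptote sigmoid, and the result is flagged via
#' `converged` and `stage_status`.
#'
#' @param series a `kinetics_series` (see [generate_kinetics()] or
#'   [read_kinetics()]): common time grid, all four compounds.
#' @param settings a [fit_settings()] object.
#' @return a list of class `biodynamic_fit`: `params`
#'   ([biodynamic_params()]), per-compound and total `sse`, per-compound
#'   `r_squared`, `n_iterations`, per-compound `converged`, `strategy`,
#'   `stage_status` (character, `"ok"` or the failure message).
#' @export
fit_biodynamic <- function(series, settings = fit_settings()) {
  stopifnot(is.data.frame(series))
  missing_cols <- setdiff(.kin_cols, names(series))
  if (length(missing_cols))
    stop("kinetics series is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  policy <- settings$censoring_policy
  status <- stats::setNames(rep("ok", 4), .compounds)
  n_iter <- stats::setNames(rep(NA_integer_, 4), .compounds)
  converged <- stats::setNames(rep(FALSE, 4), .compounds)
  placeholder <- gompertz_params(0, 1, 0)

  # stage 1: DPA and Cry as independent sigmoids
  sig_fit <- function(compound) {
    obs <- .obs_for(series, compound, policy)
    tryCatch(fit_gompertz(obs$t, obs$y, settings),
             error = function(e) {
               status[compound] <<- paste0(compound, " stage failed: ",
                                           conditionMessage(e))
               NULL
             })
  }
  dfit <- sig_fit("dpa")
  cfit <- sig_fit("cry")
  dpa_par <- if (is.null(dfit)) placeholder else dfit$params
  cry_par <- if (is.null(cfit)) placeholder else cfit$params
  if (!is.null(dfit)) { n_iter["dpa"] <- dfit$n_iterations; converged["dpa"] <- dfit$converged }
  if (!is.null(cfit)) { n_iter["cry"] <- cfit$n_iterations; converged["cry"] <- cfit$converged }

  clamp01 <- if (settings$clamp_predictions) function(x) pmax(x, 0) else identity

  # stage 2: biomass triple + Y_DPA/X against the growth-minus-death equation
  xobs <- .obs_for(series, "biomass", policy)
  dpa_x <- gompertz_value(xobs$t, dpa_par)
  x_start <- {
    ini <- gomp_init(xobs$t, xobs$y)
    consumed <- max(ini[1] - xobs$y[length(xobs$y)], 0.05)
    y0 <- min(max(dpa_x[length(dpa_x)] / consumed, 1e-4), 10)
    c(ini, y_dpa_x = unname(y0))
  }
  xres <- tryCatch({
    fn <- function(par)
      xobs$y - clamp01(par[1] * exp(-exp(-par[2] * (xobs$t - par[3]))) -
                         dpa_x / par[4])
    minpack.lm::nls.lm(par = x_start, lower = c(0, 1e-8, -Inf, 1e-8),
                       upper = rep(Inf, 4), fn = fn,
                       control = .lm_control(settings))
  }, error = function(e) {
    status["biomass"] <<- paste0("biomass stage failed: ", conditionMessage(e))
    NULL
  })
  if (!is.null(xres)) {
    bio_par <- gompertz_params(xres$par[[1]], xres$par[[2]], xres$par[[3]])
    y_dpa_x <- xres$par[[4]]
    n_iter["biomass"] <- xres$niter
    converged["biomass"] <- xres$info %in% 1:4
  } else {
    bio_par <- gomp_to_par(gomp_init(xobs$t, xobs$y))
    y_dpa_x <- x_start[[4]]
  }

  # stage 3: PHB triple + Y_DPA/PHB + Y_Cry/PHB against production minus
  # consumption
  pobs <- .obs_for(series, "phb", policy)
  dpa_p <- gompertz_value(pobs$t, dpa_par)
  cry_p <- gompertz_value(pobs$t, cry_par)
  p_start <- {
    ini <- gomp_init(pobs$t, pobs$y)
    consumed <- max(ini[1] - pobs$y[length(pobs$y)], 0.05)
    ydp0 <- min(max(dpa_p[length(dpa_p)] / (consumed / 2), 1e-4), 10)
    ycp0 <- min(max(cry_p[length(cry_p)] / (consumed / 2), 1e-4), 10)
    c(ini, y_dpa_phb = unname(ydp0), y_cry_phb = unname(ycp0))
  }
  pres <- tryCatch({
    fn <- function(par)
      pobs$y - clamp01(par[1] * exp(-exp(-par[2] * (pobs$t - par[3]))) -
                         dpa_p / par[4] - cry_p / par[5])
    minpack.lm::nls.lm(par = p_start, lower = c(0, 1e-8, -Inf, 1e-8, 1e-8),
                       upper = rep(Inf, 5), fn = fn,
                       control = .lm_control(settings))
  }, error = function(e) {
    status["phb"] <<- paste0("phb stage failed: ", conditionMessage(e))
    NULL
  })
  if (!is.null(pres)) {
    phb_par <- gompertz_params(pres$par[[1]], pres$par[[2]], pres$par[[3]])
    y_dpa_phb <- pres$par[[4]]; y_cry_phb <- pres$par[[5]]
    n_iter["phb"] <- pres$niter
    converged["phb"] <- pres$info %in% 1:4
  } else {
    phb_par <- gomp_to_par(gomp_init(pobs$t, pobs$y))
    y_dpa_phb <- p_start[[4]]; y_cry_phb <- p_start[[5]]
  }

  params <- biodynamic_params(
    biomass = bio_par, phb = phb_par, dpa = dpa_par, cry = cry_par,
    yields = yield_coefficients(y_dpa_x, y_dpa_phb, y_cry_phb),
    label = attr(series, "label"))

  joint_iter <- NA_integer_
  if (settings$strategy == "joint" && all(status == "ok")) {
    jres <- .fit_joint(series, params, settings)
    params <- jres$params
    joint_iter <- jres$n_iterations
    converged[] <- jres$converged
  }

  diag <- .fit_diagnostics(series, params, settings)
  structure(list(params = params, sse = diag$sse, r_squared = diag$r2,
                 n_iterations = c(n_iter, joint = joint_iter),
                 converged = converged, strategy = settings$strategy,
                 censoring_policy = policy, stage_status = status),
            class = "biodynamic_fit")
}

gomp_to_par <- function(ini) gompertz_params(ini[[1]], ini[[2]], ini[[3]])

# one LM problem over the pooled residuals of all four compounds
.fit_joint <- function(series, start_params, settings) {
  policy <- settings$censoring_policy
  clamp01 <- if (settings$clamp_predictions) function(x) pmax(x, 0) else identity
  obs <- lapply(.compounds, .obs_for, series = series, policy = policy)
  names(obs) <- .compounds
  fn <- function(par) {
    g <- function(t, i) par[i] * exp(-exp(-par[i + 1] * (t - par[i + 2])))
    rx <- obs$biomass$y -
      clamp01(g(obs$biomass$t, 1) - g(obs$biomass$t, 7) / par[13])
    rp <- obs$phb$y -
      clamp01(g(obs$phb$t, 4) - g(obs$phb$t, 7) / par[14] -
                g(obs$phb$t, 10) / par[15])
    rd <- obs$dpa$y - g(obs$dpa$t, 7)
    rc <- obs$cry$y - g(obs$cry$t, 10)
    c(rx, rp, rd, rc)
  }
  start <- params_to_flat(start_params)
  lower <- rep(c(0, 1e-8, -Inf), 4)
  lower <- c(lower, rep(1e-8, 3))
  res <- minpack.lm::nls.lm(par = start, lower = lower,
                            upper = rep(Inf, 15), fn = fn,
                            control = .lm_control(settings))
  list(params = flat_to_params(res$par, label = start_params$label),
       n_iterations = res$niter, converged = res$info %in% 1:4)
}

# per-compound SSE and R^2 of a parameter set against a series
.fit_diagnostics <- function(series, params, settings) {
  policy <- settings$censoring_policy
  clamp <- settings$clamp_predictions
  sse <- r2 <- stats::setNames(rep(NA_real_, 4), .compounds)
  pred_fun <- list(
    biomass = function(t) as.numeric(biomass_at(t, params, clamp = clamp)),
    phb = function(t) as.numeric(phb_at(t, params, clamp = clamp)),
    dpa = function(t) dpa_at(t, params),
    cry = function(t) cry_at(t, params))
  for (comp in .compounds) {
    o <- .obs_for(series, comp, policy)
    pred <- pred_fun[[comp]](o$t)
    sse[comp] <- sum((o$y - pred)^2)
    r2[comp] <- tryCatch(r_squared(o$y, pred), error = function(e) NA_real_)
  }
  list(sse = c(sse, total = sum(sse)), r2 = r2)
}

#' @export
print.biodynamic_fit <- function(x, ...) {
  cat("Biodynamic model fit (", x$strategy, " strategy, censored points ",
      x$censoring_policy, "d)\n", sep = "")
  for (comp in .compounds)
    cat(sprintf("  %-8s SSE = %-10.4g R2 = %-8.4f %s\n", comp,
                x$sse[comp], x$r_squared[comp],
                if (x$stage_status[comp] == "ok") "" else x$stage_status[comp]))
  cat(sprintf("  total SSE = %.4g\n", x$sse["total"]))
  print(x$params)
  invisible(x)
}
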