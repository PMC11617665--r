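#' Enzyme-inhibition kinetics
#'
#' Percent-inhibition arithmetic, sigmoidal dose-response (IC50) fitting,
#' global Michaelis-Menten inhibition fitting (Vmax, Km, Ki) under
#' competitive, uncompetitive, noncompetitive and mixed mechanisms with
#' AICc model comparison, Lineweaver-Burk diagnostics and the
#' Cheng-Prusoff IC50/Ki relation.
#'
#' All fits are nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) on log-transformed parameters, which enforces
#' positivity; standard errors come from the Gauss-Newton covariance at the
#' optimum, mapped to the natural scale by the delta method.
#'
#' @name kinetics
NULL

#' Percent inhibition from corrected absorbances
#'
#' \code{(1 - A415t / A415c) * 100}, where \code{A415t} is the corrected
#' absorbance (final minus initial) with the test compound and \code{A415c}
#' the corrected absorbance of the uninhibited control.
#'
#' @param A415t,A415c corrected absorbances (control must be positive).
#' @return Percent inhibition (100 = complete inhibition).
#' @export
percent_inhibition <- function(A415t, A415c) {
  if (any(A415c <= 0)) stop("control absorbance must be positive")
  if (any(A415t < 0)) stop("absorbances must be non-negative")
  (1 - A415t / A415c) * 100
}

#' Sigmoidal dose-response model
#'
#' \code{A100 / (1 + (IC50 / I)^s)}: percent inhibition at inhibitor
#' concentration \code{I}, saturating at \code{A100}, half-maximal at
#' \code{I = IC50}, with Hill-type cooperativity \code{s}. Zero at
#' \code{I = 0} by continuity (for \code{s > 0}).
#'
#' @param I inhibitor concentration (mM), non-negative.
#' @param A100 maximum inhibition (percent).
#' @param IC50 half-maximal concentration (mM), positive.
#' @param s cooperativity exponent, positive.
#' @return Percent inhibition, same length as \code{I}.
#' @export
dose_response_model <- function(I, A100, IC50, s = 1) {
  if (IC50 <= 0 || s <= 0) stop("IC50 and s must be positive")
  if (any(I < 0)) stop("concentrations must be non-negative")
  ifelse(I > 0, A100 / (1 + (IC50 / I)^s), 0)
}

#' Michaelis-Menten rate laws with inhibition
#'
#' \code{competitive_rate}: \code{Vmax*S / (Km*(1 + I/Ki) + S)} -- the
#' inhibitor raises the apparent Km and leaves Vmax unchanged.
#' \code{uncompetitive_rate}: \code{Vmax*S / (Km + S*(1 + I/Ki))}.
#' \code{noncompetitive_rate}: \code{Vmax*S / ((Km + S)*(1 + I/Ki))}.
#' \code{mixed_rate}: \code{Vmax*S / (Km*(1 + I/Ki) + S*(1 + I/Kiprime))}.
#' All reduce to \code{Vmax*S/(Km + S)} at \code{I = 0}.
#'
#' @param S substrate concentration (mM), positive.
#' @param I inhibitor concentration (mM), non-negative.
#' @param Vmax maximal velocity (mM/min).
#' @param Km Michaelis constant (mM).
#' @param Ki inhibition constant (mM).
#' @param Kiprime second (uncompetitive-side) inhibition constant for the
#'   mixed mechanism (mM).
#' @return Initial velocity (mM/min).
#' @export
competitive_rate <- function(S, I, Vmax, Km, Ki) {
  .check_rate_args(S, I, Vmax, Km, Ki)
  Vmax * S / (Km * (1 + I / Ki) + S)
}

#' @rdname competitive_rate
#' @export
uncompetitive_rate <- function(S, I, Vmax, Km, Ki) {
  .check_rate_args(S, I, Vmax, Km, Ki)
  Vmax * S / (Km + S * (1 + I / Ki))
}

#' @rdname competitive_rate
#' @export
noncompetitive_rate <- function(S, I, Vmax, Km, Ki) {
  .check_rate_args(S, I, Vmax, Km, Ki)
  Vmax * S / ((Km + S) * (1 + I / Ki))
}

#' @rdname competitive_rate
#' @export
mixed_rate <- function(S, I, Vmax, Km, Ki, Kiprime) {
  .check_rate_args(S, I, Vmax, Km, Ki)
  if (Kiprime <= 0) stop("Kiprime must be positive")
  Vmax * S / (Km * (1 + I / Ki) + S * (1 + I / Kiprime))
}

.check_rate_args <- function(S, I, Vmax, Km, Ki) {
  if (Vmax <= 0 || Km <= 0 || Ki <= 0) stop("Vmax, Km and Ki must be positive")
  if (any(S <= 0)) stop("substrate concentrations must be positive")
  if (any(I < 0)) stop("inhibitor concentrations must be non-negative")
}

#' Cheng-Prusoff IC50 for a competitive inhibitor
#'
#' \code{IC50 = Ki * (1 + S / Km)} at substrate concentration \code{S}.
#'
#' @param Ki inhibition constant (mM).
#' @param S assay substrate concentration (mM).
#' @param Km Michaelis constant (mM).
#' @return Predicted IC50 (mM).
#' @export
cheng_prusoff_ic50 <- function(Ki, S, Km) {
  stopifnot(Ki > 0, S > 0, Km > 0)
  Ki * (1 + S / Km)
}

# corrected Akaike information criterion for a least-squares fit
.aicc <- function(rss, n, k) {
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Levenberg-Marquardt least squares over log-parameters.
# predict_fn(theta) takes the natural-scale named parameter vector and
# returns predictions for the observations `obs`.
.lm_log_fit <- function(start, predict_fn, obs) {
  lp0 <- log(start)
  fit <- minpack.lm::nls.lm(
    par = lp0,
    fn = function(lp) obs - predict_fn(exp(lp)),
    control = minpack.lm::nls.lm.control(maxiter = 1000,
                                         ftol = 1e-14, ptol = 1e-14))
  lp <- fit$par
  est <- exp(lp)
  n <- length(obs)
  k <- length(lp)
  rss <- fit$deviance
  # Gauss-Newton covariance from a central-difference jacobian in log-space
  J <- matrix(NA_real_, n, k)
  h <- 1e-6
  for (j in seq_len(k)) {
    up <- lp; up[j] <- up[j] + h
    dn <- lp; dn[j] <- dn[j] - h
    J[, j] <- (predict_fn(exp(up)) - predict_fn(exp(dn))) / (2 * h)
  }
  se <- rep(NA_real_, k)
  if (n > k) {
    s2 <- rss / (n - k)
    V <- tryCatch(solve(crossprod(J)) * s2, error = function(e) NULL)
    if (!is.null(V)) se <- sqrt(pmax(diag(V), 0))
  }
  converged <- fit$info %in% 1:4
  if (!converged)
    stop("nonlinear fit did not converge: ", fit$message)
  list(estimate = stats::setNames(est, names(start)),
       se = stats::setNames(est * se, names(start)), # delta method
       rss = rss, n = n, k = k,
       aicc = if (n > k + 1) .aicc(rss, n, k) else NA_real_)
}

.fit_result <- function(fit, model) {
  structure(list(
    parameters = data.frame(parameter = names(fit$estimate),
                            estimate = unname(fit$estimate),
                            se = unname(fit$se)),
    model = model, rss = fit$rss, n_obs = fit$n, n_par = fit$k,
    aicc = fit$aicc), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Kinetic fit (", x$model, "), n = ", x$n_obs,
      ", RSS = ", signif(x$rss, 4), ", AICc = ", signif(x$aicc, 5), "\n",
      sep = "")
  p <- x$parameters
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-8s %.5g +/- %.3g\n", p$parameter[i], p$estimate[i], p$se[i]))
  if (!is.null(x$aicc_table)) {
    cat("Mechanism comparison (AICc):\n")
    print(x$aicc_table, row.names = FALSE)
  }
  invisible(x)
}

#' Fit the sigmoidal dose-response model (IC50 estimation)
#'
#' Nonlinear least squares of percent inhibition on inhibitor
#' concentration under the dose-response model, estimating \code{A100}
#' (unless fixed), \code{IC50} and \code{s}.
#'
#' @param data data.frame with columns \code{inhibitor_mM} and
#'   \code{response} (percent inhibition); replicate rows allowed.
#' @param fix_A100 optional fixed maximum inhibition (percent); when given,
#'   only \code{IC50} and \code{s} are estimated.
#' @return A \code{kinetic_fit} with parameter estimates, standard errors,
#'   RSS and AICc.
#' @export
fit_ic50 <- function(data, fix_A100 = NULL) {
  stopifnot(is.data.frame(data),
            all(c("inhibitor_mM", "response") %in% names(data)))
  conc <- data$inhibitor_mM
  resp <- data$response
  if (length(unique(conc[conc > 0])) < 4L)
    stop("need at least 4 distinct positive concentrations")
  m <- tapply(resp, conc, mean)
  cs <- as.numeric(names(m))
  if (max(m) < 1e-8) stop("flat data: responses are all ~0")
  if (stats::cor(rank(cs), rank(as.numeric(m))) <= 0)
    stop("flat or inverted data: responses do not increase with concentration")
  a0 <- max(resp)
  ic0 <- cs[which.min(abs(as.numeric(m) - a0 / 2))]
  if (ic0 <= 0) ic0 <- min(conc[conc > 0])
  if (is.null(fix_A100)) {
    start <- c(A100 = a0, IC50 = ic0, s = 1)
    pred <- function(th) dose_response_model(conc, th["A100"], th["IC50"], th["s"])
  } else {
    stopifnot(fix_A100 > 0)
    start <- c(IC50 = ic0, s = 1)
    pred <- function(th) dose_response_model(conc, fix_A100, th["IC50"], th["s"])
  }
  .fit_result(.lm_log_fit(start, pred, resp), "dose_response")
}

#' Global fit of inhibition kinetics (Vmax, Km, Ki)
#'
#' Fits all inhibitor-level curves simultaneously by nonlinear least
#' squares under the chosen rate law. With \code{model = "auto"} all four
#' mechanisms are fitted and the one with the lowest AICc is returned
#' (the comparison table is attached as \code{$aicc_table}).
#'
#' @param data data.frame with columns \code{substrate_mM},
#'   \code{inhibitor_mM} and \code{velocity} (mM/min).
#' @param model \code{"competitive"}, \code{"uncompetitive"},
#'   \code{"noncompetitive"}, \code{"mixed"} or \code{"auto"}.
#' @return A \code{kinetic_fit}.
#' @export
fit_inhibition <- function(data, model = c("competitive", "uncompetitive",
                                           "noncompetitive", "mixed", "auto")) {
  model <- match.arg(model)
  stopifnot(is.data.frame(data),
            all(c("substrate_mM", "inhibitor_mM", "velocity") %in% names(data)))
  S <- data$substrate_mM; I <- data$inhibitor_mM; v <- data$velocity
  if (!any(I == 0)) stop("need uninhibited (I = 0) measurements")
  if (length(unique(I)) < 2L) stop("need at least 2 inhibitor levels")
  if (length(unique(S)) < 4L) stop("need at least 4 substrate levels")

  if (model == "auto") {
    fits <- lapply(c("competitive", "uncompetitive", "noncompetitive", "mixed"),
                   function(mm) tryCatch(fit_inhibition(data, mm),
                                         error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) == 0L) stop("no mechanism could be fitted")
    tab <- data.frame(model = vapply(fits, `[[`, "", "model"),
                      aicc = vapply(fits, `[[`, 0, "aicc"))
    tab <- tab[order(tab$aicc), ]
    rownames(tab) <- NULL
    best <- fits[[which.min(vapply(fits, `[[`, 0, "aicc"))]]
    best$aicc_table <- tab
    return(best)
  }

  ki0 <- min(I[I > 0])
  start <- c(Vmax = max(v) * 1.2, Km = stats::median(S), Ki = ki0)
  pred <- switch(model,
    competitive = function(th) competitive_rate(S, I, th["Vmax"], th["Km"], th["Ki"]),
    uncompetitive = function(th) uncompetitive_rate(S, I, th["Vmax"], th["Km"], th["Ki"]),
    noncompetitive = function(th) noncompetitive_rate(S, I, th["Vmax"], th["Km"], th["Ki"]))
  if (model == "mixed") {
    start <- c(start, Kiprime = ki0)
    pred <- function(th) mixed_rate(S, I, th["Vmax"], th["Km"], th["Ki"], th["Kiprime"])
  }
  .fit_result(.lm_log_fit(start, pred, v), model)
}

#' Lineweaver-Burk diagnostics
#'
#' Ordinary least squares of \code{1/v} on \code{1/S} within each inhibitor
#' level, plus the classical pattern heuristic: a shared \code{1/v}
#' intercept indicates competitive inhibition, parallel lines (shared
#' slope) uncompetitive, and a shared \code{1/S} intercept noncompetitive.
#' Diagnostic only -- parameter estimates should come from
#' \code{\link{fit_inhibition}}.
#'
#' @param data data.frame with columns \code{substrate_mM},
#'   \code{inhibitor_mM} and \code{velocity}; all velocities must be
#'   positive.
#' @param tol relative-spread threshold below which a feature (intercepts,
#'   slopes or abscissa intercepts) counts as shared.
#' @return List of class \code{lb_fit} with \code{lines} (per-level slope,
#'   intercept, abscissa intercept, R^2), \code{spreads} and
#'   \code{classification} (\code{NA} when only one level is present).
#' @export
lineweaver_burk <- function(data, tol = 0.05) {
  stopifnot(is.data.frame(data),
            all(c("substrate_mM", "inhibitor_mM", "velocity") %in% names(data)))
  if (any(data$velocity <= 0)) stop("all velocities must be positive")
  levels_I <- sort(unique(data$inhibitor_mM))
  lines <- do.call(rbind, lapply(levels_I, function(ii) {
    d <- data[data$inhibitor_mM == ii, ]
    if (length(unique(d$substrate_mM)) < 2L)
      stop("need >= 2 substrate levels per inhibitor level")
    f <- stats::lm(I(1 / velocity) ~ I(1 / substrate_mM), data = d)
    co <- stats::coef(f)
    data.frame(inhibitor_mM = ii, slope = unname(co[2]),
               intercept = unname(co[1]),
               x_intercept = unname(-co[1] / co[2]),
               r_squared = suppressWarnings(summary(f)$r.squared))
  }))
  rel_spread <- function(x) {
    if (length(x) < 2L) return(NA_real_)
    (max(x) - min(x)) / mean(abs(x))
  }
  spreads <- c(intercept = rel_spread(lines$intercept),
               slope = rel_spread(lines$slope),
               x_intercept = rel_spread(lines$x_intercept))
  classification <- NA_character_
  if (length(levels_I) >= 2L) {
    mech <- c(intercept = "competitive", slope = "uncompetitive",
              x_intercept = "noncompetitive")
    best <- names(which.min(spreads))
    classification <- if (spreads[[best]] < tol) mech[[best]] else "mixed"
  }
  structure(list(lines = lines, spreads = spreads,
                 classification = classification),
            class = "lb_fit")
}

#' @export
print.lb_fit <- function(x, ...) {
  cat("Lineweaver-Burk fits:\n")
  print(x$lines, row.names = FALSE)
  cat("classification:", x$classification, "\n")
  invisible(x)
}
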