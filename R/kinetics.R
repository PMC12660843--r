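# 1:1 Langmuir binding kinetics for biolayer interferometry.
#
# Association: R(t) = Req (1 - exp(-(ka C + kd) t)),
#              Req  = Rmax C / (C + KD),  KD = kd / ka.
# Dissociation from the end of association:
#              R(t) = R(t_assoc) exp(-kd (t - t_assoc)).
# The fitter is global: ka, kd, Rmax are shared across all traces
# (concentrations differ), estimated by nonlinear least squares on the
# log-parameter scale with deterministic multi-start refinement.

#' Simulate a 1:1 BLI sensorgram
#'
#' @param ka Association rate constant (1/(M s)).
#' @param kd Dissociation rate constant (1/s).
#' @param C Analyte concentration (M).
#' @param Rmax Maximal response (response units).
#' @param t_assoc,t_dissoc Phase durations (s).
#' @param noise_sd Gaussian noise standard deviation (response units).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @param dt Time step (s).
#' @return A `sensorgram` data frame with columns `time`, `response`,
#'   `phase` (`"association"`/`"dissociation"`), `conc`.
#' @export
simulate_sensorgram <- function(ka, kd, C, Rmax, t_assoc = 300, t_dissoc = 600,
                                noise_sd = 0, seed = 1L, dt = 1) {
  if (any(c(ka, kd, C, Rmax) <= 0)) stop("ka, kd, C, Rmax must be > 0")
  t1 <- seq(0, t_assoc, by = dt)
  t2 <- seq(t_assoc + dt, t_assoc + t_dissoc, by = dt)
  KD <- kd / ka
  Req <- Rmax * C / (C + KD)
  kobs <- ka * C + kd
  r1 <- Req * (1 - exp(-kobs * t1))
  R_end <- Req * (1 - exp(-kobs * t_assoc))
  r2 <- R_end * exp(-kd * (t2 - t_assoc))
  sg <- data.frame(
    time = c(t1, t2),
    response = c(r1, r2),
    phase = rep(c("association", "dissociation"), c(length(t1), length(t2))),
    conc = C, stringsAsFactors = FALSE)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    sg$response <- sg$response + stats::rnorm(nrow(sg), 0, noise_sd)
  }
  attr(sg, "t_assoc") <- t_assoc
  class(sg) <- c("sensorgram", "data.frame")
  sg
}

model_response <- function(ka, kd, Rmax, traces) {
  unlist(lapply(traces, function(sg) {
    C <- sg$conc[1]
    t_assoc <- attr(sg, "t_assoc")
    if (is.null(t_assoc)) t_assoc <- max(sg$time[sg$phase == "association"])
    KD <- kd / ka
    Req <- Rmax * C / (C + KD)
    kobs <- ka * C + kd
    r <- numeric(nrow(sg))
    ia <- sg$phase == "association"
    r[ia] <- Req * (1 - exp(-kobs * sg$time[ia]))
    R_end <- Req * (1 - exp(-kobs * t_assoc))
    r[!ia] <- R_end * exp(-kd * (sg$time[!ia] - t_assoc))
    r
  }))
}

init_kinetics <- function(traces) {
  # kd from log-linear regression of each dissociation tail
  kds <- vapply(traces, function(sg) {
    d <- sg[sg$phase == "dissociation" & sg$response > 0, ]
    if (nrow(d) < 3) return(NA_real_)
    fit <- stats::lm(log(response) ~ time, data = d)
    max(-stats::coef(fit)[["time"]], 1e-8)
  }, 0)
  kd0 <- stats::median(kds, na.rm = TRUE)
  # kobs from single-exponential shape of each association phase, then
  # ka from regression of kobs on concentration
  kobs <- vapply(traces, function(sg) {
    a <- sg[sg$phase == "association", ]
    plateau <- max(a$response)
    if (plateau <= 0) return(NA_real_)
    y <- 1 - a$response / (plateau * 1.05)
    ok <- y > 1e-6 & a$time > 0
    if (sum(ok) < 3) return(NA_real_)
    fit <- stats::lm(log(y[ok]) ~ a$time[ok])
    max(-stats::coef(fit)[[2]], 1e-8)
  }, 0)
  conc <- vapply(traces, function(sg) sg$conc[1], 0)
  ok <- is.finite(kobs)
  ka0 <- if (sum(ok) >= 2) {
    max(stats::coef(stats::lm(kobs[ok] ~ conc[ok]))[[2]], 1)
  } else {
    max((mean(kobs, na.rm = TRUE) - kd0) / mean(conc), 1)
  }
  Rmax0 <- max(vapply(traces, function(sg) max(sg$response), 0))
  c(ka = ka0, kd = if (is.finite(kd0)) kd0 else 1e-3, Rmax = max(Rmax0, 1e-3))
}

#' Fit the 1:1 Langmuir model globally to one or more sensorgrams
#'
#' @param traces A `sensorgram` or list of sensorgrams sharing ka, kd and
#'   Rmax (one analyte concentration each).
#' @param restarts Deterministic restarts with +/- 10x perturbation of the
#'   initial estimates (default 3).
#' @return A `bli_fit` object with components `ka` (1/(M s)), `kd` (1/s),
#'   `KD` (M, = kd/ka), `Rmax`, `residual_rms`, `traces`, `fitted`.
#' @export
fit_kinetics <- function(traces, restarts = 3L) {
  if (inherits(traces, "sensorgram")) traces <- list(traces)
  if (length(traces) < 1) stop("at least one trace required")
  conc <- vapply(traces, function(sg) sg$conc[1], 0)
  if (any(conc <= 0)) stop("analyte concentrations must be positive")
  obs <- unlist(lapply(traces, function(sg) sg$response))
  if (max(abs(obs)) < 1e-12 || stats::sd(obs) < 1e-12) {
    stop("no signal: trace is flat")
  }
  theta0 <- init_kinetics(traces)
  resid_fun <- function(logp) {
    model_response(exp(logp[1]), exp(logp[2]), exp(logp[3]), traces) - obs
  }
  starts <- list(log(theta0))
  perturb <- log(10)
  for (r in seq_len(max(restarts - 1L, 0L))) {
    sgn <- if (r %% 2 == 1) 1 else -1
    starts[[length(starts) + 1]] <- log(theta0) + sgn * perturb
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("non-convergence: all restarts failed")
  p <- exp(best$fit$par)
  fitted <- model_response(p[1], p[2], p[3], traces)
  out <- list(ka = p[[1]], kd = p[[2]], Rmax = p[[3]],
              KD = p[[2]] / p[[1]],
              residual_rms = sqrt(mean((fitted - obs)^2)),
              traces = traces, fitted = fitted,
              convergence = best$fit$info)
  class(out) <- "bli_fit"
  out
}

#' @export
print.bli_fit <- function(x, ...) {
  cat("1:1 Langmuir kinetic fit\n")
  cat(sprintf("  ka   = %.3g 1/(M s)\n  kd   = %.3g 1/s\n  KD   = %.3g M\n",
              x$ka, x$kd, x$KD))
  cat(sprintf("  Rmax = %.3g RU, residual RMS = %.3g (%d traces)\n",
              x$Rmax, x$residual_rms, length(x$traces)))
  invisible(x)
}

#' @export
coef.bli_fit <- function(object, ...) {
  c(ka = object$ka, kd = object$kd, Rmax = object$Rmax, KD = object$KD)
}

#' @export
summary.bli_fit <- function(object, ...) {
  cat(sprintf("Global 1:1 fit over %d trace(s); concentrations: %s M\n",
              length(object$traces),
              paste(signif(vapply(object$traces, function(s) s$conc[1], 0), 3),
                    collapse = ", ")))
  print(object)
  invisible(object)
}

#' @export
predict.bli_fit <- function(object, newtraces = NULL, ...) {
  if (is.null(newtraces)) return(object$fitted)
  if (inherits(newtraces, "sensorgram")) newtraces <- list(newtraces)
  model_response(object$ka, object$kd, object$Rmax, newtraces)
}

#' @export
residuals.bli_fit <- function(object, ...) {
  unlist(lapply(object$traces, function(sg) sg$response)) - object$fitted
}

#' @export
plot.bli_fit <- function(x, ...) {
  obs <- unlist(lapply(x$traces, function(sg) sg$response))
  tt <- unlist(lapply(x$traces, function(sg) sg$time))
  graphics::plot(tt, obs, pch = ".", col = "grey40",
                 xlab = "time (s)", ylab = "response (RU)",
                 main = sprintf("1:1 fit: KD = %.3g M", x$KD), ...)
  off <- 0
  for (sg in x$traces) {
    n <- nrow(sg)
    graphics::lines(sg$time, x$fitted[off + seq_len(n)], col = "red")
    off <- off + n
  }
  invisible(x)
}

#' Equilibrium dissociation constant from rate constants
#'
#' @param ka Association rate constant (1/(M s)).
#' @param kd Dissociation rate constant (1/s).
#' @return `KD = kd / ka` (M).
#' @export
kd_from_rates <- function(ka, kd) {
  if (any(ka <= 0) || any(kd <= 0)) stop("rate constants must be > 0")
  kd / ka
}

#' Fold improvement in affinity
#'
#' @param KD_reference Reference (weaker binder) KD.
#' @param KD_variant Variant KD.
#' @return `KD_reference / KD_variant`.
#' @export
fold_improvement <- function(KD_reference, KD_variant) {
  if (any(KD_reference <= 0) || any(KD_variant <= 0)) stop("KD must be > 0")
  KD_reference / KD_variant
}

#' Shipped Fab kinetics table
#'
#' Rate constants and printed KD values for the five SC44 Fab variants
#' against the phospho-mimetic (3-pTza) and native (3-pHis) peptides, as
#' determined by BLI.
#'
#' @return Data frame with columns `fab`, `ligand`, `KD_printed`, `ka`,
#'   `kd`.
#' @export
fab_kinetics_table <- function() {
  utils::read.csv(system.file("extdata", "fab_kinetics.csv",
                              package = "phabkit"),
                  stringsAsFactors = FALSE)
}

#' Fit a standard curve and select its linear range
#'
#' The linear range is the longest contiguous run of at least 3 standards
#' whose straight-line fit has R^2 >= `r2_min` (default 0.98).
#'
#' @param points Data frame with columns `conc` and `absorbance`, ordered
#'   by concentration.
#' @param r2_min Minimum R^2 for the linear range.
#' @return A `standard_curve` list with `slope`, `intercept`,
#'   `range_idx`, `points`.
#' @export
fit_standard_curve <- function(points, r2_min = 0.98) {
  if (nrow(points) < 4) stop("at least 4 standards required")
  points <- points[order(points$conc), ]
  n <- nrow(points)
  best <- NULL
  for (i in 1:(n - 2)) {
    for (j in (i + 2):n) {
      seg <- points[i:j, ]
      fit <- stats::lm(absorbance ~ conc, data = seg)
      # R^2 computed directly: summary.lm() warns on zero-residual fits
      ss_tot <- sum((seg$absorbance - mean(seg$absorbance))^2)
      r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
      if (r2 >= r2_min) {
        if (is.null(best) || (j - i) > (best$j - best$i)) {
          best <- list(i = i, j = j, fit = fit)
        }
      }
    }
  }
  if (is.null(best)) stop("no linear range with R^2 >= ", r2_min)
  out <- list(slope = stats::coef(best$fit)[["conc"]],
              intercept = stats::coef(best$fit)[["(Intercept)"]],
              range_idx = best$i:best$j,
              points = points)
  class(out) <- "standard_curve"
  out
}

#' Interpolate an unknown concentration from a standard curve
#'
#' @param curve A `standard_curve`.
#' @param absorbance Measured absorbance of the unknown.
#' @param dilution_factor Multiplier back to the undiluted sample.
#' @return List with `conc` (NA when flagged), `in_range`, `flag`.
#' @export
estimate_concentration <- function(curve, absorbance, dilution_factor = 1) {
  rng <- curve$points$absorbance[curve$range_idx]
  in_range <- absorbance >= min(rng) & absorbance <= max(rng)
  conc <- (absorbance - curve$intercept) / curve$slope * dilution_factor
  list(conc = ifelse(in_range, conc, NA_real_),
       in_range = in_range,
       flag = ifelse(in_range, "", "outside linear range"))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Model: `y = bottom + (top - bottom) / (1 + (EC50 / x)^hill)`.
#'
#' @param points Data frame with columns `conc` (> 0) and `response`.
#' @return List with `bottom`, `top`, `ec50`, `hill`, `residual_rms`.
#' @export
fit_4pl <- function(points) {
  if (nrow(points) < 5) stop("at least 5 doses required")
  y <- points$response; x <- points$conc
  if (stats::sd(y) < 1e-12) stop("no transition: response constant across doses")
  bottom0 <- min(y); top0 <- max(y)
  mid <- (bottom0 + top0) / 2
  ec50_0 <- x[which.min(abs(y - mid))]
  start <- c(bottom = bottom0, top = top0, lec50 = log(ec50_0), hill = 1)
  fn <- function(p) {
    p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
      (1 + (exp(p[["lec50"]]) / x)^p[["hill"]]) - y
  }
  fit <- minpack.lm::nls.lm(par = start, fn = fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0, 9)) stop("non-convergence in 4PL fit")
  p <- fit$par
  list(bottom = p[["bottom"]], top = p[["top"]], ec50 = exp(p[["lec50"]]),
       hill = p[["hill"]], residual_rms = sqrt(mean(fit$fvec^2)))
}
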