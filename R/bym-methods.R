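## Standard modelling-object methods for bym_fit.

#' @export
print.bym_fit <- function(x, ...) {
  acc <- mcmc_accounting(x$config)
  cat(sprintf("BYM fit: %d areas (%d island%s), %d chains x %d saved draws\n",
              length(x$ids), sum(x$islands),
              if (sum(x$islands) == 1) "" else "s",
              length(x$chains), acc$per_chain))
  co <- coef(x)
  cat(sprintf("posterior means: alpha = %.3f, sigma_u = %.3f, sigma_v = %.3f\n",
              co["alpha"], co["sigma_u"], co["sigma_v"]))
  invisible(x)
}

#' @export
coef.bym_fit <- function(object, ...) {
  c(alpha = mean(pool_scalar(object, "alpha")),
    sigma_u = mean(pool_scalar(object, "sigma_u")),
    sigma_v = mean(pool_scalar(object, "sigma_v")))
}

#' @export
fitted.bym_fit <- function(object, ...) {
  th <- colMeans(pool_draws(object, "theta"))
  names(th) <- object$ids
  th
}

#' @export
residuals.bym_fit <- function(object, type = c("pearson", "raw"), ...) {
  type <- match.arg(type)
  mu <- object$E * fitted(object)
  r <- object$Y - mu
  if (type == "pearson") r <- r / sqrt(mu)
  names(r) <- object$ids
  r
}

#' @param object,x a `bym_fit`.
#' @param ... unused.
#' @describeIn fit_bym posterior summary table plus convergence
#'   diagnostics and the spatial fraction.
#' @export
summary.bym_fit <- function(object, ...) {
  s <- summarize_posterior(object)
  rh <- if (length(object$chains) >= 2L)
    gelman_rubin(object, c("alpha", "sigma_u", "sigma_v", "theta"))
  else NULL
  fr <- spatial_fraction(object)
  structure(list(table = s, coef = coef(object), rhat = rh,
                 spatial_fraction = fr,
                 raw_sir = object$Y / object$E,
                 converged = is.null(rh) ||
                   all(rh < 1.1, na.rm = TRUE)),
            class = "summary.bym_fit")
}

#' @export
print.summary.bym_fit <- function(x, ...) {
  cat("BYM posterior summary\n")
  print(head(x$table, 10))
  if (nrow(x$table) > 10) cat("  ...", nrow(x$table), "areas\n")
  cat(sprintf("spatial fraction: %.3f (95%% CrI %.3f-%.3f)\n",
              x$spatial_fraction$mean, x$spatial_fraction$ci_low,
              x$spatial_fraction$ci_high))
  if (!is.null(x$rhat)) {
    cat(sprintf("max R-hat: %.3f (%s)\n", max(x$rhat, na.rm = TRUE),
                if (x$converged) "all < 1.1" else "convergence warning"))
  }
  invisible(x)
}

#' @export
plot.bym_fit <- function(x, type = c("shrinkage", "scatter"), ...) {
  type <- match.arg(type)
  raw <- x$Y / x$E
  smoothed <- fitted(x)
  if (type == "shrinkage") {
    graphics::boxplot(list(raw = raw, smoothed = smoothed),
                      ylab = "SIR", ...)
  } else {
    graphics::plot(raw, smoothed, xlab = "raw SIR",
                   ylab = "posterior mean SIR", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' @export
simulate.bym_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  th <- pool_draws(object, "theta")
  idx <- sample.int(nrow(th), nsim, replace = TRUE)
  out <- vapply(idx, function(k)
    rpois(length(object$E), object$E * th[k, ]), numeric(length(object$E)))
  out <- matrix(as.integer(out), ncol = nsim,
                dimnames = list(object$ids, NULL))
  as.data.frame(out)
}
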