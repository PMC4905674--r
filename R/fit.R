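#' Maximum likelihood insertion rates
#'
#' The Poisson insertion likelihood maximizes in closed form at
#' \eqn{\hat\Phi_i = N_i / T_i} (relative insertions per Myr).
#'
#' @param counts named per-branch counts, or an \code{erv_patterns} object.
#' @param tree an \code{erv_tree}.
#' @return named numeric vector of rates over the nine branches.
#' @examples
#' counts <- setNames(erv_reference_counts()[, "HERV-K"], rownames(erv_reference_counts()))
#' round(fit_insertion_rates(counts)["h"], 2)  # 1.36
#' @export
fit_insertion_rates <- function(counts, tree = erv_tree()) {
  if (inherits(counts, "erv_patterns") || is.data.frame(counts))
    counts <- count_insertions(counts, tree)
  if (!all(.BRANCHES %in% names(counts)))
    stop("'counts' must be named over the nine branches")
  counts[.BRANCHES] / tree$lengths
}

#' Maximum likelihood deletion parameters
#'
#' Box-constrained maximization of the deletion component of the joint log
#' likelihood over \eqn{[10^{-6}, 10^2]} (for the Weibull model the bounded
#' scale quantity is the inverse scale \eqn{\psi_w^{-1}}, matching the
#' published parameterization). Optimization is multi-start in log-parameter
#' space: deterministic starts on a coarse grid plus seeded random starts,
#' each refined with L-BFGS-B. Estimates within 1e-3 (log space) of a bound
#' are flagged \code{at_bound}, the published tables' "> 100" / "< 0.14"
#' situation.
#'
#' @param patterns an \code{erv_patterns} object (one family).
#' @param tree an \code{erv_tree}.
#' @param model \code{"exponential"} or \code{"weibull"}.
#' @param n_starts number of random multi-starts added to the grid starts.
#' @param seed integer seed for the random starts.
#' @param init optional numeric vector of additional warm starts in
#'   log-parameter space (\code{log(psi_e)} or
#'   \code{c(log(inv_psi_w), log(omega))}), e.g. a previous MLE.
#' @return a list: \code{params} (a \code{deletion_params}), \code{loglik}
#'   (deletion component at the optimum), \code{at_bound} (named logical),
#'   \code{converged}, \code{n_starts_used}.
#' @export
fit_deletion <- function(patterns, tree = erv_tree(),
                         model = c("exponential", "weibull"),
                         n_starts = 16, seed = 1, init = NULL) {
  model <- match.arg(model)
  patterns <- validate_patterns(patterns)
  if (nrow(patterns) == 0) stop("at least one pattern is required")
  cp <- .collapse_patterns(patterns)
  lb <- log(1e-6); ub <- log(1e2)

  # theta: log inverse-rate-like quantities bounded to [lb, ub];
  # exponential: theta = log(psi_e); weibull: (log inv_psi_w, log omega)
  objective <- function(theta) {
    pp <- if (model == "exponential")
      deletion_params("exponential", psi = exp(theta[1]))
    else
      deletion_params("weibull", inv_psi = exp(theta[1]),
                      omega = exp(theta[2]))
    ll <- .deletion_ll_collapsed(cp$upat, cp$n, tree, pp)
    if (!is.finite(ll)) ll <- -1e10
    -ll
  }

  # a warm start (e.g. a bootstrap refit from the headline MLE) replaces the
  # deterministic grid; random starts still guard against local optima
  if (!is.null(init)) {
    starts <- list(pmin(pmax(init, lb), ub))
  } else {
    grid1 <- log(c(0.01, 0.1, 1, 10))
    starts <- if (model == "exponential") as.list(grid1)
      else { g <- expand.grid(grid1, log(c(0.15, 0.5, 1, 2)))
             lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ])) }
  }
  if (n_starts > 0) {
    rs <- .with_seed(seed, {
      k <- if (model == "exponential") 1 else 2
      lapply(seq_len(n_starts), function(i) runif(k, lb, ub))
    })
    starts <- c(starts, rs)
  }

  best <- NULL
  n_ok <- 0
  for (s in starts) {
    fit <- tryCatch(
      suppressWarnings(optim(s, objective, method = "L-BFGS-B",
                             lower = lb, upper = ub,
                             control = list(maxit = 500))),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_ok <- n_ok + 1
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(list(params = NULL, loglik = NA_real_,
                at_bound = NA, converged = FALSE, n_starts_used = 0))
  }
  theta <- best$par
  at_bound <- (theta < lb + 1e-3) | (theta > ub - 1e-3)
  params <- if (model == "exponential") {
    names(at_bound) <- "psi"
    deletion_params("exponential", psi = exp(theta[1]))
  } else {
    names(at_bound) <- c("inv_psi", "omega")
    deletion_params("weibull", inv_psi = exp(theta[1]), omega = exp(theta[2]))
  }
  list(params = params, loglik = -best$value, at_bound = at_bound,
       converged = TRUE, n_starts_used = n_ok)
}

#' Fit the phylogenetic ERV insertion-deletion model
#'
#' The main fitting interface. Given one family's site patterns it estimates
#' the nine per-branch Poisson insertion rates (closed form) and the
#' deletion parameters (numerically, see \code{\link{fit_deletion}}), and
#' assembles the joint log likelihood.
#'
#' @param patterns an \code{erv_patterns} object (one family; if several
#'   families are present, supply a subset).
#' @param tree an \code{erv_tree}.
#' @param model deletion model, \code{"exponential"} or \code{"weibull"}.
#' @param n_starts,seed multi-start control passed to
#'   \code{\link{fit_deletion}}.
#' @return an object of class \code{erv_fit} with components
#'   \code{rates} (insertion rate MLEs), \code{deletion}
#'   (\code{deletion_params} MLE), \code{loglik} (an \code{erv_loglik}),
#'   \code{counts}, \code{at_bound}, \code{converged}, \code{model},
#'   \code{tree}, \code{patterns}, \code{seed}.
#' @seealso \code{\link{anova.erv_fit}} for the likelihood-ratio model
#'   comparison, \code{\link{erv_bootstrap}} for confidence intervals,
#'   \code{\link{simulate.erv_fit}} for forward simulation at the fit.
#' @examples
#' \donttest{
#' set.seed(1)
#' pats <- simulate_patterns(200, "hcgom",
#'   params = deletion_params("weibull", inv_psi = 0.09, omega = 0.18))
#' fit <- erv_fit(pats, model = "weibull")
#' fit
#' }
#' @export
erv_fit <- function(patterns, tree = erv_tree(),
                    model = c("exponential", "weibull"),
                    n_starts = 16, seed = 1) {
  model <- match.arg(model)
  patterns <- validate_patterns(patterns)
  if (length(unique(patterns$family)) > 1)
    warning("patterns contain multiple families; fitting them jointly")
  counts <- count_insertions(patterns, tree)
  rates <- fit_insertion_rates(counts, tree)
  del <- fit_deletion(patterns, tree, model, n_starts = n_starts, seed = seed)
  if (!del$converged) stop("deletion fit failed to converge from any start")
  ll <- joint_log_likelihood(patterns, tree, rates = rates,
                             params = del$params)
  structure(list(rates = rates, deletion = del$params, loglik = ll,
                 counts = counts, at_bound = del$at_bound,
                 converged = del$converged, model = model, tree = tree,
                 patterns = patterns, seed = seed),
            class = "erv_fit")
}

#' @export
print.erv_fit <- function(x, ...) {
  cat("Phylogenetic ERV insertion-deletion fit (",
      x$model, " deletion model)\n", sep = "")
  cat(sprintf("  %d site patterns; deletion log likelihood %.2f\n",
              nrow(x$patterns), x$loglik$deletion))
  cat("  ", .format_deletion(x), "\n", sep = "")
  invisible(x)
}

.format_deletion <- function(x) {
  p <- x$deletion
  if (x$model == "exponential") {
    est <- sprintf("psi_e = %.4g per Myr", p$psi)
    if (isTRUE(x$at_bound[["psi"]])) est <- paste(est, "(at bound)")
    est
  } else {
    inv <- 1 / p$psi
    s1 <- sprintf("inverse scale = %.4g per Myr%s", inv,
                  if (isTRUE(x$at_bound[["inv_psi"]])) " (at bound)" else "")
    s2 <- sprintf("shape omega = %.4g%s", p$omega,
                  if (isTRUE(x$at_bound[["omega"]])) " (at bound)" else "")
    paste(s1, s2, sep = ", ")
  }
}

#' @export
summary.erv_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.erv_fit")
}

#' @export
print.summary.erv_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPer-branch insertion counts and rate MLEs (per Myr):\n")
  print(data.frame(branch = .BRANCHES, length_Myr = round(f$tree$lengths, 2),
                   count = f$counts, rate = round(f$rates, 3),
                   row.names = NULL))
  cat(sprintf("\nLog likelihood: total %.2f = insertion %.2f + deletion %.2f\n",
              f$loglik$total, f$loglik$insertion, f$loglik$deletion))
  cat(sprintf("Mean pre-deletion lifetime: %.3g Myr\n",
              mean_lifetime(f$deletion)))
  invisible(x)
}

#' @export
coef.erv_fit <- function(object, ...) {
  del <- if (object$model == "exponential") c(psi_e = object$deletion$psi)
  else c(inv_psi_w = 1 / object$deletion$psi, omega = object$deletion$omega)
  c(setNames(object$rates, paste0("Phi_", .BRANCHES)), del)
}

#' @export
logLik.erv_fit <- function(object, component = c("total", "deletion",
                                                 "insertion"), ...) {
  component <- match.arg(component)
  val <- object$loglik[[component]]
  df <- 9 + if (object$model == "exponential") 1 else 2
  structure(val, df = df, nobs = nrow(object$patterns), class = "logLik")
}

#' Likelihood-ratio comparison of the nested deletion models
#'
#' The exponential model is the Weibull model with shape fixed at 1, so the
#' two fits are compared with \eqn{2\Delta\ell = 2(\ell_w - \ell_e)} on one
#' degree of freedom against the chi-squared 0.001 critical value 10.83.
#' The insertion term is identical in both fits and cancels.
#'
#' @param object an \code{erv_fit} (either model).
#' @param ... the other \code{erv_fit} of the pair.
#' @param alpha significance level (default 0.001, the reference cutoff).
#' @return a data frame of class \code{erv_lrt} with the statistic, degrees
#'   of freedom, cutoff and decision.
#' @export
anova.erv_fit <- function(object, ..., alpha = 0.001) {
  others <- Filter(function(z) inherits(z, "erv_fit"), list(...))
  if (length(others) != 1)
    stop("supply exactly two fits: the exponential and the Weibull")
  fits <- list(object, others[[1]])
  models <- vapply(fits, `[[`, "", "model")
  if (!setequal(models, c("exponential", "weibull")))
    stop("one fit must be exponential and the other Weibull")
  fe <- fits[[match("exponential", models)]]
  fw <- fits[[match("weibull", models)]]
  likelihood_ratio_test(fe$loglik$deletion, fw$loglik$deletion, alpha = alpha)
}

#' Likelihood-ratio test statistic from two log likelihoods
#'
#' @param loglik_exp,loglik_weibull deletion log likelihoods of the
#'   exponential (null) and Weibull (alternative) fits on the same data.
#' @param alpha significance level (default 0.001).
#' @return a one-row data frame of class \code{erv_lrt}: \code{statistic}
#'   (\eqn{2\Delta\ell}), \code{df}, \code{cutoff}, \code{p_value},
#'   \code{reject_exponential}.
#' @examples
#' likelihood_ratio_test(-140.88, -121.79)  # statistic 38.18
#' @export
likelihood_ratio_test <- function(loglik_exp, loglik_weibull, alpha = 0.001) {
  stat <- 2 * (loglik_weibull - loglik_exp)
  if (stat < -1e-6)
    warning("negative likelihood-ratio statistic: ",
            "the Weibull optimizer likely failed (models are nested)")
  cutoff <- qchisq(1 - alpha, df = 1)
  out <- data.frame(statistic = stat, df = 1, cutoff = cutoff,
                    p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                    reject_exponential = stat > cutoff)
  class(out) <- c("erv_lrt", "data.frame")
  out
}

#' @importFrom stats pchisq
#' @export
print.erv_lrt <- function(x, ...) {
  cat(sprintf(
    "LRT (Weibull vs exponential): 2*dlogLik = %.2f on 1 df (cutoff %.2f): %s\n",
    x$statistic, x$cutoff,
    if (x$reject_exponential) "reject exponential" else "retain exponential"))
  invisible(x)
}

#' Case-resampling bootstrap for an ERV fit
#'
#' Resamples site patterns with replacement, refits insertion rates and
#' deletion parameters per replicate, and returns percentile confidence
#' intervals. Replicate seeds are derived from the master seed by counter so
#' runs are reproducible and replicates independent.
#'
#' @param fit an \code{erv_fit}.
#' @param n_reps number of bootstrap replicates.
#' @param seed master integer seed.
#' @param n_starts multi-starts per replicate refit (smaller than the
#'   headline fit for speed).
#' @param level confidence level for the percentile intervals.
#' @return an object of class \code{erv_boot}: list with \code{estimates}
#'   (replicate x parameter matrix, insertion rates then deletion
#'   parameters), \code{ci} (percentile intervals), \code{n_failed},
#'   \code{level}.
#' @export
erv_bootstrap <- function(fit, n_reps = 1000, seed = 1, n_starts = 2,
                          level = 0.95) {
  stopifnot(inherits(fit, "erv_fit"), n_reps >= 1)
  pat <- fit$patterns
  n <- nrow(pat)
  est <- vector("list", n_reps)
  failed <- 0
  for (r in seq_len(n_reps)) {
    idx <- .with_seed(seed + r, sample.int(n, n, replace = TRUE))
    bp <- validate_patterns(pat[idx, , drop = FALSE])
    rates <- fit_insertion_rates(bp, fit$tree)
    init <- if (fit$model == "exponential") log(fit$deletion$psi)
    else log(c(1 / fit$deletion$psi, fit$deletion$omega))
    del <- fit_deletion(bp, fit$tree, fit$model, n_starts = n_starts,
                        seed = seed + r, init = init)
    if (!del$converged) { failed <- failed + 1; next }
    dv <- if (fit$model == "exponential") c(psi_e = del$params$psi)
    else c(inv_psi_w = 1 / del$params$psi, omega = del$params$omega)
    est[[r]] <- c(setNames(rates, paste0("Phi_", .BRANCHES)), dv)
  }
  est <- do.call(rbind, est)
  a <- (1 - level) / 2
  ci <- apply(est, 2, quantile, probs = c(a, 1 - a), names = TRUE)
  structure(list(estimates = est, ci = ci, n_failed = failed, level = level,
                 model = fit$model, seed = seed),
            class = "erv_boot")
}

#' @export
print.erv_boot <- function(x, ...) {
  cat(sprintf("Bootstrap (%d replicates, %d failed): %.0f%% percentile CIs\n",
              nrow(x$estimates) + x$n_failed, x$n_failed, 100 * x$level))
  print(round(t(x$ci), 4))
  invisible(x)
}

#' @export
confint.erv_fit <- function(object, parm, level = 0.95, n_reps = 200,
                            seed = 1, ...) {
  bt <- erv_bootstrap(object, n_reps = n_reps, seed = seed, level = level)
  ci <- t(bt$ci)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Deletion CDF plot for a fitted model
#'
#' Plots the fitted probability that an insertion of a given age has been
#' reduced to a solo-LTR, optionally overlaying bootstrap replicate curves.
#'
#' @param x an \code{erv_fit}.
#' @param boot optional \code{erv_boot} for grey replicate curves.
#' @param max_age right end of the age axis in Myr.
#' @param ... passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.erv_fit <- function(x, boot = NULL, max_age = 40, ...) {
  age <- seq(0, max_age, length.out = 300)
  cdf <- 1 - survival(x$deletion, age)
  plot(age, cdf, type = "n", ylim = c(0, 1), xlab = "age (Myr)",
       ylab = "Pr(deleted by age)",
       main = sprintf("Deletion CDF (%s model)", x$model), ...)
  if (!is.null(boot)) {
    for (r in seq_len(nrow(boot$estimates))) {
      pp <- if (x$model == "exponential")
        deletion_params("exponential", psi = boot$estimates[r, "psi_e"])
      else deletion_params("weibull",
                           inv_psi = boot$estimates[r, "inv_psi_w"],
                           omega = boot$estimates[r, "omega"])
      graphics::lines(age, 1 - survival(pp, age), col = "grey80")
    }
  }
  graphics::lines(age, cdf, lwd = 2)
  invisible(x)
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
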