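# Survival stratification of predicted risk groups: Kaplan-Meier curves,
# two-group log-rank test, and a univariate proportional-hazards hazard
# ratio (Breslow ties), via the survival package.

#' Kaplan-Meier curves, log-rank test, and hazard ratio for two groups
#'
#' Product-limit survival estimates per group, the two-group log-rank test
#' (hypergeometric variance), and the hazard ratio from a single-covariate
#' Cox proportional-hazards fit with Breslow tie handling. The hazard ratio
#' is for the second factor level of `groups` relative to the first, so
#' order the levels as (reference, comparison) — e.g. (low-risk,
#' high-risk).
#'
#' @param times Follow-up times (e.g. months).
#' @param events Event indicator, 1 = event, 0 = censored.
#' @param groups Two-level factor (or coercible) of group membership; each
#'   group needs at least one event.
#' @param conf_level Confidence level for the hazard-ratio interval.
#' @return A `km_result`: `curves` (tibble: group, time, n_risk, n_event,
#'   surv), `logrank_chisq`, `logrank_p`, `hr`, `hr_ci`, `median_os`
#'   (named per group, `NA` when not reached).
#' @export
km_logrank <- function(times, events, groups, conf_level = 0.95) {
  stopifnot(length(times) == length(events),
            length(times) == length(groups))
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  groups <- factor(groups)
  if (nlevels(groups) != 2) {
    stop("km_logrank compares exactly two groups", call. = FALSE)
  }
  if (sum(events) == 0) {
    stop("no events observed", call. = FALSE)
  }
  if (any(tapply(events, groups, sum) == 0)) {
    stop("each group needs at least one event", call. = FALSE)
  }
  surv <- survival::Surv(times, events)
  fit <- survival::survfit(surv ~ groups)
  strata_group <- rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  curves <- tibble::tibble(
    group = factor(strata_group, levels = levels(groups)),
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    surv = fit$surv
  )
  med <- summary(fit)$table[, "median"]
  names(med) <- sub("^groups=", "", rownames(summary(fit)$table))

  sd_fit <- survival::survdiff(surv ~ groups)
  chisq <- unname(sd_fit$chisq)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)

  cox <- survival::coxph(surv ~ groups, ties = "breslow")
  hr <- unname(exp(stats::coef(cox)))
  ci <- exp(stats::confint(cox, level = conf_level))

  structure(
    list(curves = curves, logrank_chisq = chisq, logrank_p = p,
         hr = hr, hr_ci = unname(ci[1, ]), median_os = med,
         levels = levels(groups)),
    class = "km_result"
  )
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf(
    "<km_result> %s vs %s: HR = %.2f [%.2f, %.2f]; log-rank p = %.3g\n",
    x$levels[2], x$levels[1], x$hr, x$hr_ci[1], x$hr_ci[2], x$logrank_p
  ))
  invisible(x)
}

#' @rdname km_logrank
#' @param x A `km_result`.
#' @param ... Ignored.
#' @method tidy km_result
#' @export
tidy.km_result <- function(x, ...) x$curves

#' @rdname km_logrank
#' @method glance km_result
#' @export
glance.km_result <- function(x, ...) {
  tibble::tibble(
    hr = x$hr, hr_low = x$hr_ci[1], hr_high = x$hr_ci[2],
    logrank_chisq = x$logrank_chisq, logrank_p = x$logrank_p
  )
}

#' @rdname km_logrank
#' @param object A `km_result`.
#' @method autoplot km_result
#' @export
autoplot.km_result <- function(object, ...) {
  curves <- dplyr::bind_rows(
    tibble::tibble(group = factor(object$levels, levels = object$levels),
                   time = 0, n_risk = NA_integer_, n_event = NA_integer_,
                   surv = 1),
    object$curves
  )
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$surv,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "time", y = "survival probability",
      title = sprintf("HR = %.2f [%.2f, %.2f], log-rank p = %.3g",
                      object$hr, object$hr_ci[1], object$hr_ci[2],
                      object$logrank_p)
    ) +
    ggplot2::theme_minimal()
}
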