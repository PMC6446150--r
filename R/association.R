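#' Logistic association model with Wald inference
#'
#' Maximum-likelihood logistic regression (via `stats::glm`) of an adherent /
#' nonadherent outcome on one or more exposure terms, adjusted by default for
#' age (years, continuous), sex, and their product term. For every coefficient
#' the fit reports the Wald z statistic and two-sided p value from the
#' observed information, the odds ratio `exp(beta)`, and the 95% Wald interval
#' `exp(beta +/- 1.96 SE)`. Quasi-complete separation is detected from fitted
#' probabilities pinned at 0/1 and reported through the `converged` flag.
#'
#' @param data data.frame holding outcome, exposures and covariates.
#' @param outcome Name of a logical/0-1 outcome column.
#' @param exposures Character vector of exposure column names (>= 1).
#' @param covariates Covariate columns, default `c("age_years", "sex")`;
#'   use `character(0)` for an unadjusted model.
#' @param interaction Include the product of the first two covariates
#'   (age x sex under the defaults)? Default TRUE.
#' @param scope Optional label carried on the fit (used by the model suite).
#' @return Object of class `logistic_fit`: list with `terms` (data.frame:
#'   `term`, `beta`, `se`, `z`, `p`, `or`, `ci_low`, `ci_high`), `n`,
#'   `converged`, `separation`, `scope` and the model `formula`.
#' @export
#' @examples
#' d <- data.frame(y = rep(c(1, 0, 1, 0), c(80, 20, 60, 40)),
#'                 x = rep(c(1, 1, 0, 0), c(80, 20, 60, 40)))
#' fit_logistic(d, "y", "x", covariates = character(0))$terms
fit_logistic <- function(data, outcome, exposures,
                         covariates = c("age_years", "sex"),
                         interaction = TRUE, scope = NULL) {
  stopifnot(length(exposures) >= 1)
  cols <- c(outcome, exposures, covariates)
  missing <- setdiff(cols, names(data))
  if (length(missing)) stop("model columns not in data: ", paste(missing, collapse = ", "))
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols, drop = FALSE]
  if (nrow(d) == 0L) stop("no complete rows to fit")
  y <- as.integer(d[[outcome]])
  if (length(unique(y)) < 2L) stop("outcome has no cases or no non-cases")
  for (e in exposures) {
    v <- d[[e]]
    if (length(unique(v)) < 2L) stop("constant exposure column: ", e)
  }
  rhs <- c(exposures, covariates)
  if (interaction && length(covariates) >= 2) {
    rhs <- c(rhs, paste0(covariates[1], ":", covariates[2]))
  }
  fml <- stats::reformulate(rhs, response = outcome)
  d[[outcome]] <- y
  fit <- suppressWarnings(stats::glm(fml, data = d, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  eps <- 1e-8
  separation <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  terms <- data.frame(
    term = rownames(sm),
    beta = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    z = sm[, "z value"],
    p = sm[, "Pr(>|z|)"],
    row.names = NULL
  )
  terms$or <- exp(terms$beta)
  terms$ci_low <- exp(terms$beta - 1.96 * terms$se)
  terms$ci_high <- exp(terms$beta + 1.96 * terms$se)
  structure(list(terms = terms, n = nrow(d),
                 converged = fit$converged && !separation,
                 separation = separation, scope = scope, formula = fml),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit", if (!is.null(x$scope)) paste0(" [", x$scope, "]"), "  n = ",
      x$n, if (!x$converged) "  (NOT converged)", "\n", sep = "")
  t <- x$terms
  t$or <- sprintf("%.3f", t$or)
  t$ci <- sprintf("(%.3f-%.3f)", x$terms$ci_low, x$terms$ci_high)
  print(t[, c("term", "beta", "se", "z", "p", "or", "ci")], digits = 3)
  invisible(x)
}

#' Rescale an odds ratio to a different unit of increase
#'
#' A logistic coefficient beta per one unit of an exposure implies an OR
#' factor `exp(beta * delta)` per increase of `delta` units (e.g. 0.5 adjusted
#' tracking-ratio units, or 2000 steps per day tracked); the Wald CI endpoints
#' transform identically.
#'
#' @param fit A [fit_logistic()] result.
#' @param term Term name present in the fit.
#' @param delta Units of increase, > 0.
#' @return List `term`, `delta`, `or`, `ci_low`, `ci_high`, `p`.
#' @export
scaled_or <- function(fit, term, delta) {
  stopifnot(is.numeric(delta), length(delta) == 1)
  if (delta <= 0) stop("delta must be positive")
  i <- match(term, fit$terms$term)
  if (is.na(i)) stop("term not present in fit: ", term)
  b <- fit$terms$beta[i]; se <- fit$terms$se[i]
  list(term = term, delta = delta,
       or = exp(b * delta),
       ci_low = exp((b - 1.96 * se) * delta),
       ci_high = exp((b + 1.96 * se) * delta),
       p = fit$terms$p[i])
}

#' Welch two-sample t test
#'
#' Unequal-variance two-sample t with Satterthwaite degrees of freedom,
#' two-sided. Thin wrapper over `stats::t.test` returning just the statistic
#' and p value, used for the age-group and sex contrasts of the adherence
#' summary.
#'
#' @param values_a,values_b Numeric vectors, each n >= 2.
#' @return List `t`, `df`, `p`.
#' @export
welch_t_test <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 observations")
  }
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0 &&
      mean(values_a) == mean(values_b)) {
    return(list(t = 0, df = Inf, p = 1)) # degenerate identical groups
  }
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

# assemble per-(individual, condition) model rows for one methodology
model_rows <- function(adherence, metrics, demographics,
                       methodology = c("fixed", "variable"),
                       sensitivity = FALSE) {
  methodology <- match.arg(methodology)
  col <- if (sensitivity) paste0("sens_", methodology, "_adherent")
         else paste0(methodology, "_adherent")
  rows <- merge(adherence, demographics[, c("individual_id", "age_years", "sex")],
                by = "individual_id")
  rows <- merge(rows, metrics, by = "individual_id", all.x = TRUE)
  rows$adherent <- rows[[col]]
  rows <- rows[!is.na(rows$adherent), , drop = FALSE]
  rows$tracker <- !is.na(rows$ever_tracked_any) & rows$ever_tracked_any
  for (tp in ACTIVITIES) {
    cn <- paste0("ever_tracked_", tp)
    rows[[cn]] <- !is.na(rows[[cn]]) & rows[[cn]]
  }
  rows$sex <- factor(rows$sex, levels = c("F", "M"))
  # steps on a per-day-tracked, per-1000 scale for numerically sane coefficients
  rows$steps_per_day_k <- rows$steps_per_week / 7 / 1000
  rows
}

#' Fit the full inventory of association models
#'
#' For each adherence methodology (fixed and variable condition-level
#' adherent status as the outcome) fits, with age + sex (+ age x sex)
#' adjustment throughout:
#' 1 overall tracker-vs-nontracker model on the pooled per-(individual,
#' condition) rows (multi-condition individuals contribute one row per
#' condition); 3 per-condition tracker models; 4 per-activity models (ever
#' tracked that activity vs not); and, restricted to metrics-eligible
#' trackers, 2 single-metric models (adjusted tracking ratio; steps per day
#' tracked in thousands) plus 1 combined model — 11 models per methodology.
#' A scope with no eligible rows (e.g. no food loggers) is skipped with a
#' warning.
#'
#' @param adherence Adherence table from [adherence_table()] (all conditions
#'   row-bound).
#' @param metrics Tracking-metrics table from [tracking_metrics()].
#' @param demographics Demographics table.
#' @param methodologies Which outcomes to run, default both.
#' @param sensitivity Use the any-class sensitivity adherent flags instead of
#'   the condition-level flags.
#' @param interaction Passed to [fit_logistic()].
#' @return List of `logistic_fit` objects, named
#'   `<methodology>.<scope>`; scopes are `overall`, the condition ids,
#'   `activity_<type>`, `metric_ratio`, `metric_steps`, `metric_combined`.
#' @export
run_model_suite <- function(adherence, metrics, demographics,
                            methodologies = c("fixed", "variable"),
                            sensitivity = FALSE, interaction = TRUE) {
  fits <- list()
  conditions <- unique(adherence$condition)
  for (m in methodologies) {
    rows <- model_rows(adherence, metrics, demographics, m, sensitivity)
    try_fit <- function(scope, data, exposures) {
      if (nrow(data) == 0L) {
        warning("scope ", scope, " (", m, "): no eligible rows, model skipped")
        return(NULL)
      }
      f <- tryCatch(
        fit_logistic(data, "adherent", exposures, interaction = interaction,
                     scope = paste0(m, ".", scope)),
        error = function(e) {
          warning("scope ", scope, " (", m, "): ", conditionMessage(e),
                  "; model skipped")
          NULL
        })
      if (!is.null(f)) fits[[paste0(m, ".", scope)]] <<- f
    }
    try_fit("overall", rows, "tracker")
    for (cnd in conditions) {
      try_fit(cnd, rows[rows$condition == cnd, , drop = FALSE], "tracker")
    }
    for (tp in ACTIVITIES) {
      cn <- paste0("ever_tracked_", tp)
      d <- rows
      if (!any(d[[cn]])) {
        warning("scope activity_", tp, " (", m, "): no ", tp, " loggers, model skipped")
        next
      }
      try_fit(paste0("activity_", tp), d, cn)
    }
    el <- rows[!is.na(rows$metrics_eligible) & rows$metrics_eligible, , drop = FALSE]
    try_fit("metric_ratio", el, "adjusted_ratio")
    el_s <- el[!is.na(el$steps_per_day_k), , drop = FALSE]
    try_fit("metric_steps", el_s, "steps_per_day_k")
    try_fit("metric_combined", el_s, c("adjusted_ratio", "steps_per_day_k"))
  }
  fits
}

#' Flatten a model suite to one row per term per model
#'
#' @param fits List from [run_model_suite()].
#' @return data.frame: `scope`, `outcome`, `term`, `beta`, `se`, `z`, `p`,
#'   `or`, `ci_low`, `ci_high`, `n`, `converged`.
#' @export
models_table <- function(fits) {
  if (length(fits) == 0L) {
    return(data.frame(scope = character(0), outcome = character(0),
                      term = character(0), beta = numeric(0), se = numeric(0),
                      z = numeric(0), p = numeric(0), or = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      n = integer(0), converged = logical(0)))
  }
  out <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    cbind(data.frame(scope = paste(parts[-1], collapse = "."),
                     outcome = parts[1]),
          f$terms, n = f$n, converged = f$converged)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
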