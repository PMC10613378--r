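# Univariate screening tests, fixed- and random-intercept logistic models
# of participation, and manual backward model reduction.

#' Univariate association screen against participation
#'
#' For each candidate variable, compares participants with
#' non-participants: continuous variables with a two-sided Student's t-test
#' (equal variances), categorical variables with a chi-squared test without
#' continuity correction. Missing values are excluded from the tests but
#' counted per group.
#'
#' @param data physician-level data.frame containing the outcome and the
#'   variables.
#' @param outcome name of the binary outcome column (default
#'   "participated").
#' @param continuous,categorical character vectors of column names to test.
#' @return data.frame of class `univariate_report`: one row per variable
#'   with group means/SDs (continuous), test name, statistic, p-value,
#'   per-group missing counts and notes; category count tables are attached
#'   as attribute `"counts"`.
#' @export
univariate_tests <- function(data, outcome = "participated",
                             continuous = character(0),
                             categorical = character(0)) {
  y <- data[[outcome]]
  if (is.null(y) || anyNA(y) || !all(y %in% c(0, 1)))
    stopf("univariate_tests: outcome '%s' must be binary and nonmissing",
          outcome)
  g1 <- y == 1
  rows <- list()
  counts <- list()
  for (v in continuous) {
    x <- data[[v]]
    note <- ""
    stat <- p <- NA_real_
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2L) {
      note <- "constant variable; test skipped"
    } else {
      tt <- t.test(x[ok & g1], x[ok & !g1], var.equal = TRUE)
      stat <- unname(tt$statistic)
      p <- tt$p.value
    }
    rows[[v]] <- data.frame(
      variable = v, type = "continuous", test = "Student t",
      statistic = stat, p_value = p,
      mean_participated = mean(x[ok & g1]),
      sd_participated = sd(x[ok & g1]),
      mean_not = mean(x[ok & !g1]), sd_not = sd(x[ok & !g1]),
      missing_participated = sum(!ok & g1),
      missing_not = sum(!ok & !g1),
      note = note, stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    x <- data[[v]]
    ok <- !is.na(x)
    note <- ""
    stat <- p <- NA_real_
    if (length(unique(x[ok])) < 2L) {
      note <- "constant variable; test skipped"
    } else {
      tab <- table(x[ok], y[ok])
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      stat <- unname(ct$statistic)
      p <- ct$p.value
    }
    counts[[v]] <- table(ifelse(ok, as.character(x), "Missing"), y)
    rows[[v]] <- data.frame(
      variable = v, type = "categorical", test = "chi-squared",
      statistic = stat, p_value = p,
      mean_participated = NA_real_, sd_participated = NA_real_,
      mean_not = NA_real_, sd_not = NA_real_,
      missing_participated = sum(!ok & g1),
      missing_not = sum(!ok & !g1),
      note = note, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  class(out) <- c("univariate_report", "data.frame")
  out
}

#' Specify a participation model
#'
#' Terms are column names in the analysis data; interactions are written
#' `"a:b"`. The shorthand term `"age"` expands to the missingness-safe pair
#' `age_c_obs + age_observed` (centered age nullified where missing, plus
#' the observed-age indicator; see [derive_covariates()]); the pair always
#' enters and leaves the model together, and age never enters any other
#' way.
#'
#' @param terms character vector of predictor terms.
#' @param outcome binary outcome column name.
#' @param random_intercept optional grouping column (e.g. the primary
#'   billing hospital) for a random-intercept model.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(terms, outcome = "participated",
                       random_intercept = NULL) {
  terms <- as.character(terms)
  if ("age" %in% terms || "age_c_obs" %in% terms) {
    terms <- setdiff(terms, c("age", "age_c_obs", "age_observed"))
    terms <- c("age_c_obs", "age_observed", terms)
  }
  bad <- grep("(^|:)age($|:)", terms, value = TRUE)
  if (length(bad))
    stopf("model_spec: age may only enter via the age_c_obs/age_observed pair")
  out <- list(outcome = outcome, terms = unique(terms),
              random_intercept = random_intercept)
  class(out) <- "model_spec"
  out
}

spec_formula <- function(spec) {
  rhs <- if (length(spec$terms)) paste(spec$terms, collapse = " + ") else "1"
  if (!is.null(spec$random_intercept))
    rhs <- paste0(rhs, " + (1 | ", spec$random_intercept, ")")
  as.formula(paste(spec$outcome, "~", rhs))
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Participation model spec:\n  ", deparse(spec_formula(x)), "\n")
  invisible(x)
}

#' Fit a logistic participation model
#'
#' Fits the participation model by maximum likelihood: an ordinary
#' logit-link GLM, or — when the spec names a random-intercept grouping —
#' a mixed-effects logistic regression via the Laplace approximation
#' (lme4), reporting the random-intercept standard deviation tau. A tau
#' estimated at the 0 boundary is valid output. Inference is Wald:
#' odds ratios are exponentiated coefficients with 95% CIs
#' exp(estimate +/- 1.96 se). Complete separation is reported as a fit
#' note, not silent divergence; a singular (aliased) design is an error
#' naming the collinear terms.
#'
#' @param spec a [model_spec()] or a model formula (use `(1 | group)` for a
#'   random intercept).
#' @param data analysis data.frame.
#' @return object of class `peer_fit`.
#' @examples
#' d <- data.frame(y = rep(c(1, 1, 0, 0), c(20, 10, 10, 20)),
#'                 x = rep(c(1, 0, 1, 0), c(20, 10, 10, 20)))
#' f <- fit_participation(model_spec("x", outcome = "y"), d)
#' coef(summary(f))  # OR for x is ad/bc = 4
#' @export
fit_participation <- function(spec, data) {
  if (inherits(spec, "formula")) {
    has_bar <- any(grepl("|", all.names(spec), fixed = TRUE))
    form <- spec
    spec <- list(outcome = deparse(spec[[2]]),
                 terms = attr(stats::terms(lme4::nobars(spec)),
                              "term.labels"),
                 random_intercept = if (has_bar) "(from formula)" else NULL)
    class(spec) <- "model_spec"
    if (!has_bar) spec$random_intercept <- NULL
  } else if (inherits(spec, "model_spec")) {
    form <- spec_formula(spec)
  } else stopf("'spec' must be a model_spec or formula")

  mixed <- !is.null(spec$random_intercept)
  notes <- character(0)
  fit <- withCallingHandlers(
    if (mixed) {
      if (!is.null(spec$random_intercept) &&
          spec$random_intercept %in% names(data) &&
          length(unique(data[[spec$random_intercept]])) < 2L)
        stopf("fit_participation: fewer than 2 groups in '%s'; use a fixed-effect fit",
              spec$random_intercept)
      lme4::glmer(form, data = data, family = binomial("logit"))
    } else {
      glm(form, data = data, family = binomial("logit"))
    },
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg))
        msg <- paste("possible complete separation:", msg)
      notes <<- c(notes, msg)
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      notes <<- c(notes, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    })

  if (mixed) {
    ct <- summary(fit)$coefficients
    vc <- as.data.frame(lme4::VarCorr(fit))
    tau <- vc$sdcor[1]
    n <- stats::nobs(fit)
    converged <- length(fit@optinfo$conv$lme4$messages) == 0
    if (!converged)
      notes <- c(notes, unlist(fit@optinfo$conv$lme4$messages))
  } else {
    cf <- coef(fit)
    aliased <- names(cf)[is.na(cf)]
    if (length(aliased))
      stopf("singular design: collinear term(s) %s",
            paste(aliased, collapse = ", "))
    ct <- summary(fit)$coefficients
    tau <- NA_real_
    n <- stats::nobs(fit)
    converged <- fit$converged
  }
  est <- ct[, 1]; se <- ct[, 2]
  zcrit <- qnorm(0.975)
  coef_table <- data.frame(
    term = rownames(ct),
    estimate = est, se = se, z = est / se,
    p_value = 2 * pnorm(-abs(est / se)),
    or = exp(est),
    ci_low = exp(est - zcrit * se),
    ci_high = exp(est + zcrit * se),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- list(spec = spec, formula = form,
              engine = if (mixed) "glmer" else "glm",
              fit = fit, coefficients = coef_table,
              tau = tau, n = n, converged = converged, notes = notes)
  class(out) <- "peer_fit"
  out
}

#' @export
print.peer_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Participation model (%s), n = %d\n", x$engine, x$n))
  cat("  ", deparse(x$formula), "\n", sep = "")
  ct <- x$coefficients
  disp <- data.frame(term = ct$term,
                     OR = round(ct$or, digits),
                     `2.5%` = round(ct$ci_low, digits),
                     `97.5%` = round(ct$ci_high, digits),
                     p = signif(ct$p_value, digits),
                     check.names = FALSE)
  print(disp, row.names = FALSE)
  if (!is.na(x$tau))
    cat(sprintf("Random-intercept SD (tau): %.3f\n", x$tau))
  if (length(x$notes)) cat("Notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.peer_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.peer_fit")
}

#' @export
print.summary.peer_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficient table (log-odds scale):\n")
  print(x$fit$coefficients, row.names = FALSE)
  invisible(x)
}

#' @export
coef.summary.peer_fit <- function(object, ...) object$fit$coefficients

#' @export
coef.peer_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
vcov.peer_fit <- function(object, ...) as.matrix(vcov(object$fit))

#' Odds-ratio table of a fitted participation model
#'
#' @param fit a `peer_fit`.
#' @return data.frame with term, or, ci_low, ci_high, p_value.
#' @export
odds_ratios <- function(fit) {
  stopifnot(inherits(fit, "peer_fit"))
  fit$coefficients[c("term", "or", "ci_low", "ci_high", "p_value")]
}

# ---- manual backward reduction --------------------------------------------

# reduction units: the age pair moves together; interactions lock their
# main effects
reduction_units <- function(terms) {
  units <- list()
  if (all(c("age_c_obs", "age_observed") %in% terms)) {
    units$age <- list(members = c("age_c_obs", "age_observed"),
                      focal = "age_c_obs")
    terms <- setdiff(terms, c("age_c_obs", "age_observed"))
  }
  for (tm in terms) units[[tm]] <- list(members = tm, focal = tm)
  units
}

unit_removable <- function(unit_name, units) {
  members <- units[[unit_name]]$members
  if (any(grepl(":", members, fixed = TRUE))) return(TRUE)
  inter <- unlist(lapply(units, function(u)
    u$members[grepl(":", u$members, fixed = TRUE)]))
  if (length(inter) == 0) return(TRUE)
  vars_in_inter <- unique(unlist(strsplit(inter, ":", fixed = TRUE)))
  !any(members %in% vars_in_inter)
}

#' Manual backward model reduction
#'
#' Iteratively refits the model, each time removing the single least
#' significant removable term (largest Wald p at or above `alpha`), until
#' every remaining removable term is significant. Marginality is respected:
#' a main effect is never dropped while an interaction involving it
#' remains, and the age pair (age_c_obs, age_observed) is dropped or kept
#' together, judged by the centered-age coefficient. Ties in p are broken
#' by term order. An empty (intercept-only) model is a legal terminus.
#'
#' @param spec a [model_spec()].
#' @param data analysis data.frame.
#' @param alpha significance threshold (default 0.05).
#' @return list with the final `spec`, final `fit` (a `peer_fit`), and a
#'   `trace` data.frame of removals (step, unit, p_value).
#' @export
reduce_model <- function(spec, data, alpha = 0.05) {
  stopifnot(inherits(spec, "model_spec"))
  trace <- data.frame(step = integer(0), unit = character(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    fit <- fit_participation(spec, data)
    units <- reduction_units(spec$terms)
    if (length(units) == 0L) break
    ct <- fit$coefficients
    # focal p per unit; interaction rows may be named with reordered vars
    unit_p <- vapply(names(units), function(u) {
      focal <- units[[u]]$focal
      row <- match(focal, ct$term)
      if (is.na(row) && grepl(":", focal, fixed = TRUE)) {
        parts <- strsplit(focal, ":", fixed = TRUE)[[1]]
        row <- which(vapply(strsplit(ct$term, ":", fixed = TRUE),
                            function(p) setequal(p, parts), logical(1)))[1]
      }
      if (is.na(row)) NA_real_ else ct$p_value[row]
    }, numeric(1))
    removable <- vapply(names(units), unit_removable, logical(1),
                        units = units)
    candidates <- which(removable & !is.na(unit_p) & unit_p >= alpha)
    if (length(candidates) == 0L) break
    worst <- candidates[which.max(unit_p[candidates])]
    step_i <- step_i + 1L
    trace <- rbind(trace, data.frame(step = step_i,
                                     unit = names(units)[worst],
                                     p_value = unit_p[worst]))
    spec$terms <- setdiff(spec$terms, units[[worst]]$members)
  }
  list(spec = spec, fit = fit, trace = trace)
}
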