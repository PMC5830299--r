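# Matched case-control resource selection function with Monte Carlo
# variance correction.
#
# One logistic regression is fitted per control replicate (observed rows =
# cases, that replicate's simulated rows = controls, equal observation
# weights, no random effects). Because telemetry locations are strongly
# autocorrelated, model-based standard errors from any single fit are
# biased low; instead the per-term mean across the replicate fits is the
# estimate and the across-replicate standard deviation is the standard
# error, with normal-tail p-values. Backward stepwise elimination respects
# marginality: a term is removable only while no other remaining term
# contains it.

#' Canonical RSF model vocabulary
#'
#' Terms are written in the field's notation: single effects
#' `sex`, `sqrt(d2coast)`, `sqrt(depth_m)`, `sqrt(d21kiso)`, `sqrt(d2ice)`,
#' `ice_conc`, `ice_conc^2`, `sea_ice`; interactions are colon-joined.
#' `sex` is coded as a male dummy (reference F); `sea_ice` as an open-water
#' dummy (reference: within the ice field), so a negative `sqrt(d2ice)`
#' coefficient means selection for proximity to the ice edge.
#'
#' @return Character vector of the eight single-effect terms.
#' @export
rsf_single_effects <- function() {
  c("sex", "sqrt(d2coast)", "sqrt(depth_m)", "sqrt(d21kiso)", "sqrt(d2ice)",
    "ice_conc", "ice_conc^2", "sea_ice")
}

#' Initial (full) RSF model
#'
#' All eight single effects, the `sea_ice:sqrt(d2ice)` interaction, the
#' interaction of sex with every other single effect, and the three-way
#' `sex:sea_ice:sqrt(d2ice)`. The intercept is always present and is not a
#' term.
#'
#' @return Character vector of 17 terms.
#' @export
rsf_initial_terms <- function() {
  singles <- rsf_single_effects()
  c(singles,
    "sea_ice:sqrt(d2ice)",
    paste0("sex:", setdiff(singles, "sex")),
    "sex:sea_ice:sqrt(d2ice)")
}

term_factors <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

# TRUE if term a is a proper constituent of term b (all factors of a appear
# in b, and b has more factors). In addition `ice_conc` is treated as a
# constituent of `ice_conc^2` so the linear term cannot outlive the
# quadratic.
term_contained_in <- function(a, b) {
  fa <- term_factors(a); fb <- term_factors(b)
  if (length(fb) > length(fa) && all(fa %in% fb)) return(TRUE)
  identical(a, "ice_conc") && identical(b, "ice_conc^2")
}

# Terms with no other remaining term containing them (marginality).
removable_terms <- function(terms) {
  terms[!vapply(terms, function(a)
    any(vapply(setdiff(terms, a), function(b) term_contained_in(a, b),
               logical(1))), logical(1))]
}

check_formula_hierarchy <- function(terms) {
  for (a in terms) {
    fa <- term_factors(a)
    if (length(fa) > 1 && !all(fa %in% terms))
      stop(sprintf("formula violates hierarchy: '%s' lacks constituent(s) %s",
                   a, paste(setdiff(fa, terms), collapse = ", ")))
    if ("ice_conc^2" %in% fa && !("ice_conc" %in% terms))
      stop("formula violates hierarchy: ice_conc^2 requires ice_conc")
  }
  invisible(terms)
}

# Numeric column for one factor of a term.
factor_column <- function(f, data) {
  switch(f,
    "sex"           = as.numeric(data$sex == "M"),
    "sea_ice"       = as.numeric(data$sea_ice == "no"),
    "sqrt(d2coast)" = sqrt(data$d2coast),
    "sqrt(depth_m)" = sqrt(data$depth_m),
    "sqrt(d21kiso)" = sqrt(data$d21kiso),
    "sqrt(d2ice)"   = sqrt(data$d2ice),
    "ice_conc"      = data$ice_conc,
    "ice_conc^2"    = data$ice_conc^2,
    stop(sprintf("unknown model term factor '%s'", f))
  )
}

#' Design matrix for a term list
#'
#' Builds the intercept-plus-terms design matrix from a covariate table.
#' Interactions are products of their factor columns.
#'
#' @param terms Character vector of canonical terms.
#' @param data Covariate rows (columns `sex`, `sea_ice`, `d2coast`,
#'   `depth_m`, `d21kiso`, `d2ice`, `ice_conc`).
#' @return Numeric matrix with columns `(Intercept)` then `terms`.
#' @export
rsf_design_matrix <- function(terms, data) {
  cols <- lapply(terms, function(tm) {
    Reduce(`*`, lapply(term_factors(tm), factor_column, data = data))
  })
  X <- cbind(`(Intercept)` = rep(1, nrow(data)),
             do.call(cbind, c(cols, list(deparse.level = 0))))
  colnames(X) <- c("(Intercept)", terms)
  X
}

#' Linear predictor under known coefficients
#'
#' Used by the synthetic generators to score candidate habitat: the logit
#' contribution `sum(beta * x)` for each row (no intercept unless supplied
#' as `(Intercept)`).
#'
#' @param beta Named numeric vector over canonical terms.
#' @param data Covariate rows.
#' @return Numeric vector of scores.
#' @export
rsf_score <- function(beta, data) {
  terms <- setdiff(names(beta), "(Intercept)")
  s <- rep(if ("(Intercept)" %in% names(beta)) beta[["(Intercept)"]] else 0,
           nrow(data))
  for (tm in terms)
    s <- s + beta[[tm]] *
      Reduce(`*`, lapply(term_factors(tm), factor_column, data = data))
  s
}

#' Fit one replicate's logistic RSF
#'
#' Maximum-likelihood logistic regression (IRLS, tolerance 1e-8, up to 100
#' iterations) of case (1 = observed) against control (0 = simulated) rows,
#' with equal observation weights and no random effects.
#'
#' @param rows Covariate rows restricted to the cases plus one control
#'   replicate; must contain a 0/1 `case` column and both classes.
#' @param terms Model terms (character); intercept implicit.
#' @return A `replicate_fit`: list with `coef` (named), `converged`,
#'   `separation`, `loglik`, `n`.
#' @export
fit_single_rsf <- function(rows, terms) {
  if (!all(c(0, 1) %in% rows$case))
    stop("both cases and controls must be present")
  X <- rsf_design_matrix(terms, rows)
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  y <- rows$case[keep]
  # drop constant (non-identifiable) columns, keeping the intercept
  const <- apply(X, 2, function(v) diff(range(v)) == 0)
  const[1] <- FALSE
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X[, !const, drop = FALSE], y,
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  beta[names(fit$coefficients)] <- fit$coefficients
  beta[const] <- 0  # non-identifiable: no information, fixed at 0
  # (quasi-)separation: fitted values at the boundary or runaway slopes
  if (any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10) ||
      max(abs(beta[-1]), 0, na.rm = TRUE) > 15)
    sep <- TRUE
  ll <- sum(stats::dbinom(y, 1, pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12),
                          log = TRUE))
  structure(list(coef = beta, converged = fit$converged, separation = sep,
                 loglik = ll, n = length(y)),
            class = "replicate_fit")
}

fit_all_replicates <- function(rows, terms) {
  reps <- sort(unique(rows$replicate[rows$replicate > 0]))
  cases <- rows[rows$replicate == 0, , drop = FALSE]
  lapply(reps, function(r) {
    fit_single_rsf(rbind(cases, rows[rows$replicate == r, , drop = FALSE]),
                   terms)
  })
}

#' Monte Carlo inference across replicate fits
#'
#' The per-term estimate is the arithmetic mean of the coefficients over
#' the converged replicate fits; the standard error is their sample
#' standard deviation (not divided by sqrt(n): the replicate spread itself
#' is the sampling noise being corrected for); `z = mean/SE` with two-sided
#' normal p-values.
#'
#' @param fits List of [fit_single_rsf()] results.
#' @return Data frame with columns `term`, `estimate`, `se`, `z`, `p`,
#'   `degenerate` (TRUE where the across-replicate SD is 0, in which case
#'   `p` is NA and flagged rather than reported as 0).
#' @export
mc_inference <- function(fits) {
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (sum(ok) < 2)
    stop("insufficient replicates: need >= 2 converged fits")
  B <- do.call(rbind, lapply(fits[ok], function(f) f$coef))
  est <- colMeans(B)
  se <- apply(B, 2, stats::sd)
  z <- ifelse(se > 0, est / se, NA_real_)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(term = colnames(B), estimate = est, se = se, z = z, p = p,
             degenerate = se == 0, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Hierarchical backward stepwise elimination
#'
#' Starting from `initial`, repeatedly refit all replicates, run
#' [mc_inference()], and among the removable terms (those not contained in
#' any other remaining term; the intercept never leaves) delete the least
#' significant one with `p > alpha`; stop when every removable term is
#' significant. Ties are broken by removing the higher-order term first,
#' then alphabetically.
#'
#' @param rows Full covariate table (replicate 0 = cases).
#' @param initial Initial term vector (default [rsf_initial_terms()]).
#' @param alpha Significance level to stay (default 0.05).
#' @param refit Refit all replicates after every removal (default TRUE,
#'   statistically cleaner). With `FALSE`, removals are decided from the
#'   initial model's p-values (frozen), and only the final model is
#'   refitted.
#' @return An `rsf_result`: list with `final` (mc_inference table of the
#'   final model), `terms`, `trace` (data.frame term/p/step for each
#'   removal), `fits` (final replicate fits), `alpha`.
#' @export
stepwise_eliminate <- function(rows, initial = rsf_initial_terms(),
                               alpha = 0.05, refit = TRUE) {
  check_formula_hierarchy(initial)
  terms <- initial
  trace <- data.frame(term = character(), p = numeric(), step = integer(),
                      stringsAsFactors = FALSE)
  step <- 0L
  frozen <- NULL
  repeat {
    if (refit || is.null(frozen)) {
      fits <- fit_all_replicates(rows, terms)
      mc <- mc_inference(fits)
      if (!refit) frozen <- mc
    } else {
      mc <- frozen[frozen$term %in% c("(Intercept)", terms), , drop = FALSE]
    }
    rem <- removable_terms(terms)
    # a term that is identically zero in every replicate (dropped as
    # non-identifiable) carries no information and is removed first;
    # other degenerate-SE terms are kept and left flagged
    mc2 <- mc
    mc2$p <- ifelse(is.na(mc$p) & mc$estimate == 0, 1, mc$p)
    cand <- mc2[mc2$term %in% rem & !is.na(mc2$p) & mc2$p > alpha, ,
                drop = FALSE]
    if (nrow(cand) == 0) {
      if (!refit && nrow(trace) > 0) {
        fits <- fit_all_replicates(rows, terms)
        mc <- mc_inference(fits)
      }
      return(structure(list(final = mc, terms = terms, trace = trace,
                            fits = fits, alpha = alpha),
                       class = "rsf_result"))
    }
    ord <- order(-cand$p,
                 -vapply(cand$term, function(tm) length(term_factors(tm)),
                         integer(1)),
                 cand$term)
    drop_term <- cand$term[ord[1]]
    step <- step + 1L
    trace <- rbind(trace, data.frame(term = drop_term, p = cand$p[ord[1]],
                                     step = step, stringsAsFactors = FALSE))
    terms <- setdiff(terms, drop_term)
  }
}

#' @export
print.rsf_result <- function(x, ...) {
  cat("Monte Carlo RSF (", length(x$fits), " replicates, alpha = ",
      x$alpha, ")\n\n", sep = "")
  cat("Final model:\n")
  print(x$final, digits = 4)
  if (nrow(x$trace)) {
    cat("\nEliminated (in order):\n")
    print(x$trace, digits = 4)
  }
  invisible(x)
}

#' Odds-of-selection curve
#'
#' Exponentiated linear predictor of the final model along a grid of one
#' covariate, all others held at `profile`. Odds > 1 indicate chosen
#' habitat, < 1 rejected habitat. When `rows` is supplied, the relative
#' availability of the varied covariate among control rows is attached as
#' shading weights.
#'
#' @param result An `rsf_result`.
#' @param profile Named list fixing every final-model covariate except the
#'   varied one (`sex` in "F"/"M", `sea_ice` in "yes"/"no", others numeric
#'   on natural scale).
#' @param vary Name of the covariate column to vary (e.g. `"d2ice"`,
#'   `"ice_conc"`).
#' @param grid Numeric grid of values for `vary`.
#' @param rows Optional covariate table for availability weights.
#' @param include_intercept Include the fitted intercept in the linear
#'   predictor (default TRUE).
#' @return Data frame `value`, `odds`, `availability`.
#' @export
odds_of_selection <- function(result, profile, vary, grid, rows = NULL,
                              include_intercept = TRUE) {
  stopifnot(inherits(result, "rsf_result"))
  needed <- unique(unlist(lapply(result$terms, term_factors)))
  needed_cols <- unique(vapply(needed, function(f) switch(f,
    "sex" = "sex", "sea_ice" = "sea_ice", "sqrt(d2coast)" = "d2coast",
    "sqrt(depth_m)" = "depth_m", "sqrt(d21kiso)" = "d21kiso",
    "sqrt(d2ice)" = "d2ice", "ice_conc" = "ice_conc",
    "ice_conc^2" = "ice_conc"), character(1)))
  missing_cols <- setdiff(needed_cols, c(names(profile), vary))
  if (length(missing_cols))
    stop(sprintf("incomplete profile: missing %s",
                 paste(missing_cols, collapse = ", ")))
  data <- as.data.frame(profile, stringsAsFactors = FALSE)
  data <- data[rep(1, length(grid)), , drop = FALSE]
  data[[vary]] <- grid
  beta <- stats::setNames(result$final$estimate, result$final$term)
  if (!include_intercept) beta <- beta[names(beta) != "(Intercept)"]
  lp <- rsf_score(beta, data)
  avail <- rep(NA_real_, length(grid))
  if (!is.null(rows)) {
    ctl <- rows[[vary]][rows$replicate > 0]
    ctl <- ctl[is.finite(ctl)]
    if (length(ctl) > 1) {
      dens <- stats::density(ctl, from = min(grid), to = max(grid))
      avail <- stats::approx(dens$x, dens$y, xout = grid, rule = 2)$y
      avail <- avail / max(avail)
    }
  }
  data.frame(value = grid, odds = exp(lp), availability = avail)
}

#' Ice concentration of peak selection
#'
#' Stationary point of the quadratic ice-concentration effect on the logit
#' scale, `-b_lin / (2 * b_quad)`, clipped to \[0, 100\]. Returns `NA` when
#' the final model lacks the quadratic pair or the quadratic coefficient is
#' non-negative (no interior optimum).
#'
#' @param result An `rsf_result`, or a named numeric vector containing
#'   `ice_conc` and `ice_conc^2` coefficients.
#' @return Concentration in %, or `NA_real_`.
#' @export
peak_ice_concentration <- function(result) {
  beta <- if (inherits(result, "rsf_result"))
    stats::setNames(result$final$estimate, result$final$term)
  else result
  if (!all(c("ice_conc", "ice_conc^2") %in% names(beta))) return(NA_real_)
  bq <- beta[["ice_conc^2"]]
  if (!is.finite(bq) || bq >= 0) return(NA_real_)
  min(max(-beta[["ice_conc"]] / (2 * bq), 0), 100)
}
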