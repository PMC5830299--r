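# Logistic fits against independent oracles, Monte Carlo inference,
# hierarchical stepwise elimination, selection curves, and the quadratic
# concentration optimum.

mk_rows <- function(n, seed = 1) {
  set.seed(seed)
  d <- default_availability(n)
  d$case <- rbinom(n, 1, 0.5)
  d$replicate <- ifelse(d$case == 1, 0L, 1L)
  d
}

test_that("a 2x2 binary design recovers the closed-form log odds ratio", {
  # exposed = open water (sea_ice = "no"): a=30 exposed cases, b=20
  # unexposed cases, c=10 exposed controls, d=40 unexposed controls
  rows <- data.frame(
    sea_ice = rep(c("no", "yes", "no", "yes"), c(30, 20, 10, 40)),
    case = rep(c(1, 1, 0, 0), c(30, 20, 10, 40)),
    replicate = rep(c(0L, 0L, 1L, 1L), c(30, 20, 10, 40)),
    stringsAsFactors = FALSE
  )
  fit <- fit_single_rsf(rows, "sea_ice")
  expect_equal(unname(fit$coef["sea_ice"]), log(30 * 40 / (20 * 10)),
               tolerance = 1e-6)
  expect_equal(unname(fit$coef["sea_ice"]), log(6), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("ML fits match a brute-force Newton optimizer to 1e-6", {
  for (seed in 1:4) {
    rows <- mk_rows(80, seed = seed)
    terms <- c("sqrt(d2ice)", "ice_conc", "sea_ice")
    fit <- fit_single_rsf(rows, terms)
    X <- rsf_design_matrix(terms, rows)
    beta_newton <- newton_logistic(X, rows$case)
    expect_equal(unname(fit$coef), unname(beta_newton), tolerance = 1e-6)
    # intercept score equation: fitted probabilities sum to the case count
    p_hat <- plogis(drop(X %*% fit$coef))
    expect_equal(sum(p_hat), sum(rows$case), tolerance = 1e-6)
  }
})

test_that("degenerate designs are handled, not crashed", {
  rows <- mk_rows(60, seed = 9)
  rows$sea_ice <- "yes"  # constant covariate: no information
  fit <- fit_single_rsf(rows, c("sqrt(d2ice)", "sea_ice"))
  expect_equal(unname(fit$coef["sea_ice"]), 0)
  expect_error(fit_single_rsf(transform(mk_rows(40), case = 1L),
                              "sqrt(d2ice)"),
               "cases and controls")
  # perfect separation is flagged
  sep <- mk_rows(40, seed = 10)
  sep$d2ice <- ifelse(sep$case == 1, 1, 400)
  fit_sep <- fit_single_rsf(sep, "sqrt(d2ice)")
  expect_true(fit_sep$separation)
})

test_that("MC inference is the sample mean / SD across replicate fits", {
  set.seed(12)
  draws <- rnorm(20, mean = 1, sd = 0.5)
  fits <- lapply(draws, function(b)
    structure(list(coef = c("(Intercept)" = 0, "sqrt(d2ice)" = b),
                   converged = TRUE, separation = FALSE,
                   loglik = 0, n = 10), class = "replicate_fit"))
  mc <- mc_inference(fits)
  i <- mc$term == "sqrt(d2ice)"
  expect_equal(mc$estimate[i], mean(draws), tolerance = 1e-12)
  expect_equal(mc$se[i], sd(draws), tolerance = 1e-12)
  expect_equal(mc$z[i], mean(draws) / sd(draws), tolerance = 1e-12)
  expect_equal(mc$p[i], 2 * pnorm(-abs(mean(draws) / sd(draws))),
               tolerance = 1e-12)

  # zero-variance coefficients are flagged, not reported as certain
  fits0 <- lapply(1:5, function(i)
    structure(list(coef = c("(Intercept)" = 0.3, "sqrt(d2ice)" = 0.3),
                   converged = TRUE, separation = FALSE, loglik = 0, n = 10),
              class = "replicate_fit"))
  mc0 <- mc_inference(fits0)
  expect_true(all(mc0$degenerate))
  expect_true(all(is.na(mc0$p)))
  expect_error(mc_inference(fits0[1]), "insufficient replicates")
})

test_that("stepwise recovers an active term and eliminates inert ones", {
  # inert terms survive at roughly the alpha level per run, so the
  # elimination claim is checked as a rate over repeated pipelines
  inert_kept <- 0L
  est <- numeric(10)
  for (i in 1:10) {
    rows <- simulate_rsf_rows(c("sqrt(d2ice)" = -0.2), n_case = 1000,
                              n_rep = 20, seed = 50 + i)
    res <- stepwise_eliminate(rows, initial = c("sqrt(d2ice)",
                                                "sqrt(depth_m)",
                                                "sqrt(d21kiso)"))
    expect_true("sqrt(d2ice)" %in% res$terms)  # active term always stays
    inert_kept <- inert_kept +
      sum(c("sqrt(depth_m)", "sqrt(d21kiso)") %in% res$terms)
    est[i] <- res$final$estimate[res$final$term == "sqrt(d2ice)"]
    # trace and final terms are disjoint and the trace is ordered
    expect_length(intersect(res$trace$term, res$terms), 0)
    expect_equal(res$trace$step, seq_len(nrow(res$trace)))
  }
  expect_lte(inert_kept / 20, 0.3)  # alpha-level retention, with slack
  expect_true(all(est < 0))  # negative = selection for edge proximity
  expect_equal(mean(est), -0.2, tolerance = 0.25)
})

test_that("elimination respects the marginality hierarchy", {
  # pure-noise world with the full initial model: whatever the removal
  # order, no term may leave while another remaining term contains it
  rows <- simulate_rsf_rows(numeric(0), n_case = 250, n_rep = 8, seed = 52)
  res <- stepwise_eliminate(rows)
  remaining <- rsf_initial_terms()
  for (k in seq_len(nrow(res$trace))) {
    tm <- res$trace$term[k]
    others <- setdiff(remaining, tm)
    expect_false(any(vapply(others, function(b) oracle_contains(tm, b),
                            logical(1))),
                 info = paste("removed", tm, "while a container remained"))
    remaining <- others
  }
  # the quadratic never outlives the linear term and vice versa ordering
  if ("ice_conc" %in% res$trace$term && "ice_conc^2" %in% res$trace$term)
    expect_gt(which(res$trace$term == "ice_conc"),
              which(res$trace$term == "ice_conc^2"))
})

test_that("strong signal on all terms yields an empty trace", {
  rows <- simulate_rsf_rows(c("sqrt(d2ice)" = -0.5, "ice_conc" = 0.05),
                            n_case = 1500, n_rep = 10, seed = 53)
  res <- stepwise_eliminate(rows, initial = c("sqrt(d2ice)", "ice_conc"))
  expect_equal(nrow(res$trace), 0)
  expect_setequal(res$terms, c("sqrt(d2ice)", "ice_conc"))
})

test_that("frozen-p elimination decides from the initial fits only", {
  rows <- simulate_rsf_rows(c("sqrt(d2ice)" = -0.5), n_case = 600,
                            n_rep = 8, seed = 55)
  res <- stepwise_eliminate(rows, initial = c("sqrt(d2ice)", "sqrt(depth_m)",
                                              "ice_conc"), refit = FALSE)
  expect_true("sqrt(d2ice)" %in% res$terms)
  expect_length(intersect(res$trace$term, res$terms), 0)
  # frozen removals are in increasing significance (decreasing p)
  if (nrow(res$trace) > 1) expect_true(all(diff(res$trace$p) <= 0))
  # the reported final table comes from a refit of the reduced model
  expect_equal(sort(c("(Intercept)", res$terms)), sort(res$final$term))
})

test_that("MC SEs exceed naive model-based SEs under autocorrelation", {
  env <- small_env(n_days = 25)
  trs <- make_selective_tracks(env, truth = numeric(0), n_animals = 4,
                               n_steps = 60, seed = 61)
  st <- do.call(rbind, lapply(trs, decompose_steps))
  m <- fit_movement_model(st, min_steps = 100)
  ens <- simulate_ensemble(m, trs, env, n_rep = 8, seed = 62)
  rows <- build_covariate_table(trs, ens, env)
  terms <- c("sqrt(d2ice)", "ice_conc")
  fits <- sealrsf:::fit_all_replicates(rows, terms)
  mc <- mc_inference(fits)
  # naive single-replicate model-based SE via an independent glm() refit
  one <- rbind(rows[rows$replicate == 0, ], rows[rows$replicate == 1, ])
  g <- glm(case ~ sqrt(d2ice) + ice_conc, binomial(), data = one)
  naive_se <- summary(g)$coefficients["sqrt(d2ice)", "Std. Error"]
  expect_gt(mc$se[mc$term == "sqrt(d2ice)"], naive_se)
})

test_that("odds-of-selection curves follow the coefficient arithmetic", {
  # final model shaped like the canonical published fit
  beta <- c("(Intercept)" = 0.455066, "sea_ice" = -0.501833,
            "ice_conc" = 0.058692, "ice_conc^2" = -0.000370,
            "sqrt(d2ice)" = -0.206333, "sea_ice:sqrt(d2ice)" = 0.185093)
  res <- structure(list(
    final = data.frame(term = names(beta), estimate = unname(beta),
                       se = 0.1, z = 1, p = 0.01, degenerate = FALSE,
                       stringsAsFactors = FALSE),
    terms = setdiff(names(beta), "(Intercept)"),
    trace = data.frame(), fits = list(), alpha = 0.05),
    class = "rsf_result")

  grid_d2ice <- (0:10)^2  # sqrt spacing of 1
  in_ice <- odds_of_selection(res, profile = list(sex = "F",
                                                  sea_ice = "yes",
                                                  ice_conc = 50),
                              vary = "d2ice", grid = grid_d2ice)
  # within the ice: strictly decreasing with distance from the edge
  expect_true(all(diff(in_ice$odds) < 0))
  slope_in <- diff(log(in_ice$odds))
  expect_equal(slope_in, rep(-0.206333, 10), tolerance = 1e-9)

  open <- odds_of_selection(res, profile = list(sex = "F", sea_ice = "no",
                                                ice_conc = 0),
                            vary = "d2ice", grid = grid_d2ice)
  # open water: the interaction flattens the slope to -0.02124 per sqrt km
  expect_equal(diff(log(open$odds)), rep(-0.206333 + 0.185093, 10),
               tolerance = 1e-9)
  expect_equal(diff(log(open$odds))[1], -0.02124, tolerance = 1e-4)

  # all-zero coefficients: flat curve at exp(intercept)
  res0 <- res
  res0$final$estimate <- c(0.7, rep(0, 5))
  flat <- odds_of_selection(res0, profile = list(sex = "F", sea_ice = "yes",
                                                 ice_conc = 50),
                            vary = "d2ice", grid = grid_d2ice)
  expect_equal(flat$odds, rep(exp(0.7), 11))

  expect_error(odds_of_selection(res, profile = list(sex = "F"),
                                 vary = "d2ice", grid = grid_d2ice),
               "incomplete profile")

  # availability shading comes from the control rows' empirical density
  rows <- mk_rows(500, seed = 77)
  av <- odds_of_selection(res, profile = list(sex = "F", sea_ice = "yes",
                                              ice_conc = 50),
                          vary = "d2ice", grid = grid_d2ice, rows = rows)
  expect_true(all(is.finite(av$availability)))
  expect_equal(max(av$availability), 1)
})

test_that("the quadratic concentration optimum is the analytic vertex", {
  expect_equal(peak_ice_concentration(c("ice_conc" = 1,
                                        "ice_conc^2" = -0.01)), 50)
  expect_true(is.na(peak_ice_concentration(c("ice_conc" = 1,
                                             "ice_conc^2" = 0.001))))
  expect_true(is.na(peak_ice_concentration(c("ice_conc" = 1))))
  # clipping to the physical range
  expect_equal(peak_ice_concentration(c("ice_conc" = 10,
                                        "ice_conc^2" = -0.01)), 100)
})
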