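# Published coefficients used by the fixed-model tests (loaded as data, not
# fit): CD3G and NCAM1 expression plus three pathway activation components.
fixed_coefs <- c(cd3g = -1.79, ncam1 = -2.33, adrenergic_pal = 1.22,
                 endothelin_pal = -3.95, gh_pathway_pal = -7.18)

fixed_model <- function() {
  signature_model(components = names(fixed_coefs),
                  scaler = data.frame(id = names(fixed_coefs),
                                      min = 0, max = 1),
                  coefficients = unname(fixed_coefs),
                  risk_threshold = 0, orientation = "lower_is_risk")
}

test_that("min-max scaling and stored-scaler reuse", {
  m <- rbind(a = c(0, 5, 10), b = c(2, 4, 8))
  colnames(m) <- paste0("s", 1:3)
  sc <- minmax_scale(m)
  expect_equal(unname(sc$scaled["a", ]), c(0, 0.5, 1))
  expect_true(all(sc$scaled >= 0 & sc$scaled <= 1))
  # idempotent on the training matrix
  expect_equal(apply_scaler(m, sc$scaler), sc$scaled)
  # extrapolation warns, clipping clamps
  new <- rbind(a = c(-5, 20), b = c(3, 3))
  colnames(new) <- c("x1", "x2")
  expect_warning(out <- apply_scaler(new, sc$scaler), "outside")
  expect_equal(unname(out["a", ]), c(-0.5, 2))
  expect_equal(unname(apply_scaler(new, sc$scaler, clip = TRUE)["a", ]),
               c(0, 1))
  expect_error(minmax_scale(rbind(const = c(1, 1, 1))), "const")
})

test_that("ridge logistic matches the grid-search likelihood oracle", {
  set.seed(61)
  for (rep in 1:5) {
    n <- 80
    x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "f"))
    y <- runif(n) < plogis(0.4 + 1.2 * x[, 1])
    if (length(unique(y)) < 2) next
    ridge <- 1e-4
    fit <- fit_logistic(x, y, ridge = ridge)
    want <- oracle_logistic_grid(x[, 1], as.numeric(y), ridge)
    expect_equal(fit$intercept, want[1], tolerance = 1e-3)
    expect_equal(unname(fit$coefficients), want[2], tolerance = 1e-3)
    # label flip negates everything
    flip <- fit_logistic(x, !y, ridge = ridge)
    expect_equal(flip$intercept, -fit$intercept, tolerance = 1e-6)
    expect_equal(unname(flip$coefficients), -unname(fit$coefficients),
                 tolerance = 1e-6)
  }
})

test_that("logistic null coefficients shrink to zero and errors are raised", {
  set.seed(62)
  x <- matrix(rnorm(400), ncol = 2)
  y <- rbinom(200, 1, 0.4) # independent of x
  fit <- fit_logistic(x, y)
  expect_true(all(abs(fit$coefficients) < 0.3))
  expect_error(fit_logistic(x, rep(1, 200)), "both")
})

test_that("risk score reproduces loaded coefficients exactly", {
  model <- fixed_model()
  # component unit vectors return the printed coefficients
  for (comp in model$components) {
    v <- setNames(numeric(5), model$components)
    v[comp] <- 1
    expect_equal(unname(risk_score(v, model)), unname(fixed_coefs[comp]))
  }
  ones <- setNames(rep(1, 5), model$components)
  expect_equal(unname(risk_score(ones, model)), -14.03, tolerance = 1e-12)
  expect_equal(unname(risk_score(setNames(numeric(5), model$components),
                                 model)), 0)
  # affine in each component; hand-made difference to 1e-12
  v1 <- setNames(c(0.2, 0.4, 0.1, 0.9, 0.5), model$components)
  v2 <- setNames(c(0.7, 0.4, 0.1, 0.9, 0.5), model$components)
  expect_equal(unname(risk_score(v2, model) - risk_score(v1, model)),
               0.5 * fixed_coefs[["cd3g"]], tolerance = 1e-12)
  expect_error(risk_score(c(cd3g = 1), model), "missing")
})

test_that("signature JSON round-trip preserves the model", {
  model <- fixed_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_signature_json(model, path)
  back <- read_signature_json(path)
  expect_equal(back$coefficients, model$coefficients)
  expect_equal(back$scaler, model$scaler)
  expect_identical(back$orientation, model$orientation)
  expect_equal(back$risk_threshold, model$risk_threshold)
})

sim_sig_cohort <- function(n, seed, n_noise = 3, effect = -1, or_effect = 1.5,
                           n_info = 5) {
  # latent informative markers drive both hazard and response; noise rows
  # are independent
  set.seed(seed)
  z <- matrix(rnorm(n_info * n), n_info)
  noise <- matrix(rnorm(n_noise * n), n_noise)
  loghaz <- log(log(2) / 6) + colSums(z * effect / sqrt(n_info))
  t_ev <- rexp(n, exp(loghaz))
  cens <- runif(n, 0, 24)
  a <- uniroot(function(a) mean(plogis(a + colSums(z * or_effect / sqrt(n_info)))) - 0.25,
               c(-20, 20))$root
  resp <- runif(n) < plogis(a + colSums(z * or_effect / sqrt(n_info)))
  markers <- rbind(z, noise)
  rownames(markers) <- c(paste0("info", seq_len(n_info)),
                         paste0("noise", seq_len(n_noise)))
  colnames(markers) <- sprintf("S%03d", seq_len(n))
  clinical <- make_clinical(n, pmin(t_ev, cens), as.integer(t_ev <= cens),
                            ifelse(resp, "PR", "PD"))
  list(markers = markers, clinical = clinical)
}

test_that("backward elimination terminates, is bounded, and is deterministic", {
  d <- sim_sig_cohort(80, seed = 63)
  res <- backward_eliminate(d$markers, d$clinical)
  expect_s3_class(res$model, "signature_model")
  expect_true(nrow(res$trace) <= nrow(d$markers) - 1)
  expect_true(length(res$model$components) >= 1)
  # accepted removals are a prefix of the trace and improve the objective
  if (nrow(res$trace) > 1) {
    acc <- res$trace$accepted
    expect_true(all(diff(as.integer(acc)) <= 0))
  }
  res2 <- backward_eliminate(d$markers, d$clinical)
  expect_identical(res2$trace, res$trace)
  expect_equal(res2$model$coefficients, res$model$coefficients)
})

test_that("elimination stops immediately when both markers are needed", {
  set.seed(64)
  n <- 60
  z1 <- rnorm(n); z2 <- rnorm(n)
  t_ev <- rexp(n, exp(log(0.1) - 1.2 * z1 - 1.2 * z2))
  cens <- runif(n, 0, 40)
  resp <- runif(n) < plogis(-1 + 1.5 * z1 + 1.5 * z2)
  m <- rbind(m1 = z1, m2 = z2)
  colnames(m) <- sprintf("S%03d", 1:n)
  cl <- make_clinical(n, pmin(t_ev, cens), as.integer(t_ev <= cens),
                      ifelse(resp, "PR", "PD"))
  res <- backward_eliminate(m, cl)
  if (length(res$model$components) == 2)
    expect_false(any(res$trace$accepted))
})

test_that("evaluating on the training cohort reproduces the training fit", {
  d <- sim_sig_cohort(70, seed = 65)
  res <- backward_eliminate(d$markers, d$clinical)
  ev <- evaluate_signature(res$model, d$markers, d$clinical)
  expect_equal(ev$hr, res$training$hr, tolerance = 1e-10)
  expect_true(ev$auc >= 0 && ev$auc <= 1)
  # cohort of one sample: scores only
  expect_message(
    one <- evaluate_signature(res$model, d$markers[, 1, drop = FALSE],
                              d$clinical[1, , drop = FALSE]),
    "refused")
  expect_length(one$scores, 1)
  expect_true(is.na(one$auc))
  # missing PFS -> AUC-only report
  cl2 <- d$clinical
  cl2$pfs_months <- NA_real_; cl2$event <- NA_integer_
  expect_message(ev2 <- evaluate_signature(res$model, d$markers, cl2),
                 "AUC-only")
  expect_false(is.na(ev2$auc))
  expect_true(is.na(ev2$hr))
})
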