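# Multi-component risk-score signature: min-max scaling, ridge-penalized
# logistic coefficients, backward elimination against threshold-optimized
# hazard ratios, and evaluation on new cohorts.

#' Min-max scaling of a biomarker matrix
#'
#' Each biomarker (row) is rescaled to \[0, 1\] by (x - min) / (max - min) so
#' every component contributes on a common scale. The per-row (min, max)
#' pairs are returned for reuse on new cohorts.
#'
#' @param m numeric matrix, biomarkers x samples, rownames required.
#' @return list with `scaled` (matrix) and `scaler` (data.frame `id`, `min`,
#'   `max`).
#' @export
minmax_scale <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  rng <- t(apply(m, 1, range, na.rm = TRUE))
  const <- rng[, 1] == rng[, 2]
  if (any(const))
    stop("constant biomarker(s) cannot be min-max scaled: ",
         paste(rownames(m)[const], collapse = ", "))
  scaled <- (m - rng[, 1]) / (rng[, 2] - rng[, 1])
  list(scaled = scaled,
       scaler = data.frame(id = rownames(m), min = rng[, 1], max = rng[, 2],
                           row.names = NULL, stringsAsFactors = FALSE))
}

#' Apply a stored min-max scaler to a new cohort
#'
#' Values outside the training range yield scaled values outside \[0, 1\];
#' they are passed through with a warning by default, or clipped when
#' `clip = TRUE`.
#'
#' @param m numeric matrix, biomarkers x samples.
#' @param scaler data.frame from [minmax_scale()].
#' @param clip clip to \[0, 1\] instead of extrapolating.
#' @return scaled matrix.
#' @export
apply_scaler <- function(m, scaler, clip = FALSE) {
  idx <- match(rownames(m), scaler$id)
  if (any(is.na(idx)))
    stop("no stored scaler for: ",
         paste(rownames(m)[is.na(idx)], collapse = ", "))
  scaled <- (m - scaler$min[idx]) / (scaler$max[idx] - scaler$min[idx])
  out_of_range <- scaled < 0 | scaled > 1
  if (any(out_of_range, na.rm = TRUE)) {
    if (clip) {
      scaled[scaled < 0] <- 0
      scaled[scaled > 1] <- 1
    } else {
      warning(sum(out_of_range, na.rm = TRUE),
              " scaled value(s) outside [0, 1] (beyond training range), passed through")
    }
  }
  scaled
}

#' Ridge-penalized logistic regression by IRLS
#'
#' Maximum penalized likelihood with an L2 penalty on the slopes (intercept
#' unpenalized). The small default ridge guards against complete separation
#' on small cohorts without materially shrinking identifiable coefficients.
#'
#' @param x numeric matrix, samples x features.
#' @param y logical (or 0/1) outcome; responder is coded 1.
#' @param ridge penalty on squared slope norm (default 1e-4).
#' @param max_iter,tol Newton iteration controls.
#' @return list with `intercept`, `coefficients` (named), `converged`,
#'   `iterations`.
#' @export
fit_logistic <- function(x, y, ridge = 1e-4, max_iter = 100, tol = 1e-10) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  X <- cbind(1, x)
  p <- ncol(X)
  pen <- diag(c(0, rep(ridge, p - 1L)), p)
  beta <- numeric(p)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(drop(X %*% beta))
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- crossprod(X, y - mu) - pen %*% beta
    H <- crossprod(X, X * w) + pen
    step <- solve(H, grad)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("x", seq_len(p - 1L))
  list(intercept = unname(beta[1]),
       coefficients = stats::setNames(unname(beta[-1]), nm),
       converged = converged, iterations = it)
}

#' Construct a signature model
#'
#' @param components ordered biomarker ids.
#' @param scaler data.frame (`id`, `min`, `max`) covering every component.
#' @param coefficients per-component logistic regression coefficients.
#' @param intercept stored for reference; excluded from the score.
#' @param risk_threshold threshold on the score separating the two survival
#'   groups.
#' @param orientation `"higher_is_risk"` or `"lower_is_risk"`; recorded from
#'   the training fit, never assumed.
#' @return object of class `signature_model`.
#' @export
signature_model <- function(components, scaler, coefficients,
                            intercept = 0,
                            risk_threshold = NA_real_,
                            orientation = c("lower_is_risk", "higher_is_risk")) {
  orientation <- match.arg(orientation)
  stopifnot(length(components) == length(coefficients),
            all(components %in% scaler$id))
  scaler <- scaler[match(components, scaler$id), , drop = FALSE]
  if (any(scaler$min >= scaler$max)) stop("scaler must have min < max")
  structure(list(components = components,
                 scaler = scaler,
                 coefficients = stats::setNames(as.numeric(coefficients),
                                                components),
                 intercept = intercept,
                 risk_threshold = risk_threshold,
                 orientation = orientation),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %d components, threshold %.4g (%s)\n",
              length(x$components), x$risk_threshold, x$orientation))
  print(data.frame(component = x$components,
                   coefficient = unname(x$coefficients)))
  invisible(x)
}

#' Signature risk score
#'
#' Sum of scaled component values times their coefficients. The intercept is
#' excluded: the score is a ranking statistic and thresholding absorbs any
#' constant shift.
#'
#' @param scaled numeric matrix of scaled values (components x samples) or a
#'   named vector for one sample.
#' @param model a [signature_model()].
#' @return numeric score per sample.
#' @export
risk_score <- function(scaled, model) {
  if (is.null(dim(scaled))) scaled <- matrix(scaled, ncol = 1,
                                             dimnames = list(names(scaled), "s1"))
  missing <- setdiff(model$components, rownames(scaled))
  if (length(missing))
    stop("missing signature component(s): ", paste(missing, collapse = ", "))
  drop(crossprod(scaled[model$components, , drop = FALSE],
                 model$coefficients))
}

#' Backward elimination of signature components
#'
#' Starting from all candidate biomarkers (min-max scaled), the algorithm
#' repeatedly tries removing each remaining component: the reduced set is
#' refit by multivariate ridge logistic regression on responder status, risk
#' scores are computed, the score threshold is re-optimized for PFS under
#' the minimum group-size constraint, and the resulting Cox hazard ratio is
#' recorded. The removal giving the largest improvement in |log HR| is
#' accepted; the loop stops when no removal improves the stratification.
#' Ties break toward the lexicographically smallest removed id.
#'
#' @param candidates numeric matrix, biomarkers x samples (raw scale).
#' @param clinical data.frame with `sample_id`, `recist`, `pfs_months`,
#'   `event`; columns of `candidates` are matched to `sample_id`.
#' @param min_frac minimum group fraction for threshold optimization.
#' @param ridge logistic ridge penalty.
#' @return list with `model` (a [signature_model()]) and `trace`
#'   (data.frame: iteration, removed, hr, p, objective, accepted).
#' @export
backward_eliminate <- function(candidates, clinical, min_frac = 0.3,
                               ridge = 1e-4) {
  stopifnot(is.matrix(candidates), nrow(candidates) >= 2,
            !is.null(rownames(candidates)))
  idx <- match(clinical$sample_id, colnames(candidates))
  if (any(is.na(idx))) stop("clinical samples missing from candidate matrix")
  candidates <- candidates[, idx, drop = FALSE]
  resp <- map_response(clinical$recist) == "responder"
  has_resp <- !is.na(resp)
  if (sum(resp[has_resp]) == 0 || sum(!resp[has_resp]) == 0)
    stop("both response classes are required to fit the logistic model")
  has_pfs <- !is.na(clinical$pfs_months) & !is.na(clinical$event)
  sc <- minmax_scale(candidates)

  evaluate_set <- function(ids) {
    fit <- fit_logistic(t(sc$scaled[ids, has_resp, drop = FALSE]),
                        resp[has_resp], ridge = ridge)
    score <- drop(crossprod(sc$scaled[ids, , drop = FALSE],
                            fit$coefficients))
    opt <- optimize_threshold(score[has_pfs],
                              clinical$pfs_months[has_pfs],
                              clinical$event[has_pfs], min_frac)
    obj <- if (isTRUE(opt$ok)) abs(log(opt$hr)) else -Inf
    list(fit = fit, opt = opt, objective = obj)
  }

  current <- sort(rownames(candidates))
  cur <- evaluate_set(current)
  if (!is.finite(cur$objective))
    stop("no valid risk-score threshold for the full candidate set: ",
         cur$opt$reason)
  trace <- data.frame(iteration = integer(), removed = character(),
                      hr = numeric(), p = numeric(), objective = numeric(),
                      accepted = logical(), stringsAsFactors = FALSE)
  iter <- 0L
  while (length(current) > 1) {
    evals <- lapply(current, function(id)
      evaluate_set(setdiff(current, id)))
    objs <- vapply(evals, function(e) e$objective, numeric(1))
    best_i <- which(objs == max(objs))[1] # `current` sorted: smallest id wins ties
    iter <- iter + 1L
    accepted <- is.finite(objs[best_i]) && objs[best_i] > cur$objective
    trace <- rbind(trace, data.frame(
      iteration = iter, removed = current[best_i],
      hr = evals[[best_i]]$opt$hr, p = evals[[best_i]]$opt$p,
      objective = objs[best_i], accepted = accepted,
      stringsAsFactors = FALSE))
    if (!accepted) break
    current <- setdiff(current, current[best_i])
    cur <- evals[[best_i]]
  }
  model <- signature_model(
    components = current,
    scaler = sc$scaler,
    coefficients = cur$fit$coefficients[current],
    intercept = cur$fit$intercept,
    risk_threshold = cur$opt$threshold,
    orientation = if (isTRUE(cur$opt$ok) && cur$opt$hr > 1)
      "higher_is_risk" else "lower_is_risk")
  list(model = model, trace = trace,
       training = list(hr = cur$opt$hr, p = cur$opt$p,
                       objective = cur$objective))
}

#' Evaluate a signature on a cohort
#'
#' Computes per-sample risk scores, the response ROC AUC (scores oriented so
#' that responders are expected to rank higher, per the training
#' orientation), and - when PFS data are present - the Cox hazard ratio of
#' the training threshold split. The threshold is taken from the model;
#' re-optimizing it on the new cohort is an explicit opt-in.
#'
#' @param model a [signature_model()].
#' @param markers numeric matrix, biomarkers x samples, containing every
#'   model component (raw scale; the stored scaler is applied).
#' @param clinical data.frame with `sample_id`, `recist` and optionally
#'   `pfs_months`, `event`.
#' @param reoptimize re-optimize the score threshold on this cohort.
#' @param min_frac group-size constraint used when `reoptimize = TRUE`.
#' @param clip clip out-of-range scaled values (see [apply_scaler()]).
#' @return list with `scores`, `auc`, `response_p`, `hr`, `hr_p`,
#'   `threshold`, `km` (per-group Kaplan-Meier curves) — survival fields are
#'   `NA` without PFS data; all statistics are `NA` for cohorts of 1 sample.
#' @export
evaluate_signature <- function(model, markers, clinical, reoptimize = FALSE,
                               min_frac = 0.3, clip = FALSE) {
  idx <- match(clinical$sample_id, colnames(markers))
  if (any(is.na(idx))) stop("clinical samples missing from marker matrix")
  markers <- markers[, idx, drop = FALSE]
  scaled <- apply_scaler(markers[model$components, , drop = FALSE],
                         model$scaler, clip = clip)
  scores <- risk_score(scaled, model)
  out <- list(scores = stats::setNames(scores, clinical$sample_id),
              auc = NA_real_, response_p = NA_real_, hr = NA_real_,
              hr_p = NA_real_, threshold = model$risk_threshold, km = NULL)
  if (length(scores) < 2) {
    message("cohort of ", length(scores), " sample(s): statistics refused")
    return(out)
  }
  oriented <- if (model$orientation == "higher_is_risk") -scores else scores
  resp <- map_response(clinical$recist) == "responder"
  ok <- !is.na(resp)
  if (any(resp[ok]) && any(!resp[ok])) {
    out$auc <- roc_auc(oriented[ok], resp[ok])
    out$response_p <- mann_whitney(oriented[ok], resp[ok])
  }
  has_pfs <- !is.null(clinical$pfs_months) &&
    any(!is.na(clinical$pfs_months) & !is.na(clinical$event))
  if (!has_pfs) {
    message("no PFS data: AUC-only report")
    return(out)
  }
  keep <- !is.na(clinical$pfs_months) & !is.na(clinical$event)
  t <- clinical$pfs_months[keep]; e <- clinical$event[keep]
  s <- scores[keep]
  if (reoptimize) {
    opt <- optimize_threshold(s, t, e, min_frac)
    if (isTRUE(opt$ok)) {
      out$threshold <- opt$threshold; out$hr <- opt$hr; out$hr_p <- opt$p
    }
  } else if (!is.na(model$risk_threshold)) {
    high <- s > model$risk_threshold
    if (length(unique(high)) == 2 && sum(e) >= 1) {
      res <- cox_binary(t, e, high)
      out$hr <- exp(res[1]); out$hr_p <- res[2]
    }
  }
  if (!is.na(out$threshold)) {
    high <- s > out$threshold
    if (any(high) && any(!high))
      out$km <- list(high = km_curve(t[high], e[high]),
                     low = km_curve(t[!high], e[!high]))
  }
  out
}

#' Read / write a signature model as JSON
#'
#' @param model a [signature_model()].
#' @param path file path.
#' @return `read_signature_json` returns the model; the writer returns
#'   `path` invisibly.
#' @export
write_signature_json <- function(model, path) {
  obj <- list(components = model$components,
              scaler = model$scaler,
              coefficients = unname(model$coefficients),
              intercept = model$intercept,
              risk_threshold = model$risk_threshold,
              orientation = model$orientation)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature_json
#' @export
read_signature_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  signature_model(components = o$components,
                  scaler = as.data.frame(o$scaler),
                  coefficients = o$coefficients,
                  intercept = o$intercept,
                  risk_threshold = if (is.null(o$risk_threshold)) NA_real_
                                   else o$risk_threshold,
                  orientation = o$orientation)
}
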