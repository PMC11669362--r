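# Biomarker screening: RECIST response statistics (AUC, Mann-Whitney,
# Fisher), threshold-optimized Cox stratification for PFS, selection filters
# and their intersection.

#' Map RECIST categories to binary response
#'
#' CR, PR and MPR (major pathological response, used by validation cohorts)
#' map to responder; SD, PD and non-MPR to non-responder; missing stays
#' missing.
#'
#' @param recist character vector of labels.
#' @return character vector in \{"responder", "non_responder", NA\}.
#' @export
map_response <- function(recist) {
  accepted <- c(CR = "responder", PR = "responder", MPR = "responder",
                SD = "non_responder", PD = "non_responder",
                `non-MPR` = "non_responder")
  out <- rep(NA_character_, length(recist))
  present <- !is.na(recist) & recist != ""
  bad <- setdiff(unique(recist[present]), names(accepted))
  if (length(bad))
    stop("unknown RECIST label(s): ", paste(bad, collapse = ", "),
         "; accepted: ", paste(names(accepted), collapse = ", "))
  out[present] <- accepted[recist[present]]
  out
}

#' ROC AUC by the rank (Mann-Whitney) formulation
#'
#' AUC is the probability that a responder's value exceeds a non-responder's,
#' with ties counted 1/2 (midranks).
#'
#' @param values numeric marker values.
#' @param labels logical (or 0/1) responder flags, same length.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(values, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty")
  r <- rank(values) # midranks for ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-sided Mann-Whitney U test between responders and non-responders
#'
#' @inheritParams roc_auc
#' @return two-sided p-value.
#' @export
mann_whitney <- function(values, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  if (sum(labels) == 0 || sum(!labels) == 0)
    stop("both groups must be non-empty")
  suppressWarnings(
    stats::wilcox.test(values[labels], values[!labels])$p.value)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' @param a,b,c,d cell counts (rows: feature present/absent; columns:
#'   responder/non-responder).
#' @return two-sided p-value; a degenerate table (zero margin) returns 1 with
#'   a warning.
#' @export
fisher_exact <- function(a, b, c, d) {
  tab <- matrix(c(a, c, b, d), 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (zero margin); p = 1")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Cox proportional-hazards fit (Efron ties)
#'
#' Wrapper around a maximum partial-likelihood fit returning per-covariate
#' hazard ratios and Wald p-values, with monotone-likelihood /
#' non-convergence flagged rather than silently reported.
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @param covariates numeric matrix (samples x covariates) or vector.
#' @return data.frame with columns `term`, `coef`, `hr`, `se`, `p`, `flagged`.
#' @export
cox_fit <- function(times, events, covariates) {
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (sum(events) < 1) stop("at least one event is required")
  if (any(apply(x, 2, function(v) length(unique(v))) < 2))
    stop("constant covariate")
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ x, ties = "efron"),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  coefs <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(coefs)) || any(abs(coefs) > 15)) flagged <- TRUE
  data.frame(term = colnames(x), coef = unname(coefs),
             hr = exp(unname(coefs)), se = unname(se),
             p = 2 * stats::pnorm(-abs(unname(coefs) / unname(se))),
             flagged = flagged, row.names = NULL)
}

# Fast single-binary-covariate Cox fit used inside the threshold scan.
# Returns c(coef, p); NA when the fit is degenerate.
cox_binary <- function(times, events, high) {
  x <- matrix(as.numeric(high), ncol = 1)
  fit <- tryCatch(
    suppressWarnings(survival::coxph.fit(
      x, survival::Surv(times, events), strata = NULL, offset = NULL,
      init = 0, control = survival::coxph.control(),
      weights = NULL, method = "efron", rownames = NULL, resid = FALSE)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$coefficients) ||
      !is.finite(fit$var) || fit$var <= 0)
    return(c(NA_real_, NA_real_))
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var))
  c(beta, 2 * stats::pnorm(-abs(beta / se)))
}

#' Threshold-optimized dichotomization for survival
#'
#' Numeric markers are translated to categorical by the cutoff that maximizes
#' the absolute log hazard ratio of the resulting two-group Cox model,
#' subject to each group holding at least `min_frac` of the sample
#' (`ceil(min_frac * n)`). Candidate thresholds are midpoints between
#' consecutive sorted distinct values; samples are dichotomized as value >
#' threshold (high) vs <= threshold (low). Ties in |log HR| break toward the
#' smallest threshold.
#'
#' @param values numeric marker.
#' @param times,events survival data aligned with `values`.
#' @param min_frac minimum group fraction (default 0.3).
#' @return list with `threshold`, `hr`, `p`, `n_low`, `n_high`, `ok`
#'   (`FALSE`, with `reason`, when no valid split exists).
#' @export
optimize_threshold <- function(values, times, events, min_frac = 0.3) {
  ok <- !is.na(values) & !is.na(times) & !is.na(events)
  values <- values[ok]; times <- times[ok]; events <- events[ok]
  n <- length(values)
  min_n <- ceiling(min_frac * n)
  u <- sort(unique(values))
  if (length(u) < 2)
    return(list(threshold = NA_real_, hr = NA_real_, p = NA_real_,
                n_low = NA_integer_, n_high = NA_integer_, ok = FALSE,
                reason = "marker has fewer than 2 distinct values"))
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- NULL
  for (th in cand) {
    high <- values > th
    n_high <- sum(high); n_low <- n - n_high
    if (n_high < min_n || n_low < min_n) next
    res <- cox_binary(times, events, high)
    if (!is.finite(res[1])) next
    if (is.null(best) || abs(res[1]) > best$obj + 1e-12) {
      best <- list(obj = abs(res[1]), threshold = th, coef = res[1],
                   p = res[2], n_low = n_low, n_high = n_high)
    }
  }
  if (is.null(best))
    return(list(threshold = NA_real_, hr = NA_real_, p = NA_real_,
                n_low = NA_integer_, n_high = NA_integer_, ok = FALSE,
                reason = "no split satisfies the minimum group-size constraint"))
  list(threshold = best$threshold, hr = exp(best$coef), p = best$p,
       n_low = best$n_low, n_high = best$n_high, ok = TRUE, reason = NA_character_)
}

#' Kaplan-Meier curve and median survival
#'
#' @param times,events survival data.
#' @return list with `time`, `surv` (product-limit step function evaluated at
#'   the observed event/censoring times) and `median` (smallest time with
#'   survival <= 0.5, `NA` when the curve never reaches 0.5).
#' @export
km_curve <- function(times, events) {
  if (length(times) < 1) stop("at least one subject required")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  # median by the "smallest time with S(t) <= 0.5" convention (no averaging
  # when the curve hits 0.5 exactly)
  hit <- fit$surv <= 0.5
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       median = if (any(hit)) min(fit$time[hit]) else NA_real_)
}

#' Screen biomarkers against response and survival
#'
#' For every row of `markers`: ROC AUC and a response test (Mann-Whitney for
#' numeric markers, Fisher exact for binary ones) against responder status,
#' and a Cox hazard ratio against PFS (threshold-optimized dichotomization
#' for numeric markers, direct coding for binary ones). Samples missing
#' RECIST are excluded from response statistics only; samples missing PFS
#' from survival statistics only. Raw p-values drive selection (matching the
#' reference procedure); Benjamini-Hochberg columns are reported for
#' transparency but never used to select.
#'
#' @param markers numeric matrix, biomarkers x samples (binary rows allowed).
#' @param clinical data.frame with columns `sample_id`, `recist`,
#'   `pfs_months`, `event` (see [simulate_cohort()] for the full schema).
#' @param kind `"numeric"` or `"categorical"`, recycled over rows; binary
#'   rows are auto-detected when `NULL`.
#' @param min_frac minimum group fraction for threshold optimization.
#' @param hr_low,hr_high,alpha,auc_cutoff selection filter settings.
#' @return data.frame, one row per biomarker, with screening statistics and
#'   logical columns `selected_pfs`, `selected_response`, `selected_both`.
#' @export
screen_biomarkers <- function(markers, clinical, kind = NULL, min_frac = 0.3,
                              hr_low = 0.4, hr_high = 2.5, alpha = 0.05,
                              auc_cutoff = 0.62) {
  stopifnot(is.matrix(markers), !is.null(rownames(markers)))
  idx <- match(clinical$sample_id, colnames(markers))
  if (any(is.na(idx)))
    stop("clinical samples missing from marker matrix: ",
         paste(utils::head(clinical$sample_id[is.na(idx)], 5), collapse = ", "))
  markers <- markers[, idx, drop = FALSE]
  resp <- map_response(clinical$recist)
  is_resp <- resp == "responder"
  has_resp <- !is.na(is_resp)
  has_pfs <- !is.na(clinical$pfs_months) & !is.na(clinical$event)
  if (is.null(kind)) {
    kind <- ifelse(apply(markers, 1, function(v)
      all(v %in% c(0, 1), na.rm = TRUE)), "categorical", "numeric")
  } else kind <- rep(kind, length.out = nrow(markers))

  rows <- lapply(seq_len(nrow(markers)), function(i) {
    v <- markers[i, ]
    out <- list(id = rownames(markers)[i], kind = kind[i],
                hr = NA_real_, hr_p = NA_real_, threshold = NA_real_,
                n_low = NA_integer_, n_high = NA_integer_,
                auc = NA_real_, response_p = NA_real_)
    # response statistics
    vr <- v[has_resp]; lr <- is_resp[has_resp]
    if (sum(lr, na.rm = TRUE) > 0 && sum(!lr, na.rm = TRUE) > 0) {
      out$auc <- roc_auc(vr, lr)
      out$response_p <- if (kind[i] == "categorical")
        fisher_exact(sum(vr == 1 & lr), sum(vr == 1 & !lr),
                     sum(vr == 0 & lr), sum(vr == 0 & !lr))
      else mann_whitney(vr, lr)
    }
    # survival statistics
    vs <- v[has_pfs]; ts <- clinical$pfs_months[has_pfs]
    es <- clinical$event[has_pfs]
    if (sum(es, na.rm = TRUE) >= 1 && length(unique(vs)) >= 2) {
      if (kind[i] == "categorical") {
        res <- cox_binary(ts, es, vs == 1)
        out$hr <- exp(res[1]); out$hr_p <- res[2]
        out$n_low <- sum(vs == 0); out$n_high <- sum(vs == 1)
      } else {
        opt <- optimize_threshold(vs, ts, es, min_frac)
        out$hr <- opt$hr; out$hr_p <- opt$p; out$threshold <- opt$threshold
        out$n_low <- opt$n_low; out$n_high <- opt$n_high
      }
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$hr_p_bh <- stats::p.adjust(res$hr_p, method = "BH")
  res$response_p_bh <- stats::p.adjust(res$response_p, method = "BH")
  res$selected_pfs <- res$id %in% select_pfs_biomarkers(res, hr_low, hr_high, alpha)
  res$selected_response <- res$id %in%
    select_response_biomarkers(res, auc_cutoff, alpha)
  res$selected_both <- res$selected_pfs & res$selected_response
  res
}

#' Selection filters and intersection
#'
#' PFS filter: hazard ratio above `hr_high` or below `hr_low` with Cox
#' p-value below `alpha`. Response filter: response-test p-value below
#' `alpha` with AUC above `auc_cutoff`. The intersection keeps ids present in
#' both lists, in the order of the first.
#'
#' @param results data.frame from [screen_biomarkers()] (needs columns `id`,
#'   `hr`, `hr_p` / `auc`, `response_p`).
#' @param hr_low,hr_high,alpha,auc_cutoff filter settings; defaults follow
#'   the reference procedure (0.4, 2.5, 0.05, 0.62).
#' @return character vector of selected biomarker ids.
#' @export
select_pfs_biomarkers <- function(results, hr_low = 0.4, hr_high = 2.5,
                                  alpha = 0.05) {
  keep <- !is.na(results$hr) & !is.na(results$hr_p) &
    (results$hr > hr_high | results$hr < hr_low) & results$hr_p < alpha
  results$id[keep]
}

#' @rdname select_pfs_biomarkers
#' @export
select_response_biomarkers <- function(results, auc_cutoff = 0.62,
                                       alpha = 0.05) {
  keep <- !is.na(results$auc) & !is.na(results$response_p) &
    results$response_p < alpha & results$auc > auc_cutoff
  results$id[keep]
}

#' @rdname select_pfs_biomarkers
#' @param pfs_ids,response_ids id vectors from the two filters.
#' @export
intersect_biomarkers <- function(pfs_ids, response_ids) {
  pfs_ids[pfs_ids %in% response_ids]
}
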