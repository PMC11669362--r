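# Independent oracles used across the suite. These re-derive the statistics
# from first principles (enumeration, brute force, closed form) and never
# call the implementation paths they check.

# Efron-tie Cox partial log-likelihood for a single covariate, written from
# the definition: per unique event time with d tied events, the denominator
# at position l subtracts l/d of the tied events' risk contributions.
oracle_efron_loglik <- function(beta, times, events, x) {
  eta <- beta * x
  ll <- 0
  for (tt in sort(unique(times[events == 1]))) {
    D <- which(events == 1 & times == tt)
    R <- which(times >= tt)
    d <- length(D)
    sumD <- sum(exp(eta[D]))
    sumR <- sum(exp(eta[R]))
    ll <- ll + sum(eta[D]) -
      sum(vapply(seq_len(d) - 1, function(l) log(sumR - (l / d) * sumD),
                 numeric(1)))
  }
  ll
}

# Grid-search maximizer of the Efron partial likelihood: coarse grid then a
# fine refinement to step 1e-5.
oracle_cox_grid <- function(times, events, x,
                            lo = -5, hi = 5) {
  coarse <- seq(lo, hi, by = 0.01)
  ll <- vapply(coarse, oracle_efron_loglik, numeric(1),
               times = times, events = events, x = x)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  llf <- vapply(fine, oracle_efron_loglik, numeric(1),
                times = times, events = events, x = x)
  fine[which.max(llf)]
}

# AUC by explicit pairwise-win enumeration with half-credit ties.
oracle_auc_pairs <- function(values, labels) {
  labels <- as.logical(labels)
  vr <- values[labels]; vn <- values[!labels]
  wins <- 0
  for (a in vr) for (b in vn)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(vr) * length(vn))
}

# Exhaustive threshold scan with the minimum-group-size constraint, using
# survival::coxph (formula interface) per candidate; ties in |log HR| break
# toward the smallest threshold, matching the documented rule.
oracle_threshold_scan <- function(values, times, events, min_frac = 0.3) {
  n <- length(values)
  min_n <- ceiling(min_frac * n)
  u <- sort(unique(values))
  if (length(u) < 2) return(NULL)
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- NULL
  for (th in cand) {
    high <- values > th
    if (sum(high) < min_n || sum(!high) < min_n) next
    fit <- tryCatch(
      suppressWarnings(survival::coxph(
        survival::Surv(times, events) ~ high, ties = "efron")),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(coef(fit))) next
    obj <- abs(unname(coef(fit)))
    if (is.null(best) || obj > best$obj + 1e-12)
      best <- list(obj = obj, threshold = th, hr = exp(unname(coef(fit))))
  }
  best
}

# Breadth-first enumeration of nodes within `radius` hops of `center`,
# ignoring edge direction, on an explicit adjacency list.
oracle_bfs_members <- function(edges, center, radius) {
  adj <- list()
  add <- function(a, b) adj[[a]] <<- union(adj[[a]], b)
  for (k in seq_len(nrow(edges))) {
    add(edges$source[k], edges$target[k])
    add(edges$target[k], edges$source[k])
  }
  frontier <- center
  seen <- center
  for (r in seq_len(radius)) {
    nxt <- unique(unlist(adj[frontier]))
    frontier <- setdiff(nxt, seen)
    seen <- union(seen, frontier)
    if (length(frontier) == 0) break
  }
  sort(seen)
}

# Ridge-penalized logistic log-likelihood for one feature, maximized on an
# (intercept, slope) grid with refinement.
oracle_logistic_grid <- function(x, y, ridge) {
  ll <- function(a, b) {
    eta <- a + b * x
    sum(y * eta - log1p(exp(eta))) - ridge / 2 * b^2
  }
  grid_step <- function(ac, bc, width, step) {
    as <- seq(ac - width, ac + width, by = step)
    bs <- seq(bc - width, bc + width, by = step)
    vals <- outer(as, bs, Vectorize(ll))
    i <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    c(as[i[1]], bs[i[2]])
  }
  p <- grid_step(0, 0, 6, 0.05)
  p <- grid_step(p[1], p[2], 0.1, 1e-3)
  grid_step(p[1], p[2], 2e-3, 5e-5)
}

# Small aligned clinical table used by screening/signature unit tests.
make_clinical <- function(n, times, events, recist,
                          histotype = "adenocarcinoma") {
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             histotype = histotype,
             recist = recist,
             pfs_months = times,
             event = events,
             anti_pd1 = 1L, anti_pdl1 = 0L, anti_ctla4 = 0L,
             stringsAsFactors = FALSE)
}
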