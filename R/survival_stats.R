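# Survival machinery written from the explicit formulas: Kaplan-Meier
# product-limit estimator, two-group log-rank test with the Mantel-Haenszel
# hazard ratio, and Cox proportional-hazards regression (Efron ties,
# Newton-Raphson).

#' Kaplan-Meier product-limit estimate
#'
#' S(t) = prod over distinct event times t_k <= t of (1 - d_k / n_k).
#' Samples censored at an event time are counted at risk through that event
#' (events precede censorings at ties). The median survival is the smallest
#' event time with S(t) <= 0.5, `NA` if the curve never reaches 0.5.
#'
#' @param times non-negative follow-up times.
#' @param events 0/1, 1 = death observed.
#' @return list of class `km_curve`: `event_times`, `surv`, `n_at_risk`,
#'   `n_events`, `median_survival`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input")
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  tk <- sort(unique(times[events == 1]))
  if (length(tk) == 0L) {
    return(structure(list(event_times = numeric(0), surv = numeric(0),
                          n_at_risk = integer(0), n_events = integer(0),
                          median_survival = NA_real_), class = "km_curve"))
  }
  n_at_risk <- vapply(tk, function(t) sum(times >= t), numeric(1))
  n_events <- vapply(tk, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_events / n_at_risk)
  med <- if (any(surv <= 0.5)) tk[which(surv <= 0.5)[1]] else NA_real_
  structure(list(event_times = tk, surv = surv, n_at_risk = n_at_risk,
                 n_events = n_events, median_survival = med),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> ", length(x$event_times), " event times, median survival ",
      x$median_survival, "\n", sep = "")
  invisible(x)
}

#' Two-group log-rank test with Mantel-Haenszel hazard ratio
#'
#' At each distinct event time with d_k total events, n_k at risk and n1_k at
#' risk in group 1: expected events in group 1 e1_k = n1_k d_k / n_k and
#' hypergeometric variance
#' v_k = d_k (n1_k/n_k)(1 - n1_k/n_k)(n_k - d_k)/(n_k - 1)
#' (skipped when n_k = 1). The statistic is chi2 = (O1 - E1)^2 / V on 1 df,
#' and HR = (O1/E1)/(O2/E2) estimates the hazard of group 1 relative to
#' group 2.
#'
#' @param times1,events1 follow-up and status for group 1.
#' @param times2,events2 follow-up and status for group 2.
#' @return list of class `logrank_result`: `chi2`, `p`, `hr`, `o1`, `e1`,
#'   `o2`, `e2`, `v`.
#' @export
logrank_test <- function(times1, events1, times2, events2) {
  stopifnot(length(times1) == length(events1),
            length(times2) == length(events2),
            length(times1) >= 1L, length(times2) >= 1L)
  times <- c(times1, times2)
  events <- c(events1, events2)
  g1 <- rep(c(TRUE, FALSE), c(length(times1), length(times2)))
  if (sum(events) == 0) stop("log-rank test needs at least one event")
  tk <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (t in tk) {
    at <- times >= t
    nk <- sum(at)
    n1k <- sum(at & g1)
    dk <- sum(times == t & events == 1)
    d1k <- sum(times == t & events == 1 & g1)
    o1 <- o1 + d1k
    e1 <- e1 + n1k * dk / nk
    if (nk > 1)
      v <- v + dk * (n1k / nk) * (1 - n1k / nk) * (nk - dk) / (nk - 1)
  }
  o2 <- sum(events) - o1
  e2 <- sum(events) - e1
  chi2 <- if (v > 0) (o1 - e1)^2 / v else 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  hr <- if (e1 > 0 && e2 > 0 && o2 > 0) (o1 / e1) / (o2 / e2) else NA_real_
  structure(list(chi2 = chi2, p = p, hr = hr, o1 = o1, e1 = e1, o2 = o2,
                 e2 = e2, v = v), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank> chi2 = %.4f, p = %.4g, MH HR = %.4f\n",
              x$chi2, x$p, x$hr))
  invisible(x)
}

# Efron-corrected partial log-likelihood, score and information for the Cox
# model. x: n-by-p covariate matrix; beta: length-p.
.cox_loglik <- function(beta, times, events, x) {
  n <- length(times)
  p <- ncol(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ll <- 0
  score <- numeric(p)
  info <- matrix(0, p, p)
  for (t in sort(unique(times[events == 1]))) {
    risk <- times >= t
    dead <- times == t & events == 1
    d <- sum(dead)
    sw_r <- sum(w[risk])                      # sum of weights in risk set
    sx_r <- colSums(x[risk, , drop = FALSE] * w[risk])
    sxx_r <- crossprod(x[risk, , drop = FALSE] * sqrt(w[risk]))
    sw_d <- sum(w[dead])
    sx_d <- colSums(x[dead, , drop = FALSE] * w[dead])
    sxx_d <- crossprod(x[dead, , drop = FALSE] * sqrt(w[dead]))
    ll <- ll + sum(eta[dead])
    sum_xd <- colSums(x[dead, , drop = FALSE])
    score <- score + sum_xd
    for (l in seq_len(d) - 1) {
      f <- l / d
      denom <- sw_r - f * sw_d
      num <- sx_r - f * sx_d
      num2 <- sxx_r - f * sxx_d
      ll <- ll - log(denom)
      score <- score - num / denom
      info <- info + num2 / denom - tcrossprod(num / denom)
    }
  }
  list(ll = ll, score = score, info = info)
}

#' Cox proportional-hazards regression
#'
#' Maximizes the partial likelihood with the Efron correction for tied event
#' times by Newton-Raphson; converged when the largest score component is
#' below `tol` (default 1e-8) or after `max_iter` iterations. Standard errors
#' come from the inverse observed information; Wald p-values are two-sided.
#' A monotone likelihood (perfect separation: coefficients diverging) is
#' flagged via `converged = FALSE` with a diagnostic message.
#'
#' @param times,events follow-up times and 0/1 status.
#' @param covariates numeric matrix or data.frame (columns = covariates;
#'   categories must be pre-coded 0/1). Constant columns are an error.
#' @param tol,max_iter Newton-Raphson controls.
#' @return list of class `cox_result`: data.frame `coefficients`
#'   (`term`, `beta`, `hr`, `se`, `z`, `wald_p`), `loglik`, `converged`,
#'   `n`, `n_events`, `message`.
#' @export
cox_fit <- function(times, events, covariates, tol = 1e-8, max_iter = 50L) {
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(length(times) == nrow(x), length(events) == nrow(x),
            all(events %in% c(0, 1)))
  if (sum(events) < 1) stop("Cox regression needs at least one event")
  const <- apply(x, 2, function(v) diff(range(v)) == 0)
  if (any(const))
    stop("constant covariate(s): ", paste(colnames(x)[const], collapse = ", "))
  beta <- numeric(ncol(x))
  msg <- ""
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    d <- .cox_loglik(beta, times, events, x)
    if (max(abs(d$score)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(d$info, d$score), error = function(e) NULL)
    if (is.null(step)) { msg <- "singular information matrix"; break }
    # step-halving keeps the likelihood non-decreasing
    lam <- 1
    repeat {
      cand <- beta + lam * step
      if (.cox_loglik(cand, times, events, x)$ll >= d$ll - 1e-12 ||
          lam < 1e-4) break
      lam <- lam / 2
    }
    beta <- beta + lam * step
    if (max(abs(beta)) > 20) {
      msg <- "monotone likelihood (possible perfect separation)"
      break
    }
  }
  if (!converged && msg == "") msg <- "maximum iterations reached"
  d <- .cox_loglik(beta, times, events, x)
  se <- tryCatch(sqrt(diag(solve(d$info))), error = function(e)
    rep(NA_real_, ncol(x)))
  z <- beta / se
  coefs <- data.frame(term = colnames(x), beta = beta, hr = exp(beta),
                      se = se, z = z,
                      wald_p = 2 * stats::pnorm(-abs(z)),
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs, loglik = d$ll, converged = converged,
                 n = nrow(x), n_events = sum(events), message = msg),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("<cox_result> n =", x$n, ", events =", x$n_events,
      if (!x$converged) paste0(" [NOT CONVERGED: ", x$message, "]"), "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Median dichotomization
#'
#' Values strictly above the median are `"high"`, values at or below it
#' `"low"` — the tie policy used throughout the pipeline.
#'
#' @param values numeric vector, n >= 2, not all identical.
#' @return character vector of `"high"` / `"low"`, names preserved.
#' @export
dichotomize_by_median <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to dichotomize")
  if (diff(range(values)) == 0) stop("all values identical: no median split")
  out <- ifelse(values > stats::median(values), "high", "low")
  names(out) <- names(values)
  out
}
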