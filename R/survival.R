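#' Kaplan-Meier product-limit estimator
#'
#' Right-censored survival with `S(0) = 1`; the estimate drops by the
#' factor `(1 - d_t / n_t)` at every observed death time `t`.
#'
#' @param times Non-negative follow-up times.
#' @param events Logical vector; `TRUE` = death observed, `FALSE` =
#'   censored.
#' @return A `KmFit`: `data.frame`-like fields `time`, `n_risk`,
#'   `n_event`, `surv` (distinct event times only) and `surv_at(t)`, a
#'   right-continuous step-function evaluator.
#' @export
km_estimator <- function(times, events) {
  if (any(times < 0)) stop("negative survival time")
  stopifnot(length(times) == length(events))
  events <- as.logical(events)
  dt <- sort(unique(times[events]))
  n_risk <- vapply(dt, function(t) sum(times >= t), 0L)
  n_event <- vapply(dt, function(t) sum(times == t & events), 0L)
  surv <- cumprod(1 - n_event / n_risk)
  fit <- list(time = dt, n_risk = n_risk, n_event = n_event, surv = surv)
  fit$surv_at <- function(t) {
    vapply(t, function(ti) {
      i <- sum(dt <= ti)
      if (i == 0L) 1 else surv[i]
    }, numeric(1))
  }
  class(fit) <- "KmFit"
  fit
}

#' @export
print.KmFit <- function(x, ...) {
  cat(sprintf("KmFit: %d event time(s), final S = %.4f\n",
              length(x$time),
              if (length(x$surv)) x$surv[length(x$surv)] else 1))
  invisible(x)
}

#' Log-rank test across two or more groups
#'
#' The standard log-rank statistic: at every observed death time the
#' per-group observed death counts are compared to their expectation under
#' the hypergeometric distribution, and the summed observed-minus-expected
#' vector is combined through the summed covariance matrix into a
#' chi-square statistic with `g - 1` degrees of freedom.
#'
#' @param groups List of length `>= 2`; each element a list or data.frame
#'   with `times` and `events`.
#' @return List: `chisq`, `df`, `p`, `observed`, `expected`.
#' @export
logrank_test <- function(groups) {
  g <- length(groups)
  if (g < 2L) stop("need at least two groups")
  sizes <- vapply(groups, function(x) length(x$times), 0L)
  if (any(sizes == 0L)) stop("group with zero subjects")
  times <- unlist(lapply(groups, function(x) x$times))
  events <- as.logical(unlist(lapply(groups, function(x) x$events)))
  grp <- rep(seq_len(g), sizes)
  dt <- sort(unique(times[events]))
  O <- numeric(g); E <- numeric(g); V <- matrix(0, g, g)
  for (t in dt) {
    at_risk <- times >= t
    n <- sum(at_risk)
    d <- sum(times == t & events)
    if (n <= 1L || d == 0L) next
    ni <- vapply(seq_len(g), function(j) sum(at_risk & grp == j), 0L)
    di <- vapply(seq_len(g), function(j) sum(times == t & events & grp == j), 0L)
    O <- O + di
    E <- E + d * ni / n
    hyp <- d * (n - d) / (n - 1)
    for (i in seq_len(g)) for (j in seq_len(g)) {
      V[i, j] <- V[i, j] + hyp * (ni[i] / n) * ((i == j) - ni[j] / n)
    }
  }
  v <- V[-g, -g, drop = FALSE]
  diff <- (O - E)[-g]
  chisq <- tryCatch(as.numeric(t(diff) %*% solve(v, diff)),
                    error = function(e) {
                      sv <- svd(v)
                      pos <- sv$d > max(sv$d) * 1e-10
                      inv <- sv$v[, pos, drop = FALSE] %*%
                        diag(1 / sv$d[pos], sum(pos)) %*%
                        t(sv$u[, pos, drop = FALSE])
                      as.numeric(t(diff) %*% inv %*% diff)
                    })
  if (!is.finite(chisq)) chisq <- 0
  list(chisq = chisq, df = g - 1L,
       p = stats::pchisq(chisq, g - 1L, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Pairwise survival comparison of GMM subpopulations
#'
#' For one event: components with at least `min_n` tumor patients carrying
#' survival data are eligible. A global log-rank test across the eligible
#' components is followed by all pairwise log-rank tests with
#' Benjamini-Hochberg adjustment within the event; a pair is significant
#' when the global p-value and its adjusted pairwise p-value are both
#' below `alpha`.
#'
#' @param subpops Output of [summarize_subpopulations()] for the event.
#' @param fit The event's `GmmFit`.
#' @param samples Sample table with `sample_id`, `group`, `survival_time`,
#'   `event_observed`.
#' @param min_n Minimum patients per component (default 30).
#' @param alpha Significance level (default 0.01).
#' @return `data.frame` with one row per eligible pair (`event_id`,
#'   `component_i`, `component_j`, `logrank_chisq`, `p`, `adjusted_p`,
#'   `global_p`, `significant`), or `NULL` when fewer than two components
#'   are eligible.
#' @export
pairwise_survival <- function(subpops, fit, samples, min_n = 30L,
                              alpha = 0.01) {
  if (is.null(subpops)) return(NULL)
  surv <- samples[samples$group == "tumor" &
                    !is.na(samples$survival_time), , drop = FALSE]
  rownames(surv) <- surv$sample_id
  ids <- intersect(names(fit$assignments), surv$sample_id)
  comp_data <- lapply(seq_len(fit$k_selected), function(j) {
    m <- ids[fit$assignments[ids] == j]
    list(times = surv[m, "survival_time"],
         events = as.logical(surv[m, "event_observed"]))
  })
  eligible <- which(vapply(comp_data, function(x) length(x$times), 0L) >= min_n)
  if (length(eligible) < 2L) return(NULL)
  global <- logrank_test(comp_data[eligible])
  pairs <- utils::combn(eligible, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    lr <- logrank_test(comp_data[c(i, j)])
    data.frame(event_id = subpops$event_id[1L], component_i = i,
               component_j = j, logrank_chisq = lr$chisq, p = lr$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p, method = "BH")
  out$global_p <- global$p
  out$significant <- out$global_p < alpha & out$adjusted_p < alpha
  out
}
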