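#' Fit a univariate Gaussian mixture to PSI values with BIC model selection
#'
#' EM with unequal component variances, fitted for every `k` in
#' `1..k_max`. Initialization places means at the `(1..k)/(k+1)` quantiles
#' with equal weights and the pooled variance; `restarts` additional runs
#' jitter the initial means and the best log-likelihood is kept. BIC is
#' `-2 loglik + p log(n)` with `p = 3k - 1` free parameters; the `k`
#' minimizing BIC is selected and samples receive hard assignments by
#' maximum posterior. Component variances are floored at `variance_floor`
#' to keep boundary-piled PSI from collapsing a component.
#'
#' @param psi_values Named numeric vector (missing values removed by the
#'   caller); at least `min_n` observations.
#' @param k_max Maximum number of components (default 3).
#' @param seed RNG seed for the jittered restarts.
#' @param min_n Minimum observations (default 10).
#' @param variance_floor Variance lower bound (default 1e-4).
#' @param restarts Number of EM starts per `k` (default 5; the first is
#'   unjittered).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @return A `GmmFit`: `k_selected`, `weights`, `means`, `sds` (components
#'   ordered by mean), `bic` (named by k), `loglik`, `assignments` (named
#'   integer vector), `posterior`, `n`.
#' @export
fit_gmm <- function(psi_values, k_max = 3L, seed = 1L, min_n = 10L,
                    variance_floor = 1e-4, restarts = 5L, tol = 1e-6,
                    max_iter = 500L) {
  x <- psi_values
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite PSI values")
  n <- length(x)
  if (n < min_n)
    stop("too few observations for mixture fitting (", n, " < ", min_n, ")")
  set.seed(seed)
  fits <- vector("list", k_max)
  bic <- stats::setNames(rep(NA_real_, k_max), as.character(seq_len(k_max)))
  for (k in seq_len(k_max)) {
    best <- NULL
    for (r in seq_len(max(1L, restarts))) {
      mu0 <- stats::quantile(x, probs = seq_len(k) / (k + 1), names = FALSE)
      if (r > 1L) mu0 <- mu0 + stats::rnorm(k, 0, max(stats::sd(x), 0.01) * 0.25)
      f <- .em_univariate(x, mu0, variance_floor, tol, max_iter)
      if (is.null(best) || f$loglik > best$loglik) best <- f
    }
    bic[k] <- -2 * best$loglik + (3 * k - 1) * log(n)
    fits[[k]] <- best
  }
  k_sel <- as.integer(which.min(bic))
  f <- fits[[k_sel]]
  ord <- order(f$means)
  post <- f$posterior[, ord, drop = FALSE]
  assign <- max.col(post, ties.method = "first")
  names(assign) <- names(x)
  structure(list(k_selected = k_sel,
                 weights = f$weights[ord], means = f$means[ord],
                 sds = f$sds[ord], bic = bic, loglik = f$loglik,
                 assignments = assign, posterior = post, n = n,
                 data = x),
            class = "GmmFit")
}

# one EM run at fixed k; returns weights/means/sds/loglik/posterior
.em_univariate <- function(x, mu, variance_floor, tol, max_iter) {
  k <- length(mu)
  n <- length(x)
  w <- rep(1 / k, k)
  v <- rep(max(stats::var(x), variance_floor), k)
  if (is.na(v[1L])) v <- rep(variance_floor, k)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    logd <- matrix(0, n, k)
    for (j in seq_len(k))
      logd[, j] <- -0.918938533204673 - 0.5 * log(v[j]) -
        (x - mu[j])^2 / (2 * v[j]) + log(w[j])
    m <- logd[, 1L]
    for (j in seq_len(k)[-1L]) m <- pmax(m, logd[, j])
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    post <- exp(logd - lse)
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    nk <- colSums(post)
    nk <- pmax(nk, 1e-10)
    w <- nk / n
    mu <- colSums(post * x) / nk
    v <- pmax(colSums(post * outer(x, mu, "-")^2) / nk, variance_floor)
  }
  list(weights = w, means = mu, sds = sqrt(v), loglik = ll, posterior = post)
}

#' @export
print.GmmFit <- function(x, ...) {
  cat(sprintf("GmmFit: k = %d (BIC %s), n = %d\n", x$k_selected,
              paste(sprintf("%s=%.1f", names(x$bic), x$bic), collapse = " "),
              x$n))
  for (j in seq_len(x$k_selected))
    cat(sprintf("  comp %d: weight %.3f mean %.3f sd %.3f\n",
                j, x$weights[j], x$means[j], x$sds[j]))
  invisible(x)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test used for differential splicing between a
#' tumor-specific subpopulation and the control samples. The exact p-value
#' (from the exact rank-sum null distribution) is used when both groups
#' have at most `exact_max` observations and there are no ties; otherwise
#' the normal approximation with tie correction is used (no continuity
#' correction, so the two paths estimate the same quantity).
#'
#' @param x,y Numeric vectors.
#' @param exact_max Group-size bound for the exact path (default 25).
#' @return List: `statistic` (Mann-Whitney U of `x`), `p_value`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 25L) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx > 0L, ny > 0L)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && nx <= exact_max && ny <= exact_max) {
    p <- if (u > nx * ny / 2)
      stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE)
    else stats::pwilcox(u, nx, ny)
    return(list(statistic = u, p_value = min(1, 2 * p), exact = TRUE))
  }
  nt <- table(pooled)
  n <- nx + ny
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(nt^3 - nt) / (n * (n - 1)))
  z <- (u - nx * ny / 2) / sqrt(sigma2)
  list(statistic = u, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       exact = FALSE)
}

#' Summarize GMM subpopulations against the cohort labels
#'
#' For every fitted component: tumor/control membership counts, tumor
#' purity, `delta_psi` (mean PSI of the component's tumor members minus
#' mean PSI of *all* control samples, in percentage points), and a
#' two-sided Wilcoxon rank-sum p-value between the component's tumor PSI
#' and the control PSI. A component is *tumor-specific* when purity
#' `> purity_min`, tumor membership `>= n_min` and `|delta_psi| >=
#' delta_min` (plus, when `wilcox_alpha` is non-`NULL`, Wilcoxon
#' `p < wilcox_alpha`).
#'
#' @param fit A `GmmFit` (assignment names are sample ids).
#' @param samples Sample table `data.frame` with `sample_id` and `group`
#'   (`"tumor"` / `"control"`).
#' @param event_id Event identifier carried into the results.
#' @param control_psi Optional numeric vector of control PSI values;
#'   defaults to the fitted controls' PSI.
#' @param purity_min,n_min,delta_min,wilcox_alpha Gates (defaults 0.90,
#'   50, 20 percentage points, 0.05).
#' @return `data.frame`, one row per component: `event_id`, `component`,
#'   `n_tumor`, `n_control`, `purity`, `mean_psi`, `delta_psi`,
#'   `wilcoxon_p`, `tumor_specific`. `NULL` when the cohort has no
#'   controls.
#' @export
summarize_subpopulations <- function(fit, samples, event_id = NA_character_,
                                     control_psi = NULL, purity_min = 0.90,
                                     n_min = 50L, delta_min = 20,
                                     wilcox_alpha = 0.05) {
  grp <- stats::setNames(samples$group, samples$sample_id)
  ids <- names(fit$assignments)
  stopifnot(all(ids %in% names(grp)))
  is_tumor <- grp[ids] == "tumor"
  if (is.null(control_psi)) control_psi <- fit$data[!is_tumor]
  if (length(control_psi) == 0L) return(NULL)
  rows <- lapply(seq_len(fit$k_selected), function(j) {
    memb <- fit$assignments == j
    nt <- sum(memb & is_tumor); nc <- sum(memb & !is_tumor)
    if (nt + nc == 0L)
      return(data.frame(event_id = event_id, component = j, n_tumor = 0L,
                        n_control = 0L, purity = NA_real_,
                        mean_psi = NA_real_, delta_psi = NA_real_,
                        wilcoxon_p = NA_real_, tumor_specific = FALSE,
                        stringsAsFactors = FALSE))
    tpsi <- fit$data[memb & is_tumor]
    purity <- nt / (nt + nc)
    delta <- if (nt) 100 * (mean(tpsi) - mean(control_psi)) else NA_real_
    p <- if (nt) wilcoxon_rank_sum(tpsi, control_psi)$p_value else NA_real_
    spec <- !is.na(purity) && purity > purity_min && nt >= n_min &&
      !is.na(delta) && abs(delta) >= delta_min &&
      (is.null(wilcox_alpha) || (!is.na(p) && p < wilcox_alpha))
    data.frame(event_id = event_id, component = j, n_tumor = nt,
               n_control = nc, purity = purity,
               mean_psi = mean(fit$data[memb]), delta_psi = delta,
               wilcoxon_p = p, tumor_specific = spec,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
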