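#' Default configuration for cohort stratification
#'
#' @param ... Overrides for any key: `k_max`, `min_obs`, `purity_min`,
#'   `n_min_subpop`, `delta_psi_min`, `wilcox_alpha`, `n_min_survival`,
#'   `alpha`, `seed`, `variance_floor`, `restarts`, `survival_scope`
#'   (`"tumor_specific"` runs survival only on events with a
#'   tumor-specific subpopulation, `"all"` on every fitted event).
#' @return Named list of configuration values.
#' @export
stratify_config <- function(...) {
  cfg <- list(k_max = 3L, min_obs = 10L, purity_min = 0.90,
              n_min_subpop = 50L, delta_psi_min = 20, wilcox_alpha = 0.05,
              n_min_survival = 30L, alpha = 0.01, seed = 1L,
              variance_floor = 1e-4, restarts = 5L,
              survival_scope = "tumor_specific")
  utils::modifyList(cfg, list(...))
}

#' Stratify a patient cohort by per-event Gaussian mixtures
#'
#' The full stratification procedure, applied to every splicing event of a
#' PSI matrix: (1) fit a 1-3 component Gaussian mixture to the event's
#' non-missing PSI values across tumors and controls, selecting the
#' component count by BIC; (2) assign samples to subpopulations by maximum
#' posterior; (3) flag tumor-specific subpopulations (purity above
#' `purity_min`, at least `n_min_subpop` tumors, `|delta PSI|` of at least
#' `delta_psi_min` percentage points versus controls, Wilcoxon-supported);
#' (4) compare survival between subpopulations with at least
#' `n_min_survival` patients by global and pairwise log-rank tests with
#' Benjamini-Hochberg adjustment, at level `alpha`.
#'
#' Events with fewer than `min_obs` non-missing values are skipped and
#' listed in `summary$skipped`. The run is deterministic given
#' `config$seed` (each event derives its own sub-seed).
#'
#' @param psi A `PsiMatrix` from [compute_psi()], or a plain numeric
#'   matrix (events x samples) with event ids as row names.
#' @param samples Sample table `data.frame`: `sample_id`, `group`
#'   (`tumor`/`control`), optional `subtype`, and for tumors
#'   `survival_time` / `event_observed`.
#' @param config A list from [stratify_config()].
#' @return List: `subpopulations` (per-component data.frame), `survival`
#'   (per-pair data.frame), `fits` (per-event `GmmFit`s), `summary`
#'   (counts overall and by event type, plus skipped events).
#' @export
stratify_cohort <- function(psi, samples, config = stratify_config()) {
  m <- if (inherits(psi, "PsiMatrix")) psi$psi else psi
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  unknown <- setdiff(colnames(m), samples$sample_id)
  if (length(unknown))
    stop("samples absent from the sample table: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  sub_rows <- list(); surv_rows <- list(); fits <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(m))) {
    ev <- rownames(m)[i]
    v <- m[i, ]
    v <- v[!is.na(v)]
    if (length(v) < config$min_obs) {
      skipped <- c(skipped, ev)
      next
    }
    fit <- fit_gmm(v, k_max = config$k_max,
                   seed = (config$seed + i) %% .Machine$integer.max,
                   min_n = config$min_obs,
                   variance_floor = config$variance_floor,
                   restarts = config$restarts)
    fits[[ev]] <- fit
    sp <- summarize_subpopulations(fit, samples, event_id = ev,
                                   purity_min = config$purity_min,
                                   n_min = config$n_min_subpop,
                                   delta_min = config$delta_psi_min,
                                   wilcox_alpha = config$wilcox_alpha)
    if (is.null(sp)) { skipped <- c(skipped, ev); next }
    sub_rows[[ev]] <- sp
    run_surv <- config$survival_scope == "all" || any(sp$tumor_specific)
    if (run_surv) {
      sv <- pairwise_survival(sp, fit, samples,
                              min_n = config$n_min_survival,
                              alpha = config$alpha)
      if (!is.null(sv)) surv_rows[[ev]] <- sv
    }
  }
  subpops <- if (length(sub_rows)) do.call(rbind, c(sub_rows,
                                                   make.row.names = FALSE))
  else NULL
  survival <- if (length(surv_rows)) do.call(rbind, c(surv_rows,
                                                      make.row.names = FALSE))
  else NULL
  ts_events <- if (!is.null(subpops))
    unique(subpops$event_id[subpops$tumor_specific]) else character(0)
  sig_events <- if (!is.null(survival))
    unique(survival$event_id[survival$significant]) else character(0)
  etype <- function(ids) {
    t <- sub("^[^;]*;([A-Z0-9]+):.*$", "\\1", ids)
    t[t == ids] <- "other"
    t
  }
  summary <- list(
    n_events_tested = length(fits),
    n_skipped = length(skipped), skipped = skipped,
    n_tumor_specific_events = length(ts_events),
    tumor_specific_events = ts_events,
    tumor_specific_by_type = if (length(ts_events))
      table(etype(ts_events)) else table(character(0)),
    n_survival_events = length(sig_events),
    survival_events = sig_events,
    survival_by_type = if (length(sig_events))
      table(etype(sig_events)) else table(character(0)))
  list(subpopulations = subpops, survival = survival, fits = fits,
       summary = summary)
}

#' Read and validate a clinical sample table
#'
#' TSV with header; required columns `sample_id`, `group`
#' (`tumor`/`control`); optional `subtype`, `survival_time` (days),
#' `event_observed` (0/1 or TRUE/FALSE). Controls never enter survival
#' analysis, so their survival fields must be empty.
#'
#' @param path TSV path.
#' @return Validated `data.frame`.
#' @export
read_sample_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_table(d)
}

#' @rdname read_sample_table
#' @param d A data.frame to validate in place.
#' @export
validate_sample_table <- function(d) {
  stopifnot(all(c("sample_id", "group") %in% names(d)))
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id")
  if (!all(d$group %in% c("tumor", "control")))
    stop("group must be 'tumor' or 'control'")
  if (!"subtype" %in% names(d)) d$subtype <- NA_character_
  if (!"survival_time" %in% names(d)) d$survival_time <- NA_real_
  if (!"event_observed" %in% names(d)) d$event_observed <- NA
  d$event_observed <- as.logical(d$event_observed)
  ctrl <- d$group == "control"
  if (any(!is.na(d$survival_time[ctrl])))
    stop("controls must not carry survival times")
  if (any(d$survival_time < 0, na.rm = TRUE))
    stop("negative survival time")
  d
}
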