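#' Specification of a synthetic paired pre/post proteomic panel
#'
#' Generative parameters for fixture panels with the structure the pipeline
#' assumes: paired pre/post-treatment serum samples, thousands of positive
#' abundance features, a small planted informative subset whose
#' log-abundance shifts after treatment, and correlated redundant proxies of
#' each informative feature. Defaults emulate an 82-patient, 164-sample
#' cohort on a 1000-feature panel (scalable to the full 7289).
#'
#' @param n_patients patients; the panel has `2 * n_patients` samples, one
#'   pre (label 0) and one post (label 1) per patient.
#' @param n_features total features.
#' @param n_informative planted informative features.
#' @param effect_log_shift shift `delta` (log-abundance units) added to post
#'   samples on informative features.
#' @param n_proxies_per_informative correlated proxies per informative
#'   feature.
#' @param proxy_correlation correlation `rho` in (0, 1) between a proxy and
#'   its parent in log space (proxies inherit an attenuated `rho * delta`
#'   shift).
#' @param base_log_mean,base_log_sd baseline log-abundance mean and sd
#'   (log-normal abundances, RFU-like positive scale).
#' @param sample_scale_jitter_sd sd of the per-sample multiplicative scale
#'   factor (lognormal), mimicking residual assay scale wobble after
#'   normalization.
#' @param seed integer seed (required).
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_patients = 82L, n_features = 1000L,
                           n_informative = 8L, effect_log_shift = 0.8,
                           n_proxies_per_informative = 2L,
                           proxy_correlation = 0.9,
                           base_log_mean = 8, base_log_sd = 1,
                           sample_scale_jitter_sd = 0.05,
                           seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  spec <- list(
    n_patients = as.integer(n_patients),
    n_features = as.integer(n_features),
    n_informative = as.integer(n_informative),
    effect_log_shift = effect_log_shift,
    n_proxies_per_informative = as.integer(n_proxies_per_informative),
    proxy_correlation = proxy_correlation,
    base_log_mean = base_log_mean,
    base_log_sd = base_log_sd,
    sample_scale_jitter_sd = sample_scale_jitter_sd,
    seed = as.integer(seed)
  )
  if (spec$n_patients < 2L) stop("need at least 2 patients", call. = FALSE)
  if (spec$n_informative < 0L) stop("`n_informative` must be >= 0", call. = FALSE)
  planted <- spec$n_informative * (1L + spec$n_proxies_per_informative)
  if (planted > spec$n_features) {
    stop("informative features plus proxies exceed `n_features`", call. = FALSE)
  }
  if (spec$proxy_correlation <= 0 || spec$proxy_correlation >= 1) {
    stop("`proxy_correlation` must be in (0, 1)", call. = FALSE)
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic paired pre/post panel
#'
#' Log-abundances are Gaussian around `base_log_mean`; informative features
#' gain `effect_log_shift` on post samples; each proxy is a
#' `proxy_correlation`-correlated copy of its parent's (shifted)
#' standardized log signal; the remaining features are independent noise.
#' A per-sample multiplicative scale factor is applied, and abundances are
#' exponentiated to a positive RFU-like scale. Ground truth about which
#' features were planted is returned alongside -- never inside -- the
#' feature table the pipeline consumes.
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `synthetic_panel`: `table` (a
#'   [feature_table()] with `patient_ids`), `truth` (data frame: `feature`,
#'   `role` in `{informative, proxy, noise}`, `parent`), `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n_pat <- spec$n_patients
  n <- 2L * n_pat
  p <- spec$n_features
  labels <- rep(c(0L, 1L), n_pat) # pre, post per patient
  patient_ids <- rep(sprintf("P%03d", seq_len(n_pat)), each = 2L)
  sample_ids <- paste0(patient_ids, ifelse(labels == 0L, "_pre", "_post"))

  n_inf <- spec$n_informative
  n_prox <- n_inf * spec$n_proxies_per_informative
  role <- rep("noise", p)
  parent <- rep(NA_character_, p)
  inf_idx <- seq_len(n_inf)
  role[inf_idx] <- "informative"
  prox_idx <- if (n_prox > 0L) n_inf + seq_len(n_prox) else integer(0)
  role[prox_idx] <- "proxy"

  z <- matrix(stats::rnorm(n * p), n, p) # standardized log signal
  post <- labels == 1L
  if (n_inf > 0L) {
    shift_z <- spec$effect_log_shift / spec$base_log_sd
    z[post, inf_idx] <- z[post, inf_idx] + shift_z
    if (n_prox > 0L) {
      rho <- spec$proxy_correlation
      for (j in seq_len(n_prox)) {
        par_j <- ((j - 1L) %% n_inf) + 1L
        parent[prox_idx[j]] <- paste0("feat_", formatC(par_j, width = 5, flag = "0"))
        z[, prox_idx[j]] <- rho * z[, par_j] +
          sqrt(1 - rho^2) * stats::rnorm(n)
      }
    }
  }
  log_vals <- spec$base_log_mean + spec$base_log_sd * z
  jitter <- stats::rnorm(n, 0, spec$sample_scale_jitter_sd)
  log_vals <- log_vals + jitter # same multiplicative factor across a sample
  values <- exp(log_vals)
  feature_names <- paste0("feat_", formatC(seq_len(p), width = 5, flag = "0"))
  colnames(values) <- feature_names
  rownames(values) <- sample_ids
  table <- feature_table(values, labels, sample_ids, feature_names,
                         patient_ids = patient_ids)
  truth <- data.frame(feature = feature_names, role = role, parent = parent,
                      stringsAsFactors = FALSE)
  structure(list(table = table, truth = truth, spec = spec),
            class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf(
    "<synthetic_panel> %d samples x %d features (%d informative, %d proxies), seed %d\n",
    nrow(x$table$values), ncol(x$table$values),
    sum(x$truth$role == "informative"), sum(x$truth$role == "proxy"),
    x$spec$seed
  ))
  invisible(x)
}

#' Recall of planted signal groups by a selected feature set
#'
#' A planted informative feature counts as recovered if the selection
#' contains the feature itself or any of its proxies.
#'
#' @param selected character vector of selected feature names.
#' @param truth the `truth` data frame of a [generate_dataset()] result.
#' @return fraction of informative features recovered (in \[0, 1\]).
#' @export
planted_recovery_recall <- function(selected, truth) {
  inf <- truth$feature[truth$role == "informative"]
  if (!length(inf)) return(NA_real_)
  hit <- vapply(inf, function(f) {
    f %in% selected ||
      any(truth$feature[!is.na(truth$parent) & truth$parent == f] %in% selected)
  }, logical(1))
  mean(hit)
}
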