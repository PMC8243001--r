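#' Goodness-of-fit metrics for feature tables
#'
#' Computes four root-mean-square error flavours between model and target
#' features over the shared stimulation conditions: RMSE (unit weights),
#' RMSNE (weights `1/target`), RMSWE (the configured fitting weights) and
#' RMSZE (weights `1/sigma`, requiring target standard deviations). Each is
#' reported per feature and for three grouped scopes — `all`, `tau_all`
#' (the four time constants) and `I_all` (the three current features) —
#' where squared errors of the grouped features are summed per condition
#' before the mean over conditions and the root are taken.
#'
#' @param model_features,target_features feature tibbles (`irradiance`,
#'   `voltage`, `feature`, `value`; targets may carry `sigma`).
#' @param weights named list of fitting weights as in [fit_config()].
#' @return A `metric_table` tibble with columns `metric`, `scope`, `value`.
#'   RMSNE rows exclude (with a warning) conditions with zero target; RMSZE
#'   is `NA` for scopes without usable sigmas.
#' @export
#' @examples
#' t <- tibble::tibble(irradiance = 100, voltage = -60,
#'                     feature = c("i_peak", "i_ss"), value = c(2, 1))
#' m <- dplyr::mutate(t, value = c(3, 1.5))
#' goodness_of_fit(m, t)
goodness_of_fit <- function(model_features, target_features, weights = NULL) {
  if (is.null(weights)) {
    weights <- list(peak = 1, ss = 1, ratio = 1, on = 1, inact = 1,
                    off = 1, recov = 1)
  }
  wmap <- c(i_peak = weights$peak, i_ss = weights$ss, i_ratio = weights$ratio,
            tau_on = weights$on, tau_inact = weights$inact,
            tau_off = weights$off, tau_recov = weights$recov)
  tf <- target_features
  if (!"sigma" %in% names(tf)) tf$sigma <- NA_real_
  j <- dplyr::inner_join(
    dplyr::select(model_features, "irradiance", "voltage", "feature",
                  model = "value"),
    dplyr::select(tf, "irradiance", "voltage", "feature", target = "value",
                  "sigma"),
    by = c("irradiance", "voltage", "feature")) |>
    dplyr::filter(!is.na(.data$model), !is.na(.data$target))
  if (nrow(j) == 0) stop("goodness_of_fit: no shared conditions", call. = FALSE)
  j$err2 <- (j$model - j$target)^2
  if (any(j$target == 0)) {
    warning("goodness_of_fit: zero targets excluded from RMSNE",
            call. = FALSE)
  }
  if (any(!is.na(j$sigma) & j$sigma == 0)) {
    warning("goodness_of_fit: zero sigmas excluded from RMSZE",
            call. = FALSE)
  }
  j$w_rmse <- 1
  j$w_rmsne <- ifelse(j$target != 0, 1 / j$target, NA_real_)
  j$w_rmswe <- unname(wmap[j$feature])
  j$w_rmsze <- ifelse(!is.na(j$sigma) & j$sigma > 0, 1 / j$sigma, NA_real_)

  tau_feats <- c("tau_on", "tau_off", "tau_inact", "tau_recov")
  i_feats <- c("i_peak", "i_ss", "i_ratio")
  scopes <- c(stats::setNames(as.list(unique(j$feature)), unique(j$feature)),
              list(all = unique(j$feature),
                   tau_all = intersect(tau_feats, unique(j$feature)),
                   I_all = intersect(i_feats, unique(j$feature))))

  rows <- purrr::imap(scopes, function(feats, scope) {
    sub <- j[j$feature %in% feats, ]
    per_metric <- function(wcol) {
      s <- sub[!is.na(sub[[wcol]]), ]
      if (nrow(s) == 0) return(NA_real_)
      percond <- tapply(s[[wcol]]^2 * s$err2,
                        paste(s$irradiance, s$voltage), sum)
      sqrt(mean(percond))
    }
    tibble::tibble(metric = c("RMSE", "RMSNE", "RMSWE", "RMSZE"),
                   scope = scope,
                   value = c(per_metric("w_rmse"), per_metric("w_rmsne"),
                             per_metric("w_rmswe"), per_metric("w_rmsze")))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("metric_table", class(out))
  out
}

#' Write a metric table as CSV
#'
#' @param metrics a `metric_table` from [goodness_of_fit()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  readr::write_csv(metrics, path)
  invisible(path)
}
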