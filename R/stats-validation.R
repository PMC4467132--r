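#' Spearman correlation with Fisher-z confidence interval
#'
#' Computes Spearman's rho by the midrank convention (Pearson correlation of
#' midranks), a two-tailed p-value (exact null distribution for small
#' samples without ties, t approximation with ties), and a 95% confidence
#' interval from the Fisher z transform with standard error
#' `1/sqrt(n - 3)`.
#'
#' @param x,y Paired numeric vectors (n >= 4).
#' @param conf Confidence level (default 0.95).
#' @return Tibble with columns `rho`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
#' @examples
#' spearman_with_ci(1:6, c(2, 3, 5, 8, 13, 21))
spearman_with_ci <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) rlang::abort("spearman_with_ci needs at least 4 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("rho undefined: constant x or y")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  has_ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  p <- if (!has_ties && n <= 1290) {
    suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE,
                      alternative = "two.sided")$p.value)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  zcrit <- stats::qnorm(1 - (1 - conf) / 2)
  if (abs(rho) >= 1) {
    ci <- c(rho, rho)
  } else {
    z <- atanh(rho)
    se <- 1 / sqrt(n - 3)
    ci <- tanh(z + c(-1, 1) * zcrit * se)
  }
  tibble::tibble(rho = rho, ci_low = ci[1], ci_high = ci[2],
                 p = min(p, 1), n = n)
}

#' Log-linear regression R-squared
#'
#' Ordinary least squares of `log(y)` on `log(x)` (natural log; R-squared is
#' base-invariant); `R2 = 1 - SS_res / SS_tot` measures how much of the
#' experimental variation the simulation explains on the log scale.
#'
#' @param x Simulated values (> 0).
#' @param y Experimental values (> 0).
#' @return R-squared in `[0, 1]`.
#' @export
r_squared_loglinear <- function(x, y) {
  stopifnot(length(x) == length(y))
  bad <- which(!(x > 0 & y > 0))
  if (length(bad)) {
    rlang::abort(paste0("log-transform needs positive values; offending row(s): ",
                        paste(bad, collapse = ", ")))
  }
  fit <- stats::lm(log(y) ~ log(x))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log(y) - mean(log(y)))^2)
  1 - ss_res / ss_tot
}

#' Validate simulated readouts against experimental tables
#'
#' Joins a simulated `readout_table` (one prediction per treatment x
#' endpoint x time) to an experimental table with replicates (columns
#' `treatment`, `endpoint`, `replicate`, `value`, optionally `time_s`), so
#' each replicate forms one (X = simulated, Y = measured) pair sharing the
#' treatment's single prediction, and reports per endpoint the Spearman rho
#' with CI and p plus the log-linear R-squared.
#'
#' @param sim A `readout_table` from [run_experiment()].
#' @param exp_ Experimental data frame (see above).
#' @param min_pairs Minimum pairs per endpoint (default 4).
#' @return A `validation_report` object; see [tidy.validation_report()].
#' @export
validate_readouts <- function(sim, exp_, min_pairs = 4) {
  exp_ <- tibble::as_tibble(exp_)
  need <- c("treatment", "endpoint", "replicate", "value")
  miss <- setdiff(need, names(exp_))
  if (length(miss)) {
    rlang::abort(paste0("experimental table missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  keys <- c("treatment", "endpoint", if ("time_s" %in% names(exp_)) "time_s")
  sim_keys <- dplyr::distinct(sim[keys])
  exp_keys <- dplyr::distinct(exp_[keys])
  orphans <- dplyr::anti_join(exp_keys, sim_keys, by = keys)
  if (nrow(orphans)) {
    rlang::abort(paste0("experimental labels without simulated match: ",
                        paste(unique(orphans$treatment), collapse = ", ")))
  }
  joined <- dplyr::inner_join(
    dplyr::rename(sim, sim_value = "value"),
    dplyr::rename(exp_, exp_value = "value"),
    by = keys
  )
  per_ep <- joined |>
    dplyr::group_by(.data$endpoint) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < min_pairs) {
        rlang::abort(paste0("endpoint ", key$endpoint, ": fewer than ",
                            min_pairs, " pairs"))
      }
      sp <- spearman_with_ci(d$sim_value, d$exp_value)
      r2 <- r_squared_loglinear(d$sim_value, d$exp_value)
      dplyr::mutate(sp, r_squared_loglinear = r2)
    }) |>
    dplyr::ungroup()
  structure(list(results = per_ep, pairs = joined),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> simulated vs experimental readouts\n")
  print(x$results)
  invisible(x)
}

#' Tidy a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return Per-endpoint tibble: `endpoint`, `rho`, `ci_low`, `ci_high`,
#'   `p`, `n`, `r_squared_loglinear`.
#' @export
tidy.validation_report <- function(x, ...) x$results

#' One-row summary of a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return Tibble with the number of endpoints, total pairs, median rho and
#'   median R-squared.
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    n_endpoints = nrow(x$results),
    n_pairs = sum(x$results$n),
    median_rho = stats::median(x$results$rho),
    median_r_squared = stats::median(x$results$r_squared_loglinear)
  )
}

#' Scatter plot of experimental versus simulated readouts
#'
#' One panel per endpoint, experimental replicates on the Y axis against the
#' single simulated prediction on the X axis, with the 1:1 diagonal.
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.validation_report <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(.data$sim_value, .data$exp_value)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~endpoint, scales = "free") +
    ggplot2::labs(x = "simulated (X)", y = "experimental (Y)") +
    ggplot2::theme_minimal()
}
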