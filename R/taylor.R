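# Taylor's power-law mean-variance scaling across hierarchical levels.
#
# The scaling exponent b is estimated by ordinary least squares on the
# log-log mean-SD relationship. Under the default convention
# (log10(sd) ~ log10(mean)) a slope of b = 0.5 corresponds to variance
# proportional to the mean (the Poisson-like regime), b = 1 to constant CV,
# and b = 0 to constant SD. The literal Var = a * mean^b regression is
# available as convention = "var_vs_mean", under which variance linear in
# the mean gives slope 1; output metadata carries the convention so the two
# parameterizations are never silently mixed.

#' Extract (mean, sd) pairs from a tensor at a hierarchical level
#'
#' @param tensor A `metacommunity_tensor`.
#' @param level `"population"`: one pair per (unit, patch) temporal series;
#'   `"community"`: one pair per patch total series; `"region"`: population
#'   and community pairs pooled.
#' @return A tibble with columns `level`, `unit`, `patch`, `mean`, `sd`.
#'   Series with zero mean or zero SD carry no information about log-log
#'   scaling and are dropped; the number dropped is in attribute
#'   `n_dropped` and reported as a message.
#' @export
taylor_units <- function(tensor, level = c("population", "community", "region")) {
  level <- match.arg(level)
  stopifnot(inherits(tensor, "metacommunity_tensor"))
  x <- unclass(tensor)
  dn <- dimnames(x)

  pop_pairs <- function() {
    m <- apply(x, c(1, 2), mean)          # unit x patch
    s <- apply(x, c(1, 2), stats::sd)
    tibble(level = "population",
           unit = rep(dn$unit, times = length(dn$patch)),
           patch = rep(dn$patch, each = length(dn$unit)),
           mean = as.vector(m), sd = as.vector(s))
  }
  com_pairs <- function() {
    patch_tot <- apply(x, c(2, 3), sum)
    tibble(level = "community", unit = NA_character_, patch = dn$patch,
           mean = unname(apply(patch_tot, 1, mean)),
           sd = unname(apply(patch_tot, 1, stats::sd)))
  }
  pairs <- switch(level,
    population = pop_pairs(),
    community = com_pairs(),
    region = bind_rows(pop_pairs(), com_pairs())
  )
  pairs <- pairs |> filter(!is.na(.data$mean), !is.na(.data$sd))
  usable <- pairs$mean > 0 & pairs$sd > 0
  n_dropped <- sum(!usable)
  if (n_dropped > 0) {
    inform(sprintf("%d series with zero mean or zero SD excluded from the Taylor fit",
                   n_dropped))
  }
  out <- pairs[usable, ]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Fit Taylor's power law by log-log regression
#'
#' @param pairs A data frame with positive columns `mean` and `sd` (e.g.
#'   from [taylor_units()]); at least 3 usable rows.
#' @param convention `"sd_vs_mean"` (default): OLS of `log10(sd)` on
#'   `log10(mean)`, so `b = 0.5` means variance proportional to mean;
#'   `"var_vs_mean"`: OLS of `log10(sd^2)` on `log10(mean)`, slope reported
#'   as-is (linear variance-mean gives slope 1).
#' @param level Optional label (`"population"`, `"community"`, `"region"`)
#'   recorded in the fit.
#' @return A `taylor_fit`: list with `b` (slope), `intercept`, `r_squared`,
#'   `n_units`, `level`, `convention`, and the fitting `data`. `tidy()` and
#'   `glance()` methods return tibbles.
#' @examples
#' taylor_fit(data.frame(mean = c(1, 4, 16), sd = c(1, 2, 4)))$b  # 0.5
#' @export
taylor_fit <- function(pairs, convention = c("sd_vs_mean", "var_vs_mean"),
                       level = NULL) {
  convention <- match.arg(convention)
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("mean", "sd") %in% names(pairs))) {
    abort("pairs must have columns 'mean' and 'sd'")
  }
  pairs <- pairs |> filter(.data$mean > 0, .data$sd > 0)
  if (nrow(pairs) < 3) abort("need at least 3 pairs with mean > 0 and sd > 0")

  log_mean <- log10(pairs$mean)
  log_resp <- if (convention == "sd_vs_mean") log10(pairs$sd) else log10(pairs$sd^2)
  if (length(unique(log_mean)) < 2) abort("all means identical: slope undefined")
  fit <- stats::lm(log_resp ~ log_mean)
  ss_tot <- sum((log_resp - mean(log_resp))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(fit$residuals^2) / ss_tot
  structure(list(
    b = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = max(0, min(1, r2)),
    n_units = nrow(pairs),
    level = level %||% attr(pairs, "level", exact = TRUE) %||% NA_character_,
    convention = convention,
    data = pairs
  ), class = "taylor_fit")
}

#' @export
print.taylor_fit <- function(x, ...) {
  cat(sprintf("# taylor_fit (%s%s): b = %.4f, intercept = %.4f, R^2 = %.3f, n = %d\n",
              x$convention,
              if (is.na(x$level)) "" else paste0(", level = ", x$level),
              x$b, x$intercept, x$r_squared, x$n_units))
  invisible(x)
}

#' @describeIn taylor_fit Coefficients as a tibble (`term`, `estimate`).
#' @param x A `taylor_fit`.
#' @param ... Unused.
#' @export
tidy.taylor_fit <- function(x, ...) {
  tibble(term = c("intercept", "b"), estimate = c(x$intercept, x$b))
}

#' @describeIn taylor_fit One-row fit summary tibble.
#' @export
glance.taylor_fit <- function(x, ...) {
  tibble(b = x$b, intercept = x$intercept, r_squared = x$r_squared,
         n_units = x$n_units, level = x$level, convention = x$convention)
}
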