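# Variance partitioning of temporal invariability across organizational
# levels, after the metacommunity stability framework: the coefficient of
# variation of the regional aggregate factors exactly into lower-level CVs
# times synchrony ratios,
#
#   CV_C,R = CV_C,L * Psi_C,L->R          (spatial route)
#   CV_C,L = CV_S,L * Psi_S->C,L          (species route, local)
#   CV_S,R = CV_S,L * Psi_S,L->R          (species route, regional)
#   CV_C,R = CV_S,R * Psi_S->C,R
#
# where every CV is a sum of temporal SDs over the SAME denominator, the
# temporal mean of the region-wide total, and every synchrony index Psi is a
# ratio of CVs. Subadditivity of the SD of a sum guarantees Psi in [0, 1],
# which is what makes invariability (1/CV) non-decreasing from populations
# to communities to the region.

#' Temporal standard deviation and mean of a series
#'
#' Sample standard deviation (n - 1 denominator) and arithmetic mean of a
#' time series. With two time points, `sd = |x1 - x2| / sqrt(2)`.
#'
#' @param series Numeric vector of length >= 2, finite.
#' @return A list with elements `sd` and `mean`.
#' @examples
#' temporal_sd_mean(c(2, 4))  # sd = sqrt(2), mean = 3
#' @export
temporal_sd_mean <- function(series) {
  if (length(series) < 2) abort("series must have length >= 2")
  if (!is.numeric(series) || any(!is.finite(series))) {
    abort("series must be finite numeric")
  }
  list(sd = stats::sd(series), mean = mean(series))
}

#' Partition metacommunity variability into CVs and synchrony indices
#'
#' Computes the four weighted coefficients of variation (species-local,
#' community-local, species-regional, community-regional), the four
#' synchrony ratios linking them, and the corresponding invariabilities
#' (reciprocal CVs) from a unit x patch x time tensor.
#'
#' With `mu` the temporal mean of the region-wide total series:
#' * `cv_s_l` = sum over (unit, patch) of the temporal SD of each population
#'   series, divided by `mu`;
#' * `cv_c_l` = sum over patches of the SD of each patch total, over `mu`;
#' * `cv_s_r` = sum over units of the SD of each unit's regional total,
#'   over `mu`;
#' * `cv_c_r` = SD of the region-wide total, over `mu`.
#'
#' Synchrony is the ratio of CVs (square-root scale), e.g. species synchrony
#' `phi_s2c_l = cv_c_l / cv_s_l`; a variance-scale (squared) variant is
#' available via `synchrony_scale = "variance"` for comparison, but the
#' multiplicative identities above hold on the CV-ratio scale. A `0/0`
#' synchrony (all component series constant) is reported as 1 and flagged
#' degenerate rather than erroring, so batch runs survive degenerate
#' variables.
#'
#' Units containing missing cells (possible only for fruit set) are dropped
#' with a warning and the partition runs on the complete-case unit subset.
#'
#' @param tensor A `metacommunity_tensor`.
#' @param synchrony_scale `"cv_ratio"` (default) or `"variance"`.
#' @return A `partition_result`: list with numeric vectors `cv`
#'   (`s_l`, `c_l`, `s_r`, `c_r`), `phi` (`s2c_l`, `c_l2r`, `s_l2r`,
#'   `s2c_r`), `inv` (reciprocal CVs, `Inf` where CV = 0), plus `mu`,
#'   dimensions, `n_units_dropped`, and `degenerate` flags. Use [tidy()] or
#'   [glance()] to get tibbles.
#' @export
var_partition <- function(tensor, synchrony_scale = c("cv_ratio", "variance")) {
  synchrony_scale <- match.arg(synchrony_scale)
  stopifnot(inherits(tensor, "metacommunity_tensor"))
  x <- unclass(tensor)
  variable <- attr(tensor, "variable")

  n_units_dropped <- 0L
  if (anyNA(x)) {
    keep <- apply(x, 1, function(u) !anyNA(u))
    n_units_dropped <- sum(!keep)
    if (!any(keep)) abort("no complete-case units left after dropping missing cells")
    warn(sprintf("dropped %d unit(s) with missing cells; partition uses the complete-case subset",
                 n_units_dropped))
    x <- x[keep, , , drop = FALSE]
  }
  if (all(x == 0)) abort("degenerate metacommunity: all-zero tensor")

  total <- apply(x, 3, sum)                       # region-wide total series
  mu <- mean(total)
  if (mu <= 0) abort("regional temporal mean must be > 0")

  sd_pop <- apply(x, c(1, 2), stats::sd)          # per population series
  patch_tot <- apply(x, c(2, 3), sum)             # patch x time
  unit_tot <- apply(x, c(1, 3), sum)              # unit x time

  cv <- c(s_l = sum(sd_pop) / mu,
          c_l = sum(apply(patch_tot, 1, stats::sd)) / mu,
          s_r = sum(apply(unit_tot, 1, stats::sd)) / mu,
          c_r = stats::sd(total) / mu)

  ratio <- function(num, den) {
    if (den == 0) list(value = 1, degenerate = TRUE)  # 0/0: subadditivity forbids num > 0
    else list(value = num / den, degenerate = FALSE)
  }
  r <- list(s2c_l = ratio(cv["c_l"], cv["s_l"]),
            c_l2r = ratio(cv["c_r"], cv["c_l"]),
            s_l2r = ratio(cv["s_r"], cv["s_l"]),
            s2c_r = ratio(cv["c_r"], cv["s_r"]))
  phi <- vapply(r, function(e) unname(e$value), numeric(1))
  degenerate <- vapply(r, function(e) e$degenerate, logical(1))
  if (synchrony_scale == "variance") phi <- phi^2

  structure(list(
    cv = cv,
    phi = phi,
    inv = ifelse(cv == 0, Inf, 1 / cv),
    mu = mu,
    n_units = dim(x)[1], n_patches = dim(x)[2], n_times = dim(x)[3],
    n_units_dropped = n_units_dropped,
    degenerate = degenerate,
    synchrony_scale = synchrony_scale,
    variable = variable
  ), class = "partition_result")
}

#' Invariability components of a partition result
#'
#' Recomputes the invariabilities as reciprocal CVs (`1/CV`); a CV of zero
#' maps to `+Inf` (perfectly invariant, flagged in the printed result).
#'
#' @param result A `partition_result`.
#' @return The result with its `inv` field refreshed.
#' @export
invariability <- function(result) {
  stopifnot(inherits(result, "partition_result"))
  result$inv <- ifelse(result$cv == 0, Inf, 1 / result$cv)
  result
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("# partition_result <%s>: %d unit(s) x %d patch(es) x %d time point(s)\n",
              x$variable %||% "?", x$n_units, x$n_patches, x$n_times))
  if (x$n_units_dropped > 0) {
    cat(sprintf("# %d unit(s) dropped (missing cells)\n", x$n_units_dropped))
  }
  cat("CV          :", paste(sprintf("%s=%.4f", names(x$cv), x$cv), collapse = "  "), "\n")
  cat(sprintf("synchrony   : %s  (%s scale)\n",
              paste(sprintf("%s=%.4f", names(x$phi), x$phi), collapse = "  "),
              x$synchrony_scale))
  cat("invariability:", paste(sprintf("%s=%.4f", names(x$inv), x$inv), collapse = "  "), "\n")
  if (any(x$degenerate)) {
    cat("# degenerate (0/0) synchrony reported as 1:",
        paste(names(x$degenerate)[x$degenerate], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn var_partition Tidy the twelve partition components into a
#'   long tibble with columns `component`, `statistic`, `level`, `value`.
#' @param x A `partition_result`.
#' @param ... Unused.
#' @export
tidy.partition_result <- function(x, ...) {
  lev <- c(s_l = "species_local", c_l = "community_local",
           s_r = "species_regional", c_r = "community_regional")
  phi_lab <- c(s2c_l = "species_synchrony_local",
               c_l2r = "spatial_synchrony",
               s_l2r = "spatial_synchrony_species",
               s2c_r = "species_synchrony_regional")
  bind_rows(
    tibble(component = paste0("cv_", names(x$cv)), statistic = "cv",
           level = unname(lev[names(x$cv)]), value = unname(x$cv)),
    tibble(component = paste0("inv_", names(x$inv)), statistic = "invariability",
           level = unname(lev[names(x$inv)]), value = unname(x$inv)),
    tibble(component = paste0("phi_", names(x$phi)), statistic = "synchrony",
           level = unname(phi_lab[names(x$phi)]), value = unname(x$phi))
  )
}

#' @describeIn var_partition One-row summary tibble (all components wide).
#' @export
glance.partition_result <- function(x, ...) {
  tibble(
    variable = x$variable %||% NA_character_,
    cv_s_l = x$cv[["s_l"]], cv_c_l = x$cv[["c_l"]],
    cv_s_r = x$cv[["s_r"]], cv_c_r = x$cv[["c_r"]],
    phi_s2c_l = x$phi[["s2c_l"]], phi_c_l2r = x$phi[["c_l2r"]],
    phi_s_l2r = x$phi[["s_l2r"]], phi_s2c_r = x$phi[["s2c_r"]],
    inv_s_l = x$inv[["s_l"]], inv_c_l = x$inv[["c_l"]],
    inv_s_r = x$inv[["s_r"]], inv_c_r = x$inv[["c_r"]],
    n_units = x$n_units, n_patches = x$n_patches, n_times = x$n_times,
    n_units_dropped = x$n_units_dropped,
    any_degenerate = any(x$degenerate),
    synchrony_scale = x$synchrony_scale
  )
}
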