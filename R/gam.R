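#' GAM decomposition of rewiring potential into richness and space
#'
#' Fits a penalized-spline generalised additive model of rewiring potential
#' for one trophic level: a thin-plate smooth of species richness (basis
#' size `k_richness`, default 10) plus an isotropic bivariate thin-plate
#' smooth of the cell centroid coordinates (basis size `k_spatial`, default
#' 30) controlling for spatial structure. Gaussian family with identity
#' link by default (potential lives on `[0, 1]`; a quasi/beta-style family
#' can be supplied for sensitivity analysis), smoothness selected by GCV
#' (`method = "REML"` available). Cells with `NA` potential are dropped and
#' counted.
#'
#' @param map Rewiring map tibble from [potential_map()] (columns
#'   `trophic_level`, `potential`, `richness`, `lon`, `lat`).
#' @param level Trophic level to model.
#' @param k_richness Richness smooth basis size (default 10).
#' @param k_spatial Spatial smooth basis size (default 30).
#' @param method Smoothness selection criterion passed to [mgcv::gam()]
#'   (default `"GCV.Cp"`).
#' @param family Model family (default [stats::gaussian()]).
#' @param spatial Include the spatial smooth? (default `TRUE`).
#' @return An object of class `"potential_gam"` wrapping the [mgcv::gam()]
#'   fit, with `level`, `n_dropped`, `degenerate` (constant-response flag)
#'   and `deviance_explained`.
#' @export
fit_potential_gam <- function(map, level = c("resource", "consumer"),
                              k_richness = 10, k_spatial = 30,
                              method = "GCV.Cp", family = gaussian(),
                              spatial = TRUE) {
  level <- match.arg(level)
  dat <- map[map$trophic_level == level, ]
  n_dropped <- sum(is.na(dat$potential))
  dat <- dat[!is.na(dat$potential), ]
  if (nrow(dat) < 50) {
    stop_data(sprintf("need >= 50 non-NA cells to fit, got %d", nrow(dat)))
  }
  if (var(dat$richness) == 0) {
    stop_data("richness is constant across cells; nothing to decompose")
  }
  n_uni <- length(unique(dat$richness))
  k_r <- min(k_richness, n_uni - 1)
  if (k_r < k_richness) {
    warn(sprintf("only %d unique richness values; richness basis reduced to k = %d",
                 n_uni, k_r))
  }
  degenerate <- var(dat$potential) == 0
  rhs <- sprintf("s(richness, k = %d)", k_r)
  if (spatial) rhs <- paste(rhs, sprintf("+ s(lon, lat, k = %d)", k_spatial))
  form <- stats::as.formula(paste("potential ~", rhs))
  fit <- mgcv::gam(form, data = dat, family = family, method = method)
  dev_expl <- summary(fit)$dev.expl
  if (!is.finite(dev_expl)) dev_expl <- 0
  structure(
    list(model = fit, level = level, n = nrow(dat), n_dropped = n_dropped,
         k_richness = k_r, k_spatial = if (spatial) k_spatial else NA,
         spatial = spatial, method = method,
         degenerate = degenerate, deviance_explained = dev_expl,
         richness_range = range(dat$richness)),
    class = "potential_gam"
  )
}

#' @export
print.potential_gam <- function(x, ...) {
  cat(sprintf(
    "<potential_gam> %s level, n = %d (%d NA cells dropped): deviance explained %.1f%%%s\n",
    x$level, x$n, x$n_dropped, 100 * x$deviance_explained,
    if (x$degenerate) " [degenerate: constant response]" else ""
  ))
  invisible(x)
}

#' @method glance potential_gam
#' @export
glance.potential_gam <- function(x, ...) {
  s <- summary(x$model)
  st <- s$s.table
  get_row <- function(pat, col) {
    i <- grep(pat, rownames(st), fixed = TRUE)
    if (length(i)) unname(st[i[1], col]) else NA_real_
  }
  tibble::tibble(
    level = x$level,
    deviance_explained = x$deviance_explained,
    edf_richness = get_row("s(richness)", "edf"),
    edf_spatial = get_row("s(lon,lat)", "edf"),
    p_richness = get_row("s(richness)", "p-value"),
    p_spatial = get_row("s(lon,lat)", "p-value"),
    n = x$n, n_dropped = x$n_dropped, aic = stats::AIC(x$model),
    degenerate = x$degenerate
  )
}

#' @method tidy potential_gam
#' @export
tidy.potential_gam <- function(x, ...) {
  st <- summary(x$model)$s.table
  tibble::tibble(
    term = rownames(st),
    edf = unname(st[, "edf"]),
    ref_df = unname(st[, "Ref.df"]),
    statistic = unname(st[, "F"]),
    p.value = unname(st[, "p-value"])
  )
}

#' Centered partial effect of richness on rewiring potential
#'
#' Evaluates the richness smooth of a fitted decomposition over a richness
#' grid, with pointwise standard errors. The curve is subject to the usual
#' sum-to-zero centering constraint, so it reads as a deviation from the
#' model intercept. Grid points outside the training richness range are
#' flagged as extrapolation.
#'
#' @param fit A `"potential_gam"`.
#' @param richness Evaluation grid; default: `n` equally spaced points over
#'   the training range.
#' @param n Grid length when `richness` is `NULL` (default 100).
#' @return Tibble `(richness, effect, se, extrapolated)`.
#' @export
partial_effect <- function(fit, richness = NULL, n = 100) {
  rng <- fit$richness_range
  richness <- richness %||% seq(rng[1], rng[2], length.out = n)
  nd <- data.frame(richness = richness,
                   lon = mean(fit$model$model$lon %||% 0),
                   lat = mean(fit$model$model$lat %||% 0))
  pr <- predict(fit$model, newdata = nd, type = "terms", se.fit = TRUE)
  col <- grep("s(richness)", colnames(pr$fit), fixed = TRUE)
  tibble::tibble(
    richness = richness,
    effect = unname(pr$fit[, col]),
    se = unname(pr$se.fit[, col]),
    extrapolated = richness < rng[1] | richness > rng[2]
  )
}
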