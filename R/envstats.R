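#' Average sub-surface daily light intensity
#'
#' Depth-averaged daily irradiance available to phytoplankton in the upper
#' water column,
#' \deqn{I = I_0 \frac{1 - e^{-K_d Z}}{K_d Z},}
#' with `I0` the daily incident light (E m^-2 d^-1), `Kd` the diffuse
#' attenuation coefficient for down-welling irradiance (m^-1) and `Z` the
#' sampling depth (m).
#'
#' @param i0 daily incident light, E m^-2 d^-1 (>= 0).
#' @param kd diffuse attenuation coefficient, m^-1 (> 0).
#' @param z depth, m (> 0).
#' @return Sub-surface light `I` in the units of `i0`. As `kd*z` tends to
#'   zero the value tends to `i0` (the optically thin limit), which the
#'   implementation evaluates stably.
#' @examples
#' par_subsurface(40, 0.37, 3)  # about 24.16
#' @export
par_subsurface <- function(i0, kd, z) {
  if (any(kd <= 0) || any(z <= 0)) {
    stop("kd and z must be positive", call. = FALSE)
  }
  if (any(i0 < 0)) stop("i0 must be non-negative", call. = FALSE)
  u <- kd * z
  # expm1 keeps the optically thin limit (u -> 0) accurate
  i0 * (-expm1(-u)) / u
}

#' Box-Cox transform with maximum-likelihood lambda
#'
#' Finds the power-transform parameter by profile likelihood and applies
#' `y = (x^lambda - 1)/lambda` (`y = log x` at `lambda = 0`). Environmental
#' variables with heterogeneous, skewed distributions are transformed this
#' way before PCA to approach normality.
#'
#' @param x numeric vector; values `<= 0` trigger a recorded location shift
#'   (`x + shift`) making the minimum positive.
#' @param lambda optional fixed lambda, bypassing estimation.
#' @param grid lambda search interval (profile likelihood evaluated on a
#'   fine grid inside it).
#' @return List: `y` (transformed values), `lambda`, `shift`. A constant
#'   vector has no information about lambda: it is returned untransformed
#'   with `lambda = NA` and a warning.
#' @export
boxcox_transform <- function(x, lambda = NULL, grid = c(-2, 2)) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  shift <- 0
  if (any(x <= 0)) {
    shift <- -min(x) + 1e-6 * max(diff(range(x)), 1)
    x <- x + shift
  }
  if (length(unique(x)) < 2) {
    warning("constant vector: Box-Cox lambda undefined, returning identity",
            call. = FALSE)
    return(list(y = x, lambda = NA_real_, shift = shift))
  }
  if (is.null(lambda)) {
    prof <- MASS::boxcox(x ~ 1, lambda = seq(grid[1], grid[2], by = 0.01),
                         plotit = FALSE)
    lambda <- prof$x[which.max(prof$y)]
  }
  y <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  list(y = y, lambda = lambda, shift = shift)
}

#' PCA of environmental variables
#'
#' Box-Cox transforms each variable, standardises to zero mean and unit
#' variance (correlation-matrix PCA, appropriate for variables in
#' heterogeneous units), and decomposes. Reports per-variable contributions
#' to each axis in percent (squared unit-norm loading x 100; they sum to
#' 100 per axis).
#'
#' @param env data frame from [read_env_table()] (a `date` column plus
#'   numeric variables). Rows with any missing value are dropped with a
#'   message.
#' @param boxcox apply [boxcox_transform()] per variable first (default
#'   `TRUE`).
#' @param contribution_threshold_pct contributions above this are flagged
#'   `strong` (default 10).
#' @return An `env_pca` object: list with `scores` (dates x components),
#'   `loadings`, `explained` (variance fractions), `contributions`
#'   (variables x components, percent), `strong` (logical matrix),
#'   `dates`, `lambda` (fitted Box-Cox parameters).
#' @export
pca_env <- function(env, boxcox = TRUE, contribution_threshold_pct = 10) {
  vars <- setdiff(names(env), "date")
  if (length(vars) < 1) stop("no environmental variables", call. = FALSE)
  mat <- as.matrix(env[vars])
  complete <- stats::complete.cases(mat)
  if (sum(!complete) > 0) {
    message("dropping ", sum(!complete), " date(s) with missing values")
  }
  if (sum(complete) < 3) {
    stop("fewer than 3 complete dates", call. = FALSE)
  }
  mat <- mat[complete, , drop = FALSE]
  dates <- env$date[complete]
  lambda <- rep(NA_real_, length(vars))
  names(lambda) <- vars
  if (boxcox) {
    for (j in seq_along(vars)) {
      bc <- boxcox_transform(mat[, j])
      mat[, j] <- bc$y
      lambda[j] <- bc$lambda
    }
  }
  keep <- apply(mat, 2L, stats::sd) > 0
  if (sum(keep) < 2) stop("need >= 2 non-constant variables", call. = FALSE)
  if (any(!keep)) {
    message("dropping constant variable(s): ",
            paste(vars[!keep], collapse = ", "))
  }
  mat <- mat[, keep, drop = FALSE]
  p <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  explained <- p$sdev^2 / sum(p$sdev^2)
  contributions <- 100 * p$rotation^2
  structure(list(scores = p$x, loadings = p$rotation,
                 explained = explained, contributions = contributions,
                 strong = contributions > contribution_threshold_pct,
                 dates = dates, lambda = lambda),
            class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  cat(sprintf("env_pca: %d dates, %d variables; PC1+PC2 explain %.1f%%\n",
              nrow(x$scores), nrow(x$loadings),
              100 * sum(x$explained[1:min(2, length(x$explained))])))
  invisible(x)
}

#' Ward grouping of sampling dates
#'
#' Hierarchically clusters dates on their coordinates in the first PCA
#' plane (Ward criterion on Euclidean distance) and cuts the tree into `k`
#' groups. With `k = 3` the groups typically separate spring-bloom, summer
#' and winter conditions in a temperate coastal series.
#'
#' @param pca an `env_pca` object from [pca_env()], or a numeric matrix of
#'   date coordinates.
#' @param k number of groups (default 3).
#' @param n_axes number of leading components used when `pca` is an
#'   `env_pca` (default 2, the first factorial plane).
#' @return A `season_grouping` object: list with `group` (named integer
#'   vector per date), `dates`, `hclust`.
#' @export
ward_groups <- function(pca, k = 3L, n_axes = 2L) {
  if (inherits(pca, "env_pca")) {
    scores <- pca$scores[, seq_len(min(n_axes, ncol(pca$scores))),
                         drop = FALSE]
    dates <- pca$dates
  } else {
    scores <- as.matrix(pca)
    dates <- rownames(scores)
  }
  n <- nrow(scores)
  if (k < 1 || k > n) stop("k must lie in [1, n]", call. = FALSE)
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  grp <- stats::cutree(hc, k = k)
  names(grp) <- as.character(dates)
  structure(list(group = grp, dates = dates, hclust = hc),
            class = "season_grouping")
}

#' @export
print.season_grouping <- function(x, ...) {
  cat(sprintf("season_grouping: %d dates in %d groups\n",
              length(x$group), length(unique(x$group))))
  invisible(x)
}
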