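# Longitudinal trend analysis of percent scores over repeated CT scans.
#
# Default engine: linear model with a patient-level random intercept, fit by
# REML, slope tested by a Wald test with Satterthwaite degrees of freedom.
# Alternative engine: Gaussian generalized estimating equations with an
# exchangeable working correlation and robust (cluster sandwich) standard
# errors.  Nonlinearity is assessed by a likelihood-ratio test of a natural
# cubic spline in time (3 df) against the linear model, both fit by ML.

#' Assemble a longitudinal score dataset
#'
#' Keeps patients with at least two scans, orders scans in time within
#' patient, and checks the invariants: nonnegative times, strictly
#' increasing within patient, at least two patients.
#'
#' @param data Data frame with columns `patient_id`, `time_months`,
#'   `outcome` (and optionally others, which are kept).
#' @return A validated data frame of class `longitudinal_dataset`.
#' @export
longitudinal_dataset <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("patient_id", "time_months", "outcome") %in% names(data)))
  data$patient_id <- as.character(data$patient_id)
  data <- data[order(data$patient_id, data$time_months), , drop = FALSE]
  if (any(!is.finite(data$time_months)) || any(data$time_months < 0)) {
    stop("time_months must be finite and nonnegative", call. = FALSE)
  }
  visits <- table(data$patient_id)
  keep <- names(visits)[visits >= 2L]
  dropped <- sum(visits < 2L)
  if (dropped > 0L) {
    message("dropping ", dropped, " patient(s) with a single scan")
  }
  data <- data[data$patient_id %in% keep, , drop = FALSE]
  if (length(unique(data$patient_id)) < 2L) {
    stop("need at least 2 patients with at least 2 scans each", call. = FALSE)
  }
  for (p in split(data$time_months, data$patient_id)) {
    if (any(diff(p) <= 0)) {
      stop("scan times must be strictly increasing within patient",
           call. = FALSE)
    }
  }
  rownames(data) <- NULL
  class(data) <- c("longitudinal_dataset", "data.frame")
  data
}

.apply_transform <- function(y, transform) {
  switch(transform,
         identity = y,
         sqrt = {
           if (any(y < 0)) {
             stop("sqrt transform requires nonnegative outcomes", call. = FALSE)
           }
           sqrt(y)
         },
         stop("unknown transform '", transform, "'", call. = FALSE))
}

#' Fit a longitudinal trend model
#'
#' Estimates the mean change per month of a (possibly transformed) percent
#' score across repeated scans, adjusted for repeated visits per patient.
#'
#' @param data A [longitudinal_dataset()] (or a data frame accepted by it).
#' @param transform `"identity"` or `"sqrt"`; the outcome is transformed
#'   before fitting and the fitted curve is reported on the transformed
#'   scale.
#' @param engine `"lmm"` (random-intercept linear mixed model, REML,
#'   Satterthwaite Wald test; default) or `"gee"` (exchangeable Gaussian
#'   GEE with robust standard errors).
#' @param nonlinearity If `TRUE` (default) also run [test_nonlinearity()]
#'   when enough distinct time points exist; its p-value is stored in the
#'   fit.
#' @param curve_points Number of grid points for the prediction curve.
#' @return A `trend_fit`: list with `slope`, `se`, `p_value`, `intercept`,
#'   `transform`, `engine`, `nonlinearity_p`, `curve` (data frame
#'   `time_months`, `fit`, `lower`, `upper`; 95% confidence band for the
#'   population mean), `n_patients`, `n_scans`, `sigma_residual`.
#' @examples
#' d <- data.frame(patient_id = rep(1:4, each = 3),
#'                 time_months = rep(c(0, 12, 24), 4))
#' d$outcome <- 2 + 0.5 * d$time_months
#' fit_trend(d)$slope  # 0.5
#' @export
fit_trend <- function(data, transform = c("identity", "sqrt"),
                      engine = c("lmm", "gee"), nonlinearity = TRUE,
                      curve_points = 50L) {
  transform <- match.arg(transform)
  engine <- match.arg(engine)
  if (!inherits(data, "longitudinal_dataset")) {
    data <- longitudinal_dataset(data)
  }
  y <- .apply_transform(data$outcome, transform)
  t <- data$time_months
  id <- data$patient_id

  if (engine == "lmm") {
    df <- data.frame(y = y, t = t, id = id)
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(y ~ t + (1 | id), data = df,
                                      REML = TRUE)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      # degenerate data (e.g. zero residual variance): fall back to OLS with
      # a cluster-robust Wald test so exact linear inputs are still handled
      ols <- lm(y ~ t, data = df)
      vc <- .cluster_vcov(ols, df$id)
      slope <- unname(coef(ols)[2L]); se <- sqrt(vc[2L, 2L])
      p <- 2 * pnorm(-abs(slope / se))
      est <- c(coef(ols)[1L], slope)
      vc_full <- vc
      sigma_res <- summary(ols)$sigma
      descriptor <- "ols_cluster_fallback"
    } else {
      sm <- summary(fit)$coefficients
      slope <- sm["t", "Estimate"]
      se <- sm["t", "Std. Error"]
      p <- sm["t", "Pr(>|t|)"]
      est <- lme4::fixef(fit)
      vc_full <- as.matrix(vcov(fit))
      sigma_res <- stats::sigma(fit)
      descriptor <- "random_intercept_lmm_reml"
    }
  } else {
    g <- .gee_exchangeable(y, cbind(1, t), id)
    slope <- g$beta[2L]; se <- sqrt(g$vcov[2L, 2L])
    p <- 2 * pnorm(-abs(slope / se))
    est <- g$beta
    vc_full <- g$vcov
    sigma_res <- sqrt(g$sigma2)
    descriptor <- "gee_exchangeable_robust"
  }

  nl_p <- NA_real_
  if (isTRUE(nonlinearity) && length(unique(t)) >= 5L) {
    nl_p <- tryCatch(as.numeric(test_nonlinearity(data, transform)),
                     error = function(e) NA_real_)
  }

  grid <- seq(min(t), max(t), length.out = curve_points)
  Xg <- cbind(1, grid)
  fit_mean <- drop(Xg %*% est)
  se_mean <- sqrt(rowSums((Xg %*% vc_full) * Xg))
  curve <- data.frame(time_months = grid, fit = fit_mean,
                      lower = fit_mean - 1.96 * se_mean,
                      upper = fit_mean + 1.96 * se_mean)

  structure(
    list(slope = unname(slope), se = unname(se), p_value = unname(p),
         intercept = unname(est[1L]), transform = transform, engine = engine,
         model = descriptor, nonlinearity_p = nl_p, curve = curve,
         n_patients = length(unique(id)), n_scans = length(y),
         sigma_residual = sigma_res),
    class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s scale, %s\n", x$transform, x$model))
  cat(sprintf("  slope = %.5f per month (SE %.5f, p = %.4g)\n",
              x$slope, x$se, x$p_value))
  cat(sprintf("  intercept = %.4g; %d patients, %d scans\n",
              x$intercept, x$n_patients, x$n_scans))
  if (is.finite(x$nonlinearity_p)) {
    cat(sprintf("  nonlinearity LRT p = %.4g (spline vs linear)\n",
                x$nonlinearity_p))
  }
  invisible(x)
}

#' Likelihood-ratio test for a nonlinear time trend
#'
#' Compares the linear-time random-intercept model against a natural cubic
#' spline in time with 3 degrees of freedom (knots at time quantiles), both
#' fit by maximum likelihood, against a chi-square reference with 2 df.
#'
#' @param data A [longitudinal_dataset()] (or a data frame accepted by it).
#' @param transform `"identity"` or `"sqrt"`.
#' @return The LRT p-value, with attributes `statistic` and `df`.
#' @export
test_nonlinearity <- function(data, transform = c("identity", "sqrt")) {
  transform <- match.arg(transform)
  if (!inherits(data, "longitudinal_dataset")) {
    data <- longitudinal_dataset(data)
  }
  if (length(unique(data$time_months)) < 5L) {
    stop("too few distinct time points to fit the 3-df spline basis",
         call. = FALSE)
  }
  df <- data.frame(y = .apply_transform(data$outcome, transform),
                   t = data$time_months, id = data$patient_id)
  m0 <- suppressMessages(lme4::lmer(y ~ t + (1 | id), data = df, REML = FALSE))
  m1 <- suppressMessages(lme4::lmer(y ~ splines::ns(t, df = 3) + (1 | id),
                                    data = df, REML = FALSE))
  stat <- max(0, 2 * (as.numeric(logLik(m1)) - as.numeric(logLik(m0))))
  dof <- attr(logLik(m1), "df") - attr(logLik(m0), "df")
  p <- pchisq(stat, df = dof, lower.tail = FALSE)
  structure(p, statistic = stat, df = dof)
}

# Gaussian GEE, identity link, exchangeable working correlation.
# Moment estimators for the dispersion and the common within-cluster
# correlation; robust sandwich covariance clustered on id.
.gee_exchangeable <- function(y, X, id, tol = 1e-10, max_iter = 50L) {
  id <- as.character(id)
  groups <- split(seq_along(y), id)
  p <- ncol(X)
  beta <- qr.coef(qr(X), y)  # OLS start
  n_pairs <- sum(vapply(groups, function(ix) {
    m <- length(ix); m * (m - 1) / 2
  }, 0))
  max_m <- max(lengths(groups))
  rho <- 0
  for (iter in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    sigma2 <- sum(r^2) / (length(y) - p)
    cross <- sum(vapply(groups, function(ix) {
      ri <- r[ix]
      (sum(ri)^2 - sum(ri^2)) / 2
    }, 0))
    rho_new <- if (n_pairs > p) cross / ((n_pairs - p) * sigma2) else 0
    rho_new <- min(max(rho_new, -1 / max(1, max_m - 1) + 1e-6), 0.99)
    B <- matrix(0, p, p)
    U <- matrix(0, p, 1)
    for (ix in groups) {
      m <- length(ix)
      Xi <- X[ix, , drop = FALSE]
      # V^-1 for sigma2 * ((1-rho) I + rho J) has closed form
      a <- 1 / (sigma2 * (1 - rho_new))
      b <- -rho_new * a / (1 + (m - 1) * rho_new)
      XtV <- a * t(Xi) + b * tcrossprod(colSums(Xi), rep(1, m))
      B <- B + XtV %*% Xi
      U <- U + XtV %*% y[ix]
    }
    beta_new <- solve(B, U)
    if (max(abs(beta_new - beta)) < tol && abs(rho_new - rho) < tol) {
      beta <- beta_new; rho <- rho_new
      break
    }
    beta <- beta_new; rho <- rho_new
  }
  # robust sandwich
  r <- y - drop(X %*% beta)
  sigma2 <- sum(r^2) / (length(y) - p)
  B <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (ix in groups) {
    m <- length(ix)
    Xi <- X[ix, , drop = FALSE]
    a <- 1 / (sigma2 * (1 - rho))
    b <- -rho * a / (1 + (m - 1) * rho)
    XtV <- a * t(Xi) + b * tcrossprod(colSums(Xi), rep(1, m))
    B <- B + XtV %*% Xi
    u <- XtV %*% r[ix]
    M <- M + tcrossprod(u)
  }
  Binv <- solve(B)
  list(beta = drop(beta), vcov = Binv %*% M %*% Binv, rho = rho,
       sigma2 = sigma2)
}

# cluster-robust (CR0) covariance for an lm fit
.cluster_vcov <- function(fit, id) {
  X <- stats::model.matrix(fit)
  r <- resid(fit)
  bread <- solve(crossprod(X))
  meat <- matrix(0, ncol(X), ncol(X))
  for (ix in split(seq_along(r), as.character(id))) {
    u <- crossprod(X[ix, , drop = FALSE], r[ix])
    meat <- meat + tcrossprod(u)
  }
  bread %*% meat %*% bread
}
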