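## Cervid density index and beta-regression models of diet overlap.

#' Standardized cervid density index from pellet-group counts
#'
#' Transects with fewer than 12 of the 16 plots surveyed are excluded. The
#' index pools all species classes: within each class, pellet groups are
#' divided by the class' surveyed area (each surveyed plot contributes its
#' plot area once, however many rows carry its counts) and rescaled to
#' groups per 100 m2; class densities are then summed. Transects with an
#' index above `max_index` (default 25 groups / 100 m2, > 3 SD above the
#' field mean) are removed as outliers.
#'
#' @param pellets A `pellet_counts` table.
#' @param min_plots Minimum surveyed plots per transect (default 12).
#' @param max_index Outlier removal threshold (default 25).
#' @return Data frame `transect_id`, `cervid_index`, sorted by transect.
#' @export
cervid_index <- function(pellets, min_plots = 12, max_index = 25) {
  out <- lapply(sort(unique(pellets$transect_id)), function(tr) {
    px <- pellets[pellets$transect_id == tr & pellets$surveyed, ,
                  drop = FALSE]
    n_plots <- length(unique(px$plot_id))
    if (n_plots < min_plots) return(NULL)
    dens <- 0
    for (cl in unique(px$species_class)) {
      rows <- px[px$species_class == cl, , drop = FALSE]
      area <- sum(rows$plot_area_m2[!duplicated(
        paste(rows$plot_id, rows$plot_area_m2))])
      dens <- dens + sum(rows$pellet_groups) / area * 100
    }
    data.frame(transect_id = tr, cervid_index = dens,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(data.frame(transect_id = character(),
                                      cervid_index = numeric()))
  out[out$cervid_index <= max_index, , drop = FALSE]
}

#' Compress unit-interval responses away from the boundary
#'
#' The standard adjustment `y' = (y (n - 1) + 0.5) / n` maps exact 0 and 1
#' into the open interval so the beta likelihood is defined; 0.5 is a fixed
#' point.
#'
#' @param y Values in \[0,1\].
#' @param n Sample size used for the compression (defaults to `length(y)`).
#' @return Values in (0,1).
#' @export
boundary_adjust <- function(y, n = length(y)) {
  (y * (n - 1) + 0.5) / n
}

.beta_negll <- function(theta, X, y) {
  p <- ncol(X)
  eta <- X %*% theta[seq_len(p)]
  mu <- stats::plogis(eta)
  phi <- exp(theta[p + 1])
  -sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
         (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log(1 - y))
}

## analytic score of the negative log-likelihood (logit mean, log precision)
.beta_negll_grad <- function(theta, X, y) {
  p <- ncol(X)
  eta <- as.numeric(X %*% theta[seq_len(p)])
  mu <- stats::plogis(eta)
  phi <- exp(theta[p + 1])
  ystar <- log(y) - log(1 - y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  g_beta <- phi * crossprod(X, (ystar - mustar) * mu * (1 - mu))
  g_phi <- sum(mu * (ystar - mustar) + log(1 - y) -
                 digamma((1 - mu) * phi) + digamma(phi))
  -c(as.numeric(g_beta), phi * g_phi)
}

## observed information via central differences of the analytic score
.beta_obs_info <- function(theta, X, y, h = 1e-5) {
  k <- length(theta)
  H <- matrix(NA_real_, k, k)
  for (j in seq_len(k)) {
    up <- dn <- theta
    up[j] <- up[j] + h; dn[j] <- dn[j] - h
    H[, j] <- (.beta_negll_grad(up, X, y) -
                 .beta_negll_grad(dn, X, y)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Beta regression with logit mean link and log-precision
#'
#' Models `y ~ Beta(mu phi, (1 - mu) phi)` with `logit(mu) = X beta` and a
#' constant precision `phi` estimated on the log scale. Maximum likelihood
#' by BFGS from a logit-transformed least-squares start; standard errors
#' from the inverse observed information; two-sided normal z tests; the
#' pseudo-R2 is the squared correlation between `logit(yhat)` and
#' `logit(y)`.
#'
#' @param y Response strictly inside (0,1) (see [boundary_adjust()]).
#' @param X Numeric predictor matrix or data frame (no intercept column; one
#'   is added).
#' @param max_iter Maximum optimizer iterations (default 500).
#' @return List of class `"betareg_fit"`: `coefficients` (data frame with
#'   `estimate`, `se`, `z`, `p`), `phi`, `pseudo_r2`, `logLik`, `n`,
#'   `converged`, `fitted`.
#' @export
betareg_fit <- function(y, X = NULL, max_iter = 500) {
  y <- as.numeric(y)
  if (any(y <= 0 | y >= 1))
    stop("response must lie strictly inside (0,1); apply boundary_adjust()")
  X <- if (is.null(X)) matrix(nrow = length(y), ncol = 0)
       else as.matrix(as.data.frame(X))
  Xi <- cbind(`(Intercept)` = 1, X)
  if (qr(Xi)$rank < ncol(Xi))
    stop("rank-deficient predictor matrix (duplicated or constant column?)")
  if (length(y) < ncol(Xi) + 2)
    stop("need at least p + 2 observations")
  ## start: least squares on the logit scale, moment-style phi
  z <- stats::qlogis(y)
  beta0 <- stats::lm.fit(Xi, z)$coefficients
  mu0 <- stats::plogis(Xi %*% beta0)
  v <- stats::var(y - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(v, 1e-8) - 1, 1)
  theta0 <- c(beta0, log(phi0))
  ll0 <- -.beta_negll(theta0, Xi, y)
  opt <- stats::optim(theta0, .beta_negll, gr = .beta_negll_grad,
                      X = Xi, y = y, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("beta regression did not converge (code ", opt$convergence,
         ", value ", format(opt$value), ")")
  p <- ncol(Xi)
  est <- opt$par[seq_len(p)]
  vcov <- tryCatch(solve(.beta_obs_info(opt$par, Xi, y)),
                   error = function(e) matrix(NA_real_, p + 1, p + 1))
  se <- sqrt(pmax(diag(vcov)[seq_len(p)], 0))
  zstat <- est / se
  fitted <- as.numeric(stats::plogis(Xi %*% est))
  structure(list(
    coefficients = data.frame(
      term = colnames(Xi), estimate = est, se = se, z = zstat,
      p = 2 * stats::pnorm(-abs(zstat)), stringsAsFactors = FALSE,
      row.names = NULL),
    phi = exp(opt$par[p + 1]),
    pseudo_r2 = if (stats::sd(fitted) < 1e-12) NA_real_
                else stats::cor(stats::qlogis(fitted), stats::qlogis(y))^2,
    logLik = -opt$value, logLik_start = ll0, n = length(y),
    converged = TRUE, fitted = fitted), class = "betareg_fit")
}

#' @export
print.betareg_fit <- function(x, ...) {
  cat("Beta regression (logit mean link, log precision)\n")
  cat("n =", x$n, " phi =", format(x$phi, digits = 4),
      " pseudo-R2 =", format(x$pseudo_r2, digits = 3), "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Beta-regression models of overlap per stratum
#'
#' Joins the transect-scale overlap table with the covariates and fits, for
#' every landscape x season x species (intra) or species-pair (inter)
#' stratum with at least `min_n` transects, a beta regression of the Pianka
#' index on deer density (cervid index), habitat Shannon diversity and the
#' proportion of arable land. Exact-boundary overlap values (0/1) are
#' compressed with [boundary_adjust()] only in strata that contain them.
#' Predictor pairs with |correlation| > `collinearity_limit` are flagged.
#'
#' @param overlaps An `overlap` table.
#' @param covariates A `covariates` table.
#' @param min_n Minimum observations per stratum (default 8); smaller strata
#'   are skipped with a note.
#' @param collinearity_limit Screening threshold (default 0.3).
#' @return List: `fits` (one row per stratum and term with estimates and
#'   p-values plus `phi`, `pseudo_r2`, `n`), `skipped` (strata below
#'   `min_n`), `significant` (rows with p < 0.05, a compact beta/p
#'   report), `collinearity_flags`.
#' @export
drivers_analysis <- function(overlaps, covariates, min_n = 8,
                             collinearity_limit = 0.3) {
  preds <- c("cervid_index", "habitat_shannon", "arable_prop")
  ov <- merge(overlaps, covariates, by = "transect_id")
  key <- paste(ov$landscape, ov$season, ov$kind, ov$species_a, ov$species_b,
               sep = "|")
  fits <- list(); skipped <- list()
  for (k in unique(key)) {
    rows <- ov[key == k, , drop = FALSE]
    lab <- rows[1, c("landscape", "season", "kind", "species_a",
                     "species_b")]
    if (nrow(rows) < min_n) {
      skipped[[length(skipped) + 1L]] <-
        cbind(lab, data.frame(n = nrow(rows),
                              note = "insufficient sample size"))
      next
    }
    y <- rows$pianka
    if (any(y <= 0 | y >= 1)) y <- boundary_adjust(y)
    fit <- tryCatch(betareg_fit(y, rows[, preds]), error = function(e) e)
    if (inherits(fit, "error")) {
      skipped[[length(skipped) + 1L]] <-
        cbind(lab, data.frame(n = nrow(rows), note = conditionMessage(fit)))
      next
    }
    cf <- fit$coefficients
    fits[[length(fits) + 1L]] <- cbind(
      lab[rep(1, nrow(cf)), , drop = FALSE],
      cf, data.frame(phi = fit$phi, pseudo_r2 = fit$pseudo_r2, n = fit$n))
  }
  fits <- if (length(fits)) do.call(rbind, fits) else NULL
  if (!is.null(fits)) rownames(fits) <- NULL
  cc <- stats::cor(covariates[, preds])
  flags <- which(abs(cc) > collinearity_limit & upper.tri(cc), arr.ind = TRUE)
  collin <- if (nrow(flags)) data.frame(
    var_a = preds[flags[, 1]], var_b = preds[flags[, 2]],
    correlation = cc[flags], stringsAsFactors = FALSE) else NULL
  sig <- if (!is.null(fits))
    fits[fits$term != "(Intercept)" & fits$p < 0.05, , drop = FALSE]
  else NULL
  list(fits = fits,
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
       significant = sig, collinearity_flags = collin)
}
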