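#' BayesR sampler configuration
#'
#' The four mixture components have variances equal to the given fractions
#' of the current genetic variance: 0 (null component), 1e-4, 1e-3 and 1e-2
#' by convention.
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in burn-in iterations (< n_iter).
#' @param thin keep every `thin`-th post-burn-in sample.
#' @param mixture_variance_fractions four non-negative scalars, first = 0.
#' @param dirichlet_prior four positive Dirichlet concentration parameters.
#' @param seed optional integer seed applied before sampling.
#' @return an object of class `bayesr_config`.
#' @export
bayesr_config <- function(n_iter = 10000, burn_in = 2000, thin = 10,
                          mixture_variance_fractions = c(0, 1e-4, 1e-3, 1e-2),
                          dirichlet_prior = c(1, 1, 1, 1), seed = NULL) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  f <- mixture_variance_fractions
  if (f[1] != 0 || any(f < 0)) stop("variance fractions must be non-negative with the first equal to 0")
  if (any(dirichlet_prior <= 0)) stop("dirichlet_prior must be positive")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), mixture_variance_fractions = f,
                 dirichlet_prior = dirichlet_prior, seed = seed),
            class = "bayesr_config")
}

#' Fit BayesR marker effects for one trait
#'
#' Gibbs sampler over marker effects, mixture-class indicators, mixture
#' proportions and the genetic and residual variances, with component
#' variances equal to fixed fractions of the current genetic-variance
#' parameter. Phenotypes are standardized internally and effects
#' back-transformed to the phenotype scale; dosage columns are centered
#' (which changes only the intercept).
#'
#' @param dos dosage matrix (individuals x markers), training set.
#' @param phenotypes numeric vector aligned with `dos` rows (no missing
#'   values).
#' @param config a [bayesr_config()].
#' @return an object of class `marker_effects`: list with `beta` (per-marker
#'   posterior-mean effect), `class_probs` (m x 4 posterior class
#'   memberships, rows summing to 1), `var_components` (posterior-mean genic
#'   and residual variance on the phenotype scale), `intercept` and `pi`
#'   (posterior-mean mixture proportions).
#' @export
fit_bayesr <- function(dos, phenotypes, config = bayesr_config()) {
  stopifnot(inherits(config, "bayesr_config"))
  y <- as.numeric(phenotypes)
  if (length(y) != nrow(dos)) stop("phenotype length must match dosage rows")
  if (any(!is.finite(y))) stop("phenotypes must be finite")
  if (!is.null(config$seed)) set.seed(config$seed)
  mu_y <- mean(y)
  sd_y <- sd(y)
  if (sd_y == 0) stop("phenotypes are constant")
  ys <- (y - mu_y) / sd_y
  Xc <- sweep(dos, 2, colMeans(dos))
  fit <- bayesr_gibbs_cpp(Xc, ys, config$mixture_variance_fractions,
                          config$dirichlet_prior, config$n_iter,
                          config$burn_in, config$thin)
  beta <- drop(fit$beta) * sd_y
  names(beta) <- colnames(dos)
  cp <- fit$class_probs
  rownames(cp) <- colnames(dos)
  structure(list(
    beta = beta,
    class_probs = cp,
    var_components = c(genetic = fit$genic_var * sd_y^2,
                       residual = fit$sigma_e2 * sd_y^2),
    intercept = fit$mu * sd_y + mu_y - sum(beta * colMeans(dos)),
    pi = drop(fit$pi),
    n_kept = fit$n_kept
  ), class = "marker_effects")
}

#' @export
print.marker_effects <- function(x, ...) {
  nz <- sum(x$class_probs[, 1] < 0.5)
  cat("BayesR marker effects:", length(x$beta), "markers;", nz,
      "with majority non-null class;",
      sprintf("genic var %.3f, residual var %.3f\n",
              x$var_components["genetic"], x$var_components["residual"]))
  invisible(x)
}

#' Fit marker effects for both traits
#'
#' Convenience wrapper fitting [fit_bayesr()] per trait (traits are modeled
#' independently).
#'
#' @param dos training dosage matrix.
#' @param phen data.frame from [simulate_phenotypes()] (column `id` plus one
#'   column per trait) or a numeric matrix with trait columns.
#' @param config a [bayesr_config()].
#' @return named list of `marker_effects`, one per trait.
#' @export
fit_marker_effects <- function(dos, phen, config = bayesr_config()) {
  if (is.data.frame(phen)) {
    phen <- as.matrix(phen[, setdiff(names(phen), "id"), drop = FALSE])
  }
  traits <- colnames(phen)
  if (is.null(traits)) traits <- paste0("T", seq_len(ncol(phen)))
  out <- lapply(seq_along(traits), function(t) fit_bayesr(dos, phen[, t], config))
  names(out) <- traits
  out
}

#' Predict genomic estimated breeding values
#'
#' GEBV = X' beta: the plain matrix-vector product of candidate dosages with
#' the posterior-mean marker effects (no intercept; GEBVs are compared on a
#' common relative scale).
#'
#' @param dos candidate dosage matrix (individuals x markers).
#' @param effects a `marker_effects` object, or a named list of them (one
#'   per trait).
#' @return numeric vector of GEBVs, or a matrix with one column per trait
#'   when a list is given.
#' @export
predict_gebv <- function(dos, effects) {
  if (inherits(effects, "marker_effects")) {
    if (ncol(dos) != length(effects$beta)) stop("marker sets do not align")
    return(drop(dos %*% effects$beta))
  }
  out <- vapply(effects, function(e) predict_gebv(dos, e), numeric(nrow(dos)))
  rownames(out) <- rownames(dos)
  out
}

#' GBLUP heritability estimate
#'
#' REML estimate of h2 = sigma_g2 / (sigma_g2 + sigma_e2) under
#' y = mu + g + e with g ~ N(0, G sigma_g2), via the eigendecomposition of
#' the GRM and a one-dimensional profile-likelihood search. A small ridge is
#' added to the GRM diagonal when it is numerically singular.
#'
#' @param phenotypes numeric vector over the GRM's individuals.
#' @param grm a `saf_grm` (or square matrix) over the phenotyped
#'   individuals.
#' @param ridge diagonal ridge used when the smallest eigenvalue is below
#'   the tolerance.
#' @return scalar heritability estimate in \[0, 1\].
#' @export
estimate_h2_gblup <- function(phenotypes, grm, ridge = 1e-6) {
  K <- if (inherits(grm, "saf_grm")) grm$values else grm
  y <- as.numeric(phenotypes)
  n <- length(y)
  stopifnot(nrow(K) == n)
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < 1e-8) {
    message("GRM numerically singular; adding ridge ", ridge, " to the diagonal")
    eg$values <- eg$values + ridge
  }
  d <- eg$values
  z <- drop(crossprod(eg$vectors, y))
  w <- drop(crossprod(eg$vectors, rep(1, n)))
  # REML profile log-likelihood in delta = sigma_e2 / sigma_g2
  negll <- function(logdelta) {
    delta <- exp(logdelta)
    Dv <- d + delta
    sw <- sum(w^2 / Dv)
    beta <- sum(w * z / Dv) / sw
    rss <- sum((z - beta * w)^2 / Dv)
    sg2 <- rss / (n - 1)
    0.5 * ((n - 1) * log(sg2) + sum(log(Dv)) + log(sw) + (n - 1))
  }
  opt <- optimize(negll, c(-12, 12))
  delta <- exp(opt$minimum)
  1 / (1 + delta)
}
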