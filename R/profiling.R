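# Discriminative mixture clustering of per-cycle CRP curves into
# coordination patterns, Fisher-EM style: EM for a Gaussian mixture whose
# component structure lives in a latent discriminative subspace of dimension
# min(K - 1, L) re-estimated each iteration to maximize the Fisher trace
# criterion, with full component covariances inside the subspace and common
# isotropic noise outside it. K is chosen by a BIC plateau ("elbow") rule.

#' Fit a coordination-pattern clustering model
#'
#' EM alternates (E) posterior responsibilities, (F) a discriminative
#' subspace update solving the generalized eigenproblem of the Fisher
#' criterion (between-cluster over within-cluster scatter), and (M) Gaussian
#' parameters in the latent space plus a common isotropic noise variance in
#' its orthogonal complement. The log-likelihood trace is guarded: an
#' iteration that would decrease it restores the previous parameters and
#' stops. Best of `n_init` seeded restarts by log-likelihood.
#'
#' @param curves An n x L numeric matrix of CRP curves (rows = cycles), or a
#'   tibble with a `crp` list-column (see [compute_crp()]).
#' @param K Number of clusters (>= 1).
#' @param seed Integer seed controlling all restarts.
#' @param n_init Number of seeded k-means initializations (default 10).
#' @param method `"fisher_em"` (default) or `"pca_gmm"`, a Gaussian mixture
#'   on principal components (via mclust) behind the same interface, kept as
#'   a robustness fallback.
#' @param max_iter,tol EM stopping rule: relative log-likelihood change
#'   below `tol` (default 1e-8) or `max_iter` (default 500) iterations.
#' @param ridge Ridge added to scatter/covariance matrices (default 1e-6).
#' @param fstep Subspace update. `"svd"` (default) spans the weighted
#'   cluster means (the Fisher criterion under isotropic within-scatter),
#'   which keeps all between-cluster energy inside the latent subspace;
#'   `"eig"` solves the generalized eigenproblem with the estimated
#'   within-scatter, whose sampling noise can tilt the subspace off the
#'   mean span and inflate the complement noise estimate.
#' @param cov_model Latent covariance structure: `"full"` (default, one
#'   full covariance per component) or `"common"` (one full covariance
#'   shared by all components, a more parsimonious variant useful when
#'   within-pattern variability is a shared nuisance).
#' @return An object of class `"coordination_model"` with elements `K`,
#'   `basis` (L x d orthonormal), `means`, `covs`, `weights`, `noise_var`,
#'   `center`, `loglik`, `bic`, `npar`, `n`, `seed`.
#' @export
fit_profiles <- function(curves, K, seed = 1, n_init = 10,
                         method = c("fisher_em", "pca_gmm"),
                         max_iter = 500, tol = 1e-8, ridge = 1e-6,
                         fstep = c("svd", "eig"),
                         cov_model = c("full", "common")) {
  fstep <- match.arg(fstep)
  cov_model <- match.arg(cov_model)
  method <- match.arg(method)
  X <- as_curve_matrix(curves)
  n <- nrow(X); L <- ncol(X)
  if (K < 1) abort("K must be >= 1")
  if (n <= K) abort("need more curves than clusters")
  if (anyNA(X)) abort("missing values in curves")
  n_distinct_rows <- nrow(unique(X))
  if (n_distinct_rows == 1) {
    warn("all curves identical: degenerate scatter, single effective component")
    K <- 1
  }
  if (method == "pca_gmm") {
    return(fit_profiles_pca_gmm(X, K, seed))
  }
  seeds <- split_seed(seed, n_init)
  fits <- purrr::map(seeds, function(s) {
    tryCatch(fisher_em_once(X, K, s, max_iter, tol, ridge, fstep = fstep,
                            cov_model = cov_model),
             error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) abort("all clustering restarts failed")
  best <- fits[[which.max(purrr::map_dbl(fits, "loglik"))]]
  best$seed <- seed
  best
}

as_curve_matrix <- function(curves) {
  if (is.matrix(curves)) return(curves)
  if (is.data.frame(curves) && "crp" %in% names(curves)) {
    return(crp_matrix(curves))
  }
  abort("curves must be a matrix or a tibble with a `crp` list-column")
}

fisher_em_once <- function(X, K, seed, max_iter, tol, ridge,
                           fstep = c("svd", "eig"),
                           cov_model = c("full", "common")) {
  fstep <- match.arg(fstep)
  cov_model <- match.arg(cov_model)
  n <- nrow(X); L <- ncol(X)
  d <- max(min(K - 1, L), 1)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  # initial hard responsibilities from seeded k-means (PCA fallback for K=1)
  resp <- matrix(0, n, K)
  if (K == 1) {
    resp[, 1] <- 1
  } else {
    km <- with_seed(seed, kmeans(Xc, centers = K, nstart = 5, iter.max = 50))
    resp[cbind(seq_len(n), km$cluster)] <- 1
  }
  S_tot <- crossprod(Xc) / n
  par <- NULL
  prev_ll <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    nk <- pmax(colSums(resp), 1e-8)
    # F-step: discriminative subspace from soft between/within scatter
    Mk <- crossprod(resp, Xc) / nk                    # K x L component means
    B <- crossprod(Mk * sqrt(nk / n))                 # between scatter
    Wm <- S_tot - B + ridge * diag(L)                 # within scatter
    if (K == 1) {
      U <- svd(Xc, nu = 0, nv = 1)$v                  # leading PC
    } else if (fstep == "svd") {
      # Fisher criterion under isotropic within-scatter: the subspace is
      # the span of the (weighted) cluster means, so no between-cluster
      # energy leaks into the isotropic complement
      U <- eigen(B, symmetric = TRUE)$vectors[, seq_len(d), drop = FALSE]
    } else {
      ev <- eigen(solve(Wm, B), symmetric = FALSE)
      U <- Re(ev$vectors[, seq_len(d), drop = FALSE])
      U <- qr.Q(qr(U))                                # orthonormalize
    }
    # M-step in the latent space
    Y <- Xc %*% U
    wts <- nk / n
    mu <- crossprod(resp, Y) / nk                     # K x d latent means
    res_var <- (sum(Xc^2) - sum(Y^2)) / (n * max(L - d, 1))
    res_var <- max(res_var, 1e-10)
    covs <- purrr::map(seq_len(K), function(k) {
      Yk <- sweep(Y, 2, mu[k, ])
      C <- crossprod(Yk * resp[, k], Yk) / nk[k]
      C + ridge * diag(d)
    })
    if (cov_model == "common") {
      Cbar <- Reduce(`+`, purrr::map2(covs, nk, `*`)) / sum(nk)
      covs <- replicate(K, Cbar, simplify = FALSE)
    }
    # the latent subspace models structure ABOVE the complement noise
    # floor: clamp latent eigenvalues at beta so no component profits from
    # sub-noise directions (degenerate-density guard)
    covs <- purrr::map(covs, function(C) {
      e <- eigen(C, symmetric = TRUE)
      e$vectors %*% (pmax(e$values, res_var) * t(e$vectors))
    })
    # E-step
    es <- estep_dlm(Xc, U, mu, covs, wts, res_var)
    ll_new <- es$loglik
    if (ll_new < prev_ll - abs(prev_ll) * 1e-12) {
      break  # ascent safeguard: keep previous parameters
    }
    par <- list(U = U, mu = mu, covs = covs, wts = wts, res_var = res_var)
    resp <- es$resp
    ll_trace <- c(ll_trace, ll_new)
    if (is.finite(prev_ll) &&
        abs(ll_new - prev_ll) < tol * (abs(prev_ll) + 1e-12)) {
      converged <- TRUE
      prev_ll <- ll_new
      break
    }
    prev_ll <- ll_new
  }
  L_ <- ncol(X); d_ <- ncol(par$U)
  n_cov <- if (cov_model == "common") {
    d_ * (d_ + 1) / 2
  } else {
    K * d_ * (d_ + 1) / 2
  }
  npar <- (L_ * d_ - d_ * (d_ + 1) / 2) +  # orthonormal basis
    K * d_ +                                # latent means
    n_cov +                                 # latent covariance(s)
    (K - 1) + 1                             # weights + noise variance
  structure(
    list(K = K, d = d_, basis = par$U, means = par$mu, covs = par$covs,
         weights = par$wts, noise_var = par$res_var, center = center,
         loglik = prev_ll, npar = npar, n = nrow(X), L = L_,
         bic = 2 * prev_ll - npar * log(nrow(X)),
         ll_trace = ll_trace, converged = converged, method = "fisher_em",
         cov_model = cov_model),
    class = "coordination_model"
  )
}

# Component log-densities of the subspace + isotropic complement model:
# x ~ N(U mu_k (+ center), U Sigma_k U' + noise * (I - U U')).
estep_dlm <- function(Xc, U, mu, covs, wts, noise_var) {
  n <- nrow(Xc); L <- ncol(Xc); d <- ncol(U); K <- length(wts)
  Y <- Xc %*% U
  sq_full <- rowSums(Xc^2)
  sq_proj <- rowSums(Y^2)
  resid <- pmax(sq_full - sq_proj, 0)
  logdens <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    ch <- chol(covs[[k]])
    z <- forwardsolve(t(ch), t(sweep(Y, 2, mu[k, ])))
    maha <- colSums(z^2)
    logdet <- 2 * sum(log(diag(ch)))
    logdens[, k] <- log(wts[k]) - 0.5 * (
      maha + logdet + resid / noise_var + (L - d) * log(noise_var) +
        L * log(2 * pi))
  }
  mx <- apply(logdens, 1, max)
  lse <- mx + log(rowSums(exp(logdens - mx)))
  list(resp = exp(logdens - lse), loglik = sum(lse))
}

fit_profiles_pca_gmm <- function(X, K, seed) {
  if (!requireNamespace("mclust", quietly = TRUE)) {
    abort("method 'pca_gmm' requires the mclust package")
  }
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  d <- max(min(K - 1, ncol(X)), 1)
  U <- svd(Xc, nu = 0, nv = d)$v
  Y <- Xc %*% U
  fit <- with_seed(seed, mclust::Mclust(Y, G = K, verbose = FALSE,
                                        modelNames = if (d == 1) "V" else "VVV"))
  if (is.null(fit)) abort("pca_gmm fit failed")
  covs <- purrr::map(seq_len(K), function(k) {
    if (d == 1) {
      matrix(fit$parameters$variance$sigmasq[min(k, length(fit$parameters$variance$sigmasq))], 1, 1)
    } else {
      fit$parameters$variance$sigma[, , k]
    }
  })
  structure(
    list(K = K, d = d, basis = U,
         means = t(matrix(fit$parameters$mean, nrow = d)),
         covs = covs, weights = fit$parameters$pro,
         noise_var = max((sum(Xc^2) - sum(Y^2)) / (nrow(X) * max(ncol(X) - d, 1)), 1e-10),
         center = center, loglik = fit$loglik, npar = fit$df,
         n = nrow(X), L = ncol(X), bic = fit$bic,
         converged = TRUE, method = "pca_gmm"),
    class = "coordination_model"
  )
}

#' @export
print.coordination_model <- function(x, ...) {
  cat(sprintf("Coordination clustering (%s): K = %d, latent dim %d, n = %d\n",
              x$method, x$K, x$d, x$n))
  cat(sprintf("  logLik = %.2f, BIC = %.2f\n", x$loglik, x$bic))
  invisible(x)
}

#' BIC of a fitted clustering model
#'
#' `BIC = 2 * logLik - npar * log(n)`; larger is better, so a BIC curve over
#' K rises toward a plateau at the supported number of clusters.
#'
#' @param model A fitted `"coordination_model"`.
#' @return Scalar BIC.
#' @export
model_bic <- function(model) {
  if (is.null(model$loglik)) abort("unfitted model")
  if (model$n == 0) abort("no observations")
  model$bic
}

#' Choose the number of clusters at the first BIC plateau
#'
#' The first value of the plateau along increasing K: the smallest K whose
#' successor has a lower BIC (first local maximum). If BIC increases
#' strictly throughout, the largest candidate is returned with a warning.
#'
#' @param bic_by_k Named numeric vector of BIC scores; names are the
#'   candidate K in increasing order (larger BIC = better).
#' @return The selected K (integer).
#' @examples
#' select_k(coordination_bic)  # 11
#' @export
select_k <- function(bic_by_k) {
  if (length(bic_by_k) == 0) abort("empty BIC vector")
  ks <- as.integer(names(bic_by_k) %||% seq_along(bic_by_k))
  if (is.null(names(bic_by_k))) {
    warn("unnamed BIC vector: assuming candidates K = 1, 2, ...")
  }
  if (length(bic_by_k) < 2) return(ks[1])
  drop <- which(diff(bic_by_k) < 0)
  if (length(drop) == 0) {
    warn("BIC strictly increasing over the whole range: no plateau reached")
    return(ks[length(ks)])
  }
  ks[drop[1]]
}

#' Scan candidate cluster counts and score each by BIC
#'
#' @inheritParams fit_profiles
#' @param k_range Candidate K values (default 2:16).
#' @return A list with `scores` (tibble K, loglik, bic), `models` (list of
#'   fitted models, named by K) and `k_star` (the [select_k()] choice).
#' @export
scan_k <- function(curves, k_range = 2:16, seed = 1, n_init = 10, ...) {
  X <- as_curve_matrix(curves)
  seeds <- split_seed(seed, length(k_range))
  models <- purrr::map2(k_range, seeds, function(K, s) {
    fit_profiles(X, K, seed = s, n_init = n_init, ...)
  })
  names(models) <- k_range
  bics <- purrr::map_dbl(models, model_bic)
  names(bics) <- k_range
  list(
    scores = tibble(K = k_range,
                    loglik = purrr::map_dbl(models, "loglik"),
                    bic = unname(bics)),
    models = models,
    k_star = select_k(bics)
  )
}

# Posterior responsibilities of a fitted model on (new) curves.
posterior_resp <- function(model, X) {
  Xc <- sweep(X, 2, model$center)
  estep_dlm(Xc, model$basis, model$means, model$covs, model$weights,
            model$noise_var)$resp
}

#' Assign coordination-pattern labels and build per-pattern profiles
#'
#' Maximum-posterior component per cycle, then canonical relabeling of the
#' clusters by ascending circular mean of each cluster's average CRP curve,
#' replacing the arbitrary (seed-dependent) component ordering with a
#' reproducible one. Chronological cycle order is preserved.
#'
#' @param model A fitted `"coordination_model"`.
#' @param curves The curves to label (matrix or tibble with `crp` column);
#'   if a tibble, labels are appended as a `pattern` column.
#' @return A list: `labels` (integer vector, canonical ids 1..K),
#'   `profiles` (tibble: pattern, circ_mean_deg, member_count, mean_crp
#'   list-column), and `data` (the input tibble with a `pattern` column,
#'   when a tibble was supplied).
#' @export
assign_labels <- function(model, curves) {
  X <- as_curve_matrix(curves)
  if (ncol(X) != model$L) abort("curve length does not match the model")
  resp <- posterior_resp(model, X)
  raw <- max.col(resp, ties.method = "first")
  mean_curves <- purrr::map(seq_len(model$K), function(k) {
    if (sum(raw == k) == 0) return(rep(NA_real_, ncol(X)))
    colMeans(X[raw == k, , drop = FALSE])
  })
  circ <- purrr::map_dbl(mean_curves, function(mc) {
    if (anyNA(mc)) return(Inf)   # empty clusters sort last
    circ_mean_deg(mc)
  })
  perm <- order(circ)                       # canonical order
  relabel <- match(seq_len(model$K), perm)  # old id -> canonical id
  labels <- relabel[raw]
  profiles <- tibble(
    pattern = seq_len(model$K),
    circ_mean_deg = circ[perm],
    member_count = as.integer(tabulate(labels, nbins = model$K)),
    mean_crp = mean_curves[perm]
  )
  out <- list(labels = labels, profiles = profiles)
  if (is.data.frame(curves)) {
    out$data <- mutate(curves, pattern = labels)
  }
  out
}

#' @export
tidy.coordination_model <- function(x, ...) {
  tibble(
    cluster = seq_len(x$K),
    weight = x$weights,
    size = round(x$weights * x$n)
  )
}

#' @export
glance.coordination_model <- function(x, ...) {
  tibble(K = x$K, latent_dim = x$d, n = x$n, loglik = x$loglik,
         npar = x$npar, bic = x$bic, converged = x$converged,
         method = x$method)
}
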