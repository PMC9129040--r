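#' Adaptive Metropolis-within-Gibbs posterior sampling
#'
#' Samples a [mcmc_model()] (or [build_model()] result) with blocked
#' adaptive random-walk Metropolis: each block proposes jointly from a
#' multivariate normal whose covariance is learned online (Haario-style)
#' and whose global scale is tuned by Robbins-Monro toward a 23-44%
#' acceptance rate; positive parameters move multiplicatively (log-scale
#' random walk with the Jacobian correction). Adaptation runs only during
#' burn-in. If the model exposes a gauge ridge, an extra one-dimensional
#' move travels along it. A CAR field, when present, is updated by
#' chequerboard-vectorised single-site Metropolis (cells of one colour are
#' conditionally independent), its precision by its conjugate gamma draw,
#' and the field is recentred to sum to zero each sweep with the shift
#' absorbed into the adjustment intercepts (an exactly
#' likelihood-preserving move). The per-iteration deviance is recorded for
#' every retained draw.
#'
#' @param model a `spill_model`.
#' @param n_iter iterations per chain.
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param burn_in discarded adaptation iterations (default half).
#' @param thin retention stride; default keeps at most `max_kept` draws.
#' @param seed integer seed; chains use derived streams, so results are
#'   reproducible given (`seed`, `n_chains`).
#' @param init_overrides named values overriding the model's initial state.
#' @param max_kept cap on retained draws per chain when `thin` is `NULL`.
#' @return An object of class `posterior_samples`.
#' @export
sample_posterior <- function(model, n_iter = 10000, n_chains = 2,
                             burn_in = floor(n_iter / 2), thin = NULL,
                             seed = 1, init_overrides = NULL,
                             max_kept = 5000) {
  stopifnot(inherits(model, "spill_model"))
  if (n_chains < 1) stop("need at least one chain")
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (is.null(thin))
    thin <- max(1L, ceiling((n_iter - burn_in) / max_kept))
  has_car <- !is.null(model$car)
  if (has_car && is.null(model$mu_fn))
    stop("a CAR field requires the model to expose mu_fn")

  chains <- vector("list", n_chains)
  devs <- vector("list", n_chains)
  rhos <- if (has_car) vector("list", n_chains) else NULL
  accepts <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    res <- run_chain(model, n_iter, burn_in, thin,
                     derive_seed(seed, 900 + ch), ch, init_overrides)
    chains[[ch]] <- res$par
    devs[[ch]] <- res$deviance
    if (has_car) rhos[[ch]] <- res$rho
    accepts[[ch]] <- res$acceptance
  }
  out_names <- c(model$par_names, if (has_car) "tau")
  structure(list(chains = chains, deviance = devs, rho = rhos,
                 par_names = out_names,
                 config = list(n_iter = n_iter, burn_in = burn_in,
                               thin = thin, seed = seed,
                               n_chains = n_chains),
                 acceptance = accepts, model_blocks = names(model$blocks)),
            class = "posterior_samples")
}

run_chain <- function(model, n_iter, burn_in, thin, chain_seed, chain_id,
                      init_overrides) {
  set.seed(chain_seed)
  theta <- model$init
  if (!is.null(init_overrides)) {
    bad <- setdiff(names(init_overrides), model$par_names)
    if (length(bad)) stop("unknown parameters in init_overrides: ",
                          paste(bad, collapse = ", "))
    theta[names(init_overrides)] <- unlist(init_overrides)
  }
  lsf <- model$log_scale
  # overdispersed starts for chains beyond the first; jitter scales are the
  # model's if it declares them (slopes of wide covariates need far smaller
  # jitter than intercepts)
  if (chain_id > 1) {
    jsd <- model$init_jitter %||% rep(0.3, length(theta))
    for (try in 1:25) {
      cand <- theta
      z <- stats::rnorm(length(theta), sd = jsd)
      cand[lsf] <- cand[lsf] * exp(z[lsf])
      cand[!lsf] <- cand[!lsf] + z[!lsf]
      if (is.finite(model$log_posterior(cand, if (!is.null(model$car))
        rep(0, model$car$adjacency$n)))) { theta <- cand; break }
    }
  }

  has_car <- !is.null(model$car)
  rho <- NULL; tau <- NA_real_; car_env <- NULL
  if (has_car) {
    adjc <- model$car$adjacency
    n_cells <- prod(adjc$dim)
    rho <- rep(0, n_cells)
    tau <- 1
    car_env <- prepare_car(adjc)
  }
  lp <- model$log_posterior(theta, rho)
  if (!is.finite(lp)) {
    blocks_bad <- names(model$blocks)[vapply(model$blocks, function(idx)
      any(!is.finite(theta[idx])), logical(1))]
    stop("non-finite initial log-posterior",
         if (length(blocks_bad)) paste0(" (check parameter block(s): ",
                                        paste(blocks_bad, collapse = ", "),
                                        ")"))
  }

  # per-block adaptation state
  st <- lapply(model$blocks, function(idx) {
    d <- length(idx)
    list(idx = idx, d = d, ls = log(2.38 / sqrt(d)),
         target = if (d == 1) 0.44 else if (d <= 4) 0.35 else 0.234,
         mean = numeric(d), M2 = matrix(0, d, d), t = 0L, L = NULL,
         acc = 0, n_prop = 0)
  })
  ls_gauge <- log(0.3); acc_gauge <- 0; n_gauge <- 0
  ls_car <- log(0.5); cur_mu <- if (has_car) model$mu_fn(theta) else NULL

  keep_iters <- seq.int(burn_in + thin, n_iter, by = thin)
  n_keep <- length(keep_iters)
  par_store <- matrix(NA_real_, n_keep,
                      length(model$par_names) + has_car)
  dev_store <- rep(NA_real_, n_keep)
  rho_store <- if (has_car) matrix(NA_real_, n_keep, length(rho)) else NULL
  k <- 0L

  for (iter in seq_len(n_iter)) {
    adapting <- iter <= burn_in
    gam <- min(0.1, 3 / iter^0.6)
    mu_stale <- FALSE
    for (b in seq_along(st)) {
      sb <- st[[b]]
      idx <- sb$idx
      x <- theta[idx]
      fl <- lsf[idx]
      xt <- ifelse(fl, log(x), x)
      z <- stats::rnorm(sb$d)
      step <- if (!is.null(sb$L)) as.vector(sb$L %*% z) else z
      zt <- xt + exp(sb$ls) * step
      cand <- theta
      cand[idx] <- ifelse(fl, exp(zt), zt)
      lp_c <- model$log_posterior(cand, rho)
      log_alpha <- lp_c - lp + sum(zt[fl] - xt[fl])
      a_prob <- if (is.finite(log_alpha)) min(1, exp(log_alpha)) else 0
      if (stats::runif(1) < a_prob) {
        theta <- cand; lp <- lp_c; xt <- zt; mu_stale <- TRUE
      }
      if (adapting) {
        sb$ls <- sb$ls + gam * (a_prob - sb$target)
        # skip the early transient so the learned covariance reflects the
        # target, not the approach to it
        if (iter > burn_in %/% 3) {
          sb$t <- sb$t + 1L
          d1 <- xt - sb$mean
          sb$mean <- sb$mean + d1 / sb$t
          sb$M2 <- sb$M2 + tcrossprod(d1, xt - sb$mean)
          if (sb$t >= max(50, 10 * sb$d) && sb$t %% 50 == 0) {
            C <- sb$M2 / (sb$t - 1) + diag(1e-9, sb$d)
            ch <- tryCatch(chol(C), error = function(e) NULL)
            if (!is.null(ch)) sb$L <- t(ch)
          }
        }
      }
      sb$acc <- sb$acc + a_prob; sb$n_prop <- sb$n_prop + 1L
      st[[b]] <- sb
    }

    if (!is.null(model$gauge)) {
      g <- stats::rnorm(1, sd = exp(ls_gauge))
      cand <- theta
      cand[model$gauge$scale] <- cand[model$gauge$scale] * exp(g)
      cand[model$gauge$offset] <- cand[model$gauge$offset] - g
      lp_c <- model$log_posterior(cand, rho)
      log_alpha <- lp_c - lp + length(model$gauge$scale) * g
      a_prob <- if (is.finite(log_alpha)) min(1, exp(log_alpha)) else 0
      if (stats::runif(1) < a_prob) { theta <- cand; lp <- lp_c
        mu_stale <- TRUE }
      if (adapting) ls_gauge <- ls_gauge + gam * (a_prob - 0.44)
      acc_gauge <- acc_gauge + a_prob; n_gauge <- n_gauge + 1L
    }

    if (has_car) {
      if (mu_stale || is.null(cur_mu)) cur_mu <- model$mu_fn(theta)
      up <- car_sweep(model, car_env, rho, tau, theta, cur_mu,
                      exp(ls_car))
      rho <- up$rho
      if (adapting) ls_car <- ls_car + gam * (up$acc_rate - 0.44)
      quad <- sum((rho[car_env$p1] - rho[car_env$p2])^2)
      tau <- stats::rgamma(1, shape = model$car$tau_shape +
                             (car_env$n - 1) / 2,
                           rate = model$car$tau_rate + quad / 2)
      m_shift <- mean(rho)
      rho <- rho - m_shift
      if (length(model$car$intercept_idx))
        theta[model$car$intercept_idx] <-
          theta[model$car$intercept_idx] + m_shift
      lp <- model$log_posterior(theta, rho)
      cur_mu <- model$mu_fn(theta)
    }

    if (!adapting && (iter - burn_in) %% thin == 0) {
      k <- k + 1L
      rep_theta <- if (!is.null(model$to_report)) model$to_report(theta)
                   else theta
      par_store[k, ] <- c(rep_theta, if (has_car) tau)
      if (!is.null(model$deviance))
        dev_store[k] <- model$deviance(theta, rho)
      if (has_car) rho_store[k, ] <- rho
    }
  }
  colnames(par_store) <- c(model$par_names, if (has_car) "tau")
  acc <- c(vapply(st, function(s) s$acc / max(1, s$n_prop), numeric(1)),
           if (n_gauge > 0) c(gauge = acc_gauge / n_gauge))
  list(par = par_store, deviance = dev_store, rho = rho_store,
       acceptance = acc)
}

# Precompute chequerboard colours and padded neighbour table (internal).
prepare_car <- function(adjc) {
  nr <- adjc$dim[1]; nc <- adjc$dim[2]
  n <- nr * nc
  rows <- rep(seq_len(nr), nc); cols <- rep(seq_len(nc), each = nr)
  colour <- (rows %% 2) * 2 + (cols %% 2) + 1
  colours <- split(seq_len(n), colour)
  nbr <- matrix(n + 1L, n, 8)
  cnt <- integer(n)
  for (k in seq_len(nrow(adjc$pairs))) {
    i <- adjc$pairs[k, 1]; j <- adjc$pairs[k, 2]
    cnt[i] <- cnt[i] + 1L; nbr[i, cnt[i]] <- j
    cnt[j] <- cnt[j] + 1L; nbr[j, cnt[j]] <- i
  }
  list(colours = colours, nbr = nbr, deg = adjc$n_neighbours,
       p1 = adjc$pairs[, 1], p2 = adjc$pairs[, 2], n = n)
}

car_sweep <- function(model, ce, rho, tau, theta, mu0, s_prop) {
  acc_sum <- 0; n_sum <- 0
  for (ix in ce$colours) {
    cur <- rho[ix]
    prop <- cur + stats::rnorm(length(ix), sd = s_prop)
    rho_ext <- c(rho, 0)
    nbrsum <- rowSums(matrix(rho_ext[ce$nbr[ix, , drop = FALSE]],
                             length(ix), 8))
    dll <- model$car$loglik_cell(ix, mu0[ix] * exp(prop), theta) -
      model$car$loglik_cell(ix, mu0[ix] * exp(cur), theta)
    dpr <- -tau / 2 * (ce$deg[ix] * (prop^2 - cur^2) -
                         2 * (prop - cur) * nbrsum)
    la <- dll + dpr
    ap <- pmin(1, exp(pmin(la, 0)))
    ap[!is.finite(la)] <- 0
    take <- stats::runif(length(ix)) < ap
    rho[ix][take] <- prop[take]
    acc_sum <- acc_sum + sum(ap); n_sum <- n_sum + length(ix)
  }
  list(rho = rho, acc_rate = acc_sum / n_sum)
}

#' @export
print.posterior_samples <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<posterior_samples> %d chains x %d kept draws (%d iterations, burn-in %d, thin %d)\n",
    cfg$n_chains, nrow(x$chains[[1]]), cfg$n_iter, cfg$burn_in, cfg$thin))
  cat("  parameters:", paste(utils::head(x$par_names, 8), collapse = ", "),
      if (length(x$par_names) > 8) "...", "\n")
  invisible(x)
}

#' Posterior summary table
#'
#' Mean, sd, median, central 95% credible interval and cross-chain
#' [gelman_rubin()] R-hat per parameter.
#'
#' @param object a `posterior_samples`.
#' @param ... unused.
#' @return A data frame, one row per parameter.
#' @export
summary.posterior_samples <- function(object, ...) {
  draws <- do.call(rbind, object$chains)
  out <- data.frame(
    parameter = object$par_names,
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    median = apply(draws, 2, stats::median),
    lower95 = apply(draws, 2, stats::quantile, 0.025),
    upper95 = apply(draws, 2, stats::quantile, 0.975),
    row.names = NULL)
  out$rhat <- if (length(object$chains) >= 2)
    vapply(seq_along(object$par_names), function(j)
      gelman_rubin(sapply(object$chains, function(m) m[, j])), numeric(1))
  else NA_real_
  out
}

#' @export
as.data.frame.posterior_samples <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$chains), function(ch) {
    m <- x$chains[[ch]]
    data.frame(chain = ch,
               iteration = rep(seq_len(nrow(m)), times = ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  }))
}

#' Write posterior draws and summary to disk
#'
#' Long-format CSV (`chain, iteration, parameter, value`) plus a summary
#' JSON with median, sd, 95% credible interval and R-hat per parameter.
#'
#' @param samples a `posterior_samples`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_posterior <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(samples),
                   file.path(dir, "posterior_long.csv"), row.names = FALSE)
  sm <- summary(samples)
  js <- lapply(seq_len(nrow(sm)), function(i)
    list(median = sm$median[i], sd = sm$sd[i],
         cri95 = c(sm$lower95[i], sm$upper95[i]), rhat = sm$rhat[i]))
  names(js) <- sm$parameter
  jsonlite::write_json(js, file.path(dir, "posterior_summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
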