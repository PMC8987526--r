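#' Sampler settings for the hierarchical model
#'
#' @param chains number of independent chains (default 4).
#' @param warmup burn-in iterations discarded per chain (default 1000).
#' @param iter retained iterations per chain (default 1000).
#' @param seed integer seed; fits are bit-reproducible given identical
#'   settings and seed.
#' @param mu_prior_sd standard deviation of the Normal(0, .) prior on the
#'   population mean effect `mu` (log2 scale; default 10, weakly
#'   informative).
#' @param tau_prior_scale scale of the half-Cauchy prior on the
#'   between-group spread `tau` (default 2.5).
#' @return a list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, warmup = 1000, iter = 1000, seed = 1L,
                         mu_prior_sd = 10, tau_prior_scale = 2.5) {
  stopifnot(chains >= 1, warmup >= 0, iter >= 1,
            mu_prior_sd > 0, tau_prior_scale > 0)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), seed = as.integer(seed),
                 mu_prior_sd = mu_prior_sd,
                 tau_prior_scale = tau_prior_scale),
            class = "mcmc_control")
}

#' Fit the hierarchical shrinkage model to per-group effect estimates
#'
#' Fits, independently per probe, the partial-pooling model
#' \deqn{y_j \sim N(\theta_j, \sigma_j^2), \quad \theta_j = \mu + \tau \eta_j,
#'   \quad \eta_j \sim N(0, 1)}
#' across the exposure groups \eqn{j} (all dose-by-time groups plus their
#' controls for one chemical). The group-level error \eqn{\sigma_j} is fixed
#' at the replicate standard error; `mu` has a Normal(0, `mu_prior_sd`^2)
#' prior and `tau` a half-Cauchy(`tau_prior_scale`) prior. The
#' non-centered parameterization is sampled by Gibbs updates for
#' \eqn{\eta} and \eqn{\mu} (conjugate) and an independence
#' Metropolis-Hastings update for \eqn{\tau} proposing from its truncated
#' Gaussian pseudo-conditional, so probes can be updated jointly as matrix
#' operations. Probes never share information.
#'
#' Convergence is summarized per probe by split-R-hat and effective sample
#' size on `mu` and `tau`; probes with R-hat above 1.05 are flagged in the
#' `diagnostics` table and a warning is emitted (never silenced into the
#' calls). Divergent transitions are a Hamiltonian-sampler notion and are
#' reported as `NA`.
#'
#' @param estimates tibble from [group_estimates()] restricted to one
#'   chemical: columns `probe_id`, `dose_level`, `time_value`, `time_unit`,
#'   `y`, `se` (all `se > 0`); at least two groups per probe.
#' @param mcmc an [mcmc_control()].
#' @return an object of class `hier_fit`: list with `probes`, `groups`
#'   (tibble with a `group_id` key), retained draws `theta`
#'   (array draws x probes x groups), `mu` and `tau` (draws x probes),
#'   `chain` (chain index per draw), `diagnostics`, and the settings.
#' @export
fit_hierarchical <- function(estimates, mcmc = mcmc_control()) {
  est <- tibble::as_tibble(estimates)
  need <- c("probe_id", "dose_level", "time_value", "time_unit", "y", "se")
  missing <- setdiff(need, names(est))
  if (length(missing)) stop("estimates lack column(s): ",
                            paste(missing, collapse = ", "))
  if ("chemical" %in% names(est) && length(unique(est$chemical)) > 1) {
    stop("fit_hierarchical expects estimates for a single chemical")
  }
  if (any(est$se <= 0)) stop("all standard errors must be positive")
  est$group_id <- group_id(est$dose_level, est$time_value, est$time_unit)
  groups <- dplyr::distinct(est, .data$group_id, .data$dose_level,
                            .data$time_value, .data$time_unit)
  if (nrow(groups) < 2) stop("need at least two exposure groups")
  probes <- unique(est$probe_id)
  P <- length(probes); J <- nrow(groups)
  Y <- matrix(NA_real_, P, J, dimnames = list(probes, groups$group_id))
  S <- Y
  Y[cbind(match(est$probe_id, probes), match(est$group_id, groups$group_id))] <- est$y
  S[cbind(match(est$probe_id, probes), match(est$group_id, groups$group_id))] <- est$se
  if (anyNA(Y)) stop("every probe must have an estimate in every group")

  ndraw <- mcmc$iter * mcmc$chains
  mu_d <- matrix(NA_real_, ndraw, P, dimnames = list(NULL, probes))
  tau_d <- mu_d
  # draws-last layout during sampling (contiguous slice writes); permuted
  # to draws-first once at the end
  theta_t <- array(NA_real_, c(P, J, ndraw))
  chain_idx <- rep(seq_len(mcmc$chains), each = mcmc$iter)

  prec_y <- 1 / S^2
  pooled <- rowSums(Y * prec_y) / rowSums(prec_y)
  # method-of-moments spread estimate keeps initial tau away from the
  # degenerate tau = 0 funnel mouth, where Gibbs mixing is slowest
  tau_mom <- sqrt(pmax(rowMeans((Y - pooled)^2) - rowMeans(S^2), 0)) + 0.1
  A <- mcmc$tau_prior_scale
  mu_prec0 <- 1 / mcmc$mu_prior_sd^2

  for (ch in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed + 7919L * (ch - 1L))
    # overdispersed initial values around data-driven centers
    mu <- pooled + rnorm(P, 0, 1 + apply(Y, 1, sd))
    tau <- tau_mom * exp(runif(P, -0.7, 0.7))
    eta <- matrix(rnorm(P * J), P, J)
    keep0 <- (ch - 1L) * mcmc$iter
    sum_prec <- rowSums(prec_y)
    for (it in seq_len(mcmc$warmup + mcmc$iter)) {
      # eta | mu, tau (length-P vectors recycle along rows of P x J mats)
      prec_e <- 1 + prec_y * tau^2
      mean_e <- ((Y - mu) * prec_y) * tau / prec_e
      eta <- mean_e + matrix(rnorm(P * J), P, J) / sqrt(prec_e)
      # mu | eta, tau
      resid <- Y - eta * tau
      prec_mu <- sum_prec + mu_prec0
      mean_mu <- rowSums(resid * prec_y) / prec_mu
      mu <- mean_mu + rnorm(P) / sqrt(prec_mu)
      # tau | eta, mu: Gaussian-likelihood x half-Cauchy prior, tau >= 0;
      # independence MH from the truncated-Gaussian likelihood part, so the
      # acceptance ratio reduces to the prior ratio.
      q <- pmax(rowSums(eta^2 * prec_y), 1e-12)
      t0 <- rowSums(eta * (Y - mu) * prec_y) / q
      s0 <- 1 / sqrt(q)
      plo <- pnorm(0, t0, s0)
      u <- plo + runif(P) * (1 - plo)
      prop <- qnorm(pmin(u, 1 - 1e-15), t0, s0)
      prop <- pmax(prop, 1e-12)
      log_acc <- log1p((tau / A)^2) - log1p((prop / A)^2)
      accept <- log(runif(P)) < log_acc
      tau[accept] <- prop[accept]
      # interweaving (ancillary-sufficient) step: re-update (mu, tau) under
      # the centered parameterization theta = mu + tau * eta, which mixes
      # well exactly where the non-centered updates stall (small tau), then
      # map back. Proposal for tau^2 is its inverse-gamma likelihood slice;
      # the MH correction is the half-Cauchy prior density ratio on tau^2.
      if (J >= 3) {
        theta <- mu + eta * tau
        prec_muc <- J / tau^2 + mu_prec0
        mu <- rowSums(theta) / tau^2 / prec_muc + rnorm(P) / sqrt(prec_muc)
        ss <- pmax(rowSums((theta - mu)^2), 1e-300)
        rho_prop <- ss / 2 / stats::rgamma(P, shape = J / 2 - 1)
        lp_rho <- function(r) -0.5 * log(r) - log1p(r / A^2)
        acc2 <- log(runif(P)) < lp_rho(rho_prop) - lp_rho(tau^2)
        tau[acc2] <- sqrt(rho_prop[acc2])
        tau <- pmax(tau, 1e-12)
        eta <- (theta - mu) / tau
      }
      if (it > mcmc$warmup) {
        k <- keep0 + it - mcmc$warmup
        mu_d[k, ] <- mu
        tau_d[k, ] <- tau
        theta_t[, , k] <- mu + eta * tau
      }
    }
  }

  theta_d <- aperm(theta_t, c(3, 1, 2))
  dimnames(theta_d) <- list(NULL, probes, groups$group_id)

  diagnostics <- tibble::tibble(
    probe_id = probes,
    rhat_mu = split_rhat(mu_d, chain_idx),
    rhat_tau = split_rhat(tau_d, chain_idx),
    ess_mu = apply(mu_d, 2, function(x) unname(coda::effectiveSize(x))),
    ess_tau = apply(tau_d, 2, function(x) unname(coda::effectiveSize(x))),
    divergences = NA_integer_)
  diagnostics$converged <- with(diagnostics,
    pmax(rhat_mu, rhat_tau, na.rm = TRUE) <= 1.05)
  if (any(!diagnostics$converged)) {
    warning("possible non-convergence (split R-hat > 1.05) for probe(s): ",
            paste(diagnostics$probe_id[!diagnostics$converged],
                  collapse = ", "))
  }

  structure(list(probes = probes, groups = groups, theta = theta_d,
                 mu = mu_d, tau = tau_d, chain = chain_idx,
                 diagnostics = diagnostics, mcmc = mcmc),
            class = "hier_fit")
}

#' @export
print.hier_fit <- function(x, ...) {
  cat("<hier_fit> ", length(x$probes), " probes, ", nrow(x$groups),
      " groups, ", nrow(x$mu), " retained draws (",
      x$mcmc$chains, " chains)\n", sep = "")
  if (any(!x$diagnostics$converged)) {
    cat("  ", sum(!x$diagnostics$converged),
        " probe(s) flagged for R-hat > 1.05\n", sep = "")
  }
  invisible(x)
}

#' Exposure-group key
#'
#' @param dose_level,time_value,time_unit group coordinates.
#' @return character key, e.g. `"high@24hour"`.
#' @export
group_id <- function(dose_level, time_value, time_unit) {
  paste0(dose_level, "@", time_value, time_unit)
}

split_rhat <- function(draws, chain_idx) {
  chains <- unique(chain_idx)
  halves <- list()
  for (ch in chains) {
    idx <- which(chain_idx == ch)
    h <- length(idx) %/% 2
    halves <- c(halves, list(idx[seq_len(h)], idx[h + seq_len(h)]))
  }
  n <- length(halves[[1]])
  if (n < 2) return(rep(NA_real_, ncol(draws)))
  apply(draws, 2, function(x) {
    seq_means <- vapply(halves, function(i) mean(x[i]), 0)
    seq_vars <- vapply(halves, function(i) var(x[i]), 0)
    W <- mean(seq_vars)
    B <- n * var(seq_means)
    if (W < 1e-300) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  })
}

#' Highest-density interval of a sample
#'
#' Narrowest contiguous interval containing `mass` of the draws, found by
#' scanning all windows of the sorted sample.
#'
#' @param x numeric draws.
#' @param mass probability mass to cover (default 0.95).
#' @return named numeric `c(lower, upper)`.
#' @export
hdi <- function(x, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2) return(c(lower = x[1], upper = x[1]))
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}

#' Posterior difference of a treatment group against its control
#'
#' Subtracts, draw by draw, the control-group effect from the treatment
#' group effect for every probe, giving the posterior distribution of the
#' log2 fold change, and summarizes it by the median and the
#' highest-density interval.
#'
#' @param fit a [fit_hierarchical()] result.
#' @param group treatment [group_id()] present in the fit.
#' @param control control [group_id()] present in the fit.
#' @param mass HDI mass (default 0.95).
#' @return an object of class `posterior_diff`: tibble with `probe_id`,
#'   `group_id`, `control_id`, `median`, `hdi_low`, `hdi_high`, carrying the
#'   draw matrix (draws x probes) in attribute `"draws"` and the HDI mass in
#'   attribute `"mass"`.
#' @export
posterior_difference <- function(fit, group, control, mass = 0.95) {
  stopifnot(inherits(fit, "hier_fit"))
  for (k in c(group, control)) {
    if (!k %in% fit$groups$group_id) stop("unknown group key: ", k)
  }
  d <- fit$theta[, , group, drop = FALSE] - fit$theta[, , control, drop = FALSE]
  d <- matrix(d, nrow = dim(fit$theta)[1],
              dimnames = list(NULL, fit$probes))
  hdis <- apply(d, 2, hdi, mass = mass)
  out <- tibble::tibble(
    probe_id = fit$probes,
    group_id = group,
    control_id = control,
    median = unname(apply(d, 2, median)),
    hdi_low = unname(hdis[1, ]),
    hdi_high = unname(hdis[2, ]))
  attr(out, "draws") <- d
  attr(out, "mass") <- mass
  class(out) <- c("posterior_diff", class(out))
  out
}

#' ROPE decision rule for differential expression
#'
#' Declares a probe differentially expressed only when its entire
#' highest-density interval lies outside the region of practical
#' equivalence, the band of log2 fold changes within a `fold`-fold change
#' of zero: ROPE = `[log2(1/fold), log2(fold)]`. Calls are `up` when
#' `hdi_low > log2(fold)`, `down` when `hdi_high < log2(1/fold)`, otherwise
#' `nochange` (including intervals straddling a ROPE edge).
#'
#' @param diff a [posterior_difference()] result.
#' @param fold fold-change threshold defining the ROPE (default 1.5; must
#'   exceed 1).
#' @param mass HDI mass for the decision (default 0.95); the interval is
#'   recomputed from the stored draws if it differs from the mass used when
#'   the difference was formed.
#' @return tibble of probe-level calls: `probe_id`, `group_id`,
#'   `control_id`, `call` (`up`/`down`/`nochange`), `median`, `hdi_low`,
#'   `hdi_high`, `rope_low`, `rope_high`.
#' @export
rope_call <- function(diff, fold = 1.5, mass = 0.95) {
  if (fold <= 1) stop("fold must exceed 1")
  out <- tibble::as_tibble(diff)
  if (!isTRUE(all.equal(attr(diff, "mass"), mass))) {
    draws <- attr(diff, "draws")
    if (is.null(draws)) stop("difference carries no draws to recompute HDI")
    hdis <- apply(draws, 2, hdi, mass = mass)
    out$hdi_low <- unname(hdis[1, ])
    out$hdi_high <- unname(hdis[2, ])
  }
  rope_high <- log2(fold)
  rope_low <- log2(1 / fold)
  out$call <- ifelse(out$hdi_low > rope_high, "up",
                     ifelse(out$hdi_high < rope_low, "down", "nochange"))
  out$rope_low <- rope_low
  out$rope_high <- rope_high
  out[, c("probe_id", "group_id", "control_id", "call", "median",
          "hdi_low", "hdi_high", "rope_low", "rope_high")]
}

#' Aggregate probe-level calls to gene level
#'
#' A gene is called `up` (resp. `down`) in a group when at least one of its
#' probes is called in that direction and none in the opposite direction;
#' probes disagreeing in direction yield `nochange` with `conflict = TRUE`.
#' Probes without an annotation entry are excluded and reported in the
#' `"unmapped"` attribute.
#'
#' @param probe_calls tibble of [rope_call()] results (any number of
#'   groups).
#' @param annotation tibble with columns `probe_id`, `gene`.
#' @return tibble with `gene`, `group_id`, `control_id`, `call`,
#'   `conflict`, `n_probes`, `n_up`, `n_down`, `median` (probe median of
#'   largest absolute value); unmapped probe ids in attribute
#'   `"unmapped"`.
#' @export
gene_level_calls <- function(probe_calls, annotation) {
  calls <- tibble::as_tibble(probe_calls)
  ann <- tibble::as_tibble(annotation)
  unmapped <- setdiff(calls$probe_id, ann$probe_id)
  calls <- dplyr::inner_join(calls, ann[, c("probe_id", "gene")],
                             by = "probe_id")
  grouping <- c("gene", "group_id", "control_id",
                intersect(c("chemical", "dose_level", "time_value",
                            "time_unit"), names(calls)))
  out <- calls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      n_probes = dplyr::n(),
      n_up = sum(.data$call == "up"),
      n_down = sum(.data$call == "down"),
      median = .data$median[which.max(abs(.data$median))],
      .groups = "drop") |>
    dplyr::mutate(
      conflict = .data$n_up > 0 & .data$n_down > 0,
      call = dplyr::case_when(
        .data$conflict ~ "nochange",
        .data$n_up > 0 ~ "up",
        .data$n_down > 0 ~ "down",
        TRUE ~ "nochange"))
  attr(out, "unmapped") <- unmapped
  out
}
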