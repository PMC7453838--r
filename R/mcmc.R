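#' Metropolis Monte-Carlo sampler
#'
#' Random-walk Metropolis with symmetric Gaussian proposals. Starting from
#' `init`, each iteration perturbs all parameters by independent normal
#' steps and accepts the proposal with probability `min(1, p1/p0)` where
#' `p0`, `p1` are the target probabilities of the current and proposed
#' state (worked with in log space). During burn-in the common proposal
#' scale factor is adapted every 50 iterations toward an acceptance rate of
#' 20–40%; adaptation stops at the end of burn-in so the retained chain is
#' a valid Metropolis sample.
#'
#' @param loglik function mapping a named numeric parameter vector to a
#'   log-probability; may return `-Inf` for excluded states.
#' @param init named numeric vector of starting values; `loglik(init)` must
#'   be finite.
#' @param proposal_scales numeric vector (recycled to `length(init)`) of
#'   proposal standard deviations.
#' @param n_iter total number of iterations; the first `burn_in` are
#'   discarded before summaries.
#' @param burn_in iterations to discard (default 20% of `n_iter`).
#' @param seed optional integer; identical seeds give bit-identical chains.
#' @param adapt adapt the proposal scale during burn-in (default `TRUE`).
#' @return An object of class `"chain_summary"`: retained `samples`
#'   (matrix, iteration x parameter), per-parameter `mean`, `sd`, central
#'   credible intervals `ci68` and `ci95`, the post-burn-in
#'   `acceptance_rate`, and bookkeeping (`seed`, final scales).
#' @examples
#' s <- metropolis_sample(function(p) -0.5 * p^2, c(x = 0), 1,
#'                        n_iter = 2000, seed = 1)
#' s$mean
#' @export
metropolis_sample <- function(loglik, init, proposal_scales,
                              n_iter = 10000, burn_in = floor(0.2 * n_iter),
                              seed = NULL, adapt = TRUE) {
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter)
  if (!is.null(seed)) set.seed(seed)
  npar <- length(init)
  nm <- names(init)
  if (is.null(nm)) nm <- paste0("p", seq_len(npar))
  scales <- rep_len(proposal_scales, npar)
  cur <- as.numeric(init)
  cur_ll <- loglik(stats::setNames(cur, nm))
  if (!is.finite(cur_ll))
    stop("loglik(init) is not finite; choose a feasible starting point")
  samples <- matrix(NA_real_, n_iter, npar, dimnames = list(NULL, nm))
  accepted <- logical(n_iter)
  sfac <- 1
  win_acc <- 0L; win_n <- 0L
  for (i in seq_len(n_iter)) {
    prop <- cur + stats::rnorm(npar, 0, scales * sfac)
    prop_ll <- loglik(stats::setNames(prop, nm))
    if (is.finite(prop_ll) &&
        (prop_ll >= cur_ll || log(stats::runif(1)) < prop_ll - cur_ll)) {
      cur <- prop; cur_ll <- prop_ll; accepted[i] <- TRUE
    }
    samples[i, ] <- cur
    if (adapt && i <= burn_in) {
      win_acc <- win_acc + accepted[i]; win_n <- win_n + 1L
      if (win_n == 50L) {
        rate <- win_acc / win_n
        if (rate < 0.2) sfac <- sfac * 0.7
        else if (rate > 0.4) sfac <- sfac * 1.4
        win_acc <- 0L; win_n <- 0L
      }
      ## reshape proposals to the posterior geometry (2.38/sqrt(d) rule)
      if (i %% 250L == 0L && i >= 500L) {
        sds <- apply(samples[(i - 499L):i, , drop = FALSE], 2, stats::sd)
        if (all(is.finite(sds)) && all(sds > 0)) {
          scales <- 2.38 / sqrt(npar) * sds
          sfac <- 1
        }
      }
    }
  }
  keep <- samples[(burn_in + 1):n_iter, , drop = FALSE]
  acc_rate <- mean(accepted[(burn_in + 1):n_iter])
  if (acc_rate == 0)
    stop("Metropolis chain accepted no proposal after burn-in; ",
         "reduce proposal_scales or check the likelihood")
  chain_summary(keep, acceptance_rate = acc_rate, seed = seed,
                proposal_scales = scales * sfac)
}

#' Summarise posterior samples
#'
#' @param samples matrix of samples, iteration x parameter (named columns).
#' @param acceptance_rate fraction of accepted proposals.
#' @param seed seed used for the chain, if any.
#' @param proposal_scales final proposal scales.
#' @return An object of class `"chain_summary"`.
#' @export
chain_summary <- function(samples, acceptance_rate = NA_real_, seed = NULL,
                          proposal_scales = NULL) {
  samples <- as.matrix(samples)
  q <- function(p) apply(samples, 2, stats::quantile, probs = p, names = FALSE)
  structure(list(samples = samples,
                 parameters = colnames(samples),
                 mean = colMeans(samples),
                 sd = apply(samples, 2, stats::sd),
                 ci68 = rbind(lower = q(0.16), upper = q(0.84)),
                 ci95 = rbind(lower = q(0.025), upper = q(0.975)),
                 acceptance_rate = acceptance_rate,
                 seed = seed,
                 proposal_scales = proposal_scales),
            class = "chain_summary")
}

#' @export
print.chain_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Metropolis chain: %d retained samples, acceptance %.1f%%\n",
              nrow(x$samples), 100 * x$acceptance_rate))
  tab <- data.frame(mean = x$mean, sd = x$sd,
                    ci68_lo = x$ci68["lower", ], ci68_hi = x$ci68["upper", ],
                    ci95_lo = x$ci95["lower", ], ci95_hi = x$ci95["upper", ])
  print(round(tab, digits))
  invisible(x)
}

#' Write chain samples and summary to disk
#'
#' Writes the retained samples as CSV and the per-parameter summary
#' (mean, sd, 68% and 95% central intervals, acceptance rate, seed) as JSON.
#'
#' @param chain a `"chain_summary"` object.
#' @param samples_csv,summary_json output paths (either may be `NULL` to
#'   skip).
#' @return The chain, invisibly.
#' @export
write_chain <- function(chain, samples_csv = NULL, summary_json = NULL) {
  stopifnot(inherits(chain, "chain_summary"))
  if (!is.null(samples_csv))
    utils::write.csv(as.data.frame(chain$samples), samples_csv,
                     row.names = FALSE)
  if (!is.null(summary_json)) {
    per_par <- lapply(chain$parameters, function(p) {
      list(mean = chain$mean[[p]], sd = chain$sd[[p]],
           ci68 = as.numeric(chain$ci68[, p]),
           ci95 = as.numeric(chain$ci95[, p]))
    })
    names(per_par) <- chain$parameters
    out <- list(parameters = per_par,
                acceptance_rate = chain$acceptance_rate,
                n_samples = nrow(chain$samples),
                seed = chain$seed)
    jsonlite::write_json(out, summary_json, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(chain)
}
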