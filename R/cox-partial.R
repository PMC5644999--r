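#' Cox partial log-likelihood with analytic gradient
#'
#' Breslow-approximation partial log-likelihood for right-censored data:
#' `pl(beta) = sum_events lp_i - sum_t d_t * log(sum_{j in R(t)} exp(lp_j))`
#' with risk sets `R(t)` over all subjects still under observation at each
#' distinct event time. The gradient (and, on request, the Hessian) is
#' computed analytically from risk-set weighted moments.
#'
#' @param x numeric design matrix (n x p).
#' @param time observed times.
#' @param event 0/1 event indicators; at least one event is required.
#' @param beta coefficient vector of length p.
#' @param hessian also return the (negative-definite) Hessian matrix.
#' @return list with `loglik`, `gradient`, and optionally `hessian`.
#' @export
cox_partial_loglik <- function(x, time, event, beta, hessian = FALSE) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(time), length(time) == length(event),
            ncol(x) == length(beta))
  if (sum(event) == 0) stop("partial likelihood undefined without events")
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]
  X <- x[ord, , drop = FALSE]
  lp <- drop(X %*% beta)
  w <- exp(lp)
  revcs <- function(v) rev(cumsum(rev(v)))
  S0 <- revcs(w)
  S1 <- apply(w * X, 2, revcs)
  if (is.null(dim(S1))) S1 <- matrix(S1, nrow = 1)
  first <- match(t_s, t_s)          # tie groups share one risk set
  ev <- which(e_s == 1)
  ridx <- first[ev]
  denom <- S0[ridx]
  ll <- sum(lp[ev]) - sum(log(denom))
  xbar <- S1[ridx, , drop = FALSE] / denom
  grad <- colSums(X[ev, , drop = FALSE]) - colSums(xbar)
  out <- list(loglik = ll, gradient = grad)
  if (hessian) {
    p <- ncol(X)
    H <- matrix(0, p, p)
    # risk-set second moments via reverse cumulative sums of w * x_a * x_b
    pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
    S2 <- matrix(0, nrow(X), nrow(pairs))
    for (k in seq_len(nrow(pairs)))
      S2[, k] <- revcs(w * X[, pairs[k, 1]] * X[, pairs[k, 2]])
    for (j in seq_along(ev)) {
      i <- ridx[j]
      Exx <- matrix(0, p, p)
      Exx[pairs] <- S2[i, ] / denom[j]
      Exx[pairs[, c(2, 1), drop = FALSE]] <- Exx[pairs]
      H <- H - (Exx - tcrossprod(xbar[j, ]))
    }
    out$hessian <- H
  }
  out
}

#' Unpenalized Cox fit by Newton-Raphson
#'
#' Direct maximization of the Breslow partial likelihood with analytic
#' gradient and Hessian, with step-halving when a step fails to improve the
#' objective. Serves as the independent reference fit against which the
#' penalized path at lambda = 0 is checked.
#'
#' @inheritParams cox_partial_loglik
#' @param init starting coefficients (default zero).
#' @param tol convergence tolerance on the relative change in log-likelihood.
#' @param max_iter iteration cap.
#' @return list with `coef`, `loglik`, `vcov` (inverse observed information),
#'   `iterations`, `converged`.
#' @export
cox_newton_raphson <- function(x, time, event, init = NULL,
                               tol = 1e-10, max_iter = 100) {
  x <- as.matrix(x)
  p <- ncol(x)
  beta <- if (is.null(init)) rep(0, p) else init
  cur <- cox_partial_loglik(x, time, event, beta, hessian = TRUE)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    step <- solve(cur$hessian, cur$gradient)
    halving <- 0
    repeat {
      cand <- beta - step
      new <- cox_partial_loglik(x, time, event, cand, hessian = TRUE)
      if (is.finite(new$loglik) && new$loglik >= cur$loglik - 1e-12) break
      step <- step / 2
      halving <- halving + 1
      if (halving > 30) stop("Newton-Raphson step failed to improve the likelihood")
    }
    done <- abs(new$loglik - cur$loglik) <
      tol * (abs(cur$loglik) + .Machine$double.eps)
    beta <- cand
    cur <- new
    if (done) { converged <- TRUE; break }
  }
  names(beta) <- colnames(x)
  list(coef = beta, loglik = cur$loglik, vcov = solve(-cur$hessian),
       iterations = iter, converged = converged)
}

# Breslow cumulative baseline hazard at tstar, on the scale of the supplied
# (uncentered) linear predictors. If tstar exceeds the last observed time
# the value at the last event time is returned with attribute "truncated".
breslow_cumhaz <- function(time, event, lp, tstar) {
  if (tstar <= 0) return(0)
  truncated <- tstar > max(time)
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; w <- exp(lp[ord])
  S0 <- rev(cumsum(rev(w)))
  first <- match(t_s, t_s)
  ev <- which(e_s == 1 & t_s <= tstar)
  H0 <- sum(1 / S0[first[ev]])
  if (truncated) attr(H0, "truncated") <- TRUE
  H0
}

#' Breslow baseline survival and centering constant
#'
#' Computes the two calibration constants of the centered risk
#' transformation from a fitted linear predictor: `lbar`, the cohort mean
#' linear predictor (participants evaluated under their actual randomized
#' arm), and `s0 = exp(-H0(t*) * exp(lbar))`, the baseline probability of
#' remaining event free at the horizon for a subject at the cohort mean,
#' where `H0` is the Breslow cumulative baseline hazard. Predicted risk is
#' then `1 - s0^exp(lp - lbar)`.
#'
#' @param time,event outcome columns.
#' @param lp linear predictors on the natural (uncentered) scale.
#' @param horizon horizon in years; 0 gives `s0 = 1`.
#' @return list with `s0`, `lbar`, and `truncated` (TRUE when the horizon
#'   lies beyond the last observed time and the last event time was used).
#' @export
breslow_baseline <- function(time, event, lp, horizon = 5) {
  lbar <- mean(lp)
  H0 <- breslow_cumhaz(time, event, lp, horizon)
  list(s0 = exp(-as.numeric(H0) * exp(lbar)), lbar = lbar,
       truncated = isTRUE(attr(H0, "truncated")))
}
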