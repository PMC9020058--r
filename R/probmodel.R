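#' Bernoulli deregulation model
#'
#' In the generative model behind average-score subgraph inference, each
#' node carries a binary deregulation indicator: nodes inside a latent
#' subgraph are deregulated with probability `p_prime`, nodes outside with
#' background probability `p`, independently given the subgraph, with
#' `0 < p < p_prime < 1`.
#'
#' @param p Background deregulation probability.
#' @param p_prime In-subgraph deregulation probability.
#' @return A list of class `deregulation_model`.
#' @export
deregulation_model <- function(p, p_prime) {
  if (!(p > 0 && p < p_prime && p_prime < 1)) {
    stop("model requires 0 < p < p_prime < 1", call. = FALSE)
  }
  structure(list(p = p, p_prime = p_prime), class = "deregulation_model")
}

binary_scores_or_stop <- function(scores) {
  if (!is.numeric(scores) || is.null(names(scores))) {
    stop("scores must be a named numeric vector", call. = FALSE)
  }
  if (!all(scores %in% c(0, 1))) {
    stop("scores must be binary (0/1)", call. = FALSE)
  }
  scores
}

#' Log-likelihood of binary scores given a candidate subgraph
#'
#' Independent Bernoulli likelihood: nodes in `V_sub` contribute at rate
#' `p_prime`, the rest at rate `p`.
#'
#' @param scores Named numeric vector of 0/1 scores over all nodes.
#' @param V_sub Character vector: candidate subgraph node set.
#' @param model A [deregulation_model()].
#' @return The log-likelihood (scalar).
#' @export
log_likelihood <- function(scores, V_sub, model) {
  scores <- binary_scores_or_stop(scores)
  stopifnot(all(V_sub %in% names(scores)))
  inside <- names(scores) %in% V_sub
  s <- unname(scores)
  bern <- function(s, p) s * log(p) + (1 - s) * log(1 - p)
  sum(bern(s[inside], model$p_prime)) + sum(bern(s[!inside], model$p))
}

#' Maximum-likelihood deregulation rates for a fixed subgraph
#'
#' The Bernoulli rates are estimated by the sample fractions of score-1
#' nodes inside and outside the candidate subgraph. Boundary estimates of
#' 0 or 1 are permitted (profile likelihood uses the `0 * log 0 = 0`
#' convention).
#'
#' @inheritParams log_likelihood
#' @return Named vector `c(p = ..., p_prime = ...)`.
#' @export
fit_rates <- function(scores, V_sub) {
  scores <- binary_scores_or_stop(scores)
  V_sub <- unique(as.character(V_sub))
  stopifnot(all(V_sub %in% names(scores)))
  if (length(V_sub) == 0L || length(V_sub) == length(scores)) {
    stop("subgraph must be non-empty and a proper subset of the nodes",
         call. = FALSE)
  }
  inside <- names(scores) %in% V_sub
  c(p = mean(scores[!inside]), p_prime = mean(scores[inside]))
}

xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

#' Profile log-likelihood of a candidate subgraph
#'
#' Evaluates the log-likelihood at the per-subgraph maximum-likelihood
#' rates from [fit_rates()]. When the estimated rates violate the model
#' ordering (`p_prime < p`), the constrained supremum is attained at the
#' pooled rate on both sides and the model is degenerate for this
#' subgraph; the `degenerate` attribute reports this.
#'
#' @inheritParams fit_rates
#' @return The profile log-likelihood, with attribute `degenerate`.
#' @export
profile_log_likelihood <- function(scores, V_sub) {
  scores <- binary_scores_or_stop(scores)
  rates <- fit_rates(scores, V_sub)
  inside <- names(scores) %in% V_sub
  degenerate <- rates["p_prime"] < rates["p"]
  if (degenerate) {
    pp <- mean(scores)
    p <- pp
  } else {
    pp <- rates[["p_prime"]]
    p <- rates[["p"]]
  }
  s_in <- scores[inside]
  s_out <- scores[!inside]
  ll <- sum(xlogy(s_in, pp)) + sum(xlogy(1 - s_in, 1 - pp)) +
    sum(xlogy(s_out, p)) + sum(xlogy(1 - s_out, 1 - p))
  attr(ll, "degenerate") <- unname(degenerate)
  ll
}
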