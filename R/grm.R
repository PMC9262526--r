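#' Graded response model category probabilities
#'
#' Samejima's graded response model for a single item measuring one syndrome
#' element: the cumulative probability of scoring in category k or above is
#' `plogis(a * (theta_e - b_k))`, and category probabilities are successive
#' differences of the cumulative curve. The returned vector always sums to 1.
#'
#' @param item a one-row data.frame (or list) with fields `element`, `a`, and
#'   thresholds `b1..b{K-1}`, as stored in a [generate_item_bank()] bank.
#' @param theta numeric vector of latent severities, one per element, named or
#'   ordered as the bank's elements.
#' @param elements element universe giving the position of `item$element`.
#' @return numeric vector of K category probabilities.
#' @export
response_probability <- function(item, theta, elements = syndrome_elements()) {
  if (any(!is.finite(theta))) stop_("theta must be finite")
  e <- match(item$element, elements)
  if (is.na(e)) stop_("unknown element: ", item$element)
  b <- unlist(item[grep("^b[0-9]+$", names(item))])
  b <- b[!is.na(b)]
  pstar <- stats::plogis(item$a * (theta[e] - b))
  p <- c(1, pstar) - c(pstar, 0)
  unname(p)
}

# Cumulative-curve derivatives for a set of items at a 6-vector theta.
# a: n-vector, b: n x (K-1) matrix (Inf-padded), th: n-vector theta[el].
# Returns list(P [n x K], W [n x (K-1)] = dP*/dtheta, dW = d2P*/dtheta2).
grm_curves <- function(a, b, th, second = FALSE) {
  z <- a * (th - b)
  pstar <- stats::plogis(z)
  P <- cbind(1, pstar) - cbind(pstar, 0)
  W <- a * pstar * (1 - pstar)
  out <- list(P = P, W = W)
  if (second) out$dW <- a^2 * pstar * (1 - pstar) * (1 - 2 * pstar)
  out
}

# Per-item scalar Fisher information on the item's own element, vectorized
# over items. Standard GRM expected information:
#   I(theta) = sum_k (W_{k-1} - W_k)^2 / P_k,  W_0 = W_K = 0.
element_information <- function(a, b, th) {
  cv <- grm_curves(a, b, th)
  dP <- cbind(0, cv$W) - cbind(cv$W, 0)
  num <- dP^2
  P <- cv$P
  contrib <- ifelse(P > 1e-12, num / pmax(P, 1e-300), 0)
  rowSums(contrib)
}

#' Fisher information matrix of one item
#'
#' Under between-item multidimensionality an item carries information only
#' about its own element, so the 6x6 Fisher information matrix is zero except
#' for the (e, e) entry, which equals the unidimensional graded-response
#' information at `theta[e]`.
#'
#' @inheritParams response_probability
#' @return a symmetric matrix (one row/column per element) with a single
#'   non-negative non-zero entry.
#' @export
item_information <- function(item, theta, elements = syndrome_elements()) {
  if (any(!is.finite(theta))) stop_("theta must be finite")
  e <- match(item$element, elements)
  if (is.na(e)) stop_("unknown element: ", item$element)
  b <- unlist(item[grep("^b[0-9]+$", names(item))])
  b[is.na(b)] <- Inf
  info <- element_information(item$a, matrix(b, nrow = 1), theta[e])
  M <- matrix(0, length(elements), length(elements),
              dimnames = list(elements, elements))
  M[e, e] <- info
  M
}
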