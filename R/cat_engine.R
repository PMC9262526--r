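#' Multivariate normal prior over the six latent severities
#'
#' @param mean numeric vector of prior means (default 0).
#' @param covariance symmetric positive-definite covariance matrix (default
#'   identity: independent standard-normal severities).
#' @param elements element names.
#' @return object of class `ability_prior` with `mean`, `covariance` and the
#'   cached precision matrix.
#' @export
ability_prior <- function(mean = rep(0, 6), covariance = diag(6),
                          elements = syndrome_elements()) {
  k <- length(elements)
  if (length(mean) != k) stop_("prior mean must have length ", k)
  if (!all(dim(covariance) == k)) stop_("prior covariance must be ", k, "x", k)
  if (max(abs(covariance - t(covariance))) > 1e-10)
    stop_("prior covariance must be symmetric")
  ch <- tryCatch(chol(covariance), error = function(e) NULL)
  if (is.null(ch)) stop_("prior covariance must be positive definite")
  structure(list(mean = as.numeric(mean), covariance = covariance,
                 precision = chol2inv(ch), elements = elements),
            class = "ability_prior")
}

#' CAT session configuration
#'
#' @param max_items number of answers collected before the session stops
#'   (fixed-length termination; default 20).
#' @param selection_rule `"d_optimal"` (maximize the determinant of the
#'   accumulated posterior information matrix) or `"random"`.
#' @param newton_tol gradient-norm convergence tolerance of the MAP Newton
#'   solver.
#' @param newton_max_iter Newton iteration cap.
#' @param active_items optional vector of item_ids restricting the selectable
#'   pool (e.g. a 39-item short form extracted from the full bank); default
#'   `NULL` selects from the whole bank.
#' @return object of class `cat_config`.
#' @export
cat_config <- function(max_items = 20,
                       selection_rule = c("d_optimal", "random"),
                       newton_tol = 1e-8, newton_max_iter = 100,
                       active_items = NULL) {
  selection_rule <- match.arg(selection_rule)
  if (max_items < 1) stop_("max_items must be >= 1")
  structure(list(max_items = as.integer(max_items),
                 selection_rule = selection_rule,
                 newton_tol = newton_tol,
                 newton_max_iter = as.integer(newton_max_iter),
                 active_items = active_items),
            class = "cat_config")
}

# Log-posterior, gradient and (observed) Hessian of the MAP objective for
# administered items `bm` (a bank_matrices() subset) with responses `resp`.
map_pieces <- function(bm, resp, theta, prior) {
  k <- length(prior$mean)
  g <- numeric(k)
  h <- numeric(k)  # diagonal item contributions (between-item structure)
  lp <- 0
  if (length(resp)) {
    cv <- grm_curves(bm$a, bm$b, theta[bm$el], second = TRUE)
    K <- ncol(cv$P)
    idx <- cbind(seq_along(resp), resp)
    P <- pmax(cv$P[idx], 1e-300)
    dP <- (cbind(0, cv$W) - cbind(cv$W, 0))[idx]
    d2P <- (cbind(0, cv$dW) - cbind(cv$dW, 0))[idx]
    gi <- dP / P
    hi <- d2P / P - gi^2
    lp <- sum(log(P))
    for (j in seq_along(resp)) {
      g[bm$el[j]] <- g[bm$el[j]] + gi[j]
      h[bm$el[j]] <- h[bm$el[j]] + hi[j]
    }
  }
  d <- theta - prior$mean
  pd <- prior$precision %*% d
  list(logpost = lp - 0.5 * sum(d * pd),
       grad = g - as.numeric(pd),
       hess = diag(h, k) - prior$precision)
}

#' Maximum a posteriori severity estimation
#'
#' Maximizes log-likelihood plus log-prior by Newton-Raphson started from the
#' prior mean, with step-halving when a step would decrease the log-posterior
#' and a Fisher-scoring fallback when the observed Hessian is not usable.
#' With no administered items the posterior is the prior, so the estimate is
#' the prior mean and the posterior SE the prior standard deviations.
#'
#' @param items data.frame of administered items (rows of a bank's `items`).
#' @param responses integer response categories (1..K), aligned with `items`.
#' @param prior an [ability_prior()].
#' @param config a [cat_config()] (supplies `newton_tol`, `newton_max_iter`).
#' @param elements element names.
#' @return list with `theta` (MAP estimate), `se` (posterior SEs from the
#'   inverse negative Hessian at the mode), `converged`, `iterations`.
#' @export
map_estimate <- function(items, responses, prior, config = cat_config(),
                         elements = syndrome_elements()) {
  k <- length(prior$mean)
  if (length(responses) == 0 || is.null(items) || nrow(items) == 0) {
    return(list(theta = prior$mean,
                se = sqrt(diag(prior$covariance)),
                converged = TRUE, iterations = 0L))
  }
  if (nrow(items) != length(responses))
    stop_("items and responses must be aligned")
  bank <- new_item_bank(items, elements)
  bm <- bank_matrices(bank)
  theta <- prior$mean
  pc <- map_pieces(bm, responses, theta, prior)
  converged <- FALSE
  it <- 0L
  while (it < config$newton_max_iter) {
    it <- it + 1L
    if (sqrt(sum(pc$grad^2)) < config$newton_tol) { converged <- TRUE; break }
    step <- tryCatch(solve(-pc$hess, pc$grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)) || sum(step * pc$grad) <= 0) {
      # observed Hessian unusable: Fisher scoring (expected info is PD)
      info <- numeric(k)
      ii <- element_information(bm$a, bm$b, theta[bm$el])
      for (j in seq_along(responses))
        info[bm$el[j]] <- info[bm$el[j]] + ii[j]
      step <- solve(diag(info, k) + prior$precision, pc$grad)
    }
    lambda <- 1
    repeat {
      cand <- theta + lambda * step
      pc_new <- map_pieces(bm, responses, cand, prior)
      if (is.finite(pc_new$logpost) && pc_new$logpost >= pc$logpost - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { pc_new <- pc; cand <- theta; break }
    }
    theta <- cand
    pc <- pc_new
  }
  if (!converged && sqrt(sum(pc$grad^2)) < config$newton_tol) converged <- TRUE
  if (!converged)
    warning("MAP estimation did not converge; returning best iterate")
  se <- tryCatch(sqrt(diag(solve(-pc$hess))), warning = function(w) NULL,
                 error = function(e) NULL)
  if (is.null(se) || any(!is.finite(se))) {
    info <- numeric(k)
    ii <- element_information(bm$a, bm$b, theta[bm$el])
    for (j in seq_along(responses)) info[bm$el[j]] <- info[bm$el[j]] + ii[j]
    se <- sqrt(diag(solve(diag(info, k) + prior$precision)))
  }
  names(theta) <- names(se) <- elements
  list(theta = theta, se = se, converged = converged, iterations = it)
}

#' D-optimal item selection
#'
#' Among unadministered items, returns the item_id maximizing the determinant
#' of (prior precision + information of administered items + information of
#' the candidate), all evaluated at the current severity estimate. Because
#' each item is informative about a single element, the candidate adds a
#' rank-one matrix and the determinant ratio reduces to
#' `1 + info_c * Ainv[e, e]`; ties are broken by the lowest item_id.
#'
#' @param bank a `grm_item_bank`.
#' @param administered_ids item_ids already administered.
#' @param theta_hat current severity estimate.
#' @param prior an [ability_prior()].
#' @param active_items optional item_id pool restriction.
#' @return the selected item_id.
#' @export
select_next_item <- function(bank, administered_ids, theta_hat, prior,
                             active_items = NULL) {
  ids <- bank$items$item_id
  pool <- if (is.null(active_items)) ids else intersect(ids, active_items)
  cand <- setdiff(pool, administered_ids)
  if (length(cand) == 0) stop_("no unadministered items remain")
  k <- length(prior$mean)
  A <- prior$precision
  if (length(administered_ids)) {
    bm_a <- bank_matrices(bank, match(administered_ids, ids))
    info_a <- element_information(bm_a$a, bm_a$b, theta_hat[bm_a$el])
    for (j in seq_along(info_a))
      A[bm_a$el[j], bm_a$el[j]] <- A[bm_a$el[j], bm_a$el[j]] + info_a[j]
  }
  Ainv <- solve(A)
  bm_c <- bank_matrices(bank, match(cand, ids))
  info_c <- element_information(bm_c$a, bm_c$b, theta_hat[bm_c$el])
  gain <- info_c * diag(Ainv)[bm_c$el]
  best <- cand[gain == max(gain)]
  min(best)
}

#' Administer a full adaptive test session
#'
#' Iterates select-item, collect response, re-estimate until exactly
#' `max_items` answers are collected. Responses are simulated from the graded
#' response model at `true_theta`, or supplied by `response_oracle(item)`
#' (a function receiving the one-row item data.frame and returning a category
#' in 1..K).
#'
#' @param bank a `grm_item_bank`.
#' @param true_theta latent severity vector used to simulate responses.
#' @param config a [cat_config()].
#' @param prior an [ability_prior()].
#' @param response_oracle optional response-generating function overriding
#'   simulation from `true_theta`.
#' @param seed optional integer seed making the session reproducible.
#' @return object of class `cat_result`: `theta_hat`, `posterior_se`,
#'   `administered` (ordered item_ids), `responses`, `raw_cat_score`
#'   (reporting scale, `50 + 10 * theta_hat`), `converged`.
#' @export
administer_cat <- function(bank, true_theta = NULL, config = cat_config(),
                           prior = ability_prior(), response_oracle = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(true_theta) && is.null(response_oracle))
    stop_("supply true_theta or response_oracle")
  ids <- bank$items$item_id
  pool_n <- if (is.null(config$active_items)) length(ids)
            else length(intersect(ids, config$active_items))
  if (config$max_items > pool_n)
    stop_("bank (active pool) smaller than max_items")
  administered <- integer(0)
  responses <- integer(0)
  est <- map_estimate(NULL, integer(0), prior, config, bank$elements)
  for (step in seq_len(config$max_items)) {
    next_id <- if (config$selection_rule == "d_optimal") {
      select_next_item(bank, administered, est$theta, prior,
                       config$active_items)
    } else {
      pool <- if (is.null(config$active_items)) ids
              else intersect(ids, config$active_items)
      cand <- setdiff(pool, administered)
      cand[sample.int(length(cand), 1)]
    }
    row <- bank$items[match(next_id, ids), , drop = FALSE]
    resp <- if (is.null(response_oracle)) {
      p <- response_probability(row, true_theta, bank$elements)
      sample.int(length(p), 1, prob = p)
    } else {
      as.integer(response_oracle(row))
    }
    administered <- c(administered, next_id)
    responses <- c(responses, resp)
    est <- map_estimate(bank$items[match(administered, ids), , drop = FALSE],
                        responses, prior, config, bank$elements)
  }
  structure(list(theta_hat = est$theta, posterior_se = est$se,
                 administered = administered, responses = responses,
                 raw_cat_score = 50 + 10 * est$theta,
                 converged = est$converged),
            class = "cat_result")
}

#' @export
print.cat_result <- function(x, ...) {
  cat("CAT session:", length(x$administered), "items administered\n")
  print(round(rbind(theta_hat = x$theta_hat, posterior_se = x$posterior_se,
                    score = x$raw_cat_score), 3))
  invisible(x)
}

#' Score a cohort with the CAT engine
#'
#' Convenience wrapper administering one CAT session per row of a latent
#' severity matrix; returns the matrix of raw reporting-scale scores
#' (`50 + 10 * theta_hat`) with one column per element.
#'
#' @param bank a `grm_item_bank`.
#' @param theta_matrix n x 6 matrix of latent severities.
#' @param config,prior see [administer_cat()].
#' @param seed integer seed; session i runs under `seed + i`.
#' @return n x 6 matrix of raw CAT scores.
#' @export
cat_score_matrix <- function(bank, theta_matrix, config = cat_config(),
                             prior = ability_prior(), seed = 1) {
  n <- nrow(theta_matrix)
  out <- matrix(NA_real_, n, length(bank$elements),
                dimnames = list(NULL, bank$elements))
  for (i in seq_len(n)) {
    res <- administer_cat(bank, as.numeric(theta_matrix[i, ]), config, prior,
                          seed = derive_seed(seed, i))
    out[i, ] <- res$raw_cat_score
  }
  out
}
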