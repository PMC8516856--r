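# Multivariate adaptive regression splines, self-contained.
#
# Forward pass: greedy stagewise selection of reflected hinge pairs
# max(0, x - t) / max(0, t - x) multiplied into an existing basis term
# (interaction degree capped), choosing at each step the pair with the
# lowest residual sum of squares, until the term budget is reached or the
# relative RSS improvement stalls. Backward pass: prune terms one at a time
# by generalized cross-validation (GCV).

#' Fit a MARS regression model
#'
#' @param x numeric predictor matrix.
#' @param y numeric response.
#' @param degree maximum interaction degree (default 5).
#' @param maxTerms maximum number of basis terms including the intercept
#'   (default 35).
#' @param penalty GCV cost per knot (default 3, the usual choice for
#'   interaction models).
#' @param thresh forward pass stops when the relative RSS improvement of the
#'   best candidate falls below this (default 1e-4).
#' @param maxKnots knot candidates per predictor are thinned to at most this
#'   many quantiles (default 20) to bound the search.
#' @return object of class `marsFit` with `terms` (list of hinge factors),
#'   `coefficients` and `gcv`.
#' @seealso [predict.marsFit()]
#' @export
marsFit <- function(x, y, degree = 5L, maxTerms = 35L, penalty = 3,
                    thresh = 1e-4, maxKnots = 20L) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n == length(y), n >= 4, degree >= 1, maxTerms >= 1)

  # term = list of factors; factor = (var, sign, knot); intercept = empty list
  terms <- list(list())
  B <- matrix(1, n, 1)
  rss <- sum((y - mean(y))^2)

  knotCands <- lapply(seq_len(ncol(x)), function(v) {
    u <- sort(unique(x[, v]))
    if (length(u) > maxKnots) {
      u <- unique(stats::quantile(x[, v], probs = seq(0.05, 0.95,
                                                      length.out = maxKnots),
                                  type = 7, names = FALSE))
    }
    u
  })

  evalRss <- function(Bcand) {
    fit <- stats::lm.fit(Bcand, y)
    sum(fit$residuals^2)
  }

  while (ncol(B) + 1L < maxTerms) {
    best <- NULL
    bestRss <- rss
    for (m in seq_along(terms)) {
      if (length(terms[[m]]) >= degree) next
      usedVars <- vapply(terms[[m]], `[[`, numeric(1), "var")
      parent <- B[, m]
      support <- parent != 0
      if (sum(support) < 2) next
      for (v in setdiff(seq_len(ncol(x)), usedVars)) {
        for (t in knotCands[[v]]) {
          b1 <- parent * pmax(0, x[, v] - t)
          b2 <- parent * pmax(0, t - x[, v])
          cols <- cbind(b1, b2)
          signs <- c(1, -1)
          nz <- apply(cols != 0, 2, any)
          cols <- cols[, nz, drop = FALSE]
          signs <- signs[nz]
          if (!ncol(cols)) next
          r <- evalRss(cbind(B, cols))
          if (r < bestRss) {
            bestRss <- r
            best <- list(m = m, v = v, t = t, cols = cols, signs = signs)
          }
        }
      }
    }
    if (is.null(best) || (rss - bestRss) / max(rss, 1e-12) < thresh) break
    for (s in best$signs) {
      terms[[length(terms) + 1L]] <- c(terms[[best$m]],
                                       list(list(var = best$v, sign = s,
                                                 knot = best$t)))
    }
    B <- cbind(B, best$cols)
    rss <- bestRss
  }

  gcvOf <- function(Bsub) {
    M <- ncol(Bsub)
    eff <- M + penalty * (M - 1) / 2
    if (eff >= n) return(Inf)
    fit <- stats::lm.fit(Bsub, y)
    sum(fit$residuals^2) / n / (1 - eff / n)^2
  }

  # backward pruning by GCV
  keep <- seq_along(terms)
  bestKeep <- keep
  bestGcv <- gcvOf(B)
  cur <- keep
  while (length(cur) > 1L) {
    cands <- setdiff(cur, 1L)  # intercept never pruned
    gcvs <- vapply(cands, function(drop) {
      gcvOf(B[, setdiff(cur, drop), drop = FALSE])
    }, numeric(1))
    cur <- setdiff(cur, cands[which.min(gcvs)])
    if (min(gcvs) < bestGcv) {
      bestGcv <- min(gcvs)
      bestKeep <- cur
    }
  }

  Bfin <- B[, bestKeep, drop = FALSE]
  coefs <- stats::lm.fit(Bfin, y)$coefficients
  coefs[is.na(coefs)] <- 0
  structure(list(terms = terms[bestKeep], coefficients = coefs,
                 gcv = bestGcv),
            class = "marsFit")
}

marsBasis <- function(terms, x) {
  x <- as.matrix(x)
  B <- matrix(1, nrow(x), length(terms))
  for (m in seq_along(terms)) {
    for (f in terms[[m]]) {
      h <- if (f$sign > 0) pmax(0, x[, f$var] - f$knot)
           else pmax(0, f$knot - x[, f$var])
      B[, m] <- B[, m] * h
    }
  }
  B
}

#' Predict from a MARS fit
#'
#' @param object a `marsFit`.
#' @param newdata numeric predictor matrix.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.marsFit <- function(object, newdata, ...) {
  drop(marsBasis(object$terms, newdata) %*% object$coefficients)
}
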