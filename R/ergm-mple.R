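# Maximum pseudolikelihood estimation: logistic regression of the edge
# indicators on the dyad change statistics. The pseudolikelihood replaces
# the intractable ERGM likelihood everywhere in this package.

# Shared weighted-logistic fitting path; the mixture M-step calls this with
# soft dyad weights, fit_mple with unit weights, so the G = 1 mixture
# reduces to exactly this computation.
mple_fit <- function(X, y, w = NULL) {
  w <- w %||% rep(1, length(y))
  fit <- suppressWarnings(
    glm.fit(X, y, weights = w, family = binomial(), intercept = FALSE)
  )
  cf <- coef(fit)
  eta <- as.vector(X %*% cf)
  p <- plogis(eta)
  # asymptotic covariance from the Fisher information of the weighted fit
  W <- w * p * (1 - p)
  info <- crossprod(X * sqrt(W))
  vc <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(
    coefficients = setNames(cf, colnames(X)),
    se = sqrt(diag(vc)),
    vcov = vc,
    logpl = sum(w * (y * eta - log1pexp(eta))),
    converged = fit$converged
  )
}

#' Maximum pseudolikelihood estimate of ERGM parameters
#'
#' Fits the ERGM by logistic regression of the edge indicator of every dyad
#' on that dyad's change statistics (no intercept; the `edges` term plays
#' that role). Standard errors are the usual asymptotic logistic-regression
#' ones and should be read as approximate: dyads are not independent under
#' a general ERGM.
#'
#' @param graph Undirected simple `igraph` graph with at least one edge and
#'   one non-edge.
#' @param config A [stat_config()].
#' @param weights Optional non-negative per-dyad weights in the row order of
#'   the dyad enumeration `(1,2), (1,3), ..., (n-1,n)`; used by the mixture
#'   EM for soft block assignment.
#' @return An object of class `ergm_mple` with elements `coefficients`,
#'   `se`, `vcov`, `logpl` (maximized log-pseudolikelihood), `config`, `n`,
#'   `n_dyads`, `converged`.
#' @examples
#' g <- sample_ergm(30, qlogis(0.2), stat_config("edges"), seed = 1)
#' fit <- fit_mple(g, stat_config("edges"))
#' coef(fit)
#' @export
fit_mple <- function(graph, config = stat_config(), weights = NULL) {
  graph <- check_cell_graph(graph)
  A <- graph_adjacency(graph)
  n <- nrow(A)
  n_edges <- sum(A) / 2
  n_dyads <- n * (n - 1) / 2
  if (n_edges == 0) {
    abort("Empty graph: pseudolikelihood is separated (no edges to fit).")
  }
  if (n_edges == n_dyads) {
    abort("Complete graph: pseudolikelihood is separated (no non-edges).")
  }
  dd <- dyad_design(A, config)
  if (!is.null(weights)) {
    if (length(weights) != n_dyads || any(weights < 0)) {
      abort("`weights` must be non-negative with one entry per dyad.")
    }
  }
  fit <- mple_fit(dd$X, dd$y, weights)
  structure(
    c(fit, list(config = config, n = n, n_dyads = n_dyads)),
    class = "ergm_mple"
  )
}

#' @export
coef.ergm_mple <- function(object, ...) object$coefficients

#' @export
vcov.ergm_mple <- function(object, ...) object$vcov

#' @export
logLik.ergm_mple <- function(object, ...) {
  structure(object$logpl, df = length(object$coefficients),
            class = "logLik")
}

#' @export
print.ergm_mple <- function(x, ...) {
  cat(sprintf("<ergm_mple> n = %d nodes, %d dyads, log-PL = %.3f\n",
              x$n, x$n_dyads, x$logpl))
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @describeIn fit_mple Tidy the coefficient table (one row per term).
#' @param x,object An `ergm_mple` fit.
#' @param ... Unused.
#' @export
tidy.ergm_mple <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$coefficients / x$se),
    p.value = 2 * pnorm(-abs(unname(x$coefficients / x$se)))
  )
}

#' @describeIn fit_mple One-row model summary.
#' @export
glance.ergm_mple <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_dyads = x$n_dyads, logPL = x$logpl,
    n_terms = length(x$coefficients), converged = x$converged
  )
}
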