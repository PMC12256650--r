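#' Ordinary least squares fit with R-squared
#'
#' Backed by [stats::lm()]; the test suite checks it against the closed-form
#' normal-equation solution. The slope is reported signed, with its
#' magnitude alongside, since loss-per-loss rates are usually quoted as
#' magnitudes.
#'
#' @param x,y equal-length numeric vectors, n >= 3, x not constant
#' @return object of class `regression_result`: list with `slope`,
#'   `intercept`, `slope_magnitude`, `r_squared`, `n`, `residual_se`
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::var(x) == 0) stop("x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ## R^2 and sigma computed directly: summary.lm warns on perfect fits
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 slope_magnitude = abs(unname(stats::coef(fit)[2L])),
                 r_squared = 1 - ss_res / ss_tot,
                 n = n,
                 residual_se = sqrt(ss_res / (n - 2L))),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): slope %.4g, intercept %.4g, R^2 = %.3f\n",
              x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
as_report_payload.regression_result <- function(x, ...) unclass(x)

#' Spearman partial rank correlation controlling one covariate
#'
#' All three series are rank-transformed (average ranks for ties), then the
#' first-order Pearson partial correlation
#' \deqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}}
#' is computed on the ranks. The two-sided p-value comes from a t statistic
#' with n - 3 degrees of freedom — the common SPSS-style convention. If the
#' covariate is constant after ranking the function falls back to a plain
#' Spearman correlation (df = n - 2) with a warning.
#'
#' @param x,y,covariate equal-length numeric vectors, n >= 4
#' @return object of class `partial_corr_result`: list with `coefficient`,
#'   `n`, `covariate`, `p_value`, `method`
#' @export
spearman_partial <- function(x, y, covariate) {
  n <- length(x)
  if (length(y) != n || length(covariate) != n) {
    stop("x, y and covariate must have equal length", call. = FALSE)
  }
  if (n < 4L) stop("need n >= 4", call. = FALSE)
  cov_label <- deparse(substitute(covariate))
  rx <- rank(x); ry <- rank(y); rz <- rank(covariate)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) stop("x or y is constant", call. = FALSE)

  if (stats::var(rz) == 0) {
    warning("covariate is constant after ranking; falling back to plain Spearman",
            call. = FALSE)
    r <- stats::cor(rx, ry)
    df <- n - 2L
    method <- "spearman"
  } else {
    rxy <- stats::cor(rx, ry); rxz <- stats::cor(rx, rz); ryz <- stats::cor(ry, rz)
    r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    df <- n - 3L
    method <- "spearman_partial"
  }
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tstat), df)
  }
  structure(list(coefficient = r, n = n, covariate = cov_label,
                 p_value = p, method = method),
            class = "partial_corr_result")
}

#' @export
print.partial_corr_result <- function(x, ...) {
  cat(sprintf("%s (n = %d, controlling %s): coefficient = %.3f, P = %.3g\n",
              x$method, x$n, x$covariate, x$coefficient, x$p_value))
  invisible(x)
}

#' @export
as_report_payload.partial_corr_result <- function(x, ...) unclass(x)

#' Benjamini-Hochberg step-up adjustment
#'
#' Hand-implemented step-up procedure; the test suite checks it against
#' [stats::p.adjust()].
#'
#' @param p vector of p-values in (0, 1]
#' @return q-values in the input order
#' @export
bh_adjust <- function(p) {
  if (any(p <= 0 | p > 1 | is.na(p))) stop("p-values must lie in (0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * p[o]))
  q[order(o)]
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric probability P(X >= k) per term, where k is the
#' overlap of the query set with the term's gene set, K the term size, n the
#' query size and N the universe size; BH-adjusted q-values alongside.
#' Results are sorted by increasing p (ties kept in term order).
#'
#' @param gene_set character vector, a subset of `universe`
#' @param annotations named list: term -> character vector of genes (all in
#'   `universe`)
#' @param universe character vector of all genes considered
#' @return data.frame of class `enrichment_result` with columns `term`, `k`,
#'   `K`, `n`, `N`, `p`, `q`
#' @export
hypergeom_enrich <- function(gene_set, annotations, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  stray <- setdiff(gene_set, universe)
  if (length(stray)) stop("gene_set not a subset of universe: ",
                          paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  stray <- setdiff(unique(unlist(annotations)), universe)
  if (length(stray)) stop("annotated gene(s) outside universe: ",
                          paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  gene_set <- unique(gene_set)
  N <- length(universe); n <- length(gene_set)
  K <- vapply(annotations, function(g) length(unique(g)), integer(1))
  k <- vapply(annotations, function(g) length(intersect(gene_set, unique(g))), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = names(annotations), k = k, K = K, n = n, N = N,
                    p = p, q = bh_adjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' Significantly enriched terms at an FDR cut
#' @param enrichment an `enrichment_result`
#' @param fdr q-value threshold (default 0.05)
#' @return the rows with `q < fdr`
#' @export
enriched_terms <- function(enrichment, fdr = 0.05) {
  stopifnot(inherits(enrichment, "enrichment_result"))
  enrichment[enrichment$q < fdr, , drop = FALSE]
}
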