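# Chance-corrected inter-rater agreement for ordinal scales.

#' Cohen's weighted kappa for two raters
#'
#' Linearly weighted kappa over an ordered category set: with category ranks
#' \eqn{i, j} and \eqn{K} categories, agreement weights are
#' \eqn{w_{ij} = 1 - |i - j| / (K - 1)}, observed weighted agreement
#' \eqn{P_o} is the weighted cell mass of the cross-classification, expected
#' agreement \eqn{P_e} the weighted product of the observed marginals, and
#' \eqn{\kappa = (P_o - P_e)/(1 - P_e)}. With two categories the linear
#' weights degenerate and the statistic equals unweighted Cohen's kappa.
#'
#' When the two raters use a single identical category throughout,
#' \eqn{P_e = 1} and kappa is undefined; the result then carries
#' `kappa = NA` and `undefined = TRUE`.
#'
#' @param a,b Rating vectors of equal length, values drawn from `categories`.
#' @param categories Ordered vector of allowed categories; defaults to the
#'   sorted union of observed ratings.
#' @param weighting Only `"linear"` is implemented.
#' @return A `kappa_result` list: `kappa`, `weighting`, `n`, `categories`,
#'   `po`, `pe`, `undefined`.
#' @examples
#' weighted_kappa(c(1, 1, 2, 3), c(1, 2, 2, 3), categories = 1:3)  # 0.714
#' @export
weighted_kappa <- function(a, b, categories = NULL, weighting = "linear") {
  weighting <- match.arg(weighting, "linear")
  if (length(a) != length(b))
    stop("rating sequences must have equal length")
  if (length(a) < 1) stop("at least one rating pair is required")
  if (is.null(categories)) categories <- sort(unique(c(a, b)))
  if (!all(a %in% categories) || !all(b %in% categories))
    stop("ratings outside the category set")

  K <- length(categories)
  ia <- match(a, categories)
  ib <- match(b, categories)
  w <- if (K == 1) matrix(1, 1, 1) else
    1 - abs(outer(seq_len(K), seq_len(K), "-")) / (K - 1)

  n <- length(a)
  tab <- table(factor(ia, levels = seq_len(K)),
               factor(ib, levels = seq_len(K))) / n
  po <- sum(w * tab)
  pe <- sum(w * outer(rowSums(tab), colSums(tab)))

  undefined <- abs(1 - pe) < 1e-12
  kappa <- if (undefined) NA_real_ else (po - pe) / (1 - pe)

  structure(list(kappa = kappa, weighting = weighting, n = n,
                 categories = categories, po = po, pe = pe,
                 undefined = undefined),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("Weighted kappa undefined (degenerate marginals), n = %d\n",
                x$n))
  } else {
    cat(sprintf("Cohen's %s weighted kappa = %.3f (n = %d, %d categories)\n",
                x$weighting, x$kappa, x$n, length(x$categories)))
  }
  invisible(x)
}
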