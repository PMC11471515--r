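#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (`stats::p.adjust(method = "BH")`): sort
#' ascending, `adj_(i) = min over j >= i of p_(j) * m / j`, capped at 1,
#' returned in input order. `method = "bonferroni"` is offered as the more
#' stringent family-wise alternative.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return adjusted p-values in input order.
#' @export
bh_fdr <- function(pvals, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (!length(pvals)) return(numeric(0))
  stopifnot(is.numeric(pvals), all(pvals > 0), all(pvals <= 1))
  stats::p.adjust(pvals, method = method)
}

#' Significance tiering of screen results
#'
#' Pairs raw and FDR-adjusted p-values into tiers: `significant` when the
#' adjusted p-value is below 0.05; `suggestive` when the raw p-value is
#' below 0.05 but the adjusted one is not; `none` otherwise.
#'
#' @param raw raw p-values.
#' @param adjusted FDR-adjusted p-values, same length and order.
#' @param alpha significance level (default 0.05).
#' @return data.frame `raw_p`, `fdr_p`, `tier`.
#' @export
assign_tiers <- function(raw, adjusted, alpha = 0.05) {
  if (length(raw) != length(adjusted)) {
    stop("assign_tiers: raw and adjusted p-value vectors differ in length")
  }
  tier <- ifelse(adjusted < alpha, "significant",
                 ifelse(raw < alpha, "suggestive", "none"))
  data.frame(raw_p = raw, fdr_p = adjusted, tier = tier,
             stringsAsFactors = FALSE)
}
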