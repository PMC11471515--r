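#' Construct a GWAS summary-statistic dataset for one trait
#'
#' A `trait_dataset` holds one variant-level association record per SNP for a
#' single trait: alleles, effect-allele frequency, per-allele effect (`beta`,
#' in SD units for continuous traits or log-odds for binary traits), its
#' standard error, p-value and sample size.
#'
#' Validation enforces: single-nucleotide alleles with
#' `effect_allele != other_allele`, `se > 0`, `eaf` in \[0, 1\], `pval` in
#' (0, 1\], `n > 0`, and unique `variant_id`. The consistency of `pval` with
#' `beta/se` under the two-sided normal approximation is checked softly (a
#' warning when they disagree by more than a factor of ten).
#'
#' @param x data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @param trait_name character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param check_pval logical; run the soft beta/se vs p consistency check.
#'
#' @return A data.frame of class `trait_dataset` with attributes
#'   `trait_name` and `trait_type`.
#' @export
trait_dataset <- function(x, trait_name, trait_type = c("continuous", "binary"),
                          check_pval = TRUE) {
  trait_type <- match.arg(trait_type)
  req <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("trait_dataset: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x)[req]
  x$variant_id <- as.character(x$variant_id)
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) x[[col]] <- as.numeric(x[[col]])
  x$n <- as.numeric(x$n)

  nt <- c("A", "C", "G", "T")
  if (!all(x$effect_allele %in% nt) || !all(x$other_allele %in% nt)) {
    stop("trait_dataset: alleles must be single nucleotides A/C/G/T")
  }
  if (any(x$effect_allele == x$other_allele)) {
    stop("trait_dataset: effect_allele must differ from other_allele")
  }
  if (any(x$se <= 0)) stop("trait_dataset: se must be > 0")
  if (any(x$eaf < 0 | x$eaf > 1)) stop("trait_dataset: eaf must lie in [0, 1]")
  if (any(x$pval <= 0 | x$pval > 1)) stop("trait_dataset: pval must lie in (0, 1]")
  if (any(x$n <= 0)) stop("trait_dataset: n must be > 0")
  if (anyDuplicated(x$variant_id)) {
    stop("trait_dataset: variant_id must be unique (use read_summary_stats for dedup)")
  }

  if (check_pval && nrow(x)) {
    p_implied <- 2 * stats::pnorm(-abs(x$beta / x$se))
    # soft check: flag only gross inconsistency (> 10x on either side),
    # ignoring the region where both are effectively zero
    bad <- p_implied > 1e-300 & x$pval > 1e-300 &
      (x$pval / p_implied > 10 | p_implied / x$pval > 10)
    if (any(bad)) {
      warning(sprintf(
        "trait_dataset '%s': %d record(s) have p-values inconsistent with beta/se (>10x)",
        trait_name, sum(bad)))
    }
  }

  rownames(x) <- NULL
  structure(x,
            trait_name = trait_name,
            trait_type = trait_type,
            class = c("trait_dataset", "data.frame"))
}

#' @export
print.trait_dataset <- function(x, ...) {
  cat(sprintf("<trait_dataset> '%s' (%s), %d variants\n",
              attr(x, "trait_name"), attr(x, "trait_type"), nrow(x)))
  if (nrow(x)) {
    print(utils::head(as.data.frame(x), 6L))
    if (nrow(x) > 6L) cat("...\n")
  }
  invisible(x)
}

# Re-wrap a plain subset as a trait_dataset, preserving trait metadata.
restamp_dataset <- function(x, template) {
  trait_dataset(as.data.frame(x),
                trait_name = attr(template, "trait_name"),
                trait_type = attr(template, "trait_type"),
                check_pval = FALSE)
}

trait_name <- function(x) attr(x, "trait_name")
trait_type <- function(x) attr(x, "trait_type")
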