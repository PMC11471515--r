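#' Screen variants on association p-value
#'
#' Retains records whose p-value is strictly below `threshold`. Typical
#' instrument-selection thresholds for two-sample MR with modest discovery
#' cohorts are 1e-5 (metabolite panels) and 5e-6 (cytokine panels); 5e-8 is
#' the conventional genome-wide level for large binary-trait GWAS.
#'
#' @param dataset a [trait_dataset].
#' @param threshold p-value threshold in (0, 1); comparison is strict (`<`).
#' @return the filtered [trait_dataset].
#' @export
select_by_pvalue <- function(dataset, threshold) {
  stopifnot(inherits(dataset, "trait_dataset"),
            is.numeric(threshold), threshold > 0, threshold < 1)
  out <- restamp_dataset(dataset[dataset$pval < threshold, , drop = FALSE], dataset)
  if (!nrow(out)) {
    message(sprintf("select_by_pvalue('%s'): no variants below p < %g",
                    trait_name(dataset), threshold))
  }
  out
}

#' Greedy LD clumping
#'
#' Prunes correlated variants so that the retained instruments are
#' approximately independent: variants are ranked by ascending p-value
#' (ties broken by chromosome then position, for determinism), the best
#' remaining variant is kept, and any same-chromosome variant within
#' `window_kb` whose pairwise r-squared with a kept variant exceeds `r2_max`
#' is discarded.
#'
#' The result is independent of input row order. When an in-window pair has
#' no entry in the LD table, `missing_ld` decides: `"correlated"`
#' (conservative default: drop the weaker variant) or `"independent"`
#' (keep both). Cross-chromosome pairs are always independent.
#'
#' @param dataset a [trait_dataset].
#' @param ld data.frame with columns `variant_a`, `variant_b`, `r2`
#'   (unordered pairs), or `NULL` for "no LD information" in which case
#'   `missing_ld` governs every in-window pair.
#' @param r2_max r-squared threshold (default 0.001).
#' @param window_kb window in kilobases (default 10,000).
#' @param missing_ld policy for in-window pairs absent from `ld`.
#' @return the clumped [trait_dataset], sorted by ascending p-value.
#' @export
greedy_clump <- function(dataset, ld = NULL, r2_max = 0.001, window_kb = 10000,
                         missing_ld = c("correlated", "independent")) {
  stopifnot(inherits(dataset, "trait_dataset"),
            r2_max >= 0, r2_max <= 1, window_kb > 0)
  missing_ld <- match.arg(missing_ld)
  df <- as.data.frame(dataset)
  if (nrow(df) < 2L) return(dataset)

  lookup <- new.env(parent = emptyenv(), size = 2L * max(1L, NROW(ld)))
  if (!is.null(ld) && nrow(ld)) {
    stopifnot(all(c("variant_a", "variant_b", "r2") %in% names(ld)))
    for (i in seq_len(nrow(ld))) {
      a <- as.character(ld$variant_a[i]); b <- as.character(ld$variant_b[i])
      key <- paste(sort(c(a, b)), collapse = "\r")
      assign(key, as.numeric(ld$r2[i]), envir = lookup)
    }
  }
  pair_r2 <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "\r")
    if (exists(key, envir = lookup, inherits = FALSE)) {
      get(key, envir = lookup, inherits = FALSE)
    } else NA_real_
  }

  ord <- order(df$pval, df$chrom, df$pos)
  df <- df[ord, , drop = FALSE]
  n <- nrow(df)
  status <- rep("pending", n)
  window_bp <- window_kb * 1000
  n_missing <- 0L
  for (i in seq_len(n)) {
    if (status[i] != "pending") next
    status[i] <- "kept"
    for (j in seq_len(n)) {
      if (status[j] != "pending") next
      if (df$chrom[j] != df$chrom[i]) next
      if (abs(df$pos[j] - df$pos[i]) > window_bp) next
      r2 <- pair_r2(df$variant_id[i], df$variant_id[j])
      if (is.na(r2)) {
        n_missing <- n_missing + 1L
        r2 <- if (missing_ld == "correlated") 1 else 0
      }
      if (r2 > r2_max) status[j] <- "dropped"
    }
  }
  if (n_missing > 0L) {
    message(sprintf("greedy_clump('%s'): %d in-window pair(s) had no LD value; treated as %s",
                    trait_name(dataset), n_missing, missing_ld))
  }
  restamp_dataset(df[status == "kept", , drop = FALSE], dataset)
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Drop palindromic variants with intermediate allele frequency
#'
#' A/T and C/G variants cannot be strand-resolved from the alleles alone;
#' when their effect-allele frequency is near 0.5 the frequency cannot
#' resolve them either, so they are removed. Palindromic variants with a
#' frequency outside the band are retained (the frequency identifies the
#' strand).
#'
#' @param dataset a [trait_dataset].
#' @param maf_band numeric length-2, the inclusive eaf band treated as
#'   "intermediate" (default `c(0.42, 0.58)`).
#' @return the filtered [trait_dataset].
#' @export
drop_palindromes <- function(dataset, maf_band = c(0.42, 0.58)) {
  stopifnot(inherits(dataset, "trait_dataset"),
            length(maf_band) == 2L, maf_band[1] < maf_band[2])
  pal <- is_palindromic(dataset$effect_allele, dataset$other_allele)
  ambiguous <- pal & dataset$eaf >= maf_band[1] & dataset$eaf <= maf_band[2]
  if (any(ambiguous)) {
    message(sprintf("drop_palindromes('%s'): removed %d ambiguous palindromic variant(s)",
                    trait_name(dataset), sum(ambiguous)))
  }
  restamp_dataset(dataset[!ambiguous, , drop = FALSE], dataset)
}

#' Remove variants on a confounder exclusion list
#'
#' Set-difference filter for instruments known to be associated with
#' confounders of the exposure-outcome relation (e.g. BMI- or
#' smoking-associated SNPs identified from an external lookup). The list is
#' user-supplied: one variant id per element.
#'
#' @param dataset a [trait_dataset].
#' @param exclusion_list character vector of variant ids to remove.
#' @return the filtered [trait_dataset].
#' @export
exclude_listed_snps <- function(dataset, exclusion_list) {
  stopifnot(inherits(dataset, "trait_dataset"))
  exclusion_list <- as.character(exclusion_list)
  hit <- dataset$variant_id %in% exclusion_list
  if (any(hit)) {
    message(sprintf("exclude_listed_snps('%s'): removed %d listed variant(s)",
                    trait_name(dataset), sum(hit)))
  }
  out <- restamp_dataset(dataset[!hit, , drop = FALSE], dataset)
  if (!nrow(out)) warning("exclude_listed_snps: all variants excluded")
  out
}

#' Per-SNP explained variance and F-statistics
#'
#' For a standardized continuous trait, the variance explained by one SNP is
#' `R2_j = 2 * MAF_j * (1 - MAF_j) * (beta_j / SD)^2` and its strength is
#' `F_j = (N - 2) * R2_j / (1 - R2_j)`. The set-level F across the k
#' instruments, `F_set = ((N - k - 1) / k) * sum(R2) / (1 - sum(R2))`, is
#' reported as a diagnostic attribute. Instruments with per-SNP F below
#' `min_f` are flagged as weak; the conventional exclusion threshold is 10.
#'
#' @param dataset a [trait_dataset].
#' @param phenotype_sd trait standard deviation (1 for standardized traits).
#' @param min_f weak-instrument flag threshold (default 10).
#' @return data.frame with `variant_id`, `maf`, `r2`, `f_stat`, `n`, `k`,
#'   `weak`; attribute `set_f` carries the set-level F.
#' @export
compute_instrument_strength <- function(dataset, phenotype_sd = 1, min_f = 10) {
  stopifnot(inherits(dataset, "trait_dataset"), phenotype_sd > 0)
  maf <- pmin(dataset$eaf, 1 - dataset$eaf)
  r2 <- 2 * maf * (1 - maf) * (dataset$beta / phenotype_sd)^2
  if (any(r2 >= 1)) {
    stop("compute_instrument_strength: per-SNP R^2 >= 1; check effect scale / phenotype_sd")
  }
  n <- dataset$n
  k <- nrow(dataset)
  f_stat <- (n - 2) * r2 / (1 - r2)
  sum_r2 <- sum(r2)
  set_f <- if (k > 0 && sum_r2 < 1) {
    ((mean(n) - k - 1) / k) * sum_r2 / (1 - sum_r2)
  } else NA_real_
  out <- data.frame(variant_id = dataset$variant_id, maf = maf, r2 = r2,
                    f_stat = f_stat, n = n, k = k, weak = f_stat < min_f,
                    stringsAsFactors = FALSE)
  attr(out, "set_f") <- set_f
  out
}

#' Apply the weak-instrument filter
#'
#' Convenience wrapper: drops variants whose per-SNP F-statistic falls below
#' `min_f` (default 10).
#'
#' @inheritParams compute_instrument_strength
#' @return the filtered [trait_dataset].
#' @export
filter_by_f <- function(dataset, phenotype_sd = 1, min_f = 10) {
  diag <- compute_instrument_strength(dataset, phenotype_sd, min_f)
  if (any(diag$weak)) {
    message(sprintf("filter_by_f('%s'): removed %d weak instrument(s) (F < %g)",
                    trait_name(dataset), sum(diag$weak), min_f))
  }
  restamp_dataset(dataset[!diag$weak, , drop = FALSE], dataset)
}
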