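#' Harmonize exposure, outcome (and optional mediator) summary statistics
#'
#' Aligns per-SNP effects across datasets onto the exposure's effect allele
#' so that Wald ratios are meaningful. Variants are intersected on
#' `variant_id`; for each shared variant the outcome (and mediator) alleles
#' are compared with the exposure's:
#' \itemize{
#'   \item identical allele pair: effect kept as is (`kept-as-is`);
#'   \item swapped pair: effect sign flipped, `eaf` replaced by `1 - eaf`
#'     (`flipped`);
#'   \item palindromic variant (A/T or C/G) whose strand cannot be resolved —
#'     i.e. either dataset's frequency is intermediate: dropped
#'     (`dropped-palindrome`); otherwise the frequencies resolve the strand;
#'   \item any other allele combination: dropped (`dropped-missing`).
#' }
#'
#' Harmonization is idempotent: a second pass over an already-aligned set
#' changes nothing.
#'
#' @param exposure,outcome [trait_dataset]s; `exposure` supplies the
#'   instrument effects `gamma`, `outcome` the effects `capital_gamma`.
#' @param mediator optional [trait_dataset] supplying `delta`.
#' @param pal_band eaf band within which a palindromic variant is considered
#'   strand-unresolvable (default `c(0.42, 0.58)`).
#' @return data.frame of class `harmonized_set` with one row per retained
#'   variant: `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `eaf`, `gamma`, `se_gamma`, `pval_gamma`, `n_exposure`,
#'   `capital_gamma`, `se_capital_gamma`, `pval_outcome`, and (with a
#'   mediator) `delta`, `se_delta`, `pval_mediator`; plus `alignment_flag`.
#'   The attribute `dropped` records excluded variants and their flags.
#' @export
harmonize <- function(exposure, outcome, mediator = NULL,
                      pal_band = c(0.42, 0.58)) {
  stopifnot(inherits(exposure, "trait_dataset"), inherits(outcome, "trait_dataset"))
  if (!nrow(exposure) || !nrow(outcome)) stop("harmonize: empty input dataset")

  common <- intersect(exposure$variant_id, outcome$variant_id)
  if (!is.null(mediator)) {
    stopifnot(inherits(mediator, "trait_dataset"))
    common <- intersect(common, mediator$variant_id)
  }
  if (!length(common)) {
    top <- utils::head(exposure$variant_id[order(exposure$pval)], 5L)
    stop("harmonize: no shared variants between datasets; top exposure instruments absent from outcome: ",
         paste(top, collapse = ", "))
  }

  exp_df <- as.data.frame(exposure)[match(common, exposure$variant_id), ]

  align_one <- function(target, label) {
    tgt <- as.data.frame(target)[match(common, target$variant_id), ]
    same <- tgt$effect_allele == exp_df$effect_allele &
      tgt$other_allele == exp_df$other_allele
    swap <- tgt$effect_allele == exp_df$other_allele &
      tgt$other_allele == exp_df$effect_allele
    pal <- is_palindromic(exp_df$effect_allele, exp_df$other_allele)
    intermediate <- (exp_df$eaf >= pal_band[1] & exp_df$eaf <= pal_band[2]) |
      (tgt$eaf >= pal_band[1] & tgt$eaf <= pal_band[2])
    flag <- rep("dropped-missing", length(common))
    flag[same] <- "kept-as-is"
    flag[swap] <- "flipped"
    # palindromic variants: "swapped" alleles are indistinguishable from a
    # strand flip, so use frequency concordance; intermediate eaf is
    # unresolvable either way
    pal_match <- pal & (same | swap)
    flag[pal_match & intermediate] <- "dropped-palindrome"
    freq_discordant <- pal_match & !intermediate &
      ((exp_df$eaf < 0.5) != (tgt$eaf < 0.5))
    # discordant frequencies on a resolvable palindrome: the reported allele
    # is the other strand's, i.e. effectively swapped
    flag[freq_discordant & same] <- "flipped"
    flag[freq_discordant & swap] <- "kept-as-is"

    beta <- ifelse(flag == "flipped", -tgt$beta, tgt$beta)
    list(beta = beta, se = tgt$se, pval = tgt$pval, n = tgt$n, flag = flag)
  }

  out_al <- align_one(outcome, "outcome")
  flags <- out_al$flag
  med_al <- NULL
  if (!is.null(mediator)) {
    med_al <- align_one(mediator, "mediator")
    drop_m <- startsWith(med_al$flag, "dropped")
    flags[drop_m & !startsWith(flags, "dropped")] <- med_al$flag[drop_m & !startsWith(flags, "dropped")]
  }

  h <- data.frame(
    variant_id = common,
    chrom = exp_df$chrom, pos = exp_df$pos,
    effect_allele = exp_df$effect_allele, other_allele = exp_df$other_allele,
    eaf = exp_df$eaf,
    gamma = exp_df$beta, se_gamma = exp_df$se, pval_gamma = exp_df$pval,
    n_exposure = exp_df$n,
    capital_gamma = out_al$beta, se_capital_gamma = out_al$se,
    pval_outcome = out_al$pval,
    alignment_flag = flags,
    stringsAsFactors = FALSE)
  if (!is.null(med_al)) {
    h$delta <- med_al$beta
    h$se_delta <- med_al$se
    h$pval_mediator <- med_al$pval
  }

  kept <- !startsWith(h$alignment_flag, "dropped")
  dropped <- h[!kept, c("variant_id", "alignment_flag")]
  if (nrow(dropped)) {
    message(sprintf("harmonize: dropped %d variant(s) (%s)",
                    nrow(dropped),
                    paste(sprintf("%s=%d", names(table(dropped$alignment_flag)),
                                  as.integer(table(dropped$alignment_flag))),
                          collapse = ", ")))
  }
  h <- h[kept, , drop = FALSE]
  if (!nrow(h)) stop("harmonize: no variants survived allele alignment")
  rownames(h) <- NULL
  structure(h,
            exposure_name = trait_name(exposure),
            outcome_name = trait_name(outcome),
            mediator_name = if (!is.null(mediator)) trait_name(mediator) else NULL,
            dropped = dropped,
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  med <- attr(x, "mediator_name")
  cat(sprintf("<harmonized_set> %s -> %s%s, %d instruments\n",
              attr(x, "exposure_name"), attr(x, "outcome_name"),
              if (is.null(med)) "" else sprintf(" (mediator: %s)", med),
              nrow(x)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

# Internal constructor used by tests and simulations: build a harmonized_set
# directly from aligned effect vectors.
new_harmonized_set <- function(gamma, se_gamma, capital_gamma, se_capital_gamma,
                               delta = NULL, se_delta = NULL,
                               variant_id = NULL,
                               exposure_name = "exposure",
                               outcome_name = "outcome",
                               mediator_name = NULL) {
  n <- length(gamma)
  if (is.null(variant_id)) variant_id <- sprintf("rs%05d", seq_len(n))
  h <- data.frame(variant_id = variant_id,
                  chrom = "1", pos = seq_len(n),
                  effect_allele = "A", other_allele = "G",
                  eaf = 0.3,
                  gamma = gamma, se_gamma = se_gamma,
                  pval_gamma = 2 * stats::pnorm(-abs(gamma / se_gamma)),
                  n_exposure = NA_real_,
                  capital_gamma = capital_gamma,
                  se_capital_gamma = se_capital_gamma,
                  pval_outcome = 2 * stats::pnorm(-abs(capital_gamma / se_capital_gamma)),
                  alignment_flag = "kept-as-is",
                  stringsAsFactors = FALSE)
  if (!is.null(delta)) {
    h$delta <- delta
    h$se_delta <- se_delta
    h$pval_mediator <- 2 * stats::pnorm(-abs(delta / se_delta))
  }
  structure(h, exposure_name = exposure_name, outcome_name = outcome_name,
            mediator_name = mediator_name,
            dropped = h[0, c("variant_id", "alignment_flag")],
            class = c("harmonized_set", "data.frame"))
}
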