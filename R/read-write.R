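#' Read GWAS summary statistics into a trait_dataset
#'
#' Reads a tab- or comma-delimited summary-statistic file (optionally
#' gzip-compressed) with a header row. Column names are mapped to the
#' canonical schema through `column_map`; the default mapping follows the
#' common GWAS-SS layout (`SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N`).
#'
#' Cleaning rules, applied in order and counted in the returned attributes:
#' \itemize{
#'   \item rows with missing `beta`, `se`, or either allele are dropped;
#'   \item multi-allelic / indel rows (any allele not a single A/C/G/T base)
#'     are dropped;
#'   \item rows with `se <= 0`, `eaf` outside \[0,1\] or `pval` outside (0,1\]
#'     are dropped;
#'   \item duplicate `variant_id`s keep the record with the smallest p-value
#'     (first occurrence on ties, for determinism).
#' }
#'
#' @param path file path (plain or `.gz`).
#' @param column_map named character vector mapping canonical field names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`) to the file's column names. Partial maps
#'   override the defaults field-by-field.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param trait_name trait label; defaults to the file name sans extension.
#' @param quiet suppress the log message about dropped rows.
#'
#' @return A [trait_dataset] with attributes `n_dropped` (rows removed by
#'   cleaning) and `n_dedup` (rows removed as duplicates).
#' @export
read_summary_stats <- function(path, column_map = NULL,
                               trait_type = c("continuous", "binary"),
                               trait_name = NULL, quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("read_summary_stats: cannot read '", path, "'")
  if (is.null(trait_name)) {
    trait_name <- sub("\\.(txt|tsv|csv)(\\.gz)?$", "", basename(path))
  }

  default_map <- c(variant_id = "SNP", chrom = "CHR", pos = "POS",
                   effect_allele = "EA", other_allele = "OA", eaf = "EAF",
                   beta = "BETA", se = "SE", pval = "P", n = "N")
  map <- default_map
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(default_map))
    if (length(unknown)) {
      stop("read_summary_stats: unknown fields in column_map: ",
           paste(unknown, collapse = ", "))
    }
    map[names(column_map)] <- column_map
  }

  magic <- readBin(path, "raw", n = 2L)
  con <- if (length(magic) == 2L && identical(magic, as.raw(c(0x1f, 0x8b)))) {
    gzfile(path, open = "rt")
  } else {
    file(path, open = "rt")
  }
  on.exit(close(con), add = TRUE)
  first <- readLines(con, n = 1L)
  if (!length(first)) stop("read_summary_stats: empty file '", path, "'")
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(con, header = FALSE, sep = sep,
                           col.names = strsplit(first, sep, fixed = TRUE)[[1]],
                           colClasses = "character",  # alleles like "T" must not become logicals
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"",
                           na.strings = c("NA", "", "."))
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols)) {
    stop("read_summary_stats: mapped column(s) absent from file: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- stats::setNames(raw[unname(map)], names(map))
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$pos <- suppressWarnings(as.integer(df$pos))

  n_in <- nrow(df)
  keep <- !is.na(df$beta) & !is.na(df$se) &
    !is.na(df$effect_allele) & !is.na(df$other_allele)
  df <- df[keep, , drop = FALSE]

  nt <- c("A", "C", "G", "T")
  ea <- toupper(as.character(df$effect_allele))
  oa <- toupper(as.character(df$other_allele))
  snv <- ea %in% nt & oa %in% nt & ea != oa
  df <- df[snv, , drop = FALSE]

  ok <- !is.na(df$se) & df$se > 0 &
    !is.na(df$eaf) & df$eaf >= 0 & df$eaf <= 1 &
    !is.na(df$pval) & df$pval > 0 & df$pval <= 1 &
    !is.na(df$n) & df$n > 0
  df <- df[ok, , drop = FALSE]
  n_dropped <- n_in - nrow(df)

  # duplicates: keep smallest p; stable order ties -> first occurrence
  ord <- order(df$pval, seq_len(nrow(df)))
  df <- df[ord, , drop = FALSE]
  dup <- duplicated(df$variant_id)
  n_dedup <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  df <- df[order(match(df$variant_id, raw[[map[["variant_id"]]]])), , drop = FALSE]

  if (!nrow(df)) stop("read_summary_stats: no valid rows in '", path, "'")
  if (!quiet && (n_dropped || n_dedup)) {
    message(sprintf("read_summary_stats('%s'): dropped %d invalid row(s), deduplicated %d",
                    trait_name, n_dropped, n_dedup))
  }

  out <- trait_dataset(df, trait_name = trait_name, trait_type = trait_type)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_dedup") <- n_dedup
  out
}

#' Write a trait_dataset back to a tab-delimited summary-statistic file
#'
#' Uses the canonical header (`SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N`)
#' and full numeric precision (`%.17g`), so a write/read cycle round-trips
#' all finite fields bit-identically.
#'
#' @param dataset a [trait_dataset].
#' @param path output path.
#' @export
write_summary_stats <- function(dataset, path) {
  stopifnot(inherits(dataset, "trait_dataset"))
  df <- as.data.frame(dataset)
  num <- function(v) sprintf("%.17g", v)
  out <- data.frame(SNP = df$variant_id, CHR = df$chrom, POS = df$pos,
                    EA = df$effect_allele, OA = df$other_allele,
                    EAF = num(df$eaf), BETA = num(df$beta), SE = num(df$se),
                    P = num(df$pval), N = num(df$n),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

report_columns <- c("exposure", "outcome", "method", "n_snp", "beta", "se",
                    "pval", "or", "ci_low", "ci_high", "p_fdr", "het_q_p",
                    "presso_p", "tier")

#' Write an analysis report table
#'
#' Emits one tab-delimited row per (exposure, outcome, method) with the
#' journal-table formatting conventions: effect sizes, odds ratios and CI
#' bounds to 3 decimals, p-values in scientific notation with 2 decimals
#' (e.g. `9.29E-05`).
#'
#' @param rows data.frame with columns `exposure`, `outcome`, `method`,
#'   `n_snp`, `beta`, `se`, `pval`, `or`, `ci_low`, `ci_high` and optionally
#'   `p_fdr`, `het_q_p`, `presso_p`, `tier`.
#' @param path output path.
#' @export
write_report <- function(rows, path) {
  if (!is.data.frame(rows) || !nrow(rows)) {
    stop("write_report: rows must be a non-empty data.frame")
  }
  rows <- as.data.frame(rows)
  for (col in setdiff(report_columns, names(rows))) rows[[col]] <- NA
  rows <- rows[report_columns]

  fmt3 <- function(v) ifelse(is.na(v), "", sprintf("%.3f", v))
  fmtp <- function(v) ifelse(is.na(v), "", sprintf("%.2E", v))
  out <- data.frame(
    exposure = rows$exposure, outcome = rows$outcome, method = rows$method,
    nSNP = rows$n_snp,
    beta = fmt3(rows$beta), se = fmt3(rows$se), pval = fmtp(rows$pval),
    OR = fmt3(rows$or), CI_low = fmt3(rows$ci_low), CI_high = fmt3(rows$ci_high),
    P_FDR = fmtp(rows$p_fdr), Het_Q_P = fmtp(rows$het_q_p),
    PRESSO_P = fmtp(rows$presso_p),
    tier = ifelse(is.na(rows$tier), "", as.character(rows$tier)),
    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
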