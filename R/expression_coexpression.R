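# FPKM computation and binning, and Pearson coexpression screening of
# lncRNA/target pairs against a significance-derived correlation
# threshold.

#' FPKM from fragment counts
#'
#' `FPKM = fragments * 1e9 / (spliced_length * total_fragments)`.
#'
#' @param fragments fragment count mapped to the feature (>= 0).
#' @param spliced_length feature length in nt (> 0).
#' @param total_fragments total mapped fragments in the sample (> 0).
#' @return FPKM value(s); vectorized.
#' @export
fpkm_from_counts <- function(fragments, spliced_length, total_fragments) {
  if (any(fragments < 0)) stop("fragments must be non-negative")
  if (any(spliced_length <= 0)) stop("spliced length must be positive")
  if (any(total_fragments <= 0)) stop("total fragments must be positive")
  fragments * 1e9 / (spliced_length * total_fragments)
}

#' Gene-level FPKM as the sum of its isoforms
#'
#' @param isoform_fpkm numeric vector of isoform FPKM values (>= 1
#'   isoform).
#' @return The gene FPKM (sum).
#' @export
gene_fpkm <- function(isoform_fpkm) {
  if (!length(isoform_fpkm)) stop("at least one isoform required")
  if (any(isoform_fpkm < 0)) stop("FPKM must be non-negative")
  sum(isoform_fpkm)
}

#' Expression-level bin of an FPKM value
#'
#' Bins follow the conventional low / medium / high / very-high split:
#' low `[0, 1)`, medium `[1, 15]`, high `(15, 100]`, very_high
#' `(100, Inf)`.
#'
#' @param fpkm FPKM value(s), >= 0; vectorized.
#' @return Factor with levels `low`, `medium`, `high`, `very_high`.
#' @export
bin_expression <- function(fpkm) {
  if (any(fpkm < 0)) stop("FPKM must be non-negative")
  b <- cut(fpkm, breaks = c(-Inf, 1, 15, 100, Inf), right = FALSE,
           labels = c("low", "medium", "high", "very_high"))
  # upper boundaries are inclusive: medium [1,15], high (15,100]
  b[fpkm == 15] <- "medium"
  b[fpkm == 100] <- "high"
  b
}

#' Critical Pearson correlation at a given significance level
#'
#' The two-tailed critical value of r: `r_crit = t / sqrt(t^2 + df)` with
#' `t` the `1 - alpha/2` Student-t quantile at `df` degrees of freedom
#' (`df = n_samples - 2`). At df = 16 and alpha = 0.05 this gives the
#' familiar 0.468 screening threshold.
#'
#' @param df degrees of freedom (>= 1).
#' @param alpha two-tailed significance level in (0, 1].
#' @return The critical |r|.
#' @export
critical_pearson_r <- function(df, alpha = 0.05) {
  if (df < 1) stop("df must be at least 1")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  t <- qt(1 - alpha / 2, df)
  t / sqrt(t^2 + df)
}

#' Pearson coexpression screen of lncRNA/target pairs
#'
#' Pairs where either member has `FPKM_max < 1` are excluded as low
#' abundance and carry no correlation. For the rest, Pearson r is
#' computed over all samples with `df = n_samples - 2`; the verdict is
#' `positive` when `r >= r_crit`, `negative` when `r <= -r_crit`
#' (`r_crit` from [critical_pearson_r()]), otherwise `not_significant`.
#' A constant (zero-variance) expression vector leaves r undefined; such
#' pairs are reported `not_significant` with `zero_variance = TRUE` and
#' `NA` in place of r, never NaN.
#'
#' @param pairs data.frame with columns `lncrna_id` and `target_id`; both
#'   must be rows of `expr`.
#' @param expr an expression matrix (features x samples), >= 4 samples.
#' @param alpha two-tailed significance level (default 0.05).
#' @param fpkm_max_min low-abundance exclusion threshold on FPKM_max
#'   (default 1; exclusion is strict `<`).
#' @return data.frame of `CoexpressionResult` records: ids, r, n, df,
#'   p_value, r_crit, zero_variance, verdict.
#' @export
coexpression_screen <- function(pairs, expr, alpha = 0.05,
                                fpkm_max_min = 1) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("lncrna_id", "target_id") %in% names(pairs)))
    stop("pairs must have columns lncrna_id and target_id")
  m <- unclass(expr)
  n <- ncol(m)
  if (n < 4L) stop("at least 4 samples are required")
  missing_feat <- setdiff(unique(c(pairs$lncrna_id, pairs$target_id)),
                          rownames(m))
  if (length(missing_feat))
    stop("pair member absent from expression matrix: ",
         paste(missing_feat, collapse = ", "))
  df <- n - 2L
  r_crit <- critical_pearson_r(df, alpha)
  fmax <- fpkm_max(m)
  out <- data.frame(lncrna_id = pairs$lncrna_id,
                    target_id = pairs$target_id,
                    r = NA_real_, n = n, df = df, p_value = NA_real_,
                    r_crit = r_crit, zero_variance = FALSE,
                    verdict = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$lncrna_id[k]; b <- pairs$target_id[k]
    if (fmax[a] < fpkm_max_min || fmax[b] < fpkm_max_min) {
      out$verdict[k] <- "excluded_low_abundance"
      out$n[k] <- NA_integer_; out$df[k] <- NA_integer_
      out$r_crit[k] <- NA_real_
      next
    }
    x <- m[a, ]; y <- m[b, ]
    if (sd(x) == 0 || sd(y) == 0) {
      out$zero_variance[k] <- TRUE
      out$verdict[k] <- "not_significant"
      message("zero-variance expression vector in pair ", a, "/", b,
              "; correlation undefined")
      next
    }
    r <- cor(x, y)
    tstat <- r * sqrt(df / (1 - r^2))
    out$r[k] <- r
    out$p_value[k] <- if (abs(r) >= 1) 0 else 2 * pt(-abs(tstat), df)
    out$verdict[k] <- if (r >= r_crit) "positive"
      else if (r <= -r_crit) "negative" else "not_significant"
  }
  out
}
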