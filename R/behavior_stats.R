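#' Convert a raw recall score to percent accuracy
#'
#' Scores come from recall blocks of 16 object locations repeated 3 times
#' per condition, hence the default maximum of 48.  The conversion is exact
#' (100 * raw / max), e.g. 34.62/48 = 72.125%.
#'
#' @param raw_score numeric score(s) in `[0, max_score]`.
#' @param max_score maximum attainable score (default 48 = 16 items x 3
#'   blocks).
#' @return percent accuracy in `[0, 100]`.
#' @export
#' @examples
#' percent_accuracy(34.62)  # 72.125
percent_accuracy <- function(raw_score, max_score = 48) {
  if (any(raw_score < 0 | raw_score > max_score))
    stop_input("raw_score must lie in [0, ", max_score, "]")
  100 * raw_score / max_score
}

#' Paired two-tailed t test with Cohen's dz
#'
#' Classic paired t on subject-wise differences `a - b`, with two-tailed p
#' and the paired-design effect size dz = mean(diff) / SD(diff) (n - 1
#' denominator).  `dz_from_t` = t / sqrt(n) is also reported, since
#' published dz values are sometimes derived from the t statistic and the
#' two conventions need not agree once results are rounded.
#'
#' @param a,b equal-length (>= 2) per-subject scores, paired by position.
#' @return a `paired_test` list: `t`, `df`, `p`, `dz`, `dz_from_t`,
#'   `mean_diff`, `sd_diff`, `n`, `undefined` (TRUE when the differences
#'   have zero variance, in which case t and p are NA).
#' @export
#' @examples
#' paired_t_dz(c(5, 7, 9, 6), c(4, 6, 8, 7))
paired_t_dz <- function(a, b) {
  if (length(a) != length(b))
    stop_input("a and b must have equal length (paired by subject)")
  n <- length(a)
  if (n < 2) stop_input("need at least 2 pairs")
  d <- a - b
  md <- mean(d)
  sdd <- stats::sd(d)
  undefined <- sdd == 0
  if (undefined && md == 0) {
    t <- 0; p <- 1; dz <- 0
  } else if (undefined) {
    warning("zero-variance differences; t undefined", call. = FALSE)
    t <- NA_real_; p <- NA_real_; dz <- NA_real_
  } else {
    t <- md / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(t), n - 1)
    dz <- md / sdd
  }
  structure(list(t = t, df = n - 1L, p = p, dz = dz,
                 dz_from_t = if (is.na(t)) NA_real_ else t / sqrt(n),
                 mean_diff = md, sd_diff = sdd, n = n,
                 undefined = undefined && md != 0),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.3f, p = %.4g, dz = %.3f (t/sqrt(n) = %.3f)\n",
              x$df, x$t, x$p, x$dz, x$dz_from_t))
  invisible(x)
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' Standard step-up procedure over m = length(p_values) hypotheses at false
#' discovery rate `q`; rejection flags are returned in the input order.
#'
#' @param p_values p values in `[0, 1]`.
#' @param q false discovery rate (default 0.05).
#' @return logical vector of rejections (empty input gives empty output).
#' @export
#' @examples
#' benjamini_hochberg(c(0.001, 0.019, 0.033, 0.207))
benjamini_hochberg <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) return(logical(0))
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1)))
    stop_input("p values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Per-subject and group summary of a behaviour table
#'
#' Sums the block scores per subject and condition to the raw condition
#' score, converts it to percent accuracy, and summarises each condition's
#' group mean and SD.
#'
#' @param table a `behavior_table` (columns `subject`, `condition`,
#'   `block`, `score`).
#' @param max_score maximum raw score per condition (default 48).
#' @return list with `per_subject` (subject, condition, raw_score, percent)
#'   and `per_condition` (condition, mean_raw, sd_raw, mean_percent).
#' @export
behavior_summary <- function(table, max_score = 48) {
  agg <- stats::aggregate(score ~ subject + condition, data = table, sum)
  names(agg)[names(agg) == "score"] <- "raw_score"
  agg$percent <- percent_accuracy(agg$raw_score, max_score)
  grp <- do.call(rbind, lapply(split(agg, agg$condition), function(g)
    data.frame(condition = g$condition[1L],
               mean_raw = mean(g$raw_score),
               sd_raw = stats::sd(g$raw_score),
               mean_percent = mean(g$percent),
               stringsAsFactors = FALSE)))
  rownames(grp) <- NULL
  list(per_subject = agg, per_condition = grp)
}

#' Pairwise paired t tests over behaviour conditions with FDR control
#'
#' Runs [paired_t_dz()] on each requested condition pair (per-subject raw
#' condition scores, paired by subject) and appends Benjamini-Hochberg
#' rejection flags at rate `q` over the set of tests.
#'
#' @param table a `behavior_table`.
#' @param pairs list of length-2 character vectors of condition names;
#'   default: all condition pairs in order of appearance.
#' @param q false discovery rate (default 0.05).
#' @param max_score maximum raw score per condition (default 48).
#' @return data.frame: contrast, t, df, p, dz, dz_from_t, rejected.
#' @export
behavior_tests <- function(table, pairs = NULL, q = 0.05, max_score = 48) {
  summ <- behavior_summary(table, max_score)$per_subject
  conds <- unique(table$condition)
  if (is.null(pairs))
    pairs <- utils::combn(conds, 2, simplify = FALSE)
  wide <- split(summ, summ$condition)
  rows <- lapply(pairs, function(pr) {
    ga <- wide[[pr[1L]]]; gb <- wide[[pr[2L]]]
    if (is.null(ga) || is.null(gb))
      stop_input("unknown condition in pair: ", paste(pr, collapse = " vs "))
    gb <- gb[match(ga$subject, gb$subject), , drop = FALSE]
    tt <- paired_t_dz(ga$raw_score, gb$raw_score)
    data.frame(contrast = paste(pr, collapse = " vs "),
               t = tt$t, df = tt$df, p = tt$p, dz = tt$dz,
               dz_from_t = tt$dz_from_t, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rejected <- benjamini_hochberg(out$p, q)
  out
}
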