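#' Read an allele-age table
#'
#' Tab-separated columns: variant_id, group, age, lower, upper (ages in
#' generations, CI bounds from the coalescent age estimator). Records
#' violating 0 < lower <= age <= upper are dropped with a message and counted.
#'
#' @param path TSV path.
#' @return data.frame with attribute \code{n_invalid}.
#' @export
read_age_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "group", "age", "lower", "upper")
  if (!all(need %in% names(df))) {
    stop("age table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- !(df$lower > 0 & df$lower <= df$age & df$age <= df$upper) |
    is.na(df$age) | is.na(df$lower) | is.na(df$upper)
  if (any(bad)) {
    message(sum(bad), " age record(s) rejected at parse (invalid CI ordering)")
  }
  out <- df[!bad, , drop = FALSE]
  attr(out, "n_invalid") <- sum(bad)
  out
}

#' Quality-filter allele-age records
#'
#' Retains records with CI ratio (upper/lower bound) at most
#' \code{max_ci_ratio} and point age at most \code{max_age} generations.
#' Records with a zero lower bound are rejected with their own tally reason
#' rather than crashing. Filtering is idempotent, and retained + rejected
#' counts always sum to the input count (each rejected record is tallied once,
#' in the order zero_lower, ci_ratio, age_cap).
#'
#' @param records data.frame with columns age, lower, upper.
#' @param max_ci_ratio Default 10.
#' @param max_age Default 500000 generations.
#' @return List: retained (data.frame), tally (named integer vector with
#'   zero_lower, ci_ratio, age_cap).
#' @export
filter_ages <- function(records, max_ci_ratio = 10, max_age = 500000) {
  stopifnot(max_ci_ratio > 0, max_age > 0)
  zero_lower <- records$lower <= 0
  ratio_bad <- !zero_lower & (records$upper / records$lower) > max_ci_ratio
  age_bad <- !zero_lower & !ratio_bad & records$age > max_age
  keep <- !(zero_lower | ratio_bad | age_bad)
  list(retained = records[keep, , drop = FALSE],
       tally = c(zero_lower = sum(zero_lower), ci_ratio = sum(ratio_bad),
                 age_cap = sum(age_bad)))
}

#' Compare allele-age distributions between two groups
#'
#' Per-group median ages and a two-sided Wilcoxon rank-sum p-value, with an
#' optional stratification by allele-frequency bin when the records carry an
#' \code{af} column and \code{af_breaks} is given.
#'
#' @param records Filtered age records with a \code{group} column.
#' @param group_a,group_b Group labels to compare.
#' @param af_breaks Optional numeric break points for per-bin comparisons.
#' @return List: group_a, group_b, n_a, n_b, median_a, median_b, p, and
#'   optionally \code{strata} (data.frame per AF bin).
#' @export
compare_age_groups <- function(records, group_a, group_b, af_breaks = NULL) {
  a <- records$age[records$group == group_a]
  b <- records$age[records$group == group_b]
  if (!length(a) || !length(b)) {
    warning("empty group; comparison skipped")
    return(list(group_a = group_a, group_b = group_b,
                n_a = length(a), n_b = length(b),
                median_a = NA_real_, median_b = NA_real_, p = NA_real_))
  }
  p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  out <- list(group_a = group_a, group_b = group_b,
              n_a = length(a), n_b = length(b),
              median_a = stats::median(a), median_b = stats::median(b), p = p)
  if (!is.null(af_breaks) && "af" %in% names(records)) {
    bins <- cut(records$af, af_breaks, include.lowest = TRUE)
    rows <- lapply(levels(bins), function(bn) {
      sub <- records[!is.na(bins) & bins == bn, , drop = FALSE]
      sa <- sub$age[sub$group == group_a]; sb <- sub$age[sub$group == group_b]
      data.frame(bin = bn, n_a = length(sa), n_b = length(sb),
                 median_a = ifelse(length(sa), stats::median(sa), NA_real_),
                 median_b = ifelse(length(sb), stats::median(sb), NA_real_),
                 p = if (length(sa) && length(sb))
                   suppressWarnings(stats::wilcox.test(sa, sb)$p.value)
                 else NA_real_)
    })
    out$strata <- do.call(rbind, rows)
  }
  out
}
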