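#' Per-sample carrier status for a qualifying set
#'
#' A sample is a carrier iff it has dosage >= 1 for at least one qualifying
#' variant in the set. Missing genotypes count as non-carrier; the returned
#' vector carries an attribute \code{any_missing} flagging samples for which
#' that assumption was applied.
#'
#' @param set A \code{qv_set}.
#' @return Logical vector, one element per sample.
#' @export
carrier_status <- function(set) {
  G <- as.matrix(set$G)
  flags <- apply(!is.na(G) & G >= 1, 1, any)
  attr(flags, "any_missing") <- apply(is.na(G), 1, any)
  flags
}

#' Build a carrier-by-phenotype 2x2 table
#'
#' Cells: a = case carriers, b = case non-carriers, c = control carriers,
#' d = control non-carriers. If any cell is zero the Haldane-Anscombe
#' continuity correction adds 0.5 to all four cells (flagged via
#' \code{corrected}).
#'
#' @param carrier Logical carrier flags.
#' @param is_case Logical (or 0/1) case status; NA samples are dropped.
#' @return Object of class \code{carrier_table}: list(a, b, c, d, corrected,
#'   n_case, n_control), the last two holding raw stratum totals.
#' @export
carrier_table <- function(carrier, is_case) {
  stopifnot(length(carrier) == length(is_case))
  keep <- !is.na(is_case)
  carrier <- carrier[keep]; is_case <- as.logical(is_case[keep])
  tab <- list(a = sum(carrier & is_case), b = sum(!carrier & is_case),
              c = sum(carrier & !is_case), d = sum(!carrier & !is_case),
              corrected = FALSE,
              n_case = sum(is_case), n_control = sum(!is_case))
  if (min(tab$a, tab$b, tab$c, tab$d) == 0) {
    tab[c("a", "b", "c", "d")] <- lapply(tab[c("a", "b", "c", "d")], `+`, 0.5)
    tab$corrected <- TRUE
  }
  structure(tab, class = "carrier_table")
}

#' Odds ratio with Wald confidence interval on the log scale
#'
#' OR = (a d)/(b c) on the (possibly Haldane-Anscombe corrected) cells;
#' SE(log OR) = sqrt(1/a + 1/b + 1/c + 1/d); CI = exp(log OR +/- z SE).
#'
#' @param table A \code{carrier_table}.
#' @param level Confidence level, default 0.95.
#' @return List: or, log_se, ci_lower, ci_upper, level, corrected.
#' @export
#' @examples
#' odds_ratio_wald(carrier_table(rep(c(TRUE, FALSE), c(30, 170)),
#'                               rep(c(1, 0, 1, 0), c(20, 80, 10, 90))))
odds_ratio_wald <- function(table, level = 0.95) {
  stopifnot(inherits(table, "carrier_table"))
  with(table, {
    if (n_case == 0 || n_control == 0) {
      stop("empty stratum: need at least one case and one control",
           call. = FALSE)
    }
    or <- (a * d) / (b * c)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    z <- stats::qnorm(1 - (1 - level) / 2)
    list(or = or, log_se = se,
         ci_lower = exp(log(or) - z * se), ci_upper = exp(log(or) + z * se),
         level = level, corrected = corrected)
  })
}

#' Ancestry-stratified and pooled carrier odds ratios
#'
#' Builds the carrier-by-case 2x2 table within each ancestry stratum and on
#' all samples jointly (pooled counts, not a meta-analysis). Strata with zero
#' cases or zero controls are omitted with a warning.
#'
#' @param carrier Logical carrier flags.
#' @param is_case Case status (0/1 or logical; NA dropped per stratum).
#' @param ancestry Ancestry labels partitioning the samples.
#' @param level Confidence level.
#' @return List with \code{per_ancestry} (named list of estimates) and
#'   \code{pooled}.
#' @export
stratified_or <- function(carrier, is_case, ancestry, level = 0.95) {
  stopifnot(length(carrier) == length(is_case),
            length(carrier) == length(ancestry))
  per <- list()
  for (anc in sort(unique(as.character(ancestry)))) {
    idx <- ancestry == anc
    est <- tryCatch(
      odds_ratio_wald(carrier_table(carrier[idx], is_case[idx]), level),
      error = function(e) NULL)
    if (is.null(est)) {
      warning("skipping stratum '", anc, "': no cases or no controls")
    } else {
      per[[anc]] <- est
    }
  }
  pooled <- odds_ratio_wald(carrier_table(carrier, is_case), level)
  list(per_ancestry = per, pooled = pooled)
}

#' Hodges-Lehmann location shift
#'
#' Median of all pairwise differences \eqn{x_i - y_j}; the location estimate
#' paired with the Wilcoxon rank-sum test.
#'
#' @param x Carrier values (NA dropped).
#' @param y Non-carrier values (NA dropped).
#' @return Shift estimate.
#' @export
#' @examples
#' hodges_lehmann(c(1, 2), c(0, 1))  # 1
hodges_lehmann <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    stop("insufficient data: both samples must contain non-missing values")
  }
  stats::median(outer(x, y, `-`))
}

#' Trait specification
#'
#' Declares a trait's measurement kind and which direction of change is
#' clinically adverse. In the default panel the lower-is-worse traits are Age,
#' Age_AmongCase, the cognitive domains MEM/EXF/LAN/VSP and the CSF Abeta42
#' biomarker; AD, HS_S, TDP43 and CVD_S are binary; Braak, CERAD, LEWY_full,
#' CVD_ART and CVD_ATH are ordinal (higher-is-worse).
#'
#' @param name Trait name.
#' @param kind "binary", "quantitative" or "ordinal".
#' @param worse "higher" or "lower" (which direction is adverse).
#' @return List of class \code{trait_spec}.
#' @export
trait_spec <- function(name, kind = c("quantitative", "binary", "ordinal"),
                       worse = c("higher", "lower")) {
  kind <- match.arg(kind); worse <- match.arg(worse)
  structure(list(name = name, kind = kind, worse = worse),
            class = "trait_spec")
}

#' Default AD-related trait panel
#'
#' @return Named list of \code{trait_spec}.
#' @export
default_trait_specs <- function() {
  lower <- c("Age", "Age_AmongCase", "MEM", "EXF", "LAN", "VSP", "Abeta42")
  binary <- c("AD", "HS_S", "TDP43", "CVD_S")
  ordinal <- c("Braak", "CERAD", "LEWY_full", "CVD_ART", "CVD_ATH")
  quant <- c("Age", "Age_AmongCase", "MEM", "EXF", "LAN", "VSP",
             "Abeta42", "tTau", "pTau181")
  all <- unique(c(quant, binary, ordinal))
  specs <- lapply(all, function(nm) {
    trait_spec(nm,
               kind = if (nm %in% binary) "binary"
                      else if (nm %in% ordinal) "ordinal" else "quantitative",
               worse = if (nm %in% lower) "lower" else "higher")
  })
  names(specs) <- all
  specs
}

#' Direction-standardized signed score
#'
#' Maps a p-value and an effect (location shift or log-OR, positive meaning
#' carriers shifted toward higher values / higher odds) to
#' \eqn{sign(adversity) \times (-\log_{10} p)}, where the adversity sign is
#' the effect sign for higher-is-worse traits and its negation for
#' lower-is-worse traits. Positive scores mean carriers look worse.
#'
#' @param p P-value in (0, 1].
#' @param effect Finite effect estimate.
#' @param spec A \code{trait_spec}.
#' @return Signed score.
#' @export
standardize_direction <- function(p, effect, spec) {
  stopifnot(p > 0, p <= 1, is.finite(effect))
  adversity <- if (spec$worse == "higher") sign(effect) else -sign(effect)
  adversity * (-log10(p))
}

#' Carrier versus non-carrier trait comparison
#'
#' Quantitative and ordinal traits: two-sided Wilcoxon rank-sum test (exact
#' enumeration when both groups have at most \code{exact_limit} values and no
#' ties; otherwise normal approximation with tie and continuity correction)
#' plus the Hodges-Lehmann shift. Binary traits: two-sided Fisher's exact test
#' plus a (Haldane-Anscombe corrected when needed) log odds ratio as the
#' effect. Cells with fewer than 5 carriers are computed but flagged.
#'
#' @param carrier Logical carrier flags.
#' @param values Trait values aligned with \code{carrier}; NA allowed.
#' @param spec A \code{trait_spec}.
#' @param exact_limit Group-size bound for the exact Wilcoxon (default 25).
#' @return List of class \code{gene_trait_cell}: trait, kind, n_carrier,
#'   n_noncarrier, p, effect, signed_score, low_carrier_flag, untestable.
#' @export
trait_test <- function(carrier, values, spec, exact_limit = 25) {
  stopifnot(length(carrier) == length(values), inherits(spec, "trait_spec"))
  ok <- !is.na(values)
  x <- values[ok & carrier]; y <- values[ok & !carrier]
  base <- list(trait = spec$name, kind = spec$kind,
               n_carrier = length(x), n_noncarrier = length(y),
               p = NA_real_, effect = NA_real_, signed_score = NA_real_,
               low_carrier_flag = length(x) < 5, untestable = FALSE)
  if (!length(x) || !length(y)) {
    stop("need at least one carrier and one non-carrier with non-missing trait")
  }
  if (length(unique(c(x, y))) == 1L) {
    base$untestable <- TRUE
    return(structure(base, class = "gene_trait_cell"))
  }
  if (spec$kind == "binary") {
    tab <- matrix(c(sum(x == 1), sum(x == 0), sum(y == 1), sum(y == 0)), 2)
    p <- stats::fisher.test(tab)$p.value
    cells <- as.numeric(tab)
    if (min(cells) == 0) cells <- cells + 0.5
    effect <- log((cells[1] * cells[4]) / (cells[2] * cells[3]))
  } else {
    exact <- length(x) <= exact_limit && length(y) <= exact_limit &&
      !any(duplicated(c(x, y)))
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = !exact)$p.value)
    effect <- hodges_lehmann(x, y)
  }
  base$p <- min(max(p, 1e-300), 1)
  base$effect <- effect
  base$signed_score <- if (effect == 0) 0 else
    standardize_direction(base$p, effect, spec)
  structure(base, class = "gene_trait_cell")
}

#' Gene-by-trait carrier profile table
#'
#' Runs [trait_test()] for one gene's carrier flags against a panel of traits,
#' returning the long-format table used for heatmap-style summaries.
#' Age_AmongCase, when present in the specs and \code{is_case} is supplied, is
#' evaluated as the Age comparison restricted to case samples.
#'
#' @param carrier Logical carrier flags.
#' @param traits data.frame of trait columns (one row per sample).
#' @param specs Named list of \code{trait_spec}; default panel restricted to
#'   available columns.
#' @param is_case Optional case flags enabling Age_AmongCase.
#' @param gene Gene label for the output.
#' @return data.frame: gene, trait, n_carrier, n_noncarrier, p, effect,
#'   signed_score, low_carrier_flag, untestable.
#' @export
gene_trait_profile <- function(carrier, traits, specs = default_trait_specs(),
                               is_case = NULL, gene = NA_character_) {
  rows <- list()
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    if (nm == "Age_AmongCase") {
      if (is.null(is_case) || !"Age" %in% names(traits)) next
      keep <- !is.na(is_case) & is_case == 1
      cell <- tryCatch(trait_test(carrier[keep], traits$Age[keep], spec),
                       error = function(e) NULL)
    } else {
      if (!nm %in% names(traits)) next
      cell <- tryCatch(trait_test(carrier, traits[[nm]], spec),
                       error = function(e) NULL)
    }
    if (is.null(cell)) next
    rows[[nm]] <- data.frame(
      gene = gene, trait = nm, n_carrier = cell$n_carrier,
      n_noncarrier = cell$n_noncarrier, p = cell$p, effect = cell$effect,
      signed_score = cell$signed_score,
      low_carrier_flag = cell$low_carrier_flag, untestable = cell$untestable,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
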