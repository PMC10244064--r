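#' The nine sleep features analysed per hemisphere
#' @return character vector of feature names
#' @export
sleep_features <- function() {
  c("delta_power", "sw_density", "sw_amplitude", "sw_duration", "sw_slope",
    "sp_density", "sp_amplitude", "sp_duration", "sp_locking")
}

#' Lateralization index
#'
#' \eqn{LI = (X_{left} - X_{right}) / (X_{left} + X_{right})} for a
#' non-negative per-hemisphere magnitude X; bounded in [-1, 1]. When both
#' sides are exactly 0 the index is undefined and \code{NA} is returned.
#'
#' @param x_left,x_right non-negative magnitudes (vectorized)
#' @return LI in [-1, 1], or \code{NA} where both inputs are 0
#' @examples
#' lateralization_index(1.40, 1.61)   # spindle density example
#' @export
lateralization_index <- function(x_left, x_right) {
  if (any(x_left < 0, na.rm = TRUE) || any(x_right < 0, na.rm = TRUE))
    stop("lateralization index is defined for non-negative magnitudes")
  li <- (x_left - x_right) / (x_left + x_right)
  li[(x_left + x_right) == 0] <- NA_real_
  li
}

#' Probability of superiority (nonparametric effect size)
#'
#' The probability that a random draw from \code{a} exceeds a random draw
#' from \code{b}, ties counted one half:
#' \eqn{ES = [\#(a > b) + 0.5\,\#(a = b)] / (n_a n_b)}.
#'
#' @param a,b numeric samples (both nonempty)
#' @return effect size in [0, 1]
#' @export
probability_of_superiority <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  cmp <- outer(a, b, ">")
  tie <- outer(a, b, "==")
  (sum(cmp) + 0.5 * sum(tie)) / (length(a) * length(b))
}

#' Two-sided Mann-Whitney test
#'
#' Exact null distribution when both samples have at most
#' \code{exact_max} observations and no ties; otherwise the normal
#' approximation with tie and continuity correction. The returned \code{es}
#' is U / (n1 n2), the tie-corrected probability of superiority.
#'
#' @param a,b numeric samples
#' @param exact_max sample-size bound for the exact distribution (default 12)
#' @return list: \code{statistic} (U for \code{a}), \code{p}, \code{es},
#'   \code{exact}
#' @export
mann_whitney <- function(a, b, exact_max = 12) {
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= exact_max && length(b) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  u <- unname(wt$statistic)
  list(statistic = u, p = wt$p.value, es = u / (length(a) * length(b)),
       exact = exact)
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks of the pooled sample with the standard
#' tie correction; two-sided p-values are multiplied by the number of
#' comparisons performed (capped at 1), the multiple-comparison convention of
#' Dunn's test as reported by common statistics packages.
#'
#' @param values numeric vector
#' @param groups factor/character of group membership
#' @param comparisons list of length-2 character vectors naming the group
#'   pairs to contrast; default all pairs
#' @return data.frame: \code{group1}, \code{group2}, \code{z}, \code{p},
#'   \code{p_adj}
#' @export
dunn_test <- function(values, groups, comparisons = NULL) {
  groups <- as.character(groups)
  ok <- !is.na(values)
  values <- values[ok]; groups <- groups[ok]
  r <- rank(values)
  n <- length(values)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  if (is.null(comparisons)) {
    gs <- names(mean_rank)
    comparisons <- utils::combn(gs, 2, simplify = FALSE)
  }
  m <- length(comparisons)
  out <- do.call(rbind, lapply(comparisons, function(cp) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / n_g[[cp[1]]] + 1 / n_g[[cp[2]]]))
    z <- (mean_rank[[cp[1]]] - mean_rank[[cp[2]]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = cp[1], group2 = cp[2], z = z, p = p,
               p_adj = min(1, p * m), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# long LI table from a hemispheric feature table: one row per patient/feature
.li_records <- function(table, groups = NULL) {
  t <- as.data.frame(table)
  li <- lateralization_index(t$value_left, t$value_right)
  out <- data.frame(patient_id = t$patient_id, feature = t$feature, li = li,
                    stringsAsFactors = FALSE)
  if (!is.null(groups))
    out$group <- groups[match(out$patient_id, names(groups))]
  else if ("group" %in% names(t)) out$group <- t$group
  out
}

#' Group comparison of lateralization indices
#'
#' The left-focus and right-focus groups are compared on the LI of each
#' feature: delta power by a two-sided Mann-Whitney test on its own; the
#' slow-wave family (density, amplitude, duration, slope) and the spindle
#' family (density, amplitude, duration, locking) each by one Kruskal-Wallis
#' test across the group-by-feature cells followed by Dunn's contrasts of
#' left vs right focus within each feature, adjusted within the family.
#' Undefined LIs are dropped pairwise with a count. The probability of
#' superiority accompanies every contrast.
#'
#' @param records long LI table: \code{patient_id}, \code{feature},
#'   \code{li}, \code{group} (\code{"left"}/\code{"right"} focus)
#' @param families named list of feature families (default: the structure
#'   above); features not in any family are tested alone by Mann-Whitney
#' @return data.frame of class \code{"li_group_test"}: one row per feature
#'   with \code{test}, \code{statistic}, \code{p}, \code{p_adj}, \code{es},
#'   \code{n_left}, \code{n_right}, \code{n_dropped}
#' @export
group_compare <- function(records,
                          families = list(
                            sw = c("sw_density", "sw_amplitude",
                                   "sw_duration", "sw_slope"),
                            sp = c("sp_density", "sp_amplitude",
                                   "sp_duration", "sp_locking"))) {
  records <- as.data.frame(records)
  if (length(unique(records$group)) != 2L)
    stop("exactly two groups are required")
  if (min(table(unique(records[c("patient_id", "group")])$group)) < 2L)
    stop("each group needs at least 2 patients")
  feats <- unique(records$feature)
  fam_of <- function(f) {
    hit <- names(families)[vapply(families, function(v) f %in% v, TRUE)]
    if (length(hit)) hit[1] else NA_character_
  }
  rows <- list()
  for (fam in names(families)) {
    ff <- intersect(families[[fam]], feats)
    if (!length(ff)) next
    sub <- records[records$feature %in% ff & !is.na(records$li), ]
    cell <- paste(sub$feature, sub$group, sep = ":")
    kw <- stats::kruskal.test(sub$li, factor(cell))
    cmp <- lapply(ff, function(f) paste(f, c("left", "right"), sep = ":"))
    dt <- dunn_test(sub$li, cell, comparisons = cmp)
    for (i in seq_along(ff)) {
      f <- ff[i]
      a <- records$li[records$feature == f & records$group == "left"]
      b <- records$li[records$feature == f & records$group == "right"]
      drop_n <- sum(is.na(c(a, b)))
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, family = fam, test = "kruskal_dunn",
        statistic = dt$z[i], p = dt$p[i], p_adj = dt$p_adj[i],
        kw_statistic = unname(kw$statistic), kw_p = kw$p.value,
        es = probability_of_superiority(a, b),
        n_left = length(a), n_right = length(b), n_dropped = drop_n,
        stringsAsFactors = FALSE)
    }
  }
  solo <- feats[is.na(vapply(feats, fam_of, ""))]
  for (f in solo) {
    a <- records$li[records$feature == f & records$group == "left"]
    b <- records$li[records$feature == f & records$group == "right"]
    drop_n <- sum(is.na(c(a, b)))
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    mw <- mann_whitney(a, b)
    rows[[length(rows) + 1L]] <- data.frame(
      feature = f, family = NA_character_, test = "mann_whitney",
      statistic = mw$statistic, p = mw$p, p_adj = mw$p,
      kw_statistic = NA_real_, kw_p = NA_real_,
      es = probability_of_superiority(a, b),
      n_left = length(a), n_right = length(b), n_dropped = drop_n,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("li_group_test", "data.frame")
  out
}

#' Two-night stability of sleep-feature asymmetry
#'
#' Within each focus group and for each feature, a paired two-sided Wilcoxon
#' signed-rank test compares night 1 against night 2 across patients with
#' both nights. By default the per-patient LI is compared; \code{value} can
#' select the raw left or right hemisphere value instead. Fewer than
#' \code{min_pairs} complete pairs flags the row as underpowered (still
#' computed). When all paired differences are zero the p-value is reported
#' as 1.
#'
#' @param table hemispheric feature table with \code{night} in \code{1, 2}
#'   and a \code{group} column
#' @param value \code{"li"}, \code{"left"} or \code{"right"}
#' @param min_pairs underpowered threshold (default 5)
#' @return data.frame: \code{group}, \code{feature}, \code{n_pairs},
#'   \code{statistic}, \code{p}, \code{underpowered}
#' @export
night_stability <- function(table, value = c("li", "left", "right"),
                            min_pairs = 5) {
  value <- match.arg(value)
  t <- as.data.frame(table)
  pick <- function(sub) switch(value,
    li = lateralization_index(sub$value_left, sub$value_right),
    left = sub$value_left, right = sub$value_right)
  out <- list()
  for (g in unique(t$group)) for (f in unique(t$feature)) {
    s1 <- t[t$group == g & t$feature == f & t$night %in% c(1, "1"), ]
    s2 <- t[t$group == g & t$feature == f & t$night %in% c(2, "2"), ]
    common <- intersect(s1$patient_id, s2$patient_id)
    if (!length(common)) next
    v1 <- pick(s1[match(common, s1$patient_id), ])
    v2 <- pick(s2[match(common, s2$patient_id), ])
    ok <- !is.na(v1) & !is.na(v2)
    v1 <- v1[ok]; v2 <- v2[ok]
    if (all(v1 == v2)) {
      stat <- 0; p <- 1
    } else {
      wt <- suppressWarnings(stats::wilcox.test(v1, v2, paired = TRUE))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    out[[length(out) + 1L]] <- data.frame(
      group = g, feature = f, n_pairs = length(v1), statistic = stat, p = p,
      underpowered = length(v1) < min_pairs, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Paired epileptic vs non-epileptic hemisphere comparison
#'
#' Reorders each patient's (left, right) values to (epileptic,
#' non-epileptic) according to the focus label and runs a paired two-sided
#' Wilcoxon signed-rank test on the raw values, reporting the median and
#' interquartile range per side.
#'
#' @param table hemispheric feature table with a \code{group} column
#'   (\code{"left"}/\code{"right"} focus)
#' @param feature which feature to test
#' @param min_pairs underpowered threshold (default 5)
#' @return list: \code{n}, \code{statistic}, \code{p},
#'   \code{median_epileptic}, \code{iqr_epileptic},
#'   \code{median_nonepileptic}, \code{iqr_nonepileptic},
#'   \code{underpowered}
#' @export
paired_hemisphere_compare <- function(table, feature, min_pairs = 5) {
  t <- as.data.frame(table)
  t <- t[t$feature == feature, ]
  if (!nrow(t)) stop("feature not present: ", feature)
  epi <- ifelse(t$group == "left", t$value_left, t$value_right)
  non <- ifelse(t$group == "left", t$value_right, t$value_left)
  ok <- !is.na(epi) & !is.na(non)
  epi <- epi[ok]; non <- non[ok]
  if (all(epi == non)) {
    stat <- 0; p <- 1
  } else {
    wt <- suppressWarnings(stats::wilcox.test(epi, non, paired = TRUE))
    stat <- unname(wt$statistic); p <- wt$p.value
  }
  list(n = length(epi), statistic = stat, p = p,
       median_epileptic = stats::median(epi),
       iqr_epileptic = unname(stats::quantile(epi, c(0.25, 0.75))),
       median_nonepileptic = stats::median(non),
       iqr_nonepileptic = unname(stats::quantile(non, c(0.25, 0.75))),
       underpowered = length(epi) < min_pairs)
}
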