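#' @importFrom stats shapiro.test t.test oneway.test aov anova pchisq
#' @importFrom car leveneTest
NULL

#' Screening parameters
#'
#' @param fc_threshold Fold-change threshold; a miRNA is called only when
#'   its fold change is strictly greater than this value or strictly less
#'   than its reciprocal (default 1.5).
#' @param alpha Significance level; the rule is strict (`p < alpha`),
#'   default 0.05.
#' @param normality_alpha Level of the per-group Shapiro-Wilk normality
#'   check used in test selection (default 0.05).
#' @param variance_alpha Level of the Brown-Forsythe (median-centred
#'   Levene) homogeneity check (default 0.05).
#' @param top_k Number of entries per direction in [topTable()]
#'   (default 5).
#' @return A list of validated screening parameters.
#' @export
screenParams <- function(fc_threshold = 1.5, alpha = 0.05,
                         normality_alpha = 0.05, variance_alpha = 0.05,
                         top_k = 5L) {
  stopifnot(fc_threshold > 1, alpha > 0, alpha < 1,
            normality_alpha > 0, normality_alpha < 1,
            variance_alpha > 0, variance_alpha < 1, top_k >= 1L)
  list(fc_threshold = fc_threshold, alpha = alpha,
       normality_alpha = normality_alpha, variance_alpha = variance_alpha,
       top_k = as.integer(top_k))
}

## Shapiro-Wilk per group; degenerate (constant) groups are treated as
## consistent with normality rather than erroring.
groupsNormal <- function(groups, alpha) {
  all(vapply(groups, function(g) {
    if (length(unique(g)) == 1L) return(TRUE)
    shapiro.test(g)$p.value > alpha
  }, logical(1)))
}

## Brown-Forsythe homogeneity; constant groups give an undefined
## statistic and are treated as homogeneous.
groupsHomoscedastic <- function(groups, alpha) {
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  p <- tryCatch(car::leveneTest(y, g)[1L, "Pr(>F)"], error = function(e) NaN)
  if (is.na(p)) TRUE else p > alpha
}

#' Select the comparison test for a set of measurement groups
#'
#' Mirrors the screening protocol's decision tree: two groups that are
#' consistent with normality (Shapiro-Wilk per group) and variance
#' homogeneity (Brown-Forsythe) are compared with Student's t-test, two
#' groups failing either check with Welch's unequal-variance t-test; more
#' than two groups use one-way ANOVA when both checks pass and the Welch
#' ANOVA otherwise.
#'
#' @param groups List of two or more numeric vectors, each of length >= 3
#'   (normality is untestable below 3 observations).
#' @param params A [screenParams()] list.
#' @return One of `"student-t"`, `"welch-t"`, `"anova"`, `"welch-anova"`.
#' @examples
#' set.seed(1)
#' selectTest(list(rnorm(10), rnorm(10)))
#' @export
selectTest <- function(groups, params = screenParams()) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 3L))
    stop("every group needs >= 3 values (normality untestable otherwise)")
  parametric <- groupsNormal(groups, params$normality_alpha) &&
    groupsHomoscedastic(groups, params$variance_alpha)
  if (length(groups) == 2L) {
    if (parametric) "student-t" else "welch-t"
  } else {
    if (parametric) "anova" else "welch-anova"
  }
}

## p-value for a chosen test; degenerate zero-variance input is resolved
## by the limit of the statistic (equal means -> 1, different means -> 0).
testPValue <- function(groups, test) {
  degenerate <- all(vapply(groups, function(g) length(unique(g)) == 1L,
                           logical(1)))
  if (degenerate) {
    means <- vapply(groups, mean, numeric(1))
    return(if (max(means) - min(means) == 0) 1 else 0)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  out <- tryCatch(switch(test,
    "student-t"   = t.test(groups[[1L]], groups[[2L]], var.equal = TRUE)$p.value,
    "welch-t"     = t.test(groups[[1L]], groups[[2L]], var.equal = FALSE)$p.value,
    "anova"       = oneway.test(y ~ g, var.equal = TRUE)$p.value,
    "welch-anova" = oneway.test(y ~ g, var.equal = FALSE)$p.value,
    stop("unknown test: ", test)),
    error = function(e) NA_real_)
  if (is.na(out)) {
    means <- vapply(groups, mean, numeric(1))
    out <- if (max(means) - min(means) == 0) 1 else 0
  }
  out
}

#' Linear fold change between two groups
#'
#' Ratio of the case-group mean to the control-group mean on the linear
#' intensity scale; values below 1 indicate down-regulation in the case
#' group. Antisymmetric: `foldChange(a, b) * foldChange(b, a) == 1`.
#'
#' @param control Numeric vector of control-group intensities.
#' @param case Numeric vector of case-group intensities.
#' @return Positive scalar fold change.
#' @examples
#' foldChange(control = rep(100, 5), case = rep(76.5, 5))
#' @export
foldChange <- function(control, case) {
  mc <- mean(control); mk <- mean(case)
  if (!is.finite(mc) || !is.finite(mk) || mc <= 0 || mk <= 0)
    stop("fold change requires positive group means")
  mk / mc
}

#' Screen miRNAs for differential expression between two groups
#'
#' For every miRNA in the (preprocessed) array set, selects the
#' comparison test per [selectTest()], computes the linear fold change
#' (case over control) and the test p-value, and applies the compound
#' significance rule: the fold change must be *strictly* greater than
#' `fc_threshold` (or strictly less than its reciprocal) *and* the
#' p-value strictly below `alpha`. A fold change of exactly 1.5 or a
#' p-value of exactly 0.05 is therefore not significant under the
#' defaults.
#'
#' @param x A [MirnaArraySet-class] (run [preprocess()] first).
#' @param control Control group label (default `"NHF"`).
#' @param case Case group label.
#' @param params A [screenParams()] list.
#' @return A [S4Vectors::DataFrame-class] with one row per miRNA and
#'   columns `mirna`, `fold_change`, `p_value`, `neg_log10_p`,
#'   `test_used`, `direction` (`"up"`, `"down"` or `"none"` relative to
#'   fold change 1) and `significant`; the comparison and parameters are
#'   stored in its metadata.
#' @examples
#' sim <- simulateExpression(SimConfig(seed = 1))
#' res <- screenMirnas(preprocess(sim$experiment), case = "AMNHF")
#' head(as.data.frame(res))
#' @export
screenMirnas <- function(x, control = "NHF", case, params = screenParams()) {
  stopifnot(is(x, "MirnaArraySet"))
  grp <- groupLabels(x)
  for (g in c(control, case))
    if (!g %in% grp) stop("group label not present in design: ", g)
  m <- intensities(x)
  ctl <- m[, grp == control, drop = FALSE]
  cas <- m[, grp == case, drop = FALSE]

  n <- nrow(m)
  fc <- p <- numeric(n)
  test <- character(n)
  for (i in seq_len(n)) {
    groups <- list(ctl[i, ], cas[i, ])
    test[i] <- selectTest(groups, params)
    p[i] <- testPValue(groups, test[i])
    fc[i] <- foldChange(groups[[1L]], groups[[2L]])
  }
  direction <- ifelse(fc > 1, "up", ifelse(fc < 1, "down", "none"))
  significant <- (fc > params$fc_threshold | fc < 1 / params$fc_threshold) &
    p < params$alpha

  res <- S4Vectors::DataFrame(
    mirna = rownames(m), fold_change = fc, p_value = p,
    neg_log10_p = negLog10P(p), test_used = test,
    direction = direction, significant = significant,
    row.names = rownames(m))
  S4Vectors::metadata(res) <- list(control = control, case = case,
                                   params = params)
  res
}

## -log10 p with underflow protection: p below 1e-300 is capped before
## the log so the ordinate stays finite.
negLog10P <- function(p, p_floor = 1e-300) {
  capped <- p < p_floor
  if (any(capped))
    message(sum(capped), " p-value(s) below ", p_floor,
            " capped before -log10")
  -log10(pmax(p, p_floor))
}

#' Top-k up- and down-regulated tables
#'
#' Ranks screen hits into the two published-table layouts: `top_k`
#' up-regulated and `top_k` down-regulated miRNAs with p-value below
#' `alpha`, each table ordered by ascending p-value with descending fold
#' change and then miRNA id as deterministic tie-breaks. This follows
#' the published tables, which select by p-value (their down tables are
#' headed by miR-320 then miR-204 and include fold changes inside the
#' 1.5x band); the compound fold-change-and-p rule remains the
#' `significant` flag used by the volcano plot.
#'
#' @param results A screen result from [screenMirnas()].
#' @param params A [screenParams()] list (`top_k` and `alpha` are used).
#' @return List with `up` and `down` data frames; fewer than `top_k`
#'   qualifying hits yields a shorter table and a notice.
#' @export
topTable <- function(results, params = screenParams()) {
  stopifnot(nrow(results) > 0L)
  df <- as.data.frame(results)
  k <- params$top_k
  pick <- function(dir) {
    sub <- df[df$p_value < params$alpha & df$direction == dir, , drop = FALSE]
    if (nrow(sub) < k)
      message("topTable: only ", nrow(sub), " ", dir,
              "-regulated miRNAs at p < ", params$alpha,
              " for top_k = ", k)
    ord <- order(sub$p_value, -sub$fold_change, sub$mirna)
    out <- sub[ord, , drop = FALSE]
    out[seq_len(min(k, nrow(out))), , drop = FALSE]
  }
  list(up = pick("up"), down = pick("down"))
}

#' Volcano-plot coordinates
#'
#' One point per screened miRNA with the fold change on the abscissa and
#' `-log10(p)` on the ordinate; significant hits carry the screen's
#' significance flag for colouring.
#'
#' @param results A screen result from [screenMirnas()].
#' @param max_neg_log10 Cap on the ordinate for underflowing p-values
#'   (default 300).
#' @return `data.frame` with columns `mirna`, `fold_change`,
#'   `neg_log10_p`, `significant`.
#' @export
volcanoPoints <- function(results, max_neg_log10 = 300) {
  df <- as.data.frame(results)
  data.frame(mirna = df$mirna,
             fold_change = df$fold_change,
             neg_log10_p = pmin(df$neg_log10_p, max_neg_log10),
             significant = df$significant,
             stringsAsFactors = FALSE)
}

#' Per-day summary of an optical-density assay
#'
#' @param od `data.frame` from [simulateOD()] (columns `day`, `well`,
#'   `od`).
#' @return `data.frame` with per-day `n_wells`, `mean` and sample `sd`
#'   of the well ODs; a single well gives `sd = 0` with a notice.
#' @export
odSummary <- function(od) {
  stopifnot(all(c("day", "od") %in% names(od)), nrow(od) > 0L)
  days <- sort(unique(od$day))
  out <- do.call(rbind, lapply(days, function(d) {
    v <- od$od[od$day == d]
    data.frame(day = d, n_wells = length(v), mean = mean(v),
               sd = if (length(v) > 1L) sd(v) else 0)
  }))
  if (any(out$n_wells == 1L))
    message("odSummary: day(s) with a single well report sd = 0")
  out
}
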