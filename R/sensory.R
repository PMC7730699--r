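#' Validate a long sensory score table
#'
#' Checks the quantitative descriptive profile layout: columns
#' `panellist`, `session`, `sample`, `attribute`, `score`; scores within
#' 0-100; and a balanced design (every panellist x session x sample cell
#' present once for each attribute).
#'
#' @param scores long data.frame of panel scores.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_sensory_scores <- function(scores) {
  scores <- as.data.frame(scores)
  need <- c("panellist", "session", "sample", "attribute", "score")
  miss <- setdiff(need, names(scores))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(scores$score < 0 | scores$score > 100))
    stop("scores outside the 0-100 scale")
  for (att in unique(scores$attribute)) {
    sub <- scores[scores$attribute == att, ]
    tab <- table(sub$panellist, sub$session, sub$sample)
    if (any(tab != 1))
      stop("unbalanced design for attribute '", att,
           "': every panellist x session x sample cell must appear once")
  }
  scores
}

# Compact letter display for means sorted descending with one common
# honest significant difference: letters are the maximal runs of
# consecutive means whose range does not exceed `hsd` (insert-and-absorb).
cld_letters <- function(means, hsd) {
  ord <- order(-means)
  m <- means[ord]
  k <- length(m)
  # maximal run starting at each i; ends are non-decreasing in i, so a run
  # is absorbed (contained in an earlier one) iff it does not extend the end
  runs <- list()
  last_end <- 0L
  for (i in seq_len(k)) {
    j <- i
    while (j < k && m[i] - m[j + 1] <= hsd) j <- j + 1
    if (j > last_end || i == 1L) {
      runs[[length(runs) + 1L]] <- c(i, j)
      last_end <- j
    }
  }
  lett <- rep("", k)
  for (r in seq_along(runs)) {
    span <- seq(runs[[r]][1], runs[[r]][2])
    lett[span] <- paste0(lett[span], letters[r])
  }
  out <- character(k)
  out[ord] <- lett
  out
}

#' Two-way ANOVA with Tukey HSD letters for one sensory attribute
#'
#' Fits the fixed-effects model
#' `score = sample + assessor + sample:assessor` on a balanced replicated
#' panel table, then compares sample means by Tukey's honest significant
#' difference computed from the residual mean square. Letters are
#' assigned greedily from the highest mean; samples sharing a letter are
#' not significantly different at `alpha`. The residual root mean square
#' error doubles as the panel repeatability index.
#'
#' @param scores long table as in [validate_sensory_scores()].
#' @param attribute attribute name to analyse.
#' @param alpha significance level for the HSD (default 0.05).
#' @return list of class `sensory_anova` with `anova` (data.frame of F
#'   and p for sample, assessor, interaction), `tukey` (sample means with
#'   letters), `rmse`, `alpha`.
#' @export
two_way_anova_tukey <- function(scores, attribute, alpha = 0.05) {
  scores <- validate_sensory_scores(scores)
  sub <- scores[scores$attribute == attribute, ]
  if (!nrow(sub)) stop("attribute '", attribute, "' not present")
  sub$sample <- factor(sub$sample)
  sub$assessor <- factor(sub$panellist)
  fit <- aov(score ~ sample + assessor + sample:assessor, data = sub)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  pick <- function(term, col) tab[match(term, terms), col]
  anova_df <- data.frame(
    term = c("sample", "assessor", "interaction"),
    df = c(pick("sample", "Df"), pick("assessor", "Df"),
           pick("sample:assessor", "Df")),
    F = c(pick("sample", "F value"), pick("assessor", "F value"),
          pick("sample:assessor", "F value")),
    p = c(pick("sample", "Pr(>F)"), pick("assessor", "Pr(>F)"),
          pick("sample:assessor", "Pr(>F)")))
  mse <- tab[match("Residuals", terms), "Mean Sq"]
  df_res <- tab[match("Residuals", terms), "Df"]
  means <- tapply(sub$score, sub$sample, mean)
  n_per <- tapply(sub$score, sub$sample, length)
  hsd <- qtukey(1 - alpha, nlevels(sub$sample), df_res) *
    sqrt(mse / n_per[1])
  tukey <- data.frame(sample = names(means), mean = as.numeric(means),
                      letter = cld_letters(as.numeric(means), hsd))
  tukey <- tukey[order(-tukey$mean), ]
  rownames(tukey) <- NULL
  structure(list(anova = anova_df, tukey = tukey, hsd = as.numeric(hsd),
                 rmse = sqrt(mse), alpha = alpha),
            class = "sensory_anova")
}

#' @export
print.sensory_anova <- function(x, ...) {
  print(x$anova, row.names = FALSE)
  cat(sprintf("residual RMSE %.2f | HSD %.2f\n", x$rmse, x$hsd))
  print(x$tukey, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA reconstructed from group summaries
#'
#' Computes the one-way F test from per-group means and standard
#' deviations alone, the route for re-analysing published summary tables
#' when raw scores are unavailable. Between-group mean square uses the
#' group means about their grand mean; within-group mean square pools
#' the (n-1)-denominator SDs. On balanced data this equals the F computed
#' from the raw observations.
#'
#' @param means per-group means.
#' @param sds per-group standard deviations (n-1 denominator).
#' @param n_per_group common group size (>= 2).
#' @param alpha significance level.
#' @return list with `F`, `p`, `significant`, `df1`, `df2`.
#' @export
oneway_anova_from_summary <- function(means, sds, n_per_group,
                                      alpha = 0.05) {
  stopifnot(length(means) == length(sds), length(means) >= 2,
            n_per_group >= 2, all(sds >= 0))
  k <- length(means)
  df1 <- k - 1L
  df2 <- k * (n_per_group - 1L)
  msb <- n_per_group * sum((means - mean(means))^2) / df1
  msw <- sum((n_per_group - 1) * sds^2) / df2
  F <- if (msw == 0) { if (msb == 0) 0 else Inf } else msb / msw
  p <- pf(F, df1, df2, lower.tail = FALSE)
  list(F = F, p = p, significant = p < alpha, df1 = df1, df2 = df2)
}

#' Count attributes with significant sample differences
#'
#' Applies [oneway_anova_from_summary()] to every attribute of a long
#' summary table (columns `attribute`, `sample`, `mean`, `sd`) and counts
#' how many differ significantly between samples at `alpha`.
#'
#' @param summary_table long per-attribute, per-sample summary table.
#' @param n_per_group observations behind each summarized cell.
#' @param alpha significance level.
#' @return integer count; the per-attribute data.frame (with `F` and `p`)
#'   is attached as attribute `"details"`.
#' @export
count_significant_attributes <- function(summary_table, n_per_group = 28L,
                                         alpha = 0.05) {
  summary_table <- as.data.frame(summary_table)
  atts <- unique(summary_table$attribute)
  details <- do.call(rbind, lapply(atts, function(att) {
    sub <- summary_table[summary_table$attribute == att, ]
    r <- oneway_anova_from_summary(sub$mean, sub$sd, n_per_group, alpha)
    data.frame(attribute = att, F = r$F, p = r$p,
               significant = r$significant)
  }))
  structure(sum(details$significant), details = details)
}
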