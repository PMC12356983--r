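#' Median and interquartile range
#'
#' The summary used for the absolute and contrast tables: median and
#' IQR = Q3 - Q1 with linear-interpolation (type-7) quantiles.
#'
#' @param values non-empty numeric vector.
#' @return Named numeric \code{c(median, iqr)}.
#' @examples
#' summarizeMedianIQR(1:5)  # median 3, iqr 2
#' @export
summarizeMedianIQR <- function(values) {
  if (length(values) == 0L)
    stop("empty_input: cannot summarize an empty vector", call. = FALSE)
  c(median = stats::median(values),
    iqr = unname(diff(stats::quantile(values, c(0.25, 0.75), type = 7))))
}

.apply_transform <- function(x, transform, label) {
  if (transform == "none") return(x)
  bad <- sum(x <= 0)
  if (bad > 0)
    stop("nonpositive_under_log: ", bad, " non-positive value(s) in ", label,
         " cannot be log-transformed", call. = FALSE)
  log(x)
}

#' Two-group comparison: t-test on means and F-test on variances
#'
#' The classical pairing used for environment comparisons: a pooled-variance
#' independent-samples t-test (Welch by request) together with a two-sample
#' F-test for equality of variances, optionally on log-transformed values
#' (the variance stabilizer for right-skewed intensity data).  The paired
#' variant requires equal lengths.
#'
#' @param a,b numeric vectors, each with >= 3 values.
#' @param transform \code{"none"} or \code{"log"} (natural log; non-positive
#'   values raise a named error with the offender count).
#' @param paired paired t-test instead of independent samples.
#' @param welch Welch t-test instead of the pooled-variance default.
#' @return data.frame with rows for the t-test and (unpaired only) the
#'   F-test: columns \code{kind}, \code{statistic}, \code{df}, \code{df2},
#'   \code{p_value}, \code{transform}.
#' @examples
#' compareGroups(c(1, 2, 3), c(4, 5, 6))  # pooled t = -3.674, df 4
#' @export
compareGroups <- function(a, b, transform = c("none", "log"), paired = FALSE,
                          welch = FALSE) {
  transform <- match.arg(transform)
  if (length(a) < 3L || length(b) < 3L)
    stop("too_few_values: each group needs >= 3 values", call. = FALSE)
  if (paired && length(a) != length(b))
    stop("unequal_lengths: paired comparison needs equal group sizes",
         call. = FALSE)
  ta <- .apply_transform(a, transform, "group a")
  tb <- .apply_transform(b, transform, "group b")
  tt <- stats::t.test(ta, tb, paired = paired, var.equal = !welch && !paired)
  out <- data.frame(kind = if (paired) "t_paired" else "t_independent",
                    statistic = unname(tt$statistic),
                    df = unname(tt$parameter), df2 = NA_real_,
                    p_value = tt$p.value, transform = transform)
  if (!paired) {
    ft <- stats::var.test(ta, tb)
    out <- rbind(out, data.frame(kind = "F_variance",
                                 statistic = unname(ft$statistic),
                                 df = unname(ft$parameter[1]),
                                 df2 = unname(ft$parameter[2]),
                                 p_value = ft$p.value, transform = transform))
  }
  out
}

#' One-way ANOVA with Tukey-Kramer post-tests
#'
#' F-test across k groups with (k - 1, N - k) degrees of freedom, followed by
#' Tukey's honestly-significant-difference pairwise comparisons, which honour
#' unequal group sizes (the Tukey-Kramer form).
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param transform \code{"none"} or \code{"log"}.
#' @return List: \code{anova} (data.frame with F, dfs, p) and \code{tukey}
#'   (data.frame of pairwise differences with adjusted p-values).
#' @export
anovaTukey <- function(groups, transform = c("none", "log")) {
  transform <- match.arg(transform)
  if (length(groups) < 2L)
    stop("too_few_groups: ANOVA needs >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("too_few_values: every group needs >= 2 values", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  values <- .apply_transform(unlist(groups, use.names = FALSE), transform,
                             "groups")
  if (stats::sd(values) == 0)
    stop("degenerate_variance: all values identical across groups",
         call. = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit)$g
  list(anova = data.frame(kind = "anova_oneway",
                          statistic = an[1, "F value"],
                          df = an[1, "Df"], df2 = an[2, "Df"],
                          p_value = an[1, "Pr(>F)"], transform = transform),
       tukey = data.frame(pair = rownames(tuk), diff = tuk[, "diff"],
                          lwr = tuk[, "lwr"], upr = tuk[, "upr"],
                          p_adj = tuk[, "p adj"], row.names = NULL))
}

#' Normalized relative difference across illuminants
#'
#' For one metric (melanopsin, luminance or radiance), the human-made minus
#' natural mean relative to the natural mean, normalized by the maximum of
#' that relative difference across illuminants:
#' NRD_k = ((HM_k - Nat_k) / Nat_k) / max_k ((HM_k - Nat_k) / Nat_k).
#' Self-normalizing, so the maximum entry is exactly 1 and common rescaling
#' of all means cancels.
#'
#' @param hmMeans,natMeans numeric vectors of per-illuminant group means,
#'   named by illuminant, same order and length.
#' @return data.frame with columns \code{illuminant}, \code{relative_diff},
#'   \code{nrd}.
#' @examples
#' nrdTable(c(A = 3, B = 2), c(A = 1, B = 1))$nrd  # 1.0 0.5
#' @export
nrdTable <- function(hmMeans, natMeans) {
  if (length(hmMeans) < 1L || length(hmMeans) != length(natMeans))
    stop("length_mismatch: need matching per-illuminant HM and Nat means",
         call. = FALSE)
  if (any(natMeans == 0))
    stop("zero_reference: natural mean of zero makes the relative difference undefined",
         call. = FALSE)
  rel <- (hmMeans - natMeans) / natMeans
  mx <- max(rel)
  if (mx <= 0)
    stop("nonpositive_maximum: NRD normalization needs a positive maximum relative difference",
         call. = FALSE)
  data.frame(illuminant = if (is.null(names(hmMeans)))
    as.character(seq_along(hmMeans)) else names(hmMeans),
    relative_diff = unname(rel), nrd = unname(rel / mx), row.names = NULL)
}
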