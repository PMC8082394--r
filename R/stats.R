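#' Mean and sample standard deviation of a group
#'
#' Results throughout the package are summarised as mean plus/minus the
#' sample standard deviation (n - 1 denominator).
#'
#' @param values numeric vector (length >= 2 for a finite SD)
#' @return list with `mean`, `sd` and `n`
#' @export
groupSummary <- function(values) {
  if (!length(values)) stop("empty input", call. = FALSE)
  list(mean = mean(values),
       sd = if (length(values) >= 2) sd(values) else NA_real_,
       n = length(values))
}

#' Significance tiers as stars
#'
#' @param p p-value(s)
#' @return `"***"` below 0.001, `"**"` below 0.01, `"*"` below 0.05,
#'   `"ns"` otherwise
#' @export
significanceStars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Welch's unequal-variance two-tailed t-test
#'
#' The unpaired two-tailed Student's t-test with unequal variances:
#' \deqn{t = \frac{\bar a - \bar b}{\sqrt{s_a^2/n_a + s_b^2/n_b}}}
#' with Welch-Satterthwaite degrees of freedom
#' \deqn{\nu = \frac{(s_a^2/n_a + s_b^2/n_b)^2}
#'       {\frac{(s_a^2/n_a)^2}{n_a-1} + \frac{(s_b^2/n_b)^2}{n_b-1}}}
#' and the two-tailed p-value from the t distribution. Implemented from the
#' formulas with the t CDF as the only numerical primitive. When both groups
#' have zero variance and equal means, `t = 0` and `p = 1` by convention.
#' No multiple-testing correction is applied anywhere in the package;
#' each endpoint is tested at alpha = 0.05, and reports flag this.
#'
#' @param a,b numeric vectors, each of length >= 2
#' @return one-row data.frame with `meanA`, `sdA`, `nA`, `meanB`, `sdB`,
#'   `nB`, `tStat`, `dof`, `pValue`, `stars`
#' @export
welchTTest <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2)
    stop("both groups need at least 2 observations", call. = FALSE)
  ma <- mean(a); mb <- mean(b)
  va <- var(a); vb <- var(b)
  sea <- va / na; seb <- vb / nb
  se2 <- sea + seb
  if (se2 == 0) {
    tt <- 0; dof <- na + nb - 2; p <- 1
  } else {
    tt <- (ma - mb) / sqrt(se2)
    dof <- se2^2 / (sea^2 / (na - 1) + seb^2 / (nb - 1))
    p <- 2 * pt(-abs(tt), df = dof)
  }
  data.frame(meanA = ma, sdA = sqrt(va), nA = na,
             meanB = mb, sdB = sqrt(vb), nB = nb,
             tStat = tt, dof = dof, pValue = p,
             stars = significanceStars(p))
}

#' @importFrom stats var
NULL
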