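# Paired US-vs-DTI comparison statistics: exact Wilcoxon signed-rank test,
# descriptive medians/ranges, within-subject absolute differences, height
# normalization and BMI.

#' Wilcoxon signed-rank test with exact small-sample p-value
#'
#' Classic signed-rank test on paired differences: zero differences are
#' discarded, absolute differences are mid-ranked under ties, and W is the
#' sum of the ranks of the positive differences. For `n <= exactMax`
#' effective pairs the two-sided p-value is exact over all 2^n equally
#' likely sign assignments (computed by generating-function convolution,
#' identical to full enumeration, and valid under ties); beyond that a
#' normal approximation with tie and continuity corrections is used.
#' Two-sided p is twice the smaller tail probability, capped at 1.
#'
#' @param x numeric vector (differences), or first measurement if `y`
#'   given.
#' @param y optional second measurement; the test is on `x - y`.
#' @param exactMax largest n for the exact null distribution (default 25).
#' @param zeroHandling `"wilcoxon"` (drop zeros, default) or `"pratt"`
#'   (rank with zeros, then drop their ranks).
#' @return List of class `wilcoxonSR`: `statistic` (W, sum of positive
#'   ranks), `nEffective`, `pValue`, `method` ("exact" or
#'   "normal_approx").
#' @examples
#' wilcoxonSignedRank(c(1, 2, 3, 4, 5))  # W = 15, p = 2/32
#' @export
wilcoxonSignedRank <- function(x, y = NULL, exactMax = 25L,
                               zeroHandling = c("wilcoxon", "pratt")) {
  zeroHandling <- match.arg(zeroHandling)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (any(!is.finite(d))) stop("differences must be finite")
  if (all(d == 0))
    stop("all paired differences are zero; the test carries no information")
  if (zeroHandling == "wilcoxon") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r <- rank(abs(d))
    keep <- d != 0
    d <- d[keep]; r <- r[keep]
  }
  n <- length(d)
  W <- sum(r[d > 0])
  if (n <= exactMax) {
    # distribution of W over all sign assignments; work in doubled units
    # so mid-ranks (k + 0.5) stay integral
    r2 <- as.integer(round(2 * r))
    S <- sum(r2)
    counts <- numeric(S + 1L)
    counts[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(S + 1L - ri)])
      counts <- counts + shifted
    }
    tot <- 2^n
    w2 <- as.integer(round(2 * W))
    pLo <- sum(counts[seq_len(w2 + 1L)]) / tot
    pHi <- sum(counts[(w2 + 1L):(S + 1L)]) / tot
    p <- min(1, 2 * min(pLo, pHi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(z, lower.tail = FALSE))
    method <- "normal_approx"
  }
  structure(list(statistic = W, nEffective = n, pValue = p,
                 method = method), class = "wilcoxonSR")
}

#' @export
print.wilcoxonSR <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon signed-rank: W = %.1f, n = %d, two-sided p = %.6g (%s)\n",
    x$statistic, x$nEffective, x$pValue, x$method))
  invisible(x)
}

#' Mean and SD of within-subject absolute differences
#'
#' Summarizes |us - dti| over matched pairs with the sample (n - 1)
#' standard deviation.
#'
#' @param x,y paired measurements (same subjects, same units).
#' @return List with `mean`, `sd` (NA with a flag when n < 2) and `n`.
#' @export
pairedAbsSummary <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  a <- abs(x - y)
  list(mean = mean(a), sd = if (length(a) >= 2L) sd(a) else NA_real_,
       n = length(a), sdDefined = length(a) >= 2L)
}

#' Median and range
#'
#' Descriptive summary in the median (min, max) style.
#'
#' @param values nonempty numeric vector.
#' @return List with `median`, `min`, `max`.
#' @export
medianRange <- function(values) {
  if (!length(values)) stop("cannot summarize an empty vector")
  list(median = median(values), min = min(values), max = max(values))
}

#' Normalize a length by body height
#'
#' Divides a mm-valued measurement by the height expressed in mm, giving a
#' dimensionless ratio. (Any fixed positive scaling would leave the
#' rank-based comparison statistics unchanged; mm/mm keeps the quantity
#' unit-consistent.)
#'
#' @param valueMm measurement in mm.
#' @param heightCm body height in cm (> 0).
#' @return Dimensionless normalized value.
#' @export
normalizeByHeight <- function(valueMm, heightCm) {
  if (any(heightCm <= 0)) stop("height must be positive")
  valueMm / (heightCm * 10)
}

#' Body-mass index
#'
#' weight / height^2 in kg/m^2, rounded half-up to one decimal (table
#' convention).
#'
#' @param weightKg body mass in kg (> 0).
#' @param heightCm body height in cm (> 0).
#' @return BMI in kg/m^2, one decimal.
#' @export
bmi <- function(weightKg, heightCm) {
  if (any(weightKg <= 0) || any(heightCm <= 0))
    stop("weight and height must be positive")
  x <- weightKg / (heightCm / 100)^2
  floor(x * 10 + 0.5) / 10
}

#' Compare US and DTI measurements across a cohort
#'
#' For every muscle x parameter cell of a long-format table, reports the
#' median (min, max) per method, the exact Wilcoxon signed-rank p-value
#' over matched subject pairs with a significance flag at `alpha`, and the
#' mean (SD) within-subject absolute difference. When heights are present,
#' fascicle length and thickness are additionally analyzed normalized by
#' height.
#'
#' @param data data.frame with columns `subject`, `muscle`, `parameter`
#'   (e.g. "FL", "PA", "t_m"), `method` ("US"/"DTI"), `value`, and
#'   optionally `height_cm`.
#' @param alpha significance level (default 0.05; differences are called
#'   significant when p <= alpha).
#' @param normalize also run height-normalized FL and t_m when heights are
#'   available (default TRUE).
#' @return data.frame with one row per muscle x parameter x scale:
#'   medians/ranges per method, `W`, `p`, `significant`, `absMean`,
#'   `absSd`, `n`.
#' @export
compareMethods <- function(data, alpha = 0.05, normalize = TRUE) {
  need <- c("subject", "muscle", "parameter", "method", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  if (!nrow(data)) stop("empty comparison table")
  runs <- list(list(scale = "raw", data = data))
  if (normalize && "height_cm" %in% names(data)) {
    nd <- data[data$parameter %in% c("FL", "t_m"), , drop = FALSE]
    if (nrow(nd)) {
      nd$value <- normalizeByHeight(nd$value, nd$height_cm)
      runs[[2L]] <- list(scale = "height_normalized", data = nd)
    }
  }
  rows <- list()
  for (run in runs) {
    dd <- run$data
    for (mus in unique(dd$muscle)) {
      for (par in unique(dd$parameter[dd$muscle == mus])) {
        cell <- dd[dd$muscle == mus & dd$parameter == par, , drop = FALSE]
        us <- cell[cell$method == "US", c("subject", "value")]
        dti <- cell[cell$method == "DTI", c("subject", "value")]
        common <- intersect(us$subject, dti$subject)
        if (length(common) < 1L) next
        xu <- us$value[match(common, us$subject)]
        xd <- dti$value[match(common, dti$subject)]
        mrU <- medianRange(xu); mrD <- medianRange(xd)
        wt <- tryCatch(wilcoxonSignedRank(xu, xd),
                       error = function(e) NULL)
        pa <- pairedAbsSummary(xu, xd)
        rows[[length(rows) + 1L]] <- data.frame(
          muscle = mus, parameter = par, scale = run$scale,
          n = length(common),
          us_median = mrU$median, us_min = mrU$min, us_max = mrU$max,
          dti_median = mrD$median, dti_min = mrD$min, dti_max = mrD$max,
          W = if (is.null(wt)) NA_real_ else wt$statistic,
          p = if (is.null(wt)) NA_real_ else wt$pValue,
          significant = if (is.null(wt)) FALSE else wt$pValue <= alpha,
          absMean = pa$mean, absSd = pa$sd,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no muscle/parameter cell had matched US-DTI pairs")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
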