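#' Pearson correlation with least-squares best fit
#'
#' Standard method-comparison regression: Pearson's r with a two-sided
#' p-value from the exact t transform on n - 2 degrees of freedom, and the
#' least-squares line of y on x.
#'
#' @param x,y Paired measurements (length >= 3, both with nonzero variance).
#' @return List with `r`, `p_value`, `slope`, `intercept`, `n`.
#' @export
pearson_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: a variable has zero variance")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  fit <- lm(y ~ x)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(x))
}

#' Bland-Altman agreement analysis
#'
#' Differences are `b - a` (flip `orientation` for the other sign): mean
#' difference (bias), sd, and 95% limits of agreement at ±1.96 sd, plus the
#' per-pair means and differences for plotting.
#'
#' @param a,b Paired measurements (length >= 2).
#' @param orientation `"b-a"` (default) or `"a-b"`.
#' @return List with `mean_difference`, `sd`, `limits` (lower, upper) and a
#'   `table` data frame (mean, difference).
#' @export
bland_altman <- function(a, b, orientation = c("b-a", "a-b")) {
  orientation <- match.arg(orientation)
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  diffs <- if (orientation == "b-a") b - a else a - b
  m <- mean(diffs)
  s <- sd(diffs)
  list(mean_difference = m, sd = s,
       limits = c(lower = m - 1.96 * s, upper = m + 1.96 * s),
       table = data.frame(mean = (a + b) / 2, difference = diffs))
}

#' Inter-operator spread relative to the per-item average
#'
#' Each measurement is expressed as a percentage of its item's
#' cross-operator mean (100% = the average); the maximum absolute deviation
#' from 100% summarizes operator disagreement. Items whose cross-operator
#' average is zero (nothing measurable) are excluded with a notice.
#'
#' @param values Numeric matrix, rows = items, columns = operators (>= 2
#'   operators, >= 1 item).
#' @return List with `percent` (matrix, same shape minus excluded rows),
#'   `max_deviation_pct`, and `excluded_items` (row indices).
#' @export
interoperator_spread <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2) stop("need at least 2 operators")
  if (nrow(values) < 1) stop("need at least 1 item")
  item_mean <- rowMeans(values)
  excluded <- which(item_mean == 0)
  if (length(excluded) == nrow(values))
    stop("all items have zero average; nothing to compare")
  if (length(excluded)) {
    message(sprintf("excluding %d item(s) with zero average: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
    values <- values[-excluded, , drop = FALSE]
    item_mean <- item_mean[-excluded]
  }
  pct <- sweep(values, 1, item_mean, "/") * 100
  list(percent = pct, max_deviation_pct = max(abs(pct - 100)),
       excluded_items = excluded)
}

#' TTC planimetry of a 2D slice
#'
#' Pixel-counting areas on a labelled 2D slice image with classes background,
#' viable (non-ischemic), ttc_neg (infarcted) and aar_viable (area at risk,
#' viable). Injury size is expressed as TTC-negative percent of the AAR
#' (AAR = ttc_neg + aar_viable); the AAR is also reported as percent of the
#' whole slice (all non-background pixels).
#'
#' @param labels 2D matrix of class codes.
#' @param codes Named vector mapping class names to codes (defaults
#'   background 0, viable 1, ttc_neg 2, aar_viable 3).
#' @param pixel_size_mm Pixel edge length, mm (areas in mm² if given).
#' @return List with `ttc_neg_pct_of_aar`, `aar_pct_of_slice` and `areas`
#'   (per-class pixel counts or mm²).
#' @export
ttc_planimetry <- function(labels,
                           codes = c(background = 0, viable = 1,
                                     ttc_neg = 2, aar_viable = 3),
                           pixel_size_mm = NULL) {
  n <- vapply(names(codes), function(cl) sum(labels == codes[[cl]]), numeric(1))
  aar <- n[["ttc_neg"]] + n[["aar_viable"]]
  if (aar == 0) stop("no AAR pixels in the slice")
  slice <- sum(n) - n[["background"]]
  areas <- n
  if (!is.null(pixel_size_mm)) areas <- n * pixel_size_mm^2
  list(ttc_neg_pct_of_aar = 100 * n[["ttc_neg"]] / aar,
       aar_pct_of_slice = 100 * aar / slice,
       areas = areas)
}
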