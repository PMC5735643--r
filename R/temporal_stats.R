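## Nycthemeral activity profiles and the survey's test battery: chi-square
## goodness-of-fit (optionally Yates-corrected at df = 1), day/night tests
## with exposure-weighted expectations, G-tests of independence, sex-ratio
## tests, and size-structure comparisons with KS/Bartlett pre-checks.

test_result <- function(method, statistic, df, p_value,
                        corrected_statistic = NULL,
                        corrected_p_value = NULL, note = NULL) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value,
                 corrected_statistic = corrected_statistic,
                 corrected_p_value = corrected_p_value,
                 note = note),
            class = "trophon_test")
}

#' @export
print.trophon_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(round(x$statistic, 3), nsmall = 3),
      ", df = ", x$df,
      ", p = ", format.pval(x$p_value, digits = 3), "\n", sep = "")
  if (!is.null(x$corrected_statistic))
    cat("  corrected (Yates/Williams): ",
        format(round(x$corrected_statistic, 3), nsmall = 3),
        ", p = ", format.pval(x$corrected_p_value, digits = 3), "\n", sep = "")
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Chi-square goodness-of-fit test against given expectations
#'
#' Computes sum((O - E)^2 / E) with expectations proportional to `prob`
#' (equal by default). The Yates continuity correction (subtract 0.5 from
#' each |O - E| before squaring, floored at 0) is available only for the
#' two-class case, matching its use at df = 1.
#'
#' @param counts vector of nonnegative integer counts.
#' @param yates apply the Yates continuity correction (two classes only).
#' @param prob expected class probabilities; default uniform.
#' @return object of class `"trophon_test"`.
#' @examples
#' chisq_uniform(c(177, 164))               # sex-ratio style 1:1 test
#' chisq_uniform(c(39, 22), yates = TRUE)
#' @export
chisq_uniform <- function(counts, yates = FALSE, prob = NULL) {
  if (any(counts < 0) || sum(counts) <= 0)
    stop("chisq_uniform(): counts must be nonnegative with positive total",
         call. = FALSE)
  k <- length(counts)
  if (k < 2L)
    stop("chisq_uniform(): need at least two classes", call. = FALSE)
  if (is.null(prob)) prob <- rep(1 / k, k)
  if (length(prob) != k || any(prob <= 0) || abs(sum(prob) - 1) > 1e-8)
    stop("chisq_uniform(): prob must be ", k,
         " positive values summing to 1", call. = FALSE)
  E <- sum(counts) * prob
  stat <- sum((counts - E)^2 / E)
  df <- k - 1L
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  cstat <- cp <- NULL
  if (yates) {
    if (k != 2L)
      stop("chisq_uniform(): Yates correction applies only to two classes",
           call. = FALSE)
    cstat <- sum(pmax(abs(counts - E) - 0.5, 0)^2 / E)
    cp <- stats::pchisq(cstat, df, lower.tail = FALSE)
  }
  test_result("chisq_gof", stat, df, p, cstat, cp)
}

#' Activity profile over the eight net checks
#'
#' Counts of specimens captured per 3-h net check, their relative
#' frequencies, and the nocturnal/diurnal split (5 nocturnal checks,
#' 18:00-06:00; 3 diurnal).
#'
#' @param specimens validated specimen table.
#' @param group a [group_key()].
#' @return object of class `"activity_profile"`: list with `group`,
#'   `counts` (length 8), `rel_freq`, `night_count`, `day_count`.
#' @export
activity_profile <- function(specimens, group = group_key()) {
  sp <- specimens_in_group(specimens, group)
  counts <- table(factor(sp$interval, levels = net_checks))
  counts <- stats::setNames(as.integer(counts), net_checks)
  total <- sum(counts)
  structure(list(
    group = group,
    counts = counts,
    rel_freq = if (total > 0) counts / total else counts * 0,
    night_count = sum(counts[nocturnal_checks]),
    day_count = sum(counts[setdiff(net_checks, nocturnal_checks)])
  ), class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat("Activity profile (", x$group$species, ")\n", sep = "")
  print(rbind(count = x$counts, rel_freq = round(x$rel_freq, 3)))
  cat("night:", x$night_count, " day:", x$day_count, "\n")
  invisible(x)
}

#' Heterogeneity among the eight 3-h intervals
#'
#' Chi-square goodness-of-fit of the per-interval capture counts against
#' uniform expectation.
#'
#' @param profile an [activity_profile()].
#' @return `"trophon_test"` with df = 7.
#' @export
interval_heterogeneity_test <- function(profile) {
  stopifnot(inherits(profile, "activity_profile"))
  chisq_uniform(profile$counts)
}

#' Nocturnal vs diurnal capture test
#'
#' Chi-square test of the night/day capture split. With the default
#' exposure-weighted expectation the expected night share is 5/8, because
#' the design samples the night with 5 of the 8 checks; equal sampling
#' effort per interval then gives a zero statistic. `expectation = "equal"`
#' reproduces the naive 50/50 test instead.
#'
#' @param profile an [activity_profile()].
#' @param yates apply the Yates continuity correction.
#' @param expectation `"exposure"` (night weight 5/8) or `"equal"` (1/2).
#' @return `"trophon_test"` with df = 1.
#' @export
day_night_test <- function(profile, yates = FALSE,
                           expectation = c("exposure", "equal")) {
  stopifnot(inherits(profile, "activity_profile"))
  expectation <- match.arg(expectation)
  prob <- if (expectation == "exposure")
    c(length(nocturnal_checks), length(net_checks) - length(nocturnal_checks)) /
      length(net_checks)
  else c(0.5, 0.5)
  res <- chisq_uniform(c(profile$night_count, profile$day_count),
                       yates = yates, prob = prob)
  res$note <- paste0("night vs day, ", expectation, "-weighted expectation")
  res
}

#' Sex-ratio test
#'
#' Chi-square test of the male:female split against 1:1; specimens of
#' undetermined sex are excluded.
#'
#' @param specimens validated specimen table.
#' @param species optional species label to subset on.
#' @param yates apply the Yates continuity correction.
#' @return `"trophon_test"` with df = 1.
#' @export
sex_ratio_test <- function(specimens, species = NULL, yates = FALSE) {
  sp <- specimens
  if (!is.null(species)) sp <- sp[sp$species == species, , drop = FALSE]
  sp <- sp[sp$sex %in% c("male", "female"), , drop = FALSE]
  counts <- c(male = sum(sp$sex == "male"), female = sum(sp$sex == "female"))
  res <- chisq_uniform(counts, yates = yates)
  res$note <- sprintf("males = %d, females = %d", counts[1], counts[2])
  res
}

#' G-test of independence
#'
#' Log-likelihood ratio test G = 2 * sum(O * ln(O / E)) on an r x k
#' contingency table with expectations from the row and column margins;
#' zero cells contribute nothing. The optional Williams correction divides
#' G by q = 1 + (N * sum(1/rowsums) - 1)(N * sum(1/colsums) - 1) / (6 N df).
#'
#' @param tab contingency matrix of nonnegative counts; no all-zero row or
#'   column.
#' @param williams apply the Williams correction (off by default).
#' @return `"trophon_test"` with df = (r - 1)(k - 1).
#' @examples
#' g_test(rbind(c(10, 0), c(0, 10)))
#' @export
g_test <- function(tab, williams = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0))
    stop("g_test(): counts must be nonnegative", call. = FALSE)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("g_test(): table has an all-zero row or column", call. = FALSE)
  n <- sum(tab)
  E <- outer(rs, cs) / n
  G <- 2 * sum(ifelse(tab > 0, tab * log(tab / E), 0))
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  p <- stats::pchisq(G, df, lower.tail = FALSE)
  cstat <- cp <- NULL
  if (williams) {
    q <- 1 + ((n * sum(1 / rs) - 1) * (n * sum(1 / cs) - 1)) / (6 * n * df)
    cstat <- G / q
    cp <- stats::pchisq(cstat, df, lower.tail = FALSE)
  }
  test_result("g_test", G, df, p, cstat, cp)
}

#' Seasonal variation in the occurrence of one food category
#'
#' Builds the 2 x 2 (present / absent) x (flood / dry) table of
#' content-bearing stomachs for one species and category, and runs
#' [g_test()] on it.
#'
#' @param items validated stomach-item table.
#' @param specimens validated specimen table.
#' @param species species label.
#' @param category one of [food_categories].
#' @param williams apply the Williams correction.
#' @return `"trophon_test"`; the table is attached as attribute `"table"`.
#' @export
seasonal_fo_gtest <- function(items, specimens, species, category,
                              williams = FALSE) {
  if (!(category %in% food_categories))
    stop("seasonal_fo_gtest(): unknown category ", category, call. = FALSE)
  tab <- vapply(seasons, function(se) {
    cnt <- occurrence_counts(items, specimens, group_key(species, se))
    c(present = cnt$n[[category]], absent = cnt$N - cnt$n[[category]])
  }, numeric(2))
  res <- g_test(t(tab), williams = williams)
  attr(res, "table") <- t(tab)
  res
}

#' Size-structure comparison with pre-checks
#'
#' Runs the conventional battery for comparing two samples of lengths or
#' weights: Kolmogorov-Smirnov normality checks on each sample (against a
#' normal with that sample's moments), Bartlett's homoscedasticity test,
#' then Student's two-sample t-test (equal variances). Pre-check failures
#' at `alpha` are flagged, not blocking.
#'
#' @param a,b numeric samples, each of size >= 3 with positive variance.
#' @param alpha level used for the pre-check flags (default 0.05).
#' @return list with `ks`, `bartlett`, `t` (each `"trophon_test"`; `ks`
#'   summarises both samples by the larger D / smaller p, with the
#'   per-sample results in `ks_each`) and logical flags
#'   `normality_flag`, `variance_flag`.
#' @export
size_structure_compare <- function(a, b, alpha = 0.05) {
  if (length(a) < 3L || length(b) < 3L)
    stop("size_structure_compare(): each sample needs n >= 3", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("size_structure_compare(): zero-variance sample", call. = FALSE)
  ks1 <- suppressWarnings(stats::ks.test(a, "pnorm", mean(a), stats::sd(a)))
  ks2 <- suppressWarnings(stats::ks.test(b, "pnorm", mean(b), stats::sd(b)))
  worse <- if (ks1$p.value <= ks2$p.value) ks1 else ks2
  ks <- test_result("ks", unname(worse$statistic), NA_integer_,
                    worse$p.value,
                    note = "normality; worse of the two samples")
  bt <- stats::bartlett.test(list(a, b))
  bartlett <- test_result("bartlett", unname(bt$statistic),
                          unname(bt$parameter), bt$p.value)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  t_res <- test_result("t_test", unname(tt$statistic),
                       unname(tt$parameter), tt$p.value)
  list(ks = ks,
       ks_each = list(
         a = test_result("ks", unname(ks1$statistic), NA_integer_, ks1$p.value),
         b = test_result("ks", unname(ks2$statistic), NA_integer_, ks2$p.value)),
       bartlett = bartlett,
       t = t_res,
       normality_flag = min(ks1$p.value, ks2$p.value) < alpha,
       variance_flag = bt$p.value < alpha)
}

#' Allocate a sample to half-open size classes
#'
#' Bins values into classes `[lo, lo + width)` starting at `origin`
#' (default: `floor(min / width) * width`). Class counts conserve the
#' sample size.
#'
#' @param values numeric sample (possibly empty).
#' @param class_width positive class width (same units as `values`).
#' @param origin left edge of the first class; default snaps to a multiple
#'   of `class_width` at or below the minimum.
#' @return named integer vector of counts, names like `"[100,120)"`; empty
#'   input gives an empty vector.
#' @export
class_histogram <- function(values, class_width, origin = NULL) {
  if (class_width <= 0)
    stop("class_histogram(): class_width must be > 0", call. = FALSE)
  if (length(values) == 0L) return(stats::setNames(integer(0), character(0)))
  if (is.null(origin)) origin <- floor(min(values) / class_width) * class_width
  if (origin > min(values))
    stop("class_histogram(): origin must not exceed min(values)",
         call. = FALSE)
  n_classes <- ceiling((max(values) - origin) / class_width + 1e-12)
  n_classes <- max(n_classes, 1L)
  breaks <- origin + class_width * (0:n_classes)
  idx <- findInterval(values, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = n_classes)
  labels <- sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1])
  stats::setNames(as.integer(counts), labels)
}
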