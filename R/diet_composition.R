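## Diet composition indices: frequency of occurrence (FO), volumetric
## frequency (VF) and the index of feeding importance (IF), computed per
## group (species x season x interval).
##
## Conventions: FO's denominator N is the number of group stomachs that are
## non-void AND contain at least one item row; occurrence is counted once
## per stomach regardless of duplicate item rows; VF pools raw volumes
## across all stomachs of the group (the IF index is invariant to this
## choice because it only depends on FO*VF up to a common rescaling).

content_subset <- function(items, specimens, group) {
  sp <- specimens_in_group(specimens, group)
  sp <- sp[sp$repletion != "void", , drop = FALSE]
  it <- items[items$specimen_id %in% sp$specimen_id, , drop = FALSE]
  ids <- unique(it$specimen_id)
  list(specimens = sp, items = it, content_ids = ids)
}

#' Frequency of occurrence of each food category
#'
#' FO_i = 100 * n_i / N, where n_i is the number of content-bearing stomachs
#' of the group in which category i occurs (counted once per stomach) and N
#' is the number of content-bearing stomachs. Categories absent from every
#' stomach are reported as 0.
#'
#' @param items validated stomach-item table.
#' @param specimens validated specimen table.
#' @param group a [group_key()].
#' @return named numeric vector over [food_categories], percentages in
#'   \[0, 100\].
#' @export
frequency_of_occurrence <- function(items, specimens, group = group_key()) {
  cs <- content_subset(items, specimens, group)
  N <- length(cs$content_ids)
  if (N == 0L)
    stop("frequency_of_occurrence(): no content-bearing stomachs in group",
         call. = FALSE)
  occ <- unique(cs$items[, c("specimen_id", "category")])
  n_i <- table(factor(occ$category, levels = food_categories))
  fo <- 100 * as.numeric(n_i) / N
  names(fo) <- food_categories
  fo
}

#' Per-category occurrence counts and denominator
#'
#' The integer building blocks of [frequency_of_occurrence()]: `n` per
#' category and the shared denominator `N`.
#'
#' @inheritParams frequency_of_occurrence
#' @return list with elements `n` (named integer vector) and `N`.
#' @export
occurrence_counts <- function(items, specimens, group = group_key()) {
  cs <- content_subset(items, specimens, group)
  occ <- unique(cs$items[, c("specimen_id", "category")])
  n_i <- table(factor(occ$category, levels = food_categories))
  list(n = stats::setNames(as.integer(n_i), food_categories),
       N = length(cs$content_ids))
}

#' Volumetric frequency of each food category
#'
#' VF_i = 100 * (total volume of category i across all group stomachs) /
#' (total volume of all items in the group). Sums to 100 over categories.
#'
#' @inheritParams frequency_of_occurrence
#' @return named numeric vector over [food_categories], percentages summing
#'   to 100.
#' @export
volumetric_frequency <- function(items, specimens, group = group_key()) {
  cs <- content_subset(items, specimens, group)
  if (length(cs$content_ids) == 0L)
    stop("volumetric_frequency(): no content-bearing stomachs in group",
         call. = FALSE)
  tot <- tapply(cs$items$volume,
                factor(cs$items$category, levels = food_categories),
                sum, default = 0)
  tot <- as.numeric(tot)
  if (sum(tot) <= 0)
    stop("volumetric_frequency(): all item volumes are zero in group",
         call. = FALSE)
  stats::setNames(100 * tot / sum(tot), food_categories)
}

#' Index of feeding importance
#'
#' Combines frequency of occurrence and volumetric frequency into the
#' feeding-importance index IF_i = (FO_i * VF_i) / sum_j (FO_j * VF_j),
#' a proportion ranking each category's contribution to the diet. The index
#' is invariant to any common rescaling of the volumes.
#'
#' @param fo named vector of frequencies of occurrence (percent).
#' @param vf named vector of volumetric frequencies (percent), same names.
#' @return named vector of proportions in \[0, 1\] summing to 1.
#' @examples
#' fo <- c(fish = 80, crustacean = 20, insect = 20, microcrustacean = 20)
#' vf <- c(fish = 0.906, crustacean = 0.089, insect = 0.004,
#'         microcrustacean = 0.001)
#' feeding_importance(fo, vf)
#' @export
feeding_importance <- function(fo, vf) {
  if (is.null(names(fo)) || is.null(names(vf)) ||
      !setequal(names(fo), names(vf)))
    stop("feeding_importance(): fo and vf must share the same category names",
         call. = FALSE)
  vf <- vf[names(fo)]
  prod <- fo * vf
  if (all(prod == 0))
    stop("feeding_importance(): all FO x VF products are zero", call. = FALSE)
  prod / sum(prod)
}

#' Stomach repletion profile of a group
#'
#' Counts and relative frequencies of the three repletion classes (void,
#' partly full, full).
#'
#' @inheritParams frequency_of_occurrence
#' @return object of class `"repletion_profile"`: list with `group`,
#'   `counts` and `rel_freq`.
#' @export
repletion_profile <- function(specimens, group = group_key()) {
  sp <- specimens_in_group(specimens, group)
  if (nrow(sp) == 0L)
    stop("repletion_profile(): empty group", call. = FALSE)
  counts <- table(factor(sp$repletion, levels = repletion_classes))
  counts <- stats::setNames(as.integer(counts), repletion_classes)
  structure(list(group = group, counts = counts,
                 rel_freq = counts / sum(counts)),
            class = "repletion_profile")
}

#' @export
print.repletion_profile <- function(x, ...) {
  cat("Repletion profile (", x$group$species, ", ", x$group$season, ")\n",
      sep = "")
  print(round(rbind(count = x$counts, rel_freq = x$rel_freq), 3))
  invisible(x)
}

#' Per-interval repletion profiles
#'
#' One [repletion_profile()] per net-check interval (empty intervals give a
#' profile of zero counts rather than an error).
#'
#' @inheritParams frequency_of_occurrence
#' @return named list of 8 repletion profiles keyed by interval label.
#' @export
repletion_by_interval <- function(specimens, group = group_key()) {
  out <- lapply(net_checks, function(iv) {
    g <- group_key(group$species, group$season, iv)
    sp <- specimens_in_group(specimens, g)
    counts <- table(factor(sp$repletion, levels = repletion_classes))
    counts <- stats::setNames(as.integer(counts), repletion_classes)
    rel <- if (sum(counts) > 0) counts / sum(counts) else counts * 0
    structure(list(group = g, counts = counts, rel_freq = rel),
              class = "repletion_profile")
  })
  stats::setNames(out, net_checks)
}

#' Diet table for one group
#'
#' Assembles occurrence counts, FO, VF and IF for each food category with a
#' shared denominator N, i.e. one species-by-season block of a conventional
#' diet-composition table.
#'
#' @inheritParams frequency_of_occurrence
#' @return data frame of class `"diet_table"` with columns `category`, `n`,
#'   `N`, `fo_pct`, `vf_pct`, `ifi`; attribute `group` holds the group key.
#' @export
diet_table <- function(items, specimens, group = group_key()) {
  fo <- frequency_of_occurrence(items, specimens, group)
  vf <- volumetric_frequency(items, specimens, group)
  cnt <- occurrence_counts(items, specimens, group)
  ifi <- feeding_importance(fo, vf)
  out <- data.frame(category = food_categories,
                    n = cnt$n, N = cnt$N,
                    fo_pct = fo, vf_pct = vf, ifi = ifi,
                    row.names = NULL)
  attr(out, "group") <- group
  class(out) <- c("diet_table", "data.frame")
  out
}

#' @export
print.diet_table <- function(x, digits_pct = 3, digits_ifi = 4, ...) {
  g <- attr(x, "group")
  if (!is.null(g))
    cat("Diet table (", g$species, ", ", g$season, "); N = ", x$N[1],
        "\n", sep = "")
  y <- as.data.frame(x)
  y$fo_pct <- round(y$fo_pct, digits_pct)
  y$vf_pct <- round(y$vf_pct, digits_pct)
  y$ifi <- round(y$ifi, digits_ifi)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Diet tables for every species x season combination
#'
#' Convenience wrapper assembling [diet_table()] for each species/season
#' pair present in the data; pairs without content-bearing stomachs are
#' dropped with a warning.
#'
#' @param items validated stomach-item table.
#' @param specimens validated specimen table.
#' @return long data frame with columns `species`, `season`, `category`,
#'   `n`, `N`, `fo_pct`, `vf_pct`, `ifi`.
#' @export
diet_by <- function(items, specimens) {
  combos <- unique(specimens[, c("species", "season")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    g <- group_key(combos$species[i], combos$season[i])
    tab <- tryCatch(diet_table(items, specimens, g), error = function(e) NULL)
    if (is.null(tab)) {
      warning("diet_by(): no content-bearing stomachs for ",
              combos$species[i], " / ", combos$season[i], "; dropped",
              call. = FALSE)
      return(NULL)
    }
    cbind(species = combos$species[i], season = combos$season[i],
          as.data.frame(tab))
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
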