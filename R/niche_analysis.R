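## Trophic niche breadth (Levin's standardized index) and pairwise niche
## overlap (Pianka's symmetric index) on utilization matrices.

#' Levin's standardized niche breadth
#'
#' For a utilization vector p over resource states, B = 1 / sum(p_j^2) and
#' the standardized index Bi = (B - 1) / (n - 1), where n is the number of
#' available resource states. Bi is 0 when a single resource is used and 1
#' when use is uniform over all n states. Conventional bands: low (< 0.4),
#' moderate (0.4-0.6), high (> 0.6); see [classify_niche()].
#'
#' @param p nonnegative utilization vector (any scale; normalized
#'   internally).
#' @param n_states number of available resource states; defaults to
#'   `length(p)` (the full category scheme), which keeps Bi comparable
#'   across groups. Must be >= 2 and >= the number of nonzero entries.
#' @return Bi in \[0, 1\].
#' @examples
#' levins_breadth(c(1, 0, 0, 0, 0, 0))        # single resource -> 0
#' levins_breadth(rep(1 / 6, 6))              # uniform -> 1
#' @export
levins_breadth <- function(p, n_states = length(p)) {
  if (!is.numeric(p) || length(p) == 0L || any(p < 0))
    stop("levins_breadth(): p must be a nonnegative numeric vector",
         call. = FALSE)
  if (sum(p) <= 0)
    stop("levins_breadth(): zero utilization vector", call. = FALSE)
  if (n_states < 2L)
    stop("levins_breadth(): n_states must be >= 2", call. = FALSE)
  if (n_states < sum(p > 0))
    stop("levins_breadth(): n_states smaller than the number of used states",
         call. = FALSE)
  p <- p / sum(p)
  B <- 1 / sum(p^2)
  (B - 1) / (n_states - 1)
}

#' Pianka's niche overlap index
#'
#' O_jk = sum(p_j * p_k) / sqrt(sum(p_j^2) * sum(p_k^2)) for two utilization
#' vectors over the same resource states. Symmetric; 0 for disjoint resource
#' use, 1 for proportional (identical) use.
#'
#' @param p,q nonnegative utilization vectors of equal length (any scale).
#' @return overlap in \[0, 1\].
#' @examples
#' pianka_overlap(c(1, 0), c(0, 1))   # disjoint -> 0
#' pianka_overlap(c(2, 2), c(5, 5))   # proportional -> 1
#' @export
pianka_overlap <- function(p, q) {
  if (length(p) != length(q))
    stop("pianka_overlap(): vectors must cover the same resource states",
         call. = FALSE)
  if (any(p < 0) || any(q < 0))
    stop("pianka_overlap(): utilization values must be nonnegative",
         call. = FALSE)
  if (sum(p) <= 0 || sum(q) <= 0)
    stop("pianka_overlap(): zero utilization vector", call. = FALSE)
  p <- p / sum(p)
  q <- q / sum(q)
  o <- sum(p * q) / sqrt(sum(p^2) * sum(q^2))
  min(max(o, 0), 1)  # clamp floating-point spill
}

#' Classify a niche index into the conventional bands
#'
#' Low for values below 0.4, moderate for 0.4-0.6 (closed interval), high
#' above 0.6. Applies to both Levin's Bi and Pianka's overlap.
#'
#' @param value index value in \[0, 1\].
#' @return object of class `"niche_class"`: list with `value` and `band`
#'   (`"low"`, `"moderate"` or `"high"`).
#' @examples
#' classify_niche(0.999)$band
#' @export
classify_niche <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1)
    stop("classify_niche(): value must be a single number in [0, 1]",
         call. = FALSE)
  band <- if (value < 0.4) "low" else if (value <= 0.6) "moderate" else "high"
  structure(list(value = value, band = band), class = "niche_class")
}

#' @export
print.niche_class <- function(x, ...) {
  cat(format(x$value, digits = 4), " (", x$band, ")\n", sep = "")
  invisible(x)
}

#' Build a species x resource utilization matrix from a diet table
#'
#' Pivots the long output of [diet_by()] (or any data frame with `species`,
#' `category` and a measure column) into a matrix with one row per species
#' and one column per food category. The default measure is the volumetric
#' frequency; frequency of occurrence or feeding importance can be selected
#' for sensitivity analyses.
#'
#' @param diet long diet data frame (e.g. one season's rows of [diet_by()]).
#' @param measure `"vf"`, `"fo"` or `"ifi"`.
#' @return numeric matrix, rows = species, columns = [food_categories];
#'   every row has a positive sum.
#' @export
utilization_matrix <- function(diet, measure = c("vf", "fo", "ifi")) {
  measure <- match.arg(measure)
  col <- switch(measure, vf = "vf_pct", fo = "fo_pct", ifi = "ifi")
  if (!all(c("species", "category", col) %in% names(diet)))
    stop("utilization_matrix(): diet must have columns species, category, ",
         col, call. = FALSE)
  sp <- unique(diet$species)
  mat <- matrix(0, nrow = length(sp), ncol = length(food_categories),
                dimnames = list(sp, food_categories))
  for (i in seq_len(nrow(diet)))
    mat[diet$species[i], diet$category[i]] <- diet[[col]][i]
  if (any(rowSums(mat) <= 0))
    stop("utilization_matrix(): some species row has zero total utilization",
         call. = FALSE)
  mat
}

#' Niche breadth and pairwise overlap summary of a utilization matrix
#'
#' @param mat utilization matrix (rows = species, columns = resource
#'   states).
#' @param n_states number of available states for Levin's Bi; default the
#'   number of columns.
#' @return list with `breadth` (data frame: species, bi, band) and
#'   `overlap` (data frame: species_a, species_b, ojk, band).
#' @export
niche_summary <- function(mat, n_states = ncol(mat)) {
  bi <- apply(mat, 1, levins_breadth, n_states = n_states)
  breadth <- data.frame(species = rownames(mat), bi = as.numeric(bi),
                        band = vapply(bi, function(v) classify_niche(v)$band,
                                      character(1)),
                        row.names = NULL)
  pairs <- utils::combn(nrow(mat), 2)
  overlap <- data.frame(
    species_a = rownames(mat)[pairs[1, ]],
    species_b = rownames(mat)[pairs[2, ]],
    ojk = apply(pairs, 2, function(ix) pianka_overlap(mat[ix[1], ], mat[ix[2], ])),
    row.names = NULL)
  overlap$band <- vapply(overlap$ojk, function(v) classify_niche(v)$band,
                         character(1))
  list(breadth = breadth, overlap = overlap)
}
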