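#' trophon: trophic niche partitioning from stomach-content surveys
#'
#' Diet composition indices, niche breadth and overlap, RA3 randomization
#' null models, and nycthemeral activity statistics for paired specimen /
#' stomach-content tables, plus a synthetic survey generator.
#'
#' @keywords internal
"_PACKAGE"

## Fixed coding schemes shared by every stage of the pipeline.

#' Survey coding schemes
#'
#' Fixed factor levels used throughout the package: the eight 3-h net-check
#' labels (each label names the END of its 3-h window), the subset of checks
#' falling in the nocturnal period (18:00-06:00), the six broad food-item
#' categories, the two Amazonian hydrological seasons, the stomach repletion
#' classes, and the sex codes.
#'
#' @name schemes
#' @aliases net_checks nocturnal_checks food_categories seasons
#'   repletion_classes sex_levels
NULL

#' @rdname schemes
#' @export
net_checks <- c("18:00", "21:00", "24:00", "03:00", "06:00",
                "09:00", "12:00", "15:00")

#' @rdname schemes
#' @export
nocturnal_checks <- c("18:00", "21:00", "24:00", "03:00", "06:00")

#' @rdname schemes
#' @export
food_categories <- c("fish", "crustacean", "microcrustacean",
                     "insect", "plant", "other")

#' @rdname schemes
#' @export
seasons <- c("flood", "dry")

#' @rdname schemes
#' @export
repletion_classes <- c("void", "partly_full", "full")

#' @rdname schemes
#' @export
sex_levels <- c("male", "female", "undetermined")

specimen_columns <- c("specimen_id", "species", "sex", "total_length_mm",
                      "total_weight_g", "gutted_weight_g", "stomach_weight_g",
                      "capture_date", "interval", "repletion")

item_columns <- c("specimen_id", "category", "volume")

#' Hydrological season of a calendar date
#'
#' Amazonian hydrological seasons at month granularity: January-June is the
#' rainy/flood season, July-December the dry season.
#'
#' @param date a `Date`, or anything `as.Date()` accepts (e.g. "2012-03-15").
#' @return character vector of `"flood"` / `"dry"`, one per input date.
#' @examples
#' season_of(c("2012-03-15", "2011-09-20"))
#' @export
season_of <- function(date) {
  date <- tryCatch(as.Date(date), error = function(e) NA)
  if (any(is.na(date)))
    stop("season_of(): invalid or unparseable date", call. = FALSE)
  m <- as.integer(format(date, "%m"))
  ifelse(m <= 6L, "flood", "dry")
}

#' Is a net-check interval nocturnal?
#'
#' Each check label denotes the end of its 3-h window, so the 06:00 check
#' (window 03:00-06:00) belongs to the nocturnal period (18:00-06:00) and the
#' 09:00 check opens the diurnal period. Five of the eight checks are
#' nocturnal.
#'
#' @param interval character vector of net-check labels (see [net_checks]).
#' @return logical vector.
#' @examples
#' is_nocturnal(c("21:00", "06:00", "12:00"))
#' @export
is_nocturnal <- function(interval) {
  bad <- !(interval %in% net_checks)
  if (any(bad))
    stop("is_nocturnal(): unknown interval label(s): ",
         paste(unique(interval[bad]), collapse = ", "),
         "; expected one of ", paste(net_checks, collapse = ", "),
         call. = FALSE)
  interval %in% nocturnal_checks
}

#' Validate a specimen table
#'
#' Checks column presence, value domains and the record-level invariants
#' (positive length and weight, gutted and stomach weight not exceeding total
#' weight, known interval / repletion / sex codes, parseable capture date).
#' A `season` column is derived from `capture_date` when absent and checked
#' for agreement when present.
#'
#' @param specimens data frame in the specimen schema (see Details).
#' @return the validated data frame, with `capture_date` as `Date` and a
#'   `season` column guaranteed present.
#' @details Required columns: `specimen_id`, `species`, `sex`,
#'   `total_length_mm`, `total_weight_g`, `gutted_weight_g`,
#'   `stomach_weight_g`, `capture_date`, `interval`, `repletion`.
#' @export
validate_specimens <- function(specimens) {
  missing_cols <- setdiff(specimen_columns, names(specimens))
  if (length(missing_cols))
    stop("specimen table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  n <- nrow(specimens)
  if (n == 0L) {
    specimens$capture_date <- as.Date(specimens$capture_date)
    if (is.null(specimens$season)) specimens$season <- character(0)
    return(specimens)
  }

  specimens$specimen_id <- as.character(specimens$specimen_id)
  dup <- duplicated(specimens$specimen_id)
  row_err <- function(rows, what) {
    stop("specimen table, row(s) ", paste(utils::head(rows, 5L), collapse = ", "),
         ": ", what, call. = FALSE)
  }
  if (any(dup)) row_err(which(dup), "duplicated specimen_id")
  if (any(!nzchar(specimens$specimen_id)))
    row_err(which(!nzchar(specimens$specimen_id)), "empty specimen_id")

  bad <- !(specimens$sex %in% sex_levels)
  if (any(bad)) row_err(which(bad), paste0("sex must be one of ",
                                           paste(sex_levels, collapse = "/")))
  bad <- !(specimens$interval %in% net_checks)
  if (any(bad)) row_err(which(bad), paste0("interval must be one of ",
                                           paste(net_checks, collapse = ", ")))
  bad <- !(specimens$repletion %in% repletion_classes)
  if (any(bad)) row_err(which(bad), paste0("repletion must be one of ",
                                           paste(repletion_classes, collapse = "/")))

  num_cols <- c("total_length_mm", "total_weight_g",
                "gutted_weight_g", "stomach_weight_g")
  for (col in num_cols) {
    v <- specimens[[col]]
    if (!is.numeric(v) || any(is.na(v)))
      stop("specimen table: column ", col, " must be numeric with no NA",
           call. = FALSE)
  }
  bad <- specimens$total_length_mm <= 0
  if (any(bad)) row_err(which(bad), "total_length_mm must be > 0")
  bad <- specimens$total_weight_g <= 0
  if (any(bad)) row_err(which(bad), "total_weight_g must be > 0")
  bad <- specimens$gutted_weight_g < 0 | specimens$stomach_weight_g < 0
  if (any(bad)) row_err(which(bad), "gutted/stomach weight must be >= 0")
  bad <- specimens$gutted_weight_g > specimens$total_weight_g
  if (any(bad)) row_err(which(bad), "gutted_weight_g exceeds total_weight_g")
  bad <- specimens$stomach_weight_g > specimens$total_weight_g
  if (any(bad)) row_err(which(bad), "stomach_weight_g exceeds total_weight_g")

  dates <- suppressWarnings(as.Date(as.character(specimens$capture_date)))
  if (any(is.na(dates)))
    row_err(which(is.na(dates)), "capture_date is not an ISO-8601 date")
  specimens$capture_date <- dates

  derived <- season_of(dates)
  if (!is.null(specimens$season)) {
    bad <- specimens$season != derived
    if (any(bad)) row_err(which(bad),
                          "season disagrees with the one derived from capture_date")
  } else {
    specimens$season <- derived
  }
  specimens
}

#' Validate a stomach-item table against its specimen table
#'
#' Checks the item schema (known food categories, nonnegative volumes),
#' referential integrity of `specimen_id`, and the rule that a specimen with
#' repletion `"void"` carries no items.
#'
#' @param items data frame with columns `specimen_id`, `category`, `volume`.
#' @param specimens validated specimen table the items refer to.
#' @return the validated item table.
#' @export
validate_stomach_items <- function(items, specimens) {
  missing_cols <- setdiff(item_columns, names(items))
  if (length(missing_cols))
    stop("stomach-item table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(items) == 0L) return(items)

  items$specimen_id <- as.character(items$specimen_id)
  bad <- !(items$category %in% food_categories)
  if (any(bad))
    stop("stomach-item table, row(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "),
         ": unknown category ",
         paste(unique(items$category[bad]), collapse = ", "),
         "; allowed categories: ", paste(food_categories, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(items$volume) || any(is.na(items$volume)) ||
      any(items$volume < 0))
    stop("stomach-item table: volume must be numeric and >= 0", call. = FALSE)

  orphan <- !(items$specimen_id %in% specimens$specimen_id)
  if (any(orphan))
    stop("stomach-item table references unknown specimen_id(s): ",
         paste(unique(items$specimen_id[orphan]), collapse = ", "),
         call. = FALSE)

  void_ids <- specimens$specimen_id[specimens$repletion == "void"]
  bad <- items$specimen_id %in% void_ids
  if (any(bad))
    stop("stomach-item table: specimen(s) with void repletion carry items: ",
         paste(unique(items$specimen_id[bad]), collapse = ", "),
         call. = FALSE)
  items
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  counts <- vapply(c(",", ";", "\t"),
                   function(d) lengths(regmatches(header, gregexpr(d, header, fixed = TRUE))),
                   integer(1))
  if (all(counts == 0L))
    stop("cannot detect delimiter in ", path,
         " (expected comma, semicolon or tab)", call. = FALSE)
  names(counts)[which.max(counts)]
}

read_delimited <- function(path, delim) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- detect_delim(path)
  # regional exports use ';' with a decimal comma
  dec <- if (delim == ";") "," else "."
  utils::read.table(path, header = TRUE, sep = delim, dec = dec,
                    stringsAsFactors = FALSE, colClasses = NA,
                    encoding = "UTF-8")
}

#' Read and validate a specimen table
#'
#' Reads a delimited text file (delimiter auto-detected among comma,
#' semicolon and tab; decimal commas are accepted with the semicolon
#' delimiter) and applies [validate_specimens()]. Row order is preserved.
#'
#' @param path file path.
#' @param delim optional explicit delimiter; default auto-detects.
#' @return validated specimen data frame.
#' @seealso [write_specimens()]
#' @export
read_specimens <- function(path, delim = NULL) {
  df <- read_delimited(path, delim)
  df$specimen_id <- as.character(df$specimen_id)
  validate_specimens(df)
}

#' Read and validate a stomach-item table
#'
#' @param path file path.
#' @param specimens validated specimen table resolving the `specimen_id`
#'   column.
#' @param delim optional explicit delimiter; default auto-detects.
#' @return validated stomach-item data frame.
#' @seealso [write_stomach_items()]
#' @export
read_stomach_items <- function(path, specimens, delim = NULL) {
  df <- read_delimited(path, delim)
  if (nrow(df)) df$specimen_id <- as.character(df$specimen_id)
  validate_stomach_items(df, specimens)
}

#' Write specimen / stomach-item tables
#'
#' Comma-delimited UTF-8 with a header row and "." as the decimal separator;
#' dates are written ISO-8601. Reading the file back reproduces all field
#' values exactly.
#'
#' @param specimens,items validated tables.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(specimens, path) {
  out <- specimens
  out$capture_date <- format(as.Date(out$capture_date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_specimens
#' @export
write_stomach_items <- function(items, path) {
  utils::write.csv(items, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Group key for species x season x interval subsets
#'
#' A lightweight selector used by all per-group computations; the wildcard
#' `"all"` collapses an axis.
#'
#' @param species species label or `"all"`.
#' @param season `"flood"`, `"dry"` or `"all"`.
#' @param interval a net-check label or `"all"`.
#' @return an object of class `"group_key"`.
#' @examples
#' group_key("S. gibbus", season = "flood")
#' @export
group_key <- function(species = "all", season = "all", interval = "all") {
  if (!(season %in% c(seasons, "all")))
    stop("group_key(): season must be flood, dry or all", call. = FALSE)
  if (!(interval %in% c(net_checks, "all")))
    stop("group_key(): unknown interval label ", interval, call. = FALSE)
  structure(list(species = species, season = season, interval = interval),
            class = "group_key")
}

#' @export
print.group_key <- function(x, ...) {
  cat("<group: species=", x$species, ", season=", x$season,
      ", interval=", x$interval, ">\n", sep = "")
  invisible(x)
}

#' Subset a specimen table by group key
#'
#' @param specimens validated specimen table.
#' @param group a [group_key()].
#' @return the matching rows of `specimens`.
#' @export
specimens_in_group <- function(specimens, group) {
  stopifnot(inherits(group, "group_key"))
  keep <- rep(TRUE, nrow(specimens))
  if (group$species != "all") keep <- keep & specimens$species == group$species
  if (group$season != "all")  keep <- keep & specimens$season == group$season
  if (group$interval != "all") keep <- keep & specimens$interval == group$interval
  specimens[keep, , drop = FALSE]
}
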