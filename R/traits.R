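# Count-table I/O and the soft-range / ceiling transformations.
#
# Schema (CSV, UTF-8, empty field = missing):
#   species, old_label, count_min, count_max, count_mean,
#   polymorphism_reported, extinct, fad, lad

trait_columns <- c("species", "old_label", "count_min", "count_max",
                   "count_mean", "polymorphism_reported", "extinct",
                   "fad", "lad")

#' Read and validate a meristic count table
#'
#' Counts may be reported as a point value (`count_min == count_max`), a
#' documented polymorphic range (`polymorphism_reported` true), or a minimum
#' with unknown maximum (`count_max` missing). A missing `count_mean` is
#' filled with the midpoint of the available bounds.
#'
#' @param path CSV file following the package schema.
#' @return a validated data frame of records (class `trait_table`); the
#'   attribute `"validation_log"` records per-record adjustments.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("cannot read trait table: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no records in trait table ", path)
  validate_trait_table(df)
}

#' Validate an in-memory trait table
#' @param df data frame following the package schema.
#' @export
validate_trait_table <- function(df) {
  missing_cols <- setdiff(trait_columns, names(df))
  if (length(missing_cols)) {
    stop("missing trait table columns: ", paste(missing_cols, collapse = ", "))
  }
  log <- character(0)
  df$polymorphism_reported <- as.logical(df$polymorphism_reported)
  df$polymorphism_reported[is.na(df$polymorphism_reported)] <- FALSE
  df$extinct <- as.logical(df$extinct)
  df$extinct[is.na(df$extinct)] <- FALSE
  if (anyDuplicated(df$species)) {
    stop("duplicated species labels: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  }
  num <- c("count_min", "count_max", "count_mean", "fad", "lad")
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  if (any(df$count_min < 0, na.rm = TRUE)) stop("negative count_min")
  if (any(df$count_max < 0, na.rm = TRUE)) stop("negative count_max")
  bad <- !is.na(df$count_max) & df$count_min > df$count_max
  if (any(bad)) {
    stop("count_min > count_max for: ", paste(df$species[bad], collapse = ", "))
  }
  fill <- is.na(df$count_mean)
  if (any(fill)) {
    hi <- ifelse(is.na(df$count_max), df$count_min, df$count_max)
    df$count_mean[fill] <- (df$count_min[fill] + hi[fill]) / 2
    log <- c(log, sprintf("%s: count_mean filled with midpoint", df$species[fill]))
  }
  bad <- df$count_mean < df$count_min - 1e-9 |
    (!is.na(df$count_max) & df$count_mean > df$count_max + 1e-9)
  if (any(bad)) {
    stop("count_mean outside [count_min, count_max] for: ",
         paste(df$species[bad], collapse = ", "))
  }
  ext <- which(df$extinct)
  bad <- ext[!is.na(df$fad[ext]) & !is.na(df$lad[ext]) & df$fad[ext] < df$lad[ext]]
  if (length(bad)) {
    stop("fad < lad for: ", paste(df$species[bad], collapse = ", "))
  }
  class(df) <- c("trait_table", "data.frame")
  attr(df, "validation_log") <- log
  df
}

#' Write a trait table CSV (round-trips with [read_trait_table()])
#' @param df trait table data frame.
#' @param path output CSV path.
#' @export
write_trait_table <- function(df, path) {
  utils::write.csv(as.data.frame(df)[, trait_columns], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Soft minimum and maximum of a count record
#'
#' Records with documented polymorphism keep their reported range. A point
#' count `c` without polymorphism data becomes `(max(0, c - 1), c + 1)`; a
#' minimum-only count `m` (unknown maximum) becomes `(m, m + 1)`, treating the
#' reported minimum as hard.
#'
#' @param df trait table (one or more records); vectorized.
#' @return data frame with columns `low`, `high` (integers, `low >= 0`).
#' @export
resolve_soft_range <- function(df) {
  n <- nrow(df)
  low <- df$count_min
  high <- df$count_max
  min_only <- is.na(high)
  point <- !min_only & !df$polymorphism_reported & low == high
  # documented range: keep as is
  low[point] <- pmax(0, df$count_min[point] - 1)
  high[point] <- df$count_min[point] + 1
  low[min_only] <- df$count_min[min_only]
  high[min_only] <- df$count_min[min_only] + 1
  data.frame(low = low, high = high)
}

#' Discretize the mean count for ordered Markov models
#'
#' The mean is rounded to the nearest upper integer (ceiling); integer means
#' are unchanged.
#'
#' @param df trait table; vectorized.
#' @return integer vector of states.
#' @export
discretize_mean <- function(df) {
  as.integer(ceiling(df$count_mean))
}

#' Map trait records onto the tips of a tree
#'
#' @param df trait table.
#' @param phy a `phylo` whose every tip must receive exactly one record.
#' @param variant one of `"mean"`, `"min"`, `"max"` (soft minima/maxima), or
#'   `"discrete"` (ceiling of the mean).
#' @param congeneric_swaps optional named character vector mapping a record's
#'   `old_label` to the tree tip that should carry its value (the congeneric
#'   tip-swap facility).
#' @return named numeric vector in `phy$tip.label` order; unmatched records
#'   are listed in the `"unmatched"` attribute.
#' @export
map_to_tips <- function(df, phy, variant = c("mean", "min", "max", "discrete"),
                        congeneric_swaps = NULL) {
  variant <- match.arg(variant)
  target <- df$species
  if (!is.null(congeneric_swaps)) {
    hit <- match(df$old_label, names(congeneric_swaps))
    target[!is.na(hit)] <- congeneric_swaps[hit[!is.na(hit)]]
  }
  if (anyDuplicated(target)) {
    stop("two records map to the same tip: ",
         paste(unique(target[duplicated(target)]), collapse = ", "))
  }
  soft <- resolve_soft_range(df)
  value <- switch(variant,
    mean = df$count_mean,
    min = soft$low,
    max = soft$high,
    discrete = as.numeric(discretize_mean(df)))
  idx <- match(phy$tip.label, target)
  if (anyNA(idx)) {
    stop("tree tips without a trait record: ",
         paste(phy$tip.label[is.na(idx)], collapse = ", "))
  }
  out <- value[idx]
  names(out) <- phy$tip.label
  attr(out, "unmatched") <- setdiff(target, phy$tip.label)
  attr(out, "variant") <- variant
  out
}

#' Stratigraphic ranges of the extinct records, as used by
#' [sample_fossil_tip_ages()]
#' @param df trait table.
#' @export
strat_ranges <- function(df) {
  ext <- df[which(df$extinct), , drop = FALSE]
  data.frame(taxon = ext$species, fad = ext$fad, lad = ext$lad)
}
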