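#' Deprivation indicators
#'
#' Five private-infrastructure indicators enter the index, all oriented so
#' that a higher value means more deprived (less able to physically
#' distance): number of other households sharing the toilet, reliance on a
#' public/open water source, persons per sleeping room, no mobile phone, no
#' vehicle.
#'
#' @name indicators
NULL

# canonical column order; fixed contract for everything downstream
indicator_names <- function() {
  c("share_toilet", "public_water", "persons_per_room", "no_ict", "no_vehicle")
}

raw_fields <- c("toilet_sharing_count", "water_public", "n_members",
                "n_sleeping_rooms", "has_mobile", "has_vehicle")

#' Derive the indicator vector for household records
#'
#' `share_toilet` is the count of other households sharing the toilet (kept
#' as a count, not binarized); `persons_per_room` divides household members
#' by the number of sleeping rooms, with zero rooms treated as one room;
#' `no_ict` and `no_vehicle` flip the ownership flags into deprivation
#' orientation.
#'
#' @param records data frame of household records.
#' @return data frame with `household_id` and the five indicator columns in
#'   canonical order.
#' @export
derive_indicators <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(raw_fields, names(records))
  if (length(missing_cols) > 0) {
    stop("household records missing columns: ", paste(missing_cols, collapse = ", "))
  }
  data.frame(
    household_id = records$household_id,
    share_toilet = as.numeric(records$toilet_sharing_count),
    public_water = as.numeric(records$water_public),
    persons_per_room = records$n_members / pmax(records$n_sleeping_rooms, 1),
    no_ict = 1 - as.numeric(records$has_mobile),
    no_vehicle = 1 - as.numeric(records$has_vehicle),
    stringsAsFactors = FALSE
  )
}

#' Build the indicator matrix, excluding incomplete records
#'
#' Records with any missing raw field are excluded listwise (never imputed)
#' and counted per offending field in the exclusion report.
#'
#' @param records data frame of household records.
#' @return list with `matrix` (rows = retained households, columns in
#'   canonical indicator order), `household_id`, and `excluded` (named
#'   integer vector of missingness counts per raw field).
#' @export
indicator_matrix <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(raw_fields, names(records))
  if (length(missing_cols) > 0) {
    stop("household records missing columns: ", paste(missing_cols, collapse = ", "))
  }
  miss <- vapply(raw_fields, function(f) is.na(records[[f]]), logical(nrow(records)))
  miss <- matrix(miss, nrow = nrow(records))
  excluded <- stats::setNames(colSums(miss), raw_fields)
  keep <- rowSums(miss) == 0
  if (sum(keep) < 2) {
    stop("fewer than 2 complete household records; PCA undefined")
  }
  ind <- derive_indicators(records[keep, , drop = FALSE])
  m <- as.matrix(ind[, indicator_names()])
  rownames(m) <- NULL
  list(
    matrix = m,
    household_id = ind$household_id,
    excluded = as.integer(excluded) |> stats::setNames(raw_fields)
  )
}
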