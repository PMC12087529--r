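## Conversion of raw occurrence records into visits and per-species
## detection/non-detection data.
##
## A visit is the list of species recorded by one scheme in one cell on
## one date. Species recorded on a visit score 1; species of the same
## scheme recorded on other visits but not this one score 0. Visits of
## other schemes contribute nothing for a species, since absence from a
## scheme that never records the taxon is not a non-detection.

#' Filter records to the analysis windows
#'
#' Keeps rows with a full date, location precision at or below the
#' threshold, and a date inside either period window; annotates each
#' retained row with its period.
#'
#' @param records data.frame with columns species_id, scheme_id,
#'   cell_id, date, precision_m.
#' @param p1Window,p2Window character length-2 ISO date ranges of the
#'   two periods; must not overlap.
#' @param maxPrecision coarsest admissible location precision, metres.
#' @return the filtered records with a \code{period} column.
#' @export
filterRecords <- function(records,
                          p1Window = c("1990-01-01", "1999-12-31"),
                          p2Window = c("2015-01-01", "2021-12-31"),
                          maxPrecision = 1000) {
  w1 <- as.Date(p1Window); w2 <- as.Date(p2Window)
  if (any(is.na(c(w1, w2))) || w1[1] > w1[2] || w2[1] > w2[2])
    stop("period windows must be valid ISO date ranges")
  if (max(w1[1], w2[1]) <= min(w1[2], w2[2]))
    stop("period windows overlap")
  dates <- as.Date(records$date)
  ok <- !is.na(dates) &
    !is.na(records$precision_m) & records$precision_m <= maxPrecision
  inP1 <- ok & dates >= w1[1] & dates <= w1[2]
  inP2 <- ok & dates >= w2[1] & dates <= w2[2]
  out <- records[inP1 | inP2, , drop = FALSE]
  out$date <- dates[inP1 | inP2]
  out$period <- ifelse(inP1[inP1 | inP2], "P1", "P2")
  rownames(out) <- NULL
  out
}

#' Build visits from filtered records
#'
#' One visit per unique (cell, date, scheme); its species list is the
#' union of that key's records (duplicates collapse silently since
#' detection is binary per visit). List-length classes: single (1
#' species), short (2-3), long (4+). Week of year is the ISO week with
#' week 53 merged into 52.
#'
#' @param records filtered records (see \code{\link{filterRecords}});
#'   must carry a \code{period} column.
#' @return data.frame with one row per visit: visit_id, cell_id, date,
#'   scheme_id, period, week, n_species, list_length_class and a list
#'   column \code{species}.
#' @export
buildVisits <- function(records) {
  if (!"period" %in% names(records))
    stop("records must be filtered (missing 'period' column)")
  if (nrow(records) == 0) {
    return(data.frame(visit_id = character(), cell_id = integer(),
                      date = as.Date(character()), scheme_id = character(),
                      period = character(), week = integer(),
                      n_species = integer(),
                      list_length_class = factor(character(),
                        levels = c("single", "short", "long"))))
  }
  key <- paste(records$scheme_id, records$cell_id,
               as.character(records$date), sep = "|")
  ord <- order(key, records$species_id)
  records <- records[ord, , drop = FALSE]
  key <- key[ord]
  grp <- split(seq_len(nrow(records)), key)
  first <- vapply(grp, `[`, 0L, 1L)
  species <- lapply(grp, function(i) sort(unique(records$species_id[i])))
  n <- vapply(species, length, 0L)
  out <- data.frame(
    visit_id = names(grp),
    cell_id = records$cell_id[first],
    date = records$date[first],
    scheme_id = records$scheme_id[first],
    period = records$period[first],
    week = isoWeek52(records$date[first]),
    n_species = n,
    stringsAsFactors = FALSE)
  out$list_length_class <- listLengthClass(n)
  out$species <- unname(species)
  rownames(out) <- NULL
  out
}

#' Per-species detection/non-detection matrix
#'
#' One row per visit of the species' recording scheme: response 1 when
#' the species is on the visit's list, 0 otherwise. Visits of other
#' schemes are excluded.
#'
#' @param visits visit table from \code{\link{buildVisits}}.
#' @param speciesId,schemeId the species and its scheme.
#' @return data.frame with columns visit_id, cell_id, period, week,
#'   list_length_class, response.
#' @export
detectionMatrix <- function(visits, speciesId, schemeId) {
  vv <- visits[visits$scheme_id == schemeId, , drop = FALSE]
  if (nrow(vv) == 0)
    stop("scheme '", schemeId, "' has no visits")
  detected <- vapply(vv$species, function(s) speciesId %in% s, TRUE)
  if (!any(detected))
    stop("species '", speciesId, "' was never recorded in scheme '",
         schemeId, "'; non-detections are undefined")
  data.frame(
    visit_id = vv$visit_id,
    cell_id = vv$cell_id,
    period = vv$period,
    week = vv$week,
    list_length_class = vv$list_length_class,
    response = as.integer(detected),
    stringsAsFactors = FALSE)
}
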