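# Fossil occurrence pipeline: deduplication, locality merging on a fixed
# coordinate grid, binning into geological intervals by mean age, and
# interval-wise region-by-genus incidence with Simpson dissimilarity,
# clustering and ordination.

#' Cenozoic time intervals used for fossil binning
#'
#' Eocene (56.0-33.9 Ma), Oligocene (33.9-23.0 Ma), Early Miocene
#' (23.0-15.9 Ma), Mid-Late Miocene (15.9-5.33 Ma) and
#' Pliocene-Pleistocene (5.33 Ma-11.8 Ka). The Miocene/Pliocene boundary is
#' carried at 5.33 Ma on both sides so the intervals tile without overlap.
#'
#' @return data frame with columns `interval`, `old`, `young` (Ma),
#'   ordered old to young.
#' @export
cenozoic_intervals <- function() {
  data.frame(
    interval = c("Eocene", "Oligocene", "Early Miocene",
                 "Mid-Late Miocene", "Pliocene-Pleistocene"),
    old = c(56.0, 33.9, 23.0, 15.9, 5.33),
    young = c(33.9, 23.0, 15.9, 5.33, 0.0118),
    stringsAsFactors = FALSE)
}

validate_intervals <- function(intervals) {
  stopifnot(all(c("interval", "old", "young") %in% names(intervals)))
  if (any(intervals$old <= intervals$young))
    stop("each interval needs old > young")
  o <- order(intervals$old, decreasing = TRUE)
  intervals <- intervals[o, , drop = FALSE]
  if (nrow(intervals) > 1L &&
      any(intervals$young[-nrow(intervals)] <
          intervals$old[-1L] - 1e-9))
    stop("intervals overlap")
  intervals
}

#' Remove exact duplicate fossil records
#'
#' Records identical on (genus, lon, lat, min_age, max_age) are reduced to
#' one; the number removed is stored in the `n_duplicates` attribute.
#'
#' @param records fossil record data frame (see [read_fossils()]).
#' @return deduplicated records.
#' @export
dedup_occurrences <- function(records) {
  key <- records[c("genus", "lon", "lat", "min_age", "max_age")]
  dup <- duplicated(key)
  out <- records[!dup, , drop = FALSE]
  rownames(out) <- NULL
  if (sum(dup) > 0) message(sum(dup), " duplicate records removed")
  attr(out, "n_duplicates") <- sum(dup)
  out
}

#' Merge collection localities on a fixed coordinate grid
#'
#' Snaps longitude and latitude to a `tol`-degree grid (floor binning):
#' records sharing a bin share a locality id and the bin-centre coordinates
#' (`loc_lon`, `loc_lat`). Fixed binning is deterministic and idempotent,
#' unlike single-linkage chaining of nearby localities.
#'
#' @param records fossil record data frame.
#' @param tol bin width in decimal degrees (default 0.1).
#' @return records with `locality`, `loc_lon`, `loc_lat` columns added.
#' @export
merge_localities <- function(records, tol = 0.1) {
  lon_bin <- floor(records$lon / tol)
  lat_bin <- floor(records$lat / tol)
  records$locality <- paste0(lon_bin, "_", lat_bin)
  records$loc_lon <- (lon_bin + 0.5) * tol
  records$loc_lat <- (lat_bin + 0.5) * tol
  records
}

#' Assign fossil records to geological intervals by mean age
#'
#' The mean of `min_age` and `max_age` places each record in the interval
#' with `young <= mean_age < old` (young bound inclusive, old bound
#' exclusive). Records whose mean age falls outside every interval get
#' `NA`; their count is stored in the `n_unassigned` attribute.
#'
#' @param records fossil record data frame.
#' @param intervals interval table (default [cenozoic_intervals()]).
#' @return records with `mean_age` and `interval` columns added.
#' @export
assign_interval <- function(records, intervals = cenozoic_intervals()) {
  intervals <- validate_intervals(intervals)
  age <- (records$min_age + records$max_age) / 2
  idx <- vapply(age, function(a) {
    hit <- which(intervals$young <= a & a < intervals$old)
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
  records$mean_age <- age
  records$interval <- intervals$interval[idx]
  n_un <- sum(is.na(idx))
  if (n_un > 0)
    message(n_un, " records fall outside all intervals (unassigned)")
  attr(records, "n_unassigned") <- n_un
  records
}

#' Build a coordinate-to-region lookup
#'
#' Returns a vectorised function mapping (lon, lat) to a region label by
#' exact coordinate match (after rounding to `digits` decimals), typically
#' built from the grid-cell coordinates and labels of a present-day
#' regionalization. The known region set is attached as the `regions`
#' attribute.
#'
#' @param coords data frame (or matrix) whose first two columns are the
#'   reference longitudes and latitudes.
#' @param labels region label per reference coordinate.
#' @param digits coordinate rounding used for matching.
#' @return function `(lon, lat) -> region label` (NA when unmatched).
#' @export
make_region_lookup <- function(coords, labels, digits = 6) {
  coords <- as.data.frame(coords)
  key <- paste(round(coords[[1L]], digits), round(coords[[2L]], digits))
  labels <- as.character(labels)
  if (anyDuplicated(key))
    stop("duplicate reference coordinates in lookup")
  f <- function(lon, lat)
    labels[match(paste(round(lon, digits), round(lat, digits)), key)]
  attr(f, "regions") <- sort(unique(labels))
  f
}

#' Region-by-genus incidence for one geological interval
#'
#' Tabulates the records of `interval` into a binary region x genus matrix.
#' Coordinates are taken from `paleo_lon`/`paleo_lat` when those columns
#' are present and complete, otherwise from `lon`/`lat`. Known regions with
#' no records in the interval are reported with a warning; per-region
#' record counts (sampling intensity) are attached as the `record_counts`
#' attribute.
#'
#' @param records fossil records with an `interval` column (see
#'   [assign_interval()]).
#' @param lookup region lookup function (see [make_region_lookup()]).
#' @param interval interval name.
#' @return binary region x genus incidence matrix.
#' @export
region_genus_incidence <- function(records, lookup, interval) {
  if (is.null(records$interval))
    stop("records have no interval column; run assign_interval() first")
  sub <- records[!is.na(records$interval) &
                 records$interval == interval, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no records in interval '", interval, "'")
  use_paleo <- all(c("paleo_lon", "paleo_lat") %in% names(sub)) &&
    !anyNA(sub$paleo_lon) && !anyNA(sub$paleo_lat)
  lon <- if (use_paleo) sub$paleo_lon else sub$lon
  lat <- if (use_paleo) sub$paleo_lat else sub$lat
  reg <- lookup(lon, lat)
  if (anyNA(reg))
    stop(sum(is.na(reg)), " records in interval '", interval,
         "' fall outside the region lookup")
  tab <- table(factor(reg), factor(sub$genus))
  m <- matrix(as.integer(tab > 0), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  known <- attr(lookup, "regions")
  if (!is.null(known)) {
    absent <- setdiff(known, rownames(m))
    if (length(absent))
      warning("interval '", interval, "': no records for region(s) ",
              paste(absent, collapse = ", "))
  }
  attr(m, "record_counts") <- as.integer(table(reg)[rownames(m)])
  m
}

#' Clean a fossil record table and report the counts
#'
#' Runs deduplication, locality merging and interval assignment, and
#' returns the records alongside a cleaning report whose counts partition
#' the raw input rows: `n_input = n_indeterminate + n_duplicates +
#' n_unassigned + n_assigned`.
#'
#' @param records records from [read_fossils()] (its `n_raw` /
#'   `n_indeterminate` attributes, when present, feed the report).
#' @param intervals interval table.
#' @param tol locality bin width (degrees).
#' @return list with `records` (cleaned, binned) and `report` (named
#'   counts).
#' @export
clean_fossils <- function(records, intervals = cenozoic_intervals(),
                          tol = 0.1) {
  n_indet <- attr(records, "n_indeterminate") %||% 0L
  n_raw <- attr(records, "n_raw") %||% (nrow(records) + n_indet)
  rec <- dedup_occurrences(records)
  n_dup <- attr(rec, "n_duplicates")
  rec <- merge_localities(rec, tol = tol)
  rec <- assign_interval(rec, intervals)
  n_un <- attr(rec, "n_unassigned")
  report <- c(n_input = n_raw, n_indeterminate = n_indet,
              n_duplicates = n_dup, n_unassigned = n_un,
              n_assigned = sum(!is.na(rec$interval)))
  list(records = rec, report = report)
}

#' Interval-wise dissimilarity, clustering and ordination of fossil regions
#'
#' For each interval: region x genus incidence, pairwise Simpson
#' dissimilarity, UPGMA dendrogram and 2-D NMDS. Regions present in fewer
#' than two genera are excluded (with a warning); an interval with no
#' usable records is skipped with a warning; the dendrogram requires two
#' regions and the NMDS three (plus non-zero dissimilarity), otherwise that
#' component is `NULL` with a warning.
#'
#' @param records fossil records with interval assignments.
#' @param lookup region lookup function.
#' @param intervals interval table.
#' @param nmds_restarts,seed forwarded to [nmds()].
#' @return named list (one entry per interval) of lists with `incidence`,
#'   `beta`, `dendrogram`, `ordination`.
#' @export
interval_beta_series <- function(records, lookup,
                                 intervals = cenozoic_intervals(),
                                 nmds_restarts = 10, seed = NULL) {
  intervals <- validate_intervals(intervals)
  out <- vector("list", nrow(intervals))
  names(out) <- intervals$interval
  for (iv in intervals$interval) {
    m <- tryCatch(region_genus_incidence(records, lookup, iv),
                  error = function(e) {
                    warning("interval '", iv, "' skipped: ",
                            conditionMessage(e))
                    NULL
                  })
    if (is.null(m)) next
    thin <- rowSums(m) < 2
    if (any(thin)) {
      warning("interval '", iv, "': region(s) ",
              paste(rownames(m)[thin], collapse = ", "),
              " present in < 2 genera, excluded")
      m <- m[!thin, , drop = FALSE]
    }
    if (nrow(m) == 0L) next
    beta <- pairwise_beta_sim(m)
    dend <- if (nrow(m) >= 2L) linkage(beta, "UPGMA") else NULL
    ord <- NULL
    if (nrow(m) >= 3L) {
      ord <- tryCatch(nmds(beta, restarts = nmds_restarts, seed = seed),
                      error = function(e) {
                        warning("interval '", iv, "': NMDS skipped (",
                                conditionMessage(e), ")")
                        NULL
                      })
    } else {
      warning("interval '", iv, "': < 3 regions, NMDS skipped")
    }
    out[[iv]] <- list(incidence = m, beta = beta, dendrogram = dend,
                      ordination = ord)
  }
  out
}
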