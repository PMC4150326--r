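#' Correct effort-sensitive abundance measures for within-study effort
#'
#' Measures that scale with sampling effort (`abundance` and
#' `group_abundance`) are rescaled to what would have been recorded at the
#' study's maximal effort, assuming direct proportionality:
#' `corrected = value / (effort / max(effort in study))`.  Other measure
#' types (relative abundance, density, reporting rate) are left unchanged.
#' Any study-level rescaling introduced by the choice of reference effort is
#' absorbed by the study random intercept on the log scale downstream.
#'
#' @param records long-format record table with columns `study_id`,
#'   `site_id`, `taxon_id`, `measure_type`, `effort`, `value`.
#' @return the table with `value` corrected and a logical marker column
#'   `effort_corrected`; calling the function again on its own output is a
#'   no-op (with a warning).
#' @export
correct_effort <- function(records) {
  need <- c("study_id", "measure_type", "effort", "value")
  stopifnot(all(need %in% names(records)))
  if (isTRUE(attr(records, "effort_corrected")) ||
      "effort_corrected" %in% names(records)) {
    warning("records already effort-corrected; returning unchanged")
    return(records)
  }
  bad <- which(!is.finite(records$effort) | records$effort <= 0)
  if (length(bad) > 0)
    stop("non-positive effort in rows: ", paste(bad, collapse = ", "))
  sensitive <- records$measure_type %in% c("abundance", "group_abundance")
  max_eff <- stats::ave(records$effort, records$study_id, FUN = max)
  records$value <- ifelse(sensitive,
                          records$value / (records$effort / max_eff),
                          records$value)
  records$effort_corrected <- TRUE
  records
}

#' Derive the occurrence table from abundance records
#'
#' A taxon is taken to be present at a site when its recorded value there is
#' positive, and absent at the other sites of the same study -- absence is
#' only inferable within a study that recorded the taxon somewhere.  Taxa
#' never recorded with a positive value anywhere in a study are excluded
#' from that study's table.  The result has one row per (site in study x
#' taxon positively recorded in study).
#'
#' @param records record table with `study_id`, `site_id`, `taxon_id`,
#'   `value`; sites with a record row but zero value count as surveyed.
#' @return data.frame `study_id`, `site_id`, `taxon_id`, `present` (0/1).
#' @export
derive_occurrence <- function(records) {
  stopifnot(all(c("study_id", "site_id", "taxon_id", "value") %in%
                  names(records)))
  key <- paste(records$study_id, records$site_id, records$taxon_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (study, site, taxon) records; aggregate before deriving occurrence")
  out <- lapply(split(records, records$study_id), function(st) {
    sites <- sort(unique(st$site_id))
    pos <- tapply(st$value, st$taxon_id, function(v) any(v > 0))
    taxa <- sort(names(pos)[pos])
    if (length(taxa) == 0) return(NULL)
    g <- expand.grid(site_id = sites, taxon_id = taxa,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    m <- match(paste(g$site_id, g$taxon_id, sep = "\r"),
               paste(st$site_id, st$taxon_id, sep = "\r"))
    g$present <- as.integer(!is.na(m) & st$value[m] > 0)
    g$study_id <- st$study_id[1]
    g[, c("study_id", "site_id", "taxon_id", "present")]
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Area of occupancy from point records on a half-degree grid
#'
#' Sums the spherical areas of the distinct half-degree grid cells that
#' contain at least one occurrence point.  Cells are aligned to integer and
#' half-integer degree boundaries and half-open (`[a, a + 0.5)`), so a
#' point on a boundary belongs to the cell to its north-east.  Cell area is
#' `R^2 * dlon * (sin(lat2) - sin(lat1))` with `R = 6371` km.
#'
#' @param lon,lat point coordinates in decimal degrees.
#' @return area of occupancy in km^2.
#' @export
area_of_occupancy <- function(lon, lat) {
  stopifnot(length(lon) == length(lat), length(lon) >= 1)
  cl_lon <- floor(lon / 0.5) * 0.5
  cl_lat <- floor(lat / 0.5) * 0.5
  cells <- unique(data.frame(lon = cl_lon, lat = cl_lat))
  R <- 6371
  dlon <- 0.5 * pi / 180
  sum(R^2 * dlon * (sin((cells$lat + 0.5) * pi / 180) -
                    sin(cells$lat * pi / 180)))
}

#' Classify taxa as narrow- or wide-ranged by a within-group median split
#'
#' Computes each taxon's area of occupancy from its occurrence points and
#' splits each taxonomic group at the group median: strictly above the
#' median is `wide`, at or below is `narrow` (ties go to `narrow`, reading
#' "exceeded the median" strictly).  Taxa without points keep
#' `range_class = "unset"` with a warning.
#'
#' @param points data.frame with `taxon_id`, `lon`, `lat`.
#' @param taxa taxon table with `taxon_id` and `group`.
#' @return `taxa` with columns `aoo_km2` and `range_class` added.
#' @export
classify_range <- function(points, taxa) {
  stopifnot(all(c("taxon_id", "lon", "lat") %in% names(points)),
            all(c("taxon_id", "group") %in% names(taxa)))
  aoo <- vapply(split(points, points$taxon_id),
                function(p) area_of_occupancy(p$lon, p$lat), numeric(1))
  taxa$aoo_km2 <- unname(aoo[match(taxa$taxon_id, names(aoo))])
  taxa$range_class <- "unset"
  if (anyNA(taxa$aoo_km2))
    warning(sum(is.na(taxa$aoo_km2)), " taxa have no occurrence points; range_class left unset")
  for (g in unique(taxa$group)) {
    in_g <- taxa$group == g & !is.na(taxa$aoo_km2)
    if (!any(in_g)) next
    med <- stats::median(taxa$aoo_km2[in_g])
    taxa$range_class[in_g] <- ifelse(taxa$aoo_km2[in_g] > med, "wide", "narrow")
  }
  taxa
}

#' Flag forest/habitat specialists from a habitat table
#'
#' Birds are forest specialists when forest habitat is of "major"
#' importance; mammals are habitat specialists when their habitat breadth
#' (number of habitat layers used) is one.  Other groups, and taxa with no
#' habitat information, are `unknown`.
#'
#' @param taxa taxon table with `taxon_id` and `group`.
#' @param habitat_table data.frame with `taxon_id` and, per group,
#'   `forest_importance` (character; birds) or `habitat_breadth` (integer;
#'   mammals).
#' @return `taxa` with a `specialist` column
#'   (`"specialist"`/`"generalist"`/`"unknown"`).
#' @export
flag_specialists <- function(taxa, habitat_table) {
  stopifnot(all(c("taxon_id", "group") %in% names(taxa)))
  m <- match(taxa$taxon_id, habitat_table$taxon_id)
  spec <- rep("unknown", nrow(taxa))
  is_bird <- taxa$group == "birds"
  is_mammal <- taxa$group == "mammals"
  fi <- habitat_table$forest_importance[m]
  hb <- habitat_table$habitat_breadth[m]
  spec[is_bird & !is.na(fi)] <-
    ifelse(fi[is_bird & !is.na(fi)] == "major", "specialist", "generalist")
  spec[is_mammal & !is.na(hb)] <-
    ifelse(hb[is_mammal & !is.na(hb)] == 1, "specialist", "generalist")
  n_miss <- sum((is_bird & is.na(fi)) | (is_mammal & is.na(hb)))
  if (n_miss > 0)
    warning(n_miss, " birds/mammals lack habitat information; specialist = unknown")
  taxa$specialist <- spec
  taxa
}
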