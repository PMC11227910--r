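#' Conspecific seedling neighbor count (S_con)
#'
#' Number of other alive conspecific seedlings sharing the focal seedling's
#' quadrat at the given census; the focal individual itself is excluded,
#' dead or not-yet-recruited individuals are not counted.
#'
#' @param plot a [plot_dataset()]. @param tag focal seedling tag.
#' @param year census year; the focal must be alive then.
#' @return integer count >= 0.
#' @export
s_con <- function(plot, tag, year) {
  sl <- plot$seedlings
  i <- match(tag, sl$tag)
  if (is.na(i)) stop("unknown seedling tag: ", tag)
  st <- seedling_status(plot, year)
  if (is.na(st[i]) || st[i] != "A")
    stop("focal seedling ", tag, " is not alive at census ", year)
  sum(!is.na(st) & st == "A" &
      sl$quadrat_id == sl$quadrat_id[i] &
      sl$species == sl$species[i]) - 1L
}

#' Distance-weighted conspecific adult basal area (A_con)
#'
#' Sum over conspecific adults within `radius_m` of the quadrat center of
#' BA_i / Distance_i, with basal area BA = pi (dbh/2)^2 in cm^2 (dbh in cm)
#' and distance in meters from the quadrat center to the stem. The radius
#' test uses a closed ball (<=) and no edge correction is applied near the
#' plot boundary. A distance floor (default 0.1 m) guards against stems
#' mapped on top of the quadrat center.
#'
#' @param species focal species name.
#' @param center numeric length-2 quadrat center (x, y), meters.
#' @param adults adult table (`species`, `x`, `y`, `dbh`).
#' @param radius_m neighborhood radius, meters. @param d_floor distance
#'   floor, meters.
#' @return numeric, cm^2 m^-1; 0 when no conspecific adult is in range.
#' @export
a_con <- function(species, center, adults, radius_m = 20, d_floor = 0.1) {
  sel <- adults$species == species
  if (!any(sel)) return(0)
  dx <- adults$x[sel] - center[1]
  dy <- adults$y[sel] - center[2]
  d <- sqrt(dx^2 + dy^2)
  keep <- d <= radius_m
  if (!any(keep)) return(0)
  ba <- pi * (adults$dbh[sel][keep] / 2)^2
  sum(ba / pmax(d[keep], d_floor))
}

#' Heterospecific neighbor profiles of a focal seedling
#'
#' The seedling-layer profile counts alive heterospecific seedlings in the
#' focal's quadrat at the census; the adult-layer profile counts
#' heterospecific adults within `radius_m` of the quadrat center. Adult and
#' seedling neighbors include all woody species (trees, shrubs, lianas);
#' the focal species never appears in either profile.
#'
#' @inheritParams s_con
#' @param radius_m adult neighborhood radius, meters.
#' @return list with elements `seedling` and `adult`, each a named integer
#'   vector of per-species counts (possibly empty), and attributes
#'   `focal_species` and `quadrat_id`.
#' @export
neighbor_profiles <- function(plot, tag, year, radius_m = 20) {
  sl <- plot$seedlings
  i <- match(tag, sl$tag)
  if (is.na(i)) stop("unknown seedling tag: ", tag)
  st <- seedling_status(plot, year)
  if (is.na(st[i]) || st[i] != "A")
    stop("focal seedling ", tag, " is not alive at census ", year)
  sp <- sl$species[i]
  qid <- sl$quadrat_id[i]

  in_q <- !is.na(st) & st == "A" & sl$quadrat_id == qid & sl$species != sp
  seed_prof <- table_counts(sl$species[in_q])

  q <- plot$quadrats[match(qid, plot$quadrats$quadrat_id), ]
  ad <- plot$adults
  d <- sqrt((ad$x - q$center_x)^2 + (ad$y - q$center_y)^2)
  in_r <- d <= radius_m & ad$species != sp
  adult_prof <- table_counts(ad$species[in_r])

  structure(list(seedling = seed_prof, adult = adult_prof),
            focal_species = sp, quadrat_id = qid)
}

# named integer counts without table()'s factor baggage
table_counts <- function(x) {
  if (!length(x)) return(integer(0))
  tb <- table(x)
  stats::setNames(as.integer(tb), names(tb))
}
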