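#' Construct a validated plot dataset
#'
#' Bundles the four census tables of a stem-mapped forest dynamics plot into
#' a single validated object. The coordinate frame has its origin at the
#' plot's south-west corner, x increasing east and y north, in meters.
#' Subplot (r, c) spans [20c, 20c+20) x [20r, 20r+20) for the default 20 m
#' subplot size.
#'
#' @param adults data.frame with columns `tag`, `species`, `x`, `y`, `dbh`
#'   (cm). Adults are stems with DBH >= 1 cm.
#' @param seedlings data.frame with columns `tag`, `quadrat_id`, `species`
#'   and, per census year Y, `status_Y` (one of `"A"` alive, `"D"` dead, or
#'   `NA` not yet recruited) and `height_Y` (cm, may be `NA`).
#' @param quadrats data.frame with columns `quadrat_id`, `subplot_row`,
#'   `subplot_col`, optional `center_x`/`center_y` overrides (for quadrats
#'   relocated around obstacles), and `elev_c1`..`elev_c4` corner elevations
#'   in meters (order: SW, SE, NE, NW).
#' @param habitat data.frame with `quadrat_id` plus soil and light columns
#'   (see [add_topography()] and [habitat_pca()]); may be `NULL`.
#' @param census_years strictly increasing integer vector of census years.
#' @param extent numeric length-2 plot extent in meters, default
#'   `c(200, 200)`.
#' @param species_pool optional character vector of valid species names
#'   (normally the phylogeny tip labels); when given, every census species
#'   must be present in it.
#' @param non_focal_species character vector of species (e.g. lianas) that
#'   are counted as neighbors but never used as focal seedlings.
#'
#' @return An object of class `plot_dataset`: a list with the (validated)
#'   components above plus a `validation` element listing carried-forward
#'   heights and other repairs.
#' @export
plot_dataset <- function(adults, seedlings, quadrats, habitat = NULL,
                         census_years, extent = c(200, 200),
                         species_pool = NULL,
                         non_focal_species = character(0)) {
  census_years <- as.integer(census_years)
  if (length(census_years) < 1L || is.unsorted(census_years, strictly = TRUE))
    stop("census_years must be strictly increasing")

  .check_columns(adults, c("tag", "species", "x", "y", "dbh"), "adults")
  .check_columns(quadrats, c("quadrat_id", "subplot_row", "subplot_col",
                             paste0("elev_c", 1:4)), "quadrats")
  need <- c("tag", "quadrat_id", "species",
            paste0("status_", census_years), paste0("height_", census_years))
  .check_columns(seedlings, need, "seedlings")

  if (any(adults$dbh < 1))
    stop("adults: dbh < 1 for tags ",
         paste(utils::head(adults$tag[adults$dbh < 1], 5), collapse = ", "))
  if (any(adults$x < 0 | adults$x > extent[1] |
          adults$y < 0 | adults$y > extent[2]))
    stop("adults: coordinates outside the plot extent")

  if (anyDuplicated(quadrats$quadrat_id))
    stop("quadrats: duplicated quadrat_id")
  if (anyDuplicated(quadrats[, c("subplot_row", "subplot_col")]))
    stop("quadrats: more than one quadrat per subplot")

  # fill quadrat centers from the placement rule where not given explicitly
  if (is.null(quadrats$center_x)) quadrats$center_x <- NA_real_
  if (is.null(quadrats$center_y)) quadrats$center_y <- NA_real_
  miss <- is.na(quadrats$center_x) | is.na(quadrats$center_y)
  if (any(miss)) {
    ctr <- quadrat_center(quadrats$subplot_row[miss], quadrats$subplot_col[miss])
    quadrats$center_x[miss] <- ctr[, 1]
    quadrats$center_y[miss] <- ctr[, 2]
  }

  bad_q <- setdiff(seedlings$quadrat_id, quadrats$quadrat_id)
  if (length(bad_q))
    stop("seedlings reference unknown quadrat_id: ",
         paste(utils::head(bad_q, 5), collapse = ", "))

  validation <- list(carried_forward_heights = character(0))
  st <- as.matrix(seedlings[, paste0("status_", census_years), drop = FALSE])
  ht <- as.matrix(seedlings[, paste0("height_", census_years), drop = FALSE])
  bad_vals <- setdiff(unique(st[!is.na(st)]), c("A", "D"))
  if (length(bad_vals))
    stop("seedlings: unknown status value(s): ", paste(bad_vals, collapse = ", "))

  # dead -> alive is impossible; once recruited a status exists at every
  # later census
  for (i in seq_len(nrow(st))) {
    s <- st[i, ]
    rec <- which(!is.na(s))
    if (!length(rec)) next
    later <- seq(min(rec), length(s))
    if (anyNA(s[later]))
      stop("seedlings: missing status after recruitment for tag ",
           seedlings$tag[i])
    d <- which(s == "D")
    if (length(d) && any(s[seq(min(d), length(s))] == "A"))
      stop("seedlings: dead -> alive status transition for tag ",
           seedlings$tag[i])
    first_alive <- which(s == "A")[1]
    if (!is.na(first_alive)) {
      h0 <- ht[i, first_alive]
      if (!is.na(h0) && h0 < 20)
        stop("seedlings: height < 20 cm at first alive census for tag ",
             seedlings$tag[i])
      # carry forward last measured height for alive censuses missing one
      alive <- which(s == "A")
      for (j in alive) {
        if (is.na(ht[i, j])) {
          prev <- which(!is.na(ht[i, seq_len(j)]))
          if (length(prev)) {
            ht[i, j] <- ht[i, max(prev)]
            validation$carried_forward_heights <-
              c(validation$carried_forward_heights, seedlings$tag[i])
          }
        }
      }
    }
  }
  seedlings[, paste0("height_", census_years)] <- ht

  if (!is.null(species_pool)) {
    missing_sp <- setdiff(unique(c(adults$species, seedlings$species)),
                          species_pool)
    if (length(missing_sp))
      stop("species absent from the phylogeny: ",
           paste(missing_sp, collapse = ", "))
  }

  structure(list(adults = adults, seedlings = seedlings, quadrats = quadrats,
                 habitat = habitat, census_years = census_years,
                 extent = as.numeric(extent),
                 non_focal_species = non_focal_species,
                 validation = validation),
            class = "plot_dataset")
}

.check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, ": missing column(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.plot_dataset <- function(x, ...) {
  cat("<plot_dataset> ", x$extent[1], "x", x$extent[2], "m plot\n",
      "  adults:    ", nrow(x$adults), " stems, ",
      length(unique(x$adults$species)), " species\n",
      "  seedlings: ", nrow(x$seedlings), " tags, ",
      length(unique(x$seedlings$species)), " species\n",
      "  quadrats:  ", nrow(x$quadrats), "\n",
      "  censuses:  ", paste(x$census_years, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Center of the seedling quadrat attached to a subplot
#'
#' Seedling quadrats (2 x 2 m) sit at the top-right (north-east) corner of
#' each 20 x 20 m subplot. Two placement rules are supported: `"inset"`
#' (default) puts the quadrat 2 m in from the subplot's NE corner, so
#' subplot (r, c) has its quadrat center at (20c + 17, 20r + 17); `"flush"`
#' puts it flush against the corner, center at (20c + 19, 20r + 19).
#'
#' @param subplot_row,subplot_col 0-based subplot indices (vectorized).
#' @param placement_rule `"inset"` or `"flush"`.
#' @param subplot_m subplot side, m. @param quadrat_m quadrat side, m.
#' @param n_rows,n_cols grid dimensions used for range checking.
#' @return two-column matrix of (x, y) centers in meters.
#' @export
quadrat_center <- function(subplot_row, subplot_col,
                           placement_rule = c("inset", "flush"),
                           subplot_m = 20, quadrat_m = 2,
                           n_rows = 10, n_cols = 10) {
  placement_rule <- match.arg(placement_rule)
  if (any(subplot_row < 0 | subplot_row >= n_rows |
          subplot_col < 0 | subplot_col >= n_cols))
    stop("subplot index out of grid")
  inset <- if (placement_rule == "inset") quadrat_m else 0
  off <- subplot_m - inset - quadrat_m / 2
  cbind(x = subplot_col * subplot_m + off,
        y = subplot_row * subplot_m + off)
}

#' Read a plot dataset from its four CSV tables
#'
#' Files are UTF-8 CSV with a header row and "." decimal separator. Census
#' years are inferred from the `status_<year>` columns of the seedling
#' table.
#'
#' @param adult_path,seedling_path,quadrat_path,habitat_path file paths;
#'   `habitat_path` may be `NULL`.
#' @inheritParams plot_dataset
#' @return a validated [plot_dataset()].
#' @export
read_plot <- function(adult_path, seedling_path, quadrat_path,
                      habitat_path = NULL, extent = c(200, 200),
                      species_pool = NULL,
                      non_focal_species = character(0)) {
  for (p in c(adult_path, seedling_path, quadrat_path, habitat_path))
    if (!file.exists(p)) stop("file not found: ", p)
  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE,
                                    colClasses = NA, check.names = FALSE)
  adults <- rd(adult_path)
  seedlings <- rd(seedling_path)
  quadrats <- rd(quadrat_path)
  habitat <- if (!is.null(habitat_path)) rd(habitat_path) else NULL
  yrs <- sort(as.integer(sub("^status_", "",
                             grep("^status_", names(seedlings), value = TRUE))))
  if (!length(yrs)) stop("seedlings: no status_<year> columns found")
  for (col in paste0("status_", yrs))
    seedlings[[col]][!is.na(seedlings[[col]]) & seedlings[[col]] == ""] <- NA
  plot_dataset(adults, seedlings, quadrats, habitat, census_years = yrs,
               extent = extent, species_pool = species_pool,
               non_focal_species = non_focal_species)
}

#' Write a plot dataset to CSV tables
#'
#' Inverse of [read_plot()]: writes `adults.csv`, `seedlings.csv`,
#' `quadrats.csv` and (when present) `habitat.csv` under `dir`.
#'
#' @param x a `plot_dataset`. @param dir output directory, created if needed.
#' @return invisibly, the vector of files written.
#' @export
write_plot <- function(x, dir) {
  stopifnot(inherits(x, "plot_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("adults.csv", "seedlings.csv", "quadrats.csv"))
  utils::write.csv(x$adults, paths[1], row.names = FALSE)
  utils::write.csv(x$seedlings, paths[2], row.names = FALSE)
  utils::write.csv(x$quadrats, paths[3], row.names = FALSE)
  if (!is.null(x$habitat)) {
    p4 <- file.path(dir, "habitat.csv")
    utils::write.csv(x$habitat, p4, row.names = FALSE)
    paths <- c(paths, p4)
  }
  invisible(paths)
}

# status / height lookup helpers -------------------------------------------

seedling_status <- function(plot, year) {
  col <- paste0("status_", year)
  if (!col %in% names(plot$seedlings)) stop("no census in year ", year)
  plot$seedlings[[col]]
}

seedling_height <- function(plot, year) {
  plot$seedlings[[paste0("height_", year)]]
}

#' Tags of seedlings alive at a census
#' @param plot a `plot_dataset`. @param year census year.
#' @return character vector of tags.
#' @export
alive_tags <- function(plot, year) {
  plot$seedlings$tag[!is.na(seedling_status(plot, year)) &
                     seedling_status(plot, year) == "A"]
}
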