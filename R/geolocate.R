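# Geolocation of tweets to US states.
#
# Coordinates are resolved by point-in-state tests against packaged
# simplified state boundaries; free-text profile locations are matched
# against full state names, two-letter abbreviations, and the 60
# most-populated US cities, in that precedence order. DC is treated as a
# state-level unit; territories stay unresolved.

#' Load the state gazetteer
#'
#' Bundles the three packaged lookup tables used for geolocation: the 50
#' states + DC (code, name, representative interior point), the 60
#' most-populated US cities with their states, and simplified state boundary
#' polygons for point-in-state tests. All three are user-replaceable.
#'
#' @param states_path,cities_path,polygons_path Optional paths to
#'   replacement CSVs in the packaged formats (see the files under
#'   `system.file("extdata", package = "acasent")`).
#' @return A `geo_gazetteer` object.
#' @details The packaged polygons are deliberately coarse (a handful of
#'   vertices per state): the analysis only needs state membership for
#'   points well inside a state, not exact borders. Points claimed by more
#'   than one polygon (overlaps near simplified borders) resolve to the
#'   lexicographically first state code, a documented deterministic tie
#'   rule.
#' @export
load_gazetteer <- function(states_path = NULL, cities_path = NULL,
                           polygons_path = NULL) {
  if (is.null(states_path)) states_path <- acasent_file("states.csv")
  if (is.null(cities_path)) cities_path <- acasent_file("top60_cities.csv")
  if (is.null(polygons_path)) polygons_path <- acasent_file("state_polygons.csv")
  states <- read.csv(states_path, stringsAsFactors = FALSE)
  cities <- read.csv(cities_path, stringsAsFactors = FALSE)
  poly <- read.csv(polygons_path, stringsAsFactors = FALSE)
  stopifnot(all(c("code", "name", "rep_lat", "rep_lon") %in% names(states)),
            all(c("city", "state", "rank") %in% names(cities)),
            all(c("state", "lon", "lat") %in% names(poly)))
  if (nrow(states) != 51L || anyDuplicated(states$code)) {
    stop("gazetteer must list exactly the 50 states + DC, once each",
         call. = FALSE)
  }
  if (nrow(cities) != 60L) {
    stop("city table must have exactly 60 entries", call. = FALSE)
  }
  if (!all(cities$state %in% states$code)) {
    stop("city table references unknown state codes: ",
         paste(setdiff(cities$state, states$code), collapse = ", "),
         call. = FALSE)
  }
  # An ambiguous city name keeps its highest-population (lowest-rank) bearer.
  cities <- cities[order(cities$rank), , drop = FALSE]
  cities <- cities[!duplicated(tolower(cities$city)), , drop = FALSE]
  states <- states[order(states$code), , drop = FALSE]
  polys <- lapply(split(poly, poly$state), function(d) {
    cbind(lon = d$lon, lat = d$lat)
  })
  if (!all(names(polys) %in% states$code)) {
    stop("polygon table references unknown state codes", call. = FALSE)
  }
  structure(list(states = states, cities = cities, polygons = polys),
            class = "geo_gazetteer")
}

#' @export
print.geo_gazetteer <- function(x, ...) {
  cat("<geo_gazetteer> ", nrow(x$states), " state units, ",
      nrow(x$cities), " cities, ", length(x$polygons),
      " boundary polygons\n", sep = "")
  invisible(x)
}

#' Resolve coordinates to a US state
#'
#' Point-in-polygon test against the gazetteer's simplified state
#' boundaries. States are tried in lexicographic code order and the first
#' containing polygon wins, which makes points in overlap slivers of the
#' simplified borders resolve deterministically.
#'
#' @param lat,lon Numeric vectors of latitude/longitude in degrees
#'   (`lat` in \[-90, 90\], `lon` in \[-180, 180\]).
#' @param gazetteer A `geo_gazetteer` from [load_gazetteer()].
#' @return Character vector of state codes, `NA` where the point falls in
#'   no state polygon (ocean, territory, abroad).
#' @examples
#' gaz <- load_gazetteer()
#' resolve_coordinates(39.95, -75.16, gaz)  # Philadelphia -> "PA"
#' @export
resolve_coordinates <- function(lat, lon, gazetteer) {
  stopifnot(inherits(gazetteer, "geo_gazetteer"),
            length(lat) == length(lon))
  bad <- !is.na(lat) & !is.na(lon) &
    (lat < -90 | lat > 90 | lon < -180 | lon > 180)
  if (any(bad)) stop("coordinates out of range", call. = FALSE)
  out <- rep(NA_character_, length(lat))
  open <- which(!is.na(lat) & !is.na(lon))
  for (code in sort(names(gazetteer$polygons))) {
    if (!length(open)) break
    bnd <- gazetteer$polygons[[code]]
    inside <- mgcv::in.out(bnd, cbind(lon[open], lat[open]))
    if (any(inside)) {
      out[open[inside]] <- code
      open <- open[!inside]
    }
  }
  out
}

# Normalize free text for phrase matching: lowercase, punctuation to
# spaces, squeezed whitespace, padded so \b-style matching is a substring
# test on " phrase ".
normalize_phrase <- function(text) {
  x <- tolower(text)
  x <- gsub("[^a-z0-9]+", " ", x)
  paste0(" ", trimws(x), " ")
}

#' Resolve a free-text profile location to a US state
#'
#' Applies the precedence full state name > two-letter abbreviation >
#' top-60 city name over case-folded, punctuation-split text. Abbreviations
#' are deliberately conservative: a two-letter token only counts when it is
#' uppercase in the original text (`"PA"`) or directly follows a comma
#' (`"Philadelphia, pa"`), which keeps common words like "in" or "me" from
#' firing as IN or ME. `"Washington DC"` (and `"D.C."`) resolves to DC
#' rather than Washington state.
#'
#' @param text Character vector of profile location strings (`NA`/empty
#'   allowed).
#' @param gazetteer A `geo_gazetteer`.
#' @return List with `state` (character, `NA` if unresolved) and `method`
#'   (`"state_name"`, `"state_abbrev"`, `"city"`, or `"unresolved"`).
#' @examples
#' gaz <- load_gazetteer()
#' resolve_location_text("Philadelphia, PA", gaz)$state  # "PA" via abbrev
#' resolve_location_text("new york city", gaz)$state     # "NY" via city
#' @export
resolve_location_text <- function(text, gazetteer) {
  stopifnot(inherits(gazetteer, "geo_gazetteer"))
  n <- length(text)
  state <- rep(NA_character_, n)
  method <- rep("unresolved", n)
  if (!n) return(list(state = state, method = method))
  text0 <- ifelse(is.na(text), "", text)
  norm <- normalize_phrase(text0)

  st <- gazetteer$states
  name_norm <- normalize_phrase(st$name)

  # "Washington DC" / "Washington, D.C." must beat the Washington state
  # name; standalone "DC" is handled by the ordinary abbreviation scan.
  dc_hit <- grepl(" washington +d ?c ", norm)

  # 1. Full state names; earliest match position wins, ties to the
  #    lexicographically first code.
  pos <- matrix(-1L, nrow = n, ncol = nrow(st))
  for (j in seq_len(nrow(st))) {
    pos[, j] <- regexpr(name_norm[j], norm, fixed = TRUE)
  }
  for (i in seq_len(n)) {
    if (dc_hit[i]) {
      state[i] <- "DC"; method[i] <- "state_name"
      next
    }
    hits <- which(pos[i, ] > 0L)
    if (length(hits)) {
      best <- hits[order(pos[i, hits], st$code[hits])][1]
      state[i] <- st$code[best]
      method[i] <- "state_name"
    }
  }

  # 2. Two-letter abbreviations (uppercase standalone, or after a comma).
  todo <- which(is.na(state))
  if (length(todo)) {
    nodots <- gsub("[.]", "", text0[todo])
    codes <- st$code
    up <- regmatches(nodots, gregexpr("(?<![A-Za-z0-9])[A-Z]{2}(?![A-Za-z0-9])",
                                      nodots, perl = TRUE))
    cm <- regmatches(nodots,
                     gregexpr("(?<=,)[ ]*[A-Za-z]{2}(?![A-Za-z0-9])",
                              nodots, perl = TRUE))
    for (k in seq_along(todo)) {
      cand <- c(up[[k]], toupper(trimws(cm[[k]])))
      cand <- cand[cand %in% codes]
      if (length(cand)) {
        state[todo[k]] <- cand[1]
        method[todo[k]] <- "state_abbrev"
      }
    }
  }

  # 3. Top-60 city names.
  todo <- which(is.na(state))
  if (length(todo)) {
    ct <- gazetteer$cities
    city_norm <- normalize_phrase(ct$city)
    posc <- matrix(-1L, nrow = length(todo), ncol = nrow(ct))
    for (j in seq_len(nrow(ct))) {
      posc[, j] <- regexpr(city_norm[j], norm[todo], fixed = TRUE)
    }
    for (k in seq_along(todo)) {
      hits <- which(posc[k, ] > 0L)
      if (length(hits)) {
        best <- hits[order(posc[k, hits], ct$rank[hits])][1]
        state[todo[k]] <- ct$state[best]
        method[todo[k]] <- "city"
      }
    }
  }

  list(state = state, method = method)
}

#' Geocode a tweet corpus to states
#'
#' Coordinates take precedence over the profile-location text: a tweet with
#' coordinates inside a state polygon is assigned that state even when its
#' profile text says otherwise. Tweets whose coordinates resolve to no
#' state fall back to the profile text.
#'
#' @param tweets Tweet data frame from [read_tweets()].
#' @param gazetteer A `geo_gazetteer`.
#' @return A `geo_result`: list with `resolutions` (data frame `tweet_id`,
#'   `state`, `method`) and `summary` (list with `n`, `n_resolved`,
#'   `fraction_resolved`, `method_counts`).
#' @export
geocode_corpus <- function(tweets, gazetteer) {
  stopifnot(inherits(gazetteer, "geo_gazetteer"))
  n <- nrow(tweets)
  state <- rep(NA_character_, n)
  method <- rep("unresolved", n)
  has_coord <- !is.na(tweets$lat) & !is.na(tweets$lon)
  if (any(has_coord)) {
    st <- resolve_coordinates(tweets$lat[has_coord], tweets$lon[has_coord],
                              gazetteer)
    state[has_coord] <- st
    method[has_coord][!is.na(st)] <- "coordinates"
  }
  todo <- which(is.na(state) & !is.na(tweets$profile_location))
  if (length(todo)) {
    res <- resolve_location_text(tweets$profile_location[todo], gazetteer)
    state[todo] <- res$state
    method[todo] <- res$method
  }
  resolutions <- data.frame(tweet_id = tweets$id, state = state,
                            method = method, stringsAsFactors = FALSE)
  counts <- table(factor(method, levels = c("coordinates", "state_name",
                                            "state_abbrev", "city",
                                            "unresolved")))
  structure(list(resolutions = resolutions,
                 summary = list(n = n,
                                n_resolved = sum(!is.na(state)),
                                fraction_resolved = if (n) sum(!is.na(state)) / n else 0,
                                method_counts = as.list(counts))),
            class = "geo_result")
}

#' @export
print.geo_result <- function(x, ...) {
  s <- x$summary
  cat("<geo_result> ", s$n_resolved, "/", s$n, " tweets resolved (",
      sprintf("%.2f%%", 100 * s$fraction_resolved), ")\n", sep = "")
  for (m in names(s$method_counts)) {
    cat(sprintf("  %-12s %d\n", m, s$method_counts[[m]]))
  }
  invisible(x)
}
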