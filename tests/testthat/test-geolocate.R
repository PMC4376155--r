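gaz <- load_gazetteer()

# Independent even-odd ray-casting point-in-polygon oracle (NA rows
# separate loops), used to cross-check the package's resolver.
ray_cast_inside <- function(poly, px, py) {
  loops <- split.data.frame(as.data.frame(poly),
                            cumsum(is.na(poly[, 1])))
  any(vapply(loops, function(lp) {
    lp <- lp[!is.na(lp[, 1]), , drop = FALSE]
    if (nrow(lp) < 3L) return(FALSE)
    x <- lp[, 1]; y <- lp[, 2]
    n <- length(x)
    j <- n
    inside <- FALSE
    for (i in seq_len(n)) {
      if ((y[i] > py) != (y[j] > py) &&
          px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]) {
        inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1)))
}

oracle_state <- function(lat, lon) {
  hits <- names(gaz$polygons)[vapply(gaz$polygons, ray_cast_inside,
                                     logical(1), px = lon, py = lat)]
  if (length(hits)) min(hits) else NA_character_
}

test_that("the gazetteer has 51 state units, 60 cities, and valid codes", {
  expect_equal(nrow(gaz$states), 51L)
  expect_setequal(gaz$states$code,
                  c(state.abb, "DC"))
  expect_equal(nrow(gaz$cities), 60L)
  expect_true(all(gaz$cities$state %in% gaz$states$code))
  expect_setequal(names(gaz$polygons), gaz$states$code)
})

test_that("known coordinates resolve to the expected states", {
  expect_identical(resolve_coordinates(39.95, -75.16, gaz), "PA")
  expect_true(is.na(resolve_coordinates(0, 0, gaz)))
  # every state's representative interior point resolves to itself
  got <- resolve_coordinates(gaz$states$rep_lat, gaz$states$rep_lon, gaz)
  expect_identical(got, gaz$states$code)
  expect_error(resolve_coordinates(95, 0, gaz), "out of range")
})

test_that("coordinate resolution agrees with a ray-casting oracle", {
  withr::local_seed(402)
  lon <- runif(200, -125, -66)
  lat <- runif(200, 24, 50)
  got <- resolve_coordinates(lat, lon, gaz)
  want <- mapply(oracle_state, lat, lon)
  expect_identical(unname(got), unname(want))
})

test_that("a point claimed by two polygons takes the first state code", {
  # the simplified AL rectangle and the FL rectangle overlap across the
  # Florida panhandle; both claim this point, and AL < FL
  expect_true(ray_cast_inside(gaz$polygons[["AL"]], -86.5, 30.5))
  expect_true(ray_cast_inside(gaz$polygons[["FL"]], -86.5, 30.5))
  expect_identical(resolve_coordinates(30.5, -86.5, gaz), "AL")
})

test_that("location text follows the name > abbreviation > city precedence", {
  r <- resolve_location_text(
    c("Philadelphia, PA", "new york city", "Earth ✨", "West Virginia",
      "Washington", "Washington, D.C.", "Boston", "TX", "Dallas, tx",
      "in my feelings", "me and you", ""), gaz)
  expect_identical(r$state,
                   c("PA", "NY", NA, "WV", "WA", "DC", "MA", "TX", "TX",
                     NA, NA, NA))
  expect_identical(r$method[c(1, 2, 4, 7)],
                   c("state_abbrev", "state_name", "state_name", "city"))
  expect_identical(r$method[3], "unresolved")
})

test_that("a 400-string audit of unambiguous locations is 100% accurate", {
  # mirrors a manual-audit design: unambiguous strings spanning state
  # names, abbreviations and major cities, with known true states
  states <- gaz$states
  other_state_in <- function(phrase, code) {
    nn <- paste0(" ", tolower(states$name), " ")
    pp <- paste0(" ", tolower(gsub("[^A-Za-z0-9]+", " ", phrase)), " ")
    any(vapply(nn, grepl, logical(1), x = pp, fixed = TRUE) &
          states$code != code)
  }
  strings <- character(0); truth <- character(0)
  for (i in seq_len(nrow(states))) {
    code <- states$code[i]; nm <- states$name[i]
    city <- gaz$cities$city[gaz$cities$state == code]
    city <- city[!vapply(city, other_state_in, logical(1), code = code)]
    forms <- c(nm, tolower(nm), toupper(nm), code,
               sprintf("Smalltown, %s", code),
               sprintf("Lovely %s, USA", nm),
               sprintf("somewhere, %s", tolower(code)),
               if (length(city)) c(city[1], sprintf("%s, %s", city[1], code)))
    strings <- c(strings, forms)
    truth <- c(truth, rep(code, length(forms)))
  }
  # "Washington" the string is the state name, not the city: drop the bare
  # city form whose name collides with a state name handled above
  keep <- !(strings %in% c("Washington") & truth == "DC")
  strings <- strings[keep][1:400]
  truth <- truth[keep][1:400]
  r <- resolve_location_text(strings, gaz)
  expect_identical(r$state, truth)
})

test_that("geocoding a corpus is exact, order-invariant, and prefers coordinates", {
  tw <- make_tweets(rep("x", 100))
  tw$profile_location[1:40] <- "Texas"          # resolvable
  tw$lat[41:46] <- 39.95; tw$lon[41:46] <- -75.16
  tw$profile_location[41:46] <- "Texas"         # contradicts coordinates
  tw$profile_location[47:100] <- "Earth"        # unresolvable
  res <- geocode_corpus(tw, gaz)
  expect_equal(res$summary$fraction_resolved, 0.46)
  expect_identical(res$resolutions$state[41], "PA")
  expect_identical(res$resolutions$method[41], "coordinates")
  # order invariance
  perm <- sample(nrow(tw))
  res2 <- geocode_corpus(tw[perm, ], gaz)
  expect_equal(res2$summary$fraction_resolved, res$summary$fraction_resolved)
  expect_identical(res2$resolutions$state[match(tw$id, res2$resolutions$tweet_id)],
                   res$resolutions$state)
  # no geo at all
  none <- geocode_corpus(make_tweets(c("a", "b")), gaz)
  expect_equal(none$summary$fraction_resolved, 0)
})
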