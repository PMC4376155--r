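# Archived tweet corpora: JSON-lines reading and collection filters.

#' Read an archived tweet corpus from a JSON-lines file
#'
#' One JSON object per line. The default field mapping expects `id`, `text`,
#' optional `coordinates` (a `[longitude, latitude]` pair, Twitter/GeoJSON
#' order) and optional `user.location` (free-text self-reported profile
#' location). Field names are configurable for other archive dialects.
#'
#' @param path Path to a JSON-lines file.
#' @param fields Named list mapping the canonical fields `id`, `text`,
#'   `coordinates`, `location` to field names in the file; `location` may be
#'   a character vector for nested access (default `c("user", "location")`).
#' @param skip_missing_text Records without a text field are skipped with a
#'   warning when `TRUE` (default); with `FALSE` they raise an error.
#' @return Data frame with columns `id`, `text`, `lat`, `lon`,
#'   `profile_location`, `query_tag` (all `NA` where absent), one row per
#'   record in file order.
#' @details A malformed JSON line raises an error naming the line number.
#' @export
read_tweets <- function(path,
                        fields = list(id = "id", text = "text",
                                      coordinates = "coordinates",
                                      location = c("user", "location")),
                        skip_missing_text = TRUE) {
  if (!file.exists(path)) stop("tweet file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lineno <- which(nzchar(trimws(lines)))
  lines <- lines[lineno]
  n <- length(lines)
  if (n == 0L) {
    return(empty_tweets())
  }
  # Parse the whole file as one JSON array (fast path); on failure, find
  # and report the first offending line.
  d <- tryCatch(
    jsonlite::fromJSON(paste0("[", paste(lines, collapse = ","), "]"),
                       simplifyVector = TRUE, simplifyDataFrame = TRUE,
                       simplifyMatrix = FALSE),
    error = function(e) {
      for (i in seq_len(n)) {
        bad <- tryCatch({jsonlite::fromJSON(lines[i]); FALSE},
                        error = function(e2) TRUE)
        if (bad) stop("malformed JSON at line ", lineno[i], call. = FALSE)
      }
      stop("malformed JSON-lines file: ", conditionMessage(e), call. = FALSE)
    })
  if (!is.data.frame(d)) stop("unexpected JSON-lines structure", call. = FALSE)

  get_col <- function(df, key) {
    out <- df
    for (k in key) {
      if (is.null(out)) return(NULL)
      out <- if (is.data.frame(out)) out[[k]] else NULL
    }
    out
  }

  idcol <- get_col(d, fields$id)
  id <- if (is.null(idcol)) paste0("line", lineno) else as.character(idcol)
  id[is.na(id)] <- paste0("line", lineno[is.na(id)])
  textcol <- get_col(d, fields$text)
  text <- if (is.null(textcol)) rep(NA_character_, n) else as.character(textcol)
  ok <- !is.na(text) & nzchar(text)
  if (any(!ok) && !skip_missing_text) {
    stop("record at line ", lineno[which(!ok)[1]], " has no text field",
         call. = FALSE)
  }
  lat <- rep(NA_real_, n); lon <- rep(NA_real_, n)
  coord <- get_col(d, fields$coordinates)
  if (is.list(coord)) {
    has <- lengths(coord) == 2L
    if (any(has)) {
      cm <- matrix(suppressWarnings(
        as.numeric(unlist(coord[has], use.names = FALSE))), ncol = 2L,
        byrow = TRUE)
      lon[has] <- cm[, 1]
      lat[has] <- cm[, 2]
    }
  }
  loccol <- get_col(d, fields$location)
  loc <- if (is.null(loccol)) rep(NA_character_, n) else as.character(loccol)
  loc[!is.na(loc) & !nzchar(loc)] <- NA_character_
  if (any(!ok)) {
    warning(sum(!ok), " record(s) without text skipped", call. = FALSE)
  }
  data.frame(id = id[ok], text = text[ok], lat = lat[ok], lon = lon[ok],
             profile_location = loc[ok], query_tag = NA_character_,
             stringsAsFactors = FALSE)
}

empty_tweets <- function() {
  data.frame(id = character(0), text = character(0), lat = numeric(0),
             lon = numeric(0), profile_location = character(0),
             query_tag = character(0), stringsAsFactors = FALSE)
}

#' Default ACA collection terms
#'
#' The study terms: `ACA`, `#ACA`, `Obamacare`, `#Obamacare`. The acronym
#' forms are matched case-sensitively (uppercase only) so that `ACA` never
#' fires inside ordinary words; the name forms are matched
#' case-insensitively.
#'
#' @return Data frame with columns `term`, `case_sensitive`, `tag`.
#' @export
default_terms <- function() {
  data.frame(term = c("ACA", "#ACA", "Obamacare", "#Obamacare"),
             case_sensitive = c(TRUE, TRUE, FALSE, FALSE),
             tag = c("aca", "aca", "obamacare", "obamacare"),
             stringsAsFactors = FALSE)
}

#' Marketplace Twitter handles
#'
#' The federal HealthCare.gov handle plus the 17 state-based marketplace
#' handles, shipped as an editable packaged CSV (`handle`, `state`,
#' `group`).
#'
#' @param path Optional path to a replacement CSV.
#' @return Data frame with columns `handle`, `state`, `group`
#'   (`"federal"` or `"state"`).
#' @export
marketplace_handles <- function(path = NULL) {
  if (is.null(path)) path <- acasent_file("marketplace_handles.csv")
  h <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("handle", "state", "group") %in% names(h)))
  h$handle <- ifelse(startsWith(h$handle, "@"), h$handle,
                     paste0("@", h$handle))
  h
}

#' Filter tweets by collection terms
#'
#' Retains tweets whose tokenized text contains any term as a whole token
#' (never as a substring of a longer word), under each term's casing rule.
#' Because [tokenize()] expands `#tag` to the bare `tag` as well, `ACA`
#' matches a tweet containing `#ACA`. The `query_tag` column is set from the
#' first matching term, in term-list order.
#'
#' @param tweets Tweet data frame from [read_tweets()].
#' @param terms Term table as in [default_terms()] (a plain character
#'   vector is accepted and matched case-insensitively).
#' @return The retained rows, with `query_tag` set.
#' @export
filter_terms <- function(tweets, terms = default_terms()) {
  if (is.character(terms)) {
    terms <- data.frame(term = terms, case_sensitive = FALSE, tag = terms,
                        stringsAsFactors = FALSE)
  }
  stopifnot(nrow(terms) > 0L, all(c("term", "case_sensitive", "tag") %in%
                                    names(terms)))
  if (nrow(tweets) == 0L) return(tweets)
  f <- flat_tokenize(tweets$text, lower = FALSE)
  flow <- tolower(f$tokens)
  tag <- rep(NA_character_, nrow(tweets))
  for (j in seq_len(nrow(terms))) {
    hit_ids <- if (terms$case_sensitive[j]) {
      f$id[f$tokens == terms$term[j]]
    } else {
      f$id[flow == tolower(terms$term[j])]
    }
    hit_ids <- unique(hit_ids)
    hit_ids <- hit_ids[is.na(tag[hit_ids])]
    tag[hit_ids] <- terms$tag[j]
  }
  out <- tweets[!is.na(tag), , drop = FALSE]
  out$query_tag <- tag[!is.na(tag)]
  rownames(out) <- NULL
  out
}

#' Filter tweets mentioning marketplace handles
#'
#' Retains tweets whose token set contains any listed `@handle`
#' (case-insensitive), tagging them `handle_federal` or `handle_state`
#' according to the handle table's `group` column.
#'
#' @param tweets Tweet data frame.
#' @param handles Handle table as in [marketplace_handles()].
#' @return The retained rows, with `query_tag` set.
#' @export
filter_mentions <- function(tweets, handles = marketplace_handles()) {
  stopifnot(all(c("handle", "group") %in% names(handles)),
            all(startsWith(handles$handle, "@")))
  if (nrow(tweets) == 0L) return(tweets)
  f <- flat_tokenize(tweets$text, lower = TRUE)
  hl <- tolower(handles$handle)
  tag <- rep(NA_character_, nrow(tweets))
  for (j in seq_along(hl)) {
    hit_ids <- unique(f$id[f$tokens == hl[j]])
    hit_ids <- hit_ids[is.na(tag[hit_ids])]
    tag[hit_ids] <- paste0("handle_", handles$group[j])
  }
  out <- tweets[!is.na(tag), , drop = FALSE]
  out$query_tag <- tag[!is.na(tag)]
  rownames(out) <- NULL
  out
}

#' Drop duplicate tweets by id
#'
#' Overlapping term and handle queries can return the same tweet more than
#' once; the first occurrence is kept.
#'
#' @param tweets Tweet data frame.
#' @return De-duplicated data frame.
#' @export
dedupe_tweets <- function(tweets) {
  out <- tweets[!duplicated(tweets$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
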