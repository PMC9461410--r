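# Time handling: all timestamps are local wall-clock instants. They are
# stored as POSIXct in the "UTC" zone so that arithmetic is pure clock
# arithmetic with no DST transitions (a DST change inside an analysis
# window is a documented limitation, not something we model).

.VW_TZ <- "UTC"

#' Parse ISO-8601 local timestamps
#'
#' Accepts `"YYYY-MM-DDTHH:MM:SS"` or `"YYYY-MM-DD HH:MM:SS"` strings and
#' returns POSIXct in a fixed zone so that all arithmetic is plain
#' wall-clock arithmetic.
#'
#' @param x character vector of timestamps.
#' @return POSIXct vector.
#' @export
parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- .VW_TZ
    return(x)
  }
  x <- gsub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(x, tz = .VW_TZ, format = "%Y-%m-%d %H:%M:%S")
  # date-only fallback
  bad <- is.na(out) & !is.na(x) & nzchar(x)
  if (any(bad)) {
    out[bad] <- as.POSIXct(x[bad], tz = .VW_TZ, format = "%Y-%m-%d")
  }
  if (anyNA(out[!is.na(x) & nzchar(x)])) {
    stop("unparseable timestamp(s): ",
         paste(utils::head(x[is.na(out)], 3L), collapse = ", "))
  }
  out
}

#' Format timestamps back to ISO-8601
#' @param x POSIXct vector.
#' @return character vector `"YYYY-MM-DDTHH:MM:SS"`.
#' @export
format_timestamp <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S", tz = .VW_TZ)
}

# floor to the containing wall-clock hour
floor_hour <- function(x) {
  as.POSIXct(floor(as.numeric(x) / 3600) * 3600,
             origin = "1970-01-01", tz = .VW_TZ)
}

# local calendar date
local_date <- function(x) as.Date(x, tz = .VW_TZ)

# integer hour offset of timestamp(s) relative to an hour-aligned origin
hour_offset <- function(x, origin) {
  as.integer(floor((as.numeric(x) - as.numeric(origin)) / 3600))
}

# deterministic per-participant seed stream: participant k always gets the
# same substream for a given master seed, regardless of cohort size
participant_seed <- function(master_seed, k, salt = 0L) {
  s <- (as.numeric(master_seed) * 48271 + as.numeric(k) * 16807 +
          as.numeric(salt) * 69621) %% 2147483647
  as.integer(s)
}

# evaluate `expr` under a local RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
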