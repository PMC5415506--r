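## Specimen metadata: reading, validation, curation, repeatability.

.REQUIRED_COLUMNS <- c("specimen_id", "species", "year", "latitude",
                       "longitude", "sex", "month")

#' Derive collection season from month
#'
#' Seasons are two-month bins reflecting time since molt: months 1-2 map
#' to season 1, ..., months 11-12 to season 6.
#'
#' @param month integer vector in 1..12 (NA allowed: flagged, not guessed).
#' @return integer vector of seasons in 1..6 (NA where month is NA).
#' @export
#' @examples
#' seasonFromMonth(c(1, 6, 12))
seasonFromMonth <- function(month) {
  bad <- !is.na(month) & (month < 1 | month > 12 | month != round(month))
  if (any(bad))
    stop("month values must be integers in 1..12; offending: ",
         paste(unique(month[bad]), collapse = ", "))
  as.integer(ceiling(month / 2))
}

#' Derive decade of collection from year
#'
#' @param year integer vector of collection years.
#' @return integer calendar decade, \code{floor(year/10)*10}.
#' @export
decadeFromYear <- function(year) as.integer(floor(year / 10) * 10)

.detectSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a specimen metadata table
#'
#' Reads a delimited text table (comma- or tab-separated, auto-detected
#' from the header line), one row per museum specimen, checks the required
#' columns, types the fields, and derives \code{season} and \code{decade}.
#' Unknown columns are preserved. Exclusion status flags (\code{juvenile},
#' \code{molting}, \code{damaged}, \code{unsexed}) are coerced to logical;
#' missing flags are treated as \code{FALSE}.
#'
#' @param path path to the table. Required columns: \code{specimen_id},
#'   \code{species}, \code{year}, \code{latitude}, \code{longitude},
#'   \code{sex}, \code{month}. Typical optional columns: \code{subspecies},
#'   \code{altitude}, \code{wing_length}, \code{wing1}, \code{wing2}, the
#'   four status flags.
#' @return a \code{data.frame} of specimen records with derived
#'   \code{season} and \code{decade} columns. Rows whose \code{year} or
#'   coordinates fail to parse are dropped with a warning naming them.
#' @export
readSpecimenTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- .detectSep(path)
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = c("NA", ""))
  missing <- setdiff(.REQUIRED_COLUMNS, names(df))
  if (length(missing))
    stop("specimen table is missing required column(s): ",
         paste(missing, collapse = ", "))

  numify <- function(x) suppressWarnings(as.numeric(x))
  df$year <- numify(df$year)
  df$latitude <- numify(df$latitude)
  df$longitude <- numify(df$longitude)
  df$month <- numify(df$month)

  bad <- !is.finite(df$year) | !is.finite(df$latitude) | !is.finite(df$longitude) |
    df$year < 1900 | df$year > 2008
  if (any(bad)) {
    warning(sum(bad), " record(s) dropped (unparseable or out-of-range year/",
            "coordinates): ", paste(head(df$specimen_id[bad], 10), collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }

  for (flag in c("juvenile", "molting", "damaged", "unsexed")) {
    if (is.null(df[[flag]])) df[[flag]] <- FALSE
    df[[flag]] <- !is.na(df[[flag]]) & as.logical(df[[flag]])
  }
  if (!is.null(df$wing_length)) df$wing_length <- numify(df$wing_length)
  if (!is.null(df$altitude)) df$altitude <- numify(df$altitude)
  if (is.null(df$subspecies)) df$subspecies <- "nominate"

  df$season <- seasonFromMonth(df$month)
  df$decade <- decadeFromYear(df$year)

  ## missing altitude: keep the record, impute the species median
  if (any(!is.finite(df$altitude))) {
    n_imp <- sum(!is.finite(df$altitude))
    med <- tapply(df$altitude, df$species, median, na.rm = TRUE)
    idx <- !is.finite(df$altitude)
    df$altitude[idx] <- med[df$species[idx]]
    warning(n_imp, " record(s) had missing altitude; imputed species median")
  }
  if (!is.null(df$wing_length) && any(df$wing_length <= 0, na.rm = TRUE))
    stop("wing_length must be positive where present")
  rownames(df) <- NULL
  df
}

#' Exclude specimens unsuitable for measurement
#'
#' Drops juveniles, birds in molt, highly damaged specimens, and unsexed
#' individuals, mirroring standard museum-measurement practice. Missing
#' flags count as \code{FALSE}.
#'
#' @param records data.frame from [readSpecimenTable()].
#' @param quiet suppress the per-reason removal message.
#' @return the retained records.
#' @export
filterSpecimens <- function(records, quiet = FALSE) {
  flags <- c("juvenile", "molting", "damaged", "unsexed")
  for (flag in flags) {
    if (is.null(records[[flag]])) records[[flag]] <- FALSE
    records[[flag]] <- !is.na(records[[flag]]) & as.logical(records[[flag]])
  }
  removed <- vapply(flags, function(f) sum(records[[f]]), integer(1))
  keep <- !Reduce(`|`, records[flags])
  if (!quiet && any(removed > 0))
    message("filterSpecimens: removed ",
            paste(sprintf("%d %s", removed[removed > 0],
                          flags[removed > 0]), collapse = ", "))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Measurement repeatability (one-way ANOVA intraclass correlation)
#'
#' Lessells-Boag repeatability of duplicated measurements: from a one-way
#' ANOVA over specimens, \eqn{r = (MS_A - MS_W)/(MS_A + (n_0 - 1) MS_W)}
#' with \eqn{n_0 = 2} measurements per specimen.
#'
#' @param pairs data.frame with columns \code{specimen_id}, \code{first},
#'   \code{second} (the two measurements, mm).
#' @return the repeatability, a ratio in \eqn{[-1, 1]}.
#' @export
#' @examples
#' pr <- data.frame(specimen_id = letters[1:3],
#'                  first = c(10, 20, 30), second = c(12, 22, 28))
#' repeatability(pr)
repeatability <- function(pairs) {
  need <- c("specimen_id", "first", "second")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns specimen_id, first, second")
  if (nrow(pairs) < 2L) stop("repeatability needs at least 2 specimens")
  if (any(pairs$first <= 0 | pairs$second <= 0))
    stop("measurements must be positive")
  long <- data.frame(
    id = factor(rep(pairs$specimen_id, 2L)),
    value = c(pairs$first, pairs$second)
  )
  fit <- aov(value ~ id, data = long)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  ms_a <- ms[1]; ms_w <- ms[2]
  n0 <- 2
  (ms_a - ms_w) / (ms_a + (n0 - 1) * ms_w)
}
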