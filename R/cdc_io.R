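#' Age-binned annual mortality table
#'
#' Year-by-age-group death counts in the 22-group schema of the CDC WONDER
#' multiple-cause-of-death exports, with a mask for suppressed (censored)
#' cells.
#'
#' @param years contiguous calendar years.
#' @param deaths matrix of counts, \code{length(years)} x 22 (NA allowed in
#'   suppressed cells).
#' @param suppressed logical matrix of the same shape (default: where
#'   \code{deaths} is NA).
#' @param schema an \code{\link{age_bin_schema}}.
#' @return an object of class \code{mortality_table}.
#' @export
mortality_table <- function(years, deaths, suppressed = NULL,
                            schema = cdc_age_bins()) {
  years <- as.integer(years)
  deaths <- as.matrix(deaths)
  if (nrow(deaths) != length(years) || ncol(deaths) != 22)
    stop("mortality_table: deaths must be length(years) x 22")
  if (is.null(suppressed)) suppressed <- is.na(deaths)
  if (any(deaths[!suppressed] < 0, na.rm = TRUE))
    stop("mortality_table: unsuppressed death counts must be >= 0")
  dimnames(deaths) <- list(years, schema$labels)
  structure(list(years = years, deaths = deaths,
                 suppressed = suppressed, schema = schema),
            class = "mortality_table")
}

#' @export
print.mortality_table <- function(x, ...) {
  cat(sprintf("mortality_table: years %d-%d, 22 age groups, %d suppressed cells\n",
              min(x$years), max(x$years), sum(x$suppressed)))
  invisible(x)
}

# Canonicalize an age-group label to its lower bin edge, or NA.
# Accepts WONDER-style ("< 1 year", "1-4 years", "100+ years") and bare
# ("0", "1-4", "100+") dialects; matching is by parsed edges, not strings.
.parse_age_label <- function(label) {
  s <- tolower(trimws(gsub("–", "-", label)))
  s <- sub("\\s*years?$", "", s)
  if (s %in% c("< 1", "<1", "0")) return(0)
  if (grepl("^\\d+\\s*\\+$", s)) return(as.numeric(sub("\\+.*$", "", s)))
  m <- regmatches(s, regexec("^(\\d+)\\s*-\\s*(\\d+)$", s))[[1]]
  if (length(m) == 3) return(as.numeric(m[2]))
  NA_real_
}

#' Read a CDC WONDER style mortality export
#'
#' Parses a tab-delimited text file with (at least) year, age-group label
#' and death-count columns into a \code{\link{mortality_table}}. Cells whose
#' count is the word \code{Suppressed} (or empty) are masked. Row order is
#' irrelevant; age-group labels are canonicalized by their parsed bin edges,
#' so both "1-4 years" and "1-4" dialects are accepted.
#'
#' @param path file path.
#' @param schema an \code{\link{age_bin_schema}}.
#' @param year_col,age_col,deaths_col column names (case-insensitive prefix
#'   match against the header).
#' @return a \code{\link{mortality_table}}.
#' @export
read_wonder <- function(path, schema = cdc_age_bins(),
                        year_col = "Year", age_col = "Age Group",
                        deaths_col = "Deaths") {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", strip.white = TRUE)
  pick <- function(wanted) {
    hit <- which(tolower(names(raw)) == tolower(wanted))
    if (!length(hit))
      hit <- grep(paste0("^", tolower(wanted)), tolower(names(raw)))
    if (length(hit) != 1)
      stop(sprintf("read_wonder: cannot identify column '%s' in %s",
                   wanted, paste(names(raw), collapse = ", ")))
    hit
  }
  yr <- suppressWarnings(as.integer(raw[[pick(year_col)]]))
  lab <- raw[[pick(age_col)]]
  cnt <- raw[[pick(deaths_col)]]
  if (any(is.na(yr)))
    stop(sprintf("read_wonder: non-integer year at line %d",
                 which(is.na(yr))[1] + 1L))
  lower <- vapply(lab, .parse_age_label, numeric(1), USE.NAMES = FALSE)
  if (any(is.na(lower)))
    stop(sprintf("read_wonder: unknown age-group label '%s'; accepted labels look like: %s",
                 lab[which(is.na(lower))[1]],
                 paste(schema$labels, collapse = "; ")))
  bin <- match(lower, schema$edges[-23])
  if (any(is.na(bin)))
    stop(sprintf("read_wonder: age-group label '%s' does not start at a schema bin edge",
                 lab[which(is.na(bin))[1]]))
  sup <- tolower(cnt) %in% c("suppressed", "") | is.na(cnt)
  val <- suppressWarnings(as.numeric(cnt))
  bad <- !sup & (is.na(val) | val %% 1 != 0)
  if (any(bad))
    stop(sprintf("read_wonder: non-integer death count '%s' at line %d",
                 cnt[which(bad)[1]], which(bad)[1] + 1L))
  years <- sort(unique(yr))
  deaths <- matrix(NA_real_, length(years), 22)
  supm <- matrix(FALSE, length(years), 22)
  ri <- match(yr, years)
  for (k in seq_along(yr)) {
    if (!is.na(deaths[ri[k], bin[k]]) || supm[ri[k], bin[k]])
      stop(sprintf("read_wonder: duplicate cell for year %d, bin %d", yr[k], bin[k]))
    if (sup[k]) supm[ri[k], bin[k]] <- TRUE else deaths[ri[k], bin[k]] <- val[k]
  }
  missing_cells <- is.na(deaths) & !supm
  if (any(missing_cells))
    stop(sprintf("read_wonder: missing cell for year %d, age group '%s'",
                 years[which(missing_cells, arr.ind = TRUE)[1, 1]],
                 schema$labels[which(missing_cells, arr.ind = TRUE)[1, 2]]))
  mortality_table(years, deaths, supm, schema)
}

#' Write a mortality table as a WONDER style tab-delimited file
#'
#' The same dialect \code{\link{read_wonder}} parses: columns Year,
#' Age Group, Deaths; suppressed cells written as \code{Suppressed}.
#'
#' @param table a \code{\link{mortality_table}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_wonder <- function(table, path) {
  stopifnot(inherits(table, "mortality_table"))
  rows <- expand.grid(bin = 1:22, year = table$years)
  cnt <- mapply(function(b, y) {
    i <- match(y, table$years)
    if (table$suppressed[i, b]) "Suppressed"
    else format(table$deaths[i, b], scientific = FALSE, trim = TRUE)
  }, rows$bin, rows$year)
  df <- data.frame(
    "Year" = rows$year,
    "Age Group" = table$schema$labels[rows$bin],
    "Deaths" = cnt, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cumulative per-bin death counts
#'
#' Running sums of the annual counts from the first year; this is the
#' quantity the assimilation compares with the model's cumulative-death
#' block. Suppressed cells contribute 0 (with a warning).
#'
#' @param table a \code{\link{mortality_table}} over contiguous years.
#' @return matrix \code{length(years)} x 22 of cumulative counts, row
#'   \code{i} covering the years up to and including \code{years[i]}.
#' @export
to_cumulative <- function(table) {
  stopifnot(inherits(table, "mortality_table"))
  if (length(table$years) > 1 && any(diff(table$years) != 1))
    stop("to_cumulative: years must be contiguous")
  deaths <- table$deaths
  if (any(table$suppressed)) {
    warning(sprintf("to_cumulative: treating %d suppressed cells as 0",
                    sum(table$suppressed)))
    deaths[table$suppressed] <- 0
  }
  out <- apply(deaths, 2, cumsum)
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  dimnames(out) <- dimnames(table$deaths)
  out
}
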