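#' Write a daily weather series as CSV
#'
#' Header `date,rain,maxt,mint,radn` (ISO dates, mm, degC, MJ m-2),
#' preceded by `#` comment lines carrying provenance (site, seed).
#' @param x a daily weather table.
#' @param path output file.
#' @param comments extra comment lines (without the leading `#`).
#' @return `path` invisibly.
#' @export
write_weather_csv <- function(x, path, comments = NULL) {
  meta <- c(paste("site:", attr(x, "site_id") %||% "?"),
            paste("seed:", attr(x, "seed") %||% "?"),
            comments)
  write_table_csv(as.data.table(x)[, .(date, rain, maxt, mint, radn)],
                  path, comments = meta)
}

#' Read a daily weather CSV
#' @param path file with header `date,rain,maxt,mint,radn`; `#` comment
#'   lines are ignored.
#' @param site_id site label to attach.
#' @return a validated `daily_weather` table.
#' @export
read_weather_csv <- function(path, site_id = NULL) {
  out <- read_table_csv(path)
  .assert(all(c("date", "rain", "maxt", "mint", "radn") %in% names(out)),
          "weather CSV must have date,rain,maxt,mint,radn columns",
          "cropval_input_error")
  out[, date := as.Date(date)]
  setattr(out, "class", c("daily_weather", class(data.table())))
  setattr(out, "site_id", site_id %||% "file")
  validate_daily_weather(out)
  out[]
}

#' Read a whitespace-delimited met-style weather file
#'
#' Columns `year day radn maxt mint rain` (day = day of year). Comment
#' lines starting with `!` or `#` and a units line are skipped.
#' @param path met file path.
#' @param site_id site label.
#' @return a validated `daily_weather` table.
#' @export
read_met_file <- function(path, site_id = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*[!#]", lines) & nzchar(trimws(lines))]
  hdr_i <- grep("^\\s*year\\s+day", lines, ignore.case = TRUE)[1]
  .assert(!is.na(hdr_i), "met file must have a 'year day ...' header",
          "cropval_input_error")
  hdr <- tolower(strsplit(trimws(lines[hdr_i]), "\\s+")[[1]])
  body <- lines[-seq_len(hdr_i)]
  body <- body[grepl("^\\s*[0-9]", body)]   # drop units line
  dt <- fread(text = body, header = FALSE)
  setnames(dt, hdr[seq_len(ncol(dt))])
  .assert(all(c("year", "day", "radn", "maxt", "mint", "rain") %in%
                names(dt)),
          "met file needs year day radn maxt mint rain columns",
          "cropval_input_error")
  out <- dt[, .(date = as.Date(day - 1L,
                               origin = as.Date(paste0(year, "-01-01"))),
                rain, maxt, mint, radn)]
  setattr(out, "class", c("daily_weather", class(data.table())))
  setattr(out, "site_id", site_id %||% basename(path))
  validate_daily_weather(out)
  out[]
}

#' Write a table as CSV with `#` comment header lines
#' @param dt a data.frame/data.table.
#' @param path output file.
#' @param comments character lines written as `# <line>` before the header.
#' @return `path` invisibly.
#' @export
write_table_csv <- function(dt, path, comments = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con)
  writeLines(paste(names(dt), collapse = ","), con)
  if (nrow(dt)) {
    body <- do.call(paste, c(lapply(dt, function(col) {
      if (is.numeric(col)) format(col, trim = TRUE, digits = 15,
                                   scientific = FALSE)
      else as.character(col)
    }), sep = ","))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a CSV written by [write_table_csv()] (`#` comments ignored)
#' @param path file path.
#' @return a data.table.
#' @export
read_table_csv <- function(path) {
  .assert(file.exists(path), paste("missing file:", path),
          "cropval_dependency_error")
  lines <- readLines(path)
  fread(text = lines[!startsWith(lines, "#")])
}

# data rows of a csv artifact (excluding comments and header)
.csv_rows <- function(path) {
  lines <- readLines(path)
  sum(!startsWith(lines, "#")) - 1L
}

#' Write one ensemble forecast to a member-trace CSV
#' @param ens an `ensemble_forecast`.
#' @param path output file (`member,date,rain,maxt,mint,radn`).
#' @param comments extra comment lines.
#' @return `path` invisibly.
#' @export
write_ensemble_csv <- function(ens, path, comments = NULL) {
  meta <- c(paste("site:", ens$site_id),
            paste("issue_date:", format(ens$issue_date)),
            paste("skill_rho:", ens$skill_rho),
            paste("seed:", ens$seed), comments)
  write_table_csv(ens$members, path, comments = meta)
}
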