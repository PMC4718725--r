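# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  # accept "YYYY-MM-DD" or "YYYY-MM-DD HH:MM[:SS]" (or ISO-8601 with T)
  x <- gsub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  out
}

fmt_utc <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

stop_ce <- function(...) stop(..., call. = FALSE)

check_cols <- function(df, cols, what = "metadata") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_ce(what, " is missing required column(s): ",
            paste(miss, collapse = ", "))
  invisible(df)
}

# AR(1) noise with stationary sd `sd`
ar1_noise <- function(n, sd, phi = 0.97) {
  if (sd <= 0 || n == 0) return(numeric(n))
  e <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive", init = rnorm(1, 0, sd)))
}

# hours-of-day as decimal from POSIXct
hour_of_day <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

# parse "HH:MM" to decimal hours
parse_hm <- function(x) {
  p <- strsplit(x, ":", fixed = TRUE)[[1]]
  as.numeric(p[1]) + as.numeric(p[2]) / 60
}
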