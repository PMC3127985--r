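# Internal helpers: dates, intervals, seeded RNG scope.

`%||%` <- function(x, y) if (is.null(x)) y else x

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_interval <- function(x, field) {
  x <- as_date(x)
  if (length(x) != 2L || anyNA(x) || x[1] > x[2])
    stop_config(field, "must be two ordered dates (start <= end)")
  x
}

check_proportion <- function(x, field) {
  if (!is_scalar_number(x) || x < 0 || x > 1)
    stop_config(field, "must be a proportion in [0, 1]")
  x
}

## Evaluate `expr` under a fixed RNG state without disturbing the caller's
## stream; every generator entry point routes its randomness through this.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Fiscal-year defaults (April 1 to March 31).
fy_study_window    <- function() as.Date(c("1996-04-01", "2002-03-31"))
fy_comorbidity     <- function() as.Date(c("2001-04-01", "2002-03-31"))
fy_outcome         <- function() as.Date(c("2002-04-01", "2003-03-31"))

## Age in completed years at `at`.
age_at <- function(birth_date, at) {
  b <- as.POSIXlt(birth_date); a <- as.POSIXlt(at)
  age <- a$year - b$year
  before_birthday <- (a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday)
  age - as.integer(before_birthday)
}

## Inverse logit.
plogis_ <- function(x) 1 / (1 + exp(-x))

## Session cache for the small bundled tables (static across a session).
.table_cache <- new.env(parent = emptyenv())

cached_table <- function(key, expr) {
  if (!exists(key, envir = .table_cache, inherits = FALSE))
    assign(key, force(expr), envir = .table_cache)
  val <- get(key, envir = .table_cache, inherits = FALSE)
  if (data.table::is.data.table(val)) data.table::copy(val) else val
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "comorbibench")
  if (!nzchar(p)) stop("bundled data file not found: ", file, call. = FALSE)
  p
}
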