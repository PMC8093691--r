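#' Round half away from zero
#'
#' Base [round()] rounds half to even; printed tables in the movement-ecology
#' literature are almost invariably rounded half-up, so golden-value
#' comparisons use this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.0455, 3) # 0.046, where round() gives 0.045
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("roostnet_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("roostnet_data_error", "error")))
}

# "HH:MM" or "HH:MM:SS" -> seconds since local midnight
parse_tod <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  if (any(is.na(parts)) || length(parts) < 2 || length(parts) > 3) {
    stop_config("cannot parse time of day: ", x)
  }
  if (length(parts) == 2) parts <- c(parts, 0)
  parts[1] * 3600 + parts[2] * 60 + parts[3]
}

seconds_of_day <- function(timestamp) {
  lt <- as.POSIXlt(timestamp)
  lt$hour * 3600 + lt$min * 60 + lt$sec
}

# Stable md5 of an arbitrary config-like list, for provenance headers.
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
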