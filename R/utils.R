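# Internal validation helpers. Error classes are stable and documented so
# callers can condition on them (`stressorscape_<kind>_error`).

stop_domain <- function(msg, ...) {
  abort(msg, class = "stressorscape_domain_error", ...)
}

stop_frame <- function(msg, ...) {
  abort(msg, class = "stressorscape_frame_error", ...)
}

stop_schema <- function(msg, ...) {
  abort(msg, class = "stressorscape_schema_error", ...)
}

stop_key <- function(msg, ...) {
  abort(msg, class = "stressorscape_key_error", ...)
}

stop_config <- function(msg, ...) {
  abort(msg, class = "stressorscape_config_error", ...)
}

check_panel <- function(panel, arg = "panel") {
  need <- c("area_id", "date", "variable", "value")
  if (!is.data.frame(panel) || !all(need %in% names(panel))) {
    stop_schema(sprintf(
      "`%s` must be a data frame with columns %s.",
      arg, paste(sprintf("`%s`", need), collapse = ", ")
    ))
  }
  invisible(panel)
}

check_area_set <- function(areas, arg = "areas") {
  need <- c("id", "area_km2", "population", "geometry")
  if (!is.data.frame(areas) || !all(need %in% names(areas))) {
    stop_schema(sprintf(
      "`%s` must be an area set with columns %s.",
      arg, paste(sprintf("`%s`", need), collapse = ", ")
    ))
  }
  if (anyDuplicated(areas$id)) {
    stop_schema(sprintf("`%s` has duplicated area ids.", arg))
  }
  invisible(areas)
}

# Day-of-year on a 365.25-day cycle, used to key all seasonal terms.
day_of_year <- function(dates) {
  as.POSIXlt(dates)$yday + 1
}

# Shoelace area of a closed planar ring given as an n x 2 matrix.
ring_area <- function(ring) {
  x <- ring[, 1]
  y <- ring[, 2]
  n <- length(x)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

# Derive a bounded child seed from a base seed and a stage offset; keeps
# every seed inside the 32-bit integer range R requires.
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}
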