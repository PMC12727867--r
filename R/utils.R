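# Internal helpers shared across modules.

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# great-circle distance in km on the authalic sphere, vectorized over rows
haversine_km <- function(lon1, lat1, lon2, lat2, radius_km = EARTH_RADIUS_KM) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

# derive a reproducible child seed from a master seed and a stage label;
# kept below 2^31 so it is always a valid R integer
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

stop_tropirep <- function(msg, class) {
  rlang::abort(msg, class = c(class, "tropirep_error"))
}
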