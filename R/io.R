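#' Read and write population responses
#'
#' Datasets are stored as a long-format CSV with columns
#' `neuron, condition, time_ms, rate` plus a JSON sidecar (same path with the
#' extension replaced by `.json`) holding the event times, neuron labels and
#' the preprocessing flags. The round trip is lossless: rates are written with
#' full double precision.
#'
#' @param resp a [population_response()].
#' @param path CSV file path; the sidecar path is derived from it.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a [population_response()].
#' @export
write_dataset <- function(resp, path) {
  stopifnot(inherits(resp, "population_response"))
  d <- dim(resp$rates)
  df <- data.frame(
    neuron = rep(seq_len(d[1]), times = d[2] * d[3]),
    condition = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    time_ms = rep(resp$time_ms, each = d[1] * d[2]),
    rate = as.vector(resp$rates))
  # full precision so the round trip is bit-identical
  df$rate <- sprintf("%.17g", df$rate)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(events = resp$events, neuron_ids = resp$neuron_ids,
               normalized = resp$normalized, centered = resp$centered)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]*$", ".json", path)

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("neuron", "condition", "time_ms", "rate")
  missing_col <- setdiff(needed, names(df))
  if (length(missing_col))
    stop("dataset schema violation; missing column(s): ",
         paste(missing_col, collapse = ", "))
  meta_path <- sidecar_path(path)
  if (!file.exists(meta_path))
    stop("missing metadata sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("events", "neuron_ids", "normalized", "centered"))
    if (is.null(meta[[f]])) stop("metadata schema violation; missing field: ", f)
  neurons <- sort(unique(df$neuron))
  conds <- sort(unique(df$condition))
  times <- sort(unique(df$time_ms))
  if (nrow(df) != length(neurons) * length(conds) * length(times))
    stop("dataset is not a complete neuron x condition x time grid")
  rates <- array(NA_real_, c(length(neurons), length(conds), length(times)))
  rates[cbind(match(df$neuron, neurons), match(df$condition, conds),
              match(df$time_ms, times))] <- df$rate
  population_response(rates, times, as.list(meta$events),
                      neuron_ids = meta$neuron_ids,
                      normalized = isTRUE(meta$normalized),
                      centered = isTRUE(meta$centered),
                      allow_negative = TRUE)
}
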