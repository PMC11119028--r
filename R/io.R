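#' Bin raw spike times into a binary train
#'
#' Aggregates a list of spike times into half-open time bins
#' `[m * bin_size, (m + 1) * bin_size)`: a bin's symbol is 1 iff at least
#' one spike falls in it (binarisation, not counting). The train has
#' `ceiling(horizon / bin_size)` bins.
#'
#' @param times Strictly increasing spike times in `[0, horizon)`, in the
#'   same unit as `bin_size` (typically milliseconds). May be empty.
#' @param bin_size Bin duration (> 0); 10 ms is a typical choice.
#' @param horizon Total recording duration.
#' @return An integer 0/1 vector.
#' @examples
#' bin_spike_times(c(5, 12, 40), bin_size = 10, horizon = 50)  # 1 1 0 0 1
#' @export
bin_spike_times <- function(times, bin_size, horizon) {
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0) {
    stop("`bin_size` must be a positive duration", call. = FALSE)
  }
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0) {
    stop("`horizon` must be a positive duration", call. = FALSE)
  }
  times <- as.numeric(times)
  if (anyNA(times)) stop("`times` must not contain NA", call. = FALSE)
  if (length(times)) {
    if (is.unsorted(times, strictly = TRUE)) {
      stop("`times` must be strictly increasing", call. = FALSE)
    }
    if (times[1] < 0 || times[length(times)] >= horizon) {
      stop("all spike times must lie in [0, horizon)", call. = FALSE)
    }
  }
  n_bins <- ceiling(horizon / bin_size)
  out <- integer(n_bins)
  out[unique(floor(times / bin_size)) + 1L] <- 1L
  out
}

#' Read and write spike trains
#'
#' Two plain-text formats are supported: `"lines"` (one neuron per line,
#' whitespace-separated 0/1 tokens) and `"csv"` (one neuron per column with
#' a header, e.g. `x,y`). `"auto"` sniffs the format from the first line.
#' Writing then reading reproduces the symbols exactly; malformed tokens
#' are rejected with the offending line and column.
#'
#' @param path File path.
#' @param format `"auto"`, `"lines"` or `"csv"`.
#' @return `read_spike_trains()`: a tibble with one integer 0/1 column per
#'   neuron (CSV header names, else `x`/`y` for a pair, `neuron1`, ... for
#'   more).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' trains <- simulate_network(two_neuron_network(w_xy = 10), n = 100, seed = 1)
#' write_spike_trains(trains, f)
#' identical(as.data.frame(read_spike_trains(f)), as.data.frame(trains))
#' @export
read_spike_trains <- function(path, format = c("auto", "lines", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl(",", first)) "csv" else "lines"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    for (j in seq_along(df)) {
      v <- df[[j]]
      bad <- which(is.na(v) | !(v %in% c(0, 1)))
      if (length(bad)) {
        stop(sprintf("non-binary token at data row %d, column '%s' of %s",
                     bad[1], names(df)[j], path), call. = FALSE)
      }
      df[[j]] <- as.integer(v)
    }
    return(tibble::as_tibble(df))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no spike trains in ", path, call. = FALSE)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  lens <- lengths(toks)
  if (length(unique(lens)) != 1L) {
    stop(sprintf("ragged rows in %s: line 1 has %d tokens, line %d has %d",
                 path, lens[1], which(lens != lens[1])[1],
                 lens[which(lens != lens[1])[1]]), call. = FALSE)
  }
  mat <- vapply(seq_along(toks), function(i) {
    v <- toks[[i]]
    bad <- which(!v %in% c("0", "1"))
    if (length(bad)) {
      stop(sprintf("non-binary token '%s' at line %d, position %d of %s",
                   v[bad[1]], i, bad[1], path), call. = FALSE)
    }
    as.integer(v)
  }, integer(lens[1]))
  nms <- if (ncol(mat) == 2L) c("x", "y") else paste0("neuron", seq_len(ncol(mat)))
  colnames(mat) <- nms
  tibble::as_tibble(mat)
}

#' @rdname read_spike_trains
#' @param data Data frame of 0/1 columns, one per neuron.
#' @return `write_spike_trains()`: `path`, invisibly.
#' @export
write_spike_trains <- function(data, path, format = c("auto", "lines", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "lines"
  }
  data <- as.data.frame(data)
  for (j in seq_along(data)) {
    data[[j]] <- check_binary(data[[j]], sprintf("column '%s'", names(data)[j]))
  }
  if (format == "csv") {
    utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  } else {
    writeLines(vapply(data, paste, character(1), collapse = " "), path)
  }
  invisible(path)
}
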