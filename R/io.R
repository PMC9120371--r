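#' Write a simulation to disk
#'
#' `"csv"` writes the columnar time/rate table; `"rds"` writes a compressed
#' binary container holding the data together with its metadata (parameters,
#' grid, seed, dt).
#'
#' @param sim a `tc_sim` data frame
#' @param path output file
#' @param format `"csv"` or `"rds"`
#' @return `path`, invisibly
#' @export
write_trajectory <- function(sim, path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(as.data.frame(sim), path, row.names = FALSE)
  } else {
    saveRDS(list(data = as.data.frame(sim), params = attr(sim, "params"),
                 grid = attr(sim, "grid"), fs = attr(sim, "fs")), path)
  }
  invisible(path)
}

#' Read a simulation written by [write_trajectory()]
#'
#' @param path file path; format inferred from the extension
#' @return a `tc_sim` data frame (CSV round-trips lose parameter metadata)
#' @export
read_trajectory <- function(path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    obj <- readRDS(path)
    df <- obj$data
    attr(df, "grid") <- obj$grid
    attr(df, "params") <- obj$params
    attr(df, "fs") <- obj$fs
  } else {
    df <- read.csv(path)
    attr(df, "fs") <- 1 / median(diff(df$time))
  }
  class(df) <- c("tc_sim", "data.frame")
  df
}

#' Write detected events as a tab-delimited table
#'
#' @param events a [detect_spindles()] result (or any event data frame)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_events <- function(events, path) {
  write.table(as.data.frame(events), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
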