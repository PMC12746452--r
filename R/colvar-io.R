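#' Write a COLVAR-dialect whitespace table
#'
#' Plain-text column format with a leading \code{#! FIELDS} header line and
#' a leading time column, the interchange dialect of biasing engines.
#'
#' @param data data.frame or matrix; first column should be time.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeColvar <- function(data, file) {
  m <- as.matrix(data)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(colnames(m), collapse = " ")), con)
  write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a COLVAR-dialect table
#'
#' @param file path to a file written by \code{\link{writeColvar}} (or any
#'   \code{#! FIELDS}-headed whitespace table).
#' @return data.frame with the header's column names.
#' @export
readColvar <- function(file) {
  first <- readLines(file, n = 1L)
  if (!startsWith(first, "#!")) stop("missing '#! FIELDS' header line")
  fields <- strsplit(trimws(sub("^#!\\s*FIELDS", "", first)), "[[:space:]]+")[[1]]
  df <- read.table(file, comment.char = "#")
  names(df) <- fields
  df
}

#' Write a descriptor series as COLVAR text
#'
#' Columns: time, d1..d6, optionally rg and the class label.
#'
#' @param series \code{DescriptorSeries}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeDescriptorSeries <- function(series, file) {
  n <- nrow(series@values)
  tm <- if (length(series@time)) series@time else seq_len(n) - 1
  df <- data.frame(time = tm, series@values)
  names(df) <- c("time", paste0("d", 1:6))
  if (length(series@rg)) df$rg <- series@rg
  if (length(series@label)) df$label <- match(series@label,
                                              sort(unique(series@label)))
  attr(df, "labels") <- sort(unique(series@label))
  m <- as.matrix(df)
  writeColvar(m, file)
  if (length(series@label)) {
    writeLines(sort(unique(series@label)), paste0(file, ".labels"))
  }
  invisible(file)
}

#' Read a descriptor series from COLVAR text
#'
#' @param file path written by \code{\link{writeDescriptorSeries}}.
#' @return \code{DescriptorSeries}.
#' @export
readDescriptorSeries <- function(file) {
  df <- readColvar(file)
  lab <- character()
  if ("label" %in% names(df) && file.exists(paste0(file, ".labels"))) {
    levels <- readLines(paste0(file, ".labels"))
    lab <- levels[df$label]
  }
  DescriptorSeries(as.matrix(df[paste0("d", 1:6)]), time = df$time,
                   label = lab,
                   rg = if ("rg" %in% names(df)) df$rg else numeric())
}

#' Write a deposited-Gaussian log (HILLS dialect)
#'
#' Columns: time, center, sigma, height, biasfactor.
#'
#' @param bias \code{BiasPotential}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeHills <- function(bias, file) {
  n <- length(bias@centers)
  m <- cbind(time = if (n) bias@times else numeric(),
             center = bias@centers, sigma = rep(bias@sigma, n),
             height = bias@heights, biasfactor = rep(bias@gamma, n))
  colnames(m) <- c("time", "center", "sigma", "height", "biasfactor")
  writeColvar(m, file)
}

#' Read a deposited-Gaussian log
#'
#' @param file HILLS-dialect path.
#' @param temperature temperature annotation for the bias, K.
#' @return \code{BiasPotential}.
#' @export
readHills <- function(file, temperature = 300) {
  df <- readColvar(file)
  new("BiasPotential", centers = df$center, heights = df$height,
      times = df$time,
      sigma = if (nrow(df)) df$sigma[1] else 0.02,
      gamma = if (nrow(df)) df$biasfactor[1] else 8,
      temperature = temperature)
}
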