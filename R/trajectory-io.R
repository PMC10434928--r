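# Column-text trajectory files: a small header (name, rows/columns counts),
# an `endheader` line, then tab-separated labeled columns with `time` first.
# This dialect interoperates with common musculoskeletal tooling.

#' Write a labeled time series to a column-text trajectory file
#'
#' @param data data frame or matrix whose first column is \code{time}
#'   (strictly increasing); remaining columns are labeled series.
#' @param path output file path.
#' @param name dataset name recorded in the header.
#' @export
write_trajectory <- function(data, path, name = "exowalk") {
  data <- as.data.frame(data)
  if (colnames(data)[1] != "time") stop("first column must be 'time'")
  if (any(diff(data$time) <= 0)) stop("time column must be strictly increasing")
  if (anyDuplicated(colnames(data))) stop("duplicate column labels")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name,
               sprintf("nRows=%d", nrow(data)),
               sprintf("nColumns=%d", ncol(data)),
               "inDegrees=no",
               "endheader"), con)
  writeLines(paste(colnames(data), collapse = "\t"), con)
  body <- apply(data, 1, function(row)
    paste(formatC(row, format = "g", digits = 15), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read a column-text trajectory file
#'
#' @param path file path.
#' @return data frame with a \code{time} first column.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  eh <- which(lines == "endheader")
  if (length(eh) == 0) stop("malformed trajectory file: missing 'endheader'")
  header <- strsplit(lines[eh + 1], "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header)) stop("duplicate column labels")
  dat <- read.delim(text = paste(lines[(eh + 2):length(lines)], collapse = "\n"),
                    header = FALSE, sep = "\t")
  colnames(dat) <- header
  if (colnames(dat)[1] != "time") stop("first column must be 'time'")
  if (any(diff(dat$time) <= 0)) stop("non-monotone time column")
  dat
}

#' Write a reference gait to disk
#'
#' States and controls as two trajectory files plus a JSON sidecar with
#' events and scalars. GRF columns use the
#' \code{ground_force_\{r,l\}_\{vx,vy,vz,px,py,pz\}} labeling convention.
#'
#' @param ref an \code{exo_reference}.
#' @param dir output directory (created if needed).
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  states <- data.frame(time = ref$time, t(ref$q), t(ref$u))
  colnames(states) <- c("time", paste0(rownames(ref$q), "_q"),
                        paste0(rownames(ref$u), "_u"))
  write_trajectory(states, file.path(dir, "states.sto"), "reference_states")
  controls <- data.frame(time = ref$time, t(ref$e), t(ref$a),
                         if (nrow(ref$ft)) t(ref$ft), t(ref$res))
  colnames(controls) <- c("time", paste0(rownames(ref$e), "_e"),
                          paste0(rownames(ref$a), "_a"),
                          if (nrow(ref$ft)) paste0(rownames(ref$ft), "_ft"),
                          paste0(rownames(ref$res), "_res"))
  write_trajectory(controls, file.path(dir, "controls.sto"),
                   "reference_controls")
  grf <- data.frame(time = ref$time,
                    ref$grf_r, ref$cop_r, ref$grf_l, ref$cop_l)
  colnames(grf) <- c("time",
                     paste0("ground_force_r_", c("vx", "vy", "vz")),
                     paste0("ground_force_r_", c("px", "py", "pz")),
                     paste0("ground_force_l_", c("vx", "vy", "vz")),
                     paste0("ground_force_l_", c("px", "py", "pz")))
  grf[is.na(grf)] <- 0
  write_trajectory(grf, file.path(dir, "grf.sto"), "reference_grf")
  sidecar <- list(T = ref$T, speed = ref$speed, mass = ref$mass,
                  h_com = ref$h_com, events = ref$events,
                  grf_peak_bw = ref$grf_peak_bw)
  jsonlite::write_json(sidecar, file.path(dir, "reference.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
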